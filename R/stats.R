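#' Replicate summaries (mean and SEM)
#'
#' Aggregates per-replicate estimates into group means with standard errors
#' of the mean (sample standard deviation over the square root of the
#' replicate count). SEM is reported as `NA` for singleton groups.
#'
#' @param df Data frame of per-replicate estimates.
#' @param measure Name of the value column (e.g. `"percent_repair"`).
#' @param by Character vector of grouping columns present in `df`.
#' @return Data frame with the grouping columns plus `n`, `mean`, `sem`.
#' @export
summarize_estimates <- function(df, measure,
                                by = intersect(c("scenario_id", "timepoint",
                                                 "antibody"), names(df))) {
  if (!measure %in% names(df)) stop("no column '", measure, "'", call. = FALSE)
  if (!nrow(df)) {
    out <- df[, by, drop = FALSE]
    out$n <- integer(); out$mean <- numeric(); out$sem <- numeric()
    return(out)
  }
  key <- do.call(paste, c(df[by], sep = "\r"))
  out <- do.call(rbind, lapply(unique(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    v <- g[[measure]]
    cbind(g[1, by, drop = FALSE],
          data.frame(n = length(v), mean = mean(v),
                     sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Pooled-variance (homoscedastic) Student t-test
#'
#' The study's two test variants: a two-tailed pooled-variance t-test for
#' comparisons between transfected samples, and a one-tailed test (alternative:
#' `mean(a) > mean(b)`) for comparisons of transfected samples against the
#' untransfected baseline. Degrees of freedom are `n_a + n_b - 2`.
#'
#' Degenerate inputs are handled explicitly: zero pooled variance with equal
#' means yields `t = 0` (one-tailed p 0.5, two-tailed p 1); zero pooled
#' variance with unequal means yields an infinite t and a p-value reported at
#' the smallest positive double, flagged via the `degenerate` field.
#'
#' @param a,b Numeric vectors of at least two values each.
#' @param sidedness `"two_tailed"` or `"one_tailed"`.
#' @return List with `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `sidedness`, `degenerate`.
#' @export
pooled_t_test <- function(a, b, sidedness = c("two_tailed", "one_tailed")) {
  sidedness <- match.arg(sidedness)
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least two values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  delta <- mean(a) - mean(b)
  degenerate <- FALSE
  if (sp2 == 0) {
    if (delta == 0) {
      t_stat <- 0
    } else {
      t_stat <- sign(delta) * Inf
      degenerate <- TRUE
    }
  } else {
    t_stat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- if (degenerate) {
    if (sidedness == "one_tailed" && t_stat < 0) 1 else .Machine$double.xmin
  } else if (sidedness == "one_tailed") {
    pt(t_stat, df, lower.tail = FALSE)
  } else {
    2 * pt(-abs(t_stat), df)
  }
  list(t_statistic = t_stat, degrees_of_freedom = df, p_value = p,
       sidedness = sidedness, degenerate = degenerate)
}

# The study's sidedness rule: comparisons against the untransfected baseline
# are one-tailed; comparisons between transfected arms are two-tailed.
auto_sidedness <- function(group_b) {
  if (identical(group_b, "untransfected")) "one_tailed" else "two_tailed"
}
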