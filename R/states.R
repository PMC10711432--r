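#' Repair-pathway states
#'
#' The model tracks each DPC-bearing plasmid molecule through six states:
#' `NASCENT` (crosslinked, untagged), `K63_TAGGED` (crosslinked, K63
#' polyubiquitin chain attached), `K48_K63_TAGGED` (crosslinked, both K48 and
#' K63 chains), `PROTEOLYZED` (protein degraded by the proteasome, only a
#' residual peptide adduct remains; strand not yet repaired), `NER_REPAIRED`
#' and `HR_REPAIRED` (fully restored duplex; absorbing).
#'
#' @format Character vector of the six state names, in the fixed order used by
#'   every generator matrix and occupancy vector in the package.
#' @export
PATHWAY_STATES <- c(
  "NASCENT", "K63_TAGGED", "K48_K63_TAGGED",
  "PROTEOLYZED", "NER_REPAIRED", "HR_REPAIRED"
)

#' State predicates
#'
#' `crosslink_present()` is true for states that still carry the full
#' protein crosslink; the `PROTEOLYZED` state carries only a peptide adduct
#' and the `*_REPAIRED` states are restored duplex. `k63_tagged()` is true
#' for states carrying a K63 polyubiquitin chain (which includes the doubly
#' tagged state); `k48_tagged()` only for the doubly tagged state -- in this
#' model K48 conjugation always follows K63 conjugation, so K48-tagged states
#' are a subset of K63-tagged states.
#'
#' @param state Character vector of state names (elements of
#'   [PATHWAY_STATES]).
#' @return Logical vector.
#' @export
crosslink_present <- function(state) {
  check_states(state)
  state %in% c("NASCENT", "K63_TAGGED", "K48_K63_TAGGED")
}

#' @rdname crosslink_present
#' @export
k63_tagged <- function(state) {
  check_states(state)
  state %in% c("K63_TAGGED", "K48_K63_TAGGED")
}

#' @rdname crosslink_present
#' @export
k48_tagged <- function(state) {
  check_states(state)
  state == "K48_K63_TAGGED"
}

check_states <- function(state) {
  bad <- setdiff(state, PATHWAY_STATES)
  if (length(bad)) {
    stop("unknown pathway state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(state)
}

#' Construct a state distribution
#'
#' An occupancy vector over the six pathway states at a given time, either as
#' probabilities (summing to 1) or as molecule counts (non-negative integers).
#'
#' @param occupancy Numeric vector. Either a full vector in [PATHWAY_STATES]
#'   order, or a named vector naming a subset of states (the rest are zero).
#' @param time Time in hours at which the occupancy applies.
#' @param type `"probability"` or `"count"`. If missing it is inferred:
#'   integer-valued vectors not summing to 1 are treated as counts.
#' @return Object of class `dpc_state_distribution`: a named numeric vector
#'   with `time` and `type` attributes.
#' @examples
#' state_distribution(c(NASCENT = 0.5, HR_REPAIRED = 0.5), time = 3)
#' @export
state_distribution <- function(occupancy, time = 0, type = NULL) {
  if (!is.numeric(occupancy) || anyNA(occupancy)) {
    stop("occupancy must be a numeric vector without NAs", call. = FALSE)
  }
  if (!is.null(names(occupancy))) {
    check_states(names(occupancy))
    full <- setNames(numeric(6L), PATHWAY_STATES)
    full[names(occupancy)] <- full[names(occupancy)] + occupancy
    occupancy <- full
  } else if (length(occupancy) == 6L) {
    occupancy <- setNames(as.numeric(occupancy), PATHWAY_STATES)
  } else {
    stop("occupancy must be named or of length 6", call. = FALSE)
  }
  if (any(occupancy < 0)) stop("occupancy must be non-negative", call. = FALSE)
  if (!is.finite(time) || time < 0) stop("time must be finite and >= 0", call. = FALSE)
  if (is.null(type)) {
    tot <- sum(occupancy)
    type <- if (abs(tot - 1) <= 1e-9) "probability" else "count"
  }
  type <- match.arg(type, c("probability", "count"))
  if (type == "probability" && abs(sum(occupancy) - 1) > 1e-9) {
    stop("probabilities must sum to 1 within 1e-9", call. = FALSE)
  }
  if (type == "count" && any(abs(occupancy - round(occupancy)) > 1e-9)) {
    stop("counts must be integer-valued", call. = FALSE)
  }
  structure(occupancy, time = time, type = type,
            class = c("dpc_state_distribution", "numeric"))
}

#' @exportS3Method base::print
print.dpc_state_distribution <- function(x, ...) {
  cat(sprintf("<state distribution (%s) at t = %g h>\n",
              attr(x, "type"), attr(x, "time")))
  print(setNames(as.numeric(x), PATHWAY_STATES), ...)
  invisible(x)
}

# Normalize a distribution (counts or probabilities) to probabilities.
as_probability <- function(dist) {
  occ <- setNames(as.numeric(dist), PATHWAY_STATES)
  tot <- sum(occ)
  if (tot <= 0) stop("cannot normalize an empty distribution", call. = FALSE)
  state_distribution(occ / tot, time = attr(dist, "time") %||% 0,
                     type = "probability")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population summary fractions
#'
#' Collapses a state distribution into the fractions the three assays read
#' out: `repaired_fraction` (fully restored duplex, NER + HR), and
#' `removed_fraction` (protein removed from DNA: repaired plus proteolyzed --
#' the KCl-SDS assay cannot distinguish a residual peptide adduct from a
#' clean strand), plus the ubiquitin-tagged fractions seen by the pan-, K48-
#' and K63-selective antibodies.
#'
#' @param dist A [state_distribution()] (counts are normalized internally).
#' @return Named numeric vector with elements `repaired_fraction`,
#'   `removed_fraction`, `pan_ub_fraction`, `k48_fraction`, `k63_fraction`.
#' @export
population_summary <- function(dist) {
  p <- as_probability(dist)
  occ <- setNames(as.numeric(p), PATHWAY_STATES)
  repaired <- occ[["NER_REPAIRED"]] + occ[["HR_REPAIRED"]]
  k63 <- sum(occ[k63_tagged(PATHWAY_STATES)])
  c(
    repaired_fraction = repaired,
    removed_fraction  = repaired + occ[["PROTEOLYZED"]],
    pan_ub_fraction   = k63,
    k48_fraction      = sum(occ[k48_tagged(PATHWAY_STATES)]),
    k63_fraction      = k63
  )
}
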