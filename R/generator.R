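#' Build the transition-rate generator for a condition
#'
#' Assembles the 6x6 infinitesimal generator of the repair chain, gating each
#' transition by the experimental condition:
#'
#' * `NASCENT -> K63_TAGGED` at `k63_rate` (scaled by `k341r_ub_factor` for
#'   the R341 variant) -- lesion recognition, always active;
#' * `K63_TAGGED -> K48_K63_TAGGED` at `k48_rate` (same variant scaling),
#'   only in NER-proficient cells (K48 conjugation is NER-machinery
#'   dependent);
#' * `K48_K63_TAGGED -> PROTEOLYZED` at `proteolysis_rate` (scaled by
#'   `mg132_factor` under proteasome inhibition), NER arm only;
#' * `PROTEOLYZED -> NER_REPAIRED` at `ner_excision_rate`, NER arm only;
#' * `K63_TAGGED -> HR_REPAIRED` at `hr_rate` (scaled by `b02_factor` under
#'   Rad51 inhibition), only with a homologous donor.
#'
#' All other rates are zero; without NER the K48/proteolysis/excision edges
#' are absent entirely, so in NER-deficient cells with no homologous donor
#' the chain stalls in the K63-tagged state. `sprtn_deficient` is read by no
#' branch of this function.
#'
#' @param rates A [rate_set()].
#' @param condition A [dpc_condition()].
#' @return Object of class `dpc_generator`: a 6x6 matrix with state dimnames,
#'   non-negative off-diagonal entries and zero row sums; absorbing-state
#'   rows are all zero.
#' @examples
#' build_generator(rate_set(), dpc_condition(ner_functional = FALSE,
#'                                           donor = "homologous"))
#' @export
build_generator <- function(rates = rate_set(), condition = dpc_condition()) {
  rates <- as_rate_set(rates)
  condition <- as_condition(condition)
  vf <- if (condition$ogg1_variant == "R341") rates$k341r_ub_factor else 1
  Q <- matrix(0, 6L, 6L, dimnames = list(PATHWAY_STATES, PATHWAY_STATES))
  Q["NASCENT", "K63_TAGGED"] <- rates$k63_rate * vf
  if (condition$ner_functional) {
    Q["K63_TAGGED", "K48_K63_TAGGED"] <- rates$k48_rate * vf
    Q["K48_K63_TAGGED", "PROTEOLYZED"] <- rates$proteolysis_rate *
      (if (condition$proteasome_inhibited) rates$mg132_factor else 1)
    Q["PROTEOLYZED", "NER_REPAIRED"] <- rates$ner_excision_rate
  }
  if (condition$donor == "homologous") {
    Q["K63_TAGGED", "HR_REPAIRED"] <- rates$hr_rate *
      (if (condition$rad51_inhibited) rates$b02_factor else 1)
  }
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("dpc_generator", "matrix", "array"))
}

check_generator <- function(gen) {
  Q <- unclass(gen)
  if (!is.matrix(Q) || any(dim(Q) != 6L)) {
    stop("generator must be a 6x6 matrix", call. = FALSE)
  }
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("generator off-diagonal entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-12)) {
    stop("generator rows must sum to zero", call. = FALSE)
  }
  invisible(Q)
}

#' Exact (deterministic) propagation of the chain
#'
#' Evolves a state distribution for `t` hours under the generator `Q` via the
#' matrix exponential, `p(t) = p(0) exp(Qt)` -- the master-equation solution,
#' which serves as the deterministic reference for the stochastic simulator.
#'
#' @param gen A [build_generator()] result.
#' @param t Time in hours (finite, `>= 0`).
#' @param initial Initial [state_distribution()]; defaults to all mass in
#'   `NASCENT` (the freshly transfected, untagged DPC). Counts are
#'   normalized to probabilities.
#' @return A probability [state_distribution()] at time
#'   `attr(initial, "time") + t`.
#' @export
propagate_exact <- function(gen, t, initial = state_distribution(c(NASCENT = 1))) {
  Q <- check_generator(gen)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a finite number >= 0", call. = FALSE)
  }
  p0 <- as_probability(initial)
  if (t == 0) return(p0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  p <- as.numeric(p0) %*% P
  p <- pmax(as.numeric(p), 0)
  state_distribution(setNames(p / sum(p), PATHWAY_STATES),
                     time = attr(p0, "time") + t, type = "probability")
}

#' Stochastic per-molecule simulation (Gillespie)
#'
#' Simulates `n_molecules` independent realizations of the chain to time `t`
#' by the exact stochastic simulation algorithm (exponential waiting times,
#' categorical jumps), vectorized over molecules. Each molecule starts in
#' `NASCENT`. Reproducible for a given seed.
#'
#' @inheritParams propagate_exact
#' @param n_molecules Number of molecules (`>= 1`).
#' @param seed Integer seed; required (no implicit entropy).
#' @return A count [state_distribution()] at time `t` summing exactly to
#'   `n_molecules`.
#' @export
simulate_gillespie <- function(gen, t, n_molecules, seed) {
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L ||
      n_molecules < 1 || n_molecules != round(n_molecules)) {
    stop("n_molecules must be a positive integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a finite integer seed is required", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a finite number >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  counts <- gillespie_counts(gen, t, as.integer(n_molecules))
  state_distribution(counts, time = t, type = "count")
}

# Core sampler; uses the current RNG stream (callers manage seeding).
gillespie_counts <- function(gen, t, n) {
  Q <- check_generator(gen)
  exit_rate <- -diag(Q)
  state <- rep.int(1L, n)
  clock <- numeric(n)
  # The chain is acyclic (max path length 4), so this loop terminates after
  # at most four rounds of jumps plus one censoring round.
  repeat {
    active <- which(clock <= t & exit_rate[state] > 0)
    if (!length(active)) break
    clock[active] <- clock[active] + rexp(length(active), exit_rate[state[active]])
    jumpers <- active[clock[active] <= t]
    if (length(jumpers)) {
      u <- runif(length(jumpers))
      for (s in unique(state[jumpers])) {
        idx <- jumpers[state[jumpers] == s]
        pr <- Q[s, ]
        pr[s] <- 0
        pr <- pr / sum(pr)
        state[idx] <- findInterval(u[match(idx, jumpers)], cumsum(pr),
                                   left.open = TRUE) + 1L
      }
    }
  }
  setNames(tabulate(state, nbins = 6L), PATHWAY_STATES)
}

#' Total-variation distance between two distributions
#'
#' Half the L1 distance between two occupancy vectors (counts are normalized
#' first). Used to compare the stochastic simulator against exact
#' propagation.
#'
#' @param a,b [state_distribution()] objects.
#' @return Number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  pa <- as.numeric(as_probability(a))
  pb <- as.numeric(as_probability(b))
  sum(abs(pa - pb)) / 2
}
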