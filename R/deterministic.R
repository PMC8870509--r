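#' Parameters for the deterministic sweep-with-recurrent-mutation model
#'
#' Bundles the selection coefficient, mutation rate to the beneficial
#' allele, and population size, and derives the scaled selection strength
#' `alpha` (Ns for haploids, 2Ns for diploids) and the population mutation
#' parameter `theta = N * mu`.
#'
#' @param s Selection coefficient (> 0).
#' @param mu Mutation rate to the beneficial allele per generation (>= 0).
#' @param N Population size (individuals).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return An object of class `det_params` with derived `alpha` and `theta`.
#' @export
det_params <- function(s, mu = 0, N = 1e5, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(s > 0, mu >= 0, N >= 1)
  alpha <- if (ploidy == "haploid") N * s else 2 * N * s
  structure(list(s = s, mu = mu, N = N, ploidy = ploidy,
                 alpha = alpha, theta = N * mu),
            class = "det_params")
}

#' Per-generation frequency change of a beneficial allele
#'
#' Deterministic change under selection plus recurrent one-way mutation:
#' \deqn{\Delta x = \mu(1-x) + s x(1-x) = (\mu + s x)(1 - x).}
#' Back mutation is neglected: during the stochastic initial phase x is
#' very small and the deterministic phase is short.
#'
#' @param x Current allele frequency in \[0, 1\] (vectorized).
#' @param p A [det_params()] object.
#' @return Frequency change per generation (>= 0).
#' @export
delta_x <- function(x, p) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  (p$mu + p$s * x) * (1 - x)
}

#' Establishment threshold of a strongly beneficial allele
#'
#' The frequency x0 = 5/alpha above which a strongly beneficial allele
#' escapes the boundary layer and proceeds to fixation nearly
#' deterministically (alpha = Ns for haploids, 2Ns for diploids).
#'
#' @param p A [det_params()] object with `alpha > 5`.
#' @return The threshold frequency x0.
#' @export
establishment_threshold <- function(p) {
  if (p$alpha <= 5)
    stop("establishment threshold requires alpha > 5 (so that x0 < 1)")
  5 / p$alpha
}

#' Does recurrent mutation dominate selection near the threshold?
#'
#' At the establishment threshold the selective term of the frequency change
#' is s * x0 = 5/N; mutation dominates when mu exceeds it, equivalently when
#' theta = N * mu > 5. In that regime observed frequency change is primarily
#' mutational input, not selection.
#'
#' @param p A [det_params()] object.
#' @return List with `dominates` (logical) and `ratio` = mu / (s * x0).
#' @export
mutation_dominates <- function(p) {
  sx0 <- p$s * (5 / p$alpha)
  list(dominates = p$mu > sx0, ratio = if (sx0 > 0) p$mu / sx0 else Inf)
}

#' Iterate the deterministic frequency recursion
#'
#' Applies x_{t+1} = x_t + Delta x(x_t) for T generations, clipping at the
#' absorbing boundary 1. Steps where Delta x exceeds 0.5 are flagged: there
#' the one-generation difference equation leaves its validity regime (very
#' large s) and should be interpreted with care.
#'
#' @param x_start Starting frequency in \[0, 1).
#' @param p A [det_params()] object.
#' @param T Number of generations (>= 0).
#' @return An object of class `det_trajectory`: list with `x` (length T+1)
#'   and `flagged` (generation indices with Delta x > 0.5).
#' @export
integrate_trajectory <- function(x_start, p, T) {
  stopifnot(x_start >= 0, x_start < 1, T >= 0)
  x <- numeric(T + 1)
  x[1] <- x_start
  flagged <- integer(0)
  if (T > 0) for (t in seq_len(T)) {
    dx <- delta_x(x[t], p)
    if (dx > 0.5) flagged <- c(flagged, t)
    x[t + 1] <- min(1, x[t] + dx)
  }
  structure(list(x = x, flagged = flagged, params = p),
            class = "det_trajectory")
}

#' Closed-form logistic trajectory (small-s reference)
#'
#' Continuous-time solution x(t) = x0 e^{st} / (1 - x0 + x0 e^{st}) of the
#' selection-only dynamic, used as an independent reference for the discrete
#' recursion when s is small and mu = 0.
#'
#' @param x0 Starting frequency.
#' @param s Selection coefficient.
#' @param t Generations (vectorized).
#' @return Frequencies x(t).
#' @export
logistic_trajectory <- function(x0, s, t) {
  e <- x0 * exp(s * t)
  e / (1 - x0 + e)
}
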