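#' @useDynLib sweepverdict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rmultinom rbinom rpois runif rexp rlnorm setNames sd var
#' @importFrom utils write.table read.table packageVersion
NULL

NUCS <- c("A", "C", "G", "T")

#' Build the 10-genotype semidominant fitness scheme
#'
#' Constructs the fitness table for a single nucleotide site at which the
#' wild-type allele A (and its selectively equivalent state G) competes with
#' two beneficial alleles C and T. All mutations are semidominant (h = 0.5):
#' heterozygotes carrying one beneficial allele have half its homozygous
#' effect, and the C/T double heterozygote takes fitness
#' `1 + max(sC, sT)`.
#'
#' @param sC Selection coefficient of allele C (dimensionless, > -1).
#' @param sT Selection coefficient of allele T (dimensionless, > -1).
#' @return An object of class `fitness_scheme`: a list with elements `sC`,
#'   `sT` and `w`, a symmetric 4x4 matrix of genotype fitnesses indexed by
#'   nucleotide (A, C, G, T).
#' @examples
#' sch <- build_fitness_scheme(0.52, 0)
#' sch$w["C", "C"]  # 1.52
#' sch$w["A", "C"]  # 1.26
#' @export
build_fitness_scheme <- function(sC, sT) {
  stopifnot(is.numeric(sC), is.numeric(sT), length(sC) == 1L, length(sT) == 1L)
  if (sC <= -1 || sT <= -1)
    stop("selection coefficients must exceed -1 (fitness must stay positive)")
  w <- matrix(1, 4, 4, dimnames = list(NUCS, NUCS))
  w["T", "T"] <- 1 + sT
  w["C", "C"] <- 1 + sC
  w["A", "T"] <- w["T", "A"] <- w["G", "T"] <- w["T", "G"] <- 1 + 0.5 * sT
  w["A", "C"] <- w["C", "A"] <- w["G", "C"] <- w["C", "G"] <- 1 + 0.5 * sC
  w["T", "C"] <- w["C", "T"] <- 1 + max(sC, sT)
  structure(list(sC = sC, sT = sT, w = w), class = "fitness_scheme")
}

#' Simulation parameters for the single-site model
#'
#' @param N Diploid population size (individuals).
#' @param mu Mutation rate per site per generation.
#' @param generations Total generations to simulate.
#' @param snapshot_gens Generations at which allele frequencies are recorded.
#' @param seed Optional RNG seed applied by [run_replicate()].
#' @return An object of class `site_sim_params`.
#' @export
site_sim_params <- function(N = 1e5, mu = 1e-5, generations = 60,
                            snapshot_gens = c(30, 60), seed = NULL) {
  stopifnot(N >= 1, mu >= 0, mu <= 1, generations >= 0)
  N <- as.integer(round(N))
  if (any(snapshot_gens < 0 | snapshot_gens > generations))
    stop("snapshot_gens must lie in [0, generations]")
  structure(list(N = N, mu = mu, generations = as.integer(generations),
                 snapshot_gens = as.integer(snapshot_gens), seed = seed),
            class = "site_sim_params")
}

#' Advance the single-site population by one generation
#'
#' One life cycle of selection, reproduction and mutation: Hardy-Weinberg
#' genotype proportions are formed from the current allele frequencies and
#' weighted by genotype fitness; the post-selection allele frequencies seed a
#' multinomial draw of 2N gametes; each gamete then mutates with probability
#' `mu`, choosing uniformly among the three other nucleotides. This
#' gamete-level formulation has the same diffusion limit as an
#' individual-based scheme and is exact for the allele-frequency process up
#' to O(1/N) terms in the offspring-number distribution.
#'
#' @param counts Integer 4-vector of gamete counts (A, C, G, T) summing to 2N.
#' @param scheme A [build_fitness_scheme()] object.
#' @param N Diploid population size.
#' @param mu Per-site per-generation mutation rate.
#' @return Integer 4-vector of next-generation gamete counts summing to 2N.
#' @export
wf_generation <- function(counts, scheme, N, mu) {
  two_n <- 2L * as.integer(N)
  if (length(counts) != 4L || sum(counts) != two_n)
    stop("counts must be a 4-vector summing to 2N")
  p <- counts / two_n
  wmarg <- as.vector(scheme$w %*% p)        # marginal fitness of each allele
  wbar <- sum(p * wmarg)
  psel <- p * wmarg / wbar
  offspring <- as.integer(rmultinom(1L, two_n, psel))
  if (mu > 0) {
    for (i in 1:4) {
      if (offspring[i] == 0L) next
      m <- rbinom(1L, offspring[i], mu)
      if (m == 0L) next
      dest <- as.integer(rmultinom(1L, m, rep(1 / 3, 3)))
      offspring[i] <- offspring[i] - m
      offspring[-i] <- offspring[-i] + dest
    }
  }
  offspring
}

#' Simulate one replicate allele trajectory
#'
#' Runs the single-site Wright-Fisher model forward from a population fixed
#' for the wild-type allele A, recording per-generation counts of the four
#' nucleotides among the 2N gene copies.
#'
#' @param params A [site_sim_params()] object.
#' @param scheme A [build_fitness_scheme()] object.
#' @param init_counts Optional starting counts (default: all-A).
#' @return An object of class `allele_trajectory`: list with `counts`
#'   (a (generations+1) x 4 integer matrix, row t+1 = generation t), `N`,
#'   and `snapshot_gens`.
#' @export
run_replicate <- function(params, scheme, init_counts = NULL) {
  if (!is.null(params$seed)) set.seed(params$seed)
  two_n <- 2L * params$N
  counts <- if (is.null(init_counts)) c(two_n, 0L, 0L, 0L) else as.integer(init_counts)
  stopifnot(sum(counts) == two_n)
  out <- matrix(0L, params$generations + 1L, 4L,
                dimnames = list(NULL, NUCS))
  out[1L, ] <- counts
  if (params$generations > 0) {
    for (g in seq_len(params$generations)) {
      counts <- wf_generation(counts, scheme, params$N, params$mu)
      out[g + 1L, ] <- counts
    }
  }
  structure(list(counts = out, N = params$N,
                 snapshot_gens = params$snapshot_gens),
            class = "allele_trajectory")
}

#' Extract allele frequencies at a given generation
#'
#' @param traj An `allele_trajectory`.
#' @param gen Generation index (0-based; 0 is the initial state).
#' @return Named numeric 4-vector of allele frequencies.
#' @export
snapshot_freqs <- function(traj, gen) {
  stopifnot(inherits(traj, "allele_trajectory"))
  if (gen < 0 || gen > nrow(traj$counts) - 1L)
    stop("generation outside simulated range")
  f <- traj$counts[gen + 1L, ] / (2 * traj$N)
  structure(list(gen = as.integer(gen), freq = f), class = "snapshot_freqs")
}

# Deterministic counter-based seed derivation: mixes a master seed with
# stream indices into [1, 2^31 - 2] so grids are reproducible and each
# (cell, replicate) gets an independent stream.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Simulate a grid of (sC, sT) selection-coefficient combinations
#'
#' For every cell of the selection-coefficient grid, simulates `reps`
#' independent replicates of the single-site model and records allele
#' frequencies at the snapshot generations. Per-replicate seeds are derived
#' deterministically from (master seed, cell index, replicate index).
#'
#' @param sC_grid,sT_grid Numeric vectors of selection coefficients.
#' @param reps Replicates per cell.
#' @param params A [site_sim_params()] object; its `seed` is the master seed.
#' @return A data.frame of class `sweep_grid` with columns
#'   sC, sT, replicate, generation, freqA, freqC, freqG, freqT.
#' @export
run_grid <- function(sC_grid, sT_grid, reps, params) {
  stopifnot(length(sC_grid) >= 1, length(sT_grid) >= 1, reps >= 1)
  master <- if (is.null(params$seed)) 0L else params$seed
  rows <- vector("list", length(sC_grid) * length(sT_grid) * reps)
  k <- 0L
  cell <- 0L
  for (sC in sC_grid) for (sT in sT_grid) {
    cell <- cell + 1L
    scheme <- build_fitness_scheme(sC, sT)
    for (r in seq_len(reps)) {
      p <- params
      p$seed <- derive_seed(master, cell, r)
      traj <- run_replicate(p, scheme)
      for (g in params$snapshot_gens) {
        f <- snapshot_freqs(traj, g)$freq
        k <- k + 1L
        rows[[k]] <- data.frame(sC = sC, sT = sT, replicate = r,
                                generation = g, freqA = f[["A"]],
                                freqC = f[["C"]], freqG = f[["G"]],
                                freqT = f[["T"]])
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  class(out) <- c("sweep_grid", "data.frame")
  out
}
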