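#' Thresholds for frequency-based sweep classification
#'
#' Parameterizes the frequency-threshold definitions under study: a
#' "selective sweep" is called when the beneficial alleles C and T together
#' reach `sweep_freq` at generation `sweep_gen`; the call is "soft" when both
#' beneficial alleles individually reach `soft_freq` at that time. The
#' later-horizon classification at `horizon_gen` asks whether a single
#' nucleotide (>= `high_freq`, the other < `soft_freq`) or multiple
#' nucleotides were in fact brought to high frequency.
#'
#' @param sweep_freq Combined beneficial-frequency threshold (default 0.5).
#' @param soft_freq Per-allele threshold (default 0.05).
#' @param sweep_gen Evaluation generation for the sweep call (default 30).
#' @param horizon_gen Later evaluation generation (default 60).
#' @param high_freq "High frequency" threshold at the horizon (default 0.5).
#' @param single_low_max At the horizon, the losing allele must sit below
#'   this frequency for a `single_high` call (default: `soft_freq`, i.e. the
#'   second allele must have dropped out of the soft-call range; set it to
#'   `high_freq` to ask only that a single allele was brought to high
#'   frequency). No number is prescribed for this cutoff, so it is exposed
#'   as a first-class parameter.
#' @param inclusive Use `>=` at the soft threshold (default TRUE; the
#'   strict-`>` variant is available because the two printed phrasings of the
#'   rule differ).
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(sweep_freq = 0.5, soft_freq = 0.05,
                                  sweep_gen = 30, horizon_gen = 60,
                                  high_freq = 0.5,
                                  single_low_max = soft_freq,
                                  inclusive = TRUE) {
  stopifnot(soft_freq > 0, soft_freq <= sweep_freq, sweep_freq <= 1,
            sweep_gen < horizon_gen, single_low_max <= high_freq)
  structure(list(sweep_freq = sweep_freq, soft_freq = soft_freq,
                 sweep_gen = as.integer(sweep_gen),
                 horizon_gen = as.integer(horizon_gen),
                 high_freq = high_freq, single_low_max = single_low_max,
                 inclusive = inclusive),
            class = "classifier_thresholds")
}

soft_ge <- function(x, th, hi) {
  if (th$inclusive) x >= th$soft_freq else x > th$soft_freq
}

as_freq4 <- function(snap) {
  f <- if (inherits(snap, "snapshot_freqs")) snap$freq else snap
  stopifnot(length(f) == 4, all(f >= 0), abs(sum(f) - 1) < 1e-9)
  if (is.null(names(f))) names(f) <- NUCS
  f
}

check_gen <- function(snap, expected, what) {
  if (inherits(snap, "snapshot_freqs") && snap$gen != expected)
    stop(sprintf("%s expects a snapshot at generation %d, got %d",
                 what, expected, snap$gen))
}

#' Frequency-threshold sweep call
#'
#' TRUE iff the beneficial alleles together (`freq(C) + freq(T)`) have
#' reached the combined threshold at the sweep-evaluation generation.
#'
#' @param snap A [snapshot_freqs()] object or bare frequency 4-vector
#'   (A, C, G, T).
#' @param th A [classifier_thresholds()] object.
#' @return Logical.
#' @export
is_sweep_feder <- function(snap, th = classifier_thresholds()) {
  check_gen(snap, th$sweep_gen, "is_sweep_feder")
  f <- as_freq4(snap)
  unname(f["C"] + f["T"] >= th$sweep_freq)
}

#' Frequency-threshold soft-sweep call
#'
#' Given that the sweep condition holds, TRUE iff both beneficial alleles C
#' and T are individually at or above the per-allele threshold. Signals an
#' error when the conditioning sweep call fails, because the soft call is
#' defined only among sweep replicates.
#'
#' @inheritParams is_sweep_feder
#' @return Logical.
#' @export
is_soft_feder <- function(snap, th = classifier_thresholds()) {
  if (!is_sweep_feder(snap, th))
    stop("soft-sweep call is conditional on the sweep condition being met")
  f <- as_freq4(snap)
  unname(soft_ge(f["C"], th) && soft_ge(f["T"], th))
}

#' Later-horizon outcome of a called sweep
#'
#' Classifies the state at the horizon generation: `"single_high"` when
#' exactly one beneficial allele is at high frequency and the other sits
#' below `single_low_max` (by default the soft threshold); `"multiple_high"`
#' when both are at or above the soft threshold with at least one high;
#' `"neither"` otherwise.
#'
#' @inheritParams is_sweep_feder
#' @return One of `"single_high"`, `"multiple_high"`, `"neither"`.
#' @export
horizon_outcome <- function(snap, th = classifier_thresholds()) {
  check_gen(snap, th$horizon_gen, "horizon_outcome")
  f <- as_freq4(snap)
  hiC <- f[["C"]] >= th$high_freq
  hiT <- f[["T"]] >= th$high_freq
  lowC <- f[["C"]] < th$single_low_max
  lowT <- f[["T"]] < th$single_low_max
  softC <- soft_ge(f[["C"]], th)
  softT <- soft_ge(f[["T"]], th)
  if ((hiC && lowT) || (hiT && lowC)) return("single_high")
  if (softC && softT && (hiC || hiT)) return("multiple_high")
  "neither"
}

#' Per-cell sweep/soft/outcome proportions over a simulated grid
#'
#' Summarizes [run_grid()] output cell by cell: the proportion of replicates
#' called a sweep at the sweep generation, the proportion of those sweeps
#' called soft, and the proportion of the soft calls that resolve to a single
#' high-frequency nucleotide at the horizon. Conditional proportions with a
#' zero denominator are reported as `NA` (undefined), never 0.
#'
#' @param grid A `sweep_grid` data.frame from [run_grid()].
#' @param th A [classifier_thresholds()] object.
#' @return data.frame keyed by (sC, sT) with columns n_reps, n_sweep,
#'   n_soft, n_single_high, P_sweep, P_soft_given_sweep,
#'   P_single_high_given_soft.
#' @export
grid_proportions <- function(grid, th = classifier_thresholds()) {
  stopifnot(all(c(th$sweep_gen, th$horizon_gen) %in% grid$generation))
  cells <- unique(grid[, c("sC", "sT")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    g <- grid[grid$sC == cells$sC[i] & grid$sT == cells$sT[i], ]
    g30 <- g[g$generation == th$sweep_gen, ]
    g60 <- g[g$generation == th$horizon_gen, ]
    g60 <- g60[match(g30$replicate, g60$replicate), ]
    n <- nrow(g30)
    sweep <- soft <- single <- logical(n)
    for (r in seq_len(n)) {
      f30 <- c(A = g30$freqA[r], C = g30$freqC[r], G = g30$freqG[r], T = g30$freqT[r])
      sweep[r] <- is_sweep_feder(f30, th)
      soft[r] <- sweep[r] && is_soft_feder(f30, th)
      if (soft[r]) {
        f60 <- c(A = g60$freqA[r], C = g60$freqC[r], G = g60$freqG[r], T = g60$freqT[r])
        single[r] <- horizon_outcome(f60, th) == "single_high"
      }
    }
    data.frame(sC = cells$sC[i], sT = cells$sT[i],
               n_reps = n, n_sweep = sum(sweep), n_soft = sum(soft),
               n_single_high = sum(single),
               P_sweep = sum(sweep) / n,
               P_soft_given_sweep = if (sum(sweep) > 0) sum(soft) / sum(sweep) else NA_real_,
               P_single_high_given_soft = if (sum(soft) > 0) sum(single) / sum(soft) else NA_real_)
  })
  do.call(rbind, res)
}

#' Fixation-based soft/hard classification (conventional extension)
#'
#' An optional comparison mode outside the frequency-threshold definitions:
#' at the first generation where the beneficial alleles sum to frequency 1,
#' the sweep is soft iff both are at or above `soft_freq`. Returns `NA` when
#' the trajectory never reaches joint fixation of C+T.
#'
#' @param traj An `allele_trajectory`.
#' @param soft_freq Per-allele threshold at joint fixation.
#' @return `"soft"`, `"hard"`, or `NA`.
#' @export
classify_at_fixation <- function(traj, soft_freq = 0.05) {
  f <- traj$counts / (2 * traj$N)
  joint <- f[, "C"] + f[, "T"]
  hit <- which(joint >= 1 - 1e-12)
  if (!length(hit)) return(NA_character_)
  r <- hit[1]
  if (f[r, "C"] >= soft_freq && f[r, "T"] >= soft_freq) "soft" else "hard"
}
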