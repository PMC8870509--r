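#' Construct a haplotype sample
#'
#' The central container for simulated samples: `n` haploid genomes typed at
#' `S` segregating sites with base-pair positions. Allele codes are integers
#' (0 = ancestral, 1 = derived for biallelic data; larger codes are allowed
#' so multi-allelic sites need no special-casing downstream).
#'
#' @param alleles n x S integer matrix; one row per haplotype.
#' @param positions Strictly increasing site positions (bp, 0-based).
#' @param region_length Length of the simulated region in bp.
#' @param check Validate that every site is segregating (default TRUE).
#' @return An object of class `haplotype_sample`.
#' @export
haplotype_sample <- function(alleles, positions, region_length = 1e5,
                             check = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("positions must match the number of sites")
  if (ncol(alleles) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (check && ncol(alleles) > 0) {
    mono <- apply(alleles, 2, function(col) length(unique(col)) == 1L)
    if (any(mono)) stop("sample contains monomorphic sites")
  }
  structure(list(n = nrow(alleles), alleles = alleles,
                 positions = as.numeric(positions),
                 region_length = region_length),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("haplotype_sample: %d haplotypes, %d segregating sites, region %g bp\n",
              x$n, ncol(x$alleles), x$region_length))
  invisible(x)
}

#' Window specification for sliding haplotype statistics
#'
#' Windows are defined in SNP counts, not base pairs, so every window holds
#' the same amount of segregating variation. The default of 401 SNPs per
#' window with a 50-SNP step follows the convention of published
#' haplotype-homozygosity scans; regions with fewer SNPs than one window
#' yield no windows.
#'
#' @param snp_count SNPs per window (>= 2; default 401).
#' @param step SNPs between successive window starts (>= 1; default 50).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(snp_count = 401, step = 50) {
  stopifnot(snp_count >= 2, step >= 1)
  structure(list(snp_count = as.integer(snp_count), step = as.integer(step)),
            class = "window_spec")
}

#' Haplotype frequency spectrum of a window
#'
#' Groups identical allele strings over the window's sites and returns their
#' frequencies in descending order; ties are broken lexicographically by the
#' haplotype string so results are deterministic.
#'
#' @param sample A [haplotype_sample()].
#' @param window Integer vector of site indices (1-based; default all sites).
#' @return An object of class `haplotype_spectrum`: list with `freqs`
#'   (descending, summing to 1) and `counts`.
#' @export
haplotype_spectrum <- function(sample, window = seq_len(ncol(sample$alleles))) {
  if (length(window) == 0) stop("empty window")
  if (any(window < 1 | window > ncol(sample$alleles)))
    stop("window out of bounds")
  strings <- apply(sample$alleles[, window, drop = FALSE], 1, paste, collapse = "")
  tab <- table(strings)
  ord <- order(-as.integer(tab), names(tab))
  counts <- as.integer(tab)[ord]
  structure(list(freqs = counts / sample$n, counts = counts,
                 haplotypes = names(tab)[ord]),
            class = "haplotype_spectrum")
}

#' Haplotype homozygosity statistics H1, H2, H12, H2/H1
#'
#' For descending haplotype frequencies p1 >= p2 >= ...:
#' \deqn{H1 = \sum_i p_i^2,\quad
#'       H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2,\quad
#'       H2 = H1 - p_1^2.}
#' H12 pools the two most frequent haplotypes before squaring, which raises
#' power for soft sweeps (two common haplotypes) while retaining power for
#' hard sweeps; H2/H1 is small under hard sweeps and larger under soft ones.
#'
#' @param spec A [haplotype_spectrum()] or a bare numeric vector of
#'   haplotype frequencies (need not be sorted; must sum to 1).
#' @return Named list with `H1`, `H2`, `H12`, `H2_H1`.
#' @export
h_statistics <- function(spec) {
  p <- if (inherits(spec, "haplotype_spectrum")) spec$freqs else spec
  stopifnot(length(p) >= 1, all(p > 0), abs(sum(p) - 1) < 1e-9)
  p <- sort(p, decreasing = TRUE)
  H1 <- sum(p^2)
  p2 <- if (length(p) >= 2) p[2] else 0
  H12 <- (p[1] + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
  H2 <- H1 - p[1]^2
  list(H1 = H1, H2 = H2, H12 = H12, H2_H1 = H2 / H1)
}

#' Sliding-window H statistics over a haplotype sample
#'
#' Advances a `snp_count`-SNP window by `step` SNPs across the sample and
#' computes the four H statistics in each window. The final partial window
#' is dropped; a sample with fewer segregating sites than one window yields
#' an empty result with a warning.
#'
#' @param sample A [haplotype_sample()].
#' @param spec A [window_spec()].
#' @return data.frame with columns window, start_snp, end_snp, center_bp,
#'   H1, H2, H12, H2_H1 (zero rows if the sample is too short).
#' @export
sliding_h12 <- function(sample, spec = window_spec()) {
  S <- ncol(sample$alleles)
  empty <- data.frame(window = integer(0), start_snp = integer(0),
                      end_snp = integer(0), center_bp = numeric(0),
                      H1 = numeric(0), H2 = numeric(0), H12 = numeric(0),
                      H2_H1 = numeric(0))
  if (S < spec$snp_count) {
    warning(sprintf("sample has %d segregating sites; window needs %d",
                    S, spec$snp_count))
    return(empty)
  }
  starts <- seq(1L, S - spec$snp_count + 1L, by = spec$step)
  out <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:(starts[i] + spec$snp_count - 1L)
    h <- h_statistics(haplotype_spectrum(sample, idx))
    data.frame(window = i, start_snp = starts[i],
               end_snp = starts[i] + spec$snp_count - 1L,
               center_bp = mean(range(sample$positions[idx])),
               H1 = h$H1, H2 = h$H2, H12 = h$H12, H2_H1 = h$H2_H1)
  })
  do.call(rbind, out)
}

#' Summarize a distribution of window statistics
#'
#' Pooled mode aggregates every window of every replicate into one
#' distribution; per-replicate-mean mode first averages within replicate
#' and summarizes the replicate means. Sample SD uses the n-1 denominator;
#' with a single value the SD is reported as 0 and flagged.
#'
#' @param values Numeric vector of statistic values (e.g. window H12).
#' @param mode `"pooled"` or `"per_replicate_mean"`.
#' @param replicate Replicate id per value (required for per-replicate mode).
#' @return List with `mean`, `sd`, `n`, `mode`, `sd_defined`.
#' @export
summarize_distribution <- function(values, mode = c("pooled", "per_replicate_mean"),
                                   replicate = NULL) {
  mode <- match.arg(mode)
  if (!length(values)) stop("no values to summarize")
  if (mode == "per_replicate_mean") {
    if (is.null(replicate)) stop("per_replicate_mean mode needs replicate ids")
    values <- tapply(values, replicate, mean)
  }
  n <- length(values)
  list(mean = mean(values), sd = if (n > 1) sd(values) else 0,
       n = n, mode = mode, sd_defined = n > 1)
}
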