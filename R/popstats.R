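#' Mean pairwise nucleotide diversity of a sample
#'
#' Computes pi as the sum over segregating sites of 2*p*(1-p)*n/(n-1),
#' optionally restricted to a subset of sites, and optionally divided by a
#' sequence length to give per-site diversity.
#'
#' @param sample A [haplotype_sample()].
#' @param sites Site indices to include (default all).
#' @param per_bp Divide by this many base pairs (NULL = report the sum).
#' @return Numeric diversity estimate.
#' @export
pairwise_diversity <- function(sample, sites = seq_len(ncol(sample$alleles)),
                               per_bp = NULL) {
  n <- sample$n
  if (!length(sites)) return(0)
  p <- colMeans(sample$alleles[, sites, drop = FALSE] != 0L)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  if (!is.null(per_bp)) pi / per_bp else pi
}

#' Per-site diversity inside and outside exons
#'
#' Splits the segregating sites of a sample by annotation feature kind and
#' reports per-bp pairwise diversity for each kind, the standard readout
#' for the footprint of purifying selection on linked variation.
#'
#' @param sample A [haplotype_sample()].
#' @param annotation A [build_genome_annotation()] object.
#' @return data.frame with columns kind, bp, n_sites, pi_per_bp.
#' @export
diversity_by_feature <- function(sample, annotation) {
  kinds <- unique(annotation$kind)
  pos <- sample$positions
  feat_of <- function(p) {
    i <- findInterval(p, annotation$start)
    annotation$kind[i]
  }
  site_kind <- if (length(pos)) feat_of(pos) else character(0)
  out <- lapply(kinds, function(k) {
    bp <- sum((annotation$end - annotation$start)[annotation$kind == k])
    idx <- which(site_kind == k)
    data.frame(kind = k, bp = bp, n_sites = length(idx),
               pi_per_bp = pairwise_diversity(sample, idx, per_bp = bp))
  })
  do.call(rbind, out)
}

#' Hudson's Fst between two groups of haplotypes
#'
#' Ratio-of-sums Hudson estimator over all segregating sites:
#' numerator (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator p1(1-p2) + p2(1-p1).
#'
#' @param sample A [haplotype_sample()].
#' @param groups Vector of group labels, one per haplotype (2 levels).
#' @return Fst estimate (NaN if no site is informative).
#' @export
hudson_fst <- function(sample, groups) {
  g <- as.factor(groups)
  stopifnot(nlevels(g) == 2, length(g) == sample$n)
  a <- sample$alleles != 0L
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  p1 <- colMeans(a[i1, , drop = FALSE])
  p2 <- colMeans(a[!i1, , drop = FALSE])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Draw crossover counts from a recombination map
#'
#' Samples the per-meiosis crossover count the forward engine uses
#' (Poisson with mean equal to the map's total Morgan length), mainly for
#' validating the engine's recombination machinery.
#'
#' @param map A [recombination_map()].
#' @param n Number of meioses.
#' @return Integer vector of crossover counts.
#' @export
draw_crossover_counts <- function(map, n) {
  stopifnot(inherits(map, "recombination_map"))
  draw_crossover_counts_cpp(map$rate_per_bp, map$bin_size, as.integer(n))
}
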