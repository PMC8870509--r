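#' Build the exon/intron/intergenic annotation of the simulated region
#'
#' Tiles a region with `n_genes` identical genes, each exon-first
#' (alternating 5 exons and 4 introns under the defaults), followed by an
#' intergenic spacer. Any trailing base pairs left after the last
#' gene+spacer unit are assigned intergenic, so the defaults give
#' 33 x 5 x 300 = 49,500 exonic bp, i.e. exactly 49.5% of the 100-kb region.
#'
#' @param n_genes Number of genes (default 33).
#' @param exons_per_gene,exon_len Exons per gene and exon length in bp.
#' @param introns_per_gene,intron_len Introns per gene and intron length.
#' @param intergenic_len Intergenic spacer after each gene (bp).
#' @param length Total region length in bp (default 100,000).
#' @return An object of class `genome_annotation`: data.frame with 0-based
#'   half-open `start`, `end` and `kind` in (exon, intron, intergenic),
#'   plus attributes `length` and `exon_fraction`.
#' @export
build_genome_annotation <- function(n_genes = 33, exons_per_gene = 5,
                                    exon_len = 300, introns_per_gene = 4,
                                    intron_len = 100, intergenic_len = 1068,
                                    length = 100000) {
  stopifnot(exons_per_gene == introns_per_gene + 1)
  gene_len <- exons_per_gene * exon_len + introns_per_gene * intron_len
  if (n_genes * (gene_len + intergenic_len) > length)
    stop("declared features exceed region length")
  kinds <- starts <- ends <- list()
  pos <- 0L
  k <- 0L
  add <- function(kind, len) {
    if (len == 0) return(invisible())
    k <<- k + 1L
    kinds[[k]] <<- kind; starts[[k]] <<- pos; ends[[k]] <<- pos + len
    pos <<- pos + as.integer(len)
  }
  for (g in seq_len(n_genes)) {
    for (e in seq_len(exons_per_gene)) {
      add("exon", exon_len)
      if (e <= introns_per_gene) add("intron", intron_len)
    }
    add("intergenic", intergenic_len)
  }
  if (pos < length) add("intergenic", length - pos)
  df <- data.frame(start = unlist(starts), end = unlist(ends),
                   kind = unlist(kinds), stringsAsFactors = FALSE)
  # merge adjacent runs of the same kind (e.g. trailing intergenic remainder)
  run <- cumsum(c(TRUE, df$kind[-1] != df$kind[-nrow(df)]))
  df <- data.frame(start = tapply(df$start, run, min),
                   end = tapply(df$end, run, max),
                   kind = tapply(df$kind, run, `[`, 1),
                   row.names = NULL, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  stopifnot(df$end[nrow(df)] == length, all(df$start[-1] == df$end[-nrow(df)]))
  exonic <- sum((df$end - df$start)[df$kind == "exon"])
  structure(df, length = length, exon_fraction = exonic / length,
            class = c("genome_annotation", "data.frame"))
}

#' Discretized distribution of fitness effects of new mutations
#'
#' Four classes of new mutations with fixed proportions: strictly neutral,
#' mildly deleterious (-10 <= 2*N_anc*s < -1), moderately deleterious
#' (-100 <= 2*N_anc*s < -10) and strongly deleterious (2*N_anc*s < -100).
#' Within each deleterious class the selection coefficient against
#' homozygotes, s, is uniform on the interval obtained by dividing the
#' scaled bounds by 2*N_anc; the strongly deleterious class is capped below
#' at `s_cap` so fitness stays non-negative. All mutations are semidominant.
#'
#' @param proportions Class weights (neutral, mild, moderate, strong)
#'   summing to 1; default c(0.23, 0.51, 0.04, 0.22).
#' @param N_anc Ancestral diploid population size used to descale 2*N_anc*s.
#' @param s_cap Lower cap on s for the strong class (default -1).
#' @return An object of class `dfe_model` with per-class s intervals.
#' @export
dfe_model <- function(proportions = c(neutral = 0.23, mild = 0.51,
                                      moderate = 0.04, strong = 0.22),
                      N_anc = 1000, s_cap = -1) {
  stopifnot(length(proportions) == 4, abs(sum(proportions) - 1) < 1e-9,
            all(proportions >= 0))
  if (N_anc <= 0) stop("N_anc must be positive")
  two_n <- 2 * N_anc
  if (-100 / two_n <= s_cap)
    stop("N_anc too small: strong-class interval (s_cap, -100/(2*N_anc)) is empty")
  # s intervals [lo, hi) per class, on the plain s scale
  s_lo <- c(0, -10 / two_n, -100 / two_n, s_cap)
  s_hi <- c(0, -1 / two_n, -10 / two_n, -100 / two_n)
  structure(list(proportions = unname(proportions), N_anc = N_anc,
                 s_cap = s_cap, s_lo = s_lo, s_hi = s_hi,
                 classes = c("neutral", "mild", "moderate", "strong")),
            class = "dfe_model")
}

#' Sample selection coefficients from the discretized DFE
#'
#' @param dfe A [dfe_model()].
#' @param n Number of coefficients to draw.
#' @return Numeric vector of selection coefficients (<= 0; exactly 0 for the
#'   neutral class).
#' @export
sample_selection_coefficient <- function(dfe, n = 1) {
  cls <- sample.int(4L, n, replace = TRUE, prob = dfe$proportions)
  s <- numeric(n)
  for (k in 2:4) {
    idx <- cls == k
    if (any(idx)) s[idx] <- runif(sum(idx), dfe$s_lo[k], dfe$s_hi[k])
  }
  s
}

#' Build a recombination map from per-bin cM/Mb rates
#'
#' @param rates Per-bin crossover rates in cM/Mb.
#' @param bin_size Bin width in bp (default 10,000).
#' @return An object of class `recombination_map` with per-bp per-generation
#'   crossover probabilities `rate_per_bp = rates * 1e-8`.
#' @export
recombination_map <- function(rates, bin_size = 10000) {
  stopifnot(all(rates >= 0), bin_size >= 1)
  structure(list(rates_cM_Mb = as.numeric(rates),
                 rate_per_bp = as.numeric(rates) * 1e-8,
                 bin_size = as.integer(bin_size),
                 length = length(rates) * as.integer(bin_size)),
            class = "recombination_map")
}

#' Sample a 100-kb recombination map from a genome-wide rate table
#'
#' Draws a contiguous run of `region_len / bin_size` bins uniformly (with
#' replacement across draws) from a per-bin cM/Mb rate table, and resamples
#' until the acceptance rule passes. By default a region is accepted when
#' its mean rate exceeds `min_rate`; `mode = "per_bin"` instead requires
#' every bin to pass. The comparison is strict (`>`) unless
#' `inclusive = TRUE`.
#'
#' @param rate_table data.frame with columns `bin_start`, `bin_end`,
#'   `cM_per_Mb` (as written by [make_toy_rate_table()]), or a bare numeric
#'   vector of per-bin rates.
#' @param region_len Region length in bp (default 100,000).
#' @param min_rate Acceptance threshold in cM/Mb (default 0.5).
#' @param mode `"mean"` (region mean) or `"per_bin"`.
#' @param inclusive Accept regions at exactly `min_rate` (default FALSE).
#' @param max_tries Resample budget before failing with a diagnostic.
#' @return A [recombination_map()] for the sampled region.
#' @export
sample_recombination_map <- function(rate_table, region_len = 100000,
                                     min_rate = 0.5,
                                     mode = c("mean", "per_bin"),
                                     inclusive = FALSE, max_tries = 1000) {
  mode <- match.arg(mode)
  if (is.data.frame(rate_table)) {
    rates <- rate_table$cM_per_Mb
    bin_size <- as.integer(rate_table$bin_end[1] - rate_table$bin_start[1])
  } else {
    rates <- as.numeric(rate_table)
    bin_size <- 10000L
  }
  nb <- as.integer(region_len / bin_size)
  if (length(rates) < nb) stop("rate table has fewer bins than one region")
  pass <- function(x) if (inclusive) x >= min_rate else x > min_rate
  for (try in seq_len(max_tries)) {
    start <- sample.int(length(rates) - nb + 1L, 1L)
    run <- rates[start:(start + nb - 1L)]
    ok <- if (mode == "mean") pass(mean(run)) else all(pass(run))
    if (ok)
      return(recombination_map(run, bin_size))
  }
  stop(sprintf(
    "no %d-bin region with %s rate %s %g cM/Mb found in %d resamples",
    nb, mode, if (inclusive) ">=" else ">", min_rate, max_tries))
}
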