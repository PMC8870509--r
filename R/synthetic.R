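#' Generate a toy per-bin recombination-rate table
#'
#' Produces a genome-scale table of crossover rates in 10-kb bins, in the
#' TSV layout the map sampler consumes, under one of three laws: constant
#' (`uniform` with min = max), uniform, lognormal (parameterized by its
#' arithmetic mean), or a two-state hot/cold mosaic.
#'
#' @param n_bins Number of bins (>= 10).
#' @param law `"uniform"`, `"lognormal"` or `"hotcold"`.
#' @param min,max Bounds for the uniform law (cM/Mb).
#' @param mean,sdlog Mean (cM/Mb) and log-sd for the lognormal law.
#' @param cold,hot,p_hot Rates and hot-bin probability for the mosaic law.
#' @param bin_size Bin width in bp.
#' @return data.frame with columns `bin_start`, `bin_end`, `cM_per_Mb`.
#' @export
make_toy_rate_table <- function(n_bins, law = c("uniform", "lognormal", "hotcold"),
                                min = 2, max = 2, mean = 2, sdlog = 0.5,
                                cold = 0.1, hot = 3, p_hot = 0.5,
                                bin_size = 10000) {
  law <- match.arg(law)
  stopifnot(n_bins >= 10)
  rates <- switch(law,
    uniform = runif(n_bins, min, max),
    lognormal = rlnorm(n_bins, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog),
    hotcold = ifelse(runif(n_bins) < p_hot, hot, cold))
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_size,
             bin_end = seq_len(n_bins) * bin_size,
             cM_per_Mb = rates)
}

#' Construct a haplotype sample with a planted haplotype spectrum
#'
#' Builds `n` haplotypes realizing exactly the requested haplotype counts:
#' the k distinct haplotype strings are binary encodings of 0..k-1 over
#' ceiling(log2 k) sites (so every site is biallelic and segregating), and
#' any additional sites duplicate the first encoding column. The haplotype
#' spectrum over the full window therefore recovers `counts / n` exactly.
#'
#' @param n Number of haplotypes.
#' @param counts Integer counts per distinct haplotype, summing to `n`.
#' @param S Number of sites (>= ceiling(log2(length(counts)))).
#' @param region_length Region length in bp for the positions.
#' @return A [haplotype_sample()].
#' @export
make_planted_sample <- function(n, counts, S = max(2, ceiling(log2(length(counts)))),
                                region_length = 1e5) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 1), sum(counts) == n)
  k <- length(counts)
  need <- if (k == 1) 1L else as.integer(ceiling(log2(k)))
  if (S < need)
    stop(sprintf("infeasible plan: %d distinct haplotypes need >= %d sites", k, need))
  enc <- matrix(0L, k, need)
  for (i in seq_len(k))
    enc[i, ] <- as.integer(intToBits(i - 1L))[seq_len(need)]
  strings <- enc[rep(seq_len(k), counts), , drop = FALSE]
  if (S > need)
    strings <- cbind(strings, strings[, rep(1L, S - need), drop = FALSE])
  # single-haplotype plans have no segregating sites; keep the matrix anyway
  positions <- sort(sample.int(region_length, S)) - 1L
  haplotype_sample(strings, positions, region_length, check = FALSE)
}

#' Neutral coalescent sample (no recombination)
#'
#' Standard neutral coalescent for a constant-size population: with k
#' lineages the waiting time to the next coalescence is exponential with
#' rate k(k-1)/2 on the 2N-generation time scale; mutations fall on
#' branches as a Poisson process with rate theta/2 per unit branch length
#' (theta = 4*N*mu per region, diploid scaling), under infinite sites.
#' Serves as the independent equilibrium oracle for the forward engine.
#'
#' @param n Sample size (>= 2).
#' @param theta Population mutation parameter 4*N*mu for the whole region.
#' @param region_length Region length in bp for mutation positions.
#' @param seed Optional RNG seed.
#' @return A [haplotype_sample()] with attributes `tmrca` and
#'   `total_branch_length` (in 2N-generation units).
#' @export
coalescent_sample <- function(n, theta, region_length = 1e5, seed = NULL) {
  stopifnot(n >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages as lists of descendant sample indices
  lineages <- as.list(seq_len(n))
  mut_carriers <- list()   # descendant set of each mutation
  tmrca <- 0
  ttot <- 0
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    tmrca <- tmrca + t_k
    ttot <- ttot + k * t_k
    for (ln in lineages) {
      m <- rpois(1, theta / 2 * t_k)
      if (m > 0) mut_carriers <- c(mut_carriers, rep(list(ln), m))
    }
    pair <- sample.int(k, 2)
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1
  }
  S <- length(mut_carriers)
  alleles <- matrix(0L, n, S)
  if (S > 0) for (j in seq_len(S)) alleles[mut_carriers[[j]], j] <- 1L
  positions <- if (S > 0) sort(sample.int(region_length, S)) - 1L else numeric(0)
  samp <- haplotype_sample(alleles, positions, region_length, check = FALSE)
  attr(samp, "tmrca") <- tmrca
  attr(samp, "total_branch_length") <- ttot
  samp
}

#' Toy demographic-model templates
#'
#' Small, fully specified demographies with the structural features of the
#' published North American D. melanogaster models (bottleneck, split,
#' admixture pulse, post-admixture constant size) at sizes suited to
#' forward simulation on a desktop. These are structural stand-ins: the
#' numeric parameters are this package's own choices, not values fitted to
#' data.
#'
#' @param kind `"constant"`, `"bottleneck_growth"` or `"split_admixture"`.
#' @param N Reference diploid size (default 500).
#' @param generations Forward span after burn-in (default 4*N).
#' @param mutation_rate Per site per generation (default 2.5e-7, giving a
#'   per-site theta of 4*N*mu = 5e-4 at the default N).
#' @param admix_prop Admixture proportions (ancestral, daughter) for the
#'   split_admixture template.
#' @return A [demography_model()].
#' @export
make_toy_demography <- function(kind = c("constant", "bottleneck_growth",
                                         "split_admixture"),
                                N = 500, generations = 4 * N,
                                mutation_rate = 2.5e-7,
                                admix_prop = c(0.7, 0.3)) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  switch(kind,
    constant = demography_model(
      demes = data.frame(name = "pop", size = N),
      generations = generations, mutation_rate = mutation_rate,
      focal_pop = "pop"),
    bottleneck_growth = demography_model(
      demes = data.frame(name = "pop", size = N),
      events = list(
        list(type = "size_change", time = round(generations * 0.25),
             deme = "pop", size = max(2, round(N / 10))),
        list(type = "growth", time = round(generations * 0.5), deme = "pop",
             end_time = round(generations * 0.9), end_size = N)),
      generations = generations, mutation_rate = mutation_rate,
      focal_pop = "pop"),
    split_admixture = {
      stopifnot(abs(sum(admix_prop) - 1) < 1e-9)
      demography_model(
        demes = data.frame(name = c("anc", "daughter", "focal"),
                           size = c(N, 0, 0)),
        events = list(
          list(type = "split", time = round(generations * 0.2),
               source = "anc", deme = "daughter", size = max(2, round(N / 2))),
          list(type = "admixture", time = round(generations * 0.6),
               deme = "focal",
               sources = c(anc = admix_prop[1], daughter = admix_prop[2]),
               size = max(2, round(N / 2)))),
        generations = generations, mutation_rate = mutation_rate,
        focal_pop = "focal")
    })
}
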