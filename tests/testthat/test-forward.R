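test_that("genome annotation tiles the region and hits the printed exon fraction", {
  ann <- build_genome_annotation()
  expect_equal(attr(ann, "length"), 100000)
  exonic <- sum((ann$end - ann$start)[ann$kind == "exon"])
  expect_equal(exonic, 33 * 5 * 300)
  expect_equal(attr(ann, "exon_fraction"), 0.495)
  # gap/overlap-free tiling
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  expect_equal(ann$start[1], 0)
  # declared features cover 97,944 bp; the 2,056-bp remainder is intergenic
  expect_equal(33 * (5 * 300 + 4 * 100 + 1068), 97944)
  expect_equal(ann$end[nrow(ann)] - ann$start[nrow(ann)], 1068 + 2056)
  expect_identical(ann$kind[nrow(ann)], "intergenic")

  one <- build_genome_annotation(n_genes = 1, intergenic_len = 0, length = 1900)
  expect_equal(attr(one, "length"), 1900)
  expect_equal(sum((one$end - one$start)[one$kind == "exon"]), 1500)

  expect_error(build_genome_annotation(n_genes = 100), "exceed")
})

test_that("DFE sampler reproduces class weights and class bounds", {
  set.seed(401)
  dfe <- dfe_model(N_anc = 1000)
  n <- 1e5
  s <- sample_selection_coefficient(dfe, n)
  scaled <- 2 * 1000 * s
  cls_freq <- c(neutral = mean(s == 0),
                mild = mean(scaled >= -10 & scaled < -1),
                moderate = mean(scaled >= -100 & scaled < -10),
                strong = mean(scaled < -100))
  for (k in 1:4) {
    p0 <- dfe$proportions[k]
    expect_within_3se(cls_freq[k], sqrt(p0 * (1 - p0) / n), p0,
                      paste("class", k))
  }
  # mild class bounds at N_anc = 1000: s in [-0.005, -0.0005)
  mild <- s[scaled >= -10 & scaled < -1]
  expect_true(all(mild >= -0.005 & mild < -0.0005))
  # strong class: 2*N_anc*s < -100 for every draw, bounded by the cap
  strong <- s[scaled < -100]
  expect_true(all(strong >= -1))
  expect_true(all(2 * 1000 * strong < -100))
  expect_error(dfe_model(N_anc = 0), "positive")
  expect_error(dfe_model(N_anc = 40), "empty")
})

test_that("map sampling honors the acceptance rule's boundary and forced choices", {
  # all bins exactly at the threshold: rejected under strict >, accepted with >=
  flat <- make_toy_rate_table(20, "uniform", min = 0.5, max = 0.5)
  expect_error(sample_recombination_map(flat, max_tries = 50), "resamples")
  m <- sample_recombination_map(flat, inclusive = TRUE)
  expect_equal(m$rates_cM_Mb, rep(0.5, 10))

  # a single qualifying 10-bin run is always returned (per-bin rule)
  tab <- make_toy_rate_table(30, "uniform", min = 0, max = 0)
  tab$cM_per_Mb[11:20] <- 2
  set.seed(411)
  for (i in 1:20) {
    mp <- sample_recombination_map(tab, mode = "per_bin")
    expect_equal(mp$rates_cM_Mb, rep(2, 10))
  }
  # unit conversion: 2 cM/Mb -> 2e-8 per bp per generation
  expect_equal(mp$rate_per_bp, rep(2e-8, 10))
})

test_that("rescaling preserves the population-scaled products", {
  base <- make_toy_demography("bottleneck_growth", N = 1000, generations = 400,
                              mutation_rate = 1.39e-9)
  expect_identical(rescale_model(base, 1), base)

  r100 <- rescale_model(base, 100)
  expect_equal(r100$mutation_rate, 1.39e-7)
  expect_equal(r100$demes$size, 10)
  expect_equal(r100$generations, 4)
  expect_equal(r100$demes$size * r100$mutation_rate,
               base$demes$size * base$mutation_rate)
  expect_equal(r100$rate_scale, 100)

  base2 <- make_toy_demography("constant", N = 900, generations = 300,
                               mutation_rate = 1.0e-9)
  expect_equal(rescale_model(base2, 300)$mutation_rate, 3.0e-7)

  expect_error(rescale_model(base, 1000), "below 2")
  close_events <- demography_model(
    demes = data.frame(name = "pop", size = 1000),
    events = list(list(type = "size_change", time = 100, deme = "pop", size = 500),
                  list(type = "size_change", time = 110, deme = "pop", size = 800)),
    generations = 400, mutation_rate = 1e-9)
  expect_error(rescale_model(close_events, 100), "collide")
})

test_that("crossover counts per meiosis are Poisson with the map's total rate", {
  set.seed(421)
  map <- recombination_map(c(0.5, 4, 0.1, 2, 1, 0.5, 3, 0.2, 1, 0.7))
  lambda <- sum(map$rate_per_bp * map$bin_size)
  k <- draw_crossover_counts(map, 1e5)
  expect_within_3se(mean(k), sd(k) / sqrt(1e5), lambda, "mean crossovers")
  # variance equals the mean for a Poisson count
  expect_lt(abs(var(k) - lambda) / lambda, 0.05)
})

test_that("neutral equilibrium diversity matches 4*N*mu", {
  set.seed(431)
  N <- 100; mu <- 2.5e-7
  m <- make_toy_demography("constant", N = N, generations = 20, mutation_rate = mu)
  pis <- replicate(60, pairwise_diversity(simulate_region(m, map = 0, sample_n = 20),
                                          per_bp = 1e5))
  expect_within_3se(mean(pis), sd(pis) / sqrt(60), 4 * N * mu, "mean pi per site")
})

test_that("purifying selection depresses exonic diversity below intergenic", {
  set.seed(441)
  ann <- build_genome_annotation()
  # moderately/strongly deleterious mutations only, to make the footprint sharp
  dfe <- dfe_model(proportions = c(0, 0, 0.5, 0.5), N_anc = 100)
  m <- make_toy_demography("constant", N = 100, generations = 20,
                           mutation_rate = 2.5e-7)
  ratios <- replicate(50, {
    s <- simulate_region(m, annotation = ann, map = 2, dfe = dfe, sample_n = 20)
    d <- diversity_by_feature(s, ann)
    d$pi_per_bp[d$kind == "exon"] / d$pi_per_bp[d$kind == "intergenic"]
  })
  expect_lt(mean(ratios, na.rm = TRUE), 1)
  # and deleterious selection coefficients only ever attach to exonic sites
  s <- simulate_region(m, annotation = ann, map = 2, dfe = dfe, sample_n = 20,
                       seed = 442)
  sel <- attr(s, "selcoef")
  in_exon <- vapply(s$positions, function(p)
    any(p >= ann$start[ann$kind == "exon"] & p < ann$end[ann$kind == "exon"]),
    logical(1))
  expect_true(all(sel[!in_exon] == 0))
  expect_true(all(sel <= 0))
})

test_that("a deep split without migration generates positive Fst", {
  set.seed(451)
  N <- 100
  m <- demography_model(
    demes = data.frame(name = c("anc", "d2"), size = c(N, 0)),
    events = list(list(type = "split", time = 5, source = "anc",
                       deme = "d2", size = N)),
    generations = 3 * N, mutation_rate = 2.5e-7, focal_pop = "anc")
  fsts <- replicate(20, {
    s <- simulate_region(m, map = 0.5, sample_n = c(anc = 15, d2 = 15))
    hudson_fst(s, attr(s, "deme"))
  })
  expect_gt(mean(fsts), 0)
  expect_gt(mean(fsts > 0), 0.8)
})

test_that("an all-neutral DFE behaves like the selection-free engine", {
  set.seed(461)
  ann <- build_genome_annotation()
  dfe0 <- dfe_model(proportions = c(1, 0, 0, 0), N_anc = 100)
  m <- make_toy_demography("constant", N = 100, generations = 20,
                           mutation_rate = 2.5e-7)
  a <- replicate(40, pairwise_diversity(
    simulate_region(m, annotation = ann, map = 1, dfe = dfe0, sample_n = 20),
    per_bp = 1e5))
  b <- replicate(40, pairwise_diversity(
    simulate_region(m, annotation = ann, map = 1, dfe = NULL, sample_n = 20),
    per_bp = 1e5))
  se <- sqrt(var(a) / 40 + var(b) / 40)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("demography compilation validates event structure", {
  expect_error(demography_model(
    demes = data.frame(name = "pop", size = 100),
    events = list(list(type = "teleport", time = 5)),
    generations = 10, mutation_rate = 1e-9), "unknown event type")
  expect_error(demography_model(
    demes = data.frame(name = "pop", size = 100),
    events = list(list(type = "admixture", time = 5, deme = "pop",
                       sources = c(pop = 0.4), size = 50)),
    generations = 10, mutation_rate = 1e-9), "sum to 1")
  expect_error(demography_model(
    demes = data.frame(name = c("a", "a"), size = c(10, 10)),
    generations = 10, mutation_rate = 1e-9), "unique")
})
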