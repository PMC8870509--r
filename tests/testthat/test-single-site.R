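test_that("fitness scheme reproduces the semidominant genotype table", {
  neutral <- build_fitness_scheme(0, 0)
  expect_true(all(neutral$w == 1))

  sch <- build_fitness_scheme(0.52, 0)
  expect_equal(sch$w["C", "C"], 1.52)
  expect_equal(sch$w["A", "C"], 1.26)
  expect_equal(sch$w["G", "C"], 1.26)
  expect_equal(sch$w["T", "C"], 1.52)   # max rule with sT = 0
  expect_equal(sch$w["T", "T"], 1)
  expect_equal(sch$w["A", "A"], 1)

  extreme <- build_fitness_scheme(1.0, 5.2)
  expect_equal(extreme$w["T", "C"], 6.2)
  expect_true(isSymmetric(extreme$w))

  expect_error(build_fitness_scheme(-1, 0), "exceed -1")
  expect_error(build_fitness_scheme(0, -1.5), "exceed -1")
})

test_that("one generation conserves gene copies and respects absorbing states", {
  set.seed(11)
  N <- 50L
  sch <- build_fitness_scheme(0.3, 0.7)
  # absorbing without mutation
  expect_identical(wf_generation(c(100L, 0L, 0L, 0L), build_fitness_scheme(0, 0), N, 0),
                   c(100L, 0L, 0L, 0L))
  expect_identical(wf_generation(c(0L, 100L, 0L, 0L), sch, N, 0),
                   c(0L, 100L, 0L, 0L))
  # conservation over random states, with and without mutation
  for (i in 1:50) {
    counts <- as.integer(rmultinom(1, 2 * N, runif(4)))
    nxt <- wf_generation(counts, sch, N, 0.01)
    expect_identical(sum(nxt), 2L * N)
    expect_true(all(nxt >= 0L))
  }
  expect_error(wf_generation(c(1L, 1L, 1L, 1L), sch, N, 0), "summing to 2N")
})

test_that("stochastic one-step mean matches the Hardy-Weinberg enumeration oracle", {
  # printed single case: freq(C) = 0.5, sC = 0.5, deterministic update
  set.seed(21)
  N <- 50L
  sch <- build_fitness_scheme(0.5, 0)
  counts <- c(50L, 50L, 0L, 0L)
  draws <- 1e5
  fC <- numeric(draws)
  for (i in seq_len(draws)) fC[i] <- wf_generation(counts, sch, N, 0)[2] / (2 * N)
  target <- oracle_onestep_freqs(counts / (2 * N), sch)[2]
  # closed form for the diploid semidominant update, as a cross-check on the oracle
  x <- 0.5; s <- 0.5
  expect_equal(target, x * (1 + 0.5 * s * (1 + x)) / (1 + s * x), tolerance = 1e-12)
  expect_within_3se(mean(fC), sd(fC) / sqrt(draws), target, "mean freq(C)")

  # random (x, sC, sT) triples at lower replication
  for (k in 1:20) {
    sck <- runif(1, 0, 2); stk <- runif(1, 0, 2)
    schk <- build_fitness_scheme(sck, stk)
    ck <- as.integer(rmultinom(1, 2 * N, runif(4, 0.05, 1)))
    drawsk <- 4000
    fk <- matrix(0, drawsk, 4)
    for (i in seq_len(drawsk)) fk[i, ] <- wf_generation(ck, schk, N, 0) / (2 * N)
    tgt <- oracle_onestep_freqs(ck / (2 * N), schk)
    for (a in 1:4) {
      se <- sd(fk[, a]) / sqrt(drawsk)
      if (se > 0)
        expect_within_3se(mean(fk[, a]), se + 1e-12, tgt[a],
                          sprintf("triple %d allele %d", k, a))
    }
  }
})

test_that("replicates start all-A and stay there without mutational input", {
  p <- site_sim_params(N = 1000, mu = 0, generations = 40, snapshot_gens = c(30, 40),
                       seed = 5)
  tr <- run_replicate(p, build_fitness_scheme(2, 2))
  expect_true(all(tr$counts[, "A"] == 2000L))
  expect_identical(dim(tr$counts), c(41L, 4L))
  f <- snapshot_freqs(tr, 30)
  expect_equal(unname(f$freq), c(1, 0, 0, 0))
  expect_error(snapshot_freqs(tr, 50), "outside")
})

test_that("neutral mutation accumulation matches the 2N*mu*t expectation", {
  set.seed(31)
  N <- 1000L; mu <- 1e-5; gens <- 60L; reps <- 1000L
  sch <- build_fitness_scheme(0, 0)
  p <- site_sim_params(N = N, mu = mu, generations = gens, snapshot_gens = gens)
  nonA <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- run_replicate(p, sch)
    nonA[r] <- 2 * N - tr$counts[gens + 1, "A"]
  }
  expected <- 2 * N * mu * gens
  expect_within_3se(mean(nonA), sd(nonA) / sqrt(reps), expected, "mean non-A count")
})

test_that("very strong selection usually lifts beneficials past 50% by generation 30", {
  set.seed(41)
  sch <- build_fitness_scheme(5.2, 5.2)
  p <- site_sim_params(N = 1e5, mu = 1e-5, generations = 30, snapshot_gens = 30)
  hits <- 0L; reps <- 40L
  for (r in seq_len(reps)) {
    f <- snapshot_freqs(run_replicate(p, sch), 30)$freq
    if (f[["C"]] + f[["T"]] >= 0.5) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.8)
})

test_that("neutral drift fixes an allele with probability equal to its frequency", {
  set.seed(51)
  N <- 50L; x0 <- 0.3
  sch <- build_fitness_scheme(0, 0)
  reps <- 10000L
  init <- c(2L * N - as.integer(2 * N * x0), as.integer(2 * N * x0), 0L, 0L)
  fixed <- vapply(seq_len(reps), function(r)
    run_to_absorption(N, sch, init), logical(1))
  phat <- mean(fixed)
  expect_within_3se(phat, sqrt(x0 * (1 - x0) / reps), x0, "fixation probability")
})

test_that("a single semidominant beneficial copy establishes at rate about s", {
  set.seed(61)
  N <- 500L; sC <- 0.08
  sch <- build_fitness_scheme(sC, 0)
  reps <- 20000L
  init <- c(2L * N - 1L, 1L, 0L, 0L)
  # freq 0.9 is effectively past the drift barrier at 2Ns = 80
  fixed <- vapply(seq_len(reps), function(r)
    run_to_absorption(N, sch, init, fix_freq = 0.9), logical(1))
  phat <- mean(fixed)
  expect_within_3se(phat, sqrt(phat * (1 - phat) / reps), sC,
                    "establishment probability")
})

test_that("allele G is selectively equivalent to allele A", {
  # the expected one-step update must be invariant under relabeling A <-> G
  sch <- build_fitness_scheme(0.7, 1.3)
  set.seed(71)
  for (k in 1:25) {
    p <- as.vector(rmultinom(1, 100, runif(4))) / 100
    swapped <- p[c(3, 2, 1, 4)]
    e1 <- oracle_onestep_freqs(p, sch)
    e2 <- oracle_onestep_freqs(swapped, sch)
    expect_equal(e1[c(3, 2, 1, 4)], e2, tolerance = 1e-12)
  }
  # and whole-run summaries from an all-G start match the all-A start
  set.seed(72)
  pA <- site_sim_params(N = 2000, mu = 1e-4, generations = 30, snapshot_gens = 30)
  fA <- replicate(150, sum(snapshot_freqs(run_replicate(pA, sch), 30)$freq[c("C", "T")]))
  fG <- replicate(150, {
    tr <- run_replicate(pA, sch, init_counts = c(0L, 0L, 4000L, 0L))
    sum(snapshot_freqs(tr, 30)$freq[c("C", "T")])
  })
  se <- sqrt(var(fA) / 150 + var(fG) / 150)
  expect_lt(abs(mean(fA) - mean(fG)), 3 * se + 1e-12)
})

test_that("grid runs are seed-reproducible and exchangeable under C/T relabeling", {
  p <- site_sim_params(N = 1000, mu = 1e-4, generations = 60, seed = 9)
  g1 <- run_grid(1.0, 1.0, reps = 1, params = p)
  p2 <- p; p2$seed <- sweepverdict:::derive_seed(9, 1, 1)
  tr <- run_replicate(p2, build_fitness_scheme(1.0, 1.0))
  expect_equal(g1$freqC[g1$generation == 30],
               unname(snapshot_freqs(tr, 30)$freq["C"]))
  expect_equal(g1$freqT[g1$generation == 60],
               unname(snapshot_freqs(tr, 60)$freq["T"]))

  # asymmetric cell, mirrored: freq(C) under (s1, s2) matches freq(T) under (s2, s1)
  p$seed <- 10
  gA <- run_grid(1.5, 0.5, reps = 250, params = p)
  gB <- run_grid(0.5, 1.5, reps = 250, params = p)
  a <- gA$freqC[gA$generation == 30]
  b <- gB$freqT[gB$generation == 30]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})
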