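#' Define a multi-deme demographic model in forward time
#'
#' Populations are named demes with diploid sizes; scheduled events alter
#' sizes and ancestry as the simulation proceeds forward from generation 1
#' to `generations` (a burn-in at the initial sizes is added by the
#' simulator). Supported events, each a list with a `type` field and a
#' forward `time` in generations:
#' \describe{
#'   \item{size_change}{`deme`, `size`: deme holds `size` from `time` on.}
#'   \item{growth}{`deme`, `time` (start), `end_time`, `end_size`:
#'     exponential size interpolation between the two times.}
#'   \item{split}{`source`, `deme`, `size`: daughter deme founded at `time`
#'     entirely from `source`.}
#'   \item{admixture}{`deme`, `sources` (named proportions summing to 1),
#'     `size`: deme (re)founded at `time` as a mixture pulse.}
#'   \item{migration}{`from`, `to`, `rate`: from `time` on, each generation
#'     a fraction `rate` of `to`'s parents are drawn from `from`.}
#' }
#'
#' @param demes data.frame with columns `name` and `size` (initial diploid
#'   size; 0 for demes founded later by split/admixture).
#' @param events List of event lists as above (may be empty).
#' @param generations Forward time span simulated after burn-in.
#' @param mutation_rate Per site per generation mutation rate.
#' @param focal_pop Name of the deme sampled at the end.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(demes, events = list(), generations,
                             mutation_rate, focal_pop = demes$name[1]) {
  stopifnot(is.data.frame(demes), all(c("name", "size") %in% names(demes)),
            generations >= 1, mutation_rate >= 0,
            focal_pop %in% demes$name)
  if (anyDuplicated(demes$name)) stop("deme names must be unique")
  if (any(demes$size != 0 & demes$size < 2)) stop("active deme sizes must be >= 2")
  for (ev in events) {
    if (is.null(ev$type) || is.null(ev$time))
      stop("every event needs `type` and `time`")
    if (!ev$type %in% c("size_change", "growth", "split", "admixture", "migration"))
      stop("unknown event type: ", ev$type)
    if (ev$time < 1 || ev$time > generations)
      stop("event time outside [1, generations]")
    if (ev$type == "admixture" && abs(sum(ev$sources) - 1) > 1e-9)
      stop("admixture proportions must sum to 1")
  }
  structure(list(demes = demes, events = events,
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, focal_pop = focal_pop,
                 Q = 1, rate_scale = 1),
            class = "demography_model")
}

#' Rescale a demographic model by a factor Q
#'
#' Standard forward-simulation rescaling: population sizes and event
#' times/durations are divided by Q while mutation, recombination and
#' migration rates, and selection coefficients, are multiplied by Q, so the
#' products N*mu, N*r, N*m and N*s are preserved to within rounding. The
#' returned model carries `Q` and a `rate_scale` that the simulator applies
#' to the recombination map and the DFE.
#'
#' @param base A [demography_model()].
#' @param Q Rescaling factor (>= 1).
#' @return A rescaled `demography_model`.
#' @export
rescale_model <- function(base, Q) {
  stopifnot(inherits(base, "demography_model"), Q >= 1)
  if (Q == 1) return(base)
  m <- base
  m$demes$size <- round(base$demes$size / Q)
  if (any(m$demes$size != 0 & m$demes$size < 2))
    stop("rescaled deme size below 2; choose a smaller Q")
  m$generations <- as.integer(round(base$generations / Q))
  times <- vapply(base$events, function(e) e$time, numeric(1))
  if (length(times)) {
    new_times <- round(times / Q)
    gaps <- diff(sort(c(0, new_times, m$generations)))
    if (any(gaps < 1))
      stop("rescaled event times collide (gap < 1 generation); choose a smaller Q")
  }
  m$events <- lapply(base$events, function(e) {
    e$time <- max(1, round(e$time / Q))
    if (!is.null(e$end_time)) e$end_time <- max(e$time + 1, round(e$end_time / Q))
    if (!is.null(e$size)) e$size <- max(2, round(e$size / Q))
    if (!is.null(e$end_size)) e$end_size <- max(2, round(e$end_size / Q))
    if (!is.null(e$rate)) e$rate <- min(1, e$rate * Q)
    e
  })
  m$mutation_rate <- base$mutation_rate * Q
  m$Q <- base$Q * Q
  m$rate_scale <- base$rate_scale * Q
  m
}

# Compile a demography into per-generation deme sizes and ancestry rows.
# Returns sizes ((T+1) x K, generation 0 = initial/burn-in state) and a list
# of T ancestry matrices A[t][d, s] = P(parent of a deme-d offspring at
# generation t comes from deme s).
compile_demography <- function(model, burnin = 0) {
  K <- nrow(model$demes)
  Tg <- model$generations + burnin
  nm <- model$demes$name
  sizes <- matrix(rep(as.integer(model$demes$size), each = Tg + 1),
                  Tg + 1, K, dimnames = list(NULL, nm))
  base_anc <- diag(K)
  dimnames(base_anc) <- list(nm, nm)
  ancestry <- rep(list(base_anc), Tg)
  pulsed <- matrix(FALSE, Tg, K, dimnames = list(NULL, nm))
  mig <- list()   # active migration edges
  evs <- model$events
  if (length(evs)) evs <- evs[order(vapply(evs, `[[`, numeric(1), "time"))]
  for (ev in evs) {
    t0 <- ev$time + burnin
    switch(ev$type,
      size_change = {
        sizes[(t0 + 1):(Tg + 1), ev$deme] <- as.integer(ev$size)
      },
      growth = {
        t1 <- ev$end_time + burnin
        n0 <- sizes[t0, ev$deme]
        if (n0 < 2) stop("growth event on an empty deme")
        tt <- t0:t1
        traj <- round(n0 * (ev$end_size / n0)^((tt - t0) / (t1 - t0)))
        sizes[tt + 1, ev$deme] <- as.integer(traj)
        if (t1 < Tg) sizes[(t1 + 2):(Tg + 1), ev$deme] <- as.integer(ev$end_size)
      },
      split = {
        sizes[(t0 + 1):(Tg + 1), ev$deme] <- as.integer(ev$size)
        ancestry[[t0]][ev$deme, ] <- 0
        ancestry[[t0]][ev$deme, ev$source] <- 1
        pulsed[t0, ev$deme] <- TRUE
      },
      admixture = {
        sizes[(t0 + 1):(Tg + 1), ev$deme] <- as.integer(ev$size)
        ancestry[[t0]][ev$deme, ] <- 0
        ancestry[[t0]][ev$deme, names(ev$sources)] <- ev$sources
        pulsed[t0, ev$deme] <- TRUE
      },
      migration = {
        mig[[length(mig) + 1]] <- list(t0 = t0, from = ev$from, to = ev$to,
                                       rate = ev$rate)
      })
  }
  for (mg in mig) {
    for (t in mg$t0:Tg) {
      if (pulsed[t, mg$to]) next   # pulse rows override continuous migration
      A <- ancestry[[t]]
      A[mg$to, mg$from] <- A[mg$to, mg$from] + mg$rate
      A[mg$to, mg$to] <- A[mg$to, mg$to] - mg$rate
      if (A[mg$to, mg$to] < 0) stop("migration rates into one deme exceed 1")
      ancestry[[t]] <- A
    }
  }
  # validation: ancestry must not draw from empty demes
  for (t in seq_len(Tg)) {
    for (d in seq_len(K)) {
      if (sizes[t + 1, d] > 0) {
        src <- which(ancestry[[t]][d, ] > 0)
        if (any(sizes[t, src] == 0))
          stop(sprintf("generation %d: deme %s draws parents from an empty deme", t, nm[d]))
      }
    }
  }
  list(sizes = sizes, ancestry = ancestry, burnin = burnin)
}

#' Simulate a haplotype sample from a genomic region
#'
#' Forward diploid Wright-Fisher simulation of the full region: mutations
#' enter each gamete as a Poisson process over base pairs (infinite-sites on
#' integer positions, collisions redrawn); mutations landing in exons draw a
#' selection coefficient from the DFE while all other mutations are neutral;
#' fitness is semidominant and multiplicative across sites; meioses place
#' crossovers according to the recombination map; demography follows the
#' compiled per-generation plan. After `burnin` + `model$generations`
#' generations, `sample_n` haploid genomes are drawn without replacement
#' from the focal deme and monomorphic sites are dropped.
#'
#' @param model A [demography_model()] (possibly rescaled).
#' @param annotation A [build_genome_annotation()] object (or NULL for a
#'   featureless neutral region).
#' @param map A [recombination_map()], a single cM/Mb rate, or 0.
#' @param dfe A [dfe_model()] or NULL for strict neutrality.
#' @param sample_n Haploid genomes sampled from the focal deme (default 145).
#' @param region_length Region length in bp (default from annotation/map).
#' @param burnin Burn-in generations at the initial sizes (default 10 times
#'   the focal ancestral size).
#' @param seed Optional RNG seed.
#' @return A [haplotype_sample()] with attribute `selcoef` giving the
#'   selection coefficient of each retained site.
#' @export
simulate_region <- function(model, annotation = NULL, map = 0, dfe = NULL,
                            sample_n = 145, region_length = NULL,
                            burnin = NULL, seed = NULL) {
  stopifnot(inherits(model, "demography_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region_length)) {
    region_length <- if (!is.null(annotation)) attr(annotation, "length")
                     else if (inherits(map, "recombination_map")) map$length
                     else 1e5
  }
  if (!is.null(annotation) && attr(annotation, "length") != region_length)
    stop("annotation length disagrees with region length")
  if (inherits(map, "recombination_map")) {
    if (map$length != region_length)
      stop("recombination map length disagrees with region length")
    bin_rates <- map$rate_per_bp * model$rate_scale
    bin_size <- map$bin_size
  } else {
    bin_rates <- rep(as.numeric(map) * 1e-8 * model$rate_scale, 10)
    bin_size <- as.integer(region_length / 10)
  }
  if (is.null(burnin)) {
    anc0 <- model$demes$size[model$demes$size > 0][1]
    burnin <- as.integer(10 * anc0)
  }
  plan <- compile_demography(model, burnin = burnin)
  exons <- if (!is.null(annotation)) {
    ex <- annotation[annotation$kind == "exon", , drop = FALSE]
    cbind(ex$start, ex$end)
  } else matrix(integer(0), 0, 2)
  if (is.null(dfe) || nrow(exons) == 0) {
    dfe_probs <- numeric(0); s_lo <- numeric(0); s_hi <- numeric(0)
  } else {
    eff_dfe <- if (model$rate_scale != 1)
      dfe_model(dfe$proportions, N_anc = dfe$N_anc / model$rate_scale,
                s_cap = dfe$s_cap)
    else dfe
    dfe_probs <- eff_dfe$proportions
    s_lo <- eff_dfe$s_lo; s_hi <- eff_dfe$s_hi
  }
  sample_counts <- integer(nrow(model$demes))
  if (!is.null(names(sample_n))) {
    idx <- match(names(sample_n), model$demes$name)
    if (anyNA(idx)) stop("unknown deme in sample_n names")
    sample_counts[idx] <- as.integer(sample_n)
  } else {
    focal <- match(model$focal_pop, model$demes$name)
    sample_counts[focal] <- as.integer(sample_n)
  }
  res <- sim_region_cpp(plan$sizes, plan$ancestry,
                        as.integer(region_length), model$mutation_rate,
                        bin_rates, as.integer(bin_size),
                        exons, dfe_probs, s_lo, s_hi, sample_counts)
  samp <- haplotype_sample(res$alleles, res$positions,
                           region_length = region_length, check = FALSE)
  attr(samp, "selcoef") <- res$selcoef
  attr(samp, "deme") <- model$demes$name[res$deme]
  samp
}
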