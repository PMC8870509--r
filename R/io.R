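#' Write haplotype samples as ms-style blocks
#'
#' One block per sample: a `//` separator, `segsites: S`, a `positions:`
#' line with positions as fractions of the region length, and one 0/1 row
#' per haplotype. Positions are written with full precision so a read/write
#' round trip is lossless at bp resolution.
#'
#' @param samples A [haplotype_sample()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(samples, path) {
  if (inherits(samples, "haplotype_sample")) samples <- list(samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ms %d %d", samples[[1]]$n, length(samples)), con)
  writeLines("", con)
  for (s in samples) {
    writeLines("//", con)
    S <- ncol(s$alleles)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.10g", s$positions / s$region_length),
                             collapse = " ")), con)
      writeLines(apply(s$alleles, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-style haplotype blocks
#'
#' Parses the `//` / `segsites:` / `positions:` dialect (positions as
#' fractions of the region length) into [haplotype_sample()] objects.
#' Malformed records -- ragged rows, non-increasing positions, missing
#' headers -- raise errors naming the record index; `segsites: 0` records
#' yield an empty sample with a warning.
#'
#' @param path Input file path.
#' @param region_length Region length in bp used to map fractional
#'   positions to coordinates (default 1e5).
#' @return List of [haplotype_sample()] objects.
#' @export
read_ms <- function(path, region_length = 1e5) {
  lines <- readLines(path)
  recs <- which(trimws(lines) == "//")
  if (!length(recs)) stop("no '//' record separators found")
  out <- vector("list", length(recs))
  bounds <- c(recs, length(lines) + 1L)
  for (r in seq_along(recs)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (!length(block) || !grepl("^segsites:", block[1]))
      stop(sprintf("record %d: missing 'segsites:' header", r))
    S <- as.integer(sub("^segsites:\\s*", "", block[1]))
    if (is.na(S)) stop(sprintf("record %d: malformed segsites header", r))
    if (S == 0) {
      warning(sprintf("record %d has no segregating sites", r))
      out[[r]] <- haplotype_sample(matrix(integer(0), 0, 0), numeric(0),
                                   region_length, check = FALSE)
      next
    }
    if (length(block) < 2 || !grepl("^positions:", block[2]))
      stop(sprintf("record %d: missing 'positions:' header", r))
    fr <- as.numeric(strsplit(sub("^positions:\\s*", "", block[2]), "\\s+")[[1]])
    if (length(fr) != S)
      stop(sprintf("record %d: %d positions for %d sites", r, length(fr), S))
    if (any(diff(fr) <= 0))
      stop(sprintf("record %d: positions not strictly increasing", r))
    rows <- block[-(1:2)]
    if (!length(rows)) stop(sprintf("record %d: no haplotype rows", r))
    if (any(nchar(rows) != S))
      stop(sprintf("record %d: ragged haplotype rows", r))
    alleles <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    out[[r]] <- haplotype_sample(alleles, fr * region_length, region_length,
                                 check = FALSE)
  }
  out
}

#' Write a haplotype sample as VCF 4.2 text
#'
#' Haploid GT fields, 1-based positions, a contig header carrying the
#' region length. Allele codes 0/1 are written as the placeholder bases
#' A (ancestral/REF) and T (derived/ALT); the simulator tracks
#' ancestral/derived state, not nucleotide identity.
#'
#' @param sample A [haplotype_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=sim,length=%d>", as.integer(sample$region_length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  hapnames <- sprintf("hap%d", seq_len(sample$n))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", hapnames), collapse = "\t"), con)
  S <- ncol(sample$alleles)
  if (S > 0) {
    for (j in seq_len(S)) {
      gt <- as.character(sample$alleles[, j])
      writeLines(paste(c("sim", as.integer(sample$positions[j]) + 1L, ".",
                         "A", "T", ".", "PASS", ".", "GT", gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a haploid VCF written by [write_vcf()]
#'
#' @param path Input VCF path.
#' @return A [haplotype_sample()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  contig <- grep("^##contig", lines, value = TRUE)
  L <- if (length(contig)) as.numeric(sub(".*length=(\\d+).*", "\\1", contig[1])) else 1e5
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("missing #CHROM header line")
  fields <- strsplit(lines[hdr], "\t")[[1]]
  n <- length(fields) - 9L
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(haplotype_sample(matrix(integer(0), n, 0), numeric(0), L, check = FALSE))
  parts <- strsplit(body, "\t")
  pos <- vapply(parts, function(p) as.numeric(p[2]), numeric(1)) - 1
  alleles <- t(vapply(parts, function(p) as.integer(p[-seq_len(9)]), integer(n)))
  haplotype_sample(t(alleles), pos, L, check = FALSE)
}

# note: the deme-size key is `pop_size`, not `N` -- YAML 1.1 parses a bare
# `N` as the boolean FALSE
config_schema <- list(
  model = list(kind = "constant", pop_size = 500, generations = NULL,
               mutation_rate = NULL),
  dfe = list(enabled = FALSE, N_anc = 1000),
  recombination = list(kind = "constant", rate = 0.5, table = NULL),
  Q = 1, sample_n = 145, seed = 1
)

validate_section <- function(cfg, schema, prefix) {
  for (key in names(cfg)) {
    if (!key %in% names(schema))
      stop(sprintf("unknown config key `%s%s`", prefix, key))
  }
  out <- schema
  for (key in names(schema)) {
    given <- cfg[[key]]
    if (is.list(schema[[key]]) && !is.null(names(schema[[key]]))) {
      out[[key]] <- validate_section(if (is.null(given)) list() else given,
                                     schema[[key]], paste0(prefix, key, "."))
    } else if (!is.null(given)) {
      out[key] <- list(given)
    } else if (is.null(schema[[key]]) &&
               !key %in% c("table", "generations")) {
      stop(sprintf("missing required config key `%s%s`", prefix, key))
    }
  }
  out
}

#' Load and validate a simulation scenario configuration
#'
#' Reads a YAML scenario file, rejects unknown keys (naming the full key
#' path), checks required keys and value constraints, and returns the
#' configuration with defaults applied.
#'
#' @param path Path to a YAML config file.
#' @return Validated config list with attribute `defaults_applied`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  out <- validate_section(cfg, config_schema, "")
  if (is.null(out$model$mutation_rate))
    stop("missing required config key `model.mutation_rate`")
  if (is.null(out$model$generations))
    out$model$generations <- 4 * out$model$pop_size
  if (!out$model$kind %in% c("constant", "bottleneck_growth", "split_admixture"))
    stop("`model.kind` must be constant, bottleneck_growth or split_admixture")
  if (out$Q < 1) stop("`Q` must be >= 1")
  if (out$sample_n < 2) stop("`sample_n` must be >= 2")
  given_keys <- function(cfg, prefix = "") {
    unlist(lapply(names(cfg), function(k) {
      if (is.list(cfg[[k]])) given_keys(cfg[[k]], paste0(prefix, k, "."))
      else paste0(prefix, k)
    }))
  }
  all_keys <- given_keys(out)
  attr(out, "defaults_applied") <- setdiff(all_keys, given_keys(cfg))
  out
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' command, the full configuration echo (defaults included), the master
#' seed and any derived per-replicate seeds, the package version and a
#' timestamp.
#'
#' @param command Character tag for the operation.
#' @param config Configuration list (echoed verbatim).
#' @param seed Master seed.
#' @param derived_seeds Optional vector of derived per-replicate seeds.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, derived_seeds = NULL) {
  structure(list(command = command, config = config, seed = seed,
                 derived_seeds = derived_seeds,
                 package_version = as.character(packageVersion("sweepverdict")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}
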