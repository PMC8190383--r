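# Pipeline orchestration --------------------------------------------------
#
# Four re-runnable stages with plain-TSV contracts between them:
#   simulate -> FASTQ + truth TSV
#   annotate -> AIRR rearrangement TSV + rejection log
#   profile  -> per-sample feature TSV + usage matrices
#   compare  -> comparison TSV (+ correlation TSV)
# Every stage writes a JSON run manifest (config echo, seed, version,
# config hash) and stamps its TSV outputs with '#' header metadata.

config_keys <- list(
  simulate = list(
    required = c("out_dir"),
    optional = c("sample_id", "seed", "reference", "n_v", "n_d", "n_j", "n_c",
                 "v_length", "min_pairwise_divergence", "clone_count",
                 "reads_per_sample", "clone_size_alpha", "nonproductive_rate",
                 "seq_error_rate", "trim_mean", "n_insert_mean", "p_nt_prob",
                 "shm_default", "c_prefix_len")),
  annotate = list(
    required = c("reads", "reference", "out_dir"),
    optional = c("sample_id", "min_mean_q", "min_length", "floor_v",
                 "floor_j", "floor_c", "floor_d")),
  profile = list(
    required = c("airr", "out_dir"),
    optional = c("weighting")),
  compare = list(
    required = c("profiles", "metadata", "out_dir"),
    optional = c("design", "adjust", "covariate", "group_col", "pair_col")))

#' Read a pipeline configuration file
#'
#' Accepts JSON (first non-blank character `{`) or flat `key = value`
#' lines (`#` comments allowed). Values are coerced to numeric or logical
#' where they parse as such.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  body <- trimws(paste(txt, collapse = "\n"))
  if (startsWith(body, "{")) {
    return(jsonlite::fromJSON(body, simplifyVector = TRUE))
  }
  lines <- trimws(txt)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad)) stop("config line ", bad[1], " is not 'key = value'")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  coerce <- function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  stats::setNames(lapply(vals, coerce), keys)
}

check_config <- function(config, cmd) {
  spec <- config_keys[[cmd]]
  known <- c(spec$required, spec$optional)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s) for '", cmd, "': ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(spec$required, names(config))
  if (length(missing)) {
    stop("missing required config key(s) for '", cmd, "': ",
         paste(missing, collapse = ", "))
  }
  invisible(config)
}

write_manifest <- function(out_dir, cmd, config, seed) {
  cfg <- config
  cfg$reference <- NULL   # objects don't belong in the echo
  manifest <- list(tool = "ighrep", version = ighrep_version(),
                   command = cmd, seed = seed,
                   config_hash = object_hash(cfg), config = cfg,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0("manifest_", cmd, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}

stamp_meta <- function(config, seed) {
  cfg <- config; cfg$reference <- NULL
  c(tool = "ighrep", version = ighrep_version(),
    config_hash = object_hash(cfg), seed = as.character(seed))
}

#' Pipeline stage: simulate a repertoire sample
#'
#' Builds (or loads) a germline reference, simulates one sample, and
#' writes `<sample>.fastq`, `<sample>_truth.tsv`, the reference FASTA and
#' a run manifest into `out_dir`.
#'
#' @param config named list (see the package vignette) or a config file
#'   path for [read_pipeline_config()].
#' @return invisibly, a list of output paths plus the simulated sample.
#' @export
cmd_simulate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_config(config, "simulate")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sample_id <- config$sample_id %||% "S1"
  seed <- as.integer(config$seed %||% 1L)

  reference <- if (!is.null(config$reference)) {
    read_germline_set(config$reference)
  } else {
    build_synthetic_reference(
      n_v = as.integer(config$n_v %||% 15L),
      n_d = as.integer(config$n_d %||% 8L),
      n_j = as.integer(config$n_j %||% 6L),
      n_c = as.integer(config$n_c %||% 10L),
      v_length = as.integer(config$v_length %||% 291L),
      min_pairwise_divergence = config$min_pairwise_divergence %||% 0.15,
      seed = seed)
  }
  sc <- sim_config(
    reference,
    trim_mean = config$trim_mean %||% 2,
    p_nt_prob = config$p_nt_prob %||% 0.5,
    n_insert_mean = config$n_insert_mean %||% 4,
    shm_default = config$shm_default %||% 0.02,
    clone_count = as.integer(config$clone_count %||% 300L),
    reads_per_sample = as.integer(config$reads_per_sample %||% 3000L),
    clone_size_alpha = config$clone_size_alpha %||% 2.5,
    nonproductive_rate = config$nonproductive_rate %||% 0.1,
    seq_error_rate = config$seq_error_rate %||% 0.001,
    c_prefix_len = as.integer(config$c_prefix_len %||% 60L),
    seed = seed)
  sim <- simulate_sample(sc, sample_id)

  paths <- list(
    fastq = file.path(out_dir, paste0(sample_id, ".fastq")),
    truth = file.path(out_dir, paste0(sample_id, "_truth.tsv")),
    reference = file.path(out_dir, "reference.fasta"))
  write_fastq(sim$reads, paths$fastq)
  write_truth(sim$truth, paths$truth, stamp_meta(config, seed))
  if (is.null(config$reference)) write_germline_fasta(reference, paths$reference)
  else paths$reference <- config$reference
  write_manifest(out_dir, "simulate", config, seed)
  message("simulate: ", nrow(sim$reads), " reads for sample ", sample_id)
  invisible(c(paths, list(sim = sim, reference_set = reference)))
}

#' Pipeline stage: annotate reads
#'
#' Reads FASTQ, annotates against the reference, collapses duplicates, and
#' writes `<sample>_airr.tsv` (collapsed AIRR-style records) plus
#' `<sample>_rejections.tsv` and a manifest. Boundary counts (input,
#' filtered, annotated, productive, unique) are logged.
#'
#' @param config named list or config file path. Keys: `reads`,
#'   `reference`, `out_dir`, optional `sample_id` and filter/floor
#'   overrides.
#' @return invisibly, output paths plus the collapsed table and counts.
#' @export
cmd_annotate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_config(config, "annotate")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sample_id <- config$sample_id %||%
    sub("\\.(fastq|fq|fasta|fa)$", "", basename(config$reads))
  reference <- read_germline_set(config$reference)
  params <- alignment_params(
    floor_v = config$floor_v %||% 30, floor_j = config$floor_j %||% 30,
    floor_c = config$floor_c %||% 30, floor_d = config$floor_d %||% 12,
    min_mean_q = config$min_mean_q %||% 20,
    min_length = as.integer(config$min_length %||% 100L))
  ann <- annotate_sample(config$reads, reference, params)
  collapsed <- collapse_duplicates(ann$rearrangements)
  counts <- ann$counts
  counts$unique <- nrow(collapsed)
  message(sprintf(
    "annotate %s: input %d | filtered %d | annotated %d | productive %d | unique %d",
    sample_id, counts$input, counts$filtered, counts$annotated,
    counts$productive, counts$unique))
  paths <- list(
    airr = file.path(out_dir, paste0(sample_id, "_airr.tsv")),
    rejections = file.path(out_dir, paste0(sample_id, "_rejections.tsv")))
  meta <- c(stamp_meta(config, NA), sample_id = sample_id,
            vapply(counts, as.character, ""))
  write_airr(collapsed, paths$airr, meta)
  write_tsv_commented(ann$rejections, paths$rejections, meta)
  write_manifest(out_dir, "annotate", config, NA)
  invisible(c(paths, list(collapsed = collapsed, counts = counts)))
}

#' Pipeline stage: per-sample repertoire profiles
#'
#' @param config named list or config file path. Keys: `airr` (one path, a
#'   comma-separated list, or a directory of `*_airr.tsv` files),
#'   `out_dir`, optional `weighting`. Sample ids come from file names.
#' @return invisibly, output paths plus the profile table.
#' @export
cmd_profile <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_config(config, "profile")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  airr <- config$airr
  files <- if (length(airr) == 1L && dir.exists(airr)) {
    list.files(airr, pattern = "_airr\\.tsv$", full.names = TRUE)
  } else {
    trimws(unlist(strsplit(airr, ",")))
  }
  if (length(files) == 0L) stop("no AIRR tables found")
  weighting <- config$weighting %||% "clonotype"
  profiles <- lapply(files, function(f) {
    repertoire_profile(read_airr(f),
                       sample_id = sub("_airr\\.tsv$", "", basename(f)),
                       weighting = weighting)
  })
  tab <- profile_table(profiles)
  paths <- list(profiles_tsv = file.path(out_dir, "profiles.tsv"))
  write_tsv_commented(tab, paths$profiles_tsv,
                      c(stamp_meta(config, NA), weighting = weighting,
                        cdr3_length_convention = "junction aa incl. anchors"))
  for (k in c("V", "D", "J", "C")) {
    mat <- usage_matrix(profiles, k, "gene")
    if (ncol(mat) == 0L) next
    p <- file.path(out_dir, sprintf("usage_%s_gene.tsv", tolower(k)))
    write_tsv_commented(data.frame(sample_id = rownames(mat), mat,
                                   check.names = FALSE), p,
                        stamp_meta(config, NA))
    paths[[paste0("usage_", tolower(k))]] <- p
  }
  write_manifest(out_dir, "profile", config, NA)
  message("profile: ", nrow(tab), " samples, ", ncol(tab) - 1L, " features")
  invisible(c(paths, list(profiles = tab, profile_objects = profiles)))
}

#' Pipeline stage: group comparisons
#'
#' @param config named list or config file path. Keys: `profiles`
#'   (profiles TSV), `metadata` (TSV with `sample_id`, group, optional
#'   `pair_id` and covariates), `out_dir`; optional `design`, `adjust`,
#'   `covariate`, `group_col`, `pair_col`.
#' @return invisibly, output paths plus the comparison table.
#' @export
cmd_compare <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_config(config, "compare")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- read_tsv_commented(config$profiles)
  metadata <- read_tsv_commented(config$metadata)
  design <- config$design %||% "unpaired"
  adjust <- config$adjust %||% "none"
  cmp <- compare_features(profiles, metadata, design = design,
                          adjust = adjust,
                          group_col = config$group_col %||% "group",
                          pair_col = config$pair_col %||% "pair_id")
  paths <- list(comparisons_tsv = file.path(out_dir, "comparisons.tsv"))
  write_tsv_commented(cmp, paths$comparisons_tsv,
                      c(stamp_meta(config, NA), design = design,
                        multiple_testing = adjust))
  out <- list(comparisons = cmp)
  if (!is.null(config$covariate)) {
    cor_tab <- correlate_features(profiles, metadata, config$covariate)
    paths$correlations_tsv <- file.path(out_dir, "correlations.tsv")
    write_tsv_commented(cor_tab, paths$correlations_tsv, stamp_meta(config, NA))
    out$correlations <- cor_tab
  }
  write_manifest(out_dir, "compare", config, NA)
  message("compare: ", nrow(cmp), " features, design ", design,
          ", adjust ", adjust)
  invisible(c(paths, out))
}
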