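# Per-sample repertoire indices ------------------------------------------
#
# The "species" unit for diversity is the collapsed clonotype, with its
# duplicate_count as abundance. Usage and junction summaries expose both
# clonotype weighting (each clonotype once) and read weighting (by
# duplicate_count).

#' Kyte-Doolittle hydropathy values
#'
#' The published per-residue hydropathy constants (Ile +4.5 ... Arg -4.5).
#' @return named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle_table <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Load a residue hydropathy table from two-column text
#'
#' Plain whitespace/tab separated text: residue letter, raw hydropathy
#' value. Values are normalized to `[-1, 1]` by the largest absolute value
#' in the table.
#'
#' @param path file path.
#' @return named numeric vector of raw values.
#' @export
load_hydropathy_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), toupper(df[[1]]))
}

#' Normalized Kyte-Doolittle hydrophobicity of amino-acid strings
#'
#' Mean over residues of raw hydropathy divided by the table's maximum
#' absolute value (4.5 for the standard Kyte-Doolittle scale), so the
#' result lies in `[-1, 1]`: Ile-only strings score +1, Arg-only -1.
#'
#' @param aa character vector of amino-acid strings (20 standard residues).
#' @param table named numeric vector of raw hydropathy values.
#' @return numeric vector of per-string means.
#' @export
kyte_doolittle_index <- function(aa, table = kyte_doolittle_table()) {
  norm <- table / max(abs(table))
  vapply(seq_along(aa), function(k) {
    res <- strsplit(aa[k], "")[[1]]
    bad <- which(!res %in% names(norm))
    if (length(bad)) {
      stop("non-standard residue '", res[bad[1]], "' at position ", bad[1],
           " of '", aa[k], "'")
    }
    mean(norm[res])
  }, 0)
}

#' Shannon diversity index (bits)
#'
#' `-sum_i (n_i/N) log2(n_i/N)` over species abundances.
#'
#' @param counts positive abundances (reads per clonotype).
#' @return Shannon index in bits.
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0L || any(counts <= 0)) {
    stop("counts must be non-empty and positive")
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Inverse Simpson diversity index
#'
#' `1 / sum_i (n_i/N)^2` over species abundances.
#'
#' @param counts positive abundances (reads per clonotype).
#' @return inverse Simpson index (>= 1).
#' @export
simpson_index <- function(counts) {
  if (length(counts) == 0L || any(counts <= 0)) {
    stop("counts must be non-empty and positive")
  }
  p <- counts / sum(counts)
  1 / sum(p^2)
}

usage_weights <- function(table, weighting = c("clonotype", "read")) {
  weighting <- match.arg(weighting)
  if (weighting == "clonotype") rep(1, nrow(table)) else table$duplicate_count
}

#' Segment usage frequencies
#'
#' @param table collapsed rearrangement data frame.
#' @param seg_class one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param level `"gene"` for individual segments, `"family"` to roll genes
#'   up into families (id truncated at the first `-`).
#' @param weighting `"clonotype"` (each clonotype once) or `"read"`
#'   (weighted by `duplicate_count`).
#' @return named numeric vector of frequencies summing to 1 over records
#'   with a call of that class.
#' @export
gene_usage <- function(table, seg_class = "V", level = c("gene", "family"),
                       weighting = c("clonotype", "read")) {
  level <- match.arg(level)
  if (nrow(table) == 0L) stop("no annotated records")
  col <- paste0(tolower(seg_class), "_call")
  w <- usage_weights(table, weighting)
  keep <- !is.na(table[[col]])
  if (!any(keep)) stop("no ", seg_class, " calls in table")
  calls <- table[[col]][keep]
  if (level == "family") calls <- family_of(calls)
  tot <- tapply(w[keep], calls, sum)
  freq <- as.numeric(tot) / sum(w[keep])
  stats::setNames(freq, names(tot))
}

#' Somatic hypermutation rate (percent)
#'
#' Pooled ratio `100 * sum(v_mutations) / sum(v_region_length)` over the
#' selected records (long alignments weigh more, reading the definition
#' "point mutations / total V-gene nucleotides" literally).
#'
#' @param table collapsed rearrangement data frame.
#' @param isotype optional isotype class filter (e.g. `"IGHG"`, matched
#'   against [isotype_class()] of `c_call`).
#' @return SHM rate in percent.
#' @export
shm_rate <- function(table, isotype = NULL) {
  if (!is.null(isotype)) {
    table <- table[!is.na(table$c_call) &
                     isotype_class(table$c_call) == isotype, , drop = FALSE]
  }
  tot <- sum(table$v_region_length)
  if (!isTRUE(tot > 0)) stop("zero total aligned V length")
  100 * sum(table$v_mutations) / tot
}

#' Germline index per record
#'
#' Fraction of junction nucleotides covered by the V, D or J alignments;
#' 1 means a fully germline-encoded junction, low values indicate many
#' N/P nucleotides.
#'
#' @param table rearrangement data frame.
#' @return numeric vector in `[0, 1]`, `NA` where the junction is absent.
#' @export
germline_index <- function(table) {
  ifelse(is.na(table$junction), NA_real_,
         table$germline_junction_nt / nchar(table$junction))
}

#' Sample-level germline index
#'
#' @param table collapsed rearrangement data frame.
#' @param weighting `"clonotype"` or `"read"`.
#' @return weighted mean GI over records with a junction.
#' @export
sample_gi <- function(table, weighting = c("clonotype", "read")) {
  gi <- germline_index(table)
  w <- usage_weights(table, weighting)
  keep <- !is.na(gi)
  if (!any(keep)) return(NA_real_)
  sum(gi[keep] * w[keep]) / sum(w[keep])
}

#' CDR-H3 (junction) length distribution
#'
#' Lengths are amino acids and include both anchor residues (the leading
#' cysteine and the closing tryptophan).
#'
#' @param table collapsed rearrangement data frame.
#' @param isotype optional isotype class filter.
#' @param weighting `"clonotype"` or `"read"`.
#' @return list with `distribution` (named proportions over lengths,
#'   summing to 1) and `mean`.
#' @export
cdr3_length_stats <- function(table, isotype = NULL,
                              weighting = c("clonotype", "read")) {
  if (!is.null(isotype)) {
    table <- table[!is.na(table$c_call) &
                     isotype_class(table$c_call) == isotype, , drop = FALSE]
  }
  w <- usage_weights(table, weighting)
  keep <- !is.na(table$junction_aa) & nzchar(table$junction_aa)
  if (!any(keep)) return(list(distribution = numeric(0), mean = NA_real_))
  len <- nchar(table$junction_aa[keep])
  w <- w[keep]
  tot <- tapply(w, len, sum)
  list(distribution = stats::setNames(as.numeric(tot) / sum(w), names(tot)),
       mean = sum(len * w) / sum(w))
}

weighted_mean_kd <- function(table, weighting) {
  keep <- !is.na(table$junction_aa) & nzchar(table$junction_aa) &
    !grepl("[^ACDEFGHIKLMNPQRSTVWY]", table$junction_aa)
  if (!any(keep)) return(NA_real_)
  w <- usage_weights(table, weighting)[keep]
  kd <- kyte_doolittle_index(table$junction_aa[keep])
  sum(kd * w) / sum(w)
}

#' Per-sample repertoire profile
#'
#' Computes the full feature vector for one sample from its collapsed
#' rearrangement table: gene/family usage per segment class, isotype
#' usage, Shannon and Simpson diversity over clonotype abundances, CDR-H3
#' length (overall and per isotype class), normalized Kyte-Doolittle
#' hydrophobicity, SHM rate, and germline index.
#'
#' @param table collapsed rearrangement data frame.
#' @param sample_id sample label.
#' @param weighting `"clonotype"` or `"read"` weighting for usage and
#'   junction summaries (diversity always uses read abundances per
#'   clonotype).
#' @param productive_only restrict to productive records (default), the
#'   repertoire the study analyses.
#' @return object of class `repertoire_profile`.
#' @export
repertoire_profile <- function(table, sample_id = "S1",
                               weighting = c("clonotype", "read"),
                               productive_only = TRUE) {
  weighting <- match.arg(weighting)
  if (productive_only) table <- table[table$productive, , drop = FALSE]
  if (nrow(table) == 0L) stop("no (productive) records for sample ", sample_id)
  isotypes <- sort(unique(isotype_class(table$c_call[!is.na(table$c_call)])))
  per_iso <- function(f) {
    vals <- lapply(isotypes, function(i) tryCatch(f(i), error = function(e) NA_real_))
    stats::setNames(unlist(vals), isotypes)
  }
  usage <- lapply(stats::setNames(SEG_CLASSES, SEG_CLASSES), function(k) {
    ok <- tryCatch(list(
      gene = gene_usage(table, k, "gene", weighting),
      family = gene_usage(table, k, "family", weighting)),
      error = function(e) list(gene = numeric(0), family = numeric(0)))
    ok
  })
  iso_w <- usage_weights(table, weighting)
  iso_keep <- !is.na(table$c_call)
  iso_tot <- tapply(iso_w[iso_keep], isotype_class(table$c_call[iso_keep]), sum)
  structure(list(
    sample_id = sample_id,
    weighting = weighting,
    usage = usage,
    isotype_usage = stats::setNames(as.numeric(iso_tot) / sum(iso_w[iso_keep]),
                                    names(iso_tot)),
    shannon = shannon_index(table$duplicate_count),
    simpson = simpson_index(table$duplicate_count),
    cdr3_length = c(list(all = cdr3_length_stats(table, NULL, weighting)),
                    lapply(stats::setNames(isotypes, isotypes),
                           function(i) cdr3_length_stats(table, i, weighting))),
    hydrophobicity = c(all = weighted_mean_kd(table, weighting),
                       per_iso(function(i) {
                         sub <- table[isotype_class(table$c_call) == i, , drop = FALSE]
                         weighted_mean_kd(sub, weighting)
                       })),
    shm_rate = c(all = tryCatch(shm_rate(table), error = function(e) NA_real_),
                 per_iso(function(i) shm_rate(table, i))),
    gi = sample_gi(table, weighting),
    clonotype_count = nrow(table),
    read_count = sum(table$duplicate_count)),
    class = "repertoire_profile")
}

#' @export
print.repertoire_profile <- function(x, ...) {
  cat("repertoire_profile '", x$sample_id, "': ", x$clonotype_count,
      " clonotypes / ", x$read_count, " reads\n", sep = "")
  cat(sprintf("  shannon %.3f bits, simpson %.3f, gi %.3f\n",
              x$shannon, x$simpson, x$gi))
  cat(sprintf("  CDR-H3 mean %.2f aa, hydrophobicity %.3f, SHM %.3f%%\n",
              x$cdr3_length$all$mean, x$hydrophobicity[["all"]],
              x$shm_rate[["all"]]))
  invisible(x)
}

profile_features <- function(p) {
  named <- function(prefix, v) {
    if (length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(as.numeric(v), paste0(prefix, ":", names(v)))
  }
  iso <- setdiff(names(p$cdr3_length), "all")
  c(named("v_gene", p$usage$V$gene), named("v_family", p$usage$V$family),
    named("d_gene", p$usage$D$gene), named("j_gene", p$usage$J$gene),
    named("c_gene", p$usage$C$gene), named("isotype", p$isotype_usage),
    shannon = p$shannon, simpson = p$simpson,
    `cdr3_length:all` = p$cdr3_length$all$mean,
    stats::setNames(vapply(iso, function(i) p$cdr3_length[[i]]$mean, 0),
                    paste0("cdr3_length:", iso)),
    named("hydrophobicity", p$hydrophobicity),
    named("shm_rate", p$shm_rate),
    gi = p$gi,
    clonotype_count = p$clonotype_count, read_count = p$read_count)
}

#' Flatten repertoire profiles into a feature table
#'
#' One row per sample; columns are `feature:level` names (e.g.
#' `v_gene:IGHV3-1`, `shm_rate:IGHG`, `shannon`). Usage features absent in
#' a sample are zero-filled; other missing features are `NA`.
#'
#' @param profiles list of `repertoire_profile` objects.
#' @return data frame with a `sample_id` column.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "repertoire_profile")) profiles <- list(profiles)
  feats <- lapply(profiles, profile_features)
  cols <- unique(unlist(lapply(feats, names)))
  usage_like <- grepl("^(v_gene|v_family|d_gene|j_gene|c_gene|isotype):", cols)
  mat <- matrix(NA_real_, nrow = length(feats), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (k in seq_along(feats)) mat[k, names(feats[[k]])] <- feats[[k]]
  if (any(usage_like)) {
    sub <- mat[, usage_like, drop = FALSE]
    sub[is.na(sub)] <- 0
    mat[, usage_like] <- sub
  }
  out <- data.frame(sample_id = vapply(profiles, `[[`, "", "sample_id"),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Usage matrix (samples x segments)
#'
#' Numeric export suitable for heat maps of per-sample usage frequencies.
#'
#' @param profiles list of `repertoire_profile` objects.
#' @param seg_class segment class.
#' @param level `"gene"` or `"family"`.
#' @return numeric matrix, rows = samples, columns = union of observed
#'   segments (absent = 0).
#' @export
usage_matrix <- function(profiles, seg_class = "V",
                         level = c("gene", "family")) {
  level <- match.arg(level)
  if (inherits(profiles, "repertoire_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) p$usage[[seg_class]][[level]])
  cols <- sort(unique(unlist(lapply(rows, names))))
  mat <- matrix(0, nrow = length(rows), ncol = length(cols),
                dimnames = list(vapply(profiles, `[[`, "", "sample_id"), cols))
  for (k in seq_along(rows)) mat[k, names(rows[[k]])] <- rows[[k]]
  mat
}
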