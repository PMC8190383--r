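# Group comparison statistics --------------------------------------------
#
# Rank-based tests throughout, two-sided, matching the study design:
# Mann-Whitney U for unpaired contrasts, Wilcoxon signed rank for paired
# pre/post designs, Spearman correlation against continuous covariates.
# The machinery delegates to R's stats engine (wilcox.test, cor.test);
# exact null distributions are used at small n without ties, normal
# approximation with tie and continuity correction otherwise.

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when `n_x * n_y <= 400` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("empty group")
  if (all(c(x, y) == c(x, y)[1])) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values equal)"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Wilcoxon signed rank test (two-sided)
#'
#' Zero differences are dropped; midranks on absolute differences. Exact
#' null when the effective n is <= 25 with no tied magnitudes, normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y paired numeric vectors (before/after), equal length.
#' @return list with `statistic` (W, positive-rank sum), `p_value`,
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("degenerate pairing: all differences are zero")
  exact <- length(d) <= 25L && anyDuplicated(abs(d)) == 0L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_effective = length(d),
       method = if (exact) "exact" else "normal approximation")
}

#' Spearman rank correlation
#'
#' rho is the product-moment correlation of midranks; the p-value uses the
#' asymptotic t approximation.
#'
#' @param x,y numeric vectors (>= 3 pairs after removing missing values).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero rank variance (constant vector)")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Feature-wise group comparison table
#'
#' Runs one rank test per feature across a two-group contrast: the
#' Mann-Whitney U test for `design = "unpaired"`, the Wilcoxon signed rank
#' test for `design = "paired"` (pairs matched through `pair_id`).
#' Features identical across all samples get p = 1. Usage-type features
#' are zero-filled (absence of a segment is biological signal); other
#' features drop samples with missing values.
#'
#' @param profiles data frame from [profile_table()] (needs `sample_id`).
#' @param metadata data frame with `sample_id`, a group column, and for
#'   paired designs a `pair_id` column.
#' @param design `"unpaired"` or `"paired"`.
#' @param features character vector of feature columns (default: all
#'   numeric columns except bookkeeping counts).
#' @param adjust `"none"` (the study's choice) or `"bh"` for
#'   Benjamini-Hochberg adjusted p-values in `adjusted_p`.
#' @param group_col,pair_col metadata column names.
#' @return data frame sorted by p: `feature`, `contrast`, `statistic`,
#'   `p_value`, `direction` (sign of median difference, first group minus
#'   second), `adjusted_p`, `n1`, `n2`.
#' @export
compare_features <- function(profiles, metadata,
                             design = c("unpaired", "paired"),
                             features = NULL,
                             adjust = c("none", "bh"),
                             group_col = "group", pair_col = "pair_id") {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  stopifnot("sample_id" %in% names(profiles),
            "sample_id" %in% names(metadata),
            group_col %in% names(metadata))
  m <- match(profiles$sample_id, metadata$sample_id)
  if (anyNA(m)) {
    stop("samples missing from metadata: ",
         paste(profiles$sample_id[is.na(m)], collapse = ", "))
  }
  group <- as.character(metadata[[group_col]][m])
  levels <- unique(group)
  if (length(levels) != 2L) stop("need exactly two groups, got: ",
                                 paste(levels, collapse = ", "))
  g1 <- group == levels[1]; g2 <- group == levels[2]
  contrast <- paste(levels[1], "vs", levels[2])

  if (is.null(features)) {
    numeric_cols <- names(profiles)[vapply(profiles, is.numeric, NA)]
    features <- setdiff(numeric_cols, c("clonotype_count", "read_count"))
  }
  missing_feat <- setdiff(features, names(profiles))
  if (length(missing_feat)) {
    stop("features absent from profiles: ", paste(missing_feat, collapse = ", "))
  }

  pair_of <- NULL
  if (design == "paired") {
    if (!pair_col %in% names(metadata)) stop("paired design needs a '",
                                             pair_col, "' column")
    pair_of <- as.character(metadata[[pair_col]][m])
    p1 <- pair_of[g1]; p2 <- pair_of[g2]
    orphans <- c(setdiff(p1, p2), setdiff(p2, p1))
    if (length(orphans) || anyDuplicated(p1) || anyDuplicated(p2)) {
      stop("incomplete pairing; orphan pair ids: ",
           paste(unique(orphans), collapse = ", "))
    }
  }

  usage_like <- grepl("^(v_gene|v_family|d_gene|j_gene|c_gene|isotype):",
                      features)
  rows <- lapply(seq_along(features), function(k) {
    f <- features[k]
    vals <- profiles[[f]]
    if (usage_like[k]) vals[is.na(vals)] <- 0
    x <- vals[g1]; y <- vals[g2]
    if (design == "paired") {
      ord <- order(pair_of[g1]); x <- x[ord]
      ord <- order(pair_of[g2]); y <- y[ord]
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    if (length(x) < 1L || length(y) < 1L || anyNA(c(x, y))) {
      return(data.frame(feature = f, contrast = contrast,
                        statistic = NA_real_, p_value = NA_real_,
                        direction = NA_real_, n1 = length(x), n2 = length(y),
                        stringsAsFactors = FALSE))
    }
    res <- if (all(c(x, y) == c(x, y)[1])) {
      list(statistic = if (design == "unpaired") length(x) * length(y) / 2 else 0,
           p_value = 1)
    } else if (design == "unpaired") {
      mann_whitney_u(x, y)
    } else {
      tryCatch(wilcoxon_signed_rank(x, y),
               error = function(e) list(statistic = 0, p_value = 1))
    }
    data.frame(feature = f, contrast = contrast,
               statistic = res$statistic, p_value = res$p_value,
               direction = sign(stats::median(x) - stats::median(y)),
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "bh") {
    stats::p.adjust(out$p_value, method = "BH")
  } else NA_real_
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  out
}

#' Correlate features with a continuous covariate
#'
#' Spearman correlation of every feature against a metadata covariate
#' (e.g. an autoantibody titer).
#'
#' @param profiles data frame from [profile_table()].
#' @param metadata data frame with `sample_id` and the covariate column.
#' @param covariate covariate column name.
#' @param features feature columns (default as in [compare_features()]).
#' @return data frame: `feature`, `covariate`, `rho`, `p_value`, `n`.
#' @export
correlate_features <- function(profiles, metadata, covariate,
                               features = NULL) {
  stopifnot(covariate %in% names(metadata))
  m <- match(profiles$sample_id, metadata$sample_id)
  if (anyNA(m)) stop("samples missing from metadata")
  z <- as.numeric(metadata[[covariate]][m])
  if (is.null(features)) {
    numeric_cols <- names(profiles)[vapply(profiles, is.numeric, NA)]
    features <- setdiff(numeric_cols, c("clonotype_count", "read_count"))
  }
  rows <- lapply(features, function(f) {
    res <- tryCatch(spearman_cor(profiles[[f]], z), error = function(e) {
      list(rho = NA_real_, p_value = NA_real_, n = sum(!is.na(profiles[[f]]) & !is.na(z)))
    })
    data.frame(feature = f, covariate = covariate, rho = res$rho,
               p_value = res$p_value, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}
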