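#' @useDynLib ighrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Germline IGH segment references ---------------------------------------
#
# A germline set holds the reference V/D/J/C gene segments an annotator
# aligns reads against. V and J segments carry a CDR-H3 anchor: the 1-based
# offset of the first base of the conserved codon (2nd-CYS TGT/TGC for V,
# J-TRP TGG for J). All coordinates in this package are 1-based, the R
# convention.

SEG_CLASSES <- c("V", "D", "J", "C")

CANONICAL_ISOTYPES <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1",
                        "IGHG2", "IGHG4", "IGHE", "IGHA2", "IGHGP")

#' Derive the gene family from a segment id
#'
#' The family is the id truncated at the first `-`, after stripping any
#' allele suffix (`*01` etc.), so `IGHV3-30-3*02` maps to `IGHV3`.
#'
#' @param id character vector of segment ids.
#' @return character vector of family names.
#' @export
family_of <- function(id) {
  id <- sub("\\*.*$", "", id)
  sub("-.*$", "", id)
}

#' Construct a single germline segment
#'
#' @param id segment name, e.g. `"IGHV3-23"`.
#' @param seg_class one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param sequence ungapped uppercase nucleotide string over ACGT.
#' @param anchor for V and J, the 1-based offset of the first base of the
#'   conserved codon (2nd-CYS for V, J-TRP for J); `NA` for D and C.
#' @return An object of class `germline_segment`.
#' @export
germline_segment <- function(id, seg_class, sequence, anchor = NA_integer_) {
  seg_class <- match.arg(seg_class, SEG_CLASSES)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("segment '", id, "': empty sequence")
  if (grepl("[^ACGT]", sequence)) {
    stop("segment '", id, "': sequence contains non-ACGT characters")
  }
  anchor <- as.integer(anchor)
  if (seg_class %in% c("V", "J")) {
    if (is.na(anchor)) stop("segment '", id, "': ", seg_class,
                            " segment requires an anchor")
    if (anchor < 1L || anchor + 2L > nchar(sequence)) {
      stop("segment '", id, "': anchor outside sequence")
    }
    if ((anchor - 1L) %% 3L != 0L) {
      stop("segment '", id, "': anchor not in the segment reading frame")
    }
    codon <- substr(sequence, anchor, anchor + 2L)
    if (seg_class == "V" && !codon %in% c("TGT", "TGC")) {
      stop("segment '", id, "': anchor codon '", codon,
           "' is not a cysteine codon (TGT/TGC)")
    }
    if (seg_class == "J" && codon != "TGG") {
      stop("segment '", id, "': anchor codon '", codon,
           "' is not the tryptophan codon (TGG)")
    }
  } else {
    anchor <- NA_integer_
  }
  structure(list(id = id, seg_class = seg_class, family = family_of(id),
                 sequence = sequence, anchor = anchor),
            class = "germline_segment")
}

#' CDR-H3 anchor position of a segment
#'
#' @param segment a `germline_segment`.
#' @return 1-based anchor offset for V and J segments; `NA` for D and C.
#' @export
anchor_of <- function(segment) {
  stopifnot(inherits(segment, "germline_segment"))
  segment$anchor
}

#' Build a germline set from segments
#'
#' @param segments list of `germline_segment` objects.
#' @return An object of class `germline_set`.
#' @export
germline_set <- function(segments) {
  ids <- vapply(segments, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate segment id(s): ", paste(unique(dup), collapse = ", "))
  names(segments) <- ids
  structure(list(segments = segments), class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  cls <- vapply(x$segments, `[[`, "", "seg_class")
  cat("germline_set:", length(x$segments), "segments (",
      paste(sprintf("%s=%d", SEG_CLASSES, vapply(SEG_CLASSES, function(k) sum(cls == k), 0L)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Segments of one class as a named sequence vector
#'
#' @param set a `germline_set`.
#' @param seg_class segment class.
#' @return named character vector (id -> sequence).
#' @export
class_sequences <- function(set, seg_class) {
  stopifnot(inherits(set, "germline_set"))
  keep <- vapply(set$segments, function(s) s$seg_class == seg_class, NA)
  vapply(set$segments[keep], `[[`, "", "sequence")
}

class_anchors <- function(set, seg_class) {
  keep <- vapply(set$segments, function(s) s$seg_class == seg_class, NA)
  vapply(set$segments[keep], function(s) s$anchor, 0L)
}

#' Combine germline set fragments
#' @param ... `germline_set` objects.
#' @return a merged `germline_set`; duplicate ids are an error.
#' @export
merge_germline_sets <- function(...) {
  germline_set(do.call(c, lapply(list(...), `[[`, "segments")))
}

# Locate the J-TRP anchor by scanning for the canonical W-G-x-G motif.
# Returns the 1-based nt offset of the W codon, or NA.
find_j_anchor <- function(sequence) {
  for (frame in 0:2) {
    aa <- translate_nt(substr(sequence, frame + 1L, nchar(sequence)))
    hit <- regexpr("WG.G", aa)
    if (hit > 0L) return(frame + 3L * (as.integer(hit) - 1L) + 1L)
  }
  NA_integer_
}

# IMGT unique numbering places the V 2nd-CYS at codon 104 of the gapped
# alignment; gap columns are '.' characters.
IMGT_CYS104_GAPPED_NT <- (104L - 1L) * 3L + 1L

parse_fasta_headers <- function(headers) {
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  anchors <- rep(NA_integer_, length(headers))
  hit <- regmatches(headers, regexpr("anchor=[0-9]+", headers))
  has <- grepl("anchor=[0-9]+", headers)
  anchors[has] <- as.integer(sub("anchor=", "", hit))
  list(ids = ids, anchors = anchors)
}

#' Load one class of germline segments from FASTA
#'
#' Two dialects are supported. `"plain"` expects ungapped sequences; an
#' `anchor=<pos>` token in the header (as written by
#' [write_germline_fasta()]) sets the anchor, otherwise the anchor is
#' located by sequence scan (rightmost in-frame TGT/TGC for V, the W-G-x-G
#' motif for J). `"imgt_gapped"` expects IMGT gapped V sequences (`.` gap
#' characters); the 2nd-CYS is taken at IMGT codon 104 and mapped onto the
#' ungapped sequence.
#'
#' Records containing `N` are rejected with a warning (mutation counting
#' must be exact); other non-ACGT characters are a hard error.
#'
#' @param path FASTA file.
#' @param seg_class class of every record in the file.
#' @param dialect `"plain"` or `"imgt_gapped"`.
#' @return a `germline_set` containing the loaded segments.
#' @export
load_germline_fasta <- function(path, seg_class,
                                dialect = c("plain", "imgt_gapped")) {
  dialect <- match.arg(dialect)
  seg_class <- match.arg(seg_class, SEG_CLASSES)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in '", path, "'")
  hdr <- parse_fasta_headers(names(recs))
  if (anyDuplicated(hdr$ids)) {
    stop("duplicate segment id(s): ",
         paste(unique(hdr$ids[duplicated(hdr$ids)]), collapse = ", "))
  }
  segs <- list()
  for (k in seq_along(recs)) {
    seq <- toupper(as.character(recs[[k]]))
    id <- hdr$ids[k]
    anchor <- hdr$anchors[k]
    if (dialect == "imgt_gapped") {
      if (seg_class == "V") {
        gapped_prefix <- substr(seq, 1L, IMGT_CYS104_GAPPED_NT - 1L)
        anchor <- nchar(gsub("\\.", "", gapped_prefix)) + 1L
      }
      seq <- gsub("\\.", "", seq)
    }
    if (grepl("N", seq, fixed = TRUE)) {
      warning("segment '", id, "' contains N; record rejected")
      next
    }
    if (grepl("[^ACGT]", seq)) {
      stop("segment '", id, "': sequence contains non-ACGTN characters")
    }
    if (seg_class == "V" && is.na(anchor) && dialect == "plain") {
      cys <- gregexpr("TG[TC]", seq)[[1]]
      cys <- cys[(cys - 1L) %% 3L == 0L]
      if (length(cys) == 0L) stop("segment '", id, "': no in-frame cysteine codon")
      anchor <- max(cys)
    }
    if (seg_class == "J" && is.na(anchor)) {
      anchor <- find_j_anchor(seq)
      if (is.na(anchor)) stop("segment '", id, "': no W-G-x-G motif found")
    }
    segs[[length(segs) + 1L]] <- germline_segment(id, seg_class, seq, anchor)
  }
  if (length(segs) == 0L) stop("no usable records in '", path, "'")
  germline_set(segs)
}

#' Write a germline set to FASTA
#'
#' Headers carry `class=` and (for V/J) `anchor=` tokens so that a written
#' set round-trips losslessly through [read_germline_set()].
#'
#' @param set a `germline_set`.
#' @param path output FASTA path.
#' @export
write_germline_fasta <- function(set, path) {
  stopifnot(inherits(set, "germline_set"))
  lines <- unlist(lapply(set$segments, function(s) {
    hdr <- sprintf(">%s class=%s", s$id, s$seg_class)
    if (!is.na(s$anchor)) hdr <- sprintf("%s anchor=%d", hdr, s$anchor)
    c(hdr, s$sequence)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-class germline set written by [write_germline_fasta()]
#' @param path FASTA with `class=` header tokens.
#' @return a `germline_set`.
#' @export
read_germline_set <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in '", path, "'")
  hdr <- parse_fasta_headers(names(recs))
  cls <- regmatches(names(recs), regexpr("class=[VDJC]", names(recs)))
  if (length(cls) != length(recs)) stop("missing class= token in a header")
  cls <- sub("class=", "", cls)
  segs <- lapply(seq_along(recs), function(k) {
    germline_segment(hdr$ids[k], cls[k], as.character(recs[[k]]), hdr$anchors[k])
  })
  germline_set(segs)
}

# identity = 1 - levenshtein/max(length); a crude but monotone global
# similarity adequate for enforcing a divergence floor between synthetic
# segments.
pairwise_identity <- function(a, b) {
  1 - as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

# Sample a stop-free coding sequence of n_codons codons.
NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_coding_nt <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Build a synthetic germline reference
#'
#' Generates a random but structurally faithful IGH reference for testing
#' and simulation: every V segment is stop-free in its reading frame and
#' carries a TGT 2nd-CYS codon 9 nt before its 3' end; every J segment
#' carries the TGG/W-G-x-G motif at its anchor; C segments take the
#' canonical human isotype names. All pairwise identities within a class
#' are forced to at most `1 - min_pairwise_divergence`.
#'
#' @param n_v,n_d,n_j,n_c segment counts per class (all >= 1).
#' @param v_length V segment length in nt (multiple of 3).
#' @param min_pairwise_divergence minimum pairwise divergence within a
#'   class, in `[0, 1)`.
#' @param seed integer seed; the build is fully deterministic given it.
#' @param d_length,j_length,c_length lengths of D/J/C segments (nt).
#' @param max_tries resampling budget per segment for the divergence
#'   constraint.
#' @return a `germline_set`.
#' @export
build_synthetic_reference <- function(n_v, n_d = 8L, n_j = 6L, n_c = 10L,
                                      v_length = 291L,
                                      min_pairwise_divergence = 0.15,
                                      seed = 1L,
                                      d_length = 21L, j_length = 48L,
                                      c_length = 120L, max_tries = 50L) {
  stopifnot(n_v >= 1L, n_d >= 1L, n_j >= 1L, n_c >= 1L,
            min_pairwise_divergence >= 0, min_pairwise_divergence < 1,
            v_length %% 3L == 0L, v_length >= 30L)
  max_ident <- 1 - min_pairwise_divergence
  with_seed(seed, {
    draw_class <- function(n, gen) {
      out <- character(0)
      for (k in seq_len(n)) {
        for (try in seq_len(max_tries)) {
          cand <- gen()
          ok <- all(vapply(out, function(x) pairwise_identity(cand, x) <= max_ident, NA))
          if (ok) break
          cand <- NULL
        }
        if (is.null(cand)) {
          stop("could not satisfy min_pairwise_divergence = ",
               min_pairwise_divergence, " after ", max_tries,
               " tries; lower the divergence requirement")
        }
        out <- c(out, cand)
      }
      out
    }
    v_anchor <- v_length - 8L   # 1-based; codon occupies the 9th..7th last nt
    gen_v <- function() {
      s <- random_coding_nt(v_length %/% 3L)
      substr(s, v_anchor, v_anchor + 2L) <- "TGT"
      s
    }
    # J segments code FR4: stop-free in the reading frame set by the TRP
    # anchor (otherwise every junction using that J would carry an
    # in-frame stop just before the W)
    j_anchor <- 16L             # W codon; W-G-x-G motif spans nt 16..27
    gen_j <- function() {
      s <- random_coding_nt(j_length %/% 3L)
      substr(s, j_anchor, j_anchor + 11L) <- paste0(
        "TGG", sample(c("GGA", "GGT", "GGC", "GGG"), 1),
        sample(NONSTOP_CODONS, 1), sample(c("GGA", "GGT", "GGC", "GGG"), 1))
      s
    }
    v_seq <- draw_class(n_v, gen_v)
    d_seq <- draw_class(n_d, function() random_nt(d_length))
    j_seq <- draw_class(n_j, gen_j)
    c_seq <- draw_class(n_c, function() random_nt(c_length))

    v_ids <- sprintf("IGHV%d-%d", ((seq_len(n_v) - 1L) %% 7L) + 1L,
                     ((seq_len(n_v) - 1L) %/% 7L) + 1L)
    d_ids <- sprintf("IGHD%d-%d", ((seq_len(n_d) - 1L) %% 7L) + 1L,
                     ((seq_len(n_d) - 1L) %/% 7L) + 1L)
    j_ids <- sprintf("IGHJ%d", seq_len(n_j))
    c_ids <- if (n_c <= length(CANONICAL_ISOTYPES)) {
      CANONICAL_ISOTYPES[seq_len(n_c)]
    } else {
      c(CANONICAL_ISOTYPES, sprintf("IGHC%d", seq_len(n_c - length(CANONICAL_ISOTYPES))))
    }

    segs <- c(
      mapply(germline_segment, v_ids, "V", v_seq, v_anchor, SIMPLIFY = FALSE),
      mapply(germline_segment, d_ids, "D", d_seq, SIMPLIFY = FALSE),
      mapply(germline_segment, j_ids, "J", j_seq, j_anchor, SIMPLIFY = FALSE),
      mapply(germline_segment, c_ids, "C", c_seq, SIMPLIFY = FALSE))
    germline_set(segs)
  })
}
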