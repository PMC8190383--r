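# Read annotation --------------------------------------------------------
#
# Raw reads -> rearrangement records: quality filter, V/D/J/C assignment by
# affine-gap local alignment (own Smith-Waterman core in src/), translation
# in the frame set by the V anchor, productive filtering, CDR-H3 junction
# extraction (2nd-CYS .. J-TRP inclusive), and V-region mutation counting
# with the junction window excluded (junction mismatches conflate N
# nucleotides with SHM).

#' Annotation parameter set
#'
#' @param match,mismatch,gap_open,gap_extend local-alignment scores; a gap
#'   of length k costs `gap_open + k * gap_extend`.
#' @param floor_v,floor_j,floor_c,floor_d minimum alignment score for a
#'   call of that class; below the floor the segment is "not identified".
#' @param min_mean_q,min_length quality-filter thresholds (mean Phred,
#'   read length).
#' @return list of class `align_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -2,
                             gap_open = 5, gap_extend = 1,
                             floor_v = 30, floor_j = 30, floor_c = 30,
                             floor_d = 12,
                             min_mean_q = 20, min_length = 100L) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, floor_v = floor_v,
                 floor_j = floor_j, floor_c = floor_c, floor_d = floor_d,
                 min_mean_q = min_mean_q, min_length = as.integer(min_length)),
            class = "align_params")
}

#' Filter reads on mean base quality and length
#'
#' @param reads data frame with `read_id`, `sequence`, `quality`
#'   (Phred+33), e.g. from [read_fastq()].
#' @param min_mean_q minimum mean Phred quality.
#' @param min_length minimum read length (nt).
#' @return list with `reads` (retained rows), `kept`, `dropped`.
#' @export
quality_filter <- function(reads, min_mean_q = 20, min_length = 100L) {
  mean_q <- vapply(reads$quality,
                   function(q) mean(utf8ToInt(q)) - 33, 0,
                   USE.NAMES = FALSE)
  keep <- mean_q >= min_mean_q & nchar(reads$sequence) >= min_length
  list(reads = reads[keep, , drop = FALSE],
       kept = sum(keep), dropped = sum(!keep))
}

#' Align a read against a class of candidate segments
#'
#' Every candidate is aligned with the affine-gap Smith-Waterman core; the
#' highest-scoring candidate wins, ties broken by fewer mismatches, then by
#' lexicographically smallest id. Returns `NULL` when the best score is
#' below `floor`.
#'
#' @param read nucleotide string.
#' @param candidates named character vector (segment id -> sequence).
#' @param params an [alignment_params()] list.
#' @param floor minimum acceptable score.
#' @return `NULL`, or a segment call: list with `segment_id`, `score`,
#'   `read_start`, `read_end`, `seg_start`, `seg_end` (1-based, closed),
#'   `mismatches`, and the aligned column maps `read_pos` / `seg_pos`.
#' @export
align_segment <- function(read, candidates, params = alignment_params(),
                          floor = 0) {
  stopifnot(length(candidates) >= 1L, !is.null(names(candidates)))
  scores <- .sw_score_matrix(read, unname(candidates),
                             params$match, params$mismatch,
                             params$gap_open, params$gap_extend)[1L, ]
  best <- max(scores)
  if (best < floor) return(NULL)
  tied <- which(scores == best)
  tbs <- lapply(tied, function(k) {
    .sw_traceback(read, unname(candidates[k]),
                  params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  })
  mism <- vapply(tbs, `[[`, 0L, "mismatches")
  ids <- names(candidates)[tied]
  ord <- order(mism, ids)
  pick <- ord[1L]
  tb <- tbs[[pick]]
  list(segment_id = ids[pick], score = tb$score,
       read_start = tb$read_start, read_end = tb$read_end,
       seg_start = tb$seg_start, seg_end = tb$seg_end,
       mismatches = tb$mismatches,
       read_pos = tb$read_pos, seg_pos = tb$seg_pos)
}

# offset a call made on substr(read, shift + 1, ...) back onto read coords
shift_call <- function(call, shift) {
  if (is.null(call)) return(NULL)
  call$read_start <- call$read_start + shift
  call$read_end <- call$read_end + shift
  call$read_pos <- call$read_pos + shift
  call
}

# Map a 1-based segment position onto the read through the aligned columns,
# extrapolating past the alignment ends at the local (gap-adjusted) offset.
# Returns NA when the mapped position falls outside the read.
map_seg_to_read <- function(call, seg_position, read_len) {
  hit <- match(seg_position, call$seg_pos)
  pos <- if (!is.na(hit)) {
    call$read_pos[hit]
  } else {
    k <- which.min(abs(call$seg_pos - seg_position))
    call$read_pos[k] + (seg_position - call$seg_pos[k])
  }
  if (is.na(pos) || pos < 1L || pos > read_len) NA_integer_ else as.integer(pos)
}

#' Annotate one read against a germline reference
#'
#' V is aligned over the whole read; J is sought 3' of the V alignment, C
#' 3' of the J alignment, and D only within the inter-anchor window. Reads
#' lacking any of V, J or C are rejected (rejections are data, not
#' errors). The junction is the span from the first base of the V 2nd-CYS
#' codon through the last base of the J TRP codon; it is reported absent,
#' with a note, when either anchor codon is destroyed.
#'
#' @param read_seq nucleotide string.
#' @param reference a `germline_set` with V, J and C segments.
#' @param params an [alignment_params()] list.
#' @param read_id identifier copied into the record.
#' @return list with `status` (`"ok"` or a rejection reason) and, when ok,
#'   `rearrangement` (one-row data frame) and the four `calls`.
#' @export
annotate_read <- function(read_seq, reference, params = alignment_params(),
                          read_id = "read") {
  annotate_read_impl(read_seq, ref_candidates(reference), params, read_id)
}

# candidate sequences and anchors per class, extracted once per sample
ref_candidates <- function(reference) {
  stopifnot(inherits(reference, "germline_set"))
  list(seqs = lapply(stats::setNames(SEG_CLASSES, SEG_CLASSES),
                     function(k) class_sequences(reference, k)),
       anchors = lapply(stats::setNames(c("V", "J"), c("V", "J")),
                        function(k) class_anchors(reference, k)))
}

annotate_read_impl <- function(read_seq, cand, params, read_id) {
  n <- nchar(read_seq)
  v_seqs <- cand$seqs$V
  v <- align_segment(read_seq, v_seqs, params, params$floor_v)
  if (is.null(v)) return(list(status = "no V"))

  j_shift <- v$read_end
  j <- NULL
  if (n - j_shift >= 6L) {
    j <- shift_call(align_segment(substr(read_seq, j_shift + 1L, n),
                                  cand$seqs$J, params, params$floor_j), j_shift)
  }
  if (is.null(j)) return(list(status = "no J"))

  c_shift <- j$read_end
  cc <- NULL
  if (n - c_shift >= 6L) {
    cc <- shift_call(align_segment(substr(read_seq, c_shift + 1L, n),
                                   cand$seqs$C, params, params$floor_c), c_shift)
  }
  if (is.null(cc)) return(list(status = "no C"))

  v_anchor <- cand$anchors$V[[v$segment_id]]
  j_anchor <- cand$anchors$J[[j$segment_id]]
  vA <- map_seg_to_read(v, v_anchor, n)
  jT <- map_seg_to_read(j, j_anchor, n)

  junction <- NA_character_; junction_aa <- NA_character_
  junction_note <- ""
  if (is.na(vA)) {
    junction_note <- "V anchor not mappable"
  } else if (!substr(read_seq, vA, vA + 2L) %in% c("TGT", "TGC")) {
    junction_note <- "lost 2nd-CYS"
  } else if (is.na(jT) || jT + 2L > n) {
    junction_note <- "J anchor not mappable"
  } else if (substr(read_seq, jT, jT + 2L) != "TGG") {
    junction_note <- "lost J-TRP"
  } else if (jT <= vA) {
    junction_note <- "anchors out of order"
  } else {
    junction <- substr(read_seq, vA, jT + 2L)
    junction_aa <- translate_nt(junction)
  }

  # D: best-effort, only inside the inter-anchor window
  d <- NULL
  if (!is.na(vA) && !is.na(jT) && jT - 1L >= vA + 3L + 4L) {
    d_seqs <- cand$seqs$D
    if (length(d_seqs)) {
      d_shift <- vA + 2L
      d <- shift_call(align_segment(substr(read_seq, d_shift + 1L, jT - 1L),
                                    d_seqs, params, params$floor_d), d_shift)
    }
  }

  # V-region mutation counting, junction window excluded
  v_cols <- if (!is.na(vA)) which(v$read_pos < vA) else seq_along(v$read_pos)
  v_region_length <- length(v_cols)
  v_mutations <- if (v_region_length) {
    read_chars <- substring(read_seq, v$read_pos[v_cols], v$read_pos[v_cols])
    seg <- v_seqs[[v$segment_id]]
    seg_chars <- substring(seg, v$seg_pos[v_cols], v$seg_pos[v_cols])
    sum(read_chars != seg_chars)
  } else 0L

  # translation in the V-anchor frame; productive = in-frame junction and
  # no stop through the junction end
  sequence_aa <- NA_character_
  productive <- FALSE
  if (!is.na(vA)) {
    frame_start <- ((vA - 1L) %% 3L) + 1L
    sequence_aa <- translate_nt(substr(read_seq, frame_start, n))
    if (!is.na(junction)) {
      prefix_aa <- translate_nt(substr(read_seq, frame_start, jT + 2L))
      productive <- nchar(junction) %% 3L == 0L &&
        !grepl("*", prefix_aa, fixed = TRUE)
    }
  }

  # junction nucleotides covered by the V, D or J alignments
  germline_junction_nt <- NA_integer_
  if (!is.na(junction)) {
    jn_span <- vA:(jT + 2L)
    covered <- logical(length(jn_span))
    for (call in list(v, d, j)) {
      if (is.null(call)) next
      covered <- covered | (jn_span >= call$read_start & jn_span <= call$read_end)
    }
    germline_junction_nt <- sum(covered)
  }

  rearr <- data.frame(
    sequence_id = read_id,
    v_call = v$segment_id,
    d_call = if (is.null(d)) NA_character_ else d$segment_id,
    j_call = j$segment_id,
    c_call = cc$segment_id,
    junction = junction, junction_aa = junction_aa,
    junction_note = junction_note,
    productive = productive,
    duplicate_count = 1L,
    v_mutations = as.integer(v_mutations),
    v_region_length = as.integer(v_region_length),
    germline_junction_nt = germline_junction_nt,
    sequence_aa = sequence_aa,
    stringsAsFactors = FALSE)
  list(status = "ok", rearrangement = rearr,
       calls = list(v = v, d = d, j = j, c = cc))
}

empty_rearrangement <- function() {
  data.frame(sequence_id = character(0), v_call = character(0),
             d_call = character(0), j_call = character(0),
             c_call = character(0), junction = character(0),
             junction_aa = character(0), junction_note = character(0),
             productive = logical(0), duplicate_count = integer(0),
             v_mutations = integer(0), v_region_length = integer(0),
             germline_junction_nt = integer(0), sequence_aa = character(0),
             stringsAsFactors = FALSE)
}

#' Productive status of a rearrangement record
#'
#' A record is productive when its junction is present, the junction length
#' is a multiple of 3, and the V-anchor-framed translation carries no stop
#' codon through the junction.
#'
#' @param rearr one-row data frame (or a data frame) from [annotate_read()].
#' @return logical vector.
#' @export
is_productive <- function(rearr) rearr$productive

#' Junction (CDR-H3) of a rearrangement record
#' @param rearr data frame of rearrangement records.
#' @return data frame with `junction`, `junction_aa`, `junction_note`.
#' @export
extract_junction <- function(rearr) {
  rearr[, c("junction", "junction_aa", "junction_note"), drop = FALSE]
}

#' V-region mutation counts of rearrangement records
#' @param rearr data frame of rearrangement records.
#' @return data frame with `v_mutations` and `v_region_length` (both
#'   exclude the junction window).
#' @export
count_v_mutations <- function(rearr) {
  rearr[, c("v_mutations", "v_region_length"), drop = FALSE]
}

#' Annotate a full sample of reads
#'
#' Applies the quality filter (when a `quality` column is present), then
#' annotates every retained read.
#'
#' @param reads data frame (`read_id`, `sequence`, optional `quality`) or a
#'   FASTQ path.
#' @param reference a `germline_set`.
#' @param params an [alignment_params()] list.
#' @return list with `rearrangements` (data frame, one row per annotated
#'   read), `rejections` (data frame: `read_id`, `reason`), and `counts`
#'   (input / filtered / annotated / productive accounting).
#' @export
annotate_sample <- function(reads, reference, params = alignment_params()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n_input <- nrow(reads)
  if (!is.null(reads$quality)) {
    qf <- quality_filter(reads, params$min_mean_q, params$min_length)
    reads <- qf$reads
  } else {
    qf <- list(kept = n_input, dropped = 0L)
  }
  cand <- ref_candidates(reference)
  res <- lapply(seq_len(nrow(reads)), function(i) {
    annotate_read_impl(reads$sequence[i], cand, params, reads$read_id[i])
  })
  ok <- vapply(res, function(r) r$status == "ok", NA)
  rearr <- if (any(ok)) {
    do.call(rbind, lapply(res[ok], `[[`, "rearrangement"))
  } else {
    empty_rearrangement()
  }
  rej <- data.frame(read_id = reads$read_id[!ok],
                    reason = vapply(res[!ok], `[[`, "", "status"),
                    stringsAsFactors = FALSE)
  counts <- list(input = n_input, quality_dropped = qf$dropped,
                 filtered = qf$kept, rejected = sum(!ok),
                 annotated = sum(ok),
                 productive = sum(rearr$productive))
  list(rearrangements = rearr, rejections = rej, counts = counts)
}

#' Collapse identical rearrangements into clonotypes
#'
#' Records identical in (`v_call`, `j_call`, `c_call`, `junction`,
#' `sequence_aa`) merge into one row whose `duplicate_count` is the sum of
#' the merged counts; total read count is conserved.
#'
#' @param rearr data frame of rearrangement records.
#' @return collapsed data frame.
#' @export
collapse_duplicates <- function(rearr) {
  if (nrow(rearr) == 0L) return(rearr)
  key <- paste(rearr$v_call, rearr$j_call, rearr$c_call,
               rearr$junction, rearr$sequence_aa, sep = "\r")
  counts <- rowsum(rearr$duplicate_count, key)
  first <- rearr[!duplicated(key), , drop = FALSE]
  first$duplicate_count <- as.integer(counts[match(unique(key), rownames(counts))])
  rownames(first) <- NULL
  first
}

#' Write / read an AIRR-style rearrangement TSV
#'
#' Columns follow the AIRR Rearrangement vocabulary (`sequence_id`,
#' `v_call`, `d_call`, `j_call`, `c_call`, `junction`, `junction_aa`,
#' `productive`, `duplicate_count`) plus the extension columns
#' `v_mutations`, `v_region_length`, `germline_junction_nt`,
#' `sequence_aa`, `junction_note`.
#'
#' @param rearr data frame of (possibly collapsed) records.
#' @param path TSV path.
#' @param meta named character vector of `#` header metadata.
#' @export
write_airr <- function(rearr, path, meta = character()) {
  write_tsv_commented(rearr, path, meta)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  df <- read_tsv_commented(path)
  df$productive <- as.logical(df$productive)
  df
}
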