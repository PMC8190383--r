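`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so library code never perturbs a user's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param x character scalar over ACGT.
#' @return character scalar.
#' @keywords internal
revcomp_nt <- function(x) {
  if (nchar(x) == 0L) return(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# standard genetic code as a plain lookup vector (stops are "*")
GENETIC_CODE_VEC <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Translate nucleotide strings
#'
#' Translates each string in reading frame 1 under the standard genetic
#' code, truncating any incomplete trailing codon. Stop codons appear as
#' `*`; unrecognized codons as `X`.
#'
#' @param x character vector of ACGT strings.
#' @return character vector of amino-acid strings (empty for < 3 nt).
#' @export
translate_nt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) %/% 3L
    if (is.na(n) || n == 0L) return("")
    codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
    aa <- GENETIC_CODE_VEC[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write a data frame as TSV with '#' metadata header lines
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named character vector written as `# key: value` lines.
#' @export
write_tsv_commented <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path file path.
#' @return data frame (header comments are skipped).
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Stable md5 of an R object (used for config hashes in run manifests).
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

ighrep_version <- function() as.character(utils::packageVersion("ighrep"))
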