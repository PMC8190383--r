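test_that("family parsing strips alleles and truncates at the first dash", {
  expect_equal(family_of(c("IGHV3-23", "IGHV3-30-3*02", "IGHJ4", "IGHA1")),
               c("IGHV3", "IGHV3", "IGHJ4", "IGHA1"))
})

test_that("segment validation enforces anchors and alphabet", {
  expect_error(germline_segment("V1", "V", "ACGTN" , anchor = 1),
               "non-ACGT")
  expect_error(germline_segment("V1", "V", "", anchor = 1), "empty")
  # anchor codon must be cysteine for V, tryptophan for J
  expect_error(germline_segment("V1", "V", "ATGTATGGG", anchor = 4), "cysteine")
  expect_silent(germline_segment("V1", "V", "ATGTGTGGG", anchor = 4))
  expect_error(germline_segment("J1", "J", "ATGTGTGGG", anchor = 4),
               "tryptophan")
  expect_silent(germline_segment("J1", "J", "ATGTGGGGG", anchor = 4))
  # anchor must sit on a codon boundary and inside the sequence
  expect_error(germline_segment("V1", "V", "ATGTGTGGG", anchor = 3),
               "reading frame")
  expect_error(germline_segment("V1", "V", "ATGTGT", anchor = 7), "outside")
  # D and C never carry anchors
  d <- germline_segment("IGHD1-1", "D", "ACGTACGT")
  expect_true(is.na(anchor_of(d)))
})

test_that("anchor_of returns the stored V/J anchors", {
  ref <- tiny_reference()
  v <- ref$segments[["IGHV1-1"]]
  expect_identical(anchor_of(v), nchar(v$sequence) - 8L)
  expect_equal(substr(v$sequence, anchor_of(v), anchor_of(v) + 2), "TGT")
  j <- ref$segments[["IGHJ1"]]
  expect_equal(substr(j$sequence, anchor_of(j), anchor_of(j) + 2), "TGG")
})

test_that("duplicate ids are rejected", {
  s <- germline_segment("IGHD1-1", "D", "ACGTACGT")
  expect_error(germline_set(list(s, s)), "duplicate.*IGHD1-1")
})

test_that("synthetic reference is deterministic and respects its naming", {
  a <- build_synthetic_reference(n_v = 10, seed = 7)
  b <- build_synthetic_reference(n_v = 10, seed = 7)
  expect_identical(a, b)
  cls <- vapply(a$segments, `[[`, "", "seg_class")
  expect_equal(unname(table(cls)[c("V", "D", "J", "C")]),
               table(cls)[c("V", "D", "J", "C")], ignore_attr = TRUE)
  expect_equal(sum(cls == "V"), 10L)
  v_ids <- names(a$segments)[cls == "V"]
  expect_true(all(grepl("^IGHV[0-9]+-[0-9]+$", v_ids)))
  # families partition the class: family sizes sum to class size
  fams <- family_of(v_ids)
  expect_equal(sum(table(fams)), 10L)
})

test_that("one-J reference carries TGG at its anchor", {
  ref <- build_synthetic_reference(n_v = 2, n_d = 2, n_j = 1, n_c = 2, seed = 3)
  js <- Filter(function(s) s$seg_class == "J", ref$segments)
  expect_length(js, 1L)
  expect_equal(substr(js[[1]]$sequence, js[[1]]$anchor, js[[1]]$anchor + 2),
               "TGG")
})

test_that("synthetic V pairs satisfy the divergence bound (alignment oracle)", {
  ref <- build_synthetic_reference(n_v = 10, min_pairwise_divergence = 0.15,
                                   seed = 7)
  v <- vapply(Filter(function(s) s$seg_class == "V", ref$segments),
              `[[`, "", "sequence")
  pairs <- utils::combn(length(v), 2)
  ident <- apply(pairs, 2, function(p) identity_oracle(v[p[1]], v[p[2]]))
  expect_length(ident, 45L)
  expect_true(all(ident <= 0.85))
})

test_that("germline FASTA round-trips ids, classes, sequences and anchors", {
  ref <- tiny_reference()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_germline_fasta(ref, path)
  back <- read_germline_set(path)
  expect_identical(names(back$segments), names(ref$segments))
  for (id in names(ref$segments)) {
    expect_identical(back$segments[[id]][c("seg_class", "sequence", "anchor")],
                     ref$segments[[id]][c("seg_class", "sequence", "anchor")])
  }
})

test_that("load_germline_fasta handles dialects and bad input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  # plain dialect, 3 V records with anchor annotation: count preserved
  writeLines(c(">V-A anchor=4", "ATGTGTGGGACC",
               ">V-B anchor=4", "CCGTGCAAATTT",
               ">V-C anchor=4", "GGGTGTCCCAAA"), path)
  set <- load_germline_fasta(path, "V", "plain")
  expect_length(set$segments, 3L)
  expect_true(all(vapply(set$segments, `[[`, "", "seg_class") == "V"))

  # empty file
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(load_germline_fasta(empty, "V"), "no records")

  # N-containing record dropped with a warning
  writeLines(c(">V-A anchor=4", "ATGTGTGGGACC",
               ">V-N anchor=4", "ATGTGTNGGACC"), path)
  expect_warning(set <- load_germline_fasta(path, "V", "plain"), "N")
  expect_length(set$segments, 1L)

  # duplicate ids are fatal
  writeLines(c(">V-A anchor=4", "ATGTGTGGGACC",
               ">V-A anchor=4", "ATGTGTGGGACC"), path)
  expect_error(load_germline_fasta(path, "V"), "duplicate.*V-A")

  # anchor codon not cysteine after load -> validation error
  writeLines(c(">V-X anchor=4", "ATGAAAGGGACC"), path)
  expect_error(load_germline_fasta(path, "V"), "cysteine")
})

test_that("imgt_gapped dialect strips dots and remaps the 2nd-CYS anchor", {
  # gapped V of 312 positions containing 12 '.' gap columns (4 codons), so
  # the ungapped sequence has 300 nt; gapped codon 104 (positions 310-312)
  # is the 2nd-CYS
  gapped <- paste0(strrep("GCT", 10), strrep(".", 12), strrep("GCT", 89), "TGT")
  expect_equal(nchar(gapped), 312)
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Vg", gapped), path)
  set <- load_germline_fasta(path, "V", "imgt_gapped")
  seg <- set$segments[[1]]
  expect_equal(nchar(seg$sequence), 300)
  expect_equal(seg$anchor, 298L)           # ungapped offset of codon 104
  expect_equal(substr(seg$sequence, seg$anchor, seg$anchor + 2), "TGT")
})
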