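test_that("diversity indices: closed forms, bounds and errors", {
  expect_equal(shannon_index(rep(5, 8)), 3.0)
  expect_equal(shannon_index(10), 0.0)
  expect_equal(shannon_index(c(1, 1, 2)), 1.5)
  expect_equal(simpson_index(rep(3, 4)), 4.0)
  expect_equal(simpson_index(7), 1.0)
  expect_equal(simpson_index(c(1, 1, 2)), 1 / 0.375)
  expect_error(shannon_index(c(1, 0)), "positive")
  expect_error(simpson_index(numeric(0)), "positive")
  # uniform closed forms across a sweep; bounds with equality iff uniform
  set.seed(1)
  for (s in c(2, 3, 5, 9, 17, 33)) {
    expect_equal(shannon_index(rep(4, s)), log2(s))
    expect_equal(simpson_index(rep(4, s)), s)
    counts <- sample(1:50, s, replace = TRUE)
    expect_lte(shannon_index(counts), log2(s) + 1e-12)
    expect_lte(simpson_index(counts), s + 1e-12)
    expect_gte(shannon_index(counts), 0)
    expect_gte(simpson_index(counts), 1)
  }
})

test_that("gene usage: weighting, rollup and degenerate cases", {
  tab <- toy_table()
  # clonotype weighting: each record once
  u <- gene_usage(tab, "V", "gene", "clonotype")
  expect_equal(sum(u), 1)
  expect_equal(unname(u["IGHV1-1"]), 0.5)
  # read weighting uses duplicate_count
  ur <- gene_usage(tab, "V", "gene", "read")
  expect_equal(unname(ur["IGHV1-1"]), 14 / 20)
  # family rollup sums member genes
  uf <- gene_usage(tab, "V", "family", "clonotype")
  expect_equal(unname(uf["IGHV1"]), 0.75)
  expect_equal(sum(uf), 1)
  # two-record weighting example: 9/1 duplicates
  two <- tab[c(1, 2), ]
  expect_equal(unname(gene_usage(two, "V", "gene", "clonotype")), c(0.5, 0.5))
  expect_equal(unname(gene_usage(two, "V", "gene", "read")), c(0.9, 0.1))
  # all records one V
  one <- tab[c(1, 1), ]
  expect_equal(gene_usage(one, "V"), c(`IGHV1-1` = 1.0))
  # NA d_call rows are excluded from D usage but it still sums to 1
  ud <- gene_usage(tab, "D", "gene", "clonotype")
  expect_equal(sum(ud), 1)
  expect_error(gene_usage(tab[0, ], "V"), "no annotated records")
})

test_that("Kyte-Doolittle index normalizes onto [-1, 1]", {
  expect_equal(kyte_doolittle_index("III"), 1.0)
  expect_equal(kyte_doolittle_index("RRR"), -1.0)
  expect_equal(kyte_doolittle_index("IR"), 0.0)
  # oracle: mean of published raw constants / 4.5
  kd <- kyte_doolittle_table()
  aa <- "CARDW"
  expect_equal(kyte_doolittle_index(aa),
               mean(kd[strsplit(aa, "")[[1]]]) / 4.5)
  expect_error(kyte_doolittle_index("CAXW"), "position 3")
  # the shipped two-column table reproduces the built-in scale
  path <- system.file("extdata", "kyte_doolittle.tsv", package = "ighrep")
  expect_equal(load_hydropathy_table(path)[names(kd)], kd)
})

test_that("shm_rate pools mutations over aligned length", {
  tab <- toy_table()
  tab$v_mutations <- c(2L, 4L, 0L, 0L)
  tab$v_region_length <- c(200L, 200L, 100L, 100L)
  expect_equal(shm_rate(tab[1:2, ]), 1.5)       # (2+4)/400
  expect_equal(shm_rate(tab[3:4, ]), 0.0)
  # isotype stratification
  expect_equal(shm_rate(tab, "IGHG"), 100 * 4 / 300)
  expect_error(shm_rate(tab[0, ]), "zero total")
})

test_that("germline index per record and per sample", {
  tab <- toy_table()
  gi <- germline_index(tab)
  expect_equal(gi, c(1, 6 / 9, 1, 1))
  expect_true(all(gi >= 0 & gi <= 1))
  expect_equal(sample_gi(tab, "clonotype"), mean(gi))
  # a 15-nt junction with 3 N nucleotides: GI 0.8
  tab$junction[1] <- strrep("TGT", 5)
  tab$germline_junction_nt[1] <- 12L
  expect_equal(germline_index(tab)[1], 0.8)
})

test_that("cdr3_length_stats histograms are normalized", {
  tab <- toy_table()
  st <- cdr3_length_stats(tab, weighting = "clonotype")
  expect_equal(sum(st$distribution), 1)
  expect_equal(st$mean, mean(c(3, 3, 4, 2)))
  # equal split of lengths 10 and 20 -> mean 15
  tab2 <- tab[c(1, 2), ]
  tab2$junction_aa <- c(strrep("A", 10), strrep("A", 20))
  expect_equal(cdr3_length_stats(tab2, weighting = "clonotype")$mean, 15)
  expect_equal(cdr3_length_stats(tab2, weighting = "read")$mean,
               (10 * 9 + 20 * 1) / 10)
})

test_that("repertoire profile assembles consistent features", {
  fx <- tiny_annotated()
  p <- repertoire_profile(fx$collapsed, "tiny")
  expect_s3_class(p, "repertoire_profile")
  for (k in c("V", "J", "C")) {
    expect_equal(sum(p$usage[[k]]$gene), 1, tolerance = 1e-9)
    expect_equal(sum(p$usage[[k]]$family), 1, tolerance = 1e-9)
  }
  expect_equal(sum(p$isotype_usage), 1, tolerance = 1e-9)
  expect_gte(p$shannon, 0)
  expect_gte(p$simpson, 1)
  expect_true(p$gi >= 0 && p$gi <= 1)
  expect_true(p$hydrophobicity[["all"]] >= -1 && p$hydrophobicity[["all"]] <= 1)
  # duplication invariance: merging two identical samples (re-collapsing
  # the concatenated tables) leaves every feature unchanged
  doubled <- collapse_duplicates(rbind(fx$collapsed, fx$collapsed))
  expect_equal(sum(doubled$duplicate_count), 2 * sum(fx$collapsed$duplicate_count))
  p2 <- repertoire_profile(doubled, "tiny2")
  expect_equal(p2$usage$V$gene, p$usage$V$gene)
  expect_equal(p2$shannon, p$shannon)
  expect_equal(p2$simpson, p$simpson)
  expect_equal(p2$gi, p$gi)
  expect_equal(p2$hydrophobicity, p$hydrophobicity)
  expect_equal(p2$shm_rate, p$shm_rate)
  expect_equal(p2$cdr3_length$all$mean, p$cdr3_length$all$mean)
})

test_that("profile_table flattens with zero-filled usage", {
  fx <- tiny_annotated()
  half <- fx$collapsed[seq(1, nrow(fx$collapsed), 2), ]
  tab <- profile_table(list(repertoire_profile(fx$collapsed, "A"),
                            repertoire_profile(half, "B")))
  expect_equal(nrow(tab), 2L)
  expect_true("shannon" %in% names(tab))
  usage_cols <- grep("^v_gene:", names(tab), value = TRUE)
  expect_true(length(usage_cols) > 0)
  expect_false(anyNA(tab[, usage_cols]))
  # usage matrix export: rows = samples, columns = observed segments
  m <- usage_matrix(list(repertoire_profile(fx$collapsed, "A"),
                         repertoire_profile(half, "B")), "V", "gene")
  expect_equal(rownames(m), c("A", "B"))
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-9)
})

test_that("simulator GI and SHM are recovered through annotation", {
  fx <- tiny_annotated()
  col <- fx$collapsed
  # GI from annotation tracks GI from simulator truth at sample level
  truth_gi <- mean(fx$sim$truth$germline_junction_nt /
                     fx$sim$truth$junction_length)
  est_gi <- sample_gi(col, "read")
  expect_lt(abs(est_gi - truth_gi), 0.05)
  # SHM rate ~ configured 1%
  expect_lt(abs(shm_rate(col) - 1.0), 0.3)
})
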