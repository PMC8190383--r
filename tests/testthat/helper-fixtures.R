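# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small reference used across annotation/metric tests
tiny_reference <- function() {
  if (is.null(fixture_env$ref)) {
    fixture_env$ref <- build_synthetic_reference(
      n_v = 8, n_d = 5, n_j = 4, n_c = 6,
      min_pairwise_divergence = 0.15, seed = 101)
  }
  fixture_env$ref
}

# a clean (error-free, low-SHM) annotated sample reused by several tests
tiny_annotated <- function() {
  if (is.null(fixture_env$ann)) {
    ref <- tiny_reference()
    cfg <- sim_config(ref, clone_count = 40L, reads_per_sample = 200L,
                      shm_rate_by_isotype = c(IGHG = 0.01),
                      shm_default = 0.01, seq_error_rate = 0, seed = 202)
    sim <- simulate_sample(cfg, "tiny")
    ann <- annotate_sample(sim$reads, ref)
    fixture_env$ann <- list(ref = ref, cfg = cfg, sim = sim, ann = ann,
                            collapsed = collapse_duplicates(ann$rearrangements))
  }
  fixture_env$ann
}

# hand-built collapsed rearrangement table for metric unit tests
toy_table <- function() {
  data.frame(
    sequence_id = paste0("r", 1:4),
    v_call = c("IGHV1-1", "IGHV1-2", "IGHV2-1", "IGHV1-1"),
    d_call = c("IGHD1-1", NA, "IGHD1-1", "IGHD2-1"),
    j_call = c("IGHJ1", "IGHJ1", "IGHJ2", "IGHJ1"),
    c_call = c("IGHM", "IGHG1", "IGHG2", "IGHA1"),
    junction = c("TGTGCATGG", "TGTAAATGG", "TGTGCGAAATGG", "TGTTGG"),
    junction_aa = c("CAW", "CKW", "CAKW", "CW"),
    junction_note = "",
    productive = TRUE,
    duplicate_count = c(9L, 1L, 5L, 5L),
    v_mutations = c(2L, 4L, 0L, 6L),
    v_region_length = c(200L, 200L, 100L, 300L),
    germline_junction_nt = c(9L, 6L, 12L, 6L),
    sequence_aa = c("MCAW", "MCKW", "MCAKW", "MCW"),
    stringsAsFactors = FALSE)
}
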