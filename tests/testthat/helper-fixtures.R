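# The spec'd worked profile used throughout the scoring tests:
# alpha {min 0.5, Q2 1.0, max 1.5}, beta {min 2.5, Q2 3.0, max 3.5},
# epsilon +1, gap 1.0 centred at 2.0.
profile_P <- function() {
  descriptor_profile("gP", "diurnal",
                     alpha = c(0.5, 1.0, 1.5),
                     beta = c(2.5, 3.0, 3.5))
}

# Small fully-labeled study for fast end-to-end tests.
small_study <- function(seed = 1L, ...) {
  generate_full_study(synth_config(n_genes = 300L, n_x_descriptors = 20L,
                                   n_y_descriptors = 30L, seed = seed,
                                   ...))
}

# Metadata for a 24-sample stage-1 reference design, written to a TSV.
write_reference_metadata_tsv <- function(path) {
  meta <- expand.grid(replicate = c("r1", "r2", "r3"),
                      growth_phase = c("early", "late"),
                      diurnal_phase = c("light", "dark"),
                      condition = c("LC", "HC"),
                      stringsAsFactors = FALSE)
  meta$stage <- 1L
  meta$sample_id <- paste0("S", seq_len(nrow(meta)))
  meta$time <- 6
  write_table(meta[, c("sample_id", "condition", "stage", "diurnal_phase",
                       "growth_phase", "replicate", "time")], path)
  path
}
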