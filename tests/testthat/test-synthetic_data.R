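test_that("generation is deterministic under a fixed seed", {
  a <- generate_expression_dataset(synth_config(n_genes = 100L,
                                                n_x_descriptors = 5L,
                                                n_y_descriptors = 5L,
                                                seed = 42L))
  b <- generate_expression_dataset(synth_config(n_genes = 100L,
                                                n_x_descriptors = 5L,
                                                n_y_descriptors = 5L,
                                                seed = 42L))
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  c <- generate_expression_dataset(synth_config(n_genes = 100L,
                                                n_x_descriptors = 5L,
                                                n_y_descriptors = 5L,
                                                seed = 43L))
  expect_false(identical(a$expr, c$expr))
})

test_that("planted diurnal descriptors separate by the configured effect", {
  ds <- generate_expression_dataset(synth_config(seed = 7L))
  lx <- log10(ds$expr)  # raw log10, recomputing the generator's scale
  light <- ds$meta$diurnal_phase == "light"
  xdesc <- ds$truth[ds$truth$axis == "diurnal", ]
  diff <- vapply(seq_len(nrow(xdesc)), function(i) {
    v <- lx[xdesc$gene_id[i], ]
    (stats::median(v[light]) - stats::median(v[!light])) * xdesc$direction[i]
  }, numeric(1L))
  err <- abs(diff - 0.6)
  expect_lt(abs(mean(diff) - 0.6), 0.1)
  expect_gte(mean(err < 0.1), 0.9)
})

test_that("fully scrambled descriptors carry no state signal", {
  ds <- generate_expression_dataset(
    synth_config(n_genes = 220L, n_x_descriptors = 200L,
                 n_y_descriptors = 10L, mixing = 0.5, seed = 11L))
  lx <- log10(ds$expr)
  light <- ds$meta$diurnal_phase == "light"
  xids <- ds$truth$gene_id[ds$truth$axis == "diurnal"]
  p <- vapply(xids, function(g)
    stats::wilcox.test(lx[g, light], lx[g, !light])$p.value, numeric(1L))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.005)   # the null is active, not degenerate
  expect_lte(rate, 0.12)    # ~nominal 5% at 200 genes
})

test_that("growth series honor the curve contract and the seed", {
  g0 <- generate_growth_series(K = 2e6, mu = 0.9, lag = 1, n0 = 1e5,
                               times = seq(0, 30, 1), noise_cv = 0)
  expect_identical(g0$value[g0$time == 0], 1e5)
  expect_lt(abs(g0$value[g0$time == 30] / 2e6 - 1), 0.001)
  expect_true(all(diff(g0$value) >= 0))

  g1 <- generate_growth_series(K = 2e6, mu = 0.9, lag = 1, n0 = 1e5,
                               times = seq(0, 10, 0.5), noise_cv = 0.05,
                               seed = 3L)
  g2 <- generate_growth_series(K = 2e6, mu = 0.9, lag = 1, n0 = 1e5,
                               times = seq(0, 10, 0.5), noise_cv = 0.05,
                               seed = 3L)
  expect_identical(g1$value, g2$value)
  expect_error(generate_growth_series(K = 1e5, mu = 0.9, lag = 1, n0 = 1e5,
                                      times = 0:5), "K > n0")
  expect_error(generate_growth_series(K = 2e6, mu = 0.9, lag = 1, n0 = 1e5,
                                      times = c(0, 1, 1)),
               "strictly increasing")
})

test_that("Fv/Fm traces reproduce the configured per-stage CV contrast", {
  fv0 <- generate_fvfm_series(base = 0.65, cv_per_stage = 0,
                              timepoints_per_stage = 5L, replicates = 3L,
                              seed = 1L)
  cv0 <- cv_over_replicates(fv0)
  expect_true(all(cv0$cv == 0))

  fv <- generate_fvfm_series(base = 0.65, cv_per_stage = c(0.02, 0.06),
                             timepoints_per_stage = 12L, replicates = 3L,
                             seed = 5L)
  cvt <- cv_over_replicates(fv)
  ratio <- mean(cvt$cv[cvt$stage == 2]) / mean(cvt$cv[cvt$stage == 1])
  expect_gt(ratio, 3 * 0.7)
  expect_lt(ratio, 3 * 1.3)
  expect_identical(fv,
                   generate_fvfm_series(base = 0.65,
                                        cv_per_stage = c(0.02, 0.06),
                                        timepoints_per_stage = 12L,
                                        replicates = 3L, seed = 5L))
})

test_that("a full study is internally consistent and file-round-trippable", {
  st <- small_study(seed = 2L)
  expect_identical(nrow(validate_dataset(st$expr, st$meta)), 0L)
  expect_true(all(st$truth$gene_id %in% rownames(st$expr)))
  expect_identical(nrow(st$truth), 50L)

  dir <- withr::local_tempdir()
  generate_full_study(st$config, dir = dir)
  expr <- read_expression_matrix(file.path(dir, "expression_fpkm.tsv"))
  meta <- read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
  expect_equal(expr, st$expr, tolerance = 1e-12)
  expect_identical(nrow(validate_dataset(expr, meta)), 0L)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_genes = 10L, n_x_descriptors = 8L,
                            n_y_descriptors = 8L), "exceed")
  expect_error(synth_config(mixing = 0.7), "mixing")
  expect_error(synth_config(position_jitter_scale = 0.5), "jitter")
})
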