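test_that("log_transform follows the pseudocount contract", {
  expect_identical(log_transform(99, 1), 2)
  expect_identical(log_transform(0, 1), 0)
  expect_error(log_transform(0, 0), "pseudocount 0")
  m <- matrix(c(9, 99), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(log_transform(m, 1), matrix(c(1, 2), 2, 1,
               dimnames = list(c("a", "b"), "s")))
})

test_that("selection applies all three criteria", {
  st <- small_study(seed = 3L)
  sets <- select_descriptor_sets(st$expr, st$meta)

  # a flat gene is never selected
  flat <- st$expr
  flat["g00100", ] <- 50  # background gene forced identical everywhere
  s2 <- select_state_descriptors(flat, st$meta, "diurnal")
  expect_false("g00100" %in% names(s2$profiles))

  # large fold change but huge per-state spread fails the separation
  # criterion: 2.5-fold median shift, per-state SD 1.0 in log10
  expr <- st$expr
  set.seed(99)
  light <- st$meta$diurnal_phase == "light"
  noisy <- 10^(ifelse(light, log10(2.5), 0) +
               stats::rnorm(ncol(expr), 2, 1.0))
  expr["g00101", ] <- noisy
  s3 <- select_state_descriptors(expr, st$meta, "diurnal")
  g <- s3$stats[s3$stats$gene_id == "g00101", ]
  expect_false(g$selected)
  expect_lt(abs(g$median_diff), g$mean_sd)  # criterion 3 is what failed

  # weights are uniform and sum to one per axis
  expect_equal(sum(sets$x$weights), 1)
  expect_equal(sum(sets$y$weights), 1)
  expect_true(length(intersect(names(sets$x$profiles),
                               names(sets$y$profiles))) == 0L)
})

test_that("selection recovers planted descriptors with few false calls", {
  st <- small_study(seed = 4L)
  sets <- select_descriptor_sets(st$expr, st$meta)
  truth_x <- st$truth$gene_id[st$truth$axis == "diurnal"]
  truth_y <- st$truth$gene_id[st$truth$axis == "growth_phase"]
  sel_x <- names(sets$x$profiles); sel_y <- names(sets$y$profiles)
  recall <- (sum(sel_x %in% truth_x) + sum(sel_y %in% truth_y)) /
    (length(truth_x) + length(truth_y))
  fdp <- (sum(!sel_x %in% truth_x) + sum(!sel_y %in% truth_y)) /
    max(length(sel_x) + length(sel_y), 1L)
  expect_gte(recall, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("selection is symmetric in the state labels", {
  st <- small_study(seed = 5L)
  sets <- select_state_descriptors(st$expr, st$meta, "diurnal")
  meta_sw <- st$meta
  meta_sw$diurnal_phase <- ifelse(st$meta$diurnal_phase == "light",
                                  "dark", "light")
  sets_sw <- select_state_descriptors(st$expr, meta_sw, "diurnal")
  expect_setequal(names(sets$profiles), names(sets_sw$profiles))
  for (g in names(sets$profiles))
    expect_identical(sets_sw$profiles[[g]]$epsilon,
                     -sets$profiles[[g]]$epsilon)
})

test_that("tightening either threshold never adds a descriptor", {
  st <- small_study(seed = 6L)
  base <- names(select_state_descriptors(st$expr, st$meta, "diurnal",
                                         descriptor_criteria())$profiles)
  for (crit in list(descriptor_criteria(fold_change_min = 3),
                    descriptor_criteria(separation_sd_multiple = 2),
                    descriptor_criteria(alpha = 0.01))) {
    tighter <- names(select_state_descriptors(st$expr, st$meta, "diurnal",
                                              crit)$profiles)
    expect_true(all(tighter %in% base))
  }
})

test_that("label permutation yields near-zero selections", {
  ds <- generate_expression_dataset(
    synth_config(n_genes = 2000L, n_x_descriptors = 1L,
                 n_y_descriptors = 1L, seed = 8L))
  meta_perm <- ds$meta
  set.seed(81)
  meta_perm$diurnal_phase <- sample(ds$meta$diurnal_phase)
  # permuted labels must still form a valid unique design key
  meta_perm$replicate <- paste0(meta_perm$replicate, "_",
                                seq_len(nrow(meta_perm)))
  sel <- suppressWarnings(
    select_state_descriptors(ds$expr, meta_perm, "diurnal"))
  expect_lte(length(sel$profiles), 3 * 0.05 * 2000)
})

test_that("profile summaries round-trip through JSON", {
  st <- small_study(seed = 9L)
  sets <- select_descriptor_sets(st$expr, st$meta)
  tab <- summarize_descriptor_profiles(sets)
  expect_identical(nrow(tab),
                   length(sets$x$profiles) + length(sets$y$profiles))
  expect_true(all(c("q2_alpha", "epsilon", "gap") %in% colnames(tab)))
  # overlapping distributions have no gap geometry
  expect_true(all(is.na(tab$gap_center[tab$gap == 0])))

  tf <- withr::local_tempfile(fileext = ".json")
  write_descriptor_sets(sets, tf)
  back <- read_descriptor_sets(tf)
  expect_equal(summarize_descriptor_profiles(back), tab,
               tolerance = 1e-15)
  # restored sets map identically
  p1 <- map_samples(st$expr, sets$x, sets$y)
  p2 <- map_samples(st$expr, back$x, back$y)
  expect_equal(p1, p2, tolerance = 1e-15)
})

test_that("gene-set condition comparison flags planted shifts exactly", {
  # identical conditions: no gene significant, all log2FC = 0
  st <- small_study(seed = 10L)
  expr <- st$expr
  genes <- paste0("g00", 151:160)
  const <- matrix(rep(10 * (1:10), ncol(expr)), nrow = 10,
                  dimnames = list(genes, colnames(expr)))
  expr[genes, ] <- const
  res0 <- compare_gene_set_between_conditions(expr, st$meta, genes,
                                              "LC", "HC")
  expect_true(all(res0$table$log2_fc == 0))
  expect_identical(unname(res0$summary["ns"]), 10L)

  # planted 4-fold down-shift in 5 of 10 genes, 12 vs 12, sd 0.1 log10
  set.seed(101)
  hc <- st$meta$condition == "HC"
  down <- genes[1:5]
  for (g in genes) {
    mu <- 2 + ifelse(g %in% down & hc, -log10(4), 0)
    expr[g, ] <- 10^stats::rnorm(ncol(expr), mu, 0.1)
  }
  res <- compare_gene_set_between_conditions(expr, st$meta, genes,
                                             "LC", "HC", alpha = 0.001)
  flagged_down <- res$table$gene_id[res$table$direction == "down"]
  expect_setequal(flagged_down, down)
  expect_identical(unname(res$summary["down"]), 5L)

  expect_error(
    compare_gene_set_between_conditions(expr, st$meta, c("nope1", genes),
                                        "LC", "HC"), "nope1")
  expect_error(
    compare_gene_set_between_conditions(expr, st$meta, character(),
                                        "LC", "HC"), "empty")
})
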