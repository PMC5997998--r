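test_that("closer_state picks the nearer state median", {
  p <- profile_P()
  expect_identical(closer_state(1.0, p), 1L)
  expect_identical(closer_state(3.4, p), -1L)
  expect_identical(closer_state(2.0, p), 0L)   # equidistant tie
  expect_identical(closer_state(c(0, 4), p), c(1L, -1L))
})

test_that("position scores reproduce the hand-worked values", {
  p <- profile_P()
  ks <- c(1.0, 0.5, 3.5, 2.0, 1.75, 1.5)
  expect_equal(transcript_position_score(ks, p),
               c(1.5, 2.0, -2.0, 0.0, 0.5, 1.0), tolerance = 1e-15)
  # the gap edge value 1.0 arises identically from both formulas:
  # interpolation within alpha's range and the gap interpolation
  eps <- p$epsilon
  via_range <- 1.5 * 1 - eps * abs(1.5 - p$q2_alpha) /
    (2 * abs(p$max_alpha - p$q2_alpha))
  via_gap <- 2 * eps * (p$gap_center - 1.5) / p$gap
  expect_identical(via_range, 1.0)
  expect_identical(via_gap, 1.0)

  bk <- transcript_position_score(ks, p, breakdown = TRUE)
  expect_identical(bk$branch,
                   c("at_median", "below_median", "above_median",
                     "in_gap", "in_gap", "above_median"))
  expect_true(all(abs(bk$lambda) <= 2))
})

test_that("scores match the scalar oracle and stay bounded", {
  set.seed(1203)
  kappas <- seq(-3, 6, length.out = 2001)
  for (rep in 1:6) {
    p <- random_profile(gapped = rep %% 2 == 0)
    lam <- transcript_position_score(kappas, p)
    ref <- vapply(kappas, oracle_lambda, numeric(1L), p = p)
    expect_lt(max(abs(lam - ref)), 1e-12)
    expect_true(all(abs(lam) <= 2))
  }
})

test_that("scores are continuous across branch boundaries of gapped profiles", {
  # continuity holds when the closer-state switch lies inside the gap
  # (the generic case for state-separated descriptors); strongly
  # asymmetric profiles are inherently discontinuous at the switch
  set.seed(77)
  h <- 1e-13
  for (rep in 1:10) {
    p <- random_balanced_profile()
    lo_max <- if (p$epsilon == 1) p$max_alpha else p$max_beta
    hi_min <- if (p$epsilon == 1) p$min_beta else p$min_alpha
    edges <- c(p$q2_alpha, p$q2_beta, lo_max, hi_min, p$gap_center,
               p$min_alpha, p$max_beta, p$min_beta, p$max_alpha)
    jump <- abs(transcript_position_score(edges - h, p) -
                transcript_position_score(edges + h, p))
    expect_lt(max(jump), 1e-9)
  }
})

test_that("swapping the state labels negates every score", {
  set.seed(31)
  kappas <- seq(-2, 5, length.out = 501)
  for (rep in 1:5) {
    p <- random_profile(gapped = rep > 2)
    swapped <- descriptor_profile(p$gene_id, p$axis,
                                  alpha = c(p$min_beta, p$q2_beta,
                                            p$max_beta),
                                  beta = c(p$min_alpha, p$q2_alpha,
                                           p$max_alpha))
    expect_equal(transcript_position_score(kappas, swapped),
                 -transcript_position_score(kappas, p),
                 tolerance = 1e-12)
  }
})

test_that("sample coordinates are convex combinations of scores", {
  p1 <- profile_P()
  p2 <- descriptor_profile("gQ", "diurnal",
                           alpha = c(1.5, 2.0, 2.5), beta = c(4, 4.5, 5))
  py <- descriptor_profile("gY", "growth_phase",
                           alpha = c(0.5, 1.0, 1.5), beta = c(2.5, 3, 3.5))
  xset <- structure(list(axis = "diurnal",
                         profiles = list(gP = p1, gQ = p2),
                         weights = c(0.5, 0.5), pseudocount = 0),
                    class = "descriptor_set")
  yset <- structure(list(axis = "growth_phase",
                         profiles = list(gY = py),
                         weights = 1, pseudocount = 0),
                    class = "descriptor_set")
  # lambda(gP at 1.0) = 1.5; lambda(gQ at 2.875) = 2*(3.25-2.875)/1.5
  # = 0.5 (gap interpolation); equal weights average to 1.0
  pos <- map_sample_to_state_space(c(gP = 1.0, gQ = 2.875, gY = 2.0),
                                   xset, yset, sample_id = "s1")
  expect_equal(pos$s_x, 1.0)
  expect_equal(pos$s_y, 0.0)
  expect_identical(nrow(pos$breakdown_x), 2L)

  expect_error(map_sample_to_state_space(c(gP = 1.0, gY = 2.0),
                                         xset, yset), "gQ")
})

test_that("reference regions match hand geometry and classify correctly", {
  pos <- data.frame(sample_id = paste0("S", 1:8),
                    s_x = rep(c(1, 1, 3, 3), 2),
                    s_y = rep(c(1, 3, 1, 3), 2))
  meta <- data.frame(sample_id = paste0("S", 1:8),
                     condition = "LC", stage = 1L,
                     diurnal_phase = rep(c("light", "dark"), each = 4),
                     growth_phase = rep(c("early", "late"), 4),
                     replicate = paste0("r", 1:8),
                     stringsAsFactors = FALSE)
  # light-early samples sit at (1,1),(3,1): per-axis variances 2 and 0
  reg <- build_reference_regions(pos, meta, pool = FALSE)
  le <- reg[reg$state == "light-early", ]
  expect_equal(le$centroid_x, 2)
  expect_equal(le$centroid_y, 1)
  expect_equal(le$radius, 1.96 * sqrt(2))
  expect_identical(nrow(reg), 4L)

  # the spec'd four-corner state under the per-axis-RMS convention
  pos4 <- data.frame(sample_id = paste0("T", 1:4),
                     s_x = c(1, 1, 3, 3), s_y = c(1, 3, 1, 3))
  meta4 <- meta[1:4, ]
  meta4$sample_id <- pos4$sample_id
  meta4$diurnal_phase <- "light"; meta4$growth_phase <- "early"
  meta4$replicate <- paste0("r", 1:4)
  # remaining three states need >= 2 samples: reuse light-early layout
  meta_all <- do.call(rbind, lapply(1:4, function(i) {
    m <- meta4
    m$sample_id <- paste0("T", 1:4, "_", i)
    m$diurnal_phase <- c("light", "light", "dark", "dark")[i]
    m$growth_phase <- c("early", "late", "early", "late")[i]
    m$replicate <- paste0(m$replicate, "_", i)
    m
  }))
  pos_all <- do.call(rbind, lapply(1:4, function(i) {
    p <- pos4; p$sample_id <- paste0("T", 1:4, "_", i); p
  }))
  reg4 <- build_reference_regions(pos_all, meta_all, pool = FALSE,
                                  radius = "axis_rms")
  expect_equal(reg4$centroid_x, rep(2, 4))
  expect_equal(reg4$radius, rep(1.96 * sqrt(4 / 3), 4), tolerance = 1e-12)
  expect_equal(reg4$radius[1L], 2.263, tolerance = 1e-3)

  # identical replicate positions give radius zero and exact recall
  pos0 <- pos_all; pos0$s_x <- rep(c(1, -1, 1, -1), each = 4)
  pos0$s_y <- rep(c(1, 1, -1, -1), each = 4)
  reg0 <- build_reference_regions(pos0, meta_all)
  expect_true(all(reg0$radius == 0))
  expect_identical(classify_position(data.frame(s_x = 1, s_y = 1), reg0),
                   "light-early")
  expect_identical(classify_position(data.frame(s_x = 5, s_y = 5), reg0),
                   "non-distinctive")
  # equidistant tie between centroids
  expect_identical(classify_position(data.frame(s_x = 0, s_y = 0), reg0),
                   "non-distinctive")
})

test_that("leave-one-out reference positions widen the regions honestly", {
  st <- small_study(seed = 13L)
  sets <- select_descriptor_sets(st$expr, st$meta)
  pos_in <- map_samples(st$expr, sets$x, sets$y)
  pos_cv <- crossvalidated_reference_positions(st$expr, st$meta, sets)
  expect_setequal(pos_cv$sample_id, pos_in$sample_id)
  expect_false(isTRUE(all.equal(pos_cv$s_x, pos_in$s_x)))
  reg_in <- build_reference_regions(pos_in, st$meta)
  reg_cv <- build_reference_regions(pos_cv, st$meta)
  # out-of-sample scatter can only be larger: a reference sample never
  # exceeds extremes it helped define
  expect_gt(reg_cv$radius[1L], reg_in$radius[1L])
  # in-sample reference positions still classify to their own corner
  lab <- classify_position(pos_in, reg_cv)
  truth <- paste(st$meta$diurnal_phase, st$meta$growth_phase, sep = "-")
  expect_gte(mean(lab == truth), 0.95)
})

test_that("pure synthetic samples land in their labeled corner", {
  st <- small_study(seed = 12L)
  sets <- select_descriptor_sets(st$expr, st$meta)
  pos <- map_samples(st$expr, sets$x, sets$y)
  m <- st$meta
  light <- m$diurnal_phase == "light"; early <- m$growth_phase == "early"
  expect_true(all(pos$s_x[light] > 0) && all(pos$s_x[!light] < 0))
  expect_true(all(pos$s_y[early] > 0) && all(pos$s_y[!early] < 0))
  expect_true(all(abs(pos$s_x) <= 2 & abs(pos$s_y) <= 2))
})
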