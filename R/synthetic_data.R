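#' Configuration for a synthetic stress-test study
#'
#' Defines the statistical structure of a generated study: planted
#' diurnal (x-axis) and growth-phase (y-axis) descriptor transcripts with
#' state-dependent log10-FPKM medians, non-informative background genes
#' with a long-tailed mean distribution, replicate structure across
#' conditions and stages, and two independent dysregulation knobs —
#' per-(sample, descriptor) state scrambling (`mixing`) and a stage-level
#' inflation of within-state variability (`position_jitter_scale`).
#'
#' Defaults emulate the reference design of the study this package
#' models: 2 CO2 conditions x 2 diurnal phases x 2 growth phases x 3
#' replicates = 24 stage-1 transcriptomes; 60 + 220 planted descriptors
#' among 3000 genes; a twofold-plus state effect (0.6 log10) against a
#' within-state SD of 0.12 log10.
#'
#' @param n_genes Total number of genes.
#' @param n_x_descriptors,n_y_descriptors Planted light/dark and
#'   early/late marker counts (disjoint sets).
#' @param effect Separation of the two state medians, log10-FPKM units.
#' @param within_state_sd Within-state SD, log10-FPKM units.
#' @param baseline_log10_mean,baseline_log10_sd Mean/SD of per-gene
#'   baseline expression in log10 FPKM (long-tailed so the 5-FPKM filter
#'   is exercised).
#' @param conditions Character vector of condition labels.
#' @param replicates Replicates per (condition, stage, diurnal, growth).
#' @param stages Number of stress-test stages.
#' @param mixing Per-stage probability in [0, 0.5] that a descriptor's
#'   state assignment is scrambled in a given sample (recycled to
#'   `stages`).
#' @param position_jitter_scale Per-stage multiplier (>= 1) on
#'   within-state SD, inflating inter-replicate variability (recycled).
#' @param growth List of logistic-with-lag growth parameters:
#'   `K`, `mu`, `lag`, `n0`, `noise_cv`, `times` (days).
#' @param fvfm List of Fv/Fm trace parameters: `base`, `cv_per_stage`
#'   (recycled to `stages`), `timepoints_per_stage`, `fm_base`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 3000L,
                         n_x_descriptors = 60L,
                         n_y_descriptors = 220L,
                         effect = 0.6,
                         within_state_sd = 0.12,
                         baseline_log10_mean = 1.2,
                         baseline_log10_sd = 0.8,
                         conditions = c("LC", "HC"),
                         replicates = 3L,
                         stages = 1L,
                         mixing = 0,
                         position_jitter_scale = 1,
                         growth = list(K = 2e6, mu = 0.9, lag = 1.0,
                                       n0 = 1e5, noise_cv = 0.05,
                                       times = seq(0, 10, by = 0.5)),
                         fvfm = list(base = 0.65, cv_per_stage = 0.02,
                                     timepoints_per_stage = 12L,
                                     fm_base = 1500),
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_x_descriptors = as.integer(n_x_descriptors),
              n_y_descriptors = as.integer(n_y_descriptors),
              effect = effect, within_state_sd = within_state_sd,
              baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd,
              conditions = conditions,
              replicates = as.integer(replicates),
              stages = as.integer(stages),
              mixing = rep_len(mixing, stages),
              position_jitter_scale = rep_len(position_jitter_scale, stages),
              growth = growth, fvfm = fvfm, seed = as.integer(seed))
  cfg$fvfm$cv_per_stage <- rep_len(cfg$fvfm$cv_per_stage, cfg$stages)
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_x_descriptors + cfg$n_y_descriptors > cfg$n_genes)
    stop_ss("descriptor counts exceed n_genes")
  stopifnot(cfg$effect > 0, cfg$within_state_sd > 0,
            cfg$replicates >= 1L, cfg$stages >= 1L)
  if (any(cfg$mixing < 0 | cfg$mixing > 0.5))
    stop_ss("mixing must lie in [0, 0.5]")
  if (any(cfg$position_jitter_scale < 1))
    stop_ss("position_jitter_scale must be >= 1")
  invisible(cfg)
}

#' Generate a synthetic expression dataset with planted state descriptors
#'
#' Each planted descriptor is drawn log10-normal around one of two state
#' medians separated by `effect` (direction fixed per gene); background
#' genes are state-independent. With probability `mixing[stage]` a
#' descriptor's state is flipped for that (sample, gene) draw, and
#' within-state SD is multiplied by `position_jitter_scale[stage]` —
#' the two components of pre-collapse dysregulation. FPKM = 10^(log10
#' value), so all values are strictly positive.
#'
#' @param cfg A [synth_config()].
#' @return A list with `expr` (genes x samples FPKM matrix), `meta`
#'   (sample metadata data.frame), and `truth` (data.frame of planted
#'   descriptor gene ids with `axis` and `direction`).
#' @export
generate_expression_dataset <- function(cfg) {
  validate_synth_config(cfg)
  with_seed(cfg$seed, generate_expression_dataset_impl(cfg))
}

generate_expression_dataset_impl <- function(cfg) {
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  idx_x <- seq_len(cfg$n_x_descriptors)
  idx_y <- cfg$n_x_descriptors + seq_len(cfg$n_y_descriptors)

  meta <- expand.grid(replicate = paste0("r", seq_len(cfg$replicates)),
                      growth_phase = c("early", "late"),
                      diurnal_phase = c("light", "dark"),
                      stage = seq_len(cfg$stages),
                      condition = cfg$conditions,
                      stringsAsFactors = FALSE)
  meta$sample_id <- with(meta, paste(condition, paste0("s", stage),
                                     diurnal_phase, growth_phase,
                                     replicate, sep = "_"))
  meta$time <- 24 * (meta$stage - 1L) * 14 +
    ifelse(meta$growth_phase == "early", 48, 192) +
    ifelse(meta$diurnal_phase == "light", 6, 18)
  meta <- meta[, c("sample_id", "condition", "stage", "diurnal_phase",
                   "growth_phase", "replicate", "time")]

  n_s <- nrow(meta)
  base_mu <- stats::rnorm(cfg$n_genes, cfg$baseline_log10_mean,
                          cfg$baseline_log10_sd)
  # direction: +1 means up in the alpha state (light / early)
  dir_x <- sample(c(-1, 1), cfg$n_x_descriptors, replace = TRUE)
  dir_y <- sample(c(-1, 1), cfg$n_y_descriptors, replace = TRUE)

  log_expr <- matrix(NA_real_, cfg$n_genes, n_s,
                     dimnames = list(gene_ids, meta$sample_id))
  half <- cfg$effect / 2
  for (s in seq_len(n_s)) {
    st <- meta$stage[s]
    sd_s <- cfg$within_state_sd * cfg$position_jitter_scale[st]
    mix <- cfg$mixing[st]
    # background genes
    mu <- base_mu
    # x descriptors: state sign by diurnal phase, per-draw scrambling
    sgn_x <- if (meta$diurnal_phase[s] == "light") 1 else -1
    flip_x <- ifelse(stats::runif(cfg$n_x_descriptors) < mix, -1, 1)
    mu[idx_x] <- base_mu[idx_x] + half * dir_x * sgn_x * flip_x
    sgn_y <- if (meta$growth_phase[s] == "early") 1 else -1
    flip_y <- ifelse(stats::runif(cfg$n_y_descriptors) < mix, -1, 1)
    mu[idx_y] <- base_mu[idx_y] + half * dir_y * sgn_y * flip_y
    log_expr[, s] <- stats::rnorm(cfg$n_genes, mu, sd_s)
  }
  truth <- data.frame(
    gene_id = gene_ids[c(idx_x, idx_y)],
    axis = rep(c("diurnal", "growth_phase"),
               c(cfg$n_x_descriptors, cfg$n_y_descriptors)),
    direction = c(dir_x, dir_y),
    stringsAsFactors = FALSE)
  list(expr = 10 ^ log_expr, meta = meta, truth = truth)
}

#' Logistic growth curve with an explicit lag phase
#'
#' Density stays at `n0` until `lag`, then follows the classic logistic
#' \eqn{N(t) = K n_0 e^{\mu(t - lag)} / (K + n_0 (e^{\mu(t-lag)} - 1))},
#' continuous at the lag boundary with asymptote `K`.
#'
#' @param t Time, days.
#' @param K Carrying capacity, cells/mL.
#' @param mu Specific growth rate, 1/day.
#' @param lag Lag-phase duration, days.
#' @param n0 Initial density, cells/mL.
#' @return Cell densities at `t`.
#' @export
logistic_lag_curve <- function(t, K, mu, lag, n0) {
  te <- pmax(t - lag, 0)
  e <- exp(mu * te)
  K * n0 * e / (K + n0 * (e - 1))
}

#' Generate a synthetic cell-count growth series
#'
#' Logistic-with-lag curve ([logistic_lag_curve()]) with multiplicative
#' log-normal noise of coefficient of variation `noise_cv` (mean-one
#' noise, so the expected curve is unchanged).
#'
#' @param K,mu,lag,n0 Curve parameters; requires `K > n0 > 0`, `mu > 0`,
#'   `lag >= 0`.
#' @param times Strictly increasing sampling times, days.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional integer seed.
#' @param series_id Identifier recorded in the output table.
#' @return A data.frame with columns `series_id`, `time`, `value`.
#' @export
generate_growth_series <- function(K, mu, lag, n0, times, noise_cv = 0,
                                   seed = NULL, series_id = "series1") {
  if (!(K > n0 && n0 > 0)) stop_ss("need K > n0 > 0")
  if (mu <= 0) stop_ss("mu must be > 0")
  if (lag < 0) stop_ss("lag must be >= 0")
  if (any(diff(times) <= 0)) stop_ss("times must be strictly increasing")
  counts <- logistic_lag_curve(times, K, mu, lag, n0)
  if (noise_cv > 0) {
    sig <- sqrt(log(1 + noise_cv^2))
    counts <- with_seed(seed,
      counts * exp(stats::rnorm(length(times), -sig^2 / 2, sig)))
  }
  data.frame(series_id = series_id, time = times, value = counts,
             stringsAsFactors = FALSE)
}

#' Generate synthetic Fv/Fm fluorescence traces with stage-dependent CV
#'
#' Per (stage, time-point), replicate Fv/Fm values are drawn with
#' across-replicate coefficient of variation approximately
#' `cv_per_stage[stage]`, then emitted as (Fm, Fo) pairs with
#' `Fo = Fm * (1 - Fv/Fm)`. Values that would leave (0, 1) are clipped
#' with a warning.
#'
#' @param base Mean Fv/Fm, in (0, 1).
#' @param cv_per_stage Per-stage across-replicate CV of Fv/Fm.
#' @param timepoints_per_stage Time-points sampled within each stage.
#' @param replicates Replicate cultures per time-point.
#' @param seed Optional integer seed.
#' @param fm_base Mean maximal fluorescence yield (arbitrary units).
#' @return A data.frame with columns `stage`, `time_index`, `time`,
#'   `replicate`, `fm`, `fo`.
#' @export
generate_fvfm_series <- function(base = 0.65, cv_per_stage = 0.02,
                                 timepoints_per_stage = 12L,
                                 replicates = 3L, seed = NULL,
                                 fm_base = 1500) {
  if (!(base > 0 && base < 1)) stop_ss("base Fv/Fm must lie in (0, 1)")
  n_stage <- length(cv_per_stage)
  with_seed(seed, {
    rows <- expand.grid(replicate = paste0("r", seq_len(replicates)),
                        time_index = seq_len(timepoints_per_stage),
                        stage = seq_len(n_stage),
                        stringsAsFactors = FALSE)
    rows$time <- (rows$stage - 1L) * 14 +
      rows$time_index * 14 / timepoints_per_stage
    fv <- base * (1 + stats::rnorm(nrow(rows), 0,
                                   cv_per_stage[rows$stage]))
    n_clip <- sum(fv <= 0 | fv >= 1)
    if (n_clip > 0L) {
      warning(n_clip, " Fv/Fm draw(s) clipped into (0, 1)", call. = FALSE)
      fv <- pmin(pmax(fv, 1e-6), 1 - 1e-6)
    }
    fm <- fm_base * exp(stats::rnorm(nrow(rows), 0, 0.02))
    data.frame(stage = rows$stage, time_index = rows$time_index,
               time = rows$time, replicate = rows$replicate,
               fm = fm, fo = fm * (1 - fv), stringsAsFactors = FALSE)
  })
}

#' Generate a complete labeled synthetic study
#'
#' Bundles expression, growth, and Fv/Fm generators under one seed with
#' consistent condition/stage/replicate labels, and optionally writes the
#' study to a directory in the pipeline's on-disk formats.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory; created if needed.
#' @return A list of class `synthetic_study` with elements `expr`, `meta`,
#'   `truth`, `growth`, `fvfm`, and `config`.
#' @export
generate_full_study <- function(cfg = synth_config(), dir = NULL) {
  validate_synth_config(cfg)
  ds <- generate_expression_dataset(cfg)
  growth <- do.call(rbind, lapply(seq_along(cfg$conditions), function(ci) {
    do.call(rbind, lapply(seq_len(cfg$replicates), function(r) {
      generate_growth_series(
        K = cfg$growth$K, mu = cfg$growth$mu, lag = cfg$growth$lag,
        n0 = cfg$growth$n0, times = cfg$growth$times,
        noise_cv = cfg$growth$noise_cv,
        seed = cfg$seed + 1000L * ci + r,
        series_id = paste0(cfg$conditions[ci], "_r", r))
    }))
  }))
  fvfm <- do.call(rbind, lapply(seq_along(cfg$conditions), function(ci) {
    out <- generate_fvfm_series(
      base = cfg$fvfm$base, cv_per_stage = cfg$fvfm$cv_per_stage,
      timepoints_per_stage = cfg$fvfm$timepoints_per_stage,
      replicates = cfg$replicates, seed = cfg$seed + 777L * ci,
      fm_base = cfg$fvfm$fm_base)
    cbind(condition = cfg$conditions[ci], out, stringsAsFactors = FALSE)
  }))
  study <- structure(list(expr = ds$expr, meta = ds$meta, truth = ds$truth,
                          growth = growth, fvfm = fvfm, config = cfg),
                     class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(study$expr, file.path(dir, "expression_fpkm.tsv"))
  write_table(study$meta, file.path(dir, "sample_metadata.tsv"))
  write_table(study$truth, file.path(dir, "truth_descriptors.tsv"))
  write_table(study$growth, file.path(dir, "cell_counts.tsv"))
  write_table(study$fvfm, file.path(dir, "fvfm.tsv"))
  invisible(dir)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic stress-test study:", nrow(x$expr), "genes x",
      ncol(x$expr), "samples;", nrow(x$truth), "planted descriptors;",
      x$config$stages, "stage(s), seed", x$config$seed, "\n")
  invisible(x)
}
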