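#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (paths to expression, metadata, cell-count and
#' fluorescence tables) or `simulate` (a [synth_config()]) must be
#' supplied. Remaining fields tune the analysis stages; all defaults are
#' echoed into the run manifest for provenance.
#'
#' @param input Optional named list with paths `expression`, `metadata`,
#'   and optionally `counts`, `fvfm`.
#' @param simulate Optional [synth_config()] describing a synthetic
#'   study.
#' @param criteria A [descriptor_criteria()].
#' @param reference_stage Stage defining descriptors and regions.
#' @param min_fpkm Low-expression filter for the similarity matrix.
#' @param distance_stage_pairs List of length-2 stage vectors compared by
#'   the dispersion Mann-Whitney test (default: every stage against the
#'   reference stage).
#' @param cv_stage_pairs Like `distance_stage_pairs`, for the paired CV
#'   test.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            criteria = descriptor_criteria(),
                            reference_stage = 1L, min_fpkm = 5,
                            distance_stage_pairs = NULL,
                            cv_stage_pairs = NULL,
                            out_dir = "statescape_out", seed = 1L) {
  if (is.null(input) == is.null(simulate))
    stop_ss("exactly one of 'input' or 'simulate' must be given")
  structure(list(input = input, simulate = simulate, criteria = criteria,
                 reference_stage = as.integer(reference_stage),
                 min_fpkm = min_fpkm,
                 distance_stage_pairs = distance_stage_pairs,
                 cv_stage_pairs = cv_stage_pairs,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file. A `simulate` block is
#'   passed to [synth_config()]; other keys map to [pipeline_config()]
#'   arguments, with `criteria` passed to [descriptor_criteria()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$input)) args$input <- raw$input
  if (!is.null(raw$simulate))
    args$simulate <- do.call(synth_config, raw$simulate)
  if (!is.null(raw$criteria))
    args$criteria <- do.call(descriptor_criteria, raw$criteria)
  for (k in c("reference_stage", "min_fpkm", "distance_stage_pairs",
              "cv_stage_pairs", "out_dir", "seed"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(pipeline_config, args)
}

pipeline_log <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[statescape] %-22s %6.2fs", stage,
                    as.numeric(proc.time()[3L] - t0)))
}

#' Run the full resilience analysis pipeline
#'
#' Executes, in order: input validation (or study simulation), descriptor
#' selection on the reference stage, state-space mapping of every sample,
#' reference-region construction and classification, the Spearman
#' similarity matrix, replicate dispersion distances with Mann-Whitney
#' stage comparisons, Fv/Fm CV series with Wilcoxon stage comparisons,
#' and logistic growth fits. All tables are written to
#' `config$out_dir`, and `manifest.json` records the config echo, the
#' seed, and an md5 checksum for every output file. Any stage error
#' aborts with a stage-named message and leaves a `FAILED` marker next to
#' the partial outputs.
#'
#' @param config A [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3L]
  outputs <- character()
  stage_name <- "setup"
  emit <- function(object, file) {
    path <- file.path(config$out_dir, file)
    write_table(object, path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }
  on_fail <- function(e) {
    writeLines(paste0("stage '", stage_name, "': ", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop_ss("pipeline stage '", stage_name, "' failed: ",
            conditionMessage(e))
  }
  tryCatch({
    stage_name <- "load"
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- config$seed  # pipeline seed governs the study
      study <- generate_full_study(cfg)
      expr <- study$expr; meta <- study$meta
      growth <- study$growth; fvfm <- study$fvfm
      emit(study$truth, "truth_descriptors.tsv")
    } else {
      expr <- read_expression_matrix(config$input$expression)
      meta <- read_sample_metadata(config$input$metadata)
      growth <- if (!is.null(config$input$counts))
        utils::read.delim(config$input$counts) else NULL
      fvfm <- if (!is.null(config$input$fvfm))
        utils::read.delim(config$input$fvfm) else NULL
    }
    emit(expr, "expression_fpkm.tsv")
    emit(meta, "sample_metadata.tsv")
    pipeline_log(quiet, "load", t0)

    stage_name <- "validate"
    emit(validate_dataset(expr, meta), "validation_findings.tsv")
    pipeline_log(quiet, "validate", t0)

    stage_name <- "select_descriptors"
    sets <- select_descriptor_sets(expr, meta, config$criteria,
                                   config$reference_stage)
    emit(summarize_descriptor_profiles(sets), "descriptor_profiles.tsv")
    dpath <- file.path(config$out_dir, "descriptor_sets.json")
    write_descriptor_sets(sets, dpath)
    outputs[[length(outputs) + 1L]] <- dpath
    pipeline_log(quiet, "select_descriptors", t0)

    stage_name <- "map_states"
    positions <- map_samples(expr, sets$x, sets$y,
                             config$criteria$pseudocount)
    # regions from leave-one-out reference positions, so radii reflect
    # the dispersion of unseen samples rather than in-sample optimism
    cv_pos <- crossvalidated_reference_positions(expr, meta, sets,
                                                 config$reference_stage)
    regions <- build_reference_regions(cv_pos, meta,
                                       config$reference_stage)
    positions$label <- classify_position(positions, regions)
    emit(positions, "state_positions.tsv")
    emit(as.data.frame(regions), "reference_regions.tsv")
    pipeline_log(quiet, "map_states", t0)

    stage_name <- "similarity"
    sim <- pairwise_spearman(expr, config$min_fpkm)
    emit(sim$scc, "scc_matrix.tsv")
    pipeline_log(quiet, "similarity", t0)

    stage_name <- "dispersion"
    dist_df <- replicate_distance_per_timepoint(positions, meta)
    emit(dist_df, "replicate_distances.tsv")
    stages <- sort(unique(meta$stage))
    dpairs <- config$distance_stage_pairs %||%
      lapply(setdiff(stages, config$reference_stage),
             function(s) c(config$reference_stage, s))
    dist_tests <- lapply(dpairs, function(pr) {
      r <- test_distance_shift(
        dist_df$distance[dist_df$stage == pr[1L]],
        dist_df$distance[dist_df$stage == pr[2L]])
      c(list(stage_a = pr[1L], stage_b = pr[2L]), r)
    })
    pipeline_log(quiet, "dispersion", t0)

    stage_name <- "cv_fvfm"
    cv_tests <- list(); cv_tab <- NULL
    if (!is.null(fvfm)) {
      cv_tab <- cv_over_replicates(fvfm)
      emit(cv_tab, "fvfm_cv.tsv")
      cpairs <- config$cv_stage_pairs %||% dpairs
      cv_tests <- lapply(cpairs, function(pr) {
        r <- test_cv_shift(cv_tab[cv_tab$stage == pr[1L], ],
                           cv_tab[cv_tab$stage == pr[2L], ],
                           fallback = "mann_whitney")
        c(list(stage_a = pr[1L], stage_b = pr[2L]), r)
      })
    }
    pipeline_log(quiet, "cv_fvfm", t0)

    stage_name <- "growth"
    fits <- NULL
    if (!is.null(growth)) {
      fits <- do.call(rbind, lapply(unique(growth$series_id), function(id) {
        g <- growth[growth$series_id == id, ]
        f <- suppressWarnings(fit_logistic_with_lag(g))
        mu_ll <- specific_growth_rate(g, auto = TRUE)
        data.frame(series_id = id, K = f$K, mu = f$mu, lag = f$lag,
                   n0 = f$n0, converged = f$converged,
                   mu_loglinear = mu_ll$mu, stringsAsFactors = FALSE)
      }))
      emit(fits, "growth_fits.tsv")
    }
    pipeline_log(quiet, "growth", t0)

    stage_name <- "manifest"
    tests_json <- list(distance = dist_tests, cv = cv_tests)
    jpath <- file.path(config$out_dir, "test_results.json")
    jsonlite::write_json(tests_json, jpath, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    outputs[[length(outputs) + 1L]] <- jpath
    manifest <- list(
      package = "statescape",
      seed = config$seed,
      config = config_echo(config),
      outputs = lapply(sort(unlist(outputs)), function(p)
        list(file = basename(p),
             md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    unlink(file.path(config$out_dir, "FAILED"))
    pipeline_log(quiet, "manifest", t0)
    invisible(manifest)
  }, error = function(e) {
    if (grepl("^pipeline stage", conditionMessage(e))) stop(e)
    on_fail(e)
  })
}

# plain-list echo of a config for the manifest (classes stripped)
config_echo <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Scatter plot of state-space positions with reference regions
#'
#' Base-graphics rendering of mapped positions: points colored by
#' classified label, dashed circles at 1.96 SD around each reference
#' state centroid.
#'
#' @param positions Data.frame with `s_x`, `s_y` and optionally `label`.
#' @param regions Optional [build_reference_regions()] result.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_state_space <- function(positions, regions = NULL, ...) {
  lab <- positions$label %||% rep("sample", nrow(positions))
  cols <- c("light-early" = "#E69F00", "light-late" = "#D55E00",
            "dark-early" = "#56B4E9", "dark-late" = "#0072B2",
            "non-distinctive" = "grey50", sample = "black")
  plot(positions$s_x, positions$s_y, pch = 19,
       col = cols[lab], xlim = c(-2, 2), ylim = c(-2, 2),
       xlab = expression(s[x] ~ "(diurnal)"),
       ylab = expression(s[y] ~ "(growth phase)"), ...)
  abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (!is.null(regions)) {
    th <- seq(0, 2 * pi, length.out = 200)
    for (i in seq_len(nrow(regions))) {
      lines(regions$centroid_x[i] + regions$radius[i] * cos(th),
            regions$centroid_y[i] + regions$radius[i] * sin(th),
            lty = 2, col = "grey40")
      text(regions$centroid_x[i], regions$centroid_y[i],
           regions$state[i], cex = 0.7, col = "grey20")
    }
  }
  invisible(NULL)
}
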