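#' Selection criteria for state-descriptor transcripts
#'
#' A transcript qualifies as a state descriptor for an axis when, across
#' the axis's two reference states, it (1) differs significantly by a
#' two-sided rank-sum test on log10 FPKM at `alpha` (after the configured
#' multiple-testing adjustment), (2) shows at least `fold_change_min`-fold
#' change, i.e. an absolute median difference of at least
#' `log10(fold_change_min)` in log10 space, and (3) has median separation
#' of at least `separation_sd_multiple` times the mean of the two
#' per-state sample SDs (log10 space, n-1 denominator).
#'
#' @param fold_change_min Minimum fold change, linear scale (> 1).
#' @param separation_sd_multiple Required median separation in units of
#'   the average per-state SD.
#' @param alpha Significance level.
#' @param multiple_testing `"bh"` (Benjamini-Hochberg) or `"none"`.
#' @param pseudocount Added to FPKM before log10.
#' @return A list of class `descriptor_criteria`.
#' @export
descriptor_criteria <- function(fold_change_min = 2.0,
                                separation_sd_multiple = 1.0,
                                alpha = 0.05,
                                multiple_testing = c("bh", "none"),
                                pseudocount = 1.0) {
  multiple_testing <- match.arg(multiple_testing)
  if (fold_change_min <= 1) stop_ss("fold_change_min must be > 1")
  if (!(alpha > 0 && alpha < 1)) stop_ss("alpha must lie in (0, 1)")
  if (pseudocount < 0) stop_ss("pseudocount must be >= 0")
  structure(list(fold_change_min = fold_change_min,
                 separation_sd_multiple = separation_sd_multiple,
                 alpha = alpha, multiple_testing = multiple_testing,
                 pseudocount = pseudocount),
            class = "descriptor_criteria")
}

#' Log10-transform an expression matrix
#'
#' @param expr Non-negative expression matrix or vector (FPKM).
#' @param pseudocount Added before log10; with `pseudocount = 0` every
#'   value must be strictly positive.
#' @return `log10(expr + pseudocount)`, elementwise.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (pseudocount < 0) stop_ss("pseudocount must be >= 0")
  if (pseudocount == 0 && any(expr <= 0))
    stop_ss("zero values cannot be log-transformed with pseudocount 0")
  log10(expr + pseudocount)
}

axis_labels <- function(axis) {
  switch(axis,
         diurnal = list(col = "diurnal_phase", alpha = "light",
                        beta = "dark"),
         growth_phase = list(col = "growth_phase", alpha = "early",
                             beta = "late"),
         stop_ss("axis must be 'diurnal' or 'growth_phase'"))
}

# Per-gene two-sided Mann-Whitney U on rows of a log10 matrix.
# A fully tied gene has an undefined normal-approximation p; it carries
# no signal, so it gets p = 1.
rowwise_ranksum_p <- function(lexpr, in_a, in_b) {
  p <- apply(lexpr, 1L, function(v)
    suppressWarnings(
      stats::wilcox.test(v[in_a], v[in_b], exact = NULL)$p.value))
  p[is.na(p)] <- 1
  p
}

# Selection statistics for every gene on one axis (no thresholding).
axis_gene_stats <- function(lexpr, meta, axis) {
  lab <- axis_labels(axis)
  in_a <- meta[[lab$col]] == lab$alpha
  in_b <- meta[[lab$col]] == lab$beta
  if (sum(in_a) < 2L || sum(in_b) < 2L)
    stop_ss("axis '", axis, "' needs >= 2 reference samples per state")
  a <- lexpr[, in_a, drop = FALSE]
  b <- lexpr[, in_b, drop = FALSE]
  med_a <- apply(a, 1L, stats::median)
  med_b <- apply(b, 1L, stats::median)
  sd_a <- apply(a, 1L, stats::sd)
  sd_b <- apply(b, 1L, stats::sd)
  data.frame(gene_id = rownames(lexpr),
             median_diff = med_a - med_b,
             mean_sd = (sd_a + sd_b) / 2,
             p = rowwise_ranksum_p(lexpr, in_a, in_b),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select state-descriptor transcripts for one axis
#'
#' Applies the three criteria of [descriptor_criteria()] to the
#' reference-stage samples (all conditions pooled by default) and builds a
#' [descriptor_profile()] for each selected gene from its two per-state
#' log10 distributions. Uniform weights summing to one are attached.
#'
#' @param expr FPKM expression matrix (genes x samples).
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param axis `"diurnal"` or `"growth_phase"`.
#' @param criteria A [descriptor_criteria()].
#' @param reference_stage Stage whose samples are the reference
#'   population.
#' @param exclude Gene ids to exclude (e.g. descriptors already claimed
#'   by the other axis).
#' @return A list of class `descriptor_set` with `axis`, `profiles`
#'   (named list of descriptor profiles), `weights` (uniform), and
#'   `stats` (the per-gene criteria table). Zero selections produce an
#'   empty set with a warning.
#' @export
select_state_descriptors <- function(expr, meta, axis,
                                     criteria = descriptor_criteria(),
                                     reference_stage = 1L,
                                     exclude = character()) {
  expr <- validate_expression_matrix(expr)
  meta <- validate_sample_metadata(meta)
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop_ss("every expression sample needs a metadata row")
  ref <- meta$stage == reference_stage
  if (sum(ref) < 4L) stop_ss("too few reference-stage samples")
  lexpr <- log_transform(expr[, ref, drop = FALSE], criteria$pseudocount)
  mref <- meta[ref, ]

  st <- axis_gene_stats(lexpr, mref, axis)
  st$p_adj <- if (criteria$multiple_testing == "bh")
    stats::p.adjust(st$p, method = "BH") else st$p
  st$selected <- st$p_adj < criteria$alpha &
    abs(st$median_diff) >= log10(criteria$fold_change_min) &
    st$mean_sd > 0 &
    abs(st$median_diff) >= criteria$separation_sd_multiple * st$mean_sd &
    !(st$gene_id %in% exclude)

  picked <- st$gene_id[st$selected]
  if (length(picked) == 0L)
    warning("no state descriptors found for axis '", axis,
            "'; state-space mapping on this axis is impossible",
            call. = FALSE)
  lab <- axis_labels(axis)
  in_a <- mref[[lab$col]] == lab$alpha
  in_b <- mref[[lab$col]] == lab$beta
  profiles <- lapply(picked, function(g)
    descriptor_profile(g, axis, lexpr[g, in_a], lexpr[g, in_b]))
  names(profiles) <- picked
  structure(list(axis = axis, profiles = profiles,
                 weights = if (length(picked)) rep(1 / length(picked),
                                                   length(picked))
                           else numeric(),
                 stats = st,
                 pseudocount = criteria$pseudocount),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("descriptor set [", x$axis, "]: ", length(x$profiles),
      " transcripts, uniform weights\n", sep = "")
  invisible(x)
}

#' Select both descriptor sets with non-overlap enforcement
#'
#' Runs [select_state_descriptors()] on the diurnal and growth-phase axes
#' and enforces non-overlapping sets: a gene qualifying for both axes is
#' assigned to the axis where its separation-to-SD ratio
#' `|median difference| / mean SD` is larger (ties to the diurnal axis).
#'
#' @inheritParams select_state_descriptors
#' @return A list with elements `x` (diurnal set) and `y` (growth-phase
#'   set).
#' @export
select_descriptor_sets <- function(expr, meta,
                                   criteria = descriptor_criteria(),
                                   reference_stage = 1L) {
  sx <- select_state_descriptors(expr, meta, "diurnal", criteria,
                                 reference_stage)
  sy <- select_state_descriptors(expr, meta, "growth_phase", criteria,
                                 reference_stage)
  both <- intersect(names(sx$profiles), names(sy$profiles))
  if (length(both) > 0L) {
    ratio <- function(set, g) {
      r <- set$stats[match(g, set$stats$gene_id), ]
      abs(r$median_diff) / r$mean_sd
    }
    to_y <- both[ratio(sy, both) > ratio(sx, both)]
    to_x <- setdiff(both, to_y)
    sx <- drop_descriptors(sx, to_y)
    sy <- drop_descriptors(sy, to_x)
  }
  list(x = sx, y = sy)
}

drop_descriptors <- function(set, gene_ids) {
  keep <- setdiff(names(set$profiles), gene_ids)
  set$profiles <- set$profiles[keep]
  set$weights <- if (length(keep)) rep(1 / length(keep), length(keep))
                 else numeric()
  set$stats$selected <- set$stats$selected &
    !(set$stats$gene_id %in% gene_ids)
  set
}

#' Summarize descriptor profiles as a table
#'
#' One row per descriptor with its medians, extremes, orientation and gap
#' geometry; gap fields are NA when the two reference distributions
#' overlap.
#'
#' @param set A `descriptor_set` (or the list returned by
#'   [select_descriptor_sets()], whose two sets are concatenated).
#' @return A data.frame with one row per descriptor.
#' @export
summarize_descriptor_profiles <- function(set) {
  if (is.list(set) && !inherits(set, "descriptor_set") &&
      all(c("x", "y") %in% names(set)))
    return(rbind(summarize_descriptor_profiles(set$x),
                 summarize_descriptor_profiles(set$y)))
  if (length(set$profiles) == 0L)
    stop_ss("descriptor set is empty")
  do.call(rbind, lapply(set$profiles, function(p)
    data.frame(gene_id = p$gene_id, axis = p$axis,
               q2_alpha = p$q2_alpha, min_alpha = p$min_alpha,
               max_alpha = p$max_alpha, q2_beta = p$q2_beta,
               min_beta = p$min_beta, max_beta = p$max_beta,
               epsilon = p$epsilon, gap = p$gap,
               gap_center = p$gap_center,
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' Serialize / restore descriptor sets as JSON
#'
#' @param sets The list returned by [select_descriptor_sets()].
#' @param path JSON file path.
#' @return `write_descriptor_sets` returns `path` invisibly;
#'   `read_descriptor_sets` returns the restored list.
#' @export
write_descriptor_sets <- function(sets, path) {
  strip <- function(set) {
    list(axis = set$axis,
         pseudocount = set$pseudocount,
         weights = set$weights,
         profiles = lapply(set$profiles, function(p)
           unclass(p)[c("gene_id", "axis", "q2_alpha", "q2_beta",
                        "min_alpha", "max_alpha", "min_beta", "max_beta",
                        "sd_alpha", "sd_beta", "epsilon", "gap",
                        "gap_center")]))
  }
  # digits = I(17): doubles must survive the round-trip bit-exactly,
  # since profile extremes act as branch boundaries in the score
  jsonlite::write_json(list(x = strip(sets$x), y = strip(sets$y)), path,
                       auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_descriptor_sets
#' @export
read_descriptor_sets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  restore <- function(s) {
    profiles <- lapply(s$profiles, function(p) {
      p$gap_center <- p$gap_center %||% NA_real_
      structure(p, class = "descriptor_profile")
    })
    structure(list(axis = s$axis, profiles = profiles,
                   weights = unlist(s$weights),
                   pseudocount = s$pseudocount),
              class = "descriptor_set")
  }
  list(x = restore(raw$x), y = restore(raw$y))
}

#' Compare a gene set between two conditions
#'
#' Generic targeted comparison: for each gene, the log2 fold change of
#' median FPKM (condition b over condition a, pseudocount-protected), a
#' two-sided rank-sum p-value, its BH adjustment, and a direction flag
#' (`"up"` / `"down"` / `"ns"`) at `alpha` on the adjusted p.
#'
#' @param expr FPKM expression matrix.
#' @param meta Sample metadata.
#' @param gene_ids Genes to test (must all be present).
#' @param condition_a,condition_b Condition labels to compare.
#' @param alpha Significance level applied to adjusted p-values.
#' @param pseudocount Added to median FPKM before the log2 ratio.
#' @return A list with `table` (per-gene results) and `summary` (counts
#'   of up / down / ns).
#' @export
compare_gene_set_between_conditions <- function(expr, meta, gene_ids,
                                                condition_a, condition_b,
                                                alpha = 0.05,
                                                pseudocount = 1) {
  expr <- validate_expression_matrix(expr)
  meta <- validate_sample_metadata(meta)
  if (length(gene_ids) == 0L) stop_ss("gene set is empty")
  unknown <- setdiff(gene_ids, rownames(expr))
  if (length(unknown) > 0L)
    stop_ss("gene id(s) not in expression matrix: ",
            paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  in_a <- !is.na(meta$condition) & meta$condition == condition_a
  in_b <- !is.na(meta$condition) & meta$condition == condition_b
  if (sum(in_a) < 2L || sum(in_b) < 2L)
    stop_ss("both conditions need >= 2 samples")
  res <- do.call(rbind, lapply(gene_ids, function(g) {
    va <- expr[g, in_a]; vb <- expr[g, in_b]
    p <- suppressWarnings(stats::wilcox.test(va, vb, exact = NULL)$p.value)
    if (is.na(p)) p <- 1  # fully tied: no evidence of a shift
    data.frame(gene_id = g,
               median_a = stats::median(va), median_b = stats::median(vb),
               log2_fc = log2((stats::median(vb) + pseudocount) /
                              (stats::median(va) + pseudocount)),
               p = p, stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$p_adj >= alpha | res$log2_fc == 0, "ns",
                          ifelse(res$log2_fc > 0, "up", "down"))
  list(table = res,
       summary = c(up = sum(res$direction == "up"),
                   down = sum(res$direction == "down"),
                   ns = sum(res$direction == "ns")))
}
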