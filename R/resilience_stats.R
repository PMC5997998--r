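#' Pairwise Spearman similarity between transcriptomes
#'
#' Computes the Spearman rank correlation coefficient (SCC) between every
#' pair of samples, after removing noise from low-abundance transcripts:
#' only genes with FPKM at or above `min_fpkm` in **every** sample of the
#' comparison set are retained, so the same gene compendium enters each
#' comparison. Ties receive average ranks.
#'
#' @param expr FPKM expression matrix (genes x samples).
#' @param min_fpkm Minimum FPKM a gene must reach in all samples
#'   (default 5).
#' @param per_pair If TRUE, apply the filter per sample pair instead of
#'   globally (each SCC then uses its own gene set).
#' @return A list of class `similarity_matrix` with `scc` (symmetric
#'   matrix, unit diagonal) and `n_genes_used`.
#' @export
pairwise_spearman <- function(expr, min_fpkm = 5, per_pair = FALSE) {
  expr <- validate_expression_matrix(expr)
  if (ncol(expr) < 2L) stop_ss("need >= 2 samples")
  if (per_pair) {
    n <- ncol(expr)
    scc <- diag(1, n)
    dimnames(scc) <- list(colnames(expr), colnames(expr))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      keep <- expr[, i] >= min_fpkm & expr[, j] >= min_fpkm
      if (sum(keep) < 3L)
        stop_ss("fewer than 3 genes pass the ", min_fpkm,
                "-FPKM filter for pair (", colnames(expr)[i], ", ",
                colnames(expr)[j], ")")
      scc[i, j] <- scc[j, i] <-
        stats::cor(expr[keep, i], expr[keep, j], method = "spearman")
    }
    n_used <- NA_integer_
  } else {
    keep <- rowSums(expr >= min_fpkm) == ncol(expr)
    n_used <- sum(keep)
    if (n_used < 3L)
      stop_ss("fewer than 3 genes pass the ", min_fpkm, "-FPKM filter")
    scc <- stats::cor(expr[keep, , drop = FALSE], method = "spearman")
  }
  structure(list(scc = scc, n_genes_used = n_used, min_fpkm = min_fpkm),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Spearman similarity over", ncol(x$scc), "samples;",
      x$n_genes_used, "genes >=", x$min_fpkm, "FPKM in all samples\n")
  invisible(x)
}

#' Pairwise replicate distances in the state space
#'
#' For each (condition, stage, time-point) group, the Euclidean distances
#' between all unordered pairs of replicate positions in (s_x, s_y)
#' space. With k replicates a group contributes choose(k, 2) distances.
#'
#' @param positions Data.frame from [map_samples()].
#' @param meta Sample metadata; samples are grouped by condition, stage,
#'   and time-point (diurnal phase x growth phase, i.e. the sampled point
#'   within the growth cycle; the `time` column is used when present).
#' @return A data.frame with columns `condition`, `stage`, `timepoint`,
#'   `pair`, `distance`.
#' @export
replicate_distance_per_timepoint <- function(positions, meta) {
  meta <- validate_sample_metadata(meta)
  m <- meta[match(positions$sample_id, meta$sample_id), ]
  if (any(is.na(m$sample_id)))
    stop_ss("positions contain samples without metadata")
  tp <- if ("time" %in% colnames(m) && !any(is.na(m$time)))
    as.character(m$time)
  else paste(m$diurnal_phase, m$growth_phase, sep = "-")
  key <- paste(m$condition, m$stage, tp, sep = "|")
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    if (length(idx) < 2L) return(NULL)
    prs <- utils::combn(idx, 2L)
    data.frame(condition = m$condition[idx[1L]],
               stage = m$stage[idx[1L]],
               timepoint = tp[idx[1L]],
               pair = paste(m$replicate[prs[1L, ]],
                            m$replicate[prs[2L, ]], sep = "-"),
               distance = sqrt(
                 (positions$s_x[prs[1L, ]] - positions$s_x[prs[2L, ]])^2 +
                 (positions$s_y[prs[1L, ]] - positions$s_y[prs[2L, ]])^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop_ss("no group has >= 2 replicate positions")
  row.names(out) <- NULL
  out
}

#' Mann-Whitney U test for a shift between two distance distributions
#'
#' Two-sided Mann-Whitney U comparing replicate-dispersion distances of
#' two groupings (e.g. a reference stage versus the stage preceding
#' collapse). Exact p for small tie-free samples, normal approximation
#' with tie correction otherwise (as provided by [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors of distances.
#' @param exact Passed to [stats::wilcox.test()]; `NULL` (default) uses
#'   the exact distribution when both groups have < 50 values and no
#'   ties.
#' @return A list with `statistic` (U for group_a), `p_value`, `n_a`,
#'   `n_b`, and `method`.
#' @export
test_distance_shift <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_ss("both groups must be nonempty")
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(group_a), n_b = length(group_b), method = ht$method)
}

#' Coefficient of variation of replicate Fv/Fm per time-point
#'
#' @param fvfm Data.frame with columns `stage`, `time_index` (or `time`),
#'   `replicate`, and either `fvfm` or the (`fm`, `fo`) pair from which
#'   Fv/Fm is computed via [compute_fvfm()].
#' @return A data.frame with one row per (stage, time-point): `stage`,
#'   `time_index`, `n`, `mean_fvfm`, `cv` (sample SD over mean, n-1).
#' @export
cv_over_replicates <- function(fvfm) {
  if (!("fvfm" %in% colnames(fvfm))) {
    if (!all(c("fm", "fo") %in% colnames(fvfm)))
      stop_ss("need an 'fvfm' column or 'fm' and 'fo' columns")
    fvfm$fvfm <- compute_fvfm(fvfm$fm, fvfm$fo)
  }
  if (!("time_index" %in% colnames(fvfm))) {
    if (!("time" %in% colnames(fvfm))) stop_ss("need time_index or time")
    fvfm$time_index <- ave(fvfm$time, fvfm$stage,
                           FUN = function(t) match(t, sort(unique(t))))
  }
  key <- paste(fvfm$stage, fvfm$time_index, sep = "|")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    v <- fvfm$fvfm[key == k]
    if (length(v) < 2L)
      stop_ss("time-point with fewer than 2 replicates")
    if (mean(v) <= 0) stop_ss("CV undefined: non-positive mean Fv/Fm")
    data.frame(stage = fvfm$stage[key == k][1L],
               time_index = fvfm$time_index[key == k][1L],
               n = length(v), mean_fvfm = mean(v), cv = cv(v),
               stringsAsFactors = FALSE)
  }))
  out[order(out$stage, out$time_index), , drop = FALSE]
}

#' Paired test for CV inflation between two stages
#'
#' Pairs the per-time-point CV series of two stages by within-stage time
#' index (truncating to the shorter series) and applies a two-sided
#' Wilcoxon signed-rank test; zero differences are dropped, exact p is
#' used for n <= 25 without ties. With fewer than `min_pairs` usable
#' pairs the paired test is refused; `fallback = "mann_whitney"` then
#' compares the two CV distributions unpaired instead.
#'
#' @param cv_a,cv_b Numeric CV series (stage a, stage b), ordered by time
#'   index, or two rows-subsets of [cv_over_replicates()] output.
#' @param min_pairs Minimum usable (non-zero-difference) pairs.
#' @param fallback `"error"` or `"mann_whitney"`.
#' @return A list with `statistic` (signed-rank V of b over a),
#'   `p_value`, `n_pairs`, and `method`.
#' @export
test_cv_shift <- function(cv_a, cv_b, min_pairs = 5L,
                          fallback = c("error", "mann_whitney")) {
  fallback <- match.arg(fallback)
  if (is.data.frame(cv_a)) cv_a <- cv_a$cv[order(cv_a$time_index)]
  if (is.data.frame(cv_b)) cv_b <- cv_b$cv[order(cv_b$time_index)]
  n <- min(length(cv_a), length(cv_b))
  a <- cv_a[seq_len(n)]; b <- cv_b[seq_len(n)]
  usable <- sum(b - a != 0)
  if (usable < min_pairs) {
    if (fallback == "mann_whitney") {
      mw <- test_distance_shift(cv_a, cv_b)
      mw$method <- paste("fallback:", mw$method)
      return(mw)
    }
    stop_ss("only ", usable, " non-zero paired differences (< ",
            min_pairs, "); consider fallback = \"mann_whitney\"")
  }
  ht <- suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE, alternative = "two.sided",
                       exact = if (usable <= 25L) NULL else FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pairs = usable, method = ht$method)
}
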