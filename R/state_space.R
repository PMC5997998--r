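#' Construct a state-descriptor profile
#'
#' A descriptor profile stores, for one transcript, the two reference
#' expression distributions of the opposed physiological states on one
#' axis — alpha (light for the diurnal axis, early for the growth axis)
#' and beta (dark / late) — summarized by their medians Q2, extremes, the
#' orientation `epsilon` (+1 iff Q2(alpha) < Q2(beta)), and the gap
#' geometry: `gap` is the width of the empty interval between the two
#' distributions (0 when they overlap) and `gap_center` its midpoint.
#' All values are log10 FPKM.
#'
#' @param gene_id Transcript identifier.
#' @param axis `"diurnal"` or `"growth_phase"`.
#' @param alpha,beta Numeric vectors of reference log10 expression values
#'   for the alpha and beta states (>= 2 values each).
#' @return An object of class `descriptor_profile`.
#' @export
descriptor_profile <- function(gene_id, axis, alpha, beta) {
  if (length(alpha) < 2L || length(beta) < 2L)
    stop_ss("each state needs >= 2 reference values (gene ", gene_id, ")")
  q2a <- stats::median(alpha); q2b <- stats::median(beta)
  if (q2a == q2b)
    stop_ss("degenerate profile for gene ", gene_id,
            ": state medians are equal")
  p <- list(gene_id = gene_id, axis = axis,
            q2_alpha = q2a, q2_beta = q2b,
            min_alpha = min(alpha), max_alpha = max(alpha),
            min_beta = min(beta), max_beta = max(beta),
            sd_alpha = stats::sd(alpha), sd_beta = stats::sd(beta),
            epsilon = if (q2a < q2b) 1 else -1)
  lo_max <- if (p$epsilon == 1) p$max_alpha else p$max_beta
  hi_min <- if (p$epsilon == 1) p$min_beta else p$min_alpha
  p$gap <- max(hi_min - lo_max, 0)
  p$gap_center <- if (p$gap > 0) (hi_min + lo_max) / 2 else NA_real_
  class(p) <- "descriptor_profile"
  p
}

#' @export
print.descriptor_profile <- function(x, ...) {
  cat(sprintf(
    "descriptor %s [%s]: alpha{%.3g, Q2 %.3g, %.3g} beta{%.3g, Q2 %.3g, %.3g} eps %+d gap %.3g\n",
    x$gene_id, x$axis, x$min_alpha, x$q2_alpha, x$max_alpha,
    x$min_beta, x$q2_beta, x$max_beta, x$epsilon, x$gap))
  invisible(x)
}

#' Which state median is an expression value closer to?
#'
#' The piecewise selector delta: +1 when `kappa` is closer to the alpha
#' median, -1 when closer to the beta median, 0 on an exact tie.
#'
#' @param kappa Observed log10 expression value(s).
#' @param profile A [descriptor_profile()].
#' @return Integer vector of +1 / -1 / 0.
#' @export
closer_state <- function(kappa, profile) {
  da <- abs(kappa - profile$q2_alpha)
  db <- abs(kappa - profile$q2_beta)
  as.integer(sign(db - da))
}

#' Per-transcript position score
#'
#' Computes the position score lambda for observed log10 expression
#' `kappa` against a descriptor profile. If `kappa` falls inside the gap
#' between the two reference distributions, lambda is interpolated
#' linearly through the gap, `lambda = 2 * epsilon * (gap_center - kappa)
#' / gap`, reaching 0 at the gap center and +/-1 at the gap edges.
#' Otherwise lambda anchors at the median of the state selected by
#' [closer_state()] (value +/-1.5 at that median) and interpolates toward
#' the state's observed extremes (+/-2 at the outer extreme, +/-1 at the
#' inner one):
#' `lambda = 1.5*delta + epsilon*|kappa - Q2| / (2*|min - Q2|)` below the
#' median and `lambda = 1.5*delta - epsilon*|kappa - Q2| / (2*|max - Q2|)`
#' above it. Values beyond the observed reference range are clamped to
#' [-2, 2]; an exact tie between medians (no gap) scores 0.
#'
#' Positive lambda always means alpha-like (light / early) expression.
#'
#' @param kappa Observed log10 expression value(s); vectorized.
#' @param profile A [descriptor_profile()].
#' @param breakdown If TRUE return a data.frame with `kappa`, `delta`,
#'   `branch`, and `lambda`; otherwise just the lambda vector.
#' @return Numeric lambda in [-2, 2], or a breakdown data.frame.
#' @export
transcript_position_score <- function(kappa, profile, breakdown = FALSE) {
  p <- profile
  delta <- closer_state(kappa, p)
  lambda <- numeric(length(kappa))
  branch <- character(length(kappa))

  in_gap <- if (p$gap > 0) {
    lo_max <- if (p$epsilon == 1) p$max_alpha else p$max_beta
    hi_min <- if (p$epsilon == 1) p$min_beta else p$min_alpha
    kappa > lo_max & kappa < hi_min
  } else rep(FALSE, length(kappa))

  if (any(in_gap)) {
    lambda[in_gap] <- 2 * p$epsilon * (p$gap_center - kappa[in_gap]) / p$gap
    branch[in_gap] <- "in_gap"
  }
  out <- !in_gap
  if (any(out)) {
    d <- delta[out]; k <- kappa[out]
    q2 <- ifelse(d >= 0, p$q2_alpha, p$q2_beta)
    lo <- ifelse(d >= 0, p$min_alpha, p$min_beta)
    hi <- ifelse(d >= 0, p$max_alpha, p$max_beta)
    lam <- ifelse(d == 0, 0,
           ifelse(k < q2,
                  1.5 * d + p$epsilon * abs(k - q2) / (2 * abs(lo - q2)),
           ifelse(k > q2,
                  1.5 * d - p$epsilon * abs(k - q2) / (2 * abs(hi - q2)),
                  1.5 * d)))
    br <- ifelse(d == 0, "tie",
          ifelse(k < q2, "below_median",
          ifelse(k > q2, "above_median", "at_median")))
    clamp_lo <- lam < -2
    clamp_hi <- lam > 2
    lam[clamp_lo] <- -2; lam[clamp_hi] <- 2
    lam[is.nan(lam)] <- 0  # only reachable for 0/0 at a degenerate extreme
    br[clamp_lo] <- "clamped_low"; br[clamp_hi] <- "clamped_high"
    lambda[out] <- lam
    branch[out] <- br
  }
  if (breakdown)
    data.frame(kappa = kappa, delta = delta, branch = branch,
               lambda = lambda, stringsAsFactors = FALSE)
  else lambda
}

#' Map one transcriptome into the 2D physiological state space
#'
#' The coordinates are weighted averages of per-descriptor position
#' scores: `s_x = sum(w_i * lambda_i)` over the diurnal descriptor set and
#' `s_y` likewise over the growth-phase set, with weights summing to one
#' per axis (uniform by default). Positive `s_x` means light-like,
#' positive `s_y` early-like expression.
#'
#' @param log_expr Named numeric vector of log10 expression values (same
#'   pseudocount as used at descriptor selection), or a single-column
#'   slice of a log10 matrix.
#' @param x_set,y_set [descriptor_set] objects for the diurnal and
#'   growth-phase axes (see [select_state_descriptors()]).
#' @param sample_id Identifier recorded in the result.
#' @return A list of class `state_position` with `sample_id`, `s_x`,
#'   `s_y`, and per-axis breakdown data.frames.
#' @export
map_sample_to_state_space <- function(log_expr, x_set, y_set,
                                      sample_id = "sample") {
  axis_score <- function(set) {
    ids <- vapply(set$profiles, `[[`, "", "gene_id")
    missing <- setdiff(ids, names(log_expr))
    if (length(missing) > 0L)
      stop_ss("descriptor gene(s) absent from expression vector: ",
              paste(missing, collapse = ", "))
    bk <- do.call(rbind, lapply(set$profiles, function(p) {
      b <- transcript_position_score(log_expr[[p$gene_id]], p,
                                     breakdown = TRUE)
      cbind(gene_id = p$gene_id, b, stringsAsFactors = FALSE)
    }))
    list(s = sum(set$weights * bk$lambda), breakdown = bk)
  }
  x <- axis_score(x_set); y <- axis_score(y_set)
  structure(list(sample_id = sample_id, s_x = x$s, s_y = y$s,
                 breakdown_x = x$breakdown, breakdown_y = y$breakdown),
            class = "state_position")
}

#' @export
print.state_position <- function(x, ...) {
  cat(sprintf("state position %s: s_x = %.4f, s_y = %.4f\n",
              x$sample_id, x$s_x, x$s_y))
  invisible(x)
}

#' Map many samples into the state space
#'
#' @param expr FPKM expression matrix (genes x samples), untransformed.
#' @param x_set,y_set Descriptor sets for the two axes.
#' @param pseudocount Added before log10; must match the value used at
#'   selection.
#' @return A data.frame with columns `sample_id`, `s_x`, `s_y`.
#' @export
map_samples <- function(expr, x_set, y_set, pseudocount = 1) {
  lexpr <- log_transform(expr, pseudocount)
  axis_mat <- function(set) {
    ids <- vapply(set$profiles, `[[`, "", "gene_id")
    missing <- setdiff(ids, rownames(lexpr))
    if (length(missing) > 0L)
      stop_ss("descriptor gene(s) absent from expression matrix: ",
              paste(missing, collapse = ", "))
    lam <- vapply(set$profiles,
                  function(p) transcript_position_score(lexpr[p$gene_id, ], p),
                  numeric(ncol(lexpr)))
    if (is.null(dim(lam))) lam <- matrix(lam, nrow = 1L)
    drop(lam %*% set$weights)
  }
  data.frame(sample_id = colnames(lexpr),
             s_x = axis_mat(x_set), s_y = axis_mat(y_set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-validated state-space positions of the reference samples
#'
#' Positions of reference-stage samples computed out-of-sample: for each
#' reference sample, every descriptor's profile (medians, extremes, gap)
#' is rebuilt from the remaining reference samples before scoring it.
#' In-sample positions understate how far new transcriptomes scatter,
#' because a reference sample's expression can never exceed extremes it
#' itself defined; leave-one-out positions reflect the dispersion of
#' unseen samples and are the recommended input to
#' [build_reference_regions()].
#'
#' Descriptor membership and weights are kept fixed (re-running the
#' selection per fold would change the gene sets, not the geometry this
#' estimates).
#'
#' @param expr FPKM expression matrix containing the reference samples.
#' @param meta Sample metadata.
#' @param sets List with descriptor sets `x` and `y` (from
#'   [select_descriptor_sets()]).
#' @param reference_stage Stage whose samples are re-scored.
#' @return A data.frame with `sample_id`, `s_x`, `s_y`, one row per
#'   reference sample.
#' @export
crossvalidated_reference_positions <- function(expr, meta, sets,
                                               reference_stage = 1L) {
  meta <- validate_sample_metadata(meta)
  ref_ids <- meta$sample_id[meta$stage == reference_stage]
  ref_ids <- intersect(colnames(expr), ref_ids)
  if (length(ref_ids) < 5L) stop_ss("too few reference samples for LOO")
  pc <- sets$x$pseudocount %||% 1
  lexpr <- log_transform(expr[, ref_ids, drop = FALSE], pc)
  mref <- meta[match(ref_ids, meta$sample_id), ]
  score_loo <- function(set) {
    lab <- axis_labels(set$axis)
    is_a <- mref[[lab$col]] == lab$alpha
    vapply(seq_along(ref_ids), function(i) {
      lam <- vapply(set$profiles, function(p) {
        v <- lexpr[p$gene_id, -i]
        a <- is_a[-i]
        prof <- descriptor_profile(p$gene_id, p$axis, v[a], v[!a])
        transcript_position_score(lexpr[p$gene_id, i], prof)
      }, numeric(1L))
      sum(set$weights * lam)
    }, numeric(1L))
  }
  data.frame(sample_id = ref_ids,
             s_x = score_loo(sets$x), s_y = score_loo(sets$y),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the four stage-1 reference regions
#'
#' For each of the four physiological states (light/dark x early/late) the
#' reference region is a circle centred on the mean position of the
#' reference-stage samples of that state. The default radius is 1.96
#' times the standard deviation of those positions about their centroid,
#' i.e. `1.96 * sqrt(var(s_x) + var(s_y))` (the RMS distance from the
#' centroid, n-1 variances); `radius = "axis_rms"` instead uses the RMS
#' of the per-axis SDs, `1.96 * sqrt((var(s_x) + var(s_y)) / 2)`.
#'
#' @param positions Data.frame from [map_samples()] (reference-stage
#'   samples only, or filtered via `meta`).
#' @param meta Sample metadata supplying state labels.
#' @param reference_stage Stage whose samples define the regions.
#' @param radius `"distance_sd"` (default) or `"axis_rms"`.
#' @param pool If TRUE (default), the dispersion entering the radius is
#'   pooled across the four states (each sample's deviation taken from
#'   its own state centroid), giving one common radius estimated from all
#'   reference samples; with the typical 6 samples per state a per-state
#'   radius is too noisy to be useful. `pool = FALSE` estimates each
#'   state's radius from its own samples only.
#' @return A data.frame of class `reference_regions` with one row per
#'   state: `state`, `centroid_x`, `centroid_y`, `radius`, `n`.
#' @export
build_reference_regions <- function(positions, meta, reference_stage = 1L,
                                    radius = c("distance_sd", "axis_rms"),
                                    pool = TRUE) {
  radius <- match.arg(radius)
  meta <- validate_sample_metadata(meta)
  m <- meta[match(positions$sample_id, meta$sample_id), ]
  keep <- !is.na(m$stage) & m$stage == reference_stage
  pos <- positions[keep, ]; m <- m[keep, ]
  if (nrow(pos) == 0L) stop_ss("no positions in the reference stage")
  m$state <- paste(m$diurnal_phase, m$growth_phase, sep = "-")
  states <- c("light-early", "light-late", "dark-early", "dark-late")
  radius_from <- function(vx, vy) {
    if (radius == "distance_sd") 1.96 * sqrt(vx + vy)
    else 1.96 * sqrt((vx + vy) / 2)
  }
  per_state <- lapply(states, function(st) {
    p <- pos[m$state == st, ]
    if (nrow(p) < 2L)
      stop_ss("state '", st, "' has fewer than 2 reference samples")
    list(state = st, cx = mean(p$s_x), cy = mean(p$s_y),
         vx = stats::var(p$s_x), vy = stats::var(p$s_y), n = nrow(p))
  })
  if (pool) {
    # pooled within-state variances: n-1 weighted average over states
    w <- vapply(per_state, function(s) s$n - 1L, numeric(1L))
    vx <- sum(w * vapply(per_state, `[[`, 0, "vx")) / sum(w)
    vy <- sum(w * vapply(per_state, `[[`, 0, "vy")) / sum(w)
    r <- rep(radius_from(vx, vy), length(per_state))
  } else {
    r <- vapply(per_state, function(s) radius_from(s$vx, s$vy),
                numeric(1L))
  }
  out <- data.frame(
    state = vapply(per_state, `[[`, "", "state"),
    centroid_x = vapply(per_state, `[[`, 0, "cx"),
    centroid_y = vapply(per_state, `[[`, 0, "cy"),
    radius = r,
    n = vapply(per_state, function(s) s$n, numeric(1L)),
    stringsAsFactors = FALSE)
  class(out) <- c("reference_regions", class(out))
  out
}

#' Classify state-space positions against reference regions
#'
#' A position receives the label of the nearest region centroid when it
#' lies within that region's radius; otherwise — including exact
#' nearest-centroid ties — it is `"non-distinctive"`, the central area
#' where descriptor expression patterns are mixed and no reference state
#' applies.
#'
#' @param positions Data.frame with `s_x`, `s_y` (and optionally
#'   `sample_id`), or a single `state_position`.
#' @param regions A [build_reference_regions()] result.
#' @return Character vector of state labels / `"non-distinctive"`.
#' @export
classify_position <- function(positions, regions) {
  if (inherits(positions, "state_position"))
    positions <- data.frame(s_x = positions$s_x, s_y = positions$s_y)
  vapply(seq_len(nrow(positions)), function(i) {
    d <- sqrt((positions$s_x[i] - regions$centroid_x)^2 +
              (positions$s_y[i] - regions$centroid_y)^2)
    nearest <- which(d == min(d))
    if (length(nearest) > 1L) return("non-distinctive")
    if (d[nearest] <= regions$radius[nearest]) regions$state[nearest]
    else "non-distinctive"
  }, character(1L))
}
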