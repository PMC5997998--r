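# Independent scalar oracle for the per-transcript position score:
# a literal case-by-case transcription of the published piecewise rules
# (state selector delta, orientation epsilon, within-range interpolation,
# gap interpolation), with the same documented edge decisions as the
# production code: exact-tie delta -> 0, out-of-range values clamped to
# [-2, 2]. Deliberately written as plain scalar if/else, sharing no code
# with transcript_position_score().
oracle_lambda <- function(kappa, p) {
  q2a <- p$q2_alpha
  q2b <- p$q2_beta
  eps <- if (q2a < q2b) 1 else -1
  lo_max <- if (eps == 1) p$max_alpha else p$max_beta
  hi_min <- if (eps == 1) p$min_beta else p$min_alpha
  theta <- hi_min - lo_max
  if (theta > 0 && kappa > lo_max && kappa < hi_min) {
    theta_c <- (lo_max + hi_min) / 2
    return(2 * eps * (theta_c - kappa) / theta)
  }
  da <- abs(kappa - q2a)
  db <- abs(kappa - q2b)
  if (da == db) return(0)
  if (da < db) {
    delta <- 1; q2 <- q2a; mn <- p$min_alpha; mx <- p$max_alpha
  } else {
    delta <- -1; q2 <- q2b; mn <- p$min_beta; mx <- p$max_beta
  }
  lam <- if (kappa < q2) {
    1.5 * delta + eps * abs(kappa - q2) / (2 * abs(mn - q2))
  } else if (kappa > q2) {
    1.5 * delta - eps * abs(kappa - q2) / (2 * abs(mx - q2))
  } else {
    1.5 * delta
  }
  max(min(lam, 2), -2)
}

# TRUE when the equidistant point between the two medians lies strictly
# inside the gap, so the closer-state switch happens where the gap
# interpolation governs. The piecewise score is continuous everywhere
# for such profiles; for strongly asymmetric distributions (switch point
# inside one state's range) the published piecewise rules are inherently
# discontinuous at the switch.
tie_in_gap <- function(p) {
  if (p$gap <= 0) return(FALSE)
  lo_max <- if (p$epsilon == 1) p$max_alpha else p$max_beta
  hi_min <- if (p$epsilon == 1) p$min_beta else p$min_alpha
  tie <- (p$q2_alpha + p$q2_beta) / 2
  tie > lo_max && tie < hi_min
}

# Random profile whose score map is continuous (gap present, switch
# point interior to it).
random_balanced_profile <- function() {
  repeat {
    p <- random_profile(gapped = TRUE)
    if (tie_in_gap(p)) return(p)
  }
}

# Random descriptor profile from two reference samples of 8 values each.
# gapped = TRUE separates the distributions so the gap branch is
# exercised; gapped = FALSE lets them overlap.
random_profile <- function(gapped = TRUE) {
  c0 <- stats::runif(1, -1, 2)
  w1 <- stats::runif(1, 0.2, 1)
  w2 <- stats::runif(1, 0.2, 1)
  sep <- if (gapped) stats::runif(1, 0.2, 1.5) else -stats::runif(1, 0, w1)
  a <- stats::runif(8, c0, c0 + w1)
  b <- stats::runif(8, c0 + w1 + sep, c0 + w1 + sep + w2)
  if (stats::runif(1) < 0.5) {
    tmp <- a; a <- b; b <- tmp  # half the profiles have alpha on top
  }
  descriptor_profile("gtest", "diurnal", a, b)
}
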