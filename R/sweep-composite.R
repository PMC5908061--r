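#' Linkage disequilibrium r-squared between two sites
#'
#' `r2 = D^2 / (p_i (1-p_i) p_j (1-p_j))` with `D = p_ij - p_i p_j`
#' estimated from haplotype counts.
#'
#' @param hap A [hap_matrix()].
#' @param site_i,site_j Site positions (bp); both must be polymorphic.
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(hap, site_i, site_j) {
  ji <- match(site_i, hap$pos)
  jj <- match(site_j, hap$pos)
  if (is.na(ji) || is.na(jj)) abort("site not in haplotype matrix")
  x <- hap$mat[, ji]
  y <- hap$mat[, jj]
  pi_ <- mean(x)
  pj <- mean(y)
  if (pi_ %in% c(0, 1) || pj %in% c(0, 1)) {
    abort("r-squared undefined at a monomorphic site")
  }
  d <- mean(x * y) - pi_ * pj
  d^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
}

# All-pairs r2 for the (polymorphic) columns of a haplotype matrix.
# Squared Pearson correlation of 0/1 indicators equals the LD r2.
r2_matrix <- function(hap) {
  p <- derived_freqs(hap)
  if (any(p %in% c(0, 1))) abort("r2 matrix needs all sites polymorphic")
  suppressWarnings(cor(hap$mat))^2
}

#' The omega statistic on an r-squared matrix
#'
#' For each split `l` of the `S` sites into a left block `1..l` and a
#' right block, omega(l) is the mean within-block r2 divided by the mean
#' between-block r2 (denominator guarded by `eps`); the statistic is the
#' maximum over `l` in `[2, S-2]`. Elevated values mean strong LD within
#' both flanks but not across, the footprint a completed sweep leaves
#' around the fixed site.
#'
#' @param r2 Symmetric matrix of pairwise r-squared values.
#' @param eps Denominator guard.
#' @return A one-row tibble: `omega`, `split` (the argmax `l`), `S`;
#'   attribute `"per_split"` holds omega(l) for every candidate split.
#' @export
omega_stat <- function(r2, eps = 1e-9) {
  s <- nrow(r2)
  if (s < 4L) {
    out <- tibble(omega = NA_real_, split = NA_integer_, S = s)
    attr(out, "per_split") <- numeric()
    return(out)
  }
  total <- sum(r2[upper.tri(r2)])
  # incremental within-left sums over l
  wl <- numeric(s)
  for (l in 2:s) wl[l] <- wl[l - 1] + sum(r2[1:(l - 1), l])
  splits <- 2:(s - 2)
  per <- vapply(splits, function(l) {
    within_l <- wl[l]
    between <- sum(r2[1:l, (l + 1):s])
    within_r <- total - within_l - between
    num <- (within_l + within_r) / (choose(l, 2) + choose(s - l, 2))
    den <- between / (l * (s - l))
    num / max(den, eps)
  }, numeric(1))
  best <- which.max(per)
  out <- tibble(omega = per[best], split = splits[best], S = s)
  attr(out, "per_split") <- stats::setNames(per, splits)
  out
}

#' @rdname omega_stat
#' @param hap A [hap_matrix()]; its polymorphic sites form the window.
#' @param sites Optional site subset.
#' @export
omega <- function(hap, sites = NULL, eps = 1e-9) {
  if (!is.null(sites)) hap <- subset_sites(hap, sites)
  hap <- polymorphic_sites(hap)
  if (n_sites(hap) < 4L) {
    out <- tibble(omega = NA_real_, split = NA_integer_, S = n_sites(hap))
    attr(out, "per_split") <- numeric()
    return(out)
  }
  res <- omega_stat(r2_matrix(hap), eps = eps)
  res$split_pos <- hap$pos[res$split]
  res
}

#' Omega across fixed-width bins
#'
#' @param hap A [hap_matrix()].
#' @param region One-row [genomic_interval()].
#' @param bin_width Bin width in bp (default 1 kb).
#' @return A tibble: `bin_start`, `bin_end`, `omega`, `S` (`NA` omega
#'   where a bin has fewer than 4 polymorphic sites).
#' @export
omega_track <- function(hap, region, bin_width = 1000L) {
  starts <- seq(region$start[1], region$end[1], by = bin_width)
  ends <- pmin(starts + bin_width - 1L, region$end[1])
  purrr::map2_dfr(starts, ends, function(s, e) {
    in_bin <- hap$pos >= s & hap$pos <= e
    res <- omega(hap, in_bin)
    tibble(bin_start = s, bin_end = e, omega = res$omega, S = res$S)
  })
}

# P(derived count = b | e lineages escaped the sweep) for b = 0..n,
# mixing over the empirical background spectrum: the n-sample background
# is downsampled (hypergeometric, without replacement) to the e escapees
# plus one sweeping stem lineage, and the stem then expands to n - e
# copies. With e = n (full escape) the distribution is the background
# itself, so the sweep model reduces exactly to the null as p_e -> 1.
sweep_class_matrix <- function(n, bg) {
  V <- matrix(0, n + 1L, n + 1L)
  for (e in 0:n) {
    if (e == n) {
      V[2:n, e + 1L] <- bg
      next
    }
    m <- e + 1L
    for (j in seq_len(n - 1L)) {
      bp <- 0:m
      w <- stats::dhyper(bp, j, n - j, m) * bg[j]
      stem_derived <- bp / m
      V[bp + 1L, e + 1L] <- V[bp + 1L, e + 1L] + w * (1 - stem_derived)
      tgt <- bp - 1L + (n - e)
      V[tgt + 1L, e + 1L] <- V[tgt + 1L, e + 1L] + w * stem_derived
    }
  }
  V
}

#' Composite likelihood ratio scan for a completed sweep
#'
#' Nielsen-style star approximation with an empirical background: the
#' null model is the region's unfolded site frequency spectrum (0.5
#' pseudocount per class). Under the sweep model at a grid position,
#' each of the n sampled lineages at a site `d` bp away escapes the
#' hitchhiking event independently with probability
#' `p_e = 1 - exp(-alpha * d)`; the non-escaped lineages collapse onto
#' the single sweeping haplotype, and the derived count follows from
#' hypergeometric downsampling of the background spectrum to the
#' escapees plus that stem. With full escape the model reduces exactly
#' to the background, so `CLR = 2 (max_alpha sum ln P_sweep - sum ln
#' P_background)`, clipped at 0, vanishes when the fitted sweep has no
#' effect. With `include_invariant = TRUE` (default) the composite
#' likelihood also uses the probability that each position is
#' polymorphic at all, which carries the diversity trough around a
#' sweep; polymorphic-sites-only mode is available.
#'
#' @param hap A [hap_matrix()] with ancestral states known.
#' @param region Optional one-row [genomic_interval()] giving the grid
#'   and locus extent (defaults to the span of the polymorphic sites).
#' @param grid_step Spacing of test positions in bp.
#' @param alpha_grid Candidate per-bp decay rates; default 25 log-spaced
#'   points from `20/span` (a footprint no wider than the scanned
#'   region) to 0.1.
#' @param include_invariant Use invariant-position information.
#' @param pe_resolution Escape-probability discretization step.
#' @return A tibble of class `clr_scan`: `pos`, `clr`, `alpha_hat`.
#' @export
clr_scan <- function(hap, region = NULL, grid_step = 500L,
                     alpha_grid = NULL, include_invariant = TRUE,
                     pe_resolution = 0.01) {
  hap <- subset_sites(hap, hap$anc_known)
  hap <- polymorphic_sites(hap)
  s <- n_sites(hap)
  if (s == 0L) {
    return(structure(tibble(pos = integer(), clr = numeric(),
                            alpha_hat = numeric()),
                     class = c("clr_scan", class(tibble()))))
  }
  n <- n_chrom(hap)
  k <- derived_counts(hap)
  counts <- tabulate(k, nbins = n - 1L)
  bg <- (counts + 0.5) / sum(counts + 0.5)
  lo <- if (!is.null(region)) region$start[1] else min(hap$pos)
  hi <- if (!is.null(region)) region$end[1] else max(hap$pos)
  span <- hi - lo + 1L
  alpha_grid <- alpha_grid %||% 10^seq(log10(20 / span), -1,
                                       length.out = 25)
  # class probabilities tabulated over a discretized escape grid
  pe_grid <- seq(0, 1, by = pe_resolution)
  n_pe <- length(pe_grid)
  W <- vapply(pe_grid, function(pe) stats::dbinom(0:n, n, pe),
              numeric(n + 1L))
  Tm <- sweep_class_matrix(n, bg) %*% W
  Tpoly <- Tm[2:n, , drop = FALSE]
  ppoly <- pmax(colSums(Tpoly), 1e-12)        # P(polymorphic | pe)
  Tcond <- sweep(Tpoly, 2, ppoly, "/")
  p_bg <- s / span                            # per-bp polymorphism prob
  lnl_bg <- sum(log(bg[k]))
  if (include_invariant) {
    lnl_bg <- lnl_bg + s * log(p_bg) + (span - s) * log(1 - p_bg)
    qstep <- 100L
    qpos <- seq(lo + qstep / 2, hi, by = qstep)  # quantized positions
  }
  pe_bin <- function(d, a) {
    pmin(as.integer(round((1 - exp(-a * d)) / pe_resolution)) + 1L, n_pe)
  }
  grid <- seq(lo, hi, by = grid_step)
  out <- purrr::map_dfr(grid, function(x) {
    d <- abs(hap$pos - x)
    if (include_invariant) dq <- abs(qpos - x)
    best <- -Inf
    best_alpha <- alpha_grid[1]
    for (a in alpha_grid) {
      bin <- pe_bin(d, a)
      lnl <- sum(log(pmax(Tcond[cbind(k, bin)], 1e-300)))
      if (include_invariant) {
        binq <- pe_bin(dq, a)
        lnl <- lnl + sum(log(pmax(p_bg * ppoly[bin], 1e-300))) +
          qstep * sum(log(1 - pmin(p_bg * ppoly[binq], 0.99)))
      }
      if (lnl > best) {
        best <- lnl
        best_alpha <- a
      }
    }
    tibble(pos = x, clr = max(0, 2 * (best - lnl_bg)), alpha_hat = best_alpha)
  })
  class(out) <- c("clr_scan", class(out))
  out
}

#' CLR per fixed-width bin (maximum over grid positions in the bin)
#'
#' @inheritParams omega_track
#' @param ... Passed to [clr_scan()].
#' @return A tibble: `bin_start`, `bin_end`, `clr`, `alpha_hat`.
#' @export
clr_track <- function(hap, region, bin_width = 1000L, ...) {
  scan <- clr_scan(hap, region, ...)
  starts <- seq(region$start[1], region$end[1], by = bin_width)
  ends <- pmin(starts + bin_width - 1L, region$end[1])
  purrr::map2_dfr(starts, ends, function(s, e) {
    in_bin <- scan$pos >= s & scan$pos <= e
    if (!any(in_bin)) {
      return(tibble(bin_start = s, bin_end = e, clr = NA_real_,
                    alpha_hat = NA_real_))
    }
    best <- which(in_bin)[which.max(scan$clr[in_bin])]
    tibble(bin_start = s, bin_end = e, clr = scan$clr[best],
           alpha_hat = scan$alpha_hat[best])
  })
}

#' Calibrate significance thresholds on a neutral null
#'
#' Runs `simulator` `n_reps` times, collects the per-replicate summary
#' returned by `statistic` (typically the replicate's maximum CLR or
#' omega), and reports the empirical `(1 - q)` quantile for each cutoff
#' `q`. Replicates where the statistic is undefined (`NA`) are excluded
#' and counted.
#'
#' @param statistic Function: replicate output -> scalar.
#' @param simulator Function: replicate index -> replicate output (close
#'   over your null configuration; give it an explicit seed policy).
#' @param n_reps Number of replicates (>= 100 recommended).
#' @param cutoffs Tail probabilities (default 0.05 and 0.1).
#' @param seed Optional seed applied once around the whole run.
#' @return A tibble `cutoff`, `threshold`; attributes `n_used`,
#'   `n_excluded`.
#' @export
calibrate_null <- function(statistic, simulator, n_reps,
                           cutoffs = c(0.05, 0.1), seed = NULL) {
  vals <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) as.numeric(statistic(simulator(i))),
           numeric(1))
  })
  ok <- !is.na(vals)
  out <- tibble(cutoff = cutoffs,
                threshold = quantile(vals[ok], 1 - cutoffs, names = FALSE))
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

threshold_for <- function(thresholds, q) {
  i <- which(abs(thresholds$cutoff - q) < 1e-12)
  if (!length(i)) abort(sprintf("no calibrated threshold for cutoff %g", q))
  thresholds$threshold[i[1]]
}

top_flags <- function(x, top_fraction) {
  flag <- rep(FALSE, length(x))
  ok <- which(!is.na(x))
  if (!length(ok)) return(flag)
  m <- max(1L, ceiling(top_fraction * length(ok)))
  flag[ok[order(x[ok], decreasing = TRUE)[seq_len(m)]]] <- TRUE
  flag
}

#' Compound CLR + omega outlier test
#'
#' Flags each bin against the calibrated P = 0.05 and P = 0.1 null
#' thresholds and against the empirical top-1% rule, per statistic; a
#' common outlier is a bin flagged by *both* statistics under the chosen
#' criterion.
#'
#' @param clr_track,omega_track Tibbles from [clr_track()] /
#'   [omega_track()] on the same bin grid.
#' @param clr_thresholds,omega_thresholds Tibbles from
#'   [calibrate_null()] with cutoffs 0.05 and 0.1.
#' @param top_fraction Fraction for the outlier-rank rule (default 0.01).
#' @param criterion Which flag defines `common_outlier`: `"top1"`
#'   (default, the outlier bins), `"p05"` or `"p10"`.
#' @return A tibble of class `compound_track` with columns `bin_start`,
#'   `bin_end`, `clr`, `omega`, `clr_p05`, `clr_p10`, `omega_p05`,
#'   `omega_p10`, `top1_clr`, `top1_omega`, `common_outlier`.
#' @export
compound_test <- function(clr_track, omega_track, clr_thresholds,
                          omega_thresholds, top_fraction = 0.01,
                          criterion = c("top1", "p05", "p10")) {
  criterion <- match.arg(criterion)
  if (nrow(clr_track) != nrow(omega_track) ||
      any(clr_track$bin_start != omega_track$bin_start)) {
    bad <- which(c(clr_track$bin_start, -1)[seq_len(min(nrow(clr_track),
                                                        nrow(omega_track)))] !=
                   omega_track$bin_start[seq_len(min(nrow(clr_track),
                                                     nrow(omega_track)))])[1]
    abort(sprintf("bin grids differ (first mismatch at bin %d)",
                  if (is.na(bad)) min(nrow(clr_track), nrow(omega_track)) + 1L
                  else bad))
  }
  out <- tibble(
    bin_start = clr_track$bin_start, bin_end = clr_track$bin_end,
    clr = clr_track$clr, omega = omega_track$omega,
    clr_p05 = !is.na(clr_track$clr) &
      clr_track$clr >= threshold_for(clr_thresholds, 0.05),
    clr_p10 = !is.na(clr_track$clr) &
      clr_track$clr >= threshold_for(clr_thresholds, 0.1),
    omega_p05 = !is.na(omega_track$omega) &
      omega_track$omega >= threshold_for(omega_thresholds, 0.05),
    omega_p10 = !is.na(omega_track$omega) &
      omega_track$omega >= threshold_for(omega_thresholds, 0.1),
    top1_clr = top_flags(clr_track$clr, top_fraction),
    top1_omega = top_flags(omega_track$omega, top_fraction)
  )
  out$common_outlier <- switch(criterion,
    top1 = out$top1_clr & out$top1_omega,
    p05 = out$clr_p05 & out$omega_p05,
    p10 = out$clr_p10 & out$omega_p10
  )
  class(out) <- c("compound_track", class(out))
  out
}
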