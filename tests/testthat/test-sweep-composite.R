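test_that("r-squared matches haplotype-count algebra on canonical cases", {
  # identical columns: perfect LD
  h1 <- hap_matrix(cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)), c(1L, 2L))
  expect_equal(r_squared(h1, 1L, 2L), 1)
  # one copy of each gamete AB, Ab, aB, ab: D = 0
  h0 <- hap_matrix(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)), c(1L, 2L))
  expect_equal(r_squared(h0, 1L, 2L), 0)
  # complementary columns: |D| maximal
  hc <- hap_matrix(cbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)), c(1L, 2L))
  expect_equal(r_squared(hc, 1L, 2L), 1)
  hm <- hap_matrix(cbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 0L)), c(1L, 2L))
  expect_error(r_squared(hm, 1L, 2L), "monomorphic")
})

test_that("r-squared equals the contingency-count oracle on random fixtures", {
  set.seed(51)
  for (rep in 1:25) {
    h <- random_hap(8, 6)
    i <- h$pos[2]
    j <- h$pos[5]
    x <- h$mat[, 2]
    y <- h$mat[, 5]
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    n <- n11 + n10 + n01 + n00
    d <- (n11 / n) - ((n11 + n10) / n) * ((n11 + n01) / n)
    oracle <- d^2 / (((n11 + n10) / n) * (1 - (n11 + n10) / n) *
                       ((n11 + n01) / n) * (1 - (n11 + n01) / n))
    expect_equal(r_squared(h, i, j), oracle, tolerance = 1e-12)
  }
})

test_that("omega is exactly 1 for a uniform r-squared matrix, at every split", {
  for (c_val in c(0.3, 1)) {
    r2 <- matrix(c_val, 8, 8)
    diag(r2) <- 1
    res <- omega_stat(r2)
    expect_equal(res$omega, 1, tolerance = 1e-12)
    expect_equal(unname(attr(res, "per_split")), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("omega recovers the true split of a block-LD matrix (brute force)", {
  s <- 6L
  r2 <- matrix(1e-9, s, s)
  r2[1:3, 1:3] <- 1
  r2[4:6, 4:6] <- 1
  diag(r2) <- 1
  # independent brute-force evaluation of the definition
  brute <- sapply(2:(s - 2), function(l) {
    within <- 0; between <- 0
    for (i in 1:(s - 1)) for (j in (i + 1):s) {
      if ((i <= l) == (j <= l)) within <- within + r2[i, j]
      else between <- between + r2[i, j]
    }
    (within / (choose(l, 2) + choose(s - l, 2))) /
      max(between / (l * (s - l)), 1e-9)
  })
  res <- omega_stat(r2)
  expect_equal(unname(attr(res, "per_split")), brute, tolerance = 1e-9)
  expect_equal(res$split, 3L)
  expect_equal(res$omega, max(brute), tolerance = 1e-9)
})

test_that("omega on haplotypes needs 4 polymorphic sites and reports the split position", {
  h3 <- random_hap(8, 3, seed = 52)
  expect_true(is.na(omega(h3)$omega))
  h <- random_hap(10, 12, seed = 53)
  res <- omega(h)
  expect_gte(res$omega, 0)
  expect_true(res$split >= 2 && res$split <= res$S - 2)
  expect_equal(res$split_pos, h$pos[res$split])
  # row permutation invariance
  perm <- hap_matrix(h$mat[sample(10), ], h$pos)
  expect_equal(omega(perm)$omega, res$omega, tolerance = 1e-12)
})

test_that("sweep samples show elevated omega around the swept site", {
  set.seed(54)
  meds <- replicate(10, {
    seed <- sample.int(1e6, 1)
    sw <- simulate_wf(N = 150, L = 10000, mu = 2.5e-6, r = 1e-6, s = 0.1,
                      sample_n = 30, burn_in = 1500L, seed = seed)
    nt <- simulate_wf(N = 150, L = 10000, mu = 2.5e-6, r = 1e-6, s = 0,
                      sample_n = 30, burn_in = 1500L, seed = seed)
    c(sweep = omega(sw$hap)$omega, neutral = omega(nt$hap)$omega)
  })
  expect_gt(median(meds["sweep", ], na.rm = TRUE),
            median(meds["neutral", ], na.rm = TRUE))
})

test_that("CLR vanishes when the fitted sweep has no effect", {
  h <- random_hap(12, 20, seed = 55)
  scan <- clr_scan(h, genomic_interval("chr1", 1L, 300L), grid_step = 50L)
  expect_true(all(scan$clr >= 0))
  # the sweep class distribution at full escape is the background itself:
  # a huge alpha at any position gives exactly the null likelihood
  n <- n_chrom(h)
  k <- derived_counts(h)
  bg <- (tabulate(k, n - 1) + 0.5) / sum(tabulate(k, n - 1) + 0.5)
  V <- sweepreg:::sweep_class_matrix(n, bg)
  expect_equal(V[2:n, n + 1], bg, tolerance = 1e-12)
  expect_equal(colSums(V), rep(1, n + 1), tolerance = 1e-12)
})

test_that("CLR equals a brute-force model evaluation on a small fixture", {
  h <- random_hap(6, 8, seed = 56)
  region <- genomic_interval("chr1", 1L, 100L)
  alpha_grid <- c(0.01, 0.1)
  scan <- clr_scan(h, region, grid_step = 25L, alpha_grid = alpha_grid,
                   include_invariant = FALSE)
  # independent evaluation: same escape model written longhand
  n <- n_chrom(h)
  k <- derived_counts(h)
  bg <- (tabulate(k, n - 1) + 0.5) / sum(tabulate(k, n - 1) + 0.5)
  class_prob <- function(b, e) {
    if (e == n) return(bg[b])
    m <- e + 1
    tot <- 0
    for (j in seq_len(n - 1)) {
      for (bp in 0:m) {
        w <- dhyper(bp, j, n - j, m) * bg[j]
        if (bp == b) tot <- tot + w * (1 - bp / m)
        if (bp - 1 + (n - e) == b) tot <- tot + w * (bp / m)
      }
    }
    tot
  }
  site_prob <- function(b, pe) {
    num <- 0; den <- 0
    for (e in 0:n) {
      we <- dbinom(e, n, pe)
      for (bb in 1:(n - 1)) {
        p <- we * class_prob(bb, e)
        den <- den + p
        if (bb == b) num <- num + p
      }
    }
    if (den < 1e-12) return(1e-300)   # model forbids polymorphism here
    num / max(den, 1e-12)
  }
  lnl_bg <- sum(log(bg[k]))
  oracle <- sapply(seq(1, 100, by = 25), function(x) {
    best <- -Inf
    for (a in alpha_grid) {
      pe_exact <- 1 - exp(-a * abs(h$pos - x))
      pe <- round(pe_exact / 0.01) * 0.01      # match the scan's binning
      lnl <- sum(log(mapply(site_prob, k, pe)))
      best <- max(best, lnl)
    }
    max(0, 2 * (best - lnl_bg))
  })
  expect_equal(scan$clr, oracle, tolerance = 1e-9)
})

test_that("empty and degenerate CLR inputs are handled", {
  empty <- hap_matrix(matrix(0L, 6, 0), integer())
  expect_equal(nrow(clr_scan(empty)), 0L)
})

test_that("null calibration returns empirical quantiles and excludes NAs", {
  thr <- calibrate_null(function(x) x, function(i) 7, n_reps = 200)
  expect_equal(thr$threshold, c(7, 7))
  thr_u <- calibrate_null(function(x) x, function(i) runif(1),
                          n_reps = 10000, seed = 3)
  expect_lt(abs(thr_u$threshold[thr_u$cutoff == 0.05] - 0.95), 0.02)
  expect_lt(abs(thr_u$threshold[thr_u$cutoff == 0.1] - 0.90), 0.02)
  thr_na <- calibrate_null(function(x) x,
                           function(i) if (i <= 3) NA_real_ else 1,
                           n_reps = 10)
  expect_equal(attr(thr_na, "n_excluded"), 3L)
  expect_equal(attr(thr_na, "n_used"), 7L)
  # determinism under a fixed seed
  sim <- function(i) max(clr_scan(simulate_neutral_coalescent(10, 5,
                                                              span_bp = 2000),
                                  grid_step = 500L)$clr)
  t1 <- calibrate_null(function(x) x, sim, n_reps = 10, seed = 11)
  t2 <- calibrate_null(function(x) x, sim, n_reps = 10, seed = 11)
  expect_identical(t1, t2)
})

test_that("compound test conjoins per-statistic flags on a shared grid", {
  bins <- tibble::tibble(bin_start = seq(1, 2000, by = 10))
  bins$bin_end <- bins$bin_start + 9L
  clr_t <- dplyr::mutate(bins, clr = 1, alpha_hat = 0.01)
  om_t <- dplyr::mutate(bins, omega = 1, S = 10L)
  # plant two joint outliers in 200 bins: exactly the top-1% set
  clr_t$clr[c(50, 120)] <- c(9, 8)
  om_t$omega[c(50, 120)] <- c(7, 9)
  thr <- tibble::tibble(cutoff = c(0.05, 0.1), threshold = c(5, 3))
  res <- compound_test(clr_t, om_t, thr, thr)
  expect_equal(which(res$top1_clr), c(50L, 120L))
  expect_equal(which(res$top1_omega), c(50L, 120L))
  expect_equal(which(res$common_outlier), c(50L, 120L))
  expect_equal(which(res$clr_p05), c(50L, 120L))
  # CLR flagged but omega not -> no common outlier under p05
  om_low <- dplyr::mutate(bins, omega = 1, S = 10L)
  om_low$omega[50] <- 2
  res2 <- compound_test(clr_t, om_low, thr, thr, criterion = "p05")
  expect_false(res2$common_outlier[50])
  # compound count never exceeds either statistic's count
  expect_lte(sum(res$common_outlier), min(sum(res$top1_clr),
                                          sum(res$top1_omega)))
  # grid mismatch errors with the offending bin
  om_shift <- om_t
  om_shift$bin_start[3] <- om_shift$bin_start[3] + 1L
  expect_error(compound_test(clr_t, om_shift, thr, thr), "bin 3")
})
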