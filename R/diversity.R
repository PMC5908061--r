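#' Nucleotide diversity (pi)
#'
#' Mean pairwise nucleotide difference over all chromosome pairs,
#' computed from per-site allele frequencies as
#' \deqn{\pi = \frac{n}{n-1} \sum_i 2 p_i (1 - p_i)}
#' where \eqn{p_i} is the major-allele frequency of the i-th SNP (the
#' term is symmetric, so derived-allele frequency gives the same value).
#' Monomorphic sites contribute 0.
#'
#' @param hap A [hap_matrix()].
#' @param sites Optional site subset (indices or logical).
#' @return Total pi over the selected sites (a count of differences, not
#'   per bp; see [windowed_scan()] for per-bp normalization).
#' @export
nucleotide_diversity <- function(hap, sites = NULL) {
  if (!is.null(sites)) hap <- subset_sites(hap, sites)
  n <- n_chrom(hap)
  if (n < 2L) abort("nucleotide diversity needs >= 2 chromosomes")
  if (!n_sites(hap)) return(0)
  p <- derived_freqs(hap)
  n / (n - 1) * sum(2 * p * (1 - p))
}

#' Watterson's estimator of the population mutation rate
#'
#' \deqn{\theta_s = S_n / \sum_{i=1}^{n-1} 1/i}
#'
#' @param s_n Number of segregating (polymorphic) sites.
#' @param n Number of chromosomes.
#' @return The estimate (0 when `s_n = 0`).
#' @export
watterson_theta <- function(s_n, n) {
  if (n < 2L) abort("watterson_theta needs n >= 2")
  if (s_n < 0L) abort("`s_n` must be >= 0")
  s_n / sum(1 / seq_len(n - 1L))
}

# Tajima (1989) normalizing constants for a sample of n chromosomes.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' \deqn{D = (\pi - \theta_s) / \sqrt{Var(\pi - \theta_s)}}
#' with the variance estimated as \eqn{e_1 S + e_2 S (S-1)} using
#' Tajima's (1989) coefficients. Negative values indicate an excess of
#' rare variants (singleton-skewed spectra), consistent with a recent
#' sweep; positive values an excess of intermediate frequencies.
#'
#' @param hap A [hap_matrix()].
#' @param sites Optional site subset.
#' @return The D statistic, or `NA_real_` when there are no segregating
#'   sites (D is then undefined, not zero).
#' @export
tajimas_d <- function(hap, sites = NULL) {
  if (!is.null(sites)) hap <- subset_sites(hap, sites)
  n <- n_chrom(hap)
  if (n < 2L) abort("tajimas_d needs >= 2 chromosomes")
  k <- derived_counts(hap)
  seg <- k > 0L & k < n
  s <- sum(seg)
  if (s == 0L) return(NA_real_)
  pi_hat <- nucleotide_diversity(subset_sites(hap, seg))
  cst <- tajima_constants(n)
  theta <- s / cst$a1
  v <- cst$e1 * s + cst$e2 * s * (s - 1)
  (pi_hat - theta) / sqrt(v)
}

#' Sliding-window diversity scan
#'
#' Tiles `region` with windows of `window` bp advanced by `step` bp,
#' anchored at the region start; a final partial window is dropped. Each
#' window reports the segregating-site count, total and per-bp pi
#' (divided by the full window length, since pi = 0 at invariant sites),
#' Watterson's theta and Tajima's D (`NA` where undefined).
#'
#' @param hap A [hap_matrix()].
#' @param region One-row [genomic_interval()] (1-based closed).
#' @param window,step Window and step sizes in bp.
#' @return A tibble of class `window_scan` with columns `chrom`, `start`,
#'   `end`, `S`, `pi_total`, `pi_per_bp`, `theta_s`, `tajimas_d`.
#' @export
windowed_scan <- function(hap, region, window = 1000L, step = 100L) {
  if (window <= 0L) abort("`window` must be positive")
  if (step <= 0L) abort("`step` must be positive")
  len <- interval_length(region)[1]
  if (len < window) abort("region shorter than one window")
  n_win <- (len - window) %/% step + 1L
  starts <- region$start[1] + step * (seq_len(n_win) - 1L)
  ends <- starts + window - 1L
  n <- n_chrom(hap)
  k <- derived_counts(hap)
  seg <- k > 0L & k < n
  res <- purrr::map2(starts, ends, function(s, e) {
    in_win <- hap$pos >= s & hap$pos <= e & seg
    s_count <- sum(in_win)
    pi_tot <- if (s_count) nucleotide_diversity(hap, in_win) else 0
    list(
      S = s_count,
      pi_total = pi_tot,
      pi_per_bp = pi_tot / window,
      theta_s = watterson_theta(s_count, n),
      tajimas_d = if (s_count) tajimas_d(hap, in_win) else NA_real_
    )
  })
  out <- dplyr::bind_cols(
    tibble(chrom = region$chrom[1], start = starts, end = ends),
    dplyr::bind_rows(res)
  )
  class(out) <- c("window_scan", class(out))
  out
}

#' Derived-allele frequency at a site
#'
#' Percentage of called chromosomes carrying the derived allele, reported
#' to two decimals as in population summaries (e.g. 100.00 when all 5,008
#' chromosomes of a 2,504-sample diploid cohort are derived, 99.98 when
#' one is ancestral). Missing genotypes are excluded from the
#' denominator.
#'
#' @param x A [hap_matrix()] (no missing entries by construction) or a
#'   [variant_table()] plus an ancestral base.
#' @param site Site position (bp) for a `hap_matrix`, or row index/pos for
#'   a variant table.
#' @param ancestral Required for variant tables: the ancestral base at the
#'   site.
#' @return Percentage in `[0, 100]`, rounded to two decimals.
#' @export
derived_allele_frequency <- function(x, site, ancestral = NULL) {
  if (inherits(x, "hap_matrix")) {
    j <- match(site, x$pos)
    if (is.na(j)) abort("site not present in haplotype matrix")
    if (!x$anc_known[j]) abort("ancestral state unknown at this site")
    return(round(100 * mean(x$mat[, j]), 2))
  }
  i <- match(site, x$pos)
  if (is.na(i)) abort("site not present in variant table")
  if (is.null(ancestral)) abort("`ancestral` base required for variant records")
  ancestral <- toupper(ancestral)
  if (!(ancestral %in% c(x$ref[i], x$alt[i]))) {
    abort("ancestral base matches neither allele: state unknown")
  }
  al <- suppressWarnings(as.integer(unlist(
    strsplit(x$gt[[i]], "[|/]")
  )))
  al <- al[!is.na(al)]
  if (!length(al)) abort("no called chromosomes at this site")
  derived_idx <- if (ancestral == x$ref[i]) 1L else 0L
  round(100 * mean(al == derived_idx), 2)
}
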