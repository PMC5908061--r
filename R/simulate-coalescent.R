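#' Neutral coalescent sample (infinite sites, no recombination)
#'
#' Kingman coalescent in the `ms` convention: time in units of 4N0
#' generations, `theta = 4 N0 mu` per locus, mutations dropped on
#' branches as a Poisson process of rate `theta/2` per unit time and
#' placed uniformly on a unit locus scaled to `span_bp`. Under this model
#' the expected number of segregating sites is
#' `theta * sum(1/(1:(n-1)))` and the expected pairwise diversity is
#' `theta`.
#'
#' @param n Number of sampled chromosomes (>= 2).
#' @param theta Population mutation rate 4N0mu per locus (>= 0).
#' @param span_bp Physical span the unit locus is scaled to; site
#'   positions are distinct integers in `[1, span_bp]`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [hap_matrix()]; `theta = 0` gives a matrix with 0 sites.
#' @export
simulate_neutral_coalescent <- function(n, theta, span_bp = 10000L,
                                        seed = NULL) {
  if (n < 2L) abort("coalescent sample needs n >= 2")
  if (theta < 0) abort("`theta` must be >= 0")
  with_seed(seed, {
    desc <- lapply(seq_len(n), identity)   # tips under each active lineage
    carriers <- list()                     # tip sets of the mutations
    k <- n
    while (k > 1L) {
      t_k <- rexp(1L, rate = k * (k - 1L) / 2)
      m <- rpois(1L, theta / 2 * k * t_k)
      if (m > 0L) {
        on <- sample.int(k, m, replace = TRUE)
        carriers <- c(carriers, desc[on])
      }
      pair <- sample.int(k, 2L)
      desc[[pair[1]]] <- c(desc[[pair[1]]], desc[[pair[2]]])
      desc[[pair[2]]] <- NULL
      k <- k - 1L
    }
    m <- length(carriers)
    if (m == 0L) {
      return(hap_matrix(matrix(integer(), nrow = n, ncol = 0L), integer()))
    }
    pos <- integer(0)
    while (length(pos) < m) {
      pos <- unique(c(pos, ceiling(runif(m - length(pos)) * span_bp)))
    }
    pos <- sort(pos)
    mat <- matrix(0L, nrow = n, ncol = m)
    for (j in seq_len(m)) mat[carriers[[j]], j] <- 1L
    hap_matrix(mat, pos)
  })
}
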