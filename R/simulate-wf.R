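#' Forward Wright-Fisher simulation with an optional selective sweep
#'
#' Discrete-generation diploid Wright-Fisher model on an `L`-bp locus with
#' genotype fitnesses 1, `1+hs`, `1+s` at a single sweep site, per-gamete
#' crossovers falling between adjacent base pairs with probability `r`,
#' and per-site mutation at rate `mu` per generation (at most one mutation
#' retained per site). After `burn_in` neutral generations, a single
#' selected copy is introduced at `sweep_site`; runs in which the allele
#' is lost restart from the burned-in population until it reaches
#' `sampling_freq` (1.0 = fixation), when `sample_n` chromosomes are drawn
#' without replacement.
#'
#' @param N Diploid population size.
#' @param L Locus length in bp.
#' @param mu Per-site per-generation mutation rate.
#' @param r Per-adjacent-pair per-gamete recombination rate.
#' @param s Selection coefficient (`0` for neutral runs).
#' @param h Dominance coefficient in `[0, 1]`.
#' @param sweep_site Position (bp) of the selected site.
#' @param sample_n Chromosomes to sample (`<= 2N`).
#' @param sampling_freq Population frequency of the selected allele at
#'   which sampling occurs.
#' @param burn_in Neutral generations discarded before any sweep
#'   (default `10 * N`).
#' @param seed Optional integer seed.
#' @param max_restarts Give up (with an error naming the attempt count)
#'   after this many lost-allele restarts.
#' @return A list of class `wf_sim`: `hap` (a [hap_matrix()] of the
#'   sampled chromosomes restricted to sample-polymorphic sites, coded
#'   0 = ancestral) and `sweep` (list with `pos`, `trajectory` of
#'   population frequencies, `final_freq`, `restarts`).
#' @export
simulate_wf <- function(N = 500L, L = 50000L, mu = 5e-7, r = 2e-6, s = 0,
                        h = 0.5, sweep_site = NULL, sample_n = 50L,
                        sampling_freq = 1.0, burn_in = 10L * N, seed = NULL,
                        max_restarts = 1000L) {
  if (h < 0 || h > 1) abort("`h` must lie in [0, 1]")
  if (s < 0) abort("`s` must be >= 0")
  if (sample_n > 2L * N) abort("`sample_n` must be <= 2N")
  sweep_site <- as.integer(sweep_site %||% (L %/% 2L))
  with_seed(seed, {
    raw <- wf_simulate_cpp(as.integer(N), as.integer(L), mu, r, s, h,
                           sweep_site, as.integer(sample_n), sampling_freq,
                           as.integer(burn_in), as.integer(max_restarts),
                           1000000L)
    ord <- order(raw$positions)
    mat <- raw$sample[, ord, drop = FALSE]
    pos <- raw$positions[ord]
    k <- colSums(mat)
    poly <- k > 0L & k < nrow(mat)
    hap <- hap_matrix(mat[, poly, drop = FALSE], pos[poly])
    structure(
      list(
        hap = hap,
        sweep = list(
          pos = if (s > 0) sweep_site else NA_integer_,
          trajectory = raw$trajectory,
          final_freq = raw$final_freq,
          restarts = raw$restarts
        ),
        config = list(N = N, L = L, mu = mu, r = r, s = s, h = h,
                      sample_n = sample_n, sampling_freq = sampling_freq,
                      burn_in = burn_in)
      ),
      class = "wf_sim"
    )
  })
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("<wf_sim> N=%d L=%d s=%g: %d chromosomes x %d segregating sites\n",
              x$config$N, x$config$L, x$config$s,
              n_chrom(x$hap), n_sites(x$hap)))
  if (x$config$s > 0) {
    cat(sprintf("  sweep at %d bp reached freq %.3f after %d restart(s)\n",
                x$sweep$pos, x$sweep$final_freq, x$sweep$restarts))
  }
  invisible(x)
}
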