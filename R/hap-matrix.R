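#' Phased haplotype matrix
#'
#' The substrate of all selection statistics: a binary matrix of sampled
#' chromosomes (rows) by polymorphic sites (columns), coded `0` for the
#' ancestral and `1` for the derived allele, together with strictly
#' increasing 1-based base-pair positions and a per-site flag recording
#' whether the ancestral state is actually known. Sites whose ancestral
#' state is unknown stay in the matrix (their `0`/`1` coding is then
#' reference/alternate) but are excluded from polarized statistics.
#'
#' @param mat Integer or logical matrix, chromosomes x sites, entries 0/1.
#' @param pos Integer vector of 1-based site positions, strictly increasing,
#'   one per column of `mat`.
#' @param chrom Chromosome (contig) label, single string.
#' @param anc_known Logical vector, one per site; `TRUE` where the 0/1
#'   coding is ancestral/derived. Defaults to all `TRUE`.
#'
#' @return An object of class `hap_matrix`.
#' @export
#' @examples
#' h <- hap_matrix(rbind(c(0, 1), c(1, 1), c(0, 0)), pos = c(10L, 25L))
#' n_chrom(h)
#' n_sites(h)
hap_matrix <- function(mat, pos, chrom = "chr1", anc_known = NULL) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  mat <- matrix(as.integer(mat), nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  if (length(pos) != ncol(mat)) {
    abort("`pos` must have one entry per column of `mat`.")
  }
  pos <- as.integer(pos)
  if (ncol(mat) > 1L && any(diff(pos) <= 0L)) {
    abort("site positions must be strictly increasing")
  }
  if (length(mat) && !all(mat %in% c(0L, 1L))) {
    abort("haplotype matrix entries must be 0 or 1")
  }
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    abort("`chrom` must be a single non-empty string")
  }
  anc_known <- anc_known %||% rep(TRUE, ncol(mat))
  if (length(anc_known) != ncol(mat)) {
    abort("`anc_known` must have one entry per site")
  }
  structure(
    list(mat = mat, pos = pos, chrom = chrom, anc_known = as.logical(anc_known)),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf(
    "<hap_matrix> %d chromosomes x %d sites on %s%s\n",
    nrow(x$mat), ncol(x$mat), x$chrom,
    if (ncol(x$mat)) sprintf(" [%d..%d bp]", min(x$pos), max(x$pos)) else ""
  ))
  nu <- sum(!x$anc_known)
  if (nu) cat(sprintf("  %d site(s) with unknown ancestral state\n", nu))
  invisible(x)
}

#' Number of chromosomes / sites in a haplotype matrix
#'
#' @param hap A [hap_matrix()].
#' @return An integer.
#' @export
n_chrom <- function(hap) nrow(hap$mat)

#' @rdname n_chrom
#' @export
n_sites <- function(hap) ncol(hap$mat)

#' Derived-allele counts and frequencies per site
#'
#' @param hap A [hap_matrix()].
#' @return For `derived_counts()` an integer vector; for `derived_freqs()`
#'   a numeric vector in `[0, 1]`.
#' @export
derived_counts <- function(hap) {
  if (!n_sites(hap)) return(integer())
  as.integer(colSums(hap$mat))
}

#' @rdname derived_counts
#' @export
derived_freqs <- function(hap) {
  if (!n_sites(hap)) return(numeric())
  colSums(hap$mat) / n_chrom(hap)
}

#' Restrict a haplotype matrix to a set of sites
#'
#' @param hap A [hap_matrix()].
#' @param sites Integer column indices, or a logical vector over sites.
#' @return A [hap_matrix()] with the selected columns.
#' @export
subset_sites <- function(hap, sites) {
  if (is.logical(sites)) sites <- which(sites)
  sites <- as.integer(sites)
  hap_matrix(hap$mat[, sites, drop = FALSE], hap$pos[sites], hap$chrom,
             hap$anc_known[sites])
}

#' Polymorphic-site filter
#'
#' Keeps sites segregating in the sample (0 < derived count < n).
#'
#' @param hap A [hap_matrix()].
#' @return A [hap_matrix()].
#' @export
polymorphic_sites <- function(hap) {
  k <- derived_counts(hap)
  subset_sites(hap, k > 0L & k < n_chrom(hap))
}

#' Summarise the site frequency make-up of a haplotype sample
#'
#' One row per site: position, derived count, derived-allele frequency and
#' major-allele frequency, plus the ancestral-known flag.
#'
#' @param hap A [hap_matrix()].
#' @return A tibble with columns `pos`, `derived_count`, `daf`, `maf_major`,
#'   `anc_known`.
#' @export
site_frequencies <- function(hap) {
  k <- derived_counts(hap)
  n <- n_chrom(hap)
  daf <- if (length(k)) k / n else numeric()
  tibble(
    pos = hap$pos,
    derived_count = k,
    daf = daf,
    maf_major = pmax(daf, 1 - daf),
    anc_known = hap$anc_known
  )
}
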