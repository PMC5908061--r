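#' Extended haplotype homozygosity around a core allele
#'
#' For the chromosomes carrying `allele` at the core site, EHH at an
#' offset is the fraction of carrier pairs whose haplotypes are identical
#' over every site from the core out to that offset. It equals 1 at the
#' core and is non-increasing outward in each direction.
#'
#' @param hap A [hap_matrix()].
#' @param core Core site position (bp).
#' @param allele `0` (ancestral) or `1` (derived).
#' @param direction `"both"`, `"left"` or `"right"`.
#' @return A tibble of class `ehh_curve` with columns `pos`, `offset`
#'   (signed bp; 0 at the core), `ehh`; attributes `core_pos`, `allele`,
#'   `n_carriers`.
#' @export
ehh <- function(hap, core, allele, direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  j0 <- match(core, hap$pos)
  if (is.na(j0)) abort("core site not in haplotype matrix")
  carriers <- which(hap$mat[, j0] == allele)
  k <- length(carriers)
  if (k < 2L) abort("EHH undefined: core allele carried by < 2 chromosomes")
  pairs_total <- choose(k, 2)
  walk <- function(idx_seq, sign) {
    grp <- rep(1L, k)
    purrr::map_dfr(idx_seq, function(j) {
      col <- hap$mat[carriers, j]
      grp <<- as.integer(interaction(grp, col, drop = TRUE))
      sizes <- tabulate(grp)
      tibble(pos = hap$pos[j],
             offset = sign * abs(hap$pos[j] - core),
             ehh = sum(choose(sizes, 2)) / pairs_total)
    })
  }
  core_row <- tibble(pos = core, offset = 0L, ehh = 1)
  left <- if (direction %in% c("both", "left") && j0 > 1L) {
    walk(rev(seq_len(j0 - 1L)), -1L)
  } else tibble(pos = integer(), offset = integer(), ehh = numeric())
  right <- if (direction %in% c("both", "right") && j0 < n_sites(hap)) {
    walk(seq(j0 + 1L, n_sites(hap)), 1L)
  } else tibble(pos = integer(), offset = integer(), ehh = numeric())
  out <- dplyr::bind_rows(left[rev(seq_len(nrow(left))), ], core_row, right)
  attr(out, "core_pos") <- core
  attr(out, "allele") <- allele
  attr(out, "n_carriers") <- k
  class(out) <- c("ehh_curve", class(out))
  out
}

# Integrate one side of an EHH curve by the trapezoid rule, walking
# outward until EHH drops below `min_ehh` (that trapezoid is included) or
# the matrix edge is reached (edge-truncated). A gap wider than
# `max_gap` bp invalidates the integral.
integrate_ehh_side <- function(hap, j0, carriers, step_idx, min_ehh, max_gap) {
  k <- length(carriers)
  pairs_total <- choose(k, 2)
  grp <- rep(1L, k)
  area <- 0
  prev_x <- 0
  prev_e <- 1
  for (j in step_idx) {
    x <- abs(hap$pos[j] - hap$pos[j0])
    if (x - prev_x > max_gap) {
      return(list(area = NA_real_, edge = FALSE, reason = "integration gap"))
    }
    grp <- as.integer(interaction(grp, hap$mat[carriers, j], drop = TRUE))
    e <- sum(choose(tabulate(grp), 2)) / pairs_total
    area <- area + (prev_e + e) / 2 * (x - prev_x)
    prev_x <- x
    prev_e <- e
    if (e < min_ehh) return(list(area = area, edge = FALSE, reason = NA_character_))
  }
  list(area = area, edge = TRUE, reason = NA_character_)
}

#' Unstandardized integrated haplotype score at one site
#'
#' Integrates the ancestral-core and derived-core EHH curves outward in
#' both directions (trapezoid rule over physical bp) until EHH falls
#' below `min_ehh` or the region edge is hit, and reports
#' `uihs = ln(iHH_A / iHH_D)`. Long shared haplotypes on the derived
#' background give negative values.
#'
#' @param hap A [hap_matrix()] (ancestral states must be known at `site`).
#' @param site Core site position (bp).
#' @param min_ehh EHH truncation threshold (default 0.05).
#' @param maf Minor-allele-frequency cutoff: sites with derived frequency
#'   outside `[maf, 1 - maf]` are not scored.
#' @param max_gap Maximum bp gap between consecutive sites crossed during
#'   integration; beyond it the score is invalidated.
#' @return A one-row tibble: `pos`, `daf`, `ihh_a`, `ihh_d`, `uihs`,
#'   `edge_truncated`, `valid`, `reason`.
#' @export
unstandardized_ihs <- function(hap, site, min_ehh = 0.05, maf = 0.05,
                               max_gap = 20000L) {
  j0 <- match(site, hap$pos)
  if (is.na(j0)) abort("site not in haplotype matrix")
  if (!hap$anc_known[j0]) abort("ancestral state unknown at site")
  daf <- mean(hap$mat[, j0])
  base <- tibble(pos = site, daf = daf, ihh_a = NA_real_, ihh_d = NA_real_,
                 uihs = NA_real_, edge_truncated = NA, valid = FALSE,
                 reason = NA_character_)
  if (daf < maf || daf > 1 - maf) {
    base$reason <- "outside MAF bounds"
    return(base)
  }
  left_idx <- rev(seq_len(j0 - 1L))
  right_idx <- if (j0 < n_sites(hap)) seq(j0 + 1L, n_sites(hap)) else integer()
  edge <- FALSE
  ihh <- numeric(2)
  for (a in 0:1) {
    carriers <- which(hap$mat[, j0] == a)
    if (length(carriers) < 2L) {
      base$reason <- "EHH undefined: < 2 carriers"
      return(base)
    }
    l <- integrate_ehh_side(hap, j0, carriers, left_idx, min_ehh, max_gap)
    r <- integrate_ehh_side(hap, j0, carriers, right_idx, min_ehh, max_gap)
    if (is.na(l$area) || is.na(r$area)) {
      base$reason <- "integration gap"
      return(base)
    }
    edge <- edge || l$edge || r$edge
    ihh[a + 1L] <- l$area + r$area
  }
  if (any(ihh <= 0)) {
    base$reason <- "zero iHH"
    return(base)
  }
  tibble(pos = site, daf = daf, ihh_a = ihh[1], ihh_d = ihh[2],
         uihs = log(ihh[1] / ihh[2]), edge_truncated = edge, valid = TRUE,
         reason = NA_character_)
}

#' Score every eligible site of a haplotype matrix
#'
#' @inheritParams unstandardized_ihs
#' @param drop_edge_truncated Drop scores whose integration hit the
#'   region edge before EHH decayed below `min_ehh` (default keeps them,
#'   flagged).
#' @return A tibble, one row per eligible site (see
#'   [unstandardized_ihs()]); pipe into [standardize_ihs()].
#' @export
ihs_scan <- function(hap, min_ehh = 0.05, maf = 0.05, max_gap = 20000L,
                     drop_edge_truncated = FALSE) {
  k <- derived_counts(hap)
  n <- n_chrom(hap)
  eligible <- which(hap$anc_known & k > 0L & k < n)
  out <- purrr::map_dfr(hap$pos[eligible], function(p) {
    unstandardized_ihs(hap, p, min_ehh = min_ehh, maf = maf,
                       max_gap = max_gap)
  })
  if (drop_edge_truncated && nrow(out)) {
    out <- dplyr::filter(out, !.data$valid | !.data$edge_truncated)
  }
  out
}

#' Standardize iHS within derived-frequency bins
#'
#' Within each derived-allele-frequency bin the unstandardized scores are
#' centred and scaled to mean 0, sd 1, removing the frequency dependence
#' of haplotype ages. Bins holding fewer than `min_bin_n` scores are
#' merged with their nearest occupied neighbour. `|iHS| > 2` flags a
#' score as extreme and the sign infers the selected allele (positive:
#' longer ancestral haplotypes, `A`; negative: `D`).
#'
#' @param scores Tibble from [ihs_scan()] (needs `daf` and `uihs`).
#' @param bins Number of equal-width frequency bins (default 50).
#' @param min_bin_n Minimum scores per bin before merging (default 10).
#' @return `scores` with added columns `bin` (the merged frequency bin
#'   each score was standardized in), `ihs`, `extreme`,
#'   `selected_allele`.
#' @export
standardize_ihs <- function(scores, bins = 50L, min_bin_n = 10L) {
  out <- scores
  out$ihs <- NA_real_
  out$bin <- NA_integer_
  usable <- which(out$valid & !is.na(out$uihs))
  if (length(usable)) {
    bin <- pmin(pmax(ceiling(out$daf[usable] * bins), 1L), bins)
    # merge sparse bins with their nearest occupied neighbour
    repeat {
      counts <- table(bin)
      sparse <- names(counts)[counts < min_bin_n]
      if (!length(sparse) || length(counts) == 1L) break
      b <- as.integer(sparse[1])
      others <- as.integer(setdiff(names(counts), sparse[1]))
      if (!length(others)) break
      target <- others[which.min(abs(others - b))]
      bin[bin == b] <- target
    }
    out$bin[usable] <- bin
    for (b in unique(bin)) {
      at <- usable[bin == b]
      m <- mean(out$uihs[at])
      # population (1/n) standard deviation: a two-score bin {-1, 1}
      # standardizes to exactly {-1, 1}
      s <- sqrt(mean((out$uihs[at] - m)^2))
      if (length(at) < 2L || is.na(s) || s == 0) {
        warn(sprintf("iHS bin with %d identical score(s): standardized value undefined",
                     length(at)))
        next
      }
      out$ihs[at] <- (out$uihs[at] - m) / s
    }
  }
  out$extreme <- !is.na(out$ihs) & abs(out$ihs) > 2
  out$selected_allele <- infer_selected_allele(out$ihs)
  class(out) <- c("ihs_scan", class(out))
  out
}

#' Infer the selected allele from a standardized iHS score
#'
#' Positive scores mean haplotypes on the ancestral background are
#' longer (selected allele `A`); negative scores point to the derived
#' allele (`D`). Scores within `tol` of zero are `undetermined`.
#'
#' @param ihs Numeric vector of standardized scores.
#' @param tol Tie tolerance.
#' @return Character vector of `"A"`, `"D"`, `"undetermined"` (NA in,
#'   NA out).
#' @export
infer_selected_allele <- function(ihs, tol = 1e-9) {
  dplyr::case_when(
    is.na(ihs) ~ NA_character_,
    ihs > tol ~ "A",
    ihs < -tol ~ "D",
    TRUE ~ "undetermined"
  )
}
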