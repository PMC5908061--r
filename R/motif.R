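#' Position weight matrix
#'
#' Per-position base-probability model of a transcription-factor binding
#' motif. A pseudocount is added to every cell and rows renormalized, so
#' no cell is zero and log-odds scores stay finite.
#'
#' @param mat Numeric matrix, width x 4, columns A, C, G, T; rows should
#'   sum to ~1 (probabilities) or may be counts.
#' @param name Motif name.
#' @param background Background frequencies over A, C, G, T.
#' @param pseudocount Added per cell before renormalization (default
#'   0.1).
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.1) {
  if (ncol(mat) != 4L) abort("PWM must have 4 columns (A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  mat <- (mat + pseudocount) / (rowSums(mat) + 4 * pseudocount)
  colnames(mat) <- BASES
  structure(list(name = name, mat = mat, background = stats::setNames(
    as.numeric(background), BASES), width = nrow(mat),
    pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d (consensus %s)\n", x$name, x$width,
              consensus(x)))
  invisible(x)
}

#' Consensus k-mer of a PWM (argmax base per column)
#'
#' @param x A [pwm()].
#' @return A string of length `width`.
#' @export
consensus <- function(x) {
  paste(BASES[apply(x$mat, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM or DNA string
#'
#' @param x A [pwm()] or character string.
#' @return Same type as the input.
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "pwm")) {
    m <- x$mat[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
    colnames(m) <- BASES
    out <- x
    out$mat <- m
    return(out)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Log-odds score of a k-mer against a PWM
#'
#' `sum_j log2( p_pwm(j, base_j) / p_bg(base_j) )` in bits; the
#' pseudocount is already folded into the matrix.
#'
#' @param x A [pwm()].
#' @param kmer String of length `width` over A, C, G, T (an `N` makes the
#'   score undefined: `NA`).
#' @return Score in bits.
#' @export
logodds_score <- function(x, kmer) {
  b <- strsplit(toupper(kmer), "")[[1]]
  if (length(b) != x$width) abort("k-mer length must equal PWM width")
  idx <- match(b, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(log2(x$mat[cbind(seq_len(x$width), idx)] / x$background[idx]))
}

# Discretized per-column scores (integer units of `resolution` bits) and
# the exact distribution of their sum under the background model,
# computed by convolution across columns.
score_distribution <- function(x, resolution = 1e-3) {
  cols <- round(log2(x$mat / matrix(x$background, x$width, 4, byrow = TRUE)) /
                  resolution)
  offset_min <- sum(apply(cols, 1, min))
  offset_max <- sum(apply(cols, 1, max))
  probs <- numeric(offset_max - offset_min + 1L)
  # running support starts at 0 before any column
  cur <- 1
  cur_min <- 0
  for (j in seq_len(x$width)) {
    nxt_min <- cur_min + min(cols[j, ])
    nxt <- numeric(cur_min + max(cols[j, ]) - nxt_min + length(cur))
    for (b in 1:4) {
      sft <- cur_min + cols[j, b] - nxt_min
      idx <- seq_along(cur) + sft
      nxt[idx] <- nxt[idx] + cur * x$background[b]
    }
    cur <- nxt
    cur_min <- nxt_min
  }
  list(probs = cur, min = cur_min, max = cur_min + length(cur) - 1L,
       cols = cols, resolution = resolution)
}

#' Exact p-value of a PWM score
#'
#' `P(score(X) >= s)` for a random background k-mer, computed by dynamic
#' programming over per-column scores discretized to 1/1000-bit bins and
#' convolved across columns. Monotone non-increasing in `s`; a score at
#' or below the minimum achievable gives `p = 1`.
#'
#' @param x A [pwm()].
#' @param score Score in bits (as returned by [logodds_score()]).
#' @param resolution Discretization bin width in bits.
#' @return The p-value in `(0, 1]`.
#' @export
score_pvalue <- function(x, score, resolution = 1e-3) {
  dist <- score_distribution(x, resolution)
  pvalue_from_distribution(dist, score)
}

pvalue_from_distribution <- function(dist, score) {
  t <- as.integer(round(score / dist$resolution))
  if (t <= dist$min) return(1)
  if (t > dist$max) return(0)
  sum(dist$probs[(t - dist$min + 1L):length(dist$probs)])
}

#' Scan a sequence for PWM hits at an exact p-value threshold
#'
#' Scores every placement on the forward and (by default) reverse
#' strand and keeps placements with `p <= threshold` (default 1e-3).
#' Placements containing `N` are skipped. Hits are sorted by position,
#' then strand.
#'
#' @param sequence DNA string (or named character vector of sequences).
#' @param x A [pwm()].
#' @param threshold P-value threshold.
#' @param both_strands Also scan the reverse complement motif.
#' @return A tibble of class `motif_hits`: `seq_id`, `start` (1-based,
#'   forward-strand coordinates), `strand`, `kmer` (motif-oriented),
#'   `score`, `p_value`, `neg_log10_p`.
#' @export
scan_pwm <- function(sequence, x, threshold = 1e-3, both_strands = TRUE) {
  seqs <- if (is.null(names(sequence))) {
    stats::setNames(sequence, paste0("seq", seq_along(sequence)))
  } else sequence
  dist_f <- score_distribution(x)
  rc <- reverse_complement(x)
  dist_r <- if (both_strands) score_distribution(rc) else NULL
  out <- purrr::imap_dfr(seqs, function(s, id) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < x$width) return(tibble())
    starts <- seq_len(L - x$width + 1L)
    rows <- purrr::map_dfr(starts, function(i) {
      kmer <- substr(s, i, i + x$width - 1L)
      res <- tibble()
      sc <- logodds_score(x, kmer)
      if (!is.na(sc)) {
        p <- pvalue_from_distribution(dist_f, sc)
        if (p <= threshold) {
          res <- dplyr::bind_rows(res, tibble(
            seq_id = id, start = i, strand = "+", kmer = kmer,
            score = sc, p_value = p))
        }
        if (both_strands) {
          sc_r <- logodds_score(rc, kmer)
          p_r <- pvalue_from_distribution(dist_r, sc_r)
          if (p_r <= threshold) {
            res <- dplyr::bind_rows(res, tibble(
              seq_id = id, start = i, strand = "-",
              kmer = reverse_complement(kmer), score = sc_r, p_value = p_r))
          }
        }
      }
      res
    })
    rows
  })
  if (!nrow(out)) {
    out <- tibble(seq_id = character(), start = integer(),
                  strand = character(), kmer = character(),
                  score = numeric(), p_value = numeric())
  }
  out <- dplyr::arrange(out, .data$seq_id, .data$start, .data$strand)
  out$neg_log10_p <- -log10(out$p_value)
  class(out) <- c("motif_hits", class(out))
  out
}

#' Effect of an ancestral vs derived allele on motif binding affinity
#'
#' Scores the best motif placement covering the variant with each allele
#' substituted into the sequence and reports score and p-value deltas.
#' The placement (over both strands) maximizes the *smaller* of the two
#' allele scores, so the choice is symmetric in the alleles. If no
#' placement reaches `relaxed_threshold` with either allele the variant
#' is reported as `not-in-motif`.
#'
#' @param x A [pwm()].
#' @param sequence Context DNA string.
#' @param pos 1-based variant position within `sequence`.
#' @param ancestral,derived The two alleles (single bases).
#' @param relaxed_threshold P-value below which a placement counts as a
#'   motif (default 1e-2).
#' @return A one-row tibble of class `allele_effect`: `pos`, `ancestral`,
#'   `derived`, `strand`, `placement_start`, `score_ancestral`,
#'   `score_derived`, `p_ancestral`, `p_derived`, `delta_score`,
#'   `delta_neg_log10_p`, `direction`.
#' @export
allele_effect <- function(x, sequence, pos, ancestral, derived,
                          relaxed_threshold = 1e-2) {
  sequence <- toupper(sequence)
  ancestral <- toupper(ancestral)
  derived <- toupper(derived)
  sub_at <- function(s, i, b) {
    paste0(substr(s, 1, i - 1L), b, substr(s, i + 1L, nchar(s)))
  }
  seq_a <- sub_at(sequence, pos, ancestral)
  seq_d <- sub_at(sequence, pos, derived)
  dist_f <- score_distribution(x)
  rc <- reverse_complement(x)
  dist_r <- score_distribution(rc)
  starts <- max(1L, pos - x$width + 1L):min(pos, nchar(sequence) - x$width + 1L)
  best <- NULL
  for (i in starts) {
    for (strand in c("+", "-")) {
      m <- if (strand == "+") x else rc
      dist <- if (strand == "+") dist_f else dist_r
      sa <- logodds_score(m, substr(seq_a, i, i + x$width - 1L))
      sd_ <- logodds_score(m, substr(seq_d, i, i + x$width - 1L))
      if (is.na(sa) || is.na(sd_)) next
      cand <- list(start = i, strand = strand, sa = sa, sd = sd_,
                   pa = pvalue_from_distribution(dist, sa),
                   pd = pvalue_from_distribution(dist, sd_))
      if (is.null(best) || min(cand$sa, cand$sd) > min(best$sa, best$sd)) {
        best <- cand
      }
    }
  }
  in_motif <- !is.null(best) &&
    min(best$pa, best$pd) <= relaxed_threshold
  if (!in_motif) {
    out <- tibble(pos = pos, ancestral = ancestral, derived = derived,
                  strand = NA_character_, placement_start = NA_integer_,
                  score_ancestral = NA_real_, score_derived = NA_real_,
                  p_ancestral = NA_real_, p_derived = NA_real_,
                  delta_score = NA_real_, delta_neg_log10_p = NA_real_,
                  direction = "not-in-motif")
  } else {
    delta <- best$sd - best$sa
    out <- tibble(
      pos = pos, ancestral = ancestral, derived = derived,
      strand = best$strand, placement_start = best$start,
      score_ancestral = best$sa, score_derived = best$sd,
      p_ancestral = best$pa, p_derived = best$pd,
      delta_score = delta,
      delta_neg_log10_p = -log10(best$pd) + log10(best$pa),
      direction = dplyr::case_when(
        ancestral == derived | abs(delta) < 1e-12 ~ "neutral",
        delta > 0 ~ "derived-increases",
        TRUE ~ "derived-decreases"
      )
    )
  }
  class(out) <- c("allele_effect", class(out))
  out
}

#' Cross-species reference-allele filter for motif variants
#'
#' Keeps variants where the human and chimpanzee reference bases both
#' carry the derived allele, the macaque (outgroup) reference carries
#' the ancestral allele, and the variant lies inside a reported motif
#' hit. Variants with a missing species reference are excluded with a
#' reason.
#'
#' @param variants Tibble with columns `pos`, `derived`, `ancestral`,
#'   `human_ref`, `chimp_ref`, `macaque_ref` (and optionally `seq_id`).
#' @param hits A [scan_pwm()] result (needs `start` and the motif width
#'   attribute via `motif_width`; pass the scanning PWM).
#' @param x The [pwm()] used for the scan (gives the hit width).
#' @return The passing rows, with attribute `"excluded"`: tibble of
#'   `pos` and `reason`.
#' @export
cross_species_filter <- function(variants, hits, x) {
  need <- c("pos", "derived", "ancestral", "human_ref", "chimp_ref",
            "macaque_ref")
  if (!all(need %in% names(variants))) {
    abort(sprintf("variants need columns %s", paste(need, collapse = ", ")))
  }
  in_hit <- vapply(variants$pos, function(p) {
    any(hits$start <= p & p <= hits$start + x$width - 1L)
  }, logical(1))
  miss <- is.na(variants$human_ref) | is.na(variants$chimp_ref) |
    is.na(variants$macaque_ref)
  pass <- !miss &
    variants$human_ref == variants$derived &
    variants$chimp_ref == variants$derived &
    variants$macaque_ref == variants$ancestral &
    in_hit
  reason <- dplyr::case_when(
    pass ~ NA_character_,
    miss ~ "missing species reference",
    !in_hit ~ "outside motif hits",
    TRUE ~ "reference alleles inconsistent with derived/ancestral pattern"
  )
  out <- variants[pass, ]
  out$in_motif <- TRUE
  attr(out, "excluded") <- tibble(pos = variants$pos[!pass],
                                  reason = reason[!pass])
  out
}
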