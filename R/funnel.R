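#' TAD containment filter
#'
#' Intersects the supplied TAD intervals (per chromosome) into a single
#' common interval and keeps the regions fully contained in it. Regions
#' straddling a boundary are rejected: TADs mediate most
#' enhancer-promoter interactions within their boundaries, so candidate
#' enhancers are required to share the promoter's domain.
#'
#' @param regions A [genomic_interval()] tibble of candidate regions.
#' @param tads A [genomic_interval()] tibble of TAD calls (e.g. one per
#'   tissue layer); their intersection is used.
#' @return The kept regions; attribute `"tad"` holds the intersected
#'   interval.
#' @export
tad_filter <- function(regions, tads) {
  inter <- dplyr::summarise(dplyr::group_by(tads, .data$chrom),
                            start = max(.data$start), end = min(.data$end),
                            .groups = "drop")
  inter <- dplyr::filter(inter, .data$end >= .data$start)
  if (!nrow(inter)) {
    warn("empty TAD intersection: all regions rejected")
    out <- regions[0, ]
    attr(out, "tad") <- inter
    return(out)
  }
  keep <- purrr::pmap_lgl(regions, function(chrom, start, end, ...) {
    any(inter$chrom == chrom & inter$start <= start & end <= inter$end)
  })
  out <- regions[keep, ]
  attr(out, "tad") <- inter
  out
}

#' Link distal regions to a promoter by tag-density correlation
#'
#' Pearson correlation (Spearman available) between each distal region's
#' accessibility profile and the promoter's profile across cell types;
#' a region is linked when the correlation reaches `min_corr`
#' (inclusive: exactly 0.7 links at the default threshold).
#'
#' @param tags Tag-density tibble (`region_id` + one column per cell
#'   type), as from [read_tag_density()].
#' @param promoter_id Region id of the promoter row.
#' @param distal_ids Region ids to test (default: all but the promoter).
#' @param min_corr Linking threshold (default 0.7).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble: `region_id`, `correlation`, `linked`, `reason`
#'   (`NA` unless the correlation was undefined).
#' @export
link_enhancers <- function(tags, promoter_id, distal_ids = NULL,
                           min_corr = 0.7,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(tags) - 1L < 3L) abort("need >= 3 cell types to correlate")
  if (!promoter_id %in% tags$region_id) abort("promoter row not found")
  distal_ids <- distal_ids %||% setdiff(tags$region_id, promoter_id)
  mat <- as.matrix(tags[-1])
  rownames(mat) <- tags$region_id
  prom <- mat[promoter_id, ]
  purrr::map_dfr(distal_ids, function(id) {
    if (!id %in% rownames(mat)) abort(sprintf("region %s not in tag matrix", id))
    row <- mat[id, ]
    if (sd(row) == 0 || sd(prom) == 0) {
      return(tibble(region_id = id, correlation = NA_real_, linked = FALSE,
                    reason = "zero-variance profile"))
    }
    r <- cor(row, prom, method = method)
    tibble(region_id = id, correlation = r, linked = r >= min_corr,
           reason = NA_character_)
  })
}

#' Group-differential peak calls
#'
#' In strict mode a region is differential when the mark is present in
#' *all* group-A samples and in *none* of group B (e.g. H3K27ac in every
#' macaque brain but no human or chimpanzee sample). Lenient fractions
#' are available for noisy data.
#'
#' @param peaks Peak-call tibble (see [read_peak_calls()]).
#' @param group_a,group_b Group labels.
#' @param mode `"strict"` or `"lenient"`.
#' @param min_frac_a,max_frac_b Lenient-mode presence fractions.
#' @return A tibble: `region_id`, `a_present`, `a_total`, `b_present`,
#'   `b_total`, `differential`.
#' @export
differential_marks <- function(peaks, group_a, group_b, mode = c("strict",
                               "lenient"), min_frac_a = 1, max_frac_b = 0) {
  mode <- match.arg(mode)
  known <- peaks$group %in% c(group_a, group_b)
  if (any(!known)) {
    warn(sprintf("%d sample row(s) in neither group ignored", sum(!known)))
    peaks <- peaks[known, ]
  }
  if (!nrow(peaks)) abort("both groups must be non-empty")
  if (mode == "strict") {
    min_frac_a <- 1
    max_frac_b <- 0
  }
  out <- peaks |>
    dplyr::mutate(in_a = .data$group %in% group_a) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      a_present = sum(.data$peak & .data$in_a),
      a_total = sum(.data$in_a),
      b_present = sum(.data$peak & !.data$in_a),
      b_total = sum(!.data$in_a),
      .groups = "drop"
    )
  out$differential <- out$a_present >= min_frac_a * out$a_total &
    out$b_present <= max_frac_b * out$b_total
  out
}

#' The five-step candidate cis-regulatory funnel
#'
#' Applies, in order: TAD containment, promoter-correlation linking,
#' group-differential histone marks, (optional) chromatin-contact
#' evidence, and finally ranking of the surviving regions by
#' lineage-specific acceleration (most negative signed score first).
#' The final candidate is the top-ranked survivor.
#'
#' @param regions Candidate [genomic_interval()] tibble (names are
#'   region ids).
#' @param tads TAD intervals for [tad_filter()].
#' @param tags Tag-density tibble for [link_enhancers()].
#' @param peaks Peak-call tibble for [differential_marks()].
#' @param contacts Tibble `region_id`, `contact` (logical), or `NULL` to
#'   skip the contact filter.
#' @param accel Tibble `element`, `score`, `accelerated` (e.g.
#'   [rank_elements()] input built from [subtree_lrt()] results).
#' @param promoter_id Promoter row id in `tags`.
#' @param group_a,group_b Peak-call group labels for the differential
#'   step.
#' @param min_corr Linking threshold.
#' @return A tibble of class `candidate_report`: one row per region with
#'   per-filter booleans (`pass_tad`, `pass_link`, `pass_diff`,
#'   `pass_contact`), `correlation`, `accel_score`, `rank` (NA for
#'   non-survivors) and `final_candidate`.
#' @export
candidate_funnel <- function(regions, tads, tags, peaks, contacts, accel,
                             promoter_id, group_a, group_b,
                             min_corr = 0.7) {
  if (!nrow(regions)) {
    return(structure(tibble(region_id = character()),
                     class = c("candidate_report", class(tibble()))))
  }
  ids <- regions$name
  in_tad <- ids %in% tad_filter(regions, tads)$name
  links <- link_enhancers(tags, promoter_id,
                          distal_ids = intersect(ids, tags$region_id),
                          min_corr = min_corr)
  linked <- stats::setNames(links$linked, links$region_id)[ids]
  corr <- stats::setNames(links$correlation, links$region_id)[ids]
  diffs <- differential_marks(peaks, group_a, group_b)
  differential <- stats::setNames(diffs$differential, diffs$region_id)[ids]
  contact <- if (is.null(contacts)) rep(TRUE, length(ids)) else {
    stats::setNames(contacts$contact, contacts$region_id)[ids]
  }
  score <- stats::setNames(accel$score, accel$element)[ids]
  accelerated <- stats::setNames(accel$accelerated, accel$element)[ids]
  out <- tibble(
    region_id = ids,
    pass_tad = !is.na(in_tad) & in_tad,
    correlation = unname(corr),
    pass_link = !is.na(linked) & linked,
    pass_diff = !is.na(differential) & differential,
    pass_contact = !is.na(contact) & contact,
    accel_score = unname(score),
    accelerated = unname(accelerated)
  )
  out$survivor <- out$pass_tad & out$pass_link & out$pass_diff &
    out$pass_contact & !is.na(out$accel_score)
  out$rank <- NA_integer_
  surv <- which(out$survivor)
  if (length(surv)) {
    ord <- surv[order(-as.integer(out$accelerated[surv]),
                      out$accel_score[surv], out$region_id[surv])]
    out$rank[ord] <- seq_along(ord)
  }
  out$final_candidate <- !is.na(out$rank) & out$rank == 1L
  class(out) <- c("candidate_report", class(out))
  out
}
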