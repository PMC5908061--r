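#' Synthetic regulatory-funnel fixture
#'
#' Builds, from a seed, every input of [candidate_funnel()] with one
#' planted candidate (the DHS2 analogue, region `DHS2`):
#' 12 distal regions inside a TAD whose accessibility profiles correlate
#' at >= 0.7 with the promoter profile (plus 3 outside-TAD decoys below
#' 0.7); 5 regions whose H3K27ac-like peaks are present in all macaque
#' samples and absent from every human/chimpanzee sample; 3 regions with
#' chromatin-contact evidence; and alignments in which exactly one
#' contact-supported region evolved faster on the human-chimpanzee
#' subtree. A short sequence carries two NRSF-like motif instances whose
#' derived alleles raise the motif score, with a cross-species variant
#' table in which exactly two variants pass [cross_species_filter()].
#'
#' @param seed Integer seed; the fixture is deterministic given the seed.
#' @param n_cell_types Cell types in the tag-density matrix.
#' @param element_length Alignment columns per region.
#' @param multiplier Subtree rate multiplier planted on the candidate.
#' @return A list of class `funnel_fixture` with elements `regions`,
#'   `tads`, `tags`, `peaks`, `contacts`, `tree`, `subtree`,
#'   `alignments`, `accel`, `pwm`, `sequence`, `variants`,
#'   `candidate_id`, `promoter_id`, `groups`.
#' @export
make_funnel_fixture <- function(seed = 1L, n_cell_types = 12L,
                                element_length = 300L, multiplier = 4) {
  with_seed(seed, {
    ids <- paste0("DHS", 1:12)
    decoys <- paste0("OUT", 1:3)
    regions <- genomic_interval(
      chrom = "chr1",
      start = c(100000L + 5000L * (0:11), 60000L, 70000L, 215000L),
      end = c(100600L + 5000L * (0:11), 60600L, 70600L, 215600L),
      name = c(ids, decoys)
    )
    tads <- genomic_interval("chr1", c(95000L, 98000L), c(210000L, 240000L),
                             name = c("TAD_CP", "TAD_GZ"))
    # tag densities: linked rows follow the promoter profile, decoys don't
    prom <- runif(n_cell_types, 1, 10)
    draw_linked <- function() {
      repeat {
        row <- prom * runif(1, 0.5, 2) + stats::rnorm(n_cell_types, 0, 1.5)
        row <- pmax(row, 0)
        if (sd(row) > 0 && cor(row, prom) >= 0.75) return(row)
      }
    }
    draw_decoy <- function() {
      repeat {
        row <- runif(n_cell_types, 1, 10)
        if (cor(row, prom) < 0.65) return(row)
      }
    }
    tag_rows <- rbind(
      matrix(prom, nrow = 1),
      t(vapply(seq_along(ids), function(i) draw_linked(),
               numeric(n_cell_types))),
      t(vapply(seq_along(decoys), function(i) draw_decoy(),
               numeric(n_cell_types)))
    )
    tags <- dplyr::bind_cols(
      tibble(region_id = c("promoter", ids, decoys)),
      as_tibble(stats::setNames(as.data.frame(round(tag_rows, 4)),
                                paste0("cell", seq_len(n_cell_types))))
    )
    # peak calls: macaque-only H3K27ac at 5 regions (the promoter pattern)
    samples <- tibble(
      sample_id = c("RM1", "RM2", "RM3", "HS1", "HS2", "HS3", "Ch1", "Ch2"),
      group = c(rep("macaque", 3), rep("human_chimp", 5))
    )
    differential_ids <- c("DHS1", "DHS2", "DHS3", "DHS4", "DHS6")
    peaks <- tidyr::crossing(region_id = c(ids, decoys),
                             sample_id = samples$sample_id) |>
      dplyr::left_join(samples, by = "sample_id") |>
      dplyr::mutate(
        peak = ifelse(.data$region_id %in% differential_ids,
                      .data$group == "macaque", TRUE),
        intensity = ifelse(.data$peak, round(runif(dplyr::n(), 5, 35), 2),
                           NA_real_)
      )
    contacts <- tibble(region_id = c(ids, decoys),
                       contact = c(ids, decoys) %in% c("DHS1", "DHS2", "DHS3"))
    # alignments: only the candidate's element is accelerated
    tree <- ape::read.tree(text = paste0(
      "(((human:0.0067,chimp:0.0068):0.009,gorilla:0.009):0.025,",
      "macaque:0.038);"))
    subtree <- c("human", "chimp")
    model <- phylo_model("JC69")
    candidate <- "DHS2"
    for (attempt in 1:20) {
      alignments <- purrr::map(stats::setNames(ids, ids), function(id) {
        simulate_alignment(tree, element_length, model,
                           subtree = if (id == candidate) subtree else NULL,
                           multiplier = if (id == candidate) multiplier else 1)
      })
      accel <- purrr::map_dfr(ids, function(id) {
        r <- subtree_lrt(alignments[[id]], tree, model, subtree)
        dplyr::bind_cols(tibble(element = id), tidy(r))
      })
      contact_ids <- contacts$region_id[contacts$contact]
      sub <- accel[accel$element %in% contact_ids, ]
      best <- sub$element[order(-as.integer(sub$accelerated), sub$score)][1]
      ok <- best == candidate && sub$accelerated[sub$element == candidate] &&
        sub$p_value[sub$element == candidate] < 0.05
      if (ok) break
    }
    # NRSF-like motif, sequence with two planted instances, variant table
    pwm_obj <- read_meme_pwm(system.file("extdata", "nrsf_like.meme",
                                         package = "sweepreg"))[[1]]
    cons <- consensus(pwm_obj)
    w <- pwm_obj$width
    # variant columns: derived allele = consensus base, ancestral = the
    # base with the lowest probability in that column
    var_cols <- c(4L, 7L)
    anc_base <- vapply(var_cols, function(j) {
      BASES[which.min(pwm_obj$mat[j, ])]
    }, character(1))
    der_base <- vapply(var_cols, function(j) {
      BASES[which.max(pwm_obj$mat[j, ])]
    }, character(1))
    plant <- function(s, at, insert) {
      paste0(substr(s, 1, at - 1L), insert, substr(s, at + nchar(insert),
                                                   nchar(s)))
    }
    motif_pos <- c(61L + var_cols[1] - 1L, 121L + var_cols[2] - 1L)
    repeat {
      bg_seq <- paste(sample(BASES, 200, replace = TRUE,
                             prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
      sequence <- plant(plant(bg_seq, 61L, cons), 121L, cons)
      hits <- scan_pwm(sequence, pwm_obj)
      covers <- function(p) any(hits$start <= p & p <= hits$start + w - 1L)
      if (covers(motif_pos[1]) && covers(motif_pos[2]) && !covers(30L)) break
    }
    variants <- tibble(
      pos = c(motif_pos, 30L, 65L, 124L, 150L),
      ancestral = c(anc_base, "A", anc_base[1], anc_base[2], "C"),
      derived = c(der_base, "G", der_base[1], der_base[2], "T"),
      human_ref = c(der_base, "G", der_base[1], anc_base[2], "T"),
      chimp_ref = c(der_base, "G", der_base[1], der_base[2], "T"),
      macaque_ref = c(anc_base, "A", der_base[1], anc_base[2], NA)
    )
    structure(
      list(regions = regions, tads = tads, tags = tags, peaks = peaks,
           contacts = contacts, tree = tree, subtree = subtree,
           alignments = alignments, accel = accel, pwm = pwm_obj,
           sequence = sequence, variants = variants,
           candidate_id = candidate, promoter_id = "promoter",
           groups = list(a = "macaque", b = "human_chimp")),
      class = "funnel_fixture"
    )
  })
}

#' @export
print.funnel_fixture <- function(x, ...) {
  cat(sprintf(
    "<funnel_fixture> %d regions, %d cell types, planted candidate %s\n",
    nrow(x$regions), ncol(x$tags) - 1L, x$candidate_id))
  invisible(x)
}

#' Run the candidate funnel on a fixture
#'
#' Convenience wrapper wiring a [make_funnel_fixture()] into
#' [candidate_funnel()].
#'
#' @param fixture A `funnel_fixture`.
#' @param use_contacts Apply the contact filter (default `TRUE`).
#' @return A `candidate_report` tibble.
#' @export
run_funnel <- function(fixture, use_contacts = TRUE) {
  candidate_funnel(
    regions = fixture$regions,
    tads = fixture$tads,
    tags = fixture$tags,
    peaks = fixture$peaks,
    contacts = if (use_contacts) fixture$contacts else NULL,
    accel = fixture$accel,
    promoter_id = fixture$promoter_id,
    group_a = fixture$groups$a,
    group_b = fixture$groups$b
  )
}
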