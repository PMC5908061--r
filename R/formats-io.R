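#' Genomic intervals
#'
#' One row per interval, 1-based closed coordinates (`end >= start`).
#' Conversion to/from BED's 0-based half-open convention happens only in
#' [read_bed()] / [write_bed()].
#'
#' @param chrom Character vector of contig names (non-empty).
#' @param start,end Integer 1-based inclusive bounds.
#' @param name Optional interval names.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_) {
  if (any(!nzchar(chrom))) abort("`chrom` must be non-empty")
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end < start)) abort("interval `end` must be >= `start`")
  tibble(chrom = as.character(chrom), start = start, end = end,
         name = as.character(name))
}

interval_length <- function(interval) interval$end - interval$start + 1L

#' Variant records
#'
#' A tidy table of biallelic SNVs: one row per record with the quality
#' annotations used by [filter_variants()] and a list-column `gt` holding,
#' per record, one `"a|b"` (phased) or `"a/b"` (unphased) genotype string
#' per sample. Missing alleles are `"."`.
#'
#' @param chrom,pos,ref,alt,qual,mq,mq0,dp Per-record fields; `pos` is
#'   1-based. `ref`/`alt` must be single bases.
#' @param gt List of character genotype vectors (one element per record,
#'   one string per sample), or a character matrix records x samples.
#' @param samples Sample names.
#' @param id Optional record ids.
#' @return A tibble of class `variant_tbl` with attribute `"samples"`.
#' @export
variant_table <- function(chrom, pos, ref, alt, qual, mq, mq0, dp, gt,
                          samples, id = NA_character_) {
  if (is.matrix(gt)) gt <- lapply(seq_len(nrow(gt)), function(i) gt[i, ])
  bad <- nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad)) abort("`variant_table()` holds biallelic SNVs only")
  out <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = rep_len(as.character(id), length(pos)),
    ref = toupper(ref), alt = toupper(alt),
    qual = as.numeric(qual), mq = as.numeric(mq),
    mq0 = as.integer(mq0), dp = as.integer(dp),
    gt = gt
  )
  if (length(gt) && length(samples) != length(gt[[1]])) {
    abort("`samples` length must match the genotype vectors")
  }
  attr(out, "samples") <- as.character(samples)
  class(out) <- c("variant_tbl", class(out))
  out
}

vcf_samples <- function(variants) attr(variants, "samples")

#' Read a VCF into a variant table
#'
#' Restricted to the subset of VCF v4.x this pipeline consumes: biallelic
#' SNVs with `MQ`, `MQ0` and `DP` INFO annotations and `GT` genotypes.
#' Multiallelic records and indels are excluded with a logged count
#' (`skip`, the default) or raise an error (`error`). Records must be
#' position-sorted within each contig.
#'
#' @param path VCF file (plain text).
#' @param region Optional one-row [genomic_interval()]; only overlapping
#'   records are returned.
#' @param multiallelic `"skip"` or `"error"`.
#' @return A [variant_table()], sorted by position, with attributes
#'   `"samples"` and `"n_skipped"`.
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  samples <- setdiff(colnames(gt_raw), "FORMAT")
  if (nrow(fix) == 0L) {
    return(variant_table(character(), integer(), character(), character(),
                         numeric(), numeric(), integer(), integer(),
                         list(), samples))
  }
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  for (ct in unique(chrom)) {
    p <- pos[chrom == ct]
    if (is.unsorted(p)) {
      bad <- which(diff(p) < 0)[1] + 1L
      abort(sprintf("VCF not position-sorted: record %s:%d out of order",
                    ct, p[bad]))
    }
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(multi) && multiallelic == "error") {
    abort(sprintf("multiallelic record at %s:%d", chrom[which(multi)[1]],
                  pos[which(multi)[1]]))
  }
  drop <- multi | indel
  n_skipped <- sum(drop)
  if (n_skipped) {
    inform(sprintf("read_vcf: skipped %d multiallelic/indel record(s)", n_skipped))
  }
  keep <- which(!drop)
  info_num <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    x[keep]
  }
  gts <- lapply(keep, function(i) {
    g <- gt_raw[i, samples, drop = TRUE]
    sub("^([^:]*).*$", "\\1", g)
  })
  out <- variant_table(
    chrom = chrom[keep], pos = pos[keep],
    id = fix[keep, "ID"],
    ref = ref[keep], alt = alt[keep],
    qual = suppressWarnings(as.numeric(fix[keep, "QUAL"])),
    mq = info_num("MQ"), mq0 = as.integer(info_num("MQ0")),
    dp = as.integer(info_num("DP")),
    gt = gts, samples = samples
  )
  if (!is.null(region)) {
    out <- dplyr::filter(out, .data$chrom == region$chrom[1],
                         .data$pos >= region$start[1],
                         .data$pos <= region$end[1])
    attr(out, "samples") <- samples
    class(out) <- c("variant_tbl", setdiff(class(out), "variant_tbl"))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant table as plain-text VCF v4.2
#'
#' @param variants A [variant_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- vcf_samples(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with MQ 0\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    r <- variants[i, ]
    info <- sprintf("MQ=%s;MQ0=%d;DP=%d", format(r$mq, trim = TRUE),
                    r$mq0, r$dp)
    paste(c(r$chrom, r$pos, ifelse(is.na(r$id), ".", r$id), r$ref, r$alt,
            format(r$qual, trim = TRUE), "PASS", info, "GT", r$gt[[1]]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Quality-filter variant records
#'
#' Retains records with `MQ >= mq_min`, `QUAL >= qual_min` and
#' `MQ0/DP < mq0_dp_max` (strict `<`). Records with `DP = 0` are rejected
#' with reason `"undefined MQ0/DP ratio"`. Input order is preserved and
#' the filter is idempotent.
#'
#' @param variants A [variant_table()].
#' @param mq_min,qual_min,mq0_dp_max Thresholds.
#' @param on_missing What to do with records missing an annotation:
#'   `"error"` (default), `"drop"`, or `"keep"`.
#' @return The kept records, with attribute `"rejected"`: a tibble of
#'   `pos` and `reason` for each removed record.
#' @export
filter_variants <- function(variants, mq_min = 30, qual_min = 30,
                            mq0_dp_max = 0.1,
                            on_missing = c("error", "drop", "keep")) {
  on_missing <- match.arg(on_missing)
  miss <- is.na(variants$mq) | is.na(variants$qual) | is.na(variants$mq0) |
    is.na(variants$dp)
  if (any(miss) && on_missing == "error") {
    abort(sprintf("record at %s:%d is missing a quality annotation",
                  variants$chrom[which(miss)[1]], variants$pos[which(miss)[1]]))
  }
  reason <- rep(NA_character_, nrow(variants))
  dp0 <- !miss & variants$dp == 0L
  reason[dp0] <- "undefined MQ0/DP ratio"
  ok <- !miss & !dp0 &
    variants$mq >= mq_min & variants$qual >= qual_min &
    (variants$mq0 / variants$dp) < mq0_dp_max
  reason[!ok & !dp0 & !miss] <- "failed MQ/QUAL/MQ0-DP criteria"
  reason[miss] <- "missing annotation"
  if (on_missing == "keep") ok[miss] <- TRUE
  out <- variants[ok, ]
  attr(out, "samples") <- vcf_samples(variants)
  class(out) <- class(variants)
  attr(out, "rejected") <- tibble(pos = variants$pos[!ok],
                                  reason = reason[!ok])
  out
}

#' Build a haplotype matrix from phased variant records
#'
#' Polarizes genotypes to ancestral (0) / derived (1) using a map of
#' ancestral alleles. Sites whose ancestral base matches neither allele,
#' or is absent from the map, are kept but flagged unknown. All genotypes
#' must be phased; by default any site with a missing allele call is
#' dropped so that the chromosome count stays constant across sites.
#'
#' @param variants A [variant_table()].
#' @param ancestral Named character vector (names = positions) or a tibble
#'   with columns `pos` and `ancestral`.
#' @param on_missing `"drop_site"` (default) or `"keep"` (missing entries
#'   become an error downstream).
#' @return A [hap_matrix()] whose rows are `sample.1`, `sample.2`, ...
#' @export
to_haplotype_matrix <- function(variants, ancestral,
                                on_missing = c("drop_site", "keep")) {
  on_missing <- match.arg(on_missing)
  if (is.data.frame(ancestral)) {
    anc <- stats::setNames(toupper(ancestral$ancestral), ancestral$pos)
  } else {
    anc <- stats::setNames(toupper(ancestral), names(ancestral))
  }
  samples <- vcf_samples(variants)
  n_rec <- nrow(variants)
  if (n_rec == 0L) {
    return(hap_matrix(matrix(integer(), nrow = 2L * length(samples), ncol = 0L),
                      integer(), chrom = "chr1"))
  }
  cols <- vector("list", n_rec)
  unknown <- logical(n_rec)
  has_missing <- logical(n_rec)
  for (i in seq_len(n_rec)) {
    g <- variants$gt[[i]]
    if (any(grepl("/", g, fixed = TRUE))) {
      abort(sprintf("unphased genotype at %s:%d: haplotype statistics undefined",
                    variants$chrom[i], variants$pos[i]))
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    al <- suppressWarnings(as.integer(unlist(parts)))
    has_missing[i] <- anyNA(al)
    a <- anc[as.character(variants$pos[i])]
    if (is.na(a) || !(a %in% c(variants$ref[i], variants$alt[i]))) {
      unknown[i] <- TRUE
      cols[[i]] <- al
    } else if (a == variants$ref[i]) {
      cols[[i]] <- al
    } else {
      cols[[i]] <- 1L - al
    }
  }
  keep <- if (on_missing == "drop_site") !has_missing else rep(TRUE, n_rec)
  mat <- do.call(cbind, cols[keep])
  if (is.null(mat)) mat <- matrix(integer(), nrow = 2L * length(samples), ncol = 0L)
  rownames(mat) <- paste(rep(samples, each = 2L), 1:2, sep = ".")
  hap_matrix(mat, variants$pos[keep], chrom = variants$chrom[1],
             anc_known = !unknown[keep])
}

#' Read / write BED intervals
#'
#' BED3/BED6, 0-based half-open on disk; converted to the package's
#' 1-based closed convention in memory.
#'
#' @param path File path.
#' @return `read_bed()`: a [genomic_interval()] tibble.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (ncol(raw) < 3L) abort("BED needs at least 3 columns")
  genomic_interval(raw[[1]], raw[[2]] + 1L, raw[[3]],
                   name = if (ncol(raw) >= 4L) raw[[4]] else NA_character_)
}

#' @rdname read_bed
#' @param intervals A [genomic_interval()] tibble.
#' @export
write_bed <- function(intervals, path) {
  has_name <- !all(is.na(intervals$name))
  df <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  if (has_name) df$name <- intervals$name
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write a multi-species alignment block (aligned FASTA)
#'
#' @param path FASTA file; all rows must have equal length.
#' @return A character matrix (species x columns, upper case, `-` gaps)
#'   of class `alignment_block`.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    abort("ragged alignment: all FASTA rows must have equal length")
  }
  mat <- toupper(as.character(as.matrix(dna)))
  alignment_block(mat)
}

#' @rdname read_fasta_alignment
#' @param block An `alignment_block` character matrix.
#' @export
write_fasta_alignment <- function(block, path) {
  lines <- character(0)
  for (i in seq_len(nrow(block))) {
    lines <- c(lines, paste0(">", rownames(block)[i]),
               paste(block[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Alignment block constructor
#'
#' @param mat Character matrix, species x aligned columns; rownames are
#'   species ids.
#' @return The validated matrix with class `alignment_block`.
#' @export
alignment_block <- function(mat) {
  if (is.null(rownames(mat))) abort("alignment rows must be named by species")
  if (anyDuplicated(rownames(mat))) abort("species ids must be unique")
  mat[] <- toupper(mat)
  structure(mat, class = c("alignment_block", class(mat)))
}

#' Read a Newick tree (branch lengths required)
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length)) abort("Newick tree must carry branch lengths")
  tree
}

#' Read a MEME minimal-format motif file
#'
#' Parses letter-probability matrices and background frequencies. Rows not
#' summing to 1 within 1e-6 are renormalized with a warning. The returned
#' matrices have the pseudocount folded in (see [pwm()]).
#'
#' @param path MEME minimal motif file.
#' @param pseudocount Added per cell before normalization (default 0.1).
#' @return A named list of [pwm()] objects.
#' @export
read_meme_pwm <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toupper(toks[c(TRUE, FALSE)])
    bg <- vals[c("A", "C", "G", "T")]
  }
  motif_at <- grep("^MOTIF\\b", lines)
  out <- list()
  for (m in motif_at) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr_at <- m + grep("^letter-probability matrix", lines[(m + 1):length(lines)])[1]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr_at]))
    rows <- lines[(hdr_at + 1L):(hdr_at + w)]
    mat <- do.call(rbind, lapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 1e-6)) {
      warn(sprintf("motif %s: %d row(s) renormalized to sum 1", name,
                   sum(abs(sums - 1) > 1e-6)))
      mat <- mat / sums
    }
    colnames(mat) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(mat, name = name, background = bg,
                       pseudocount = pseudocount)
  }
  out
}

#' Write / read a fixed-step wiggle track
#'
#' @param scores Numeric vector of per-step scores.
#' @param path Output file.
#' @param chrom Contig name.
#' @param start 1-based start of the first step.
#' @param step Step (and span) in bp.
#' @return `write_wig()`: `path` invisibly. `read_wig()`: a tibble with
#'   columns `chrom`, `pos`, `score` and attribute `"step"`.
#' @export
write_wig <- function(scores, path, chrom = "chr1", start = 1L, step = 1L) {
  hdr <- sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                 chrom, as.integer(start), as.integer(step), as.integer(step))
  writeLines(c(hdr, sprintf("%.6g", scores)), path)
  invisible(path)
}

#' @rdname write_wig
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^fixedStep", hdr)) abort("only fixedStep wiggle is supported")
  get <- function(key) sub(sprintf(".*\\b%s=(\\S+).*", key), "\\1", hdr)
  start <- as.integer(get("start"))
  step <- as.integer(get("step"))
  scores <- as.numeric(lines[-1])
  out <- tibble(chrom = get("chrom"),
                pos = start + step * (seq_along(scores) - 1L),
                score = scores)
  attr(out, "step") <- step
  out
}

#' Read / write a tag-density matrix (regions x cell types)
#'
#' TSV with a header row of cell-type ids and a leading `region_id`
#' column; densities must be non-negative with no missing cells.
#'
#' @param path File path.
#' @return A tibble: `region_id` plus one numeric column per cell type.
#' @export
read_tag_density <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(x)[1] <- "region_id"
  vals <- as.matrix(x[-1])
  if (anyNA(vals)) abort("tag-density matrix has missing cells")
  if (any(vals < 0)) abort("tag densities must be non-negative")
  if (ncol(vals) < 2L) abort("need >= 2 cell types for correlation")
  x
}

#' @rdname read_tag_density
#' @param tags Tibble as returned by `read_tag_density()`.
#' @export
write_tag_density <- function(tags, path) {
  readr::write_tsv(tags, path, progress = FALSE)
  invisible(path)
}

#' Read / write a per-sample peak-call table
#'
#' Long TSV with columns `region_id`, `sample_id`, `group`, `peak`
#' (logical) and optional `intensity` (-log10 P, present only where
#' `peak` is `TRUE`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_peak_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("region_id", "sample_id", "group", "peak")
  if (!all(need %in% names(x))) {
    abort(sprintf("peak table must have columns %s", paste(need, collapse = ", ")))
  }
  x$peak <- as.logical(x$peak)
  if ("intensity" %in% names(x) && any(!x$peak & !is.na(x$intensity))) {
    abort("intensity present for a region/sample without a peak")
  }
  x
}

#' @rdname read_peak_calls
#' @param peaks Tibble as returned by `read_peak_calls()`.
#' @export
write_peak_calls <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}
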