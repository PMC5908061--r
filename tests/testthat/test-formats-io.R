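test_that("VCF round trip preserves records and skips multiallelics/indels", {
  toy <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  v <- suppressMessages(read_vcf(toy))
  expect_equal(nrow(v), 2L)              # 4 records, 1 multiallelic + 1 indel
  expect_equal(attr(v, "n_skipped"), 2L)
  expect_equal(v$pos, c(100L, 400L))
  expect_equal(vcf_samples(v), c("S1", "S2"))
  expect_error(read_vcf(toy, multiallelic = "error"), "multiallelic")

  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, out)
  v2 <- read_vcf(out)
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$ref, v$ref)
  expect_equal(v2$alt, v$alt)
  expect_equal(v2$mq, v$mq)
  expect_equal(v2$mq0, v$mq0)
  expect_equal(v2$dp, v$dp)
  expect_equal(v2$gt, v$gt)

  # region restriction and empty body
  r <- read_vcf(out, region = genomic_interval("chr1", 350L, 500L))
  expect_equal(r$pos, 400L)
  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(readLines(out)[1:6], empty)
  expect_equal(nrow(read_vcf(empty)), 0L)
})

test_that("unsorted VCF input is rejected with the offending record named", {
  toy <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_toy_vcf(withr::local_tempfile(fileext = ".vcf")))
  writeLines(c(lines[1:6], lines[10], lines[7]), toy)   # 400 before 100
  expect_error(suppressMessages(read_vcf(toy)), "chr1:100")
})

test_that("variant filter applies the MQ/QUAL/MQ0-DP rule at its boundaries", {
  gt <- matrix("0|1", nrow = 10, ncol = 1)
  v <- variant_table(chrom = "chr1", pos = 1:10 * 10L, ref = "A", alt = "G",
                     qual = c(30, 30, 29.9, rep(30, 7)),
                     mq = c(30, 29.9, rep(30, 8)),
                     mq0 = c(0, 0, 0, 2, rep(0, 6)),
                     dp = c(20L, 20L, 20L, 20L, rep(20L, 6)),
                     gt = gt, samples = "S1")
  kept <- filter_variants(v)
  # exact boundary record (MQ=30, QUAL=30, MQ0=0, DP=20) is kept
  expect_true(10L %in% kept$pos)
  # MQ=29.9 removed, QUAL=29.9 removed, MQ0/DP=0.1 removed (strict <)
  expect_false(any(c(20L, 30L, 40L) %in% kept$pos))
  expect_equal(nrow(kept), 7L)
  # order preserved and idempotent
  expect_equal(kept$pos, sort(kept$pos))
  again <- filter_variants(kept)
  expect_equal(again$pos, kept$pos)
})

test_that("DP = 0 records are rejected as undefined MQ0/DP", {
  v <- variant_table("chr1", 5L, "A", "G", qual = 99, mq = 60, mq0 = 0L,
                     dp = 0L, gt = matrix("0|1", 1, 1), samples = "S1")
  kept <- filter_variants(v)
  expect_equal(nrow(kept), 0L)
  expect_equal(attr(kept, "rejected")$reason, "undefined MQ0/DP ratio")
})

test_that("missing annotations follow the configured policy", {
  v <- variant_table("chr1", c(1L, 2L), "A", "G", qual = c(99, NA),
                     mq = 60, mq0 = 0L, dp = 20L,
                     gt = matrix("0|1", 2, 1), samples = "S1")
  expect_error(filter_variants(v), "missing")
  expect_equal(filter_variants(v, on_missing = "drop")$pos, 1L)
  expect_equal(filter_variants(v, on_missing = "keep")$pos, c(1L, 2L))
})

test_that("haplotype matrix construction polarizes by the ancestral allele", {
  gt <- rbind(c("0|1", "1|1"))
  v <- variant_table("chr1", 50L, "A", "G", 99, 60, 0L, 20L, gt,
                     samples = c("S1", "S2"))
  h_ref <- to_haplotype_matrix(v, c(`50` = "A"))
  expect_equal(as.integer(h_ref$mat), c(0L, 1L, 1L, 1L))
  # ancestral = alt flips the coding
  h_alt <- to_haplotype_matrix(v, c(`50` = "G"))
  expect_equal(as.integer(h_alt$mat), 1L - c(0L, 1L, 1L, 1L))
  # ancestral matching neither allele flags the site unknown
  h_unk <- to_haplotype_matrix(v, c(`50` = "T"))
  expect_false(h_unk$anc_known[1])
  expect_equal(n_sites(h_unk), 1L)
})

test_that("unphased and missing genotypes are handled as specified", {
  v_unph <- variant_table("chr1", 5L, "A", "G", 99, 60, 0L, 20L,
                          rbind(c("0/1")), samples = "S1")
  expect_error(to_haplotype_matrix(v_unph, c(`5` = "A")), "unphased")
  v_miss <- variant_table("chr1", c(5L, 9L), "A", "G", 99, 60, 0L, 20L,
                          rbind(c("0|1"), c(".|1")), samples = "S1")
  h <- to_haplotype_matrix(v_miss, c(`5` = "A", `9` = "A"))
  expect_equal(h$pos, 5L)              # missing-genotype site dropped
})

test_that("five-site fixture with one unknown ancestral site is fully kept and flagged", {
  gt <- matrix("0|1", nrow = 5, ncol = 2)
  v <- variant_table("chr1", c(10L, 20L, 30L, 40L, 50L), "A", "G",
                     99, 60, 0L, 20L, gt, samples = c("S1", "S2"))
  anc <- c(`10` = "A", `20` = "G", `30` = "T", `40` = "A", `50` = "A")
  h <- to_haplotype_matrix(v, anc)
  expect_equal(n_sites(h), 5L)
  expect_equal(sum(!h$anc_known), 1L)
  expect_false(h$anc_known[3])
})

test_that("BED round trip is identity and byte-stable", {
  iv <- genomic_interval("chr1", c(1L, 101L, 501L), c(100L, 200L, 900L),
                         name = c("a", "b", "c"))
  p1 <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, p1)
  back <- read_bed(p1)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$name, iv$name)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("Newick reading requires branch lengths and counts nodes", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.1):0.05,C:0.15);", p)
  tr <- read_newick(p)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  writeLines("((A,B),C);", p)
  expect_error(read_newick(p), "branch lengths")
})

test_that("aligned FASTA round trips and ragged input errors", {
  block <- aln(human = "ACGT-A", chimp = "ACGTTA", macaque = "ACTTTA")
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(block, p)
  back <- read_fasta_alignment(p)
  expect_equal(unclass(back), unclass(block), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(block))
  writeLines(c(">a", "ACGT", ">b", "AC"), p)
  expect_error(read_fasta_alignment(p), "ragged")
})

test_that("MEME minimal parsing returns the motif at its declared width", {
  pwms <- read_meme_pwm(system.file("extdata", "nrsf_like.meme",
                                    package = "sweepreg"))
  expect_length(pwms, 1L)
  expect_equal(pwms[[1]]$width, 10L)
  expect_equal(rowSums(pwms[[1]]$mat), rep(1, 10), tolerance = 1e-9)
  # rows not summing to 1 are renormalized with a warning
  p <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF bad",
    "letter-probability matrix: alength= 4 w= 2",
    " 0.5 0.5 0.5 0.5",
    " 0.25 0.25 0.25 0.25"
  ), p)
  expect_warning(bad <- read_meme_pwm(p), "renormalized")
  expect_equal(rowSums(bad$bad$mat), rep(1, 2), tolerance = 1e-9)
})

test_that("fixed-step wiggle write/read round trips byte-stably", {
  p1 <- withr::local_tempfile(fileext = ".wig")
  write_wig(c(0.5, -1.25, 3), p1, chrom = "chr4", start = 101L, step = 100L)
  w <- read_wig(p1)
  expect_equal(w$pos, c(101L, 201L, 301L))
  expect_equal(w$score, c(0.5, -1.25, 3))
  p2 <- withr::local_tempfile(fileext = ".wig")
  write_wig(w$score, p2, chrom = "chr4", start = 101L, step = 100L)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("tag-density and peak-call tables validate their invariants", {
  tp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_id\tc1\tc2", "r1\t1.5\t2", "r2\t0\t4"), tp)
  tags <- read_tag_density(tp)
  expect_equal(dim(tags), c(2L, 3L))
  writeLines(c("region_id\tc1\tc2", "r1\t-1\t2"), tp)
  expect_error(read_tag_density(tp), "non-negative")

  pp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_id\tsample_id\tgroup\tpeak\tintensity",
               "r1\ts1\tA\tTRUE\t18.02", "r1\ts2\tB\tFALSE\tNA"), pp)
  peaks <- read_peak_calls(pp)
  expect_equal(peaks$intensity, c(18.02, NA))
  writeLines(c("region_id\tsample_id\tgroup\tpeak\tintensity",
               "r1\ts1\tA\tFALSE\t18.02"), pp)
  expect_error(read_peak_calls(pp), "without a peak")
})

test_that("haplotype matrix construction is sample-order invariant up to rows", {
  gt <- rbind(c("0|1", "1|0"), c("1|1", "0|0"))
  v1 <- variant_table("chr1", c(10L, 20L), "A", "G", 99, 60, 0L, 20L, gt,
                      samples = c("S1", "S2"))
  v2 <- variant_table("chr1", c(10L, 20L), "A", "G", 99, 60, 0L, 20L,
                      gt[, 2:1], samples = c("S2", "S1"))
  anc <- c(`10` = "A", `20` = "A")
  h1 <- to_haplotype_matrix(v1, anc)
  h2 <- to_haplotype_matrix(v2, anc)
  expect_equal(h1$mat[order(rownames(h1$mat)), ],
               h2$mat[order(rownames(h2$mat)), ])
})
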