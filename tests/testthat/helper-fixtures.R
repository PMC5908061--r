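# Shared fixtures and independent oracles used across test files.

# Brute-force nucleotide diversity: mean pairwise difference count over
# all chromosome pairs.
brute_pi <- function(hap) {
  m <- hap$mat
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(m[i, ] != m[j, ])
    }
  }
  tot / choose(n, 2)
}

# Independent Tajima's D evaluation, written directly from the 1989
# coefficient definitions (separate code path from the package).
oracle_tajimas_d <- function(hap) {
  m <- hap$mat
  n <- nrow(m)
  k <- colSums(m)
  seg <- k > 0 & k < n
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  pi_hat <- brute_pi(list(mat = m[, seg, drop = FALSE]))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * s + (c2 / (a1^2 + a2)) * s * (s - 1)
  (pi_hat - s / a1) / sqrt(v)
}

# Random haplotype fixture with at least one copy of each allele per site.
random_hap <- function(n, s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * s, 1, runif(1, 0.2, 0.8)), nrow = n)
    k <- colSums(m)
    if (all(k > 0 & k < n)) break
  }
  hap_matrix(m, sort(sample.int(10 * s, s)))
}

# Random PWM of width k (probability rows), via the package constructor.
random_pwm <- function(k, seed = NULL, pseudocount = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rgamma(4 * k, 1), ncol = 4)
  m <- m / rowSums(m)
  pwm(m, name = "rand", pseudocount = pseudocount)
}

# Exhaustive PWM p-value: enumerate all 4^k k-mers on the same
# discretized per-column score scale the DP uses.
enum_pvalue <- function(x, score, resolution = 1e-3) {
  k <- x$width
  cols <- round(log2(x$mat / matrix(x$background, k, 4, byrow = TRUE)) /
                  resolution)
  t <- as.integer(round(score / resolution))
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  totals <- grid
  tot <- integer(nrow(grid))
  pr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- grid[i, ]
    tot[i] <- sum(cols[cbind(seq_len(k), idx)])
    pr[i] <- prod(x$background[idx])
  }
  sum(pr[tot >= t])
}

toy_tree <- function() {
  ape::read.tree(text = paste0(
    "(((human:0.0067,chimp:0.0068):0.009,gorilla:0.009):0.025,",
    "macaque:0.038);"))
}

# Hand-built alignment block from per-species strings.
aln <- function(...) {
  rows <- list(...)
  alignment_block(do.call(rbind, lapply(rows, function(s) {
    strsplit(s, "")[[1]]
  })) |> (\(m) { rownames(m) <- names(rows); m })())
}

# Small VCF written verbatim (independent of write_vcf) with one
# multiallelic record and one indel.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"MQ0\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG\t50\tPASS\tMQ=40;MQ0=0;DP=30\tGT\t0|1\t1|1",
    "chr1\t200\t.\tC\tT,G\t50\tPASS\tMQ=40;MQ0=0;DP=30\tGT\t0|1\t0|2",
    "chr1\t300\t.\tG\tGA\t50\tPASS\tMQ=40;MQ0=0;DP=30\tGT\t0|1\t0|0",
    "chr1\t400\t.\tT\tC\t50\tPASS\tMQ=40;MQ0=0;DP=30\tGT\t0|0\t0|1"
  ), path)
  path
}

# One reusable funnel fixture per test session (construction is a few
# seconds; several files assert different slices of it).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_funnel_fixture(seed = 42L)
    cache
  }
})
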