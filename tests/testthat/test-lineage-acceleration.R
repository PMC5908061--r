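test_that("column likelihoods match closed forms and brute-force state sums", {
  tree2 <- ape::read.tree(text = "(a:0.1,b:0.2);")
  block_same <- aln(a = "A", b = "A")
  # two-leaf JC69, total length t: P(same obs base) = 1/4 (1/4 + 3/4 e^{-4t/3})
  t_tot <- 0.3
  expected <- log(0.25 * (0.25 + 0.75 * exp(-4 * t_tot / 3)))
  expect_equal(column_log_likelihood(block_same, tree2), expected,
               tolerance = 1e-12)
  # columns of gaps/N carry probability 1
  block_missing <- aln(a = "-N", b = "N-")
  expect_equal(column_log_likelihood(block_missing, tree2), c(0, 0))
  # brute-force sum over all internal states for 3- and 5-leaf trees
  brute <- function(block, tree, model) {
    tree <- stats::reorder(tree, "postorder")
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      model$P(tree$edge.length[e])
    })
    root <- tree$edge[nrow(tree$edge), 1]
    internal <- (n_tip + 1):n_node
    sapply(seq_len(ncol(block)), function(col) {
      obs <- match(block[tree$tip.label, col], c("A", "C", "G", "T"))
      states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
      tot <- 0
      for (r in seq_len(nrow(states))) {
        assign_state <- function(node) {
          if (node <= n_tip) obs[node] else states[r, match(node, internal)]
        }
        pr <- model$pi[assign_state(root)]
        for (e in seq_len(nrow(tree$edge))) {
          a <- assign_state(tree$edge[e, 1])
          b <- assign_state(tree$edge[e, 2])
          if (is.na(b)) next
          if (is.na(a)) stop("internal NA")
          pr <- pr * Ps[[e]][a, b]
        }
        tot <- tot + pr
      }
      log(tot)
    })
  }
  model <- phylo_model("JC69")
  tree3 <- ape::read.tree(text = "((a:0.1,b:0.15):0.05,c:0.2);")
  block3 <- aln(a = "ACG", b = "ACT", c = "GCT")
  expect_equal(column_log_likelihood(block3, tree3, model),
               unname(brute(block3, tree3, model)), tolerance = 1e-10)
  tree5 <- toy_tree()
  block5 <- simulate_alignment(tree5, 6, seed = 71)
  expect_equal(column_log_likelihood(block5, tree5, model),
               unname(brute(block5, tree5, model)), tolerance = 1e-10)
  # HKY85 agrees with the brute force too
  hky <- phylo_model("HKY85", kappa = 3, base_freqs = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(column_log_likelihood(block3, tree3, hky),
               unname(brute(block3, tree3, hky)), tolerance = 1e-10)
})

test_that("likelihood handles conflicting observations on a zero-length tree", {
  tree0 <- ape::read.tree(text = "(a:0,b:0);")
  conflict <- aln(a = "A", b = "C")
  expect_identical(column_log_likelihood(conflict, tree0), -Inf)
})

test_that("subtree LRT is calibrated and degenerate cases are flat", {
  tree <- toy_tree()
  same <- alignment_block(matrix("A", 4, 30,
                                 dimnames = list(tree$tip.label, NULL)))
  res <- subtree_lrt(same, tree, subtree = c("human", "chimp"))
  expect_lt(res$lambda, 1e-6)
  expect_gt(res$p_value, 0.99)
  expect_lt(abs(res$score), 0.01)
  # entirely missing element: undefined, not an error
  gap <- alignment_block(matrix("-", 4, 5,
                                dimnames = list(tree$tip.label, NULL)))
  expect_false(subtree_lrt(gap, tree, subtree = c("human", "chimp"))$defined)
  # non-clade tip sets are rejected
  al <- simulate_alignment(tree, 20, seed = 72)
  expect_error(subtree_lrt(al, tree, subtree = c("human", "macaque")),
               "clade")
})

test_that("nested-model inequality holds on random alignments", {
  tree <- toy_tree()
  set.seed(73)
  for (rep in 1:8) {
    al <- simulate_alignment(tree, 60,
                             multiplier = sample(c(1, 2, 4), 1),
                             subtree = c("human", "chimp"))
    res <- subtree_lrt(al, tree, subtree = c("human", "chimp"))
    expect_gte(res$lnl_alt, res$lnl_null)
    expect_gte(res$lambda, 0)
  }
})

test_that("planted subtree acceleration is detected with a negative score", {
  tree <- toy_tree()
  hits <- sapply(1:8, function(i) {
    al <- simulate_alignment(tree, 500, subtree = c("human", "chimp"),
                             multiplier = 4, seed = 700 + i)
    r <- subtree_lrt(al, tree, subtree = c("human", "chimp"))
    c(p = r$p_value, score = r$score, scale = r$subtree_scale / r$scale_rest)
  })
  expect_gte(mean(hits["p", ] < 0.01), 0.8)
  expect_true(all(hits["score", hits["p", ] < 0.01] < 0))
  # median fitted rate ratio within a factor 1.5 of the planted multiplier
  expect_gt(median(hits["scale", ]), 4 / 1.5)
  expect_lt(median(hits["scale", ]), 4 * 1.5)
})

test_that("null alignments do not over-reject", {
  tree <- toy_tree()
  ps <- sapply(1:20, function(i) {
    al <- simulate_alignment(tree, 300, seed = 800 + i)
    subtree_lrt(al, tree, subtree = c("human", "chimp"))$p_value
  })
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("scores are antisymmetric in the subtree choice on a mirrored tree", {
  two_clade <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.02,(c:0.05,d:0.05):0.02);")
  al <- simulate_alignment(two_clade, 400, subtree = c("a", "b"),
                           multiplier = 3, seed = 74)
  r_ab <- subtree_lrt(al, two_clade, subtree = c("a", "b"))
  r_cd <- subtree_lrt(al, two_clade, subtree = c("c", "d"))
  expect_true(r_ab$accelerated)
  expect_lt(r_ab$score, 0)
  expect_false(r_cd$accelerated)
  expect_gt(r_cd$score, 0)
})

test_that("basewise scores flag subtree-specific columns and zero invariants", {
  tree <- toy_tree()
  block <- aln(human = "AAC", chimp = "AAC", gorilla = "AAA",
               macaque = "AAA")
  # col 1-2 invariant; col 3: human-chimp differ from the others
  scores <- basewise_scores(block, tree, subtree = c("human", "chimp"))
  expect_equal(nrow(scores), 3L)
  expect_lt(abs(scores$score[1]), 0.05)
  expect_lt(scores$score[3], 0)
  gap_block <- aln(human = "-", chimp = "-", gorilla = "-", macaque = "-")
  expect_equal(basewise_scores(gap_block, tree,
                               subtree = c("human", "chimp"))$score, 0)
})

test_that("element ranking puts the most accelerated first with stable ties", {
  res <- tibble::tibble(
    element = c("DHS1", "DHS2", "DHS3", "DHS4"),
    score = c(0.3, -4.2, -1.1, 0.3),
    accelerated = c(FALSE, TRUE, TRUE, FALSE)
  )
  ranked <- rank_elements(res)
  expect_equal(ranked$element, c("DHS2", "DHS3", "DHS1", "DHS4"))
  expect_equal(ranked$rank, 1:4)
  ties <- tibble::tibble(element = c("b", "a"), score = c(0, 0),
                         accelerated = FALSE)
  expect_equal(rank_elements(ties)$element, c("a", "b"))
  expect_error(rank_elements(tibble::tibble(element = "x", score = NA,
                                            accelerated = NA)), "defined")
})

test_that("tidy and glance return one-row summaries", {
  tree <- toy_tree()
  al <- simulate_alignment(tree, 50, seed = 75)
  r <- subtree_lrt(al, tree, subtree = c("human", "chimp"))
  td <- tidy(r)
  expect_equal(nrow(td), 1L)
  expect_true(all(c("lambda", "p_value", "score", "subtree_scale") %in%
                    names(td)))
  expect_identical(glance(r), td)
})
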