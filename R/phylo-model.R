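BASES <- c("A", "C", "G", "T")

#' Nucleotide substitution model
#'
#' JC69 (default) or HKY85. Branch lengths are in expected substitutions
#' per site; rate matrices are scaled so that one unit of branch length
#' yields one expected substitution at equilibrium.
#'
#' @param model `"JC69"` or `"HKY85"`.
#' @param kappa Transition/transversion rate ratio (HKY85 only).
#' @param base_freqs Equilibrium frequencies over A, C, G, T (must sum
#'   to 1; JC69 forces 1/4 each).
#' @return An object of class `phylo_model` with elements `model`, `pi`
#'   and `P(t)`, the 4x4 transition-probability matrix function.
#' @export
phylo_model <- function(model = c("JC69", "HKY85"), kappa = 2,
                        base_freqs = rep(0.25, 4)) {
  model <- match.arg(model)
  if (abs(sum(base_freqs) - 1) > 1e-9) abort("`base_freqs` must sum to 1")
  if (model == "JC69") {
    pi <- rep(0.25, 4)
    P <- function(t) {
      e <- exp(-4 * t / 3)
      p_same <- 0.25 + 0.75 * e
      p_diff <- 0.25 - 0.25 * e
      m <- matrix(p_diff, 4, 4, dimnames = list(BASES, BASES))
      diag(m) <- p_same
      m
    }
  } else {
    pi <- as.numeric(base_freqs)
    names(pi) <- BASES
    # HKY85 rate matrix; transitions A<->G, C<->T get factor kappa
    Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    ti <- function(a, b) (a == "A" && b == "G") || (a == "G" && b == "A") ||
      (a == "C" && b == "T") || (a == "T" && b == "C")
    for (a in BASES) for (b in BASES) {
      if (a != b) Q[a, b] <- pi[b] * (if (ti(a, b)) kappa else 1)
    }
    diag(Q) <- -rowSums(Q)
    scale <- -sum(pi * diag(Q))
    Q <- Q / scale
    P <- function(t) {
      m <- ape::matexpo(Q * t)
      dimnames(m) <- list(BASES, BASES)
      m
    }
  }
  structure(list(model = model, pi = stats::setNames(pi, BASES), P = P,
                 kappa = if (model == "HKY85") kappa else NA_real_),
            class = "phylo_model")
}

# Edge indices (rows of tree$edge) belonging to the clade spanned by
# `tips`, including the clade's stem branch. `tips` may be a single tip.
subtree_edges <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    abort(sprintf("subtree tip(s) not in tree: %s",
                  paste(tips[is.na(idx)], collapse = ", ")))
  }
  if (length(idx) == 1L) {
    return(which(tree$edge[, 2] == idx))
  }
  mrca <- ape::getMRCA(tree, idx)
  nodes <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% nodes, 2]
    grown <- union(nodes, kids)
    if (length(grown) == length(nodes)) break
    nodes <- grown
  }
  clade_tips <- nodes[nodes <= length(tree$tip.label)]
  if (!setequal(clade_tips, idx)) {
    abort("named tips do not form a proper clade of the tree")
  }
  which(tree$edge[, 2] %in% nodes)   # includes the stem edge (child = mrca)
}

#' Simulate a multi-species alignment on a tree
#'
#' Columns are drawn independently: the root base comes from the model's
#' equilibrium frequencies and substitutions occur along each branch
#' under the model's transition probabilities. Branches inside the
#' `subtree` clade (including its stem) have their lengths multiplied by
#' `multiplier`, emulating lineage-specific acceleration.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param element_length Number of alignment columns.
#' @param model A [phylo_model()].
#' @param subtree Optional character vector of tip labels spanning the
#'   accelerated clade.
#' @param multiplier Rate multiplier (> 0) for the subtree branches.
#' @param seed Optional integer seed.
#' @return An [alignment_block()] with one row per tree tip.
#' @export
simulate_alignment <- function(tree, element_length, model = phylo_model(),
                               subtree = NULL, multiplier = 1, seed = NULL) {
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (multiplier <= 0) abort("`multiplier` must be > 0")
  tree <- stats::reorder(tree, "cladewise")
  scale <- rep(1, nrow(tree$edge))
  if (!is.null(subtree)) scale[subtree_edges(tree, subtree)] <- multiplier
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    states <- matrix(NA_integer_, n_node, element_length)
    root <- n_tip + 1L
    states[root, ] <- sample.int(4L, element_length, replace = TRUE,
                                 prob = model$pi)
    # parent rows of tree$edge precede children in a preorder ("cladewise")
    ord <- seq_len(nrow(tree$edge))
    for (e in ord) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      P <- model$P(tree$edge.length[e] * scale[e])
      ps <- states[parent, ]
      cs <- integer(element_length)
      for (a in 1:4) {
        at <- which(ps == a)
        if (length(at)) {
          cs[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[a, ])
        }
      }
      states[child, ] <- cs
    }
    mat <- matrix(BASES[states[seq_len(n_tip), , drop = FALSE]],
                  nrow = n_tip, dimnames = list(tree$tip.label, NULL))
    alignment_block(mat)
  })
}
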