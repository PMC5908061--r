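#' Per-column log-likelihood of an alignment under a scaled tree
#'
#' Felsenstein pruning over the tree, with branch lengths multiplied by
#' `scale_rest` (all branches outside the named subtree) and
#' `subtree_scale` (branches inside the clade spanned by `subtree`,
#' including its stem). Gaps, `N` and other ambiguity codes are treated
#' as missing data (leaf likelihood 1 for every state); a column with no
#' data has log-likelihood 0.
#'
#' @param block An [alignment_block()]; rownames must include every tree
#'   tip.
#' @param tree `ape::phylo` with branch lengths.
#' @param model A [phylo_model()].
#' @param scale_rest Shared scale for branches outside the subtree.
#' @param subtree Character vector of tip labels, or `NULL` for a single
#'   shared scale.
#' @param subtree_scale Scale for the subtree branches.
#' @return Numeric vector of per-column log-likelihoods (`-Inf` where a
#'   zero-length tree conflicts with the observed bases).
#' @export
column_log_likelihood <- function(block, tree, model = phylo_model(),
                                  scale_rest = 1, subtree = NULL,
                                  subtree_scale = 1) {
  tree <- stats::reorder(tree, "postorder")
  miss <- setdiff(tree$tip.label, rownames(block))
  if (length(miss)) {
    abort(sprintf("alignment lacks species: %s", paste(miss, collapse = ", ")))
  }
  scale <- rep(scale_rest, nrow(tree$edge))
  if (!is.null(subtree)) scale[subtree_edges(tree, subtree)] <- subtree_scale
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_col <- ncol(block)
  partial <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    b <- block[tree$tip.label[i], ]
    m <- matrix(1, 4, n_col)
    obs <- match(b, BASES)           # NA for gaps/N/ambiguity
    seen <- which(!is.na(obs))
    if (length(seen)) {
      m[, seen] <- 0
      m[cbind(obs[seen], seen)] <- 1
    }
    partial[[i]] <- m
  }
  for (e in seq_len(nrow(tree$edge))) {   # postorder: children first
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    P <- model$P(tree$edge.length[e] * scale[e])
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
  }
  root <- tree$edge[nrow(tree$edge), 1]
  lik <- colSums(model$pi * partial[[root]])
  out <- rep(-Inf, n_col)
  out[lik > 0] <- log(lik[lik > 0])
  out
}

# Total log-likelihood for the scale pair, used by the LRT optimizers.
element_lnl <- function(block, tree, model, scale_rest, subtree, subtree_scale) {
  sum(column_log_likelihood(block, tree, model, scale_rest, subtree,
                            subtree_scale))
}

#' Subtree acceleration likelihood-ratio test
#'
#' phyloP-style test for lineage-specific rate change: the null model
#' fits one shared rate multiplier for the whole tree, the alternative
#' fits separate multipliers for the named subtree and the remainder.
#' The statistic is `Lambda = 2 (lnL_alt - lnL_null)`, compared to a
#' chi-squared distribution with 1 df. The signed score follows the
#' CONACC convention: `-log10(p)` positive when the subtree is slower
#' (conserved), negative when faster (accelerated).
#'
#' @param block An [alignment_block()].
#' @param tree `ape::phylo` with branch lengths.
#' @param model A [phylo_model()].
#' @param subtree Character vector of tip labels spanning a proper clade.
#' @param element Optional column range `c(first, last)` restricting the
#'   test to part of the block.
#' @param bounds Search interval for every rate multiplier.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param boundary_correction Halve the p-value at the boundary (mixture
#'   chi-squared); default plain chi-squared.
#' @return An object of class `subtree_lrt` (see [tidy.subtree_lrt()]).
#' @export
subtree_lrt <- function(block, tree, model = phylo_model(), subtree,
                        element = NULL, bounds = c(1e-4, 100), tol = 1e-8,
                        boundary_correction = FALSE) {
  if (!is.null(element)) {
    block <- block[, element[1]:element[2], drop = FALSE]
    block <- alignment_block(block)
  }
  informative <- any(block[tree$tip.label, ] %in% BASES)
  if (!informative) {
    out <- list(lnl_null = 0, lnl_alt = 0, scale_all = NA_real_,
                scale_rest = NA_real_, subtree_scale = NA_real_,
                lambda = NA_real_, p_value = NA_real_, score = NA_real_,
                accelerated = NA, n_columns = ncol(block), defined = FALSE,
                subtree = subtree)
    class(out) <- "subtree_lrt"
    return(out)
  }
  log_bounds <- log(bounds)
  # null: one shared scale
  f_null <- function(lc) element_lnl(block, tree, model, exp(lc), NULL, 1)
  opt0 <- optimize(f_null, log_bounds, maximum = TRUE, tol = 1e-10)
  scale_all <- exp(opt0$maximum)
  lnl_null <- opt0$objective
  # alternative: coordinate ascent from the null optimum; each accepted
  # step must improve, so lnl_alt >= lnl_null by construction
  sr <- scale_all
  ss <- scale_all
  lnl_alt <- element_lnl(block, tree, model, sr, subtree, ss)
  for (it in seq_len(50L)) {
    prev <- lnl_alt
    o1 <- optimize(function(lc) element_lnl(block, tree, model, sr, subtree,
                                            exp(lc)),
                   log_bounds, maximum = TRUE, tol = 1e-10)
    if (o1$objective > lnl_alt) {
      ss <- exp(o1$maximum)
      lnl_alt <- o1$objective
    }
    o2 <- optimize(function(lc) element_lnl(block, tree, model, exp(lc),
                                            subtree, ss),
                   log_bounds, maximum = TRUE, tol = 1e-10)
    if (o2$objective > lnl_alt) {
      sr <- exp(o2$maximum)
      lnl_alt <- o2$objective
    }
    if (lnl_alt - prev < tol) break
  }
  lnl_alt <- max(lnl_alt, lnl_null)
  lambda <- 2 * (lnl_alt - lnl_null)
  p <- pchisq(lambda, df = 1, lower.tail = FALSE)
  if (boundary_correction) p <- p / 2
  accelerated <- ss > sr
  score <- -log10(p) * (if (accelerated) -1 else 1)
  out <- list(lnl_null = lnl_null, lnl_alt = lnl_alt, scale_all = scale_all,
              scale_rest = sr, subtree_scale = ss, lambda = lambda,
              p_value = p, score = score, accelerated = accelerated,
              n_columns = ncol(block), defined = TRUE, subtree = subtree)
  class(out) <- "subtree_lrt"
  out
}

#' @export
print.subtree_lrt <- function(x, ...) {
  if (!x$defined) {
    cat("<subtree_lrt> undefined (element entirely missing)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<subtree_lrt> %d columns; subtree {%s}\n  scales: rest %.4g, subtree %.4g; Lambda = %.4g, p = %.3g\n  %s (signed score %.3f)\n",
    x$n_columns, paste(x$subtree, collapse = ","), x$scale_rest,
    x$subtree_scale, x$lambda, x$p_value,
    if (isTRUE(x$accelerated)) "accelerated" else "conserved/neutral",
    x$score))
  invisible(x)
}

#' Tidy a subtree acceleration test
#'
#' @param x A [subtree_lrt()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy subtree_lrt
#' @export
tidy.subtree_lrt <- function(x, ...) {
  tibble(lnl_null = x$lnl_null, lnl_alt = x$lnl_alt,
         scale_all = x$scale_all, scale_rest = x$scale_rest,
         subtree_scale = x$subtree_scale, lambda = x$lambda,
         p_value = x$p_value, score = x$score, accelerated = x$accelerated,
         n_columns = x$n_columns, defined = x$defined)
}

#' @rdname tidy.subtree_lrt
#' @method glance subtree_lrt
#' @export
glance.subtree_lrt <- function(x, ...) tidy(x)

#' Base-by-base acceleration scores
#'
#' Applies [subtree_lrt()] to each alignment column; columns with no data
#' score 0. The result can be written as a fixed-step wiggle track with
#' [write_wig()].
#'
#' @inheritParams subtree_lrt
#' @return A tibble with columns `column`, `score`, `p_value`,
#'   `subtree_scale`, `scale_rest`.
#' @export
basewise_scores <- function(block, tree, model = phylo_model(), subtree,
                            ...) {
  purrr::map_dfr(seq_len(ncol(block)), function(j) {
    r <- subtree_lrt(block, tree, model, subtree, element = c(j, j), ...)
    tibble(column = j,
           score = if (r$defined) r$score else 0,
           p_value = r$p_value,
           subtree_scale = r$subtree_scale,
           scale_rest = r$scale_rest)
  })
}

#' Rank elements by lineage-specific acceleration
#'
#' Accelerated elements first, ordered by ascending signed score (most
#' negative = most accelerated); ties broken by element id.
#'
#' @param results Tibble with columns `element`, `score`, `accelerated`
#'   (e.g. `tidy()` rows from [subtree_lrt()] with an `element` column
#'   added).
#' @return The input with a `rank` column, sorted.
#' @export
rank_elements <- function(results) {
  if (any(is.na(results$score))) abort("all elements must have defined scores")
  out <- dplyr::arrange(results, dplyr::desc(.data$accelerated), .data$score,
                        .data$element)
  out$rank <- seq_len(nrow(out))
  out
}
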