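# Recombination breakpoint detection by tree-misfit partitioning: for every
# candidate split the alignment's two parts each get their own NJ tree, and
# the improvement of the two-tree least-squares fit over the single
# full-data tree is compared with a permutation null obtained by shuffling
# column order (which destroys positional structure but preserves the
# site-pattern composition).

codon_pdist <- function(aln, sites = NULL) {
  sites <- sites %||% seq_len(aln$n_sites)
  X <- aln$codon[sites, , drop = FALSE]
  n <- ncol(X)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      D[i, j] <- D[j, i] <- if (any(ok)) mean(X[ok, i] != X[ok, j]) else 0
    }
  }
  D
}

#' Scan a codon alignment for a recombination breakpoint
#'
#' For each candidate breakpoint `b` in `[margin, S - margin]`, NJ trees are
#' built for sites `1..b` and `b+1..S` and scored by the summed squared
#' misfit between each tree's tip-to-tip distances and its own partition's
#' p-distance matrix; the improvement over fitting the single full-data tree
#' to both partitions is the scan statistic. Significance comes from
#' `n_perm` random permutations of column order (empirical upper-tail
#' p-value of the best improvement). A breakpoint is reported only when
#' p < 0.05.
#'
#' @param aln a `codon_aln` with at least `2 * margin + 1` sites and 4 taxa.
#' @param margin closest allowed distance of a breakpoint to either end.
#' @param n_perm number of column-order permutations.
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return object of class `breakpoint_result`: `breakpoint` (codon index or
#'   NA), `improvement`, `p_value`, `partitions` (list of `list(sites,
#'   tree)`, two entries when a breakpoint is reported, one otherwise) and
#'   `scan` (tibble `candidate`, `improvement`).
#' @export
detect_breakpoints <- function(aln, margin = 20L, n_perm = 100L, seed = NULL) {
  S <- aln$n_sites
  N <- aln$n_taxa
  if (S < 2L * margin + 1L) stop("alignment too short for margin ", margin)
  if (N < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  X <- aln$codon
  pairs <- utils::combn(N, 2L)
  P <- ncol(pairs)
  diffs <- matrix(0L, S, P)
  valid <- matrix(0L, S, P)
  for (p in seq_len(P)) {
    xi <- X[, pairs[1, p]]; xj <- X[, pairs[2, p]]
    ok <- !is.na(xi) & !is.na(xj)
    valid[, p] <- as.integer(ok)
    diffs[ok, p] <- as.integer(xi[ok] != xj[ok])
  }
  candidates <- seq.int(margin, S - margin)
  orders <- rbind(seq_len(S),
                  t(vapply(seq_len(n_perm), function(i) sample.int(S),
                           integer(S))))
  res <- cpp_scan_breakpoints(diffs, valid, N, candidates, orders)
  best <- which.max(res$obs)
  obs_best <- res$obs[best]
  pval <- (1 + sum(res$perm_max >= obs_best)) / (n_perm + 1)
  bp <- if (pval < 0.05) candidates[best] else NA_integer_
  if (!is.na(bp)) {
    partitions <- list(
      list(sites = seq_len(bp),
           tree = nj_tree(codon_pdist(aln, seq_len(bp)))),
      list(sites = (bp + 1L):S,
           tree = nj_tree(codon_pdist(aln, (bp + 1L):S))))
  } else {
    partitions <- list(list(sites = seq_len(S),
                            tree = nj_tree(codon_pdist(aln))))
  }
  structure(list(breakpoint = bp, improvement = obs_best, p_value = pval,
                 partitions = partitions,
                 scan = tibble(candidate = candidates,
                               improvement = as.numeric(res$obs))),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat("<breakpoint_result> no breakpoint (p = ", signif(x$p_value, 3),
        ")\n", sep = "")
  } else {
    cat("<breakpoint_result> breakpoint at codon ", x$breakpoint,
        " (improvement ", signif(x$improvement, 4), ", p = ",
        signif(x$p_value, 3), ")\n", sep = "")
  }
  invisible(x)
}
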