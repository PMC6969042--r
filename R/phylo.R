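# Distance-based phylogenetics: Poisson-corrected protein distances,
# neighbor joining with deterministic tie-breaking and non-negative branch
# lengths, Felsenstein column bootstrap mapped onto the full-data tree, and
# outgroup-rooted monophyly tests.

#' Pairwise protein distances from a gapped alignment
#'
#' p-distance over shared non-gap columns per pair, Poisson-corrected as
#' `d = -ln(1 - p)`. Pairs with `p >= 0.95` are flagged saturated and set to
#' the largest finite corrected distance observed in the matrix.
#'
#' @param msa named character vector of equal-length gapped proteins (>= 3).
#' @param model `"poisson"` (corrected) or `"p"` (raw proportion).
#' @return symmetric distance matrix with a `saturated` attribute (logical
#'   matrix).
#' @export
protein_distance <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  n <- length(msa)
  if (n < 3L) stop("need at least 3 sequences")
  rows <- do.call(rbind, strsplit(toupper(msa), ""))
  isres <- matrix(rows %in% c(AA_ALPHABET, "X"), nrow = n)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- isres[i, ] & isres[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        stop("no shared non-gap columns between ", names(msa)[i], " and ",
             names(msa)[j])
      }
      p <- sum(rows[i, shared] != rows[j, shared]) / ns
      if (p >= 0.95) {
        sat[i, j] <- sat[j, i] <- TRUE
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        d <- if (model == "poisson") -log(1 - p) else p
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  if (any(sat)) {
    mx <- max(D[!is.na(D)])
    D[is.na(D)] <- mx
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q break
#' deterministically on the lexicographically smallest pair of cluster
#' representative labels; negative branch-length estimates are clamped to 0
#' with the deficit moved to the sibling branch.
#'
#' @param dm symmetric distance matrix with dimnames (>= 3 taxa).
#' @return unrooted [ape::phylo].
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L, !is.null(rownames(dm)))
  if (any(!is.finite(dm))) stop("non-finite distances")
  rank <- rank(rownames(dm), ties.method = "first") - 1L
  res <- cpp_nj(dm, as.integer(rank), rownames(dm), FALSE)
  ape::read.tree(text = res$newick)
}

#' Bootstrap support for the NJ tree of a protein alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and maps bipartition frequencies (percent) onto the full-data
#' tree's internal nodes.
#'
#' @param msa named character vector of gapped proteins (>= 4).
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @param model distance model, see [protein_distance()].
#' @return the full-data [ape::phylo] with `node.label` holding supports.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = NULL,
                              model = "poisson") {
  if (length(msa) < 4L) stop("need at least 4 taxa")
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  full <- nj_tree(protein_distance(msa, model))
  rows <- strsplit(toupper(msa), "")
  nc <- unique(lengths(rows))
  stopifnot(length(nc) == 1L)
  boot_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_msa <- vapply(rows, function(r) paste(r[cols], collapse = ""),
                      character(1))
    boot_trees[[b]] <- nj_tree(protein_distance(rep_msa, model))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(round(100 * counts / n_reps))
  full
}

#' Test monophyly of a taxon subset
#'
#' The tree is rooted on `outgroup` first (when given); the subset is
#' monophyletic iff it is exactly the leaf set of some node, whose support
#' label is returned.
#'
#' @param tree [ape::phylo], with `node.label` supports if available.
#' @param taxa_subset character vector of tip labels.
#' @param outgroup optional tip label (or vector) to root on.
#' @return list with `monophyletic` (logical) and `support` (numeric or NA).
#' @export
is_monophyletic <- function(tree, taxa_subset, outgroup = NULL) {
  unknown <- setdiff(taxa_subset, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  ntip <- length(tree$tip.label)
  tips <- match(taxa_subset, tree$tip.label)
  if (length(tips) == ntip) {
    root_node <- ntip + 1L
    supp <- if (!is.null(tree$node.label)) {
      suppressWarnings(as.numeric(tree$node.label[1]))
    } else NA_real_
    return(list(monophyletic = TRUE, support = supp))
  }
  if (length(tips) == 1L) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  mrca <- ape::getMRCA(tree, tips)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  mono <- setequal(clade_tips, taxa_subset)
  supp <- if (mono && !is.null(tree$node.label)) {
    suppressWarnings(as.numeric(tree$node.label[mrca - ntip]))
  } else NA_real_
  list(monophyletic = mono, support = supp)
}

#' Root-to-tip path lengths
#'
#' Reports each leaf's distance from the root (rooting on `outgroup` first
#' when given), the statistic used to flag fast-evolving, typically
#' pseudogene-rich, leaves.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param outgroup optional rooting tip(s).
#' @return tibble `taxon`, `root_to_tip`.
#' @export
root_to_tip <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  tibble(taxon = tree$tip.label, root_to_tip = depths[seq_len(ntip)])
}
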