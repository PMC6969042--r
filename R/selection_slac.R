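# SLAC: counting-based per-site selection. Ancestral codons come from Fitch
# parsimony (ties broken toward the lexicographically smallest codon);
# observed synonymous / nonsynonymous changes are summed over branches with
# multi-nucleotide codon changes averaged over all minimal mutational paths
# (stop-free paths preferred, equal weight). Each site's expected synonymous
# fraction comes from the average synonymous-site proportion of the codons
# observed at the site, and significance from a two-tailed extended binomial
# test that tolerates fractional counts.

# normalize the tree-per-partition argument shared by slac() and fel()
as_partitions <- function(aln, trees) {
  if (is.null(trees)) stop("a tree (or partition list) is required")
  if (inherits(trees, "breakpoint_result")) return(trees$partitions)
  if (inherits(trees, "phylo")) {
    return(list(list(sites = seq_len(aln$n_sites), tree = trees)))
  }
  stopifnot(is.list(trees))
  trees
}

check_partition_tree <- function(aln, part) {
  if (!setequal(part$tree$tip.label, aln$taxa)) {
    stop("tree leaves do not match alignment taxa")
  }
  part
}

# regularized-incomplete-beta extension of the binomial tails to real
# counts: P(X <= k) and P(X >= k) for k successes in n trials at success
# probability p. SLAC tests each direction with its own tail (too few
# synonymous changes = positive selection; too few nonsynonymous =
# negative), so the reported p is the tail matching the observed deviation.
ext_binom_tails <- function(k, n, p) {
  if (n <= 0) return(c(lower = 1, upper = 1))
  p <- min(max(p, 1e-12), 1 - 1e-12)
  lower <- if (k >= n) 1 else pbeta(1 - p, n - k, k + 1)
  upper <- if (k <= 0) 1 else pbeta(p, k, n - k + 1)
  c(lower = lower, upper = upper)
}

#' Per-site selection by the counting (SLAC) method
#'
#' @param aln a `codon_aln`.
#' @param tree_per_partition an [ape::phylo] (single partition), a
#'   `breakpoint_result` (its partitions and trees are used), or a list of
#'   `list(sites, tree)`.
#' @param alpha_level significance level for calls (the classical screen
#'   uses P < 0.1).
#' @param kappa transition/transversion ratio used for the expected
#'   synonymous site fractions; `NULL` (default) estimates it by fitting the
#'   single-omega MG94 model to the first partition, the counting method's
#'   usual model-fit first stage.
#' @return tibble of class `site_selection`: `site` (1-based alignment
#'   position), `partition`, `method`, `n_syn`, `n_nonsyn`, `e_syn`
#'   (expected synonymous fraction), `dn`, `ds`, `statistic` (normalized
#'   dN - dS), `p_value`, `call`.
#' @export
slac <- function(aln, tree_per_partition, alpha_level = 0.1, kappa = NULL) {
  parts <- as_partitions(aln, tree_per_partition)
  pc <- codon_path_counts()
  if (is.null(kappa)) {
    pt <- prep_tree(aln, parts[[1L]]$tree, parts[[1L]]$sites)
    kappa <- fit_mg94_global(pt$X, pt$edge, pt$blen)$kappa
  }
  sf <- codon_syn_fraction(kappa)
  out <- list()
  for (pi in seq_along(parts)) {
    part <- check_partition_tree(aln, parts[[pi]])
    # binary trees make Fitch counts exact and root-invariant; resolve any
    # multifurcation (e.g. the unrooted trifurcation) with zero-length edges
    tree <- ape::reorder.phylo(ape::multi2di(part$tree), "postorder")
    sites <- part$sites
    X <- aln$codon[sites, match(tree$tip.label, aln$taxa), drop = FALSE]
    S <- nrow(X)
    ntip <- length(tree$tip.label)
    nnode <- max(tree$edge)
    tlen <- sum(tree$edge.length)
    # Fitch bottom-up state sets, vectorized across sites
    sets <- vector("list", nnode)
    for (t in seq_len(ntip)) {
      m <- matrix(FALSE, S, 61)
      obs <- !is.na(X[, t])
      m[cbind(which(obs), X[obs, t])] <- TRUE
      m[!obs, ] <- TRUE  # missing tip: uninformative
      sets[[t]] <- m
    }
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (is.null(sets[[par]])) {
        sets[[par]] <- sets[[ch]]
      } else {
        inter <- sets[[par]] & sets[[ch]]
        ok <- rowSums(inter) > 0
        sets[[par]][ok, ] <- inter[ok, ]
        sets[[par]][!ok, ] <- sets[[par]][!ok, , drop = FALSE] |
          sets[[ch]][!ok, , drop = FALSE]
      }
    }
    root <- tree$edge[nrow(tree$edge), 1]
    state <- matrix(NA_integer_, S, nnode)
    state[, root] <- max.col(sets[[root]], "first")
    for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- state[, par]
      keep <- sets[[ch]][cbind(seq_len(S), ps)]
      state[, ch] <- ifelse(keep, ps, max.col(sets[[ch]], "first"))
    }
    ns <- numeric(S); nn <- numeric(S)
    for (e in seq_len(nrow(tree$edge))) {
      a <- state[, tree$edge[e, 1]]; b <- state[, tree$edge[e, 2]]
      ns <- ns + pc$syn[cbind(a, b)]
      nn <- nn + pc$nonsyn[cbind(a, b)]
    }
    es <- vapply(seq_len(S), function(s) {
      obs <- X[s, !is.na(X[s, ])]
      if (length(obs) == 0L) return(NA_real_)
      mean(sf[obs])
    }, numeric(1))
    ds <- ifelse(is.na(es) | es == 0, 0, ns / es) / max(tlen, 1e-12)
    dn <- ifelse(is.na(es) | es == 1, 0, nn / (1 - es)) / max(tlen, 1e-12)
    stat <- dn - ds
    pvals <- vapply(seq_len(S), function(s) {
      tot <- ns[s] + nn[s]
      if (is.na(es[s]) || tot == 0) return(1)
      tails <- ext_binom_tails(ns[s], tot, es[s])
      # tail matching the observed deviation: fewer synonymous changes than
      # expected indicates positive selection, fewer nonsynonymous negative
      if (stat[s] > 0) tails[["lower"]] else if (stat[s] < 0)
        tails[["upper"]] else 1
    }, numeric(1))
    call <- rep("neutral", S)
    call[stat > 0 & pvals < alpha_level] <- "positive"
    call[stat < 0 & pvals < alpha_level] <- "negative"
    call[ns + nn == 0] <- "neutral"
    out[[pi]] <- tibble(site = sites, partition = pi, method = "SLAC",
                        n_syn = ns, n_nonsyn = nn, e_syn = es, dn = dn,
                        ds = ds, statistic = stat, p_value = pvals,
                        call = call)
  }
  res <- bind_rows(out) %>% arrange(.data$site)
  attr(res, "alpha_level") <- alpha_level
  attr(res, "n_sites") <- aln$n_sites
  class(res) <- c("site_selection", class(res))
  res
}

#' Combine per-site selection results across methods
#'
#' Builds the tiered site report used for integrative tables: sites found by
#' every supplied method, by at least `k` methods, and by any method.
#' External methods' site lists (e.g. REL or MEME run elsewhere) can be
#' supplied as plain numeric site vectors.
#'
#' @param results_by_method named list; each element is a `site_selection`
#'   tibble (its `call == "positive"` sites are used) or a numeric vector of
#'   1-based site positions.
#' @param rule which tier defines the `selected` column of the per-site
#'   table: `"all"`, `"ge_k"` or `"any"`.
#' @param k method count for the `ge_k` tier.
#' @return list of class `site_integration`: `sites` (tibble `site`,
#'   `methods`, `n_methods`), `tiers` (list `all`, `ge_k`, `any`), `rule`.
#' @export
integrate_sites <- function(results_by_method, rule = c("all", "ge_k", "any"),
                            k = 2L) {
  rule <- match.arg(rule)
  if (length(results_by_method) == 0L) stop("no method results supplied")
  if (is.null(names(results_by_method))) {
    stop("results_by_method must be a named list")
  }
  ranges <- purrr::compact(lapply(results_by_method, attr, "n_sites"))
  if (length(unique(unlist(ranges))) > 1L) {
    stop("inconsistent site ranges across methods: ",
         paste(unlist(ranges), collapse = " vs "))
  }
  site_sets <- lapply(results_by_method, function(r) {
    if (is.data.frame(r)) sort(unique(r$site[r$call == "positive"]))
    else sort(unique(as.integer(r)))
  })
  all_sites <- sort(unique(unlist(site_sets)))
  n_m <- vapply(all_sites, function(s) {
    sum(vapply(site_sets, function(x) s %in% x, logical(1)))
  }, integer(1))
  meth <- vapply(all_sites, function(s) {
    paste(names(site_sets)[vapply(site_sets, function(x) s %in% x, logical(1))],
          collapse = ",")
  }, character(1))
  tiers <- list(
    all = all_sites[n_m == length(site_sets)],
    ge_k = all_sites[n_m >= k],
    any = all_sites
  )
  structure(list(
    sites = tibble(site = all_sites, methods = meth, n_methods = n_m,
                   selected = all_sites %in% tiers[[rule]]),
    tiers = tiers, rule = rule, k = k),
    class = "site_integration")
}

#' @export
print.site_integration <- function(x, ...) {
  cat("<site_integration> ", nrow(x$sites), " site(s); all-methods tier: {",
      paste(x$tiers$all, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
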