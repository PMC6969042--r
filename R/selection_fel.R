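# Fixed-effects likelihood (FEL) per-site selection and the global single-
# omega MG94 fit. The codon model is MG94 x HKY with equal codon
# frequencies; with uniform frequencies the rate matrix is symmetric and the
# pruning likelihood runs off one symmetric eigendecomposition per rate
# pair (see src/codon_lik.cpp). The global stage estimates kappa, a branch-
# length scale and a shared omega; the site stage fixes those and fits
# per-site synonymous (alpha) and nonsynonymous (beta) rates, testing
# beta = alpha with a 1-df chi-squared LRT.

aln_loglik <- function(X, edge, blen, kappa, alpha, beta) {
  pr <- codon_pairs()
  sum(cpp_mg94_site_loglik(X, edge, blen, kappa,
                           rep(alpha, length.out = nrow(X)),
                           rep(beta, length.out = nrow(X)),
                           pr, mg94_neutral_rate(kappa)))
}

site_logliks <- function(X, edge, blen, kappa, alpha, beta) {
  pr <- codon_pairs()
  cpp_mg94_site_loglik(X, edge, blen, kappa,
                       rep(alpha, length.out = nrow(X)),
                       rep(beta, length.out = nrow(X)),
                       pr, mg94_neutral_rate(kappa))
}

prep_tree <- function(aln, tree, sites = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total branch length")
  sites <- sites %||% seq_len(aln$n_sites)
  X <- aln$codon[sites, match(tree$tip.label, aln$taxa), drop = FALSE]
  list(X = X, edge = tree$edge, blen = tree$edge.length, tree = tree,
       sites = sites)
}

# maximize the single-omega model over (kappa, scale, omega)
fit_mg94_global <- function(X, edge, blen, init = c(2, 1, 1)) {
  nll <- function(p) {
    kappa <- exp(p[1]); s <- exp(p[2]); omega <- exp(p[3])
    -aln_loglik(X, edge, blen, kappa, s, s * omega)
  }
  fit <- optim(log(init), nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-8))
  list(kappa = exp(fit$par[1]), scale = exp(fit$par[2]),
       omega = exp(fit$par[3]), loglik = -fit$value,
       converged = fit$convergence == 0)
}

#' Global dN/dS with a profile-likelihood confidence interval
#'
#' Fits the single-omega MG94 model (kappa, branch-length scale, omega) to
#' the whole alignment and, optionally, profiles the likelihood over omega
#' for a 95% interval from the 1-df likelihood ratio. Omega is "significantly
#' different from 1" iff 1 falls outside that interval.
#'
#' @param aln a `codon_aln`.
#' @param tree [ape::phylo] whose tips match the alignment taxa.
#' @param ci compute the profile-likelihood interval (slower).
#' @return object of class `mg94_fit` with `omega`, `kappa`, `scale`,
#'   `loglik`, `ci` (length-2 or NULL), `sig_diff_from_1`.
#' @export
global_omega <- function(aln, tree, ci = TRUE) {
  pt <- prep_tree(aln, tree)
  if (ncol(pt$X) < 3L) stop("need at least 3 sequences")
  fit <- fit_mg94_global(pt$X, pt$edge, pt$blen)
  prof <- function(omega) {
    nll <- function(p) {
      -aln_loglik(pt$X, pt$edge, pt$blen, exp(p[1]), exp(p[2]),
                  exp(p[2]) * omega)
    }
    f <- optim(log(c(fit$kappa, fit$scale)), nll, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-7))
    -f$value
  }
  interval <- NULL
  if (ci) {
    crit <- stats::qchisq(0.95, df = 1) / 2
    drop_at <- function(w) fit$loglik - prof(w) - crit
    lo <- tryCatch({
      lower <- fit$omega / 2
      while (drop_at(lower) < 0 && lower > 1e-4) lower <- lower / 2
      if (drop_at(lower) < 0) 0 else
        uniroot(drop_at, c(lower, fit$omega), tol = 1e-3)$root
    }, error = function(e) NA_real_)
    hi <- tryCatch({
      upper <- fit$omega * 2
      while (drop_at(upper) < 0 && upper < 100) upper <- upper * 2
      if (drop_at(upper) < 0) Inf else
        uniroot(drop_at, c(fit$omega, upper), tol = 1e-3)$root
    }, error = function(e) NA_real_)
    interval <- c(lower = lo, upper = hi)
  }
  structure(list(omega = fit$omega, kappa = fit$kappa, scale = fit$scale,
                 loglik = fit$loglik, converged = fit$converged,
                 ci = interval,
                 sig_diff_from_1 = if (is.null(interval)) NA else
                   !is.na(interval[1]) && !is.na(interval[2]) &&
                   (1 < interval[1] || 1 > interval[2]),
                 n_sites = nrow(pt$X), n_taxa = ncol(pt$X)),
            class = "mg94_fit")
}

#' @export
print.mg94_fit <- function(x, ...) {
  cat("<mg94_fit> omega = ", signif(x$omega, 4), ", kappa = ",
      signif(x$kappa, 4), ", logLik = ", round(x$loglik, 2), "\n", sep = "")
  if (!is.null(x$ci)) {
    cat("  95% profile CI [", signif(x$ci[1], 4), ", ", signif(x$ci[2], 4),
        "]\n", sep = "")
  }
  invisible(x)
}

#' Per-site selection by fixed-effects likelihood (FEL)
#'
#' @inheritParams slac
#' @return tibble of class `site_selection`: `site`, `partition`, `method`,
#'   `alpha` and `beta` (per-site synonymous / nonsynonymous rates),
#'   `statistic` (beta - alpha), `lrt`, `p_value`, `call`, `converged`.
#' @export
fel <- function(aln, tree_per_partition, alpha_level = 0.1) {
  parts <- as_partitions(aln, tree_per_partition)
  out <- list()
  for (pi in seq_along(parts)) {
    part <- check_partition_tree(aln, parts[[pi]])
    pt <- prep_tree(aln, part$tree, part$sites)
    if (ncol(pt$X) < 3L) stop("need at least 3 sequences")
    glob <- fit_mg94_global(pt$X, pt$edge, pt$blen)
    S <- nrow(pt$X)
    rows <- vector("list", S)
    pr <- codon_pairs()
    c1 <- mg94_neutral_rate(glob$kappa)
    # Q(alpha, beta) = alpha * Q(1, beta/alpha): one eigendecomposition per
    # omega = beta/alpha, with alpha entering only as an eigenvalue scale
    get_eig <- function(omega) cpp_mg94_eig(glob$kappa, omega, pr, c1)
    e_null <- get_eig(1)
    for (s in seq_len(S)) {
      Xs <- pt$X[s, , drop = FALSE]
      nll_at <- function(eig, logalpha) {
        -cpp_site_loglik_eig(Xs, pt$edge, pt$blen, eig$U, eig$lam,
                             exp(logalpha))
      }
      null <- optimize(function(lr) nll_at(e_null, lr),
                       c(log(1e-7), log(100)), tol = 1e-5)
      prof_alpha <- function(logw) {
        eig <- get_eig(exp(logw))
        opt <- optimize(function(la) nll_at(eig, la),
                        c(log(1e-7), log(100)), tol = 1e-4)
        list(value = opt$objective, logalpha = opt$minimum)
      }
      outer <- optimize(function(lw) prof_alpha(lw)$value,
                        c(log(1e-6), log(200)), tol = 5e-3)
      inner <- prof_alpha(outer$minimum)
      conv <- is.finite(inner$value)
      lrt <- max(0, 2 * (null$objective - inner$value))
      pval <- if (!conv) 1 else pchisq(lrt, df = 1, lower.tail = FALSE)
      a <- exp(inner$logalpha); b <- a * exp(outer$minimum)
      call <- if (conv && b > a && pval < alpha_level) "positive"
        else if (conv && a > b && pval < alpha_level) "negative"
        else "neutral"
      rows[[s]] <- tibble(site = pt$sites[s], partition = pi, method = "FEL",
                          alpha = a, beta = b, statistic = b - a, lrt = lrt,
                          p_value = pval, call = call, converged = conv)
    }
    out[[pi]] <- bind_rows(rows)
  }
  res <- bind_rows(out) %>% arrange(.data$site)
  attr(res, "alpha_level") <- alpha_level
  attr(res, "n_sites") <- aln$n_sites
  attr(res, "global") <- NULL
  class(res) <- c("site_selection", class(res))
  res
}
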