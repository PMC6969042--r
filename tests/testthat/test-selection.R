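toy_tree <- ape::read.tree(text = "(a:0.3,b:0.25,c:0.2);")

codon_aln_from <- function(codon_strings) {
  # codon_strings: named character of equal-length in-frame CDS
  n <- nchar(codon_strings[1]) / 3
  mat <- vapply(codon_strings, function(s) {
    olfactoR:::codon_index(substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n)))
  }, integer(n))
  if (n == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(codon_strings)))
  olfactoR:::new_codon_aln(mat, names(codon_strings))
}

test_that("threading a protein MSA onto CDS round-trips", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 71)
  set.seed(72)
  prots <- vapply(1:4, function(i) {
    olfactoR:::mutate_protein(pg$template$seq, 0.1, integer())
  }, character(1))
  names(prots) <- paste0("g", 1:4)
  cds <- vapply(prots, function(p) {
    paste0(olfactoR:::back_translate(p), "TAA")
  }, character(1))
  aln <- thread_codon_alignment(prots, cds)  # ungapped case
  expect_equal(dim(aln), c(312L, 4L))
  expect_false(anyNA(aln$codon))
  expect_identical(unname(translate_codon_aln(aln)), unname(prots))
  # one gap becomes one codon gap at the same column
  gapped <- prots
  gapped[1] <- paste0("--", substr(prots[1], 3, 312))
  cds1 <- cds
  cds1[1] <- paste0(olfactoR:::back_translate(substr(prots[1], 3, 312)), "TAA")
  aln2 <- thread_codon_alignment(gapped, cds1)
  expect_true(all(is.na(aln2$codon[1:2, 1])))
  expect_false(anyNA(aln2$codon[, 2:4]))
  # mismatches are reported with the offending record
  bad <- cds
  bad["g2"] <- cds[["g3"]]
  expect_error(thread_codon_alignment(prots, bad), "g2")
})

test_that("codon alignment FASTA round-trips through gapped CDS", {
  tr <- sim_gene_tree(5, 0.2, seed = 73)
  aln <- simulate_codon_alignment(tr, rep(1, 30), seed = 74)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(codon_aln_strings(aln), f)
  back <- read_codon_aln(f)
  expect_identical(back$codon, aln$codon[, back$taxa])
})

test_that("SLAC is silent on identical sequences", {
  s <- paste(rep("ATGGCT", 10), collapse = "")
  aln <- codon_aln_from(c(a = s, b = s, c = s))
  res <- slac(aln, toy_tree, kappa = 2)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$call == "neutral"))
  expect_true(all(res$n_syn + res$n_nonsyn == 0))
})

test_that("SLAC counts match hand enumeration over minimal paths", {
  # site 1: single nonsynonymous change AAA(K)->GAA(E) on one branch
  # site 2: single synonymous change AAA(K)->AAG(K)
  # site 3: two-nt change AAA->AGG: both minimal paths give 1 syn + 1 nonsyn
  aln <- codon_aln_from(c(a = "AAAAAAAAA", b = "GAAAAGAGG", c = "AAAAAAAAA"))
  res <- slac(aln, toy_tree, kappa = 1)
  expect_equal(res$n_nonsyn, c(1, 0, 1))
  expect_equal(res$n_syn, c(0, 1, 1))
  # with kappa = 1 the expected synonymous fraction is the codon average of
  # the site's observed codons
  sf <- olfactoR:::codon_syn_fraction(1)
  idx <- olfactoR:::codon_index(c("AAA", "GAA", "AAA"))
  expect_equal(res$e_syn[1], mean(sf[idx]))
})

test_that("SLAC counts are invariant to taxon order and rerooting", {
  tr <- sim_gene_tree(8, 0.15, seed = 75)
  aln <- simulate_codon_alignment(tr, runif(25, 0, 2), seed = 76)
  base <- slac(aln, tr, kappa = 2)
  perm <- aln
  ord <- sample(aln$n_taxa)
  perm$codon <- aln$codon[, ord]
  perm$taxa <- aln$taxa[ord]
  res_perm <- slac(perm, tr, kappa = 2)
  expect_equal(base$n_syn + base$n_nonsyn, res_perm$n_syn + res_perm$n_nonsyn,
               tolerance = 1e-9)
  reroot <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  res_root <- slac(aln, reroot, kappa = 2)
  expect_equal(base$n_syn + base$n_nonsyn, res_root$n_syn + res_root$n_nonsyn,
               tolerance = 1e-9)
})

test_that("pruning likelihood equals exhaustive enumeration on toys", {
  skip_if_not_installed("Matrix")
  set.seed(77)
  trees <- list(
    ape::read.tree(text = "(a:0.2,b:0.35,c:0.1);"),
    ape::read.tree(text = "((a:0.15,b:0.2):0.1,c:0.3,d:0.25);"))
  for (tr in trees) {
    n <- length(tr$tip.label)
    mat <- matrix(sample.int(61L, 3L * n, replace = TRUE), nrow = 3)
    mat[2, 1] <- NA  # missing datum integrates out
    aln <- olfactoR:::new_codon_aln(mat, tr$tip.label)
    for (pars in list(c(2, 1), c(1.5, 0.3), c(3, 4))) {
      pt <- olfactoR:::prep_tree(aln, tr)
      got <- sum(olfactoR:::site_logliks(pt$X, pt$edge, pt$blen, pars[1],
                                         1, pars[2]))
      want <- brute_force_codon_loglik(aln, tr, pars[1], pars[2])
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the eigensystem fast path agrees with the generic likelihood", {
  tr <- sim_gene_tree(6, 0.2, seed = 78)
  aln <- simulate_codon_alignment(tr, rep(1, 10), seed = 79)
  pt <- olfactoR:::prep_tree(aln, tr)
  pr <- olfactoR:::codon_pairs()
  c1 <- olfactoR:::mg94_neutral_rate(1.7)
  for (w in c(0.2, 1, 3)) {
    eig <- olfactoR:::cpp_mg94_eig(1.7, w, pr, c1)
    for (a in c(0.5, 1, 2)) {
      fast <- olfactoR:::cpp_site_loglik_eig(pt$X, pt$edge, pt$blen, eig$U,
                                             eig$lam, rep(a, 10))
      slow <- olfactoR:::site_logliks(pt$X, pt$edge, pt$blen, 1.7, a, a * w)
      expect_equal(fast, slow, tolerance = 1e-8)
    }
  }
})

test_that("FEL is calibrated under purifying selection on a small alignment", {
  tr <- sim_gene_tree(6, 0.25, seed = 80)
  aln <- simulate_codon_alignment(tr, rep(0, 40), seed = 81)
  res <- fel(aln, tr, alpha_level = 0.1)
  expect_lte(mean(res$call == "positive"), 0.1)
  # beta estimates stay near zero when no nonsynonymous change can occur
  expect_lt(stats::median(res$beta), 0.05)
  expect_error(fel(aln, sim_gene_tree(5, 0.2, seed = 1)), "match")
})

test_that("degenerate selection inputs are rejected", {
  s <- paste(rep("ATGGCT", 5), collapse = "")
  two <- codon_aln_from(c(a = s, b = s))
  pair_tree <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expect_error(fel(two, pair_tree), "at least 3")
  aln <- codon_aln_from(c(a = s, b = s, c = s))
  zero_tree <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_error(global_omega(aln, zero_tree), "zero total branch length")
})

test_that("global omega recovers strong purifying selection", {
  tr <- sim_gene_tree(8, 0.2, seed = 82)
  aln <- simulate_codon_alignment(tr, rep(0.2, 150), kappa = 2, seed = 83)
  fit <- global_omega(aln, tr, ci = TRUE)
  expect_lt(fit$omega, 1)
  expect_true(fit$sig_diff_from_1)
  expect_lt(fit$ci[["upper"]], 1)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "omega"], fit$omega)
  expect_true(is.finite(glance(fit)$logLik))
})

test_that("site integration reproduces the published tier example", {
  out <- integrate_sites(list(SLAC = c(109, 274),
                              FEL = c(6, 109, 111, 114, 209, 219, 274)))
  expect_equal(out$tiers$all, c(109, 274))
  expect_equal(out$tiers$any, sort(unique(c(6, 109, 111, 114, 209, 219, 274))))
  one <- integrate_sites(list(SLAC = c(5, 9)))
  expect_equal(one$tiers$all, c(5, 9))
  expect_equal(one$tiers$any, c(5, 9))
  disjoint <- integrate_sites(list(m1 = 1:3, m2 = 7:9))
  expect_equal(length(disjoint$tiers$all), 0L)
  expect_error(integrate_sites(list()), "no method")
})
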