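test_that("protein distances match closed forms", {
  msa <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(c(rep("A", 90), rep("C", 10)), collapse = ""),
           c = paste(rep("A", 100), collapse = ""))
  D <- protein_distance(msa)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], -log(0.9), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(D)))
  expect_true(all(diag(D) == 0))
})

test_that("saturated pairs are flagged and capped", {
  msa <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(rep("C", 100), collapse = ""),
           c = paste(c(rep("A", 80), rep("D", 20)), collapse = ""))
  D <- protein_distance(msa)
  sat <- attr(D, "saturated")
  expect_true(sat["a", "b"])
  expect_equal(D["a", "b"], max(D[!sat]))
  # gaps shrink the shared-column denominator
  msag <- c(a = "AAAA--", b = "AA--CC", c = "AAAACC")
  Dg <- protein_distance(msag, model = "p")
  expect_equal(Dg["a", "b"], 0)
  expect_error(protein_distance(c(a = "A---", b = "-CCC", c = "ACCC")),
               "shared")
})

test_that("NJ recovers additive trees exactly", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(est, true), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(62)
  for (rep in 1:4) {
    n <- 10
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.05, 0.5)
    D <- ape::cophenetic.phylo(true) + matrix(runif(n * n, 0, 0.01), n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    expect_equal(ape::dist.topo(nj_tree(D), ape::nj(as.dist(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("3 taxa give the unique star with solvable branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(length(tr$tip.label), 3L)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["a", "b"], 3)
  expect_equal(cd["a", "c"], 4)
  expect_equal(cd["b", "c"], 5)
})

test_that("negative branch estimates are clamped to zero", {
  # a deliberately non-additive matrix that drives an NJ branch negative
  D <- matrix(c(0, 1, 5, 4,
                1, 0, 5, 4.2,
                5, 5, 0, 1,
                4, 4.2, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  Dna <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(Dna), "non-finite")
})

test_that("bootstrap supports are deterministic and bounded", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 63, n_families = 2)
  msa <- family_seed_msa(pg, n_per = 4, divergence = 0.1)
  t1 <- bootstrap_support(msa, n_reps = 20, seed = 7)
  t2 <- bootstrap_support(msa, n_reps = 20, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  supports <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(supports[!is.na(supports)] >= 0 &
                    supports[!is.na(supports)] <= 100))
  one <- bootstrap_support(msa, n_reps = 1, seed = 8)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("well-separated clusters earn high support and monophyly", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 64, n_families = 2,
                    family_divergence = 0.4)
  msa <- family_seed_msa(pg, n_per = 5, divergence = 0.05)
  set.seed(65)
  out <- olfactoR:::mutate_protein(pg$template$seq, 0.5, integer())
  msa <- c(msa, outg = out)
  tree <- bootstrap_support(msa, n_reps = 100, seed = 9)
  fam1 <- names(msa)[startsWith(names(msa), "f1_")]
  mono <- is_monophyletic(tree, fam1, outgroup = "outg")
  expect_true(mono$monophyletic)
  expect_gte(mono$support, 90)
  # a subset split across families is not monophyletic
  mixed <- c(fam1[1:2], names(msa)[startsWith(names(msa), "f2_")][1])
  expect_false(is_monophyletic(tree, mixed, outgroup = "outg")$monophyletic)
  # the full in-group is monophyletic once the outgroup roots the tree
  expect_true(is_monophyletic(tree, setdiff(names(msa), "outg"),
                              outgroup = "outg")$monophyletic)
  expect_error(is_monophyletic(tree, "no_such_taxon"), "unknown")
})

test_that("bipartition supports are invariant to input row order", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 66, n_families = 2)
  msa <- family_seed_msa(pg, n_per = 4, divergence = 0.1)
  t1 <- bootstrap_support(msa, n_reps = 25, seed = 11)
  set.seed(12)
  t2 <- bootstrap_support(msa[sample(length(msa))], n_reps = 25, seed = 11)
  labs1 <- setNames(t1$node.label, vapply(
    (length(t1$tip.label) + 1):max(t1$edge), function(nd) {
      paste(sort(ape::extract.clade(t1, nd)$tip.label), collapse = ",")
    }, character(1)))
  labs2 <- setNames(t2$node.label, vapply(
    (length(t2$tip.label) + 1):max(t2$edge), function(nd) {
      paste(sort(ape::extract.clade(t2, nd)$tip.label), collapse = ",")
    }, character(1)))
  shared <- intersect(names(labs1), names(labs2))
  expect_gt(length(shared), 0L)
  expect_equal(labs1[shared], labs2[shared])
})

test_that("root-to-tip lengths flag fast-evolving leaves", {
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:5):0.5,e:1.5);")
  r2t <- root_to_tip(tr)
  expect_equal(nrow(r2t), 5L)
  expect_equal(r2t$root_to_tip[r2t$taxon == "d"],
               max(r2t$root_to_tip))
})
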