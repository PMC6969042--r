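test_that("the template hosts its motifs once and is deterministic", {
  t1 <- make_or_template(seed = 1)
  t2 <- make_or_template(seed = 1)
  expect_identical(t1$seq, t2$seq)
  expect_equal(nchar(t1$seq), 312L)
  hits <- gregexpr("MAYDRYVAIC", t1$seq, fixed = TRUE)[[1]]
  expect_equal(length(hits), 1L)
  expect_equal(hits[1] - 1L,
               t1$motif_map$start[t1$motif_map$motif == "MAYDRYVAIC"])
  expect_error(make_or_template(seed = 1, length_aa = 90), "too short")
})

test_that("the template's hydropathy segmentation gives exactly 7 TMs", {
  tpl <- make_or_template(seed = 4)
  tm <- predict_tm_domains(tpl$seq)
  expect_equal(nrow(tm$segments), 7L)
})

test_that("planted truth matches construction for simple cases", {
  pg <- plant_genes(1, 0, 0, 0, 0, contig_len = 5000, divergence = 0.05,
                    seed = 7)
  expect_equal(nrow(pg$contigs), 1L)
  expect_equal(pg$truth$true_class, "intact")
  expect_equal(pg$truth$end - pg$truth$start, 939L)

  pg2 <- plant_genes(0, 6, 0, 0, 0, seed = 8)
  stops <- vapply(seq_len(6), function(i) {
    tr <- pg2$truth[i, ]
    g <- substr(pg2$contigs$seq[i], tr$start + 1, tr$end)
    if (tr$strand == "-") g <- revcomp(g)
    aa <- translate_dna(g)
    grepl("\\*.", aa)  # internal stop (premature) or shifted frame junk
  }, logical(1))
  prem <- grepl("premature_stop", pg2$truth$disruption)
  expect_true(any(prem))
  expect_true(all(stops[prem]))
})

test_that("same seed gives byte-identical synthetic genomes", {
  a <- plant_genes(2, 2, 2, 2, 2, seed = 13)
  b <- plant_genes(2, 2, 2, 2, 2, seed = 13)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth, b$truth)
})

test_that("planted genes respect the class invariants", {
  pg <- plant_genes(3, 3, 3, 5, 4, seed = 17)
  tr <- pg$truth
  expect_true(all(tr$disruption[tr$true_class == "intact"] == ""))
  trunc <- tr[tr$true_class == "truncated", ]
  lens <- nchar(pg$contigs$seq[match(trunc$contig_id, pg$contigs$id)])
  expect_true(all(trunc$start < 3L | trunc$end > lens - 3L))
  # decoys never contain the diagnostic motif
  dec <- tr[tr$true_class == "decoy", ]
  for (i in seq_len(nrow(dec))) {
    g <- substr(pg$contigs$seq[match(dec$contig_id[i], pg$contigs$id)],
                dec$start[i] + 1, dec$end[i])
    if (dec$strand[i] == "-") g <- revcomp(g)
    expect_false(grepl("MAYDRYVAIC", translate_dna(g), fixed = TRUE))
  }
  # intact genes pass the 75-aa filter with start and stop by construction
  orfs <- find_orfs(pg$contigs)
  for (cid in tr$contig_id[tr$true_class == "intact"]) {
    o <- orfs[orfs$contig_id == cid & orfs$has_start & orfs$has_stop &
                nchar(orfs$aa_seq) == 312, ]
    expect_equal(nrow(o), 1L)
  }
})

test_that("codon simulation respects omega = 0 and short branches", {
  tr <- ape::read.tree(text = "((a:2,b:2):1,(c:2,d:2):1);")
  aln <- simulate_codon_alignment(tr, rep(0, 30), kappa = 2, seed = 5)
  prot <- do.call(rbind, strsplit(unname(translate_codon_aln(aln)), ""))
  expect_true(all(apply(prot, 2, function(col) length(unique(col)) == 1L)))

  tiny <- ape::read.tree(text = "((a:1e-9,b:1e-9):1e-9,(c:1e-9,d:1e-9):1e-9);")
  aln2 <- simulate_codon_alignment(tiny, rep(1, 50), kappa = 2, seed = 6)
  str <- codon_aln_strings(aln2)
  expect_true(all(str == str[1]))
})

test_that("simulated alignments never contain stop codons and are seeded", {
  tr <- sim_gene_tree(8, 0.2, seed = 9)
  a <- simulate_codon_alignment(tr, runif(40, 0, 3), kappa = 2, seed = 10)
  expect_false(anyNA(a$codon))
  expect_false(any(grepl("\\*", translate_codon_aln(a))))
  set.seed(99)
  b <- simulate_codon_alignment(tr, attr(a, "truth")$site_omega, kappa = 2,
                                seed = 10)
  expect_identical(a$codon, b$codon)
  expect_error(simulate_codon_alignment(tr, c(-1, 1)), "nonnegative")
  expect_error(simulate_codon_alignment(tr, rep(1, 10), breakpoint = 20,
                                        tree2 = tr), "outside")
})

test_that("breakpoint simulation switches topology at the breakpoint", {
  t1 <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,(c:0.5,d:0.5):0.5);")
  t2 <- ape::read.tree(text = "((a:0.5,c:0.5):0.5,(b:0.5,d:0.5):0.5);")
  aln <- simulate_codon_alignment(t1, rep(1, 60), breakpoint = 30,
                                  tree2 = t2, seed = 11)
  expect_equal(aln$n_sites, 60L)
  expect_equal(aln$taxa, t1$tip.label)
})
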