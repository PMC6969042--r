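build_classified <- function(pg, seed = 20L) {
  msa <- family_seed_msa(pg)
  hmm <- build_profile_hmm(msa)
  orfs <- find_orfs(pg$contigs)
  hits <- search_orfs(hmm, orfs, seed = seed)
  classify_repertoire(orfs, hits, profile_len = hmm$L)
}

test_that("planted classes are recovered exactly on a mixed repertoire", {
  pg <- plant_genes(4, 4, 4, 5, 3, seed = 42)
  genes <- build_classified(pg)
  got <- table(factor(genes$integrity,
                      levels = c("intact", "partial", "pseudogene",
                                 "truncated")))
  expect_equal(unname(c(got)), c(4L, 4L, 4L, 5L))
  # intact genes carry no disruptions; pseudogenes carry recorded ones
  expect_true(all(genes$disruptions[genes$integrity == "intact"] == ""))
  expect_true(all(grepl("premature_stop|frameshift",
                        genes$disruptions[genes$integrity == "pseudogene"])))
  expect_true(all(genes$n_pieces[genes$integrity == "pseudogene"] >= 2L))
})

test_that("classification is invariant to contig reverse-complementation", {
  pg <- plant_genes(2, 2, 2, 2, 0, seed = 43)
  genes_a <- build_classified(pg)
  rc <- pg
  rc$contigs$seq <- revcomp(pg$contigs$seq)
  genes_b <- build_classified(rc)
  tab <- function(g) table(g$contig_id, g$integrity)
  expect_equal(tab(genes_a), tab(genes_b))
})

test_that("the four integrity classes are exhaustive and exclusive", {
  pg <- plant_genes(3, 3, 3, 3, 2, seed = 44)
  genes <- build_classified(pg)
  expect_true(all(genes$integrity %in%
                    c("intact", "partial", "pseudogene", "truncated")))
  expect_equal(anyDuplicated(unlist(strsplit(genes$orf_ids, ","))), 0L)
})

test_that("repertoire summary reproduces the printed-count arithmetic", {
  counts <- tibble::tibble(
    clade = "gamma-c", family = "f",
    integrity = c("intact", "pseudogene", "partial"),
    n = c(20L, 15L, 21L))
  genes <- repertoire_from_counts(counts)
  s <- summarize_repertoire(genes)
  expect_equal(sum(s$non_edge$n), 56L)
  expect_equal(s$non_edge$percent[s$non_edge$integrity == "intact"], 36)
  expect_equal(s$ratio_disrupted_intact, 1.8, tolerance = 1e-12)
})

test_that("summary handles empty input and clade maps", {
  s0 <- summarize_repertoire(tibble::tibble(family = character(),
                                            integrity = character()))
  expect_equal(s0$n_genes, 0L)
  genes <- tibble::tibble(family = c("a", "b", "zz"),
                          integrity = c("intact", "truncated", "partial"))
  s <- summarize_repertoire(genes, clade_map = c(a = "gamma-c", b = "gamma"))
  expect_setequal(s$clades$clade, c("gamma-c", "gamma", "unknown"))
  expect_equal(sum(s$clades$n), 3L)
})

test_that("per-scaffold locus distances match brute-force arithmetic", {
  set.seed(45)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    genes <- tibble::tibble(
      gene_id = paste0("g", seq_len(n)),
      contig_id = sample(c("c1", "c2", "c3"), n, replace = TRUE),
      start = sample.int(10000, n), strand = sample(c("+", "-"), n, TRUE),
      integrity = sample(c("intact", "pseudogene"), n, TRUE))
    genes$end <- genes$start + sample(300:900, n)
    rep_out <- suppressWarnings(loci_per_scaffold(genes))
    # oracle: sort per contig, difference adjacent intervals
    want <- list()
    for (ctg in unique(genes$contig_id)) {
      sub <- genes[genes$contig_id == ctg, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1L) {
        want[[ctg]] <- sub$start[-1] - sub$end[-nrow(sub)]
      }
    }
    got <- split(rep_out$distances$gap_bp, rep_out$distances$contig_id)
    expect_equal(got[order(names(got))],
                 want[order(names(want))], ignore_attr = TRUE)
    expect_equal(sum(rep_out$per_scaffold$n_loci), n)
  }
})

test_that("a 44-bp gap between two loci is reported as 44", {
  genes <- tibble::tibble(gene_id = c("a", "b"), contig_id = "c1",
                          start = c(100L, 1083L), end = c(1039L, 2022L),
                          strand = "+", integrity = c("pseudogene", "intact"))
  out <- loci_per_scaffold(genes)
  expect_equal(out$distances$gap_bp, 44L)
  expect_equal(out$distances$integrity_pair, "intact/pseudogene")
  one <- loci_per_scaffold(genes[1, ])
  expect_equal(nrow(one$distances), 0L)
})

test_that("the packaged census reproduces its printed totals", {
  census <- or_repertoire_census()
  expect_equal(sum(census$n_genes), 220L)
  expect_equal(sum(census$intact), 20L)
  expect_equal(sum(census$pseudogene), 15L)
  expect_equal(sum(census$intact[census$clade == "gamma-c"]), 17L)
  long <- census_counts(census)
  expect_equal(sum(long$n), 218L)  # two unplaced genes lack a breakdown
})
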