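test_that("match emissions follow the pseudocount formula and 50% gap rule", {
  msa <- c(a = "ACDE", b = "ACDE")
  hmm <- build_profile_hmm(msa, pseudocount_weight = 0)
  expect_equal(hmm$L, 4L)
  expect_equal(unname(hmm$match_emis[1, "A"]), 1)
  expect_equal(sum(hmm$match_emis[1, ] > 0), 1L)  # indicator rows

  msa2 <- c(a = "A-DE", b = "-CDE", c = "--DE", d = "A-DE")
  hmm2 <- build_profile_hmm(msa2)
  # column 2 is 3/4 gaps: excluded; column 1 is half gaps: excluded too
  expect_equal(hmm2$match_cols, c(3L, 4L))
  expect_error(build_profile_hmm(c(a = "--", b = "--")), "match columns")
  expect_error(build_profile_hmm(c(a = "AC", b = "ACD")), "ragged")
  expect_error(build_profile_hmm(c(a = "AC")), "at least 2")
})

test_that("emission and transition rows are normalized probabilities", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 3)
  msa <- family_seed_msa(pg, n_per = 3)
  hmm <- build_profile_hmm(msa)
  expect_true(all(abs(rowSums(hmm$match_emis) - 1) < 1e-9))
  for (src in c("M", "I", "D")) {
    p <- 2^hmm$trans[, paste0(src, c("M", "I", "D"))]
    expect_true(all(abs(rowSums(p, na.rm = TRUE) - 1) < 1e-9))
  }
})

test_that("Viterbi equals brute-force path enumeration on toy HMMs", {
  set.seed(41)
  for (rep in 1:4) {
    L <- sample(2:4, 1)
    seed_seqs <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "D", "E", "F", "G"), L, replace = TRUE),
            collapse = "")
    }, character(1))
    hmm <- build_profile_hmm(setNames(seed_seqs, paste0("s", 1:3)),
                             pseudocount_weight = 1)
    for (n in c(2, 4, 6)) {
      seq <- paste(sample(c("A", "C", "D", "E", "F", "G", "K"), n,
                          replace = TRUE), collapse = "")
      dp <- olfactoR:::hmm_score(hmm, c(x = seq))
      brute <- brute_force_viterbi(hmm, seq)
      expect_equal(dp, brute, tolerance = 1e-9)
    }
  }
})

test_that("the profile separates true sequences from shuffles", {
  tpl <- make_or_template(seed = 6)
  msa <- make_seed_msa(tpl, n = 20, divergence = 0.05, seed = 7)
  hmm <- build_profile_hmm(msa)
  true_score <- olfactoR:::hmm_score(hmm, c(t = tpl$seq))
  set.seed(8)
  shuffles <- vapply(1:200, function(i) {
    paste(sample(strsplit(tpl$seq, "")[[1]]), collapse = "")
  }, character(1))
  expect_true(true_score > max(olfactoR:::hmm_score(hmm, shuffles)))
})

test_that("search_orfs self-detects its seed sequences at E <= 1e-10", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 9)
  msa <- family_seed_msa(pg)
  hmm <- build_profile_hmm(msa)
  hits <- search_orfs(hmm, msa, e_cutoff = 1e-10, seed = 10)
  expect_setequal(hits$orf_id, names(msa))
  expect_true(all(hits$e_value <= 1e-10))
})

test_that("raising the E-value cutoff never removes a hit", {
  pg <- plant_genes(2, 0, 1, 0, 2, seed = 12)
  msa <- family_seed_msa(pg)
  hmm <- build_profile_hmm(msa)
  orfs <- find_orfs(pg$contigs)
  strict <- search_orfs(hmm, orfs, e_cutoff = 1e-10, seed = 13)
  loose <- search_orfs(hmm, orfs, e_cutoff = 1e-2, seed = 13)
  expect_true(all(strict$orf_id %in% loose$orf_id))
  # and E-values are monotone decreasing in bit score
  expect_true(all(diff(loose$e_value[order(loose$bit_score)]) <= 0))
})

test_that("search_orfs rejects an empty ORF set", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 14)
  hmm <- build_profile_hmm(family_seed_msa(pg))
  expect_error(search_orfs(hmm, character(0)), "empty")
})

test_that("align_to_hmm reproduces seed columns and keeps contracts", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 15)
  msa <- family_seed_msa(pg)
  hmm <- build_profile_hmm(msa)
  aligned <- align_to_hmm(hmm, msa)
  # ungapped seeds: every seed column is a match column, rows reproduce
  expect_identical(unname(aligned), unname(msa))
  expect_equal(length(aligned), length(msa))
  expect_true(all(nchar(aligned) == hmm$L))
  two <- align_to_hmm(hmm, c(a = msa[[1]], b = msa[[1]]))
  expect_identical(two[["a"]], two[["b"]])
})
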