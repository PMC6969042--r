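test_that("assign_family recovers exact and below-threshold cases", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 3)
  panel <- pg$families
  res <- assign_family(c(q = panel$seq[2]), panel)
  expect_equal(res$family, panel$family[2])
  expect_equal(res$identity, 1)
  set.seed(4)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 300,
                       replace = TRUE), collapse = "")
  expect_equal(assign_family(c(q = junk), panel)$family, "unknown")
  expect_error(assign_family(c(q = junk), panel[0, ]), "empty")
})

test_that("family assignment is >= 95% correct on diverged synthetic genes", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 5, n_families = 2,
                    family_divergence = 0.35)
  set.seed(6)
  queries <- character(40)
  truth <- integer(40)
  for (i in 1:40) {
    truth[i] <- sample(2, 1)
    queries[i] <- olfactoR:::mutate_protein(pg$families$seq[truth[i]], 0.1,
                                            pg$template$protected)
  }
  names(queries) <- paste0("q", 1:40)
  res <- assign_family(queries, pg$families)
  expect_gte(mean(res$family == pg$families$family[truth]), 0.95)
})

test_that("scan_motifs finds canonical motifs with mismatch tolerance", {
  tpl <- make_or_template(seed = 7)
  hits <- scan_motifs(tpl$seq)
  mm <- tpl$motif_map
  expect_equal(as.integer(hits$start[hits$motif == "MAYDRYVAIC"]),
               mm$start[mm$motif == "MAYDRYVAIC"])
  expect_equal(as.integer(hits$start[hits$motif == "FSTC(LP)H"]),
               mm$start[mm$motif == "FSTCxH"])
  expect_true(all(hits$found))

  poly <- paste(rep("A", 100), collapse = "")
  none <- scan_motifs(poly)
  expect_false(any(none$found))

  one_off <- paste0("GGGG", "MAYDRYVAIW", "GGGG")
  h <- scan_motifs(one_off)
  expect_true(h$found[h$motif == "MAYDRYVAIC"])
  expect_equal(h$mismatches[h$motif == "MAYDRYVAIC"], 1L)
  expect_equal(as.integer(h$start[h$motif == "MAYDRYVAIC"]), 4L)
  # the bracketed position must be L or P even with the mismatch budget
  expect_false(scan_motifs("AAAFSTCAHAAA")$found[2])
  expect_true(scan_motifs("AAAFSTCPHAAA")$found[2])
})

test_that("conservation profile matches closed-form columns", {
  msa <- c(a = "AAC", b = "ACD", c = "AFE", d = "AWG")
  prof <- conservation_profile(msa)
  expect_equal(prof$info[1], log2(20))
  expect_true(all(abs(rowSums(prof$freq, na.rm = TRUE) - 1) < 1e-9 |
                    is.na(prof$info)))
  # a uniform 20-way column has zero information
  msa20 <- setNames(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    paste0("s", 1:20))
  prof20 <- conservation_profile(msa20)
  expect_equal(prof20$info[1], 0)
  # all-gap columns are flagged as NA
  msag <- c(a = "A-C", b = "A-D")
  expect_true(is.na(conservation_profile(msag)$info[2]))
})

test_that("motif columns are more conserved than the background", {
  pg <- plant_genes(0, 0, 0, 0, 0, seed = 8)
  msa <- family_seed_msa(pg, n_per = 6, divergence = 0.15)
  prof <- conservation_profile(msa)
  protected <- pg$template$protected
  expect_gt(mean(prof$info[protected]), mean(prof$info[-protected]))
})

test_that("TM prediction labels domains with an extracellular N-terminus", {
  tpl <- make_or_template(seed = 9)
  tm <- predict_tm_domains(tpl$seq)
  expect_equal(nrow(tm$segments), 7L)
  dom <- tm$domains
  loop_after <- function(k) {
    dom$domain[which(dom$domain == paste0("TM", k)) + 1L]
  }
  expect_equal(loop_after(1), "IC1")
  expect_equal(loop_after(2), "EC1")
  expect_equal(loop_after(3), "IC2")
  expect_equal(loop_after(5), "IC3")
  expect_equal(loop_after(7), "C")
  # ligand-pocket landmark positions fall in TM3 and TM7
  seg <- tm$segments
  expect_true(seg$start[3] <= 109 && 109 <= seg$end[3])
  expect_true(seg$start[7] <= 274 && 274 <= seg$end[7])
})

test_that("TM prediction degenerate inputs behave", {
  poly_ser <- paste(rep("S", 60), collapse = "")
  expect_equal(nrow(predict_tm_domains(poly_ser)$segments), 0L)
  expect_error(predict_tm_domains("SSS"), "window")
})
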