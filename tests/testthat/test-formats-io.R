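test_that("read_fasta parses records and enforces invariants", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first seq", "ACGT", ">b", "NNACGT"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$seq, c("ACGT", "NNACGT"))
  expect_equal(recs$description[1], "first seq")

  writeLines(c(">a", "ACGT", ">a", "GGTT"), f)
  expect_error(read_fasta(f), "duplicate")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("FASTA round-trip is the identity on random record sets", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(1:8, 1)
    recs <- tibble::tibble(
      id = paste0("s", seq_len(n)),
      description = ifelse(runif(n) < 0.5, "", paste("desc", seq_len(n))),
      seq = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T", "N"), sample(5:300, 1),
                     replace = TRUE), collapse = "")
      }, character(1)))
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(recs, f, width = sample(c(10, 60, 1000), 1))
    back <- read_fasta(f)
    expect_equal(back$id, recs$id)
    expect_equal(back$seq, recs$seq)
    expect_equal(back$description, recs$description)
  }
})

test_that("write_gff3 converts to 1-based inclusive coordinates", {
  genes <- tibble::tibble(gene_id = "g1", contig_id = "c1", start = 0L,
                          end = 939L, strand = "+", family = "fam01",
                          integrity = "intact", disruptions = "")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  cols <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(cols[4:5]), c(1L, 939L))
  expect_match(cols[9], "integrity=intact")
})

test_that("write_gff3 handles empty input and bounds violations", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tibble::tibble(gene_id = character(), contig_id = character(),
                            start = integer(), end = integer(),
                            strand = character(), family = character(),
                            integrity = character()), f)
  expect_equal(readLines(f), "##gff-version 3")
  genes <- tibble::tibble(gene_id = "g1", contig_id = "c1", start = 10L,
                          end = 999L, strand = "+", family = "x",
                          integrity = "intact")
  expect_error(write_gff3(genes, f, contig_lengths = c(c1 = 500L)),
               "outside contig bounds")
})

test_that("written GFF3 is readable by an independent parser", {
  skip_if_not_installed("rtracklayer")
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:3), contig_id = c("c1", "c1", "c2"),
    start = c(0L, 1000L, 5L), end = c(939L, 1500L, 600L),
    strand = c("+", "-", "+"), family = c("a", "b", "a"),
    integrity = c("intact", "partial", "pseudogene"),
    disruptions = c("", "missing_start", "premature_stop@42"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), 3L)
  expect_equal(BiocGenerics::start(gr), genes$start + 1L)
  expect_equal(BiocGenerics::end(gr), genes$end)
  expect_equal(gr$integrity, genes$integrity)
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):0.5,c:1.5);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(ape::cophenetic.phylo(tr2)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)

  writeLines("((a:1,b:1)92:0.1,c:1.5,d:0.2);", f)
  tr3 <- read_newick(f)
  expect_true("92" %in% tr3$node.label)
  write_newick(tr3, f)
  expect_true("92" %in% read_newick(f)$node.label)

  set.seed(3)
  big <- ape::rtree(20)
  write_newick(big, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(big), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(back)[big$tip.label, big$tip.label],
               ape::cophenetic.phylo(big)[big$tip.label, big$tip.label],
               tolerance = 1e-9)
})

test_that("malformed Newick is rejected", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1:0.5,c:1.5;", f)
  expect_error(read_newick(f))
})
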