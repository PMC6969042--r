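# Planted-genome generator: contigs carrying OR genes of known class
# (intact, pseudogene, partial, contig-edge truncated) plus non-OR decoys,
# with a truth table recording exactly what was planted. This is the ground
# truth against which the ORF scanner, the HMM search and the integrity
# classifier are validated.

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# e sense codons followed by an in-frame TAA: used to guarantee that reading
# stretches planted without their own stop terminate shortly downstream
sense_codon_run <- function(e) {
  if (e <= 0L) return("TAA")
  paste0(paste(sample(sense_codons(), e, replace = TRUE), collapse = ""), "TAA")
}

# The ORF scanner reports a CDS from the first ATG of a reading stretch when
# one exists. A planted stretch is only recoverable at the 75-aa filter if
# that convention leaves a long-enough CDS; this checks a piece of protein
# sequence for it (no M at all is fine: the CDS then starts at the stretch).
stretch_recoverable <- function(piece, min_cds = 80L) {
  m <- regexpr("M", piece, fixed = TRUE)[1]
  m < 0L || (nchar(piece) - m + 1L) >= min_cds
}

#' Plant OR genes and decoys in synthetic contigs
#'
#' Generates one contig per planted element. Every OR gene is a
#' back-translated family template with i.i.d. amino-acid divergence outside
#' the motif positions; class-specific disruptions are then applied:
#' pseudogenes get one premature stop codon or a 1-2 nt frameshifting indel,
#' partial genes lose their start and/or stop but stay internal to the
#' contig, truncated genes are cut by the contig edge, and decoys are
#' length- and composition-matched random-codon ORFs carrying no OR motifs.
#' An in-frame stop is always planted immediately upstream of a gene (and a
#' few codons downstream of stop-less partials) so the planted reading
#' stretch has well-defined boundaries; disruption positions are resampled
#' until every planted piece yields a reportable (>= 75 aa) CDS under the
#' first-ATG convention of [find_orfs()]. Each element lands on a random
#' strand.
#'
#' @param n_intact,n_pseudo,n_partial,n_truncated,n_decoys class counts.
#' @param contig_len contig length in bp; must leave >= 1 kb flanks around
#'   internal genes.
#' @param divergence per-site amino-acid substitution probability relative to
#'   the family template.
#' @param seed integer seed (the whole output is byte-identical per seed).
#' @param n_families,family_divergence passed to [make_family_templates()].
#' @param length_aa template length, see [make_or_template()].
#' @return list with `contigs` (tibble `id`, `seq`), `truth` (tibble
#'   `gene_id`, `contig_id`, `start`, `end`, `strand`, `true_class`,
#'   `family`, `disruption`; 0-based half-open intervals), `template`
#'   (the base `or_template`) and `families` (the family template panel).
#' @export
plant_genes <- function(n_intact, n_pseudo, n_partial, n_truncated, n_decoys,
                        contig_len = 4000L, divergence = 0.05, seed = 1L,
                        n_families = 3L, family_divergence = 0.35,
                        length_aa = 312L) {
  set.seed(seed)
  L <- as.integer(length_aa)
  template <- make_or_template(seed = NULL, length_aa = L)
  fams <- make_family_templates(template, n_families, family_divergence)
  gene_nt <- 3L * L + 3L
  if (contig_len < gene_nt + 2L * 1000L + 10L) {
    stop("infeasible packing: contig_len ", contig_len,
         " cannot host a ", gene_nt, " nt gene with 1 kb flanks")
  }
  kmax <- L - 97L  # latest codon a disruption may hit with both pieces >= 75 aa
  if (kmax < 90L) stop("infeasible packing: length_aa too short for disruptions")
  classes <- rep(c("intact", "pseudogene", "partial", "truncated", "decoy"),
                 c(n_intact, n_pseudo, n_partial, n_truncated, n_decoys))
  template_codons <- strsplit(back_translate(template$seq), "(?<=...)",
                              perl = TRUE)[[1]]
  rows <- vector("list", length(classes))
  contigs <- vector("list", length(classes))
  for (g in seq_along(classes)) {
    cls <- classes[g]
    contig_id <- sprintf("ctg%04d", g)
    gene_id <- sprintf("gene%04d", g)
    fam <- fams[sample.int(nrow(fams), 1L), ]
    disruption <- ""
    protein <- NULL
    if (cls == "decoy") {
      repeat {
        body <- paste(sample(template_codons[-c(1L, L)], L - 2L, replace = TRUE),
                      collapse = "")
        cds <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
        hits <- scan_motifs(translate_dna(cds))
        if (!hits$found[hits$motif == "MAYDRYVAIC"]) break
      }
      fam$family <- "none"
    } else {
      protein <- mutate_protein(fam$seq, divergence, template$protected)
      cds <- paste0(back_translate(protein), sample(c("TAA", "TAG", "TGA"), 1L))
    }
    append_stop <- FALSE  # plant a downstream in-frame stop run after the gene?
    if (cls == "pseudogene") {
      if (runif(1) < 0.5) {
        repeat {
          k <- sample(90:kmax, 1L)
          if (stretch_recoverable(substr(protein, k + 1L, L))) break
        }
        substr(cds, 3L * k - 2L, 3L * k) <- "TAA"
        disruption <- paste0("premature_stop@", k)
      } else {
        repeat {
          j0 <- sample(90:kmax, 1L)
          if (stretch_recoverable(substr(protein, j0 + 1L, L))) break
        }
        nd <- sample(1:2, 1L)
        cds <- paste0(substr(cds, 1L, 3L * j0),
                      substr(cds, 3L * j0 + nd + 1L, nchar(cds)))
        disruption <- paste0("frameshift@", 3L * j0)
        append_stop <- TRUE  # frame-shifted tail needs a terminating context
      }
    } else if (cls == "partial") {
      kind <- sample(c("missing_start", "missing_stop", "missing_both"), 1L)
      repeat {
        d5 <- sample(60:100, 1L)
        d3 <- sample(60:100, 1L)
        piece <- switch(kind,
          missing_start = substr(protein, d5 + 1L, L),
          missing_stop = protein,
          missing_both = substr(protein, d5 + 1L, L - d3 - 1L))
        if (stretch_recoverable(piece)) break
      }
      if (kind %in% c("missing_start", "missing_both")) {
        cds <- substr(cds, 3L * d5 + 1L, nchar(cds))
      }
      if (kind %in% c("missing_stop", "missing_both")) {
        cds <- substr(cds, 1L, nchar(cds) - 3L * d3 - 3L)
        append_stop <- TRUE
      }
      disruption <- sub("missing_both", "missing_start;missing_stop", kind)
    }
    if (cls == "truncated") {
      repeat {
        keep <- sample(85:230, 1L)  # codons kept, >= the 75-aa reporting filter
        side <- sample(c("left", "right"), 1L)
        if (side == "right" ||
            stretch_recoverable(substr(protein, L - keep + 2L, L))) break
      }
      flank <- paste0(random_dna(contig_len - 3L * keep - 3L), "TAA")
      if (side == "right") {
        # 5' part of the gene runs off the right contig edge
        seq <- paste0(flank, substr(cds, 1L, 3L * keep))
        start <- nchar(flank)
        end <- nchar(seq)
      } else {
        # 3' part of the gene (with its stop) abuts the left contig edge
        part <- substr(cds, nchar(cds) - 3L * keep + 1L, nchar(cds))
        seq <- paste0(part, random_dna(contig_len - nchar(part)))
        start <- 0L
        end <- nchar(part)
      }
      disruption <- "edge_cut"
    } else {
      tail_ctx <- if (append_stop) sense_codon_run(sample(5:15, 1L)) else ""
      planted <- paste0("TAA", cds, tail_ctx)
      room <- contig_len - nchar(planted)
      left <- sample(1000:(room - 1000L), 1L)
      seq <- paste0(random_dna(left), planted, random_dna(room - left))
      start <- left + 3L
      end <- start + nchar(cds)
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      seq <- revcomp(seq)
      tmp <- start
      start <- nchar(seq) - end
      end <- nchar(seq) - tmp
    }
    contigs[[g]] <- tibble(id = contig_id, seq = seq)
    rows[[g]] <- tibble(gene_id = gene_id, contig_id = contig_id,
                        start = start, end = end, strand = strand,
                        true_class = cls, family = fam$family,
                        disruption = disruption)
  }
  list(contigs = bind_rows(contigs), truth = bind_rows(rows),
       template = template, families = fams)
}
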