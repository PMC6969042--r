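# End-to-end orchestration: ORF discovery -> profile-HMM annotation ->
# integrity classification -> profile alignment of intact genes ->
# conservation / motif / TM profiling -> NJ tree with bootstrap ->
# recombination-aware per-site selection. One global seed fans out to
# per-stage seeds by fixed offsets, so reruns are byte-identical.

#' Build a pipeline configuration
#'
#' @param contigs path to a contig FASTA, or a tibble with `id`/`seq`.
#' @param seed_msa seed alignment(s) for the search profile: a named
#'   character vector (one MSA), a list of them (e.g. full-length and
#'   partial-gene profiles; hits are unioned), or path(s) to gapped FASTA.
#' @param panel family reference panel: tibble `family`/`seq`, named
#'   character vector, or FASTA path whose record ids are family labels.
#' @param clade_map named character vector family -> clade (optional).
#' @param outdir output directory (created); `NULL` skips file output.
#' @param min_aa,evalue,alpha,identity thresholds: minimum ORF length,
#'   HMM E-value cutoff, selection significance level, family-assignment
#'   identity floor.
#' @param gard scan for a recombination breakpoint before selection.
#' @param methods selection methods to run (subset of `"slac"`, `"fel"`).
#' @param bootstrap bootstrap replicates for the tree stage.
#' @param seed global seed.
#' @return list of class `or_pipeline_config`.
#' @export
or_pipeline_config <- function(contigs, seed_msa, panel, clade_map = NULL,
                               outdir = NULL, min_aa = 75L, evalue = 1e-10,
                               alpha = 0.1, identity = 0.4, gard = TRUE,
                               methods = c("slac", "fel"), bootstrap = 100L,
                               seed = 1L) {
  stopifnot(min_aa > 0, evalue > 0, alpha > 0, identity > 0, bootstrap >= 1)
  structure(list(contigs = contigs, seed_msa = seed_msa, panel = panel,
                 clade_map = clade_map, outdir = outdir, min_aa = min_aa,
                 evalue = evalue, alpha = alpha, identity = identity,
                 gard = gard, methods = methods, bootstrap = bootstrap,
                 seed = seed),
            class = "or_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' File-path fields (`contigs`, `seed_msa`, `panel`) are validated to exist.
#'
#' @param path YAML file with fields matching [or_pipeline_config()].
#' @return list of class `or_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("contigs", "seed_msa", "panel")) {
    if (is.character(y[[f]]) && !all(file.exists(y[[f]]))) {
      stop("configured ", f, " path does not exist: ", y[[f]])
    }
  }
  do.call(or_pipeline_config, y)
}

load_seqs <- function(x, alphabet) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    recs <- read_fasta(x, alphabet)
    return(setNames(recs$seq, recs$id))
  }
  if (is.data.frame(x)) return(setNames(x$seq, x$id))
  x
}

#' Run the OR repertoire pipeline
#'
#' Stages: six-frame ORF discovery with the `min_aa` filter; profile-HMM
#' search of every ORF at the configured E-value cutoff (several seed
#' profiles are unioned); integrity classification with frameshift /
#' premature-stop merging; family assignment of each locus; repertoire and
#' per-scaffold summaries; profile alignment of the intact genes only,
#' followed by conservation, motif and transmembrane profiling; NJ tree
#' with column bootstrap; and, on the intact-gene codon alignment,
#' breakpoint-aware SLAC/FEL selection with a global dN/dS fit. Selection is
#' restricted to intact genes: pseudogenes and fragments would violate the
#' coding model.
#'
#' @param config an `or_pipeline_config`.
#' @return list of class `or_pipeline_report` with per-stage results
#'   (`orfs`, `hits`, `genes`, `summary`, `loci`, `msa`, `conservation`,
#'   `motifs`, `tm`, `tree`, `root_to_tip`, `selection`, `log`).
#' @export
run_or_pipeline <- function(config) {
  stopifnot(inherits(config, "or_pipeline_config"))
  stage_seed <- function(k) (config$seed + 1000L * k) %% .Machine$integer.max
  log <- list()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log[[length(log) + 1L]] <<- msg
  }
  contigs <- config$contigs
  if (is.character(contigs) && length(contigs) == 1L) {
    contigs <- read_fasta(contigs, "dna")
  }
  if (!is.data.frame(contigs)) {
    contigs <- tibble(id = names(contigs), seq = unname(contigs))
  }
  note("stage orfs: ", nrow(contigs), " contig(s)")
  orfs <- find_orfs(contigs, min_aa = config$min_aa)
  note("stage orfs: ", nrow(orfs), " ORF(s) >= ", config$min_aa, " aa")

  seed_msas <- config$seed_msa
  if (is.character(seed_msas) && all(file.exists(seed_msas))) {
    seed_msas <- lapply(seed_msas, function(p) {
      recs <- read_fasta(p, "protein")
      setNames(recs$seq, recs$id)
    })
  }
  if (!is.list(seed_msas)) seed_msas <- list(seed_msas)
  hmms <- lapply(seed_msas, build_profile_hmm)
  hit_sets <- lapply(seq_along(hmms), function(i) {
    search_orfs(hmms[[i]], orfs, e_cutoff = config$evalue,
                seed = stage_seed(1L) + i)
  })
  hits <- bind_rows(hit_sets) %>%
    group_by(.data$orf_id) %>%
    dplyr::slice_max(.data$bit_score, n = 1L, with_ties = FALSE) %>%
    ungroup()
  note("stage annotate: ", nrow(hits), " OR-positive ORF(s) at E <= ",
       format(config$evalue))
  profile_len <- max(vapply(hmms, `[[`, integer(1), "L"))

  genes <- classify_repertoire(orfs, hits, profile_len = profile_len)
  panel <- config$panel
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    recs <- read_fasta(panel, "protein")
    panel <- tibble(family = recs$id, seq = recs$seq)
  }
  if (is.character(panel)) panel <- tibble(family = names(panel), seq = unname(panel))
  if (nrow(genes) > 0L) {
    fam <- assign_family(setNames(genes$aa_seq, genes$gene_id), panel,
                         min_identity = config$identity)
    genes <- genes %>% left_join(fam %>% select(gene_id = "query", "family",
                                                "identity"),
                                 by = "gene_id")
  } else {
    genes$family <- character()
    genes$identity <- numeric()
  }
  note("stage classify: ", nrow(genes), " locus/loci")
  summary <- summarize_repertoire(genes, config$clade_map)
  loci <- loci_per_scaffold(genes)

  intact <- genes %>% filter(.data$integrity == "intact")
  msa <- NULL; conservation <- NULL; motifs <- NULL; tm <- NULL
  tree <- NULL; r2t <- NULL; selection <- NULL
  if (nrow(intact) >= 2L) {
    msa <- align_to_hmm(hmms[[1L]], setNames(intact$aa_seq, intact$gene_id))
    conservation <- conservation_profile(msa)
    motifs <- bind_rows(lapply(seq_len(nrow(intact)), function(i) {
      scan_motifs(intact$aa_seq[i]) %>% mutate(gene_id = intact$gene_id[i])
    }))
    tm <- predict_tm_domains(intact$aa_seq[1L])
  } else {
    note("stage align: fewer than 2 intact genes; alignment stages skipped")
  }
  if (nrow(intact) >= 4L) {
    tree <- bootstrap_support(msa, n_reps = config$bootstrap,
                              seed = stage_seed(2L))
    r2t <- root_to_tip(tree)
    note("stage tree: ", config$bootstrap, " bootstrap replicate(s)")
    # selection on intact genes only
    cds <- orf_cds_for_genes(orfs, intact)
    aln <- thread_codon_alignment(msa, cds)
    bp <- NULL
    parts <- aln_tree_partition(aln)
    if (isTRUE(config$gard) && aln$n_sites >= 41L) {
      bp <- detect_breakpoints(aln, seed = stage_seed(3L))
      if (!is.na(bp$breakpoint)) {
        note("stage selection: breakpoint at codon ", bp$breakpoint,
             " (p = ", signif(bp$p_value, 3), ")")
        parts <- bp$partitions
      } else {
        note("stage selection: no significant breakpoint")
      }
    }
    sel <- list(breakpoint = bp)
    if ("slac" %in% config$methods) {
      sel$slac <- slac(aln, parts, alpha_level = config$alpha)
    }
    if ("fel" %in% config$methods) {
      sel$fel <- fel(aln, parts, alpha_level = config$alpha)
    }
    sel$global <- global_omega(aln, parts[[1L]]$tree, ci = FALSE)
    present <- purrr::compact(sel[intersect(c("slac", "fel"), names(sel))])
    if (length(present) > 0L) {
      sel$integration <- integrate_sites(present, rule = "all")
    }
    selection <- sel
    note("stage selection: methods ", paste(config$methods, collapse = ","))
  } else {
    note("stage selection: fewer than 4 intact genes; skipped")
  }

  report <- structure(list(
    orfs = orfs, hits = hits, genes = genes, summary = summary, loci = loci,
    msa = msa, conservation = conservation, motifs = motifs, tm = tm,
    tree = tree, root_to_tip = r2t, selection = selection,
    config = config, log = unlist(log)),
    class = "or_pipeline_report")
  if (!is.null(config$outdir)) write_pipeline_outputs(report, config$outdir)
  report
}

# recover each intact gene's CDS (stop stripped) from its ORF record
orf_cds_for_genes <- function(orfs, genes) {
  cds <- vapply(seq_len(nrow(genes)), function(i) {
    o <- orfs[orfs$orf_id == strsplit(genes$orf_ids[i], ",")[[1]][1], ]
    nt <- o$nt_seq[1]
    if (o$has_stop[1]) nt <- substr(nt, 1L, nchar(nt) - 3L)
    nt
  }, character(1))
  setNames(cds, genes$gene_id)
}

aln_tree_partition <- function(aln) {
  list(list(sites = seq_len(aln$n_sites),
            tree = nj_tree(codon_pdist(aln))))
}

write_pipeline_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(report$orfs, p("orfs.tsv"))
  readr::write_tsv(report$hits, p("hits.tsv"))
  readr::write_tsv(report$genes, p("genes.tsv"))
  write_gff3(report$genes, p("genes.gff3"))
  readr::write_tsv(report$summary$by_family, p("repertoire_by_family.tsv"))
  readr::write_tsv(report$loci$per_scaffold, p("loci_per_scaffold.tsv"))
  if (nrow(report$loci$distances) > 0L) {
    readr::write_tsv(report$loci$distances, p("locus_distances.tsv"))
  }
  if (!is.null(report$msa)) {
    write_fasta(report$msa, p("intact_alignment.faa"))
    freq <- as_tibble(report$conservation$freq)
    freq$column <- seq_len(nrow(freq))
    freq$information <- report$conservation$info
    readr::write_tsv(freq, p("conservation_profile.tsv"))
    readr::write_tsv(report$motifs, p("motifs.tsv"))
  }
  if (!is.null(report$tree)) {
    write_newick(report$tree, p("intact_nj_bootstrap.nwk"))
    readr::write_tsv(report$root_to_tip, p("root_to_tip.tsv"))
  }
  if (!is.null(report$selection)) {
    for (m in intersect(c("slac", "fel"), names(report$selection))) {
      readr::write_tsv(report$selection[[m]], p(paste0("selection_", m, ".tsv")))
    }
    if (!is.null(report$selection$integration)) {
      readr::write_tsv(report$selection$integration$sites,
                       p("selection_integration.tsv"))
    }
  }
  writeLines(report$log, p("pipeline.log"))
  invisible(outdir)
}

#' @export
print.or_pipeline_report <- function(x, ...) {
  cat("<or_pipeline_report>\n")
  cat("  ", nrow(x$orfs), " ORFs, ", nrow(x$hits), " OR-positive, ",
      nrow(x$genes), " loci\n", sep = "")
  print(x$summary)
  invisible(x)
}
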