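# Integrity classification of OR-positive loci, with the precedence used
# for fragmented-assembly repertoires: (1) truncated when the reading
# stretch is cut by a contig edge; (2) pseudogene when a premature in-frame
# stop or an inferred frameshift interrupts an otherwise full-span homology
# envelope (two same-strand hits to the profile whose envelopes tile it,
# within 100 nt; same frame = premature stop, different frame = frameshift;
# partners merge into one record); (3) intact when start and stop are
# present and the CDS length is within 10% of the profile length;
# (4) partial otherwise.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# order loci along the strand-oriented reading direction
strand_order <- function(start, end, strand) {
  ifelse(strand == "+", start, -end)
}

#' Classify OR-positive ORFs into integrity classes
#'
#' Applies the truncated / pseudogene / intact / partial rules to every ORF
#' with a qualifying profile hit, merging frameshift and premature-stop
#' partners (same contig and strand, envelopes tiling the profile, within
#' `merge_window` nt along the reading direction) into single pseudogene
#' records.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param hits hit tibble from [search_orfs()]; only ORFs present here are
#'   classified.
#' @param profile_len profile length in match states (the expected intact
#'   CDS length in amino acids).
#' @param merge_window maximum nt gap between frameshift partners (hits to
#'   the same profile in different frames).
#' @param stop_merge_window maximum nt gap between same-frame premature-stop
#'   partners, whose pairing is driven by envelope complementarity.
#' @param length_tol intact CDS length tolerance as a fraction of
#'   `profile_len`.
#' @param min_tile_cover minimum fraction of the profile that partner
#'   envelopes must jointly cover to call a disruption.
#' @return tibble of genes: `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `integrity`, `disruptions`, `aa_seq` (longest piece), `orf_ids`,
#'   `n_pieces`, `bit_score` (best piece), `hmm_from`, `hmm_to` (merged
#'   envelope span).
#' @export
classify_repertoire <- function(orfs, hits, profile_len,
                                merge_window = 100L, stop_merge_window = 600L,
                                length_tol = 0.1, min_tile_cover = 0.8) {
  keep <- orfs %>% filter(.data$orf_id %in% hits$orf_id)
  if (nrow(keep) == 0L) {
    return(tibble(gene_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  integrity = character(), disruptions = character(),
                  aa_seq = character(), orf_ids = character(),
                  n_pieces = integer(), bit_score = numeric(),
                  hmm_from = integer(), hmm_to = integer()))
  }
  keep <- keep %>%
    left_join(hits %>% select("orf_id", "bit_score", "hmm_from", "hmm_to"),
              by = "orf_id") %>%
    mutate(.ord = strand_order(.data$start, .data$end, .data$strand)) %>%
    arrange(.data$contig_id, .data$strand, .data$.ord)
  groups <- split(keep, paste(keep$contig_id, keep$strand))
  genes <- list()
  for (grp in groups) {
    used <- rep(FALSE, nrow(grp))
    i <- 1L
    while (i <= nrow(grp)) {
      members <- i
      # chain merge: extend with the next ORF while the pair looks like
      # disruption partners tiling the profile
      while (TRUE) {
        j <- max(members) + 1L
        if (j > nrow(grp)) break
        a <- grp[max(members), ]; b <- grp[j, ]
        # proximity is judged between reading stretches (the CDS may start
        # well inside its stretch when the first ATG is late)
        gap <- if ("stretch_start" %in% names(grp)) {
          if (a$strand == "+") b$stretch_start - a$stretch_end
          else a$stretch_start - b$stretch_end
        } else {
          if (a$strand == "+") b$start - a$end else a$start - b$end
        }
        hi <- max(grp$hmm_to[members])
        # partners must jointly reconstruct one full-length locus, either by
        # complementary profile envelopes or - because TM-helix composition
        # makes fragment envelopes self-similar - by complementary lengths:
        # the pieces plus the skipped stretch between them add up to about
        # one profile length
        env_ok <- b$hmm_from >= hi - 30L && b$hmm_to > hi
        span_aa <- (max(grp$end[c(members, j)]) -
                      min(grp$start[c(members, j)])) / 3
        len_ok <- span_aa >= 0.7 * profile_len && span_aa <= 1.25 * profile_len
        # same-frame partners (premature stop) are bounded by complementarity,
        # not the frameshift proximity window: the reported downstream CDS
        # may start well after the interrupting stop codon
        win <- if (a$frame == b$frame) stop_merge_window else merge_window
        if (gap <= win && (env_ok || len_ok)) {
          members <- c(members, j)
        } else break
      }
      piece <- grp[members, ]
      merged_cover <- (max(piece$hmm_to) - min(piece$hmm_from) + 1L) / profile_len
      merged_span <- (max(piece$end) - min(piece$start)) / 3 / profile_len
      if (length(members) > 1L &&
          (merged_cover >= min_tile_cover || merged_span >= min_tile_cover)) {
        # disruption partners: one pseudogene record
        disr <- character()
        for (k in seq_len(length(members) - 1L)) {
          a <- piece[k, ]; b <- piece[k + 1L, ]
          if (a$frame == b$frame) {
            disr <- c(disr, paste0("premature_stop@", nchar(a$aa_seq) + 1L))
          } else {
            off <- if (a$strand == "+") a$end - piece$start[1] else
              piece$end[1] - a$start
            disr <- c(disr, paste0("frameshift@", off))
          }
        }
        longest <- which.max(nchar(piece$aa_seq))
        genes[[length(genes) + 1L]] <- tibble(
          contig_id = piece$contig_id[1], start = min(piece$start),
          end = max(piece$end), strand = piece$strand[1],
          integrity = if (any(piece$edge5) || any(piece$edge3)) "truncated"
                      else "pseudogene",
          disruptions = paste(disr, collapse = ";"),
          aa_seq = piece$aa_seq[longest],
          orf_ids = paste(piece$orf_id, collapse = ","),
          n_pieces = length(members),
          bit_score = max(piece$bit_score),
          hmm_from = min(piece$hmm_from), hmm_to = max(piece$hmm_to))
      } else {
        for (k in seq_along(members)) {
          o <- piece[k, ]
          cls <- if (o$edge5 || o$edge3) {
            "truncated"
          } else if (o$has_start && o$has_stop &&
                     nchar(o$aa_seq) >= (1 - length_tol) * profile_len &&
                     nchar(o$aa_seq) <= (1 + length_tol) * profile_len) {
            "intact"
          } else {
            "partial"
          }
          disr <- if (cls == "truncated") "edge_cut"
            else if (cls == "partial") {
              paste(c(if (!o$has_start) "missing_start",
                      if (!o$has_stop) "missing_stop",
                      if (o$has_start && o$has_stop) "incomplete_span"),
                    collapse = ";")
            } else ""
          genes[[length(genes) + 1L]] <- tibble(
            contig_id = o$contig_id, start = o$start, end = o$end,
            strand = o$strand, integrity = cls, disruptions = disr,
            aa_seq = o$aa_seq, orf_ids = o$orf_id, n_pieces = 1L,
            bit_score = o$bit_score, hmm_from = o$hmm_from,
            hmm_to = o$hmm_to)
        }
      }
      i <- max(members) + 1L
    }
  }
  out <- bind_rows(genes) %>% arrange(.data$contig_id, .data$start)
  out %>% mutate(gene_id = sprintf("ORgene%04d", seq_len(nrow(out))),
                 .before = 1L)
}

#' Summarize an OR repertoire
#'
#' Deterministic counts by family and integrity class plus the headline
#' repertoire statistics: totals per integrity class, clade totals, the
#' non-edge (intact + partial + pseudogene) breakdown with round-half-up
#' percentages, and the (pseudogene + partial) : intact ratio.
#'
#' @param genes tibble with at least `family` and `integrity` columns (e.g.
#'   [classify_repertoire()] output joined with family assignments); an
#'   optional `clade` column is used directly, otherwise `clade_map` is
#'   applied to `family`.
#' @param clade_map named character vector mapping family to clade; families
#'   not covered map to `"unknown"`.
#' @return list of class `repertoire_summary`: `by_family` (family x
#'   integrity counts), `totals` (per integrity), `clades` (per clade),
#'   `non_edge` (counts and round-half-up percentages among non-truncated
#'   genes), `ratio_disrupted_intact`, `n_genes`.
#' @export
summarize_repertoire <- function(genes, clade_map = NULL) {
  classes <- c("intact", "partial", "pseudogene", "truncated")
  if (nrow(genes) == 0L) {
    return(structure(list(
      by_family = tibble(family = character(), clade = character(),
                         integrity = character(), n = integer()),
      totals = setNames(rep(0L, 4), classes),
      clades = tibble(clade = character(), n = integer()),
      non_edge = tibble(integrity = classes[1:3], n = 0L, percent = NA_real_),
      ratio_disrupted_intact = NA_real_, n_genes = 0L),
      class = "repertoire_summary"))
  }
  if (!"clade" %in% names(genes)) {
    cl <- if (is.null(clade_map)) rep("unknown", nrow(genes)) else
      unname(clade_map[genes$family])
    cl[is.na(cl)] <- "unknown"
    genes$clade <- cl
  }
  if (!"family" %in% names(genes)) genes$family <- "unknown"
  by_family <- genes %>%
    dplyr::count(.data$clade, .data$family, .data$integrity, name = "n") %>%
    arrange(.data$clade, .data$family, .data$integrity)
  totals <- vapply(classes, function(k) sum(genes$integrity == k), integer(1))
  clades <- genes %>% dplyr::count(.data$clade, name = "n")
  ne <- genes %>% filter(.data$integrity != "truncated")
  ne_counts <- vapply(classes[1:3], function(k) sum(ne$integrity == k), integer(1))
  ne_tot <- sum(ne_counts)
  non_edge <- tibble(
    integrity = classes[1:3], n = unname(ne_counts),
    percent = if (ne_tot > 0) round_half_up(100 * unname(ne_counts) / ne_tot)
              else NA_real_)
  ratio <- if (totals["intact"] > 0) {
    (totals["pseudogene"] + totals["partial"]) / totals["intact"]
  } else NA_real_
  structure(list(by_family = by_family, totals = totals, clades = clades,
                 non_edge = non_edge,
                 ratio_disrupted_intact = unname(ratio),
                 n_genes = nrow(genes)),
            class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("<repertoire_summary> ", x$n_genes, " genes: ",
      paste(names(x$totals), x$totals, collapse = ", "), "\n", sep = "")
  if (!is.na(x$ratio_disrupted_intact)) {
    cat("  (pseudogene+partial):intact = ",
        round(x$ratio_disrupted_intact, 2), "\n", sep = "")
  }
  invisible(x)
}

#' Expand a family-count census into one row per gene
#'
#' Turns a Table-style census (one row per family x integrity with a count
#' column) into the per-gene tibble [summarize_repertoire()] expects.
#'
#' @param counts tibble with `clade`, `family`, `integrity`, `n`.
#' @return tibble with one row per gene.
#' @export
repertoire_from_counts <- function(counts) {
  counts[rep(seq_len(nrow(counts)), counts$n),
         setdiff(names(counts), "n")] %>% as_tibble()
}

#' Per-scaffold locus report
#'
#' Counts OR loci per scaffold and, for multi-locus scaffolds, reports each
#' adjacent pair's end-to-start gap in bp together with the integrity classes
#' involved. Same-strand overlapping loci are flagged, not fatal.
#'
#' @param genes tibble with `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `integrity`.
#' @return list with `per_scaffold` (tibble `contig_id`, `n_loci`) and
#'   `distances` (tibble `contig_id`, `gene_a`, `gene_b`, `gap_bp`,
#'   `integrity_pair`, `overlapping`).
#' @export
loci_per_scaffold <- function(genes) {
  per <- genes %>% dplyr::count(.data$contig_id, name = "n_loci")
  multi <- genes %>%
    group_by(.data$contig_id) %>%
    filter(n() > 1L) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    ungroup()
  dist_rows <- list()
  for (ctg in unique(multi$contig_id)) {
    sub <- multi %>% filter(.data$contig_id == ctg)
    for (k in seq_len(nrow(sub) - 1L)) {
      a <- sub[k, ]; b <- sub[k + 1L, ]
      gap <- b$start - a$end
      over <- gap < 0L && a$strand == b$strand
      if (over) {
        warning("overlapping same-strand loci on ", ctg, ": ",
                a$gene_id, " / ", b$gene_id)
      }
      dist_rows[[length(dist_rows) + 1L]] <- tibble(
        contig_id = ctg, gene_a = a$gene_id, gene_b = b$gene_id,
        gap_bp = gap,
        integrity_pair = paste(sort(c(a$integrity, b$integrity)), collapse = "/"),
        overlapping = over)
    }
  }
  distances <- bind_rows(dist_rows)
  if (nrow(distances) == 0L) {
    distances <- tibble(contig_id = character(), gene_a = character(),
                        gene_b = character(), gap_bp = integer(),
                        integrity_pair = character(), overlapping = logical())
  }
  list(per_scaffold = per, distances = distances)
}

#' Packaged OR repertoire census
#'
#' A family-by-integrity census of 220 olfactory receptor genes mined from a
#' fragmented procellariiform seabird assembly, as packaged example data:
#' one row per subfamily with its clade, total gene count and integrity
#' breakdown (the breakdown of two unplaced genes in the `unknown` family
#' was not resolved, so integrity columns sum to 218).
#'
#' @param path TSV path; defaults to the packaged census.
#' @return tibble with columns `clade`, `family`, `n_genes`, `intact`,
#'   `partial`, `pseudogene`, `truncated`.
#' @export
or_repertoire_census <- function(path = system.file("extdata",
                                                    "or_repertoire_census.tsv",
                                                    package = "olfactoR")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Long (one row per family x integrity) form of a census table
#' @param census wide census tibble, see [or_repertoire_census()].
#' @return tibble `clade`, `family`, `integrity`, `n`.
#' @export
census_counts <- function(census = or_repertoire_census()) {
  census %>%
    tidyr::pivot_longer(c("intact", "partial", "pseudogene", "truncated"),
                        names_to = "integrity", values_to = "n") %>%
    filter(.data$n > 0) %>%
    select("clade", "family", "integrity", "n")
}
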