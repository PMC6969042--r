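# Six-frame ORF enumeration with the getorf-like maximal stop-to-stop
# convention. A reading stretch is a maximal run of sense codons in one frame;
# the reported CDS starts at the stretch's first ATG when one exists and at
# the stretch start otherwise, so start-less partial genes remain
# discoverable. Codons containing N translate to X and never terminate a
# stretch.

#' Find open reading frames in assembly contigs
#'
#' Scans all six frames of each contig for maximal stop-free reading
#' stretches and reports those whose translated CDS is at least `min_aa`
#' amino acids long. Coordinates are 0-based half-open on the forward strand;
#' `frame` is the 0/1/2 offset on the reported strand. `edge5`/`edge3` flag
#' stretches cut by a contig boundary (no in-frame stop context on that side),
#' the operational definition of a contig-edge truncated locus.
#'
#' @param contigs a tibble with `id` and `seq` columns (as from
#'   [read_fasta()]) or a named character vector of DNA sequences.
#' @param min_aa minimum translated CDS length to report; the classical
#'   repertoire-mining filter discards ORFs shorter than 75 amino acids.
#' @return tibble with one row per ORF: `orf_id`, `contig_id`, `start`,
#'   `end`, `strand`, `frame`, `nt_seq`, `aa_seq`, `has_start`, `has_stop`,
#'   `edge5`, `edge3`, plus `stretch_start`/`stretch_end` giving the bounds
#'   of the full reading stretch the CDS was reported from. `nt_seq`
#'   includes the terminal stop codon when `has_stop`; `aa_seq` never
#'   includes the stop.
#' @export
find_orfs <- function(contigs, min_aa = 75L) {
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs), seq = unname(contigs))
  }
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  bad <- grepl("[^ACGTNacgtn]", contigs$seq)
  if (any(bad)) {
    stop("non-DNA characters in contig(s): ",
         paste(contigs$id[bad], collapse = ", "))
  }
  out <- purrr::map2(contigs$id, toupper(contigs$seq), scan_contig_orfs,
                     min_aa = as.integer(min_aa))
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(orf_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  frame = integer(), nt_seq = character(), aa_seq = character(),
                  has_start = logical(), has_stop = logical(),
                  edge5 = logical(), edge3 = logical(),
                  stretch_start = integer(), stretch_end = integer())
  }
  res
}

scan_contig_orfs <- function(contig_id, seq, min_aa) {
  lc <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (lc - f) %/% 3L
      if (ncod < 1L) next
      aa <- strsplit(translate_dna(substr(s, f + 1L, f + 3L * ncod)), "")[[1]]
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops - 1L, ncod)
      for (k in seq_along(seg_start)) {
        a <- seg_start[k]; b <- seg_end[k]
        if (a > b) next
        has_stop <- k < length(seg_start)  # segment bounded by a stop on the right
        edge5 <- k == 1L
        edge3 <- !has_stop
        atg <- a - 1L + match("M", aa[a:b])
        has_start <- !is.na(atg)
        cds_a <- if (has_start) atg else a
        aa_len <- b - cds_a + 1L
        if (aa_len < min_aa) next
        nt_a <- f + 3L * (cds_a - 1L) + 1L
        nt_b <- f + 3L * (b + as.integer(has_stop))
        nt_sa <- f + 3L * (a - 1L) + 1L  # full reading stretch, for context
        if (strand == "+") {
          start0 <- nt_a - 1L; end0 <- nt_b
          sstart0 <- nt_sa - 1L; send0 <- nt_b
        } else {
          start0 <- lc - nt_b; end0 <- lc - nt_a + 1L
          sstart0 <- lc - nt_b; send0 <- lc - nt_sa + 1L
        }
        rows[[length(rows) + 1L]] <- tibble(
          orf_id = paste0(contig_id, ":", start0, "-", end0, "(", strand, ")"),
          contig_id = contig_id, start = start0, end = end0,
          strand = strand, frame = f,
          nt_seq = substr(s, nt_a, nt_b),
          aa_seq = paste(aa[cds_a:b], collapse = ""),
          has_start = has_start, has_stop = has_stop,
          edge5 = edge5, edge3 = edge3,
          stretch_start = sstart0, stretch_end = send0
        )
      }
    }
  }
  bind_rows(rows)
}
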