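# Synthetic OR gene templates. A template is a 312-aa (by default) class-A
# GPCR-like protein with seven strongly hydrophobic stretches separated by
# hydrophilic loops, carrying the canonical OR motifs at fixed, recorded
# positions: MAYDRYVAIC at the TM3-IC2 boundary, FSTC(L|P)H at the end of
# IC3, one conserved cysteine in each of EC1 and EC2, and a conserved proline
# in TM7. Divergence applied by the genome generator never touches these
# motif positions, so they stay detectable, mirroring their conservation in
# real repertoires.

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# canonical domain layout for a 312-aa template, 1-based inclusive bounds
or_template_layout <- function(length_aa) {
  base <- tibble(
    domain = c("N", "TM1", "IC1", "TM2", "EC1", "TM3", "IC2", "TM4", "EC2",
               "TM5", "IC3", "TM6", "EC3", "TM7", "C"),
    start = c(1, 26, 49, 59, 82, 97, 120, 140, 163, 197, 220, 236, 259, 271, 294),
    end   = c(25, 48, 58, 81, 96, 119, 139, 162, 196, 219, 235, 258, 270, 293, 312)
  )
  if (length_aa == 312L) return(base)
  sc <- length_aa / 312
  ends <- round(base$end * sc)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- base
  out$start <- starts
  out$end <- ends
  tm <- grepl("^TM", out$domain)
  if (any(out$end - out$start + 1L < ifelse(tm, 19L, 1L)) || ends[15] != length_aa) {
    stop("length_aa = ", length_aa,
         " is too short to host seven >=19-residue transmembrane stretches ",
         "and the canonical motifs")
  }
  out
}

#' Generate a synthetic olfactory-receptor template protein
#'
#' @param seed integer seed; `NULL` uses the ambient RNG state.
#' @param length_aa template length in amino acids (default 312, the length of
#'   a full single-exon avian OR); lengths that cannot host the seven
#'   transmembrane stretches plus motifs raise an error.
#' @return an object of class `or_template`: a list with `seq` (protein
#'   string), `motif_map` (tibble of motif names with 0-based `start` and
#'   exclusive `end`), `regions` (domain layout, 1-based inclusive) and
#'   `protected` (1-based motif positions never mutated by the generators).
#' @export
make_or_template <- function(seed = NULL, length_aa = 312L) {
  stopifnot(length_aa >= 60L)
  if (!is.null(seed)) set.seed(seed)
  regions <- or_template_layout(as.integer(length_aa))
  L <- regions$end[nrow(regions)]
  tm_pool <- c("I", "V", "L", "F", "A", "M")
  tm_w <- c(3, 3, 3, 2, 1, 1)
  loop_pool <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "P", "H", "Y")
  aa <- character(L)
  for (r in seq_len(nrow(regions))) {
    idx <- regions$start[r]:regions$end[r]
    if (grepl("^TM", regions$domain[r])) {
      aa[idx] <- sample(tm_pool, length(idx), replace = TRUE, prob = tm_w)
    } else {
      aa[idx] <- sample(loop_pool, length(idx), replace = TRUE)
    }
  }
  reg <- function(d) regions[regions$domain == d, ]
  # motif anchors, scaled with the layout
  dry_start <- reg("TM3")$end - 1L              # MAYDRYVAIC straddles TM3|IC2
  fst_start <- reg("IC3")$end - 5L              # FSTC(L|P)H ends IC3
  ec1_cys <- reg("EC1")$end - 2L
  ec2_cys <- reg("EC2")$start + 16L
  tm7_pro <- reg("TM7")$start + 14L
  aa[dry_start:(dry_start + 9L)] <- strsplit("MAYDRYVAIC", "")[[1]]
  aa[fst_start:(fst_start + 5L)] <- strsplit("FSTCLH", "")[[1]]
  aa[ec1_cys] <- "C"
  aa[ec2_cys] <- "C"
  aa[tm7_pro] <- "P"
  aa[1] <- "M"
  motif_map <- tibble(
    motif = c("start_met", "MAYDRYVAIC", "FSTCxH", "EC1_cys", "EC2_cys", "TM7_pro"),
    start = c(0L, dry_start - 1L, fst_start - 1L, ec1_cys - 1L, ec2_cys - 1L, tm7_pro - 1L),
    end = c(1L, dry_start + 9L, fst_start + 5L, ec1_cys, ec2_cys, tm7_pro)
  )
  protected <- sort(unique(unlist(
    purrr::map2(motif_map$start + 1L, motif_map$end, seq)
  )))
  structure(list(seq = paste(aa, collapse = ""), motif_map = motif_map,
                 regions = regions, protected = protected),
            class = "or_template")
}

# i.i.d. amino-acid substitutions outside protected positions, using the
# ambient RNG. `rate` is the per-site substitution probability.
mutate_protein <- function(seq, rate, protected = integer()) {
  aa <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(aa), protected)
  hit <- free[runif(length(free)) < rate]
  for (i in hit) {
    aa[i] <- sample(setdiff(AA_ALPHABET, aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

#' Derive family template proteins from a base template
#'
#' Each family is the base template with a fixed fraction of non-motif
#' positions substituted, emulating divergent OR subfamilies that still share
#' the canonical motifs.
#'
#' @param template an `or_template`.
#' @param n_families number of families.
#' @param family_divergence fraction of non-motif positions substituted per
#'   family template.
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return tibble with columns `family` and `seq`.
#' @export
make_family_templates <- function(template, n_families = 3L,
                                  family_divergence = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa0 <- strsplit(template$seq, "")[[1]]
  free <- setdiff(seq_along(aa0), template$protected)
  k <- round(family_divergence * length(free))
  fams <- purrr::map_chr(seq_len(n_families), function(f) {
    aa <- aa0
    for (i in sample(free, k)) aa[i] <- sample(setdiff(AA_ALPHABET, aa[i]), 1L)
    paste(aa, collapse = "")
  })
  tibble(family = sprintf("fam%02d", seq_len(n_families)), seq = fams)
}

#' Simulate an ungapped seed alignment of template variants
#'
#' Useful as the seed MSA from which the search profile HMM is built.
#'
#' @param template an `or_template` (or any protein template with a
#'   `protected` set; plain strings get an empty protected set).
#' @param n number of variant sequences.
#' @param divergence per-site substitution probability outside motifs.
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return named character vector of equal-length proteins (an MSA).
#' @export
make_seed_msa <- function(template, n = 12L, divergence = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq0 <- if (inherits(template, "or_template")) template$seq else template
  prot <- if (inherits(template, "or_template")) template$protected else integer()
  out <- vapply(seq_len(n), function(i) mutate_protein(seq0, divergence, prot),
                character(1))
  names(out) <- sprintf("seed%02d", seq_len(n))
  out
}

# uniform-codon-usage back-translation (no codon bias model), ambient RNG
back_translate <- function(protein) {
  ct <- codon_table()
  by_aa <- split(names(ct), ct)
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(cods, collapse = "")
}
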