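# Genetic-code tables and codon-level bookkeeping shared by the ORF scanner,
# the synthetic-data generators and the selection machinery. The standard
# nuclear code is used throughout (single-exon avian OR genes).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The 64 codons and their standard-code translations
#' @keywords internal
codon_table <- function() {
  if (!is.null(.olfactoR_cache$codon_table)) return(.olfactoR_cache$codon_table)
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  names(aa) <- codons
  .olfactoR_cache$codon_table <- aa
  aa
}

#' The 61 sense codons, lexicographic order
#' @keywords internal
sense_codons <- function() {
  ct <- codon_table()
  names(ct)[ct != "*"]
}

#' Translate DNA to protein, one amino acid per codon
#'
#' Codons containing any character other than ACGT (for example `N`) translate
#' to `X` and never count as stop codons. Trailing nucleotides that do not fill
#' a codon are dropped.
#'
#' @param dna character vector of DNA strings.
#' @return character vector of protein strings (`*` marks stop codons).
#' @export
translate_dna <- function(dna) {
  ct <- codon_table()
  vapply(dna, function(s) {
    s <- toupper(s)
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    cod <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- unname(ct[cod])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#' @param dna character vector of DNA strings (may contain N).
#' @return character vector.
#' @export
revcomp <- function(dna) {
  vapply(dna, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Single-nucleotide neighbour structure of the 61 sense codons:
# a data frame of ordered pairs (i, j) one nucleotide apart, with transition
# and synonymy flags. Used to build MG94 rate matrices and SLAC site counts.
codon_pairs <- function() {
  if (!is.null(.olfactoR_cache$codon_pairs)) return(.olfactoR_cache$codon_pairs)
  sc <- sense_codons()
  ct <- codon_table()
  n <- length(sc)
  mat <- do.call(rbind, strsplit(sc, ""))
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      a <- mat[i, diff]; b <- mat[j, diff]
      ti <- (a %in% c("A", "G") && b %in% c("A", "G")) ||
        (a %in% c("C", "T") && b %in% c("C", "T"))
      k <- k + 1L
      out[[k]] <- c(i, j, as.integer(ti), as.integer(ct[sc[i]] == ct[sc[j]]))
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j", "transition", "synonymous")
  .olfactoR_cache$codon_pairs <- m
  m
}

# Per-codon synonymous site fraction: among the single-nucleotide mutations
# of the codon that do not create a stop codon, the (kappa-weighted)
# fraction that are synonymous. Transitions are kappa times as likely as
# transversions, and transitions are disproportionately synonymous, so the
# neutral expectation rises with kappa.
codon_syn_fraction <- function(kappa = 1) {
  key <- sprintf("syn_frac_%.6g", kappa)
  if (!is.null(.olfactoR_cache[[key]])) return(.olfactoR_cache[[key]])
  cp <- codon_pairs()
  n <- length(sense_codons())
  w <- ifelse(cp[, "transition"] == 1L, kappa, 1)
  syn <- vapply(seq_len(n), function(i) {
    sum(w[cp[, "i"] == i & cp[, "synonymous"] == 1L])
  }, numeric(1))
  viable <- vapply(seq_len(n), function(i) sum(w[cp[, "i"] == i]), numeric(1))
  .olfactoR_cache[[key]] <- syn / viable
  .olfactoR_cache[[key]]
}

# Average synonymous / nonsynonymous change counts over all minimal mutational
# paths between every ordered codon pair. Paths passing through a stop codon
# are excluded; when every minimal path is blocked, all paths are used. Each
# path gets equal weight. Returns list(syn = 61 x 61, nonsyn = 61 x 61).
codon_path_counts <- function() {
  if (!is.null(.olfactoR_cache$path_counts)) return(.olfactoR_cache$path_counts)
  sc <- sense_codons()
  ct <- codon_table()
  n <- length(sc)
  syn <- matrix(0, n, n)
  nonsyn <- matrix(0, n, n)
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  split3 <- function(s) strsplit(s, "")[[1]]
  for (i in seq_len(n)) {
    ci <- split3(sc[i])
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- split3(sc[j])
      diff <- which(ci != cj)
      nd <- length(diff)
      paths <- perms[[nd]]
      tally <- function(ord, allow_stop) {
        cur <- ci; s_cnt <- 0; n_cnt <- 0
        for (pos in diff[ord]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          aa_cur <- ct[paste(cur, collapse = "")]
          aa_nxt <- ct[paste(nxt, collapse = "")]
          if (!allow_stop && aa_nxt == "*") return(NULL)
          if (aa_cur == aa_nxt) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
          cur <- nxt
        }
        c(s_cnt, n_cnt)
      }
      res <- purrr::compact(lapply(paths, tally, allow_stop = FALSE))
      if (length(res) == 0L) res <- lapply(paths, tally, allow_stop = TRUE)
      m <- do.call(rbind, res)
      syn[i, j] <- mean(m[, 1])
      nonsyn[i, j] <- mean(m[, 2])
    }
  }
  .olfactoR_cache$path_counts <- list(syn = syn, nonsyn = nonsyn)
  .olfactoR_cache$path_counts
}

# Map codon strings to 1-based indices in sense_codons(); codons with gaps,
# Ns or stops map to NA (treated as missing data).
codon_index <- function(codons) {
  idx <- match(toupper(codons), sense_codons())
  idx
}
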