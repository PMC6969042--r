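# Codon alignments: a 61-sense-codon state matrix (sites x taxa) threaded
# from a protein MSA and CDS sequences, or simulated directly. Codons
# containing gaps or ambiguity characters are missing data (NA).

new_codon_aln <- function(mat, taxa, protein_cols = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) == length(taxa))
  colnames(mat) <- taxa
  structure(list(codon = mat, taxa = taxa, n_sites = nrow(mat),
                 n_taxa = length(taxa),
                 protein_cols = protein_cols %||% seq_len(nrow(mat))),
            class = "codon_aln")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codon_aln <- function(x, ...) {
  cat("<codon_aln> ", x$n_sites, " codon sites x ", x$n_taxa, " taxa; ",
      sum(is.na(x$codon)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.codon_aln <- function(x) c(x$n_sites, x$n_taxa)

#' Thread a protein alignment onto coding sequences
#'
#' Each protein row's ungapped translation must equal the translation of its
#' CDS (terminal stop codons are stripped first); every protein gap becomes a
#' codon gap at the same column.
#'
#' @param protein_msa named character vector of equal-length gapped proteins.
#' @param cds_records named character vector of in-frame CDS DNA (or a tibble
#'   with `id` and `seq`), covering every MSA row.
#' @return a `codon_aln` object.
#' @export
thread_codon_alignment <- function(protein_msa, cds_records) {
  if (is.data.frame(cds_records)) {
    cds_records <- setNames(cds_records$seq, cds_records$id)
  }
  taxa <- names(protein_msa)
  missing <- setdiff(taxa, names(cds_records))
  if (length(missing) > 0L) {
    stop("no CDS record for aligned sequence(s): ", paste(missing, collapse = ", "))
  }
  ncol_aln <- unique(nchar(protein_msa))
  if (length(ncol_aln) != 1L) stop("ragged protein alignment")
  sc <- sense_codons()
  mat <- matrix(NA_integer_, nrow = ncol_aln, ncol = length(taxa))
  for (t in seq_along(taxa)) {
    cds <- toupper(cds_records[[taxa[t]]])
    if (nchar(cds) %% 3L != 0L) {
      stop("CDS length of ", taxa[t], " is not a multiple of 3")
    }
    cods <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    aa <- strsplit(translate_dna(cds), "")[[1]]
    if (length(aa) > 0L && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      stop("internal stop codon in CDS of ", taxa[t], " at codon ",
           which(aa == "*")[1])
    }
    row <- strsplit(protein_msa[[t]], "")[[1]]
    res_idx <- which(!row %in% c("-", "."))
    if (length(res_idx) != length(aa) ||
        any(row[res_idx] != aa & row[res_idx] != "X" & aa != "X")) {
      bad <- if (length(res_idx) != length(aa)) 1L else
        which(row[res_idx] != aa & row[res_idx] != "X" & aa != "X")[1]
      stop("translation mismatch for ", taxa[t], " at aligned residue ", bad)
    }
    mat[res_idx, t] <- codon_index(cods)
  }
  new_codon_aln(mat, taxa)
}

#' Render a codon alignment as gapped nucleotide strings
#' @param aln a `codon_aln`.
#' @return named character vector (one gapped CDS string per taxon).
#' @export
codon_aln_strings <- function(aln) {
  sc <- sense_codons()
  out <- apply(aln$codon, 2, function(col) {
    cods <- ifelse(is.na(col), "---", sc[col])
    paste(cods, collapse = "")
  })
  setNames(out, aln$taxa)
}

#' Translate a codon alignment to a gapped protein MSA
#' @param aln a `codon_aln`.
#' @return named character vector of gapped proteins.
#' @export
translate_codon_aln <- function(aln) {
  sc <- sense_codons()
  ct <- codon_table()
  out <- apply(aln$codon, 2, function(col) {
    aa <- ifelse(is.na(col), "-", unname(ct[sc[col]]))
    paste(aa, collapse = "")
  })
  setNames(out, aln$taxa)
}

#' Read a gapped codon alignment from FASTA
#' @param path FASTA file of aligned, in-frame CDS (gaps in codon triplets).
#' @return a `codon_aln`.
#' @export
read_codon_aln <- function(path) {
  recs <- read_fasta(path, alphabet = "dna")
  len <- unique(nchar(recs$seq))
  if (length(len) != 1L || len %% 3L != 0L) {
    stop("aligned CDS records must share one length divisible by 3")
  }
  sc <- sense_codons()
  ct <- codon_table()
  mat <- vapply(toupper(recs$seq), function(s) {
    cods <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    idx <- match(cods, sc)
    stops <- !is.na(match(cods, names(ct)[ct == "*"]))
    if (any(stops[-length(stops)])) {
      stop("internal stop codon in aligned record")
    }
    idx
  }, integer(len %/% 3L))
  # strip the terminal column when it holds stop codons
  term <- vapply(toupper(recs$seq), function(s) {
    cod <- substr(s, len - 2L, len)
    !is.na(codon_table()[cod]) && codon_table()[cod] == "*"
  }, logical(1))
  if (any(term)) mat <- mat[-nrow(mat), , drop = FALSE]
  new_codon_aln(mat, recs$id)
}

#' Simulate a random gene tree
#'
#' Random topology with exponentially distributed branch lengths, the shape
#' used for the package's synthetic selection studies.
#'
#' @param n_taxa number of tips.
#' @param mean_brlen mean branch length (expected substitutions per codon
#'   site at the neutral reference rate).
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return an unrooted [ape::phylo] with tip labels `t1..tn`.
#' @export
sim_gene_tree <- function(n_taxa, mean_brlen = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_brlen)
  tr
}

# MG94 x HKY instantaneous rate matrix over the 61 sense codons with equal
# codon frequencies. Off-diagonal entries are kappa^[transition] for
# synonymous and omega * kappa^[transition] for nonsynonymous single-nt
# changes. Scaled so that the omega = 1 matrix has unit expected rate.
mg94_q <- function(kappa, omega) {
  cp <- codon_pairs()
  n <- length(sense_codons())
  Q <- matrix(0, n, n)
  rate <- ifelse(cp[, "transition"] == 1L, kappa, 1) *
    ifelse(cp[, "synonymous"] == 1L, 1, omega)
  Q[cbind(cp[, "i"], cp[, "j"])] <- rate
  diag(Q) <- -rowSums(Q)
  Q / mg94_neutral_rate(kappa)
}

mg94_neutral_rate <- function(kappa) {
  cp <- codon_pairs()
  n <- length(sense_codons())
  sum(ifelse(cp[, "transition"] == 1L, kappa, 1)) / n
}

#' Simulate a codon alignment with site-specific dN/dS
#'
#' Sites evolve independently under an MG94-style codon substitution process
#' with equal codon frequencies, transition/transversion ratio `kappa` and
#' per-site `omega`. Branch lengths are expected substitutions per codon site
#' at the neutral (`omega = 1`) reference rate. When `breakpoint` is given,
#' sites after it evolve along `tree2` instead of `tree`, emulating a
#' recombination breakpoint. Stop codons are never generated.
#'
#' @param tree an [ape::phylo] (or Newick string) with positive branch lengths.
#' @param site_omega numeric vector of per-codon-site dN/dS values (>= 0);
#'   its length sets the alignment length.
#' @param kappa transition/transversion ratio (> 0).
#' @param breakpoint optional codon index `b`; sites `1..b` follow `tree`,
#'   sites `b+1..S` follow `tree2`.
#' @param tree2 second topology, required with `breakpoint`.
#' @param seed integer seed; `NULL` uses the ambient RNG.
#' @return a `codon_aln` with attribute `truth` recording the inputs.
#' @export
simulate_codon_alignment <- function(tree, site_omega, kappa = 2,
                                     breakpoint = NULL, tree2 = NULL,
                                     seed = NULL) {
  # evaluate arguments before touching the RNG (lazy promises would
  # otherwise consume the seeded stream)
  force(site_omega); force(kappa); force(breakpoint)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.character(tree2)) tree2 <- ape::read.tree(text = tree2)
  if (any(site_omega < 0)) stop("site_omega must be nonnegative")
  if (kappa <= 0) stop("kappa must be positive")
  if (!is.null(seed)) set.seed(seed)
  S <- length(site_omega)
  if (!is.null(breakpoint)) {
    if (is.null(tree2)) stop("breakpoint requires tree2")
    if (breakpoint < 1L || breakpoint >= S) stop("breakpoint outside sequence")
  }
  sim_part <- function(tr, omegas) {
    stopifnot(all(tr$edge.length > 0))
    n <- length(tr$tip.label)
    nn <- max(tr$edge)
    s <- length(omegas)
    states <- matrix(NA_integer_, nrow = s, ncol = nn)
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
    states[, root] <- sample.int(61L, s, replace = TRUE)
    omega_class <- match(omegas, unique(omegas))
    eigs <- lapply(unique(omegas), function(w) eigen(mg94_q(kappa, w), symmetric = TRUE))
    ord <- reorder(tr, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t_e <- ord$edge.length[e]
      for (cl in unique(omega_class)) {
        eg <- eigs[[cl]]
        P <- eg$vectors %*% (exp(eg$values * t_e) * t(eg$vectors))
        P[P < 0] <- 0
        idx <- which(omega_class == cl)
        par_states <- states[idx, par]
        for (ps in unique(par_states)) {
          rows <- idx[par_states == ps]
          states[rows, child] <- sample.int(61L, length(rows), replace = TRUE,
                                            prob = P[ps, ])
        }
      }
    }
    states[, seq_len(n), drop = FALSE]
  }
  if (is.null(breakpoint)) {
    mat <- sim_part(tree, site_omega)
    taxa <- tree$tip.label
  } else {
    stopifnot(setequal(tree$tip.label, tree2$tip.label))
    left <- sim_part(tree, site_omega[seq_len(breakpoint)])
    right <- sim_part(tree2, site_omega[(breakpoint + 1L):S])
    right <- right[, match(tree$tip.label, tree2$tip.label), drop = FALSE]
    mat <- rbind(left, right)
    taxa <- tree$tip.label
  }
  aln <- new_codon_aln(mat, taxa)
  attr(aln, "truth") <- list(site_omega = site_omega, kappa = kappa,
                             breakpoint = breakpoint)
  aln
}
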