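# Shared builders for synthetic fixtures. Everything is generated in code
# under fixed seeds; nothing is read from disk except the packaged census.

# seed alignment spanning the family templates a planted genome was built
# from (the realistic input: profiles are built from known family members)
family_seed_msa <- function(pg, n_per = 4L, divergence = 0.05, seed = 99L) {
  unlist(lapply(seq_len(nrow(pg$families)), function(i) {
    tpl <- structure(list(seq = pg$families$seq[i],
                          protected = pg$template$protected),
                     class = "or_template")
    m <- make_seed_msa(tpl, n = n_per, divergence = divergence,
                       seed = seed + i)
    setNames(m, paste0("f", i, "_", names(m)))
  }))
}

# independent six-frame ORF enumerator used as the oracle for find_orfs():
# translation through Biostrings, plain loops, no shared code path
brute_force_orfs <- function(contig_id, seq, min_aa = 75L) {
  lc <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 0:2) {
      ncod <- (lc - f) %/% 3L
      if (ncod < 1L) next
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1L, f + 3L * ncod)),
        no.init.codon = TRUE)), "")[[1]]
      bounds <- c(0L, which(aa == "*"), ncod + 1L)
      bounds <- unique(bounds)
      for (k in seq_len(length(bounds) - 1L)) {
        a <- bounds[k] + 1L
        b <- bounds[k + 1L] - 1L
        if (a > b) next
        has_stop <- bounds[k + 1L] <= ncod
        m <- which(aa[a:b] == "M")
        has_start <- length(m) > 0L
        cds_a <- if (has_start) a + m[1] - 1L else a
        if (b - cds_a + 1L < min_aa) next
        nt_a <- f + 3L * (cds_a - 1L) + 1L
        nt_b <- f + 3L * (b + as.integer(has_stop))
        if (strand == "+") {
          start0 <- nt_a - 1L
          end0 <- nt_b
        } else {
          start0 <- lc - nt_b
          end0 <- lc - nt_a + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig_id, start = start0, end = end0, strand = strand,
          frame = f, aa_seq = paste(aa[cds_a:b], collapse = ""),
          has_start = has_start, has_stop = has_stop,
          edge5 = bounds[k] == 0L, edge3 = !has_stop)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$start, out$end, out$strand, out$frame), ]
}

random_contig <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive glocal Viterbi for toy profile HMMs: enumerates every split of
# the sequence into flank / core / flank and every M-I-D path through the
# match states, mirroring the scoring semantics independently of the DP
brute_force_viterbi <- function(hmm, seq) {
  x <- match(strsplit(seq, "")[[1]], strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  lo <- log2(sweep(hmm$match_emis, 2, hmm$background, "/"))
  tr <- hmm$trans
  L <- hmm$L
  n <- length(x)
  best <- -Inf
  # recursive enumeration: position k (next match state), i residues of the
  # core consumed so far (absolute index into x), prev state
  recurse <- function(k, i, prev, score) {
    if (score < best - 1e4) return()
    if (k == L + 1L) {
      best <<- max(best, score)
      return()
    }
    # match k (consumes a residue)
    if (i < n) {
      recurse(k + 1L, i + 1L, "M",
              score + tr[k, paste0(prev, "M")] + lo[k, x[i + 1L]])
    }
    # delete k
    recurse(k + 1L, i, "D", score + tr[k, paste0(prev, "D")])
    # insert at k-1 (consumes a residue, stays before match k); only
    # meaningful after at least one core state, and capped to avoid blowup
    if (k > 1L && k <= L && i < n) {
      recurse(k, i + 1L, "I", score + tr[k, paste0(prev, "I")])
    }
  }
  for (entry in 0:n) {  # residues consumed by the free N-flank
    recurse(1L, entry, "M", 0)
  }
  best
}

# exhaustive codon-alignment likelihood by summation over all ancestral
# states, with transition probabilities from matrix exponentials (Matrix)
brute_force_codon_loglik <- function(aln, tree, kappa, omega) {
  tree <- ape::reorder.phylo(tree, "postorder")
  X <- aln$codon[, match(tree$tip.label, aln$taxa), drop = FALSE]
  Q <- olfactoR:::mg94_q(kappa, omega)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internal <- (ntip + 1L):nnode
  root <- tree$edge[nrow(tree$edge), 1]
  total <- 0
  for (s in seq_len(nrow(X))) {
    grid <- do.call(expand.grid, rep(list(1:61), length(internal)))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      states <- rep(NA_integer_, nnode)
      states[internal] <- as.integer(grid[g, ])
      states[seq_len(ntip)] <- X[s, ]
      pr <- 1 / 61
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        if (is.na(states[ch])) next  # missing tip integrates out
        pr <- pr * P[[e]][states[par], states[ch]]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}
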