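# Profile hidden Markov model over protein seed alignments: match states are
# the seed columns with < 50% gaps; emissions mix observed counts with a
# background pseudocount; scoring is glocal Viterbi in log2-odds space
# against an i.i.d. background, with significance calibrated by fitting a
# Gumbel distribution to the scores of shuffled input sequences.

aa_index <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(a) {
    i <- match(a, AA_ALPHABET)
    i[is.na(i)] <- 21L  # X / unknown: background emission, log-odds 0
    i - 1L
  })
}

#' Build a profile HMM from a protein seed alignment
#'
#' Match columns are those with less than 50% gaps. Match emissions are
#' `(counts + pseudocount_weight * background) / total`; insert states emit
#' the background. Transition probabilities are estimated from the implied
#' match/insert/delete paths of the seed sequences with the same pseudocount
#' weight.
#'
#' @param seed_msa named character vector of equal-length gapped protein
#'   sequences (>= 2).
#' @param pseudocount_weight nonnegative weight of the background
#'   pseudocount; 0 gives pure maximum-likelihood (indicator) emissions.
#' @param background length-20 amino-acid frequency vector (default uniform).
#' @return an object of class `profile_hmm` with elements `L`, `match_emis`
#'   (L x 20), `background`, `trans` (log2-probability matrix), `match_cols`.
#' @export
build_profile_hmm <- function(seed_msa, pseudocount_weight = 1,
                              background = rep(1 / 20, 20)) {
  if (length(seed_msa) < 2L) stop("need at least 2 aligned seed sequences")
  lens <- unique(nchar(seed_msa))
  if (length(lens) != 1L) stop("ragged seed alignment")
  rows <- do.call(rbind, strsplit(toupper(seed_msa), ""))
  rows[rows == "."] <- "-"
  gap_frac <- colMeans(rows == "-")
  match_cols <- which(gap_frac < 0.5)
  L <- length(match_cols)
  if (L == 0L) stop("no match columns: every column is at least half gaps")
  bg <- background / sum(background)
  emis <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (l in seq_len(L)) {
    col <- rows[, match_cols[l]]
    cnt <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    e <- as.numeric(cnt) + pseudocount_weight * bg
    if (sum(e) == 0) e <- bg
    emis[l, ] <- e / sum(e)
  }
  # transition counts along each sequence's implied state path
  tr_names <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  cnt <- matrix(0, nrow = L + 1L, ncol = 9L, dimnames = list(NULL, tr_names))
  is_match_col <- seq_len(ncol(rows)) %in% match_cols
  for (r in seq_len(nrow(rows))) {
    prev <- "M"  # begin treated as match state 0
    l <- 0L
    for (cix in seq_len(ncol(rows))) {
      res <- rows[r, cix] != "-"
      if (is_match_col[cix]) {
        st <- if (res) "M" else "D"
        cnt[l + 1L, paste0(prev, st)] <- cnt[l + 1L, paste0(prev, st)] + 1
        prev <- st
        l <- l + 1L
      } else if (res) {
        cnt[l + 1L, paste0(prev, "I")] <- cnt[l + 1L, paste0(prev, "I")] + 1
        prev <- "I"
      }
    }
  }
  # structured transition prior: match states strongly continue; delete
  # states, rarely observed in mostly-ungapped seeds, get a long-extension
  # prior so fragmentary sequences (contig-edge truncations, pieces flanking
  # premature stops) traverse unmatched profile positions at modest cost
  # instead of being priced out of detection.
  prior <- rbind(M = c(M = 0.90, I = 0.05, D = 0.05),
                 I = c(M = 0.50, I = 0.50, D = 0.00),
                 D = c(M = 0.10, I = 0.00, D = 0.90))
  trans <- matrix(-Inf, nrow = L + 1L, ncol = 9L, dimnames = list(NULL, tr_names))
  for (l in seq_len(L + 1L)) {
    for (src in c("M", "I", "D")) {
      cols <- paste0(src, c("M", "I", "D"))
      v <- cnt[l, cols] + pseudocount_weight * prior[src, ]
      if (sum(v) == 0) v <- prior[src, ]  # unobserved source state
      trans[l, cols] <- log2(v / sum(v))
    }
  }
  structure(list(L = L, match_emis = emis, background = bg, trans = trans,
                 match_cols = match_cols,
                 pseudocount_weight = pseudocount_weight),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$L, " match states (from ",
      length(x$match_cols), " seed columns)\n", sep = "")
  invisible(x)
}

# L x 21 log2-odds emission matrix (column 21 = X, log-odds 0)
hmm_log_odds <- function(hmm) {
  lo <- log2(sweep(hmm$match_emis, 2, hmm$background, "/"))
  cbind(lo, 0)
}

hmm_score <- function(hmm, proteins) {
  xs <- aa_index(proteins)
  cpp_viterbi_score(xs, hmm_log_odds(hmm), hmm$trans)
}

# maximum-likelihood Gumbel fit (location mu, scale beta)
fit_gumbel <- function(x) {
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  c(mu = fit$par[1], beta = exp(fit$par[2]))
}

gumbel_upper_tail <- function(s, mu, beta) {
  z <- (s - mu) / beta
  # P(S >= s) = 1 - exp(-exp(-z)); for large z this underflows to exp(-z)
  ifelse(z > 30, exp(-z), -expm1(-exp(-z)))
}

#' Search ORFs with a profile HMM
#'
#' Scores each ORF's translation with glocal Viterbi against the profile and
#' converts bit scores to E-values via a Gumbel null distribution fitted by
#' maximum likelihood to the scores of `n_null` shuffled, length- and
#' composition-matched sequences (shuffles of the input ORFs themselves,
#' cycled). The E-value is the Gumbel upper-tail probability times the number
#' of ORFs searched.
#'
#' @param hmm a `profile_hmm`.
#' @param orfs ORF tibble from [find_orfs()] (uses `aa_seq`), or a named
#'   character vector of proteins.
#' @param e_cutoff report hits with E-value at or below this (classical
#'   repertoire screens use 1e-10).
#' @param n_null number of shuffled sequences for the Gumbel fit.
#' @param seed integer seed for the shuffles; `NULL` uses the ambient RNG.
#' @return tibble of hits sorted by decreasing bit score: `orf_id`,
#'   `bit_score`, `e_value`, `env_from`, `env_to`, `hmm_from`, `hmm_to`,
#'   `alignment_row` (the implied row over match states). The Gumbel
#'   parameters are attached as attribute `gumbel`.
#' @export
search_orfs <- function(hmm, orfs, e_cutoff = 1e-10, n_null = 1000L,
                        seed = NULL) {
  if (is.data.frame(orfs)) {
    proteins <- setNames(orfs$aa_seq, orfs$orf_id)
  } else {
    proteins <- orfs
  }
  if (length(proteins) == 0L) stop("empty ORF set")
  if (is.null(names(proteins))) names(proteins) <- paste0("seq", seq_along(proteins))
  if (!is.null(seed)) set.seed(seed)
  scores <- hmm_score(hmm, proteins)
  shuffle_one <- function(i) {
    s <- strsplit(proteins[[((i - 1L) %% length(proteins)) + 1L]], "")[[1]]
    paste(sample(s), collapse = "")
  }
  nulls <- vapply(seq_len(n_null), shuffle_one, character(1))
  null_scores <- hmm_score(hmm, nulls)
  g <- fit_gumbel(null_scores)
  pvals <- gumbel_upper_tail(scores, g["mu"], g["beta"])
  evals <- pvals * length(proteins)
  keep <- which(evals <= e_cutoff)
  keep <- keep[order(scores[keep], decreasing = TRUE)]
  lo <- hmm_log_odds(hmm)
  xs <- aa_index(proteins)
  rows <- lapply(keep, function(i) {
    al <- cpp_viterbi_align(xs[[i]], lo, hmm$trans)
    aa <- strsplit(toupper(proteins[[i]]), "")[[1]]
    row <- ifelse(al$match_pos > 0, aa[pmax(al$match_pos, 1L)], "-")
    tibble(orf_id = names(proteins)[i], bit_score = scores[i],
           e_value = evals[i], env_from = al$env_from, env_to = al$env_to,
           hmm_from = al$hmm_from, hmm_to = al$hmm_to,
           alignment_row = paste(row, collapse = ""))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(orf_id = character(), bit_score = numeric(),
                  e_value = numeric(), env_from = integer(),
                  env_to = integer(), hmm_from = integer(),
                  hmm_to = integer(), alignment_row = character())
  }
  attr(out, "gumbel") <- g
  out
}

#' Align proteins to a profile HMM
#'
#' Projects each protein's Viterbi path onto the match states: one row per
#' sequence, one column per match state, insertions collapsed.
#'
#' @param hmm a `profile_hmm`.
#' @param proteins named character vector of proteins.
#' @return named character vector of gapped rows, all of length `hmm$L`.
#' @export
align_to_hmm <- function(hmm, proteins) {
  lo <- hmm_log_odds(hmm)
  xs <- aa_index(proteins)
  out <- vapply(seq_along(proteins), function(i) {
    al <- cpp_viterbi_align(xs[[i]], lo, hmm$trans)
    if (al$env_from == 0L) {
      stop("sequence ", names(proteins)[i],
           " aligns to the profile by deletions only")
    }
    aa <- strsplit(toupper(proteins[[i]]), "")[[1]]
    paste(ifelse(al$match_pos > 0, aa[pmax(al$match_pos, 1L)], "-"),
          collapse = "")
  }, character(1))
  setNames(out, names(proteins))
}
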