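# Functional annotation of OR-positive ORFs: family assignment against a
# tagged reference panel, canonical motif scanning, per-column conservation
# profiling, and Kyte-Doolittle transmembrane segmentation with the class-A
# GPCR extracellular-N-terminus topology.

#' Assign a protein to an OR family by best panel identity
#'
#' Global (Needleman-Wunsch) alignment against every panel member; identity
#' is computed over aligned residue pairs (gap positions excluded). The best
#' identity wins; below `min_identity` the family is `"unknown"`. Ties break
#' deterministically by panel order.
#'
#' @param protein a single protein string, or a named character vector (one
#'   assignment per element).
#' @param reference_panel a tibble with `family` and `seq` columns (as from
#'   [make_family_templates()]), or a named character vector whose names are
#'   family labels.
#' @param min_identity identity threshold below which `"unknown"` is
#'   returned.
#' @return tibble with `query`, `family`, `identity`.
#' @export
assign_family <- function(protein, reference_panel, min_identity = 0.4) {
  if (is.character(reference_panel)) {
    reference_panel <- tibble(family = names(reference_panel),
                              seq = unname(reference_panel))
  }
  if (nrow(reference_panel) == 0L) stop("empty reference panel")
  if (is.null(names(protein))) {
    names(protein) <- if (length(protein) == 1L) "query" else
      paste0("query", seq_along(protein))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  subject <- Biostrings::AAStringSet(gsub("[*]", "X", reference_panel$seq))
  rows <- purrr::map(seq_along(protein), function(q) {
    pat <- gsub("[*]", "X", protein[[q]])
    pid <- vapply(seq_len(length(subject)), function(s) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pat), subject[[s]], type = "global",
        substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5)
      Biostrings::pid(al, type = "PID2") / 100
    }, numeric(1))
    best <- which.max(pid)  # which.max takes the first maximum: panel order
    tibble(query = names(protein)[q],
           family = if (pid[best] >= min_identity) reference_panel$family[best]
                    else "unknown",
           identity = pid[best])
  })
  bind_rows(rows)
}

# sliding mismatch counts of a fixed pattern; `wild` marks positions where a
# set of residues is allowed; positions in `strict` may not mismatch at all
motif_best_hit <- function(aa, pattern, max_mm, wild = list(), strict = integer()) {
  p <- strsplit(pattern, "")[[1]]
  L <- length(p)
  n <- length(aa)
  if (n < L) return(NULL)
  best <- NULL
  for (s in seq_len(n - L + 1L)) {
    win <- aa[s:(s + L - 1L)]
    ok <- win == p
    for (w in names(wild)) {
      i <- as.integer(w)
      ok[i] <- win[i] %in% wild[[w]]
    }
    mm <- sum(!ok)
    if (mm <= max_mm && all(ok[strict])) {
      if (is.null(best) || mm < best$mm) best <- list(start = s - 1L, mm = mm)
      if (best$mm == 0L) break
    }
  }
  best
}

#' Scan a protein for the canonical OR motifs
#'
#' Reports, with 0-based positions: the MAYDRYVAIC motif (up to 2
#' mismatches), the F-S-T-C-(L|P)-H pattern (up to 1 mismatch outside the
#' bracketed position, which must be L or P), and every cysteine position.
#' Absence is a result, not an error.
#'
#' @param protein protein string.
#' @return tibble with columns `motif`, `found`, `start` (0-based, NA when
#'   not found), `mismatches`, plus one `cysteines` row whose `start` holds
#'   a comma-separated position list.
#' @export
scan_motifs <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  dry <- motif_best_hit(aa, "MAYDRYVAIC", max_mm = 2L)
  fst <- motif_best_hit(aa, "FSTCLH", max_mm = 1L,
                        wild = list(`5` = c("L", "P")), strict = 5L)
  cys <- which(aa == "C") - 1L
  tibble(
    motif = c("MAYDRYVAIC", "FSTC(LP)H", "cysteines"),
    found = c(!is.null(dry), !is.null(fst), length(cys) > 0L),
    start = c(if (is.null(dry)) NA_character_ else as.character(dry$start),
              if (is.null(fst)) NA_character_ else as.character(fst$start),
              paste(cys, collapse = ",")),
    mismatches = c(if (is.null(dry)) NA_integer_ else dry$mm,
                   if (is.null(fst)) NA_integer_ else fst$mm,
                   NA_integer_)
  )
}

#' Per-column conservation profile of a protein alignment
#'
#' Column amino-acid frequencies ignore gaps; information content is
#' `log2(20) - H` with `H` the Shannon entropy of the frequencies (the
#' sequence-logo scale). All-gap columns are flagged and carry NA.
#'
#' @param msa named character vector of equal-length gapped proteins (>= 2).
#' @param domains optional domain labeling tibble (columns `domain`, `start`,
#'   `end`, 1-based on alignment columns) merged into the output.
#' @return list of class `conservation_profile`: `freq` (columns x 20
#'   matrix), `info` (bits per column), `coverage` (non-gap fraction),
#'   `domain` (label per column or NA).
#' @export
conservation_profile <- function(msa, domains = NULL) {
  if (length(msa) < 2L) stop("need at least 2 aligned sequences")
  rows <- do.call(rbind, strsplit(toupper(msa), ""))
  nc <- ncol(rows)
  freq <- matrix(NA_real_, nrow = nc, ncol = 20,
                 dimnames = list(NULL, AA_ALPHABET))
  info <- rep(NA_real_, nc)
  cover <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- rows[, j]
    res <- col[col %in% AA_ALPHABET]
    cover[j] <- length(res) / nrow(rows)
    if (length(res) == 0L) next  # all-gap column: flagged by NA
    f <- as.numeric(table(factor(res, levels = AA_ALPHABET))) / length(res)
    freq[j, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    info[j] <- log2(20) - h
  }
  dom <- rep(NA_character_, nc)
  if (!is.null(domains)) {
    for (r in seq_len(nrow(domains))) {
      idx <- domains$start[r]:domains$end[r]
      idx <- idx[idx >= 1 & idx <= nc]
      dom[idx] <- domains$domain[r]
    }
  }
  structure(list(freq = freq, info = info, coverage = cover, domain = dom),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", length(x$info), " columns; mean information ",
      round(mean(x$info, na.rm = TRUE), 2), " bits\n", sep = "")
  invisible(x)
}

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Sliding-window mean hydropathy; maximal runs above `threshold` become
#' candidate transmembrane segments, extended to at least 17 residues and
#' split when longer than 25. Segments are numbered N- to C-terminal and
#' loops are labeled IC/EC alternately assuming an extracellular N-terminus
#' (the class-A GPCR / olfactory receptor topology), so the loop after TM1
#' is IC1, after TM2 is EC1, and so on.
#'
#' @param protein protein string, longer than `window`.
#' @param window sliding-window width (odd).
#' @param threshold hydropathy call threshold.
#' @return list of class `tm_prediction`: `segments` (tibble `segment`,
#'   `start`, `end`, 1-based inclusive), `domains` (tibble covering the full
#'   protein with TM/IC/EC/N/C labels) and `hydropathy` (per-residue score,
#'   NA at the ends).
#' @export
predict_tm_domains <- function(protein, window = 19L, threshold = 1.6) {
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  if (n <= window) stop("sequence not longer than the hydropathy window")
  kd <- unname(KYTE_DOOLITTLE[aa])
  kd[is.na(kd)] <- 0
  half <- (window - 1L) %/% 2L
  score <- rep(NA_real_, n)
  cs <- cumsum(c(0, kd))
  centers <- (half + 1L):(n - half)
  score[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  above <- !is.na(score) & score > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- starts[k]; b <- ends[k]
    len <- b - a + 1L
    if (len > 25L) {
      nparts <- ceiling(len / 25L)
      cut <- floor(seq(a - 1L, b, length.out = nparts + 1L))
      for (p in seq_len(nparts)) segs[[length(segs) + 1L]] <- c(cut[p] + 1L, cut[p + 1L])
    } else {
      segs[[length(segs) + 1L]] <- c(a, b)
    }
  }
  # extend short segments symmetrically to 17 residues, within bounds
  segs <- lapply(segs, function(s) {
    len <- s[2] - s[1] + 1L
    if (len < 17L) {
      need <- 17L - len
      s[1] <- max(1L, s[1] - ceiling(need / 2))
      s[2] <- min(n, s[2] + (17L - (s[2] - s[1] + 1L)))
      s[1] <- max(1L, s[2] - 16L)
    }
    s
  })
  # merge any overlaps introduced by extension
  if (length(segs) > 1L) {
    merged <- list(segs[[1]])
    for (k in 2:length(segs)) {
      last <- merged[[length(merged)]]
      if (segs[[k]][1] <= last[2]) {
        merged[[length(merged)]][2] <- max(last[2], segs[[k]][2])
      } else {
        merged[[length(merged)]] <- last
        merged[[length(merged) + 1L]] <- segs[[k]]
      }
    }
    segs <- merged
  }
  seg_tbl <- if (length(segs) == 0L) {
    tibble(segment = character(), start = integer(), end = integer())
  } else {
    tibble(segment = paste0("TM", seq_along(segs)),
           start = vapply(segs, function(s) as.integer(s[1]), integer(1)),
           end = vapply(segs, function(s) as.integer(s[2]), integer(1)))
  }
  # loop labeling: extracellular N-terminus, so TM1 ends intracellular
  dom <- list()
  if (nrow(seg_tbl) > 0L) {
    if (seg_tbl$start[1] > 1L) {
      dom[[1]] <- tibble(domain = "N", start = 1L, end = seg_tbl$start[1] - 1L)
    }
    for (k in seq_len(nrow(seg_tbl))) {
      dom[[length(dom) + 1L]] <- tibble(domain = seg_tbl$segment[k],
                                        start = seg_tbl$start[k],
                                        end = seg_tbl$end[k])
      nxt <- if (k < nrow(seg_tbl)) seg_tbl$start[k + 1L] - 1L else n
      if (nxt >= seg_tbl$end[k] + 1L) {
        lab <- if (k == nrow(seg_tbl)) "C" else
          paste0(if (k %% 2L == 1L) "IC" else "EC", ceiling(k / 2))
        dom[[length(dom) + 1L]] <- tibble(domain = lab,
                                          start = seg_tbl$end[k] + 1L,
                                          end = nxt)
      }
    }
  } else {
    dom[[1]] <- tibble(domain = "N", start = 1L, end = n)
  }
  structure(list(segments = seg_tbl, domains = bind_rows(dom),
                 hydropathy = score),
            class = "tm_prediction")
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat("<tm_prediction> ", nrow(x$segments), " transmembrane segment(s)\n",
      sep = "")
  invisible(x)
}
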