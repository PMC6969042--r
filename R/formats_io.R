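# FASTA / GFF3 / Newick input-output and the coordinate conventions used
# throughout the package. Internally every interval is 0-based half-open on
# the forward strand of its contig; conversion to 1-based inclusive
# coordinates happens only when GFF3 is written.

#' Read a FASTA file into a tibble of sequence records
#'
#' @param path path to a (possibly gapped) FASTA file.
#' @param alphabet `"dna"` or `"protein"`; only used to tag the records, the
#'   sequences themselves are kept verbatim (whitespace stripped, case
#'   preserved).
#' @return a tibble with columns `id`, `description`, `seq`, `alphabet`,
#'   one row per record in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- as.character(set)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA record(s): ",
         paste(id[!nzchar(seqs)], collapse = ", "))
  }
  tibble(id = id, description = desc, seq = unname(seqs), alphabet = alphabet)
}

#' Write sequence records to FASTA
#'
#' @param x a tibble with `id` and `seq` columns (optionally `description`),
#'   or a named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- tibble(id = names(x), description = "", seq = unname(x))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# percent-encode the characters GFF3 reserves inside attribute values
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write classified OR genes as GFF3
#'
#' Internal 0-based half-open intervals are converted to the 1-based inclusive
#' convention of GFF3. Each gene becomes one `gene` feature carrying `family`,
#' `integrity` and `disruptions` attributes.
#'
#' @param genes a tibble of genes with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`, `family`, `integrity` and optionally
#'   `disruptions` (character, `;`-free) — as produced by
#'   [classify_repertoire()].
#' @param path output path.
#' @param contig_lengths optional named vector of contig lengths; when given,
#'   every interval is checked against its contig bounds.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) == 0L) return(invisible(path))
  stopifnot(all(genes$start >= 0), all(genes$end > genes$start))
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[genes$contig_id]
    bad <- is.na(len) | genes$end > len
    if (any(bad)) {
      stop("gene interval outside contig bounds: ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
  }
  disr <- if ("disruptions" %in% names(genes)) genes$disruptions else rep("", nrow(genes))
  disr[is.na(disr)] <- ""
  attrs <- paste0(
    "ID=", gff3_escape(genes$gene_id),
    ";family=", gff3_escape(genes$family),
    ";integrity=", gff3_escape(genes$integrity),
    ifelse(nzchar(disr), paste0(";disruptions=", gff3_escape(disr)), "")
  )
  writeLines(paste(genes$contig_id, "olfactoR", "gene",
                   genes$start + 1L, genes$end, ".", genes$strand, ".",
                   attrs, sep = "\t"), con)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' branch lengths and keep internal-node support labels. Round-trips preserve
#' topology, branch lengths and supports.
#'
#' @param path file path.
#' @return `read_newick()` returns an [ape::phylo] object; `write_newick()`
#'   returns `path` invisibly.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("failed to parse Newick file ", path, ": ", conditionMessage(e))
  })
  if (is.null(tr)) stop("failed to parse Newick file ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in ", path)
  }
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object (internal-node labels, if present, are
#'   written as support values).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
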