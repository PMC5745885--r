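#' Load a reference proteome from FASTA
#'
#' Reads a (multi-line) protein FASTA into a [Proteome-class] object. The
#' accession is the first whitespace-delimited token of each header and must
#' be unique. Gene symbols are extracted from the header with
#' \code{geneRegex} (first capture group); an optional two-column
#' accession-to-gene TSV sidecar (\code{geneMap}, columns \code{accession},
#' \code{gene}) overrides header-derived symbols.
#'
#' Sequences may contain the 20 standard residues plus \code{X} (unknown);
#' any other character is an error naming the offending record. \code{X}
#' never matches a query position during the search.
#'
#' @param path FASTA file.
#' @param geneRegex regular expression with one capture group applied to
#'   each header line; default matches UniProt-style \code{GN=SYMBOL} tags.
#' @param geneMap optional path to an accession-to-gene TSV sidecar.
#' @return a [Proteome-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 GN=GENE1", "MAKVAELVHFLQQ", ">P2", "MSTNPKPQRKT"), fa)
#' p <- loadProteome(fa)
#' proteomeLength(p)
#' @export
loadProteome <- function(path, geneRegex = "GN=([^[:space:]]+)",
                         geneMap = NULL) {
  if (!file.exists(path))
    stop(sprintf("proteome FASTA not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    stop(sprintf("empty FASTA: %s", path))
  headers <- names(aa)
  acc <- sub("[[:space:]].*$", "", headers)
  if (any(acc == ""))
    stop("FASTA header without an accession token")
  if (anyDuplicated(acc))
    stop(sprintf("duplicated accession(s) in FASTA: %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  # alphabet check, naming the record
  seqs <- as.character(aa)
  for (i in seq_along(seqs)) {
    res <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(res, AA_PROTEOME)
    if (length(bad))
      stop(sprintf("record %s contains invalid character(s): %s",
                   acc[i], paste(bad, collapse = ", ")))
    if (nchar(seqs[[i]]) == 0L)
      stop(sprintf("record %s has an empty sequence", acc[i]))
  }
  gene <- rep(NA_character_, length(aa))
  hit <- regexpr(geneRegex, headers, perl = TRUE)
  has <- hit != -1L
  if (any(has))
    gene[has] <- sub(paste0(".*?", geneRegex, ".*"), "\\1",
                     headers[has], perl = TRUE)
  if (!is.null(geneMap)) {
    gm <- read.delim(geneMap, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("accession", "gene") %in% colnames(gm)))
      stop("gene map sidecar needs columns 'accession' and 'gene'")
    idx <- match(acc, gm$accession)
    gene[!is.na(idx)] <- gm$gene[idx[!is.na(idx)]]
  }
  names(aa) <- acc
  new("Proteome", aa = aa, gene = gene, description = desc)
}

#' Find all natural epitopes of a query peptide
#'
#' Scans every length-l window of every protein and returns those within
#' \code{K} mismatches (Hamming distance; insertions/deletions are not
#' considered) of the query, each exactly once, with its mismatch count k,
#' source accession, gene symbol and 0-based start offset. \code{X} in a
#' proteome window always counts as a mismatch.
#'
#' The scan is a vectorised byte-comparison over all window offsets; it
#' satisfies (and is property-tested against) a naive per-window
#' Hamming-distance oracle.
#'
#' @param query peptide of 7-25 standard residues.
#' @param proteome a [Proteome-class].
#' @param K maximal mismatch count, \code{0 <= K <= nchar(query)}.
#' @return a [NaturalEpitopeSet-class], ordered by (accession, start).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 GN=G1", "MAKVAELVHFLQQ"), fa)
#' findNaturalEpitopes("KVAELVHFL", loadProteome(fa), K = 0)
#' @export
findNaturalEpitopes <- function(query, proteome, K = 2L) {
  checkQueryPeptide(query)
  stopifnot(is(proteome, "Proteome"))
  l <- nchar(query)
  K <- as.integer(K)
  if (K < 0L || K > l)
    stop(sprintf("K must lie in [0, %d]", l))
  qraw <- charToRaw(query)
  seqs <- as.character(proteome@aa)
  genes <- proteome@gene
  accs <- names(proteome@aa)

  out <- vector("list", length(seqs))
  for (p in seq_along(seqs)) {
    sraw <- charToRaw(seqs[[p]])
    n <- length(sraw)
    if (n < l) next
    nw <- n - l + 1L
    mism <- integer(nw)
    idx <- seq_len(nw)
    for (j in seq_len(l))
      mism <- mism + (sraw[idx + (j - 1L)] != qraw[j])
    keep <- which(mism <= K)
    if (!length(keep)) next
    out[[p]] <- data.frame(
      ne_sequence = substring(seqs[[p]], keep, keep + l - 1L),
      k = as.integer(mism[keep]),
      accession = accs[p],
      gene = genes[p],
      start = keep - 1L,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(ne_sequence = character(), k = integer(),
                       accession = character(), gene = character(),
                       start = integer(), stringsAsFactors = FALSE)
  new("NaturalEpitopeSet", query = query, hits = DataFrame(hits))
}

#' Keep unique natural epitopes
#'
#' Collapses NEs to at most one per (sequence, gene) pair so that isoforms
#' of one gene do not double-count their abundance; when the gene symbol is
#' unknown the accession takes its place, so hits in distinct genes are
#' always retained. The retained representative is the first by
#' (accession, start); output is sorted by (k, accession, start).
#'
#' @param nes a [NaturalEpitopeSet-class].
#' @return a deduplicated, sorted [NaturalEpitopeSet-class].
#' @export
deduplicateNEs <- function(nes) {
  stopifnot(is(nes, "NaturalEpitopeSet"))
  h <- as.data.frame(nes@hits)
  if (nrow(h)) {
    entity <- ifelse(is.na(h$gene), h$accession, h$gene)
    h <- h[order(h$accession, h$start), , drop = FALSE]
    h <- h[!duplicated(paste(h$ne_sequence, entity, sep = "\r")), ,
           drop = FALSE]
    h <- h[order(h$k, h$accession, h$start), , drop = FALSE]
    rownames(h) <- NULL
  }
  new("NaturalEpitopeSet", query = nes@query, hits = DataFrame(h))
}

#' Export a natural-epitope table as TSV
#'
#' Writes one row per NE with both 0-based half-open and 1-based inclusive
#' coordinates; presentation-score columns are included when present.
#'
#' @param nes a [NaturalEpitopeSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeNETable <- function(nes, path) {
  stopifnot(is(nes, "NaturalEpitopeSet"))
  h <- as.data.frame(nes@hits)
  l <- nchar(nes@query)
  df <- data.frame(query = rep(nes@query, nrow(h)),
                   ne_sequence = h$ne_sequence, k = h$k,
                   accession = h$accession, gene = h$gene,
                   start0 = h$start, end0 = h$start + l,
                   start1 = h$start + 1L, end1 = h$start + l,
                   stringsAsFactors = FALSE)
  for (col in c("p_cl", "a_tap", "a_mhc", "q"))
    if (col %in% colnames(h)) df[[col]] <- formatNum(h[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
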