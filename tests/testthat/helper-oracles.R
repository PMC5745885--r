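# Independent oracles and small builders used across the test files.
# These deliberately re-derive results with naive per-window / per-cell
# arithmetic so the package implementations are checked against a second,
# simpler route.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

writeFasta <- function(seqs, path, genes = NULL) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    gn <- if (!is.null(genes) && !is.na(genes[i]))
      paste0(" GN=", genes[i]) else ""
    lines <- c(lines, paste0(">", names(seqs)[i], gn), seqs[[i]])
  }
  writeLines(lines, path)
  path
}

randomPeptide <- function(l) paste(sample(AA, l, replace = TRUE),
                                   collapse = "")

# Mutate exactly k distinct positions of a peptide (independent of the
# package's generator).
mutateAt <- function(pep, k) {
  r <- strsplit(pep, "")[[1]]
  for (p in sample(seq_along(r), k))
    r[p] <- sample(setdiff(AA, r[p]), 1)
  paste(r, collapse = "")
}

# Naive O(N*l) sliding-window Hamming scan over a Proteome.
bruteForceNEs <- function(query, proteome, K) {
  l <- nchar(query)
  qraw <- charToRaw(query)
  seqs <- as.character(proteinSequences(proteome))
  genes <- geneSymbols(proteome)
  rows <- list()
  for (acc in names(seqs)) {
    s <- seqs[[acc]]
    if (nchar(s) < l) next
    for (st in seq_len(nchar(s) - l + 1)) {
      win <- substr(s, st, st + l - 1)
      k <- sum(charToRaw(win) != qraw)
      if (k <= K)
        rows[[length(rows) + 1L]] <- data.frame(
          ne_sequence = win, k = as.integer(k), accession = acc,
          gene = unname(genes[acc]), start = st - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(ne_sequence = character(), k = integer(),
                      accession = character(), gene = character(),
                      start = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df[order(df$accession, df$start), , drop = FALSE]
}

# Build a NaturalEpitopeSet directly (rows must be Hamming-consistent).
makeNESet <- function(query, df) {
  methods::new("NaturalEpitopeSet", query = query,
               hits = S4Vectors::DataFrame(df))
}

# All-zero scoring matrix of a given kind.
zeroMatrix <- function(kind, nr, intercept = 0) {
  m <- matrix(0, nrow = nr, ncol = 20, dimnames = list(NULL, AA))
  scoringMatrix(kind, m, intercept)
}

randomMatrix <- function(kind, nr, intercept = 0, sd = 0.5) {
  m <- matrix(rnorm(nr * 20, 0, sd), nrow = nr,
              dimnames = list(NULL, AA))
  scoringMatrix(kind, m, intercept)
}

# Permissive scorers: everything cleaves (P_CL ~ 1) and binds strongly,
# so Q passes the default thresholds for every peptide.
permissiveMatrices <- function(l = 9L) {
  list(cleavage = zeroMatrix("cleavage", 12L, intercept = 8),
       tap = zeroMatrix("tap", 4L, intercept = -1),
       mhc = zeroMatrix("mhc", l, intercept = -1))
}

# Tissue weight scheme from a literal named vector, via the YAML loader.
makeScheme <- function(weights, defaultWeight = 0.5) {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(sprintf("%s: %.17g", names(weights), weights),
               sprintf("default_weight: %.17g", defaultWeight)), f)
  loadTissueWeights(f)
}

# Expression table from a literal matrix.
makeTable <- function(m, databaseId = "db1", unit = "ppm") {
  expressionTable(m, databaseId, unit)
}

# A proteome guaranteed to contain no window within K mismatches of
# queries made of W/Y (it is all alanine).
blankProteome <- function() {
  fa <- tempfile(fileext = ".fasta")
  writeFasta(c(P1 = strrep("A", 60)), fa, genes = "G1")
  loadProteome(fa)
}
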