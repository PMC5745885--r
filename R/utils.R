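# Internal helpers shared across modules.

# Hamming distance between equal-length strings.
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("Hamming distance requires equal-length strings")
  sum(charToRaw(a) != charToRaw(b))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Validate a query peptide: 7-25 residues over the 20 standard amino acids.
checkQueryPeptide <- function(query) {
  if (!is.character(query) || length(query) != 1L || is.na(query))
    stop("query must be a single peptide string")
  l <- nchar(query)
  if (l < 7L || l > 25L)
    stop(sprintf("query peptide must be 7-25 residues long, got %d", l))
  res <- strsplit(query, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, AA20)
  if (length(bad))
    stop(sprintf("query contains non-standard residue(s): %s",
                 paste(unique(bad), collapse = ", ")))
  invisible(query)
}

# Stable scientific-ish formatting for TSV output (deterministic bytes).
formatNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
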