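#' Proteome: a set of protein sequences searched for natural epitopes
#'
#' Thin wrapper around a [Biostrings::AAStringSet] holding one entry per
#' protein record (accession as name) together with an optional gene symbol
#' per record. The total residue count N of the proteome enters the
#' mismatch-probability model P(k) (see [mismatchProbability()]).
#'
#' @slot aa AAStringSet of protein sequences, names are unique accessions.
#' @slot gene character vector parallel to \code{aa}; NA when no gene symbol
#'   is known. Used to map natural epitopes to expression-table entities.
#' @slot description character vector of FASTA description lines.
#' @export
setClass("Proteome",
  representation(aa = "AAStringSet", gene = "character",
                 description = "character"))

setValidity("Proteome", function(object) {
  msg <- character()
  n <- length(object@aa)
  if (n == 0L)
    msg <- c(msg, "proteome contains no records")
  nm <- names(object@aa)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all records must be named by accession")
  else if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicated accession(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(object@gene) != n || length(object@description) != n)
    msg <- c(msg, "gene and description must be parallel to the sequences")
  if (n > 0L && any(Biostrings::width(object@aa) == 0L))
    msg <- c(msg, "empty sequence(s) present")
  if (length(msg)) msg else TRUE
})

#' NaturalEpitopeSet: proteome segments matching a query within k mismatches
#'
#' Holds, for one query peptide, every proteome window at Hamming distance
#' at most K, with provenance (accession, gene, 0-based start offset) and,
#' after [scoreNaturalEpitopes()], the presentation scores P_CL, A_TAP,
#' A_MHC and Q.
#'
#' @slot query the query peptide (7-25 standard residues).
#' @slot hits a [S4Vectors::DataFrame] with columns \code{ne_sequence},
#'   \code{k}, \code{accession}, \code{gene}, \code{start} (0-based,
#'   half-open) and optionally \code{p_cl}, \code{a_tap}, \code{a_mhc},
#'   \code{q}.
#' @export
setClass("NaturalEpitopeSet",
  representation(query = "character", hits = "DataFrame"))

setValidity("NaturalEpitopeSet", function(object) {
  msg <- character()
  if (length(object@query) != 1L || is.na(object@query))
    msg <- c(msg, "query must be a single peptide string")
  need <- c("ne_sequence", "k", "accession", "gene", "start")
  miss <- setdiff(need, colnames(object@hits))
  if (length(miss))
    return(paste("missing hit column(s):", paste(miss, collapse = ", ")))
  h <- object@hits
  if (nrow(h)) {
    l <- nchar(object@query)
    if (any(nchar(h$ne_sequence) != l))
      msg <- c(msg, "every NE must have the query's length")
    if (any(h$k < 0L) || any(h$k > l))
      msg <- c(msg, "mismatch counts must lie in [0, query length]")
    hd <- mapply(hammingDistance, h$ne_sequence,
                 MoreArgs = list(b = object@query), USE.NAMES = FALSE)
    if (any(hd != h$k))
      msg <- c(msg, "stored k must equal the Hamming distance to the query")
    if (any(h$start < 0L))
      msg <- c(msg, "start offsets are 0-based and must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' ScoringMatrix: log-additive position-specific scorer
#'
#' Position x residue weight table plus an intercept, standing behind the
#' three presentation predictors: proteasomal cleavage (logistic output in
#' [0,1]), TAP transport and MHC binding (both log10 IC50-like affinities,
#' lower = stronger). See [cleavageProbability()], [tapAffinity()],
#' [mhcAffinity()].
#'
#' @slot kind one of \code{"cleavage"}, \code{"tap"}, \code{"mhc"}.
#' @slot weights numeric matrix, rows = positions, columns = the 20 standard
#'   residues. Cleavage matrices have an even number of rows (a window
#'   centred on the cleaved bond); TAP matrices have 4 rows (3 N-terminal
#'   positions + the C-terminal residue); MHC matrices have one row per
#'   residue of the supported peptide length.
#' @slot intercept scalar offset on the logit / log10 scale.
#' @export
setClass("ScoringMatrix",
  representation(kind = "character", weights = "matrix",
                 intercept = "numeric"))

setValidity("ScoringMatrix", function(object) {
  msg <- character()
  if (!object@kind %in% c("cleavage", "tap", "mhc"))
    msg <- c(msg, "kind must be 'cleavage', 'tap' or 'mhc'")
  w <- object@weights
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
    msg <- c(msg, "weights must be finite numeric")
  if (!identical(sort(colnames(w)), sort(AA20)))
    msg <- c(msg, "weights must cover exactly the 20 standard residues")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (object@kind == "cleavage" && nrow(w) %% 2L != 0L)
    msg <- c(msg, "cleavage matrices need an even number of positions")
  if (object@kind == "tap" && nrow(w) != 4L)
    msg <- c(msg, "TAP matrices have 4 rows (3 N-terminal + C-terminal)")
  if (length(msg)) msg else TRUE
})

#' ExpressionTable: tissues x entities abundance matrix from one database
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: rows are entities
#' (gene symbols or protein accessions), columns are tissues, the single
#' assay \code{"abundance"} holds non-negative abundance values in the
#' declared unit (\code{ppm} protein abundance, \code{fpkm} transcript
#' expression, or ordinal \code{ihc_score} 0-3 immunohistochemistry levels).
#'
#' @slot databaseId short identifier of the source database (e.g. "Pax4").
#' @slot unit one of \code{"ppm"}, \code{"fpkm"}, \code{"ihc_score"}.
#' @export
setClass("ExpressionTable",
  contains = "SummarizedExperiment",
  representation(databaseId = "character", unit = "character"))

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (length(object@unit) != 1L ||
      !object@unit %in% c("ppm", "fpkm", "ihc_score"))
    msg <- c(msg, "unit must be 'ppm', 'fpkm' or 'ihc_score'")
  if (length(object@databaseId) != 1L || !nzchar(object@databaseId))
    msg <- c(msg, "databaseId must be a non-empty string")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (anyNA(a) || any(a < 0))
    msg <- c(msg, "abundances must be non-negative and non-missing")
  if (identical(object@unit, "ihc_score") && length(a) &&
      !all(a %in% 0:3))
    msg <- c(msg, "ihc_score values must lie in {0, 1, 2, 3}")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate entity rows")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate tissue columns after normalization")
  if (length(msg)) msg else TRUE
})

#' TissueWeightScheme: importance weight per tissue type
#'
#' Maps canonical tissue names to weights in [0,1]; the shipped default
#' follows an organ-failure-severity hierarchy: 1 for tissues whose damage
#' is immediately life threatening (lung/respiratory, brain/nervous,
#' blood/immune, heart, liver), 0.8 / 0.5 / 0.3 for decreasing severity and
#' 0 for immunologically irrelevant or non-healthy samples (testis, fetal
#' tissue, cancer cell lines, ...). Tissues absent from the scheme get
#' \code{defaultWeight}.
#'
#' @slot weights named numeric vector, values in [0,1].
#' @slot defaultWeight weight applied to unlisted tissues (default 0.5).
#' @export
setClass("TissueWeightScheme",
  representation(weights = "numeric", defaultWeight = "numeric"))

setValidity("TissueWeightScheme", function(object) {
  msg <- character()
  w <- object@weights
  if (is.null(names(w)) || anyNA(names(w)) || anyDuplicated(names(w)))
    msg <- c(msg, "weights must be uniquely named by tissue")
  if (anyNA(w) || any(w < 0) || any(w > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  dw <- object@defaultWeight
  if (length(dw) != 1L || is.na(dw) || dw < 0 || dw > 1)
    msg <- c(msg, "defaultWeight must be a scalar in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MismatchModel: random-match probabilities and normalized mismatch weights
#'
#' For a query of length l searched with up to K mismatches in a proteome of
#' N residues, P(k) is the probability that a random peptide occurs with k
#' mismatches somewhere in the proteome,
#' \deqn{P(k) = 1 - (1 - 0.05^{l-k})^{N-l+1},}
#' and the normalized mismatch weight is \eqn{v(k) = (1/P(k)) / \sum_k 1/P(k)}.
#' Rarer (lower-k) matches get larger weight in the tissue profile.
#'
#' @slot l query length.
#' @slot K maximal mismatch count.
#' @slot N proteome length in residues.
#' @slot pMatch per-position random match probability (1/20 by default).
#' @slot P numeric vector P(0..K).
#' @slot v numeric vector v(0..K), summing to 1.
#' @export
setClass("MismatchModel",
  representation(l = "integer", K = "integer", N = "numeric",
                 pMatch = "numeric", P = "numeric", v = "numeric"))

setValidity("MismatchModel", function(object) {
  msg <- character()
  if (object@N < object@l)
    msg <- c(msg, "proteome length N must be at least the query length")
  if (length(object@P) != object@K + 1L || length(object@v) != object@K + 1L)
    msg <- c(msg, "P and v must have K + 1 entries")
  if (any(object@P <= 0) || any(object@P > 1))
    msg <- c(msg, "P(k) must lie in (0, 1]")
  if (abs(sum(object@v) - 1) > 1e-12)
    msg <- c(msg, "mismatch weights must sum to 1")
  if (object@K > 0L && any(diff(object@v) >= 0))
    msg <- c(msg, "v(k) must be strictly decreasing in k")
  if (length(msg)) msg else TRUE
})

#' CRResult: tissue profiles and cross-reactivity indices for one query
#'
#' Per abundance database: the tissue profile S(t), the tissue-weighted
#' index I_CR and its bootstrap standard deviation; plus the arithmetic
#' mean of I_CR over databases and the run parameters.
#'
#' @slot query the query peptide.
#' @slot perDatabase named list (by database id); each element a list with
#'   components \code{S} (named numeric tissue profile), \code{I_CR}
#'   (scalar) and \code{error} (bootstrap standard deviation).
#' @slot averagedICR arithmetic mean of the per-database I_CR values.
#' @slot parameters list of run parameters (K, qThreshold,
#'   cleavageThreshold, tapWeight, seed, ...).
#' @export
setClass("CRResult",
  representation(query = "character", perDatabase = "list",
                 averagedICR = "numeric", parameters = "list"))

setValidity("CRResult", function(object) {
  msg <- character()
  if (!length(object@perDatabase))
    msg <- c(msg, "at least one database result is required")
  if (is.null(names(object@perDatabase)))
    msg <- c(msg, "perDatabase must be named by database id")
  ok <- vapply(object@perDatabase, function(d)
    is.list(d) && all(c("S", "I_CR", "error") %in% names(d)), logical(1))
  if (!all(ok))
    return("each database entry needs components S, I_CR and error")
  icr <- vapply(object@perDatabase, function(d) d$I_CR, numeric(1))
  if (abs(object@averagedICR - mean(icr)) > 1e-12 * max(1, abs(mean(icr))))
    msg <- c(msg, "averagedICR must equal the mean of per-database I_CR")
  if (length(msg)) msg else TRUE
})
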