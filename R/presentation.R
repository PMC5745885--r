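#' Construct a scoring matrix
#'
#' Log-additive position-specific scoring matrices stand behind the three
#' steps of the MHC class I presentation pathway: proteasomal cleavage,
#' TAP transport and MHC binding. They share one file format and one S4
#' class; the \code{kind} tag selects the evaluation rule (see
#' [cleavageProbability()], [tapAffinity()], [mhcAffinity()]). Users of
#' external neural-network predictors can bypass matrices entirely via
#' [loadPrecomputedScores()].
#'
#' @param kind "cleavage", "tap" or "mhc".
#' @param weights numeric matrix, rows = positions, columns named by the 20
#'   standard residues.
#' @param intercept scalar offset (logit scale for cleavage, log10 nM for
#'   affinities).
#' @return a [ScoringMatrix-class].
#' @export
scoringMatrix <- function(kind, weights, intercept = 0) {
  weights <- as.matrix(weights)
  weights <- weights[, AA20, drop = FALSE]  # canonical residue order
  new("ScoringMatrix", kind = kind, weights = weights,
      intercept = as.numeric(intercept))
}

#' Read / write scoring matrices as TSV
#'
#' Format: tab-separated, header \code{pos} followed by the 20 residue
#' letters; one row per position (labelled 1..L) plus a final row labelled
#' \code{intercept} whose value is repeated across the residue columns
#' (the first column is read back).
#'
#' @param path TSV file.
#' @param kind matrix kind tag ("cleavage", "tap", "mhc").
#' @return [ScoringMatrix-class] for the reader; the path (invisibly) for
#'   the writer.
#' @export
readScoringMatrix <- function(path, kind) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1] != "pos" || !all(AA20 %in% colnames(df)))
    stop(sprintf("malformed scoring matrix %s: need columns pos + 20 residues",
                 path))
  ir <- which(df$pos == "intercept")
  if (length(ir) != 1L)
    stop(sprintf("scoring matrix %s needs exactly one intercept row", path))
  intercept <- as.numeric(df[ir, AA20[1]])
  w <- as.matrix(df[-ir, AA20, drop = FALSE])
  storage.mode(w) <- "double"
  rownames(w) <- NULL
  scoringMatrix(kind, w, intercept)
}

#' @rdname readScoringMatrix
#' @param m a [ScoringMatrix-class] to serialize.
#' @export
writeScoringMatrix <- function(m, path) {
  stopifnot(is(m, "ScoringMatrix"))
  w <- m@weights
  df <- data.frame(pos = c(seq_len(nrow(w)), "intercept"),
                   stringsAsFactors = FALSE)
  for (a in AA20)
    df[[a]] <- formatNum(c(w[, a], m@intercept))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sum position weights for a residue string; positions outside the matrix or
# non-scoring symbols (padding) contribute 0.
.matrixScore <- function(m, residues) {
  s <- 0
  for (i in seq_along(residues)) {
    r <- residues[i]
    if (i <= nrow(m@weights) && r %in% colnames(m@weights))
      s <- s + m@weights[i, r]
  }
  as.numeric(s)
}

#' Proteasomal cleavage probability at the NE's C-terminal bond
#'
#' Scores a window centred on the bond after the last residue of the
#' peptide: the upstream half of the window covers the peptide's C-terminal
#' residues (reaching into \code{flankBefore} if the peptide is shorter than
#' the half-window), the downstream half covers \code{flankAfter}. Window
#' positions with no residue available are padded neutrally (score 0). The
#' result is \code{plogis(intercept + sum of position weights)}, a
#' probability in [0, 1].
#'
#' @param peptide the NE sequence.
#' @param matrix a cleavage [ScoringMatrix-class] with an even number of
#'   rows 2h (h positions each side of the bond).
#' @param flankBefore,flankAfter up to 6 protein residues on each side of
#'   the NE, used as cleavage context.
#' @return cleavage probability in [0, 1].
#' @export
cleavageProbability <- function(peptide, matrix, flankBefore = "",
                                flankAfter = "") {
  stopifnot(is(matrix, "ScoringMatrix"))
  if (matrix@kind != "cleavage")
    stop("matrix kind must be 'cleavage'")
  half <- nrow(matrix@weights) %/% 2L
  ctx <- paste0(flankBefore, peptide, flankAfter)
  bond <- nchar(flankBefore) + nchar(peptide)  # bond after this position
  pos <- (bond - half + 1L):(bond + half)      # window in context coords
  res <- rep(".", length(pos))                 # "." = neutral padding
  ok <- pos >= 1L & pos <= nchar(ctx)
  res[ok] <- substring(ctx, pos[ok], pos[ok])
  unname(plogis(matrix@intercept + .matrixScore(matrix, res)))
}

#' TAP transport affinity of a peptide
#'
#' Consensus-style TAP score: the C-terminal residue dominates, the three
#' N-terminal residues contribute scaled by \code{tapWeight}:
#' \deqn{\log_{10} A_{TAP} = b + W[4, c] + tapWeight \sum_{i=1}^{3} W[i, p_i]}
#' Lower affinity values mean stronger predicted transport.
#'
#' @param peptide the NE sequence (>= 4 residues).
#' @param matrix a TAP [ScoringMatrix-class] (4 rows: N-terminal positions
#'   1-3 and the C-terminal residue).
#' @param tapWeight weight on the N-terminal contribution (default 0.2).
#' @return positive IC50-like affinity (nominal nM).
#' @export
tapAffinity <- function(peptide, matrix, tapWeight = 0.2) {
  stopifnot(is(matrix, "ScoringMatrix"))
  if (matrix@kind != "tap")
    stop("matrix kind must be 'tap'")
  if (tapWeight < 0)
    stop("tapWeight must be >= 0")
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (length(res) < 4L)
    stop("peptide too short for TAP scoring")
  w <- matrix@weights
  nterm <- sum(vapply(1:3, function(i)
    if (res[i] %in% colnames(w)) w[i, res[i]] else 0, numeric(1)))
  cres <- res[length(res)]
  cterm <- if (cres %in% colnames(w)) w[4L, cres] else 0
  unname(10^(matrix@intercept + cterm + tapWeight * nterm))
}

#' MHC class I binding affinity of a peptide
#'
#' Position-additive log-affinity over the whole peptide:
#' \eqn{\log_{10} A_{MHC} = b + \sum_i W[i, p_i]}. Matrices are provided per
#' supported peptide length; a length mismatch is an error.
#'
#' @param peptide the NE sequence.
#' @param matrix an MHC [ScoringMatrix-class] with \code{nchar(peptide)}
#'   rows.
#' @return positive IC50-like affinity (nominal nM); lower = stronger.
#' @export
mhcAffinity <- function(peptide, matrix) {
  stopifnot(is(matrix, "ScoringMatrix"))
  if (matrix@kind != "mhc")
    stop("matrix kind must be 'mhc'")
  if (nrow(matrix@weights) != nchar(peptide))
    stop(sprintf("no MHC matrix for peptide length %d (matrix covers %d)",
                 nchar(peptide), nrow(matrix@weights)))
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  unname(10^(matrix@intercept + .matrixScore(matrix, res)))
}

#' Combined presentation score Q
#'
#' \deqn{Q = P_{CL} / (A_{TAP} \cdot A_{MHC})} where \eqn{P_{CL}} is the
#' proteasomal cleavage probability and the A's are IC50-like affinities
#' (lower = stronger binding), so larger Q means the peptide is more likely
#' to be processed, transported and presented on MHC class I.
#'
#' @param pCl cleavage probability in [0, 1] (vectorized).
#' @param aTap,aMhc positive affinities (vectorized).
#' @return Q, same length as the inputs.
#' @examples
#' qScore(0.5, 50, 500)  # 2e-05
#' @export
qScore <- function(pCl, aTap, aMhc) {
  if (any(is.na(pCl)) || any(pCl < 0) || any(pCl > 1))
    stop("cleavage probability must lie in [0, 1]")
  if (any(is.na(aTap)) || any(aTap <= 0) || any(is.na(aMhc)) ||
      any(aMhc <= 0))
    stop("affinities must be positive")
  pCl / (aTap * aMhc)
}

#' Load precomputed presentation scores
#'
#' Ingests per-NE scores produced by external predictors. The TSV must have
#' columns \code{ne_sequence}, \code{p_cl}, \code{a_tap}, \code{a_mhc}; any
#' \code{q} column in the file is ignored and Q is always recomputed as
#' \code{p_cl / (a_tap * a_mhc)}.
#'
#' @param path TSV file.
#' @return data.frame with columns ne_sequence, p_cl, a_tap, a_mhc, q.
#' @export
loadPrecomputedScores <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("ne_sequence", "p_cl", "a_tap", "a_mhc")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("precomputed scores %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  for (col in c("p_cl", "a_tap", "a_mhc")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at data row %d", path, col, bad[1]))
    df[[col]] <- v
  }
  bad <- which(df$p_cl < 0 | df$p_cl > 1)
  if (length(bad))
    stop(sprintf("%s: p_cl outside [0,1] at data row %d", path, bad[1]))
  bad <- which(df$a_tap <= 0 | df$a_mhc <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive affinity at data row %d", path, bad[1]))
  data.frame(ne_sequence = df$ne_sequence, p_cl = df$p_cl,
             a_tap = df$a_tap, a_mhc = df$a_mhc,
             q = qScore(df$p_cl, df$a_tap, df$a_mhc),
             stringsAsFactors = FALSE)
}

#' Score every natural epitope of a set
#'
#' Attaches P_CL, A_TAP, A_MHC and Q to each NE, either by evaluating the
#' three scoring matrices (cleavage context — up to 6 flanking residues on
#' each side — is extracted from the source protein via the NE's
#' coordinates) or by joining a precomputed score table.
#'
#' @param nes a [NaturalEpitopeSet-class].
#' @param proteome the [Proteome-class] the NEs came from (needed for
#'   cleavage flanks when scoring with matrices).
#' @param matrices named list with elements \code{cleavage}, \code{tap} and
#'   \code{mhc} (a single [ScoringMatrix-class] or, for \code{mhc}, a list
#'   keyed by peptide length).
#' @param scores alternatively, a precomputed score table from
#'   [loadPrecomputedScores()]; every NE sequence must be covered.
#' @param tapWeight N-terminal TAP weight, default 0.2.
#' @return the input set with score columns p_cl, a_tap, a_mhc, q.
#' @export
scoreNaturalEpitopes <- function(nes, proteome = NULL, matrices = NULL,
                                 scores = NULL, tapWeight = 0.2) {
  stopifnot(is(nes, "NaturalEpitopeSet"))
  h <- as.data.frame(nes@hits)
  if (nrow(h) == 0L) {
    h$p_cl <- numeric(0); h$a_tap <- numeric(0)
    h$a_mhc <- numeric(0); h$q <- numeric(0)
    return(new("NaturalEpitopeSet", query = nes@query, hits = DataFrame(h)))
  }
  if (!is.null(scores)) {
    idx <- match(h$ne_sequence, scores$ne_sequence)
    if (anyNA(idx))
      stop(sprintf("no precomputed scores for NE(s): %s",
                   paste(unique(h$ne_sequence[is.na(idx)]), collapse = ", ")))
    h$p_cl <- scores$p_cl[idx]
    h$a_tap <- scores$a_tap[idx]
    h$a_mhc <- scores$a_mhc[idx]
  } else {
    if (is.null(matrices) ||
        !all(c("cleavage", "tap", "mhc") %in% names(matrices)))
      stop("matrices must list 'cleavage', 'tap' and 'mhc' scorers")
    stopifnot(is(proteome, "Proteome"))
    seqs <- as.character(proteome@aa)
    l <- nchar(nes@query)
    mhcFor <- function(len) {
      m <- matrices$mhc
      if (is(m, "ScoringMatrix")) return(m)
      mm <- m[[as.character(len)]]
      if (is.null(mm))
        stop(sprintf("no MHC matrix for peptide length %d", len))
      mm
    }
    pcl <- atap <- amhc <- numeric(nrow(h))
    for (i in seq_len(nrow(h))) {
      src <- seqs[[h$accession[i]]]
      s0 <- h$start[i]
      before <- substring(src, max(1L, s0 - 5L), s0)
      after <- substring(src, s0 + l + 1L,
                         min(nchar(src), s0 + l + 6L))
      pcl[i] <- cleavageProbability(h$ne_sequence[i], matrices$cleavage,
                                    flankBefore = before, flankAfter = after)
      atap[i] <- tapAffinity(h$ne_sequence[i], matrices$tap, tapWeight)
      amhc[i] <- mhcAffinity(h$ne_sequence[i], mhcFor(l))
    }
    h$p_cl <- pcl; h$a_tap <- atap; h$a_mhc <- amhc
  }
  h$q <- qScore(h$p_cl, h$a_tap, h$a_mhc)
  new("NaturalEpitopeSet", query = nes@query, hits = DataFrame(h))
}

#' Filter natural epitopes by presentation scores
#'
#' Keeps NEs whose combined score exceeds the Q threshold and whose
#' cleavage probability reaches the cleavage threshold:
#' \code{q > qThreshold & p_cl >= cleavageThreshold}. The defaults mirror
#' the web-form defaults (Q > 1e-4, P_CL >= 0.7).
#'
#' @param nes a scored [NaturalEpitopeSet-class].
#' @param qThreshold minimum combined presentation score (exclusive).
#' @param cleavageThreshold minimum cleavage probability (inclusive).
#' @return the filtered [NaturalEpitopeSet-class].
#' @export
filterNEs <- function(nes, qThreshold = 1e-4, cleavageThreshold = 0.7) {
  stopifnot(is(nes, "NaturalEpitopeSet"))
  if (qThreshold < 0 || cleavageThreshold < 0)
    stop("thresholds must be >= 0")
  h <- nes@hits
  if (!all(c("q", "p_cl") %in% colnames(h)))
    stop("NEs must be scored before filtering (see scoreNaturalEpitopes)")
  keep <- h$q > qThreshold & h$p_cl >= cleavageThreshold
  new("NaturalEpitopeSet", query = nes@query,
      hits = h[keep, , drop = FALSE])
}
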