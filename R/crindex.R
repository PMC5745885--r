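#' Probability of finding a random peptide with k mismatches in a proteome
#'
#' For a peptide of length \code{l} and a proteome of \code{N} residues,
#' each window position matches a random query position with probability
#' 0.05 (uniform 20-letter alphabet), so
#' \deqn{P(k) = 1 - (1 - 0.05^{l-k})^{N-l+1}.}
#' Evaluated stably via \code{expm1}/\code{log1p} since \eqn{0.05^{l-k}}
#' underflows quickly.
#'
#' @param l peptide length.
#' @param k mismatch count (vectorized), \code{0 <= k <= l}.
#' @param N proteome length in residues, \code{N >= l}.
#' @param pMatch per-position random match probability (default 0.05).
#' @return P(k), in (0, 1].
#' @examples
#' mismatchProbability(9, 0, 6.5e7)  # ~1.2694e-4
#' @export
mismatchProbability <- function(l, k, N, pMatch = 0.05) {
  if (N < l)
    stop("proteome length N must be at least the peptide length l")
  if (any(k < 0) || any(k > l))
    stop("k must lie in [0, l]")
  # P = 1 - (1 - p^(l-k))^(N-l+1), with p^(l-k) possibly ~1e-17
  -expm1((N - l + 1) * log1p(-pMatch^(l - k)))
}

#' Normalized mismatch weights v(k)
#'
#' \deqn{v(k) = (1/P(k)) / \sum_{k'=0}^{K} 1/P(k')} so that rare (low-k)
#' matches dominate the tissue profile; the weights sum to 1 and decrease
#' strictly in k. For a 9-mer against a proteome of 6.5e7 residues with
#' K = 3 the weights are approximately 0.95, 0.048, 0.0024, 0.0002.
#'
#' @inheritParams mismatchProbability
#' @param K maximal mismatch count.
#' @return numeric vector v(0..K), named "0".."K".
#' @export
mismatchWeights <- function(l, K, N, pMatch = 0.05) {
  P <- mismatchProbability(l, 0:K, N, pMatch)
  inv <- 1 / P
  setNames(inv / sum(inv), as.character(0:K))
}

#' Construct a MismatchModel
#'
#' Bundles l, K, N with the derived P(k) and v(k) vectors (see
#' [mismatchProbability()] and [mismatchWeights()]).
#'
#' @inheritParams mismatchWeights
#' @return a [MismatchModel-class].
#' @export
mismatchModel <- function(l, K, N, pMatch = 0.05) {
  P <- mismatchProbability(l, 0:K, N, pMatch)
  inv <- 1 / P
  new("MismatchModel", l = as.integer(l), K = as.integer(K),
      N = as.numeric(N), pMatch = pMatch, P = P, v = inv / sum(inv))
}

# Abundance aggregation convention for the tissue profile. The raw
# log10(sum) form is undefined at 0 and negative below 1 abundance unit;
# the default log10(1 + sum) is 0 at 0, non-negative, and asymptotically
# equal to the raw form. Both contribute 0 for an empty/zero sum. Kept in
# one place so the two conventions can be compared.
abundanceLog <- function(total, convention = c("offset1", "raw")) {
  convention <- match.arg(convention)
  if (total <= 0) return(0)
  if (convention == "offset1") log10(1 + total) else log10(total)
}

# Abundance matrix (NE x tissue) for a set of NEs against one table,
# gene-first / accession-fallback, missing entity = 0.
.abundanceMatrix <- function(h, table) {
  tissues <- colnames(table)
  m <- matrix(0, nrow = nrow(h), ncol = length(tissues),
              dimnames = list(NULL, tissues))
  for (i in seq_len(nrow(h)))
    for (t in tissues)
      m[i, t] <- abundanceOf(table, t, gene = h$gene[i],
                             accession = h$accession[i])
  m
}

#' Per-tissue cross-reactivity profile S(t)
#'
#' For each tissue t of the database,
#' \deqn{S(t) = \sum_{k=0}^{K} v(k) \log_{10}\!\left[1 + \sum_{i=1}^{M(k)}
#'   a(i,t)\right]} where the inner sum runs over the unique,
#' presentation-filtered NEs with mismatch count k and a(i,t) is the
#' abundance of the i-th NE's source entity in tissue t. An empty (or
#' all-zero) inner sum contributes 0. Aggregation iterates tissues and NEs
#' in sorted order so results are bit-reproducible.
#'
#' @param nes a deduplicated, filtered [NaturalEpitopeSet-class]; every
#'   \code{k} must be at most the model's K.
#' @param table an [ExpressionTable-class].
#' @param model a [MismatchModel-class].
#' @param convention abundance log convention, \code{"offset1"} (default,
#'   log10(1+x)) or \code{"raw"} (log10(x), 0 when the sum is 0).
#' @return named numeric vector S over the table's tissues (sorted names).
#' @export
tissueProfile <- function(nes, table, model,
                          convention = c("offset1", "raw")) {
  stopifnot(is(nes, "NaturalEpitopeSet"), is(table, "ExpressionTable"),
            is(model, "MismatchModel"))
  convention <- match.arg(convention)
  tissues <- sort(colnames(table))
  S <- setNames(numeric(length(tissues)), tissues)
  h <- as.data.frame(nes@hits)
  if (nrow(h) == 0L) return(S)
  if (any(h$k > model@K))
    stop("NE mismatch count exceeds the model's K")
  h <- h[order(h$k, h$accession, h$start), , drop = FALSE]
  a <- .abundanceMatrix(h, table)
  v <- model@v
  for (t in tissues) {
    s <- 0
    for (k in 0:model@K) {
      rows <- which(h$k == k)
      if (!length(rows)) next
      s <- s + v[k + 1L] * abundanceLog(sum(a[rows, t]), convention)
    }
    S[t] <- s
  }
  S
}

#' Tissue-weighted cross-reactivity index I_CR
#'
#' Weighted average of the tissue profile over the tissues present:
#' \deqn{I_{CR} = \frac{\sum_t w(t) S(t)}{\sum_t w(t)}} with w(t) from the
#' weight scheme (tissues missing from the scheme get its default weight).
#' Large values flag epitopes whose near-matches are abundantly presented
#' in vital tissues.
#'
#' @param S named numeric tissue profile (from [tissueProfile()]).
#' @param scheme a [TissueWeightScheme-class].
#' @return scalar I_CR.
#' @export
weightedCRIndex <- function(S, scheme) {
  if (!length(S) || is.null(names(S)))
    stop("S must be a named tissue profile")
  w <- weightOf(scheme, names(S), warn = FALSE)
  sw <- sum(w)
  if (sw == 0)
    stop("all tissue weights are zero; I_CR is undefined")
  sum(w * S) / sw
}

#' Bootstrap standard deviation of I_CR
#'
#' Recomputes the index \code{reps} times on random subsamples of
#' \code{floor(frac * n)} NEs (never fewer than 1, drawn without
#' replacement) and returns the standard deviation (n-1 denominator) of
#' the replicate indices. Deterministic for a fixed seed; an empty NE set
#' yields 0.
#'
#' @inheritParams tissueProfile
#' @param scheme a [TissueWeightScheme-class].
#' @param reps number of bootstrap replicates (default 10).
#' @param frac subsample fraction (default 0.9).
#' @param seed RNG seed.
#' @return scalar bootstrap standard deviation.
#' @export
bootstrapError <- function(nes, table, model, scheme, reps = 10L,
                           frac = 0.9, seed = 1L,
                           convention = c("offset1", "raw")) {
  stopifnot(is(nes, "NaturalEpitopeSet"))
  if (reps < 2L) stop("reps must be >= 2")
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  convention <- match.arg(convention)
  n <- length(nes)
  if (n == 0L) return(0)
  m <- max(1L, as.integer(floor(frac * n)))
  idxs <- withSeed(seed,
    lapply(seq_len(reps), function(r) sort(sample.int(n, m))))
  icr <- vapply(idxs, function(ii) {
    S <- tissueProfile(nes[ii], table, model, convention)
    weightedCRIndex(S, scheme)
  }, numeric(1))
  if (length(unique(icr)) == 1L) return(0)  # identical replicates
  sd(icr)
}

#' Average cross-reactivity indices over databases
#'
#' Unweighted arithmetic mean of the per-database I_CR values; the
#' per-database values are kept alongside in [CRResult-class].
#'
#' @param icr numeric vector of per-database indices.
#' @return scalar mean.
#' @export
averageOverDatabases <- function(icr) {
  if (!length(icr)) stop("no database results to average")
  mean(icr)
}

#' Compute a full CRResult across databases
#'
#' Runs [tissueProfile()], [weightedCRIndex()] and [bootstrapError()] for
#' each expression database and averages the indices.
#'
#' @inheritParams bootstrapError
#' @param tables named list of [ExpressionTable-class] objects (names
#'   default to their database ids).
#' @param parameters list of run parameters recorded in the result.
#' @return a [CRResult-class].
#' @export
computeCRResult <- function(nes, tables, model, scheme, reps = 10L,
                            frac = 0.9, seed = 1L,
                            convention = c("offset1", "raw"),
                            parameters = list()) {
  convention <- match.arg(convention)
  if (is(tables, "ExpressionTable")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, databaseId, character(1))
  per <- lapply(tables, function(tab) {
    S <- tissueProfile(nes, tab, model, convention)
    list(S = S,
         I_CR = weightedCRIndex(S, scheme),
         error = bootstrapError(nes, tab, model, scheme, reps = reps,
                                frac = frac, seed = seed,
                                convention = convention))
  })
  icr <- vapply(per, function(d) d$I_CR, numeric(1))
  new("CRResult", query = nes@query, perDatabase = per,
      averagedICR = averageOverDatabases(icr),
      parameters = c(parameters, list(reps = reps, frac = frac,
                                      seed = seed,
                                      convention = convention)))
}
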