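#' @export
setGeneric("proteomeLength", function(x) standardGeneric("proteomeLength"))

#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @export
setGeneric("proteinSequences",
           function(x) standardGeneric("proteinSequences"))

#' @export
setGeneric("queryPeptide", function(x) standardGeneric("queryPeptide"))

#' @export
setGeneric("neTable", function(x) standardGeneric("neTable"))

#' @export
setGeneric("databaseId", function(x) standardGeneric("databaseId"))

#' @export
setGeneric("abundanceUnit", function(x) standardGeneric("abundanceUnit"))

#' @export
setGeneric("tissueWeights", function(x) standardGeneric("tissueWeights"))

#' @export
setGeneric("defaultWeight", function(x) standardGeneric("defaultWeight"))

#' @export
setGeneric("mismatchProbabilities",
           function(x) standardGeneric("mismatchProbabilities"))

#' @export
setGeneric("normalizedWeights",
           function(x) standardGeneric("normalizedWeights"))

#' @export
setGeneric("crIndices", function(x) standardGeneric("crIndices"))

#' @export
setGeneric("averagedCRIndex", function(x) standardGeneric("averagedCRIndex"))

#' @export
setGeneric("tissueProfiles", function(x) standardGeneric("tissueProfiles"))

#' @export
setGeneric("crParameters", function(x) standardGeneric("crParameters"))

# ---- Proteome ---------------------------------------------------------------

#' @describeIn Proteome-class total residue count N over all records.
#' @param x a Proteome.
#' @export
setMethod("proteomeLength", "Proteome",
          function(x) sum(Biostrings::width(x@aa)))

#' @describeIn Proteome-class gene symbol per record (NA when unknown),
#'   named by accession.
#' @export
setMethod("geneSymbols", "Proteome",
          function(x) setNames(x@gene, names(x@aa)))

#' @describeIn Proteome-class the underlying AAStringSet.
#' @export
setMethod("proteinSequences", "Proteome", function(x) x@aa)

#' @describeIn Proteome-class number of protein records.
#' @export
setMethod("length", "Proteome", function(x) length(x@aa))

#' @describeIn Proteome-class record accessions.
#' @export
setMethod("names", "Proteome", function(x) names(x@aa))

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome with %d records, N = %d residues\n",
              length(object), proteomeLength(object)))
  ng <- sum(!is.na(object@gene))
  cat(sprintf("  gene symbols: %d/%d records\n", ng, length(object)))
})

# ---- NaturalEpitopeSet ------------------------------------------------------

#' @describeIn NaturalEpitopeSet-class the query peptide.
#' @param x a NaturalEpitopeSet.
#' @export
setMethod("queryPeptide", "NaturalEpitopeSet", function(x) x@query)

#' @describeIn NaturalEpitopeSet-class the hit DataFrame.
#' @export
setMethod("neTable", "NaturalEpitopeSet", function(x) x@hits)

#' @describeIn NaturalEpitopeSet-class number of natural epitopes.
#' @export
setMethod("length", "NaturalEpitopeSet", function(x) nrow(x@hits))

#' @describeIn NaturalEpitopeSet-class subset the hits, keeping the query.
#' @param i row index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "NaturalEpitopeSet", function(x, i, j, ..., drop = FALSE) {
  new("NaturalEpitopeSet", query = x@query, hits = x@hits[i, , drop = FALSE])
})

#' @export
#' @method as.data.frame NaturalEpitopeSet
as.data.frame.NaturalEpitopeSet <- function(x, ...) {
  df <- as.data.frame(x@hits)
  df <- cbind(query = rep(x@query, nrow(df)), df)
  rownames(df) <- NULL
  df
}

setMethod("show", "NaturalEpitopeSet", function(object) {
  cat(sprintf("NaturalEpitopeSet: %d hit(s) for query %s\n",
              length(object), object@query))
  if (length(object)) {
    tab <- table(factor(object@hits$k, levels = 0:max(object@hits$k)))
    cat("  by mismatch count:",
        paste(sprintf("k=%s: %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    cat(sprintf("  scored: %s\n",
                if ("q" %in% colnames(object@hits)) "yes" else "no"))
  }
})

# ---- ExpressionTable --------------------------------------------------------

#' @describeIn ExpressionTable-class source database identifier.
#' @param x an ExpressionTable.
#' @export
setMethod("databaseId", "ExpressionTable", function(x) x@databaseId)

#' @describeIn ExpressionTable-class abundance unit tag.
#' @export
setMethod("abundanceUnit", "ExpressionTable", function(x) x@unit)

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable %s [%s]: %d entities x %d tissues\n",
              object@databaseId, object@unit, nrow(object), ncol(object)))
  cat("  tissues:", paste(head(colnames(object), 5), collapse = ", "),
      if (ncol(object) > 5) "..." else "", "\n")
})

# ---- TissueWeightScheme -----------------------------------------------------

#' @describeIn TissueWeightScheme-class named weight vector.
#' @param x a TissueWeightScheme.
#' @export
setMethod("tissueWeights", "TissueWeightScheme", function(x) x@weights)

#' @describeIn TissueWeightScheme-class weight for tissues not in the scheme.
#' @export
setMethod("defaultWeight", "TissueWeightScheme", function(x) x@defaultWeight)

setMethod("show", "TissueWeightScheme", function(object) {
  cat(sprintf("TissueWeightScheme: %d tissues, default weight %.2f\n",
              length(object@weights), object@defaultWeight))
  for (w in sort(unique(object@weights), decreasing = TRUE)) {
    nm <- names(object@weights)[object@weights == w]
    cat(sprintf("  w=%.1f: %s\n", w, paste(nm, collapse = ", ")))
  }
})

# ---- MismatchModel ----------------------------------------------------------

#' @describeIn MismatchModel-class the vector P(0..K).
#' @param x a MismatchModel.
#' @export
setMethod("mismatchProbabilities", "MismatchModel", function(x) x@P)

#' @describeIn MismatchModel-class the normalized weights v(0..K).
#' @export
setMethod("normalizedWeights", "MismatchModel", function(x) x@v)

setMethod("show", "MismatchModel", function(object) {
  cat(sprintf("MismatchModel: l = %d, K = %d, N = %g\n",
              object@l, object@K, object@N))
  cat("  v(k):", paste(sprintf("%.4g", object@v), collapse = ", "), "\n")
})

# ---- CRResult ---------------------------------------------------------------

#' @describeIn CRResult-class named per-database I_CR vector.
#' @param x a CRResult.
#' @export
setMethod("crIndices", "CRResult", function(x)
  vapply(x@perDatabase, function(d) d$I_CR, numeric(1)))

#' @describeIn CRResult-class mean I_CR over databases.
#' @export
setMethod("averagedCRIndex", "CRResult", function(x) x@averagedICR)

#' @describeIn CRResult-class named list of per-database tissue profiles.
#' @export
setMethod("tissueProfiles", "CRResult", function(x)
  lapply(x@perDatabase, function(d) d$S))

#' @describeIn CRResult-class run parameter list.
#' @export
setMethod("crParameters", "CRResult", function(x) x@parameters)

setMethod("show", "CRResult", function(object) {
  cat(sprintf("CRResult for query %s\n", object@query))
  icr <- crIndices(object)
  err <- vapply(object@perDatabase, function(d) d$error, numeric(1))
  for (db in names(icr))
    cat(sprintf("  %-12s I_CR = %.4f +/- %.4f\n", db, icr[db], err[db]))
  cat(sprintf("  averaged I_CR = %.4f\n", object@averagedICR))
})
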