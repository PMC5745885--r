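#' Construct an ExpressionTable
#'
#' @param values numeric matrix, rows = entities (gene symbols or protein
#'   accessions), columns = tissues.
#' @param databaseId short source identifier (e.g. "Pax4", "E-Mtab-513").
#' @param unit "ppm", "fpkm" or "ihc_score".
#' @return an [ExpressionTable-class].
#' @export
expressionTable <- function(values, databaseId, unit) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(abundance = values))
  obj <- new("ExpressionTable", se, databaseId = databaseId, unit = unit)
  # one-warning-per-missing-entity bookkeeping for abundanceOf()
  metadata(obj)$warnedMissing <- new.env(parent = emptyenv())
  obj
}

#' Load a tissues x entities abundance table from TSV
#'
#' The file has a header row (first column the entity-id column, remaining
#' columns tissue names) and one row per entity. Tissue names are passed
#' through [normalizeTissue()] when a synonym map is supplied. Negative
#' values, duplicate entities and (for \code{ihc_score} tables) values
#' outside {0,1,2,3} are rejected.
#'
#' @param path TSV file.
#' @param databaseId source identifier.
#' @param unit "ppm", "fpkm" or "ihc_score".
#' @param synonyms optional named character vector mapping raw tissue labels
#'   to canonical names (see [loadSynonymMap()]).
#' @return an [ExpressionTable-class].
#' @export
loadExpressionTable <- function(path, databaseId, unit, synonyms = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("%s: need an entity column plus at least one tissue", path))
  entities <- as.character(df[[1]])
  if (anyDuplicated(entities))
    stop(sprintf("%s: duplicate entity row(s): %s", path,
                 paste(unique(entities[duplicated(entities)]),
                       collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop(sprintf("%s: non-numeric or missing abundance value", path))
  if (any(m < 0))
    stop(sprintf("%s: negative abundance value", path))
  rownames(m) <- entities
  tissues <- colnames(m)
  if (!is.null(synonyms))
    tissues <- normalizeTissue(tissues, synonyms)
  else
    tissues <- trimws(tolower(tissues))
  if (anyDuplicated(tissues))
    stop(sprintf("%s: tissue names collide after normalization: %s", path,
                 paste(unique(tissues[duplicated(tissues)]),
                       collapse = ", ")))
  colnames(m) <- tissues
  expressionTable(m, databaseId, unit)
}

#' Serialize an ExpressionTable as TSV (order-normalized)
#'
#' Entities are written in sorted order, tissues in stored order, so that
#' load -> write -> load -> write is byte-stable.
#'
#' @param x an [ExpressionTable-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  stopifnot(is(x, "ExpressionTable"))
  m <- assay(x, "abundance")
  m <- m[order(rownames(m)), , drop = FALSE]
  df <- data.frame(entity = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (t in colnames(m)) df[[t]] <- formatNum(m[, t])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize tissue labels
#'
#' Lowercases and trims each label and maps it through the synonym table.
#' Labels with no synonym entry pass through (lowercased/trimmed) unchanged,
#' with one warning listing them, so unknown vocabularies degrade loudly
#' rather than silently.
#'
#' @param name character vector of raw tissue labels.
#' @param synonyms named character vector raw -> canonical; keys are
#'   matched case-insensitively.
#' @return canonical tissue names, same length as \code{name}.
#' @export
normalizeTissue <- function(name, synonyms) {
  key <- trimws(tolower(name))
  names(synonyms) <- trimws(tolower(names(synonyms)))
  idx <- match(key, names(synonyms))
  out <- ifelse(is.na(idx), key, unname(synonyms[idx]))
  if (anyNA(idx)) {
    unmapped <- unique(key[is.na(idx)])
    warning(sprintf("tissue label(s) not in synonym map, passed through: %s",
                    paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Look up the abundance a(i,t) of a natural epitope's source entity
#'
#' Resolution order: gene symbol first, then accession; an entity absent
#' from the table yields abundance 0 (absence of evidence of expression is
#' treated as no expression) with one warning per entity per table.
#'
#' @param table an [ExpressionTable-class].
#' @param tissue tissue name (must be a column of the table).
#' @param gene gene symbol of the NE's source protein (NA if unknown).
#' @param accession source protein accession.
#' @return non-negative abundance in the table's unit.
#' @export
abundanceOf <- function(table, tissue, gene = NA_character_,
                        accession = NA_character_) {
  stopifnot(is(table, "ExpressionTable"))
  if (!tissue %in% colnames(table))
    stop(sprintf("unknown tissue '%s' in database %s", tissue,
                 table@databaseId))
  m <- assay(table, "abundance")
  entity <- if (!is.na(gene) && gene %in% rownames(m)) gene
            else if (!is.na(accession) && accession %in% rownames(m))
              accession
            else NA_character_
  if (is.na(entity)) {
    label <- if (!is.na(gene)) gene else accession
    warned <- metadata(table)$warnedMissing
    if (!is.null(warned) && is.null(warned[[as.character(label)]])) {
      warned[[as.character(label)]] <- TRUE
      warning(sprintf(
        "entity '%s' absent from database %s; abundance treated as 0",
        label, table@databaseId), call. = FALSE)
    }
    return(0)
  }
  m[entity, tissue]
}

#' Load a tissue synonym map from a key:value YAML config
#'
#' @param path YAML file mapping raw tissue labels to canonical names; when
#'   NULL the map shipped with the package is used.
#' @return named character vector raw -> canonical.
#' @export
loadSynonymMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_synonyms.yaml",
                        package = "epicross", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  setNames(vapply(y, as.character, character(1)), names(y))
}

#' Load a tissue weight scheme from a key:value YAML config
#'
#' The file maps canonical tissue names to weights in [0,1] (the shipped
#' default uses the canonical severity categories 1 / 0.8 / 0.5 / 0.3 / 0)
#' and may define \code{default_weight} for tissues not listed (shipped
#' default 0.5: unknown tissues land in the middle category rather than
#' being silently ignored).
#'
#' @param path YAML file; NULL for the shipped default scheme.
#' @return a [TissueWeightScheme-class].
#' @export
loadTissueWeights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_weights.yaml",
                        package = "epicross", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  dw <- 0.5
  if (!is.null(y$default_weight)) {
    dw <- as.numeric(y$default_weight)
    y$default_weight <- NULL
  }
  w <- vapply(y, as.numeric, numeric(1))
  new("TissueWeightScheme", weights = w, defaultWeight = dw)
}

#' @rdname loadTissueWeights
#' @export
defaultTissueWeights <- function() loadTissueWeights(NULL)

#' Resolve weights for a set of tissues
#'
#' @param scheme a [TissueWeightScheme-class].
#' @param tissues character vector of canonical tissue names.
#' @param warn warn once about tissues falling back to the default weight.
#' @return named numeric weight vector over \code{tissues}.
#' @export
weightOf <- function(scheme, tissues, warn = TRUE) {
  stopifnot(is(scheme, "TissueWeightScheme"))
  idx <- match(tissues, names(scheme@weights))
  w <- ifelse(is.na(idx), scheme@defaultWeight, scheme@weights[idx])
  if (warn && anyNA(idx))
    warning(sprintf("tissue(s) not in weight scheme, default %.2f used: %s",
                    scheme@defaultWeight,
                    paste(unique(tissues[is.na(idx)]), collapse = ", ")),
            call. = FALSE)
  setNames(w, tissues)
}
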