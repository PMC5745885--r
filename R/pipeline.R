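#' Default parameter sets
#'
#' \code{"web-default"} mirrors the interactive defaults: TAP weight 0.2,
#' cleavage threshold 0.7, Q threshold 1e-4, up to K = 2 mismatches.
#' \code{"study"} is the stricter setting used for group comparisons:
#' K = 1 with the same thresholds (use \code{qThreshold = 0.02} on top of
#' it to restrict to the top ~10% most immunogenic NEs).
#'
#' @param preset "web-default" or "study".
#' @return list with K, qThreshold, tapWeight, cleavageThreshold.
#' @export
crDefaults <- function(preset = c("web-default", "study")) {
  preset <- match.arg(preset)
  switch(preset,
    "web-default" = list(K = 2L, qThreshold = 1e-4, tapWeight = 0.2,
                         cleavageThreshold = 0.7),
    "study" = list(K = 1L, qThreshold = 1e-4, tapWeight = 0.2,
                   cleavageThreshold = 0.7))
}

#' Run a full cross-reactivity assessment for one query peptide
#'
#' Pipeline: find all natural epitopes within K mismatches, deduplicate per
#' (sequence, gene), attach presentation scores (matrices or precomputed),
#' filter by Q and cleavage thresholds, then compute per-database tissue
#' profiles, tissue-weighted indices with bootstrap errors, and the
#' cross-database average. Filter-stage counts (raw, unique, passing) are
#' recorded and logged for auditability.
#'
#' @param query peptide of 7-25 standard residues.
#' @param proteome a [Proteome-class].
#' @param tables named list of [ExpressionTable-class] objects.
#' @param matrices scorer list (see [scoreNaturalEpitopes()]); ignored when
#'   \code{scores} is given.
#' @param scores optional precomputed score table
#'   ([loadPrecomputedScores()]).
#' @param K,qThreshold,tapWeight,cleavageThreshold assessment parameters;
#'   defaults are the web-form defaults (see [crDefaults()]).
#' @param scheme a [TissueWeightScheme-class] (shipped default scheme when
#'   NULL).
#' @param reps,frac bootstrap replicates and subsample fraction.
#' @param seed RNG seed for the bootstrap.
#' @param convention abundance log convention (see [tissueProfile()]).
#' @param outDir optional directory: writes \code{nes.tsv},
#'   \code{profile_<db>.tsv}, \code{summary.tsv} and \code{run_meta.json};
#'   outputs are byte-identical for identical inputs and seed.
#' @param verbose log stage counts with [message()].
#' @return list with components \code{result} ([CRResult-class]),
#'   \code{nes} (the filtered [NaturalEpitopeSet-class]) and \code{counts}
#'   (raw / unique / passing).
#' @export
runAssessment <- function(query, proteome, tables, matrices = NULL,
                          scores = NULL, K = 2L, qThreshold = 1e-4,
                          tapWeight = 0.2, cleavageThreshold = 0.7,
                          scheme = NULL, reps = 10L, frac = 0.9,
                          seed = 1L, convention = "offset1",
                          outDir = NULL, verbose = TRUE) {
  checkQueryPeptide(query)
  if (qThreshold < 0 || cleavageThreshold < 0 || tapWeight < 0)
    stop("thresholds and tapWeight must be >= 0")
  if (is.null(scheme)) scheme <- defaultTissueWeights()
  if (is(tables, "ExpressionTable")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, databaseId, character(1))

  raw <- findNaturalEpitopes(query, proteome, K = K)
  uniq <- deduplicateNEs(raw)
  scored <- scoreNaturalEpitopes(uniq, proteome = proteome,
                                 matrices = matrices, scores = scores,
                                 tapWeight = tapWeight)
  passing <- filterNEs(scored, qThreshold = qThreshold,
                       cleavageThreshold = cleavageThreshold)
  counts <- c(raw = length(raw), unique = length(uniq),
              passing = length(passing))
  if (verbose)
    message(sprintf(
      "[%s] NEs: %d raw -> %d unique -> %d passing (Q > %g, P_CL >= %g)",
      query, counts["raw"], counts["unique"], counts["passing"],
      qThreshold, cleavageThreshold))

  model <- mismatchModel(nchar(query), K, proteomeLength(proteome))
  params <- list(query = query, K = as.integer(K), qThreshold = qThreshold,
                 tapWeight = tapWeight,
                 cleavageThreshold = cleavageThreshold,
                 N = proteomeLength(proteome))
  result <- computeCRResult(passing, tables, model, scheme, reps = reps,
                            frac = frac, seed = seed,
                            convention = convention, parameters = params)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeNETable(passing, file.path(outDir, "nes.tsv"))
    for (db in names(tables)) {
      S <- result@perDatabase[[db]]$S
      w <- weightOf(scheme, names(S), warn = FALSE)
      prof <- data.frame(tissue = names(S), S = formatNum(unname(S)),
                         weight = formatNum(unname(w)),
                         stringsAsFactors = FALSE)
      write.table(prof,
                  file.path(outDir, paste0("profile_",
                                           gsub("[^A-Za-z0-9_.-]", "_", db),
                                           ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    icr <- crIndices(result)
    err <- vapply(result@perDatabase, function(d) d$error, numeric(1))
    summ <- data.frame(database = names(icr),
                       I_CR = formatNum(unname(icr)),
                       bootstrap_error = formatNum(unname(err)),
                       averaged_I_CR = formatNum(result@averagedICR),
                       stringsAsFactors = FALSE)
    write.table(summ, file.path(outDir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    meta <- c(params, list(reps = reps, frac = frac, seed = seed,
                           convention = convention,
                           counts = as.list(counts),
                           databases = names(tables),
                           package_version =
                             as.character(packageVersion("epicross"))))
    jsonlite::write_json(meta, file.path(outDir, "run_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(result = result, nes = passing, counts = counts)
}

#' Assess a panel of peptides and summarise per group
#'
#' Runs [runAssessment()] for each peptide; invalid peptides are reported
#' and skipped without aborting the batch. With a \code{groups} vector the
#' summary gains per-group statistics of the averaged index (mean, median,
#' quartiles) — the box-plot numbers for group comparisons.
#'
#' @param peptides character vector, or a file path (one peptide per line,
#'   or FASTA if the first non-empty line starts with ">").
#' @param groups optional character vector parallel to the peptides.
#' @param ... arguments passed on to [runAssessment()] (proteome, tables,
#'   matrices/scores, thresholds, seed, ...).
#' @return list with \code{summary} (one row per attempted peptide:
#'   peptide, group, status, n_nes, I_CR, error) and \code{groupStats}
#'   (NULL without groups).
#' @export
batchAssessment <- function(peptides, groups = NULL, ...) {
  if (length(peptides) == 1L && file.exists(peptides))
    peptides <- readPeptideFile(peptides)
  if (!length(peptides))
    stop("no peptides to assess")
  if (!is.null(groups) && length(groups) != length(peptides))
    stop("groups must be parallel to peptides")
  rows <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    p <- peptides[i]
    r <- tryCatch(runAssessment(p, ...), error = function(e) e)
    if (inherits(r, "error")) {
      message(sprintf("skipping peptide %s: %s", p, conditionMessage(r)))
      rows[[i]] <- data.frame(peptide = p,
                              group = if (is.null(groups)) NA_character_
                                      else groups[i],
                              status = "skipped", n_nes = NA_integer_,
                              I_CR = NA_real_, error = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      err <- vapply(r$result@perDatabase, function(d) d$error, numeric(1))
      rows[[i]] <- data.frame(peptide = p,
                              group = if (is.null(groups)) NA_character_
                                      else groups[i],
                              status = "ok",
                              n_nes = unname(r$counts["passing"]),
                              I_CR = averagedCRIndex(r$result),
                              error = mean(err),
                              stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  groupStats <- NULL
  if (!is.null(groups)) {
    ok <- summary$status == "ok"
    groupStats <- do.call(rbind, lapply(split(summary$I_CR[ok],
                                              summary$group[ok]),
      function(x) data.frame(n = length(x), mean = mean(x),
                             median = median(x),
                             q25 = unname(quantile(x, 0.25)),
                             q75 = unname(quantile(x, 0.75)))))
    groupStats <- cbind(group = rownames(groupStats), groupStats)
    rownames(groupStats) <- NULL
  }
  list(summary = summary, groupStats = groupStats)
}

#' Read peptides from a plain list or FASTA file
#'
#' @param path one peptide per line, or FASTA.
#' @return character vector of peptides.
#' @export
readPeptideFile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop(sprintf("empty peptide file: %s", path))
  if (startsWith(lines[1], ">")) {
    aa <- Biostrings::readAAStringSet(path)
    as.character(aa)
  } else {
    lines
  }
}
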