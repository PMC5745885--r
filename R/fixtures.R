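#' Specification for a synthetic fixture bundle
#'
#' Describes a seeded, fully reproducible test universe: a random proteome
#' with planted near-matches of chosen query peptides, abundance tables in
#' the three unit conventions with planted gene/tissue abundances, and
#' scoring matrices optionally biased so a named peptide crosses the
#' default presentation filters. Background residues are uniform over the
#' 20 standard amino acids, matching the 0.05 per-position match
#' probability assumed by [mismatchProbability()].
#'
#' @param seed integer master seed; every emitted byte is a function of it.
#' @param nProteins number of background proteins.
#' @param proteinLength residues per protein.
#' @param planted data.frame with columns \code{query}, \code{k},
#'   \code{tissue}, \code{abundance}, \code{gene}: each query is embedded
#'   once at exactly Hamming distance \code{k}, its host protein is
#'   assigned \code{gene}, and that gene receives \code{abundance} in
#'   \code{tissue} in every generated table.
#' @param databases data.frame with columns \code{database_id}, \code{unit}
#'   (ppm / fpkm / ihc_score) and \code{n_tissues}.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(seed, nProteins = 50L, proteinLength = 200L,
                        planted = NULL, databases = NULL) {
  if (is.null(planted))
    planted <- data.frame(query = character(), k = integer(),
                          tissue = character(), abundance = numeric(),
                          gene = character(), stringsAsFactors = FALSE)
  if (is.null(databases))
    databases <- data.frame(
      database_id = c("Pax4", "E-Mtab-513", "HPA"),
      unit = c("ppm", "fpkm", "ihc_score"),
      n_tissues = c(8L, 8L, 8L), stringsAsFactors = FALSE)
  stopifnot(all(c("query", "k", "tissue", "abundance", "gene") %in%
                  colnames(planted)),
            all(c("database_id", "unit", "n_tissues") %in%
                  colnames(databases)))
  if (nrow(planted)) {
    if (any(planted$k > nchar(planted$query)))
      stop("planted k must not exceed the query length")
    if (any(planted$abundance < 0))
      stop("planted abundances must be >= 0")
  }
  structure(list(seed = as.integer(seed), nProteins = as.integer(nProteins),
                 proteinLength = as.integer(proteinLength),
                 planted = planted, databases = databases),
            class = "fixtureSpec")
}

# Mutate exactly k distinct positions of a peptide (to different residues).
.mutatePeptide <- function(query, k) {
  res <- strsplit(query, "", fixed = TRUE)[[1]]
  if (k == 0L) return(query)
  pos <- sample(seq_along(res), k)
  for (p in pos)
    res[p] <- sample(setdiff(AA20, res[p]), 1L)
  paste(res, collapse = "")
}

#' Generate a seeded random proteome with planted near-matches
#'
#' Background proteins are uniform random residue strings; each planted
#' (query, k) pair is embedded in its own protein as a window at exactly
#' Hamming distance k (k distinct positions mutated to different residues),
#' and the host protein carries the planted gene symbol. Ground-truth
#' coordinates are returned (and optionally written as a TSV sidecar).
#'
#' @param spec a [fixtureSpec()].
#' @param fastaPath optional path to write the FASTA (byte-identical for a
#'   given seed).
#' @param truthPath optional path for the ground-truth sidecar TSV.
#' @return list with components \code{proteome} ([Proteome-class]) and
#'   \code{truth} (data.frame query, accession, gene, start0, k,
#'   planted_sequence).
#' @export
generateProteome <- function(spec, fastaPath = NULL, truthPath = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  planted <- spec$planted
  if (nrow(planted) && any(nchar(planted$query) > spec$proteinLength))
    stop("planted peptide longer than proteinLength")
  if (nrow(planted) > spec$nProteins)
    stop("more planted peptides than proteins")
  res <- withSeed(spec$seed, {
    seqs <- vapply(seq_len(spec$nProteins), function(i)
      paste(sample(AA20, spec$proteinLength, replace = TRUE),
            collapse = ""), character(1))
    genes <- sprintf("GENE%04d", seq_len(spec$nProteins))
    truth <- NULL
    if (nrow(planted)) {
      truth <- data.frame(query = planted$query,
                          accession = sprintf("ACC%04d", seq_len(nrow(planted))),
                          gene = planted$gene,
                          start0 = NA_integer_, k = planted$k,
                          planted_sequence = NA_character_,
                          stringsAsFactors = FALSE)
      for (i in seq_len(nrow(planted))) {
        l <- nchar(planted$query[i])
        ne <- .mutatePeptide(planted$query[i], planted$k[i])
        s0 <- sample.int(spec$proteinLength - l + 1L, 1L) - 1L
        s <- seqs[i]
        seqs[i] <- paste0(substring(s, 1L, s0), ne,
                          substring(s, s0 + l + 1L, nchar(s)))
        genes[i] <- planted$gene[i]
        truth$start0[i] <- s0
        truth$planted_sequence[i] <- ne
      }
    }
    list(seqs = seqs, genes = genes, truth = truth)
  })
  acc <- sprintf("ACC%04d", seq_len(spec$nProteins))
  aa <- Biostrings::AAStringSet(res$seqs)
  names(aa) <- sprintf("%s GN=%s synthetic protein %d", acc, res$genes,
                       seq_len(spec$nProteins))
  proteome <- new("Proteome", aa = setNames(aa, acc), gene = res$genes,
                  description = sprintf("GN=%s synthetic protein %d",
                                        res$genes, seq_len(spec$nProteins)))
  if (!is.null(fastaPath)) {
    out <- aa
    names(out) <- sprintf("%s GN=%s synthetic protein %d", acc, res$genes,
                          seq_len(spec$nProteins))
    Biostrings::writeXStringSet(out, fastaPath, width = 80L)
  }
  truth <- res$truth
  if (is.null(truth))
    truth <- data.frame(query = character(), accession = character(),
                        gene = character(), start0 = integer(),
                        k = integer(), planted_sequence = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(truthPath))
    write.table(truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(proteome = proteome, truth = truth)
}

# Canonical tissue pool used when generating tables; planted tissues are
# placed first so they are always included.
.tissuePool <- function(plantedTissues) {
  pool <- c("lung/respiratory system", "brain/nervous system",
            "blood/immune system", "heart", "liver", "digestive system",
            "skin", "kidney", "prostate", "eye", "mammary tissue",
            "tonsils", "testis", "spleen", "appendix", "gall bladder",
            "urinary bladder", "various glands", "soft tissue",
            "reproductive organs", "fetal tissue", "cancer cell lines")
  unique(c(plantedTissues, pool))
}

#' Generate seeded expression tables with planted abundances
#'
#' One [ExpressionTable-class] per row of the spec's \code{databases}:
#' entities are the proteome's gene symbols; background abundances are
#' log-uniform over [0.1, 1000] for ppm/fpkm and uniform over {0..3} for
#' ihc_score tables; planted (gene, tissue) cells are overwritten with the
#' planted abundance (clamped to 0..3 and rounded for ihc_score tables).
#' Background values depend on the seed; planted cells do not.
#'
#' @param spec a [fixtureSpec()].
#' @param genes character vector of entity names (typically
#'   \code{unique(geneSymbols(proteome))}).
#' @param dir optional directory: each table is also written as
#'   \code{<database_id>.tsv}.
#' @return named list of [ExpressionTable-class] objects.
#' @export
generateExpressionTables <- function(spec, genes, dir = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  genes <- unique(genes)
  planted <- spec$planted
  tissues0 <- .tissuePool(unique(planted$tissue))
  tables <- withSeed(spec$seed + 1L, {
    out <- list()
    for (d in seq_len(nrow(spec$databases))) {
      dbid <- spec$databases$database_id[d]
      unit <- spec$databases$unit[d]
      nt <- min(spec$databases$n_tissues[d], length(tissues0))
      tissues <- tissues0[seq_len(nt)]
      m <- if (unit == "ihc_score")
        matrix(sample(0:3, length(genes) * nt, replace = TRUE),
               nrow = length(genes))
      else
        matrix(10^runif(length(genes) * nt, -1, 3), nrow = length(genes))
      dimnames(m) <- list(genes, tissues)
      if (nrow(planted))
        for (i in seq_len(nrow(planted))) {
          g <- planted$gene[i]; t <- planted$tissue[i]
          if (g %in% genes && t %in% tissues) {
            ab <- planted$abundance[i]
            if (unit == "ihc_score") ab <- min(3, max(0, round(ab)))
            m[g, t] <- ab
          }
        }
      out[[dbid]] <- expressionTable(m, dbid, unit)
    }
    out
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (dbid in names(tables))
      writeExpressionTable(tables[[dbid]], file.path(dir,
                                                     paste0(dbid, ".tsv")))
  }
  tables
}

#' Generate seeded scoring matrices, optionally biased for one peptide
#'
#' Random small-weight matrices (normal, sd 0.3) with intercepts chosen so
#' unbiased peptides score mid-range (cleavage around 0.5, affinities
#' around 10-100 nM, Q spanning several orders of magnitude). When
#' \code{biasPeptide} is given, its residues are boosted so that peptide
#' (and its exact proteome matches) reliably crosses the default filters:
#' cleavage >= 0.9 and strong TAP/MHC affinities.
#'
#' @param spec a [fixtureSpec()].
#' @param lengths peptide lengths to provide MHC matrices for.
#' @param biasPeptide optional peptide to favour.
#' @param dir optional directory to write \code{cleavage.tsv},
#'   \code{tap.tsv}, \code{mhc_<l>.tsv}.
#' @return list with elements \code{cleavage}, \code{tap}, \code{mhc}
#'   (named list by length).
#' @export
generateScoringMatrices <- function(spec, lengths = 9L, biasPeptide = NULL,
                                    dir = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  mats <- withSeed(spec$seed + 2L, {
    rmat <- function(nr) {
      m <- matrix(stats::rnorm(nr * 20, 0, 0.3), nrow = nr,
                  dimnames = list(NULL, AA20))
      m
    }
    cl <- scoringMatrix("cleavage", rmat(12L), intercept = 0)
    tap <- scoringMatrix("tap", rmat(4L), intercept = 1)
    mhc <- lapply(setNames(lengths, as.character(lengths)),
                  function(l) scoringMatrix("mhc", rmat(l), intercept = 2))
    list(cleavage = cl, tap = tap, mhc = mhc)
  })
  if (!is.null(biasPeptide)) {
    res <- strsplit(biasPeptide, "", fixed = TRUE)[[1]]
    l <- length(res)
    # cleavage: upstream half-window = the peptide's C-terminal residues
    w <- mats$cleavage@weights
    half <- nrow(w) %/% 2L
    up <- res[(l - half + 1L):l]
    for (j in seq_len(half)) w[j, up[j]] <- w[j, up[j]] + 1.5
    mats$cleavage <- scoringMatrix("cleavage", w, mats$cleavage@intercept)
    # TAP: favour the 3 N-terminal residues and the C-terminus
    w <- mats$tap@weights
    for (j in 1:3) w[j, res[j]] <- w[j, res[j]] - 1
    w[4L, res[l]] <- w[4L, res[l]] - 1
    mats$tap <- scoringMatrix("tap", w, mats$tap@intercept)
    # MHC: lower log-affinity along the peptide
    key <- as.character(l)
    if (!is.null(mats$mhc[[key]])) {
      w <- mats$mhc[[key]]@weights
      for (j in seq_len(l)) w[j, res[j]] <- w[j, res[j]] - 0.7
      mats$mhc[[key]] <- scoringMatrix("mhc", w, mats$mhc[[key]]@intercept)
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeScoringMatrix(mats$cleavage, file.path(dir, "cleavage.tsv"))
    writeScoringMatrix(mats$tap, file.path(dir, "tap.tsv"))
    for (key in names(mats$mhc))
      writeScoringMatrix(mats$mhc[[key]],
                         file.path(dir, paste0("mhc_", key, ".tsv")))
  }
  mats
}

#' Generate a complete on-disk fixture bundle
#'
#' Proteome FASTA + ground truth, one TSV per expression database, and the
#' three scoring-matrix TSVs, all under one directory and all a pure
#' function of the spec's seed.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @param biasPeptide optional peptide favoured by the scoring matrices
#'   (defaults to the first planted query, if any).
#' @return named list of paths plus the in-memory objects.
#' @export
generateFixtureBundle <- function(spec, dir, biasPeptide = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(biasPeptide) && nrow(spec$planted))
    biasPeptide <- spec$planted$query[1]
  fastaPath <- file.path(dir, "proteome.fasta")
  truthPath <- file.path(dir, "truth.tsv")
  pr <- generateProteome(spec, fastaPath, truthPath)
  tables <- generateExpressionTables(spec, unique(pr$proteome@gene),
                                     dir = dir)
  lens <- if (nrow(spec$planted)) unique(nchar(spec$planted$query)) else 9L
  mats <- generateScoringMatrices(spec, lengths = lens,
                                  biasPeptide = biasPeptide, dir = dir)
  list(fasta = fastaPath, truth = truthPath,
       tables = file.path(dir, paste0(names(tables), ".tsv")),
       proteome = pr$proteome, truthTable = pr$truth,
       expression = tables, matrices = mats)
}
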