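## CSV readers for docking scores, reference ligands and activity tables.

#' Read a compound-by-target docking-score matrix
#'
#' CSV with the compound id in the first column and one column per target.
#' Reference scores are read separately ([readReferenceScores()]) and must
#' cover every target column.
#'
#' @param path score CSV.
#' @param referenceScores named positive numeric vector, or the path of a
#'   reference-score CSV.
#' @return A [ScoreMatrix].
#' @export
readScoreMatrix <- function(path, referenceScores) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("score CSV needs a compound column plus at least one target")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    if (is.character(referenceScores) && length(referenceScores) == 1L)
        referenceScores <- readReferenceScores(referenceScores)
    ScoreMatrix(m, referenceScores)
}

#' Read per-target reference-ligand scores
#'
#' CSV laid out like the bundled target table: a `target` column, a `score`
#' column, and any number of annotation columns (`uniprot`, `pdb`,
#' `reference_ligand`, ...) which are ignored here.
#'
#' @param path reference-score CSV.
#' @return Named numeric vector, target id -> reference score.
#' @export
readReferenceScores <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("target", "score") %in% names(df)))
        stop("reference-score CSV needs 'target' and 'score' columns")
    if (anyDuplicated(df$target))
        stop("duplicate target id(s) in reference-score CSV")
    setNames(as.numeric(df$score), df$target)
}

#' Read a compound activity table
#'
#' CSV with columns `compound`, `inhibition` (fraction in \code{[0, 1]} at the
#' assay concentration) and optional logical columns `glycoside` and
#' `is_drug`.
#'
#' @param path activity CSV.
#' @return `data.frame` with the columns above.
#' @export
readActivityTable <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("compound", "inhibition") %in% names(df)))
        stop("activity CSV needs 'compound' and 'inhibition' columns")
    if (anyDuplicated(df$compound))
        stop("duplicate compound id(s) in activity CSV")
    if (any(df$inhibition < 0 | df$inhibition > 1))
        stop("inhibition must be a fraction in [0, 1]")
    if (is.null(df$glycoside)) df$glycoside <- FALSE
    if (is.null(df$is_drug)) df$is_drug <- FALSE
    df$glycoside <- as.logical(df$glycoside)
    df$is_drug <- as.logical(df$is_drug)
    df
}
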