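## Ranking, activity correlation, and the single-target baseline.

#' Rank compounds by a network-impact metric
#'
#' Stable descending sort of the metrics table by `ne_decrease`,
#' `nf_decrease` or `combination`; ties are broken by compound id in
#' lexicographic (C-locale) order. The more a compound decreases network
#' efficiency, the more potent it is predicted to be.
#'
#' @param x a [ScreeningReport] or a metrics `data.frame` with a `compound`
#'   column.
#' @param key ranking metric.
#' @return Same type as `x`, with rows reordered (and, for a report, the
#'   `rankingKey` updated).
#' @export
rankCompounds <- function(x, key = c("ne_decrease", "nf_decrease",
                                     "combination")) {
    key <- match.arg(key)
    tab <- if (is(x, "ScreeningReport")) screeningMetrics(x) else x
    if (!nrow(tab)) stop("metrics table is empty")
    if (!key %in% names(tab)) stop("unknown ranking key: ", key)
    ord <- order(-tab[[key]], tab$compound, method = "radix")
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    if (is(x, "ScreeningReport")) {
        x@metrics <- tab
        x@rankingKey <- key
        validObject(x)
        x
    } else tab
}

#' Pearson product-moment correlation
#'
#' The linear (least-squares) correlation coefficient between two equal
#' length vectors. Requires at least 3 paired observations and nonzero
#' variance in both.
#'
#' @param x,y numeric vectors.
#' @return Scalar `r` in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined: zero variance")
    cor(x, y)
}

#' Correlate predicted network impact with experimental activity
#'
#' Joins a per-compound metrics table with an activity table on compound id
#' (an unmatched metrics compound is an error naming it), optionally
#' restricts to non-glycoside compounds, and returns the Pearson r together
#' with the least-squares slope and intercept of
#' `inhibition ~ predictor`. Glycosides are excluded in the
#' `"nonglycoside"` subset because flexible sugar moieties degrade
#' docking-score reliability.
#'
#' @param metrics a [ScreeningReport], a metrics `data.frame`, or the
#'   bundled activity fixture (which already carries metric columns).
#' @param activity `data.frame` with columns `compound`, `inhibition`
#'   (fraction in \code{[0, 1]}) and optionally `glycoside`; defaults to
#'   `metrics` when that table already contains `inhibition`.
#' @param predictor `"ne_decrease"`, `"nf_decrease"` or `"combination"`.
#' @param subset `"all"` or `"nonglycoside"`.
#' @return One-row `data.frame`: `predictor`, `subset`, `n`, `r`, `slope`,
#'   `intercept`.
#' @examples
#' tab2 <- loadFixture("compounds_table2")
#' correlateActivity(tab2, predictor = "ne_decrease")       # all 21
#' correlateActivity(tab2, predictor = "combination",
#'                   subset = "nonglycoside")               # 14 compounds
#' @export
correlateActivity <- function(metrics, activity = NULL,
                              predictor = c("ne_decrease", "nf_decrease",
                                            "combination"),
                              subset = c("all", "nonglycoside")) {
    predictor <- match.arg(predictor)
    subset <- match.arg(subset)
    tab <- if (is(metrics, "ScreeningReport")) screeningMetrics(metrics)
           else as.data.frame(metrics)
    if (!predictor %in% names(tab))
        stop("metrics table has no '", predictor, "' column")
    correlateColumn(tab, activity, xcol = predictor,
                    predictorName = predictor, subset = subset)
}

#' Single-target correlation baseline
#'
#' The traditional virtual-screening baseline the network model is compared
#' against: the Pearson correlation of one target's raw docking-score column
#' with experimental inhibition, ignoring the rest of the pathway.
#'
#' @param scores a [ScoreMatrix].
#' @param activity activity `data.frame` (`compound`, `inhibition`,
#'   optionally `glycoside`).
#' @param target target id present in `scores`.
#' @param subset `"all"` or `"nonglycoside"`.
#' @return One-row `data.frame` as for [correlateActivity()], with the
#'   predictor named `score:<target>`.
#' @export
singleTargetCorrelation <- function(scores, activity, target,
                                    subset = c("all", "nonglycoside")) {
    stopifnot(is(scores, "ScoreMatrix"))
    subset <- match.arg(subset)
    if (!target %in% targetNames(scores))
        stop("unknown target id: ", target)
    tab <- data.frame(compound = compoundNames(scores),
                      score = dockingScores(scores)[, target],
                      stringsAsFactors = FALSE)
    correlateColumn(tab, activity, xcol = "score",
                    predictorName = paste0("score:", target),
                    subset = match.arg(subset))
}

## join metrics column xcol with activity$inhibition and correlate
correlateColumn <- function(tab, activity, xcol, predictorName, subset) {
    if (is.null(activity)) {
        if (!"inhibition" %in% names(tab))
            stop("no activity table supplied and metrics table has no ",
                 "'inhibition' column")
        activity <- tab
    }
    activity <- as.data.frame(activity)
    if (!all(c("compound", "inhibition") %in% names(activity)))
        stop("activity table needs columns 'compound' and 'inhibition'")
    if (any(activity$inhibition < 0 | activity$inhibition > 1))
        stop("inhibition must be a fraction in [0, 1]")
    idx <- match(tab$compound, activity$compound)
    if (anyNA(idx))
        stop("compound(s) missing from activity table: ",
             paste(tab$compound[is.na(idx)], collapse = ", "))
    glyco <- if (is.null(activity$glycoside)) rep(FALSE, nrow(activity))
             else as.logical(activity$glycoside)
    joined <- data.frame(x = tab[[xcol]],
                         y = activity$inhibition[idx],
                         glycoside = glyco[idx])
    if (subset == "nonglycoside")
        joined <- joined[!joined$glycoside, , drop = FALSE]
    if (nrow(joined) < 3L)
        stop("fewer than 3 compounds after subsetting")
    r <- pearsonR(joined$x, joined$y)
    slope <- r * sd(joined$y) / sd(joined$x)
    data.frame(predictor = predictorName, subset = subset, n = nrow(joined),
               r = r, slope = slope,
               intercept = mean(joined$y) - slope * mean(joined$x),
               stringsAsFactors = FALSE)
}
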