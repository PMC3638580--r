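## Docking score -> edge value transform and network reweighting.

#' Transform a docking score into an edge value
#'
#' The edge value (EV) imposed on a target's outgoing edges grows
#' exponentially with the compound's docking score relative to the target's
#' reference ligand:
#' \deqn{EV = 10^{(score_{ligand}/score_{reference}) \times 2.30}}
#' and is clamped to `[floor, cap]`. A compound scoring exactly the
#' reference score yields `10^2.30`, approximately 200; a score of 0 falls
#' below the floor and is fixed to 10. The transform is monotone
#' nondecreasing in the score and hits the floor for all
#' `score/reference <= log10(floor)/constant` (about 0.4348 at defaults).
#'
#' @param score numeric vector of docking scores (higher = stronger
#'   predicted binding); `NA` is treated as 0 (no measurable binding).
#' @param referenceScore strictly positive reference-ligand score(s).
#' @param constant exponent constant (default 2.30).
#' @param floor,cap clamp bounds (defaults 10 and 99999).
#' @return Numeric vector of edge values in `[floor, cap]`.
#' @examples
#' edgeValue(5.02, 5.02)   # ~199.5
#' edgeValue(0, 5.02)      # 10 (floor)
#' @export
edgeValue <- function(score, referenceScore, constant = 2.30,
                      floor = 10, cap = 99999) {
    if (any(!is.finite(referenceScore)) || any(referenceScore <= 0))
        stop("reference score must be finite and strictly positive")
    if (floor > cap) stop("floor must not exceed cap")
    score[is.na(score)] <- 0
    ev <- 10^(constant * score / referenceScore)
    pmin(pmax(ev, floor), cap)
}

#' Build the perturbation profile of one compound
#'
#' Looks up the compound's row of the [ScoreMatrix] and converts every
#' docking score to an edge value with [edgeValue()], producing one EV per
#' target. Missing scores are treated as 0 (they land on the floor and leave
#' the target's edges effectively unperturbed) and reported via a message.
#'
#' @param scores a [ScoreMatrix].
#' @param compound compound id present in `scores`.
#' @param constant,floor,cap passed to [edgeValue()].
#' @return A [PerturbationProfile].
#' @export
buildProfile <- function(scores, compound, constant = 2.30,
                         floor = 10, cap = 99999) {
    stopifnot(is(scores, "ScoreMatrix"))
    if (!compound %in% compoundNames(scores))
        stop("unknown compound id: ", compound)
    row <- dockingScores(scores)[compound, ]
    if (anyNA(row))
        message(sprintf("compound '%s': %d missing score(s) treated as 0",
                        compound, sum(is.na(row))))
    refs <- referenceScores(scores)
    ev <- edgeValue(row, refs, constant = constant, floor = floor, cap = cap)
    PerturbationProfile(compound, setNames(ev, targetNames(scores)))
}

#' Apply a perturbation profile to a baseline network
#'
#' Returns a new network in which every edge whose source node is one of the
#' profile's targets carries that target's edge value; all remaining edges
#' keep their baseline weight. The topology (node and edge sets) is
#' untouched and the input network is not modified. The network is expected
#' to be at baseline weights (all equal to the initial weight) so that
#' non-target edges stay at 10.
#'
#' @param net a [PathwayNetwork] at baseline weights.
#' @param profile a [PerturbationProfile] whose targets are all nodes of
#'   `net`.
#' @return A reweighted [PathwayNetwork].
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' prof <- PerturbationProfile("cmpd", c(B = 200))
#' pathwayEdges(applyProfile(net, prof))
#' @export
applyProfile <- function(net, profile) {
    stopifnot(is(net, "PathwayNetwork"), is(profile, "PerturbationProfile"))
    ev <- profile@edgeValues
    missing <- setdiff(names(ev), pathwayNodes(net)$id)
    if (length(missing))
        stop("profile target(s) absent from network: ",
             paste(missing, collapse = ", "))
    edges <- pathwayEdges(net)
    hit <- match(edges$from, names(ev))
    sel <- !is.na(hit)
    edges$weight[sel] <- unname(ev[hit[sel]])
    out <- net
    out@edges <- edges
    validObject(out)
    out
}
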