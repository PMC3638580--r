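## Reading and writing PathwayNetwork objects.
##
## Edge-list TSV dialect:
##   source<TAB>target[<TAB>weight]
##   '#'  comment lines
##   '%node id<TAB>label<TAB>kind'  optional node declarations
##   '%exit id'                     optional explicit exit declaration
## SIF dialect: source<TAB>interaction<TAB>target, where a numeric
## interaction field is interpreted as the edge weight.
## GraphML: 'weight' edge attribute, 'label'/'kind'/'exit' node attributes.

#' Read a pathway network from a file
#'
#' Parses a directed pathway network from an edge-list TSV, a SIF file or a
#' GraphML file and returns a validated [PathwayNetwork]. Edges without an
#' explicit weight receive `initialWeight`. TSV/SIF files may carry `#`
#' comments, `%node id<TAB>label<TAB>kind` declarations and `%exit id`
#' directives; when any `%node` declaration is present, every edge endpoint
#' must be declared and an unknown endpoint is a parse error naming the line.
#' Node-id matching is exact and case-sensitive.
#'
#' @param path file to read.
#' @param format `"tsv"`, `"sif"` or `"graphml"`; default guesses from the
#'   file extension (falling back to `"tsv"`).
#' @param initialWeight weight for edges that do not declare one.
#' @param weightFloor,weightCap admissible weight range.
#' @return A [PathwayNetwork].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC"), f)
#' readPathwayNetwork(f)
#' @export
readPathwayNetwork <- function(path,
                               format = c("guess", "tsv", "sif", "graphml"),
                               initialWeight = 10,
                               weightFloor = 10, weightCap = 99999) {
    format <- match.arg(format)
    if (format == "guess") format <- guessFormat(path)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "graphml")
        return(readGraphML(path, weightFloor, weightCap))
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    nodeDecl <- NULL
    exits <- character()
    edges <- list()
    for (i in which(keep)) {
        line <- lines[[i]]
        if (startsWith(line, "%")) {
            fields <- strsplit(sub("^%\\S+\\s+", "", line), "\t",
                               fixed = TRUE)[[1]]
            if (startsWith(line, "%node")) {
                nodeDecl <- rbind(nodeDecl, data.frame(
                    id = fields[1],
                    label = if (length(fields) >= 2) fields[2] else fields[1],
                    kind = if (length(fields) >= 3) fields[3] else "protein",
                    stringsAsFactors = FALSE))
            } else if (startsWith(line, "%exit")) {
                exits <- c(exits, fields[1])
            } else {
                stop(sprintf("line %d: unknown directive '%s'", i, line))
            }
            next
        }
        fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
        edges[[length(edges) + 1L]] <- parseEdgeLine(fields, format, i,
                                                     initialWeight)
    }
    edges <- do.call(rbind, edges)
    if (is.null(edges))
        edges <- data.frame(from = character(), to = character(),
                            weight = numeric(), stringsAsFactors = FALSE)
    if (!is.null(nodeDecl)) {
        unknown <- !(c(edges$from, edges$to) %in% nodeDecl$id)
        if (any(unknown)) {
            bad <- unique(c(edges$from, edges$to)[unknown])
            stop(sprintf("edge references undeclared node(s): %s",
                         paste(bad, collapse = ", ")))
        }
    }
    net <- PathwayNetwork(edges, nodes = nodeDecl, exitNodes = exits,
                          weightFloor = weightFloor, weightCap = weightCap,
                          initialWeight = initialWeight)
    validObject(net)
    net
}

parseEdgeLine <- function(fields, format, lineNo, initialWeight) {
    if (format == "sif") {
        if (length(fields) != 3L)
            stop(sprintf(
                "line %d: SIF needs 'source<TAB>interaction<TAB>target'",
                lineNo))
        w <- suppressWarnings(as.numeric(fields[2]))
        data.frame(from = fields[1], to = fields[3],
                   weight = if (is.na(w)) initialWeight else w,
                   stringsAsFactors = FALSE)
    } else {
        if (!length(fields) %in% c(2L, 3L))
            stop(sprintf("line %d: expected 2 or 3 tab-separated fields",
                         lineNo))
        w <- if (length(fields) == 3L) as.numeric(fields[3]) else NA_real_
        if (length(fields) == 3L && is.na(w))
            stop(sprintf("line %d: weight '%s' is not numeric",
                         lineNo, fields[3]))
        data.frame(from = fields[1], to = fields[2],
                   weight = if (is.na(w)) initialWeight else w,
                   stringsAsFactors = FALSE)
    }
}

readGraphML <- function(path, weightFloor, weightCap) {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    nd <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(
        id = nd$name,
        label = if (!is.null(nd$label)) nd$label else nd$name,
        kind = if (!is.null(nd$kind)) nd$kind else "protein",
        stringsAsFactors = FALSE)
    exits <- if (!is.null(nd$exit)) nd$name[nd$exit > 0] else character()
    PathwayNetwork(ed, nodes = nodes, exitNodes = exits,
                   weightFloor = weightFloor, weightCap = weightCap)
}

guessFormat <- function(path) {
    switch(tolower(tools::file_ext(path)),
           sif = "sif", graphml = "graphml", xml = "graphml", "tsv")
}

#' Write a pathway network to a file
#'
#' Serialises a [PathwayNetwork] so that [readPathwayNetwork()] reproduces
#' the nodes (ids, labels, kinds), edges, weights and explicit exit set
#' exactly. TSV and SIF output include `%node` and `%exit` directives;
#' GraphML stores `label`/`kind`/`exit` node attributes and the `weight`
#' edge attribute.
#'
#' @param net a [PathwayNetwork].
#' @param path output file.
#' @param format `"tsv"`, `"sif"` or `"graphml"` (default guessed from the
#'   extension).
#' @return `path`, invisibly.
#' @export
writePathwayNetwork <- function(net, path,
                                format = c("guess", "tsv", "sif", "graphml")) {
    stopifnot(is(net, "PathwayNetwork"))
    validObject(net)
    format <- match.arg(format)
    if (format == "guess") format <- guessFormat(path)
    if (format == "graphml") {
        nd <- pathwayNodes(net)
        g <- igraph::graph_from_data_frame(
            pathwayEdges(net), directed = TRUE,
            vertices = data.frame(name = nd$id, label = nd$label,
                                  kind = nd$kind,
                                  exit = as.integer(nd$id %in% exitNodes(net)),
                                  stringsAsFactors = FALSE))
        igraph::write_graph(g, path, format = "graphml")
        return(invisible(path))
    }
    nd <- pathwayNodes(net)
    ed <- pathwayEdges(net)
    lines <- c(
        sprintf("%%node %s\t%s\t%s", nd$id, nd$label, nd$kind),
        sprintf("%%exit %s", exitNodes(net)),
        if (format == "sif")
            sprintf("%s\t%s\t%s", ed$from, fmtWeight(ed$weight), ed$to)
        else
            sprintf("%s\t%s\t%s", ed$from, ed$to, fmtWeight(ed$weight)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

## full-precision decimal so that read(write(x)) restores the double bitwise
fmtWeight <- function(w) sprintf("%.17g", w)
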