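## Run configuration shared by the pipeline and the command line.

#' Pipeline run configuration
#'
#' Bundles the tunable constants of the perturbation pipeline. The defaults
#' are the model's published operating point: initial edge weight 10, weight
#' floor 10, weight cap 99999, exponent constant 2.30, ordered pair mode.
#'
#' @param initialWeight baseline weight of every edge.
#' @param weightFloor,weightCap admissible weight range.
#' @param exponentConstant exponent constant of the edge-value transform.
#' @param pairMode `"ordered"` or `"unordered"` (see [networkEfficiency()]).
#' @param exitOverride character vector of exit node ids overriding
#'   auto-detection (empty = auto-detect sinks).
#' @param rankingKey default ranking metric.
#' @param subset default correlation subset.
#' @param seed integer seed for stochastic commands.
#' @return A validated list of class `runConfig`.
#' @export
runConfig <- function(initialWeight = 10, weightFloor = 10,
                      weightCap = 99999, exponentConstant = 2.30,
                      pairMode = c("ordered", "unordered"),
                      exitOverride = character(),
                      rankingKey = c("ne_decrease", "nf_decrease",
                                     "combination"),
                      subset = c("all", "nonglycoside"),
                      seed = 1L) {
    pairMode <- match.arg(pairMode)
    rankingKey <- match.arg(rankingKey)
    subset <- match.arg(subset)
    if (!(weightFloor <= initialWeight && initialWeight <= weightCap))
        stop("need weightFloor <= initialWeight <= weightCap")
    if (exponentConstant <= 0) stop("exponentConstant must be positive")
    structure(list(initialWeight = initialWeight, weightFloor = weightFloor,
                   weightCap = weightCap,
                   exponentConstant = exponentConstant, pairMode = pairMode,
                   exitOverride = as.character(exitOverride),
                   rankingKey = rankingKey, subset = subset,
                   seed = as.integer(seed)),
              class = "runConfig")
}

#' Read a run configuration from a key-value text file
#'
#' One `key = value` pair per line, `#` comments allowed; keys match the
#' arguments of [runConfig()] in either camelCase or snake_case.
#' `exitOverride` takes a comma-separated id list. Values given here can be
#' overridden by command-line flags.
#'
#' @param path configuration file.
#' @param base configuration to start from (default [runConfig()]).
#' @return A `runConfig` list.
#' @export
readRunConfig <- function(path, base = runConfig()) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    args <- as.list(base)
    numeric_keys <- c("initialWeight", "weightFloor", "weightCap",
                      "exponentConstant")
    for (line in lines) {
        kv <- strsplit(line, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L)
            stop("malformed config line: ", line)
        key <- camelKey(trimws(kv[1]))
        val <- trimws(kv[2])
        if (!key %in% names(args))
            stop("unknown config key: ", trimws(kv[1]))
        args[[key]] <- switch(key,
            exitOverride = trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
            seed = as.integer(val),
            if (key %in% numeric_keys) as.numeric(val) else val)
    }
    do.call(runConfig, args)
}

camelKey <- function(key) {
    gsub("_(\\w)", "\\U\\1", key, perl = TRUE)
}
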