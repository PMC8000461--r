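#' Run configuration with pipeline defaults
#'
#' Bundles every tunable parameter of the pipeline. The defaults are the
#' method's published operating point: sketches at k = 21 and k = 51 with
#' 2,000 hashes, 1,020 nt query fragments retained at over 30% coverage and
#' over 70% identity, Jaccard brackets at 0.2475 (corresponding to 95% ANI
#' at k = 21) and 0.0025 (70% ANI), and 95%-level LINgroups.
#'
#' @param kPrimary k-mer length of the first-stage (representative) search
#'   sketch.
#' @param kSecondary k-mer length used within a 95%-level LINgroup.
#' @param sketchSize sketch capacity `n` (hashes per signature).
#' @param fragmentLength query fragment length in nt for ANI.
#' @param minCoverage,minIdentity retention filters for fragment hits, in
#'   percent; both are strict (`>`) comparisons.
#' @param jaccardUpper,jaccardLower bracket cutoffs for the first-stage
#'   classification; empirical calibrations at k = 21, n = 2,000.
#' @param groupingANI ANI level (percent) of the LINgroup used for
#'   representative-based search; must be a threshold of the grouping
#'   scheme.
#' @param wordSize exact-match seed length of the built-in fragment
#'   aligner.
#' @param seed optional integer seed for operations that draw randomness.
#' @param logLevel `"info"` to log each assignment (bracket, subject, J,
#'   ANI), `"quiet"` to suppress.
#'
#' @return a named list of class `linforgeConfig`.
#' @export
linforgeConfig <- function(kPrimary = 21L, kSecondary = 51L,
                           sketchSize = 2000L, fragmentLength = 1020L,
                           minCoverage = 30, minIdentity = 70,
                           jaccardUpper = 0.2475, jaccardLower = 0.0025,
                           groupingANI = 95, wordSize = 12L,
                           seed = NULL, logLevel = "info") {
  stopifnot(kPrimary >= 1, kSecondary >= 1, sketchSize >= 1,
            fragmentLength >= 1, minCoverage >= 0, minCoverage <= 100,
            minIdentity >= 0, minIdentity <= 100,
            jaccardLower >= 0, jaccardUpper > jaccardLower,
            jaccardUpper <= 1, groupingANI > 0, groupingANI <= 100,
            logLevel %in% c("info", "quiet"))
  structure(list(
    kPrimary = as.integer(kPrimary), kSecondary = as.integer(kSecondary),
    sketchSize = as.integer(sketchSize),
    fragmentLength = as.integer(fragmentLength),
    minCoverage = minCoverage, minIdentity = minIdentity,
    jaccardUpper = jaccardUpper, jaccardLower = jaccardLower,
    groupingANI = groupingANI, wordSize = as.integer(wordSize),
    seed = seed, logLevel = logLevel), class = "linforgeConfig")
}

#' Read a configuration file and merge it over the defaults
#'
#' @param path YAML file whose keys are [linforgeConfig()] arguments.
#' @return a `linforgeConfig` list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(linforgeConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(linforgeConfig, vals)
}

.log_info <- function(config, ...) {
  if (is.null(config$logLevel) || config$logLevel != "quiet")
    message(sprintf(...))
  invisible(NULL)
}
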