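.TABLE1 <- c(70, 75, 80, 85, 90, 95, 96, 97, 98, 98.5, 99, 99.25, 99.5,
             99.75, 99.9, 99.925, 99.95, 99.975, 99.99, 99.999)

.BUILTIN_SCHEMES <- c("lin20", "lin300", "lin3000", "lin_fine")

.new_scheme <- function(name, thresholdsInt, labels = character()) {
  obj <- new("LINScheme", name = name,
             thresholdsInt = as.numeric(thresholdsInt),
             posLabels = as.character(labels))
  validObject(obj)
  obj
}

#' Build a LIN scheme on a regular ANI grid
#'
#' Thresholds are `start, start + step, ..., stop` inclusive, computed on
#' an exact integer grid (resolution 1e-5 percent) rather than by repeated
#' addition, so no floating-point drift accumulates even for very fine
#' steps.
#'
#' @param start,stop first and last ANI threshold (percent), `start < stop`.
#' @param step grid spacing (percent), positive; `stop - start` must be an
#'   integer multiple of `step` within the grid tolerance.
#' @param name scheme label.
#' @return a [LINScheme-class] with `round((stop - start) / step) + 1`
#'   positions.
#' @examples
#' length(buildScheme(70, 99.9, 0.1))   # 300 positions
#' length(buildScheme(70, 99.99, 0.01)) # 3000 positions
#' @export
buildScheme <- function(start, stop, step, name = "custom_grid") {
  si <- .as_grid(start); ei <- .as_grid(stop); pi_ <- .as_grid(step)
  if (pi_ <= 0) stop("step must be positive (and at least 1e-5)")
  if (ei <= si) stop("stop must be greater than start")
  if ((ei - si) %% pi_ != 0)
    stop("(stop - start) is not an integer multiple of step on the grid")
  n <- (ei - si) %/% pi_
  if (start < 70)
    warning("scheme includes ANI thresholds below 70%; ANI does not ",
            "reflect evolutionary relationships below 70%")
  .new_scheme(name, si + pi_ * (0:n))
}

#' Build a LIN scheme from an explicit threshold list
#'
#' @param thresholds strictly increasing ANI percentages in (0, 100].
#' @param name scheme label.
#' @param labels optional per-position labels, same length as
#'   `thresholds`.
#' @return a [LINScheme-class]. Thresholds below 70% are permitted but
#'   trigger a warning: ANI does not reflect evolutionary relationships
#'   below 70%.
#' @export
parseScheme <- function(thresholds, name = "custom", labels = character()) {
  if (!length(thresholds)) stop("threshold list must be non-empty")
  ti <- .as_grid(thresholds)
  if (any(diff(ti) <= 0))
    stop("thresholds must be strictly increasing")
  if (any(ti <= 0) || any(ti > 100 * .GRID))
    stop("thresholds must lie in (0, 100]")
  if (any(thresholds < 70))
    warning("scheme includes ANI thresholds below 70%; ANI does not ",
            "reflect evolutionary relationships below 70%")
  .new_scheme(name, ti, labels)
}

#' Built-in LIN schemes
#'
#' Four default schemes are registered: `"lin20"`, the 20-position scheme
#' with hand-picked thresholds from 70% to 99.999% ANI labelled `A`..`T`
#' (genus- to strain-level resolution); `"lin300"` (70 to 99.9 by 0.1);
#' `"lin3000"` (70 to 99.99 by 0.01, for highly resolved within-species
#' matrices); and `"lin_fine"` (70 to 99.99999 by 0.00001). Note that the
#' `lin_fine` grid contains 3,000,000 positions — the value its start,
#' stop and step imply — which differs from the 300,000 sometimes quoted
#' for this scheme; the grid arithmetic is authoritative here.
#'
#' @param name one of `"lin20"`, `"lin300"`, `"lin3000"`, `"lin_fine"`.
#' @return a [LINScheme-class].
#' @examples
#' builtinScheme("lin20")
#' @export
builtinScheme <- function(name = c("lin20", "lin300", "lin3000",
                                   "lin_fine")) {
  name <- match.arg(name)
  switch(name,
    lin20 = .new_scheme("lin20", .as_grid(.TABLE1), LETTERS[1:20]),
    lin300 = buildScheme(70, 99.9, 0.1, name = "lin300"),
    lin3000 = buildScheme(70, 99.99, 0.01, name = "lin3000"),
    lin_fine = buildScheme(70, 99.99999, 0.00001, name = "lin_fine"))
}

#' @describeIn thresholds number of positions in the scheme
#' @export
setMethod("length", "LINScheme", function(x) length(x@thresholdsInt))

#' Scheme accessors
#'
#' `thresholds` returns the ANI thresholds in percent; `positionLabels`
#' the per-position labels (empty when unlabelled); `schemeName` the
#' scheme's label.
#'
#' @param x,scheme a [LINScheme-class].
#' @return numeric / character vectors.
#' @export
thresholds <- function(scheme) {
  stopifnot(is(scheme, "LINScheme"))
  .from_grid(scheme@thresholdsInt)
}

#' @rdname thresholds
#' @export
positionLabels <- function(scheme) {
  stopifnot(is(scheme, "LINScheme"))
  scheme@posLabels
}

#' @rdname thresholds
#' @export
schemeName <- function(scheme) {
  stopifnot(is(scheme, "LINScheme"))
  scheme@name
}

#' Number of leading LIN positions shared at a given ANI
#'
#' Counts the leading positions whose threshold is lower than or equal to
#' `ani`; an ANI exactly equal to a threshold shares that position.
#' Comparison happens on the scheme's exact grid so boundary values
#' classify deterministically.
#'
#' @param scheme a [LINScheme-class].
#' @param ani ANI value(s) in percent, in `[0, 100]`; vectorised.
#' @return integer vector of shared depths in `0..length(scheme)`.
#' @examples
#' sharedDepth(builtinScheme("lin20"), 95.4575) # 6: positions A-F
#' @export
sharedDepth <- function(scheme, ani) {
  stopifnot(is(scheme, "LINScheme"))
  if (any(ani < 0 | ani > 100)) stop("ani must lie in [0, 100]")
  findInterval(.as_grid(ani), scheme@thresholdsInt)
}

setMethod("show", "LINScheme", function(object) {
  t <- thresholds(object)
  cat(sprintf("LINScheme '%s': %d positions, %g%% .. %g%% ANI\n",
              object@name, length(t), t[1L], t[length(t)]))
  if (length(object@posLabels))
    cat("  labels:", paste(object@posLabels, collapse = " "), "\n")
  invisible(object)
})

# serialisable description of a scheme for the store's scheme table
.scheme_to_record <- function(scheme) {
  if (scheme@name %in% .BUILTIN_SCHEMES)
    return(data.frame(name = scheme@name, source = "builtin",
                      definition = scheme@name, stringsAsFactors = FALSE))
  data.frame(name = scheme@name, source = "explicit",
             definition = paste(format(thresholds(scheme), trim = TRUE,
                                       scientific = FALSE),
                                collapse = ","),
             stringsAsFactors = FALSE)
}

.scheme_from_record <- function(rec) {
  if (rec$source == "builtin") return(builtinScheme(rec$definition))
  suppressWarnings(
    parseScheme(as.numeric(strsplit(rec$definition, ",")[[1L]]),
                name = rec$name))
}
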