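# thresholds live on an exact integer grid of 1e-5 ANI percentage points so
# that 0.1-steps never accumulate floating-point drift and boundary ANI
# values classify deterministically
.GRID <- 1e5

.as_grid <- function(x) round(x * .GRID)
.from_grid <- function(x) x / .GRID

#' LIN scheme: ordered ANI thresholds defining LIN positions
#'
#' A `LINScheme` maps LIN positions to strictly increasing ANI thresholds
#' (percent). Thresholds are stored on an exact decimal grid with 1e-5
#' percent resolution, so comparisons against ANI values are free of
#' floating-point drift.
#'
#' @slot name scheme label, e.g. `"lin20"`.
#' @slot thresholdsInt integer-valued thresholds in units of 1e-5 percent.
#' @slot posLabels optional per-position labels (`A`..`T` for the
#'   20-position scheme); empty when unlabelled.
#'
#' @seealso [buildScheme()], [parseScheme()], [builtinScheme()],
#'   [sharedDepth()]
#' @export
setClass("LINScheme",
  representation(name = "character", thresholdsInt = "numeric",
                 posLabels = "character"))

setValidity("LINScheme", function(object) {
  t <- object@thresholdsInt
  if (length(t) == 0L) return("scheme must have at least one threshold")
  if (any(t != round(t))) return("thresholds not on the integer grid")
  if (any(diff(t) <= 0)) return("thresholds must be strictly increasing")
  if (t[1L] <= 0 || t[length(t)] > 100 * .GRID)
    return("thresholds must lie in (0, 100]")
  if (length(object@posLabels) &&
      length(object@posLabels) != length(t))
    return("position labels must match the number of thresholds")
  TRUE
})

#' Bottom-n MinHash signature of a genome
#'
#' The `n` smallest 53-bit hash values of the canonical k-mer set of a
#' genome, sorted increasingly. Signatures with equal `k` and capacity can
#' be compared with [jaccard()].
#'
#' @slot genomeId identifier of the sketched genome.
#' @slot k k-mer length.
#' @slot capacity sketch capacity `n` (hash count ceiling).
#' @slot hashes sorted distinct hash values (doubles holding exact 53-bit
#'   integers).
#' @export
setClass("GenomeSignature",
  representation(genomeId = "character", k = "integer",
                 capacity = "integer", hashes = "numeric"))

setValidity("GenomeSignature", function(object) {
  h <- object@hashes
  if (length(h) > object@capacity) return("more hashes than capacity")
  if (length(h) > 1L && any(diff(h) <= 0))
    return("hashes must be strictly increasing")
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' One-way fragment-based ANI result
#'
#' Result of aligning every fragment of a query genome against a subject
#' genome. `ani` is the mean percent identity of the retained fragment
#' hits; it is `NA` when no hit passes the coverage/identity filters, which
#' is the explicit "no significant similarity" outcome.
#'
#' @slot queryId,subjectId genome identifiers.
#' @slot ani mean identity of retained hits (percent), or `NA`.
#' @slot retained number of fragment hits passing the filters.
#' @slot fragments total number of query fragments.
#' @export
setClass("ANIResult",
  representation(queryId = "character", subjectId = "character",
                 ani = "numeric", retained = "integer",
                 fragments = "integer"))

setValidity("ANIResult", function(object) {
  if (object@retained > object@fragments)
    return("retained count exceeds fragment count")
  if (object@retained >= 1L && is.na(object@ani))
    return("ani must be defined when hits were retained")
  TRUE
})

#' Outcome of the first-stage representative search
#'
#' @slot bracket one of `"same_f_group"`, `"shared_a"`, `"novel"`.
#' @slot bestSubject id of the best-matching representative (length 0 when
#'   the store is empty).
#' @slot jaccard the winning Jaccard estimate (`NA` when empty).
#' @export
setClass("SearchOutcome",
  representation(bracket = "character", bestSubject = "character",
                 jaccard = "numeric"))

#' Embedded store of genomes, LINs, signatures and ANI records
#'
#' Mutable single-writer store backed by an environment; persisted as a
#' directory of TSV tables plus a LINgroup-organised signature file layout
#' (see [saveStore()] / [openStore()]).
#'
#' @slot env environment holding the genome, taxonomy, scheme, LIN and ANI
#'   tables, in-memory signatures, and the run configuration.
#' @export
setClass("LINStore", representation(env = "environment"))

#' Symmetric genome similarity matrix
#'
#' @slot labels ordered genome identifiers.
#' @slot values symmetric numeric matrix; percent ANI (`kind = "ani"`,
#'   diagonal 100) or Jaccard (`kind = "jaccard"`, diagonal 1).
#' @slot kind `"ani"` or `"jaccard"`.
#' @export
setClass("SimilarityMatrix",
  representation(labels = "character", values = "matrix",
                 kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    return("values must be an n x n numeric matrix matching labels")
  if (!(object@kind %in% c("ani", "jaccard")))
    return("kind must be 'ani' or 'jaccard'")
  if (n && max(abs(v - t(v))) > 1e-9) return("matrix must be symmetric")
  top <- if (object@kind == "ani") 100 else 1
  if (n && max(abs(diag(v) - top)) > 1e-9)
    return(sprintf("diagonal must equal %g", top))
  if (n && (min(v) < -1e-9 || max(v) > top + 1e-9))
    return("values out of range")
  TRUE
})
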