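#' Cut a genome into consecutive fragments
#'
#' Each contig is cut independently into consecutive non-overlapping
#' windows of `fragmentLength` nt; a trailing fragment shorter than
#' `fragmentLength` is kept.
#'
#' @param sequences genome (character contigs, `DNAStringSet`, or FASTA
#'   path).
#' @param fragmentLength window size in nt (default 1,020).
#' @return character vector of fragments in contig order.
#' @examples
#' length(fragmentGenome(strrep("A", 2500), 1020)) # 3: 1020/1020/460
#' @export
fragmentGenome <- function(sequences, fragmentLength = 1020L) {
  stopifnot(fragmentLength >= 1)
  contigs <- .as_contigs(sequences)
  contigs <- contigs[nchar(contigs) > 0L]
  if (!length(contigs)) stop("empty genome: no non-empty contigs")
  unlist(lapply(contigs, function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = fragmentLength)
    substring(s, starts, pmin(starts + fragmentLength - 1L, n))
  }), use.names = FALSE)
}

#' One-way fragment-based ANI of a query against a subject genome
#'
#' The query is cut into fragments ([fragmentGenome()]); each fragment's
#' best local alignment against the subject (both strands) is found by the
#' built-in seeded aligner: exact-match word seeding followed by
#' per-diagonal maximal-scoring ungapped extension (match +1, mismatch
#' -1), best hit per fragment, ties broken by lowest subject coordinate.
#' Identity is matches over alignment columns and coverage is alignment
#' columns over the fragment's length. A hit is retained iff coverage is
#' strictly greater than `minCoverage` AND identity strictly greater than
#' `minIdentity`; the one-way ANI is the arithmetic mean of retained
#' identities.
#'
#' @param query,subject genomes (character contigs, `DNAStringSet`, or
#'   FASTA paths).
#' @param config a [linforgeConfig()]; fragment length, filters and seed
#'   word size are taken from it.
#' @param queryId,subjectId identifiers carried into the result.
#' @return an [ANIResult-class]; `aniValue()` is `NA` when no hit passes
#'   the filters ("no significant similarity").
#' @export
oneWayANI <- function(query, subject, config = linforgeConfig(),
                      queryId = "query", subjectId = "subject") {
  frags <- fragmentGenome(query, config$fragmentLength)
  subj <- .as_contigs(subject)
  subj <- subj[nchar(subj) > 0L]
  if (!length(subj)) stop("empty genome: no non-empty contigs")
  # concatenate contigs with an N joint long enough that no scoring
  # segment can bridge two contigs
  joint <- strrep("N", 100L)
  hits <- .fragment_hits(frags, paste(subj, collapse = joint),
                         config$wordSize)
  keep <- !is.na(hits[, "identity"]) & hits[, "identity"] >= 0 &
    hits[, "coverage"] > config$minCoverage &
    hits[, "identity"] > config$minIdentity
  ani <- if (any(keep)) mean(hits[keep, "identity"]) else NA_real_
  new("ANIResult", queryId = as.character(queryId),
      subjectId = as.character(subjectId), ani = ani,
      retained = as.integer(sum(keep)), fragments = length(frags))
}

#' Reciprocal (two-way averaged) ANI between two genomes
#'
#' Computes [oneWayANI()] in both directions and returns the arithmetic
#' mean, the convention used for symmetric ANI matrices. If either
#' direction finds no significant similarity, `NA` is returned (the
#' outcome propagates).
#'
#' @inheritParams oneWayANI
#' @param a,b genomes.
#' @param aId,bId identifiers.
#' @return numeric ANI in percent, or `NA_real_`.
#' @export
reciprocalANI <- function(a, b, config = linforgeConfig(),
                          aId = "a", bId = "b") {
  ab <- oneWayANI(a, b, config, queryId = aId, subjectId = bId)
  ba <- oneWayANI(b, a, config, queryId = bId, subjectId = aId)
  if (!hasSignificantSimilarity(ab) || !hasSignificantSimilarity(ba))
    return(NA_real_)
  (aniValue(ab) + aniValue(ba)) / 2
}

#' ANI result accessors
#'
#' @param x an [ANIResult-class].
#' @return `aniValue`: the one-way ANI (percent, `NA` when undefined);
#'   `retainedFragments` / `totalFragments`: hit counts;
#'   `hasSignificantSimilarity`: whether any fragment hit passed the
#'   filters.
#' @export
aniValue <- function(x) x@ani

#' @rdname aniValue
#' @export
retainedFragments <- function(x) x@retained

#' @rdname aniValue
#' @export
totalFragments <- function(x) x@fragments

#' @rdname aniValue
#' @export
hasSignificantSimilarity <- function(x) x@retained >= 1L

setMethod("show", "ANIResult", function(object) {
  val <- if (hasSignificantSimilarity(object))
    sprintf("ANI = %.4f%%", object@ani) else "no significant similarity"
  cat(sprintf("ANIResult %s -> %s: %s (%d/%d fragments retained)\n",
              object@queryId, object@subjectId, val, object@retained,
              object@fragments))
  invisible(object)
})

#' Write a per-pair ANI report as TSV
#'
#' @param results list of [ANIResult-class] objects (typically both
#'   directions of each pair).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeANIReport <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(query = r@queryId, subject = r@subjectId, ani = r@ani,
               retained = r@retained, fragments = r@fragments,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
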