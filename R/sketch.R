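#' Compute a bottom-n MinHash signature of a genome
#'
#' Enumerates every k-mer of every contig, skips k-mers containing any
#' non-ACGT character, canonicalises each k-mer as the lexicographic
#' minimum of itself and its reverse complement (so a sequence and its
#' reverse complement sketch identically), hashes the canonical k-mer with
#' MurmurHash3 (x64_128 h1, fixed seed 42, truncated to 53 bits so hashes
#' are exact R doubles), and keeps the `n` smallest distinct values.
#'
#' @param sequences genome as a character vector of contigs, a
#'   `DNAStringSet`, or a FASTA path. Case-insensitive.
#' @param genomeId identifier stored in the signature.
#' @param k k-mer length.
#' @param n sketch capacity; the signature holds `min(n, #distinct
#'   canonical k-mers)` hashes.
#' @return a [GenomeSignature-class]. When every sequence is shorter than
#'   `k` (or no window is ACGT-only) the signature is empty and a warning
#'   is raised.
#' @export
computeSignature <- function(sequences, genomeId = "", k = 21L, n = 2000L) {
  contigs <- .as_contigs(sequences)
  hashes <- .sketch_hashes(contigs, as.integer(k), as.integer(n))
  if (length(hashes) == 0L)
    warning("no valid k-mers at k = ", k,
            ": every sequence is shorter than k or contains no ACGT-only ",
            "window; signature is empty")
  new("GenomeSignature", genomeId = as.character(genomeId),
      k = as.integer(k), capacity = as.integer(n), hashes = hashes)
}

#' Estimate Jaccard similarity from two bottom sketches
#'
#' Mash-style bottom-sketch estimator: let `U` be the `min(n, |union|)`
#' smallest hashes of the union of the two sketches; the estimate is the
#' fraction of `U` present in both sketches. Unlike the naive
#' intersection-over-union of the two sketches this is an unbiased
#' estimate of the Jaccard similarity of the full canonical k-mer sets;
#' when `n` is at least the union size it is exact.
#'
#' @param a,b [GenomeSignature-class] objects with equal `k` and capacity.
#' @return similarity in `[0, 1]`. Two empty signatures compare as 0 with
#'   a warning.
#' @export
setGeneric("jaccard", function(a, b) standardGeneric("jaccard"))

#' @rdname jaccard
#' @export
setMethod("jaccard", signature("GenomeSignature", "GenomeSignature"),
  function(a, b) {
    if (a@k != b@k)
      stop(sprintf("k-mer length mismatch: %d vs %d", a@k, b@k))
    if (a@capacity != b@capacity)
      stop(sprintf("sketch capacity mismatch: %d vs %d",
                   a@capacity, b@capacity))
    if (length(a@hashes) == 0L && length(b@hashes) == 0L) {
      warning("both signatures are empty; Jaccard defined as 0")
      return(0)
    }
    u <- sort(unique(c(a@hashes, b@hashes)))
    u <- u[seq_len(min(a@capacity, length(u)))]
    shared <- sum(u %in% a@hashes & u %in% b@hashes)
    shared / length(u)
  })

#' Signature accessors
#'
#' @param sig a [GenomeSignature-class].
#' @return `signatureHashes`: sorted hash values; `kmerSize`: the k-mer
#'   length; `sketchCapacity`: the capacity `n`.
#' @export
signatureHashes <- function(sig) sig@hashes

#' @rdname signatureHashes
#' @export
kmerSize <- function(sig) sig@k

#' @rdname signatureHashes
#' @export
sketchCapacity <- function(sig) sig@capacity

setMethod("show", "GenomeSignature", function(object) {
  cat(sprintf("GenomeSignature '%s': k = %d, %d/%d hashes\n",
              object@genomeId, object@k, length(object@hashes),
              object@capacity))
  invisible(object)
})

# signature file IO: one JSON document per genome holding every sketch;
# hashes are 53-bit integers, serialised as decimal strings so the
# round-trip is bit-exact
.write_signature_file <- function(sigs, path) {
  recs <- lapply(sigs, function(s)
    list(genome_id = s@genomeId, k = s@k, n = s@capacity,
         hashes = sprintf("%.0f", s@hashes)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

.read_signature_file <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  sigs <- lapply(recs, function(r)
    new("GenomeSignature", genomeId = r$genome_id, k = as.integer(r$k),
        capacity = as.integer(r$n), hashes = as.numeric(r$hashes)))
  names(sigs) <- vapply(sigs, function(s) as.character(s@k), "")
  sigs
}
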