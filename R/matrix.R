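#' Construct a similarity matrix
#'
#' @param values symmetric numeric matrix (percent ANI or Jaccard).
#' @param labels genome ids (defaults to the matrix dimnames).
#' @param kind `"ani"` or `"jaccard"`.
#' @return a [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(values, labels = rownames(values),
                             kind = c("ani", "jaccard")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  dimnames(values) <- list(labels, labels)
  obj <- new("SimilarityMatrix", labels = as.character(labels),
             values = values, kind = kind)
  validObject(obj)
  obj
}

#' Matrix accessors
#'
#' @param x a [SimilarityMatrix-class].
#' @export
similarityValues <- function(x) x@values

#' @rdname similarityValues
#' @export
matrixLabels <- function(x) x@labels

#' @rdname similarityValues
#' @export
matrixKind <- function(x) x@kind

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d genomes\n", object@kind,
              length(object@labels)))
  if (length(object@labels)) {
    k <- min(5L, length(object@labels))
    print(round(object@values[seq_len(k), seq_len(k), drop = FALSE], 4))
    if (length(object@labels) > k) cat("...\n")
  }
  invisible(object)
})

# founding genome (lowest insertion order) of LIN number `value` at
# position `pos` under `prefix`
.founder_of <- function(store, scheme, prefix, pos, value) {
  lins <- store@env$lins[[scheme]]
  ids <- names(lins)[vapply(lins, function(l)
    identical(l[seq_len(pos - 1L)], as.integer(prefix)) &&
      l[pos] == value, logical(1))]
  if (!length(ids)) return(NULL)
  ids[which.min(.insertion_order(store, ids))]
}

#' Infer the ANI of a genome pair from stored LINs and ANI records
#'
#' If a precise ANI was recorded directly between the pair (either
#' direction) it is returned as is. Otherwise the pair's LINs diverge at
#' some position p; the two numbers there were each created by a founding
#' event, and the recorded ANI of the later-created number's founding
#' event is propagated to the whole pair — that computation is the one
#' that separated the two branches, so every cross-branch pair inherits
#' it. When no founding record exists (a novel first-position founder)
#' the threshold of the last shared position is returned instead, or 0
#' when the pair shares no position at all.
#'
#' @param store a [LINStore-class].
#' @param x,y genome ids with LINs under `scheme`.
#' @param scheme scheme name (`NULL` for the grouping scheme).
#' @param detail return a list with the inference `rule`
#'   (`"direct"`, `"propagated"`, `"threshold"`) alongside the value.
#' @return numeric ANI in percent (or a list when `detail = TRUE`).
#' @export
inferPairwise <- function(store, x, y, scheme = NULL, detail = FALSE) {
  e <- store@env
  if (is.null(scheme)) scheme <- e$groupingScheme
  sch <- .get_scheme(store, scheme)
  lx <- linOf(store, x, scheme); ly <- linOf(store, y, scheme)
  if (is.null(lx) || is.null(ly))
    stop("both genomes need a LIN under scheme '", scheme, "'")
  done <- function(value, rule)
    if (detail) list(value = value, rule = rule) else value

  a <- e$ani
  i <- which((a$query_id == x & a$subject_id == y) |
               (a$query_id == y & a$subject_id == x))
  if (length(i)) return(done(a$ani[i[1L]], "direct"))

  diff_pos <- which(lx != ly)
  if (!length(diff_pos)) {
    # identical LINs: similarity reaches beyond the scheme's top
    # threshold; propagate the later genome's founding record
    later <- if (.insertion_order(store, x) > .insertion_order(store, y))
      x else y
    rec <- recordedANI(store, later)
    if (!is.null(rec)) return(done(rec$ani, "propagated"))
    return(done(thresholds(sch)[length(sch)], "threshold"))
  }
  p <- diff_pos[1L]
  prefix <- lx[seq_len(p - 1L)]
  fx <- .founder_of(store, scheme, prefix, p, lx[p])
  fy <- .founder_of(store, scheme, prefix, p, ly[p])
  later <- if (.insertion_order(store, fx) > .insertion_order(store, fy))
    fx else fy
  rec <- recordedANI(store, later)
  if (!is.null(rec)) return(done(rec$ani, "propagated"))
  done(if (p > 1L) thresholds(sch)[p - 1L] else 0, "threshold")
}

#' Infer the complete pairwise ANI matrix
#'
#' Applies [inferPairwise()] to every genome pair. Although only one
#' precise ANI computation is stored per genome (after the first), all
#' n(n-1)/2 off-diagonal entries are filled; the matrix is symmetric by
#' construction with a diagonal of 100.
#'
#' @param store a [LINStore-class] with at least one assigned genome.
#' @param scheme scheme name (`NULL` for the grouping scheme).
#' @return a [SimilarityMatrix-class] of kind `"ani"`.
#' @export
fullMatrix <- function(store, scheme = NULL) {
  if (is.null(scheme)) scheme <- store@env$groupingScheme
  ids <- genomeIds(store)
  ids <- ids[!vapply(lapply(ids, linOf, store = store, scheme = scheme),
                     is.null, logical(1))]
  if (!length(ids)) stop("no genome has a LIN under scheme '", scheme, "'")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- inferPairwise(store, ids[i], ids[j], scheme)
  similarityMatrix(m, ids, "ani")
}

#' Complete-linkage hierarchical clustering of a similarity matrix
#'
#' Clusters on distance `100 - ANI` (or `1 - Jaccard`) with the complete
#' linkage criterion (inter-cluster distance = maximum pairwise
#' distance). Deterministic: `stats::hclust` resolves ties by merge
#' order, which is fixed by the label order of the input.
#'
#' @param sm a [SimilarityMatrix-class].
#' @return an `hclust` object labelled with the genome ids.
#' @export
completeLinkage <- function(sm) {
  stopifnot(is(sm, "SimilarityMatrix"))
  top <- if (sm@kind == "ani") 100 else 1
  hclust(as.dist(top - sm@values), method = "complete")
}

#' Mantel correlation between two similarity matrices
#'
#' Pearson correlation of the vectorised upper triangles, with
#' significance from simultaneous row/column permutations of the second
#' matrix: `p = (1 + #{permuted r >= observed r}) / (permutations + 1)`.
#'
#' @param m1,m2 [SimilarityMatrix-class] objects with identical labels in
#'   identical order.
#' @param permutations number of random permutations (default 999).
#' @param seed optional seed; given the same seed the p-value is
#'   reproducible.
#' @return list with `r`, `p`, and `permutations`. A constant matrix
#'   leaves the correlation undefined: `r` and `p` are `NA` with a
#'   warning.
#' @export
mantelTest <- function(m1, m2, permutations = 999L, seed = NULL) {
  stopifnot(is(m1, "SimilarityMatrix"), is(m2, "SimilarityMatrix"),
            permutations >= 1L)
  if (!identical(m1@labels, m2@labels))
    stop("matrix labels differ (or are ordered differently)")
  ut <- upper.tri(m1@values)
  v1 <- m1@values[ut]; v2 <- m2@values[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant matrix: Mantel correlation undefined")
    return(list(r = NA_real_, p = NA_real_,
                permutations = as.integer(permutations)))
  }
  r <- cor(v1, v2)
  n <- length(m1@labels)
  count <- .with_seed(seed, {
    hits <- 0L
    for (b in seq_len(permutations)) {
      idx <- sample.int(n)
      rp <- cor(v1, m2@values[idx, idx][ut])
      if (rp >= r) hits <- hits + 1L
    }
    hits
  })
  list(r = r, p = (1 + count) / (permutations + 1),
       permutations = as.integer(permutations))
}

#' Export a similarity matrix as labelled TSV
#'
#' Values are written at full precision; rounding to a scheme's
#' granularity is the caller's choice (`digits`), never applied
#' internally.
#'
#' @param sm a [SimilarityMatrix-class].
#' @param path output path.
#' @param digits optional rounding for the exported copy only.
#' @return the path, invisibly.
#' @export
exportMatrix <- function(sm, path, digits = NULL) {
  v <- sm@values
  if (!is.null(digits)) v <- round(v, digits)
  write.table(v, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labelled similarity matrix TSV
#'
#' @param path TSV written by [exportMatrix()].
#' @param kind `"ani"` or `"jaccard"`.
#' @return a [SimilarityMatrix-class].
#' @export
readMatrix <- function(path, kind = c("ani", "jaccard")) {
  kind <- match.arg(kind)
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  similarityMatrix(as.matrix(df), rownames(df), kind)
}

#' Export a complete-linkage dendrogram in Newick format
#'
#' @param hc an `hclust` from [completeLinkage()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}
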