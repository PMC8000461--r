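#' Generate a random i.i.d. genome sequence
#'
#' Sites are drawn independently: G or C with probability `gc` (split
#' evenly), A or T otherwise. The same seed always yields the same
#' sequence.
#'
#' @param length sequence length in nt.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a single character string.
#' @export
randomGenome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  .with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste(bases, collapse = "")
  })
}

#' Evolve a sequence by substitutions and indels
#'
#' Substitutions hit each site independently with probability `subRate`
#' and always change the base (uniform among the three alternatives), so
#' with `indelRate = 0` the true-alignment identity is exactly
#' `1 - (#substituted sites) / length`. Indels occur per site with
#' probability `indelRate` (insertions and deletions equally likely,
#' geometric lengths with mean 2). The true parent/child alignment is
#' returned for oracle use.
#'
#' @param parent character string.
#' @param subRate per-site substitution probability in `[0, 0.5)`.
#' @param indelRate per-site indel initiation probability.
#' @param seed integer seed.
#' @return list with `child` (character), `parentAligned` /
#'   `childAligned` (gapped alignment strings), and `identity` (fraction
#'   of alignment columns that match).
#' @export
evolveGenome <- function(parent, subRate, indelRate = 0, seed = 1L) {
  stopifnot(subRate >= 0, subRate < 0.5, indelRate >= 0, indelRate < 0.5)
  .with_seed(seed, {
    p <- strsplit(parent, "")[[1L]]
    n <- length(p)
    child <- p
    hit <- which(runif(n) < subRate)
    if (length(hit)) {
      alts <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                       "A", "C", "G"), nrow = 3,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
      child[hit] <- alts[cbind(sample.int(3L, length(hit), replace = TRUE),
                               match(p[hit], colnames(alts)))]
    }
    if (indelRate == 0) {
      pa <- parent
      ca <- paste(child, collapse = "")
      return(list(child = ca, parentAligned = pa, childAligned = ca,
                  identity = 1 - length(hit) / n))
    }
    events <- which(runif(n) < indelRate)
    pa_parts <- character(0); ca_parts <- character(0)
    cursor <- 1L
    for (e in events) {
      if (e < cursor) next
      pa_parts <- c(pa_parts, paste(p[cursor:e], collapse = ""))
      ca_parts <- c(ca_parts, paste(child[cursor:e], collapse = ""))
      len <- rgeom(1L, 0.5) + 1L
      if (runif(1L) < 0.5) { # insertion in the child
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        pa_parts <- c(pa_parts, strrep("-", len))
        ca_parts <- c(ca_parts, ins)
        cursor <- e + 1L
      } else {               # deletion from the child
        del_end <- min(n, e + len)
        if (del_end >= e + 1L) {
          pa_parts <- c(pa_parts, paste(p[(e + 1L):del_end],
                                        collapse = ""))
          ca_parts <- c(ca_parts, strrep("-", del_end - e))
        }
        cursor <- del_end + 1L
      }
    }
    if (cursor <= n) {
      pa_parts <- c(pa_parts, paste(p[cursor:n], collapse = ""))
      ca_parts <- c(ca_parts, paste(child[cursor:n], collapse = ""))
    }
    pa <- paste(pa_parts, collapse = "")
    ca <- paste(ca_parts, collapse = "")
    pav <- strsplit(pa, "")[[1L]]; cav <- strsplit(ca, "")[[1L]]
    list(child = gsub("-", "", ca), parentAligned = pa, childAligned = ca,
         identity = mean(pav == cav & pav != "-"))
  })
}

#' Describe a simulated clade
#'
#' The tree is a nested list: internal nodes are
#' `list(rate = <edge rate above the node>, children = list(...))`, leaves
#' are `list(rate = ..., name = "leaf_id")`. The root's rate is ignored.
#' Expected identity between two leaves is the product of per-edge k-mer
#' survival, `prod(1 - rate)`, over the edges on the path connecting
#' them — divergence composes multiplicatively because it is
#' parameterised per edge.
#'
#' @param tree nested node list as above.
#' @param genomeLength ancestral genome length (nt); at least ten fragment
#'   lengths for ANI work.
#' @param gc GC fraction of the ancestral genome.
#' @param indelRate per-site indel rate on every edge (default 0, which
#'   keeps the analytic identity oracle exact).
#' @param seed integer seed; all outputs are fully determined by it.
#' @return a `cladeSpec` list.
#' @export
cladeSpec <- function(tree, genomeLength = 50000L, gc = 0.5,
                      indelRate = 0, seed = 1L) {
  stopifnot(genomeLength >= 1, indelRate >= 0, indelRate < 0.5)
  .check_node <- function(node) {
    if (!is.null(node$rate))
      stopifnot(node$rate >= 0, node$rate < 0.5)
    if (!is.null(node$children)) lapply(node$children, .check_node)
    else stopifnot(is.character(node$name))
    invisible(NULL)
  }
  .check_node(tree)
  structure(list(tree = tree, genomeLength = as.integer(genomeLength),
                 gc = gc, indelRate = indelRate, seed = as.integer(seed)),
            class = "cladeSpec")
}

#' Convenience spec: two planted groups
#'
#' A balanced two-group clade: the root splits into two internal edges of
#' rate `betweenRate` each, and each internal node carries `nPerGroup`
#' leaves on edges of rate `withinRate`. With the defaults, within-group
#' expected identity is `(1 - withinRate)^2` (about 99%) and cross-group
#' identity `(1 - betweenRate)^2 (1 - withinRate)^2` (about 93%), placing
#' the planted split on opposite sides of the 95% ANI species threshold.
#'
#' @param nPerGroup leaves per group.
#' @param withinRate,betweenRate per-edge substitution rates.
#' @inheritParams cladeSpec
#' @return a `cladeSpec`.
#' @export
twoGroupClade <- function(nPerGroup = 5L, withinRate = 0.005,
                          betweenRate = 0.03, genomeLength = 50000L,
                          gc = 0.5, indelRate = 0, seed = 1L) {
  leaf <- function(g, i) list(rate = withinRate,
                              name = sprintf("g%d_%02d", g, i))
  grp <- function(g) list(rate = betweenRate,
                          children = lapply(seq_len(nPerGroup), leaf,
                                            g = g))
  cladeSpec(list(rate = 0, children = list(grp(1L), grp(2L))),
            genomeLength = genomeLength, gc = gc, indelRate = indelRate,
            seed = seed)
}

#' Simulate a clade of genomes with known pairwise divergence
#'
#' Simulates sequences down the tree of a [cladeSpec()] and returns the
#' leaf genomes together with the analytic expected pairwise identity
#' matrix (fractions, unit diagonal).
#'
#' @param spec a `cladeSpec`.
#' @return list with `sequences` (named character vector, one genome per
#'   leaf, in tree order) and `expected` (symmetric identity matrix with
#'   leaf labels).
#' @export
makeClade <- function(spec) {
  stopifnot(inherits(spec, "cladeSpec"))
  root_seq <- randomGenome(spec$genomeLength, spec$gc, seed = spec$seed)
  seqs <- character(0)
  paths <- list() # per-leaf vector of edge ids from the root
  edge_rates <- numeric(0)
  edge_n <- 0L
  walk <- function(node, seq, path) {
    if (!is.null(node$children)) {
      for (child in node$children) {
        edge_n <<- edge_n + 1L
        id <- edge_n
        edge_rates[id] <<- child$rate
        ev <- evolveGenome(seq, child$rate, spec$indelRate,
                           seed = spec$seed + 1000L * id)
        walk(child, ev$child, c(path, id))
      }
    } else {
      seqs[node$name] <<- seq
      paths[[node$name]] <<- path
    }
  }
  walk(spec$tree, root_seq, integer(0))
  leaves <- names(seqs)
  n <- length(leaves)
  expected <- matrix(1, n, n, dimnames = list(leaves, leaves))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    pi_ <- paths[[i]]; pj <- paths[[j]]
    path_edges <- c(setdiff(pi_, pj), setdiff(pj, pi_))
    expected[i, j] <- expected[j, i] <- prod(1 - edge_rates[path_edges])
  }
  list(sequences = seqs, expected = expected)
}

#' Write a simulated clade to disk
#'
#' Writes one FASTA file per leaf genome plus the expected pairwise
#' identity matrix as a labelled TSV.
#'
#' @param clade result of [makeClade()].
#' @param dir output directory (created if needed).
#' @return named character vector of FASTA paths, invisibly; the matrix is
#'   at `file.path(dir, "expected_identity.tsv")`.
#' @export
writeClade <- function(clade, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(clade$sequences), function(id) {
    p <- file.path(dir, paste0(id, ".fasta"))
    set <- Biostrings::DNAStringSet(clade$sequences[[id]])
    names(set) <- id
    Biostrings::writeXStringSet(set, p)
    p
  }, "")
  write.table(clade$expected,
              file.path(dir, "expected_identity.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  invisible(paths)
}
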