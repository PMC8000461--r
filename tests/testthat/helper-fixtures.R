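# shared fixtures and independent oracles; everything is generated in code

quiet_config <- function(...) linforgeConfig(logLevel = "quiet", ...)

# exact-Jaccard oracle: enumerate every k-mer of both genomes as strings,
# canonicalise with Biostrings, and compute |A n B| / |A u B| directly --
# fully independent of the package's hashing path
canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(toupper(seq), 1:(n - k + 1L), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

exact_jaccard <- function(a, b, k) {
  A <- canonical_kmer_set(a, k)
  B <- canonical_kmer_set(b, k)
  length(intersect(A, B)) / length(union(A, B))
}

# synthetic signature with chosen hash values (for boundary probes)
synthetic_sig <- function(hashes, id = "syn", k = 21L, n = 2000L) {
  new("GenomeSignature", genomeId = id, k = as.integer(k),
      capacity = as.integer(n), hashes = as.numeric(sort(hashes)))
}

# minimal FASTA on disk, for store bookkeeping tests that never align
tiny_fasta <- function(id, dir = withr::local_tempdir(.local_envir = parent.frame()),
                       seq = NULL) {
  if (is.null(seq)) seq <- randomGenome(400, seed = utf8ToInt(substr(id, 1, 1)) +
                                          nchar(id))
  p <- file.path(dir, paste0(id, ".fasta"))
  writeLines(c(paste0(">", id), seq), p)
  p
}

# replay the incremental assignment logic against a known true-ANI matrix,
# without sequences: subject = most similar already-stored genome, novel
# below 70% ANI. Exercises assignLIN/allocateNumber/recordANI exactly as
# addGenome would, with the ANI oracle replacing alignment.
replay_store <- function(true_ani, order = seq_len(nrow(true_ani)),
                         scheme = builtinScheme("lin20"), dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  ids <- rownames(true_ani)
  store <- createStore(schemes = list(scheme),
                       groupingScheme = schemeName(scheme),
                       config = quiet_config())
  sn <- schemeName(scheme)
  for (i in seq_along(order)) {
    id <- ids[order[i]]
    registerGenome(store, tiny_fasta(id, dir), genomeId = id)
    if (i == 1L) {
      recordLIN(store, id, sn, rep(0L, length(scheme)))
      next
    }
    prev <- ids[order[seq_len(i - 1L)]]
    anis <- true_ani[id, prev]
    subject <- prev[which.max(anis)]
    ani <- true_ani[id, subject]
    if (ani < 70) {
      recordLIN(store, id, sn, assignLIN(NULL, 0, sn, store))
    } else {
      recordLIN(store, id, sn,
                assignLIN(linOf(store, subject, sn), ani, sn, store))
      recordANI(store, id, subject, ani)
    }
  }
  store
}

# enumerate all permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}

# naive O(n^3) complete-linkage agglomeration; returns sorted merge heights
naive_complete_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    heights <- c(heights, best[1L])
    clusters[[best[2L]]] <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters[[best[3L]]] <- NULL
  }
  sort(heights)
}

# random symmetric ANI-like matrix with unit-free values in [lo, hi]
random_ani_matrix <- function(n, lo = 65, hi = 100, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n, lo, hi), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    dimnames(m) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
    m
  })
}
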