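# run `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# coerce genome input (character contigs, DNAStringSet/DNAString, or a
# FASTA path) to an upper-case character vector of contig sequences
.as_contigs <- function(x) {
  if (is(x, "DNAStringSet")) return(toupper(as.character(x)))
  if (is(x, "DNAString")) return(toupper(as.character(x)))
  if (is.character(x)) {
    if (length(x) == 1L && !grepl("^[ACGTNacgtnRYSWKMBDHVryswkmbdhv-]*$", x) &&
        file.exists(x))
      return(toupper(as.character(Biostrings::readDNAStringSet(x))))
    return(toupper(x))
  }
  stop("cannot interpret genome input of class ", class(x)[1L])
}

.read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("unreadable FASTA: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L || sum(Biostrings::width(set)) == 0L)
    stop("empty FASTA: ", path)
  set
}
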