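#' Create an empty LIN store
#'
#' The store realises a small relational contract — genome, taxonomy,
#' scheme, LIN and ANI tables connected by genome id and scheme name —
#' plus the LINgroup-organised signature layout. It is held in memory
#' (single writer) and persisted as a directory of TSV tables and JSON
#' signature files by [saveStore()].
#'
#' @param schemes list of [LINScheme-class] objects to register. The
#'   20-position scheme is always registered in addition.
#' @param config a [linforgeConfig()].
#' @param groupingScheme name of the scheme whose prefix defines the
#'   search LINgroups; defaults to `"lin20"`. The grouping depth is the
#'   number of positions with threshold at or below `config$groupingANI`
#'   (95 by default — the species level, position F of the 20-position
#'   scheme).
#' @param path optional directory the store will be saved to.
#' @return a [LINStore-class].
#' @export
createStore <- function(schemes = list(), config = linforgeConfig(),
                        groupingScheme = "lin20", path = NULL) {
  e <- new.env(parent = emptyenv())
  e$genomes <- data.frame(genome_id = character(), fasta_path = character(),
                          checksum = character(),
                          insertion_order = integer(),
                          stringsAsFactors = FALSE)
  e$taxonomy <- list()     # genome_id -> named character vector
  e$schemes <- list()
  e$lins <- list()         # scheme name -> (genome_id -> integer vector)
  e$ani <- data.frame(query_id = character(), subject_id = character(),
                      ani = numeric(), rec_order = integer(),
                      stringsAsFactors = FALSE)
  e$sigs <- list()         # genome_id -> (as.character(k) -> signature)
  e$repGroups <- character(0) # grouping-prefix key -> representative id
  e$config <- config
  e$groupingScheme <- groupingScheme
  e$path <- path
  store <- new("LINStore", env = e)
  for (s in schemes) addScheme(store, s)
  if (!("lin20" %in% names(e$schemes)))
    addScheme(store, builtinScheme("lin20"))
  if (!(groupingScheme %in% names(e$schemes)))
    stop("grouping scheme '", groupingScheme, "' is not registered")
  store
}

#' Register a scheme with a store
#'
#' @param store a [LINStore-class].
#' @param scheme a [LINScheme-class].
#' @return the store, invisibly.
#' @export
addScheme <- function(store, scheme) {
  e <- store@env
  nm <- schemeName(scheme)
  if (nm %in% names(e$schemes)) {
    warning("scheme '", nm, "' already registered; keeping existing")
    return(invisible(store))
  }
  if (nrow(e$genomes))
    stop("cannot add scheme '", nm, "' after genomes were assigned")
  e$schemes[[nm]] <- scheme
  e$lins[[nm]] <- list()
  invisible(store)
}

.get_scheme <- function(store, name = NULL) {
  e <- store@env
  if (is.null(name)) name <- e$groupingScheme
  sch <- e$schemes[[name]]
  if (is.null(sch)) stop("unknown scheme: ", name)
  sch
}

#' Store accessors
#'
#' @param store a [LINStore-class].
#' @param name scheme name (`NULL` for the grouping scheme).
#' @return `genomeIds`: ids in insertion order; `nGenomes`: count;
#'   `schemeNames`: registered scheme names; `storeScheme`: a scheme by
#'   name; `storeConfig`: the run configuration; `aniRecords`: the ANI
#'   table as a data frame.
#' @export
genomeIds <- function(store) store@env$genomes$genome_id

#' @rdname genomeIds
#' @export
nGenomes <- function(store) nrow(store@env$genomes)

#' @rdname genomeIds
#' @export
schemeNames <- function(store) names(store@env$schemes)

#' @rdname genomeIds
#' @export
storeScheme <- function(store, name = NULL) .get_scheme(store, name)

#' @rdname genomeIds
#' @export
storeConfig <- function(store) store@env$config

#' @rdname genomeIds
#' @export
aniRecords <- function(store) store@env$ani

# grouping prefix depth: leading positions at or below the grouping ANI
.group_depth <- function(store) {
  sharedDepth(.get_scheme(store), store@env$config$groupingANI)
}

.group_key <- function(lin, depth) paste(lin[seq_len(depth)],
                                         collapse = "_")

#' Register a genome with the store
#'
#' Persists the genome's location with the next insertion order.
#' Registration is idempotent on identical path + content checksum: the
#' existing record is returned with a warning instead of a duplicate.
#'
#' @param store a [LINStore-class].
#' @param fastaPath readable, non-empty FASTA file.
#' @param taxonomy optional named character vector of free-form rank
#'   fields (genus, species, strain, ...).
#' @param genomeId identifier; defaults to the file name without
#'   extension.
#' @return list with `genomeId`, `fastaPath`, `insertionOrder`, and
#'   `existed` (TRUE when the registration was a no-op).
#' @export
registerGenome <- function(store, fastaPath, taxonomy = NULL,
                           genomeId = NULL) {
  e <- store@env
  .read_fasta(fastaPath) # validates readability and non-emptiness
  sum <- unname(tools::md5sum(fastaPath))
  if (is.null(genomeId))
    genomeId <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(fastaPath))
  hit <- which(e$genomes$checksum == sum &
                 normalizePath(e$genomes$fasta_path) ==
                   normalizePath(fastaPath))
  if (length(hit)) {
    rec <- e$genomes[hit[1L], ]
    warning("genome already registered as '", rec$genome_id,
            "'; returning existing record")
    return(list(genomeId = rec$genome_id, fastaPath = rec$fasta_path,
                insertionOrder = rec$insertion_order, existed = TRUE))
  }
  if (genomeId %in% e$genomes$genome_id)
    stop("genome id '", genomeId, "' already in use for different content")
  ord <- nrow(e$genomes) + 1L
  e$genomes <- rbind(e$genomes,
                     data.frame(genome_id = genomeId,
                                fasta_path = fastaPath, checksum = sum,
                                insertion_order = ord,
                                stringsAsFactors = FALSE))
  if (!is.null(taxonomy)) e$taxonomy[[genomeId]] <- taxonomy
  list(genomeId = genomeId, fastaPath = fastaPath, insertionOrder = ord,
       existed = FALSE)
}

.insertion_order <- function(store, genomeId) {
  g <- store@env$genomes
  g$insertion_order[match(genomeId, g$genome_id)]
}

#' Record a LIN assignment
#'
#' Stores the LIN of a genome under a scheme (one assignment per genome
#' and scheme). When the scheme is the store's grouping scheme and the
#' LIN opens a new grouping-level LINgroup, the genome becomes that
#' LINgroup's representative.
#'
#' @param store a [LINStore-class].
#' @param genomeId a registered genome.
#' @param scheme scheme name.
#' @param lin integer vector of scheme length.
#' @return the store, invisibly.
#' @export
recordLIN <- function(store, genomeId, scheme, lin) {
  e <- store@env
  sch <- .get_scheme(store, scheme)
  if (!(genomeId %in% e$genomes$genome_id))
    stop("unknown genome: ", genomeId)
  if (length(lin) != length(sch))
    stop("LIN length ", length(lin), " does not match scheme length ",
         length(sch))
  if (any(lin < 0) || any(lin != round(lin)))
    stop("LIN positions must be non-negative integers")
  if (!is.null(e$lins[[scheme]][[genomeId]]))
    stop("genome '", genomeId, "' already has a LIN under scheme '",
         scheme, "'")
  e$lins[[scheme]][[genomeId]] <- as.integer(lin)
  if (identical(scheme, e$groupingScheme)) {
    key <- .group_key(lin, .group_depth(store))
    if (!(key %in% names(e$repGroups))) {
      rep <- setNames(genomeId, key)
      e$repGroups <- c(e$repGroups, rep)
    }
  }
  invisible(store)
}

#' Look up a stored LIN
#'
#' @inheritParams recordLIN
#' @param scheme scheme name (`NULL` for the grouping scheme).
#' @return integer vector, or `NULL` when unassigned.
#' @export
linOf <- function(store, genomeId, scheme = NULL) {
  if (is.null(scheme)) scheme <- store@env$groupingScheme
  store@env$lins[[scheme]][[genomeId]]
}

#' Record one precise ANI computation
#'
#' @param store a [LINStore-class].
#' @param queryId,subjectId registered genomes.
#' @param ani reciprocal ANI in percent.
#' @return the store, invisibly.
#' @export
recordANI <- function(store, queryId, subjectId, ani) {
  e <- store@env
  stopifnot(queryId %in% e$genomes$genome_id,
            subjectId %in% e$genomes$genome_id,
            is.numeric(ani), ani >= 0, ani <= 100)
  if (queryId %in% e$ani$query_id)
    stop("genome '", queryId, "' already has an ANI record")
  e$ani <- rbind(e$ani,
                 data.frame(query_id = queryId, subject_id = subjectId,
                            ani = ani, rec_order = nrow(e$ani) + 1L,
                            stringsAsFactors = FALSE))
  invisible(store)
}

#' The single recorded ANI computation of a genome
#'
#' Every genome added after the first carries exactly one precise ANI
#' computation (its founding event); genomes classified as novel carry
#' none.
#'
#' @inheritParams recordLIN
#' @return list with `queryId`, `subjectId`, `ani`, or `NULL`.
#' @export
recordedANI <- function(store, genomeId) {
  a <- store@env$ani
  i <- match(genomeId, a$query_id)
  if (is.na(i)) return(NULL)
  list(queryId = a$query_id[i], subjectId = a$subject_id[i],
       ani = a$ani[i])
}

#' Allocate the smallest unused number under a LIN prefix
#'
#' Returns the smallest non-negative integer not yet used at position
#' `length(prefix) + 1` among stored LINs that start with `prefix`
#' exactly. Assignments are recorded immediately by the caller
#' ([recordLIN()]), which reserves the number; the store is single
#' writer.
#'
#' @param store a [LINStore-class].
#' @param scheme scheme name.
#' @param prefix integer vector of leading LIN values (possibly empty).
#' @return a non-negative integer.
#' @export
allocateNumber <- function(store, scheme, prefix) {
  sch <- .get_scheme(store, scheme)
  pos <- length(prefix) + 1L
  if (pos > length(sch))
    stop("prefix length ", length(prefix),
         " leaves no position to allocate in scheme of length ",
         length(sch))
  lins <- store@env$lins[[scheme]]
  used <- vapply(lins, function(l) {
    if (length(prefix) &&
        !identical(l[seq_along(prefix)], as.integer(prefix)))
      return(NA_integer_)
    l[pos]
  }, integer(1))
  used <- sort(unique(used[!is.na(used)]))
  candidates <- 0:length(used)
  min(setdiff(candidates, used))
}

#' Genomes whose LIN starts with a prefix
#'
#' @param store a [LINStore-class].
#' @param prefix integer vector of leading LIN values.
#' @param scheme scheme name (`NULL` for the grouping scheme).
#' @return genome ids in insertion order; empty for an unknown prefix.
#' @export
membersOf <- function(store, prefix, scheme = NULL) {
  e <- store@env
  if (is.null(scheme)) scheme <- e$groupingScheme
  lins <- e$lins[[scheme]]
  if (is.null(lins)) stop("unknown scheme: ", scheme)
  ids <- names(lins)[vapply(lins, function(l)
    identical(l[seq_along(prefix)], as.integer(prefix)), logical(1))]
  ids[order(.insertion_order(store, ids))]
}

#' Representative genomes of the grouping-level LINgroups
#'
#' The first member (by insertion order) of each grouping-level LINgroup
#' (95%-level by default).
#'
#' @param store a [LINStore-class].
#' @return genome ids, in order of LINgroup creation.
#' @export
representatives <- function(store) unname(store@env$repGroups)

#' Grouping-level LINgroup key of a genome
#'
#' @inheritParams recordLIN
#' @return the underscore-joined grouping prefix, e.g. `"0_0_0_0_0_0"`.
#' @export
groupKeyOf <- function(store, genomeId) {
  lin <- linOf(store, genomeId)
  if (is.null(lin)) stop("genome '", genomeId, "' has no LIN yet")
  .group_key(lin, .group_depth(store))
}

.set_signature <- function(store, sig) {
  e <- store@env
  id <- sig@genomeId
  if (is.null(e$sigs[[id]])) e$sigs[[id]] <- list()
  e$sigs[[id]][[as.character(sig@k)]] <- sig
  invisible(store)
}

#' Retrieve a stored signature
#'
#' @inheritParams recordLIN
#' @param k k-mer length of the wanted sketch.
#' @return a [GenomeSignature-class], or `NULL`.
#' @export
getSignature <- function(store, genomeId, k) {
  store@env$sigs[[genomeId]][[as.character(k)]]
}

setMethod("show", "LINStore", function(object) {
  e <- object@env
  cat(sprintf(paste0("LINStore: %d genome(s), %d scheme(s) [%s], ",
                     "%d ANI record(s), %d LINgroup(s)\n"),
              nrow(e$genomes), length(e$schemes),
              paste(names(e$schemes), collapse = ", "), nrow(e$ani),
              length(e$repGroups)))
  invisible(object)
})

#' Persist a store to disk
#'
#' Writes the genome, taxonomy, scheme, LIN and ANI tables as TSV, the
#' configuration as YAML, and the signature files in the LINgroup layout:
#' `signatures/groups/<prefix>/<id>.sig` for every member and
#' `signatures/representatives/<id>.sig` for the first member of each
#' grouping-level LINgroup. Genomes registered but not yet assigned go to
#' `signatures/groups/unassigned/`.
#'
#' @param store a [LINStore-class].
#' @param path target directory; defaults to the store's own path.
#' @return the path, invisibly.
#' @export
saveStore <- function(store, path = NULL) {
  e <- store@env
  if (is.null(path)) path <- e$path
  if (is.null(path)) stop("store has no path; pass one explicitly")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(df, file.path(path, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  tsv(e$genomes, "genome.tsv")
  tax_df <- if (length(e$taxonomy)) {
    ranks <- unique(unlist(lapply(e$taxonomy, names)))
    rows <- lapply(names(e$taxonomy), function(id) {
      v <- e$taxonomy[[id]]
      c(genome_id = id, setNames(unname(v[ranks]), ranks))
    })
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else data.frame(genome_id = character(), stringsAsFactors = FALSE)
  tsv(tax_df, "taxonomy.tsv")
  tsv(do.call(rbind, lapply(e$schemes, .scheme_to_record)), "scheme.tsv")
  lin_rows <- list()
  for (sn in names(e$lins)) for (id in names(e$lins[[sn]]))
    lin_rows[[length(lin_rows) + 1L]] <-
      data.frame(genome_id = id, scheme = sn,
                 lin = paste(e$lins[[sn]][[id]], collapse = "_"),
                 stringsAsFactors = FALSE)
  tsv(if (length(lin_rows)) do.call(rbind, lin_rows) else
        data.frame(genome_id = character(), scheme = character(),
                   lin = character(), stringsAsFactors = FALSE),
      "lin.tsv")
  tsv(e$ani, "ani.tsv")
  yaml::write_yaml(c(e$config[!vapply(e$config, is.null, TRUE)],
                     list(groupingScheme = e$groupingScheme)),
                   file.path(path, "config.yaml"))
  sig_root <- file.path(path, "signatures")
  unlink(sig_root, recursive = TRUE)
  rep_dir <- file.path(sig_root, "representatives")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- representatives(store)
  for (id in names(e$sigs)) {
    lin <- linOf(store, id)
    key <- if (is.null(lin)) "unassigned"
           else .group_key(lin, .group_depth(store))
    gdir <- file.path(sig_root, "groups", key)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    .write_signature_file(e$sigs[[id]],
                          file.path(gdir, paste0(id, ".sig")))
    if (id %in% reps)
      .write_signature_file(e$sigs[[id]],
                            file.path(rep_dir, paste0(id, ".sig")))
  }
  e$path <- path
  invisible(path)
}

#' Reopen a persisted store
#'
#' @param path directory written by [saveStore()].
#' @return a [LINStore-class] equivalent to the saved one.
#' @export
openStore <- function(path) {
  if (!dir.exists(path)) stop("no store at ", path)
  tsv <- function(name, ...) {
    f <- file.path(path, name)
    read.delim(f, stringsAsFactors = FALSE, colClasses = "character", ...)
  }
  cfg_all <- yaml::read_yaml(file.path(path, "config.yaml"))
  grouping <- cfg_all$groupingScheme
  cfg_all$groupingScheme <- NULL
  config <- do.call(linforgeConfig, cfg_all)
  sch_df <- tsv("scheme.tsv")
  schemes <- lapply(seq_len(nrow(sch_df)),
                    function(i) .scheme_from_record(sch_df[i, ]))
  store <- createStore(schemes = schemes, config = config,
                       groupingScheme = grouping, path = path)
  e <- store@env
  g <- tsv("genome.tsv")
  g$insertion_order <- as.integer(g$insertion_order)
  e$genomes <- g[order(g$insertion_order), , drop = FALSE]
  tax <- tsv("taxonomy.tsv")
  if (nrow(tax))
    for (i in seq_len(nrow(tax))) {
      v <- unlist(tax[i, setdiff(names(tax), "genome_id"), drop = TRUE])
      e$taxonomy[[tax$genome_id[i]]] <- v[!is.na(v)]
    }
  lin_df <- tsv("lin.tsv")
  if (nrow(lin_df))
    for (i in order(match(lin_df$genome_id, e$genomes$genome_id)))
      recordLIN(store, lin_df$genome_id[i], lin_df$scheme[i],
                as.integer(strsplit(lin_df$lin[i], "_")[[1L]]))
  ani <- tsv("ani.tsv")
  ani$ani <- as.numeric(ani$ani)
  ani$rec_order <- as.integer(ani$rec_order)
  e$ani <- ani[order(ani$rec_order), , drop = FALSE]
  sig_files <- list.files(file.path(path, "signatures", "groups"),
                          pattern = "\\.sig$", recursive = TRUE,
                          full.names = TRUE)
  for (f in sig_files) {
    sigs <- .read_signature_file(f)
    for (s in sigs) .set_signature(store, s)
  }
  store
}
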