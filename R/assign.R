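#' Bracket a Jaccard similarity against the calibration cutoffs
#'
#' At k = 21 with 2,000-hash sketches, a Jaccard similarity above 0.2475
#' corresponds to over 95% ANI (the query belongs to an existing
#' 95%-level LINgroup) and one above 0.0025 to over 70% ANI (the query
#' shares at least the first LIN position). Both constants are empirical
#' calibrations, not formula-derived, and are configurable.
#'
#' @param j Jaccard similarity estimate(s); vectorised.
#' @param upper,lower bracket cutoffs.
#' @return character vector: `"same_f_group"` when `j > upper`,
#'   `"shared_a"` when `lower < j <= upper`, `"novel"` when `j <= lower`.
#' @export
jaccardBracket <- function(j, upper = 0.2475, lower = 0.0025) {
  ifelse(j > upper, "same_f_group",
         ifelse(j > lower, "shared_a", "novel"))
}

#' First-stage search: classify a query against the representatives
#'
#' Computes the Jaccard estimate of the query's k = 21 sketch against the
#' representative of every existing grouping-level LINgroup, takes the
#' maximum (ties broken by the earlier representative, i.e. lowest
#' insertion order), and brackets it with [jaccardBracket()].
#'
#' @param querySig query [GenomeSignature-class] at the primary k.
#' @param repSigs named list of representative signatures at the same k,
#'   ordered by insertion.
#' @param config a [linforgeConfig()].
#' @return a [SearchOutcome-class]; an empty representative list yields
#'   `"novel"` with no subject.
#' @export
classifyQuery <- function(querySig, repSigs, config = linforgeConfig()) {
  if (!length(repSigs))
    return(new("SearchOutcome", bracket = "novel",
               bestSubject = character(0), jaccard = NA_real_))
  js <- vapply(repSigs, function(s) jaccard(querySig, s), numeric(1))
  best <- which.max(js) # first maximum = lowest insertion order
  new("SearchOutcome",
      bracket = jaccardBracket(js[[best]], config$jaccardUpper,
                               config$jaccardLower),
      bestSubject = names(repSigs)[best], jaccard = unname(js[[best]]))
}

#' Outcome accessors
#'
#' @param x a [SearchOutcome-class].
#' @export
searchBracket <- function(x) x@bracket

#' @rdname searchBracket
#' @export
bestSubject <- function(x) x@bestSubject

#' @rdname searchBracket
#' @export
bestJaccard <- function(x) x@jaccard

setMethod("show", "SearchOutcome", function(object) {
  subj <- if (length(object@bestSubject)) object@bestSubject else "<none>"
  cat(sprintf("SearchOutcome: %s (best subject %s, J = %s)\n",
              object@bracket, subj, format(object@jaccard)))
  invisible(object)
})

#' Second-stage search: most similar genome within a LINgroup
#'
#' Ranks the members of the candidate LINgroup by Jaccard similarity to
#' the query and returns the best one. The caller supplies sketches at
#' the resolution matching the bracket: k = 51 inside a 95%-level group
#' (high ANI needs long k-mers for resolution), k = 21 otherwise. Ties go
#' to the earlier member.
#'
#' @param querySig query [GenomeSignature-class].
#' @param memberSigs named list of member signatures at the same k,
#'   ordered by insertion.
#' @return the id of the most similar member.
#' @export
mostSimilarInGroup <- function(querySig, memberSigs) {
  stopifnot(length(memberSigs) >= 1L)
  js <- vapply(memberSigs, function(s) jaccard(querySig, s), numeric(1))
  names(memberSigs)[which.max(js)]
}

#' Derive a new LIN from the subject's LIN and the computed ANI
#'
#' Copies the subject's LIN from the first position through the last
#' position whose threshold is lower than or equal to the ANI, assigns
#' the next position the smallest number not yet used under that exact
#' prefix (reserved via the store), and fills the remaining positions
#' with zeros. When the ANI reaches the scheme's top threshold there is
#' no position left to individualise and the subject's full LIN is
#' copied — LINs are deliberately not unique; genome ids are.
#'
#' @param subjectLin the subject's LIN, or `NULL` for a novel genome (a
#'   fresh number at the first position, zeros after).
#' @param ani reciprocal ANI in percent.
#' @param scheme scheme name (resolved in `store`).
#' @param store a [LINStore-class] used for number allocation.
#' @return integer LIN of scheme length.
#' @export
assignLIN <- function(subjectLin, ani, scheme, store) {
  sch <- .get_scheme(store, scheme)
  len <- length(sch)
  if (is.null(subjectLin)) {
    d <- 0L
  } else {
    stopifnot(length(subjectLin) == len, ani >= 0, ani <= 100)
    d <- sharedDepth(sch, ani)
  }
  if (d == len) return(as.integer(subjectLin))
  prefix <- if (d > 0L) as.integer(subjectLin[seq_len(d)]) else integer(0)
  as.integer(c(prefix, allocateNumber(store, scheme, prefix),
               rep(0L, len - d - 1L)))
}

#' Add a genome to the store and assign its LIN(s)
#'
#' Orchestrates the full incremental flow: register the genome, sketch it
#' at both k values, classify it against the representatives of the
#' existing 95%-level LINgroups ([classifyQuery()]), locate the single
#' most similar stored genome within the winning group
#' ([mostSimilarInGroup()]), compute one precise reciprocal ANI against
#' that subject, and assign a LIN under every registered scheme from the
#' subject's LIN and that one ANI value. The ANI record and signatures
#' are persisted in the store; a genome that opens a new 95%-level
#' LINgroup becomes its representative.
#'
#' The first genome of a store receives the all-zero LIN under every
#' scheme, with no ANI computation. A query whose best Jaccard falls at
#' or below the lower cutoff is novel: fresh number at the first
#' position, zeros after, no ANI computation. If the bracket promised
#' similarity but the precise ANI finds none ("no significant
#' similarity"), the genome is demoted to novel with a warning — a
#' calibration disagreement worth auditing.
#'
#' @param store a [LINStore-class].
#' @param fastaPath genome assembly FASTA (possibly multi-contig).
#' @param taxonomy optional named character vector of rank fields.
#' @param genomeId optional identifier (defaults to the file name).
#' @return invisibly, a list with `genomeId`, `bracket`, `subject`,
#'   `jaccard`, `ani` and `lins` (named list of assigned LINs).
#' @export
addGenome <- function(store, fastaPath, taxonomy = NULL,
                      genomeId = NULL) {
  e <- store@env
  cfg <- e$config
  rec <- registerGenome(store, fastaPath, taxonomy, genomeId)
  id <- rec$genomeId
  if (rec$existed && !is.null(linOf(store, id)))
    return(invisible(list(genomeId = id, bracket = "existing",
                          subject = character(0), jaccard = NA_real_,
                          ani = NA_real_,
                          lins = lapply(setNames(nm = schemeNames(store)),
                                        linOf, store = store,
                                        genomeId = id))))
  seqs <- .as_contigs(.read_fasta(fastaPath))
  sigP <- computeSignature(seqs, id, k = cfg$kPrimary,
                           n = cfg$sketchSize)
  sigS <- computeSignature(seqs, id, k = cfg$kSecondary,
                           n = cfg$sketchSize)
  .set_signature(store, sigP)
  .set_signature(store, sigS)

  reps <- setdiff(representatives(store), id)
  repSigs <- lapply(setNames(nm = reps), getSignature, store = store,
                    k = cfg$kPrimary)
  out <- classifyQuery(sigP, repSigs, cfg)
  bracket <- out@bracket
  subject <- character(0)
  ani <- NA_real_

  if (rec$insertionOrder == 1L) {
    bracket <- "first_genome"
    lins <- lapply(setNames(nm = schemeNames(store)), function(sn)
      rep(0L, length(.get_scheme(store, sn))))
  } else if (bracket != "novel") {
    key_prefix <- linOf(store, out@bestSubject)[seq_len(.group_depth(store))]
    members <- setdiff(membersOf(store, key_prefix), id)
    k2 <- if (bracket == "same_f_group") cfg$kSecondary else cfg$kPrimary
    qsig <- if (bracket == "same_f_group") sigS else sigP
    memberSigs <- lapply(setNames(nm = members), getSignature,
                         store = store, k = k2)
    subject <- mostSimilarInGroup(qsig, memberSigs)
    ani <- reciprocalANI(seqs,
                         .as_contigs(.read_fasta(
                           e$genomes$fasta_path[
                             match(subject, e$genomes$genome_id)])),
                         cfg, aId = id, bId = subject)
    if (is.na(ani)) {
      warning("bracket '", bracket, "' promised similarity to '",
              subject, "' but precise ANI found no significant ",
              "similarity; treating '", id, "' as novel (calibration ",
              "disagreement)")
      bracket <- "novel"
      subject <- character(0)
      lins <- lapply(setNames(nm = schemeNames(store)), function(sn)
        assignLIN(NULL, 0, sn, store))
    } else {
      lins <- lapply(setNames(nm = schemeNames(store)), function(sn)
        assignLIN(linOf(store, subject, sn), ani, sn, store))
    }
  } else {
    lins <- lapply(setNames(nm = schemeNames(store)), function(sn)
      assignLIN(NULL, 0, sn, store))
  }

  for (sn in names(lins)) recordLIN(store, id, sn, lins[[sn]])
  if (length(subject) && !is.na(ani)) recordANI(store, id, subject, ani)
  .log_info(cfg,
            "add %s: bracket=%s subject=%s J=%s ANI=%s LIN=%s", id,
            bracket,
            if (length(subject)) subject else "-",
            format(out@jaccard), format(ani),
            paste(lins[[e$groupingScheme]], collapse = "_"))
  invisible(list(genomeId = id, bracket = bracket, subject = subject,
                 jaccard = out@jaccard, ani = ani, lins = lins))
}
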