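.empty_assignments <- function() {
  data.frame(locus_id = character(), status = character(),
             family = character(), superfamily = character(),
             within_intact = logical(), overlap_fraction = numeric(),
             best_identity = numeric(), best_span = numeric(),
             stringsAsFactors = FALSE)
}

#' Attribute loci to annotated elements by coordinate containment
#'
#' A locus is `within_te` when at least `containment` of its span lies
#' inside a single annotated element; when several elements qualify, the one
#' with the largest overlap wins (tie: smaller element start).  All other
#' loci are provisionally `unknown_repeat` until
#' [assignLociBySimilarity()] has seen them.
#'
#' @param loci a loci `GRanges` from [clusterHits()].
#' @param annotations an annotation `GRanges` from [readTEAnnotations()].
#' @param params an [AssignParams-class].
#' @return a `data.frame` with one row per locus: `locus_id`, `status`
#'   (`within_te` / `unknown_repeat`), `family`, `superfamily`,
#'   `within_intact`, `overlap_fraction`, `best_identity`, `best_span`
#'   (the latter two `NA` until similarity assignment).
#' @export
associateLoci <- function(loci, annotations, params = AssignParams()) {
  validObject(params)
  if (length(loci) == 0L) return(.empty_assignments())
  if (length(annotations) &&
      !any(as.character(seqnames(loci)) %in%
           as.character(seqnames(annotations))))
    warning("no chromosome name shared between loci and annotations; ",
            "naming schemes probably differ")
  res <- data.frame(locus_id = mcols(loci)$locus_id,
                    status = "unknown_repeat",
                    family = NA_character_, superfamily = NA_character_,
                    within_intact = FALSE, overlap_fraction = 0,
                    best_identity = NA_real_, best_span = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(annotations) == 0L) return(res)
  ov <- suppressWarnings(findOverlaps(loci, annotations,
                                      ignore.strand = TRUE))
  if (length(ov)) {
    qh <- queryHits(ov)
    sh <- subjectHits(ov)
    ow <- pmin(end(loci)[qh], end(annotations)[sh]) -
          pmax(start(loci)[qh], start(annotations)[sh]) + 1L
    # winner per locus: largest overlap, tie -> smaller annotation start
    o <- order(qh, -ow, start(annotations)[sh])
    first <- !duplicated(qh[o])
    qw <- qh[o][first]
    sw <- sh[o][first]
    frac <- (ow[o][first]) / width(loci)[qw]
    res$overlap_fraction[qw] <- frac     # best fraction, attributed or not
    hit <- frac >= params@containment
    qw <- qw[hit]; sw <- sw[hit]
    res$status[qw] <- "within_te"
    res$family[qw] <- mcols(annotations)$family[sw]
    res$superfamily[qw] <- mcols(annotations)$superfamily[sw]
    res$within_intact[qw] <- mcols(annotations)$intact[sw]
  }
  res
}

# Local alignment under BLAST-like scoring (match +1, mismatch -2, affine
# gaps 5/2): extension through non-homologous sequence is unprofitable, so
# the alignment stays confined to the genuinely similar segment and its
# column identity is meaningful.
.local_align_best <- function(subject_seq, exemplar) {
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  best <- NULL
  for (qry in list(exemplar, reverseComplement(exemplar))) {
    pa <- pairwiseAlignment(qry, subject_seq, type = "local",
                            substitutionMatrix = mat,
                            gapOpening = 5, gapExtension = 2)
    cols <- nchar(pa)
    cand <- list(identity = nmatch(pa) / cols, span = cols,
                 score = score(pa))
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Assign orphan loci to element families by flanking-sequence similarity
#'
#' Loci that are not inside any annotated element are compared, with `flank`
#' bp of context on each side (clipped at chromosome ends), against one
#' exemplar sequence per element family.  The best local alignment against
#' each exemplar (both orientations) is scored; when some exemplar reaches
#' `assign_identity` over at least `assign_min_span` alignment columns, the
#' locus becomes `similarity_assigned` to that family (ties: higher
#' identity, then longer span, then label order).  Loci matching no exemplar
#' stay `unknown_repeat`.
#'
#' @param loci a loci `GRanges`.
#' @param genome the genome `DNAStringSet` the loci live on.
#' @param exemplars a named `DNAStringSet`, one exemplar per family.
#' @param params an [AssignParams-class].
#' @param assignments the `data.frame` from [associateLoci()]; rows with
#'   `status == "within_te"` are left untouched.
#' @param annotations optional annotation `GRanges` used to look up the
#'   superfamily of an assigned family.
#' @return the updated assignment `data.frame`.
#' @export
assignLociBySimilarity <- function(loci, genome, exemplars,
                                   params = AssignParams(),
                                   assignments = NULL, annotations = NULL) {
  validObject(params)
  if (length(exemplars) == 0L)
    stop("usage error: empty exemplar library")
  if (is.null(names(exemplars)) || any(!nzchar(names(exemplars))))
    stop("usage error: exemplars must be named by family")
  if (is.null(assignments))
    assignments <- associateLoci(loci, GRanges(), params)
  supmap <- character()
  if (!is.null(annotations) && length(annotations))
    supmap <- vapply(split(mcols(annotations)$superfamily,
                           mcols(annotations)$family),
                     `[[`, character(1), 1L)
  todo <- which(assignments$status != "within_te")
  for (i in todo) {
    chrom <- as.character(seqnames(loci))[i]
    s <- max(1L, start(loci)[i] - params@flank)
    e <- min(nchar(genome[[chrom]]), end(loci)[i] + params@flank)
    region <- subseq(genome[[chrom]], s, e)
    hits <- lapply(seq_along(exemplars), function(k)
      .local_align_best(region, exemplars[[k]]))
    ok <- vapply(hits, function(h)
      h$identity >= params@assign_identity &&
      h$span >= params@assign_min_span, logical(1))
    if (any(ok)) {
      idx <- which(ok)
      o <- order(-vapply(hits[idx], `[[`, numeric(1), "identity"),
                 -vapply(hits[idx], `[[`, numeric(1), "span"),
                 names(exemplars)[idx])
      k <- idx[o[1L]]
      assignments$status[i] <- "similarity_assigned"
      assignments$family[i] <- names(exemplars)[k]
      assignments$superfamily[i] <-
        if (names(exemplars)[k] %in% names(supmap))
          supmap[[names(exemplars)[k]]] else "Unknown"
      assignments$best_identity[i] <- hits[[k]]$identity
      assignments$best_span[i] <- hits[[k]]$span
    } else {
      assignments$status[i] <- "unknown_repeat"
    }
  }
  assignments
}

#' Classify every locus: within an element, similarity-assigned, or unknown
#'
#' Runs [associateLoci()] and, when a genome and exemplar library are
#' supplied, [assignLociBySimilarity()] on the remainder, so that every
#' locus receives exactly one of the three statuses.
#'
#' @inheritParams assignLociBySimilarity
#' @param annotations an annotation `GRanges`.
#' @return the assignment `data.frame` (one row per locus).
#' @export
classifyLoci <- function(loci, annotations, genome = NULL, exemplars = NULL,
                         params = AssignParams()) {
  assignments <- associateLoci(loci, annotations, params)
  if (!is.null(genome) && !is.null(exemplars) && length(exemplars))
    assignments <- assignLociBySimilarity(loci, genome, exemplars, params,
                                          assignments, annotations)
  assignments
}
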