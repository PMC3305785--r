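#' Cluster unique hits into discrete loci
#'
#' Single linear pass per chromosome over hits sorted by (chrom, start): a
#' hit starts a new locus exactly when the gap between it and the previous
#' member (bases strictly between them) exceeds `max_gap_locus`.  With
#' `per_family = TRUE` the pass is made separately for every monomer family,
#' yielding the per-repeat locus counts of the census table; the default
#' pooled mode defines the loci used for element attribution and array
#' analysis.
#'
#' @param hits a deduplicated hits `GRanges` sorted by (chrom, start);
#'   unsorted input is refused rather than silently reordered.
#' @param params a [ClusterParams-class].
#' @return a `GRanges` of loci sorted by (chrom, start) with mcols
#'   `locus_id` (`"chrom:start-end"`), `n_hits`, `families`
#'   (`CharacterList` of member labels), `members` (`IntegerList` of indices
#'   into `hits`) and, in per-family mode, `family`.
#' @export
clusterHits <- function(hits, params = ClusterParams()) {
  validObject(params)
  empty <- GRanges(locus_id = character(), n_hits = integer(),
                   families = CharacterList(), members = IntegerList())
  if (length(hits) == 0L) return(empty)
  ord <- order(as.integer(seqnames(hits)), start(hits))
  if (!identical(ord, seq_along(hits)))
    stop("usage error: hits must be sorted by (chrom, start); ",
         "use sort(hits, ignore.strand = TRUE)")
  fam <- mcols(hits)$family
  key <- if (params@per_family)
    paste(as.character(seqnames(hits)), fam, sep = "\r")
  else as.character(seqnames(hits))
  idx <- split(seq_along(hits), key)
  loci <- lapply(idx, function(i) {
    s <- start(hits)[i]
    e <- end(hits)[i]
    n <- length(i)
    brk <- c(TRUE, s[-1L] - e[-n] - 1L > params@max_gap_locus)
    cid <- cumsum(brk)
    res <- lapply(split(seq_len(n), cid), function(j) {
      list(chrom = as.character(seqnames(hits))[i[j[1L]]],
           start = s[j[1L]], end = max(e[j]), members = i[j])
    })
    res
  })
  loci <- unlist(loci, recursive = FALSE, use.names = FALSE)
  gr <- GRanges(vapply(loci, `[[`, character(1), "chrom"),
                IRanges(vapply(loci, `[[`, integer(1), "start"),
                        vapply(loci, `[[`, integer(1), "end")))
  members <- IntegerList(lapply(loci, `[[`, "members"))
  mcols(gr)$locus_id <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                                start(gr), end(gr))
  mcols(gr)$n_hits <- lengths(members)
  mcols(gr)$families <- CharacterList(lapply(members, function(i)
    sort(unique(fam[i]))))
  mcols(gr)$members <- members
  if (params@per_family) {
    mcols(gr)$family <- vapply(as.list(members), function(i) fam[i[1L]],
                               character(1))
    mcols(gr)$locus_id <- paste(mcols(gr)$locus_id, mcols(gr)$family,
                                sep = ":")
  }
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  gr[o]
}

#' Per-family unique-hit and locus counts
#'
#' For each monomer family, the number of unique hits and the number of
#' discrete loci obtained by clustering that family's hits alone with the
#' same gap threshold (the "Total hits / No. of discrete loci" pairs of the
#' census table).
#'
#' @inheritParams clusterHits
#' @return a `data.frame` with columns `family`, `total_hits`, `n_loci`,
#'   ordered by family label.
#' @export
perFamilyCounts <- function(hits, params = ClusterParams()) {
  pf <- ClusterParams(max_gap_locus = params@max_gap_locus, per_family = TRUE)
  loci <- clusterHits(hits, pf)
  fams <- sort(unique(mcols(hits)$family))
  data.frame(
    family = fams,
    total_hits = as.integer(table(factor(mcols(hits)$family, levels = fams))),
    n_loci = as.integer(table(factor(mcols(loci)$family, levels = fams))),
    stringsAsFactors = FALSE)
}
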