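# Greedy selection: walk candidates in priority order, keep one unless a
# previously kept candidate conflicts with it.  Conflict pairs must be
# symmetric (both directions present).
.greedy_select <- function(n, ord, pair_from, pair_to) {
  adj <- unname(split(pair_to, factor(pair_from, levels = seq_len(n))))
  keep <- logical(n)
  dead <- logical(n)
  for (i in ord) {
    if (dead[i]) next
    keep[i] <- TRUE
    dead[adj[[i]]] <- TRUE
  }
  keep
}

.scan_strand <- function(text, consensus, emax, bmax, strand) {
  L <- nchar(consensus)
  raw <- scan_motif_cpp(text, consensus, as.integer(emax))
  w <- raw$end - raw$start0
  ok <- abs(w - L) <= bmax
  data.frame(start = raw$start0[ok] + 1L, end = raw$end[ok],
             edits = raw$cost[ok], strand = rep(strand, sum(ok)))
}

# Reduce overlapping same-family candidates to local maxima:
# highest identity, tie -> leftmost, tie -> longest, tie -> plus strand.
.reduce_candidates <- function(cand) {
  if (nrow(cand) < 2L) return(cand)
  ord <- order(-cand$identity, cand$start, -(cand$end - cand$start),
               cand$strand)
  ov <- findOverlaps(IRanges(cand$start, cand$end), drop.self = TRUE)
  keep <- .greedy_select(nrow(cand), ord, queryHits(ov), subjectHits(ov))
  cand[keep, , drop = FALSE]
}

#' Scan a genome for approximate monomer matches
#'
#' Finds every locally maximal semi-global alignment of each monomer
#' consensus against the genome (both strands) whose identity reaches
#' `min_identity`.  Identity is defined as `1 - edits / L` where `edits` is
#' the minimal number of substitutions plus indels needed to align the full
#' consensus (length `L`) against a genomic window, so a 26-bp monomer
#' tolerates at most two edits at the default 0.90 threshold.  Observed hit
#' lengths are confined to `[L * (1 - band), L * (1 + band)]`.  Minus-strand
#' matches are found by scanning the reverse complement of the consensus and
#' reported in plus-strand coordinates with strand `-`.  Overlapping
#' same-family candidates are reduced to local maxima (highest identity,
#' tie: leftmost, tie: longest).
#'
#' `N` bases never match any consensus base, so assembly gaps cannot seed
#' hits.
#'
#' @param genome a named [Biostrings::DNAStringSet] (see [readGenome()]).
#' @param motifs a [MotifSet-class] of monomer consensus sequences, each at
#'   least 10 bp (shorter monomers are refused: the identity model is
#'   meaningless below that scale).
#' @param params a [ScanParams-class].
#' @return a `GRanges` of hits sorted by (chrom, start), with mcols
#'   `family` (label), `identity` (fraction), `edits` (integer) and strand;
#'   `seqlengths` are set from the genome.
#' @examples
#' motifs <- defaultMotifs()
#' genome <- DNAStringSet(c(chr1 = paste0(
#'   strrep("T", 100), as.character(motifs[["A"]]), strrep("G", 100))))
#' scanGenome(genome, motifs)
#' @export
scanGenome <- function(genome, motifs, params = ScanParams()) {
  if (!is(genome, "DNAStringSet"))
    stop("usage error: 'genome' must be a DNAStringSet")
  if (!is(motifs, "MotifSet")) motifs <- MotifSet(motifs)
  validObject(params)
  if (length(genome) == 0L) stop("usage error: empty genome")
  if (any(width(motifs) < 10L))
    stop("usage error: monomer(s) shorter than 10 bp: ",
         paste(motifLabels(motifs)[width(motifs) < 10L], collapse = ", "))
  out <- vector("list", length(genome) * length(motifs))
  k <- 0L
  for (chrom in names(genome)) {
    text <- as.character(genome[[chrom]])
    for (lab in motifLabels(motifs)) {
      cons <- as.character(motifs[[lab]])
      L <- nchar(cons)
      emax <- floor((1 - params@min_identity) * L + 1e-9)
      bmax <- floor(params@band * L + 1e-9)
      cand <- .scan_strand(text, cons, emax, bmax, "+")
      if (params@both_strands) {
        rc <- as.character(reverseComplement(DNAString(cons)))
        cand <- rbind(cand, .scan_strand(text, rc, emax, bmax, "-"))
      }
      cand$identity <- 1 - cand$edits / L
      cand <- .reduce_candidates(cand)
      if (nrow(cand)) {
        k <- k + 1L
        out[[k]] <- GRanges(chrom, IRanges(cand$start, cand$end),
                            strand = cand$strand, family = lab,
                            identity = cand$identity,
                            edits = as.integer(cand$edits))
      }
    }
  }
  gr <- if (k) suppressWarnings(do.call(c, out[seq_len(k)]))
        else GRanges(family = character(), identity = numeric(),
                     edits = integer())
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- width(genome)
  sort(gr, ignore.strand = TRUE)
}

#' Resolve cross-family matches into a unique hit set
#'
#' Two hits conflict when they overlap by more than `overlap_frac` of the
#' shorter hit (families sharing sub-repeats, such as two monomers with a
#' common tail, genuinely cross-match).  Conflicts are resolved in favor of
#' the higher identity, then the longer hit, then the lexicographically
#' smaller family label, so the result is deterministic regardless of input
#' order.
#'
#' @param hits a hits `GRanges` (from [scanGenome()] or [readHitTable()]).
#' @param overlap_frac conflict threshold as a fraction of the shorter hit;
#'   default 0.5.
#' @return the retained hits, sorted by (chrom, start).
#' @export
dedupeHits <- function(hits, overlap_frac = 0.5) {
  if (length(hits) < 2L) return(sort(hits, ignore.strand = TRUE))
  hits <- sort(hits, ignore.strand = TRUE)
  ov <- findOverlaps(hits, drop.self = TRUE, ignore.strand = TRUE)
  qh <- queryHits(ov)
  sh <- subjectHits(ov)
  ovw <- pmin(end(hits)[qh], end(hits)[sh]) -
         pmax(start(hits)[qh], start(hits)[sh]) + 1L
  conflict <- ovw > overlap_frac * pmin(width(hits)[qh], width(hits)[sh])
  ord <- order(-mcols(hits)$identity, -width(hits), mcols(hits)$family,
               as.integer(seqnames(hits)), start(hits))
  keep <- .greedy_select(length(hits), ord, qh[conflict], sh[conflict])
  hits[keep]
}
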