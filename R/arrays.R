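#' Ordered monomer labels of a locus
#'
#' @param locus a single locus (one row of the `GRanges` from
#'   [clusterHits()]).
#' @param hits the hits `GRanges` the locus `members` index into.
#' @return a `data.frame` with one row per member monomer, in genomic order:
#'   `label`, `start`, `end`, `strand`, and `gap_before` (bases strictly
#'   between this monomer and the previous one; 0 for the first).
#' @export
labelSequence <- function(locus, hits) {
  if (length(locus) != 1L)
    stop("usage error: 'locus' must be a single locus")
  i <- mcols(locus)$members[[1L]]
  i <- i[order(start(hits)[i], end(hits)[i])]
  s <- start(hits)[i]
  e <- end(hits)[i]
  data.frame(label = mcols(hits)$family[i], start = s, end = e,
             strand = as.character(strand(hits))[i],
             gap_before = c(0L, s[-1L] - e[-length(e)] - 1L),
             stringsAsFactors = FALSE)
}

.canonical_rotation <- function(unit) {
  ch <- strsplit(unit, "")[[1L]]
  n <- length(ch)
  min(vapply(seq_len(n) - 1L, function(k)
    paste(ch[(((seq_len(n) - 1L) + k) %% n) + 1L], collapse = ""),
    character(1)))
}

# Best tandem run in a label vector: maximal count*u cover, tie -> smaller
# unit, tie -> leftmost.  Returns NULL when no unit repeats at least twice.
.best_run <- function(lab, max_unit_len) {
  n <- length(lab)
  best <- NULL
  for (u in seq_len(min(max_unit_len, n %/% 2L))) {
    eq <- lab[seq_len(n - u)] == lab[seq_len(n - u) + u]
    r <- integer(n - u)
    run <- 0L
    for (j in (n - u):1L) {        # longest all-TRUE run of eq starting at j
      run <- if (eq[j]) run + 1L else 0L
      r[j] <- run
    }
    k <- 1L + r %/% u              # tandem count of the unit starting at p
    cover <- u * k
    cover[k < 2L] <- 0L
    p <- which.max(cover)          # leftmost maximum
    if (cover[p] > 0L &&
        (is.null(best) || cover[p] > best$cover))
      best <- list(p = p, u = u, k = k[p], cover = cover[p])
  }
  best
}

# Recursive maximal-run-first decomposition of one gap-free block.
# Emits segments (kind "tandem" or "remainder") covering indices from..to.
.decompose_block <- function(lab, offset, max_unit_len) {
  n <- length(lab)
  if (n == 0L) return(list())
  run <- .best_run(lab, max_unit_len)
  if (is.null(run))
    return(list(list(kind = "remainder",
                     unit = paste(lab, collapse = ""), count = 1L,
                     from = offset + 1L, to = offset + n)))
  p <- run$p
  len <- run$u * run$k
  c(.decompose_block(lab[seq_len(p - 1L)], offset, max_unit_len),
    list(list(kind = "tandem",
              unit = paste(lab[p:(p + run$u - 1L)], collapse = ""),
              count = run$k, from = offset + p, to = offset + p + len - 1L)),
    .decompose_block(lab[seq_len(n - p - len + 1L) + p + len - 1L],
                     offset + p + len - 1L, max_unit_len))
}

#' Decompose a locus's monomer sequence into tandem-array segments
#'
#' Finds the maximal-cover tandem run (largest `count * unit_length`, ties
#' to the smaller unit, then the leftmost start), cuts it out, and recurses
#' on both sides; monomers in no run accumulate into remainder segments.  A
#' junction gap larger than `max_gap_tandem` always terminates a run (the
#' "unbroken" boundary), so the label sequence is first split into gap-free
#' blocks.  Units are reported both as they occur (phase-preserving, e.g.
#' `"ABAC"`) and as their lexicographically smallest rotation, since pattern
#' phase is meaningful when comparing arrays.
#'
#' @param labels the `data.frame` from [labelSequence()], or a character
#'   vector of labels (gaps then taken as 0).
#' @param params a [TandemParams-class].
#' @param locus_id identifier copied into the segment table.
#' @return a list with `segments` (a `data.frame`: `locus_id`, `kind`,
#'   `unit`, `canonical_unit`, `count`, `n_monomers`, `start`, `end`,
#'   `span_bp`, in genomic order), `remainder` (concatenation of all
#'   non-tandem labels) and `label_string`.
#' @examples
#' decomposeArray(strsplit("ABACABACABAC", "")[[1]])$segments
#' @export
decomposeArray <- function(labels, params = TandemParams(), locus_id = NA) {
  validObject(params)
  if (is.character(labels)) {
    n <- length(labels)
    labels <- data.frame(label = labels,
                         start = cumsum(c(1L, rep(1L, n - 1L))),
                         end = seq_len(n), strand = "+",
                         gap_before = 0L, stringsAsFactors = FALSE)
    labels$end <- labels$start
  }
  stopifnot(nrow(labels) >= 1L)
  blk <- cumsum(labels$gap_before > params@max_gap_tandem |
                  seq_len(nrow(labels)) == 1L)
  segs <- list()
  for (b in split(seq_len(nrow(labels)), blk))
    segs <- c(segs, .decompose_block(labels$label[b], b[1L] - 1L,
                                     params@max_unit_len))
  df <- data.frame(
    locus_id = locus_id,
    kind = vapply(segs, `[[`, character(1), "kind"),
    unit = vapply(segs, `[[`, character(1), "unit"),
    count = vapply(segs, `[[`, integer(1), "count"),
    from = vapply(segs, `[[`, integer(1), "from"),
    to = vapply(segs, `[[`, integer(1), "to"),
    stringsAsFactors = FALSE)
  df$canonical_unit <- ifelse(df$kind == "tandem",
                              vapply(df$unit, .canonical_rotation,
                                     character(1)), NA_character_)
  df$n_monomers <- df$to - df$from + 1L
  df$start <- labels$start[df$from]
  df$end <- labels$end[df$to]
  df$span_bp <- df$end - df$start + 1L
  df <- df[order(df$from),
           c("locus_id", "kind", "unit", "canonical_unit", "count",
             "n_monomers", "start", "end", "span_bp")]
  rownames(df) <- NULL
  list(segments = df,
       remainder = paste(df$unit[df$kind == "remainder"], collapse = ""),
       label_string = paste(labels$label, collapse = ""))
}

#' Decompose every locus
#'
#' @param loci a loci `GRanges` from [clusterHits()].
#' @param hits the hits `GRanges` the loci were built from.
#' @param params a [TandemParams-class].
#' @return the combined segment `data.frame` over all loci (see
#'   [decomposeArray()]).
#' @export
decomposeLoci <- function(loci, hits, params = TandemParams()) {
  out <- lapply(seq_along(loci), function(i)
    decomposeArray(labelSequence(loci[i], hits), params,
                   locus_id = mcols(loci)$locus_id[i])$segments)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Rank unbroken tandem arrays by genomic span
#'
#' @param segments the segment `data.frame` from [decomposeLoci()].
#' @return the tandem segments ordered by `span_bp` (descending), ties by
#'   `count` then input order.
#' @export
longestUnbroken <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L)
    return(segments[integer(0), , drop = FALSE])
  t <- segments[segments$kind == "tandem", , drop = FALSE]
  t <- t[order(-t$span_bp, -t$count), , drop = FALSE]
  rownames(t) <- NULL
  t[, c("locus_id", "unit", "canonical_unit", "count", "span_bp", "start",
        "end")]
}

#' Per-family sequence and length variant profiles
#'
#' @param hits a unique hits `GRanges` with mcols `family`, `edits`.
#' @param motifs the [MotifSet-class] the hits were called against; every
#'   hit family must be one of its labels.
#' @return a named list, one entry per family: `identity_histogram` (counts
#'   by edit distance from the consensus; 0 = identical),
#'   `length_histogram` (counts by observed length), `frac_identical`, `n`.
#' @export
variantProfiles <- function(hits, motifs) {
  labs <- motifLabels(motifs)
  fam <- mcols(hits)$family
  if (length(hits) && any(!fam %in% labs))
    stop("data error: hit(s) with unknown family label: ",
         paste(unique(fam[!fam %in% labs]), collapse = ", "))
  setNames(lapply(labs, function(lab) {
    i <- which(fam == lab)
    list(family = lab,
         identity_histogram = table(mcols(hits)$edits[i]),
         length_histogram = table(width(hits)[i]),
         frac_identical = if (length(i)) mean(mcols(hits)$edits[i] == 0L)
                          else NA_real_,
         n = length(i))
  }), labs)
}
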