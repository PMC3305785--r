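.hit_cols <- function(tbl) grep("_hits$", names(tbl), value = TRUE)
.num_cols <- function(tbl)
  setdiff(names(tbl), c("family", "superfamily"))

#' Build the per-family census table
#'
#' One row per element family seen in the annotations or the assignments:
#' the number of intact annotated copies, per-monomer-family total hits and
#' locus counts restricted to the `within_te` loci of that family, and the
#' number of `similarity_assigned` loci (`additional_loci`).  Rows `Others`
#' and `Unknown` carry, respectively, loci assigned ambiguously (none under
#' the deterministic tie-break used here) and `unknown_repeat` loci.  The
#' final `Total` row is the column sum of all family rows.
#'
#' @param loci a loci `GRanges` from [clusterHits()] (pooled mode).
#' @param hits the hits `GRanges` the loci were built from.
#' @param assignments the assignment `data.frame` from [classifyLoci()].
#' @param annotations the annotation `GRanges`.
#' @param motifs the [MotifSet-class] defining the monomer columns.
#' @return a `data.frame` with columns `family`, `superfamily`,
#'   `intact_copies`, `<label>_hits` and `<label>_loci` per monomer family,
#'   and `additional_loci`.
#' @export
buildSummaryTable <- function(loci, hits, assignments, annotations, motifs) {
  labs <- motifLabels(motifs)
  ann_fams <- unique(mcols(annotations)$family)
  fams <- union(ann_fams,
                sort(unique(assignments$family[
                  assignments$status == "similarity_assigned"])))
  sup_of <- function(f) {
    s <- unique(mcols(annotations)$superfamily[mcols(annotations)$family == f])
    if (length(s) == 0L) "Unknown" else if (length(s) > 1L) "Multi" else s
  }
  rows <- lapply(fams, function(f) {
    row <- list(family = f, superfamily = sup_of(f),
                intact_copies = sum(mcols(annotations)$family == f &
                                      mcols(annotations)$intact))
    in_f <- which(assignments$status == "within_te" &
                    assignments$family == f)
    members <- mcols(loci)$members[in_f]
    for (lab in labs) {
      per_locus <- vapply(as.list(members), function(i)
        sum(mcols(hits)$family[i] == lab), integer(1))
      row[[paste0(lab, "_hits")]] <- sum(per_locus)
      row[[paste0(lab, "_loci")]] <- sum(per_locus > 0L)
    }
    row$additional_loci <- sum(assignments$status == "similarity_assigned" &
                                 assignments$family == f)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  extra <- data.frame(family = c("Others", "Unknown"),
                      superfamily = c("Multi", NA_character_),
                      stringsAsFactors = FALSE)
  for (cl in .num_cols(tbl)) extra[[cl]] <- NA_integer_
  extra$additional_loci <- c(0L,
                             sum(assignments$status == "unknown_repeat"))
  tbl <- rbind(tbl, extra)
  tot <- summaryTotals(tbl)
  tbl <- rbind(tbl, cbind(data.frame(family = "Total",
                                     superfamily = NA_character_,
                                     stringsAsFactors = FALSE),
                          as.data.frame(tot)))
  rownames(tbl) <- NULL
  tbl
}

#' Read a census table from TSV
#'
#' Reads a table in the layout written by [writeSummaryTable()] (columns
#' `family`, `superfamily`, `intact_copies`, `<label>_hits`/`<label>_loci`
#' pairs, `additional_loci`); the marker `ND` (not determined) becomes `NA`.
#' A published census supplied in this layout can be fed directly to
#' [summaryTotals()], [avgRepeatsPerElement()] and [outsideTECount()].
#'
#' @param path path to the tab-separated table (with header).
#' @return the census `data.frame`.
#' @export
readSummaryTable <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("family", "intact_copies", "additional_loci")
  if (!all(need %in% names(tbl)))
    stop("census-table error: missing column(s): ",
         paste(setdiff(need, names(tbl)), collapse = ", "))
  for (cl in .num_cols(tbl))
    tbl[[cl]] <- suppressWarnings(as.integer(ifelse(tbl[[cl]] %in%
                                                      c("ND", "NA", ""),
                                                    NA, tbl[[cl]])))
  tbl
}

#' Write a census table to TSV
#'
#' @param tbl the census `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTable <- function(tbl, path) {
  out <- tbl
  for (cl in .num_cols(out)) out[[cl]][is.na(out[[cl]])] <- "ND"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Column sums of the family rows of a census table
#'
#' Recomputes the `Total` row from scratch (any stored `Total` row is
#' excluded), treating `NA`/`ND` entries as zero.
#'
#' @param tbl a census `data.frame`.
#' @return a one-row `data.frame` of column sums.
#' @export
summaryTotals <- function(tbl) {
  rows <- tbl[tbl$family != "Total", , drop = FALSE]
  as.data.frame(lapply(rows[.num_cols(tbl)], function(v)
    as.integer(sum(v, na.rm = TRUE))))
}

#' Average number of monomer repeats per element
#'
#' The ratio of total hits to discrete loci for one monomer family within
#' one element family, rounded to one decimal.
#'
#' @param total_hits,n_loci counts from the census table.
#' @return `round(total_hits / n_loci, 1)`.
#' @examples
#' avgRepeatsPerElement(13293, 1561)  # 8.5
#' @export
avgRepeatsPerElement <- function(total_hits, n_loci) {
  if (any(n_loci == 0L))
    stop("undefined ratio: n_loci is zero")
  round(total_hits / n_loci, 1L)
}

#' Unique hits outside annotated elements
#'
#' @param total_unique_hits genome-wide unique hit count.
#' @param tbl a census `data.frame`; its per-monomer `<label>_hits` columns
#'   count the hits inside annotated elements.
#' @return `total_unique_hits` minus the within-element hit total.
#' @export
outsideTECount <- function(total_unique_hits, tbl) {
  rows <- tbl[tbl$family != "Total", , drop = FALSE]
  within <- sum(vapply(rows[.hit_cols(tbl)], function(v)
    sum(v, na.rm = TRUE), numeric(1)))
  if (total_unique_hits < within)
    stop("consistency error: table hit total (", within,
         ") exceeds the genome-wide unique hit count (", total_unique_hits,
         ")")
  as.integer(total_unique_hits - within)
}

#' Windowed density tracks of minisatellite hits and elements
#'
#' Counts unique hits (pooled and per monomer family, by start position) and
#' annotated elements (by midpoint) in consecutive fixed-width windows of
#' each chromosome.  Windows are half-open, so a feature sitting exactly on
#' a boundary counts in the right-hand window.
#'
#' @param hits a unique hits `GRanges`.
#' @param annotations an annotation `GRanges`.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   `seqlengths` of `hits`.
#' @param window window width in bp; default 100000.
#' @param te_mode how element density is counted: `"midpoint"` (one count
#'   per element, at its midpoint) or `"coverage"` (covered bp per window,
#'   in units of windows, robust to elements straddling boundaries).
#' @return a `data.frame` with one row per window: `chrom`, `start`, `end`
#'   (1-based closed bounds), `ms` (all families pooled), one column per
#'   family, and `te`.
#' @export
densityTracks <- function(hits, annotations, chrom_lengths = NULL,
                          window = 100000L,
                          te_mode = c("midpoint", "coverage")) {
  te_mode <- match.arg(te_mode)
  if (window < 1L) stop("usage error: window must be >= 1")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- seqlengths(hits)
    if (any(is.na(chrom_lengths)))
      stop("usage error: supply chrom_lengths (seqlengths of hits unset)")
  }
  labs <- sort(unique(mcols(hits)$family))
  out <- lapply(names(chrom_lengths), function(chrom) {
    nw <- as.integer(ceiling(chrom_lengths[[chrom]] / window))
    win0 <- function(pos0) pmin(pos0 %/% window, nw - 1L) + 1L
    h <- hits[as.character(seqnames(hits)) == chrom]
    a <- annotations[as.character(seqnames(annotations)) == chrom]
    df <- data.frame(chrom = chrom,
                     start = (seq_len(nw) - 1L) * window + 1L,
                     end = pmin(seq_len(nw) * window,
                                chrom_lengths[[chrom]]))
    df$ms <- tabulate(win0(start(h) - 1L), nbins = nw)
    for (lab in labs)
      df[[lab]] <- tabulate(win0(start(h)[mcols(h)$family == lab] - 1L),
                            nbins = nw)
    if (te_mode == "midpoint") {
      mid0 <- (start(a) - 1L + end(a)) %/% 2L
      df$te <- tabulate(win0(mid0), nbins = nw)
    } else {
      cv <- coverage(ranges(a), width = chrom_lengths[[chrom]])
      df$te <- viewSums(Views(cv, start = df$start, end = df$end)) / window
    }
    df
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlation of minisatellite and element densities
#'
#' @param track the `data.frame` from [densityTracks()] (or any frame with
#'   columns `ms` and `te`).
#' @return a list with `rank` (Spearman) and `linear` (Pearson)
#'   coefficients; a zero-variance vector yields `NA` rather than an error.
#' @export
densityCorrelation <- function(track) {
  ms <- track$ms
  te <- track$te
  if (length(ms) < 3L)
    stop("usage error: need at least 3 windows")
  safe_cor <- function(method) {
    if (stats::sd(ms) == 0 || stats::sd(te) == 0) return(NA_real_)
    stats::cor(ms, te, method = method)
  }
  list(rank = safe_cor("spearman"), linear = safe_cor("pearson"))
}
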