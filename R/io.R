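#' Read genome sequences from FASTA
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `A`/`C`/`G`/`T`/`N` is rejected with the offending record and position
#' named.  Record ids are the first whitespace-delimited token of the header
#' and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA format error: no records in '", path, "'")
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    stop("FASTA format error: record with empty id in '", path, "'")
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(raw))))
  if (any(nchar(seqs) == 0L))
    stop("FASTA format error: empty sequence for record '",
         ids[which(nchar(seqs) == 0L)[1L]], "'")
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("FASTA format error: illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  setNames(DNAStringSet(seqs), ids)
}

#' Read monomer consensus sequences from FASTA
#'
#' @inheritParams readGenome
#' @return a [MotifSet-class] whose labels are the FASTA ids.
#' @export
readMotifs <- function(path) {
  MotifSet(readGenome(path))
}

#' The packaged synthetic monomer consensus set
#'
#' Five synthetic stand-in monomers with the field-typical family lengths of
#' 26, 38, 37, 105 and 43 bp (labels `A` to `E`).  Families B and C share
#' nine of their last eleven bases, so the cross-family deduplication path is
#' exercised; the families are otherwise mutually dissimilar.  These are
#' generated stand-ins, not the published consensus sequences.
#'
#' @return a [MotifSet-class] of five monomers.
#' @examples
#' motifLengths(defaultMotifs())
#' @export
defaultMotifs <- function() {
  readMotifs(system.file("extdata", "monomer_consensus_synthetic.fasta",
                         package = "rtms", mustWork = TRUE))
}

.as_flag <- function(x) {
  if (is.null(x)) return(FALSE)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read transposable-element annotations
#'
#' Reads GFF3 or BED6 element annotations into a `GRanges` with metadata
#' columns `family`, `superfamily` (one of `Gypsy`, `Copia`, `Unknown`) and
#' `intact` (logical).  GFF3 attribute keys are configurable because
#' annotation sources differ in their naming; for BED the family is taken
#' from the `name` field.  Coordinates follow the GRanges convention
#' (1-based, closed) internally, so a GFF3 feature `101..200` and a BED line
#' `100 200` describe the same bases and parse to identical ranges.
#'
#' @param path annotation file path.
#' @param dialect `"gff3"` or `"bed"`.
#' @param family_key,superfamily_key,intact_key GFF3 attribute keys carrying
#'   the element family, superfamily, and intactness flag.
#' @return a `GRanges` with mcols `family`, `superfamily`, `intact`.
#' @export
readTEAnnotations <- function(path, dialect = c("gff3", "bed"),
                              family_key = "family",
                              superfamily_key = "superfamily",
                              intact_key = "intact") {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gff3") {
    mc <- mcols(gr)
    fam <- if (family_key %in% names(mc)) as.character(mc[[family_key]]) else
      stop("annotation error: GFF3 attribute '", family_key, "' absent from '",
           path, "'")
    sup <- if (superfamily_key %in% names(mc)) as.character(mc[[superfamily_key]])
           else rep(NA_character_, length(gr))
    int <- if (intact_key %in% names(mc))
             unname(vapply(mc[[intact_key]], .as_flag, logical(1)))
           else rep(FALSE, length(gr))
  } else {
    fam <- if ("name" %in% names(mcols(gr))) as.character(mcols(gr)$name)
           else rep(NA_character_, length(gr))
    sup <- rep(NA_character_, length(gr))
    int <- rep(FALSE, length(gr))
  }
  if (any(is.na(fam) | !nzchar(fam)))
    stop("annotation error: record ", which(is.na(fam) | !nzchar(fam))[1L],
         " in '", path, "' has no family")
  sup[is.na(sup) | !nzchar(sup)] <- "Unknown"
  if (any(width(gr) < 1L))
    stop("annotation error: record ", which(width(gr) < 1L)[1L],
         " in '", path, "' has an empty interval")
  mcols(gr) <- DataFrame(family = fam, superfamily = sup, intact = int)
  gr
}

#' Write transposable-element annotations
#'
#' Inverse of [readTEAnnotations()]: GFF3 output carries `family`,
#' `superfamily` and `intact` as attributes and round-trips 1-based closed
#' coordinates; BED output stores the family in the `name` field.
#'
#' @param annotations a `GRanges` with mcols `family`, `superfamily`, `intact`.
#' @param path output file path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
writeTEAnnotations <- function(annotations, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  gr <- annotations
  if (dialect == "gff3") {
    mcols(gr)$type <- "mobile_genetic_element"
    mcols(gr)$source <- "rtms"
    mcols(gr)$intact <- tolower(as.character(mcols(annotations)$intact))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    mcols(gr) <- DataFrame(name = mcols(annotations)$family)
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a 12-column BLAST-tabular hit table
#'
#' Accepts the standard tabular dialect (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, e-value, bit score) as produced by external search tools, as an
#' alternative to the internal scanner.  Subject coordinates are 1-based
#' closed with strand inferred from `sstart > send`; percent identity is
#' stored as a fraction, and `mismatches + gap opens` is taken as the edit
#' count.
#'
#' @param path path to the tab-separated table (no header).
#' @return a hits `GRanges` with mcols `family`, `identity`, `edits`.
#' @export
readHitTable <- function(path) {
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 12L)
    stop("hit-table error: expected 12 tab-separated columns, found ",
         ncol(tab))
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")
  num <- suppressWarnings(lapply(tab[c("pident", "mismatch", "gapopen",
                                       "sstart", "send")], as.numeric))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stop("hit-table error: non-numeric field on line ", bad[1L])
  strand <- ifelse(num$sstart <= num$send, "+", "-")
  gr <- GRanges(tab$sseqid,
                IRanges(pmin(num$sstart, num$send), pmax(num$sstart, num$send)),
                strand = strand,
                family = tab$qseqid,
                identity = num$pident / 100,
                edits = as.integer(num$mismatch + num$gapopen))
  sort(gr, ignore.strand = TRUE)
}

#' Write hits to a 12-column BLAST-tabular table
#'
#' Mirrors the dialect accepted by [readHitTable()], so a write/read cycle
#' preserves coordinates, strand, family, identity and edit count.
#'
#' @param hits a hits `GRanges` (mcols `family`, `identity`, `edits`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsTable <- function(hits, path) {
  hits <- sort(hits, ignore.strand = TRUE)
  minus <- as.character(strand(hits)) == "-"
  tab <- data.frame(
    qseqid = mcols(hits)$family,
    sseqid = as.character(seqnames(hits)),
    pident = sprintf("%.3f", 100 * mcols(hits)$identity),
    length = width(hits),
    mismatch = mcols(hits)$edits,
    gapopen = 0L,
    qstart = 1L,
    qend = width(hits),
    sstart = ifelse(minus, end(hits), start(hits)),
    send = ifelse(minus, start(hits), end(hits)),
    evalue = 0, bitscore = 0)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write hits or loci as BED6
#'
#' Output columns are chrom, 0-based start, end, name (monomer family for
#' hits, locus id for loci), score (`round(1000 * identity)` for hits, the
#' member count for loci) and strand.  Rows are sorted by (chrom, start,
#' end), so output is deterministic and re-readable.
#'
#' @param records a hits or loci `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(records, path) {
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  mc <- mcols(records)
  name <- if ("family" %in% names(mc)) as.character(mc$family)
          else if ("locus_id" %in% names(mc)) as.character(mc$locus_id)
          else rep(".", length(records))
  score <- if ("identity" %in% names(mc)) as.integer(round(1000 * mc$identity))
           else if ("n_hits" %in% names(mc)) as.integer(mc$n_hits)
           else rep(0L, length(records))
  strand <- as.character(strand(records))
  strand[strand == "*"] <- "."
  tab <- data.frame(chrom = as.character(seqnames(records)),
                    start = start(records) - 1L, end = end(records),
                    name = name, score = score, strand = strand)
  tab <- tab[order(tab$chrom, tab$start, tab$end), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
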