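.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate one monomer copy: independent per-base substitutions, then at most
# `max_indels` single-base indel events.  Returns the mutated sequence and
# the edit count (substitutions + indel events).
.mutate_seq <- function(seq, sub_rate, indel_rate, max_indels = 2L) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  nsub <- 0L
  if (sub_rate > 0) {
    hit <- which(runif(L) < sub_rate)
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    nsub <- length(hit)
  }
  nind <- 0L
  if (indel_rate > 0) {
    nind <- min(max_indels, rbinom(1L, L, indel_rate))
    for (k in seq_len(nind)) {
      if (runif(1L) < 0.5 && length(ch) > 1L) {
        ch <- ch[-sample.int(length(ch), 1L)]
      } else {
        at <- sample.int(length(ch) + 1L, 1L)
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = at - 1L)
      }
    }
  }
  list(seq = paste(ch, collapse = ""), edits = nsub + nind)
}

# Assemble a tandem array of mutated monomers.  Coordinates are 1-based
# relative to the returned sequence.
.build_array <- function(unit, count, motifs, sub_rate, indel_rate,
                         spacer_len) {
  labels <- rep(strsplit(unit, "")[[1L]], count)
  pieces <- character(0)
  rows <- vector("list", length(labels))
  pos <- 0L
  for (i in seq_along(labels)) {
    if (i > 1L && spacer_len > 0L) {
      pieces <- c(pieces, .rand_dna(spacer_len))
      pos <- pos + spacer_len
    }
    m <- .mutate_seq(as.character(motifs[[labels[i]]]), sub_rate, indel_rate)
    w <- nchar(m$seq)
    rows[[i]] <- data.frame(label = labels[i], start = pos + 1L,
                            end = pos + w, edits = m$edits,
                            stringsAsFactors = FALSE)
    pieces <- c(pieces, m$seq)
    pos <- pos + w
  }
  list(seq = paste(pieces, collapse = ""),
       monomers = do.call(rbind, rows))
}

.flip_coords <- function(df, len) {
  if (nrow(df) == 0L) return(df)
  s <- df$start
  df$start <- len - df$end + 1L
  df$end <- len - s + 1L
  df$strand <- ifelse(df$strand == "+", "-", "+")
  df[order(df$start), , drop = FALSE]
}

# One planted feature: a sequence plus a relative-coordinate feature table
# (kind, label, unit, count, start, end, strand, edits, orphan_type).
.feature_row <- function(kind, label, unit = NA, count = NA, start, end,
                         strand = "+", edits = NA, orphan_type = NA) {
  data.frame(kind = kind, label = label, unit = unit,
             count = as.integer(count), start = as.integer(start),
             end = as.integer(end), strand = strand,
             edits = as.integer(edits), orphan_type = orphan_type,
             stringsAsFactors = FALSE)
}

.build_planted <- function(type, spec, motifs, body, element_id) {
  ap <- spec@array_patterns
  k <- sample.int(nrow(ap), 1L, prob = ap$weight)
  arr <- .build_array(ap$unit[k], ap$count[k], motifs, spec@sub_rate,
                      spec@indel_rate, spec@spacer_len)
  labs <- motifLabels(motifs)
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  add_seq <- function(s) {
    pieces <<- c(pieces, s)
    pos <<- pos + nchar(s)
  }
  if (type == "element") {
    add_seq(body)
  } else if (type == "flank") {
    add_seq(.mutate_seq(substr(body, 1L, min(spec@flank_len, nchar(body))),
                        spec@flank_divergence, 0)$seq)
  }
  arr_start <- pos + 1L
  m <- arr$monomers
  m$start <- m$start + pos
  m$end <- m$end + pos
  feats[[length(feats) + 1L]] <-
    .feature_row("array", NA_character_, ap$unit[k], ap$count[k],
                 arr_start, pos + nchar(arr$seq), orphan_type = type)
  feats[[length(feats) + 1L]] <-
    .feature_row("monomer", m$label, start = m$start, end = m$end,
                 edits = m$edits)
  add_seq(arr$seq)
  if (type == "element" && spec@de_tail && all(c("D", "E") %in% labs)) {
    add_seq(.rand_dna(120L))
    for (lab in c("D", "E")) {
      mm <- .mutate_seq(as.character(motifs[[lab]]), spec@sub_rate,
                        spec@indel_rate)
      feats[[length(feats) + 1L]] <-
        .feature_row("monomer", lab, start = pos + 1L,
                     end = pos + nchar(mm$seq), edits = mm$edits)
      add_seq(mm$seq)
    }
    add_seq(.rand_dna(100L))
    mm <- .mutate_seq(as.character(motifs[["E"]]), spec@sub_rate,
                      spec@indel_rate)
    feats[[length(feats) + 1L]] <-
      .feature_row("monomer", "E", start = pos + 1L,
                   end = pos + nchar(mm$seq), edits = mm$edits)
    add_seq(mm$seq)
  }
  if (type == "flank") {
    b <- nchar(body)
    add_seq(.mutate_seq(substr(body, max(1L, b - spec@flank_len + 1L), b),
                        spec@flank_divergence, 0)$seq)
  }
  seq <- paste(pieces, collapse = "")
  feats <- do.call(rbind, feats)
  if (type == "element")
    feats <- rbind(.feature_row("element", spec@family, start = 1L,
                                end = nchar(seq)), feats)
  if (runif(1L) < spec@minus_strand_prob) {
    seq <- as.character(reverseComplement(DNAString(seq)))
    feats <- .flip_coords(feats, nchar(seq))
  }
  feats$element_id <- element_id
  list(seq = seq, feats = feats)
}

.generate <- function(spec, motifs) {
  labs <- motifLabels(motifs)
  bad <- setdiff(unique(unlist(strsplit(spec@array_patterns$unit, ""))), labs)
  if (length(bad))
    stop("usage error: array pattern labels not in the motif set: ",
         paste(bad, collapse = ", "))
  body <- .rand_dna(spec@element_body_len)
  types <- c(rep("element", spec@n_elements),
             rep("flank", spec@orphans_with_flank),
             rep("random", spec@orphans_random))
  nchrom <- length(spec@chrom_lengths)
  chrom_names <- paste0("chr", seq_len(nchrom))
  assign <- rep(seq_len(nchrom), length.out = length(types))
  planted <- lapply(seq_along(types), function(i)
    .build_planted(types[i], spec, motifs,
                   body, sprintf("%s_%02d", types[i], i)))
  seqs <- character(nchrom)
  truth <- list()
  for (ci in seq_len(nchrom)) {
    idx <- which(assign == ci)
    f <- planted[idx]
    lens <- vapply(f, function(x) nchar(x$seq), integer(1))
    k <- length(f)
    slack <- spec@chrom_lengths[ci] - sum(lens) -
      (k + 1L) * spec@min_spacing
    if (slack < 0L)
      stop("sizing error: planted content does not fit chromosome '",
           chrom_names[ci], "' (need ",
           sum(lens) + (k + 1L) * spec@min_spacing, " bp, have ",
           spec@chrom_lengths[ci], ")")
    gaps <- spec@min_spacing +
      if (k >= 0L) as.integer(rmultinom(1L, slack, rep(1, k + 1L))) else slack
    pieces <- character(0)
    pos <- 0L
    for (j in seq_len(k)) {
      pieces <- c(pieces, .rand_dna(gaps[j]))
      pos <- pos + gaps[j]
      ft <- f[[j]]$feats
      ft$start <- ft$start + pos
      ft$end <- ft$end + pos
      ft$chrom <- chrom_names[ci]
      truth[[length(truth) + 1L]] <- ft
      pieces <- c(pieces, f[[j]]$seq)
      pos <- pos + lens[j]
    }
    pieces <- c(pieces, .rand_dna(gaps[k + 1L]))
    seqs[ci] <- paste(pieces, collapse = "")
  }
  truth <- do.call(rbind, truth)
  gr <- GRanges(truth$chrom, IRanges(truth$start, truth$end),
                strand = truth$strand,
                kind = truth$kind, label = truth$label, unit = truth$unit,
                count = truth$count, edits = truth$edits,
                orphan_type = truth$orphan_type,
                element_id = truth$element_id)
  seqlevels(gr) <- chrom_names
  seqlengths(gr) <- nchar(seqs)
  gr <- sort(gr, ignore.strand = TRUE)
  el <- gr[mcols(gr)$kind == "element"]
  annotations <- GRanges(seqnames(el), ranges(el), strand = strand(el),
                         family = mcols(el)$label,
                         superfamily = spec@superfamily,
                         intact = runif(length(el)) < spec@intact_prob)
  list(genome = setNames(DNAStringSet(seqs), chrom_names),
       truth = gr,
       annotations = annotations,
       exemplars = setNames(DNAStringSet(body), spec@family),
       motifs = motifs,
       spec = spec)
}

#' Generate a synthetic genome with planted minisatellite arrays
#'
#' Plants copies of a retroelement-like template (shared random body plus an
#' interleaved monomer array downstream of it) and orphan arrays into
#' uniform random background chromosomes, mutating every monomer copy
#' independently, and records full ground truth for every planted feature.
#' Generation is fully deterministic given `spec` (including its seed), and
#' the caller's RNG state is left untouched.
#'
#' @param spec a [SimSpec-class].
#' @param motifs the [MotifSet-class] to plant; defaults to
#'   [defaultMotifs()].
#' @return a list: `genome` (`DNAStringSet`), `truth` (`GRanges` with mcols
#'   `kind` in element/array/monomer, `label`, `unit`, `count`, `edits`,
#'   `orphan_type`, `element_id`), `annotations` (element records in
#'   [readTEAnnotations()] layout), `exemplars` (the element body template,
#'   named by family), `motifs`, and the `spec`.
#' @examples
#' sim <- simulateGenome(SimSpec(n_elements = 2L, chrom_lengths = 60000L))
#' table(mcols(sim$truth)$kind)
#' @export
simulateGenome <- function(spec = SimSpec(), motifs = defaultMotifs()) {
  validObject(spec)
  if (!is(motifs, "MotifSet")) motifs <- MotifSet(motifs)
  withr::with_seed(spec@seed, .generate(spec, motifs))
}

#' Write a simulation to files
#'
#' Emits `<prefix>_genome.fasta`, `<prefix>_truth.gff3`,
#' `<prefix>_truth.tsv`, `<prefix>_annotations.gff3` and
#' `<prefix>_motifs.fasta`.
#'
#' @param sim the list returned by [simulateGenome()].
#' @param prefix output path prefix.
#' @return the written paths, invisibly.
#' @export
writeSimulation <- function(sim, prefix) {
  paths <- c(genome = paste0(prefix, "_genome.fasta"),
             truth_gff = paste0(prefix, "_truth.gff3"),
             truth_tsv = paste0(prefix, "_truth.tsv"),
             ann = paste0(prefix, "_annotations.gff3"),
             motifs = paste0(prefix, "_motifs.fasta"))
  writeXStringSet(sim$genome, paths[["genome"]])
  gr <- sim$truth
  mcols(gr)$type <- "region"
  mcols(gr)$source <- "rtms"
  rtracklayer::export(gr, paths[["truth_gff"]], format = "gff3")
  tt <- as.data.frame(sim$truth)
  write.table(tt, paths[["truth_tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeTEAnnotations(sim$annotations, paths[["ann"]], "gff3")
  writeXStringSet(sim$motifs, paths[["motifs"]])
  invisible(paths)
}

.match_stage <- function(truth_gr, det_gr, tolerance, same_label = FALSE,
                         priority = NULL, mode = "reciprocal") {
  nt <- length(truth_gr)
  nd <- length(det_gr)
  if (nd == 0L || nt == 0L)
    return(list(pairs = data.frame(det = integer(), truth = integer()),
                n_truth = nt, n_det = nd))
  ov <- findOverlaps(det_gr, truth_gr, ignore.strand = TRUE)
  qh <- queryHits(ov)
  sh <- subjectHits(ov)
  ow <- pmin(end(det_gr)[qh], end(truth_gr)[sh]) -
        pmax(start(det_gr)[qh], start(truth_gr)[sh]) + 1L
  covered <- if (mode == "reciprocal")
    ow >= 0.5 * width(det_gr)[qh] & ow >= 0.5 * width(truth_gr)[sh]
  else  # "truth": the truth span must be half-covered (loci may extend
        # over neighboring monomers bookkept outside the truth array span)
    ow >= 0.5 * width(truth_gr)[sh]
  near <- abs(start(det_gr)[qh] - start(truth_gr)[sh]) <= tolerance &
          abs(end(det_gr)[qh] - end(truth_gr)[sh]) <= tolerance
  ok <- covered | near
  if (same_label)
    ok <- ok & mcols(det_gr)$family[qh] == mcols(truth_gr)$label[sh]
  qh <- qh[ok]; sh <- sh[ok]; ow <- ow[ok]
  o <- if (is.null(priority)) order(-ow) else order(-priority[qh], -ow)
  used_d <- logical(nd)
  used_t <- logical(nt)
  pd <- pt <- integer(0)
  for (i in o) {
    if (used_d[qh[i]] || used_t[sh[i]]) next
    used_d[qh[i]] <- TRUE
    used_t[sh[i]] <- TRUE
    pd <- c(pd, qh[i])
    pt <- c(pt, sh[i])
  }
  list(pairs = data.frame(det = pd, truth = pt), n_truth = nt, n_det = nd)
}

#' Score detections against simulation ground truth
#'
#' A detected hit matches a truth monomer when the labels agree and the
#' intervals overlap reciprocally by at least 50% (or both boundaries fall
#' within `tolerance` bp); matching is one-to-one, greedy by detected
#' identity.  Loci are matched against truth arrays the same way (greedy by
#' overlap), and assignments are scored against the status each truth array
#' implies: arrays inside elements should be `within_te`, template-flanked
#' orphans `similarity_assigned`, and background orphans `unknown_repeat`.
#'
#' @param truth the truth `GRanges` from [simulateGenome()].
#' @param hits,loci detected hit / locus `GRanges` (either may be `NULL`).
#' @param assignments assignment `data.frame` from [classifyLoci()]
#'   (requires `loci`).
#' @param tolerance boundary slop in bp; default 5.
#' @return a `data.frame` with one row per scored stage: `stage`,
#'   `n_truth`, `n_detected`, `matched`, `precision`, `recall`.  Precision
#'   is `NA` when nothing was detected.
#' @export
evaluateDetection <- function(truth, hits = NULL, loci = NULL,
                              assignments = NULL, tolerance = 5L) {
  if (!is.null(hits) && length(hits) &&
      !any(as.character(seqnames(hits)) %in%
           as.character(seqnames(truth))))
    stop("usage error: detections and truth name different chromosomes")
  rows <- list()
  stage_row <- function(stage, m, correct = NULL) {
    matched <- if (is.null(correct)) nrow(m$pairs) else sum(correct)
    data.frame(stage = stage, n_truth = m$n_truth, n_detected = m$n_det,
               matched = matched,
               precision = if (m$n_det == 0L) NA_real_ else matched / m$n_det,
               recall = if (m$n_truth == 0L) NA_real_ else
                 matched / m$n_truth,
               stringsAsFactors = FALSE)
  }
  if (!is.null(hits)) {
    tm <- truth[mcols(truth)$kind == "monomer"]
    m <- .match_stage(tm, hits, tolerance, same_label = TRUE,
                      priority = mcols(hits)$identity)
    rows[[length(rows) + 1L]] <- stage_row("hits", m)
  }
  if (!is.null(loci)) {
    ta <- truth[mcols(truth)$kind == "array"]
    m <- .match_stage(ta, loci, tolerance, mode = "truth")
    rows[[length(rows) + 1L]] <- stage_row("loci", m)
    if (!is.null(assignments)) {
      want <- c(element = "within_te", flank = "similarity_assigned",
                random = "unknown_repeat")
      exp_status <- want[mcols(ta)$orphan_type[m$pairs$truth]]
      got <- assignments$status[m$pairs$det]
      rows[[length(rows) + 1L]] <-
        stage_row("assignment", m, correct = got == exp_status)
    }
  }
  do.call(rbind, rows)
}
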