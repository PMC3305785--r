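hits_from_labels <- function(labels, gaps = rep(0L, length(labels)),
                             chrom = "chr1", origin = 101L) {
  w <- c(A = 26L, B = 38L, C = 37L, D = 105L, E = 43L)[labels]
  start <- integer(length(labels))
  pos <- origin
  for (i in seq_along(labels)) {
    pos <- pos + gaps[i]
    start[i] <- pos
    pos <- pos + w[i]
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + w - 1L),
                               strand = "+", family = labels, identity = 1,
                               edits = 0L)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

locus_of <- function(hits) {
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(hits)[1],
    IRanges::IRanges(min(GenomicRanges::start(hits)),
                     max(GenomicRanges::end(hits))),
    locus_id = "L1", n_hits = length(hits),
    members = IRanges::IntegerList(list(seq_along(hits))))
}

test_that("label sequences carry genomic order and junction gaps", {
  h <- hits_from_labels(c("A", "B", "A"), gaps = c(0L, 0L, 100L))
  ls <- labelSequence(locus_of(h), h)
  expect_identical(ls$label, c("A", "B", "A"))
  expect_equal(ls$gap_before, c(0L, 0L, 100L))
  expect_equal(ls$start[2], 127L)
  single <- hits_from_labels("A")
  expect_equal(nrow(labelSequence(locus_of(single), single)), 1L)
})

test_that("pure interleaved arrays decompose to a single tandem segment", {
  d <- decomposeArray(strsplit("ABACABACABAC", "")[[1]])
  seg <- d$segments[d$segments$kind == "tandem", ]
  expect_equal(nrow(seg), 1L)
  expect_identical(seg$unit, "ABAC")
  expect_equal(seg$count, 3L)
  expect_identical(d$remainder, "")
})

test_that("a 17x ABC array followed by ABA leaves ABA as remainder", {
  lab <- c(rep(c("A", "B", "C"), 17), "A", "B", "A")
  d <- decomposeArray(lab)
  top <- d$segments[d$segments$kind == "tandem", ][1, ]
  expect_identical(top$unit, "ABC")
  expect_equal(top$count, 17L)
  expect_identical(d$remainder, "ABA")
})

test_that("single monomers and oversized junction gaps break runs", {
  expect_identical(decomposeArray("A")$remainder, "A")
  expect_equal(sum(decomposeArray("A")$segments$kind == "tandem"), 0L)
  # [AB]x2, 100-bp break, [AB]x2: the break forbids one [AB]x4 run
  h <- hits_from_labels(rep(c("A", "B"), 4),
                        gaps = c(0L, 0L, 0L, 0L, 100L, 0L, 0L, 0L))
  d <- decomposeArray(labelSequence(locus_of(h), h))
  segs <- d$segments[d$segments$kind == "tandem", ]
  expect_equal(segs$count, c(2L, 2L))
  expect_identical(segs$unit, c("AB", "AB"))
  # genomic spans include internal gaps
  expect_equal(segs$span_bp[1], 2L * 64L)
})

test_that("decomposition conserves the label string on random inputs", {
  set.seed(31)
  for (i in 1:60) {
    lab <- if (i %% 2) random_labels(sample(1:30, 1)) else repeat_rich_labels()
    d <- decomposeArray(lab)
    rebuilt <- paste(ifelse(d$segments$kind == "tandem",
                            strrep(d$segments$unit, d$segments$count),
                            d$segments$unit), collapse = "")
    expect_identical(rebuilt, paste(lab, collapse = ""))
  }
})

test_that("the top segment matches the exhaustive maximum-cover oracle", {
  set.seed(32)
  for (i in 1:150) {
    lab <- if (i %% 3 == 0) random_labels(sample(4:30, 1),
                                          alphabet = c("A", "B", "C"))
           else repeat_rich_labels()
    d <- decomposeArray(lab)
    segs <- d$segments[d$segments$kind == "tandem", , drop = FALSE]
    o <- oracle_best_run(lab)
    if (is.null(o)) {
      expect_equal(nrow(segs), 0L)
    } else {
      segs <- segs[order(-segs$n_monomers, nchar(segs$unit), segs$start), ]
      expect_identical(segs$unit[1], o$unit)
      expect_equal(segs$count[1], o$k)
      expect_equal(segs$start[1], o$p)
    }
  }
})

test_that("rotations of a pure tandem array share one canonical unit", {
  base <- rep(c("A", "B", "A", "C"), 5)
  canon <- vapply(0:3, function(r) {
    lab <- if (r == 0) base else c(base[-seq_len(r)], base[seq_len(r)])
    lab <- lab[1:16]
    d <- decomposeArray(lab)
    d$segments$canonical_unit[d$segments$kind == "tandem"][1]
  }, character(1))
  expect_equal(length(unique(canon)), 1L)
  expect_identical(unique(canon), "ABAC")
})

test_that("unbroken arrays rank by span with count as tie-break", {
  segs <- data.frame(
    locus_id = c("L1", "L2", "L3", "L4"),
    kind = c("tandem", "tandem", "remainder", "tandem"),
    unit = c("ABC", "ABAC", "A", "AB"),
    canonical_unit = c("ABC", "AABC", NA, "AB"),
    count = c(17L, 37L, 1L, 37L),
    n_monomers = c(51L, 148L, 1L, 74L),
    start = c(1L, 1L, 1L, 1L), end = c(2990L, 4760L, 26L, 4760L),
    span_bp = c(2990L, 4760L, 26L, 4760L))
  r <- longestUnbroken(segs)
  expect_equal(r$span_bp, c(4760L, 4760L, 2990L))
  expect_equal(r$count[1], 37L)
  expect_identical(r$locus_id[1:2], c("L2", "L4"))
  expect_equal(nrow(longestUnbroken(segs[0, ])), 0L)
})

test_that("variant profiles tabulate edits and lengths per family", {
  h <- c(hits_from_labels(c("A", "A", "A"), gaps = c(0L, 500L, 500L)))
  S4Vectors::mcols(h)$edits <- c(0L, 0L, 1L)
  p <- variantProfiles(h, defaultMotifs())
  expect_equal(as.integer(p$A$identity_histogram), c(2L, 1L))
  expect_equal(p$A$frac_identical, 2 / 3)
  expect_equal(p$A$n, 3L)
  expect_equal(p$B$n, 0L)
  expect_true(is.na(p$B$frac_identical))
  # histogram totals equal per-family unique-hit counts
  expect_equal(sum(p$A$identity_histogram), 3L)
  bad <- h
  S4Vectors::mcols(bad)$family <- "Z"
  expect_error(variantProfiles(bad, defaultMotifs()), "unknown family")
})
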