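small_spec <- function(...) {
  SimSpec(n_elements = 3L, orphans_with_flank = 1L, orphans_random = 1L,
          chrom_lengths = c(90000L, 90000L), ...)
}

test_that("generation is byte-identical under a fixed seed", {
  a <- simulateGenome(small_spec(seed = 17L))
  b <- simulateGenome(small_spec(seed = 17L))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  pa <- writeSimulation(a, file.path(tempdir(), "simA"))
  pb <- writeSimulation(b, file.path(tempdir(), "simB"))
  expect_identical(unname(tools::md5sum(pa)) , unname(tools::md5sum(pb)))
  c <- simulateGenome(small_spec(seed = 18L))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("a noise-free planted census is recovered exactly at every stage", {
  sim <- simulateGenome(small_spec(sub_rate = 0, indel_rate = 0, seed = 23L))
  cen <- runCensus(sim$genome, sim$motifs, sim$annotations, sim$exemplars)
  tm <- sim$truth[S4Vectors::mcols(sim$truth)$kind == "monomer"]
  # every planted monomer recovered at identity 1 and exact coordinates
  expect_equal(length(cen$unique_hits), length(tm))
  expect_true(all(S4Vectors::mcols(cen$unique_hits)$identity == 1))
  expect_equal(GenomicRanges::start(cen$unique_hits),
               GenomicRanges::start(tm))
  expect_equal(GenomicRanges::end(cen$unique_hits), GenomicRanges::end(tm))
  expect_identical(S4Vectors::mcols(cen$unique_hits)$family,
                   S4Vectors::mcols(tm)$label)
  ev <- evaluateDetection(sim$truth, cen$unique_hits, cen$loci,
                          cen$assignments)
  expect_equal(ev$precision, rep(1, 3))
  expect_equal(ev$recall, rep(1, 3))
  # planted array units and counts come back from the decomposition
  ta <- sim$truth[S4Vectors::mcols(sim$truth)$kind == "array"]
  top <- longestUnbroken(cen$segments)
  top <- top[order(top$start), ]
  ta <- ta[order(GenomicRanges::start(ta))]
  expect_equal(nrow(top), length(ta))
  # a minus-strand array reads as the reversed unit along the plus strand
  expected_unit <- mapply(function(u, st) {
    ch <- strsplit(u, "")[[1]]
    if (st == "-") ch <- rev(ch)
    rtms:::.canonical_rotation(paste(ch, collapse = ""))
  }, S4Vectors::mcols(ta)$unit, as.character(GenomicRanges::strand(ta)),
  USE.NAMES = FALSE)
  expect_identical(top$canonical_unit, expected_unit)
  expect_equal(top$count, S4Vectors::mcols(ta)$count)
})

test_that("monomer mutation load matches its binomial expectation", {
  spec <- SimSpec(n_elements = 12L, orphans_with_flank = 0L,
                  orphans_random = 0L, sub_rate = 0.05, indel_rate = 0,
                  de_tail = FALSE, chrom_lengths = c(200000L, 200000L),
                  array_patterns = data.frame(unit = "ABAC", count = 10L,
                                              weight = 1),
                  seed = 29L)
  sim <- simulateGenome(spec)
  tm <- sim$truth[S4Vectors::mcols(sim$truth)$kind == "monomer"]
  edits_a <- S4Vectors::mcols(tm)$edits[S4Vectors::mcols(tm)$label == "A"]
  n <- length(edits_a)
  expect_gte(n, 200L)
  expected <- 26 * 0.05
  se <- sqrt(26 * 0.05 * 0.95) / sqrt(n)
  expect_lt(abs(mean(edits_a) - expected), 3 * se)
})

test_that("planted content that cannot fit is a sizing error", {
  expect_error(simulateGenome(SimSpec(chrom_lengths = 8000L,
                                      n_elements = 4L)),
               "sizing error.*chr1")
})

test_that("evaluation arithmetic behaves at the edges", {
  sim <- simulateGenome(small_spec(sub_rate = 0, indel_rate = 0, seed = 31L))
  tm <- sim$truth[S4Vectors::mcols(sim$truth)$kind == "monomer"]
  perfect <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tm), IRanges::IRanges(GenomicRanges::start(tm),
                                                  GenomicRanges::end(tm)),
    strand = GenomicRanges::strand(tm),
    family = S4Vectors::mcols(tm)$label, identity = 1, edits = 0L)
  ev <- evaluateDetection(sim$truth, hits = perfect)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # one spurious extra detection: precision n/(n+1), recall unchanged
  fake <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 30),
                                 strand = "+", family = "A", identity = 0.9,
                                 edits = 2L)
  ev2 <- evaluateDetection(sim$truth, hits = c(perfect, fake))
  n <- length(tm)
  expect_equal(ev2$precision, n / (n + 1))
  expect_equal(ev2$recall, 1)
  # nothing detected: recall 0, precision undefined
  ev3 <- evaluateDetection(sim$truth, hits = perfect[0])
  expect_equal(ev3$recall, 0)
  expect_true(is.na(ev3$precision))
})

test_that("recall degrades as the substitution rate crosses the threshold", {
  base <- list(n_elements = 4L, orphans_with_flank = 0L, orphans_random = 0L,
               indel_rate = 0, de_tail = FALSE,
               chrom_lengths = c(80000L, 80000L),
               array_patterns = data.frame(unit = "ABAC", count = 6L,
                                           weight = 1))
  recall_at <- function(rate) {
    sim <- simulateGenome(do.call(SimSpec, c(base, list(sub_rate = rate,
                                                        seed = 37L))))
    uniq <- dedupeHits(scanGenome(sim$genome, sim$motifs))
    ev <- evaluateDetection(sim$truth, hits = uniq)
    ev$recall
  }
  lo <- recall_at(0.02)
  hi <- recall_at(0.15)
  expect_gte(lo, hi)
  expect_gte(lo, 0.8)   # expected identity 0.98 x L, well above 0.90
  expect_lt(hi, 0.5)    # expected identity ~0.85, below the threshold
})
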