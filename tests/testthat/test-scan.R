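motifs <- defaultMotifs()
consA <- as.character(motifs[["A"]])

make_genome <- function(...) Biostrings::DNAStringSet(c(...))

test_that("an exact planted copy yields exactly one perfect hit", {
  g <- make_genome(chr1 = paste0(strrep("T", 100), consA, strrep("G", 100)))
  h <- scanGenome(g, motifs)
  expect_equal(length(h), 1L)
  expect_equal(GenomicRanges::start(h), 101)
  expect_equal(GenomicRanges::end(h), 126)
  expect_identical(as.character(GenomicRanges::strand(h)), "+")
  expect_equal(S4Vectors::mcols(h)$identity, 1.0)
  expect_equal(S4Vectors::mcols(h)$edits, 0L)
})

test_that("the 90% identity threshold admits 2 but not 3 edits on a 26-bp monomer", {
  set.seed(41)
  two <- mutate_copy(consA, nsub = 2L)
  three <- mutate_copy(consA, nsub = 3L)
  g <- make_genome(chr1 = paste0(rand_dna(200), two, rand_dna(200), three,
                                 rand_dna(200)))
  h <- scanGenome(g, MotifSet(c(A = consA)))
  expect_equal(length(h), 1L)
  expect_equal(S4Vectors::mcols(h)$edits, 2L)
  expect_equal(S4Vectors::mcols(h)$identity, 24 / 26)
  expect_equal(GenomicRanges::start(h), 201)
  # the independent alignment oracle agrees on the full hit set
  o <- oracle_scan(as.character(g[[1]]), consA)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 201L)
  expect_equal(o$edits, 2L)
})

test_that("a reverse-complement copy is reported on the minus strand at the same place", {
  g <- make_genome(chr1 = paste0(strrep("T", 100), revcomp(consA),
                                 strrep("G", 100)))
  h <- scanGenome(g, motifs)
  expect_equal(length(h), 1L)
  expect_equal(GenomicRanges::start(h), 101)
  expect_equal(GenomicRanges::end(h), 126)
  expect_identical(as.character(GenomicRanges::strand(h)), "-")
  expect_equal(S4Vectors::mcols(h)$identity, 1.0)
})

test_that("N bases count as mismatches, never matches", {
  set.seed(42)
  ch <- strsplit(consA, "")[[1]]
  two_n <- ch; two_n[c(4, 14)] <- "N"
  three_n <- ch; three_n[c(4, 14, 22)] <- "N"
  g <- make_genome(chr1 = paste0(rand_dna(150), paste(two_n, collapse = ""),
                                 rand_dna(150), paste(three_n, collapse = ""),
                                 rand_dna(150)))
  h <- scanGenome(g, MotifSet(c(A = consA)))
  expect_equal(length(h), 1L)
  expect_equal(GenomicRanges::start(h), 151)
  expect_equal(S4Vectors::mcols(h)$edits, 2L)
})

test_that("monomers shorter than 10 bp are refused", {
  g <- make_genome(chr1 = rand_dna(100))
  expect_error(scanGenome(g, MotifSet(c(Z = "ACGTACG"))), "shorter than 10")
})

test_that("lowering the identity threshold only ever adds hits", {
  set.seed(43)
  pieces <- unlist(lapply(1:12, function(i)
    c(rand_dna(300), mutate_copy(consA, nsub = sample(0:3, 1)))))
  g <- make_genome(chr1 = paste0(paste(pieces, collapse = ""), rand_dna(300)))
  ms <- MotifSet(c(A = consA))
  strict <- scanGenome(g, ms, ScanParams(min_identity = 0.95))
  loose <- scanGenome(g, ms, ScanParams(min_identity = 0.90))
  key <- function(h) paste(GenomicRanges::start(h), GenomicRanges::end(h),
                           GenomicRanges::strand(h))
  expect_true(all(key(strict) %in% key(loose)))
  expect_gt(length(loose), length(strict))
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  set.seed(44)
  pieces <- c(rand_dna(200), consA, rand_dna(200), revcomp(consA),
              rand_dna(200), mutate_copy(consA, nsub = 2), rand_dna(200))
  txt <- paste(pieces, collapse = "")
  n <- nchar(txt)
  ms <- MotifSet(c(A = consA))
  fwd <- scanGenome(make_genome(chr1 = txt), ms)
  rev <- scanGenome(make_genome(chr1 = revcomp(txt)), ms)
  expect_equal(length(fwd), length(rev))
  expect_equal(sort(S4Vectors::mcols(rev)$edits),
               sort(S4Vectors::mcols(fwd)$edits))
  # exact copies mirror exactly; co-optimal mutated alignments may resolve
  # to a window shifted by up to their edit count
  mirror_start <- sort(n - GenomicRanges::end(rev) + 1)
  fwd_start <- sort(GenomicRanges::start(fwd))
  expect_true(all(abs(mirror_start - fwd_start) <=
                    sort(S4Vectors::mcols(fwd)$edits)))
  exact_f <- fwd[S4Vectors::mcols(fwd)$edits == 0L]
  exact_r <- rev[S4Vectors::mcols(rev)$edits == 0L]
  expect_equal(sort(n - GenomicRanges::end(exact_r) + 1),
               sort(GenomicRanges::start(exact_f)))
  flip <- c("+" = "-", "-" = "+")
  expect_identical(
    sort(as.character(flip[as.character(GenomicRanges::strand(rev))])),
    sort(as.character(GenomicRanges::strand(fwd))))
})

test_that("scan matches the exhaustive alignment oracle on noisy planted genomes", {
  set.seed(45)
  fams <- c("A", "C")
  for (rep in 1:4) {
    pieces <- character(0)
    for (i in 1:10) {
      lab <- sample(fams, 1)
      cons <- as.character(motifs[[lab]])
      copy <- mutate_copy(cons, nsub = sample(0:3, 1), indel = runif(1) < 0.3)
      if (runif(1) < 0.5) copy <- revcomp(copy)
      pieces <- c(pieces, rand_dna(1500), copy)
    }
    txt <- paste0(paste(pieces, collapse = ""), rand_dna(1500))
    g <- make_genome(chr1 = txt)
    for (lab in fams) {
      cons <- as.character(motifs[[lab]])
      got <- scanGenome(g, MotifSet(setNames(cons, lab)))
      want <- oracle_scan(txt, cons)
      expect_equal(length(got), nrow(want))
      expect_equal(GenomicRanges::start(got), want$start)
      expect_equal(GenomicRanges::end(got), want$end)
      expect_equal(S4Vectors::mcols(got)$edits, want$edits)
      expect_identical(as.character(GenomicRanges::strand(got)), want$strand)
    }
  }
})
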