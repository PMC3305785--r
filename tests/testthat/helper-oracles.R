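# Independent oracles used to cross-check the package implementations.
# They share only the *definitions* (identity = 1 - edits/L over a
# semi-global alignment; maximal-cover tandem runs), not the code paths:
# the scan oracle is a vectorized row-DP over motif positions plus
# utils::adist for window recovery, the local-alignment oracle is a plain
# Smith-Waterman matrix with traceback, and the decomposition oracle is an
# exhaustive double loop over unit lengths and phases.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Apply `nsub` substitutions (and optionally one 1-bp indel) to a sequence.
mutate_copy <- function(seq, nsub = 0L, indel = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  if (nsub > 0L) {
    at <- sample.int(length(ch), nsub)
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  if (indel) {
    if (runif(1) < 0.5 && length(ch) > 1L) ch <- ch[-sample.int(length(ch), 1L)]
    else {
      at <- sample.int(length(ch) + 1L, 1L)
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = at - 1L)
    }
  }
  paste(ch, collapse = "")
}

# Minimal semi-global edit distance of `motif` vs every window of `text`
# ending at position j, for all j at once (row-DP over motif positions; the
# insertion dependency along the text is resolved with the cummin trick).
oracle_end_costs <- function(text, motif) {
  tv <- strsplit(text, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  n <- length(tv)
  j <- 0:n
  dp <- rep(0L, n + 1L)
  for (i in seq_along(mv)) {
    sub <- as.integer(tv != mv[i])
    t <- c(i, pmin(dp[1:n] + sub, dp[2:(n + 1L)] + 1L))
    dp <- cummin(t - j) + j
  }
  dp[-1L]
}

# All scan candidates of one motif on one strand: end positions within the
# edit budget, with the shortest optimal window recovered via utils::adist.
oracle_candidates <- function(text, motif, strand, min_identity, band) {
  L <- nchar(motif)
  emax <- floor((1 - min_identity) * L + 1e-9)
  bmax <- floor(band * L + 1e-9)
  ec <- oracle_end_costs(text, motif)
  rows <- list()
  for (j in which(ec <= emax)) {
    e <- ec[j]
    for (W in max(1L, L - e):(L + e)) {
      s1 <- j - W + 1L
      if (s1 < 1L) next
      if (utils::adist(motif, substr(text, s1, j)) == e) {
        if (abs(W - L) <= bmax)
          rows[[length(rows) + 1L]] <-
            data.frame(start = s1, end = j, edits = e, strand = strand,
                       identity = 1 - e / L, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), edits = integer(),
               strand = character(), identity = numeric())
}

# Full oracle for one family: both strands, then local-maximum reduction
# (highest identity, tie leftmost, tie longest, tie plus strand).
oracle_scan <- function(text, motif, min_identity = 0.90, band = 0.10,
                        both_strands = TRUE) {
  cand <- oracle_candidates(text, motif, "+", min_identity, band)
  if (both_strands)
    cand <- rbind(cand,
                  oracle_candidates(text, revcomp(motif), "-", min_identity,
                                    band))
  if (nrow(cand) > 1L) {
    ord <- order(-cand$identity, cand$start, -(cand$end - cand$start),
                 cand$strand)
    keep <- dead <- rep(FALSE, nrow(cand))
    for (i in ord) {
      if (dead[i]) next
      keep[i] <- TRUE
      dead[cand$start <= cand$end[i] & cand$end >= cand$start[i]] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# Plain Smith-Waterman (linear gap) with traceback; returns the best local
# alignment's score, column count and match count.
oracle_local <- function(a, b, match = 1, mismatch = -2, gap = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1L, n + 1L)
  P <- matrix(0L, m + 1L, n + 1L)  # 0 stop, 1 diag, 2 up, 3 left
  for (i in seq_len(m)) {
    s <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(n)) {
      d <- H[i, j] + s[j]
      u <- H[i, j + 1L] - gap
      l <- H[i + 1L, j] - gap
      best <- max(0, d, u, l)
      H[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == 0) 0L else if (best == d) 1L
                           else if (best == u) 2L else 3L
    }
  }
  at <- which(H == max(H), arr.ind = TRUE)[1L, ]
  i <- at[1L]; j <- at[2L]
  nm <- 0L; cols <- 0L
  while (P[i, j] != 0L) {
    cols <- cols + 1L
    if (P[i, j] == 1L) {
      nm <- nm + as.integer(av[i - 1L] == bv[j - 1L])
      i <- i - 1L; j <- j - 1L
    } else if (P[i, j] == 2L) i <- i - 1L else j <- j - 1L
  }
  list(score = max(H), cols = cols, nmatch = nm,
       identity = if (cols) nm / cols else NA_real_)
}

# Exhaustive maximum-cover tandem run over all unit lengths and phases,
# honoring the junction-gap constraint.  Ties: smaller unit, then leftmost.
oracle_best_run <- function(lab, gaps = rep(0L, length(lab)),
                            max_unit_len = 6L, max_gap = 10L) {
  n <- length(lab)
  best <- NULL
  for (u in seq_len(max(0L, min(max_unit_len, n %/% 2L)))) {
    for (p in seq_len(n - 2L * u + 1L)) {
      k <- 1L
      while (p + (k + 1L) * u - 1L <= n &&
             all(lab[(p + k * u):(p + (k + 1L) * u - 1L)] ==
                   lab[(p + (k - 1L) * u):(p + k * u - 1L)]))
        k <- k + 1L
      # truncate at the first oversized junction gap inside the run
      jg <- gaps[(p + 1L):(p + k * u - 1L)]
      brk <- which(jg > max_gap)
      if (length(brk)) k <- min(k, brk[1L] %/% u)
      if (k >= 2L) {
        cover <- k * u
        if (is.null(best) || cover > best$cover)
          best <- list(p = p, u = u, k = k, cover = cover,
                       unit = paste(lab[p:(p + u - 1L)], collapse = ""))
      }
    }
  }
  best
}

# Random label string generators for decomposition tests.
random_labels <- function(n, alphabet = c("A", "B", "C", "D", "E"))
  sample(alphabet, n, replace = TRUE)

repeat_rich_labels <- function() {
  unit <- sample(c("AB", "ABC", "ABAC", "ACB", "AABC"), 1L)
  k <- sample(2:7, 1L)
  lab <- c(random_labels(sample(0:4, 1L)),
           rep(strsplit(unit, "")[[1]], k),
           random_labels(sample(0:4, 1L)))
  head(lab, 30L)
}
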