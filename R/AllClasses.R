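#' MotifSet: a labeled set of minisatellite monomer consensus sequences
#'
#' A thin wrapper around [Biostrings::DNAStringSet] whose validity method
#' enforces the contract the scanner relies on: every monomer carries a
#' unique, non-empty label (the `names()`), and consensus sequences are plain
#' `A`/`C`/`G`/`T` strings (ambiguity codes are not meaningful in a consensus
#' used for identity scoring).
#'
#' @slot .Data inherited `DNAStringSet` payload.
#' @seealso [MotifSet()], [readMotifs()], [defaultMotifs()]
#' @exportClass MotifSet
setClass("MotifSet", contains = "DNAStringSet")

setValidity("MotifSet", function(object) {
  msgs <- character()
  labs <- names(object)
  if (length(object) == 0L)
    msgs <- c(msgs, "a MotifSet must contain at least one monomer")
  if (is.null(labs) || any(!nzchar(labs)))
    msgs <- c(msgs, "every monomer must have a non-empty label")
  else if (anyDuplicated(labs))
    msgs <- c(msgs, sprintf("duplicate monomer labels: %s",
                            paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  if (length(object)) {
    af <- alphabetFrequency(object, baseOnly = TRUE)
    if (any(af[, "other"] > 0))
      msgs <- c(msgs, "monomer consensus sequences must contain only A, C, G, T")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifSet
#'
#' @param x a named character vector of DNA strings, or a named
#'   `DNAStringSet`; names are the family labels (e.g. `"A"` to `"E"`).
#' @return a validated [MotifSet-class].
#' @examples
#' MotifSet(c(A = "ACGTACGTACGTACGTACGTACGTAC"))
#' @export
MotifSet <- function(x) {
  if (is.character(x)) x <- DNAStringSet(toupper(x))
  new("MotifSet", as(x, "DNAStringSet"))
}

#' @describeIn MotifSet family labels of the monomers.
#' @param object,x a `MotifSet`.
#' @export
motifLabels <- function(x) names(x)

#' @describeIn MotifSet monomer lengths in bp, named by label.
#' @export
motifLengths <- function(x) setNames(width(x), names(x))

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet with %d monomer famil%s\n", length(object),
              if (length(object) == 1L) "y" else "ies"))
  cat(sprintf("  %s\n", paste(sprintf("%s (%d bp)", names(object), width(object)),
                              collapse = ", ")))
})

.check_fraction <- function(value, what, lo = 0, hi = 1) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < lo || value > hi)
    sprintf("%s must be a single number in [%g, %g]", what, lo, hi)
  else character()
}

#' ScanParams: parameters of the approximate monomer scan
#'
#' @slot min_identity minimal identity (matching fraction of the consensus
#'   length after optimal semi-global alignment) for a hit to be retained;
#'   default 0.90, the census threshold.
#' @slot band maximal net indel allowance as a fraction of the monomer
#'   length: observed hit lengths are confined to
#'   `[L * (1 - band), L * (1 + band)]`; default 0.10.
#' @slot both_strands scan the reverse complement as well; default `TRUE`.
#' @seealso [ScanParams()], [scanGenome()]
#' @exportClass ScanParams
setClass("ScanParams",
         representation(min_identity = "numeric", band = "numeric",
                        both_strands = "logical"),
         prototype(min_identity = 0.90, band = 0.10, both_strands = TRUE))

setValidity("ScanParams", function(object) {
  msgs <- c(.check_fraction(object@min_identity, "min_identity"),
            .check_fraction(object@band, "band", 0, 0.499))
  if (length(object@min_identity) == 1L && !is.na(object@min_identity) &&
      object@min_identity <= 0)
    msgs <- c(msgs, "min_identity must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScanParams-class
#' @param min_identity,band,both_strands see the class slots.
#' @return a validated `ScanParams` object.
#' @export
ScanParams <- function(min_identity = 0.90, band = 0.10, both_strands = TRUE) {
  new("ScanParams", min_identity = min_identity, band = band,
      both_strands = both_strands)
}

#' @rdname ScanParams-class
#' @param x a `ScanParams` object.
#' @export
minIdentity <- function(x) x@min_identity

#' @rdname ScanParams-class
#' @export
scanBand <- function(x) x@band

setMethod("show", "ScanParams", function(object) {
  cat(sprintf("ScanParams: min_identity=%.3g, band=%.3g, both_strands=%s\n",
              object@min_identity, object@band, object@both_strands))
})

#' ClusterParams: parameters of hit-to-locus clustering
#'
#' @slot max_gap_locus maximal gap in bp between consecutive member hits of
#'   one locus; a larger gap starts a new locus. Default 250 bp: wider than
#'   the ~100-bp breaks seen inside arrays, narrower than typical
#'   inter-element distances.
#' @slot per_family cluster each monomer family separately (the per-repeat
#'   locus counts of the census table) instead of pooling all families.
#' @seealso [clusterHits()], [perFamilyCounts()]
#' @exportClass ClusterParams
setClass("ClusterParams",
         representation(max_gap_locus = "integer", per_family = "logical"),
         prototype(max_gap_locus = 250L, per_family = FALSE))

setValidity("ClusterParams", function(object) {
  if (length(object@max_gap_locus) != 1L || is.na(object@max_gap_locus) ||
      object@max_gap_locus < 0L)
    "max_gap_locus must be a single non-negative integer"
  else TRUE
})

#' @rdname ClusterParams-class
#' @param max_gap_locus,per_family see the class slots.
#' @export
ClusterParams <- function(max_gap_locus = 250L, per_family = FALSE) {
  new("ClusterParams", max_gap_locus = as.integer(max_gap_locus),
      per_family = per_family)
}

#' @rdname ClusterParams-class
#' @param x a `ClusterParams` object.
#' @export
maxGapLocus <- function(x) x@max_gap_locus

setMethod("show", "ClusterParams", function(object) {
  cat(sprintf("ClusterParams: max_gap_locus=%d bp, per_family=%s\n",
              object@max_gap_locus, object@per_family))
})

#' AssignParams: parameters of locus-to-element attribution
#'
#' @slot containment fraction of a locus span that must lie inside a single
#'   annotated element for the locus to count as within it; default 0.5
#'   (set to 1 for strict containment).
#' @slot assign_identity minimal identity of the best local alignment for
#'   similarity-based family assignment of loci outside annotations;
#'   default 0.80.
#' @slot assign_min_span minimal aligned span (alignment columns) for
#'   similarity assignment; default 400 bp.
#' @slot flank bp of flanking sequence taken on each side of an orphan locus
#'   before aligning against family exemplars; default 1000.
#' @seealso [associateLoci()], [assignLociBySimilarity()]
#' @exportClass AssignParams
setClass("AssignParams",
         representation(containment = "numeric", assign_identity = "numeric",
                        assign_min_span = "integer", flank = "integer"),
         prototype(containment = 0.5, assign_identity = 0.80,
                   assign_min_span = 400L, flank = 1000L))

setValidity("AssignParams", function(object) {
  msgs <- c(.check_fraction(object@containment, "containment"),
            .check_fraction(object@assign_identity, "assign_identity"))
  if (object@assign_min_span < 1L)
    msgs <- c(msgs, "assign_min_span must be >= 1")
  if (object@flank < 0L)
    msgs <- c(msgs, "flank must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AssignParams-class
#' @param containment,assign_identity,assign_min_span,flank see the class slots.
#' @export
AssignParams <- function(containment = 0.5, assign_identity = 0.80,
                         assign_min_span = 400L, flank = 1000L) {
  new("AssignParams", containment = containment,
      assign_identity = assign_identity,
      assign_min_span = as.integer(assign_min_span), flank = as.integer(flank))
}

setMethod("show", "AssignParams", function(object) {
  cat(sprintf(paste0("AssignParams: containment=%.2f, assign_identity=%.2f, ",
                     "assign_min_span=%d bp, flank=%d bp\n"),
              object@containment, object@assign_identity,
              object@assign_min_span, object@flank))
})

#' TandemParams: parameters of tandem-array decomposition
#'
#' @slot max_gap_tandem maximal spacer in bp between adjacent monomers of an
#'   "unbroken" tandem run; a larger junction gap always terminates the run.
#'   Default 10 bp (the arrays contrast with ~100-bp breaks).
#' @slot max_unit_len maximal repeating-unit length in monomers; default 6.
#' @seealso [decomposeArray()], [decomposeLoci()]
#' @exportClass TandemParams
setClass("TandemParams",
         representation(max_gap_tandem = "integer", max_unit_len = "integer"),
         prototype(max_gap_tandem = 10L, max_unit_len = 6L))

setValidity("TandemParams", function(object) {
  msgs <- character()
  if (object@max_gap_tandem < 0L) msgs <- c(msgs, "max_gap_tandem must be >= 0")
  if (object@max_unit_len < 1L) msgs <- c(msgs, "max_unit_len must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TandemParams-class
#' @param max_gap_tandem,max_unit_len see the class slots.
#' @export
TandemParams <- function(max_gap_tandem = 10L, max_unit_len = 6L) {
  new("TandemParams", max_gap_tandem = as.integer(max_gap_tandem),
      max_unit_len = as.integer(max_unit_len))
}

setMethod("show", "TandemParams", function(object) {
  cat(sprintf("TandemParams: max_gap_tandem=%d bp, max_unit_len=%d monomers\n",
              object@max_gap_tandem, object@max_unit_len))
})

#' SimSpec: design of a synthetic genome with planted minisatellite arrays
#'
#' Describes the study conditions the generator emulates: a uniform random
#' background genome, copies of one retroelement-like template whose body is
#' followed by an interleaved monomer array (mirroring an element carrying
#' its minisatellite region between coding sequence and LTR), and orphan
#' array loci outside any element -- some flanked by diverged template
#' sequence (resolvable by similarity), some dropped into plain background.
#'
#' @slot chrom_lengths chromosome lengths in bp.
#' @slot n_elements number of planted element copies.
#' @slot element_body_len length of the shared element body template in bp.
#' @slot array_patterns `data.frame` with columns `unit` (monomer label
#'   string, e.g. `"ABAC"`), `count` (tandem repeats per planted array) and
#'   `weight` (sampling weight).
#' @slot orphans_with_flank number of orphan arrays flanked by diverged
#'   copies of the element template.
#' @slot orphans_random number of orphan arrays in plain background.
#' @slot flank_len length in bp of each template-derived orphan flank.
#' @slot flank_divergence per-base substitution rate applied to orphan flanks.
#' @slot sub_rate per-base substitution rate inside planted monomers.
#' @slot indel_rate per-base indel rate inside planted monomers (at most two
#'   indel events per monomer, so identity accounting stays interpretable).
#' @slot minus_strand_prob probability that a planted array (with its host
#'   element) is reverse-complemented.
#' @slot spacer_len bp of random spacer between adjacent monomers.
#' @slot de_tail append, after each element's array, a ~120-bp gap followed
#'   by one D and one E monomer and a ~100-bp break before a second E
#'   monomer, mirroring the downstream structure observed in real elements.
#' @slot min_spacing minimal background spacing around planted features.
#' @slot family,superfamily annotation labels given to planted elements.
#' @slot intact_prob probability an element is annotated as intact.
#' @slot seed integer seed; generation is fully deterministic given the spec.
#' @seealso [simulateGenome()], [SimSpec()]
#' @exportClass SimSpec
setClass("SimSpec",
         representation(chrom_lengths = "integer", n_elements = "integer",
                        element_body_len = "integer", array_patterns = "data.frame",
                        orphans_with_flank = "integer", orphans_random = "integer",
                        flank_len = "integer", flank_divergence = "numeric",
                        sub_rate = "numeric", indel_rate = "numeric",
                        minus_strand_prob = "numeric", spacer_len = "integer",
                        de_tail = "logical", min_spacing = "integer",
                        family = "character", superfamily = "character",
                        intact_prob = "numeric", seed = "integer"),
         prototype(chrom_lengths = c(250000L, 250000L), n_elements = 8L,
                   element_body_len = 4000L,
                   array_patterns = data.frame(
                     unit = c("ABAC", "ABC", "ACB"),
                     count = c(8L, 6L, 4L),
                     weight = c(0.6, 0.25, 0.15),
                     stringsAsFactors = FALSE),
                   orphans_with_flank = 2L, orphans_random = 2L,
                   flank_len = 600L, flank_divergence = 0.10,
                   sub_rate = 0.01, indel_rate = 0.001,
                   minus_strand_prob = 0.3, spacer_len = 0L, de_tail = TRUE,
                   min_spacing = 1000L, family = "GmrS1",
                   superfamily = "Gypsy", intact_prob = 1, seed = 1L))

setValidity("SimSpec", function(object) {
  msgs <- c(.check_fraction(object@sub_rate, "sub_rate", 0, 0.5),
            .check_fraction(object@indel_rate, "indel_rate", 0, 0.5),
            .check_fraction(object@flank_divergence, "flank_divergence", 0, 0.5),
            .check_fraction(object@minus_strand_prob, "minus_strand_prob"),
            .check_fraction(object@intact_prob, "intact_prob"))
  if (any(object@chrom_lengths < 1L))
    msgs <- c(msgs, "chromosome lengths must be positive")
  if (object@n_elements < 0L || object@orphans_with_flank < 0L ||
      object@orphans_random < 0L)
    msgs <- c(msgs, "feature counts must be non-negative")
  ap <- object@array_patterns
  if (!all(c("unit", "count", "weight") %in% names(ap)) || nrow(ap) == 0L)
    msgs <- c(msgs, "array_patterns needs columns unit, count, weight and >= 1 row")
  else if (any(ap$count < 1L) || any(ap$weight < 0) || sum(ap$weight) <= 0)
    msgs <- c(msgs, "array_patterns counts must be >= 1 and weights non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimSpec-class
#' @param ... slot values overriding the defaults (see the class slots).
#' @return a validated `SimSpec` object.
#' @examples
#' SimSpec(n_elements = 4L, sub_rate = 0)
#' @export
SimSpec <- function(...) {
  args <- list(...)
  int_slots <- c("chrom_lengths", "n_elements", "element_body_len",
                 "orphans_with_flank", "orphans_random", "flank_len",
                 "spacer_len", "min_spacing", "seed")
  for (nm in intersect(names(args), int_slots))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "SimSpec"), args))
}

setMethod("show", "SimSpec", function(object) {
  cat("SimSpec:\n")
  cat(sprintf("  chromosomes: %s bp\n",
              paste(object@chrom_lengths, collapse = ", ")))
  cat(sprintf("  %d elements (+%d flanked / %d random orphan arrays)\n",
              object@n_elements, object@orphans_with_flank,
              object@orphans_random))
  cat(sprintf("  patterns: %s\n",
              paste(sprintf("[%s]x%d", object@array_patterns$unit,
                            object@array_patterns$count), collapse = ", ")))
  cat(sprintf("  sub_rate=%.3g, indel_rate=%.3g, minus_strand_prob=%.2g, seed=%d\n",
              object@sub_rate, object@indel_rate, object@minus_strand_prob,
              object@seed))
})
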