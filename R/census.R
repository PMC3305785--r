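#' Run the full minisatellite census pipeline
#'
#' Convenience wrapper chaining [scanGenome()], [dedupeHits()],
#' [clusterHits()], [perFamilyCounts()], [classifyLoci()],
#' [decomposeLoci()], [variantProfiles()], [buildSummaryTable()] and
#' [densityTracks()].
#'
#' @param genome a named `DNAStringSet`.
#' @param motifs a [MotifSet-class]; defaults to [defaultMotifs()].
#' @param annotations optional annotation `GRanges`; without it the
#'   attribution, census table and TE density steps are skipped.
#' @param exemplars optional named `DNAStringSet` of family exemplars for
#'   similarity assignment.
#' @param scan_params,cluster_params,assign_params,tandem_params parameter
#'   objects; defaults as documented on each class.
#' @param window density window in bp; default 100000.
#' @return a list: `hits` (all locally maximal matches), `unique_hits`,
#'   `loci`, `per_family` (hit/locus counts), `assignments`, `segments`
#'   (array decomposition), `profiles`, `summary` (census table) and
#'   `density` (windowed track with correlation attribute).
#' @export
runCensus <- function(genome, motifs = defaultMotifs(), annotations = NULL,
                      exemplars = NULL, scan_params = ScanParams(),
                      cluster_params = ClusterParams(),
                      assign_params = AssignParams(),
                      tandem_params = TandemParams(), window = 100000L) {
  hits <- scanGenome(genome, motifs, scan_params)
  uniq <- dedupeHits(hits)
  loci <- clusterHits(uniq, cluster_params)
  res <- list(hits = hits, unique_hits = uniq, loci = loci,
              per_family = perFamilyCounts(uniq, cluster_params))
  if (!is.null(annotations)) {
    res$assignments <- classifyLoci(loci, annotations, genome, exemplars,
                                    assign_params)
    res$summary <- buildSummaryTable(loci, uniq, res$assignments,
                                     annotations, motifs)
  }
  res$segments <- decomposeLoci(loci, uniq, tandem_params)
  res$profiles <- variantProfiles(uniq, motifs)
  if (!is.null(annotations)) {
    res$density <- densityTracks(uniq, annotations,
                                 setNames(width(genome), names(genome)),
                                 window)
    attr(res$density, "correlation") <-
      if (nrow(res$density) >= 3L) densityCorrelation(res$density)
      else list(rank = NA_real_, linear = NA_real_)
  }
  res
}
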