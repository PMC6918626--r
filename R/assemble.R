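#' Assemble one bundle into transcripts
#'
#' Runs the per-locus core: splice-graph construction, phasing-path
#' extraction and graph decomposition, then converts the resulting paths into
#' transcripts.
#'
#' @param records Record tibble of one bundle.
#' @param chrom,strand Bundle location.
#' @param gene_id Gene identifier assigned to the locus.
#' @param params List of parameters (see [sf_defaults()] names
#'   `min_boundary_reads`, `boundary_allowance`, `min_intron_size`,
#'   `min_transcript_coverage`, `peel_floor`).
#' @return List with `transcripts`, `graph`, `phasing`, `decomposition`.
#' @export
assemble_bundle <- function(records, chrom, strand, gene_id = "G1",
                            params = sf_defaults()) {
  graph <- build_splice_graph(
    records, chrom = chrom, strand = strand,
    min_boundary_reads = params$min_boundary_reads,
    boundary_allowance = params$boundary_allowance,
    min_intron_size = params$min_intron_size
  )
  phasing <- extract_phasing_paths(records, graph)
  decomp <- decompose_graph(
    graph, phasing,
    min_transcript_coverage = params$min_transcript_coverage,
    peel_floor = params$peel_floor
  )
  attr(decomp, "vertices") <- graph$vertices
  tx <- decomposition_to_transcripts(decomp, gene_id = gene_id)
  list(transcripts = tx, graph = graph, phasing = phasing,
       decomposition = decomp)
}

#' Assemble transcripts from spliced long-read alignments
#'
#' The full pipeline: parse and smooth alignments, attach read classes, group
#' records into bundles, build one boundary-aware splice graph per bundle,
#' extract each long read's phasing path, decompose every graph into
#' weighted transcript paths that preserve all phasing paths, and finally
#' collapse nearly redundant isoforms by single-linkage clustering.
#'
#' @param alignments Path to a SAM/BAM file, or a record tibble from
#'   [read_alignments()].
#' @param classification Optional classification table (path, data frame, or
#'   `read_id`/`read_class` tibble); reads default to `NFL_INTERNAL`.
#' @param out_gtf Optional path; when given, the final transcripts are
#'   written there with [write_gtf()].
#' @param min_intron_size Minimum intron length (bp); default 50.
#' @param bundle_gap Locus chaining gap (bp); default 50.
#' @param min_mapping_quality MAPQ filter; default 1.
#' @param min_boundary_reads Boundary-call threshold; default 3.
#' @param boundary_allowance Boundary run spacing allowance (bp); default 10.
#' @param max_cluster_intron_distance Clustering allowance (bp); default 10.
#' @param cluster Set `FALSE` to skip post-assembly clustering.
#' @param min_transcript_coverage Abundance floor for reported transcripts;
#'   default 1.
#' @param peel_floor Residual floor for peeling extra paths; default 1.
#' @return An `sf_assembly`: list with `transcripts` (final tibble),
#'   `transcripts_raw` (pre-clustering), and a one-row `summary` tibble
#'   (bundles, graphs, phasing paths, transcript counts pre/post clustering).
#' @export
assemble <- function(alignments, classification = NULL, out_gtf = NULL,
                     min_intron_size = 50L, bundle_gap = 50L,
                     min_mapping_quality = 1L, min_boundary_reads = 3L,
                     boundary_allowance = 10L,
                     max_cluster_intron_distance = 10L, cluster = TRUE,
                     min_transcript_coverage = 1.0, peel_floor = 1.0) {
  params <- list(
    min_intron_size = min_intron_size, bundle_gap = bundle_gap,
    min_mapping_quality = min_mapping_quality,
    min_boundary_reads = min_boundary_reads,
    boundary_allowance = boundary_allowance,
    max_cluster_intron_distance = max_cluster_intron_distance,
    min_transcript_coverage = min_transcript_coverage,
    peel_floor = peel_floor
  )
  records <- if (is.data.frame(alignments)) {
    alignments
  } else {
    read_alignments(alignments, classification = classification,
                    min_intron_size = min_intron_size,
                    min_mapping_quality = min_mapping_quality)
  }
  bundles <- make_bundles(records, bundle_gap = bundle_gap)
  if (nrow(bundles) == 0L) {
    warn("no usable alignments; producing an empty assembly")
    tx <- empty_transcripts()
    if (!is.null(out_gtf)) {
      write_gtf(tx, out_gtf)
    }
    return(structure(list(
      transcripts = tx, transcripts_raw = tx,
      summary = tibble(n_bundles = 0L, n_graphs = 0L, n_phasing_paths = 0L,
                       n_transcripts_raw = 0L, n_transcripts = 0L)
    ), class = "sf_assembly"))
  }
  n_phasing <- 0L
  pieces <- map(seq_len(nrow(bundles)), function(i) {
    res <- assemble_bundle(
      bundles$records[[i]], chrom = bundles$chrom[i],
      strand = bundles$strand[i],
      gene_id = sprintf("G%04d", bundles$bundle_id[i]), params = params
    )
    n_phasing <<- n_phasing + nrow(res$phasing)
    res$transcripts
  })
  raw <- bind_rows(pieces)
  final <- if (cluster) {
    cluster_transcripts(raw, allowance = max_cluster_intron_distance)
  } else {
    arrange(raw, .data$chrom, .data$start, .data$transcript_id)
  }
  if (!is.null(out_gtf)) {
    write_gtf(final, out_gtf)
  }
  structure(list(
    transcripts = final, transcripts_raw = raw,
    summary = tibble(
      n_bundles = nrow(bundles), n_graphs = nrow(bundles),
      n_phasing_paths = n_phasing, n_transcripts_raw = nrow(raw),
      n_transcripts = nrow(final)
    )
  ), class = "sf_assembly")
}

#' @export
print.sf_assembly <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sf_assembly> %d bundle(s), %d phasing path(s), %d transcript(s) (%d before clustering)\n",
    s$n_bundles, s$n_phasing_paths, s$n_transcripts, s$n_transcripts_raw))
  invisible(x)
}
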