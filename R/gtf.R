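#' Write transcripts to a GTF file
#'
#' GTF2.2 output: one `transcript` line followed by one `exon` line per exon,
#' 1-based inclusive coordinates, attributes `gene_id`, `transcript_id` and
#' `cov` (the predicted abundance, 4 decimal places). Ordering is
#' deterministic: (chrom, start, transcript_id).
#'
#' @param tx Transcript tibble.
#' @param path Destination file.
#' @param source Value for the GTF source column; default `"spliceflow"`.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(tx, path, source = "spliceflow") {
  tx <- arrange(tx, .data$chrom, .data$start, .data$transcript_id)
  lines <- character()
  if (nrow(tx) > 0L) {
    lines <- unlist(pmap(tx, function(chrom, strand, exons, abundance,
                                      transcript_id, gene_id, start, end,
                                      ...) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; cov "%.4f";',
                       gene_id, transcript_id, abundance)
      txl <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, source, start + 1L, end, strand, attrs)
      exl <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, source, exons[, "start"] + 1L, exons[, "end"],
                     strand, attrs)
      c(txl, exl)
    }))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read transcripts from a GTF file
#'
#' Exon features are grouped by `transcript_id`, sorted, and converted to the
#' internal 0-based half-open convention. Reading is gzip-transparent and
#' tolerates quoted or unquoted attribute values. Transcript features without
#' any exon are skipped with a warning. The `cov` attribute, when present,
#' becomes the abundance (otherwise `NA`).
#'
#' @param path GTF file (optionally gzipped).
#' @return A transcript tibble.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(meta)) {
    abort("GTF lacks transcript_id attributes")
  }
  type <- as.character(meta$type)
  tx_ids_seen <- unique(meta$transcript_id[type == "transcript"])
  ex <- gr[type == "exon" & !is.na(meta$transcript_id)]
  if (length(ex) == 0L) {
    if (length(tx_ids_seen)) {
      warn(sprintf("%d transcript(s) without exons skipped",
                   length(tx_ids_seen)))
    }
    return(empty_transcripts())
  }
  exm <- S4Vectors::mcols(ex)
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L, # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    transcript_id = as.character(exm$transcript_id),
    gene_id = if ("gene_id" %in% names(exm)) {
      as.character(exm$gene_id)
    } else {
      NA_character_
    },
    cov = if ("cov" %in% names(exm)) {
      suppressWarnings(as.numeric(exm$cov))
    } else {
      NA_real_
    }
  )
  skipped <- setdiff(tx_ids_seen, unique(df$transcript_id))
  if (length(skipped)) {
    warn(sprintf("%d transcript(s) without exons skipped", length(skipped)))
  }
  out <- df %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      exons = list(cbind(start = as.integer(.data$start),
                         end = as.integer(.data$end))),
      abundance = first(.data$cov),
      gene_id = first(.data$gene_id),
      .groups = "drop"
    )
  validate_transcripts(
    select(out, "chrom", "strand", "exons", "abundance", "transcript_id",
           "gene_id")
  ) %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)
}
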