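# ---- transcript tibbles -----------------------------------------------------
#
# A transcript set is a tibble with columns:
#   chrom, strand, exons (list of start/end matrices, 0-based half-open),
#   abundance, transcript_id, gene_id
# Exons are sorted, non-overlapping, separated by >= 1 bp.

#' Construct a transcript tibble
#'
#' @param chrom,strand Character vectors.
#' @param exons List of integer matrices with columns `start`, `end`
#'   (0-based, half-open), one row per exon, sorted and non-overlapping.
#' @param abundance Numeric, non-negative.
#' @param transcript_id,gene_id Identifiers.
#' @return A validated transcript tibble with derived columns `start`, `end`,
#'   `n_exons`.
#' @export
new_transcripts <- function(chrom, strand, exons, abundance,
                            transcript_id, gene_id) {
  tx <- tibble(
    chrom = as.character(chrom), strand = as.character(strand),
    exons = exons, abundance = as.numeric(abundance),
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id)
  )
  validate_transcripts(tx)
}

validate_transcripts <- function(tx) {
  ok <- map_lgl(tx$exons, function(e) {
    is.matrix(e) && nrow(e) >= 1L && all(e[, "end"] > e[, "start"]) &&
      (nrow(e) < 2L || all(e[-1L, "start"] > e[-nrow(e), "end"]))
  })
  if (!all(ok)) {
    abort("invalid exon chains (unsorted, overlapping or empty exons)")
  }
  if (any(tx$abundance < 0, na.rm = TRUE)) {
    abort("negative abundance")
  }
  tx$start <- map_int(tx$exons, function(e) as.integer(e[1L, "start"]))
  tx$end <- map_int(tx$exons, function(e) as.integer(e[nrow(e), "end"]))
  tx$n_exons <- map_int(tx$exons, nrow)
  tx
}

# intron chain of one exon matrix: (donor, acceptor) pairs; 0-row for
# single-exon transcripts
tx_junctions <- function(exons) {
  k <- nrow(exons)
  if (k < 2L) {
    return(cbind(donor = integer(), acceptor = integer()))
  }
  cbind(donor = exons[-k, "end"], acceptor = exons[-1L, "start"])
}

# canonical string key of a transcript's intron chain (chrom, strand,
# junction coordinates); NA key for single-exon transcripts
chain_key <- function(tx) {
  keys <- map_chr(tx$exons, function(e) {
    j <- tx_junctions(e)
    if (nrow(j) == 0L) {
      return(NA_character_)
    }
    paste(paste(j[, "donor"], j[, "acceptor"], sep = "-"), collapse = ",")
  })
  ifelse(is.na(keys), NA_character_,
         paste(tx$chrom, tx$strand, keys, sep = "|"))
}

# convert a decomposition path (internal vertex chain) to an exon matrix:
# consecutive abutting vertices merge into one exon, junctions split
path_to_exons <- function(vertices_tbl, path) {
  st <- vertices_tbl$start[path]
  en <- vertices_tbl$end[path]
  k <- length(path)
  if (k == 1L) {
    return(cbind(start = st, end = en))
  }
  new_exon <- c(TRUE, st[-1L] != en[-k])
  grp <- cumsum(new_exon)
  cbind(start = as.integer(tapply(st, grp, min)),
        end = as.integer(tapply(en, grp, max)))
}

#' Turn a decomposition into transcripts
#'
#' @param decomp An `sf_decomposition`.
#' @param gene_id Gene identifier to assign (one locus per graph).
#' @return A transcript tibble; transcript ids are `<gene_id>.<path_id>`.
#' @export
decomposition_to_transcripts <- function(decomp, gene_id = "G1") {
  if (nrow(decomp$paths) == 0L) {
    return(empty_transcripts())
  }
  # vertices coordinates travel with the decomposition via the graph used to
  # build it; callers pass them through attr when needed
  vt <- attr(decomp, "vertices")
  if (is.null(vt)) {
    abort("decomposition lacks vertex coordinates; use assemble_bundle()")
  }
  exons <- map(decomp$paths$vertices, ~ path_to_exons(vt, .x))
  new_transcripts(
    chrom = decomp$chrom, strand = decomp$strand, exons = exons,
    abundance = decomp$paths$abundance,
    transcript_id = paste0(gene_id, ".", decomp$paths$path_id),
    gene_id = gene_id
  )
}

empty_transcripts <- function() {
  tibble(
    chrom = character(), strand = character(), exons = list(),
    abundance = numeric(), transcript_id = character(),
    gene_id = character(), start = integer(), end = integer(),
    n_exons = integer()
  )
}
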