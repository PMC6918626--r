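#' Smooth a spliced CIGAR into genomic segments
#'
#' Long-read alignments are indel-rich; a lone insertion or deletion in the
#' middle of an exon is almost always a sequencing error, not structure.
#' Smoothing therefore keeps only the intron signal: match/mismatch ops extend
#' the current segment, insertions are invisible on the reference, deletions of
#' any length are merged into the current segment (they still consume
#' reference and count toward coverage), and an `N` op opens a new segment
#' only when it is at least `min_intron_size` long — shorter `N` ops are
#' merged like deletions, filtering spurious junctions created by aligners
#' from long deletion errors.
#'
#' @param cigar CIGAR string.
#' @param pos 0-based reference start of the alignment.
#' @param min_intron_size Minimum intron length (bp) for an `N` op to be kept
#'   as a junction; default 50.
#' @return An integer matrix with columns `start`, `end` (0-based, half-open),
#'   one row per segment; or `NULL` when the record must be rejected (CIGAR
#'   beginning or ending in a kept intron, or an empty segment between two
#'   kept introns).
#' @export
#' @examples
#' smooth_cigar("100M2D50M", 1000)          # one segment [1000, 1152)
#' smooth_cigar("10M60N10M", 0)             # junction kept: two segments
#' smooth_cigar("10M30N10M", 0)             # 30 < 50: merged into [0, 50)
smooth_cigar <- function(cigar, pos, min_intron_size = 50L) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref <- ops %in% c("M", "=", "X", "D", "N")
  ops <- ops[ref]
  lens <- lens[ref]
  if (!length(ops)) {
    return(NULL)
  }
  is_break <- ops == "N" & lens >= min_intron_size
  if (is_break[1L] || is_break[length(ops)]) {
    return(NULL)
  }
  off_end <- cumsum(lens)
  off_start <- off_end - lens
  grp <- cumsum(is_break)
  seg_ops <- !is_break
  # a group with no reference-consuming op between two kept introns would be a
  # zero-length segment
  groups <- seq.int(0L, grp[length(grp)])
  if (!all(groups %in% grp[seg_ops])) {
    return(NULL)
  }
  start <- vapply(groups, function(g) min(off_start[seg_ops & grp == g]), 0)
  end <- vapply(groups, function(g) max(off_end[seg_ops & grp == g]), 0)
  cbind(start = as.integer(pos + start), end = as.integer(pos + end))
}

#' Resolve the transcript strand of an alignment
#'
#' Long-read aligners report the transcribed strand of a spliced alignment in
#' the `XS` tag (from splice-site motifs) or as `ts` (transcript strand
#' relative to the read's mapping strand). When neither tag is present the
#' strand is unknown; such records are later placed on both strands so that
#' neither interpretation is lost.
#'
#' @param mapping_strand `"+"` or `"-"` (from the SAM flag).
#' @param xs,ts Tag values (`"+"`, `"-"`) or `NA` when absent.
#' @return `"+"`, `"-"` or `"*"` (unknown).
#' @export
resolve_strand <- function(mapping_strand, xs = NA_character_,
                           ts = NA_character_) {
  n <- max(length(mapping_strand), length(xs), length(ts))
  mapping_strand <- rep_len(as.character(mapping_strand), n)
  xs <- rep_len(as.character(xs), n)
  ts <- rep_len(as.character(ts), n)
  flip <- c("+" = "-", "-" = "+")
  out <- rep("*", n)
  use_ts <- is.na(xs) & !is.na(ts) & ts %in% c("+", "-")
  out[use_ts] <- ifelse(ts[use_ts] == "+", mapping_strand[use_ts],
                        flip[mapping_strand[use_ts]])
  use_xs <- !is.na(xs) & xs %in% c("+", "-")
  out[use_xs] <- xs[use_xs]
  out
}

# boundary positions for records of known strand; terminal coordinates of the
# smoothed segments (0-based half-open: left end = first start, right end =
# last end). 5' is the left end on the forward strand, the right end on the
# reverse strand.
record_boundaries <- function(strand, start, end, read_class) {
  left <- ifelse(strand == "+", start, NA_integer_)
  right <- ifelse(strand == "+", end, NA_integer_)
  b5 <- ifelse(strand == "+", start, end)
  b3 <- ifelse(strand == "+", end, start)
  has5 <- read_class %in% c("FULL_LENGTH", "NFL_5ONLY") & strand != "*"
  has3 <- read_class %in% c("FULL_LENGTH", "NFL_3ONLY") & strand != "*"
  list(
    boundary_5p = ifelse(has5, b5, NA_integer_),
    boundary_3p = ifelse(has3, b3, NA_integer_)
  )
}

#' Read spliced long-read alignments into smoothed records
#'
#' Parses a SAM or BAM file (primary alignments only), smooths each CIGAR with
#' [smooth_cigar()], resolves the transcript strand and attaches the read
#' completeness class from a classification table. Reads missing from the
#' classification are treated as `NFL_INTERNAL` (no boundary information is
#' claimed for them).
#'
#' @param file Path to a SAM or BAM file. Text SAM is converted on the fly.
#' @param classification Optional classification: a path or data frame
#'   accepted by [parse_classification()], or a tibble with columns
#'   `read_id`, `read_class`.
#' @param min_intron_size Passed to [smooth_cigar()].
#' @param min_mapping_quality Records with MAPQ below this are dropped
#'   (MAPQ 255 "unavailable" is kept). Default 1.
#' @return A tibble of alignment records: `read_id`, `chrom`, `strand`
#'   (`"+"`, `"-"`, `"*"`), `read_class`, `segments` (list of start/end
#'   matrices, 0-based half-open), `start`, `end`, `n_segments`,
#'   `boundary_5p`, `boundary_3p`.
#' @export
read_alignments <- function(file, classification = NULL,
                            min_intron_size = 50L, min_mapping_quality = 1L) {
  stopifnot(file.exists(file))
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = c("XS", "ts")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    return(empty_records())
  }
  xs <- res$tag$XS %||% rep(NA_character_, n)
  ts <- res$tag$ts %||% rep(NA_character_, n)
  keep <- is.na(res$mapq) | res$mapq == 255L | res$mapq >= min_mapping_quality
  segments <- map2(res$cigar, res$pos - 1L, smooth_cigar,
                   min_intron_size = min_intron_size)
  bad <- map_lgl(segments, is.null)
  if (any(bad & keep)) {
    warn(sprintf("rejected %d record(s) with unusable CIGARs", sum(bad & keep)))
  }
  keep <- keep & !bad
  rec <- tibble(
    read_id = as.character(res$qname)[keep],
    chrom = as.character(res$rname)[keep],
    strand = resolve_strand(as.character(res$strand)[keep],
                            as.character(xs)[keep], as.character(ts)[keep]),
    segments = segments[keep]
  )
  rec$start <- map_int(rec$segments, function(s) s[1L, "start"])
  rec$end <- map_int(rec$segments, function(s) s[nrow(s), "end"])
  rec$n_segments <- map_int(rec$segments, nrow)

  rec$read_class <- "NFL_INTERNAL"
  if (!is.null(classification)) {
    cls <- classification
    if (!(is.data.frame(cls) && "read_class" %in% names(cls))) {
      cls <- parse_classification(cls)
    }
    idx <- match(rec$read_id, cls$read_id)
    if (anyNA(idx)) {
      warn(sprintf("%d aligned read(s) absent from classification; treated as NFL_INTERNAL",
                   sum(is.na(idx))))
    }
    rec$read_class[!is.na(idx)] <- cls$read_class[idx[!is.na(idx)]]
  }
  b <- record_boundaries(rec$strand, rec$start, rec$end, rec$read_class)
  rec$boundary_5p <- b$boundary_5p
  rec$boundary_3p <- b$boundary_3p
  arrange(rec, .data$chrom, .data$start, .data$end, .data$read_id) %>%
    select("read_id", "chrom", "strand", "read_class", "segments",
           "start", "end", "n_segments", "boundary_5p", "boundary_3p")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_records <- function() {
  tibble(
    read_id = character(), chrom = character(), strand = character(),
    read_class = character(), segments = list(), start = integer(),
    end = integer(), n_segments = integer(),
    boundary_5p = integer(), boundary_3p = integer()
  )
}

#' Group alignment records into loci (bundles)
#'
#' Single-linkage chaining per chromosome and strand: a record joins the open
#' bundle iff its start lies closer than `bundle_gap` past the running maximum
#' end, so each bundle is a maximal chained cluster of near-overlapping
#' alignments — the unit on which a splice graph is built. Records of unknown
#' strand (`"*"`) are copied onto both strands, with their boundary positions
#' reinterpreted for each strand.
#'
#' @param records A record tibble from [read_alignments()].
#' @param bundle_gap Maximum gap (bp) bridged within a bundle; default 50.
#' @return A tibble with one row per bundle: `bundle_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_reads` and a `records` list-column.
#' @export
make_bundles <- function(records, bundle_gap = 50L) {
  stopifnot(bundle_gap >= 0L)
  if (nrow(records) == 0L) {
    return(tibble(bundle_id = integer(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_reads = integer(), records = list()))
  }
  unknown <- filter(records, .data$strand == "*")
  known <- filter(records, .data$strand != "*")
  if (nrow(unknown) > 0L) {
    both <- bind_rows(mutate(unknown, strand = "+"),
                      mutate(unknown, strand = "-"))
    b <- record_boundaries(both$strand, both$start, both$end, both$read_class)
    both$boundary_5p <- b$boundary_5p
    both$boundary_3p <- b$boundary_3p
    records <- bind_rows(known, both)
  } else {
    records <- known
  }
  records <- arrange(records, .data$chrom, .data$strand, .data$start,
                     .data$end, .data$read_id)
  grouped <- records %>%
    group_by(.data$chrom, .data$strand) %>%
    mutate(
      run_end = cummax(lag(.data$end, default = first(.data$end))),
      new_bundle = row_number() == 1L |
        .data$start >= .data$run_end + bundle_gap,
      local_bundle = cumsum(.data$new_bundle)
    ) %>%
    ungroup()
  out <- grouped %>%
    select(-"run_end", -"new_bundle") %>%
    tidyr::nest(records = -c("chrom", "strand", "local_bundle")) %>%
    mutate(
      start = map_int(.data$records, ~ min(.x$start)),
      end = map_int(.data$records, ~ max(.x$end)),
      n_reads = map_int(.data$records, nrow)
    ) %>%
    arrange(.data$chrom, .data$start, .data$strand) %>%
    mutate(bundle_id = row_number()) %>%
    select("bundle_id", "chrom", "strand", "start", "end", "n_reads",
           "records")
  out
}
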