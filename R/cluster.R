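#' Are two transcripts nearly redundant?
#'
#' True iff the transcripts are on the same chromosome and strand, have the
#' same (non-zero) number of splice junctions, and for every junction the sum
#' of the absolute donor and acceptor position differences is within
#' `allowance`. Symmetric; undefined (false) for single-exon transcripts.
#'
#' @param exons1,exons2 Exon matrices (0-based half-open).
#' @param chrom1,chrom2,strand1,strand2 Location of each transcript.
#' @param allowance Per-junction allowance in bp; default 10.
#' @return Logical scalar.
#' @export
transcripts_similar <- function(exons1, exons2, chrom1 = "1", chrom2 = "1",
                                strand1 = "+", strand2 = "+",
                                allowance = 10L) {
  stopifnot(allowance >= 0L)
  if (chrom1 != chrom2 || strand1 != strand2) {
    return(FALSE)
  }
  j1 <- tx_junctions(exons1)
  j2 <- tx_junctions(exons2)
  if (nrow(j1) == 0L || nrow(j1) != nrow(j2)) {
    return(FALSE)
  }
  all(abs(j1[, "donor"] - j2[, "donor"]) +
        abs(j1[, "acceptor"] - j2[, "acceptor"]) <= allowance)
}

#' Single-linkage clustering of nearly redundant transcripts
#'
#' Builds an undirected similarity graph over multi-exon transcripts (edges
#' where [transcripts_similar()] holds) and collapses each connected
#' component to one consensus transcript: the member with the highest
#' abundance (ties: longer span, then leftmost, then lexicographic id), with
#' abundance set to the component sum and its two end-exons extended so the
#' consensus spans every member (internal junctions unchanged). Single-exon
#' transcripts pass through unclustered.
#'
#' @param tx Transcript tibble.
#' @param allowance Per-junction allowance in bp (the
#'   `max_cluster_intron_distance` parameter); default 10.
#' @return A transcript tibble with one row per cluster (plus single-exon
#'   pass-throughs), total abundance conserved.
#' @export
cluster_transcripts <- function(tx, allowance = 10L) {
  if (nrow(tx) == 0L) {
    return(tx)
  }
  singles <- filter(tx, .data$n_exons < 2L)
  multi <- filter(tx, .data$n_exons >= 2L)
  if (nrow(multi) == 0L) {
    return(arrange(tx, .data$chrom, .data$start, .data$transcript_id))
  }
  multi <- mutate(multi,
                  n_junc = .data$n_exons - 1L,
                  first_donor = map_int(.data$exons,
                                        ~ as.integer(.x[1L, "end"])))
  groups <- multi %>%
    mutate(.row = row_number()) %>%
    group_by(.data$chrom, .data$strand, .data$n_junc) %>%
    group_split()

  out <- map(groups, function(g) {
    g <- arrange(g, .data$first_donor, .data$transcript_id)
    n <- nrow(g)
    edges <- list()
    # a similar pair cannot differ by more than `allowance` at the first
    # donor, so a sorted sliding window is equivalent to all-pairs
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && g$first_donor[j] - g$first_donor[i] <= allowance) {
        if (transcripts_similar(g$exons[[i]], g$exons[[j]],
                                g$chrom[i], g$chrom[j],
                                g$strand[i], g$strand[j],
                                allowance = allowance)) {
          edges[[length(edges) + 1L]] <- c(i, j)
        }
        j <- j + 1L
      }
    }
    gr <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges)) {
      gr <- igraph::add_edges(gr, unlist(edges))
    }
    comp <- igraph::components(gr)$membership
    g$cluster <- comp
    g %>%
      group_by(.data$cluster) %>%
      group_map(~ collapse_cluster(.x)) %>%
      bind_rows()
  })
  res <- bind_rows(bind_rows(out), singles)
  res <- select(res, -any_of(c("n_junc", "first_donor", ".row", "cluster")))
  arrange(res, .data$chrom, .data$start, .data$transcript_id)
}

collapse_cluster <- function(members) {
  if (nrow(members) == 1L) {
    return(members)
  }
  ord <- order(-members$abundance, -(members$end - members$start),
               members$start, members$transcript_id)
  rep_row <- members[ord[1L], ]
  exons <- rep_row$exons[[1L]]
  exons[1L, "start"] <- min(members$start)
  exons[nrow(exons), "end"] <- max(members$end)
  rep_row$exons <- list(exons)
  rep_row$abundance <- sum(members$abundance)
  rep_row$start <- as.integer(exons[1L, "start"])
  rep_row$end <- as.integer(exons[nrow(exons), "end"])
  rep_row
}
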