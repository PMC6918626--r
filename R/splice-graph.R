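#' Collect typed positions from a bundle
#'
#' Flattens a bundle's records into a single position-sorted sequence of typed
#' events: splice donors/acceptors from every junction of every read, and
#' 5'/3' boundary positions contributed only by boundary reads (full-length
#' and single-primer reads — never `NFL_INTERNAL`, which is treated like a
#' short read). Ties at equal coordinates place splice events before boundary
#' events, so a splice site always interrupts a boundary run at its own
#' position.
#'
#' @param records Record tibble (one bundle's `records` element).
#' @return A tibble `pos`, `type` (`donor`, `acceptor`, `b5`, `b3`), sorted.
#' @export
collect_positions <- function(records) {
  splice <- map(records$segments, function(s) {
    k <- nrow(s)
    if (k < 2L) {
      return(NULL)
    }
    tibble(pos = as.integer(c(s[-k, "end"], s[-1L, "start"])),
           type = rep(c("donor", "acceptor"), each = k - 1L))
  })
  splice <- bind_rows(splice)
  b5 <- tibble(pos = records$boundary_5p[!is.na(records$boundary_5p)],
               type = "b5")
  b3 <- tibble(pos = records$boundary_3p[!is.na(records$boundary_3p)],
               type = "b3")
  ev <- bind_rows(splice, b5, b3)
  if (nrow(ev) == 0L) {
    return(tibble(pos = integer(), type = character()))
  }
  ev$is_boundary <- ev$type %in% c("b5", "b3")
  ev <- arrange(ev, .data$pos, .data$is_boundary, .data$type)
  select(ev, "pos", "type")
}

#' Call transcript boundaries from a sorted event sequence
#'
#' Scans for maximal runs of same-type boundary events that are (a) not
#' interrupted by a splice event or a boundary event of the other type and
#' (b) spaced at most `boundary_allowance` apart between consecutive members.
#' A run of at least `min_boundary_reads` events becomes one boundary call.
#' On the forward strand a 5' run is reported at its leftmost position and a
#' 3' run at its rightmost; on the reverse strand the reporting is mirrored
#' (the 5' end of a reverse-strand transcript is the genomically rightmost).
#'
#' @param events Event tibble from [collect_positions()].
#' @param strand `"+"` or `"-"`.
#' @param min_boundary_reads Minimum run size to call a boundary; default 3.
#' @param boundary_allowance Maximum spacing (bp) between consecutive run
#'   members; default 10.
#' @return A tibble of calls: `kind` (`start_5p`/`end_3p`), `position`,
#'   `support`, `side` (`left`/`right` — the genomic side of the vertex the
#'   call anchors).
#' @export
call_boundaries <- function(events, strand = "+", min_boundary_reads = 3L,
                            boundary_allowance = 10L) {
  stopifnot(min_boundary_reads >= 1L, boundary_allowance >= 0L)
  calls <- list()
  run_type <- NA_character_
  run_pos <- integer()

  emit <- function() {
    if (!is.na(run_type) && length(run_pos) >= min_boundary_reads) {
      if (run_type == "b5") {
        pos <- if (strand == "+") min(run_pos) else max(run_pos)
        kind <- "start_5p"
      } else {
        pos <- if (strand == "+") max(run_pos) else min(run_pos)
        kind <- "end_3p"
      }
      side <- if ((run_type == "b5") == (strand == "+")) "left" else "right"
      calls[[length(calls) + 1L]] <<- tibble(
        kind = kind, position = as.integer(pos),
        support = length(run_pos), side = side
      )
    }
  }

  for (i in seq_len(nrow(events))) {
    type <- events$type[i]
    pos <- events$pos[i]
    if (!type %in% c("b5", "b3")) { # splice event: break any run
      emit()
      run_type <- NA_character_
      run_pos <- integer()
    } else if (identical(type, run_type) &&
               pos - run_pos[length(run_pos)] <= boundary_allowance) {
      run_pos <- c(run_pos, pos)
    } else {
      emit()
      run_type <- type
      run_pos <- pos
    }
  }
  emit()
  if (!length(calls)) {
    return(tibble(kind = character(), position = integer(),
                  support = integer(), side = character()))
  }
  distinct(bind_rows(calls))
}

#' Partition a bundle's covered genome into partial exons
#'
#' The covered genome of a bundle is cut at every splice position, every
#' called transcript boundary, and every zero-coverage gap. Each resulting
#' piece is a partial exon — a splice-graph vertex — whose weight is the mean
#' per-base read coverage over its interval.
#'
#' @param records Record tibble of one bundle.
#' @param boundaries Boundary calls from [call_boundaries()].
#' @return A tibble `vertex`, `start`, `end` (0-based half-open), `weight`.
#' @export
segment_partial_exons <- function(records, boundaries) {
  segs <- do.call(rbind, records$segments)
  ir <- IRanges::IRanges(start = segs[, "start"] + 1L, end = segs[, "end"])
  cov <- IRanges::coverage(ir)
  covered <- IRanges::reduce(ir)
  splice <- collect_positions(records)
  cuts <- sort(unique(c(
    splice$pos[splice$type %in% c("donor", "acceptor")],
    boundaries$position
  )))
  pieces <- list()
  for (i in seq_along(covered)) {
    a <- IRanges::start(covered)[i] - 1L # back to 0-based half-open
    b <- IRanges::end(covered)[i]
    inner <- cuts[cuts > a & cuts < b]
    bnd <- c(a, inner, b)
    pieces[[i]] <- tibble(start = bnd[-length(bnd)], end = bnd[-1L])
  }
  px <- bind_rows(pieces)
  v <- IRanges::Views(cov, start = px$start + 1L, end = px$end)
  px$weight <- as.numeric(IRanges::viewMeans(v))
  px <- arrange(px, .data$start)
  px$vertex <- seq_len(nrow(px))
  select(px, "vertex", "start", "end", "weight")
}

#' Build the splice graph of one bundle
#'
#' Vertices are the partial exons; edges carry read support. Junction edges
#' connect the vertex ending at a junction's donor to the vertex starting at
#' its acceptor, weighted by the number of reads spanning that junction.
#' Adjacency edges connect genomically abutting vertices crossed contiguously
#' by at least one read, weighted by the crossing-read count. The virtual
#' source `s` (index 0) links to every vertex holding a transcript-start
#' boundary at its left end and to every vertex with no other incoming edge;
#' symmetrically for the target `t` (index `n_vertices + 1`). Source/sink
#' edge weights are the counts of reads whose alignment starts (resp. ends)
#' inside the vertex. The graph is a DAG in coordinate order; reverse-strand
#' loci keep genomic coordinates and a strand flag.
#'
#' @param records Record tibble of one bundle.
#' @param chrom,strand Bundle location.
#' @param min_boundary_reads,boundary_allowance Passed to
#'   [call_boundaries()].
#' @param min_intron_size Junction sanity check (introns shorter than this
#'   cannot occur after smoothing).
#' @return A `splice_graph` object: list with `chrom`, `strand`, `vertices`,
#'   `edges` (`from`, `to`, `weight`, `kind`), `boundaries`, `n_reads`.
#' @export
build_splice_graph <- function(records, chrom = records$chrom[1],
                               strand = "+", min_boundary_reads = 3L,
                               boundary_allowance = 10L,
                               min_intron_size = 50L) {
  stopifnot(nrow(records) > 0L)
  events <- collect_positions(records)
  boundaries <- call_boundaries(events, strand = strand,
                                min_boundary_reads = min_boundary_reads,
                                boundary_allowance = boundary_allowance)
  vertices <- segment_partial_exons(records, boundaries)
  n <- nrow(vertices)

  # junction census across reads
  juncs <- bind_rows(map(records$segments, function(s) {
    k <- nrow(s)
    if (k < 2L) {
      return(NULL)
    }
    tibble(donor = s[-k, "end"], acceptor = s[-1L, "start"])
  }))
  edges <- tibble(from = integer(), to = integer(), weight = numeric(),
                  kind = character())
  if (nrow(juncs) > 0L) {
    jc <- count(juncs, .data$donor, .data$acceptor, name = "weight")
    if (any(jc$acceptor - jc$donor < min_intron_size)) {
      abort("junction shorter than min_intron_size survived smoothing")
    }
    u <- match(jc$donor, vertices$end)
    v <- match(jc$acceptor, vertices$start)
    if (anyNA(u) || anyNA(v)) {
      abort("junction references a position with no matching partial exon")
    }
    edges <- bind_rows(edges, tibble(from = u, to = v,
                                     weight = as.numeric(jc$weight),
                                     kind = "junction"))
  }

  # adjacency edges between abutting vertices crossed by >= 1 read
  if (n > 1L) {
    abut <- which(vertices$end[-n] == vertices$start[-1L])
    for (i in abut) {
      bp <- vertices$end[i]
      crossing <- sum(map_lgl(records$segments, function(s) {
        any(s[, "start"] < bp & s[, "end"] > bp)
      }))
      if (crossing >= 1L) {
        edges <- bind_rows(edges, tibble(from = i, to = i + 1L,
                                         weight = as.numeric(crossing),
                                         kind = "adjacency"))
      }
    }
  }

  starts_in <- function(v) {
    sum(records$start >= vertices$start[v] & records$start < vertices$end[v])
  }
  ends_in <- function(v) {
    sum(records$end > vertices$start[v] & records$end <= vertices$end[v])
  }

  src_v <- unique(c(
    match(boundaries$position[boundaries$side == "left"], vertices$start),
    setdiff(seq_len(n), edges$to)
  ))
  src_v <- sort(src_v[!is.na(src_v)])
  snk_v <- unique(c(
    match(boundaries$position[boundaries$side == "right"], vertices$end),
    setdiff(seq_len(n), edges$from)
  ))
  snk_v <- sort(snk_v[!is.na(snk_v)])

  edges <- bind_rows(
    edges,
    tibble(from = 0L, to = src_v,
           weight = as.numeric(vapply(src_v, starts_in, 0L)),
           kind = "source_link"),
    tibble(from = snk_v, to = n + 1L,
           weight = as.numeric(vapply(snk_v, ends_in, 0L)),
           kind = "sink_link")
  )
  edges <- arrange(edges, .data$from, .data$to)

  structure(
    list(chrom = chrom, strand = strand, vertices = vertices, edges = edges,
         boundaries = boundaries, n_reads = nrow(records)),
    class = "splice_graph"
  )
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("<splice_graph> %s:%d-%d (%s)  %d vertices, %d edges, %d reads\n",
              x$chrom, min(x$vertices$start), max(x$vertices$end), x$strand,
              nrow(x$vertices), nrow(x$edges), x$n_reads))
  invisible(x)
}

# project one read's segments onto the ordered chain of vertices it covers;
# NULL when the read is incompatible with the graph's junction structure
project_read <- function(segments, vertices) {
  chain <- integer()
  k <- nrow(segments)
  for (i in seq_len(k)) {
    s <- segments[i, "start"]
    e <- segments[i, "end"]
    hit <- which(vertices$start < e & vertices$end > s)
    if (!length(hit)) {
      return(NULL)
    }
    if (i > 1L) {
      # junction: previous segment must end exactly at a vertex right border
      # and this one start exactly at a vertex left border
      if (vertices$end[chain[length(chain)]] != segments[i - 1L, "end"] ||
          vertices$start[hit[1L]] != s) {
        return(NULL)
      }
    }
    chain <- c(chain, hit)
  }
  chain
}

#' Extract phasing paths from a bundle's reads
#'
#' Each read's segment chain is projected onto the ordered chain of partial
#' exons it covers; a read covers a vertex if it overlaps at least one base of
#' it and its junctions are compatible with the vertex borders (terminal
#' vertices may be covered partially — truncated reads still phase interior
#' exons). Chains spanning more than two vertices become phasing paths:
#' the per-molecule constraints that decomposition must keep intact.
#' Identical chains are merged with summed support; a chain that is a
#' contiguous subsequence of a longer one is retained as its own constraint.
#'
#' @param records Record tibble of one bundle.
#' @param graph The bundle's [build_splice_graph()] result.
#' @return A tibble `chain` (list of vertex index vectors), `support`.
#' @export
extract_phasing_paths <- function(records, graph) {
  chains <- map(records$segments, project_read, vertices = graph$vertices)
  bad <- map_lgl(chains, is.null)
  if (any(bad)) {
    warn(sprintf("%d read(s) incompatible with the splice graph were excluded from phasing",
                 sum(bad)))
  }
  chains <- chains[!bad]
  chains <- chains[map_int(chains, length) >= 3L]
  if (!length(chains)) {
    return(tibble(chain = list(), support = integer()))
  }
  key <- map_chr(chains, paste, collapse = ",")
  tab <- tibble(key = key, chain = chains) %>%
    group_by(.data$key) %>%
    summarise(chain = .data$chain[1L], support = n(), .groups = "drop") %>%
    arrange(.data$key)
  select(tab, "chain", "support")
}
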