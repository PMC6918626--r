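# fixture builders used across the suite; all data is constructed in code

seg <- function(...) {
  m <- do.call(rbind, list(...))
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

seg_from <- function(starts, lens) {
  m <- cbind(start = as.integer(starts), end = as.integer(starts + lens))
  m[order(m[, "start"]), , drop = FALSE]
}

# k valid segments: positive lengths, inter-segment gaps >= 50 (the default
# minimum intron size)
random_segs <- function(k, start0 = NULL) {
  if (is.null(start0)) start0 <- sample(0:40, 1L)
  lens <- sample(30:90, k, replace = TRUE)
  gaps <- if (k > 1L) sample(50:300, k - 1L, replace = TRUE) else integer()
  starts <- start0 + cumsum(c(0L, head(lens, -1L) + gaps))
  seg_from(starts, lens)
}

empty_boundaries <- function() {
  tibble::tibble(kind = character(), position = integer(),
                 support = integer(), side = character())
}

fix_record <- function(read_id, segs, chrom = "chr1", strand = "+",
                       read_class = "NFL_INTERNAL") {
  start <- segs[1L, "start"]
  end <- segs[nrow(segs), "end"]
  has5 <- read_class %in% c("FULL_LENGTH", "NFL_5ONLY") && strand != "*"
  has3 <- read_class %in% c("FULL_LENGTH", "NFL_3ONLY") && strand != "*"
  tibble::tibble(
    read_id = read_id, chrom = chrom, strand = strand,
    read_class = read_class, segments = list(segs),
    start = as.integer(start), end = as.integer(end),
    n_segments = nrow(segs),
    boundary_5p = if (has5) {
      as.integer(if (strand == "+") start else end)
    } else {
      NA_integer_
    },
    boundary_3p = if (has3) {
      as.integer(if (strand == "+") end else start)
    } else {
      NA_integer_
    }
  )
}

# the five-partial-exon worked example: exons a..e, long reads spanning
# (a,c,e) and (b,c,d), plus two-exon reads that skew the junction weights so
# a weight-only decomposition would break both phasing paths
fig_exons <- list(
  a = c(100L, 200L), b = c(300L, 400L), c = c(500L, 600L),
  d = c(700L, 800L), e = c(900L, 1000L)
)

fig_bundle <- function() {
  ex <- fig_exons
  dplyr::bind_rows(
    fix_record("green", seg(ex$a, ex$c, ex$e)),
    fix_record("blue", seg(ex$b, ex$c, ex$d)),
    fix_record("short_ac", seg(ex$a, ex$c)),
    fix_record("short_cd", seg(ex$c, ex$d))
  )
}

# synthetic splice graph with planted weighted s-t paths; weights are exact
# sums of the planted path abundances
random_planted_graph <- function(seed, max_vertices = 7L, max_phasing = 4L) {
  set.seed(seed)
  n0 <- sample(4:max_vertices, 1L)
  k <- sample(2:4, 1L)
  paths0 <- lapply(seq_len(k), function(i) {
    len <- sample(2:n0, 1L)
    sort(sample(seq_len(n0), len))
  })
  used <- sort(unique(unlist(paths0)))
  remap <- match(seq_len(n0), used)
  paths <- lapply(paths0, function(p) remap[p])
  n <- length(used)
  x <- sample(1:6, k, replace = TRUE)

  edge_list <- list()
  for (i in seq_len(k)) {
    v <- c(0L, paths[[i]], n + 1L)
    for (j in seq_len(length(v) - 1L)) {
      key <- paste(v[j], v[j + 1L])
      prev <- edge_list[[key]]
      edge_list[[key]] <- (if (is.null(prev)) 0 else prev) + x[i]
    }
  }
  parts <- strsplit(names(edge_list), " ")
  edges <- tibble::tibble(
    from = as.integer(vapply(parts, `[`, "", 1L)),
    to = as.integer(vapply(parts, `[`, "", 2L)),
    weight = as.numeric(unlist(edge_list)),
    kind = "junction"
  )
  edges$kind[edges$from == 0L] <- "source_link"
  edges$kind[edges$to == n + 1L] <- "sink_link"
  edges <- dplyr::arrange(edges, from, to)

  vertices <- tibble::tibble(
    vertex = seq_len(n),
    start = (seq_len(n) - 1L) * 300L,
    end = (seq_len(n) - 1L) * 300L + 100L,
    weight = 1
  )
  graph <- structure(
    list(chrom = "chrS", strand = "+", vertices = vertices, edges = edges,
         boundaries = tibble::tibble(kind = character(), position = integer(),
                                     support = integer(), side = character()),
         n_reads = sum(x)),
    class = "splice_graph"
  )

  chains <- list()
  for (p in paths) {
    if (length(p) >= 3L && length(chains) < max_phasing) {
      len <- sample(3:length(p), 1L)
      s <- sample(seq_len(length(p) - len + 1L), 1L)
      chains[[length(chains) + 1L]] <- p[s:(s + len - 1L)]
    }
  }
  chains <- chains[!duplicated(vapply(chains, paste, "", collapse = ","))]
  phasing <- if (length(chains)) {
    tibble::tibble(chain = chains, support = rep(1L, length(chains)))
  } else {
    tibble::tibble(chain = list(), support = integer())
  }
  list(graph = graph, planted = paths, x = x, phasing = phasing)
}

# random multi-exon transcript set for clustering / io tests
random_transcripts <- function(seed, n = 10L, chrom = "chr1") {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(2:5, 1L)
    starts <- cumsum(sample(100:400, k)) + sample(0:50, 1L)
    lens <- sample(50:90, k, replace = TRUE)
    ex <- cbind(start = as.integer(starts), end = as.integer(starts + lens))
    tibble::tibble(
      chrom = chrom, strand = sample(c("+", "-"), 1L), exons = list(ex),
      abundance = round(stats::runif(1L, 1, 20), 3),
      transcript_id = sprintf("T%03d", i), gene_id = sprintf("G%03d", i)
    )
  })
  spliceflow:::validate_transcripts(dplyr::bind_rows(rows))
}
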