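test_that("event collection orders splice and boundary positions", {
  fl <- fix_record("fl", seg(c(0L, 100L), c(200L, 300L)),
                   read_class = "FULL_LENGTH")
  ev <- collect_positions(fl)
  expect_equal(ev$pos, c(0L, 100L, 200L, 300L))
  expect_equal(ev$type, c("b5", "donor", "acceptor", "b3"))

  # internal reads contribute splice events only
  internal <- fix_record("i", seg(c(0L, 100L), c(200L, 300L)))
  expect_equal(collect_positions(internal)$type, c("donor", "acceptor"))

  # splice events sort before boundary events at equal coordinates
  tie <- dplyr::bind_rows(
    fix_record("x", seg(c(0L, 100L), c(200L, 300L))),
    fix_record("y", seg(c(50L, 100L)), read_class = "NFL_3ONLY")
  )
  evt <- collect_positions(tie)
  at100 <- evt$type[evt$pos == 100L]
  expect_equal(at100, c("donor", "b3"))
})

test_that("event multiset equals a per-read enumeration", {
  set.seed(21)
  for (case in 1:10) {
    recs <- dplyr::bind_rows(lapply(1:15, function(i) {
      fix_record(sprintf("r%02d", i), random_segs(sample(1:3, 1)),
                 read_class = sample(c("FULL_LENGTH", "NFL_5ONLY",
                                       "NFL_3ONLY", "NFL_INTERNAL"), 1))
    }))
    ev <- collect_positions(recs)
    manual <- list()
    for (i in seq_len(nrow(recs))) {
      s <- recs$segments[[i]]
      if (nrow(s) > 1) {
        for (j in seq_len(nrow(s) - 1)) {
          manual[[length(manual) + 1L]] <- c(s[j, "end"], 1)
          manual[[length(manual) + 1L]] <- c(s[j + 1, "start"], 2)
        }
      }
      if (!is.na(recs$boundary_5p[i])) {
        manual[[length(manual) + 1L]] <- c(recs$boundary_5p[i], 3)
      }
      if (!is.na(recs$boundary_3p[i])) {
        manual[[length(manual) + 1L]] <- c(recs$boundary_3p[i], 4)
      }
    }
    m <- do.call(rbind, manual)
    codes <- c("donor", "acceptor", "b5", "b3")
    expect_equal(sort(paste(ev$pos, ev$type)),
                 sort(paste(m[, 1], codes[m[, 2]])))
  }
})

test_that("boundary calls require uninterrupted concordant runs", {
  mk <- function(pos, type) tibble::tibble(pos = pos, type = type)
  # three concordant 5' events: one call at the leftmost position
  got <- call_boundaries(mk(c(100L, 102L, 103L), rep("b5", 3)))
  expect_equal(got$kind, "start_5p")
  expect_equal(got$position, 100L)
  expect_equal(got$support, 3L)
  # two events at the default threshold: none
  expect_equal(nrow(call_boundaries(mk(c(100L, 102L), rep("b5", 2)))), 0L)
  # run broken by a splice event
  ev <- mk(c(500L, 501L, 502L, 503L), c("b3", "b3", "donor", "b3"))
  expect_equal(nrow(call_boundaries(ev)), 0L)
  got2 <- call_boundaries(ev, min_boundary_reads = 2L)
  expect_equal(got2$kind, "end_3p")
  expect_equal(got2$position, 501L) # rightmost of the run
  # spacing beyond the allowance splits the run
  spread <- mk(c(100L, 102L, 150L), rep("b5", 3))
  expect_equal(nrow(call_boundaries(spread, boundary_allowance = 10L)), 0L)
  expect_equal(nrow(call_boundaries(spread, boundary_allowance = 50L)), 1L)
  # reverse strand mirrors the reported position
  rev5 <- call_boundaries(mk(c(900L, 902L, 903L), rep("b5", 3)), strand = "-")
  expect_equal(rev5$position, 903L)
})

test_that("boundary calling matches the run-scan oracle and is monotone", {
  set.seed(22)
  for (case in 1:40) {
    n <- sample(5:25, 1)
    ev <- tibble::tibble(
      pos = sort(sample(0:300, n, replace = TRUE)),
      type = sample(c("b5", "b3", "donor", "acceptor"), n, replace = TRUE)
    )
    ev <- dplyr::arrange(ev, pos, type %in% c("b5", "b3"), type)
    for (thr in c(1L, 2L, 3L)) {
      got <- call_boundaries(ev, min_boundary_reads = thr,
                             boundary_allowance = 10L)
      want <- oracle_boundary_calls(ev, "+", thr, 10L)
      expect_equal(sort(paste(got$kind, got$position, got$support)),
                   sort(paste(want$kind, want$position, want$support)))
    }
    # raising the threshold never creates a new call
    calls2 <- call_boundaries(ev, min_boundary_reads = 2L)
    calls3 <- call_boundaries(ev, min_boundary_reads = 3L)
    expect_true(all(paste(calls3$kind, calls3$position) %in%
                      paste(calls2$kind, calls2$position)))
  }
})

test_that("partial-exon segmentation cuts at splice, boundary and gap", {
  # one uncut read
  one <- fix_record("r", seg(c(0L, 100L)))
  px <- segment_partial_exons(one, empty_boundaries())
  expect_equal(px$start, 0L)
  expect_equal(px$end, 100L)
  expect_equal(px$weight, 1.0)

  # the five-partial-exon worked example
  px5 <- segment_partial_exons(fig_bundle(), empty_boundaries())
  expect_equal(nrow(px5), 5L)
  expect_equal(px5$start, c(100L, 300L, 500L, 700L, 900L))
  expect_equal(px5$end, c(200L, 400L, 600L, 800L, 1000L))
  expect_equal(px5$weight, c(2, 1, 4, 2, 1))

  # a boundary call strictly inside an exon splits the vertex there
  b <- tibble::tibble(kind = "start_5p", position = 40L, support = 3L,
                      side = "left")
  cut <- segment_partial_exons(one, b)
  expect_equal(cut$start, c(0L, 40L))
  expect_equal(cut$end, c(40L, 100L))
})

test_that("partial-exon weights equal the pileup oracle means", {
  set.seed(23)
  for (case in 1:8) {
    recs <- dplyr::bind_rows(lapply(1:12, function(i) {
      fix_record(sprintf("r%02d", i), random_segs(sample(1:3, 1)))
    }))
    px <- segment_partial_exons(recs, empty_boundaries())
    pile <- oracle_pileup(recs, min(px$start), max(px$end))
    for (i in seq_len(nrow(px))) {
      idx <- (px$start[i]:(px$end[i] - 1L)) - min(px$start) + 1L
      expect_equal(px$weight[i], mean(pile[idx]))
    }
  }
})

test_that("the worked example builds the expected five-vertex graph", {
  g <- build_splice_graph(fig_bundle(), strand = "+")
  expect_equal(nrow(g$vertices), 5L)
  j <- g$edges[g$edges$kind == "junction", ]
  expect_equal(paste(j$from, j$to), c("1 3", "2 3", "3 4", "3 5"))
  expect_equal(j$weight, c(2, 1, 2, 1))
  expect_equal(nrow(g$edges[g$edges$kind == "adjacency", ]), 0L)
  # source/sink links on the unanchored terminal vertices
  expect_setequal(g$edges$to[g$edges$from == 0L], c(1L, 2L))
  expect_setequal(g$edges$from[g$edges$to == 6L], c(4L, 5L))
})

test_that("graph edges are a DAG with full s-t reachability and conserved junction weight", {
  set.seed(24)
  for (case in 1:8) {
    recs <- dplyr::bind_rows(lapply(1:15, function(i) {
      fix_record(sprintf("r%02d", i), random_segs(sample(1:4, 1)))
    }))
    g <- build_splice_graph(recs, strand = "+")
    # DAG in coordinate order
    expect_true(all(g$edges$from < g$edges$to))
    # reachability from s and co-reachability to t for every vertex
    n <- nrow(g$vertices)
    reach <- rep(FALSE, n + 2L)
    reach[1L] <- TRUE
    for (i in order(g$edges$from)) {
      if (reach[g$edges$from[i] + 1L]) reach[g$edges$to[i] + 1L] <- TRUE
    }
    coreach <- rep(FALSE, n + 2L)
    coreach[n + 2L] <- TRUE
    for (i in order(-g$edges$to)) {
      if (coreach[g$edges$to[i] + 1L]) coreach[g$edges$from[i] + 1L] <- TRUE
    }
    expect_true(all(reach) && all(coreach))
    # junction edge weights equal the per-read census
    census <- oracle_junction_counts(recs)
    j <- g$edges[g$edges$kind == "junction", ]
    expect_equal(sum(j$weight), sum(unlist(census)))
    for (i in seq_len(nrow(j))) {
      key <- paste(g$vertices$end[j$from[i]], g$vertices$start[j$to[i]])
      expect_equal(j$weight[i], as.numeric(census[[key]]))
    }
  }
})

test_that("adjacency edges count reads crossing the breakpoint", {
  # a boundary call splits a covered exon; only some reads cross the cut
  recs <- dplyr::bind_rows(
    fix_record("cross1", seg(c(0L, 100L))),
    fix_record("cross2", seg(c(0L, 100L))),
    fix_record("right", seg(c(40L, 100L)), read_class = "NFL_5ONLY"),
    fix_record("right2", seg(c(40L, 100L)), read_class = "NFL_5ONLY"),
    fix_record("right3", seg(c(40L, 100L)), read_class = "NFL_5ONLY")
  )
  g <- build_splice_graph(recs, strand = "+")
  expect_equal(g$vertices$start, c(0L, 40L))
  adj <- g$edges[g$edges$kind == "adjacency", ]
  expect_equal(adj$weight, 2) # only the two full-span reads cross
  # the called 5' boundary gives vertex 2 a source link with 3 starting reads
  src <- g$edges[g$edges$from == 0L, ]
  expect_true(2L %in% src$to)
  expect_equal(src$weight[src$to == 2L], 3)
})

test_that("phasing paths are per-read vertex projections of length > 2", {
  g <- build_splice_graph(fig_bundle(), strand = "+")
  ph <- extract_phasing_paths(fig_bundle(), g)
  chains <- lapply(ph$chain, identity)
  expect_setequal(lapply(chains, paste, collapse = ","),
                  list("1,3,5", "2,3,4"))
  expect_equal(ph$support, c(1L, 1L))
  # two-exon reads contribute no phasing path
  two <- fix_record("t", seg(c(100L, 200L), c(500L, 600L)))
  g2 <- build_splice_graph(two, strand = "+")
  expect_equal(nrow(extract_phasing_paths(two, g2)), 0L)
})

test_that("phasing projection agrees with the naive overlap oracle", {
  set.seed(25)
  for (case in 1:8) {
    recs <- dplyr::bind_rows(lapply(1:12, function(i) {
      fix_record(sprintf("r%02d", i), random_segs(sample(2:4, 1)))
    }))
    g <- build_splice_graph(recs, strand = "+")
    ph <- extract_phasing_paths(recs, g)
    manual <- list()
    for (i in seq_len(nrow(recs))) {
      chain <- oracle_project(recs$segments[[i]], g$vertices)
      if (length(chain) >= 3L) {
        manual[[length(manual) + 1L]] <- paste(chain, collapse = ",")
      }
    }
    got <- rep(vapply(ph$chain, paste, "", collapse = ","), ph$support)
    expect_equal(sort(got), sort(unlist(manual)))
    # chains strictly increase in coordinate order
    expect_true(all(vapply(ph$chain, function(ch) all(diff(ch) > 0), TRUE)))
  }
})
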