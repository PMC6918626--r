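# ---- path utilities ---------------------------------------------------------

# is `a` a contiguous subsequence of `b`?
is_contiguous_subseq <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  if (la > lb) {
    return(FALSE)
  }
  for (i in seq_len(lb - la + 1L)) {
    if (all(b[i:(i + la - 1L)] == a)) {
      return(TRUE)
    }
  }
  FALSE
}

# keep only chains that are not contiguous subsequences of another chain
maximal_chains <- function(chains) {
  n <- length(chains)
  if (n <= 1L) {
    return(chains)
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] &&
          (length(chains[[i]]) < length(chains[[j]]) ||
           (length(chains[[i]]) == length(chains[[j]]) && i > j)) &&
          is_contiguous_subseq(chains[[i]], chains[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  chains[keep]
}

edge_key <- function(from, to) paste(from, to, sep = ">")

# edge row indices used by a path given as internal vertices; includes the
# implicit source (0) and sink (n+1) hops
path_edge_rows <- function(path, graph) {
  n <- nrow(graph$vertices)
  v <- c(0L, path, n + 1L)
  idx <- match(edge_key(v[-length(v)], v[-1L]),
               edge_key(graph$edges$from, graph$edges$to))
  if (anyNA(idx)) {
    abort("path uses an edge absent from the splice graph")
  }
  idx
}

# ---- seeding ----------------------------------------------------------------

# greedy left/right extension of a phasing chain into a full s-t path;
# at each frontier prefer an edge forced by a phasing path running through the
# frontier vertex, else the incident edge of largest weight (ties: lower
# vertex index)
extend_chain <- function(chain, graph, phasing_chains) {
  edges <- graph$edges
  n <- nrow(graph$vertices)

  pick <- function(cands, weights) {
    best <- which(weights == max(weights))
    cands[best][which.min(cands[best])]
  }
  forced_neighbor <- function(cur, nxt, left) {
    hits <- integer()
    for (q in phasing_chains) {
      k <- which(q == cur)
      if (length(k) == 1L) {
        if (left && k > 1L && k < length(q) && !is.na(nxt) &&
            q[k + 1L] == nxt) {
          hits <- c(hits, q[k - 1L])
        }
        if (!left && k < length(q) && k > 1L && !is.na(nxt) &&
            q[k - 1L] == nxt) {
          hits <- c(hits, q[k + 1L])
        }
      }
    }
    unique(hits)
  }

  path <- chain
  repeat {
    cur <- path[1L]
    inc <- edges[edges$to == cur, ]
    if (nrow(inc) == 0L) {
      abort("vertex with no incoming edge encountered during seeding")
    }
    nxt <- if (length(path) > 1L) path[2L] else NA_integer_
    forced <- forced_neighbor(cur, nxt, left = TRUE)
    forced <- forced[forced %in% inc$from]
    cand <- if (length(forced)) {
      inc[inc$from %in% forced, ]
    } else {
      inc
    }
    nb <- pick(cand$from, cand$weight)
    if (nb == 0L) {
      break
    }
    path <- c(nb, path)
  }
  repeat {
    cur <- path[length(path)]
    out <- edges[edges$from == cur, ]
    if (nrow(out) == 0L) {
      abort("vertex with no outgoing edge encountered during seeding")
    }
    nxt <- if (length(path) > 1L) path[length(path) - 1L] else NA_integer_
    forced <- forced_neighbor(cur, nxt, left = FALSE)
    forced <- forced[forced %in% out$to]
    cand <- if (length(forced)) {
      out[out$to %in% forced, ]
    } else {
      out
    }
    nb <- pick(cand$to, cand$weight)
    if (nb == n + 1L) {
      break
    }
    path <- c(path, nb)
  }
  path
}

# maximum-bottleneck s-t path under edge values `val` (same order as
# graph$edges), optionally forced through edge row `through`; vertices are in
# topological (coordinate) order 0..n+1 by construction
bottleneck_path <- function(graph, val, through = NULL) {
  edges <- graph$edges
  n <- nrow(graph$vertices)
  nodes <- 0:(n + 1L)
  dp_dir <- function(forward) {
    best <- rep(-Inf, n + 2L)
    prev <- rep(NA_integer_, n + 2L)
    if (forward) {
      best[1L] <- Inf
      ord <- seq_len(nrow(edges))[order(edges$from, edges$to)]
      for (i in ord) {
        u <- edges$from[i]
        v <- edges$to[i]
        cand <- min(best[u + 1L], val[i])
        if (cand > best[v + 1L] ||
            (cand == best[v + 1L] && !is.na(prev[v + 1L]) && u < prev[v + 1L])) {
          best[v + 1L] <- cand
          prev[v + 1L] <- u
        }
      }
    } else {
      best[n + 2L] <- Inf
      ord <- seq_len(nrow(edges))[order(-edges$to, -edges$from)]
      for (i in ord) {
        u <- edges$from[i]
        v <- edges$to[i]
        cand <- min(best[v + 1L], val[i])
        if (cand > best[u + 1L] ||
            (cand == best[u + 1L] && !is.na(prev[u + 1L]) && v < prev[u + 1L])) {
          best[u + 1L] <- cand
          prev[u + 1L] <- v
        }
      }
    }
    list(best = best, prev = prev)
  }
  fwd <- dp_dir(TRUE)
  bwd <- dp_dir(FALSE)
  trace <- function(prev, from_node, backwards) {
    out <- integer()
    cur <- from_node
    while (!is.na(cur) && cur >= 0L && cur <= n + 1L) {
      out <- c(out, cur)
      cur <- prev[cur + 1L]
      if (length(out) > n + 2L) {
        abort("cycle detected while tracing a path")
      }
    }
    if (backwards) rev(out) else out
  }
  if (is.null(through)) {
    # best path ending at t
    left <- trace(fwd$prev, n + 1L, backwards = TRUE)
    path <- left
  } else {
    u <- edges$from[through]
    v <- edges$to[through]
    left <- trace(fwd$prev, u, backwards = TRUE)
    right <- trace(bwd$prev, v, backwards = FALSE)
    path <- c(left, right)
  }
  path[path >= 1L & path <= n] # internal vertices only
}

#' Seed candidate transcript paths
#'
#' One candidate source-to-target path per maximal phasing path (a chain that
#' is not a contiguous subsequence of another), built by greedy extension: at
#' each frontier the incident edge of largest weight is taken unless a phasing
#' path running through the frontier vertex forces the step (ties break to the
#' lower vertex index). Each seed contains its phasing chain contiguously by
#' construction. When no phasing path exists, the single maximum-bottleneck
#' source-to-target path is seeded instead.
#'
#' @param graph A `splice_graph`.
#' @param phasing Phasing tibble from [extract_phasing_paths()].
#' @return A list of integer vectors (internal vertex chains).
#' @export
seed_paths <- function(graph, phasing) {
  if (is.null(phasing) || nrow(phasing) == 0L) {
    return(list(bottleneck_path(graph, graph$edges$weight)))
  }
  chains <- phasing$chain
  mx <- maximal_chains(chains)
  seeds <- map(mx, extend_chain, graph = graph, phasing_chains = chains)
  seeds[!duplicated(map_chr(seeds, paste, collapse = ","))]
}

#' Fit path abundances by linear programming
#'
#' Solves `min sum_e |w_e - sum_{p through e} x_p|` subject to `x_p >= 0` by
#' the standard absolute-value split, using the simplex method. All weighted
#' edges — junction, adjacency and source/sink links — enter the objective.
#' Deterministic for fixed inputs.
#'
#' @param graph A `splice_graph`.
#' @param paths List of candidate paths (internal vertex chains).
#' @return List with `abundance` (per path), `l1_deviation`, and `assigned`
#'   (fitted flow per edge row).
#' @export
fit_abundances <- function(graph, paths) {
  stopifnot(length(paths) >= 1L)
  E <- nrow(graph$edges)
  P <- length(paths)
  A <- matrix(0, nrow = E, ncol = P)
  for (p in seq_len(P)) {
    A[path_edge_rows(paths[[p]], graph), p] <- 1
  }
  w <- graph$edges$weight
  obj <- c(rep(0, P), rep(1, 2L * E))
  A3 <- cbind(A, diag(E), -diag(E))
  res <- boot::simplex(a = obj, A3 = A3, b3 = w, maxi = FALSE,
                       n.iter = 100L * (P + 3L * E + 2L), eps = 1e-9)
  if (res$solved != 1L) {
    abort(sprintf("abundance LP did not converge (graph %s:%s, %d paths, %d edges)",
                  graph$chrom, graph$strand, P, E))
  }
  x <- unname(res$soln[seq_len(P)])
  list(abundance = x, l1_deviation = unname(res$value),
       assigned = as.numeric(A %*% x))
}

#' Peel residual coverage into additional paths
#'
#' While some edge's positive residual (weight minus assigned flow) is at
#' least `floor`, adds the maximum-bottleneck source-to-target path through
#' the largest-residual edge and refits abundances; edges whose bottleneck
#' path is already a candidate are skipped in favour of the next-largest
#' residual. Terminates after at most one added path per edge, or as soon as
#' no residual edge yields a new path.
#'
#' @param graph A `splice_graph`.
#' @param paths Current candidate paths.
#' @param floor Smallest residual worth a new path; default 1 (one read).
#' @return List with `paths`, `abundance`, `l1_deviation`, `assigned`.
#' @export
peel_residual <- function(graph, paths, floor = 1.0) {
  stopifnot(floor > 0)
  fit <- fit_abundances(graph, paths)
  keys <- map_chr(paths, paste, collapse = ",")
  for (iter in seq_len(nrow(graph$edges))) {
    resid <- graph$edges$weight - fit$assigned
    hot <- order(-resid)
    hot <- hot[resid[hot] >= floor]
    added <- FALSE
    for (i in hot) {
      cand <- bottleneck_path(graph, resid, through = i)
      key <- paste(cand, collapse = ",")
      if (!key %in% keys) {
        paths <- c(paths, list(cand))
        keys <- c(keys, key)
        fit <- fit_abundances(graph, paths)
        added <- TRUE
        break
      }
    }
    if (!added) {
      break
    }
  }
  c(list(paths = paths), fit)
}

#' Decompose a splice graph into transcript paths
#'
#' The three-objective decomposition: (1) every phasing path is preserved —
#' contained contiguously in some output path; (2) read-coverage deviation is
#' minimized by linear programming; (3) the number of paths is kept small by
#' seeding only maximal phasing chains and peeling residual coverage with a
#' floor. Candidates below `min_transcript_coverage` are dropped unless the
#' drop would leave a phasing path uncovered, in which case the
#' highest-abundance covering candidate is retained.
#'
#' @param graph A `splice_graph`.
#' @param phasing Phasing tibble from [extract_phasing_paths()].
#' @param min_transcript_coverage Drop threshold on fitted abundance;
#'   default 1.
#' @param peel_floor Passed to [peel_residual()]; default 1.
#' @return An `sf_decomposition`: `paths` tibble (`path_id`, `vertices`
#'   list-column, `abundance`), `l1_deviation` (final LP fit, before the
#'   coverage filter), and `phasing` tibble mapping each phasing chain to the
#'   `path_id` covering it.
#' @export
decompose_graph <- function(graph, phasing = NULL,
                            min_transcript_coverage = 1.0, peel_floor = 1.0) {
  seeds <- seed_paths(graph, phasing)
  res <- peel_residual(graph, seeds, floor = peel_floor)
  paths <- res$paths
  x <- res$abundance

  keep <- x >= min_transcript_coverage - 1e-9
  cover_id <- integer()
  if (!is.null(phasing) && nrow(phasing) > 0L) {
    for (ci in seq_len(nrow(phasing))) {
      covering <- which(map_lgl(paths, is_contiguous_subseq,
                                a = phasing$chain[[ci]]))
      if (!length(covering)) {
        abort("internal error: phasing path not covered by any candidate")
      }
      kept_cov <- covering[keep[covering]]
      if (!length(kept_cov)) {
        best <- covering[which.max(x[covering])]
        keep[best] <- TRUE
        kept_cov <- best
      }
      cover_id[ci] <- kept_cov[which.max(x[kept_cov])]
    }
  }
  idx_map <- cumsum(keep)
  out_paths <- tibble(
    path_id = seq_len(sum(keep)),
    vertices = paths[keep],
    abundance = x[keep]
  )
  phasing_out <- if (!is.null(phasing) && nrow(phasing) > 0L) {
    tibble(chain = phasing$chain, support = phasing$support,
           path_id = idx_map[cover_id])
  } else {
    tibble(chain = list(), support = integer(), path_id = integer())
  }
  structure(
    list(paths = out_paths, l1_deviation = res$l1_deviation,
         phasing = phasing_out, chrom = graph$chrom, strand = graph$strand),
    class = "sf_decomposition"
  )
}

#' @export
print.sf_decomposition <- function(x, ...) {
  cat(sprintf("<sf_decomposition> %d path(s), L1 deviation %.4g, %d phasing path(s) covered\n",
              nrow(x$paths), x$l1_deviation, nrow(x$phasing)))
  invisible(x)
}
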