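# independent reference implementations ("oracles"); deliberately naive and
# coded differently from the package internals

# CIGAR walk: accumulate reference-consuming ops, breaking only at N >= min
oracle_cigar_segments <- function(cigar, pos, min_intron = 50L) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  segs <- list()
  cur_start <- pos
  cur <- pos
  open <- FALSE
  for (i in seq_along(ops)) {
    op <- ops[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (!open) {
        cur_start <- cur
        open <- TRUE
      }
      cur <- cur + lens[i]
    } else if (op == "N") {
      if (lens[i] >= min_intron) {
        if (!open) {
          return(NULL) # leading intron or empty segment between introns
        }
        segs[[length(segs) + 1L]] <- c(cur_start, cur)
        open <- FALSE
        cur <- cur + lens[i]
      } else {
        if (!open) {
          cur_start <- cur
          open <- TRUE
        }
        cur <- cur + lens[i]
      }
    } # I/S/H/P: no reference advance
  }
  if (open) {
    segs[[length(segs) + 1L]] <- c(cur_start, cur)
  } else {
    return(NULL) # trailing kept intron
  }
  m <- do.call(rbind, segs)
  colnames(m) <- c("start", "end")
  m
}

# connected components of the interval chaining relation (edge when the gap
# between two records is < bundle_gap), per chrom+strand
oracle_bundle_components <- function(records, bundle_gap) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          records$chrom[i] == records$chrom[j] &&
          records$strand[i] == records$strand[j]) {
        gap <- max(records$start[i], records$start[j]) -
          min(records$end[i], records$end[j])
        if (gap < bundle_gap) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

# boundary-run scan recoded over a typed event string
oracle_boundary_calls <- function(events, strand, min_n, allowance) {
  if (nrow(events) == 0L) {
    return(data.frame(kind = character(), position = integer(),
                      support = integer()))
  }
  n <- nrow(events)
  brk <- rep(FALSE, n)
  if (n >= 2L) {
    for (i in 2:n) {
      brk[i] <- events$type[i] != events$type[i - 1L] ||
        !(events$type[i] %in% c("b5", "b3")) ||
        events$pos[i] - events$pos[i - 1L] > allowance
    }
  }
  run <- cumsum(brk)
  out <- list()
  for (r in unique(run)) {
    sel <- events[run == r, ]
    if (!(sel$type[1L] %in% c("b5", "b3")) || nrow(sel) < min_n) {
      next
    }
    if (sel$type[1L] == "b5") {
      pos <- if (strand == "+") min(sel$pos) else max(sel$pos)
      kind <- "start_5p"
    } else {
      pos <- if (strand == "+") max(sel$pos) else min(sel$pos)
      kind <- "end_3p"
    }
    out[[length(out) + 1L]] <- data.frame(kind = kind, position = pos,
                                          support = nrow(sel))
  }
  if (!length(out)) {
    return(data.frame(kind = character(), position = integer(),
                      support = integer()))
  }
  unique(do.call(rbind, out))
}

# per-base pileup over a window, as a plain integer vector
oracle_pileup <- function(records, from, to) {
  v <- integer(to - from)
  for (s in records$segments) {
    for (i in seq_len(nrow(s))) {
      idx <- (s[i, "start"]:(s[i, "end"] - 1L)) - from + 1L
      v[idx] <- v[idx] + 1L
    }
  }
  v
}

# junction and breakpoint-crossing census, one read at a time
oracle_junction_counts <- function(records) {
  out <- list()
  for (s in records$segments) {
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      key <- paste(s[i, "end"], s[i + 1L, "start"])
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# naive projection of a read onto vertices by base overlap
oracle_project <- function(segs, vertices) {
  hits <- integer()
  for (v in seq_len(nrow(vertices))) {
    for (i in seq_len(nrow(segs))) {
      if (segs[i, "start"] < vertices$end[v] &&
          segs[i, "end"] > vertices$start[v]) {
        hits <- c(hits, v)
        break
      }
    }
  }
  sort(unique(hits))
}

# contiguous-subsequence check via string containment
oracle_contig_subseq <- function(a, b) {
  grepl(paste0(",", paste(a, collapse = ","), ","),
        paste0(",", paste(b, collapse = ","), ","), fixed = TRUE)
}

# are the edge weights an exact non-negative combination of the given paths?
# (nonnegative least squares residual ~ 0)
oracle_exactly_realizable <- function(graph, paths) {
  E <- nrow(graph$edges)
  key <- paste(graph$edges$from, graph$edges$to)
  A <- matrix(0, E, length(paths))
  n <- nrow(graph$vertices)
  for (p in seq_along(paths)) {
    v <- c(0L, paths[[p]], n + 1L)
    A[match(paste(v[-length(v)], v[-1L]), key), p] <- 1
  }
  fit <- pracma::lsqnonneg(A, graph$edges$weight)
  sqrt(fit$resid.norm) < 1e-6
}

# union-find over an explicit pairwise similarity matrix
oracle_cluster_membership <- function(tx, allowance) {
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && tx$n_exons[i] >= 2L && tx$n_exons[j] >= 2L &&
          transcripts_similar(tx$exons[[i]], tx$exons[[j]],
                              tx$chrom[i], tx$chrom[j],
                              tx$strand[i], tx$strand[j],
                              allowance = allowance)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

# shared exonic bases by explicit base bitmaps
oracle_shared_bases <- function(e1, e2) {
  lim <- max(e1[, "end"], e2[, "end"])
  b1 <- logical(lim)
  b2 <- logical(lim)
  for (i in seq_len(nrow(e1))) b1[(e1[i, "start"] + 1L):e1[i, "end"]] <- TRUE
  for (i in seq_len(nrow(e2))) b2[(e2[i, "start"] + 1L):e2[i, "end"]] <- TRUE
  sum(b1 & b2)
}

# brute-force PR curve: every threshold, recompute matches from scratch
oracle_pr_auc <- function(pred, ref) {
  pk <- spliceflow:::chain_key(pred)
  rk <- spliceflow:::chain_key(ref)
  ab <- ifelse(is.na(pred$abundance), 0, pred$abundance)
  pts <- NULL
  for (th in sort(unique(ab), decreasing = TRUE)) {
    sel <- ab >= th
    pts <- rbind(pts, c(sens = sum(rk %in% pk[sel]) / length(rk),
                        prec = mean(pk[sel] %in% rk)))
  }
  pts <- pts[order(pts[, "sens"], -pts[, "prec"]), , drop = FALSE]
  s <- c(0, pts[, "sens"])
  p <- c(pts[1L, "prec"], pts[, "prec"])
  sum(diff(s) * (p[-length(p)] + p[-1L]) / 2)
}
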