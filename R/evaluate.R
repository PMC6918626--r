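#' Exact intron-chain match
#'
#' Two multi-exon transcripts match iff they have identical junction
#' sequences at exact coordinates on the same chromosome and strand. The
#' outer boundaries of the terminal exons are ignored — a correctly predicted
#' known transcript may differ in TSS/TES.
#'
#' @param exons_pred,exons_ref Exon matrices.
#' @param chrom_pred,chrom_ref,strand_pred,strand_ref Locations.
#' @return Logical scalar; `FALSE` when either transcript is single-exon.
#' @export
intron_chain_match <- function(exons_pred, exons_ref,
                               chrom_pred = "1", chrom_ref = "1",
                               strand_pred = "+", strand_ref = "+") {
  if (chrom_pred != chrom_ref || strand_pred != strand_ref) {
    return(FALSE)
  }
  jp <- tx_junctions(exons_pred)
  jr <- tx_junctions(exons_ref)
  nrow(jp) > 0L && nrow(jp) == nrow(jr) && all(jp == jr)
}

# shared exonic bases between two exon matrices on the same chrom/strand
shared_exonic_bases <- function(e1, e2) {
  ir1 <- IRanges::IRanges(e1[, "start"] + 1L, e1[, "end"])
  ir2 <- IRanges::IRanges(e2[, "start"] + 1L, e2[, "end"])
  sum(IRanges::width(IRanges::intersect(ir1, ir2)))
}

exonic_length <- function(e) sum(e[, "end"] - e[, "start"])

# best-match fraction of each transcript in `a` against the set `b`
# (same chrom & strand required); returns a numeric vector in [0, 1]
best_fractions <- function(a, b) {
  map_dbl(seq_len(nrow(a)), function(i) {
    cand <- which(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
                    b$start < a$end[i] & b$end > a$start[i])
    if (!length(cand)) {
      return(0)
    }
    len <- exonic_length(a$exons[[i]])
    max(map_dbl(cand, function(j) {
      shared_exonic_bases(a$exons[[i]], b$exons[[j]]) / len
    }))
  })
}

fraction_bins <- function(frac) {
  pct <- frac * 100
  bins <- c("0-50", "50-75", "75-95", "95-100")
  idx <- findInterval(pct, c(0, 50, 75, 95), rightmost.closed = FALSE)
  idx[pct >= 95] <- 4L # 95-100 right-closed
  table(factor(bins[idx], levels = bins))
}

#' Precision-recall AUC over coverage thresholds
#'
#' Sweeps a threshold over the sorted unique prediction abundances
#' (descending); at each threshold the predictions with abundance at or above
#' it are scored by intron-chain matching, giving one (sensitivity,
#' precision) point. The area is integrated by the trapezoid rule over
#' sensitivity, anchored at (0, precision of the first point) — a single
#' threshold point therefore contributes the rectangle `precision x
#' sensitivity`.
#'
#' @param pred,ref Transcript tibbles (multi-exon rows are used).
#' @return List with `auc` and the `curve` tibble
#'   (`threshold`, `sensitivity`, `precision`).
#' @export
pr_auc <- function(pred, ref) {
  pred <- filter(pred, .data$n_exons >= 2L)
  ref <- filter(ref, .data$n_exons >= 2L)
  if (nrow(pred) == 0L || nrow(ref) == 0L) {
    return(list(auc = 0, curve = tibble(threshold = numeric(),
                                        sensitivity = numeric(),
                                        precision = numeric())))
  }
  pk <- chain_key(pred)
  rk <- chain_key(ref)
  ab <- ifelse(is.na(pred$abundance), 0, pred$abundance)
  thresholds <- sort(unique(ab), decreasing = TRUE)
  pts <- map(thresholds, function(th) {
    sel <- ab >= th
    tibble(
      threshold = th,
      sensitivity = sum(rk %in% pk[sel]) / length(rk),
      precision = mean(pk[sel] %in% rk)
    )
  }) %>% bind_rows()
  curve <- arrange(pts, .data$sensitivity, desc(.data$precision))
  s <- c(0, curve$sensitivity)
  p <- c(curve$precision[1L], curve$precision)
  auc <- sum(diff(s) * (head(p, -1L) + tail(p, -1L)) / 2)
  list(auc = auc, curve = curve)
}

#' Evaluate predicted transcripts against a reference annotation
#'
#' Intron-chain metrics: a reference transcript is correctly predicted when
#' some prediction matches its intron chain exactly ([intron_chain_match()]);
#' each reference is counted once. Sensitivity is correct / known references,
#' precision is matching predictions / predictions — both over multi-exon
#' transcripts, since the intron chain is undefined for single-exon ones.
#' Also computed: PR-AUC over coverage thresholds, the count of potential
#' novel isoforms (predictions sharing at least one junction with the
#' reference but matching no full chain), their NIC/NNC split (novel
#' junctions built from known vs novel donors/acceptors), and base-level
#' matched/assembled fraction histograms over all transcripts.
#'
#' @param pred,ref Transcript tibbles (e.g. from [read_gtf()]).
#' @return An `sf_eval` object; see [glance.sf_eval()] for the one-row
#'   summary.
#' @export
evaluate_transcripts <- function(pred, ref) {
  pred_m <- filter(pred, .data$n_exons >= 2L)
  ref_m <- filter(ref, .data$n_exons >= 2L)
  pk <- chain_key(pred_m)
  rk <- chain_key(ref_m)

  n_correct <- sum(rk %in% pk)
  n_pred_match <- sum(pk %in% rk)
  sensitivity <- if (nrow(ref_m)) n_correct / nrow(ref_m) else 0
  precision <- if (nrow(pred_m)) n_pred_match / nrow(pred_m) else 0

  # junction-level catalogs for novel-isoform classification
  ref_j <- map(seq_len(nrow(ref_m)), function(i) {
    j <- tx_junctions(ref_m$exons[[i]])
    if (nrow(j)) {
      paste(ref_m$chrom[i], ref_m$strand[i], j[, "donor"], j[, "acceptor"])
    } else {
      character()
    }
  })
  ref_j_set <- unique(unlist(ref_j))
  ref_d_set <- unique(unlist(map(seq_len(nrow(ref_m)), function(i) {
    j <- tx_junctions(ref_m$exons[[i]])
    paste(ref_m$chrom[i], ref_m$strand[i], j[, "donor"])
  })))
  ref_a_set <- unique(unlist(map(seq_len(nrow(ref_m)), function(i) {
    j <- tx_junctions(ref_m$exons[[i]])
    paste(ref_m$chrom[i], ref_m$strand[i], j[, "acceptor"])
  })))

  novel_class <- rep(NA_character_, nrow(pred_m))
  shares_junction <- rep(FALSE, nrow(pred_m))
  for (i in seq_len(nrow(pred_m))) {
    if (pk[i] %in% rk) {
      next
    }
    j <- tx_junctions(pred_m$exons[[i]])
    jkey <- paste(pred_m$chrom[i], pred_m$strand[i], j[, "donor"],
                  j[, "acceptor"])
    known <- jkey %in% ref_j_set
    shares_junction[i] <- any(known)
    novel <- j[!known, , drop = FALSE]
    if (nrow(novel) == 0L) {
      novel_class[i] <- "NIC" # new combination of known junctions
    } else {
      dk <- paste(pred_m$chrom[i], pred_m$strand[i], novel[, "donor"]) %in%
        ref_d_set
      ak <- paste(pred_m$chrom[i], pred_m$strand[i], novel[, "acceptor"]) %in%
        ref_a_set
      novel_class[i] <- if (all(dk) && all(ak)) "NIC" else "NNC"
    }
  }
  # the weak criterion: a non-matching prediction sharing >= 1 junction
  potential_novel <- sum(shares_junction)

  pr <- pr_auc(pred_m, ref_m)
  matched <- best_fractions(pred, ref)
  assembled <- best_fractions(ref, pred)

  structure(
    list(
      n_reference_known = nrow(ref_m),
      n_predicted = nrow(pred_m),
      n_correct = n_correct,
      sensitivity = sensitivity,
      precision = precision,
      pr_auc = pr$auc,
      pr_curve = pr$curve,
      potential_novel = potential_novel,
      n_nic = sum(novel_class == "NIC", na.rm = TRUE),
      n_nnc = sum(novel_class == "NNC", na.rm = TRUE),
      matched_fraction_bins = fraction_bins(matched),
      assembled_fraction_bins = fraction_bins(assembled),
      matched_fraction = matched,
      assembled_fraction = assembled,
      pred_matches = tibble(transcript_id = pred_m$transcript_id,
                            chain_match = pk %in% rk,
                            novel_class = novel_class)
    ),
    class = "sf_eval"
  )
}

#' Format an evaluation as TSV report lines
#'
#' One `metric<TAB>value` line per summary metric, followed by the
#' matched/assembled fraction histograms.
#'
#' @param ev An `sf_eval`.
#' @return Character vector of TSV lines.
#' @export
format_tsv_report <- function(ev) {
  g <- glance(ev)
  c(
    paste(names(g), unlist(g), sep = "\t"),
    paste0("matched_fraction_", names(ev$matched_fraction_bins), "\t",
           as.integer(ev$matched_fraction_bins)),
    paste0("assembled_fraction_", names(ev$assembled_fraction_bins), "\t",
           as.integer(ev$assembled_fraction_bins))
  )
}

#' @export
print.sf_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<sf_eval> %d predicted / %d known multi-exon reference\n",
           "  correct: %d   sensitivity: %.4f   precision: %.4f   PR-AUC: %.4f\n",
           "  potential novel: %d (NIC %d / NNC %d)\n"),
    x$n_predicted, x$n_reference_known, x$n_correct, x$sensitivity,
    x$precision, x$pr_auc, x$potential_novel, x$n_nic, x$n_nnc))
  invisible(x)
}
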