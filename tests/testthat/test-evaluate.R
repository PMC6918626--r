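mk_tx <- function(id, exons, chrom = "chr1", strand = "+", ab = 1) {
  new_transcripts(chrom, strand, list(exons), ab, id, paste0("g_", id))
}

test_that("intron-chain matching ignores terminal exon boundaries only", {
  ref <- seg(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  same_chain <- seg(c(50L, 100L), c(200L, 300L), c(400L, 450L))
  expect_true(intron_chain_match(same_chain, ref))
  shifted <- seg(c(0L, 100L), c(201L, 300L), c(400L, 500L))
  expect_false(intron_chain_match(shifted, ref))
  expect_false(intron_chain_match(ref, ref, strand_pred = "+",
                                  strand_ref = "-"))
  # single-exon chains never match
  expect_false(intron_chain_match(seg(c(0L, 100L)), seg(c(0L, 100L))))
  # randomized agreement with direct sequence comparison
  set.seed(61)
  for (i in 1:40) {
    a <- random_segs(sample(2:4, 1))
    b <- if (stats::runif(1) < 0.5) a else random_segs(sample(2:4, 1))
    ja <- spliceflow:::tx_junctions(a)
    jb <- spliceflow:::tx_junctions(b)
    want <- nrow(ja) == nrow(jb) && all(ja == jb)
    expect_equal(intron_chain_match(a, b), want)
  }
})

test_that("sensitivity and precision follow the counting definitions", {
  refs <- dplyr::bind_rows(
    mk_tx("r1", seg(c(0L, 100L), c(200L, 300L))),
    mk_tx("r2", seg(c(1000L, 1100L), c(1200L, 1300L))),
    mk_tx("r3", seg(c(2000L, 2100L), c(2200L, 2300L)))
  )
  # identical sets: perfect scores
  ev <- evaluate_transcripts(refs, refs)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)

  # 3 refs, 2 preds, 1 match
  preds <- dplyr::bind_rows(
    mk_tx("p1", seg(c(10L, 100L), c(200L, 290L))), # matches r1
    mk_tx("p2", seg(c(5000L, 5100L), c(5300L, 5400L)))
  )
  ev2 <- evaluate_transcripts(preds, refs)
  expect_equal(ev2$n_correct, 1L)
  expect_equal(ev2$sensitivity, 1 / 3)
  expect_equal(ev2$precision, 1 / 2)

  # duplicate predictions of one reference count the reference once
  dup <- dplyr::bind_rows(
    mk_tx("p1", seg(c(0L, 100L), c(200L, 300L))),
    mk_tx("p1b", seg(c(20L, 100L), c(200L, 340L)))
  )
  ev3 <- evaluate_transcripts(dup, refs)
  expect_equal(ev3$n_correct, 1L)
  expect_equal(ev3$precision, 1)

  # removing a correct prediction never increases sensitivity
  ev4 <- evaluate_transcripts(preds[2, ], refs)
  expect_lte(ev4$sensitivity, ev2$sensitivity)

  # input order invariance
  ev5 <- evaluate_transcripts(preds[2:1, ], refs[c(3, 1, 2), ])
  expect_equal(glance(ev5), glance(ev2))
})

test_that("random scenarios agree with a double-loop matching oracle", {
  set.seed(62)
  for (case in 1:10) {
    refs <- dplyr::bind_rows(lapply(1:8, function(i) {
      mk_tx(sprintf("r%d", i), random_segs(sample(2:4, 1), start0 = i * 3000L))
    }))
    preds <- dplyr::bind_rows(lapply(1:8, function(i) {
      src <- sample(8, 1)
      ex <- if (stats::runif(1) < 0.6) {
        refs$exons[[src]]
      } else {
        random_segs(sample(2:4, 1), start0 = src * 3000L)
      }
      mk_tx(sprintf("p%d", i), ex, ab = sample(1:5, 1))
    }))
    ev <- evaluate_transcripts(preds, refs)
    n_corr <- 0L
    for (i in seq_len(nrow(refs))) {
      hit <- FALSE
      for (j in seq_len(nrow(preds))) {
        if (intron_chain_match(preds$exons[[j]], refs$exons[[i]],
                               preds$chrom[j], refs$chrom[i],
                               preds$strand[j], refs$strand[i])) {
          hit <- TRUE
        }
      }
      n_corr <- n_corr + hit
    }
    expect_equal(ev$n_correct, n_corr)
  }
})

test_that("PR-AUC sweeps coverage thresholds with trapezoid integration", {
  refs <- dplyr::bind_rows(
    mk_tx("r1", seg(c(0L, 100L), c(200L, 300L))),
    mk_tx("r2", seg(c(1000L, 1100L), c(1200L, 1300L)))
  )
  # perfect predictor at every threshold
  perfect <- dplyr::mutate(refs, abundance = c(5, 2),
                           transcript_id = c("p1", "p2"))
  expect_equal(pr_auc(perfect, refs)$auc, 1.0)
  # one threshold point: rectangle precision x sensitivity
  one <- mk_tx("p1", seg(c(0L, 100L), c(200L, 300L)), ab = 3)
  both <- dplyr::bind_rows(one,
                           mk_tx("px", seg(c(5000L, 5100L), c(5200L, 5300L)),
                                 ab = 3))
  expect_equal(pr_auc(both, refs)$auc, 0.5 * 0.5)
  # randomized agreement with the brute-force oracle
  set.seed(63)
  for (case in 1:10) {
    refs_r <- dplyr::bind_rows(lapply(1:6, function(i) {
      mk_tx(sprintf("r%d", i), random_segs(3, start0 = i * 3000L))
    }))
    preds_r <- dplyr::bind_rows(lapply(1:10, function(i) {
      src <- sample(6, 1)
      ex <- if (stats::runif(1) < 0.5) {
        refs_r$exons[[src]]
      } else {
        random_segs(3, start0 = src * 3000L)
      }
      mk_tx(sprintf("p%d", i), ex, ab = sample(1:4, 1))
    }))
    expect_equal(pr_auc(preds_r, refs_r)$auc,
                 oracle_pr_auc(preds_r, refs_r), tolerance = 1e-10)
  }
})

test_that("base-level fractions and bins follow the interval definitions", {
  ref <- mk_tx("r", seg(c(0L, 100L), c(200L, 300L)))
  # identical: both fractions 1, in the 95-100 bin
  ev <- evaluate_transcripts(ref, ref)
  expect_equal(unname(ev$matched_fraction_bins["95-100"]), 1L)
  expect_equal(unname(ev$assembled_fraction_bins["95-100"]), 1L)
  # prediction covering exactly half the reference, fully inside it
  half <- mk_tx("p", seg(c(0L, 100L)))
  ev2 <- evaluate_transcripts(half, ref)
  expect_equal(ev2$assembled_fraction, 0.5)
  expect_equal(ev2$matched_fraction, 1.0)
  expect_equal(unname(ev2$assembled_fraction_bins["50-75"]), 1L)
  # random exon sets agree with the bitmap oracle
  set.seed(64)
  for (case in 1:20) {
    a <- random_segs(sample(1:4, 1))
    b <- random_segs(sample(1:4, 1))
    pa <- mk_tx("a", a)
    pb <- mk_tx("b", b)
    evx <- evaluate_transcripts(pa, pb)
    expect_equal(evx$matched_fraction,
                 oracle_shared_bases(a, b) / sum(a[, "end"] - a[, "start"]))
  }
})

test_that("novel isoform classes split on junction catalog membership", {
  refs <- dplyr::bind_rows(
    mk_tx("r1", seg(c(0L, 100L), c(200L, 300L), c(400L, 500L))),
    mk_tx("r2", seg(c(0L, 100L), c(600L, 700L)))
  )
  preds <- dplyr::bind_rows(
    # new combination of known junctions: NIC
    mk_tx("nic", seg(c(0L, 100L), c(200L, 300L), c(600L, 700L))),
    # novel junction from known donor + known acceptor: NIC
    mk_tx("nic2", seg(c(0L, 100L), c(400L, 500L))),
    # novel acceptor: NNC
    mk_tx("nnc", seg(c(0L, 100L), c(250L, 300L), c(400L, 500L))),
    # full match: not novel
    mk_tx("fsm", seg(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  )
  ev <- evaluate_transcripts(preds, refs)
  expect_equal(ev$n_nic, 2L)
  expect_equal(ev$n_nnc, 1L)
  # nic2 shares no complete junction with the catalog, so the weaker
  # shares-a-junction count covers only the other two novel predictions
  expect_equal(ev$potential_novel, 2L)
  cls <- tidy(ev)
  expect_equal(cls$novel_class[cls$transcript_id == "nic"], "NIC")
  expect_equal(cls$novel_class[cls$transcript_id == "nnc"], "NNC")
  expect_true(cls$chain_match[cls$transcript_id == "fsm"])
})
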