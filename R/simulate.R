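#' Simulation configuration
#'
#' Describes the generative model for synthetic long-read data: multi-isoform
#' genes whose isoforms share splice junctions (exon-skipping variants of a
#' full-chain isoform, forcing branching splice graphs), reads drawn as
#' transcript copies subject to length-dependent 5'/3' truncation (incomplete
#' cDNA synthesis: the longer the transcript, the less likely a read is full
#' length), and indel-dominated alignment errors injected into the CIGARs
#' without moving the reference footprint.
#'
#' @param n_genes Number of genes; default 20.
#' @param isoforms_per_gene Integer range `c(min, max)`; default 2-3.
#' @param exons_per_gene Integer range for the full-chain isoform; default
#'   3-8 (raised as needed so every skip variant stays multi-exon).
#' @param exon_length,intron_length Length ranges in bp; intron lengths must
#'   stay at or above the assembler's minimum intron size.
#' @param depth Reads simulated per isoform; default 5.
#' @param p_truncate_5p,p_truncate_3p Probability that a read loses the
#'   respective transcript end: a scalar, or a non-decreasing function of
#'   transcript length. Default: logistic in length with midpoint 2500 bp and
#'   scale 500 bp, reflecting that full-length reads become unlikely beyond
#'   ~2.5 kb.
#' @param indel_rate Per-base indel probability; default 0.01 (CCS-like,
#'   indel-dominated).
#' @param max_indel_len Maximum injected indel length; default 3.
#' @param gene_gap Intergenic spacing in bp; default 2000.
#' @param bases_per_chrom Chromosome capacity; genes overflow onto additional
#'   chromosomes. Default 300000.
#' @param min_read_keep Minimum surviving read length after truncation;
#'   default 100.
#' @return An `sf_sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, isoforms_per_gene = c(2L, 3L),
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(100L, 300L),
                       intron_length = c(60L, 400L),
                       depth = 5L,
                       p_truncate_5p = function(len) stats::plogis((len - 2500) / 500),
                       p_truncate_3p = function(len) stats::plogis((len - 2500) / 500),
                       indel_rate = 0.01, max_indel_len = 3L,
                       gene_gap = 2000L, bases_per_chrom = 300000L,
                       min_read_keep = 100L) {
  as_prob_fun <- function(p) {
    if (is.function(p)) {
      return(p)
    }
    stopifnot(is.numeric(p), p >= 0, p <= 1)
    function(len) rep(p, length(len))
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    depth = as.integer(depth),
    p_truncate_5p = as_prob_fun(p_truncate_5p),
    p_truncate_3p = as_prob_fun(p_truncate_3p),
    indel_rate = indel_rate, max_indel_len = as.integer(max_indel_len),
    gene_gap = as.integer(gene_gap),
    bases_per_chrom = as.integer(bases_per_chrom),
    min_read_keep = as.integer(min_read_keep)
  )
  stopifnot(cfg$n_genes >= 1L, cfg$depth >= 1L,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1)
  structure(cfg, class = "sf_sim_config")
}

rint <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
}

# map a kept transcript interval [q0, q1) (5'->3' transcript coordinates)
# onto genomic segments, given the isoform's exons and strand
transcript_interval_to_segments <- function(exons, strand, q0, q1) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  lens <- exons[ord, "end"] - exons[ord, "start"]
  c1 <- cumsum(lens)
  c0 <- c1 - lens
  segs <- list()
  for (i in seq_along(ord)) {
    lo <- max(q0, c0[i])
    hi <- min(q1, c1[i])
    if (lo >= hi) {
      next
    }
    o0 <- lo - c0[i]
    o1 <- hi - c0[i]
    e <- exons[ord[i], ]
    if (strand == "+") {
      segs[[length(segs) + 1L]] <- c(e["start"] + o0, e["start"] + o1)
    } else {
      segs[[length(segs) + 1L]] <- c(e["end"] - o1, e["end"] - o0)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

# CIGAR for genomic segments with injected indels inside exon matches; the
# reference footprint is unchanged (D ops replace matched bases, I ops
# consume none)
segments_to_cigar <- function(segments, indel_rate, max_indel_len) {
  seg_ops <- map(seq_len(nrow(segments)), function(i) {
    m <- segments[i, "end"] - segments[i, "start"]
    ops <- list(c("M", m))
    if (indel_rate > 0 && m > 4L) {
      n_ind <- stats::rbinom(1L, m, indel_rate)
      if (n_ind > 0L) {
        pos <- sort(sample(2:(m - 2L), min(n_ind, max(1L, m %/% 8L)),
                           replace = FALSE))
        types <- sample(c("I", "D"), length(pos), replace = TRUE)
        lens <- rint(c(1L, max_indel_len), length(pos))
        out <- list()
        prev <- 0L
        for (k in seq_along(pos)) {
          if (types[k] == "D") {
            d <- min(lens[k], m - pos[k] - 1L)
            if (d < 1L || pos[k] - prev < 1L) next
            out[[length(out) + 1L]] <- c("M", pos[k] - prev)
            out[[length(out) + 1L]] <- c("D", d)
            prev <- pos[k] + d
          } else {
            if (pos[k] - prev < 1L) next
            out[[length(out) + 1L]] <- c("M", pos[k] - prev)
            out[[length(out) + 1L]] <- c("I", lens[k])
            prev <- pos[k]
          }
        }
        if (m - prev >= 1L) {
          out[[length(out) + 1L]] <- c("M", m - prev)
        }
        ops <- out
      }
    }
    ops
  })
  pieces <- character()
  for (i in seq_along(seg_ops)) {
    if (i > 1L) {
      gap <- segments[i, "start"] - segments[i - 1L, "end"]
      pieces <- c(pieces, paste0(gap, "N"))
    }
    pieces <- c(pieces, map_chr(seg_ops[[i]],
                                ~ paste0(.x[2L], .x[1L])))
  }
  paste(pieces, collapse = "")
}

#' Simulate a long-read dataset
#'
#' Generates a genome (FASTA), a multi-isoform annotation (GTF), pre-aligned
#' reads (SAM, coordinate-sorted on conversion), a read-classification table
#' (TSV) and a per-read truth table. Reads are emitted as alignments rather
#' than sequences so the pipeline needs no external aligner; spliced reads
#' carry their transcript strand in the `XS` tag while unspliced reads carry
#' none (strand unknown downstream). Deterministic for a fixed seed.
#'
#' @param config An [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with file paths (`genome`, `annotation`,
#'   `alignments`, `classification`), the true `transcripts` tibble and the
#'   per-read `truth` tibble.
#' @export
simulate_reads <- function(config = sim_config(), out_dir = tempfile("sim"),
                           seed = 1L) {
  stopifnot(inherits(config, "sf_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  # ---- genes and isoforms
  tx_rows <- list()
  chrom_i <- 1L
  cursor <- 1000L
  chrom_used <- integer()
  for (g in seq_len(config$n_genes)) {
    n_iso <- rint(config$isoforms_per_gene)
    # >= 4 exons whenever a skip variant exists, so skipping an internal exon
    # always leaves at least one junction shared with the full chain
    n_ex <- max(rint(config$exons_per_gene), n_iso + 1L,
                if (n_iso > 1L) 4L else 3L)
    ex_len <- rint(config$exon_length, n_ex)
    in_len <- rint(config$intron_length, n_ex - 1L)
    span <- sum(ex_len) + sum(in_len)
    if (span + 2L * config$gene_gap > config$bases_per_chrom) {
      abort("gene span exceeds chromosome capacity; increase bases_per_chrom")
    }
    if (cursor + span + config$gene_gap > config$bases_per_chrom) {
      chrom_i <- chrom_i + 1L
      cursor <- 1000L
    }
    starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
    exons <- cbind(start = as.integer(starts),
                   end = as.integer(starts + ex_len))
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("SIMG%04d", g)
    chrom <- paste0("chr", chrom_i)
    prev_used <- if (chrom %in% names(chrom_used)) chrom_used[[chrom]] else 0L
    chrom_used[chrom] <- max(prev_used, cursor + span)

    iso_exons <- list(exons)
    if (n_iso > 1L) {
      skippable <- 2L:(n_ex - 1L)
      skip <- sample(skippable, n_iso - 1L)
      for (s in skip) {
        iso_exons[[length(iso_exons) + 1L]] <- exons[-s, , drop = FALSE]
      }
    }
    for (k in seq_along(iso_exons)) {
      tx_rows[[length(tx_rows) + 1L]] <- tibble(
        chrom = chrom, strand = strand, exons = list(iso_exons[[k]]),
        abundance = as.numeric(config$depth),
        transcript_id = sprintf("%s.t%d", gene_id, k), gene_id = gene_id
      )
    }
    cursor <- cursor + span + config$gene_gap
  }
  transcripts <- validate_transcripts(bind_rows(tx_rows))

  # ---- reads
  read_rows <- list()
  sam_lines <- character()
  read_n <- 0L
  for (i in seq_len(nrow(transcripts))) {
    exons <- transcripts$exons[[i]]
    strand <- transcripts$strand[i]
    L <- exonic_length(exons)
    p5 <- config$p_truncate_5p(L)
    p3 <- config$p_truncate_3p(L)
    for (r in seq_len(config$depth)) {
      read_n <- read_n + 1L
      t5 <- stats::runif(1) < p5
      t3 <- stats::runif(1) < p3
      u5 <- 0L
      u3 <- 0L
      if (t5) {
        avail <- L - config$min_read_keep
        if (avail >= 1L) u5 <- sample.int(avail, 1L) else t5 <- FALSE
      }
      if (t3) {
        avail <- L - config$min_read_keep - u5
        if (avail >= 1L) u3 <- sample.int(avail, 1L) else t3 <- FALSE
      }
      cls_flags <- if (!t5 && !t3) {
        c(1L, 1L, 1L)
      } else if (t5 && !t3) {
        c(0L, 1L, 1L) # 5' end lost
      } else if (!t5 && t3) {
        c(1L, 0L, 0L) # 3' end lost
      } else {
        c(0L, 0L, 0L)
      }
      segs <- transcript_interval_to_segments(exons, strand, u5, L - u3)
      cig <- segments_to_cigar(segs, config$indel_rate, config$max_indel_len)
      rid <- sprintf("r%06d", read_n)
      tags <- if (nrow(segs) >= 2L) paste0("\tXS:A:", strand) else ""
      sam_lines <- c(sam_lines, sprintf(
        "%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
        rid, transcripts$chrom[i], segs[1L, "start"] + 1L, cig, tags))
      read_rows[[length(read_rows) + 1L]] <- tibble(
        read_id = rid, gene_id = transcripts$gene_id[i],
        transcript_id = transcripts$transcript_id[i],
        has_5p = cls_flags[1L], has_3p = cls_flags[2L],
        has_polyA = cls_flags[3L],
        read_class = classify_flags(cls_flags[1L], cls_flags[2L],
                                    cls_flags[3L]),
        q0 = u5, q1 = L - u3, tx_length = L, n_segments = nrow(segs)
      )
    }
  }
  truth <- bind_rows(read_rows)

  # ---- outputs
  chroms <- names(chrom_used)
  chrom_len <- pmax(chrom_used + 1000L, 2000L)
  genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, ""))
  names(genome) <- chroms
  genome_path <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(genome, genome_path)

  annotation_path <- file.path(out_dir, "annotation.gtf")
  write_gtf(transcripts, annotation_path, source = "spliceflow_sim")

  sam_path <- file.path(out_dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len))
  con <- file(sam_path, open = "wb")
  writeLines(c(header, sam_lines), con)
  close(con)

  class_path <- file.path(out_dir, "classification.tsv")
  readr::write_tsv(
    select(truth, "read_id", "has_5p", "has_3p", "has_polyA"),
    class_path, progress = FALSE
  )

  invisible(list(
    genome = genome_path, annotation = annotation_path,
    alignments = sam_path, classification = class_path,
    transcripts = transcripts, truth = truth
  ))
}
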