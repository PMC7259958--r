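#' Configuration for the rolling-circle read simulator
#'
#' The defaults emulate the study conditions of a bacterial rolling-circle
#' transcript-error experiment: 300-nt single-end reads over circularized RNA
#' fragments of mostly 25-150 nt (lognormal, median ~60 nt), a
#' reverse-transcriptase error rate of 1e-4 per nt per repeat, per-site
#' transcript-error rates in the 1e-6 to 1e-5 range, and a per-cycle quality
#' profile declining from Q38 to Q28 across the read. Errors are planted at
#' three causal tiers: transcript errors are molecule-level (present on every
#' repeat), reverse-transcription errors are repeat-level, and sequencing
#' errors are cycle-level — the separation the rolling-circle design exploits.
#'
#' @param seed integer seed fixing every downstream draw.
#' @param n_reads number of reads to simulate.
#' @param n_cds,cds_len number and length (nt, incl. stop codon) of CDS genes.
#' @param rrna_copies,rrna_len,rrna_divergence rRNA-like family: copy count,
#'   length, and fraction of planted fixed differences between copies (the
#'   copies stay above 90% identity so the paralog filter is exercised).
#' @param trna_n,trna_len tRNA-like genes.
#' @param intergenic intergenic spacer length (nt).
#' @param code_table NCBI translation-table id for the simulated genome.
#' @param expression_sdlog lognormal sd of per-transcript expression weights.
#' @param error_rate per-site transcript-error rate.
#' @param spectrum_weights named 12-vector of relative substitution weights
#'   (`"X>Y"` on the sense strand); default is C->U-biased with a general
#'   transition bias.
#' @param indel_rate per-site molecule-level indel error rate.
#' @param rt_rate reverse-transcription error rate per nt per repeat.
#' @param read_len read length (nt).
#' @param frag_meanlog,frag_sdlog,frag_min,frag_max fragment-length lognormal
#'   parameters and clamps.
#' @param qual_start,qual_end,qual_jitter,qual_min,qual_max per-cycle mean
#'   Phred quality (linear from `qual_start` to `qual_end`), Gaussian jitter
#'   sd, and clamps.
#' @param planted_site optional list(`gene_id`, `tpos`, `alt`, `freq`): plant
#'   a specific substitution at a fixed molecule frequency.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 1e5,
                       n_cds = 20L, cds_len = 600L,
                       rrna_copies = 2L, rrna_len = 1500L,
                       rrna_divergence = 0.02,
                       trna_n = 2L, trna_len = 80L,
                       intergenic = 100L, code_table = "11",
                       expression_sdlog = 0.6,
                       error_rate = 1e-5,
                       spectrum_weights = NULL,
                       indel_rate = 0,
                       rt_rate = 1e-4, read_len = 300L,
                       frag_meanlog = log(60), frag_sdlog = 0.35,
                       frag_min = 25L, frag_max = 150L,
                       qual_start = 38, qual_end = 28, qual_jitter = 3,
                       qual_min = 2L, qual_max = 40L,
                       planted_site = NULL) {
  if (is.null(spectrum_weights)) {
    bases <- c("A", "C", "G", "T")
    cats <- as.vector(outer(bases, bases, function(a, b) paste0(a, ">", b)))
    cats <- cats[substr(cats, 1, 1) != substr(cats, 3, 3)]
    spectrum_weights <- stats::setNames(rep(1, 12), cats)
    spectrum_weights[c("A>G", "G>A", "T>C")] <- 2
    spectrum_weights["C>T"] <- 10
  }
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              n_cds = n_cds, cds_len = cds_len, rrna_copies = rrna_copies,
              rrna_len = rrna_len, rrna_divergence = rrna_divergence,
              trna_n = trna_n, trna_len = trna_len, intergenic = intergenic,
              code_table = code_table, expression_sdlog = expression_sdlog,
              error_rate = error_rate, spectrum_weights = spectrum_weights,
              indel_rate = indel_rate, rt_rate = rt_rate,
              read_len = as.integer(read_len),
              frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
              frag_min = as.integer(frag_min), frag_max = as.integer(frag_max),
              qual_start = qual_start, qual_end = qual_end,
              qual_jitter = qual_jitter, qual_min = qual_min,
              qual_max = qual_max, planted_site = planted_site)
  stopifnot(cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$rt_rate >= 0, cfg$rt_rate <= 1,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            cfg$frag_min >= 1, cfg$frag_max >= cfg$frag_min,
            cfg$read_len >= 2 * cfg$frag_min,
            all(cfg$spectrum_weights >= 0), length(cfg$spectrum_weights) == 12)
  class(cfg) <- "sim_config"
  cfg
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate an annotated genome and expression profile
#'
#' Generates a single-replicon genome with CDS genes (start codon, random
#' non-stop codons, stop codon), a duplicated rRNA-like family with planted
#' fixed differences between copies, and tRNA-like genes, separated by random
#' intergenic spacers. Gene strands are drawn at random. Expression weights
#' are lognormal.
#'
#' @param config `sim_config`.
#' @return list with `genome` (`annotated_genome`), `expression` (data.frame
#'   `gene_id`, `weight`), and `paralog_diffs` (planted fixed differences
#'   between rRNA copies).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  gc_tab <- genetic_code_table(config$code_table)
  stops <- names(gc_tab)[gc_tab == "*"]
  nonstop <- setdiff(names(gc_tab), stops)
  genes <- list()
  add_gene <- function(id, kind, subkind, seq) {
    genes[[length(genes) + 1]] <<- list(id = id, kind = kind,
                                        subkind = subkind, seq = seq)
  }
  stopifnot(config$cds_len %% 3 == 0, config$cds_len >= 9)
  for (i in seq_len(config$n_cds)) {
    body <- sample(nonstop, config$cds_len / 3 - 2, replace = TRUE)
    add_gene(sprintf("cds_%03d", i), "cds", "cds",
             paste(c("ATG", body, sample(stops, 1)), collapse = ""))
  }
  paralog_diffs <- NULL
  if (config$rrna_copies > 0) {
    base <- .rand_seq(config$rrna_len)
    add_gene("rrna_1", "ncRNA", "rRNA", base)
    ndiff <- max(1L, floor(config$rrna_divergence * config$rrna_len))
    for (cp in seq_len(config$rrna_copies - 1)) {
      posns <- sort(sample(config$rrna_len, ndiff))
      s <- base
      refb <- substring(s, posns, posns)
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      for (j in seq_along(posns)) substr(s, posns[j], posns[j]) <- altb[j]
      add_gene(sprintf("rrna_%d", cp + 1), "ncRNA", "rRNA", s)
      paralog_diffs <- rbind(paralog_diffs, data.frame(
        copy = sprintf("rrna_%d", cp + 1), tpos = posns, ref = refb,
        alt = altb, stringsAsFactors = FALSE, row.names = NULL))
    }
  }
  for (i in seq_len(config$trna_n)) {
    add_gene(sprintf("trna_%d", i), "ncRNA", "tRNA", .rand_seq(config$trna_len))
  }

  strands <- sample(c("+", "-"), length(genes), replace = TRUE)
  segs <- character(0)
  feats <- list()
  pos <- 1L
  for (i in seq_along(genes)) {
    spacer <- .rand_seq(config$intergenic)
    segs <- c(segs, spacer)
    pos <- pos + config$intergenic
    g <- genes[[i]]
    w <- nchar(g$seq)
    refseg <- if (strands[i] == "+") g$seq else revcomp(g$seq)
    segs <- c(segs, refseg)
    feats[[i]] <- data.frame(gene_id = g$id, replicon = "chr1", start = pos,
                             end = pos + w - 1L, strand = strands[i],
                             kind = g$kind, subkind = g$subkind,
                             stringsAsFactors = FALSE)
    pos <- pos + w
  }
  segs <- c(segs, .rand_seq(config$intergenic))
  genome <- annotated_genome(c(chr1 = paste(segs, collapse = "")),
                             do.call(rbind, feats), config$code_table)
  expression <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "id"),
    weight = stats::rlnorm(length(genes), 0, config$expression_sdlog),
    stringsAsFactors = FALSE)
  list(genome = genome, expression = expression,
       paralog_diffs = paralog_diffs)
}

#' Write a simulated reference to FASTA / GFF3 / expression TSV
#'
#' @param sim result of [simulate_reference()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_reference <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genome.gff3")
  expr <- file.path(dir, "expression.tsv")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome$sequences), fasta)
  ft <- sim$genome$features
  gr <- GenomicRanges::GRanges(ft$replicon, IRanges::IRanges(ft$start, ft$end),
                               ft$strand)
  gr$type <- ifelse(ft$kind == "cds", "CDS",
                    ifelse(ft$subkind == "rRNA", "rRNA",
                           ifelse(ft$subkind == "tRNA", "tRNA", "ncRNA")))
  gr$ID <- ft$gene_id
  gr$locus_tag <- ft$gene_id
  gr$phase <- ifelse(ft$kind == "cds", 0L, NA_integer_)
  rtracklayer::export(gr, gff, format = "gff3")
  utils::write.table(sim$expression, expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(fasta = fasta, gff = gff, expression = expr)
}

# 256 x 3 raw lookup: the three alternative bases of each base byte
.alt_base_table <- function() {
  tab <- matrix(as.raw(0), 256, 3)
  for (b in c("A", "C", "G", "T")) {
    others <- setdiff(c("A", "C", "G", "T"), b)
    tab[as.integer(charToRaw(b)), ] <- charToRaw(paste(others, collapse = ""))
  }
  tab
}

#' Simulate rolling-circle reads with a complete truth table
#'
#' Per read: a transcript is drawn proportional to expression weight times
#' length, a fragment position and lognormal length are drawn, transcript
#' errors (and optionally 1-nt indels) are planted once per molecule — shared
#' by all repeats — the fragment is rotated by a uniform ligation-junction
#' offset and tiled to the read length, then reverse-transcription errors are
#' overlaid independently per position (equivalent to independent errors per
#' repeat per nt) and sequencing errors per cycle according to the simulated
#' quality profile. Every event is recorded so each read can be reconstructed
#' exactly from the truth table.
#'
#' @param config `sim_config`.
#' @param genome `annotated_genome` from [simulate_reference()] (or
#'   user-supplied).
#' @param expression data.frame `gene_id`, `weight`.
#' @return list with `reads` (data.frame `read_id`, `seq`, `qual`) and
#'   `truth` (list of data.frames: `fragments`, `tx_errors`, `indels`,
#'   `rt_errors`, `seq_errors`).
#' @export
simulate_reads <- function(config, genome, expression) {
  set.seed(config$seed + 1L)
  n <- config$n_reads
  L <- config$read_len
  ft <- genome$features
  ft <- ft[match(expression$gene_id, ft$gene_id), ]
  width <- ft$end - ft$start + 1L
  txseq <- vapply(seq_len(nrow(ft)), function(i)
    feature_sequence(genome, ft[i, ]), character(1))
  names(txseq) <- ft$gene_id

  prob <- expression$weight * width
  txi <- sample.int(nrow(ft), n, replace = TRUE, prob = prob)
  w <- width[txi]
  fl <- as.integer(round(stats::rlnorm(n, config$frag_meanlog, config$frag_sdlog)))
  fl <- pmax(config$frag_min, pmin(fl, config$frag_max, w, L %/% 2L))
  start <- as.integer(floor(stats::runif(n) * (w - fl + 1))) + 1L
  frag <- substring(txseq[txi], start, start + fl - 1L)
  read_id <- sprintf("read_%07d", seq_len(n))

  sw <- config$spectrum_weights
  bases <- c("A", "C", "G", "T")
  tx_err <- list()
  ne <- stats::rbinom(n, fl, config$error_rate)
  for (i in which(ne > 0L)) {
    posns <- sample.int(fl[i], ne[i])
    for (p in posns) {
      refb <- substr(frag[i], p, p)
      wts <- sw[paste0(refb, ">", setdiff(bases, refb))]
      altb <- sample(setdiff(bases, refb), 1, prob = wts)
      substr(frag[i], p, p) <- altb
      tx_err[[length(tx_err) + 1]] <- data.frame(
        read_id = read_id[i], transcript = ft$gene_id[txi[i]],
        frag_pos = p, tpos = start[i] + p - 1L, ref = refb, alt = altb,
        cause = "transcript", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$planted_site)) {
    ps <- config$planted_site
    gi <- which(ft$gene_id == ps$gene_id)
    stopifnot(length(gi) == 1)
    cover <- which(txi == gi & start <= ps$tpos & start + fl - 1L >= ps$tpos)
    sel <- cover[stats::runif(length(cover)) < ps$freq]
    for (i in sel) {
      p <- ps$tpos - start[i] + 1L
      refb <- substr(frag[i], p, p)
      substr(frag[i], p, p) <- ps$alt
      tx_err[[length(tx_err) + 1]] <- data.frame(
        read_id = read_id[i], transcript = ps$gene_id, frag_pos = p,
        tpos = ps$tpos, ref = refb, alt = ps$alt, cause = "planted",
        stringsAsFactors = FALSE)
    }
  }
  indel_truth <- list()
  if (config$indel_rate > 0) {
    ni <- stats::rbinom(n, fl, config$indel_rate)
    for (i in which(ni > 0L)) {
      p <- sample.int(fl[i] - 1L, 1L) + 1L   # keep ends intact
      if (stats::runif(1) < 0.5 && fl[i] > config$frag_min) {
        frag[i] <- paste0(substr(frag[i], 1L, p - 1L),
                          substr(frag[i], p + 1L, fl[i]))
        fl[i] <- fl[i] - 1L
        indel_truth[[length(indel_truth) + 1]] <- data.frame(
          read_id = read_id[i], frag_pos = p, type = "deletion", base = NA,
          stringsAsFactors = FALSE)
      } else {
        b <- sample(bases, 1)
        frag[i] <- paste0(substr(frag[i], 1L, p), b,
                          substr(frag[i], p + 1L, fl[i]))
        fl[i] <- fl[i] + 1L
        indel_truth[[length(indel_truth) + 1]] <- data.frame(
          read_id = read_id[i], frag_pos = p, type = "insertion", base = b,
          stringsAsFactors = FALSE)
      }
    }
  }

  rot <- as.integer(floor(stats::runif(n) * fl))
  rfrag <- paste0(substring(frag, rot + 1L, fl), substring(frag, 1L, rot))
  reads <- substr(strrep(rfrag, ceiling(L / fl)), 1L, L)

  # raw byte matrix (cycle x read) for positionwise error overlay
  m <- matrix(charToRaw(paste(reads, collapse = "")), nrow = L)
  qm <- matrix(as.raw(0), nrow = L, ncol = n)
  alt_tab <- .alt_base_table()
  qmean <- config$qual_start +
    (config$qual_end - config$qual_start) * (seq_len(L) - 1) / (L - 1)
  rt_err <- vector("list", L)
  seq_err <- vector("list", L)
  for (cyc in seq_len(L)) {
    hit <- which(stats::runif(n) < config$rt_rate)
    if (length(hit) > 0) {
      cur <- m[cyc, hit]
      new <- alt_tab[cbind(as.integer(cur), sample.int(3, length(hit),
                                                       replace = TRUE))]
      m[cyc, hit] <- new
      rt_err[[cyc]] <- data.frame(read = hit, cycle = cyc,
                                  ref = rawToChar(cur, multiple = TRUE),
                                  alt = rawToChar(new, multiple = TRUE),
                                  stringsAsFactors = FALSE)
    }
    q <- as.integer(round(stats::rnorm(n, qmean[cyc], config$qual_jitter)))
    q <- pmax(config$qual_min, pmin(config$qual_max, q))
    qm[cyc, ] <- as.raw(q + 33L)
    eps <- 10^(-q / 10)
    hit <- which(stats::runif(n) < eps)
    if (length(hit) > 0) {
      cur <- m[cyc, hit]
      new <- alt_tab[cbind(as.integer(cur), sample.int(3, length(hit),
                                                       replace = TRUE))]
      m[cyc, hit] <- new
      seq_err[[cyc]] <- data.frame(read = hit, cycle = cyc,
                                   ref = rawToChar(cur, multiple = TRUE),
                                   alt = rawToChar(new, multiple = TRUE),
                                   stringsAsFactors = FALSE)
    }
  }
  big <- rawToChar(as.vector(m))
  starts_chr <- seq(1L, by = L, length.out = n)
  seqs <- substring(big, starts_chr, starts_chr + L - 1L)
  bigq <- rawToChar(as.vector(qm))
  quals <- substring(bigq, starts_chr, starts_chr + L - 1L)

  truth <- list(
    fragments = data.frame(read_id = read_id, transcript = ft$gene_id[txi],
                           tx_start = start, frag_len = fl, rotation = rot,
                           stringsAsFactors = FALSE),
    tx_errors = if (length(tx_err)) do.call(rbind, tx_err) else NULL,
    indels = if (length(indel_truth)) do.call(rbind, indel_truth) else NULL,
    rt_errors = data.table::rbindlist(rt_err[!vapply(rt_err, is.null, TRUE)]),
    seq_errors = data.table::rbindlist(seq_err[!vapply(seq_err, is.null, TRUE)]))
  list(reads = data.frame(read_id = read_id, seq = seqs, qual = quals,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}
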