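#' Map consensus fragments to the reference via their tandem duplicates
#'
#' The original RNA fragment is a rotation of the consensus (the ligation
#' junction can fall anywhere within the repeat). A tandem duplicate of the
#' consensus contains exactly one contiguous copy of the original fragment, so
#' the longest mapped block of the duplicate identifies both the junction
#' (rotation offset) and the reference anchor. The built-in mapper seeds with
#' exact k-mers, votes on diagonals, and places the period-length window where
#' the exact-match count is maximal; a paired-diagonal search recovers single
#' indels of up to `max_gap` nt. Fragments aligning equally well (score within
#' one match) to more than one locus are marked non-unique; following the
#' retention rule for repeated ncRNA genes, non-unique fragments are kept only
#' when they map to an ncRNA locus. Four nucleotides at both ends of the
#' reorganized consensus are excluded from the assayed mask because mapping is
#' ambiguous at fragment ends.
#'
#' @param cs `consensus_set` from [consensus_set()].
#' @param genome `annotated_genome`.
#' @param k seed k-mer length.
#' @param min_block_identity minimum fraction of exact matches within the
#'   placed window for a fragment to be accepted.
#' @param max_gap largest indel length searched within a block.
#' @param trim nucleotides trimmed from each end of the reorganized consensus
#'   when defining assayed positions.
#' @return Object of class `mapped_fragments`: `table` (one row per retained
#'   fragment: `read_id`, `replicon`, `start` (1-based), `strand`, `period`,
#'   `rotation`, `score`, `unique`, `class`, indel fields, `fwd_frag`),
#'   `qidx`/`q`/`depth` lists aligned with the table, and `counts` of filter
#'   outcomes.
#' @export
map_fragments <- function(cs, genome, k = 15L, min_block_identity = 0.9,
                          max_gap = 3L, trim = 4L) {
  res <- cpp_map_fragments(unname(genome$sequences), cs$table$seq,
                           as.integer(k), min_block_identity,
                           as.integer(max_gap))
  tab <- res$table
  status <- res$status
  counts <- c(fragments_in = nrow(cs$table),
              unmapped = sum(status == 1L),
              junction_unresolved = sum(status == 2L))
  .finalize_fragments(tab, res$qidx, status, cs, genome, counts, trim)
}

.finalize_fragments <- function(tab, qidx, status, cs, genome, counts, trim) {
  if (nrow(tab) == 0) {
    out <- list(table = tab, qidx = list(), q = list(), depth = list(),
                counts = c(counts, non_unique_dropped = 0L, retained = 0L),
                trim = trim)
    class(out) <- "mapped_fragments"
    return(out)
  }
  tab$read_id <- cs$table$read_id[tab$query]
  tab$replicon <- names(genome$sequences)[tab$ref]
  span <- tab$period + ifelse(tab$indel_type == 1L, tab$indel_len,
                              ifelse(tab$indel_type == 2L, -tab$indel_len, 0L))
  tab$unique <- tab$n_loci == 1L
  tab$class <- .fragment_class(tab$replicon, tab$start, tab$start + span - 1L,
                               tab$strand, genome)
  keep <- tab$unique | tab$class == "ncRNA"
  counts <- c(counts, non_unique_dropped = sum(!keep), retained = sum(keep))
  q <- cs$q[tab$query][keep]
  depth <- cs$depth[tab$query][keep]
  qidx <- qidx[keep]
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab, qidx = qidx, q = q, depth = depth,
              counts = counts, trim = trim)
  class(out) <- "mapped_fragments"
  out
}

# region class of each fragment span: the overlapped feature class with the
# largest overlap on the matching strand (cds preferred on ties); "other" when
# no feature overlaps.
.fragment_class <- function(replicon, start, end, strand, genome) {
  fr <- GenomicRanges::GRanges(replicon, IRanges::IRanges(start, end), strand)
  ft <- genome$features
  fg <- GenomicRanges::GRanges(ft$replicon, IRanges::IRanges(ft$start, ft$end),
                               ft$strand)
  hits <- GenomicRanges::findOverlaps(fr, fg)
  cls <- rep("other", length(fr))
  if (length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(fr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(fg)[S4Vectors::subjectHits(hits)]))
    kind <- ft$kind[S4Vectors::subjectHits(hits)]
    dt <- data.table::data.table(
      q = S4Vectors::queryHits(hits), kind = kind, ov = ov)
    pick <- dt[order(-ov, kind), .SD[1], by = "q"]
    cls[pick$q] <- pick$kind
  }
  cls
}

#' @export
print.mapped_fragments <- function(x, ...) {
  cat("mapped_fragments:", nrow(x$table), "retained of",
      x$counts["fragments_in"], "(unmapped:", x$counts["unmapped"],
      ", junction unresolved:", x$counts["junction_unresolved"],
      ", non-unique dropped:", x$counts["non_unique_dropped"], ")\n")
  invisible(x)
}

#' Write tandem duplicates of consensus fragments for external alignment
#'
#' Production-scale runs map the duplicated consensus sequences with a
#' short-read aligner (e.g. BWA) and feed the SAM back via
#' [import_alignments()].
#'
#' @param cs `consensus_set`.
#' @param path output FASTA path.
#' @return Invisibly, the path.
#' @export
write_duplicated_fasta <- function(cs, path) {
  lines <- character(2L * nrow(cs$table))
  lines[seq(1, length(lines), 2)] <- paste0(">", cs$table$read_id)
  lines[seq(2, length(lines), 2)] <- paste0(cs$table$seq, cs$table$seq)
  writeLines(lines, path)
  invisible(path)
}

#' Import externally produced alignments of duplicated consensus sequences
#'
#' Builds the same `mapped_fragments` structure as [map_fragments()] from a
#' SAM file of alignments of the tandem-duplicated consensus sequences (see
#' [write_duplicated_fasta()]). The longest aligned block (M/=/X runs merged
#' across indels of at most `max_gap` nt) must span at least one full period;
#' its query start fixes the rotation and its reference start the anchor.
#' Records whose read id is absent from the consensus set are skipped with a
#' warning. Mapping quality below `min_mapq`, or the presence of secondary or
#' supplementary alignments for a read, marks the fragment non-unique.
#'
#' @param sam_path path to the SAM file.
#' @param cs `consensus_set` the duplicates were derived from.
#' @param genome `annotated_genome`.
#' @param min_mapq mapping-quality threshold below which a fragment is
#'   considered non-unique (the uniqueness criterion is configurable because
#'   aligners encode multi-mapping differently).
#' @param max_gap largest indel merged into a block.
#' @param trim end trimming of the reorganized consensus, as in
#'   [map_fragments()].
#' @return `mapped_fragments` object.
#' @export
import_alignments <- function(sam_path, cs, genome, min_mapq = 10L,
                              max_gap = 3L, trim = 4L) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  is_mapped <- !bitwAnd(rec$flag, 4L)
  is_secondary <- bitwAnd(rec$flag, 256L) > 0 | bitwAnd(rec$flag, 2048L) > 0
  has_secondary <- rec$qname[is_secondary & is_mapped]

  idx_by_id <- stats::setNames(seq_len(nrow(cs$table)), cs$table$read_id)
  primary <- which(is_mapped & !is_secondary)
  known <- rec$qname[primary] %in% names(idx_by_id)
  if (any(!known)) {
    warning(sum(!known), " SAM record(s) with read ids absent from the ",
            "consensus set; skipped")
  }
  primary <- primary[known]

  rows <- list()
  qidx_list <- list()
  status <- integer(nrow(cs$table))  # parallels builtin: 1 unmapped, 2 unresolved
  status[] <- 1L
  for (i in primary) {
    qi <- idx_by_id[[rec$qname[i]]]
    P <- nchar(cs$table$seq[qi])
    cig <- rec$cigar[i]
    blocks <- .cigar_blocks(cig, max_gap)
    if (is.null(blocks)) stop("malformed CIGAR: ", cig)
    best <- blocks$blocks[which.max(blocks$blocks$qlen), , drop = FALSE]
    if (best$qlen < P) { status[qi] <- 2L; next }
    t0 <- best$qstart - 1L                       # 0-based start in stored SEQ
    strand <- if (bitwAnd(rec$flag[i], 16L)) "-" else "+"
    anchor <- rec$pos[i] + best$rshift           # 1-based ref start of block
    ev <- blocks$events
    ev <- ev[ev$qpos >= best$qstart & ev$qpos <= best$qstart + P - 2L, ,
             drop = FALSE]
    if (nrow(ev) > 0) {
      e <- ev[1, ]
      itype <- if (e$op == "D") 1L else 2L
      iqoff <- e$qpos - best$qstart + 1L          # first fragment offset after the event
      ilen <- e$len
    } else {
      itype <- 0L; iqoff <- 0L; ilen <- 0L
    }
    ii <- 0:(P - 1)
    qidx <- as.integer(if (strand == "+") (t0 + ii) %% P else
      (2 * P - 1 - t0 - ii) %% P)
    stored <- as.character(rec$seq[i])
    rows[[length(rows) + 1]] <- data.frame(
      query = qi, ref = match(as.character(rec$rname[i]), names(genome$sequences)),
      start = anchor, strand = strand, rotation = t0 %% P, period = P,
      score = best$qlen, n_loci = if (rec$mapq[i] < min_mapq ||
                                      rec$qname[i] %in% has_secondary) 2L else 1L,
      indel_type = itype, indel_qoff = iqoff, indel_len = ilen,
      fwd_frag = substr(stored, t0 + 1L, t0 + P), stringsAsFactors = FALSE)
    qidx_list[[length(qidx_list) + 1]] <- qidx
    status[qi] <- 0L
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = integer(0))
  counts <- c(fragments_in = nrow(cs$table),
              unmapped = sum(status == 1L),
              junction_unresolved = sum(status == 2L))
  .finalize_fragments(tab, qidx_list, status, cs, genome, counts, trim)
}

# Decompose a CIGAR into aligned blocks along the query, merging across indels
# of length <= max_gap. Returns per-block query start/length and the reference
# shift of the block start relative to POS, plus indel events (query position
# of the last aligned base before the event).
.cigar_blocks <- function(cigar, max_gap) {
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) return(NULL)
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  if (length(ops) == 0 || any(!ops %in% c("M", "=", "X", "I", "D", "S", "H", "N", "P"))) {
    return(NULL)
  }
  qpos <- 0L   # consumed query bases (soft-clipped included)
  rshift <- 0L # consumed ref bases relative to POS
  blocks <- data.frame(qstart = integer(0), qlen = integer(0),
                       rshift = integer(0))
  events <- data.frame(qpos = integer(0), op = character(0), len = integer(0),
                       stringsAsFactors = FALSE)
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur)) rbind(blocks, as.data.frame(cur)) else blocks
  }
  for (i in seq_along(ops)) {
    op <- ops[i]; ln <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (is.null(cur)) cur <- list(qstart = qpos + 1L, qlen = 0L, rshift = rshift)
      cur$qlen <- cur$qlen + ln
      qpos <- qpos + ln; rshift <- rshift + ln
    } else if (op == "I") {
      if (!is.null(cur) && ln <= max_gap) {
        events <- rbind(events, data.frame(qpos = qpos, op = "I", len = ln,
                                           stringsAsFactors = FALSE))
        cur$qlen <- cur$qlen + ln   # inserted bases stay inside the block
      } else {
        blocks <- flush(cur, blocks); cur <- NULL
      }
      qpos <- qpos + ln
    } else if (op == "D" || op == "N") {
      if (!is.null(cur) && ln <= max_gap && op == "D") {
        events <- rbind(events, data.frame(qpos = qpos, op = "D", len = ln,
                                           stringsAsFactors = FALSE))
      } else {
        blocks <- flush(cur, blocks); cur <- NULL
      }
      rshift <- rshift + ln
    } else if (op %in% c("S", "H")) {
      blocks <- flush(cur, blocks); cur <- NULL
      if (op == "S") qpos <- qpos + ln
    }
  }
  blocks <- flush(cur, blocks)
  if (nrow(blocks) == 0) return(NULL)
  list(blocks = blocks, events = events)
}
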