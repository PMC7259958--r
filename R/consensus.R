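#' Read rolling-circle FASTQ reads
#'
#' Loads single-end reads (Phred+33 qualities) into a plain data frame used by
#' the consensus stage.
#'
#' @param fastq_path path to a FASTQ file.
#' @return data.frame with `read_id`, `seq`, `qual` (quality string).
#' @export
read_rolling_reads <- function(fastq_path) {
  x <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Detect the tandem-repeat period of a read by autocorrelation
#'
#' For each candidate period `P`, the identity fraction
#' `f(P) = #\{i : b_i == b_(i+P), both non-N\} / #\{i <= L-P : both non-N\}`
#' is computed; the maximizing `P` is returned if `f(P)` reaches
#' `min_identity`. Ties between equally scoring periods are broken toward the
#' smallest period (the fundamental period, since multiples of the true period
#' score equally on noiseless reads).
#'
#' @param bases base-call string of one read.
#' @param min_period smallest candidate period (nt). The default of 25 nt
#'   matches the smallest circularizable fragments and avoids trivial
#'   micro-periods.
#' @param max_period largest candidate period; default `floor(L/2)` so that at
#'   least two repeats are present.
#' @param min_identity acceptance threshold on `f(P)`; random sequence scores
#'   about 0.25-0.4, true tandem repeats near 1.
#' @return list with `period`, `identity`, `repeats`, or `NULL` when the read
#'   is too short or no candidate period reaches `min_identity`.
#' @export
detect_period <- function(bases, min_period = 25L, max_period = NULL,
                          min_identity = 0.85) {
  L <- nchar(bases)
  if (is.null(max_period)) max_period <- L %/% 2L
  res <- cpp_detect_periods(bases, as.integer(min_period), as.integer(max_period))
  if (is.na(res$period[1]) || res$identity[1] < min_identity) return(NULL)
  list(period = res$period[1], identity = res$identity[1],
       repeats = res$repeats[1])
}

#' Collapse the repeats of one read into a Bayesian consensus fragment
#'
#' Position `j` of the consensus collects the base calls at read positions
#' `j, j+P, j+2P, ...` together with their Phred-decoded error probabilities.
#' With a uniform prior over A, C, G, T, the posterior of base `a` is
#' proportional to the product over calls of `1 - eps` (call equals `a`) or
#' `eps/3` (call differs). The consensus call is the posterior maximizer and
#' its recomputed error probability is `q_j = 1 - posterior(c_j)`. Columns of
#' unequal depth (the `L mod P` tail contributes one extra call to the first
#' positions) are handled identically. Posterior ties and all-N columns emit
#' `N` with `q = 1`.
#'
#' @param bases base-call string of the read.
#' @param qual either the Phred+33 quality string or a numeric vector of
#'   per-base error probabilities.
#' @param period repeat period `P` from [detect_period()].
#' @param eps_floor lower clamp on decoded error probabilities (Q60 cap), so a
#'   single call can never be treated as error-free.
#' @param min_repeats minimum repeat count `floor(L/P)`; fragments with fewer
#'   repeats cannot separate reverse-transcription errors from template
#'   changes and are rejected.
#' @return list with `seq` (consensus string of length `P`), `q` (posterior
#'   error probabilities), `depth` (calls per column), `period`.
#' @export
build_consensus <- function(bases, qual, period, eps_floor = 1e-6,
                            min_repeats = 2L) {
  L <- nchar(bases)
  P <- as.integer(period)
  if (L %/% P < min_repeats) {
    stop("fewer than ", min_repeats, " tandem repeats; fragment rejected")
  }
  if (is.character(qual)) {
    eps <- 10^(-(utf8ToInt(qual) - 33L) / 10)
  } else {
    eps <- as.numeric(qual)
  }
  stopifnot(length(eps) == L)
  eps <- pmin(pmax(eps, eps_floor), 0.75)
  calls <- strsplit(bases, "")[[1]]
  cons <- character(P)
  qout <- numeric(P)
  dep <- integer(P)
  basesACGT <- c("A", "C", "G", "T")
  for (j in seq_len(P)) {
    idx <- seq(j, L, by = P)
    dep[j] <- length(idx)
    keep <- calls[idx] %in% basesACGT
    if (!any(keep)) {
      cons[j] <- "N"
      qout[j] <- 1
      next
    }
    cj <- calls[idx][keep]
    ej <- eps[idx][keep]
    lp <- vapply(basesACGT, function(a) {
      sum(ifelse(cj == a, log1p(-ej), log(ej / 3)))
    }, numeric(1))
    best <- which.max(lp)
    if (any(lp[-best] > lp[best] - 1e-9)) {
      cons[j] <- "N"
      qout[j] <- 1
    } else {
      rel <- exp(lp - lp[best])
      cons[j] <- basesACGT[best]
      qout[j] <- sum(rel[-best]) / sum(rel)
    }
  }
  list(seq = paste(cons, collapse = ""), q = qout, depth = dep, period = P)
}

#' Run period detection and consensus building over a read set
#'
#' Batch version of [detect_period()] + [build_consensus()] with full filter
#' accounting. Reads that are too short, below the identity threshold, or with
#' fewer than `min_repeats` repeats are rejected and tallied.
#'
#' @param reads data.frame from [read_rolling_reads()] (columns `read_id`,
#'   `seq`, `qual`).
#' @inheritParams detect_period
#' @inheritParams build_consensus
#' @return list of class `consensus_set`: `table` (data.frame `read_id`,
#'   `seq`, `period`, `identity`, `repeats`), `q` and `depth` (lists of
#'   per-fragment vectors), and `counts` (reads in / rejected per reason).
#' @export
consensus_set <- function(reads, min_period = 25L, max_period = NULL,
                          min_identity = 0.85, eps_floor = 1e-6,
                          min_repeats = 2L) {
  n <- nrow(reads)
  maxp <- if (is.null(max_period)) max(nchar(reads$seq)) %/% 2L else
    as.integer(max_period)
  det <- cpp_detect_periods(reads$seq, as.integer(min_period), maxp)
  too_short <- is.na(det$period)
  low_identity <- !too_short & det$identity < min_identity
  few_repeats <- !too_short & !low_identity & det$repeats < min_repeats
  ok <- !(too_short | low_identity | few_repeats)
  cons <- cpp_build_consensus(reads$seq[ok], reads$qual[ok],
                              det$period[ok], eps_floor)
  tab <- data.frame(
    read_id = reads$read_id[ok],
    seq = as.character(cons$consensus),
    period = det$period[ok],
    identity = det$identity[ok],
    repeats = det$repeats[ok],
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, q = cons$q, depth = cons$depth,
         counts = c(reads_in = n, too_short = sum(too_short),
                    low_identity = sum(low_identity),
                    too_few_repeats = sum(few_repeats),
                    consensus_built = sum(ok))),
    class = "consensus_set"
  )
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("consensus_set:", nrow(x$table), "fragments from", x$counts["reads_in"],
      "reads (too short:", x$counts["too_short"], ", low identity:",
      x$counts["low_identity"], ", <2 repeats:", x$counts["too_few_repeats"],
      ")\n")
  invisible(x)
}

#' Write consensus fragments as FASTQ plus a TSV sidecar
#'
#' The FASTQ quality string encodes the recomputed posterior error
#' probabilities re-encoded to Phred, capped at Q70 (the operative posterior
#' threshold downstream is 1e-7, i.e. Q70). The sidecar records the repeat
#' structure of each fragment.
#'
#' @param cs `consensus_set`.
#' @param fastq_path output FASTQ path.
#' @param tsv_path optional output TSV path (`read_id`, `period`, `identity`,
#'   `repeats`).
#' @return Invisibly, the FASTQ path.
#' @export
write_consensus <- function(cs, fastq_path, tsv_path = NULL) {
  qstr <- vapply(cs$q, function(q) {
    qi <- pmin(70L, as.integer(round(-10 * log10(pmax(q, 1e-10)))))
    intToUtf8(qi + 33L)
  }, character(1))
  lines <- character(4L * nrow(cs$table))
  lines[seq(1, length(lines), 4)] <- paste0("@", cs$table$read_id)
  lines[seq(2, length(lines), 4)] <- cs$table$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- qstr
  writeLines(lines, fastq_path)
  if (!is.null(tsv_path)) {
    utils::write.table(cs$table[, c("read_id", "period", "identity", "repeats")],
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fastq_path)
}
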