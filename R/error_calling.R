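#' Accumulate per-site pileups of consensus calls
#'
#' Every assayed consensus position (inside the 4-nt end trim) with a non-N
#' call and posterior error probability `q <= q_threshold` contributes one
#' count to its reference site; excluded calls contribute nothing, including
#' to coverage. Counts are bucketed by alignment strand, which for transcribed
#' regions is the transcript sense strand, and reported in sense orientation
#' (base calls and the reference base of minus-strand sites are complemented).
#'
#' @param fragments `mapped_fragments`.
#' @param genome `annotated_genome`.
#' @param q_threshold posterior error-probability ceiling for a consensus call
#'   to be assayed. The default 1e-7 sits two orders of magnitude below
#'   typical transcript-error rates (1e-6 to 1e-5 per nt), so residual
#'   sequencing miscalls are negligible.
#' @return Object of class `site_pileup`: a data.table with one row per
#'   covered (position, strand): `replicon`, `pos` (1-based), `strand`, `ref`
#'   (sense-strand reference base), sense-space base counts `nA`, `nC`, `nG`,
#'   `nT`, indel event counts `ins`, `del`, coverage `n`, and annotation
#'   columns `gene_id`, `class`.
#' @export
accumulate_pileup <- function(fragments, genome, q_threshold = 1e-7) {
  tab <- fragments$table
  ref_len <- as.integer(nchar(genome$sequences))
  mats <- cpp_accumulate_pileup(
    ref_len, tab$ref, tab$start, as.integer(tab$strand == "-"),
    tab$fwd_frag, fragments$qidx, fragments$q,
    tab$indel_type, tab$indel_qoff, tab$indel_len,
    trim = fragments$trim, q_max = q_threshold)

  out <- vector("list", length(mats))
  for (ri in seq_along(mats)) {
    M <- mats[[ri]]
    refname <- names(genome$sequences)[ri]
    refchars <- strsplit(genome$sequences[[ri]], "")[[1]]
    per_strand <- list()
    for (st in c("+", "-")) {
      off <- if (st == "+") 0L else 4L
      ioff <- if (st == "+") 9L else 10L
      doff <- if (st == "+") 11L else 12L
      cov <- M[off + 1L, ] + M[off + 2L, ] + M[off + 3L, ] + M[off + 4L, ]
      keep <- which(cov > 0L | M[ioff, ] > 0L | M[doff, ] > 0L)
      if (length(keep) == 0) next
      if (st == "+") {
        dt <- data.table::data.table(
          replicon = refname, pos = keep, strand = st, ref = refchars[keep],
          nA = M[off + 1L, keep], nC = M[off + 2L, keep],
          nG = M[off + 3L, keep], nT = M[off + 4L, keep])
      } else {
        # sense space on the minus strand: complement calls and reference
        dt <- data.table::data.table(
          replicon = refname, pos = keep, strand = st,
          ref = c(A = "T", C = "G", G = "C", T = "A", N = "N")[refchars[keep]],
          nA = M[off + 4L, keep], nC = M[off + 3L, keep],
          nG = M[off + 2L, keep], nT = M[off + 1L, keep])
      }
      dt$ins <- M[ioff, keep]
      dt$del <- M[doff, keep]
      dt$n <- cov[keep]
      per_strand[[st]] <- dt
    }
    out[[ri]] <- data.table::rbindlist(per_strand)
  }
  pile <- data.table::rbindlist(out)
  if (nrow(pile) == 0) {
    pile <- data.table::data.table(
      replicon = character(0), pos = integer(0), strand = character(0),
      ref = character(0), nA = integer(0), nC = integer(0), nG = integer(0),
      nT = integer(0), ins = integer(0), del = integer(0), n = integer(0))
  }
  ann <- .annotate_sites(pile, genome)
  pile$gene_id <- ann$gene_id
  pile$class <- ann$class
  data.table::setattr(pile, "class", c("site_pileup", class(pile)))
  pile
}

# first matching-strand feature per site (cds preferred), plus region class
.annotate_sites <- function(pile, genome) {
  n <- nrow(pile)
  gene_id <- rep(NA_character_, n)
  class <- rep("other", n)
  if (n == 0) return(list(gene_id = gene_id, class = class))
  ft <- genome$features
  sites <- GenomicRanges::GRanges(pile$replicon,
                                  IRanges::IRanges(pile$pos, pile$pos),
                                  pile$strand)
  fg <- GenomicRanges::GRanges(ft$replicon, IRanges::IRanges(ft$start, ft$end),
                               ft$strand)
  hits <- GenomicRanges::findOverlaps(sites, fg)
  if (length(hits) > 0) {
    dt <- data.table::data.table(
      q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits),
      kind = ft$kind[S4Vectors::subjectHits(hits)])
    pick <- dt[order(kind), .SD[1], by = "q"]   # "cds" sorts before "ncRNA"
    gene_id[pick$q] <- ft$gene_id[pick$s]
    class[pick$q] <- pick$kind
  }
  list(gene_id = gene_id, class = class)
}

#' Call transcript errors from site pileups
#'
#' Each alternative base supported by at least one consensus call and by less
#' than `max_frequency` of the reads at its site yields an error call. An
#' alternative at or above `max_frequency` marks the site as a putative
#' genetic variant: the site is removed from the error calls and from the
#' assayed denominators. For ncRNA sites, an alternative base equal to the
#' aligned base of another copy of the same ncRNA family is excluded as
#' putative paralog cross-mapping.
#'
#' @param pileups `site_pileup` from [accumulate_pileup()].
#' @param genome `annotated_genome`.
#' @param max_frequency strict site-frequency ceiling (a frequency exactly
#'   equal to `max_frequency` is excluded).
#' @param paralog_filter apply the ncRNA paralog filter.
#' @param cluster_identity global-identity threshold for grouping ncRNA genes
#'   into paralog families.
#' @return Object of class `error_calls`: `calls` (data.frame of substitution
#'   calls with `replicon`, `pos`, `strand`, `gene_id`, `class`, `ref`, `alt`,
#'   `k`, `n`, `freq`), `sites` (surviving assayed sites with coverage),
#'   and `counts` (variant-filtered sites, paralog-filtered calls).
#' @export
call_errors <- function(pileups, genome, max_frequency = 0.01,
                        paralog_filter = TRUE, cluster_identity = 0.9) {
  pile <- data.table::as.data.table(pileups)[n > 0L]
  bases <- c("A", "C", "G", "T")
  countcols <- c("nA", "nC", "nG", "nT")

  cnt <- as.matrix(pile[, countcols, with = FALSE])
  refidx <- match(pile$ref, bases)                  # NA for ref N
  altmax <- 0L
  alt_any <- rep(FALSE, nrow(pile))
  variant <- rep(FALSE, nrow(pile))
  for (b in 1:4) {
    isalt <- !is.na(refidx) & refidx != b
    k <- cnt[, b]
    variant <- variant | (isalt & k / pile$n >= max_frequency & k > 0L)
    alt_any <- alt_any | (isalt & k > 0L)
  }
  variant[is.na(refidx)] <- TRUE   # unassayable reference base (N): drop
  sites <- pile[!variant]
  n_variant <- sum(variant)

  calls <- list()
  scnt <- as.matrix(sites[, countcols, with = FALSE])
  srefidx <- match(sites$ref, bases)
  for (b in 1:4) {
    sel <- which(srefidx != b & scnt[, b] > 0L)
    if (length(sel) == 0) next
    calls[[length(calls) + 1]] <- data.frame(
      replicon = sites$replicon[sel], pos = sites$pos[sel],
      strand = sites$strand[sel], gene_id = sites$gene_id[sel],
      class = sites$class[sel], ref = sites$ref[sel], alt = bases[b],
      k = scnt[sel, b], n = sites$n[sel],
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(replicon = character(0), pos = integer(0), strand = character(0),
               gene_id = character(0), class = character(0), ref = character(0),
               alt = character(0), k = integer(0), n = integer(0))
  n_paralog <- 0L
  if (paralog_filter && nrow(calls) > 0) {
    drop <- .paralog_filter(calls, genome, cluster_identity)
    n_paralog <- sum(drop)
    calls <- calls[!drop, , drop = FALSE]
  }
  if (nrow(calls) > 0) {
    calls$freq <- calls$k / calls$n
    calls <- calls[order(calls$replicon, calls$pos, calls$alt), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls$freq <- numeric(0)
  }
  structure(
    list(calls = calls, sites = sites,
         counts = c(sites_in = nrow(pile), variant_sites_dropped = n_variant,
                    paralog_filtered = n_paralog, calls = nrow(calls))),
    class = "error_calls")
}

# TRUE for calls whose alt base equals the aligned base of another copy of the
# same ncRNA family (genes clustered at >= cluster_identity global identity)
.paralog_filter <- function(calls, genome, cluster_identity) {
  drop <- rep(FALSE, nrow(calls))
  nc <- genome$features[genome$features$kind == "ncRNA", , drop = FALSE]
  if (nrow(nc) < 2) return(drop)
  seqs <- vapply(seq_len(nrow(nc)), function(i)
    feature_sequence(genome, nc[i, ]), character(1))
  nn <- nrow(nc)
  pid <- function(a, b) {
    al <- Biostrings::pairwiseAlignment(a, b, type = "global")
    Biostrings::pid(al) / 100
  }
  adj <- matrix(FALSE, nn, nn)
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    if (abs(nchar(seqs[i]) - nchar(seqs[j])) / max(nchar(seqs[i]), nchar(seqs[j])) >
        (1 - cluster_identity)) next
    adj[i, j] <- adj[j, i] <- pid(seqs[i], seqs[j]) >= cluster_identity
  }
  cl <- .single_linkage(adj)
  in_nc <- which(calls$class == "ncRNA" & calls$gene_id %in% nc$gene_id)
  if (length(in_nc) == 0) return(drop)
  for (ci in unique(cl)) {
    members <- which(cl == ci)
    if (length(members) < 2) next
    for (i in members) {
      others <- setdiff(members, i)
      gi <- nc$gene_id[i]
      sel <- in_nc[calls$gene_id[in_nc] == gi]
      if (length(sel) == 0) next
      feat_i <- nc[i, ]
      tpos <- ref_to_transcript(feat_i, calls$pos[sel])
      for (j in others) {
        mp <- .aligned_map(seqs[i], seqs[j])
        jpos <- mp[tpos]
        okj <- !is.na(jpos)
        if (!any(okj)) next
        base_j <- substring(seqs[j], jpos[okj], jpos[okj])
        hit <- calls$alt[sel][okj] == base_j
        drop[sel[okj][hit]] <- TRUE
      }
    }
  }
  drop
}

.single_linkage <- function(adj) {
  n <- nrow(adj)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && cl[i] != cl[j]) {
        m <- min(cl[i], cl[j]); cl[cl == cl[i] | cl == cl[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cl
}

# position map from seq a to seq b via global pairwise alignment
.aligned_map <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a, b, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  mp <- rep(NA_integer_, nchar(a))
  ia <- 0L; ib <- 0L
  for (kk in seq_along(pa)) {
    da <- pa[kk] != "-"; db <- pb[kk] != "-"
    if (da) ia <- ia + 1L
    if (db) ib <- ib + 1L
    if (da && db) mp[ia] <- ib
  }
  mp
}

#' @export
print.error_calls <- function(x, ...) {
  cat("error_calls:", nrow(x$calls), "substitution calls over",
      nrow(x$sites), "assayed sites (variant sites dropped:",
      x$counts["variant_sites_dropped"], ", paralog-filtered:",
      x$counts["paralog_filtered"], ")\n")
  invisible(x)
}

#' Transcript-error rate of a genomic region class
#'
#' The rate is the number of error calls divided by the total number of
#' ribonucleotides assayed in the region (sum of surviving site coverages).
#' With zero errors the rate is 0 and a one-sided 95% upper bound of
#' `3 / assayed` (rule of three) is attached.
#'
#' @param ec `error_calls`.
#' @param region `"all"`, `"cds"`, `"ncRNA"` or `"other"`. A site overlapped
#'   by features of both classes counts in each class's denominator.
#' @param genome `annotated_genome`, required for class-specific regions so
#'   that overlapping annotation is honored.
#' @return list with `rate`, `errors`, `assayed`, and `upper95` (rule-of-three
#'   bound, only meaningful at zero errors). `rate` is `NA` when nothing was
#'   assayed.
#' @export
error_rate <- function(ec, region = "all", genome = NULL) {
  stopifnot(region %in% c("all", "cds", "ncRNA", "other"))
  sites <- ec$sites
  calls <- ec$calls
  if (region != "all") {
    if (is.null(genome)) {
      keep_s <- sites$class == region
      keep_c <- calls$class == region
    } else {
      keep_s <- .in_region(sites$replicon, sites$pos, sites$strand, region, genome)
      keep_c <- .in_region(calls$replicon, calls$pos, calls$strand, region, genome)
    }
    sites <- sites[keep_s, ]
    calls <- calls[keep_c, , drop = FALSE]
  }
  assayed <- sum(as.numeric(sites$n))
  nerr <- sum(calls$k)   # each supporting call is one erroneous molecule
  if (assayed == 0) {
    return(list(rate = NA_real_, errors = nerr, assayed = 0,
                upper95 = NA_real_))
  }
  list(rate = nerr / assayed, errors = nerr, assayed = assayed,
       upper95 = 3 / assayed)
}

#' Summarize error rates across biological replicates
#'
#' @param rates list of [error_rate()] results, one per replicate.
#' @return list with `mean`, `sem` (standard error of the mean across
#'   replicates), `n_replicates`, and the per-replicate `rates`.
#' @export
error_rate_summary <- function(rates) {
  r <- vapply(rates, function(x) x$rate, numeric(1))
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no replicate with a defined rate")
  list(mean = mean(r),
       sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
       n_replicates = length(r), rates = r)
}

.in_region <- function(replicon, pos, strand, region, genome) {
  if (length(pos) == 0) return(logical(0))
  ft <- genome$features
  sites <- GenomicRanges::GRanges(replicon, IRanges::IRanges(pos, pos), strand)
  if (region == "other") {
    fg <- GenomicRanges::GRanges(ft$replicon, IRanges::IRanges(ft$start, ft$end),
                                 ft$strand)
    return(GenomicRanges::countOverlaps(sites, fg) == 0)
  }
  ft <- ft[ft$kind == region, , drop = FALSE]
  if (nrow(ft) == 0) return(rep(FALSE, length(sites)))
  fg <- GenomicRanges::GRanges(ft$replicon, IRanges::IRanges(ft$start, ft$end),
                               ft$strand)
  GenomicRanges::countOverlaps(sites, fg) > 0
}

#' Conditional substitution spectrum
#'
#' For each of the 12 ordered base substitutions X->Y on the RNA sense strand,
#' the conditional rate is the number of X->Y error calls divided by the
#' number of X ribonucleotides assayed (coverage summed over surviving sites
#' with sense reference base X). Reference bases with zero assayed coverage
#' yield `NA` rates, not 0.
#'
#' @param ec `error_calls`.
#' @return data.frame of class `substitution_spectrum`: `from`, `to` (DNA
#'   alphabet; T denotes U on the transcript), `count`, `assayed`, `rate`.
#' @export
substitution_spectrum <- function(ec) {
  bases <- c("A", "C", "G", "T")
  a_x <- vapply(bases, function(b)
    sum(as.numeric(ec$sites$n[ec$sites$ref == b])), numeric(1))
  out <- expand.grid(from = bases, to = bases, stringsAsFactors = FALSE)
  out <- out[out$from != out$to, ]
  out <- out[order(out$from, out$to), ]
  out$count <- mapply(function(f, t)
    sum(ec$calls$k[ec$calls$ref == f & ec$calls$alt == t]), out$from, out$to)
  out$assayed <- a_x[out$from]
  out$rate <- ifelse(out$assayed > 0, out$count / out$assayed, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("substitution_spectrum", "data.frame")
  out
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  y <- as.data.frame(x)
  rna <- c(A = "A", C = "C", G = "G", T = "U")
  y$substitution <- paste0(rna[y$from], "→", rna[y$to])
  print(y[, c("substitution", "count", "assayed", "rate")], row.names = FALSE)
  invisible(x)
}

#' Call insertion/deletion transcript errors
#'
#' Indel events at assayed sites pass the same strict site-frequency filter as
#' substitutions (`events / coverage < max_frequency`); gaps falling in the
#' trimmed fragment ends were never recorded. The indel error rate uses the
#' same assayed-nucleotide denominator as the substitution rate, so the ratio
#' of the two is directly comparable.
#'
#' @param ec `error_calls`.
#' @param max_frequency strict frequency ceiling, as in [call_errors()].
#' @return list with `calls` (data.frame: `replicon`, `pos`, `strand`,
#'   `gene_id`, `class`, `type` (`insertion`/`deletion`), `k`, `n`), `rate`,
#'   and `ratio_to_substitution` (indel rate over substitution rate).
#' @export
call_indel_errors <- function(ec, max_frequency = 0.01) {
  s <- ec$sites
  rows <- list()
  for (ty in c("ins", "del")) {
    k <- s[[ty]]
    sel <- which(k > 0L & k / s$n < max_frequency)
    if (length(sel) == 0) next
    rows[[ty]] <- data.frame(
      replicon = s$replicon[sel], pos = s$pos[sel], strand = s$strand[sel],
      gene_id = s$gene_id[sel], class = s$class[sel],
      type = if (ty == "ins") "insertion" else "deletion",
      k = k[sel], n = s$n[sel], stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon = character(0), pos = integer(0), strand = character(0),
               gene_id = character(0), class = character(0), type = character(0),
               k = integer(0), n = integer(0))
  rownames(calls) <- NULL
  assayed <- sum(as.numeric(s$n))
  rate <- if (assayed > 0) sum(calls$k) / assayed else NA_real_
  subs_rate <- if (assayed > 0) sum(ec$calls$k) / assayed else NA_real_
  list(calls = calls, rate = rate,
       ratio_to_substitution = if (!is.na(subs_rate) && subs_rate > 0)
         rate / subs_rate else NA_real_)
}

#' Sliding-window error-rate track
#'
#' Per-window transcript-error rate along each replicon (both strands pooled).
#' Windows whose assayed coverage falls below `min_assayed` get an `NA` rate
#' (insufficient coverage to detect errors), mirroring blank windows in
#' genome-wide error plots.
#'
#' @param ec `error_calls`.
#' @param genome `annotated_genome`.
#' @param window window size in bp (10 kb for typical bacterial genomes, 1 kb
#'   for very small ones).
#' @param step step size in bp.
#' @param min_assayed minimum assayed nucleotides for a window to be reported.
#' @return data.frame: `replicon`, `start`, `end`, `errors`, `assayed`,
#'   `rate`.
#' @export
window_error_track <- function(ec, genome, window = 10000L, step = 1L,
                               min_assayed = 1e4) {
  out <- list()
  for (rn in names(genome$sequences)) {
    L <- nchar(genome$sequences[[rn]])
    cov <- numeric(L); err <- numeric(L)
    s <- ec$sites[ec$sites$replicon == rn, ]
    if (nrow(s) > 0) {
      agg <- data.table::as.data.table(s)[, list(n = sum(n)), by = "pos"]
      cov[agg$pos] <- agg$n
    }
    cl <- ec$calls[ec$calls$replicon == rn, , drop = FALSE]
    if (nrow(cl) > 0) {
      agg <- data.table::as.data.table(cl)[, list(k = sum(k)), by = "pos"]
      err[agg$pos] <- agg$k
    }
    w <- min(window, L)
    starts <- seq(1L, max(1L, L - w + 1L), by = step)
    ccov <- c(0, cumsum(cov)); cerr <- c(0, cumsum(err))
    a <- ccov[starts + w] - ccov[starts]
    e <- cerr[starts + w] - cerr[starts]
    out[[rn]] <- data.frame(replicon = rn, start = starts,
                            end = starts + w - 1L, errors = e, assayed = a,
                            rate = ifelse(a >= min_assayed, e / a, NA_real_))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write error calls as TSV and minimal VCF
#'
#' The TSV reports the RNA alphabet (U for T) in 1-based coordinates; the VCF
#' (v4.2) keeps the DNA alphabet with INFO keys `K` (supporting calls), `N`
#' (coverage) and `CLASS`.
#'
#' @param ec `error_calls`.
#' @param tsv_path optional TSV output path.
#' @param vcf_path optional VCF output path.
#' @return Invisibly, `NULL`.
#' @export
write_error_calls <- function(ec, tsv_path = NULL, vcf_path = NULL) {
  calls <- ec$calls
  if (!is.null(tsv_path)) {
    rna <- c(A = "A", C = "C", G = "G", T = "U")
    out <- calls
    out$ref <- rna[out$ref]
    out$alt <- rna[out$alt]
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=K,Number=1,Type=Integer,Description=\"Supporting consensus calls\">",
             "##INFO=<ID=N,Number=1,Type=Integer,Description=\"Assayed coverage\">",
             "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Region class\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(calls) > 0) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_fwd <- ifelse(calls$strand == "-", comp[calls$ref], calls$ref)
      alt_fwd <- ifelse(calls$strand == "-", comp[calls$alt], calls$alt)
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tK=%d;N=%d;CLASS=%s",
              calls$replicon, calls$pos, ref_fwd, alt_fwd, calls$k, calls$n,
              calls$class)
    } else character(0)
    writeLines(c(hdr, body), vcf_path)
  }
  invisible(NULL)
}
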