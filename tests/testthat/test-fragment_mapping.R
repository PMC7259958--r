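# helper: run a set of fragments (already consensus-level strings) through the
# built-in mapper by wrapping them in a consensus_set-like object
cs_from_frags <- function(frags, q = NULL) {
  tab <- data.frame(read_id = sprintf("f%03d", seq_along(frags)),
                    seq = frags,
                    period = nchar(frags), identity = 1,
                    repeats = 4L, stringsAsFactors = FALSE)
  if (is.null(q)) q <- lapply(nchar(frags), function(P) rep(1e-9, P))
  structure(list(table = tab, q = q,
                 depth = lapply(nchar(frags), function(P) rep(4L, P)),
                 counts = c(reads_in = length(frags), too_short = 0,
                            low_identity = 0, too_few_repeats = 0,
                            consensus_built = length(frags))),
            class = "consensus_set")
}

rotate <- function(s, rot) {
  P <- nchar(s)
  paste0(substr(s, rot + 1, P), substr(s, 1, rot))
}

test_that("exact fragments are recovered at every junction position", {
  g <- toy_genome(seed = 11)
  f <- g$features[1, ]   # plus-strand CDS
  frag <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  rots <- c(0, 1, 3, 17, 30, 45, 59)
  cs <- cs_from_frags(vapply(rots, function(r) rotate(frag, r), character(1)))
  mf <- map_fragments(cs, g)
  expect_equal(nrow(mf$table), length(rots))
  expect_true(all(mf$table$start == f$start))
  expect_true(all(mf$table$strand == "+"))
  expect_true(all(mf$table$fwd_frag == frag))   # rotation undone exactly
  expect_true(all(mf$table$unique))
  expect_true(all(mf$table$class == "cds"))
})

test_that("minus-strand (transcript-sense) fragments map to the minus strand", {
  g <- toy_genome(seed = 11)
  f <- g$features[2, ]   # minus-strand CDS
  tseq <- feature_sequence(g, f)        # transcript orientation
  frag <- substr(tseq, 11, 70)
  cs <- cs_from_frags(c(rotate(frag, 0), rotate(frag, 23)))
  mf <- map_fragments(cs, g)
  expect_equal(nrow(mf$table), 2)
  expect_true(all(mf$table$strand == "-"))
  # anchor: transcript positions 11..70 of a minus gene occupy ref
  # [end-69 .. end-10]
  expect_true(all(mf$table$start == f$end - 69L))
  # forward-space fragment is the reverse complement of the transcript window
  expect_true(all(mf$table$fwd_frag == revcomp(frag)))
})

test_that("assayed positions per accepted fragment are exactly P - 8", {
  g <- toy_genome(seed = 12)
  f <- g$features[1, ]
  frag <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  cs <- cs_from_frags(rotate(frag, 7))
  mf <- map_fragments(cs, g)
  pile <- accumulate_pileup(mf, g)
  expect_equal(sum(pile$n), 60 - 8)
  expect_true(all(pile$strand == "+"))
  # no mismatches anywhere
  refs <- pile$ref
  cnt <- as.matrix(pile[, c("nA", "nC", "nG", "nT")])
  expect_true(all(cnt[cbind(seq_len(nrow(pile)), match(refs, BASES))] == pile$n))
})

test_that("fragments from duplicated ncRNA map non-uniquely but are retained", {
  g <- toy_genome(seed = 13, rrna = TRUE)
  rr <- g$features[g$features$gene_id == "rrnaA", ]
  frag_rr <- substr(g$sequences[["chr1"]], rr$start + 20, rr$start + 79)
  # a unique CDS fragment forced non-unique is dropped instead
  f <- g$features[1, ]
  frag_cds <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  cs <- cs_from_frags(c(frag_rr, frag_cds))
  mf <- map_fragments(cs, g)
  expect_equal(nrow(mf$table), 2)
  rrrow <- mf$table[mf$table$class == "ncRNA", ]
  expect_false(rrrow$unique)
  expect_equal(rrrow$n_loci, 2L)
  expect_true(mf$table$unique[mf$table$class == "cds"])
})

test_that("a duplicated CDS makes its fragments non-unique and dropped", {
  set.seed(14)
  cds <- paste0("ATG", paste(sample(c("GCT", "CAA", "GAA", "TGC"), 40,
                                    replace = TRUE), collapse = ""), "TAA")
  seq <- paste0(rand_dna(60), cds, rand_dna(60), cds, rand_dna(60))
  g <- annotated_genome(
    c(chr1 = seq),
    data.frame(gene_id = c("dupA", "dupB"), replicon = "chr1",
               start = c(61L, 61L + nchar(cds) + 60L),
               end = c(60L + nchar(cds), 60L + 2 * nchar(cds) + 60L),
               strand = "+", kind = "cds", subkind = "cds",
               stringsAsFactors = FALSE),
    "11")
  frag <- substr(cds, 10, 69)
  mf <- map_fragments(cs_from_frags(frag), g)
  expect_equal(nrow(mf$table), 0)
  expect_equal(unname(mf$counts["non_unique_dropped"]), 1)
})

test_that("a planted 1-nt deletion is recovered as an indel event", {
  g <- toy_genome(seed = 15)
  f <- g$features[1, ]
  frag <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  del_at <- 30
  frag_del <- paste0(substr(frag, 1, del_at - 1), substr(frag, del_at + 1, 60))
  cs <- cs_from_frags(rotate(frag_del, 11))
  mf <- map_fragments(cs, g)
  expect_equal(nrow(mf$table), 1)
  expect_equal(mf$table$indel_type, 1L)
  expect_equal(mf$table$indel_len, 1L)
  expect_equal(mf$table$start, f$start)
  # the deleted reference base sits right after fragment offset indel_qoff - 1
  expect_equal(mf$table$start + mf$table$indel_qoff, f$start + del_at - 1)
  pile <- accumulate_pileup(mf, g)
  expect_equal(sum(pile$del), 1L)
  expect_equal(pile$pos[pile$del == 1L], f$start + del_at - 1L)
})

test_that("SAM import agrees with the built-in mapper on fixtures", {
  g <- toy_genome(seed = 16)
  f <- g$features[1, ]
  fm <- g$features[2, ]
  frag1 <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  frag2 <- substr(feature_sequence(g, fm), 5, 64)
  cons <- c(rotate(frag1, 13), rotate(frag2, 41))
  cs <- cs_from_frags(cons)
  builtin <- map_fragments(cs, g)

  # construct SAM records equivalent to the built-in alignments: the stored
  # SEQ is the (strand-oriented) duplicate and the aligned block starts at the
  # built-in window offset (= rotation), with soft clips around it
  P <- 60L
  mkrec <- function(qname, cons_seq, row) {
    cc <- paste0(cons_seq, cons_seq)
    minus <- row$strand == "-"
    stored <- if (minus) as.character(revcomp(cc)) else cc
    t0 <- row$rotation
    cig <- paste0(if (t0 > 0) paste0(t0, "S") else "", P, "M",
                  if (P - t0 > 0) paste0(P - t0, "S") else "")
    paste(qname, if (minus) 16L else 0L, "chr1", row$start, 60L, cig, "*",
          0L, 0L, stored, strrep("I", 2 * P), sep = "\t")
  }
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:chr1\tLN:", nchar(g$sequences[["chr1"]])),
    mkrec("f001", cons[1], builtin$table[builtin$table$read_id == "f001", ]),
    mkrec("f002", cons[2], builtin$table[builtin$table$read_id == "f002", ]))
  samf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, samf)
  imported <- import_alignments(samf, cs, g)
  expect_equal(nrow(imported$table), 2)
  for (col in c("read_id", "replicon", "start", "strand", "rotation",
                "period", "fwd_frag")) {
    expect_equal(imported$table[[col]], builtin$table[[col]], info = col)
  }
  expect_identical(imported$qidx, builtin$qidx)
})

test_that("SAM flags drive uniqueness and unknown ids are skipped", {
  g <- toy_genome(seed = 17)
  f <- g$features[1, ]
  frag <- substr(g$sequences[["chr1"]], f$start, f$start + 59)
  cs <- cs_from_frags(frag)
  cc <- paste0(frag, frag)
  rec <- function(qn, mapq, flag = 0L) {
    paste(qn, flag, "chr1", f$start, mapq, "60M60S", "*", 0L, 0L, cc,
          strrep("I", 120), sep = "\t")
  }
  samf <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:chr1\tLN:", nchar(g$sequences[["chr1"]])),
               rec("f001", 0L), rec("ghost", 60L)), samf)
  expect_warning(mf <- import_alignments(samf, cs, g), "absent")
  # MAPQ 0 -> non-unique; in a CDS, dropped
  expect_equal(nrow(mf$table), 0)
  expect_equal(unname(mf$counts["non_unique_dropped"]), 1)

  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:chr1\tLN:", nchar(g$sequences[["chr1"]])),
               rec("f001", 60L)), samf)
  mf2 <- import_alignments(samf, cs, g)
  expect_true(mf2$table$unique)
  expect_equal(mf2$table$rotation, 0L)
  expect_equal(mf2$table$start, f$start)
})

test_that("CIGAR with an internal deletion yields the indel event", {
  g <- toy_genome(seed = 18)
  f <- g$features[1, ]
  frag <- substr(g$sequences[["chr1"]], f$start, f$start + 60)  # 61 ref nt
  frag_del <- paste0(substr(frag, 1, 39), substr(frag, 41, 61)) # 60 query nt
  cs <- cs_from_frags(frag_del)
  cc <- paste0(frag_del, frag_del)
  sam <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:chr1\tLN:", nchar(g$sequences[["chr1"]])),
           paste("f001", 0L, "chr1", f$start, 60L, "39M1D21M60S", "*", 0L, 0L,
                 cc, strrep("I", 120), sep = "\t"))
  samf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, samf)
  mf <- import_alignments(samf, cs, g)
  expect_equal(nrow(mf$table), 1)
  expect_equal(mf$table$indel_type, 1L)
  expect_equal(mf$table$indel_qoff, 39L)
  expect_equal(mf$table$indel_len, 1L)
  builtin <- map_fragments(cs, g)
  expect_equal(builtin$table$indel_type, 1L)
  expect_equal(builtin$table$indel_len, 1L)
  # homopolymer context can shift the reported gap by a base or two
  expect_lte(abs(builtin$table$indel_qoff - 39L), 2L)
  expect_equal(builtin$table$start, mf$table$start)

  # malformed CIGAR: the walker refuses it, and the import path raises
  expect_null(tryCatch(circlecall:::.cigar_blocks("40Q80M", 3L),
                       error = function(e) NULL))
})
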