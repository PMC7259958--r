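# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

phred_chr <- function(q) intToUtf8(as.integer(q) + 33L)

# Direct-product Bayesian posterior over {A,C,G,T} for one consensus column:
# uniform prior, per-call error probabilities eps (already clamped by caller).
# Returns the normalized posterior vector.
posterior_oracle <- function(calls, eps) {
  stopifnot(length(calls) == length(eps))
  post <- vapply(BASES, function(a) {
    0.25 * prod(ifelse(calls == a, 1 - eps, eps / 3))
  }, numeric(1))
  post / sum(post)
}

# Exhaustive identity-fraction scan over all candidate periods; same tie rule
# as the implementation (strictly greater f wins, so the smallest P is kept).
period_oracle <- function(bases, min_period, max_period = NULL) {
  a <- strsplit(bases, "")[[1]]
  L <- length(a)
  if (is.null(max_period)) max_period <- L %/% 2L
  if (L < 2 * min_period || max_period < min_period) return(NULL)
  bestP <- NA_integer_; bestf <- -1
  for (P in min_period:max_period) {
    x <- a[seq_len(L - P)]
    y <- a[seq_len(L - P) + P]
    ok <- x != "N" & y != "N"
    f <- if (any(ok)) sum(x[ok] == y[ok]) / sum(ok) else 0
    if (f > bestf + 1e-12) { bestf <- f; bestP <- P }
  }
  list(period = bestP, identity = bestf, repeats = L %/% bestP)
}

# Brute-force codon tally over the concatenated sense-strand CDS sequences.
codon_tally_oracle <- function(genome) {
  cds <- genome$features[genome$features$kind == "cds" & genome$features$valid_cds, ]
  s <- paste(vapply(seq_len(nrow(cds)), function(i)
    feature_sequence(genome, cds[i, ]), character(1)), collapse = "")
  counts <- setNames(numeric(64), all_codons(genome$code_table_id))
  for (i in seq(1, nchar(s), 3)) {
    cd <- substr(s, i, i + 2)
    counts[cd] <- counts[cd] + 1
  }
  counts / sum(counts)
}

# Exhaustive 64-codon x 9-change expectation of effect fractions.
expected_effect_oracle <- function(rates, usage, code_table) {
  gc_tab <- genetic_code_table(code_table)
  tot <- c(synonymous = 0, missense = 0, nonsense = 0, other = 0)
  for (cd in names(gc_tab)) {
    ej <- numeric(0); eff <- character(0)
    for (p in 1:3) {
      refb <- substr(cd, p, p)
      for (b in setdiff(BASES, refb)) {
        alt_cd <- cd
        substr(alt_cd, p, p) <- b
        aa_r <- gc_tab[[cd]]; aa_a <- gc_tab[[alt_cd]]
        e <- if (aa_r == "*" && aa_a != "*") "other"
          else if (aa_r != "*" && aa_a == "*") "nonsense"
          else if (aa_r == aa_a) "synonymous" else "missense"
        ej <- c(ej, rates[[paste0(refb, ">", b)]])
        eff <- c(eff, e)
      }
    }
    if (sum(ej) == 0) next
    mu <- ej / sum(ej)
    for (lv in names(tot)) tot[lv] <- tot[lv] + usage[[cd]] * sum(mu[eff == lv])
  }
  tot / sum(tot)
}

# One-off codon enumeration: all 64 codons x 3 positions x 3 substitutions.
one_off_oracle <- function(code_table) {
  gc_tab <- genetic_code_table(code_table)
  stops <- names(gc_tab)[gc_tab == "*"]
  hits <- character(0)
  for (cd in names(gc_tab)) {
    if (cd %in% stops) next
    for (p in 1:3) for (b in setdiff(BASES, substr(cd, p, p))) {
      x <- cd; substr(x, p, p) <- b
      if (x %in% stops) hits <- c(hits, cd)
    }
  }
  sort(unique(hits))
}

# A minimal two-gene genome used by several mapping/calling tests:
# one plus-strand CDS, one minus-strand CDS, and optionally an rRNA pair.
toy_genome <- function(seed = 1, cds_len = 90, rrna = FALSE, code_table = "11") {
  set.seed(seed)
  gc_tab <- genetic_code_table(code_table)
  stops <- names(gc_tab)[gc_tab == "*"]
  nonstop <- setdiff(names(gc_tab), stops)
  mk_cds <- function() paste(c("ATG", sample(nonstop, cds_len / 3 - 2, TRUE),
                               sample(stops, 1)), collapse = "")
  g1 <- mk_cds(); g2 <- mk_cds()
  feats <- data.frame(
    gene_id = c("geneA", "geneB"), replicon = "chr1",
    start = c(51, 51 + cds_len + 50), end = c(50 + cds_len, 50 + 2 * cds_len + 50),
    strand = c("+", "-"), kind = "cds", subkind = "cds",
    stringsAsFactors = FALSE)
  segs <- c(rand_dna(50), g1, rand_dna(50), as.character(revcomp(g2)))
  if (rrna) {
    rr <- rand_dna(200)
    p0 <- 2 * cds_len + 150   # 50 + cds + 50 + cds + 49, next base starts the rRNA
    feats <- rbind(feats, data.frame(
      gene_id = c("rrnaA", "rrnaB"), replicon = "chr1",
      start = c(p0, p0 + 250), end = c(p0 + 199, p0 + 449),
      strand = "+", kind = "ncRNA", subkind = "rRNA",
      stringsAsFactors = FALSE))
    segs <- c(segs, rand_dna(49), rr, rand_dna(50), rr)
  }
  segs <- c(segs, rand_dna(50))
  annotated_genome(c(chr1 = paste(segs, collapse = "")), feats, code_table)
}

# Build a perfect rolling-circle read from a fragment: rotate by `rot`, tile
# to `read_len`, constant quality `q`.
rolling_read <- function(frag, rot = 0, read_len = 300, q = 38) {
  P <- nchar(frag)
  rf <- paste0(substr(frag, rot + 1, P), substr(frag, 1, rot))
  seq <- substr(strrep(rf, ceiling(read_len / P)), 1, read_len)
  list(seq = seq, qual = strrep(phred_chr(q), read_len))
}

reads_df <- function(rr, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(rr))
  data.frame(read_id = ids,
             seq = vapply(rr, `[[`, character(1), "seq"),
             qual = vapply(rr, `[[`, character(1), "qual"),
             stringsAsFactors = FALSE)
}

# Construct a site_pileup-compatible data.table directly (unit tests for the
# calling filters).
make_pileup <- function(...) {
  rows <- list(...)
  dt <- data.table::rbindlist(lapply(rows, function(r) {
    base <- list(replicon = "chr1", pos = 1L, strand = "+", ref = "A",
                 nA = 0L, nC = 0L, nG = 0L, nT = 0L, ins = 0L, del = 0L,
                 n = 0L, gene_id = NA_character_, class = "other")
    base[names(r)] <- r
    base$n <- base$nA + base$nC + base$nG + base$nT
    base
  }))
  data.table::setattr(dt, "class", c("site_pileup", class(dt)))
  dt
}
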