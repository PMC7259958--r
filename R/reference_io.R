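#' Load and index a reference genome with its annotation
#'
#' Reads a (multi-record) FASTA and a GFF3 annotation into an annotated-genome
#' object used by all downstream stages. Sequences are upper-cased and non-ACGT
#' bases are masked to `N`. Features of GFF type `CDS`, `rRNA`, `tRNA` and
#' `ncRNA` are recognized; all other feature types are ignored (their count is
#' reported in the returned object). CDS features whose length is not a
#' multiple of 3 are kept but flagged invalid and excluded from effect
#' annotation.
#'
#' Coordinates are 1-based inclusive on the reference strand throughout.
#' Transcript coordinates run 5'->3' on the sense strand of each feature.
#'
#' @param fasta_path path to the reference FASTA.
#' @param gff_path path to the GFF3 annotation.
#' @param code_table NCBI genetic-code table identifier (e.g. `"11"` for
#'   bacteria, `"4"` for Mollicutes where UGA encodes Trp). There is no safe
#'   universal default across bacteria, so the caller must choose.
#' @return An object of class `annotated_genome`: a list with `sequences`
#'   (named character vector of replicons), `features` (data.frame with
#'   `gene_id`, `replicon`, `start`, `end`, `strand`, `kind`, `subkind`,
#'   `valid_cds`), `code_table_id`, `genetic_code`, and `n_skipped_features`.
#' @export
load_reference <- function(fasta_path, gff_path, code_table) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqchar <- toupper(as.character(seqs))
  seqchar <- gsub("[^ACGT]", "N", seqchar)

  gff <- rtracklayer::import(gff_path, format = "gff3")
  keep_types <- c("CDS", "rRNA", "tRNA", "ncRNA")
  type <- as.character(gff$type)
  n_skipped <- sum(!type %in% keep_types)
  gff <- gff[type %in% keep_types]
  type <- as.character(gff$type)

  missing_rep <- setdiff(unique(as.character(GenomicRanges::seqnames(gff))),
                         names(seqchar))
  if (length(missing_rep) > 0) {
    stop("annotation references replicon(s) absent from FASTA: ",
         paste(missing_rep, collapse = ", "))
  }

  ids <- .feature_ids(gff)
  feats <- data.frame(
    gene_id = ids,
    replicon = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    kind = ifelse(type == "CDS", "cds", "ncRNA"),
    subkind = ifelse(type == "CDS", "cds",
                     ifelse(type == "rRNA", "rRNA",
                            ifelse(type == "tRNA", "tRNA", "other"))),
    stringsAsFactors = FALSE
  )
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  annotated_genome(seqchar, feats, code_table, n_skipped = n_skipped)
}

.feature_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else
    rep(NA_character_, length(gr))
  id <- pick("locus_tag")
  for (col in c("gene", "Name", "ID")) {
    alt <- pick(col)
    id <- ifelse(is.na(id) | id == "", alt, id)
  }
  fallback <- paste0("feature_", seq_along(gr))
  ifelse(is.na(id) | id == "", fallback, id)
}

#' Construct an annotated genome from in-memory components
#'
#' Constructor shared by [load_reference()] and the simulator. Validates
#' feature coordinates against their replicons and flags CDS features whose
#' strand-resolved length is not a multiple of 3.
#'
#' @param sequences named character vector (or `DNAStringSet`) of replicon
#'   sequences.
#' @param features data.frame with columns `gene_id`, `replicon`, `start`,
#'   `end`, `strand`, `kind` (`cds`/`ncRNA`) and optionally `subkind`.
#' @param code_table NCBI genetic-code table id.
#' @param n_skipped count of ignored annotation records (bookkeeping).
#' @return `annotated_genome` object.
#' @export
annotated_genome <- function(sequences, features, code_table, n_skipped = 0L) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || anyNA(names(sequences))) {
    stop("replicon sequences must be named")
  }
  stopifnot(is.data.frame(features))
  if (!"subkind" %in% names(features)) {
    features$subkind <- ifelse(features$kind == "cds", "cds", "other")
  }
  bad_rep <- setdiff(features$replicon, names(sequences))
  if (length(bad_rep) > 0) {
    stop("features reference unknown replicon(s): ",
         paste(bad_rep, collapse = ", "))
  }
  rlen <- nchar(sequences)[features$replicon]
  if (any(features$start < 1 | features$end > rlen | features$start > features$end)) {
    stop("feature coordinates outside replicon bounds")
  }
  if (!all(features$kind %in% c("cds", "ncRNA"))) {
    stop("feature kind must be 'cds' or 'ncRNA'")
  }
  width <- features$end - features$start + 1L
  features$valid_cds <- features$kind == "cds" & width %% 3L == 0L
  n_bad <- sum(features$kind == "cds" & !features$valid_cds)
  if (n_bad > 0) {
    warning(n_bad, " CDS feature(s) with length not divisible by 3; ",
            "flagged and excluded from effect annotation")
  }
  gc_tab <- genetic_code_table(code_table)
  structure(
    list(sequences = sequences, features = features,
         code_table_id = as.character(code_table), genetic_code = gc_tab,
         n_skipped_features = as.integer(n_skipped)),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", length(x$sequences), "replicon(s),",
      sum(nchar(x$sequences)), "nt;",
      sum(x$features$kind == "cds"), "CDS,",
      sum(x$features$kind == "ncRNA"), "ncRNA features;",
      "genetic code table", x$code_table_id, "\n")
  invisible(x)
}

#' NCBI genetic-code table
#'
#' @param code_table NCBI translation-table id (character or integer).
#' @return Named character vector mapping the 64 codons to amino acids
#'   (`*` = stop).
#' @export
genetic_code_table <- function(code_table) {
  out <- tryCatch(
    Biostrings::getGeneticCode(as.character(code_table)),
    error = function(e) stop("unknown genetic-code table: ", code_table)
  )
  out[order(names(out))]
}

#' Sense-strand sequence of a feature
#'
#' @param genome `annotated_genome`.
#' @param feature a single row of `genome$features` (or gene id).
#' @return Character scalar, 5'->3' on the sense strand.
#' @export
feature_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    feature <- genome$features[genome$features$gene_id == feature, , drop = FALSE]
    if (nrow(feature) != 1) stop("gene id not found or not unique")
  }
  s <- substr(genome$sequences[[feature$replicon]], feature$start, feature$end)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a nucleotide string
#' @param x character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between transcript and reference coordinates
#'
#' Transcript coordinates are 1-based and run 5'->3' on the sense strand of
#' the feature; reference coordinates are 1-based on the reference strand.
#'
#' @param feature one row of an `annotated_genome` feature table.
#' @param tpos transcript position(s).
#' @param rpos reference position(s).
#' @return Integer vector of converted positions.
#' @export
transcript_to_ref <- function(feature, tpos) {
  w <- feature$end - feature$start + 1L
  if (any(tpos < 1 | tpos > w)) stop("transcript position outside feature")
  as.integer(if (feature$strand == "+") feature$start + tpos - 1L else
    feature$end - tpos + 1L)
}

#' @rdname transcript_to_ref
#' @export
ref_to_transcript <- function(feature, rpos) {
  if (any(rpos < feature$start | rpos > feature$end)) {
    stop("reference position outside feature")
  }
  as.integer(if (feature$strand == "+") rpos - feature$start + 1L else
    feature$end - rpos + 1L)
}

#' Codon usage of an annotated genome
#'
#' Tallies codons over all valid CDS features (sense strand, stop codons
#' included) and normalizes to frequencies over the 64 codons.
#'
#' @param genome `annotated_genome`.
#' @return Named numeric vector of length 64 summing to 1 (zero-frequency
#'   codons present), with attribute `total_codons`.
#' @export
codon_usage <- function(genome) {
  cds <- genome$features[genome$features$kind == "cds" & genome$features$valid_cds, ,
                         drop = FALSE]
  if (nrow(cds) == 0) stop("no valid CDS features; cannot compute codon usage")
  codons <- all_codons(genome$code_table_id)
  counts <- stats::setNames(numeric(64), codons)
  for (i in seq_len(nrow(cds))) {
    s <- feature_sequence(genome, cds[i, ])
    cc <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    cc <- cc[!grepl("N", cc, fixed = TRUE)]
    tab <- table(cc)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  total <- sum(counts)
  if (total == 0) stop("no codons tallied")
  structure(counts / total, total_codons = total)
}

#' All 64 codons in the table order of a genetic code
#' @param code_table NCBI translation-table id.
#' @return Character vector of the 64 codons.
#' @export
all_codons <- function(code_table = "11") {
  names(genetic_code_table(code_table))
}

#' Codons one substitution away from a stop codon
#'
#' Returns every non-stop codon that differs from at least one stop codon of
#' the given genetic code at exactly one position ("one-off codons"). Stop
#' codons themselves are excluded even when they are one substitution from
#' another stop codon.
#'
#' @param code_table NCBI translation-table id.
#' @return Sorted character vector of one-off codons.
#' @export
one_off_codon_set <- function(code_table) {
  gc_tab <- genetic_code_table(code_table)
  stops <- names(gc_tab)[gc_tab == "*"]
  if (length(stops) == 0) stop("genetic code table has no stop codons")
  bases <- c("A", "C", "G", "T")
  neighb <- unique(unlist(lapply(stops, function(s) {
    out <- character(0)
    for (pos in 1:3) {
      for (b in bases) {
        if (substr(s, pos, pos) == b) next
        x <- s
        substr(x, pos, pos) <- b
        out <- c(out, x)
      }
    }
    out
  })))
  sort(setdiff(neighb, stops))
}
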