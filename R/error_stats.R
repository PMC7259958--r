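#' Classify the coding effect of a substitution
#'
#' Compares the reference codon to the error codon under the genome's genetic
#' code. Errors in ncRNA or unannotated positions are `noncoding`; errors in a
#' CDS flagged for invalid length are `unknown` and excluded from effect
#' tallies. A change in the initiation codon that destroys it (the altered
#' codon is no longer a start codon of the table) is `start_loss`; a change
#' that turns the stop codon into a coding codon is `stop_loss`.
#'
#' @param genome `annotated_genome`.
#' @param replicon replicon id.
#' @param pos 1-based reference position.
#' @param alt alternative base on the sense strand of the containing gene.
#' @param strand optional strand of the call, used to disambiguate overlapping
#'   genes on opposite strands.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`, `"start_loss"`,
#'   `"stop_loss"`, `"noncoding"`, `"unknown"`.
#' @export
classify_effect <- function(genome, replicon, pos, alt, strand = NULL) {
  ft <- genome$features
  cand <- which(ft$replicon == replicon & ft$start <= pos & ft$end >= pos &
                  (if (is.null(strand)) TRUE else ft$strand == strand))
  if (length(cand) == 0) return("noncoding")
  cds <- cand[ft$kind[cand] == "cds"]
  if (length(cds) == 0) return("noncoding")
  f <- ft[cds[1], ]
  if (!f$valid_cds) return("unknown")
  tpos <- ref_to_transcript(f, pos)
  tseq <- feature_sequence(genome, f)
  ci <- (tpos - 1L) %/% 3L
  off <- (tpos - 1L) %% 3L
  codon <- substr(tseq, ci * 3L + 1L, ci * 3L + 3L)
  if (grepl("N", codon, fixed = TRUE)) return("unknown")
  alt_codon <- codon
  substr(alt_codon, off + 1L, off + 1L) <- alt
  .codon_change_effect(codon, alt_codon, genome$genetic_code,
                       first_codon = ci == 0L)
}

.codon_change_effect <- function(ref_codon, alt_codon, gc_tab,
                                 first_codon = FALSE) {
  aa_ref <- gc_tab[[ref_codon]]
  aa_alt <- gc_tab[[alt_codon]]
  if (first_codon) {
    inits <- .init_codons(gc_tab)
    if (ref_codon %in% inits && !(alt_codon %in% inits)) return("start_loss")
  }
  if (aa_ref == "*" && aa_alt != "*") return("stop_loss")
  if (aa_ref != "*" && aa_alt == "*") return("nonsense")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

.init_codons <- function(gc_tab) {
  alt <- attr(gc_tab, "alt_init_codons")
  unique(c(names(gc_tab)[gc_tab == "M"], alt, "ATG"))
}

#' Annotate error calls with coding effects
#'
#' @param ec `error_calls`.
#' @param genome `annotated_genome`.
#' @return The `error_calls` object with an `effect` column added to `calls`.
#' @export
annotate_effects <- function(ec, genome) {
  calls <- ec$calls
  calls$effect <- vapply(seq_len(nrow(calls)), function(i)
    classify_effect(genome, calls$replicon[i], calls$pos[i], calls$alt[i],
                    calls$strand[i]), character(1))
  ec$calls <- calls
  ec
}

#' Expected effect percentages from codon usage and the substitution spectrum
#'
#' Under random error generation without error correction, the expected
#' fraction of effect class `E` is `sum_i P_i * P_i(E)` over the 64 codons,
#' where `P_i` is the codon-usage frequency and `P_i(E)` weights the 9
#' single-base changes of codon `i` by their normalized substitution
#' probabilities `mu_j = e_j / sum_j e_j` (the `e_j` being the conditional
#' rates of the corresponding base substitutions). Changes that create a stop
#' are `nonsense`; changes destroying a reference stop codon are tallied as
#' `other` (stop loss); a reference stop mutating into another stop is
#' synonymous. Start loss is positional and not representable in a per-codon
#' expectation; it is part of the residual `other` mass only through stop
#' codons here.
#'
#' @param spectrum `substitution_spectrum` (or data.frame with `from`, `to`,
#'   `rate`).
#' @param usage codon-usage vector from [codon_usage()].
#' @param code_table NCBI translation-table id.
#' @return list with `fractions` (named: synonymous, missense, nonsense,
#'   other; sums to 1), `percentages` (the same times 100), and `by_codon`
#'   (64 x 4 matrix of per-codon effect probabilities).
#' @export
expected_effect_percentages <- function(spectrum, usage, code_table) {
  gc_tab <- genetic_code_table(code_table)
  rates <- .spectrum_rate_lookup(spectrum)
  if (all(rates == 0)) stop("all-zero substitution spectrum")
  codons <- names(gc_tab)
  stopifnot(setequal(names(usage), codons))
  bases <- c("A", "C", "G", "T")
  eff_levels <- c("synonymous", "missense", "nonsense", "other")
  by_codon <- matrix(0, nrow = 64, ncol = 4,
                     dimnames = list(codons, eff_levels))
  for (cd in codons) {
    ej <- numeric(9)
    eff <- character(9)
    jj <- 0L
    for (p in 1:3) {
      refb <- substr(cd, p, p)
      for (b in setdiff(bases, refb)) {
        jj <- jj + 1L
        ej[jj] <- rates[[paste0(refb, ">", b)]]
        alt_cd <- cd
        substr(alt_cd, p, p) <- b
        e <- .codon_change_effect(cd, alt_cd, gc_tab)
        eff[jj] <- if (e %in% c("synonymous", "missense", "nonsense")) e else "other"
      }
    }
    tot <- sum(ej)
    if (tot == 0) next   # codon unreachable under this spectrum
    mu <- ej / tot
    for (lv in eff_levels) by_codon[cd, lv] <- sum(mu[eff == lv])
  }
  fr <- as.numeric(usage[codons] %*% by_codon)
  names(fr) <- eff_levels
  fr <- fr / sum(fr)
  list(fractions = fr, percentages = 100 * fr, by_codon = by_codon)
}

.spectrum_rate_lookup <- function(spectrum) {
  sp <- as.data.frame(spectrum)
  stopifnot(all(c("from", "to", "rate") %in% names(sp)))
  r <- sp$rate
  r[is.na(r)] <- 0
  stats::setNames(r, paste0(sp$from, ">", sp$to))
}

#' Observed effect percentages of coding substitutions
#'
#' Fractions among `synonymous`, `missense`, `nonsense` and `other`
#' (start/stop-loss) for effect-annotated calls in valid CDS. `noncoding` and
#' `unknown` calls are excluded.
#'
#' @param ec effect-annotated `error_calls` (see [annotate_effects()]).
#' @return list with `counts`, `fractions` and `percentages`.
#' @export
observed_effect_percentages <- function(ec) {
  stopifnot("effect" %in% names(ec$calls))
  eff <- ec$calls$effect
  k <- ec$calls$k   # each supporting call is one erroneous molecule
  counts <- c(synonymous = sum(k[eff == "synonymous"]),
              missense = sum(k[eff == "missense"]),
              nonsense = sum(k[eff == "nonsense"]),
              other = sum(k[eff %in% c("start_loss", "stop_loss")]))
  tot <- sum(counts)
  if (tot == 0) stop("no coding-effect calls")
  list(counts = counts, fractions = counts / tot,
       percentages = 100 * counts / tot)
}

#' Chi-squared test of observed effect counts against expected fractions
#'
#' @param observed named integer vector of observed counts.
#' @param expected expected fractions for the same categories (renormalized).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
observed_vs_expected_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2)
  if (sum(observed) == 0) stop("total observed count is zero")
  p <- expected / sum(expected)
  if (any(p <= 0)) {
    keep <- p > 0
    if (any(observed[!keep] > 0)) stop("observed counts in zero-expectation categories")
    observed <- observed[keep]; p <- p[keep] / sum(p[keep])
  }
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Test the transition/transversion bias of a substitution spectrum
#'
#' Tests whether transition counts exceed the expectation under rate equality
#' across the included substitution categories, weighting by the assayed
#' opportunity of each category (coverage of the mutated-from base). Specific
#' categories (e.g. `"C>T"`, i.e. C->U on the transcript) can be excluded to
#' ask whether the bias persists without them.
#'
#' @param spectrum `substitution_spectrum`.
#' @param exclude character vector of categories (`"X>Y"`) to exclude.
#' @return list with `statistic`, `df`, `p_value`, observed transition /
#'   transversion counts and their expected values.
#' @export
transition_bias_test <- function(spectrum, exclude = character(0)) {
  sp <- as.data.frame(spectrum)
  sp$cat <- paste0(sp$from, ">", sp$to)
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  sp <- sp[!sp$cat %in% exclude & !is.na(sp$rate), , drop = FALSE]
  if (nrow(sp) < 2 || length(unique(sp$cat %in% transitions)) < 2) {
    stop("need included categories of both transition and transversion type")
  }
  is_ts <- sp$cat %in% transitions
  obs <- c(transitions = sum(sp$count[is_ts]),
           transversions = sum(sp$count[!is_ts]))
  opp <- c(sum(sp$assayed[is_ts]), sum(sp$assayed[!is_ts]))
  if (any(opp == 0) || sum(obs) == 0) stop("insufficient counts/opportunity")
  ht <- suppressWarnings(stats::chisq.test(obs, p = opp / sum(opp)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), observed = obs,
       expected = sum(obs) * opp / sum(opp))
}

#' Per-gene Poisson enrichment of transcript errors
#'
#' For each gene, the expected error count is the transcriptome-wide error
#' rate times the gene's assayed coverage; the upper-tail Poisson probability
#' `P(X >= k)` is Bonferroni-corrected over the number of genes with at least
#' one detected error.
#'
#' @param ec `error_calls`.
#' @param genome `annotated_genome`.
#' @param rate transcriptome-wide per-nucleotide error rate; computed from
#'   `ec` when `NULL`.
#' @param alpha family-wise significance level.
#' @return data.frame: `gene_id`, `k`, `coverage`, `lambda`, `p`,
#'   `p_bonferroni`, `significant`, `anomalous` (errors with zero coverage —
#'   indicates an upstream bug).
#' @export
gene_enrichment <- function(ec, genome, rate = NULL, alpha = 0.05) {
  sites <- data.table::as.data.table(ec$sites)[!is.na(gene_id)]
  cov <- sites[, list(coverage = sum(as.numeric(n))), by = "gene_id"]
  calls <- ec$calls[!is.na(ec$calls$gene_id), , drop = FALSE]
  kk <- tapply(calls$k, calls$gene_id, sum)
  cov$k <- as.integer(kk[cov$gene_id])
  cov$k[is.na(cov$k)] <- 0L
  if (is.null(rate)) {
    rate <- sum(ec$calls$k) / sum(as.numeric(ec$sites$n))
  }
  poisson_enrichment(cov$k, cov$coverage, rate, alpha, gene_id = cov$gene_id)
}

#' Poisson enrichment core on per-gene summaries
#'
#' @param k observed error counts per gene.
#' @param coverage assayed coverage per gene.
#' @param rate transcriptome-wide per-nucleotide error rate.
#' @param alpha family-wise significance level.
#' @param gene_id optional gene identifiers.
#' @return data.frame as in [gene_enrichment()].
#' @export
poisson_enrichment <- function(k, coverage, rate, alpha = 0.05,
                               gene_id = NULL) {
  stopifnot(length(k) == length(coverage))
  lambda <- rate * coverage
  p <- stats::ppois(k - 1, lambda, lower.tail = FALSE)   # P(X >= k); k=0 -> 1
  anomalous <- lambda == 0 & k > 0
  m <- sum(k > 0)
  p_bonf <- pmin(1, p * max(m, 1L))
  data.frame(
    gene_id = if (is.null(gene_id)) paste0("gene_", seq_along(k)) else gene_id,
    k = k, coverage = coverage, lambda = lambda, p = p,
    p_bonferroni = p_bonf,
    significant = k > 0 & p_bonf <= alpha,
    anomalous = anomalous, stringsAsFactors = FALSE)
}

#' Positional series of nonsense errors along mRNAs
#'
#' Each assayed CDS site upstream of the original stop codon contributes its
#' distance to the stop (nt from the first base of the stop codon, counting
#' upstream along the mRNA), its coverage, and its nonsense-error count.
#' Frequencies are pooled across genes per distance. A 100-nt sliding window
#' (visualization only) and two normalization variants are provided: the
#' nonsense-error frequency divided by the all-error frequency, and divided by
#' the coverage-weighted abundance of one-off codons (non-stop codons one
#' substitution away from a stop).
#'
#' Distance points with zero nonsense errors keep finite regression weights
#' through the continuity-corrected frequency `(k + 0.5) / (n + 1)` used for
#' the variance estimate `p(1-p)/n`.
#'
#' @param ec effect-annotated `error_calls`.
#' @param genome `annotated_genome`.
#' @param window sliding-window size (nt) for the visualization track.
#' @param step window step size (nt).
#' @return list with `points` (per-distance data.frame: `distance`, `k`, `n`,
#'   `k_all`, `p`, `variance`, `weight`, `norm_all`, `norm_oneoff`,
#'   `oneoff_cov`), `windows` (windowed series), and `n_genes` /
#'   `skipped_genes`.
#' @export
nonsense_distance_series <- function(ec, genome, window = 100L, step = 1L) {
  stopifnot("effect" %in% names(ec$calls))
  ft <- genome$features
  cds <- ft[ft$kind == "cds" & ft$valid_cds, , drop = FALSE]
  oneoff <- one_off_codon_set(genome$code_table_id)
  sites <- data.table::as.data.table(ec$sites)
  calls <- data.table::as.data.table(ec$calls)
  pts <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(cds))) {
    f <- cds[i, ]
    tseq <- feature_sequence(genome, f)
    w <- nchar(tseq)
    last_codon <- substr(tseq, w - 2L, w)
    if (is.na(genome$genetic_code[last_codon]) ||
        genome$genetic_code[[last_codon]] != "*") {
      skipped <- c(skipped, f$gene_id)
      next
    }
    ss <- sites[gene_id == f$gene_id & n > 0L]
    if (nrow(ss) == 0) next
    tpos <- ref_to_transcript(f, ss$pos)
    stop_tpos <- w - 2L
    d <- stop_tpos - tpos
    keep <- d >= 1L
    if (!any(keep)) next
    ss <- ss[keep]; tpos <- tpos[keep]; d <- d[keep]
    codon_start <- ((tpos - 1L) %/% 3L) * 3L + 1L
    codons <- substr(rep(tseq, length(tpos)), codon_start, codon_start + 2L)
    in_oneoff <- codons %in% oneoff
    cl <- calls[gene_id == f$gene_id]
    k_non <- integer(nrow(ss)); k_all <- integer(nrow(ss))
    if (nrow(cl) > 0) {
      key <- paste(ss$replicon, ss$pos)
      non <- cl[cl$effect == "nonsense", ]
      nn <- tapply(non$k, paste(non$replicon, non$pos), sum)
      aa <- tapply(cl$k, paste(cl$replicon, cl$pos), sum)
      k_non <- as.integer(nn[key]); k_non[is.na(k_non)] <- 0L
      k_all <- as.integer(aa[key]); k_all[is.na(k_all)] <- 0L
    }
    pts[[length(pts) + 1]] <- data.table::data.table(
      distance = d, n = ss$n, k = k_non, k_all = k_all,
      oneoff_cov = ifelse(in_oneoff, ss$n, 0L))
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " CDS without a terminal stop codon skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  if (length(pts) == 0) stop("no assayed CDS sites upstream of a stop codon")
  all_pts <- data.table::rbindlist(pts)
  agg <- all_pts[, list(k = sum(k), n = sum(as.numeric(n)),
                        k_all = sum(k_all),
                        oneoff_cov = sum(as.numeric(oneoff_cov))),
                 by = "distance"]
  data.table::setorder(agg, distance)
  agg$p <- agg$k / agg$n
  ptil <- (agg$k + 0.5) / (agg$n + 1)
  agg$variance <- ptil * (1 - ptil) / agg$n
  agg$weight <- 1 / agg$variance
  agg$norm_all <- ifelse(agg$k_all > 0, agg$p / (agg$k_all / agg$n), NA_real_)
  agg$norm_oneoff <- ifelse(agg$oneoff_cov > 0,
                            agg$p / (agg$oneoff_cov / agg$n), NA_real_)
  pointsdf <- as.data.frame(agg)

  dmax <- max(agg$distance)
  starts <- seq(1L, max(1L, dmax - window + 1L), by = step)
  kcum <- ncum <- acum <- ocum <- numeric(dmax + 1L)
  kcum[agg$distance + 1L] <- agg$k
  ncum[agg$distance + 1L] <- agg$n
  acum[agg$distance + 1L] <- agg$k_all
  ocum[agg$distance + 1L] <- agg$oneoff_cov
  kcum <- cumsum(kcum); ncum <- cumsum(ncum)
  acum <- cumsum(acum); ocum <- cumsum(ocum)
  wend <- pmin(starts + window - 1L, dmax)
  wk <- kcum[wend + 1L] - kcum[starts]
  wn <- ncum[wend + 1L] - ncum[starts]
  wa <- acum[wend + 1L] - acum[starts]
  wo <- ocum[wend + 1L] - ocum[starts]
  windows <- data.frame(
    start = starts, end = wend, k = wk, n = wn,
    p = ifelse(wn > 0, wk / wn, NA_real_),
    sd = ifelse(wn > 0, sqrt(pmax(wk / wn * (1 - wk / wn), 0) / pmax(wn, 1)), NA_real_),
    norm_all = ifelse(wa > 0, (wk / wn) / (wa / wn), NA_real_),
    norm_oneoff = ifelse(wo > 0, (wk / wn) / (wo / wn), NA_real_))
  list(points = pointsdf, windows = windows,
       n_genes = length(pts), skipped_genes = skipped)
}

#' Weighted linear regression of error frequency on distance to the stop codon
#'
#' Weighted least squares of the per-distance frequencies on distance, with
#' weights equal to the reciprocal binomial variance `p(1-p)/n` (continuity
#' corrected at `p = 0`). Individual (unbinned) distance points are used, not
#' the sliding-window series.
#'
#' @param points data.frame with columns `distance` (or `x`), `p` (or `y`) and
#'   `weight` (or `w`).
#' @return list with `slope`, `intercept`, `p_value` (two-sided, slope),
#'   `stderr`, `n`.
#' @export
weighted_regression <- function(points) {
  x <- if ("distance" %in% names(points)) points$distance else points$x
  y <- if ("p" %in% names(points)) points$p else points$y
  w <- if ("weight" %in% names(points)) points$weight else points$w
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3) stop("need at least 3 points with finite weights")
  if (length(unique(x)) < 2) stop("slope undefined: all x identical")
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = sm$coefficients[2, 4], stderr = sm$coefficients[2, 2],
       n = length(x))
}

#' Expected contamination from low-frequency genetic mutations
#'
#' Genetic mutations that arise during cell culture are sampled by the assay
#' like transcript errors; their expected contribution is `mu * g` errors per
#' transcribed site (mutation rate per site per generation times generations
#' of growth), which as a fraction of the measured transcript-error rate is
#' `mu * g / rate`.
#'
#' @param mu per-site per-generation genomic mutation rate.
#' @param g number of generations during culture growth.
#' @param rate measured transcript-error rate per site.
#' @return The contamination fraction. A warning is emitted when it reaches 1.
#' @export
contamination_fraction <- function(mu, g, rate) {
  stopifnot(mu > 0, g >= 0, rate > 0)
  fr <- mu * g / rate
  if (fr >= 1) warning("contamination fraction >= 1: ",
                       "genetic mutations could explain all observed errors")
  fr
}
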