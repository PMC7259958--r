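test_that("coding effects are classified under the genome's genetic code", {
  # CDS: ATG | CAA | GCT | TGG | TAA on the plus strand
  cds <- "ATGCAAGCTTGGTAA"
  mk <- function(tab) annotated_genome(
    c(chr1 = paste0("GGGGG", cds, "GGGGG")),
    data.frame(gene_id = "g1", replicon = "chr1", start = 6L, end = 20L,
               strand = "+", kind = "cds", subkind = "cds",
               stringsAsFactors = FALSE), tab)
  g11 <- mk("11")
  # CAA -> TAA (position 4 of CDS, ref C -> T): Gln to stop
  expect_equal(classify_effect(g11, "chr1", 9L, "T"), "nonsense")
  # GCT -> GCC: Ala to Ala
  expect_equal(classify_effect(g11, "chr1", 13L, "C"), "synonymous")
  # TGG -> TGA: stop under table 11, Trp under table 4
  expect_equal(classify_effect(g11, "chr1", 17L, "A"), "nonsense")
  g4 <- mk("4")
  expect_equal(classify_effect(g4, "chr1", 17L, "A"), "synonymous")
  # ATG -> ATA destroys the start codon
  expect_equal(classify_effect(g11, "chr1", 8L, "A"), "start_loss")
  # TAA -> CAA destroys the stop codon
  expect_equal(classify_effect(g11, "chr1", 18L, "C"), "stop_loss")
  # outside any CDS
  expect_equal(classify_effect(g11, "chr1", 2L, "C"), "noncoding")
})

test_that("effects in length-flagged CDS are unknown and excluded", {
  feats <- data.frame(gene_id = "bad", replicon = "chr1", start = 6L,
                      end = 15L, strand = "+", kind = "cds", subkind = "cds",
                      stringsAsFactors = FALSE)
  expect_warning(g <- annotated_genome(c(chr1 = strrep("ACGT", 10)), feats, "11"))
  expect_equal(classify_effect(g, "chr1", 8L, "C"), "unknown")
})

test_that("a single-codon usage with one open channel forces missense", {
  usage <- setNames(numeric(64), all_codons("11"))
  usage["AAA"] <- 1
  sp <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  sp <- sp[sp$from != sp$to, ]
  sp$rate <- ifelse(sp$from == "A" & sp$to == "C", 1e-5, 0)
  ee <- expected_effect_percentages(sp, usage, "11")
  # AAA with only A->C available: CAA, ACA, AAC are all missense
  expect_equal(unname(ee$fractions["missense"]), 1)
  expect_equal(sum(ee$fractions), 1)
})

test_that("expected effects equal the exhaustive 64x9 enumeration oracle", {
  set.seed(51)
  cats <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  cats <- cats[cats$from != cats$to, ]
  for (i in 1:20) {
    sp <- cats
    sp$rate <- runif(12, 0, 1e-5)
    u <- runif(64); u <- u / sum(u)
    usage <- setNames(u, all_codons("11"))
    tab <- sample(c("11", "4", "1"), 1)
    ee <- expected_effect_percentages(sp, usage, tab)
    orc <- expected_effect_oracle(setNames(sp$rate, paste0(sp$from, ">", sp$to)),
                                  usage, tab)
    expect_equal(ee$fractions, orc, tolerance = 1e-12)
    expect_equal(sum(ee$fractions), 1, tolerance = 1e-12)
  }
  # uniform usage, uniform spectrum
  sp <- cats; sp$rate <- 1e-6
  usage <- setNames(rep(1 / 64, 64), all_codons("11"))
  ee <- expected_effect_percentages(sp, usage, "11")
  orc <- expected_effect_oracle(setNames(sp$rate, paste0(sp$from, ">", sp$to)),
                                usage, "11")
  expect_equal(ee$fractions, orc, tolerance = 1e-12)
  expect_error(expected_effect_percentages(
    within(sp, rate <- 0), usage, "11"), "all-zero")
})

test_that("observed-vs-expected chi-squared matches closed forms", {
  r <- observed_vs_expected_test(c(50, 50), c(0.5, 0.5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- observed_vs_expected_test(c(30, 60, 10), c(0.3, 0.6, 0.1))
  expect_equal(r$statistic, 0)
  r <- observed_vs_expected_test(c(60, 40), c(0.5, 0.5))
  expect_equal(r$statistic, 4)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0455, tolerance = 1e-3)
  expect_error(observed_vs_expected_test(c(0, 0), c(0.5, 0.5)), "zero")
})

test_that("transition bias test detects planted bias and handles the null", {
  mk_spec <- function(rates, assayed = 1e6) {
    cats <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
    cats <- cats[cats$from != cats$to, ]
    cats <- cats[order(cats$from, cats$to), ]
    cats$assayed <- assayed
    cats$count <- round(rates * assayed)
    cats$rate <- cats$count / cats$assayed
    cats
  }
  # exact rate equality: statistic 0
  sp0 <- mk_spec(rep(2e-5, 12))
  r0 <- transition_bias_test(sp0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # transitions at 3x the transversion rate, C->U excluded, still detected
  rates <- rep(1e-5, 12)
  names(rates) <- paste0(sp0$from, ">", sp0$to)
  rates[c("A>G", "G>A", "C>T", "T>C")] <- 3e-5
  sp1 <- mk_spec(rates)
  r1 <- transition_bias_test(sp1, exclude = "C>T")
  expect_lt(r1$p_value, 0.005)
  expect_gt(r1$observed["transitions"], r1$expected[1])
  # excluding everything but one category is undefined
  expect_error(transition_bias_test(sp1[sp1$from == "A" & sp1$to == "G", ]),
               "transversion")
})

test_that("Poisson enrichment matches the closed-form tail and flags planting", {
  # P(X >= 5 | lambda = 1) = 1 - e^-1 (1 + 1 + 1/2 + 1/6 + 1/24)
  pe <- poisson_enrichment(k = 5L, coverage = 1, rate = 1)
  expect_equal(pe$p, 1 - exp(-1) * (1 + 1 + 1 / 2 + 1 / 6 + 1 / 24),
               tolerance = 1e-12)
  expect_equal(round(pe$p, 5), 0.00366)
  expect_equal(poisson_enrichment(0L, 100, 1e-5)$p, 1)
  # one gene planted at 10x the global rate among 200 genes
  set.seed(61)
  cov <- rep(1e5, 200)
  rate <- 5e-6
  k <- rpois(200, rate * cov)
  k[17] <- rpois(1, 10 * rate * cov[17])
  pe <- poisson_enrichment(k, cov, rate)
  expect_true(pe$significant[17])
  expect_equal(sum(pe$significant), 1)
  # errors with zero coverage are anomalous
  expect_true(poisson_enrichment(2L, 0, 1e-5)$anomalous)
})

test_that("nonsense distance series conserves counts and distances", {
  # single plus-strand gene; construct an annotated error set directly
  set.seed(71)
  nonstop <- setdiff(all_codons("11"),
                     names(genetic_code_table("11"))[genetic_code_table("11") == "*"])
  cds <- paste(c("ATG", sample(nonstop, 98, TRUE), "TAA"), collapse = "")
  g <- annotated_genome(
    c(chr1 = paste0(strrep("G", 10), cds, strrep("G", 10))),
    data.frame(gene_id = "g1", replicon = "chr1", start = 11L,
               end = 10L + nchar(cds), strand = "+", kind = "cds",
               subkind = "cds", stringsAsFactors = FALSE), "11")
  w <- nchar(cds)
  sites <- data.table::data.table(
    replicon = "chr1", pos = 11L:(10L + w), strand = "+",
    ref = strsplit(cds, "")[[1]],
    nA = 0L, nC = 0L, nG = 0L, nT = 0L, ins = 0L, del = 0L, n = 1000L,
    gene_id = "g1", class = "cds")
  # nonsense errors only within the last 100 nt upstream of the stop
  stop_t <- w - 2L
  tpos_non <- c(stop_t - 5L, stop_t - 50L, stop_t - 99L)
  calls <- data.frame(
    replicon = "chr1", pos = 10L + c(tpos_non, 30L), strand = "+",
    gene_id = "g1", class = "cds", ref = "C", alt = "T",
    k = c(2L, 1L, 1L, 3L), n = 1000L,
    effect = c("nonsense", "nonsense", "nonsense", "missense"),
    stringsAsFactors = FALSE)
  ec <- structure(list(calls = calls, sites = sites, counts = c()),
                  class = "error_calls")
  ns <- nonsense_distance_series(ec, g)
  expect_equal(sum(ns$points$k), 4)                 # all nonsense molecules
  expect_true(all(ns$points$distance[ns$points$k > 0] < 100))
  expect_equal(sort(ns$points$distance[ns$points$k > 0]), c(5, 50, 99))
  # weights are finite everywhere, including k = 0 points
  expect_true(all(is.finite(ns$points$weight) & ns$points$weight > 0))
  # all-error normalization at the missense site distance
  d30 <- stop_t - 30L
  expect_equal(ns$points$k_all[ns$points$distance == d30], 3)
})

test_that("one-off normalization flattens a series tracking one-off abundance", {
  # gene whose 3' half is rich in one-off codons: nonsense mass proportional
  # to one-off coverage cancels in the normalized series
  oneoff <- one_off_codon_set("11")
  nononeoff <- setdiff(setdiff(all_codons("11"), oneoff),
                       names(genetic_code_table("11"))[genetic_code_table("11") == "*"])
  set.seed(72)
  cds <- paste(c("ATG", sample(nononeoff, 50, TRUE),
                 sample(oneoff, 49, TRUE), "TAA"), collapse = "")
  g <- annotated_genome(
    c(chr1 = paste0(strrep("G", 10), cds, strrep("G", 10))),
    data.frame(gene_id = "g1", replicon = "chr1", start = 11L,
               end = 10L + nchar(cds), strand = "+", kind = "cds",
               subkind = "cds", stringsAsFactors = FALSE), "11")
  w <- nchar(cds)
  tref <- strsplit(cds, "")[[1]]
  sites <- data.table::data.table(
    replicon = "chr1", pos = 11L:(10L + w), strand = "+", ref = tref,
    nA = 0L, nC = 0L, nG = 0L, nT = 0L, ins = 0L, del = 0L, n = 500L,
    gene_id = "g1", class = "cds")
  # plant one nonsense molecule at every site inside a one-off codon
  codon_idx <- (seq_len(w) - 1L) %/% 3L
  codons <- substring(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  in_oneoff <- codons %in% oneoff
  sel <- which(in_oneoff & seq_len(w) < w - 2L)
  calls <- data.frame(
    replicon = "chr1", pos = 10L + sel, strand = "+", gene_id = "g1",
    class = "cds", ref = tref[sel], alt = "A", k = 1L, n = 500L,
    effect = "nonsense", stringsAsFactors = FALSE)
  ec <- structure(list(calls = calls, sites = sites, counts = c()),
                  class = "error_calls")
  ns <- nonsense_distance_series(ec, g)
  norm <- ns$points$norm_oneoff[!is.na(ns$points$norm_oneoff) & ns$points$k > 0]
  expect_gt(length(norm), 10)
  expect_equal(norm, rep(norm[1], length(norm)))   # exactly flat
})

test_that("weighted regression matches closed forms and OLS with equal weights", {
  # constant response: zero slope (summary warns about the degenerate fit)
  r <- suppressWarnings(
    weighted_regression(data.frame(distance = 1:10, p = rep(0.3, 10),
                                   weight = runif(10, 1, 2))))
  expect_equal(r$slope, 0, tolerance = 1e-12)
  # exact linear fit: slope recovered, p -> 0
  r <- suppressWarnings(
    weighted_regression(data.frame(distance = 1:10, p = 2 * (1:10),
                                   weight = rep(1, 10))))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-12)
  # equal weights reproduce ordinary least squares
  set.seed(81)
  x <- 1:30; y <- 0.01 - 1e-4 * x + rnorm(30, 0, 1e-3)
  rw <- weighted_regression(data.frame(distance = x, p = y, weight = rep(5, 30)))
  ols <- lm(y ~ x)
  expect_equal(rw$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(rw$p_value, summary(ols)$coefficients[2, 4], tolerance = 1e-9)
  expect_error(weighted_regression(data.frame(distance = rep(1, 5),
                                              p = rnorm(5), weight = 1)),
               "identical")
  expect_error(weighted_regression(data.frame(distance = 1:2, p = 1:2,
                                              weight = 1)), "3 points")
})

test_that("genetic-mutation contamination fraction follows mu*g/rate", {
  expect_equal(contamination_fraction(1e-10, 30, 5.84e-6),
               1e-10 * 30 / 5.84e-6)
  expect_equal(round(contamination_fraction(1e-10, 30, 5.84e-6), 7), 5.137e-4)
  expect_equal(contamination_fraction(1e-10, 0, 5.84e-6), 0)
  expect_warning(f <- contamination_fraction(1e-7, 30, 3e-6), "fraction")
  expect_equal(f, 1)
})
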