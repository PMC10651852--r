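# two-gene fixture: g1 (+) with three exons, g2 (-) downstream antisense
context_annotation <- function() {
  tibble::tibble(
    gene_id = c(rep("g1", 3), rep("g2", 2)),
    transcript_id = c(rep("g1.t1", 3), rep("g2.t1", 2)),
    chrom = "chr1",
    strand = c(rep("+", 3), rep("-", 2)),
    feature = "exon",
    exon_rank = c(1:3, 1:2),
    start = c(1000L, 2500L, 5000L, 9000L, 7800L),
    end = c(1499L, 2899L, 6000L, 9399L, 8199L))
}

test_that("introns are derived with sense-aware splice sites", {
  introns <- annotation_introns(context_annotation())
  g1 <- introns[introns$strand == "+", ]
  expect_equal(nrow(g1), 2)
  expect_equal(g1$ss5_pos, c(1500L, 2900L))
  expect_equal(g1$ss3_pos, c(2499L, 4999L))
  expect_equal(g1$intron_size, c(1000L, 2100L))
  expect_equal(g1$is_last_intron, c(FALSE, TRUE))
  g2 <- introns[introns$strand == "-", ]
  expect_equal(g2$ss5_pos, 8999L)   # first intronic base in sense
  expect_equal(g2$ss3_pos, 8200L)
  expect_true(g2$is_last_intron)
})

test_that("intronic sites split into composite and skipped types", {
  ann <- context_annotation()
  sites <- tibble::tibble(chrom = "chr1", pos = c(2000L, 4000L),
                          strand = "+")
  # no junction evidence: both composite
  jx0 <- tibble::tibble(chrom = character(), strand = character(),
                        acceptor_pos = integer())
  expect_equal(classify_intronic_type(sites, ann, jx0)$intronic_type,
               c("composite", "composite"))
  # an acceptor used between the 5'SS and the second site
  jx <- tibble::tibble(chrom = "chr1", strand = "+", acceptor_pos = 3800L)
  expect_equal(classify_intronic_type(sites, ann, jx)$intronic_type,
               c("composite", "skipped"))
  # a terminal-exon position errors
  expect_error(classify_intronic_type(
    tibble::tibble(chrom = "chr1", pos = 5500L, strand = "+"), ann, jx),
    "not intronic")
})

test_that("intronic features report sense distances and sizes", {
  ann <- context_annotation()
  gg <- generate_genome(n_genes = 4, seed = 3)
  genome <- c(chr1 = random_dna_fixture(12000, seed = 4))
  f <- compute_features(
    tibble::tibble(chrom = "chr1", pos = 3050L, strand = "+",
                   polyastrength = -1),
    ann, genome, type = "intronic")
  expect_equal(f$dist_to_upstream_ss, 150)
  expect_equal(f$dist_to_downstream_ss, 1949)
  expect_equal(f$intron_size, 2100)
  expect_equal(f$upstream_exon_size, 400)
  expect_equal(f$downstream_exon_size, 1001)
  expect_true(f$is_last_intron)
  expect_true(is.finite(f$ss5_strength) && is.finite(f$ss3_strength_down))
})

test_that("terminal pair selection applies the 8-fold usage rule", {
  sites <- tibble::tibble(
    gene_id = c("a", "a", "b", "b", "c", "c", "d"),
    chrom = "chr1", strand = c("+", "+", "+", "+", "-", "-", "+"),
    pos = c(100L, 900L, 2000L, 2600L, 5000L, 5700L, 8000L),
    usage = c(0.9, 0.1, 0.6, 0.4, 0.08, 0.92, 0.5),
    strength = c(2, -1, 1, 0.5, -2, 2, 0))
  pairs <- select_terminal_pairs(sites, seed = 2)
  expect_setequal(pairs$gene_id, c("a", "c"))   # b: 1.5-fold, d: single site
  a <- pairs[pairs$gene_id == "a", ]
  expect_equal(a$pos_proximal, 100)
  expect_true(a$proximal_is_high)
  c_ <- pairs[pairs$gene_id == "c", ]
  # minus strand: proximal is the higher coordinate
  expect_equal(c_$pos_proximal, 5700)
  expect_true(c_$proximal_is_high)
  # terminal-pair features
  ann <- context_annotation()
  f <- compute_features(
    dplyr::mutate(a, gene_id = "g1"), ann,
    c(chr1 = random_dna_fixture(12000, seed = 5)),
    type = "terminal_pair")
  expect_equal(f$pair_distance, 800)
  expect_equal(f$last_intron_size, 2100)
  # distance from g1 3' end (6000) to antisense gene end 9399... sense "+":
  # nearest antisense gene START above 6000 is 7800
  expect_equal(f$dist_to_downstream_antisense_gene, 1800)
  expect_equal(f$relative_strength_vs_distal, 3)
})

test_that("quantile matching equalises strength distributions", {
  withr::with_seed(7, {
    used <- tibble::tibble(polyastrength = rnorm(2000, 1, 1),
                           id = paste0("u", 1:2000))
    unused <- tibble::tibble(polyastrength = rnorm(2000, -1, 1),
                             id = paste0("n", 1:2000))
    matched <- suppressWarnings(
      quantile_match_by_strength(used, unused, seed = 3))
    tab <- table(matched$group)
    expect_equal(unname(tab["used"]), unname(tab["unused"]))
    smd <- with(matched,
                abs(mean(polyastrength[group == "used"]) -
                      mean(polyastrength[group == "unused"])) /
                  sd(polyastrength))
    expect_lt(smd, 0.1)
    # reproducible
    m2 <- suppressWarnings(quantile_match_by_strength(used, unused, seed = 3))
    expect_identical(matched$id, m2$id)
  })
})

test_that("logistic fitting recovers planted coefficients and drops noise", {
  withr::with_seed(11, {
    n <- 5000
    X <- tibble::tibble(strength = rnorm(n), log_distance = rnorm(n),
                        noise = rnorm(n))
    eta <- 2 * X$strength - 1 * X$log_distance
    y <- rbinom(n, 1, plogis(eta))
    clf <- fit_usage_classifier(X, y)
    expect_false("noise" %in% clf$features)
    expect_gt(clf$coefficients[["strength"]], 0)
    expect_lt(clf$coefficients[["log_distance"]], 0)
    expect_lt(abs(clf$coefficients[["strength"]] - 2) / 2, 0.2)
    expect_lt(abs(clf$coefficients[["log_distance"]] + 1), 0.2)
    # calibrated probabilities track the truth
    p <- predict_usage_probability(clf, X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auroc(p, y), 0.8)
    # label-independent features collapse to ~intercept
    y0 <- rbinom(n, 1, 0.5)
    clf0 <- fit_usage_classifier(X, y0)
    expect_lte(length(clf0$features), 1)   # chance retention at alpha 0.05
    # broom-style accessors
    td <- tidy(clf)
    expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
    expect_equal(glance(clf)$n, n)
  })
})

test_that("perfect separation falls back to a penalised fit", {
  X <- withr::with_seed(21, tibble::tibble(
    x = c(rnorm(50, -6), rnorm(50, 6)), z = rnorm(100)))
  y <- rep(c(0, 1), each = 50)
  clf <- fit_usage_classifier(X, y)
  expect_true(clf$separation)
  p <- predict_usage_probability(clf, X)
  expect_gt(auroc(p, y), 0.99)
})

test_that("the APA differential test combines Fisher, BH and usage change", {
  counts <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 2),
    condition = rep(c("brain", "other"), 2),
    proximal = c(90L, 10L, 50L, 50L),
    distal = c(10L, 90L, 50L, 50L))
  res <- apa_differential_test(counts)
  g1 <- res[res$gene_id == "g1" & res$condition == "brain", ]
  expect_lt(g1$p_value, 1e-10)
  expect_equal(g1$usage, 0.9)
  expect_equal(g1$usage_change, 0.4)
  expect_true(g1$significant)
  g2 <- res[res$gene_id == "g2", ]
  expect_true(all(g2$p_value == 1))
  expect_false(any(g2$significant))
  # adjusted p below alpha but usage change under 0.1: not significant
  counts3 <- tibble::tibble(gene_id = "g3",
                            condition = c("a", "b"),
                            proximal = c(520L, 480L), distal = c(480L, 520L))
  res3 <- apa_differential_test(counts3, min_usage_change = 0.1)
  expect_true(all(abs(res3$usage_change) < 0.1))
  expect_false(any(res3$significant))
  # genes with an all-zero margin are skipped
  counts0 <- tibble::tibble(gene_id = "g0", condition = c("a", "b"),
                            proximal = c(0L, 0L), distal = c(5L, 5L))
  expect_equal(nrow(apa_differential_test(counts0)), 0)
})

test_that("Benjamini-Hochberg adjustment matches a reference step-up", {
  step_up_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- runif(sample(5:200, 1))^sample(1:3, 1)
      expect_equal(p.adjust(p, "BH"), step_up_bh(p), tolerance = 1e-15)
    }
  })
})
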