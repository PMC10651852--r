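test_that("cleavage entropy matches closed forms and a brute-force oracle", {
  delta <- c(1, rep(0, 49))
  expect_equal(cleavage_entropy(delta), 0)
  expect_equal(cleavage_entropy(rep(0.02, 50)), log(50), tolerance = 1e-12)
  two <- numeric(50); two[c(10, 30)] <- 0.5
  expect_equal(cleavage_entropy(two), log(2), tolerance = 1e-12)
  oracle <- function(p) { s <- 0; for (x in p) if (x > 0) s <- s - x * log(x); s }
  withr::with_seed(8, {
    for (i in 1:25) {
      p <- runif(50); p <- p / sum(p)
      expect_equal(cleavage_entropy(p), oracle(p), tolerance = 1e-12)
      expect_lte(cleavage_entropy(p), log(50) + 1e-12)
    }
  })
})

test_that("motif families follow the published rules and precedence", {
  expect_equal(classify_motif_family("AATAAA"), "PAS_AAUAAA")
  expect_equal(classify_motif_family("ATTAAA"), "PAS_variant")
  expect_equal(classify_motif_family("AGTAAA"), "PAS_variant")
  # 5 Ts with a T first
  expect_equal(classify_motif_family("TTTTTA"), "U_rich")
  expect_equal(classify_motif_family("ATTTTT"), "none")   # first base not T
  expect_equal(classify_motif_family("TTTTAC"), "none")   # only 4 Ts
  # GU/CU-rich tetramers
  expect_equal(classify_motif_family("GTGTAA"), "GU_CU_rich")
  expect_equal(classify_motif_family("ATCTGT"), "GU_CU_rich")
  # UGUA outranks GU/CU-rich; GU/CU-rich outranks U-rich
  expect_equal(classify_motif_family("TGTATT"), "UGUA")
  expect_equal(classify_motif_family("TTGTGT"), "GU_CU_rich")
  # G-rich
  expect_equal(classify_motif_family("GGGGGA"), "G_rich")
  expect_equal(classify_motif_family("AGGGGG"), "none")
  expect_equal(classify_motif_family("ACGTAC"), "none")
  expect_error(classify_motif_family("ACGT"), "length 6")
  expect_equal(classify_motif_family(c("AATAAA", "ACGTAC")),
               c("PAS_AAUAAA", "none"))
})

test_that("hexamer disruption finds the planted PAS and ignores deep flanks", {
  m <- full_polyaid()$model
  w <- world_full()
  s <- w$sites[1, ]
  win <- extract_window(w$genome, s$chrom, s$pos, s$strand)
  imp <- hexamer_importance(win, m, n_repl = 30, seed = 3,
                            starts = c(1L, 30L, 95L, 121L))
  expect_equal(nrow(imp), 4)
  expect_equal(imp$position, c(-120L, -91L, -26L, 0L))
  pas_delta <- imp$delta_logodds[imp$position == -26L]
  flank_delta <- imp$delta_logodds[imp$position %in% c(-120L, -91L)]
  expect_lt(pas_delta, 0)
  expect_gt(pas_delta * -1, 10 * max(abs(flank_delta)))
  # deterministic under a fixed seed
  imp2 <- hexamer_importance(win, m, n_repl = 30, seed = 3,
                             starts = c(1L, 30L, 95L, 121L))
  expect_identical(imp$delta_logodds, imp2$delta_logodds)
})

test_that("positional profiles aggregate sums and per-site scores", {
  fake <- dplyr::bind_rows(
    tibble::tibble(hexamer = "AATAAA", position = -26L,
                   delta_logodds = c(-1, -3), n_repl = 10L),
    tibble::tibble(hexamer = "CCCCCC", position = 10L,
                   delta_logodds = -2, n_repl = 10L))
  prof <- fake |>
    dplyr::group_by(hexamer, position) |>
    dplyr::summarise(sum_importance = sum(-delta_logodds),
                     n_occurrences = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(per_site_importance = sum_importance / n_occurrences)
  expect_equal(prof$sum_importance[prof$hexamer == "AATAAA"], 4)
  expect_equal(prof$per_site_importance[prof$hexamer == "AATAAA"], 2)
  expect_equal(prof$per_site_importance[prof$hexamer == "CCCCCC"], 2)
})

test_that("significance calls use a strict 99.99th-percentile background", {
  # flat profile: every central value equals the background percentile,
  # and the comparison is strict, so nothing is called
  flat <- tidyr::expand_grid(hexamer = c("AAAAAA", "CCCCCC"),
                             position = -120:114) |>
    dplyr::mutate(sum_importance = 1, n_occurrences = 1,
                  per_site_importance = 1)
  expect_equal(nrow(significant_hexamers(flat)), 0)
  # one hexamer spiked far above the max background at a central position
  spiked <- flat
  spiked$sum_importance[spiked$hexamer == "AAAAAA" &
                          spiked$position == -26] <- 10 * max(
                            flat$sum_importance)
  calls <- significant_hexamers(spiked)
  expect_equal(attr(calls, "hexamers"), "AAAAAA")
  expect_equal(calls$position, -26L)
  # the same spike in the deep flank is background, not a call
  flank_spike <- flat
  flank_spike$sum_importance[flank_spike$position == -100 &
                               flank_spike$hexamer == "AAAAAA"] <- 10
  expect_false("AAAAAA" %in%
                 attr(significant_hexamers(flank_spike), "hexamers"))
  # OR-combination across two profiles
  both <- significant_hexamers(list(flat, spiked))
  expect_true("AAAAAA" %in% attr(both, "hexamers"))
  expect_length(attr(both, "threshold"), 2)
  expect_error(significant_hexamers(flat[abs(flat$position) <= 40, ]),
               "background")
})

test_that("entropy group analysis separates planted low/high cohorts", {
  withr::with_seed(12, {
    n <- 120
    make_site <- function(i, high) {
      sd <- if (high) 8 else 0.7
      v <- cleavage_profile(sd)
      seq <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                   collapse = "")
      seq <- str_sub_replace(seq, 95L, "AATAAA")
      # high-entropy sites carry a second AATAAA upstream
      if (high) seq <- str_sub_replace(seq, 75L, "AATAAA")
      tibble::tibble(site_id = paste0("s", i), seq = seq,
                     obs_vector = list(v), pred_vector = list(v),
                     high = high)
    }
    sites <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      make_site(i, i > n / 2)))
    res <- entropy_group_analysis(sites)
    grp <- res$groups
    expect_true(all(grp$group[grp$site_id %in% sites$site_id[sites$high]]
                    %in% c("high", "middle")))
    lows <- grp$site_id[grp$group == "low"]
    expect_true(all(!sites$high[match(lows, sites$site_id)]))
    # the planted double-PAS enrichment is detected in the -120..-31 region
    t1 <- res$tests[res$tests$region == "-120..-31" &
                      res$tests$family == "PAS_AAUAAA", ]
    expect_lt(t1$prop_p, 0.05)
    expect_gt(t1$frac_high, t1$frac_low)
  })
  # identical vectors: no separation, no tests
  same <- tibble::tibble(site_id = paste0("s", 1:10),
                         seq = strrep("C", 240),
                         obs_vector = rep(list(rep(0.02, 50)), 10),
                         pred_vector = rep(list(rep(0.02, 50)), 10))
  res2 <- entropy_group_analysis(same)
  expect_equal(nrow(res2$tests), 0)
  expect_true(all(res2$groups$group == "middle"))
})

test_that("the chi-squared machinery reproduces a textbook table", {
  tab <- matrix(c(90, 10, 10, 90), 2)
  p <- chisq.test(tab, correct = FALSE)$p.value
  expect_lt(p, 1e-10)
})

test_that("motif sliding preserves length and context", {
  win <- paste(rep(c("A", "C", "G", "T"), 60), collapse = "")
  win <- str_sub_replace(win, 95L, "AATAAA")
  win <- str_sub_replace(win, 131L, "GTGTGT")
  stub <- function(w) {
    n <- length(w)
    clv <- matrix(1 / 50, 50, n)
    list(p_class = rep(1, n), cleavage = clv)
  }
  res <- motif_distance_perturbation(win, c(95L, 100L), c(131L, 136L),
                                     0:5, stub)
  expect_equal(nrow(res), 6)
  expect_true(all(nchar(res$seq) == 240))
  expect_identical(res$seq[1], win)
  expect_equal(res$delta_entropy[1], 0)
  # the motif itself moves intact; the context refills the gap
  expect_identical(substr(res$seq[4], 134, 139), "GTGTGT")
  expect_identical(substr(res$seq[4], 131, 133), substr(win, 137, 139))
  expect_identical(substr(res$seq[4], 1, 130), substr(win, 1, 130))
  # moving upstream works symmetrically
  res2 <- motif_distance_perturbation(win, c(95L, 100L), c(131L, 136L),
                                      -3, stub)
  expect_identical(substr(res2$seq[1], 128, 133), "GTGTGT")
  expect_error(motif_distance_perturbation(win, c(95L, 100L),
                                           c(131L, 136L), -31, stub),
               "collide")
})

test_that("optimal motif configurations are counted at their windows", {
  base <- strrep("C", 240)
  base <- str_sub_replace(base, 95L, "AATAAA")     # PAS at -26
  base <- str_sub_replace(base, 131L, "GTGTGT")    # CstF at +10
  r <- count_optimal_motifs(base)
  expect_true(r$eligible)
  expect_equal(r$n_optional, 0)
  # + UGUA 14 nt upstream of the PAS
  w1 <- str_sub_replace(base, 81L, "TGTA")
  expect_equal(count_optimal_motifs(w1)$n_optional, 1)
  # + U-rich between cleavage and PAS, + G-rich 30 nt past the CstF motif
  w3 <- str_sub_replace(w1, 108L, "TTTTTT")
  w3 <- str_sub_replace(w3, 161L, "GGGGGG")
  r3 <- count_optimal_motifs(w3)
  expect_equal(r3$n_optional, 3)
  expect_true(r3$has_ugua && r3$has_urich_between && r3$has_grich)
  # + a second CstF motif
  w4 <- str_sub_replace(w3, 145L, "TGTCTG")
  expect_equal(count_optimal_motifs(w4)$n_optional, 4)
  # ineligible: no CstF motif within 30 nt downstream
  w5 <- str_sub_replace(strrep("C", 240), 95L, "AATAAA")
  expect_false(count_optimal_motifs(w5)$eligible)
  # ineligible: PAS outside the 10-30 nt upstream band
  w6 <- str_sub_replace(strrep("C", 240), 60L, "AATAAA")
  w6 <- str_sub_replace(w6, 131L, "GTGTGT")
  expect_false(count_optimal_motifs(w6)$eligible)
})
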