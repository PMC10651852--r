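test_that("scan retention applies both thresholds strictly", {
  seq <- strrep("A", 1239)   # 1000 scannable anchors
  rec <- scan_sequence(seq, stub_model(0.6, 0.06))
  expect_equal(nrow(rec), 1000)
  expect_true(all(rec$retained))
  # centre probability at the threshold boundary fails (strict >)
  rec2 <- scan_sequence(seq, stub_model(0.6, 0.04))
  expect_false(any(rec2$retained))
  rec3 <- scan_sequence(seq, stub_model(0.5, 0.06))
  expect_false(any(rec3$retained))
  # a short sequence yields no records
  expect_equal(nrow(scan_sequence(strrep("A", 100), stub_model(1, 1))), 0)
})

test_that("consolidation overlays vectors and picks the max position", {
  # single retained record with a delta at offset 0 -> site at the anchor
  delta_stub <- function(at) function(w) {
    clv <- matrix(0, 50, length(w)); clv[at, ] <- 1
    list(p_class = rep(0.9, length(w)), cleavage = clv)
  }
  seq <- strrep("C", 260)
  rec <- scan_sequence(seq, delta_stub(26))
  rec$retained <- rec$anchor_pos == 130
  sites <- consolidate(rec)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$pos, 130)
  expect_equal(sum(sites$cleavage[[1]]), 1, tolerance = 1e-9)
  # three overlapping records whose deltas hit the same genomic base
  rec2 <- scan_sequence(seq, function(w) {
    n <- length(w)
    clv <- matrix(0, 50, n)
    for (j in seq_len(n)) clv[26, j] <- 1   # delta at each anchor itself
    list(p_class = rep(0.9, n), cleavage = clv)
  })
  # hand-build: anchors 129,130,131 with deltas all at genomic 130
  rec2 <- rec2[rec2$anchor_pos %in% 129:131, ]
  rec2$retained <- TRUE
  v <- numeric(50)
  rec2$cleavage[[1]] <- {x <- numeric(50); x[27] <- 1; x}  # 130 = 129 + 1
  rec2$cleavage[[2]] <- {x <- numeric(50); x[26] <- 1; x}
  rec2$cleavage[[3]] <- {x <- numeric(50); x[25] <- 1; x}  # 130 = 131 - 1
  sites2 <- consolidate(rec2)
  expect_equal(nrow(sites2), 1)
  expect_equal(sites2$pos, 130)
  # averaged probability mass is all at the representative
  expect_equal(sites2$cleavage[[1]][26], 1)
  # tie between two genomic maxima resolves 5'-most
  rec3 <- rec2[1:2, ]
  rec3$cleavage[[1]] <- {x <- numeric(50); x[26] <- 1; x}  # at 129
  rec3$cleavage[[2]] <- {x <- numeric(50); x[26] <- 1; x}  # at 130
  sites3 <- consolidate(rec3)
  expect_equal(sites3$pos, 129)
  # background subtraction drops all-background vectors
  rec4 <- rec2[1, ]
  rec4$cleavage[[1]] <- rep(0.02, 50)
  expect_equal(nrow(consolidate(rec4)), 0)
})

test_that("gap handling splits clusters of retained anchors", {
  seq <- strrep("C", 400)
  rec <- scan_sequence(seq, stub_model(0.9, 0.5))
  rec$retained <- rec$anchor_pos %in% c(130:135, 140:145)
  expect_equal(nrow(consolidate(rec, gap = 0)), 2)
  expect_equal(nrow(consolidate(rec, gap = 4)), 1)
})

test_that("mean cleavage position matches its dot-product definition", {
  delta <- function(i) { v <- numeric(50); v[i] <- 1; v }
  expect_equal(mean_cleavage_position(delta(7)), 7)
  expect_equal(mean_cleavage_position(rep(0.02, 50)), 25.5)
  v <- numeric(50); v[10] <- 0.5; v[20] <- 0.5
  expect_equal(mean_cleavage_position(v), 15)
  expect_warning(m <- mean_cleavage_position(rep(1, 50)), "renormalis")
  expect_equal(m, 25.5)
})

test_that("genomic location classes follow the stated precedence", {
  ann <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1", strand = "+",
    feature = "exon", exon_rank = 1:3,
    start = c(1000L, 2000L, 5000L), end = c(1500L, 2400L, 6000L))
  ext <- extend_terminal_exon(ann, chrom_sizes = c(chr1 = 20000L))
  probe <- function(pos) {
    classify_genomic_location(
      tibble::tibble(chrom = "chr1", pos = pos, strand = "+"),
      ann, ext)$genomic_class
  }
  expect_equal(probe(5500L), "terminal_exonic")
  expect_equal(probe(2100L), "upstream_exonic")
  expect_equal(probe(1700L), "intronic")
  expect_equal(probe(6300L), "extended_terminal_exonic")
  expect_equal(probe(15000L), "intergenic")
  # wrong strand falls through to intergenic
  expect_equal(classify_genomic_location(
    tibble::tibble(chrom = "chr1", pos = 5500L, strand = "-"),
    ann, ext)$genomic_class, "intergenic")
})

test_that("scan + consolidate is translation-equivariant", {
  w <- scan_world()
  m <- full_polyaid()$model
  s <- w$sites[1, ]
  lo <- s$pos - 400L; hi <- s$pos + 400L
  seq0 <- substr(w$genome[[s$chrom]], lo, hi)
  k <- 17L
  seq_shift <- substr(w$genome[[s$chrom]], lo - k, hi)
  calls0 <- consolidate(scan_sequence(seq0, m))
  calls1 <- consolidate(scan_sequence(seq_shift, m))
  # interior calls shift by exactly k
  inner0 <- calls0$pos[calls0$pos > 130 & calls0$pos < nchar(seq0) - 130]
  inner1 <- calls1$pos[calls1$pos - k > 130 &
                         calls1$pos - k < nchar(seq0) - 130]
  expect_equal(inner1, inner0 + k)
})

test_that("a no-op variant has zero strength delta and is not significant", {
  w <- scan_world()
  m <- full_polyaid()$model
  ms <- toy_polyastrength()$model
  s <- w$sites[1, ]
  pos <- s$pos - 24L   # inside the PAS hexamer
  ref <- substr(w$genome[[s$chrom]], pos, pos)
  v <- tibble::tibble(variant_id = "noop", chrom = s$chrom, pos = pos,
                      ref = ref, alt = ref, strand = s$strand)
  eff <- predict_variant_effect(v, w$genome, m, ms,
                                important_hexamers = c("AATAAA"))
  expect_true(eff$evaluated)
  expect_equal(eff$delta_strength, 0)
  expect_false(eff$significant)
})
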