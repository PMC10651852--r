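test_that("genome generation is deterministic and respects its parameters", {
  g1 <- generate_genome(n_genes = 10, seed = 5)
  g2 <- generate_genome(n_genes = 10, seed = 5)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation, g2$annotation)
  expect_equal(length(unique(g1$annotation$gene_id)), 10)
  # exons are disjoint and ordered within each gene
  by_gene <- split(g1$annotation, g1$annotation$gene_id)
  for (df in by_gene) {
    df <- df[order(df$start), ]
    expect_true(all(df$end >= df$start))
    if (nrow(df) > 1) expect_true(all(diff(df$start) > 0))
  }
  g3 <- generate_genome(n_genes = 10, seed = 6)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("planted sites carry the grammar at the stated offsets", {
  gg <- generate_genome(n_genes = 12, seed = 7)
  pl <- plant_polya_sites(gg$genome, gg$annotation, grammar_spec(),
                          sites_per_gene = 1:2, seed = 8)
  expect_gt(nrow(pl$sites), 0)
  for (i in seq_len(nrow(pl$sites))) {
    s <- pl$sites[i, ]
    w <- extract_window(pl$genome, s$chrom, s$pos, s$strand)
    # PAS hexamer occupies sense offsets -26..-21 (window base 95..100)
    expect_identical(substr(w, 95, 100), s$pas_hexamer)
    # CA dinucleotide at the cleavage site (offsets -1, 0)
    expect_identical(substr(w, 120, 121), "CA")
    # mandatory CstF motif at the sampled downstream offset
    expect_identical(substr(w, 121 + s$cstf_offset, 126 + s$cstf_offset),
                     "GTGTGT")
  }
  # per-gene usage fractions sum to 1
  us <- tapply(pl$sites$usage, pl$sites$gene_id, sum)
  expect_true(all(abs(us - 1) < 1e-12))
  # strength is monotone in motif content within a PAS class
  can <- pl$sites[pl$sites$pas_hexamer == "AATAAA", ]
  if (nrow(can) > 2) {
    expect_true(all(diff(can$strength[order(can$n_optional)]) >= 0))
  }
})

test_that("simulated reads reflect usage, depth and dispersion", {
  w <- world_simple()
  # totals: reads ~ sum(usage * depth) per sample within Poisson noise
  expected <- sum(w$sites$usage) * 400 * 2
  expect_lt(abs(nrow(w$alignments) - expected) / expected, 0.1)
  # observed entropy grows with dispersion
  gg <- generate_genome(n_genes = 6, seed = 61)
  ents <- vapply(c(0.5, 2, 6), function(sd) {
    pl <- plant_polya_sites(gg$genome, gg$annotation,
                            grammar_spec(cleavage_dispersion = sd),
                            sites_per_gene = 1, seed = 62)
    sim <- simulate_pass_reads(pl$genome, pl$sites, depth = 400, seed = 63)
    reads <- extract_pass_reads(sim$alignments, pl$genome)
    s <- pl$sites[1, ]
    offs <- reads$cleavage_pos[reads$chrom == s$chrom &
                                 reads$strand == s$strand &
                                 abs(reads$cleavage_pos - s$pos) <= 25] -
      s$pos
    tab <- tabulate(offs + 26, nbins = 50)
    cleavage_entropy(tab / sum(tab))
  }, numeric(1))
  expect_true(all(diff(ents) > 0))
  # zero dispersion: every intended 3' end is at the planted position
  pl0 <- plant_polya_sites(gg$genome, gg$annotation,
                           grammar_spec(cleavage_dispersion = 0),
                           sites_per_gene = 1, seed = 62)
  sim0 <- simulate_pass_reads(pl0$genome, pl0$sites, depth = 50, seed = 64)
  expect_true(all(sim0$truth$intended_cleavage %in% pl0$sites$pos))
})

test_that("simulated variants have the intended effect on the PAS", {
  w <- world_full()
  vars <- simulate_variants(w$genome, w$sites, n_neutral = 5, seed = 9)
  expect_true(all(c("create", "destroy", "none") %in% vars$intended_effect))
  apply_variant <- function(v) {
    g <- w$genome
    expect_identical(substr(g[[v$chrom]], v$pos, v$pos), v$ref)
    g[[v$chrom]] <- str_sub_replace(g[[v$chrom]], v$pos, v$alt)
    g
  }
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$intended_effect == "none") next
    s <- w$sites[w$sites$site_id == v$site_id, ]
    g2 <- apply_variant(v)
    w_ref <- extract_window(w$genome, s$chrom, s$pos, s$strand)
    w_alt <- extract_window(g2, s$chrom, s$pos, s$strand)
    if (v$intended_effect == "destroy") {
      expect_identical(substr(w_ref, 95, 100), "AATAAA")
      expect_false(grepl("AATAAA", substr(w_alt, 91, 104)))
    } else {
      expect_identical(substr(w_ref, 95, 100), "AATAAT")
      expect_identical(substr(w_alt, 95, 100), "AATAAA")
    }
  }
  # neutral variants are far from every planted site
  none <- vars[vars$intended_effect == "none", ]
  for (i in seq_len(nrow(none))) {
    expect_gt(min(abs(none$pos[i] - w$sites$pos)), 120)
  }
})

test_that("background scrubbing removes stray signals but keeps planted ones", {
  gg <- generate_genome(n_genes = 8, seed = 71)
  pl <- plant_polya_sites(gg$genome, gg$annotation, simple_grammar(),
                          sites_per_gene = 2, seed = 72)
  sc <- scrub_background(pl$genome, pl$sites, seed = 73)
  hits <- gregexpr("AATAAA", sc[[1]], fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  # every remaining occurrence is near a planted site
  plus_sites <- pl$sites$pos
  expect_true(all(vapply(hits, function(h)
    any(abs(h + 2 - plus_sites) <= 150), logical(1))))
  for (i in seq_len(nrow(pl$sites))) {
    s <- pl$sites[i, ]
    w <- extract_window(sc, s$chrom, s$pos, s$strand)
    expect_identical(substr(w, 95, 100), s$pas_hexamer)
  }
})
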