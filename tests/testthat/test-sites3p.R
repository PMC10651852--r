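# reference genome for hand-built alignment fixtures:
# positions 51-55 are "GAAAA"; everything else is C
fixture_genome <- function() {
  c(chr1 = paste0(strrep("C", 50), "GAAAA", strrep("C", 45),
                  "TTTTG", strrep("C", 50)))
}

aln_row <- function(end, tail, strand = "+", mapq = 60L, secondary = FALSE) {
  tibble::tibble(chrom = "chr1", strand = strand, align_end = end,
                 tail = tail, mapq = mapq, secondary = secondary,
                 sample_id = "s1", lineage = "L1")
}

test_that("PASS extraction applies the non-genomic-A and first-A rules", {
  g <- fixture_genome()
  # tail of 3 As at a non-A base with no downstream As: kept, cleavage at end
  r <- extract_pass_reads(aln_row(30L, "AAA"), g)
  expect_equal(nrow(r), 1)
  expect_equal(r$cleavage_pos, 30)
  expect_equal(r$n_nongenomic_a, 3)
  # a single tail A is below the >=2 threshold
  expect_equal(nrow(extract_pass_reads(aln_row(30L, "A"), g)), 0)
  # read ending inside the reference A-run with 2 extra As: first A of run
  r <- extract_pass_reads(aln_row(55L, "AA"), g)
  expect_equal(r$cleavage_pos, 52)
  # alignment end abutting the A-run: matching tail As are genomic
  r <- extract_pass_reads(aln_row(51L, "AAAAAA"), g)
  expect_equal(r$n_nongenomic_a, 2)   # 6 tail As - 4 genomic
  expect_equal(r$cleavage_pos, 52)
  # after subtraction fewer than 2 non-genomic As remain: rejected
  expect_equal(nrow(extract_pass_reads(aln_row(51L, "AAAAA"), g)), 0)
})

test_that("minus-strand reads are mirrored correctly", {
  g <- fixture_genome()   # TTTT at 101-104 precedes G at 105
  r <- extract_pass_reads(aln_row(101L, "AAA", strand = "-"), g)
  # cleavage assigned to the 5'-most sense A (= highest T coordinate)
  expect_equal(r$cleavage_pos, 104)
  expect_equal(r$strand, "-")
})

test_that("non-unique and malformed reads are rejected with reasons", {
  g <- fixture_genome()
  al <- dplyr::bind_rows(
    aln_row(30L, "AAA", mapq = 3L),
    aln_row(30L, "AAA", secondary = TRUE),
    aln_row(30L, NA_character_),
    aln_row(500L, "AAA"))
  out <- extract_pass_reads(al, g)
  expect_equal(nrow(out), 0)
  rej <- attr(out, "rejected")
  expect_setequal(rej$reason, c("not_unique", "no_tail", "off_chromosome"))
})

# independent brute-force greedy clustering oracle
oracle_cluster <- function(pos_counts, window = 24L, strand = "+") {
  reps <- integer(0); totals <- integer(0)
  while (nrow(pos_counts) > 0) {
    mx <- max(pos_counts$n)
    cand <- pos_counts$pos[pos_counts$n == mx]
    seed <- if (strand == "+") min(cand) else max(cand)
    member <- abs(pos_counts$pos - seed) <= window
    reps <- c(reps, seed); totals <- c(totals, sum(pos_counts$n[member]))
    pos_counts <- pos_counts[!member, , drop = FALSE]
  }
  tibble::tibble(pos = reps, n = totals)
}

reads_from_counts <- function(counts, strand = "+") {
  tibble::tibble(chrom = "chr1",
                 cleavage_pos = rep(counts$pos, counts$n),
                 strand = strand, n_nongenomic_a = 2L,
                 sample_id = "s1", lineage = "L1")
}

test_that("clustering matches the greedy oracle and conserves reads", {
  cases <- list(
    tibble::tibble(pos = c(100L, 110L, 140L), n = c(5L, 20L, 3L)),
    tibble::tibble(pos = 500L, n = 7L),
    tibble::tibble(pos = c(200L, 224L), n = c(20L, 20L)))
  for (counts in cases) {
    got <- cluster_sites(reads_from_counts(counts))
    exp <- oracle_cluster(counts)
    expect_equal(got$pos, sort(exp$pos))
    expect_equal(got$read_count_total[order(got$pos)],
                 exp$n[order(exp$pos)])
    expect_equal(sum(got$read_count_total), sum(counts$n))
  }
  # the documented example: {100:5, 110:20, 140:3}
  got <- cluster_sites(reads_from_counts(cases[[1]]))
  expect_equal(got$pos, c(110, 140))
  expect_equal(got$read_count_total, c(25, 3))
  # tie at 24 nt separation collapses to one cluster seeded 5'-most
  got <- cluster_sites(reads_from_counts(cases[[3]]))
  expect_equal(got$pos, 200)
  expect_equal(got$read_count_total, 40)
  # on the minus strand the 5'-most tie-break picks the higher coordinate
  got <- cluster_sites(reads_from_counts(cases[[3]], strand = "-"))
  expect_equal(got$pos, 224)
})

test_that("clustering random read sets conserves counts and is idempotent", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      counts <- tibble::tibble(pos = sort(sample(1000:2000, 30)),
                               n = sample(1:30, 30, replace = TRUE))
      got <- cluster_sites(reads_from_counts(counts))
      expect_equal(sum(got$read_count_total), sum(counts$n))
      expect_equal(got$pos, oracle_cluster(counts)$pos |> sort())
      # representatives >= 49 nt apart re-cluster to themselves
      reps <- got[diff(c(-100L, got$pos)) >= 49, ]
      if (nrow(reps) > 1) {
        re <- cluster_sites(reads_from_counts(
          tibble::tibble(pos = reps$pos, n = reps$read_count_total)))
        expect_equal(re$pos, reps$pos)
      }
    }
  })
})

test_that("site filtering enforces read support and lineage fraction", {
  mk_site <- function(id, total, by_lin, gene = "g1") {
    tibble::tibble(site_id = id, chrom = "chr1", strand = "+", pos = 100L,
                   read_count_total = total,
                   read_count_by_lineage = list(by_lin), gene_id = gene)
  }
  gene_tot <- tibble::tibble(gene_id = "g1",
                             lineage = c("L1", "L2"),
                             reads = c(1000L, 1000L))
  sites <- dplyr::bind_rows(
    mk_site("below_reads", 9L, c(L1 = 9L)),
    mk_site("kept", 10L, c(L1 = 31L)),            # 3.1% in L1
    mk_site("below_frac", 50L, c(L1 = 20L, L2 = 20L)))  # 2% everywhere
  out <- filter_sites(sites, gene_tot)
  expect_equal(out$site_id, "kept")
  rem <- attr(out, "removed")
  expect_equal(rem$reason[rem$site_id == "below_reads"], "below_min_reads")
  expect_equal(rem$reason[rem$site_id == "below_frac"], "below_min_fraction")
  # exactly 2% fails the strict > rule; a zero gene total drops the site
  zero_tot <- tibble::tibble(gene_id = "g1", lineage = "L1", reads = 0L)
  out2 <- filter_sites(mk_site("s", 50L, c(L1 = 50L)), zero_tot)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "removed")$reason, "gene_total_zero")
})

test_that("terminal-exon extension stops at the next same-strand TSS", {
  ann <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    transcript_id = c("a.1", "b.1", "c.1"),
    chrom = "chr1", strand = "+", feature = "exon", exon_rank = 1L,
    start = c(1000L, 18000L, 8200L), end = c(5000L, 19000L, 8800L))
  ext <- extend_terminal_exon(ann, chrom_sizes = c(chr1 = 50000L))
  # gene a: next same-strand TSS at 8200, gap 3199 < 5000
  expect_equal(ext$ext_len[ext$gene_id == "a"], 3199L)
  expect_equal(ext$ext_end[ext$gene_id == "a"], 8199L)
  # gene c: next TSS at 18000, 9199 nt away -> capped at 5 kb
  expect_equal(ext$ext_len[ext$gene_id == "c"], 5000L)
  # gene b: no downstream gene -> clamped at the chromosome end
  expect_equal(ext$ext_len[ext$gene_id == "b"], 5000L)
  ext2 <- extend_terminal_exon(ann, chrom_sizes = c(chr1 = 20000L))
  expect_equal(ext2$ext_len[ext2$gene_id == "b"], 1000L)
  # minus strand mirrors: extension runs to lower coordinates
  ann_m <- dplyr::mutate(ann, strand = "-")
  ext_m <- extend_terminal_exon(ann_m, chrom_sizes = c(chr1 = 50000L))
  expect_equal(ext_m$ext_len[ext_m$gene_id == "b"], 5000L)
  expect_equal(ext_m$ext_end[ext_m$gene_id == "b"], 17999L)
  expect_equal(ext_m$ext_len[ext_m$gene_id == "c"], 3199L)
})

test_that("planted-site recovery: clustering finds exactly the planted sites", {
  w <- world_simple()
  sites <- cluster_sites(w$reads)
  ext <- extend_terminal_exon(w$annotation)
  sites <- assign_sites_to_genes(sites, w$annotation, ext)
  kept <- filter_sites(sites)
  expect_equal(nrow(kept), nrow(w$sites))
  tol <- pmax(1, ceiling(w$sites$dispersion_sd))
  for (i in seq_len(nrow(w$sites))) {
    s <- w$sites[i, ]
    d <- min(abs(kept$pos[kept$strand == s$strand] - s$pos))
    expect_lte(d, tol[i])
  }
  # conservation within each chrom/strand (before expression filtering)
  tot <- tapply(sites$read_count_total, sites$strand, sum)
  reads_by_strand <- table(w$reads$strand)
  expect_equal(as.integer(tot[names(reads_by_strand)]),
               as.integer(reads_by_strand))
})
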