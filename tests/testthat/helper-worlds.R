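# Shared synthetic "study worlds" and trained toy models, built once per
# test session and cached.  Problem sizes are the desk-scale study
# conditions described in the methods vignette.

pg_cache <- new.env(parent = emptyenv())

pg_get <- function(name, build) {
  if (is.null(pg_cache[[name]])) pg_cache[[name]] <- build()
  pg_cache[[name]]
}

# single-signal grammar: canonical PAS, fixed CstF distance (sharp cleavage)
simple_grammar <- function() {
  grammar_spec(pas_choices = c(AATAAA = 1), pas_bonus = c(AATAAA = 3),
               cstf_range = 10:10)
}

# world A: 50 planted sites under the single-signal grammar, deep coverage
world_simple <- function() pg_get("world_simple", function() {
  gg <- generate_genome(n_genes = 25, terminal_exon_size = c(540L, 800L),
                        seed = 11)
  pl <- plant_polya_sites(gg$genome, gg$annotation, simple_grammar(),
                          sites_per_gene = 2, seed = 12)
  sim <- simulate_pass_reads(pl$genome, pl$sites, depth = 400, seed = 13)
  reads <- extract_pass_reads(sim$alignments, pl$genome)
  list(annotation = gg$annotation, genome = pl$genome, sites = pl$sites,
       alignments = sim$alignments, truth = sim$truth, reads = reads)
})

# world B: 300 genes under the full grammar (variable PAS, motif content
# and PAS-CstF distance with distance-coupled cleavage dispersion);
# trains the full-grammar PolyaID and hosts the importance / heterogeneity
# analyses
world_full <- function() pg_get("world_full", function() {
  gg <- generate_genome(n_genes = 300, seed = 21)
  pl <- plant_polya_sites(gg$genome, gg$annotation, grammar_spec(),
                          sites_per_gene = 2, seed = 22)
  sim <- simulate_pass_reads(pl$genome, pl$sites, depth = 300, seed = 23)
  reads <- extract_pass_reads(sim$alignments, pl$genome)
  list(annotation = gg$annotation, genome = pl$genome, sites = pl$sites,
       alignments = sim$alignments, truth = sim$truth, reads = reads)
})

# world C: a larger 450-gene panel (sequence truth only, no reads) whose
# planted strengths train PolyaStrength
strength_world <- function() pg_get("strength_world", function() {
  gg <- generate_genome(n_genes = 450, seed = 21)
  pl <- plant_polya_sites(gg$genome, gg$annotation, grammar_spec(),
                          sites_per_gene = 2, seed = 22)
  list(annotation = gg$annotation, genome = pl$genome, sites = pl$sites)
})

# world D: a fresh 450-gene panel for the variant-effect checks (held out
# from both models' training)
variant_world <- function() pg_get("variant_world", function() {
  gg <- generate_genome(n_genes = 450, seed = 51)
  pl <- plant_polya_sites(gg$genome, gg$annotation, grammar_spec(),
                          sites_per_gene = 2, seed = 52)
  list(annotation = gg$annotation, genome = pl$genome, sites = pl$sites)
})

# PolyaID example tibble for a set of sites (positives: shifted windows
# with read-derived cleavage labels; negatives matched 1:1)
polyaid_examples <- function(world, sites, neg_seed, split_seed) {
  pos <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    rp <- world$reads$cleavage_pos[
      world$reads$chrom == s$chrom & world$reads$strand == s$strand &
        abs(world$reads$cleavage_pos - s$pos) <= 25]
    if (length(rp) < 10) return(NULL)
    build_positive_examples(s, world$genome, rp)
  }))
  neg <- build_negative_examples(world$genome, world$annotation, world$sites,
                                 world$reads$cleavage_pos, n = nrow(pos),
                                 seed = neg_seed)
  split_dataset(dplyr::bind_rows(pos, neg), seed = split_seed)
}

# reduced PolyaID trained 4 epochs on ~5000 examples from world A
toy_polyaid <- function() pg_get("toy_polyaid", function() {
  w <- world_simple()
  ex <- polyaid_examples(w, w$sites, neg_seed = 14, split_seed = 15)
  cfg <- polya_model_config("polyaid", conv_filters = 16, rnn_units = 16,
                            max_epochs = 4, seed = 7)
  m <- train_polya_model(build_polya_model(cfg),
                         ex[ex$split == "train", ],
                         ex[ex$split == "validation", ])
  list(model = m, examples = ex)
})

# full-grammar PolyaID (200 training sites of world B, 12 epochs) used for
# scanning, motif-importance, heterogeneity and variant analyses
full_polyaid <- function() pg_get("full_polyaid", function() {
  w <- world_full()
  ex <- polyaid_examples(w, w$sites[seq_len(200), ], neg_seed = 24,
                         split_seed = 25)
  cfg <- polya_model_config("polyaid", conv_filters = 16, rnn_units = 16,
                            max_epochs = 12, seed = 7)
  m <- train_polya_model(build_polya_model(cfg),
                         ex[ex$split == "train", ],
                         ex[ex$split == "validation", ])
  list(model = m, examples = ex)
})

# PolyaStrength trained on the planted log2-odds strengths of world C
toy_polyastrength <- function() pg_get("toy_polyastrength", function() {
  w <- strength_world()
  ex <- dplyr::bind_rows(lapply(seq_len(nrow(w$sites)), function(i) {
    s <- w$sites[i, ]
    dir <- if (s$strand == "+") 1L else -1L
    shifts <- -5:5
    tibble::tibble(
      site_id = s$site_id, shift = shifts,
      seq = vapply(shifts, function(sh)
        extract_window(w$genome, s$chrom, s$pos + dir * sh, s$strand),
        character(1)),
      label_class = 1, label_usage = s$strength, truth = s$strength)
  }))
  ex <- ex[!is.na(ex$seq), ]
  ex <- split_dataset(ex, seed = 26)
  cfg <- polya_model_config("polyastrength", conv_filters = 16,
                            rnn_units = 16, learning_rate = 0.003,
                            dropout = 0.2, max_epochs = 40, seed = 8,
                            trunk = "flatten")
  m <- train_polya_model(build_polya_model(cfg),
                         ex[ex$split == "train", ],
                         ex[ex$split == "validation", ])
  list(model = m, examples = ex)
})

# 50-kb single-signal genome with scrubbed background, used for the
# scanning recovery checks
scan_world <- function() pg_get("scan_world", function() {
  gg <- generate_genome(n_genes = 16, seed = 41)
  pl <- plant_polya_sites(gg$genome, gg$annotation, simple_grammar(),
                          sites_per_gene = 2, seed = 42)
  genome <- scrub_background(pl$genome, pl$sites, seed = 43)
  list(genome = genome, annotation = gg$annotation, sites = pl$sites)
})

random_dna_fixture <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# rank-based AUROC
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic stub PolyaID: constant p and a delta/constant vector
stub_model <- function(p_class, center, delta_at = 26L) {
  function(windows) {
    n <- length(windows)
    clv <- matrix((1 - center) / 49, nrow = 50, ncol = n)
    clv[delta_at, ] <- center
    list(p_class = rep(p_class, n), cleavage = clv)
  }
}
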