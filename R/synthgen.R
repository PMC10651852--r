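#' Motif grammar for synthetic polyA sites
#'
#' Describes the sequence grammar written around each planted cleavage site:
#' a polyadenylation signal (PAS) hexamer ending `pas_offset` nt upstream of
#' the cleavage position, a mandatory downstream GU-rich CstF motif at a
#' variable distance, and optional UGUA, U-rich, second-CstF and G-rich
#' elements at their field-standard windows.  Planted site strength is a
#' monotone function of the PAS type and the number of optional motifs, and
#' the cleavage dispersion (standard deviation of read 3' ends around the
#' site) grows linearly with the PAS-CstF distance, so that models trained
#' on the synthetic data can learn both site strength and the
#' heterogeneity mechanism.
#'
#' @param pas_offset Distance (nt) from the cleavage position to the PAS
#'   hexamer end; default 21 (the hexamer occupies offsets -26..-21).
#' @param pas_choices Named probabilities over PAS hexamers planted at
#'   sites.  The default mixes the canonical signal, a common variant and a
#'   broken signal (AATAAT) that a single point variant can convert to
#'   canonical.
#' @param pas_bonus Named strength bonus per PAS hexamer.
#' @param cstf_range Integer offsets (downstream of cleavage) at which the
#'   mandatory GU-rich motif may start.
#' @param optional_prob Presence probability of each optional motif
#'   (UGUA, upstream U-rich, second CstF, G-rich).
#' @param optional_bonus Strength increment per optional motif present.
#' @param strength_base Baseline strength (log2-odds usage scale).
#' @param cleavage_dispersion Fixed read 3'-end dispersion (sd, nt), or
#'   `NULL` for the distance-dependent default
#'   `0.3 + 0.25 * max(0, cstf_offset - 8)`.
#' @param background_gc GC fraction of background sequence.
#' @return A `grammar_spec` list.
#' @export
grammar_spec <- function(pas_offset = 21L,
                         pas_choices = c(AATAAA = 0.55, ATTAAA = 0.2,
                                         AATAAT = 0.25),
                         pas_bonus = c(AATAAA = 3, ATTAAA = 1.5, AATAAT = 0),
                         cstf_range = 5:35,
                         optional_prob = c(tgta = 0.5, urich = 0.5,
                                           cstf2 = 0.4, grich = 0.4),
                         optional_bonus = 0.8,
                         strength_base = -4,
                         cleavage_dispersion = NULL,
                         background_gc = 0.45) {
  stopifnot(pas_offset >= 6, all(cstf_range >= 1),
            is.null(cleavage_dispersion) || cleavage_dispersion >= 0)
  structure(list(pas_offset = as.integer(pas_offset),
                 pas_choices = pas_choices / sum(pas_choices),
                 pas_bonus = pas_bonus,
                 cstf_range = as.integer(cstf_range),
                 optional_prob = optional_prob,
                 optional_bonus = optional_bonus,
                 strength_base = strength_base,
                 cleavage_dispersion = cleavage_dispersion,
                 background_gc = background_gc),
            class = "grammar_spec")
}

#' Generate a random genome with gene structure
#'
#' Genes are laid along a single synthetic chromosome with random exon /
#' intron structure and intergenic gaps; strands alternate so both
#' orientations are exercised.  The sense-terminal exon is made long enough
#' to host planted polyA sites.
#'
#' @param n_genes Number of genes.
#' @param n_exons Integer vector of possible exon counts per gene.
#' @param exon_size,intron_size,intergenic Length-2 ranges (nt) for internal
#'   exons, introns and intergenic gaps.
#' @param terminal_exon_size Range for the sense-terminal exon.
#' @param chrom Chromosome name.
#' @param gc Background GC fraction.
#' @param seed Integer seed (full determinism).
#' @return List with `genome` (named character vector) and `annotation`
#'   (exon-level tibble: `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `feature`, `exon_rank` in sense order, `start`, `end`).
#' @export
generate_genome <- function(n_genes = 16L, n_exons = 2:4,
                            exon_size = c(120L, 300L),
                            intron_size = c(250L, 700L),
                            intergenic = c(600L, 1500L),
                            terminal_exon_size = c(420L, 700L),
                            chrom = "chrS", gc = 0.45, seed = 1L) {
  stopifnot(n_genes >= 1, all(exon_size > 0), all(intron_size > 0))
  with_seed(seed, {
    rows <- list()
    cursor <- sample(intergenic[1]:intergenic[2], 1)
    for (g in seq_len(n_genes)) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      k <- sample(rep(n_exons, 2), 1)
      ex_len <- sample(exon_size[1]:exon_size[2], k, replace = TRUE)
      # the sense-terminal exon (rightmost on +, leftmost on -) is long
      term_len <- sample(terminal_exon_size[1]:terminal_exon_size[2], 1)
      if (strand == "+") ex_len[k] <- term_len else ex_len[1] <- term_len
      in_len <- if (k > 1) {
        sample(intron_size[1]:intron_size[2], k - 1L, replace = TRUE)
      } else integer(0)
      starts <- integer(k); ends <- integer(k)
      p <- cursor
      for (i in seq_len(k)) {
        starts[i] <- p
        ends[i] <- p + ex_len[i] - 1L
        p <- ends[i] + 1L + if (i < k) in_len[i] else 0L
      }
      rank <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      rows[[g]] <- tibble::tibble(
        gene_id = sprintf("gene%02d", g),
        transcript_id = sprintf("gene%02d.t1", g),
        chrom = chrom, strand = strand, feature = "exon",
        exon_rank = rank, start = starts, end = ends)
      cursor <- ends[k] + sample(intergenic[1]:intergenic[2], 1)
    }
    annotation <- dplyr::bind_rows(rows)
    total <- max(annotation$end) + sample(intergenic[1]:intergenic[2], 1)
    genome <- stats::setNames(random_dna(total, gc), chrom)
    list(genome = genome, annotation = annotation)
  })
}

#' Discretised Gaussian cleavage profile
#'
#' The generator's model of cleavage imprecision: a Gaussian over the 50
#' vector indices, discretised to integer offsets and renormalised.
#'
#' @param sd Standard deviation in nt (`0` gives a delta).
#' @param center Index of the anchor (default 26 = offset 0).
#' @return A length-50 probability vector.
#' @export
cleavage_profile <- function(sd, center = 26L) {
  idx <- 1:50
  if (sd <= 0) {
    v <- numeric(50); v[center] <- 1
    return(v)
  }
  p <- stats::pnorm(idx - center + 0.5, 0, sd) -
    stats::pnorm(idx - center - 0.5, 0, sd)
  p / sum(p)
}

# write a motif into the genome in sense coordinates around a site
plant_motif <- function(genome, chrom, pos, strand, offset, motif) {
  if (strand == "+") {
    start <- pos + offset
    genome[[chrom]] <- str_sub_replace(genome[[chrom]], start, motif)
  } else {
    start <- pos - offset - nchar(motif) + 1L
    genome[[chrom]] <- str_sub_replace(genome[[chrom]], start, revcomp(motif))
  }
  genome
}

#' Plant polyA sites with a motif grammar into a genome
#'
#' Rewrites the sequence around chosen positions in each gene's sense
#' terminal exon to carry the grammar motifs at their sampled offsets, and
#' defines ground-truth strength (monotone in motif content) and per-gene
#' usage fractions (softmax of strength on the log2 scale).  A CA
#' dinucleotide is written at offsets -1..0 so the cleavage position is the
#' first A of its genomic A-run, matching the read-assignment convention.
#'
#' @param genome Named character vector (from [generate_genome()]).
#' @param annotation Exon tibble (from [generate_genome()]).
#' @param grammar A [grammar_spec()].
#' @param sites_per_gene Integer vector of possible site counts per gene.
#' @param seed Integer seed.
#' @return List with the rewritten `genome` and a `sites` truth tibble
#'   (`site_id`, `gene_id`, `chrom`, `pos`, `strand`, `pas_hexamer`,
#'   `cstf_offset`, motif presence flags, `n_optional`, `strength`,
#'   `usage`, `dispersion_sd`).
#' @export
plant_polya_sites <- function(genome, annotation, grammar = grammar_spec(),
                              sites_per_gene = 1:2, seed = 1L) {
  with_seed(seed, {
    genes <- annotation |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
    term <- annotation |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::filter(.data$exon_rank == max(.data$exon_rank)) |>
      dplyr::ungroup()
    out <- list()
    sid <- 0L
    for (gi in seq_len(nrow(term))) {
      te <- term[gi, ]
      n_sites <- sample(rep(sites_per_gene, 2), 1)
      width <- te$end - te$start + 1L
      # keep sites >= 150 nt from exon edges and >= 90 nt apart
      usable <- (te$start + 150L):(te$end - 150L)
      if (length(usable) < 1L) next
      pos <- integer(0)
      for (s in seq_len(n_sites)) {
        cand <- usable[vapply(usable, function(p) all(abs(p - pos) >= 90L),
                              logical(1))]
        if (!length(cand)) break
        pos <- c(pos, sample(rep(cand, 2), 1))
      }
      pos <- sort(pos)
      for (p in pos) {
        sid <- sid + 1L
        pas <- sample(names(grammar$pas_choices), 1,
                      prob = grammar$pas_choices)
        pas_start <- -(grammar$pas_offset + 5L)
        dcst <- sample(rep(grammar$cstf_range, 2), 1)
        has <- c(tgta = runif(1) < grammar$optional_prob[["tgta"]],
                 urich = runif(1) < grammar$optional_prob[["urich"]],
                 cstf2 = runif(1) < grammar$optional_prob[["cstf2"]],
                 grich = runif(1) < grammar$optional_prob[["grich"]])
        genome <- plant_motif(genome, te$chrom, p, te$strand, pas_start, pas)
        genome <- plant_motif(genome, te$chrom, p, te$strand, -1L, "CA")
        genome <- plant_motif(genome, te$chrom, p, te$strand, dcst, "GTGTGT")
        if (has[["tgta"]]) {
          genome <- plant_motif(genome, te$chrom, p, te$strand,
                                sample(-60:-32, 1), "TGTA")
        }
        if (has[["urich"]]) {
          genome <- plant_motif(genome, te$chrom, p, te$strand,
                                sample(-15:-8, 1), "TTTTTT")
        }
        c2 <- NA_integer_
        if (has[["cstf2"]]) {
          c2 <- dcst + sample(7:15, 1)
          genome <- plant_motif(genome, te$chrom, p, te$strand, c2, "TGTCTG")
        }
        if (has[["grich"]]) {
          gstart <- max(dcst + 18L, if (is.na(c2)) -Inf else c2 + 8L)
          genome <- plant_motif(genome, te$chrom, p, te$strand,
                                gstart + sample(0:8, 1), "GGGGGG")
        }
        sd_i <- if (is.null(grammar$cleavage_dispersion)) {
          0.3 + 0.25 * max(0, dcst - 8L)
        } else grammar$cleavage_dispersion
        out[[sid]] <- tibble::tibble(
          site_id = sprintf("site%03d", sid), gene_id = te$gene_id,
          chrom = te$chrom, pos = p, strand = te$strand,
          pas_hexamer = pas, cstf_offset = dcst,
          has_tgta = has[["tgta"]], has_urich = has[["urich"]],
          has_cstf2 = has[["cstf2"]], has_grich = has[["grich"]],
          n_optional = sum(has),
          strength = grammar$strength_base +
            grammar$pas_bonus[[pas]] + grammar$optional_bonus * sum(has),
          dispersion_sd = sd_i)
      }
    }
    sites <- dplyr::bind_rows(out) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(usage = 2^.data$strength / sum(2^.data$strength)) |>
      dplyr::ungroup()
    list(genome = genome, sites = sites)
  })
}

#' Remove accidental signal motifs from the background of a synthetic genome
#'
#' Random background occasionally contains exact polyadenylation signals by
#' chance; in a planted-motif benchmark these make the truth set ambiguous
#' (a scanner that calls them is not wrong).  This rewrites every occurrence
#' of the given motifs (on both strands) that is not within `flank` nt of a
#' planted site by mutating a central base, re-checking that no listed
#' motif is recreated.
#'
#' @param genome Named character vector (typically the planted genome).
#' @param sites Truth tibble from [plant_polya_sites()].
#' @param motifs Sense-strand motifs to scrub; default the PAS hexamers the
#'   default grammar can plant.
#' @param flank Protection radius around planted sites (nt); default 150.
#' @param seed Integer seed.
#' @return The scrubbed genome.
#' @export
scrub_background <- function(genome, sites,
                             motifs = c("AATAAA", "ATTAAA", "AATAAT"),
                             flank = 150L, seed = 1L) {
  pats <- unique(c(motifs, revcomp(motifs)))
  with_seed(seed, {
    for (chrom in names(genome)) {
      seqs <- genome[[chrom]]
      protect <- sites$pos[sites$chrom == chrom]
      changed <- TRUE
      guard <- 0L
      while (changed && guard < 10L) {
        changed <- FALSE
        guard <- guard + 1L
        for (p in pats) {
          # lookahead finds overlapping occurrences too
          hits <- gregexpr(paste0("(?=", p, ")"), seqs, perl = TRUE)[[1]]
          hits <- hits[hits > 0]
          occ_in <- function(s) {
            sort(unique(unlist(lapply(pats, function(q) {
              o <- gregexpr(paste0("(?=", q, ")"), s, perl = TRUE)[[1]]
              o[o > 0]
            }))))
          }
          for (h in hits) {
            if (length(protect) && any(abs(h + 2L - protect) <= flank)) next
            lo <- max(1L, h - 5L); hi <- min(nchar(seqs), h + 10L)
            before <- occ_in(substr(seqs, lo, hi))
            done <- FALSE
            for (mid in c(h + 2L, h + 3L)) {
              cur <- substr(seqs, mid, mid)
              for (b in sample(setdiff(c("A", "C", "G", "T"), cur))) {
                cand <- str_sub_replace(seqs, mid, b)
                after <- occ_in(substr(cand, lo, hi))
                # the edit must remove this occurrence and create no new one
                if (!((h - lo + 1L) %in% after) &&
                    all(after %in% setdiff(before, h - lo + 1L))) {
                  seqs <- cand
                  changed <- TRUE
                  done <- TRUE
                  break
                }
              }
              if (done) break
            }
          }
        }
      }
      genome[[chrom]] <- seqs
    }
    genome
  })
}

# sense-strand A-run length starting at (and including) genomic position g;
# 0 if the base at g is not a sense A
sense_a_run_down <- function(chrom_chars, g, strand, max_run = 50L) {
  base <- if (strand == "+") "A" else "T"
  dir <- if (strand == "+") 1L else -1L
  n <- 0L
  while (n < max_run) {
    p <- g + dir * n
    if (p < 1L || p > length(chrom_chars) || chrom_chars[p] != base) break
    n <- n + 1L
  }
  n
}

#' Simulate PASS-read alignments around planted sites
#'
#' Per site and sample, read counts are Poisson with mean
#' `usage * depth`; read 3' ends are drawn from a discretised Gaussian
#' (site-specific sd) truncated at +/-25 nt.  Each read carries a
#' non-genomic A tail of 2-10 nt; when the cleavage position abuts a
#' genomic A-run the aligner is emulated by extending the alignment through
#' the matching reference As (so the first-A assignment convention in
#' [extract_pass_reads()] is exercised).  A small fraction of reads is
#' emitted with low mapping quality or a secondary flag to exercise the
#' uniqueness filter.
#'
#' @param genome Named character vector.
#' @param sites Truth tibble from [plant_polya_sites()].
#' @param depth Expected PASS reads per gene and sample.
#' @param samples Tibble with `sample_id` and `lineage` (one row per
#'   library).
#' @param frac_low_mapq,frac_secondary Fractions of degraded reads.
#' @param seed Integer seed.
#' @return List with `alignments` (tibble: `read_id`, `chrom`, `strand`,
#'   `align_end`, `tail`, `mapq`, `secondary`, `sample_id`, `lineage`) and
#'   `truth` (read-level tibble with the intended cleavage position and
#'   source site).
#' @export
simulate_pass_reads <- function(genome, sites, depth = 150,
                                samples = tibble::tibble(
                                  sample_id = c("s1", "s2"),
                                  lineage = c("L1", "L2")),
                                frac_low_mapq = 0.02,
                                frac_secondary = 0.01,
                                seed = 1L) {
  stopifnot(depth > 0)
  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  runs <- lapply(chars, function(cc) list(A = base_run_table(cc, "A"),
                                          T = base_run_table(cc, "T")))
  with_seed(seed, {
    parts <- list()
    for (i in seq_len(nrow(sites))) {
      st <- sites[i, ]
      dir <- if (st$strand == "+") 1L else -1L
      rt <- if (st$strand == "+") runs[[st$chrom]]$A else runs[[st$chrom]]$T
      for (j in seq_len(nrow(samples))) {
        n <- rpois(1, st$usage * depth)
        if (n == 0) next
        offs <- pmin(pmax(round(rnorm(n, 0, st$dispersion_sd)), -25L), 25L)
        p_cleave <- st$pos + dir * offs
        nxt <- p_cleave + dir
        # aligner extension through reference As downstream of the cleavage
        k <- integer(n)
        inb <- nxt >= 1L & nxt <= length(rt$is_base)
        hit <- inb & rt$is_base[pmax(pmin(nxt, length(rt$is_base)), 1L)]
        k[hit] <- if (st$strand == "+") {
          rt$end[nxt[hit]] - nxt[hit] + 1L
        } else {
          nxt[hit] - rt$start[nxt[hit]] + 1L
        }
        parts[[length(parts) + 1L]] <- tibble::tibble(
          chrom = st$chrom, strand = st$strand,
          align_end = p_cleave + dir * k,
          tail = strrep("A", sample(2:10, n, replace = TRUE)),
          mapq = ifelse(runif(n) < frac_low_mapq, 3L, 60L),
          secondary = runif(n) < frac_secondary,
          sample_id = samples$sample_id[j],
          lineage = samples$lineage[j],
          site_id = st$site_id, gene_id = st$gene_id,
          intended_cleavage = p_cleave)
      }
    }
    all <- dplyr::bind_rows(parts)
    all$read_id <- sprintf("r%06d", seq_len(nrow(all)))
    list(alignments = dplyr::select(all, "read_id", "chrom", "strand",
                                    "align_end", "tail", "mapq", "secondary",
                                    "sample_id", "lineage"),
         truth = dplyr::select(all, "read_id", "site_id", "gene_id",
                               "intended_cleavage"))
  })
}

#' Simulate point variants with known effects on polyA signals
#'
#' Produces a balanced mix of PAS-destroying variants (a canonical AATAAA
#' broken to AACAAA at a planted site), PAS-creating variants (a planted
#' broken signal AATAAT repaired to AATAAA), and neutral variants far from
#' any planted site, with left-normalised single-nucleotide records.
#'
#' @param genome Named character vector (with planted sites).
#' @param sites Truth tibble from [plant_polya_sites()].
#' @param n_neutral Number of neutral variants.
#' @param pas_offset Offset of the PAS start relative to cleavage
#'   (default -26, matching the default grammar).
#' @param min_isolation Minimum distance (nt) to any other planted site for
#'   a site to receive a variant; default 250, so the +/-120-nt scan around
#'   the variant cannot be dominated by an unaffected neighbouring site and
#'   the intended effect is unambiguous.
#' @param max_dispersion Maximum cleavage dispersion (sd, nt) of target
#'   sites; default 2.  Highly dispersed sites have diffuse, ill-defined
#'   cleavage, so a variant's "intended" effect on them is ambiguous.
#' @param seed Integer seed.
#' @return Tibble: `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `strand` (gene strand; `"+"` for neutral), `intended_effect`
#'   (`create` / `destroy` / `none`), `site_id`.
#' @export
simulate_variants <- function(genome, sites, n_neutral = 10L,
                              pas_offset = -26L, min_isolation = 250L,
                              max_dispersion = 2, seed = 1L) {
  iso <- vapply(seq_len(nrow(sites)), function(i) {
    d <- abs(sites$pos[-i][sites$chrom[-i] == sites$chrom[i]] -
               sites$pos[i])
    !length(d) || min(d) >= min_isolation
  }, logical(1))
  if ("dispersion_sd" %in% names(sites)) {
    iso <- iso & sites$dispersion_sd <= max_dispersion
  }
  all_sites <- sites
  sites <- sites[iso, , drop = FALSE]
  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sense_variant <- function(st, offset, alt_sense) {
    # genomic record for a sense-strand substitution at `offset` from pos
    if (st$strand == "+") {
      gpos <- st$pos + offset
      ref <- chars[[st$chrom]][gpos]
      alt <- alt_sense
    } else {
      gpos <- st$pos - offset
      ref <- chars[[st$chrom]][gpos]
      alt <- comp[[alt_sense]]
    }
    list(pos = gpos, ref = ref, alt = alt)
  }
  with_seed(seed, {
    out <- list(); vid <- 0L
    destroyable <- sites[sites$pas_hexamer == "AATAAA", ]
    for (i in seq_len(nrow(destroyable))) {
      st <- destroyable[i, ]
      # break the canonical signal to the weak AATAAT (the grammar's
      # broken-PAS class, the exact inverse of a creating variant),
      # falling back to other in-hexamer substitutions; reject edits whose
      # flanking sequence recreates a shifted functional PAS
      win <- extract_window(genome, st$chrom, st$pos, st$strand)
      ok_edit <- NULL
      for (edit in list(list(off = 5L, b = "T"), list(off = 2L, b = "C"),
                        list(off = 3L, b = "C"), list(off = 4L, b = "C"))) {
        ctx <- substr(win, 87, 108)        # sense offsets -34..-13
        local <- 95L + edit$off - 87L + 1L # hexamer starts at window 95
        ctx_alt <- str_sub_replace(ctx, local, edit$b)
        if (!grepl("AATAAA|ATTAAA", ctx_alt)) {
          ok_edit <- edit
          break
        }
      }
      if (is.null(ok_edit)) next
      v <- sense_variant(st, pas_offset + ok_edit$off, ok_edit$b)
      vid <- vid + 1L
      out[[vid]] <- tibble::tibble(variant_id = sprintf("var%03d", vid),
                                   chrom = st$chrom, pos = v$pos,
                                   ref = v$ref, alt = v$alt,
                                   strand = st$strand,
                                   intended_effect = "destroy",
                                   site_id = st$site_id)
    }
    creatable <- sites[sites$pas_hexamer == "AATAAT", ]
    for (i in seq_len(nrow(creatable))) {
      st <- creatable[i, ]
      v <- sense_variant(st, pas_offset + 5L, "A")   # AATAAT -> AATAAA
      vid <- vid + 1L
      out[[vid]] <- tibble::tibble(variant_id = sprintf("var%03d", vid),
                                   chrom = st$chrom, pos = v$pos,
                                   ref = v$ref, alt = v$alt,
                                   strand = st$strand,
                                   intended_effect = "create",
                                   site_id = st$site_id)
    }
    chrom <- names(genome)[1]
    cc <- chars[[chrom]]
    drawn <- 0L; guard <- 0L
    while (drawn < n_neutral && guard < 500L) {
      guard <- guard + 1L
      gpos <- sample(200:(length(cc) - 200L), 1)
      if (any(abs(gpos - all_sites$pos[all_sites$chrom == chrom]) <
                200L)) next
      ref <- cc[gpos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      # avoid accidentally creating or destroying a canonical signal
      ctx <- cc[max(1, gpos - 5L):min(length(cc), gpos + 5L)]
      ctx_alt <- ctx
      ctx_alt[gpos - max(1, gpos - 5L) + 1L] <- alt
      pat <- function(x) paste(x, collapse = "")
      if (grepl("AATAAA|ATTAAA|TTTATT|TTTAAT", pat(ctx)) ||
          grepl("AATAAA|ATTAAA|TTTATT|TTTAAT", pat(ctx_alt))) next
      drawn <- drawn + 1L; vid <- vid + 1L
      out[[vid]] <- tibble::tibble(variant_id = sprintf("var%03d", vid),
                                   chrom = chrom, pos = gpos,
                                   ref = ref, alt = alt, strand = "+",
                                   intended_effect = "none",
                                   site_id = NA_character_)
    }
    dplyr::bind_rows(out)
  })
}
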