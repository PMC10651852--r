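#' Extract polyA-site-supporting (PASS) reads from alignments
#'
#' A read qualifies as a PASS read when it is uniquely mapped (mapping
#' quality at or above `min_mapq` and not a secondary alignment) and its
#' soft-clipped tail contains at least `min_tail_a` As that do not match the
#' reference downstream of the alignment end.  When the (possibly extended)
#' alignment end falls inside a genomic A-run the cleavage position is
#' assigned to the first A of that run, because the terminal genomic As
#' cannot be distinguished from polyadenylation.  Minus-strand reads are
#' handled by mirroring: their tails are leading reference Ts, and all
#' positions are reported in transcript sense.
#'
#' @param alignments Tibble with `chrom`, `strand`, `align_end` (genomic
#'   coordinate of the 3'-most aligned base in transcript sense), `tail`
#'   (soft-clipped tail in sense orientation, i.e. a run of As) and
#'   optionally `mapq`, `secondary`, `sample_id`, `lineage`.
#' @param genome Named character vector of chromosome sequences.
#' @param min_tail_a Minimum non-genomic As; default 2.
#' @param min_mapq Mapping-quality cutoff defining "uniquely mapped";
#'   default 10.
#' @param sample_map Optional tibble (`sample_id`, `lineage`) used when
#'   `alignments` lacks a lineage column.
#' @return Tibble of PASS reads (`chrom`, `cleavage_pos`, `strand`,
#'   `n_nongenomic_a`, `sample_id`, `lineage`).  Rejected reads, with
#'   reasons, are attached as the `"rejected"` attribute.
#' @export
extract_pass_reads <- function(alignments, genome, min_tail_a = 2L,
                               min_mapq = 10L, sample_map = NULL) {
  al <- tibble::as_tibble(alignments)
  if (!"mapq" %in% names(al)) al$mapq <- 60L
  if (!"secondary" %in% names(al)) al$secondary <- FALSE
  if (!"sample_id" %in% names(al)) al$sample_id <- "sample1"
  if (!"lineage" %in% names(al) && !is.null(sample_map)) {
    al <- dplyr::left_join(al, sample_map, by = "sample_id")
  }
  if (!"lineage" %in% names(al)) al$lineage <- al$sample_id

  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  runsA <- lapply(chars, base_run_table, base = "A")
  runsT <- lapply(chars, base_run_table, base = "T")
  n <- nrow(al)
  keep <- logical(n)
  reason <- character(n)
  cleavage <- integer(n)
  nga <- integer(n)
  tail_lens <- nchar(gsub("[^A]", "", toupper(ifelse(is.na(al$tail), "",
                                                     al$tail))))
  for (grp in split(seq_len(n),
                    paste(al$chrom, al$strand))) {
    chrom <- al$chrom[grp[1]]
    strand <- al$strand[grp[1]]
    if (!chrom %in% names(chars)) { reason[grp] <- "unknown_chromosome"; next }
    clen <- length(chars[[chrom]])
    rt <- if (strand == "+") runsA[[chrom]] else runsT[[chrom]]
    dir <- if (strand == "+") 1L else -1L
    e <- al$align_end[grp]
    bad_pos <- e < 1L | e > clen
    bad_tail <- is.na(al$tail[grp]) | !nzchar(al$tail[grp])
    bad_uniq <- al$secondary[grp] | al$mapq[grp] < min_mapq
    tl <- tail_lens[grp]
    # reference As immediately downstream of the alignment end absorb
    # matching tail As (they may be genomic)
    nxt <- pmin(pmax(e + dir, 1L), clen)
    g <- integer(length(grp))
    inb <- (e + dir) >= 1L & (e + dir) <= clen
    hit <- inb & rt$is_base[nxt]
    g[hit] <- if (strand == "+") rt$end[nxt[hit]] - nxt[hit] + 1L
    else nxt[hit] - rt$start[nxt[hit]] + 1L
    matched <- pmin(g, tl)
    nng <- tl - matched
    too_few <- nng < min_tail_a
    e2 <- pmin(pmax(e + dir * matched, 1L), clen)
    # first-A assignment: jump to the start of the A-run containing e2
    cl <- e2
    on_a <- rt$is_base[e2]
    cl[on_a] <- if (strand == "+") rt$start[e2[on_a]] else rt$end[e2[on_a]]
    ok <- !bad_pos & !bad_tail & !bad_uniq & !too_few
    keep[grp] <- ok
    cleavage[grp] <- cl
    nga[grp] <- nng
    reason[grp] <- dplyr::case_when(
      bad_pos ~ "off_chromosome",
      bad_tail ~ "no_tail",
      bad_uniq ~ "not_unique",
      too_few ~ "too_few_nongenomic_a",
      TRUE ~ "")
  }
  out <- tibble::tibble(chrom = al$chrom[keep], cleavage_pos = cleavage[keep],
                        strand = al$strand[keep], n_nongenomic_a = nga[keep],
                        sample_id = al$sample_id[keep],
                        lineage = al$lineage[keep])
  rej <- al[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  attr(out, "rejected") <- rej
  out
}

#' Cluster PASS-read cleavage positions into polyA sites
#'
#' Greedy clustering per chromosome and strand: the position with the most
#' PASS reads seeds a cluster (ties broken to the 5'-most position,
#' strand-aware); all positions within `window` nt join it; the seed is the
#' representative position; repeat on the remainder.  Every read is
#' assigned to exactly one cluster, so read counts are conserved.
#'
#' @param reads PASS-read tibble from [extract_pass_reads()].
#' @param window Clustering half-width (nt); default 24.
#' @return Site tibble: `site_id`, `chrom`, `strand`, `pos`,
#'   `read_count_total`, and a `read_count_by_lineage` list-column of named
#'   integer vectors.
#' @export
cluster_sites <- function(reads, window = 24L) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(site_id = character(), chrom = character(),
                          strand = character(), pos = integer(),
                          read_count_total = integer(),
                          read_count_by_lineage = list()))
  }
  groups <- reads |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_split()
  out <- lapply(groups, function(g) {
    counts <- g |>
      dplyr::count(.data$cleavage_pos, name = "n") |>
      dplyr::arrange(.data$cleavage_pos)
    strand <- g$strand[1]
    res <- list()
    while (nrow(counts) > 0) {
      mx <- max(counts$n)
      cand <- counts$cleavage_pos[counts$n == mx]
      seed <- five_prime_most(cand, strand)
      member <- abs(counts$cleavage_pos - seed) <= window
      in_cluster <- g$cleavage_pos %in% counts$cleavage_pos[member]
      lin <- table(g$lineage[in_cluster])
      res[[length(res) + 1L]] <- tibble::tibble(
        chrom = g$chrom[1], strand = strand, pos = seed,
        read_count_total = sum(counts$n[member]),
        read_count_by_lineage = list(
          stats::setNames(as.integer(lin), names(lin))))
      counts <- counts[!member, , drop = FALSE]
    }
    dplyr::bind_rows(res)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos) |>
    dplyr::mutate(site_id = sprintf("pa%05d", dplyr::row_number()),
                  .before = 1)
}

#' Filter called sites by read support and relative expression
#'
#' Keeps sites supported by at least `min_reads` total PASS reads whose
#' expression relative to the gene's total PASS reads exceeds `min_frac` in
#' at least one cell/tissue lineage.
#'
#' @param sites Site tibble (with `gene_id` and `read_count_by_lineage`;
#'   see [assign_sites_to_genes()]).
#' @param gene_read_totals Tibble `gene_id`, `lineage`, `reads` (per-lineage
#'   gene totals); computed with [gene_totals_from_sites()] if omitted.
#' @param min_reads Minimum total read support; default 10.
#' @param min_frac Minimum within-gene fraction in some lineage (strictly
#'   exceeded); default 0.02.
#' @return The filtered site tibble; removed sites with reasons are attached
#'   as the `"removed"` attribute.  Sites without a gene (intergenic) are
#'   judged on read support alone.
#' @export
filter_sites <- function(sites, gene_read_totals = NULL, min_reads = 10L,
                         min_frac = 0.02) {
  if (is.null(gene_read_totals)) {
    gene_read_totals <- gene_totals_from_sites(sites)
  }
  frac_ok <- vapply(seq_len(nrow(sites)), function(i) {
    gid <- sites$gene_id[i]
    if (is.na(gid)) return(TRUE)
    lin <- sites$read_count_by_lineage[[i]]
    tot <- gene_read_totals[gene_read_totals$gene_id == gid, ]
    if (nrow(tot) == 0 || all(tot$reads == 0)) return(NA)
    any(vapply(names(lin), function(l) {
      gl <- tot$reads[tot$lineage == l]
      length(gl) == 1 && gl > 0 && lin[[l]] / gl > min_frac
    }, logical(1)))
  }, logical(1))
  reads_ok <- sites$read_count_total >= min_reads
  keep <- reads_ok & !is.na(frac_ok) & frac_ok
  removed <- sites[!keep, , drop = FALSE]
  removed$reason <- dplyr::case_when(
    !reads_ok[!keep] ~ "below_min_reads",
    is.na(frac_ok[!keep]) ~ "gene_total_zero",
    TRUE ~ "below_min_fraction")
  out <- sites[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Per-lineage gene read totals from called sites
#'
#' @param sites Site tibble with `gene_id` and `read_count_by_lineage`.
#' @return Tibble `gene_id`, `lineage`, `reads`.
#' @export
gene_totals_from_sites <- function(sites) {
  sites |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::mutate(.lin = lapply(.data$read_count_by_lineage, function(x) {
      tibble::tibble(lineage = names(x), reads = as.integer(x))
    })) |>
    dplyr::select("gene_id", ".lin") |>
    tidyr::unnest(".lin") |>
    dplyr::group_by(.data$gene_id, .data$lineage) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
}

#' Extend gene 3' ends for terminal-exon site capture
#'
#' Each gene's 3' end is extended downstream by at most `max_ext` nt, never
#' reaching the transcription start site of the next gene on the same
#' strand, and clamped at the chromosome end.
#'
#' @param annotation Exon-level annotation tibble.
#' @param max_ext Maximum extension (nt); default 5000.
#' @param chrom_sizes Named integer vector of chromosome lengths (optional).
#' @return Tibble `gene_id`, `chrom`, `strand`, `ext_start`, `ext_end`,
#'   `ext_len` (the half-open extension interval downstream of the gene in
#'   sense direction; `ext_len` can be 0).
#' @export
extend_terminal_exon <- function(annotation, max_ext = 5000L,
                                 chrom_sizes = NULL) {
  genes <- annotation |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    same <- genes[genes$chrom == g$chrom & genes$strand == g$strand &
                    genes$gene_id != g$gene_id, ]
    if (g$strand == "+") {
      tss <- same$start[same$start > g$end]
      gap <- if (length(tss)) min(tss) - g$end - 1L else Inf
      lim <- if (!is.null(chrom_sizes)) chrom_sizes[[g$chrom]] - g$end else Inf
      len <- max(0L, min(max_ext, gap, lim))
      tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = "+",
                     ext_start = g$end + 1L, ext_end = g$end + len,
                     ext_len = as.integer(len))
    } else {
      tss <- same$end[same$end < g$start]
      gap <- if (length(tss)) g$start - max(tss) - 1L else Inf
      lim <- g$start - 1L
      len <- max(0L, min(max_ext, gap, lim))
      tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = "-",
                     ext_start = g$start - len, ext_end = g$start - 1L,
                     ext_len = as.integer(len))
    }
  })
  dplyr::bind_rows(out)
}

#' Assign called sites to genes
#'
#' A site is assigned to the gene whose span (optionally plus its 3'
#' extension) contains it on the matching strand; when several genes match,
#' the one whose body (rather than extension) contains the site wins.
#'
#' @param sites Site tibble.
#' @param annotation Exon-level annotation tibble.
#' @param extensions Optional extension tibble from [extend_terminal_exon()].
#' @return `sites` with a `gene_id` column (NA when intergenic).
#' @export
assign_sites_to_genes <- function(sites, annotation, extensions = NULL) {
  genes <- annotation |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  sites$gene_id <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    hit <- genes$gene_id[genes$chrom == s$chrom & genes$strand == s$strand &
                           genes$start <= s$pos & genes$end >= s$pos]
    if (length(hit)) return(hit[1])
    if (!is.null(extensions)) {
      hit <- extensions$gene_id[extensions$chrom == s$chrom &
                                  extensions$strand == s$strand &
                                  extensions$ext_start <= s$pos &
                                  extensions$ext_end >= s$pos]
      if (length(hit)) return(hit[1])
    }
    NA_character_
  }, character(1))
  sites
}

#' Call expressed polyA sites from alignments end-to-end
#'
#' Convenience pipeline: [extract_pass_reads()] then [cluster_sites()],
#' gene assignment and [filter_sites()].
#'
#' @inheritParams extract_pass_reads
#' @inheritParams cluster_sites
#' @inheritParams filter_sites
#' @param annotation Exon-level annotation tibble.
#' @param max_ext Terminal extension limit passed to
#'   [extend_terminal_exon()].
#' @return Filtered site tibble with gene assignments.
#' @export
call_polya_sites <- function(alignments, genome, annotation,
                             window = 24L, min_reads = 10L, min_frac = 0.02,
                             min_tail_a = 2L, min_mapq = 10L,
                             max_ext = 5000L, sample_map = NULL) {
  reads <- extract_pass_reads(alignments, genome, min_tail_a, min_mapq,
                              sample_map)
  sites <- cluster_sites(reads, window)
  ext <- extend_terminal_exon(annotation, max_ext,
                              vapply(genome, nchar, integer(1)))
  sites <- assign_sites_to_genes(sites, annotation, ext)
  filter_sites(sites, min_reads = min_reads, min_frac = min_frac)
}
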