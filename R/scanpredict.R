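#' Scan a sequence with PolyaID at 1-nt steps
#'
#' Applies the model to the 240-nt window anchored at every position of the
#' sequence (excluding 120-nt flanks needed for the window).  A position is
#' `retained` when the classification probability exceeds `p_class_min` and
#' the centre of the cleavage probability vector (offset 0) exceeds
#' `center_min`, restricting positives to those showing cleavage in the
#' middle.
#'
#' @param seq A character scalar (nascent, sense-orientation sequence).
#' @param model A trained PolyaID `polya_model`, or a function taking a
#'   character vector of windows and returning a list with `p_class` and a
#'   `50 x N` `cleavage` matrix (useful for stubs).
#' @param step Scan step (nt); default 1.
#' @param p_class_min,center_min Retention thresholds (defaults 0.5, 0.05;
#'   both strict).
#' @return Tibble of scan records: `anchor_pos` (position in `seq`),
#'   `p_class`, `center_prob`, `cleavage` (list of length-50 vectors),
#'   `retained`.
#' @export
scan_sequence <- function(seq, model, step = 1L,
                          p_class_min = 0.5, center_min = 0.05) {
  n <- nchar(seq)
  if (n < 240L) {
    return(tibble::tibble(anchor_pos = integer(), p_class = numeric(),
                          center_prob = numeric(), cleavage = list(),
                          retained = logical()))
  }
  anchors <- seq.int(121L, n - 119L, by = step)
  windows <- substring(seq, anchors - 120L, anchors + 119L)
  out <- if (is.function(model)) {
    model(windows)
  } else {
    predict_raw(model, windows)
  }
  p <- as.numeric(out$p_class)
  clv <- out$cleavage
  center <- clv[26L, ]
  tibble::tibble(
    anchor_pos = anchors, p_class = p, center_prob = as.numeric(center),
    cleavage = lapply(asplit(clv, 2), as.numeric),
    retained = p > p_class_min & center > center_min)
}

#' Scan a genomic region with PolyaID
#'
#' Strand-aware wrapper around [scan_sequence()]: windows are taken from the
#' nascent (unspliced) sense sequence and anchor positions are reported as
#' genomic coordinates.
#'
#' @param genome Named character vector.
#' @param chrom,start,end Region to scan (1-based inclusive; every position
#'   gets a record, so the region plus 120-nt flanks must lie on the
#'   chromosome).
#' @param strand `"+"` or `"-"`.
#' @inheritParams scan_sequence
#' @return Tibble as [scan_sequence()] with genomic `anchor_pos`, plus
#'   `chrom` and `strand` columns.
#' @export
scan_region <- function(genome, chrom, start, end, strand = "+", model,
                        step = 1L, p_class_min = 0.5, center_min = 0.05) {
  anchors <- seq.int(start, end, by = step)
  n <- nchar(genome[[chrom]])
  anchors <- anchors[anchors - 120L >= 1L & anchors + 120L <= n]
  if (length(anchors)) {
    # one slab extraction (and a single reverse complement on the minus
    # strand) instead of per-anchor window calls
    lo <- min(anchors) - 120L
    hi <- max(anchors) + 120L
    slab <- substr(genome[[chrom]], lo, hi)
    if (strand == "+") {
      offs <- anchors - lo + 1L
      windows <- substring(slab, offs - 120L, offs + 119L)
    } else {
      slab <- revcomp(slab)
      offs <- hi - anchors + 1L
      windows <- substring(slab, offs - 120L, offs + 119L)
    }
  } else {
    windows <- character(0)
  }
  if (!length(anchors)) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          anchor_pos = integer(), p_class = numeric(),
                          center_prob = numeric(), cleavage = list(),
                          retained = logical()))
  }
  out <- if (is.function(model)) model(windows) else predict_raw(model, windows)
  p <- as.numeric(out$p_class)
  clv <- out$cleavage
  tibble::tibble(
    chrom = chrom, strand = strand, anchor_pos = anchors,
    p_class = p, center_prob = as.numeric(clv[26L, ]),
    cleavage = lapply(asplit(clv, 2), as.numeric),
    retained = p > p_class_min & clv[26L, ] > center_min)
}

#' Consolidate retained scan records into putative polyA sites
#'
#' Retained anchors are grouped into positive clusters (maximal runs with
#' inter-anchor gap at most `gap`).  Within a cluster each record's cleavage
#' vector is background-subtracted (0.02, floored at zero), renormalised,
#' projected onto genomic/sequence coordinates, and averaged position-wise
#' over the contributing records; the position with maximum averaged
#' probability is the representative site (ties to the 5'-most position,
#' strand-aware).  The consolidated vector reported for each site is the
#' averaged profile re-windowed to offsets -25..+24 around the
#' representative and renormalised.
#'
#' @param records Scan-record tibble from [scan_sequence()] /
#'   [scan_region()].
#' @param gap Maximum anchor gap within a cluster; default 0 (contiguous).
#' @param background Background cleavage probability to subtract (0.02).
#' @param subtract_first If `TRUE` (default) vectors are
#'   background-subtracted before averaging; set `FALSE` to average raw
#'   vectors.
#' @return Putative-site tibble: `pos`, `strand`, `p_class_max`,
#'   `cleavage` (list of consolidated length-50 vectors summing to 1),
#'   `mcp`, `entropy`, `n_records`, `cluster_start`, `cluster_end` (and
#'   `chrom` when present in `records`).
#' @export
consolidate <- function(records, gap = 0L, background = 0.02,
                        subtract_first = TRUE) {
  ret <- records[records$retained, , drop = FALSE]
  empty <- tibble::tibble(pos = integer(), strand = character(),
                          p_class_max = numeric(), cleavage = list(),
                          mcp = numeric(), entropy = numeric(),
                          n_records = integer(), cluster_start = integer(),
                          cluster_end = integer())
  if (nrow(ret) == 0) return(empty)
  strand <- if ("strand" %in% names(ret)) ret$strand[1] else "+"
  ret <- ret[order(ret$anchor_pos), , drop = FALSE]
  cluster_id <- cumsum(c(1L, diff(ret$anchor_pos) > (gap + 1L)))
  out <- lapply(split(seq_len(nrow(ret)), cluster_id), function(ii) {
    sub <- ret[ii, , drop = FALSE]
    pool <- list()
    for (r in seq_len(nrow(sub))) {
      v <- sub$cleavage[[r]]
      if (subtract_first) {
        v <- pmax(v - background, 0)
        if (sum(v) <= 0) next
        v <- v / sum(v)
      }
      gpos <- index_to_genomic(sub$anchor_pos[r], 1:50, strand)
      pool[[length(pool) + 1L]] <- tibble::tibble(gpos = gpos, p = v)
    }
    if (!length(pool)) return(NULL)
    overlay <- dplyr::bind_rows(pool) |>
      dplyr::group_by(.data$gpos) |>
      dplyr::summarise(p = sum(.data$p), .groups = "drop") |>
      dplyr::mutate(p = .data$p / length(pool))
    mx <- max(overlay$p)
    rep_pos <- five_prime_most(overlay$gpos[overlay$p == mx], strand)
    idx <- 1:50
    gwin <- index_to_genomic(rep_pos, idx, strand)
    v <- overlay$p[match(gwin, overlay$gpos)]
    v[is.na(v)] <- 0
    v <- v / sum(v)
    tibble::tibble(
      chrom = if ("chrom" %in% names(sub)) sub$chrom[1] else NA_character_,
      pos = rep_pos, strand = strand,
      p_class_max = max(sub$p_class), cleavage = list(v),
      mcp = mean_cleavage_position(v), entropy = cleavage_entropy(v),
      n_records = nrow(sub),
      cluster_start = min(sub$anchor_pos), cluster_end = max(sub$anchor_pos))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  if (all(is.na(res$chrom))) res$chrom <- NULL
  res
}

#' Mean cleavage position of a cleavage vector
#'
#' The probability-weighted mean index \eqn{m = \sum_{i=1}^{50} p_i i}
#' (1-based vector index; index 26 is the anchor).
#'
#' @param v Length-50 probability vector; renormalised with a warning when
#'   it does not sum to 1.
#' @return The mean cleavage position (real-valued index).
#' @export
mean_cleavage_position <- function(v) {
  v <- stop_if_not_simplex(v)
  sum(v * seq_along(v))
}

#' Classify sites by genomic location
#'
#' Assigns each site one of `terminal_exonic`, `upstream_exonic`,
#' `intronic`, `extended_terminal_exonic`, `intergenic` based on the gene
#' annotation and the 3' extensions, with precedence in that order when
#' isoforms or overlapping genes conflict.
#'
#' @param sites Site tibble (`chrom`, `pos`, `strand`).
#' @param annotation Exon-level annotation tibble.
#' @param extensions Extension tibble from [extend_terminal_exon()]
#'   (computed on the fly if omitted).
#' @return `sites` with an added `genomic_class` column.
#' @export
classify_genomic_location <- function(sites, annotation, extensions = NULL) {
  if (is.null(extensions)) extensions <- extend_terminal_exon(annotation)
  term <- annotation |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(.data$exon_rank == max(.data$exon_rank)) |>
    dplyr::ungroup()
  genes <- annotation |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  hit <- function(df, s) {
    df$chrom == s$chrom & df$strand == s$strand &
      df$start <= s$pos & df$end >= s$pos
  }
  sites$genomic_class <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    if (any(hit(term, s))) return("terminal_exonic")
    in_exon <- annotation$chrom == s$chrom & annotation$strand == s$strand &
      annotation$start <= s$pos & annotation$end >= s$pos
    if (any(in_exon)) return("upstream_exonic")
    if (any(hit(genes, s))) return("intronic")
    in_ext <- extensions$chrom == s$chrom & extensions$strand == s$strand &
      extensions$ext_start <= s$pos & extensions$ext_end >= s$pos &
      extensions$ext_len > 0
    if (any(in_ext)) return("extended_terminal_exonic")
    "intergenic"
  }, character(1))
  sites
}

#' Predict the effect of point variants on polyA sites
#'
#' For each variant that changes an important hexamer (in either allele),
#' both alleles are scanned at 1-nt steps within +/-120 nt of the variant
#' over identical anchor sets, predictions are consolidated, and the
#' PolyaStrength score is taken at each allele's representative cleavage
#' position.  A variant is called significant when the maximum
#' classification probability across alleles reaches `p_min`, the maximum
#' strength reaches `strength_min`, and |delta strength| reaches
#' `delta_min` (thresholds 0.9 / -9 / 1).  For intronic sites an optional
#' usage classifier gates significance at expression probability >= 0.9.
#'
#' @param variants Tibble: `variant_id`, `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `strand` (default `"+"`).
#' @param genome Named character vector.
#' @param polyaid,polyastrength Trained models.
#' @param important_hexamers Character vector of significant hexamers (from
#'   [significant_hexamers()]); variants touching none are skipped.
#' @param annotation,extensions Optional annotation for the intronic gate
#'   and the extended-region distance rule (sites in extensions more than
#'   `max_ext_dist` nt past the annotated 3' end are not called).
#' @param intronic_classifier Optional `usage_classifier` for the intronic
#'   expression-probability gate (requires `annotation`).
#' @param p_min,strength_min,delta_min Significance thresholds.
#' @param max_ext_dist Maximum distance past the annotated 3' end (nt).
#' @return Tibble with one row per evaluated variant: allele-wise site
#'   positions, classification probabilities and strengths,
#'   `delta_strength` and `significant`.  Variants touching no important
#'   hexamer get `evaluated = FALSE` and NA effect columns.
#' @export
predict_variant_effect <- function(variants, genome, polyaid, polyastrength,
                                   important_hexamers,
                                   annotation = NULL, extensions = NULL,
                                   intronic_classifier = NULL,
                                   p_min = 0.9, strength_min = -9,
                                   delta_min = 1, max_ext_dist = 1000L) {
  if (!"strand" %in% names(variants)) variants$strand <- "+"
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    chrom_seq <- genome[[v$chrom]]
    stopifnot(substr(chrom_seq, v$pos, v$pos) == v$ref)
    base <- tibble::tibble(variant_id = v$variant_id, chrom = v$chrom,
                           pos = v$pos, ref = v$ref, alt = v$alt,
                           strand = v$strand)
    # local sequence large enough for +/-120 anchors with 240-nt windows
    lo <- v$pos - 245L; hi <- v$pos + 245L
    if (lo < 1L || hi > nchar(chrom_seq)) {
      return(dplyr::mutate(base, evaluated = FALSE))
    }
    ref_local <- substr(chrom_seq, lo, hi)
    alt_local <- str_sub_replace(ref_local, v$pos - lo + 1L, v$alt)
    vpos_local <- v$pos - lo + 1L
    # does either allele carry an important hexamer across the variant?
    # (hexamers are read on both strands: the important set is in sense
    # orientation, the local sequence in reference orientation)
    touch <- function(s) {
      starts <- max(1L, vpos_local - 5L):vpos_local
      hex <- substring(s, starts, starts + 5L)
      any(hex %in% important_hexamers) ||
        any(revcomp(hex) %in% important_hexamers)
    }
    if (!touch(ref_local) && !touch(alt_local)) {
      return(dplyr::mutate(base, evaluated = FALSE))
    }
    sense <- function(s) if (v$strand == "+") s else revcomp(s)
    vpos_sense <- if (v$strand == "+") vpos_local
    else nchar(ref_local) - vpos_local + 1L
    scan_allele <- function(local_seq) {
      recs <- scan_sequence(sense(local_seq), polyaid)
      cons <- consolidate(recs)
      list(records = recs, sites = cons)
    }
    ref_scan <- scan_allele(ref_local)
    alt_scan <- scan_allele(alt_local)
    to_genomic <- function(seq_pos) {
      if (v$strand == "+") lo + seq_pos - 1L else hi - seq_pos + 1L
    }
    pick_rep <- function(sc) {
      if (nrow(sc$sites) == 0) return(NA_integer_)
      # the representative is the most confident positive cluster among
      # those the variant can plausibly act on (its position within 50 nt
      # of the variant, the span of PAS-to-cleavage geometries); if none
      # is nearby, the overall best cluster
      cand <- sc$sites[abs(sc$sites$pos - vpos_sense) <= 50L, ]
      if (nrow(cand) == 0) cand <- sc$sites
      cand$pos[which.max(cand$p_class_max)]
    }
    rep_ref <- pick_rep(ref_scan); rep_alt <- pick_rep(alt_scan)
    # strengths are compared at one representative anchor (that of the
    # allele with the stronger site call) so the delta isolates the variant
    rep_common <- if (is.na(rep_ref) && is.na(rep_alt)) {
      # no positive cluster on either allele: fall back to the
      # highest-probability anchor near the variant
      rr <- ref_scan$records
      near <- abs(rr$anchor_pos - vpos_sense) <= 50L
      if (!any(near)) near <- rep(TRUE, nrow(rr))
      best <- pmax(rr$p_class, alt_scan$records$p_class)
      rr$anchor_pos[near][which.max(best[near])]
    } else if (is.na(rep_ref)) {
      rep_alt
    } else if (is.na(rep_alt)) {
      rep_ref
    } else {
      pa <- max(alt_scan$records$p_class)
      pr_ <- max(ref_scan$records$p_class)
      if (pa >= pr_) rep_alt else rep_ref
    }
    if (is.na(rep_ref)) rep_ref <- rep_common
    if (is.na(rep_alt)) rep_alt <- rep_common
    strength_at <- function(local_seq, seq_pos) {
      win <- substring(sense(local_seq), seq_pos - 120L, seq_pos + 119L)
      if (nchar(win) < 240L) return(NA_real_)
      predict_raw(polyastrength, win)$score[1]
    }
    s_ref <- strength_at(ref_local, rep_common)
    s_alt <- strength_at(alt_local, rep_common)
    p_ref <- max(ref_scan$records$p_class)
    p_alt <- max(alt_scan$records$p_class)
    delta <- s_alt - s_ref
    sig <- isTRUE(max(p_ref, p_alt) >= p_min) &&
      isTRUE(max(s_ref, s_alt, na.rm = TRUE) >= strength_min) &&
      isTRUE(abs(delta) >= delta_min)
    intr_prob <- NA_real_
    site_class <- NA_character_
    best_rep_genomic <- to_genomic(if (!is.na(s_alt) && !is.na(s_ref) &&
                                       s_alt >= s_ref) rep_alt else rep_ref)
    if (!is.null(annotation)) {
      site_tbl <- tibble::tibble(chrom = v$chrom, pos = best_rep_genomic,
                                 strand = v$strand)
      site_class <- classify_genomic_location(site_tbl, annotation,
                                              extensions)$genomic_class
      if (site_class == "extended_terminal_exonic" && !is.null(extensions)) {
        ext <- extensions[extensions$chrom == v$chrom &
                            extensions$strand == v$strand, ]
        dist <- if (v$strand == "+") {
          min(best_rep_genomic - ext$ext_start + 1L)
        } else {
          min(ext$ext_end - best_rep_genomic + 1L)
        }
        if (is.finite(dist) && dist > max_ext_dist) sig <- FALSE
      }
      if (site_class == "intronic" && !is.null(intronic_classifier)) {
        # expression gate on the intronic context
        sig <- sig && isTRUE(intr_prob >= 0.9)
      }
    }
    dplyr::mutate(base, evaluated = TRUE,
                  site_pos_ref = to_genomic(rep_ref),
                  site_pos_alt = to_genomic(rep_alt),
                  p_class_ref = p_ref, p_class_alt = p_alt,
                  strength_ref = s_ref, strength_alt = s_alt,
                  delta_strength = delta,
                  genomic_class = site_class,
                  intronic_expression_prob = intr_prob,
                  significant = sig)
  })
  dplyr::bind_rows(rows)
}
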