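#' Hexamer disruption importance for one sequence window
#'
#' Every overlapping hexamer in the 240-nt window is replaced by `n_repl`
#' randomised hexamers (the same draws are reused at every position for
#' variance reduction) while the rest of the sequence is kept fixed, and
#' the effect is the median change in the model's log-odds output
#' (log-odds classification probability for PolyaID, raw score for
#' PolyaStrength) across replacements.  Negative medians mean the hexamer
#' supports the prediction.
#'
#' @param window A 240-nt sequence (anchor at base 121).
#' @param model Trained `polya_model`.
#' @param n_repl Number of randomised replacements; default 100.
#' @param seed Integer seed for the replacement draws.
#' @param starts Optional subset of hexamer start positions (1..235) to
#'   evaluate; default all.
#' @return Tibble: `hexamer`, `position` (start offset relative to the
#'   anchor, -120..+114), `delta_logodds` (median), `n_repl`.
#' @export
hexamer_importance <- function(window, model, n_repl = 100L, seed = 1L,
                               starts = NULL) {
  stopifnot(nchar(window) == 240L)
  if (is.null(starts)) starts <- 1:235
  repl <- with_seed(seed, {
    vapply(seq_len(n_repl), function(i) {
      paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE), collapse = "")
    }, character(1))
  })
  seqs <- character(length(starts) * n_repl)
  k <- 0L
  for (s in starts) {
    for (r in repl) {
      k <- k + 1L
      seqs[k] <- str_sub_replace(window, s, r)
    }
  }
  logodds <- function(out) {
    if (model$config$task == "polyaid") {
      p <- pmin(pmax(as.numeric(out$p_class), 1e-7), 1 - 1e-7)
      qlogis(p)
    } else {
      as.numeric(out$score)
    }
  }
  base <- logodds(predict_raw(model, window))
  scores <- logodds(predict_raw(model, seqs, chunk = 512L))
  deltas <- matrix(scores, nrow = n_repl)  # columns follow `starts`
  tibble::tibble(
    hexamer = substring(window, starts, starts + 5L),
    position = starts - 121L,
    delta_logodds = apply(deltas - base, 2, median),
    n_repl = n_repl)
}

#' Positional importance profile over a set of sites
#'
#' Runs [hexamer_importance()] on each site window and aggregates, per
#' (hexamer, position), the summed importance (sum over sites of the
#' negated median delta log-odds, so positive = supportive) and the
#' per-site importance (sum divided by occurrence count).
#'
#' @param windows Character vector of 240-nt site windows (intended for
#'   well-expressed sites, e.g. >= 100 PASS reads and usage >= 5%).
#' @param model Trained `polya_model`.
#' @inheritParams hexamer_importance
#' @return Tibble: `hexamer`, `position` (-120..+114), `sum_importance`,
#'   `n_occurrences`, `per_site_importance`.
#' @export
positional_profile <- function(windows, model, n_repl = 100L, seed = 1L,
                               starts = NULL) {
  per_site <- lapply(seq_along(windows), function(i) {
    hexamer_importance(windows[[i]], model, n_repl, seed + i - 1L, starts)
  })
  dplyr::bind_rows(per_site) |>
    dplyr::group_by(.data$hexamer, .data$position) |>
    dplyr::summarise(sum_importance = sum(-.data$delta_logodds),
                     n_occurrences = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(per_site_importance =
                    .data$sum_importance / .data$n_occurrences)
}

#' Call hexamers important for polyA site formation
#'
#' Motifs further than `flank` nt from the site are assumed not to act in
#' polyA site formation, so their summed importance scores form the
#' background (null) distribution; its 99.99th percentile is the
#' false-discovery threshold.  A hexamer is called important when its
#' summed importance at some position inside the central +/-`flank` window
#' strictly exceeds that threshold, under either of the supplied profiles.
#'
#' @param profile Profile tibble from [positional_profile()] (one model), or
#'   a list of profiles (e.g. PolyaID and PolyaStrength), in which case a
#'   hexamer is important if called under either model.
#' @param flank Background boundary (nt): positions with
#'   |position| > `flank` are background, positions within it are
#'   candidates; default 40.
#' @param prob Background percentile; default 0.9999.
#' @return Tibble of calls (`hexamer`, `position`, `sum_importance`), with
#'   the important-hexamer set in attribute `"hexamers"` and the per-profile
#'   threshold(s) in attribute `"threshold"`.
#' @export
significant_hexamers <- function(profile, flank = 40L, prob = 0.9999) {
  profiles <- if (is.data.frame(profile)) list(profile) else profile
  calls <- lapply(profiles, function(pr) {
    bg <- pr$sum_importance[abs(pr$position) > flank]
    if (!length(bg)) stop("empty background: no positions beyond the flank")
    thr <- quantile(bg, prob, names = FALSE)
    res <- pr[abs(pr$position) <= flank & pr$sum_importance > thr,
              c("hexamer", "position", "sum_importance")]
    attr(res, "threshold") <- thr
    res
  })
  out <- dplyr::bind_rows(calls) |> dplyr::distinct()
  attr(out, "hexamers") <- unique(out$hexamer)
  attr(out, "threshold") <- vapply(calls, attr, numeric(1), "threshold")
  out
}

# packaged PAS-variant table (editable at inst/extdata/pas_variants.tsv)
pas_variant_table <- function() {
  if (!is.null(.pg_env$pas_variants)) return(.pg_env$pas_variants)
  path <- system.file("extdata", "pas_variants.tsv", package = "polyagrammar")
  tab <- if (nzchar(path)) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    data.frame(hexamer = character(0))
  }
  .pg_env$pas_variants <- tab
  tab
}

#' Classify a hexamer into a cis-element family
#'
#' Families: `PAS_AAUAAA` (the canonical signal), `PAS_variant` (ATTAAA and
#' the packaged single-nucleotide variants of AATAAA), `UGUA` (contains
#' TGTA), `GU_CU_rich` (contains GTGT, TGTG, GTCT, TGTC, CTGT or TCTG),
#' `U_rich` (at least 5 Ts with a T in the first position), `G_rich`
#' (at least 5 Gs with a G first), else `none`.  Hexamers matching several
#' rules resolve with precedence
#' PAS > GU/CU-rich > UGUA > U-rich > G-rich (so GTGTAA is GU/CU-rich
#' even though it also contains TGTA).
#'
#' @param hexamer Character vector of hexamers (DNA alphabet; U as T).
#' @return Character vector of family names.
#' @export
classify_motif_family <- function(hexamer) {
  hexamer <- toupper(hexamer)
  if (any(nchar(hexamer) != 6L)) stop("hexamers must have length 6")
  variants <- pas_variant_table()$hexamer
  gu_cu <- c("GTGT", "TGTG", "GTCT", "TGTC", "CTGT", "TCTG")
  vapply(hexamer, function(h) {
    if (h == "AATAAA") return("PAS_AAUAAA")
    if (h %in% variants) return("PAS_variant")
    if (any(vapply(gu_cu, grepl, logical(1), x = h, fixed = TRUE))) {
      return("GU_CU_rich")
    }
    if (grepl("TGTA", h, fixed = TRUE)) return("UGUA")
    chars <- strsplit(h, "", fixed = TRUE)[[1]]
    if (sum(chars == "T") >= 5 && chars[1] == "T") return("U_rich")
    if (sum(chars == "G") >= 5 && chars[1] == "G") return("G_rich")
    "none"
  }, character(1), USE.NAMES = FALSE)
}

#' Shannon entropy of a cleavage vector
#'
#' \eqn{E = -\sum_i p_i \log p_i} (natural log, `0 log 0 := 0`); ranges
#' from 0 (perfectly precise cleavage) to log(50) (maximally heterogeneous).
#'
#' @param v Length-50 probability vector.
#' @return Scalar entropy.
#' @export
cleavage_entropy <- function(v) {
  nz <- v > 0
  -sum(v[nz] * log(v[nz]))
}

#' Compare motif content between low- and high-entropy sites
#'
#' Sites are ranked by both the observed (read-based) and predicted
#' (model-based) cleavage entropy; the low group is the intersection of the
#' bottom `top_frac` under both measures, the high group the intersection
#' of the top `top_frac`.  Within four site subregions (-120..-31, -30..0,
#' 1..30, 31..120 nt, closed intervals) the occurrence of each motif family
#' is compared between groups with a chi-squared test on the 2x2 count
#' table and a two-proportion test.
#'
#' @param sites Tibble with `site_id`, `seq` (240-nt window), and either
#'   list-columns `obs_vector` / `pred_vector` (length-50) or numeric
#'   columns `entropy_observed` / `entropy_predicted`.
#' @param families Motif families to test.
#' @param top_frac Tail fraction defining the groups; default 0.2.
#' @return List with `groups` (per-site tibble: entropies and group
#'   membership `low` / `high` / `middle`) and `tests` (per region x family:
#'   counts, chi-squared statistic and p-values).  Tests are skipped when a
#'   group has fewer than 2 sites.
#' @export
entropy_group_analysis <- function(sites,
                                   families = c("PAS_AAUAAA", "U_rich",
                                                "GU_CU_rich"),
                                   top_frac = 0.2) {
  if (!"entropy_observed" %in% names(sites)) {
    sites$entropy_observed <- vapply(sites$obs_vector, cleavage_entropy,
                                     numeric(1))
  }
  if (!"entropy_predicted" %in% names(sites)) {
    sites$entropy_predicted <- vapply(sites$pred_vector, cleavage_entropy,
                                      numeric(1))
  }
  n <- nrow(sites)
  k <- max(1L, floor(top_frac * n))
  rank_obs <- rank(sites$entropy_observed, ties.method = "first")
  rank_pred <- rank(sites$entropy_predicted, ties.method = "first")
  distinct_obs <- length(unique(sites$entropy_observed)) > 1
  low <- rank_obs <= k & rank_pred <= k
  high <- rank_obs > n - k & rank_pred > n - k
  if (!distinct_obs) low <- high <- rep(FALSE, n)
  group <- ifelse(low, "low", ifelse(high, "high", "middle"))
  groups <- tibble::tibble(site_id = sites$site_id,
                           entropy_observed = sites$entropy_observed,
                           entropy_predicted = sites$entropy_predicted,
                           group = group)
  regions <- tibble::tibble(region = c("-120..-31", "-30..0", "1..30",
                                       "31..120"),
                            lo = c(-120L, -30L, 1L, 31L),
                            hi = c(-31L, 0L, 30L, 120L))
  lo_seq <- sites$seq[group == "low"]
  hi_seq <- sites$seq[group == "high"]
  if (length(lo_seq) < 2 || length(hi_seq) < 2) {
    return(list(groups = groups, tests = tibble::tibble()))
  }
  has_motif <- function(seqs, fam, lo, hi) {
    # hexamer starts whose full hexamer lies inside the closed region
    starts <- (lo + 121L):(hi + 121L - 5L)
    starts <- starts[starts >= 1L & starts <= 235L]
    vapply(seqs, function(s) {
      hex <- substring(s, starts, starts + 5L)
      any(classify_motif_family(hex) == fam)
    }, logical(1), USE.NAMES = FALSE)
  }
  tests <- list()
  for (r in seq_len(nrow(regions))) {
    for (fam in families) {
      a <- has_motif(lo_seq, fam, regions$lo[r], regions$hi[r])
      b <- has_motif(hi_seq, fam, regions$lo[r], regions$hi[r])
      tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2)
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
      pr <- suppressWarnings(prop.test(c(sum(a), sum(b)),
                                       c(length(a), length(b))))
      tests[[length(tests) + 1L]] <- tibble::tibble(
        region = regions$region[r], family = fam,
        n_low = length(a), n_high = length(b),
        frac_low = mean(a), frac_high = mean(b),
        chisq_stat = unname(chi$statistic), chisq_p = chi$p.value,
        prop_p = pr$p.value)
    }
  }
  list(groups = groups, tests = dplyr::bind_rows(tests))
}

#' Slide a motif through its context and measure the entropy change
#'
#' Moves the motif in `motif_b_span` by `shift` nt (positive = downstream)
#' through the surrounding sequence: the displaced context nucleotides
#' refill the vacated span, the rest of the window is unchanged and the
#' length stays 240.  The model's predicted cleavage entropy for the
#' perturbed window is compared with the original.
#'
#' @param window A 240-nt sequence.
#' @param motif_a_span,motif_b_span Length-2 integer vectors `(start, end)`
#'   of the two motifs in window coordinates (1..240); the spans must not
#'   overlap and the shift must not make them collide or leave the window.
#' @param shift Integer shift (may be a vector; 0 returns the window
#'   unchanged).
#' @param model Trained PolyaID `polya_model` (or stub function as in
#'   [scan_sequence()]).
#' @return Tibble: `shift`, `seq`, `entropy`, `delta_entropy` (relative to
#'   shift 0).
#' @export
motif_distance_perturbation <- function(window, motif_a_span, motif_b_span,
                                        shift, model) {
  stopifnot(nchar(window) == 240L, length(motif_a_span) == 2L,
            length(motif_b_span) == 2L)
  a1 <- motif_a_span[1]; a2 <- motif_a_span[2]
  b1 <- motif_b_span[1]; b2 <- motif_b_span[2]
  if (max(a1, b1) <= min(a2, b2)) stop("motif spans overlap")
  slide <- function(k) {
    chars <- strsplit(window, "", fixed = TRUE)[[1]]
    if (k == 0) return(window)
    nb1 <- b1 + k; nb2 <- b2 + k
    if (nb1 < 1L || nb2 > 240L) stop("shift leaves the window")
    if (nb1 <= a2 && a1 <= nb2) stop("shift collides with the other motif")
    motif <- chars[b1:b2]
    new <- chars
    if (k > 0) {
      new[b1:(b1 + k - 1L)] <- chars[(b2 + 1L):(b2 + k)]
    } else {
      new[(b2 + k + 1L):b2] <- chars[(b1 + k):(b1 - 1L)]
    }
    new[nb1:nb2] <- motif
    paste(new, collapse = "")
  }
  seqs <- vapply(shift, slide, character(1))
  out <- if (is.function(model)) model(seqs) else predict_raw(model, seqs)
  ent <- apply(out$cleavage, 2, cleavage_entropy)
  base <- if (any(shift == 0)) ent[which(shift == 0)[1]] else {
    e0 <- if (is.function(model)) model(window) else predict_raw(model, window)
    cleavage_entropy(e0$cleavage[, 1])
  }
  tibble::tibble(shift = shift, seq = seqs, entropy = ent,
                 delta_entropy = ent - base)
}

#' Count optimally positioned motifs in a polyA site window
#'
#' Eligible sites carry an AATAAA starting 10-30 nt upstream of the
#' cleavage position and a CstF motif (U-rich or GU/CU-rich hexamer)
#' beginning within 30 nt downstream.  For eligible sites the four optional
#' elements are counted at their optimal windows: UGUA 0-40 nt upstream of
#' the AATAAA, a U-rich motif between the cleavage site and the AATAAA, a
#' G-rich element within 50 nt downstream of the CstF motif, and a second
#' CstF motif.
#'
#' @param window A 240-nt sequence (anchor at base 121).
#' @return One-row tibble: `eligible`, `pas_start` (offset), `cstf_start`
#'   (offset), flags `has_ugua`, `has_urich_between`, `has_grich`,
#'   `has_second_cstf`, and `n_optional` (0-4; NA when ineligible).
#' @export
count_optimal_motifs <- function(window) {
  stopifnot(nchar(window) == 240L)
  starts <- 1:235
  hex <- substring(window, starts, starts + 5L)
  offs <- starts - 121L
  fam <- classify_motif_family(hex)
  pas_cand <- offs[hex == "AATAAA" & offs >= -30L & offs <= -10L]
  cstf_all <- offs[fam %in% c("U_rich", "GU_CU_rich")]
  cstf_cand <- cstf_all[cstf_all >= 1L & cstf_all <= 30L]
  if (!length(pas_cand) || !length(cstf_cand)) {
    return(tibble::tibble(eligible = FALSE, pas_start = NA_integer_,
                          cstf_start = NA_integer_, has_ugua = NA,
                          has_urich_between = NA, has_grich = NA,
                          has_second_cstf = NA, n_optional = NA_integer_))
  }
  pas <- max(pas_cand)          # the PAS closest to the cleavage site
  cstf <- min(cstf_cand)        # the first downstream CstF motif
  # UGUA (TGTA tetramer) 0-40 nt upstream of the AATAAA
  tgta_starts <- 1:237
  tgta_offs <- tgta_starts[substring(window, tgta_starts,
                                     tgta_starts + 3L) == "TGTA"] - 121L
  has_ugua <- any(tgta_offs >= pas - 40L & tgta_offs < pas)
  urich <- offs[fam == "U_rich"]
  has_urich_between <- any(urich >= pas + 6L & urich <= -5L)
  grich <- offs[classify_motif_family(hex) == "G_rich"]
  has_grich <- any(grich > cstf & grich <= cstf + 50L)
  has_second_cstf <- any(cstf_all >= 1L & cstf_all <= 30L &
                           abs(cstf_all - cstf) >= 6L)
  tibble::tibble(eligible = TRUE, pas_start = pas, cstf_start = cstf,
                 has_ugua = has_ugua, has_urich_between = has_urich_between,
                 has_grich = has_grich, has_second_cstf = has_second_cstf,
                 n_optional = sum(has_ugua, has_urich_between, has_grich,
                                  has_second_cstf))
}
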