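#' Introns implied by an exon-level annotation
#'
#' @param annotation Exon tibble (`gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_rank`, `start`, `end`).
#' @return Tibble of introns with sense-ordered `intron_rank`, genomic
#'   `start`/`end`, and the sense 5'/3' splice-site coordinates
#'   (`ss5_pos` = first intronic base, `ss3_pos` = last intronic base).
#' @export
annotation_introns <- function(annotation) {
  minus <- annotation |>
    dplyr::filter(.data$strand == "-") |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) |>
    dplyr::group_modify(function(df, g) {
      df <- df[order(df$exon_rank), ]
      k <- nrow(df)
      if (k < 2L) return(tibble::tibble())
      up <- df[-k, ]   # sense-upstream exons (higher coordinates)
      dn <- df[-1L, ]
      tibble::tibble(intron_rank = 1:(k - 1L),
                     start = dn$end + 1L, end = up$start - 1L,
                     ss5_pos = up$start - 1L, ss3_pos = dn$end + 1L,
                     upstream_exon_size = up$end - up$start + 1L,
                     downstream_exon_size = dn$end - dn$start + 1L)
    }) |>
    dplyr::ungroup()
  plus <- annotation |>
    dplyr::filter(.data$strand == "+") |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) |>
    dplyr::group_modify(function(df, g) {
      df <- df[order(df$exon_rank), ]
      k <- nrow(df)
      if (k < 2L) return(tibble::tibble())
      up <- df[-k, ]; dn <- df[-1L, ]
      tibble::tibble(intron_rank = 1:(k - 1L),
                     start = up$end + 1L, end = dn$start - 1L,
                     ss5_pos = up$end + 1L, ss3_pos = dn$start - 1L,
                     upstream_exon_size = up$end - up$start + 1L,
                     downstream_exon_size = dn$end - dn$start + 1L)
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(plus, minus) |>
    dplyr::mutate(intron_size = abs(.data$end - .data$start) + 1L) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(is_last_intron = .data$intron_rank ==
                    max(.data$intron_rank)) |>
    dplyr::ungroup()
}

#' Classify intronic polyA sites as composite or skipped
#'
#' A site is `skipped` when splicing occurs between the host intron's 5'
#' splice site and the polyA site (a used 3' splice site lies between
#' them); otherwise it is `composite`.
#'
#' @param sites Site tibble (`chrom`, `pos`, `strand`).
#' @param annotation Exon-level annotation tibble.
#' @param junctions Splice-junction evidence: tibble with `chrom`,
#'   `strand`, `acceptor_pos` (genomic coordinate of a used 3' splice
#'   site).
#' @return `sites` with an added `intronic_type` column; sites not inside
#'   any intron raise an error.
#' @export
classify_intronic_type <- function(sites, annotation, junctions) {
  introns <- annotation_introns(annotation)
  sites$intronic_type <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    host <- introns[introns$chrom == s$chrom & introns$strand == s$strand &
                      introns$start <= s$pos & introns$end >= s$pos, ]
    if (nrow(host) == 0) {
      stop("site at ", s$chrom, ":", s$pos, " is not intronic")
    }
    host <- host[1, ]
    between <- if (s$strand == "+") {
      junctions$acceptor_pos > host$ss5_pos & junctions$acceptor_pos < s$pos
    } else {
      junctions$acceptor_pos < host$ss5_pos & junctions$acceptor_pos > s$pos
    }
    hitj <- junctions$chrom == s$chrom & junctions$strand == s$strand &
      between
    if (any(hitj)) "skipped" else "composite"
  }, character(1))
  sites
}

#' Build a position-weight-matrix splice-site scorer from an annotation
#'
#' Donor (5'SS) sites are scored over a 9-nt window (last 3 exonic + first
#' 6 intronic bases) and acceptors (3'SS) over 23 nt (last 20 intronic +
#' first 3 exonic), with log2 odds against the genome's background base
#' frequencies and a 0.5 pseudocount.  The scorer is pluggable: any
#' function with the same signature can replace it in
#' [compute_features()].
#'
#' @param annotation Exon-level annotation tibble.
#' @param genome Named character vector.
#' @return A `splice_scorer` object (list of PWMs) with a
#'   `score(chrom, pos, strand, type)` closure; `pos` is the first/last
#'   intronic base (ss5_pos / ss3_pos from [annotation_introns()]).
#' @export
build_splice_pwm <- function(annotation, genome) {
  introns <- annotation_introns(annotation)
  get_win <- function(chrom, pos, strand, type) {
    if (type == "donor") {
      if (strand == "+") extract_window(genome, chrom, pos, strand, 3L, 5L)
      else extract_window(genome, chrom, pos, strand, 3L, 5L)
    } else {
      if (strand == "+") extract_window(genome, chrom, pos, strand, 19L, 3L)
      else extract_window(genome, chrom, pos, strand, 19L, 3L)
    }
  }
  collect <- function(type) {
    pos <- if (type == "donor") introns$ss5_pos else introns$ss3_pos
    w <- vapply(seq_len(nrow(introns)), function(i) {
      get_win(introns$chrom[i], pos[i], introns$strand[i], type)
    }, character(1))
    w[!is.na(w)]
  }
  pwm_from <- function(seqs) {
    if (!length(seqs)) return(NULL)
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    vapply(seq_len(ncol(m)), function(j) {
      counts <- table(factor(m[, j], levels = c("A", "C", "G", "T"))) + 0.5
      as.numeric(counts / sum(counts))
    }, numeric(4))
  }
  all_bases <- table(factor(strsplit(paste(genome, collapse = ""), "",
                                     fixed = TRUE)[[1]],
                            levels = c("A", "C", "G", "T")))
  bg <- as.numeric(all_bases + 1) / sum(all_bases + 1)
  pwms <- list(donor = pwm_from(collect("donor")),
               acceptor = pwm_from(collect("acceptor")))
  score_seq <- function(seq, type) {
    pwm <- pwms[[type]]
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    sum(log2(pwm[cbind(idx, seq_along(idx))] / bg[idx]), na.rm = TRUE)
  }
  structure(list(
    pwms = pwms, background = bg,
    score = function(chrom, pos, strand, type) {
      w <- get_win(chrom, pos, strand, type)
      if (is.na(w)) return(NA_real_)
      score_seq(w, type)
    }), class = "splice_scorer")
}

#' Gene-structure features for intronic or terminal-exonic polyA sites
#'
#' For intronic sites: distance to the upstream 5'SS and downstream 3'SS,
#' splice-site strengths (host donor/acceptor plus the upstream intron's
#' acceptor), exon/intron sizes and a last-intron flag.  For terminal
#' pairs: pair distance, last-intron size, distance to the nearest
#' downstream antisense gene, and the strength difference relative to the
#' distal site.  Distances are reported in nt on the sense strand.
#'
#' @param sites For `type = "intronic"`: site tibble (`chrom`, `pos`,
#'   `strand`, optionally `polyastrength`).  For `type = "terminal_pair"`:
#'   pair tibble from [select_terminal_pairs()].
#' @param annotation Exon-level annotation tibble.
#' @param genome Named character vector (used by the splice scorer).
#' @param type `"intronic"` or `"terminal_pair"`.
#' @param scorer Optional `splice_scorer` (built from the annotation when
#'   omitted).
#' @return Feature tibble (one row per site or per pair member).
#' @export
compute_features <- function(sites, annotation, genome,
                             type = c("intronic", "terminal_pair"),
                             scorer = NULL) {
  type <- match.arg(type)
  if (type == "intronic") {
    if (is.null(scorer)) scorer <- build_splice_pwm(annotation, genome)
    introns <- annotation_introns(annotation)
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      host <- introns[introns$chrom == s$chrom & introns$strand == s$strand &
                        introns$start <= s$pos & introns$end >= s$pos, ]
      if (nrow(host) == 0) stop("site at ", s$pos, " not in an intron")
      host <- host[1, ]
      dist_up <- if (s$strand == "+") s$pos - host$ss5_pos
      else host$ss5_pos - s$pos
      dist_dn <- if (s$strand == "+") host$ss3_pos - s$pos
      else s$pos - host$ss3_pos
      upstream_acceptor <- introns[
        introns$transcript_id == host$transcript_id &
          introns$intron_rank == host$intron_rank - 1L, ]
      tibble::tibble(
        site_type = "intronic",
        polyastrength = if ("polyastrength" %in% names(s)) s$polyastrength
        else NA_real_,
        dist_to_upstream_ss = dist_up, dist_to_downstream_ss = dist_dn,
        ss5_strength = scorer$score(s$chrom, host$ss5_pos, s$strand, "donor"),
        ss3_strength_down = scorer$score(s$chrom, host$ss3_pos, s$strand,
                                         "acceptor"),
        ss3_strength_up = if (nrow(upstream_acceptor)) {
          scorer$score(s$chrom, upstream_acceptor$ss3_pos[1], s$strand,
                       "acceptor")
        } else NA_real_,
        upstream_exon_size = host$upstream_exon_size,
        downstream_exon_size = host$downstream_exon_size,
        intron_size = host$intron_size,
        is_last_intron = host$is_last_intron)
    })
    dplyr::bind_rows(rows)
  } else {
    genes <- annotation |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
    introns <- annotation_introns(annotation)
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      p <- sites[i, ]
      last_intron <- introns[introns$chrom == p$chrom &
                               introns$strand == p$strand &
                               introns$is_last_intron, ]
      host_gene <- genes[genes$gene_id == p$gene_id, ]
      last_size <- if (nrow(last_intron)) {
        hosts <- last_intron[last_intron$start >= host_gene$start &
                               last_intron$end <= host_gene$end, ]
        if (nrow(hosts)) hosts$intron_size[1] else NA_integer_
      } else NA_integer_
      anti <- genes[genes$chrom == p$chrom & genes$strand != p$strand, ]
      gene_3p <- if (p$strand == "+") host_gene$end else host_gene$start
      d_anti <- if (p$strand == "+") {
        cand <- anti$start[anti$start > gene_3p]
        if (length(cand)) min(cand) - gene_3p else NA_integer_
      } else {
        cand <- anti$end[anti$end < gene_3p]
        if (length(cand)) gene_3p - max(cand) else NA_integer_
      }
      tibble::tibble(
        site_type = "terminal_pair", gene_id = p$gene_id,
        polyastrength = p$strength_proximal,
        pair_distance = abs(p$pos_distal - p$pos_proximal),
        last_intron_size = last_size,
        dist_to_downstream_antisense_gene = d_anti,
        relative_strength_vs_distal = p$strength_proximal -
          p$strength_distal,
        proximal_is_high = p$proximal_is_high)
    })
    dplyr::bind_rows(rows)
  }
}

#' Quantile-match used and unused sites on strength
#'
#' Both groups are binned on their PolyaStrength scores using shared
#' quantile breaks; within each bin the same number of used and unused
#' sites is sampled (the smaller count), equalising the strength
#' distribution so that other genomic features can be compared without
#' strength confounding.
#'
#' @param used,unused Site tibbles with a `strength_col` column.
#' @param n_bins Number of strength bins; default 20 (finer strata leave
#'   less residual within-bin confounding).
#' @param strength_col Column holding the strength score.
#' @param seed Integer seed.
#' @return Tibble of the matched sample with a `group` column
#'   (`used` / `unused`); empty bins contribute nothing (with a warning).
#' @export
quantile_match_by_strength <- function(used, unused, n_bins = 20L,
                                       strength_col = "polyastrength",
                                       seed = 1L) {
  stopifnot(nrow(used) > 0, nrow(unused) > 0)
  all_s <- c(used[[strength_col]], unused[[strength_col]])
  breaks <- unique(quantile(all_s, probs = seq(0, 1, length.out = n_bins + 1)))
  cut_bin <- function(x) cut(x, breaks, include.lowest = TRUE)
  ub <- cut_bin(used[[strength_col]])
  nb <- cut_bin(unused[[strength_col]])
  with_seed(seed, {
    out <- lapply(levels(ub), function(b) {
      iu <- which(ub == b); inn <- which(nb == b)
      k <- min(length(iu), length(inn))
      if (k == 0) {
        if (length(iu) + length(inn) > 0) {
          warning("bin ", b, " empty on one side; contributes 0 sites")
        }
        return(NULL)
      }
      dplyr::bind_rows(
        dplyr::mutate(used[sample(iu, k), , drop = FALSE], group = "used"),
        dplyr::mutate(unused[sample(inn, k), , drop = FALSE],
                      group = "unused"))
    })
    dplyr::bind_rows(out)
  })
}

#' Fit a logistic usage classifier on standardised features
#'
#' Features are centred and scaled, a maximum-likelihood logistic
#' regression is fit, and features whose two-sided Wald p-value is >= 0.05
#' are dropped (largest first) with refitting until all remaining features
#' are significant.  Under perfect separation the fit falls back to a
#' ridge-penalised model (flagged in the result).
#'
#' @param features Numeric feature tibble (columns are predictors; logical
#'   columns are coerced to 0/1).
#' @param labels Binary vector (1 = used / high-usage).
#' @param alpha Significance cutoff for keeping features; default 0.05.
#' @return A `usage_classifier` object with elements `coefficients`,
#'   `intercept`, `feature_scaling`, `p_values`, `dropped`, `separation`.
#' @export
fit_usage_classifier <- function(features, labels, alpha = 0.05) {
  X <- as.data.frame(lapply(features, function(x) as.numeric(x)))
  keep_rows <- complete.cases(X) & !is.na(labels)
  X <- X[keep_rows, , drop = FALSE]
  y <- as.numeric(labels[keep_rows])
  centers <- vapply(X, mean, numeric(1))
  scales <- vapply(X, sd, numeric(1))
  scales[scales == 0 | is.na(scales)] <- 1
  Xs <- as.data.frame(scale(X, centers, scales))
  fit_once <- function(vars) {
    df <- cbind(Xs[, vars, drop = FALSE], .y = y)
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(fit = fit, separation = sep)
  }
  vars <- names(Xs)
  dropped <- character(0)
  # under perfect separation Wald statistics are meaningless, so skip the
  # backward elimination and go straight to the penalised fallback
  full <- fit_once(vars)
  if (!full$separation) {
    repeat {
      res <- fit_once(vars)
      sm <- summary(res$fit)$coefficients
      pv <- sm[setdiff(rownames(sm), "(Intercept)"), 4]
      names(pv) <- setdiff(rownames(sm), "(Intercept)")
      worst <- names(pv)[which.max(pv)]
      if (length(pv) == 0 || max(pv) < alpha) break
      vars <- setdiff(vars, worst)
      dropped <- c(dropped, worst)
      if (length(vars) == 0) break
    }
  }
  final <- fit_once(vars)
  model <- final$fit
  if (final$separation && requireNamespace("glmnet", quietly = TRUE) &&
      length(vars) >= 2) {
    xm <- as.matrix(Xs[, vars, drop = FALSE])
    rg <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    co <- as.numeric(coef(rg))
    names(co) <- rownames(coef(rg))
    coefs <- co[vars]; intercept <- co[["(Intercept)"]]
    pvals <- rep(NA_real_, length(vars)); names(pvals) <- vars
  } else {
    co <- coef(model)
    coefs <- co[vars]
    intercept <- co[["(Intercept)"]]
    sm <- summary(model)$coefficients
    pvals <- sm[vars, 4]
    names(pvals) <- vars
  }
  structure(list(coefficients = coefs, intercept = intercept,
                 feature_scaling = list(center = centers[vars],
                                        scale = scales[vars]),
                 p_values = pvals, features = vars, dropped = dropped,
                 separation = final$separation,
                 glm = if (final$separation) NULL else model,
                 n = length(y)),
            class = "usage_classifier")
}

#' @export
print.usage_classifier <- function(x, ...) {
  cat(sprintf("<usage_classifier: %d features, n = %d%s>\n",
              length(x$features), x$n,
              if (x$separation) ", penalised (separation)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Coefficients and p-values of a usage classifier
#' @param x A `usage_classifier`.
#' @param ... Unused.
#' @export
tidy.usage_classifier <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coefficients)),
                 p.value = c(NA_real_, unname(x$p_values)))
}

#' One-row model summary of a usage classifier
#' @param x A `usage_classifier`.
#' @param ... Unused.
#' @export
glance.usage_classifier <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 n_dropped = length(x$dropped), separation = x$separation,
                 deviance = if (is.null(x$glm)) NA_real_ else x$glm$deviance)
}

#' Predict usage probability from a fitted classifier
#'
#' @param clf A `usage_classifier`.
#' @param feature_vector Tibble/data frame with the classifier's feature
#'   columns (unscaled; the stored scaling is applied).
#' @return Numeric vector of calibrated probabilities in `[0, 1]`.
#' @export
predict_usage_probability <- function(clf, feature_vector) {
  X <- as.data.frame(lapply(feature_vector[clf$features], as.numeric))
  Xs <- scale(X, clf$feature_scaling$center, clf$feature_scaling$scale)
  eta <- clf$intercept + as.numeric(as.matrix(Xs) %*% clf$coefficients)
  plogis(eta)
}

#' Select proximal/distal terminal-exon site pairs
#'
#' For each gene with at least two terminal-exonic sites, the strongest
#' site (highest usage) is paired with a randomly chosen site showing at
#' least `fold` lower usage; pairs are labelled proximal/distal by sense
#' coordinate order and by which member carries the high usage.
#'
#' @param sites Site tibble with `gene_id`, `chrom`, `pos`, `strand`,
#'   `usage`, and optionally `strength`.
#' @param fold Minimum usage fold difference; default 8.
#' @param seed Integer seed for the partner draw.
#' @return Pair tibble: `gene_id`, `chrom`, `strand`, `pos_proximal`,
#'   `pos_distal`, `usage_proximal`, `usage_distal`, `strength_proximal`,
#'   `strength_distal`, `proximal_is_high`.  Genes without a qualifying
#'   partner are skipped.
#' @export
select_terminal_pairs <- function(sites, fold = 8, seed = 1L) {
  with_seed(seed, {
    out <- sites |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_map(function(df, g) {
        if (nrow(df) < 2L) return(NULL)
        top <- df[which.max(df$usage), ]
        partners <- df[df$usage <= top$usage / fold, , drop = FALSE]
        if (nrow(partners) == 0) return(NULL)
        other <- partners[sample.int(nrow(partners), 1), ]
        two <- dplyr::bind_rows(top, other)
        ord <- if (two$strand[1] == "+") order(two$pos) else
          order(two$pos, decreasing = TRUE)
        prox <- two[ord[1], ]; dist <- two[ord[2], ]
        tibble::tibble(
          gene_id = g$gene_id, chrom = prox$chrom, strand = prox$strand,
          pos_proximal = prox$pos, pos_distal = dist$pos,
          usage_proximal = prox$usage, usage_distal = dist$usage,
          strength_proximal = if ("strength" %in% names(prox)) prox$strength
          else NA_real_,
          strength_distal = if ("strength" %in% names(dist)) dist$strength
          else NA_real_,
          proximal_is_high = prox$usage >= dist$usage)
      }, .keep = TRUE)
    dplyr::bind_rows(out)
  })
}

#' Per-gene APA differential test across conditions
#'
#' For each gene and condition, the proximal/distal read counts in that
#' condition are compared with the pooled counts of all other conditions
#' using a Fisher exact test; p-values are Benjamini-Hochberg adjusted
#' across all gene x condition tests.  A gene is significant in a
#' condition when the adjusted p-value is below `alpha` and the absolute
#' usage change relative to the across-condition mean is at least
#' `min_usage_change`.
#'
#' @param counts Tibble: `gene_id`, `condition`, `proximal`, `distal`
#'   (read counts of the top-2 terminal sites).
#' @param alpha Adjusted-p cutoff; default 0.05.
#' @param min_usage_change Minimum |usage - mean usage|; default 0.1.
#' @return Tidy tibble: per gene x condition `p_value`, `p_adjusted`,
#'   `usage`, `usage_change`, `significant`.  Genes with an all-zero
#'   margin are skipped.
#' @export
apa_differential_test <- function(counts, alpha = 0.05,
                                  min_usage_change = 0.1) {
  res <- counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(df, g) {
      if (sum(df$proximal) == 0 || sum(df$distal) == 0 ||
          any(df$proximal + df$distal == 0)) {
        return(NULL)
      }
      usage <- df$proximal / (df$proximal + df$distal)
      mean_usage <- mean(usage)
      pv <- vapply(seq_len(nrow(df)), function(i) {
        tab <- matrix(c(df$proximal[i], df$distal[i],
                        sum(df$proximal[-i]), sum(df$distal[-i])), 2)
        fisher.test(tab)$p.value
      }, numeric(1))
      tibble::tibble(gene_id = g$gene_id, condition = df$condition,
                     proximal = df$proximal, distal = df$distal,
                     usage = usage, usage_change = usage - mean_usage,
                     p_value = pv)
    }, .keep = TRUE) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(res)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adjusted < alpha &
    abs(res$usage_change) >= min_usage_change
  res
}
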