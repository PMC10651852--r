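#' One-hot encode a 240-nt sequence window
#'
#' Rows are ordered A, C, G, T.  Each non-N column sums to 1; columns with an
#' N (or any non-ACGT character) are all zero.
#'
#' @param seq A single 240-nt string.
#' @return A `4 x 240` numeric matrix.
#' @export
one_hot <- function(seq) {
  if (nchar(seq) != 240L) stop("sequence must be exactly 240 nt")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- matrix(0, 4L, 240L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(chars, c("A", "C", "G", "T"))
  keep <- !is.na(idx)
  m[cbind(idx[keep], which(keep))] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param m A `4 x 240` one-hot matrix as produced by [one_hot()].
#' @return A 240-character string; all-zero columns decode to `"N"`.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  bases <- c("A", "C", "G", "T")
  out <- apply(m, 2, function(col) {
    if (sum(col) == 0) "N" else bases[which.max(col)]
  })
  paste(out, collapse = "")
}

#' Build shifted positive training examples for one polyA site
#'
#' One 240-nt example is produced per shift in `shifts` (default -25..+25,
#' 51 examples), each anchored at `pos + shift` in sense orientation.  The
#' cleavage label is the site's PASS-read 3'-end distribution re-centred on
#' the shifted anchor, truncated to offsets -25..+24 and renormalised to 1.
#'
#' @param site One-row tibble (or list) with `chrom`, `pos`, `strand` and a
#'   `site_id`.
#' @param genome Named character vector of chromosome sequences.
#' @param read_positions Integer vector of PASS-read cleavage positions
#'   supporting the site (genomic coordinates).
#' @param shifts Integer vector of anchor shifts (sense orientation).
#' @return Tibble with columns `site_id`, `shift`, `seq`, `label_class` (1),
#'   `label_cleavage` (list of length-50 simplex vectors) and `origin`.
#'   Shifts whose window runs off the chromosome are skipped, as are shifts
#'   whose 50-nt label window captures none of the site's reads (such
#'   windows show no cleavage in the middle, so a positive label with a
#'   zero cleavage vector would be contradictory).
#' @export
build_positive_examples <- function(site, genome, read_positions,
                                    shifts = -25:25) {
  site <- as.list(site)
  dir <- if (site$strand == "+") 1L else -1L
  rows <- lapply(shifts, function(s) {
    anchor <- site$pos + dir * s
    seq <- extract_window(genome, site$chrom, anchor, site$strand)
    if (is.na(seq)) return(NULL)
    offs <- dir * (read_positions - anchor)
    offs <- offs[offs >= -25L & offs <= 24L]
    if (!length(offs)) return(NULL)
    v <- numeric(50)
    tab <- table(offset_to_index(offs))
    v[as.integer(names(tab))] <- as.numeric(tab)
    v <- v / sum(v)
    tibble::tibble(site_id = as.character(site$site_id), shift = s, seq = seq,
                   label_class = 1, label_cleavage = list(v),
                   origin = "positive_shifted")
  })
  dplyr::bind_rows(rows)
}

#' Build negative training examples
#'
#' Three origins in configurable proportions: random intergenic windows,
#' shuffled transcript windows, and neighbour windows anchored 50-100 nt from
#' a called polyA site whose central 50 nt contain no PASS reads.  All
#' negatives get class label 0 and the constant cleavage vector 0.02
#' (summing to 1 exactly).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annotation Exon-level annotation tibble (columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`).
#' @param sites Called site tibble (`chrom`, `pos`, `strand`).
#' @param read_positions Integer vector of all PASS-read cleavage positions
#'   (the coverage track used for the neighbour check).
#' @param n Total number of negatives to draw.
#' @param mix Named proportions for origins `intergenic`, `shuffled`,
#'   `neighbor`.
#' @param seed Integer seed.
#' @return Tibble with the same columns as [build_positive_examples()].
#' @export
build_negative_examples <- function(genome, annotation, sites, read_positions,
                                    n, mix = c(intergenic = 1, shuffled = 1,
                                               neighbor = 1),
                                    seed = 1L) {
  mix <- mix / sum(mix)
  n_each <- round(n * mix)
  n_each[1] <- n - sum(n_each[-1])
  const_vec <- rep(0.02, 50)

  with_seed(seed, {
    gene_spans <- annotation |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")

    draw_intergenic <- function(k) {
      out <- character(0)
      guard <- 0L
      while (length(out) < k && guard < 50L) {
        guard <- guard + 1L
        chrom <- sample(names(genome), 1)
        len <- nchar(genome[[chrom]])
        anchors <- sample(121:(len - 119L), min(4L * k, len %/% 10L))
        spans <- gene_spans[gene_spans$chrom == chrom, ]
        in_gene <- vapply(anchors, function(a) {
          any(a >= spans$start - 120L & a <= spans$end + 120L)
        }, logical(1))
        anchors <- anchors[!in_gene]
        if (length(anchors)) {
          out <- c(out, extract_windows(genome, chrom,
                                        head(anchors, k - length(out)), "+"))
        }
      }
      out[!is.na(out)]
    }

    draw_shuffled <- function(k) {
      picks <- gene_spans[sample.int(nrow(gene_spans), k, replace = TRUE), ]
      vapply(seq_len(k), function(i) {
        g <- picks[i, ]
        width <- g$end - g$start + 1L
        if (width < 240L) {
          seq <- extract_window(genome, g$chrom,
                                max(121L, g$start + 120L), g$strand)
        } else {
          a <- sample(seq(g$start + 120L, g$end - 119L), 1)
          seq <- extract_window(genome, g$chrom, a, g$strand)
        }
        if (is.na(seq)) seq <- random_dna(240L)
        paste(sample(strsplit(seq, "")[[1]]), collapse = "")
      }, character(1))
    }

    draw_neighbor <- function(k) {
      out <- character(0)
      if (nrow(sites) == 0) return(out)
      guard <- 0L
      while (length(out) < k && guard < 40L) {
        guard <- guard + 1L
        idx <- sample.int(nrow(sites), max(2L * (k - length(out)), 10L),
                          replace = TRUE)
        d <- sample(50:100, length(idx), replace = TRUE) *
          sample(c(-1L, 1L), length(idx), replace = TRUE)
        for (j in seq_along(idx)) {
          if (length(out) >= k) break
          s <- sites[idx[j], ]
          anchor <- s$pos + d[j]
          # reject anchors whose central 50 nt (offsets -25..+24) hold a read
          lo <- anchor - 25L; hi <- anchor + 24L
          if (s$strand == "-") { lo <- anchor - 24L; hi <- anchor + 25L }
          if (any(read_positions >= lo & read_positions <= hi)) next
          seq <- extract_window(genome, s$chrom, anchor, s$strand)
          if (!is.na(seq)) out <- c(out, seq)
        }
      }
      if (length(out) < k) {
        warning("neighbor pool exhausted; rebalancing with intergenic draws")
        out <- c(out, draw_intergenic(k - length(out)))
      }
      out
    }

    seqs <- c(draw_intergenic(n_each[["intergenic"]]),
              draw_shuffled(n_each[["shuffled"]]),
              draw_neighbor(n_each[["neighbor"]]))
    origins <- rep(c("neg_intergenic", "neg_shuffled", "neg_neighbor"),
                   times = c(n_each[["intergenic"]], n_each[["shuffled"]],
                             length(seqs) - n_each[["intergenic"]] -
                               n_each[["shuffled"]]))
    tibble::tibble(
      site_id = paste0("neg_", seq_along(seqs)),
      shift = 0L, seq = seqs, label_class = 0,
      label_cleavage = rep(list(const_vec), length(seqs)),
      origin = origins)
  })
}

#' Relative usage and log2-odds of a polyA site
#'
#' Usage is the ratio of a site's supporting reads to the summed reads of the
#' two most highly expressed sites in the gene,
#' \eqn{u_i = n_i / (n_{top} + n_{second})}, log-odds transformed as
#' \eqn{o_i = \log_2(u_i / (1 - u_i))}.  When the ratio is degenerate (0 or
#' 1) a pseudocount of 0.5 reads is applied to both numerator and
#' denominator before the transform.
#'
#' @param n_i Reads supporting the site (vectorised).
#' @param n_top,n_second Reads of the most and second-most expressed site.
#' @return Tibble with `n_i`, `n_top`, `n_second`, `u_i`, `o_i`.
#' @export
usage_logodds <- function(n_i, n_top, n_second) {
  stopifnot(all(n_top >= n_second), all(n_second >= 0))
  tot <- n_top + n_second
  if (any(tot == 0)) stop("n_top + n_second must be positive")
  u <- n_i / tot
  degen <- u <= 0 | u >= 1
  u[degen] <- (n_i[degen] + 0.5) / (tot[degen] + 1)
  tibble::tibble(n_i = n_i, n_top = n_top, n_second = n_second,
                 u_i = u, o_i = log2(u / (1 - u)))
}

#' Split examples into training / validation / test sets at the site level
#'
#' All shifted examples of one site travel together (splitting is by
#' `site_id`), preventing leakage of near-identical shifted windows across
#' splits.  Positive and negative site groups are allocated separately so
#' the class balance of each split matches the input.
#'
#' @param examples Example tibble with `site_id` and `label_class`.
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return The input tibble with an added `split` factor column
#'   (`train` / `validation` / `test`).
#' @export
split_dataset <- function(examples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  key <- examples |>
    dplyr::distinct(.data$site_id, .data$label_class)
  assign_split <- function(ids) {
    n <- length(ids)
    sizes <- floor(n * fractions)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    rep(c("train", "validation", "test"), times = sizes)
  }
  with_seed(seed, {
    key <- key |>
      dplyr::group_by(.data$label_class) |>
      dplyr::group_modify(function(df, g) {
        df <- df[sample.int(nrow(df)), , drop = FALSE]
        df$split <- assign_split(df$site_id)
        df
      }) |>
      dplyr::ungroup()
  })
  examples |>
    dplyr::left_join(key, by = c("site_id", "label_class")) |>
    dplyr::mutate(split = factor(.data$split,
                                 levels = c("train", "validation", "test")))
}
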