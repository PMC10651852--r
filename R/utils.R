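#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that works on plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences (alphabet A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run code with a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, code) {
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, code)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
    force(code)
  }
}

#' Extract the 240-nt sense-strand window around an anchor position
#'
#' The window covers offsets -120..+119 around the anchor (the anchor is the
#' 121st base of the returned sequence).  On the minus strand the genomic
#' interval is mirrored and reverse-complemented so that the returned string
#' always reads 5'->3' in transcript sense.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param anchor Anchor position (1-based genomic coordinate).
#' @param strand `"+"` or `"-"`.
#' @param flank_up,flank_down Number of bases upstream/downstream of the
#'   anchor in sense orientation (defaults 120 and 119, giving 240 nt).
#' @return A character scalar of length `flank_up + flank_down + 1`, or
#'   `NA_character_` when the window runs off the chromosome.
#' @export
extract_window <- function(genome, chrom, anchor, strand = "+",
                           flank_up = 120L, flank_down = 119L) {
  seqs <- genome[[chrom]]
  n <- nchar(seqs)
  if (strand == "+") {
    s <- anchor - flank_up
    e <- anchor + flank_down
    if (s < 1L || e > n) return(NA_character_)
    substr(seqs, s, e)
  } else {
    s <- anchor - flank_down
    e <- anchor + flank_up
    if (s < 1L || e > n) return(NA_character_)
    revcomp(substr(seqs, s, e))
  }
}

# vectorised window extraction; returns NA for off-chromosome anchors
extract_windows <- function(genome, chrom, anchors, strand,
                            flank_up = 120L, flank_down = 119L) {
  strand <- rep_len(strand, length(anchors))
  chrom <- rep_len(chrom, length(anchors))
  out <- character(length(anchors))
  for (i in seq_along(anchors)) {
    out[i] <- extract_window(genome, chrom[i], anchors[i], strand[i],
                             flank_up, flank_down)
  }
  out
}

# random DNA with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Replace a substring in place
#'
#' @param x Character scalar.
#' @param start 1-based start position.
#' @param value Replacement text (the region `start..start+nchar(value)-1`
#'   is overwritten; the string length is unchanged).
#' @return The modified string.
#' @export
str_sub_replace <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}

# strand-aware "5'-most" pick among candidate coordinates
five_prime_most <- function(pos, strand) {
  if (strand == "+") min(pos) else max(pos)
}

# cleavage-vector index <-> sense offset conversion.  The 50-length vector
# covers offsets -25..+24 around its anchor; offset 0 sits at index 26.
offset_to_index <- function(offset) offset + 26L
index_to_offset <- function(index) index - 26L

# sense-strand genomic coordinate for a vector index around an anchor
index_to_genomic <- function(anchor, index, strand) {
  off <- index_to_offset(index)
  if (strand == "+") anchor + off else anchor - off
}

# Per-chromosome base-run tables used for the genomic A-run logic.
# For base b, positions inside a b-run get the run start/end; others NA.
base_run_table <- function(chrom_chars, base) {
  is_b <- chrom_chars == base
  r <- rle(is_b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- rep(NA_integer_, length(chrom_chars))
  run_end <- rep(NA_integer_, length(chrom_chars))
  for (i in which(r$values)) {
    run_start[starts[i]:ends[i]] <- starts[i]
    run_end[starts[i]:ends[i]] <- ends[i]
  }
  list(start = run_start, end = run_end, is_base = is_b)
}

stop_if_not_simplex <- function(v, tol = 1e-6) {
  if (abs(sum(v) - 1) > tol) {
    warning("vector does not sum to 1; renormalising")
    v <- v / sum(v)
  }
  v
}
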