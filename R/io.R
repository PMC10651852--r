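#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write called sites as BED6+
#'
#' Standard BED columns (0-based half-open; the site occupies one base)
#' plus `read_count`, `usage` and `genomic_class` when present.
#'
#' @param sites Site tibble (`chrom`, `pos`, `strand`, optionally
#'   `site_id`, `read_count_total`, `usage`, `genomic_class`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(
    chrom = sites$chrom,
    start = sites$pos - 1L,
    end = sites$pos,
    name = if ("site_id" %in% names(sites)) sites$site_id else ".",
    score = if ("read_count_total" %in% names(sites))
      sites$read_count_total else 0L,
    strand = sites$strand)
  if ("usage" %in% names(sites)) df$usage <- round(sites$usage, 4)
  if ("genomic_class" %in% names(sites)) df$genomic_class <- sites$genomic_class
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export an annotation tibble as GTF
#'
#' Uses rtracklayer when available.
#'
#' @param annotation Exon-level annotation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write GTF")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- annotation$feature
  gr$gene_id <- annotation$gene_id
  gr$transcript_id <- annotation$transcript_id
  gr$exon_number <- annotation$exon_rank
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Import an exon-level annotation from GTF
#'
#' @param path GTF file.
#' @return Annotation tibble in the package's exon-level layout.
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GTF")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tibble::tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = "exon",
    exon_rank = as.integer(gr$exon_number),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))
}

#' Write simulated variants as a minimal VCF
#'
#' Plain-text VCFv4.2 with the intended effect in the INFO field; intended
#' for the package's synthetic single-nucleotide fixtures.
#'
#' @param variants Variant tibble from [simulate_variants()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Intended effect on polyA grammar\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tEFFECT=%s",
                  variants$chrom, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, variants$intended_effect)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF into a variant tibble
#'
#' @param path VCF file (uncompressed text).
#' @return Variant tibble (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `intended_effect` when present).
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    variant_id = vapply(parts, `[[`, character(1), 3),
    chrom = vapply(parts, `[[`, character(1), 1),
    pos = as.integer(vapply(parts, `[[`, character(1), 2)),
    ref = vapply(parts, `[[`, character(1), 4),
    alt = vapply(parts, `[[`, character(1), 5),
    intended_effect = sub("^.*EFFECT=([^;]+).*$", "\\1",
                          vapply(parts, `[[`, character(1), 8)))
}

#' Read 3'-end alignments from SAM/BAM into the package's alignment layout
#'
#' Uses Rsamtools; soft-clipped tail As (plus-strand reads) or leading Ts
#' (minus-strand reads) are recovered from the CIGAR string and reported as
#' sense-orientation A tails.
#'
#' @param path SAM or BAM file (SAM files are converted on the fly).
#' @return Alignment tibble compatible with [extract_pass_reads()].
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "seq", "mapq",
             "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  rows <- lapply(seq_len(n), function(i) {
    cigar <- b$cigar[i]
    strand <- as.character(b$strand[i])
    ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    kinds <- sub("^\\d+", "", toks)
    ref_len <- sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
    seqc <- as.character(b$seq[i])
    if (strand == "+") {
      align_end <- b$pos[i] + ref_len - 1L
      tail <- if (kinds[length(kinds)] == "S") {
        substring(seqc, nchar(seqc) - lens[length(lens)] + 1L, nchar(seqc))
      } else ""
      tail_sense <- tail
    } else {
      align_end <- b$pos[i]
      tail <- if (kinds[1] == "S") substring(seqc, 1L, lens[1]) else ""
      tail_sense <- revcomp(tail)   # leading Ts -> sense As
    }
    tibble::tibble(read_id = b$qname[i], chrom = as.character(b$rname[i]),
                   strand = strand, align_end = align_end,
                   tail = tail_sense, mapq = b$mapq[i],
                   secondary = bitwAnd(b$flag[i], 256L) > 0L)
  })
  dplyr::bind_rows(rows)
}
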