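# AnnotatedGenome: the frame for every codon-aware statistic. Coordinates are
# 0-based half-open throughout the package; conversions to/from 1-based
# formats (GFF3, SAM) happen at the file boundary only.

#' Construct an annotated genome
#'
#' @param id genome identifier.
#' @param sequence nucleotide string over `ACGT` (uppercased on input).
#' @param genes data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open) and `strand` (`+`/`-`). Gene lengths must be multiples of 3.
#' @param masked data.frame with columns `start`, `end` (0-based half-open)
#'   of regions excluded from recruitment and from all length denominators,
#'   e.g. the ribosomal operon. Stored as intervals; the sequence itself is
#'   not altered, so original coordinates are preserved.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence,
                             genes = empty_genes(),
                             masked = empty_intervals()) {
  sequence <- toupper(sequence)
  g <- list(id = as.character(id), sequence = sequence,
            genes = as.data.frame(genes), masked = as.data.frame(masked))
  class(g) <- "annotated_genome"
  validate_genome(g)
  g
}

empty_genes <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(start = integer(0), end = integer(0))
}

validate_genome <- function(g) {
  L <- nchar(g$sequence)
  if (grepl("[^ACGTN]", g$sequence)) {
    stop("genome sequence contains characters outside ACGTN")
  }
  ge <- g$genes
  if (nrow(ge)) {
    if (any(ge$end <= ge$start)) stop("gene with end <= start")
    if (any(ge$start < 0 | ge$end > L)) {
      stop("gene interval outside [0, genome length)")
    }
    if (any((ge$end - ge$start) %% 3L != 0L)) {
      bad <- ge$gene_id[(ge$end - ge$start) %% 3L != 0L]
      stop("gene length not a multiple of 3: ", paste(bad, collapse = ", "))
    }
    if (!all(ge$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  }
  mk <- g$masked
  if (nrow(mk)) {
    if (any(mk$start < 0 | mk$end > L | mk$end <= mk$start)) {
      i <- which(mk$start < 0 | mk$end > L | mk$end <= mk$start)[1]
      stop(sprintf("masked interval out of bounds: [%d,%d)", mk$start[i], mk$end[i]))
    }
  }
  invisible(g)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %d genes, %d bp masked\n",
              x$id, nchar(x$sequence), nrow(x$genes),
              nchar(x$sequence) - effective_length(x)))
  invisible(x)
}

#' Mask genome regions
#'
#' Marks intervals (e.g. the ribosomal operon cluster) to be excluded from
#' read recruitment and from all length denominators such as the RPKG genome
#' length. Masking is recorded as an interval set carried alongside the
#' sequence; coordinates are unchanged.
#'
#' @param genome an [annotated_genome].
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @return the genome with the intervals added to its mask.
#' @export
mask_regions <- function(genome, intervals) {
  stopifnot(inherits(genome, "annotated_genome"))
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0) return(genome)
  L <- nchar(genome$sequence)
  bad <- intervals$start < 0 | intervals$end > L | intervals$end <= intervals$start
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("mask interval out of bounds: [%d,%d) on %d-bp genome",
                 intervals$start[i], intervals$end[i], L))
  }
  genome$masked <- reduce_intervals(rbind(genome$masked, intervals[c("start", "end")]))
  validate_genome(genome)
  genome
}

# union of 0-based half-open intervals via IRanges
reduce_intervals <- function(iv) {
  if (nrow(iv) == 0) return(empty_intervals())
  r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

masked_width <- function(genome) {
  iv <- reduce_intervals(genome$masked)
  sum(iv$end - iv$start)
}

#' Effective (unmasked) genome length
#'
#' Genome length minus the union of masked intervals; the denominator used
#' for RPKG.
#'
#' @param genome an [annotated_genome].
#' @return integer length in bp.
#' @export
effective_length <- function(genome) {
  nchar(genome$sequence) - masked_width(genome)
}

# coding sequence of a gene in reading frame (minus-strand genes are
# reverse-complemented)
gene_sequence <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  s <- substr(genome$sequence, genome$genes$start[i] + 1L, genome$genes$end[i])
  if (genome$genes$strand[i] == "-") s <- reverse_complement(s)
  s
}
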