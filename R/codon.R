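# Genetic-code lookup machinery shared by the simulator, the microdiversity
# statistics and the synonymous-site mask. Codons are encoded base-by-base
# (A=0, C=1, G=2, T=3) into 0..63; all per-codon quantities are precomputed
# once into flat lookup tables at first use.

BASES <- c("A", "C", "G", "T")

# cached environment for lazy-built tables
.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- character(64L)
  aa <- character(64L)
  for (i in 0:63) {
    b <- c(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
    codons[i + 1L] <- paste0(BASES[b + 1L], collapse = "")
    aa[i + 1L] <- unname(gc_map[codons[i + 1L]])
  }
  is_stop <- aa == "*"
  # syn_alt[[code+1]][[pos]] : integer vector of alternative bases (0..3) at
  # codon position pos (1..3) that leave the amino acid unchanged (stops are
  # never synonymous alternatives of a sense codon)
  syn_alt <- vector("list", 64L)
  # classification of every single-base change: syn_change[code+1, pos, alt+1]
  # TRUE = synonymous (stop-creating changes count as nonsynonymous)
  syn_change <- array(NA, dim = c(64L, 3L, 4L))
  for (i in 0:63) {
    b <- c(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
    syn_alt[[i + 1L]] <- vector("list", 3L)
    for (pos in 1:3) {
      alts <- integer(0)
      for (nb in 0:3) {
        if (nb == b[pos]) next
        b2 <- b
        b2[pos] <- nb
        j <- b2[1] * 16L + b2[2] * 4L + b2[3]
        syn <- !is_stop[j + 1L] && !is_stop[i + 1L] && aa[j + 1L] == aa[i + 1L]
        syn_change[i + 1L, pos, nb + 1L] <- syn
        if (syn) alts <- c(alts, nb)
      }
      syn_alt[[i + 1L]][[pos]] <- alts
    }
  }
  # Nei-Gojobori fractional expected sites per sense codon
  s_sites <- rep(NA_real_, 64L)
  for (i in 0:63) {
    if (is_stop[i + 1L]) next
    s <- 0
    for (pos in 1:3) s <- s + sum(syn_change[i + 1L, pos, ], na.rm = TRUE) / 3
    s_sites[i + 1L] <- s
  }
  tab <- list(codons = codons, aa = aa, is_stop = is_stop,
              syn_alt = syn_alt, syn_change = syn_change,
              s_sites = s_sites, n_sites = ifelse(is_stop, NA_real_, 3 - s_sites))
  .codon_env$tab <- tab
  tab
}

# encode a nucleotide string to integer bases 0..3 (NA for anything else)
encode_bases <- function(x) {
  v <- utf8ToInt(x)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

decode_bases <- function(b) {
  intToUtf8(c(65L, 67L, 71L, 84L)[b + 1L])
}

codon_code_from_bases <- function(b1, b2, b3) b1 * 16L + b2 * 4L + b3

# reverse complement of a codon code (code of revcomp'ed triplet)
revcomp_codon_code <- function(code) {
  b <- cbind(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L)
  rc <- 3L - b[, c(3L, 2L, 1L), drop = FALSE]
  rc[, 1L] * 16L + rc[, 2L] * 4L + rc[, 3L]
}

translate_codon <- function(codon) {
  tab <- codon_tables()
  unname(tab$aa[match(codon, tab$codons)])
}

#' Expected synonymous and nonsynonymous site counts of a codon
#'
#' Fractional site counting: at each of the three codon positions the
#' synonymous-site contribution is the fraction of the three single-base
#' alternatives that preserve the encoded amino acid; the nonsynonymous
#' contribution is the complement, so `s + n = 3` for every sense codon.
#' Changes that create a stop codon count as nonsynonymous.
#'
#' @param ref_codon character vector of sense codons over `ACGT`.
#' @return data.frame with columns `codon`, `s` (synonymous sites) and
#'   `n` (nonsynonymous sites).
#' @examples
#' expected_sites("TTT")  # s = 1/3: only TTC stays Phe
#' expected_sites("TGG")  # Trp has no synonymous neighbor: s = 0
#' @export
expected_sites <- function(ref_codon) {
  tab <- codon_tables()
  ref_codon <- toupper(ref_codon)
  bad <- grepl("[^ACGT]", ref_codon) | nchar(ref_codon) != 3L
  if (any(bad)) {
    stop("codon(s) containing non-ACGT characters or wrong length: ",
         paste(ref_codon[bad], collapse = ", "))
  }
  idx <- match(ref_codon, tab$codons)
  if (any(tab$is_stop[idx])) {
    stop("stop codon(s) passed to expected_sites(): ",
         paste(ref_codon[tab$is_stop[idx]], collapse = ", "))
  }
  data.frame(codon = ref_codon, s = tab$s_sites[idx], n = tab$n_sites[idx],
             stringsAsFactors = FALSE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
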