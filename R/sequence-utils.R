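#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. The package works in RNA space
#' internally; DNA/RNA conversion happens only at I/O boundaries.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over A/C/G/U (plus any ambiguity codes present
#'   in the input, which downstream code treats as unpairable mismatches).
#' @export
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

#' Normalize a nucleotide string to the DNA alphabet
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector with U converted to T, uppercased.
#' @export
as_dna <- function(x) chartr("Uu", "TT", toupper(x))

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA sequences (A/C/G/U; N allowed).
#' @return reverse complement, RNA alphabet.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGUN", "UGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T; N allowed).
#' @return reverse complement, DNA alphabet.
#' @export
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings; any character
# difference (including N vs a base) counts as one mismatch.
str_hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("hamming distance requires equal lengths")
  sum(ca != cb)
}

# Natural sort for miRNA family names: numeric core first, then the full
# name, so miR528 sorts before miR5049 the way biologists list families.
family_order <- function(fams) {
  core <- suppressWarnings(as.numeric(sub("^miR", "", fams)))
  core[is.na(core)] <- Inf
  order(core, fams)
}

sort_families <- function(fams) fams[family_order(fams)]
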