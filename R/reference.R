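#' Canonical miRNA family name from a miRBase-style identifier
#'
#' Reduces a full mature-miRNA name to its family, so that homologues
#' found through references from different species and arms collapse to
#' one family per lineage. The grammar strips an optional species prefix
#' (e.g. `bdi-`), is case-insensitive on "miR", drops the letter variant
#' suffix (`a`, `b`, ...), an optional precursor copy number (`-1`, `.2`),
#' and an optional arm suffix (`-5p`/`-3p`).
#'
#' @param ref_id character vector of miRNA identifiers, e.g.
#'   `"bdi-miR156a-5p"` or `"osa-miR2118b"`.
#' @return character vector of family names, e.g. `"miR156"`.
#' @examples
#' assign_family(c("bdi-miR156a-5p", "osa-miR2118b", "ata-miR9783-3p"))
#' @export
assign_family <- function(ref_id) {
  if (length(ref_id) == 0) return(character(0))
  if (any(is.na(ref_id) | !nzchar(ref_id))) {
    stop("miRNA identifiers must be non-empty strings")
  }
  pat <- "^(?:[A-Za-z][A-Za-z0-9]{1,4}-)?[Mm][Ii][Rr]-?([0-9]+)[a-z]*(?:[-.][0-9]+)?(?:-[35]p)?$"
  m <- regmatches(ref_id, regexec(pat, ref_id))
  bad <- vapply(m, length, integer(1)) != 2L
  if (any(bad)) {
    stop("cannot parse miRNA identifier(s): ",
         paste(utils::head(ref_id[bad], 5), collapse = ", "))
  }
  paste0("miR", vapply(m, `[`, character(1), 2L))
}

#' Read a reference set of mature miRNAs
#'
#' Reads a FASTA file of mature miRNA sequences with miRBase-dialect
#' headers (`>bdi-miR156a-5p ...`). Sequences are normalized to RNA
#' (T converted to U) and uppercased. Entries containing ambiguous bases
#' (anything outside A/C/G/U) are rejected with a warning, since a
#' reference with undefined positions cannot anchor a homology scan.
#'
#' @param path path to a FASTA file of mature miRNAs.
#' @return a data.frame with columns `id`, `family`, `sequence` (RNA).
#' @seealso [assign_family()]
#' @export
read_mature_mirnas <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as_rna(as.character(ss))
  clean <- !grepl("[^ACGU]", seqs)
  if (any(!clean)) {
    warning(sum(!clean), " reference sequence(s) with ambiguous bases rejected")
  }
  if (!any(clean)) stop("no usable reference miRNAs in ", path)
  ids <- ids[clean]
  seqs <- unname(seqs[clean])
  data.frame(id = ids, family = assign_family(ids), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Build a reference miRNA table from named sequences
#'
#' Convenience constructor used by the synthetic panel generator and in
#' examples: takes a named character vector of mature sequences (names are
#' miRBase-style identifiers) and returns the same table that
#' [read_mature_mirnas()] produces from a FASTA file.
#'
#' @param seqs named character vector of mature miRNA sequences.
#' @return data.frame with columns `id`, `family`, `sequence`.
#' @export
reference_mirnas <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("reference sequences must be named with miRNA identifiers")
  }
  seqs_rna <- as_rna(seqs)
  if (any(grepl("[^ACGU]", seqs_rna))) {
    stop("reference miRNAs must be unambiguous A/C/G/U sequences")
  }
  data.frame(id = names(seqs), family = assign_family(names(seqs)),
             sequence = unname(seqs_rna), stringsAsFactors = FALSE)
}

#' Read a genome assembly
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases the
#' sequence and trims FASTA descriptions to the first word, so contig
#' names match annotation files.
#'
#' @param path path to a (multi-)FASTA genome file.
#' @return a [Biostrings::DNAStringSet] of contigs.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- Biostrings::DNAStringSet(toupper(g))
  g
}

# Coerce user input (named character vector or DNAStringSet) to a
# DNAStringSet of uppercase contigs.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("contig", seq_along(genome))
    }
    return(Biostrings::DNAStringSet(as_dna(genome)))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}
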