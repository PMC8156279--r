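#' Write accepted miRNA loci as GFF3
#'
#' One `miRNA_primary_transcript` feature per precursor with a child
#' `miRNA` feature for the mature. Internal 0-based half-open coordinates
#' are converted to GFF3's 1-based inclusive convention.
#'
#' @param loci locus table from [discover_mirnome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci) > 0) {
    for (i in seq_len(nrow(loci))) {
      id <- sprintf("%s_%s_%d", loci$lineage[i], loci$family[i], i)
      writeLines(sprintf(
        "%s\tpanmirnome\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
        loci$seq_id[i], loci$pre_start[i] + 1L, loci$pre_end[i],
        loci$strand[i], id, loci$family[i]), con)
      writeLines(sprintf(
        "%s\tpanmirnome\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
        loci$seq_id[i], loci$mat_start[i] + 1L, loci$mat_end[i],
        loci$strand[i], id, id), con)
    }
  }
  invisible(path)
}

#' Write a data.frame as a TSV file
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-family precursor FASTA files
#'
#' One FASTA per family, containing every accepted precursor across
#' lineages — the export used for downstream multiple alignment or GO
#' annotation with external tools.
#'
#' @param loci combined locus table (must include `precursor_seq`).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_family_precursors <- function(loci, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in unique(loci$family)) {
    rows <- loci[loci$family == f, , drop = FALSE]
    ids <- sprintf("%s|%s:%d-%d(%s)", rows$lineage, rows$seq_id,
                   rows$pre_start, rows$pre_end, rows$strand)
    ss <- Biostrings::RNAStringSet(stats::setNames(rows$precursor_seq, ids))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(f, ".fa")))
  }
  invisible(dir)
}

#' Write a presence matrix as TSV
#'
#' @param pm a `presence_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(pm, path) {
  df <- cbind(data.frame(family = pm$families, stringsAsFactors = FALSE),
              as.data.frame(pm$present * 1L, row.names = NULL))
  write_tsv(df, path)
}
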