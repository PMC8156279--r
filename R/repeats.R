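#' Read repeat annotations from a BED file
#'
#' @param path BED file (first three columns chrom, start, end; 0-based
#'   half-open, the native BED convention).
#' @return data.frame `seq_id`, `start`, `end` (0-based half-open).
#' @export
read_repeat_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  data.frame(seq_id = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Read repeat annotations from a RepeatMasker .out file
#'
#' Parses the standard RepeatMasker table (3 header lines, whitespace
#' separated; query coordinates 1-based inclusive) and converts to the
#' package's 0-based half-open convention.
#'
#' @param path RepeatMasker `.out` file.
#' @return data.frame `seq_id`, `start`, `end` (0-based half-open).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(seq_id = vapply(fields, `[`, character(1), 5L),
             start = as.integer(vapply(fields, `[`, character(1), 6L)) - 1L,
             end = as.integer(vapply(fields, `[`, character(1), 7L)),
             stringsAsFactors = FALSE)
}

#' Fraction of a precursor covered by repeat annotations
#'
#' Repeat intervals are union-merged before coverage is computed, so
#' overlapping repeat calls are not double-counted.
#'
#' @param interval numeric length-2 vector `c(start, end)`, 0-based
#'   half-open, of the precursor on its contig.
#' @param repeats data.frame with `start`, `end` columns (0-based
#'   half-open), already restricted to the precursor's contig. Extra
#'   columns are ignored.
#' @return covered fraction in `[0, 1]`.
#' @examples
#' masked_fraction(c(0, 100), data.frame(start = c(10, 50), end = c(60, 80)))
#' @export
masked_fraction <- function(interval, repeats) {
  start <- as.integer(interval[1]); end <- as.integer(interval[2])
  if (end <= start) stop("zero-length precursor interval")
  if (is.null(repeats) || nrow(repeats) == 0) return(0)
  rep_ir <- IRanges::reduce(IRanges::IRanges(start = repeats$start + 1L,
                                             end = repeats$end))
  pre_ir <- IRanges::IRanges(start = start + 1L, end = end)
  ov <- IRanges::intersect(rep_ir, pre_ir)
  sum(IRanges::width(ov)) / (end - start)
}

#' Classify a precursor as repetitive
#'
#' A precursor is repetitive when repeats cover strictly more than half of
#' its length; exactly half is not repetitive.
#'
#' @param fraction covered fraction in `[0, 1]` from [masked_fraction()].
#' @return logical vector.
#' @export
classify_repetitive <- function(fraction) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must be in [0, 1]")
  fraction > 0.5
}

#' Annotate a locus table with repeat content
#'
#' @param loci locus table from [discover_mirnome()] (needs `seq_id`,
#'   `pre_start`, `pre_end`).
#' @param repeats repeat annotation data.frame with `seq_id`, `start`,
#'   `end` (0-based half-open), e.g. from [read_repeat_bed()].
#' @return `loci` with added `repeat_fraction` and `repetitive` columns.
#' @export
annotate_repetitive <- function(loci, repeats) {
  frac <- numeric(nrow(loci))
  if (nrow(loci) > 0) {
    for (i in seq_len(nrow(loci))) {
      r <- repeats[repeats$seq_id == loci$seq_id[i], , drop = FALSE]
      frac[i] <- masked_fraction(c(loci$pre_start[i], loci$pre_end[i]), r)
    }
  }
  loci$repeat_fraction <- frac
  loci$repetitive <- classify_repetitive(frac)
  loci
}
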