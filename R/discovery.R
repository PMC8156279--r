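#' Scan a genome for mature-miRNA candidate hits
#'
#' Finds every window, on both strands, whose substitution-only Hamming
#' distance to a reference mature miRNA is at most `max_mismatch`
#' (default 1, homology-scan convention). Indels are not considered at
#' this step; they surface later as structural bulges after folding.
#' Ambiguous bases (N) in a genomic window count as mismatches.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector of
#'   contigs.
#' @param refs reference table from [read_mature_mirnas()] or
#'   [reference_mirnas()].
#' @param max_mismatch maximum Hamming distance to a reference (default 1).
#' @param lineage lineage label recorded in the hits.
#' @return data.frame of candidate hits with 0-based half-open coordinates
#'   on the forward strand: `lineage`, `seq_id`, `strand`, `start`, `end`,
#'   `mismatches`, `ref_id`, `family`, `mature_genomic_seq` (RNA, read on
#'   the hit strand).
#' @export
find_candidate_hits <- function(genome, refs, max_mismatch = 1L,
                                lineage = "lineage") {
  genome <- as_genome(genome)
  empty <- data.frame(lineage = character(0), seq_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      ref_id = character(0), family = character(0),
                      mature_genomic_seq = character(0),
                      stringsAsFactors = FALSE)
  if (length(genome) == 0 || nrow(refs) == 0) return(empty)
  rows <- list()
  for (r in seq_len(nrow(refs))) {
    pat_rna <- refs$sequence[r]
    pat <- Biostrings::DNAString(as_dna(pat_rna))
    rcpat <- Biostrings::reverseComplement(pat)
    for (ci in seq_along(genome)) {
      subject <- genome[[ci]]
      if (length(subject) < length(pat)) next
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rcpat
        mt <- Biostrings::matchPattern(p, subject,
                                       max.mismatch = max_mismatch,
                                       fixed = TRUE)
        if (length(mt) == 0) next
        win <- as.character(mt)
        mature <- if (strand == "+") as_rna(win) else revcomp_rna(as_rna(win))
        mm <- vapply(mature, str_hamming, integer(1), b = pat_rna,
                     USE.NAMES = FALSE)
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lineage, seq_id = names(genome)[ci], strand = strand,
          start = BiocGenerics::start(mt)[keep] - 1L,
          end = BiocGenerics::end(mt)[keep],
          mismatches = mm[keep], ref_id = refs$id[r],
          family = refs$family[r],
          mature_genomic_seq = mature[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$seq_id, hits$start, hits$strand, hits$ref_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract a precursor window around a candidate hit
#'
#' Cuts the genomic window covering the mature plus 5'/3' flanks, on the
#' hit's strand, truncating at contig boundaries. `flank_up` is the flank
#' on the precursor's 5' side, so on the minus strand it extends toward
#' higher genomic coordinates.
#'
#' @param genome contigs as in [find_candidate_hits()].
#' @param hit one-row data.frame (a row of the hit table).
#' @param flank_up,flank_down flank lengths in nt (default 100 each).
#' @return list with `precursor_seq` (RNA, precursor sense),
#'   `mature_offset` (0-based offset of the mature within the precursor),
#'   `mature_length`, `genomic_start`/`genomic_end` (0-based half-open,
#'   forward strand), `strand`, `seq_id`.
#' @export
extract_precursor <- function(genome, hit, flank_up = 100L,
                              flank_down = 100L) {
  stopifnot(flank_up >= 0, flank_down >= 0)
  genome <- as_genome(genome)
  if (!hit$seq_id %in% names(genome)) stop("unknown contig: ", hit$seq_id)
  contig <- genome[[hit$seq_id]]
  L <- length(contig)
  if (hit$start < 0 || hit$end > L || hit$start >= hit$end) {
    stop("hit lies outside contig ", hit$seq_id)
  }
  if (hit$strand == "+") {
    g0 <- max(0L, hit$start - as.integer(flank_up))
    g1 <- min(L, hit$end + as.integer(flank_down))
    pre <- as_rna(as.character(Biostrings::subseq(contig, g0 + 1L, g1)))
    offset <- hit$start - g0
  } else {
    g0 <- max(0L, hit$start - as.integer(flank_down))
    g1 <- min(L, hit$end + as.integer(flank_up))
    pre <- revcomp_rna(as_rna(as.character(
      Biostrings::subseq(contig, g0 + 1L, g1))))
    offset <- g1 - hit$end
  }
  list(precursor_seq = pre, mature_offset = as.integer(offset),
       mature_length = hit$end - hit$start,
       genomic_start = as.integer(g0), genomic_end = as.integer(g1),
       strand = hit$strand, seq_id = hit$seq_id)
}

#' Screen a folded precursor candidate against hairpin criteria
#'
#' Applies the four-criteria screen used in homology-based plant miRNA
#' discovery:
#'
#' 1. no mismatches at the Dicer cut sites — both terminal nucleotides of
#'    the mature must be base-paired;
#' 2. no multi-branched loop in the hairpin containing the mature — within
#'    the enclosure spanned by the mature's outermost paired bases and
#'    their partners, no closing helix may be followed by a new opening
#'    helix;
#' 3. the mature may not lie in the head of the hairpin — zero overlap
#'    with any terminal (hairpin) loop;
#' 4. at most `max_mature_mismatch` unpaired positions within the mature
#'    and `max_star_mismatch` within the star span (the region on the
#'    opposite arm between the partners of the mature's outermost paired
#'    bases).
#'
#' G:U wobbles count as paired. A mature with no paired position at all
#' fails with `star_mismatches` equal to the mature length and an empty
#' star span.
#'
#' @param cand precursor candidate from [extract_precursor()] (any list
#'   with `precursor_seq`, `mature_offset`, `mature_length`).
#' @param struct [fold()] result for `cand$precursor_seq`.
#' @param max_mature_mismatch,max_star_mismatch screen thresholds
#'   (defaults 4 and 6).
#' @return list of class `screen_result`: logical flags
#'   `dicer_ends_paired`, `no_multibranch`, `mature_not_in_head`, counts
#'   `mature_mismatches`, `star_mismatches`, `star_span` (1-based
#'   inclusive precursor coordinates or NULL), and `passed`.
#' @export
evaluate_hairpin <- function(cand, struct, max_mature_mismatch = 4L,
                             max_star_mismatch = 6L) {
  pt <- struct$pair_table
  n <- length(pt)
  L <- cand$mature_length
  m0 <- cand$mature_offset + 1L
  m1 <- cand$mature_offset + L
  if (m1 > n) stop("mature does not fit in precursor")
  mat_pos <- m0:m1
  paired <- mat_pos[pt[mat_pos] != 0L]
  mature_mismatches <- L - length(paired)

  if (length(paired) == 0L) {
    res <- list(dicer_ends_paired = FALSE, no_multibranch = FALSE,
                mature_not_in_head = FALSE,
                mature_mismatches = mature_mismatches,
                star_mismatches = L, star_span = NULL, passed = FALSE)
    class(res) <- "screen_result"
    return(res)
  }

  dicer_ends_paired <- pt[m0] != 0L && pt[m1] != 0L

  partners <- pt[paired]
  lo <- min(c(paired, partners))
  hi <- max(c(paired, partners))
  enc <- substr(struct$dotbracket, lo, hi)
  no_multibranch <- !grepl("\\).*\\(", enc)

  loops <- hairpin_loops(pt)
  in_head <- any(vapply(loops, function(lp) m0 <= lp[2] && m1 >= lp[1],
                        logical(1)))
  mature_not_in_head <- !in_head

  pfirst <- paired[1]
  plast <- paired[length(paired)]
  s0 <- min(pt[pfirst], pt[plast])
  s1 <- max(pt[pfirst], pt[plast])
  star_span <- c(s0, s1)
  star_mismatches <- sum(pt[s0:s1] == 0L)

  passed <- dicer_ends_paired && no_multibranch && mature_not_in_head &&
    mature_mismatches <= max_mature_mismatch &&
    star_mismatches <= max_star_mismatch

  res <- list(dicer_ends_paired = dicer_ends_paired,
              no_multibranch = no_multibranch,
              mature_not_in_head = mature_not_in_head,
              mature_mismatches = mature_mismatches,
              star_mismatches = star_mismatches,
              star_span = star_span, passed = passed)
  class(res) <- "screen_result"
  res
}

#' Discover the miRNome of one lineage
#'
#' Composes the homology scan, precursor extraction, folding, and the
#' hairpin screen, then deduplicates accepted loci: loci of the same
#' family whose precursor intervals overlap on the same strand collapse to
#' the hit with fewest mismatches, ties broken by lower folding energy,
#' then by leftmost start. A lineage's family set is the set of distinct
#' families with at least one accepted locus.
#'
#' @inheritParams find_candidate_hits
#' @param flank_up,flank_down precursor flanks in nt (default 100 each).
#' @param engine folding engine, see [fold()].
#' @param max_mature_mismatch,max_star_mismatch screen thresholds.
#' @return data.frame of accepted loci, one row per deduplicated locus:
#'   lineage, family, ref_id, seq_id, strand, `pre_start`/`pre_end` and
#'   `mat_start`/`mat_end` (0-based half-open, forward strand),
#'   `mature_offset`, `mismatches`, `mfe`, `dotbracket`, `precursor_seq`,
#'   screen flags, and `engine`. The attribute `lineage` carries the
#'   label; use [mirnome_families()] for the family set.
#' @export
discover_mirnome <- function(genome, refs, lineage = "lineage",
                             max_mismatch = 1L, flank_up = 100L,
                             flank_down = 100L,
                             engine = c("fallback", "thermo"),
                             max_mature_mismatch = 4L,
                             max_star_mismatch = 6L) {
  engine <- match.arg(engine)
  genome <- as_genome(genome)
  hits <- find_candidate_hits(genome, refs, max_mismatch = max_mismatch,
                              lineage = lineage)
  cols <- c("lineage", "family", "ref_id", "seq_id", "strand", "pre_start",
            "pre_end", "mat_start", "mat_end", "mature_offset",
            "mismatches", "mfe", "dotbracket", "precursor_seq",
            "dicer_ends_paired", "no_multibranch", "mature_not_in_head",
            "mature_mismatches", "star_mismatches", "engine")
  empty <- function() {
    df <- data.frame(lineage = character(0), family = character(0),
                     ref_id = character(0), seq_id = character(0),
                     strand = character(0), pre_start = integer(0),
                     pre_end = integer(0), mat_start = integer(0),
                     mat_end = integer(0), mature_offset = integer(0),
                     mismatches = integer(0), mfe = numeric(0),
                     dotbracket = character(0), precursor_seq = character(0),
                     dicer_ends_paired = logical(0),
                     no_multibranch = logical(0),
                     mature_not_in_head = logical(0),
                     mature_mismatches = integer(0),
                     star_mismatches = integer(0), engine = character(0),
                     stringsAsFactors = FALSE)
    attr(df, "lineage") <- lineage
    df
  }
  if (nrow(hits) == 0) return(empty())
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, , drop = FALSE]
    cand <- extract_precursor(genome, hit, flank_up = flank_up,
                              flank_down = flank_down)
    struct <- fold(cand$precursor_seq, engine = engine)
    sc <- evaluate_hairpin(cand, struct,
                           max_mature_mismatch = max_mature_mismatch,
                           max_star_mismatch = max_star_mismatch)
    if (!sc$passed) next
    rows[[i]] <- data.frame(
      lineage = hit$lineage, family = hit$family, ref_id = hit$ref_id,
      seq_id = hit$seq_id, strand = hit$strand,
      pre_start = cand$genomic_start, pre_end = cand$genomic_end,
      mat_start = hit$start, mat_end = hit$end,
      mature_offset = cand$mature_offset, mismatches = hit$mismatches,
      mfe = struct$mfe, dotbracket = struct$dotbracket,
      precursor_seq = cand$precursor_seq,
      dicer_ends_paired = sc$dicer_ends_paired,
      no_multibranch = sc$no_multibranch,
      mature_not_in_head = sc$mature_not_in_head,
      mature_mismatches = sc$mature_mismatches,
      star_mismatches = sc$star_mismatches, engine = engine,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty())
  loci <- do.call(rbind, rows)
  loci <- dedup_loci(loci)
  loci <- loci[, cols]
  loci <- loci[order(loci$seq_id, loci$pre_start, loci$strand,
                     family_order(loci$family)), , drop = FALSE]
  rownames(loci) <- NULL
  attr(loci, "lineage") <- lineage
  loci
}

# Collapse same-family, same-strand loci with overlapping precursor
# intervals: keep fewest mismatches, then lowest mfe, then leftmost start.
dedup_loci <- function(loci) {
  keys <- paste(loci$family, loci$seq_id, loci$strand, sep = "\r")
  keep <- logical(nrow(loci))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    ir <- IRanges::IRanges(start = loci$pre_start[idx] + 1L,
                           end = loci$pre_end[idx])
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(
      ir, IRanges::reduce(ir)))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      best <- members[order(loci$mismatches[members], loci$mfe[members],
                            loci$pre_start[members])][1]
      keep[best] <- TRUE
    }
  }
  loci[keep, , drop = FALSE]
}

#' Family set of a discovered miRNome
#'
#' @param loci locus table from [discover_mirnome()].
#' @return character vector of distinct family names, natural-sorted.
#' @export
mirnome_families <- function(loci) {
  sort_families(unique(loci$family))
}
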