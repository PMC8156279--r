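#' Global alignment identity between two sequences
#'
#' Identity under a maximum-match global alignment (match +1, mismatch 0,
#' gap 0, no affine term): with these scores the optimal score equals the
#' maximum number of aligned identical bases M, and every unmatched base
#' occupies its own column, so identity is defined as
#' `M / (n1 + n2 - M)`, a deterministic function of the two sequences.
#' Identical sequences give 1; disjoint alphabets give 0.
#'
#' @param a,b nucleotide sequences (DNA or RNA).
#' @return identity in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  a <- as_dna(a); b <- as_dna(b)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 0)
  M <- Biostrings::score(aln)
  M / (nchar(a) + nchar(b) - M)
}

#' Greedy identity clustering of transcripts
#'
#' Longest-first incremental clustering in the CD-HIT-EST tradition:
#' sequences are sorted by decreasing length (ties by id), and each
#' sequence joins the first existing cluster whose representative it
#' matches at `identity` or better under [alignment_identity()];
#' otherwise it founds a new cluster. Representatives are therefore the
#' longest member of each cluster (ties resolved lexicographically by
#' id through the sort).
#'
#' @param seqs named character vector of transcript sequences.
#' @param identity identity threshold in `[0, 1]` (default 0.90).
#' @return list of clusters; each cluster is a list with `representative`
#'   (id) and `members` (character vector of ids, representative first).
#' @export
cluster_transcripts <- function(seqs, identity = 0.90) {
  if (length(seqs) == 0) return(list())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]]$representative
      if (alignment_identity(seqs[[id]], seqs[[rep_id]]) >= identity) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(representative = id, members = id)
    }
  }
  clusters
}

#' Representative sequences of a clustering
#'
#' @param clusters result of [cluster_transcripts()].
#' @param seqs the sequence set that was clustered.
#' @return named character vector of representative sequences.
#' @export
cluster_representatives <- function(clusters, seqs) {
  ids <- vapply(clusters, `[[`, character(1), "representative")
  seqs[ids]
}

#' Multiplicity bin scheme
#'
#' The 11 bins used to summarize how many targets a miRNA family has
#' (and how many families target a transcript): 1, 2-5, 6-10, 11-20,
#' 21-50, 51-100, 101-200, 201-300, 301-400, 401-500, >500.
#'
#' @return data.frame `label`, `lo`, `hi` (inclusive; `hi = Inf` for the
#'   open top bin).
#' @export
multiplicity_bins <- function() {
  lo <- c(1, 2, 6, 11, 21, 51, 101, 201, 301, 401, 501)
  hi <- c(1, 5, 10, 20, 50, 100, 200, 300, 400, 500, Inf)
  data.frame(label = c("1", "2-5", "6-10", "11-20", "21-50", "51-100",
                       "101-200", "201-300", "301-400", "401-500", ">500"),
             lo = lo, hi = hi, stringsAsFactors = FALSE)
}

bin_counts <- function(x, bins) {
  vapply(seq_len(nrow(bins)),
         function(i) sum(x >= bins$lo[i] & x <= bins$hi[i]), numeric(1))
}

#' Multiplicity distributions of a target-hit table
#'
#' For each lineage, counts distinct targets per miRNA family and
#' distinct families per target, histograms both over the 11
#' [multiplicity_bins()], and averages the histograms across lineages.
#'
#' @param hits target table from [predict_targets()] (needs `lineage`,
#'   `family`, `transcript`).
#' @return list with matrices `mirna_side` and `target_side` (lineage x
#'   bin counts) and their cross-lineage means `mirna_mean`,
#'   `target_mean`.
#' @export
multiplicity_distribution <- function(hits) {
  bins <- multiplicity_bins()
  lineages <- unique(hits$lineage)
  mside <- matrix(0, length(lineages), nrow(bins),
                  dimnames = list(lineages, bins$label))
  tside <- mside
  for (lin in lineages) {
    h <- hits[hits$lineage == lin, , drop = FALSE]
    per_fam <- tapply(h$transcript, h$family,
                      function(x) length(unique(x)))
    per_tx <- tapply(h$family, h$transcript,
                     function(x) length(unique(x)))
    mside[lin, ] <- bin_counts(as.numeric(per_fam), bins)
    tside[lin, ] <- bin_counts(as.numeric(per_tx), bins)
  }
  list(mirna_side = mside, target_side = tside,
       mirna_mean = colMeans(mside), target_mean = colMeans(tside))
}

#' Mine conserved miRNA teams
#'
#' A team occurrence is two (or more) miRNA families predicted to target
#' the same transcript in the same lineage. In the default `"pairs"`
#' mode every unordered family pair co-targeting a transcript counts,
#' and a pair's support is the number of lineages with at least one
#' co-targeted transcript. `"exact"` mode instead counts complete family
#' sets (the exact set of families on a transcript), which misses
#' near-exact teams by design — a stringent variant useful to audit the
#' pair-mode results.
#'
#' @param hits target table from [predict_targets()].
#' @param min_support minimum number of supporting lineages (default 1).
#' @param mode `"pairs"` (default) or `"exact"`.
#' @return data.frame sorted by decreasing support then team name. For
#'   `"pairs"`: `family1`, `family2` (lexicographically ordered),
#'   `support`, `lineages` (comma-joined). For `"exact"`: `families`
#'   (comma-joined set), `support`, `lineages`.
#' @export
find_teams <- function(hits, min_support = 1L, mode = c("pairs", "exact")) {
  mode <- match.arg(mode)
  occ <- list()   # team key -> set of lineages
  for (lin in unique(hits$lineage)) {
    h <- hits[hits$lineage == lin, , drop = FALSE]
    fam_by_tx <- tapply(h$family, h$transcript,
                        function(x) sort(unique(x)), simplify = FALSE)
    keys <- character(0)
    for (fams in fam_by_tx) {
      if (length(fams) < 2) next
      if (mode == "pairs") {
        prs <- utils::combn(fams, 2)
        keys <- c(keys, apply(prs, 2, paste, collapse = "\r"))
      } else {
        keys <- c(keys, paste(fams, collapse = "\r"))
      }
    }
    for (k in unique(keys)) occ[[k]] <- c(occ[[k]], lin)
  }
  if (mode == "pairs") {
    empty <- data.frame(family1 = character(0), family2 = character(0),
                        support = integer(0), lineages = character(0),
                        stringsAsFactors = FALSE)
  } else {
    empty <- data.frame(families = character(0), support = integer(0),
                        lineages = character(0), stringsAsFactors = FALSE)
  }
  if (length(occ) == 0) return(empty)
  support <- vapply(occ, function(l) length(unique(l)), integer(1))
  keep <- support >= min_support
  if (!any(keep)) return(empty)
  occ <- occ[keep]; support <- support[keep]
  key <- names(occ)
  lins <- vapply(occ, function(l) paste(sort(unique(l)), collapse = ","),
                 character(1))
  if (mode == "pairs") {
    parts <- strsplit(key, "\r", fixed = TRUE)
    res <- data.frame(family1 = vapply(parts, `[`, character(1), 1L),
                      family2 = vapply(parts, `[`, character(1), 2L),
                      support = unname(support), lineages = unname(lins),
                      stringsAsFactors = FALSE)
    res <- res[order(-res$support, res$family1, res$family2), ,
               drop = FALSE]
  } else {
    res <- data.frame(families = gsub("\r", ",", key, fixed = TRUE),
                      support = unname(support), lineages = unname(lins),
                      stringsAsFactors = FALSE)
    res <- res[order(-res$support, res$families), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
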