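#' Target-scoring scheme
#'
#' Per-position penalties for a miRNA:target duplex, in the tradition of
#' plant target-prediction tools (miRU / psRNATarget family): Watson-Crick
#' pair 0, G:U wobble 0.5, mismatch 1, gap 2, with every penalty doubled
#' in the seed-weighted region, miRNA positions 2-13 counted from the 5'
#' end. The cumulative penalty is the "expectation" of a site; lower is
#' stronger, and sites are kept up to a configurable maximum (default 3).
#'
#' @param wc,gu,mismatch,gap per-position penalties.
#' @param seed_start,seed_end seed-weighted miRNA positions (inclusive).
#' @param seed_multiplier penalty multiplier inside the seed region.
#' @return a named list of weights consumed by [score_duplex()] and
#'   [find_sites()].
#' @export
target_scoring <- function(wc = 0, gu = 0.5, mismatch = 1, gap = 2,
                           seed_start = 2L, seed_end = 13L,
                           seed_multiplier = 2) {
  list(wc = wc, gu = gu, mismatch = mismatch, gap = gap,
       seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
       seed_multiplier = seed_multiplier)
}

#' Score a miRNA:target duplex alignment
#'
#' @param states character vector of per-column duplex states, in
#'   `c("WC", "GU", "MM", "GAP")`.
#' @param positions miRNA position (1-based, 5' to 3') each column is
#'   attributed to; a gap column takes the adjacent miRNA position.
#' @param weights scoring scheme from [target_scoring()].
#' @return the expectation penalty (non-negative scalar).
#' @examples
#' # single mismatch at position 15 vs the same mismatch in the seed
#' score_duplex("MM", 15)
#' score_duplex("MM", 5)
#' @export
score_duplex <- function(states, positions = seq_along(states),
                         weights = target_scoring()) {
  if (length(states) != length(positions)) {
    stop("states and positions must have equal length")
  }
  pen <- c(WC = weights$wc, GU = weights$gu, MM = weights$mismatch,
           GAP = weights$gap)
  if (any(!states %in% names(pen))) stop("unknown duplex state")
  mult <- ifelse(positions >= weights$seed_start &
                 positions <= weights$seed_end, weights$seed_multiplier, 1)
  sum(pen[states] * mult)
}

#' Per-position duplex states of an ungapped site
#'
#' The miRNA binds its target antiparallel: miRNA position 1 (5' end)
#' pairs with the 3'-most base of the site.
#'
#' @param mirna mature miRNA (RNA, 5' to 3').
#' @param site target site subsequence (mRNA sense, 5' to 3'), same
#'   length as `mirna`.
#' @return character vector of states per miRNA position.
#' @export
duplex_states <- function(mirna, site) {
  mirna <- as_rna(mirna); site <- as_rna(site)
  if (nchar(mirna) != nchar(site)) stop("ungapped duplex needs equal lengths")
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t <- rev(strsplit(site, "", fixed = TRUE)[[1]])
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

# Penalty lookup matrix over A/C/G/U/N for miRNA base (row) vs target
# base (column). N never pairs.
penalty_matrix <- function(weights) {
  b <- c("A", "C", "G", "U", "N")
  P <- matrix(weights$mismatch, 5, 5, dimnames = list(b, b))
  P["A", "U"] <- weights$wc; P["U", "A"] <- weights$wc
  P["G", "C"] <- weights$wc; P["C", "G"] <- weights$wc
  P["G", "U"] <- weights$gu; P["U", "G"] <- weights$gu
  P
}

encode_nt <- function(chars) {
  i <- match(chars, c("A", "C", "G", "U"))
  i[is.na(i)] <- 5L
  i
}

# Best expectation per window for all window starts. Returns a data.frame
# (start, width, expectation) with `start` 1-based on the transcript and
# windows of width L (ungapped) and, when max_bulge == 1, L+1 (one target
# bulge) and L-1 (one miRNA bulge). Exhaustive over gap placements.
scan_windows <- function(mirna, transcript, weights, max_bulge = 1L) {
  m <- encode_nt(strsplit(as_rna(mirna), "", fixed = TRUE)[[1]])
  t <- encode_nt(strsplit(as_rna(transcript), "", fixed = TRUE)[[1]])
  L <- length(m); n <- length(t)
  if (n < L) stop("transcript shorter than miRNA")
  P <- penalty_matrix(weights)
  w <- ifelse(seq_len(L) >= weights$seed_start &
              seq_len(L) <= weights$seed_end, weights$seed_multiplier, 1)
  gapw <- weights$gap * w

  out <- list()

  # ungapped windows, width L
  ns <- n - L + 1L
  sc <- numeric(ns)
  for (i in seq_len(L)) {
    sc <- sc + w[i] * P[cbind(m[i], t[seq_len(ns) + (L - i)])]
  }
  out[[1]] <- data.frame(start = seq_len(ns), width = L, expectation = sc)

  if (max_bulge >= 1L) {
    # width L + 1: one unpaired target base (gap in the miRNA row)
    ns2 <- n - L
    if (ns2 >= 1) {
      A <- matrix(0, ns2, L)   # miRNA pos i before the bulge
      B <- matrix(0, ns2, L)   # miRNA pos j at/after the bulge
      for (i in seq_len(L)) {
        A[, i] <- w[i] * P[cbind(m[i], t[seq_len(ns2) + (L + 1L - i)])]
        B[, i] <- w[i] * P[cbind(m[i], t[seq_len(ns2) + (L - i)])]
      }
      SA <- cbind(0, t(apply(A, 1, cumsum)))          # SA[, b] = sum_{i<b}
      SBrev <- t(apply(B[, L:1, drop = FALSE], 1, cumsum))
      SB <- cbind(SBrev[, L:1, drop = FALSE], 0)      # SB[, b] = sum_{j>=b}
      best <- rep(Inf, ns2)
      for (b in seq_len(L + 1L)) {
        gp <- gapw[min(b, L)]
        best <- pmin(best, SA[, b] + gp + SB[, b])
      }
      out[[2]] <- data.frame(start = seq_len(ns2), width = L + 1L,
                             expectation = best)
    }
    # width L - 1: one unpaired miRNA base (gap in the target row)
    ns3 <- n - L + 2L
    CC <- matrix(0, ns3, L)   # miRNA pos i before its bulge
    DD <- matrix(0, ns3, L)   # miRNA pos i after its bulge
    for (i in seq_len(L)) {
      if (i <= L - 1L) {
        CC[, i] <- w[i] * P[cbind(m[i], t0_index(t, seq_len(ns3) + (L - 1L - i)))]
      }
      if (i >= 2L) {
        DD[, i] <- w[i] * P[cbind(m[i], t0_index(t, seq_len(ns3) + (L - i)))]
      }
    }
    SC <- cbind(0, t(apply(CC[, seq_len(max(L - 1L, 1L)), drop = FALSE], 1,
                           cumsum)))                  # SC[, b] = sum_{i<b}
    SDrev <- t(apply(DD[, L:1, drop = FALSE], 1, cumsum))
    SD <- cbind(SDrev[, L:1, drop = FALSE], 0)        # SD[, b] = sum_{i>b}... see below
    best <- rep(Inf, ns3)
    for (b in seq_len(L)) {
      sc_b <- SC[, min(b, ncol(SC))] + gapw[b] +
        (if (b < L) SD[, b + 1L] else 0)
      best <- pmin(best, sc_b)
    }
    out[[3]] <- data.frame(start = seq_len(ns3), width = L - 1L,
                           expectation = best)
  }
  do.call(rbind, out)
}

# Index helper tolerating out-of-range indices (returns N) for the
# shortened-window scan whose last start rows touch the transcript end.
t0_index <- function(t, idx) {
  v <- rep(5L, length(idx))
  ok <- idx >= 1L & idx <= length(t)
  v[ok] <- t[idx[ok]]
  v
}

#' Find candidate target sites of a miRNA on a transcript
#'
#' Scans every window of the miRNA's length L and, by default, L+1 and
#' L-1 (admitting one bulge on either side of the duplex), scores each
#' window exhaustively over gap placements with [score_duplex()]'s
#' scheme, and reports non-overlapping local minima with expectation at
#' most `expectation_max`. Selection is greedy by (expectation, then
#' position); output is ordered by position, then expectation.
#'
#' @param mirna mature miRNA sequence (RNA, 5' to 3').
#' @param transcript transcript sequence (mRNA sense; T or U accepted).
#' @param expectation_max penalty cutoff, inclusive (default 3).
#' @param weights scoring scheme from [target_scoring()].
#' @param max_bulge 0 (ungapped only) or 1 (default).
#' @return data.frame `start`, `end` (1-based inclusive transcript
#'   coordinates), `width`, `expectation`.
#' @export
find_sites <- function(mirna, transcript, expectation_max = 3,
                       weights = target_scoring(), max_bulge = 1L) {
  cand <- scan_windows(mirna, transcript, weights, max_bulge = max_bulge)
  cand <- cand[cand$expectation <= expectation_max + 1e-9, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      width = integer(0), expectation = numeric(0))
  if (nrow(cand) == 0) return(empty)
  # clip L-1 windows whose end would exceed the transcript
  n <- nchar(transcript)
  cand <- cand[cand$start + cand$width - 1L <= n, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$expectation, cand$start, cand$width), ,
               drop = FALSE]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + cand$width[i] - 1L)
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  res <- cand[keep, , drop = FALSE]
  res$end <- res$start + res$width - 1L
  res <- res[order(res$start, res$expectation), c("start", "end", "width",
                                                  "expectation")]
  rownames(res) <- NULL
  res
}

#' Target-site accessibility (UPE)
#'
#' Energy needed to open the target site: the difference between the
#' minimum folding energy of the site's context window with the site
#' constrained unpaired and the unconstrained minimum. The context window
#' is the site plus 25 nt on each side, clipped to the transcript.
#' Non-negative by construction; units follow the folding engine
#' (kcal/mol for `"thermo"`, base pairs for the bundled `"fallback"`).
#'
#' @param transcript transcript sequence.
#' @param site_start,site_end site coordinates, 1-based inclusive.
#' @param engine folding engine, see [fold()].
#' @param context_flank context on each side of the site (default 25 nt).
#' @return UPE value (>= 0).
#' @export
compute_upe <- function(transcript, site_start, site_end,
                        engine = c("fallback", "thermo"),
                        context_flank = 25L) {
  engine <- match.arg(engine)
  transcript <- as_rna(transcript)
  n <- nchar(transcript)
  stopifnot(site_start >= 1, site_end <= n, site_start <= site_end)
  w0 <- max(1L, site_start - as.integer(context_flank))
  w1 <- min(n, site_end + as.integer(context_flank))
  sub <- substr(transcript, w0, w1)
  blocked <- (site_start:site_end) - w0 + 1L
  free <- fold(sub, engine = engine)
  open <- fold(sub, engine = engine, blocked = blocked)
  max(0, open$mfe - free$mfe)
}

#' Predict targets of a panel of miRNA families across lineages
#'
#' All-vs-all site search of each family's mature miRNA against each
#' lineage's coding sequences, with the expectation cutoff and (when
#' enabled) the accessibility cutoff applied to every site.
#'
#' @param matures named character vector: family -> mature miRNA (RNA).
#' @param cds_by_lineage named list (by lineage) of named character
#'   vectors of CDS sequences.
#' @param mirnomes optional named list of per-lineage family sets; when
#'   given, only families present in a lineage are searched there.
#' @param expectation_max expectation cutoff, inclusive (default 3).
#' @param upe_max accessibility cutoff, inclusive (default 25); used only
#'   when `use_upe` is TRUE.
#' @param use_upe compute and filter on UPE (default TRUE).
#' @param engine folding engine for UPE.
#' @param weights scoring scheme from [target_scoring()].
#' @return data.frame `lineage`, `family`, `transcript`, `start`, `end`
#'   (1-based inclusive), `expectation`, `upe` (NA when `use_upe` is
#'   FALSE). Lineages missing from `cds_by_lineage` are skipped with a
#'   warning.
#' @export
predict_targets <- function(matures, cds_by_lineage, mirnomes = NULL,
                            expectation_max = 3, upe_max = 25,
                            use_upe = TRUE,
                            engine = c("fallback", "thermo"),
                            weights = target_scoring()) {
  engine <- match.arg(engine)
  lineages <- names(cds_by_lineage)
  rows <- list()
  for (lin in lineages) {
    cds <- cds_by_lineage[[lin]]
    if (is.null(cds) || length(cds) == 0) {
      warning("no CDS for lineage ", lin, "; skipped")
      next
    }
    fams <- sort_families(names(matures))
    if (!is.null(mirnomes)) fams <- fams[fams %in% mirnomes[[lin]]]
    for (fam in fams) {
      for (tx in sort(names(cds))) {
        txseq <- cds[[tx]]
        if (nchar(txseq) < nchar(matures[[fam]])) next
        sites <- find_sites(matures[[fam]], txseq,
                            expectation_max = expectation_max,
                            weights = weights)
        if (nrow(sites) == 0) next
        upe <- rep(NA_real_, nrow(sites))
        if (use_upe) {
          for (i in seq_len(nrow(sites))) {
            upe[i] <- compute_upe(txseq, sites$start[i], sites$end[i],
                                  engine = engine)
          }
          ok <- upe <= upe_max + 1e-9
          sites <- sites[ok, , drop = FALSE]
          upe <- upe[ok]
        }
        if (nrow(sites) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lin, family = fam, transcript = tx,
          start = sites$start, end = sites$end,
          expectation = sites$expectation, upe = upe,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lineage = character(0), family = character(0),
                      transcript = character(0), start = integer(0),
                      end = integer(0), expectation = numeric(0),
                      upe = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
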