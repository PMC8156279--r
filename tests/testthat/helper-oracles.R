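# Independent oracles used to cross-check the package implementation.
# These deliberately use naive algorithms (per-base loops, exhaustive
# enumeration, textbook DP) and share no code with the functions they
# verify.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, k) {
  if (k == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# --- brute-force Hamming scan -------------------------------------------
# Vectorized per-offset comparison over all window starts; minus strand
# handled by scanning for the reverse complement.
oracle_scan <- function(genome_str, seq_id, refs, max_mm, lineage = "lineage") {
  gch <- strsplit(genome_str, "", fixed = TRUE)[[1]]
  n <- length(gch)
  rows <- list()
  for (r in seq_len(nrow(refs))) {
    ref_rna <- refs$sequence[r]
    L <- nchar(ref_rna)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") as_dna(ref_rna) else revcomp_dna(as_dna(ref_rna))
      pch <- strsplit(pat, "", fixed = TRUE)[[1]]
      mm <- integer(length(starts))
      for (j in seq_len(L)) {
        mm <- mm + (gch[starts + j - 1L] != pch[j])
      }
      hit <- which(mm <= max_mm)
      for (s in hit) {
        win <- substr(genome_str, s, s + L - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lineage, seq_id = seq_id, strand = strand,
          start = s - 1L, end = s + L - 1L, mismatches = mm[s],
          ref_id = refs$id[r], family = refs$family[r],
          mature_genomic_seq = if (strand == "+") as_rna(win) else
            revcomp_rna(as_rna(win)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lineage = character(0), seq_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      ref_id = character(0), family = character(0),
                      mature_genomic_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$seq_id, out$start, out$strand, out$ref_id), , drop = FALSE]
}

# --- naive duplex window scoring ----------------------------------------
# Enumerates every window of width L and L +/- 1 and every single-gap
# placement with plain character vectors, scoring through the public
# score_duplex() on explicit state/position columns.
oracle_window_scores <- function(mirna, transcript,
                                 weights = target_scoring()) {
  mirna <- as_rna(mirna)
  tr <- as_rna(transcript)
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  L <- length(m)
  n <- nchar(tr)
  state1 <- function(mc, tc) {
    if ((mc == "A" && tc == "U") || (mc == "U" && tc == "A") ||
        (mc == "G" && tc == "C") || (mc == "C" && tc == "G")) "WC"
    else if ((mc == "G" && tc == "U") || (mc == "U" && tc == "G")) "GU"
    else "MM"
  }
  rows <- list()
  for (w in c(L, L + 1L, L - 1L)) {
    if (w < 1) next
    for (s in seq_len(max(0, n - w + 1L))) {
      rch <- rev(strsplit(substr(tr, s, s + w - 1L), "", fixed = TRUE)[[1]])
      best <- Inf
      if (w == L) {
        st <- mapply(state1, m, rch)
        best <- score_duplex(st, seq_len(L), weights)
      } else if (w == L + 1L) {
        for (b in seq_len(L + 1L)) {
          st <- character(0); po <- integer(0)
          for (k in seq_len(L + 1L)) {
            if (k < b) { st <- c(st, state1(m[k], rch[k])); po <- c(po, k) }
            else if (k == b) { st <- c(st, "GAP"); po <- c(po, min(b, L)) }
            else { st <- c(st, state1(m[k - 1L], rch[k])); po <- c(po, k - 1L) }
          }
          best <- min(best, score_duplex(st, po, weights))
        }
      } else {
        for (b in seq_len(L)) {
          st <- character(0); po <- integer(0)
          for (i in seq_len(L)) {
            if (i < b) { st <- c(st, state1(m[i], rch[i])); po <- c(po, i) }
            else if (i == b) { st <- c(st, "GAP"); po <- c(po, b) }
            else { st <- c(st, state1(m[i], rch[i - 1L])); po <- c(po, i) }
          }
          best <- min(best, score_duplex(st, po, weights))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(start = s, width = w,
                                              expectation = best)
    }
  }
  do.call(rbind, rows)
}

# Same greedy non-overlap selection as documented for find_sites, applied
# to oracle scores.
oracle_find_sites <- function(mirna, transcript, expectation_max = 3,
                              weights = target_scoring()) {
  cand <- oracle_window_scores(mirna, transcript, weights)
  cand <- cand[cand$expectation <= expectation_max + 1e-9, , drop = FALSE]
  n <- nchar(transcript)
  cand <- cand[cand$start + cand$width - 1L <= n, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      width = integer(0), expectation = numeric(0)))
  }
  cand <- cand[order(cand$expectation, cand$start, cand$width), ,
               drop = FALSE]
  taken <- logical(n); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + cand$width[i] - 1L)
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  res <- cand[keep, , drop = FALSE]
  res$end <- res$start + res$width - 1L
  res <- res[order(res$start, res$expectation),
             c("start", "end", "width", "expectation")]
  rownames(res) <- NULL
  res
}

# --- per-base repeat mask -----------------------------------------------
oracle_masked_fraction <- function(interval, repeats) {
  covered <- logical(interval[2] - interval[1])
  if (nrow(repeats) > 0) {
    for (r in seq_len(nrow(repeats))) {
      for (p in seq(repeats$start[r], repeats$end[r] - 1L)) {
        idx <- p - interval[1] + 1L
        if (idx >= 1 && idx <= length(covered)) covered[idx] <- TRUE
      }
    }
  }
  mean(covered)
}

# --- LCS-based global identity and greedy clustering --------------------
oracle_identity <- function(a, b) {
  a <- as_dna(a); b <- as_dna(b)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- integer(length(y) + 1L)
  for (i in seq_along(x)) {
    cur <- integer(length(y) + 1L)
    for (j in seq_along(y)) {
      cur[j + 1L] <- max(prev[j + 1L], cur[j],
                         prev[j] + (x[i] == y[j]))
    }
    prev <- cur
  }
  M <- prev[length(y) + 1L]
  M / (length(x) + length(y) - M)
}

oracle_cluster <- function(seqs, identity = 0.90) {
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (oracle_identity(seqs[[id]],
                          seqs[[clusters[[k]]$representative]]) >= identity) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <-
        list(representative = id, members = id)
  }
  clusters
}

# --- brute-force team enumeration ---------------------------------------
oracle_teams <- function(hits) {
  sup <- list()
  for (lin in unique(hits$lineage)) {
    h <- hits[hits$lineage == lin, ]
    pairs_here <- character(0)
    for (tx in unique(h$transcript)) {
      fams <- sort(unique(h$family[h$transcript == tx]))
      if (length(fams) < 2) next
      for (i in seq_len(length(fams) - 1L)) {
        for (j in seq(i + 1L, length(fams))) {
          pairs_here <- c(pairs_here, paste(fams[i], fams[j], sep = "|"))
        }
      }
    }
    for (p in unique(pairs_here)) sup[[p]] <- c(sup[[p]], lin)
  }
  if (length(sup) == 0) {
    return(data.frame(family1 = character(0), family2 = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(sup), "|", fixed = TRUE)
  out <- data.frame(family1 = vapply(parts, `[`, character(1), 1L),
                    family2 = vapply(parts, `[`, character(1), 2L),
                    support = vapply(sup, length, integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$family1, out$family2), ]
  rownames(out) <- NULL
  out
}

# --- shared synthetic panel (built once per test run) -------------------
panel_env <- new.env(parent = emptyenv())
shared_panel <- function() {
  if (is.null(panel_env$panel)) {
    panel_env$panel <- generate_panel(default_panel_config(101L))
  }
  panel_env$panel
}
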