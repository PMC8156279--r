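# Synthetic lineage panels with planted ground truth.
#
# The generator emulates, at desk scale, the inputs of a pan-genome miRNA
# survey: one genome per lineage with hairpin-forming miRNA loci planted
# according to a configured presence matrix, repeat tracts, and coding
# sequences carrying complementary target sites of controlled penalty.
# Everything is drawn from one seeded RNG stream and verified by
# construction: hairpins must pass the screen, and each lineage's planted
# loci and target sites must be recovered exactly by the pipeline before
# the panel is emitted (backgrounds are redrawn on collision, within a
# retry budget).

random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_dna <- function(n, gc = 0.5) as_dna(random_rna(n, gc))

# A base that can neither Watson-Crick pair nor wobble with `m`.
nonpairing_base <- function(m) {
  comp <- chartr("ACGU", "UGCA", m)
  wob <- switch(m, G = "U", U = "G", "")
  setdiff(c("A", "C", "G", "U"), c(comp, wob))[1]
}

#' Design a screen-passing precursor hairpin
#'
#' Builds a precursor as `pad + mature + loop + revcomp(mature) +
#' revcomp(pad)`: a perfect stem carrying the mature on its 5' arm, a
#' terminal loop, and a pad helix below the duplex. The construction is
#' folded with the bundled engine and screened with [evaluate_hairpin()]
#' before being returned; a construction that does not pass (possible for
#' pathological matures, or deliberately through `corrupt_star_at`) is
#' refused with an error naming the failing criterion.
#'
#' @param mature mature miRNA (RNA, 18-24 nt).
#' @param loop_len terminal loop length (default 6 nt, unpaired A's).
#' @param pad_helix length of the closing helix below the duplex
#'   (default 10 bp).
#' @param pad_seq optional explicit pad sequence (otherwise drawn from
#'   the current RNG stream).
#' @param star_wobbles number of star positions converted from
#'   Watson-Crick to G:U wobble pairing (default 4, fewer when the
#'   mature has fewer interior G/U bases). Wobbles keep the star fully
#'   paired but move its sequence away from the mature's exact reverse
#'   complement, so the star arm of a planted locus is not itself
#'   re-detected as a minus-strand mature hit by the homology scan.
#' @param corrupt_star_at mature positions whose star-side partner is
#'   mutated so it cannot pair — a stress mode used to exercise the
#'   refusal path.
#' @return list with `precursor` (RNA), `mature_offset` (0-based),
#'   `structure` and `screen`.
#' @export
design_hairpin <- function(mature, loop_len = 6L, pad_helix = 10L,
                           pad_seq = NULL, star_wobbles = 4L,
                           corrupt_star_at = integer(0)) {
  mature <- as_rna(mature)
  L <- nchar(mature)
  if (L < 18 || L > 24) stop("mature length must be 18-24 nt")
  if (grepl("[^ACGU]", mature)) stop("mature must be unambiguous RNA")
  pad <- if (is.null(pad_seq)) random_rna(pad_helix) else as_rna(pad_seq)
  star <- strsplit(revcomp_rna(mature), "", fixed = TRUE)[[1]]
  mch <- strsplit(mature, "", fixed = TRUE)[[1]]
  if (star_wobbles > 0) {
    eligible <- setdiff(which(mch %in% c("G", "U")), c(1L, 2L, L - 1L, L))
    take <- eligible[unique(round(seq(1, length(eligible),
                                      length.out = min(star_wobbles,
                                                       length(eligible)))))]
    for (i in take) {
      star[L - i + 1L] <- if (mch[i] == "G") "U" else "G"
    }
  }
  if (length(corrupt_star_at) > 0) {
    for (i in corrupt_star_at) {
      star[L - i + 1L] <- nonpairing_base(mch[i])
    }
  }
  precursor <- paste0(pad, mature, strrep("A", loop_len),
                      paste(star, collapse = ""), revcomp_rna(pad))
  cand <- list(precursor_seq = precursor,
               mature_offset = nchar(pad), mature_length = L)
  struct <- fold(precursor, engine = "fallback")
  screen <- evaluate_hairpin(cand, struct)
  if (!screen$passed) {
    crit <- c(dicer_ends_paired = screen$dicer_ends_paired,
              no_multibranch = screen$no_multibranch,
              mature_not_in_head = screen$mature_not_in_head,
              mature_mismatches_ok = screen$mature_mismatches <= 4,
              star_mismatches_ok = screen$star_mismatches <= 6)
    stop("designed hairpin fails screen: ",
         paste(names(crit)[!crit], collapse = ", "))
  }
  list(precursor = precursor, mature_offset = nchar(pad),
       structure = struct, screen = screen)
}

#' Default synthetic panel configuration
#'
#' Six lineages and ten miRNA families whose planted lineage counts span
#' all four conservation groups (for a 6-lineage panel the scaled group
#' boundaries are rare <= 1, moderately conserved 2-4, highly conserved
#' 5, common 6). Two miRNA teams are planted in every lineage
#' (miR156+miR529 and miR397+miR164, all four families common), one
#' family's precursors sit inside repeat tracts (miR394), one rare family
#' has no target anywhere (miR2873), and two families carry decoy sites
#' engineered to a penalty of 3.5, above the reporting cutoff. Family
#' names are real plant miRNA family names; mature sequences are
#' synthetic, drawn from the seeded RNG.
#'
#' @param seed integer seed; fully determines every byte of the panel.
#' @return configuration list for [generate_panel()].
#' @export
default_panel_config <- function(seed = 101L) {
  list(
    seed = as.integer(seed),
    lineage_names = c("Bd21", "Bd1-1", "ABR2", "Arn1", "Mon3", "Koz1"),
    genome_length = 12000L,
    gc = 0.45,
    flank = 100L,
    max_mismatch = 1L,
    loop_len = 6L,
    pad_helix = 10L,
    mature_length = 21L,
    families = data.frame(
      name = c("miR156", "miR529", "miR397", "miR164", "miR394",
               "miR845", "miR398", "miR5068", "miR5161", "miR2873"),
      count = c(6L, 6L, 6L, 6L, 5L, 5L, 4L, 3L, 1L, 1L),
      stringsAsFactors = FALSE),
    repetitive_family = "miR394",
    partial_repeat_family = "miR156",
    no_target_family = "miR2873",
    teams = list(c("miR156", "miR529"), c("miR397", "miR164")),
    decoys = data.frame(family = c("miR398", "miR5068"), penalty = 3.5,
                        stringsAsFactors = FALSE),
    cds_length = 300L,
    site_offset = 150L,
    lineage_cds_mutations = 3L,
    retry = 50L
  )
}

# Draw one mature per family such that (a) all pairwise Hamming distances
# are large so references never cross-hit planted loci, (b) the non-seed
# tail has a G/U position available for a wobble decoy mutation, and
# (c) enough interior G/U positions exist for the star-wobble design.
draw_matures <- function(cfg) {
  L <- cfg$mature_length
  fams <- cfg$families$name
  matures <- character(0)
  for (f in fams) {
    for (try in seq_len(cfg$retry)) {
      m <- random_rna(L, gc = 0.5)
      ch <- strsplit(m, "", fixed = TRUE)[[1]]
      tail_gu <- any(ch[16:(L - 1)] %in% c("G", "U"))
      interior_gu <- sum(ch[3:(L - 2)] %in% c("G", "U")) >= 4
      far <- all(vapply(matures, str_hamming, integer(1), a = m) >= 6)
      if (tail_gu && interior_gu && far) break
      m <- NULL
    }
    if (is.null(m)) stop("could not draw a usable mature for ", f)
    matures[f] <- m
  }
  matures
}

# Target site with an exact, hand-computable penalty: start from the
# perfect complement and corrupt specific miRNA positions. `plan` is a
# data.frame with columns pos (miRNA position) and kind ("MM" or "GU").
corrupted_site <- function(mature, plan, weights = target_scoring()) {
  L <- nchar(mature)
  mch <- strsplit(mature, "", fixed = TRUE)[[1]]
  site <- strsplit(revcomp_rna(mature), "", fixed = TRUE)[[1]]
  # site index pairing miRNA position i is L - i + 1
  for (r in seq_len(nrow(plan))) {
    i <- plan$pos[r]
    j <- L - i + 1L
    if (plan$kind[r] == "MM") {
      site[j] <- nonpairing_base(mch[i])
    } else {                                  # GU wobble
      if (!mch[i] %in% c("G", "U")) stop("GU corruption needs G or U")
      site[j] <- if (mch[i] == "G") "U" else "G"
    }
  }
  site <- paste(site, collapse = "")
  states <- duplex_states(mature, site)
  list(site = site, penalty = score_duplex(states, weights = weights))
}

#' Generate a synthetic lineage panel with planted truth
#'
#' Draws mature sequences, designs screen-passing hairpins, plants them
#' in per-lineage random genomes per the configured presence matrix
#' (alternating strands), lays down repeat tracts, and builds per-lineage
#' CDS sets with planted target sites, team transcripts and decoys. Each
#' lineage is verified by running the actual discovery and target
#' pipeline against the planted truth; backgrounds are redrawn on any
#' mismatch, and generation fails loudly if the retry budget is
#' exhausted. The same configuration therefore always yields the same,
#' provably recoverable panel.
#'
#' @param cfg configuration from [default_panel_config()].
#' @return object of class `mirna_panel`: list with `config`, `refs`
#'   (reference miRNA table), `matures`, `hairpins`, `genomes`,
#'   `repeats`, `cds`, and `truth` (presence matrix, loci, repetitive
#'   flags, targets, decoys, teams).
#' @export
generate_panel <- function(cfg = default_panel_config()) {
  set.seed(cfg$seed)
  lineages <- cfg$lineage_names
  n_lin <- length(lineages)
  fams <- cfg$families$name
  weights <- target_scoring()

  matures <- draw_matures(cfg)
  refs <- reference_mirnas(stats::setNames(
    matures, paste0("bdi-", fams, "a-5p")))

  hairpins <- lapply(matures, design_hairpin, loop_len = cfg$loop_len,
                     pad_helix = cfg$pad_helix)

  # presence matrix: team families span all lineages by construction;
  # other families get a random draw of the configured size
  present <- matrix(FALSE, length(fams), n_lin,
                    dimnames = list(fams, lineages))
  for (k in seq_along(fams)) {
    cnt <- cfg$families$count[k]
    present[k, sample(lineages, cnt)] <- TRUE
  }
  for (tm in cfg$teams) {
    if (!all(rowSums(present[tm, , drop = FALSE]) == n_lin)) {
      stop("team families must be configured present in all lineages")
    }
  }

  pre_len <- 2L * cfg$pad_helix + 2L * cfg$mature_length + cfg$loop_len
  flank <- cfg$flank

  genomes <- list(); repeats <- list(); loci_rows <- list()
  for (lin in lineages) {
    fams_here <- fams[present[, lin]]
    ok <- FALSE
    for (try in seq_len(cfg$retry)) {
      g <- random_dna(cfg$genome_length, cfg$gc)
      rep_rows <- list(); lrows <- list()
      for (k in seq_along(fams_here)) {
        f <- fams_here[k]
        ki <- match(f, fams)
        pos <- 400L + (ki - 1L) * 1000L            # 0-based precursor start
        strand <- if (ki %% 2L == 1L) "+" else "-"
        pre_dna <- as_dna(hairpins[[f]]$precursor)
        if (strand == "-") pre_dna <- revcomp_dna(pre_dna)
        substr(g, pos + 1L, pos + pre_len) <- pre_dna
        if (strand == "+") {
          mat0 <- pos + cfg$pad_helix
        } else {
          mat0 <- pos + pre_len - cfg$pad_helix - cfg$mature_length
        }
        mat1 <- mat0 + cfg$mature_length
        lrows[[k]] <- data.frame(
          lineage = lin, family = f, seq_id = "chr1", strand = strand,
          pre_start = pos, pre_end = pos + pre_len,
          mat_start = mat0, mat_end = mat1,
          repetitive = identical(f, cfg$repetitive_family),
          stringsAsFactors = FALSE)
        # repeat truth: full coverage of the discovered window for the
        # repetitive family; ~30% partial coverage for one control family
        if (identical(f, cfg$repetitive_family)) {
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            seq_id = "chr1", start = mat0 - flank, end = mat1 + flank,
            stringsAsFactors = FALSE)
        }
        if (identical(f, cfg$partial_repeat_family)) {
          win0 <- mat0 - flank
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            seq_id = "chr1", start = win0, end = win0 + 66L,
            stringsAsFactors = FALSE)
        }
      }
      # background repeat tract away from any planted locus
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        seq_id = "chr1", start = 60L, end = 220L, stringsAsFactors = FALSE)
      ltab <- do.call(rbind, lrows)
      disc <- discover_mirnome(c(chr1 = g), refs, lineage = lin,
                               max_mismatch = cfg$max_mismatch,
                               flank_up = flank, flank_down = flank)
      if (planted_loci_recovered(disc, ltab)) {
        genomes[[lin]] <- c(chr1 = g)
        repeats[[lin]] <- do.call(rbind, rep_rows)
        loci_rows[[lin]] <- ltab
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not generate a clean genome for lineage ", lin)
  }
  truth_loci <- do.call(rbind, loci_rows)
  rownames(truth_loci) <- NULL

  # ---- coding sequences with planted sites ------------------------------
  target_fams <- setdiff(fams, cfg$no_target_family)
  decoy_fams <- cfg$decoys$family
  ok <- FALSE
  for (try in seq_len(cfg$retry)) {
    backbones <- list()
    site_at <- list()   # gene -> data.frame(family, offset0, site, penalty)
    for (f in target_fams) {
      gene <- paste0("g_", f)
      backbones[[gene]] <- random_dna(cfg$cds_length, 0.5)
      site_at[[gene]] <- data.frame(
        family = f, offset0 = cfg$site_offset,
        site = as_dna(revcomp_rna(matures[[f]])), penalty = 0,
        stringsAsFactors = FALSE)
    }
    for (ti in seq_along(cfg$teams)) {
      tm <- cfg$teams[[ti]]
      gene <- paste0("team", ti)
      backbones[[gene]] <- random_dna(cfg$cds_length, 0.5)
      site_at[[gene]] <- data.frame(
        family = tm, offset0 = c(60L, 200L),
        site = as_dna(revcomp_rna(unname(matures[tm]))), penalty = 0,
        stringsAsFactors = FALSE)
    }
    decoy_truth <- list()
    for (f in decoy_fams) {
      gene <- paste0("decoy_", f)
      backbones[[gene]] <- random_dna(cfg$cds_length, 0.5)
      L <- cfg$mature_length
      gu_pos <- which(strsplit(matures[[f]], "", fixed = TRUE)[[1]] %in%
                        c("G", "U"))
      gu_pos <- setdiff(gu_pos[gu_pos >= 16 & gu_pos <= L - 1L], 15L)[1]
      corr <- corrupted_site(matures[[f]], data.frame(
        pos = c(5L, 15L, gu_pos), kind = c("MM", "MM", "GU"),
        stringsAsFactors = FALSE))
      target_penalty <- cfg$decoys$penalty[match(f, decoy_fams)]
      if (abs(corr$penalty - target_penalty) > 1e-9) {
        stop("decoy corruption produced penalty ", corr$penalty,
             " instead of ", target_penalty)
      }
      site_at[[gene]] <- data.frame(
        family = f, offset0 = cfg$site_offset, site = as_dna(corr$site),
        penalty = corr$penalty, stringsAsFactors = FALSE)
      decoy_truth[[f]] <- data.frame(family = f, gene = gene,
                                     penalty = corr$penalty,
                                     stringsAsFactors = FALSE)
    }

    cds <- list(); target_rows <- list(); decoy_rows <- list()
    for (lin in lineages) {
      fams_here <- fams[present[, lin]]
      seqs <- character(0)
      for (gene in names(backbones)) {
        needed <- site_at[[gene]]$family
        if (!all(needed %in% fams_here)) next
        s <- backbones[[gene]]
        site_cols <- unlist(lapply(seq_len(nrow(site_at[[gene]])),
          function(r) {
            o <- site_at[[gene]]$offset0[r]
            (o + 1L):(o + nchar(site_at[[gene]]$site[r]))
          }))
        # per-lineage neutral substitutions outside planted sites
        mpos <- sample(setdiff(seq_len(nchar(s)), site_cols),
                       cfg$lineage_cds_mutations)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in mpos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }
        s <- paste(ch, collapse = "")
        for (r in seq_len(nrow(site_at[[gene]]))) {
          o <- site_at[[gene]]$offset0[r]
          w <- nchar(site_at[[gene]]$site[r])
          substr(s, o + 1L, o + w) <- site_at[[gene]]$site[r]
        }
        tx <- paste0(lin, "_", gene)
        seqs[tx] <- s
        for (r in seq_len(nrow(site_at[[gene]]))) {
          o <- site_at[[gene]]$offset0[r]
          w <- nchar(site_at[[gene]]$site[r])
          row <- data.frame(lineage = lin,
                            family = site_at[[gene]]$family[r],
                            transcript = tx, start = o + 1L, end = o + w,
                            penalty = site_at[[gene]]$penalty[r],
                            stringsAsFactors = FALSE)
          if (gene %in% paste0("decoy_", decoy_fams)) {
            decoy_rows[[length(decoy_rows) + 1L]] <- row
          } else {
            target_rows[[length(target_rows) + 1L]] <- row
          }
        }
      }
      cds[[lin]] <- seqs
    }
    truth_targets <- do.call(rbind, target_rows)
    truth_decoys <- do.call(rbind, decoy_rows)

    mirnomes <- lapply(stats::setNames(lineages, lineages),
                       function(l) fams[present[, l]])
    hits <- predict_targets(matures, cds, mirnomes = mirnomes,
                            expectation_max = 3, upe_max = 25,
                            use_upe = TRUE, engine = "fallback",
                            weights = weights)
    if (planted_targets_recovered(hits, truth_targets)) {
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("could not generate clean coding sequences for the panel")

  teams_truth <- do.call(rbind, lapply(cfg$teams, function(tm) {
    tm <- sort(tm)
    data.frame(family1 = tm[1], family2 = tm[2], support = n_lin,
               lineages = paste(sort(lineages), collapse = ","),
               stringsAsFactors = FALSE)
  }))

  truth <- list(
    presence = present,
    groups = stats::setNames(
      as.character(classify_conservation(rowSums(present),
                                         n_lineages = n_lin)), fams),
    loci = truth_loci,
    repetitive_families = stats::setNames(
      fams %in% cfg$repetitive_family, fams),
    targets = truth_targets,
    decoys = truth_decoys,
    teams = teams_truth)

  panel <- list(config = cfg, refs = refs, matures = matures,
                hairpins = hairpins, genomes = genomes, repeats = repeats,
                cds = cds, truth = truth, engine = "fallback")
  class(panel) <- "mirna_panel"
  panel
}

# Exact recovery check: same families, and every planted mature interval
# found with matching strand, with no extra loci.
planted_loci_recovered <- function(disc, truth) {
  if (nrow(disc) != nrow(truth)) return(FALSE)
  key <- function(df) sort(paste(df$family, df$seq_id, df$strand,
                                 df$mat_start, df$mat_end))
  identical(key(disc), key(truth))
}

planted_targets_recovered <- function(hits, truth) {
  key <- function(df) sort(paste(df$lineage, df$family, df$transcript,
                                 df$start, df$end))
  if (nrow(hits) != nrow(truth)) return(FALSE)
  if (!identical(key(hits), key(truth))) return(FALSE)
  m <- merge(hits, truth,
             by = c("lineage", "family", "transcript", "start", "end"))
  all(abs(m$expectation - m$penalty) < 1e-9)
}

#' @export
print.mirna_panel <- function(x, ...) {
  cat("Synthetic lineage panel:", length(x$genomes), "lineages,",
      nrow(x$config$families), "families (seed ", x$config$seed, ")\n")
  cat("Planted loci:", nrow(x$truth$loci),
      "| planted target sites:", nrow(x$truth$targets), "\n")
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Emits the reference matures FASTA, per-lineage genome FASTA, CDS
#' FASTA and repeat BED files, plus a machine-readable `truth.json`.
#'
#' @param panel a `mirna_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("genomes", "cds", "repeats")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  refs_ss <- Biostrings::RNAStringSet(
    stats::setNames(panel$refs$sequence, panel$refs$id))
  Biostrings::writeXStringSet(refs_ss, file.path(dir, "mature_refs.fa"))
  for (lin in names(panel$genomes)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lin)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(panel$genomes[[lin]]),
      file.path(dir, "genomes", paste0(safe, ".fa")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(panel$cds[[lin]]),
      file.path(dir, "cds", paste0(safe, ".fa")))
    bed <- panel$repeats[[lin]]
    utils::write.table(bed, file.path(dir, "repeats", paste0(safe, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  truth <- panel$truth
  truth$presence <- cbind(
    data.frame(family = rownames(truth$presence), stringsAsFactors = FALSE),
    as.data.frame(truth$presence, row.names = NULL))
  # named atomic vectors serialize as bare arrays; keep the names
  truth$groups <- as.list(truth$groups)
  truth$repetitive_families <- as.list(truth$repetitive_families)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
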