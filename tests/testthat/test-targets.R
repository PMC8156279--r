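test_that("duplex penalties follow the seed-weighted scheme", {
  expect_equal(score_duplex(rep("WC", 21)), 0)
  expect_equal(score_duplex("MM", 15), 1.0)
  expect_equal(score_duplex("MM", 5), 2.0)
  expect_equal(score_duplex(c("GU", "MM"), c(3, 20)), 2.0)
  expect_equal(score_duplex(c("GAP", "GU"), c(14, 14)), 2.5)
  # additivity and permutation invariance among equal-weight positions
  expect_equal(score_duplex(c("MM", "GU"), c(15, 20)),
               score_duplex("MM", 20) + score_duplex("GU", 15))
})

test_that("ungapped duplex states respect antiparallel pairing", {
  # miRNA 5'-ACGU / site 5'-ACGU: position 1 (A) meets site 3' base (U)
  expect_equal(duplex_states("ACGU", "ACGU"), c("WC", "WC", "WC", "WC"))
  expect_equal(duplex_states("GGGG", "TTTT"), rep("GU", 4))
  expect_equal(duplex_states("AAAA", "AAAA"), rep("MM", 4))
})

test_that("a planted perfect-complement site is reported exactly once", {
  set.seed(50)
  m <- as_rna(random_seq(21))
  tx <- random_seq(400)
  substr(tx, 151, 171) <- as_dna(revcomp_rna(m))
  sites <- find_sites(m, tx)
  perfect <- sites[sites$expectation == 0, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(c(perfect$start, perfect$end), c(151L, 171L))
})

test_that("a site engineered above the cutoff is not reported", {
  set.seed(51)
  m <- paste0("ACGUACGUACGUAC", "GUACGUA")    # fixed mature, G/U rich tail
  tx <- random_seq(300)
  site <- strsplit(revcomp_rna(m), "", fixed = TRUE)[[1]]
  mch <- strsplit(m, "", fixed = TRUE)[[1]]
  L <- nchar(m)
  # seed mismatch (2.0) + tail mismatch (1.0) + tail wobble (0.5) = 3.5
  corrupt <- function(i, kind) {
    j <- L - i + 1L
    site[j] <<- if (kind == "GU") {
      chartr("GU", "UG", mch[i])
    } else {
      setdiff(c("A", "C", "G", "U"),
              c(chartr("ACGU", "UGCA", mch[i]),
                switch(mch[i], G = "U", U = "G", "")))[1]
    }
  }
  corrupt(5L, "MM"); corrupt(15L, "MM"); corrupt(19L, "GU")
  site <- paste(site, collapse = "")
  expect_equal(score_duplex(duplex_states(m, site)), 3.5)
  substr(tx, 101, 121) <- as_dna(site)
  sites <- find_sites(m, tx, expectation_max = 3.0)
  expect_false(any(sites$start <= 121 & sites$end >= 101))
  # at a permissive cutoff the same site is the best reported one
  sites4 <- find_sites(m, tx, expectation_max = 4.0)
  expect_true(any(sites4$start == 101 & sites4$expectation == 3.5))
})

test_that("site search equals exhaustive window scoring", {
  set.seed(52)
  m <- as_rna(random_seq(20))
  tx <- random_seq(250)
  substr(tx, 101, 120) <- as_dna(revcomp_rna(m))
  got_scores <- panmirnome:::scan_windows(m, tx, target_scoring())
  want_scores <- oracle_window_scores(m, tx)
  key <- function(df) df[order(df$width, df$start), ]
  expect_equal(key(got_scores)$expectation, key(want_scores)$expectation)
  # and the selected site lists agree at a permissive cutoff
  got <- find_sites(m, tx, expectation_max = 12)
  want <- oracle_find_sites(m, tx, expectation_max = 12)
  expect_equal(got, want)
})

test_that("lowering the expectation cutoff never adds sites", {
  set.seed(53)
  m <- as_rna(random_seq(21))
  tx <- random_seq(500)
  substr(tx, 201, 221) <- as_dna(revcomp_rna(m))
  loose <- find_sites(m, tx, expectation_max = 10)
  for (cut in c(6, 3, 1, 0)) {
    tight <- find_sites(m, tx, expectation_max = cut)
    expect_true(all(paste(tight$start, tight$end) %in%
                      paste(loose$start, loose$end)))
    expect_lte(nrow(tight), nrow(loose))
  }
})

test_that("accessibility is zero in an unpairable context and positive
           inside a strong hairpin", {
  m <- strrep("U", 21)                       # site = poly-A
  tx <- strrep("A", 100)
  expect_equal(compute_upe(tx, 40, 60), 0)
  # the same site locked inside a designed stem
  site <- strrep("A", 21)
  stem <- strrep("U", 21)
  tx2 <- paste0(strrep("G", 5), stem, site, strrep("C", 5))
  upe <- compute_upe(tx2, 27, 47)
  expect_gt(upe, 0)
})

test_that("the accessibility cutoff is inclusive at the boundary", {
  set.seed(54)
  m <- as_rna(random_seq(21))
  tx <- random_seq(200)
  substr(tx, 91, 111) <- as_dna(revcomp_rna(m))
  upe <- compute_upe(tx, 91, 111)
  cds <- list(L1 = c(t1 = tx))
  at <- predict_targets(c(miR1 = m), cds, upe_max = upe)
  expect_true(any(at$transcript == "t1" & at$start == 91))
  below <- predict_targets(c(miR1 = m), cds, upe_max = upe - 0.5)
  expect_false(any(below$transcript == "t1" & below$start == 91))
})

test_that("panel-wide prediction is deterministic and honors planted truth", {
  panel <- shared_panel()
  mirnomes <- lapply(stats::setNames(colnames(panel$truth$presence),
                                     colnames(panel$truth$presence)),
                     function(l) rownames(panel$truth$presence)[
                       panel$truth$presence[, l]])
  h1 <- predict_targets(panel$matures, panel$cds, mirnomes = mirnomes)
  h2 <- predict_targets(panel$matures, panel$cds, mirnomes = mirnomes)
  expect_identical(h1, h2)
  truth <- panel$truth$targets
  expect_setequal(paste(h1$lineage, h1$family, h1$transcript, h1$start),
                  paste(truth$lineage, truth$family, truth$transcript,
                        truth$start))
  # planted penalties are recovered exactly
  m <- merge(h1, truth, by = c("lineage", "family", "transcript", "start"))
  expect_equal(m$expectation, m$penalty)
  # the no-target family retrieves nothing anywhere
  expect_false(panel$config$no_target_family %in% h1$family)
  # decoys (penalty 3.5) are never reported
  expect_false(any(paste(h1$transcript, h1$family) %in%
                     paste(panel$truth$decoys$transcript,
                           panel$truth$decoys$family)))
})

test_that("lineages without coding sequences are skipped with a warning", {
  expect_warning(
    res <- predict_targets(c(miR1 = strrep("ACG", 7)),
                           list(L1 = character(0))),
    "skipped")
  expect_equal(nrow(res), 0L)
})
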