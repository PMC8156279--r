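test_that("alignment identity matches the LCS-based oracle", {
  set.seed(60)
  expect_equal(alignment_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(alignment_identity("AAAA", "CCCC"), 0)
  for (i in 1:8) {
    a <- random_seq(sample(40:90, 1))
    b <- if (i %% 2 == 0) mutate_seq(a, sample(1:10, 1))
         else random_seq(sample(40:90, 1))
    expect_equal(alignment_identity(a, b), oracle_identity(a, b),
                 tolerance = 1e-9)
  }
})

test_that("identical sequences form one cluster", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  cl <- cluster_transcripts(seqs)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members), c("a", "b", "c"))
  expect_equal(cl[[1]]$representative, "a")
})

test_that("near-identical pairs merge and divergent pairs split at 90%", {
  set.seed(61)
  long <- random_seq(300)
  near <- substr(mutate_seq(long, 3), 1, 290)    # high identity, shorter
  expect_gte(oracle_identity(long, near), 0.90)
  cl <- cluster_transcripts(c(tx_long = long, tx_near = near))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$representative, "tx_long")  # longest member

  far <- mutate_seq(long, 70)
  expect_lt(oracle_identity(long, far), 0.90)
  cl2 <- cluster_transcripts(c(tx_long = long, tx_far = far))
  expect_length(cl2, 2L)
})

test_that("clustering equals the greedy oracle and satisfies the
           member-identity invariant", {
  set.seed(62)
  base <- replicate(5, random_seq(sample(60:90, 1)))
  seqs <- character(0)
  for (i in seq_along(base)) {
    for (j in 1:4) {
      seqs[sprintf("s%02d_%d", i, j)] <-
        mutate_seq(base[i], sample(0:4, 1))
    }
  }
  seqs <- c(seqs, u1 = random_seq(75), u2 = random_seq(85))
  got <- cluster_transcripts(seqs, identity = 0.90)
  want <- oracle_cluster(seqs, identity = 0.90)
  norm <- function(cl) lapply(cl, function(x)
    list(rep = x$representative, members = sort(x$members)))
  expect_equal(norm(got), norm(want))
  for (cl in got) {
    expect_true(cl$representative %in% cl$members)
    for (mem in cl$members) {
      expect_gte(alignment_identity(seqs[[mem]],
                                    seqs[[cl$representative]]), 0.90)
    }
  }
  reps <- cluster_representatives(got, seqs)
  expect_equal(unname(reps[1]),
               seqs[[got[[1]]$representative]])
})

test_that("multiplicity histograms use the declared bins and conserve mass", {
  bins <- multiplicity_bins()
  expect_equal(nrow(bins), 11L)
  expect_equal(bins$lo[1], 1); expect_equal(bins$hi[1], 1)
  expect_equal(bins$label[2], "2-5")
  expect_true(is.infinite(bins$hi[11]))
  # family with 3 targets in each of 2 lineages -> mean 1.0 in bin 2-5
  hits <- data.frame(
    lineage = rep(c("L1", "L2"), each = 3),
    family = "miR1",
    transcript = paste0("t", c(1:3, 1:3)),
    stringsAsFactors = FALSE)
  md <- multiplicity_distribution(hits)
  expect_equal(unname(md$mirna_mean["2-5"]), 1.0)
  expect_equal(sum(md$mirna_mean), 1.0)
  # every target hit by exactly one family -> all target mass in bin 1
  expect_equal(unname(md$target_mean["1"]), 3.0)
  expect_equal(sum(md$target_side["L1", ]), 3)
})

test_that("multiplicity histograms equal a brute-force tally", {
  set.seed(63)
  hits <- data.frame(
    lineage = sample(paste0("L", 1:3), 400, replace = TRUE),
    family = sample(paste0("miR", 1:12), 400, replace = TRUE),
    transcript = sample(paste0("t", 1:40), 400, replace = TRUE),
    stringsAsFactors = FALSE)
  md <- multiplicity_distribution(hits)
  bins <- multiplicity_bins()
  for (lin in unique(hits$lineage)) {
    h <- unique(hits[hits$lineage == lin, ])
    fam_counts <- table(unique(h[c("family", "transcript")])$family)
    for (b in seq_len(nrow(bins))) {
      expect_equal(unname(md$mirna_side[lin, b]),
                   sum(fam_counts >= bins$lo[b] & fam_counts <= bins$hi[b]))
    }
    expect_equal(sum(md$mirna_side[lin, ]), length(fam_counts))
    expect_equal(sum(md$target_side[lin, ]),
                 length(unique(h$transcript)))
  }
})

test_that("team mining matches brute-force pair enumeration", {
  set.seed(64)
  hits <- data.frame(
    lineage = sample(paste0("L", 1:5), 300, replace = TRUE),
    family = sample(paste0("miR", 1:8), 300, replace = TRUE),
    transcript = sample(paste0("t", 1:25), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- find_teams(hits)
  want <- oracle_teams(hits)
  expect_equal(got[c("family1", "family2", "support")], want)
  # support is monotone in min_support and pair mode covers exact mode
  for (ms in 1:5) {
    sub <- find_teams(hits, min_support = ms)
    expect_true(all(sub$support >= ms))
    expect_true(all(paste(sub$family1, sub$family2) %in%
                      paste(got$family1, got$family2)))
  }
  ex <- find_teams(hits, mode = "exact")
  pair_keys <- paste(got$family1, got$family2)
  for (i in seq_len(nrow(ex))) {
    fams <- strsplit(ex$families[i], ",")[[1]]
    prs <- utils::combn(sort(fams), 2)
    expect_true(all(paste(prs[1, ], prs[2, ]) %in% pair_keys))
  }
})

test_that("a pair co-targeting in every lineage reaches full support", {
  lineages <- paste0("L", 1:6)
  hits <- data.frame(
    lineage = rep(lineages, each = 2),
    family = rep(c("miR397", "miR164"), 6),
    transcript = rep("tx_common", 12),
    stringsAsFactors = FALSE)
  teams <- find_teams(hits, min_support = 6)
  expect_equal(nrow(teams), 1L)
  expect_equal(teams$family1, "miR164")
  expect_equal(teams$family2, "miR397")
  expect_equal(teams$support, 6L)
  # no multi-family transcript -> no teams
  solo <- hits; solo$transcript <- paste0(solo$family, "_own")
  expect_equal(nrow(find_teams(solo)), 0L)
})
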