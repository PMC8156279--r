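mk_ref <- function(seq, id = "bdi-miR156a-5p") {
  reference_mirnas(stats::setNames(seq, id))
}

test_that("a planted exact copy is found once at the planted coordinates", {
  set.seed(11)
  ref <- as_rna(random_seq(21))
  g <- random_seq(10000)
  substr(g, 4001, 4021) <- as_dna(ref)
  hits <- find_candidate_hits(c(chr1 = g), mk_ref(ref))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 4000L)
  expect_equal(plus$end, 4021L)
  expect_equal(plus$mismatches, 0L)
  expect_equal(plus$mature_genomic_seq, ref)
})

test_that("a planted reverse complement is found on the minus strand", {
  set.seed(12)
  ref <- as_rna(random_seq(21))
  g <- random_seq(8000)
  substr(g, 2001, 2021) <- revcomp_dna(as_dna(ref))
  hits <- find_candidate_hits(c(chr1 = g), mk_ref(ref))
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, 2000L)
  expect_equal(minus$mature_genomic_seq, ref)
})

test_that("a copy with two substitutions is rejected at max_mismatch 1", {
  set.seed(13)
  ref <- as_rna(random_seq(21))
  g <- random_seq(5000)
  planted <- strsplit(as_dna(ref), "", fixed = TRUE)[[1]]
  for (p in c(5L, 15L)) {
    planted[p] <- setdiff(c("A", "C", "G", "T"), planted[p])[1]
  }
  substr(g, 1001, 1021) <- paste(planted, collapse = "")
  hits <- find_candidate_hits(c(chr1 = g), mk_ref(ref))
  expect_false(any(hits$start == 1000L))
  hits2 <- find_candidate_hits(c(chr1 = g), mk_ref(ref), max_mismatch = 2L)
  expect_true(any(hits2$start == 1000L & hits2$mismatches == 2L))
})

test_that("the scanner matches a brute-force Hamming scan", {
  set.seed(14)
  g <- random_seq(10000)
  refs <- reference_mirnas(stats::setNames(
    replicate(5, as_rna(random_seq(21))),
    paste0("bdi-miR", 1:5, "a-5p")))
  got <- find_candidate_hits(c(chrA = g), refs, max_mismatch = 2L)
  want <- oracle_scan(g, "chrA", refs, max_mm = 2L)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("precursor extraction arithmetic and truncation are exact", {
  set.seed(15)
  g <- random_seq(10000)
  hit <- data.frame(seq_id = "chr1", strand = "+", start = 1000L,
                    end = 1021L, stringsAsFactors = FALSE)
  pc <- extract_precursor(c(chr1 = g), hit, 100L, 100L)
  expect_equal(c(pc$genomic_start, pc$genomic_end), c(900L, 1121L))
  expect_equal(pc$mature_offset, 100L)
  expect_equal(substr(pc$precursor_seq, 101, 121),
               as_rna(substr(g, 1001, 1021)))
  # truncation at the contig start
  hit2 <- data.frame(seq_id = "chr1", strand = "+", start = 30L, end = 51L,
                     stringsAsFactors = FALSE)
  pc2 <- extract_precursor(c(chr1 = g), hit2, 100L, 100L)
  expect_equal(c(pc2$genomic_start, pc2$genomic_end), c(0L, 151L))
  expect_equal(pc2$mature_offset, 30L)
  expect_error(extract_precursor(c(chr1 = g),
    data.frame(seq_id = "chr1", strand = "+", start = 9995L, end = 10016L),
    10L, 10L), "outside")
})

test_that("minus-strand extraction equals the plus-strand case on the
           reverse-complemented contig", {
  set.seed(16)
  g <- random_seq(3000)
  hit_minus <- data.frame(seq_id = "chr1", strand = "-", start = 1000L,
                          end = 1021L, stringsAsFactors = FALSE)
  pc <- extract_precursor(c(chr1 = g), hit_minus, flank_up = 100L,
                          flank_down = 50L)
  expect_equal(c(pc$genomic_start, pc$genomic_end), c(950L, 1121L))
  expect_equal(pc$mature_offset, 100L)
  # oracle: the same locus on the reverse-complemented contig, plus strand
  grc <- revcomp_dna(g)
  hit_plus <- data.frame(seq_id = "chr1", strand = "+",
                         start = 3000L - 1021L, end = 3000L - 1000L,
                         stringsAsFactors = FALSE)
  pc_o <- extract_precursor(c(chr1 = grc), hit_plus, flank_up = 100L,
                            flank_down = 50L)
  expect_equal(pc$precursor_seq, pc_o$precursor_seq)
  expect_equal(pc$mature_offset, pc_o$mature_offset)
})

# hand-built structures isolating each screening criterion
test_that("each hairpin screening criterion is evaluated independently", {
  mk <- function(db) list(dotbracket = db, pair_table = pair_table(db))
  cand <- function(off, len) list(precursor_seq = strrep("N", 99),
                                  mature_offset = off, mature_length = len)

  # clean 15-bp stem, 5-nt loop; mature = stem positions 6..15 on the 5' arm
  db_ok <- paste0(strrep("(", 15), ".....", strrep(")", 15))
  r <- evaluate_hairpin(cand(5L, 10L), mk(db_ok))
  expect_true(r$passed)
  expect_equal(r$mature_mismatches, 0L)
  expect_equal(r$star_mismatches, 0L)
  expect_equal(r$star_span, c(21, 30))

  # criterion 1: 5'-terminal mature base unpaired
  db_dicer <- paste0("(((((.", strrep("(", 9), ".....",
                     strrep(")", 9), ".)))))")
  r <- evaluate_hairpin(cand(5L, 10L), mk(db_dicer))
  expect_false(r$dicer_ends_paired)
  expect_false(r$passed)
  expect_true(r$no_multibranch && r$mature_not_in_head)

  # criterion 2: two helices branch inside the mature's enclosure
  db_multi <- "((((..((((....))))..((((....))))..))))"
  r <- evaluate_hairpin(cand(0L, 4L), mk(db_multi))
  expect_false(r$no_multibranch)
  expect_false(r$passed)
  expect_true(r$dicer_ends_paired && r$mature_not_in_head)

  # criterion 3: mature straddles the terminal loop
  r <- evaluate_hairpin(cand(12L, 10L), mk(db_ok))
  expect_false(r$mature_not_in_head)
  expect_false(r$passed)
  expect_true(r$dicer_ends_paired && r$no_multibranch)

  # criterion 4: five bulged mature positions exceed the mismatch budget
  db_bulge <- "((((((((.....(((....))))))))))"
  # positions:  1-5 pad+2 stem, 8-12 bulged, 13-15 stem, loop, closers
  db_bulge <- paste0("(((((", "((", ".....", "(((", "....",
                     ")))", "))", ")))))")
  r <- evaluate_hairpin(cand(5L, 10L), mk(db_bulge))
  expect_equal(r$mature_mismatches, 5L)
  expect_false(r$passed)
  expect_true(r$dicer_ends_paired && r$no_multibranch &&
                r$mature_not_in_head)
  expect_equal(r$star_mismatches, 0L)

  # fully unpaired mature: no star definable
  db_flat <- paste0("((((", strrep(".", 20), "))))....")
  r <- evaluate_hairpin(cand(6L, 10L), mk(db_flat))
  expect_false(r$passed)
  expect_equal(r$star_mismatches, 10L)
  expect_null(r$star_span)
})

test_that("discovery recovers planted families and deduplicates variants", {
  set.seed(17)
  m <- as_rna(random_seq(21))
  set.seed(18)
  hp <- design_hairpin(m)
  g <- random_seq(4000)
  pre <- as_dna(hp$precursor)
  substr(g, 1001, 1000 + nchar(pre)) <- pre
  # two references of the same family: exact, and a 1-mismatch variant
  m2 <- strsplit(m, "", fixed = TRUE)[[1]]
  m2[10] <- setdiff(c("A", "C", "G", "U"), m2[10])[1]
  refs <- reference_mirnas(c("bdi-miR156a-5p" = m,
                             "osa-miR156b" = paste(m2, collapse = "")))
  loci <- discover_mirnome(c(chr1 = g), refs)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$family, "miR156")
  expect_equal(loci$ref_id, "bdi-miR156a-5p")   # fewest mismatches wins
  expect_equal(loci$mat_start, 1000L + hp$mature_offset)
  expect_true(loci$dicer_ends_paired & loci$no_multibranch &
                loci$mature_not_in_head)
  expect_lte(loci$mature_mismatches, 4L)
  expect_lte(loci$star_mismatches, 6L)
})

test_that("reverse-complementing a contig leaves accepted loci invariant", {
  set.seed(19)
  m <- as_rna(random_seq(21))
  set.seed(20)
  hp <- design_hairpin(m)
  g <- random_seq(3000)
  pre <- as_dna(hp$precursor)
  substr(g, 501, 500 + nchar(pre)) <- pre
  refs <- mk_ref(m)
  fwd <- discover_mirnome(c(chr1 = g), refs)
  rev <- discover_mirnome(c(chr1 = revcomp_dna(g)), refs)
  expect_equal(nrow(fwd), nrow(rev))
  L <- nchar(g)
  expect_setequal(paste(rev$strand, rev$mat_start, rev$mat_end),
                  paste(ifelse(fwd$strand == "+", "-", "+"),
                        L - fwd$mat_end, L - fwd$mat_start))
})

test_that("random background yields no false families", {
  set.seed(21)
  g <- random_seq(100000)
  refs <- reference_mirnas(stats::setNames(
    replicate(5, as_rna(random_seq(21))),
    paste0("bdi-miR", c(156, 319, 396, 529, 827), "a-5p")))
  hits <- find_candidate_hits(c(chr1 = g), refs)
  expect_equal(nrow(hits), 0L)
})
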