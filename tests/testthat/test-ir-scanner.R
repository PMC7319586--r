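test_that("promoter sequences validate alphabet and anchor", {
  expect_error(promoter_sequence("ACGTN"), class = "coopfit_parse_error")
  expect_error(promoter_sequence(""), "non-empty")
  ps <- promoter_sequence("acgt", id = "p1")
  expect_equal(ps$sequence, "ACGT")
  expect_equal(ps$anchor, 5L)
})

test_that("a planted perfect pair is recovered with exact coordinates", {
  pl <- plant_inverted_repeats(
    200, list(list(arm_length = 23, spacer = 13, position = 60)), seed = 11)
  hits <- find_inverted_repeats(pl$sequence, 23, c(0, 20), 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$left_start, pl$truth$left_start)
  expect_equal(hits$right_end, pl$truth$right_end)
  expect_equal(hits$spacer, 13L)
  expect_equal(hits$mismatches, 0L)
  # the right arm is the reverse complement of the left arm
  expect_equal(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(hits$right_arm))),
    hits$left_arm)
})

test_that("poly-C sequences and short sequences yield no hits", {
  polyc <- promoter_sequence(strrep("C", 200))
  expect_equal(nrow(find_inverted_repeats(polyc, 23, c(0, 20), 0)), 0)
  short <- promoter_sequence("ACGTACGT")
  expect_equal(nrow(find_inverted_repeats(short, 23, c(0, 20), 0)), 0)
})

test_that("two planted pairs with a 4 bp inter-pair gap are both recovered", {
  # IR1..IR4 architecture: 23 bp arms, 13 bp spacers, 4 bp between the pairs
  pos1 <- 10
  pos2 <- pos1 + 2 * 23 + 13 + 4
  pl <- plant_inverted_repeats(
    220, list(list(arm_length = 23, spacer = 13, position = pos1),
              list(arm_length = 23, spacer = 13, position = pos2)),
    seed = 5)
  hits <- as.data.frame(find_inverted_repeats(pl$sequence, 23, c(0, 20), 2,
                                              overlap = "all"))
  found <- merge(hits, pl$truth)
  expect_equal(nrow(found), 2)
  found <- found[order(found$left_start), ]
  gap <- found$left_start[2] - found$right_end[1] - 1L
  expect_equal(gap, 4L)
  expect_equal(found$spacer, c(13L, 13L))
})

test_that("planted pairs with mutations are recovered across many seeds", {
  for (i in 1:60) {
    spacer <- if (i %% 2) 3 else 13
    mut <- i %% 3
    pl <- plant_inverted_repeats(
      200, list(list(arm_length = 23, spacer = spacer, position = 50,
                     mutations = mut)), seed = 1000 + i)
    hits <- as.data.frame(find_inverted_repeats(pl$sequence, 23, c(0, 20), 2,
                                                overlap = "all"))
    expect_equal(nrow(merge(hits, pl$truth)), 1)
  }
})

test_that("scanning the reverse complement mirrors the coordinates", {
  for (seed in 1:10) {
    pl <- plant_inverted_repeats(
      150, list(list(arm_length = 23, spacer = 7, position = 40)),
      seed = seed)
    n <- nchar(pl$sequence$sequence)
    rc <- promoter_sequence(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pl$sequence$sequence))))
    fwd <- as.data.frame(find_inverted_repeats(pl$sequence, 23, c(0, 20), 0,
                                               overlap = "all"))
    rev <- as.data.frame(find_inverted_repeats(rc, 23, c(0, 20), 0,
                                               overlap = "all"))
    expect_equal(nrow(fwd), nrow(rev))
    mirrored <- data.frame(left_start = n - rev$right_end + 1L,
                           left_end = n - rev$right_start + 1L,
                           right_start = n - rev$left_end + 1L,
                           right_end = n - rev$left_start + 1L,
                           spacer = rev$spacer,
                           mismatches = rev$mismatches)
    cols <- names(mirrored)
    expect_equal(fwd[order(fwd$left_start), cols],
                 mirrored[order(mirrored$left_start), cols],
                 ignore_attr = TRUE)
  }
})

test_that("identical inputs give identical ordered output", {
  pl <- plant_inverted_repeats(
    300, list(list(arm_length = 23, spacer = 13, position = 100,
                   mutations = 2)), seed = 99)
  h1 <- find_inverted_repeats(pl$sequence, 23, c(0, 20), 4)
  h2 <- find_inverted_repeats(pl$sequence, 23, c(0, 20), 4)
  expect_identical(h1, h2)
})

test_that("promoter-relative coordinates anchor at the start codon", {
  # anchor 132: position 131 is -1, position 1 is -131
  hits <- data.frame(seq_id = "p", left_start = 1L, left_end = 23L,
                     right_start = 109L, right_end = 131L,
                     arm_length = 23L, spacer = 85L, mismatches = 0L)
  class(hits) <- c("ir_hits", "data.frame")
  rel <- to_promoter_coordinates(hits, anchor = 132)
  expect_equal(rel$left_start, -131L)
  expect_equal(rel$right_end, -1L)
  back <- from_promoter_coordinates(rel, anchor = 132)
  expect_equal(as.data.frame(back), as.data.frame(hits))
  expect_error(to_promoter_coordinates(hits, anchor = 100),
               class = "coopfit_range_error")
})

test_that("consensus matrices count bases exactly and flag ties as IUPAC", {
  cm <- consensus_matrix(c("ACGT", "ACGT"))
  expect_equal(cm$consensus, "ACGT")
  expect_true(all(apply(cm$freqs, 2, max) == 1))

  cm2 <- consensus_matrix(c("ACGT", "ACGA"))
  expect_equal(unname(cm2$freqs["T", 4]), 0.5)
  expect_equal(unname(cm2$freqs["A", 4]), 0.5)
  expect_equal(cm2$consensus, "ACGW")

  expect_error(consensus_matrix(c("ACGT", "ACG")), class = "coopfit_input_error")
  expect_error(consensus_matrix("ACGT"), "at least 2")

  # seeded arms: recovered frequencies equal empirical counts exactly
  set.seed(31)
  arms <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = "")
  }, character(1))
  cm3 <- consensus_matrix(arms)
  chars <- do.call(rbind, strsplit(arms, ""))
  for (p in c(1, 12, 23)) {
    counts <- table(factor(chars[, p], levels = c("A", "C", "G", "T")))
    expect_equal(unname(cm3$freqs[, p]), as.numeric(counts) / 6)
  }
  expect_equal(colSums(cm3$freqs), rep(1, 23), ignore_attr = TRUE)
})

test_that("arm scoring against a consensus matrix is exact", {
  cm <- consensus_matrix(c("AAAA", "AAAA"))
  expect_equal(score_arm_against_consensus("AAAA", cm), 0)
  cm2 <- consensus_matrix(c("AAAA", "CAAA"))
  expect_equal(score_arm_against_consensus("AAAA", cm2), 0.5)
  # uniform matrix: every arm scores 0.75 * L exactly
  uniform <- consensus_matrix(c("ACGT", "CGTA", "GTAC", "TACG"))
  expect_true(all(uniform$freqs == 0.25))
  set.seed(8)
  for (i in 1:5) {
    arm <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    expect_equal(score_arm_against_consensus(arm, uniform), 3)
  }
  expect_error(score_arm_against_consensus("AAA", cm),
               class = "coopfit_input_error")
})
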