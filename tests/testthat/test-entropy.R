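test_that("feeder frequencies follow the gap/ambiguity sharing rules", {
  # a gap spreads 1/5 over A,C,G,T and the real-indel state E
  expect_equal(columnStateFrequencies(c("A", "A", "C", "-")),
               c(A = 0.55, C = 0.30, G = 0.05, T = 0.05, E = 0.05))
  # Y = 1/2 C + 1/2 T
  expect_equal(columnStateFrequencies(c("Y", "C")),
               c(A = 0, C = 0.75, G = 0, T = 0.25, E = 0))
  expect_equal(columnStateFrequencies("A"),
               c(A = 1, C = 0, G = 0, T = 0, E = 0))
  # B = 1/3 C + 1/3 G + 1/3 T
  expect_equal(unname(columnStateFrequencies("B")["C"]), 1 / 3)
  expect_error(columnStateFrequencies(c("A", "Z")), "unknown symbol")
  expect_error(columnStateFrequencies(character(0)), "empty")
  # frequencies always sum to 1
  set.seed(41)
  for (i in 1:25) {
    col <- sample(c("A", "C", "G", "T", "R", "Y", "B", "N", "-"),
                  sample(1:20, 1), replace = TRUE)
    expect_equal(sum(columnStateFrequencies(col)), 1, tolerance = 1e-12)
  }
})

test_that("column entropy matches closed forms and the brute-force oracle", {
  expect_equal(columnEntropy(columnStateFrequencies(rep("A", 7))), 0)
  expect_equal(columnEntropy(columnStateFrequencies(c("A", "A", "C", "C"))),
               log(2))
  # frozen from bruteColumnEntropy(c("A","A","C","-"))
  expect_equal(columnEntropy(columnStateFrequencies(c("A", "A", "C", "-"))),
               1.139362032746471, tolerance = 1e-10)
  expect_equal(columnEntropy(columnStateFrequencies(c("A", "A", "C", "-"))),
               bruteColumnEntropy(c("A", "A", "C", "-")), tolerance = 1e-12)
})

test_that("the N feeder rule switches between 5 and 4 states", {
  f5 <- columnStateFrequencies("N", nStates = 5L)
  f4 <- columnStateFrequencies("N", nStates = 4L)
  expect_equal(unname(f5["E"]), 0.2)
  expect_equal(unname(f4["E"]), 0)
  expect_equal(unname(f4["A"]), 0.25)
  expect_equal(columnEntropy(f5), log(5))
  expect_equal(columnEntropy(f4), log(4))
})

test_that("entropy profile flags gap columns and localises variation", {
  prof <- entropyProfile(makeAln(c("ACGT", "ACGT")))
  expect_equal(entropies(prof), rep(0, 4))
  expect_false(any(gapFlag(prof)))

  prof2 <- entropyProfile(makeAln(c("ACGT", "ACTT")))
  expect_equal(which(entropies(prof2) > 0), 3L)

  prof3 <- entropyProfile(makeAln(c("AC-T", "ACTT")))
  expect_equal(gapFlag(prof3), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(gapFraction(prof3)[3], 0.5)
})

test_that("gap columns carry more entropy than the base they could hide", {
  set.seed(42)
  for (i in 1:10) {
    depth <- sample(4:20, 1)
    col <- sample(c("A", "C", "G", "T"), depth, replace = TRUE)
    gapped <- col
    gapped[1] <- "-"
    majority <- names(which.max(table(col)))
    replaced <- col
    replaced[1] <- majority
    expect_gt(columnEntropy(columnStateFrequencies(gapped)),
              columnEntropy(columnStateFrequencies(replaced)))
  }
})

test_that("heterogeneity summary partitions entropy and bounds h", {
  aln <- makeAln(c("AC-TGG", "ACTTGG", "ACTAGG"))
  prof <- entropyProfile(aln)
  het <- heterogeneitySummary(prof)
  expect_equal(het$H_total, het$H_f + het$H_g)
  expect_equal(het$H_total, sum(entropies(prof)), tolerance = 1e-12)
  expect_true(het$h >= 0 && het$h <= 1)
  expect_equal(het$positionsHPosGapfree + het$positionsHZeroGapfree,
               sum(!gapFlag(prof)))
  expect_equal(het$meanEntropy, mean(entropies(prof)))

  # h is invariant to column order and to duplicating all rows
  strs <- c("ACGTAC", "ACTTAG", "GCTTAG")
  perm <- c(3, 1, 6, 2, 5, 4)
  h1 <- heterogeneitySummary(entropyProfile(makeAln(strs)))$h
  permStrs <- vapply(strsplit(strs, ""), function(x)
    paste0(x[perm], collapse = ""), "")
  h2 <- heterogeneitySummary(entropyProfile(makeAln(permStrs)))$h
  h3 <- heterogeneitySummary(entropyProfile(makeAln(c(strs, strs))))$h
  expect_equal(h1, h2)
  expect_equal(h1, h3)
})

test_that("h hits its bounds on conserved and equidistributed alignments", {
  cons <- entropyProfile(makeAln(c("ACGT", "ACGT", "ACGT")))
  expect_warning(het0 <- heterogeneitySummary(cons), "conserved")
  expect_equal(het0$h, 0)

  # every column has its occurring states at equal frequency
  eq <- entropyProfile(makeAln(c("AAGG", "CCTT", "GGAA", "TTCC")))
  expect_equal(heterogeneitySummary(eq, "occurring_states")$h, 1)
  # under the fixed 5-state ceiling the same alignment stays below 1
  expect_lt(heterogeneitySummary(eq, "uniform5")$h, 1)
  # an all-N alignment equidistributes all five states: h = 1 in both modes
  allN <- entropyProfile(makeAln(c("NNN", "NNN")))
  expect_equal(heterogeneitySummary(allN, "occurring_states")$h, 1)
  expect_equal(heterogeneitySummary(allN, "uniform5")$h, 1)
})

test_that("high-entropy runs use strict thresholds and minimum length", {
  prof <- new("EntropyProfile",
              entropies = c(0.1, 2.0, 2.0, 0.1, 2.0),
              gapFlag = c(FALSE, TRUE, TRUE, FALSE, FALSE),
              gapFraction = c(0, 0.5, 0.9, 0, 0),
              occurringStates = c(2L, 5L, 5L, 2L, 4L))
  runs <- highEntropyRuns(prof, threshold = 1.5, minLength = 2)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start, 2L)
  expect_equal(runs$end, 3L)
  expect_equal(runs$length, 2L)
  expect_equal(runs$meanGapFrequency, 70)
  # the lone column 5 passes only when minLength drops to 1
  expect_equal(nrow(highEntropyRuns(prof, minLength = 1)), 2L)
  # strictly greater than the threshold: a column at exactly 1.5 is out
  profEq <- new("EntropyProfile", entropies = c(1.5, 1.5),
                gapFlag = c(FALSE, FALSE), gapFraction = c(0, 0),
                occurringStates = c(5L, 5L))
  expect_equal(nrow(highEntropyRuns(profEq)), 0L)
  expect_equal(nrow(highEntropyRuns(entropyProfile(makeAln(c("AC", "AC"))))),
               0L)
})
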