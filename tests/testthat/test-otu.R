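test_that("pairwise PSI respects the usable-column mask", {
  aln <- makeAln(c("AC-T", "ACGT"))
  usable <- usableColumns(aln)
  expect_equal(usable, c(1L, 2L, 4L))
  m <- alignmentMatrix(aln)
  expect_equal(pairwisePSI(m[1, ], m[2, ], usable), 1.0)
  expect_equal(pairwisePSI("ACGT", "ACGA", 1:4), 0.75)
  expect_equal(pairwisePSI("ACGT", "ACGT", 1:4), 1.0)
  expect_equal(pairwisePSI("ACGT", "AGCT", 1:4),
               pairwisePSI("AGCT", "ACGT", 1:4))
  expect_error(pairwisePSI("ACGT", "ACGT", integer(0)), "usable")
})

test_that("seed clustering joins identical sequences and splits planted clusters", {
  ident <- makeAln(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"))
  tab <- clusterOTUs(ident, 0.95)
  expect_equal(nOtus(tab), 1L)
  expect_equal(unname(otuSizes(tab)), 3L)
  expect_equal(otuSeeds(tab), "s1")
  expect_error(clusterOTUs(ident, 1), "cutoff")

  # two planted clusters, 20% apart, <= 1% within
  base1 <- strrep("ACGTTGCAAC", 10)
  base2 <- strrep("TGCAACGTTG", 10)
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- to
    paste0(v, collapse = "")
  }
  aln <- makeAln(c(base1, mut(base1, 7, "T"), base2, mut(base2, 13, "A")),
                 ids = c("a1", "a2", "b1", "b2"))
  for (linkage in c("seed", "single")) {
    tab <- clusterOTUs(aln, 0.95, linkage = linkage)
    expect_equal(nOtus(tab), 2L)
    expect_setequal(otuMembers(tab)[[1]], c("a1", "a2"))
    expect_setequal(otuMembers(tab)[[2]], c("b1", "b2"))
  }
})

test_that("every sequence lands in exactly one OTU at any cutoff", {
  set.seed(51)
  sim <- simulateAlignment(nSequences = 24, nClusters = 6, seed = 99)
  for (cutoff in c(0.9, 0.95, 0.99)) {
    tab <- clusterOTUs(sim$alignment, cutoff)
    ids <- sort(unname(unlist(otuMembers(tab))))
    expect_equal(ids, sort(sequenceIds(sim$alignment)))
    expect_equal(sum(otuSizes(tab)), 24L)
  }
})

test_that("single-linkage OTU counts never drop as the cutoff rises", {
  sim <- simulateAlignment(nSequences = 20, nClusters = 4,
                           withinDivergence = 0.03, seed = 7)
  counts <- vapply(c(0.90, 0.95, 0.97, 0.99), function(co) {
    nOtus(clusterOTUs(sim$alignment, co, linkage = "single"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("OTU classes separate singletons, quasi-singletons and multitons", {
  aln <- makeAln(c("ACGTAC", "ACGTAC", "AC-TAC", "ACGTAT", "GGGGGG"),
                 ids = c("q1", "q2", "q3", "m1", "x1"))
  # q1..q3 identical over usable columns (gap column 3 is masked), m1 differs
  tab <- clusterOTUs(aln, 0.8)
  tab <- classifyOTUs(tab, aln)
  cls <- otuClasses(tab)
  sizes <- otuSizes(tab)
  expect_equal(unname(cls[sizes == 1]), "singleton")
  big <- which.max(sizes)
  expect_true(cls[big] %in% c("quasi_singleton", "multiton"))
  # explicit checks on controlled tables
  t2 <- clusterOTUs(aln[c("q1", "q2", "q3"), ], 0.8)
  expect_equal(unname(otuClasses(classifyOTUs(t2, aln[c("q1", "q2", "q3"), ]))),
               "quasi_singleton")
  t3 <- clusterOTUs(aln[c("q1", "m1"), ], 0.8)
  expect_equal(unname(otuClasses(classifyOTUs(t3, aln[c("q1", "m1"), ]))),
               "multiton")
  expect_error(classifyOTUs(tab, aln[c("q1", "q2"), ]), "missing")
})

test_that("diversity indices match closed forms and vegan's Shannon", {
  # 35 OTUs, 24 singletons, 1 doubleton: classic Chao1 = 35 + 24^2/2
  ab <- c(rep(1, 24), 2, rep(3, 10))
  div <- diversityIndices(ab)
  expect_equal(div$S_obs, 35L)
  expect_equal(div$F1, 24)
  expect_equal(div$F2, 1)
  expect_equal(div$chao1, 323.0)
  expect_equal(div$evenness_E, div$shannon_H / log(35))
  expect_equal(div$shannon_H, unname(vegan::diversity(ab, index = "shannon")))

  even <- diversityIndices(c(5, 5, 5, 5))
  expect_equal(even$shannon_H, log(4))
  expect_equal(even$evenness_E, 1.0)

  # doubleton-free fallback and the chao1 >= S bound
  noF2 <- diversityIndices(c(1, 1, 1, 5))
  expect_equal(noF2$chao1, 4 + 3 * 2 / 2)
  set.seed(61)
  for (i in 1:10) {
    ab <- sample(1:6, sample(3:12, 1), replace = TRUE)
    expect_gte(diversityIndices(ab)$chao1, length(ab))
  }
  expect_equal(diversityIndices(c(3, 4))$chao1, 2)
  expect_equal(diversityIndices(5)$evenness_E, 0)
  expect_error(diversityIndices(numeric(0)), "empty")
})

test_that("analytic rarefaction matches vegan and its own endpoints", {
  expect_equal(rarefactionCurve(5)$expectedOtus, rep(1, 5))
  ab <- c(9, 5, 3, 1, 1, 2)
  cur <- rarefactionCurve(ab)
  expect_equal(cur$expectedOtus[nrow(cur)], length(ab))
  expect_true(all(diff(cur$expectedOtus) >= -1e-12))
  vg <- as.numeric(vegan::rarefy(ab, sample = cur$n))
  expect_equal(cur$expectedOtus, vg, tolerance = 1e-8)
})

test_that("Monte-Carlo rarefaction agrees with the analytic expectation", {
  ab <- c(7, 4, 2, 1, 1)
  ana <- rarefactionCurve(ab)
  mc <- rarefactionCurve(ab, method = "montecarlo", replicates = 300,
                         seed = 71)
  expect_equal(mc$n, ana$n)
  tol <- 3 * mc$se + 1 / 300
  expect_true(all(abs(mc$expectedOtus - ana$expectedOtus) <= tol))
  # deterministic under a fixed seed
  mc2 <- rarefactionCurve(ab, method = "montecarlo", replicates = 300,
                          seed = 71)
  expect_identical(mc, mc2)
  expect_error(rarefactionCurve(ab, method = "montecarlo", replicates = 0),
               "replicates")
})
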