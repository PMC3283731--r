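test_that("three-taxon NJ solves the three-point equations exactly", {
  # leaf branch lengths x, y, z give d(ab)=x+y, d(ac)=x+z, d(bc)=y+z
  x <- 0.10; y <- 0.20; z <- 0.30
  d <- matrix(c(0, x + y, x + z,
                x + y, 0, y + z,
                x + z, y + z, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- buildNJTree(d, variant = "classic_nj")
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[c("a", "b", "c")], c(a = x, b = y, c = z))
  expect_error(buildNJTree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive four-taxon trees exactly", {
  true <- ape::read.tree(text = "((a:0.10,b:0.20):0.07,c:0.15,d:0.25);")
  D <- ape::cophenetic.phylo(true)
  for (variant in c("bionj", "classic_nj")) {
    tr <- buildNJTree(D, variant = variant)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), true)), 0)
    expect_equal(sort(tr$edge.length),
                 sort(true$edge.length), tolerance = 1e-6)
  }
  # undefined distances abort with the pair named
  Dna <- D
  Dna["a", "c"] <- Dna["c", "a"] <- NA
  expect_error(buildNJTree(Dna), "\\(a, c\\)")
})

test_that("negative branch clamping conserves total length", {
  tr <- ape::read.tree(text = "((a:0.1,b:-0.02):0.05,c:0.2,d:0.1);")
  clamped <- clampNegativeBranches(tr)
  expect_true(all(clamped$edge.length >= 0))
  expect_equal(sum(clamped$edge.length), sum(tr$edge.length))
})

test_that("MRCA queries honour the rooting policy", {
  tr <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.1,c:0.2):0.3,(d:0.1,e:0.15):0.3,f:0.9);")
  res <- mrcaNode(tr, c("a", "b"), rootPolicy = NULL)
  kids <- res$tree$edge[res$tree$edge[, 1] == res$node, 2]
  expect_setequal(res$tree$tip.label[kids], c("a", "b"))
  # the MRCA of everything is the root
  all_ <- mrcaNode(tr, tr$tip.label, rootPolicy = NULL)
  expect_equal(all_$node, length(tr$tip.label) + 1L)
  # nested clade on the 6-leaf fixture: {a,b,c} meet below {a,b}
  abc <- mrcaNode(tr, c("a", "b", "c"), rootPolicy = NULL)
  ab <- mrcaNode(tr, c("a", "b"), rootPolicy = NULL)
  expect_true(abc$node != ab$node)
  desc <- phangorn::Descendants(tr, abc$node, "tips")[[1]]
  expect_setequal(tr$tip.label[desc], c("a", "b", "c"))
  expect_error(mrcaNode(tr, c("a", "zz")), "unknown label")
  expect_error(mrcaNode(tr, "a"), "at least 2")
})

test_that("OTU internal distance is the deepest member below the MRCA", {
  tr <- ape::read.tree(
    text = "((x:0.01,y:0.03):0.10,(z:0.10,w:0.10):0.05);")
  expect_equal(otuInternalDistance(tr, c("x", "y")), 0.03)
  expect_equal(otuInternalDistance(tr, c("z", "w")), 0.10)
  expect_error(otuInternalDistance(tr, "x"), "singleton")
  # quasi-singletons have zero internal distance
  tq <- ape::read.tree(text = "((p:0,q:0):0.1,(r:0.2,s:0.3):0.1);")
  expect_equal(otuInternalDistance(tq, c("p", "q")), 0)
  # pairwise fallback: half the maximum within-OTU distance
  D <- ape::cophenetic.phylo(tr)
  expect_equal(otuInternalDistance(tr, c("x", "y"), method = "pairwise",
                                   dm = D), (0.01 + 0.03) / 2)
  # triangle bound: internal distance <= max leaf-to-leaf path
  expect_lte(otuInternalDistance(tr, c("x", "y", "z")),
             max(D[c("x", "y", "z"), c("x", "y", "z")]))
})

test_that("bootstrap supports a deep planted split and is reproducible", {
  set.seed(91)
  sim <- simulateAlignment(nSequences = 10, nClusters = 2,
                           withinDivergence = 0.01, betweenDivergence = 0.4,
                           overhangMax = 0, ambiguityRate = 0, seed = 17)
  aln <- sim$alignment
  bs1 <- bootstrapSupports(aln, replicates = 30, seed = 5)
  bs2 <- bootstrapSupports(aln, replicates = 30, seed = 5)
  expect_identical(bs1$supports, bs2$supports)
  # the bipartition separating the two planted clusters is always found
  grp <- sim$truth$clusters
  rooted <- rootTree(bs1$tree)
  expect_true(ape::is.monophyletic(rooted, names(grp)[grp == "c01"]))
  expect_gte(max(bs1$supports[-1]), 100 * (30 - bs1$failedReplicates) / 30)
  # a single replicate can only give 0 or 100
  one <- bootstrapSupports(aln, replicates = 1, seed = 2)
  expect_true(all(one$supports %in% c(0, 100)))
})

test_that("monophyly report separates clean from interleaved groups", {
  tr <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2):0.1,(e:0.2,f:0.2):0.1);")
  supports <- c(100, 90, 80, 70, 60)  # one per internal node
  grouping <- c(a = "G1", b = "G1", c = "G2", d = "G2", e = "G2", f = "G3")
  rep_ <- monophylyReport(tr, supports, grouping, rootPolicy = NULL)
  g <- rep_$groups
  expect_true(g$monophyletic[g$group == "G1"])
  expect_false(g$monophyletic[g$group == "G2"])  # c,d,e interleaved with f
  expect_equal(rep_$treeMeanSupport, mean(supports))
  expect_equal(rep_$nSupportsOver49, 5L)
  expect_error(monophylyReport(tr, supports, c(zz = "G9")), "zero leaves")
})
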