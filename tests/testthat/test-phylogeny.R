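test_that("pairwise-deletion p-distances match hand counts", {
  expect_equal(pdistance_matrix(c(a = "ACDEF", b = "ACDEF"))["a", "b"], 0)
  expect_equal(pdistance_matrix(c(a = "ACDEF", b = "ACDFF"))["a", "b"],
               0.2)
  D <- pdistance_matrix(c(a = "AC-EF", b = "ACDEF"))
  expect_equal(D["a", "b"], 0)
  expect_equal(attr(D, "sites")["a", "b"], 4L)
  expect_error(pdistance_matrix(c(a = "--A", b = "AA-")), "a / b")
  expect_error(pdistance_matrix(c(a = "ACD", b = "AC")), "ragged")
})

test_that("p-distance equals a brute-force per-pair loop", {
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aln <- vapply(1:6, function(i)
    paste(sample(c(aa, "-"), 40, replace = TRUE,
                 prob = c(rep(1, 20), 4)), collapse = ""), character(1))
  names(aln) <- letters[1:6]
  D <- pdistance_matrix(aln)
  for (i in 1:5) for (j in (i + 1):6) {
    x <- strsplit(aln[i], "")[[1]]; y <- strsplit(aln[j], "")[[1]]
    ok <- x != "-" & y != "-"
    expect_equal(D[i, j], sum(x[ok] != y[ok]) / sum(ok))
  }
})

test_that("neighbor joining is exact on three taxa and additive data", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  # closed form: lA = (d12+d13-d23)/2 etc.
  lens <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])],
                   t3$tip.label)
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)

  t4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D4 <- additive_distances(t4)
  nj4 <- neighbor_joining(D4)
  expect_equal(ape::dist.topo(ape::unroot(t4), nj4), 0,
               ignore_attr = TRUE)
  # branch lengths: patristic distances reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(D4), colnames(D4)],
               D4, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D4; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("random additive matrices are recovered, matching ape's NJ", {
  set.seed(77)
  for (k in 1:25) {
    tr <- ape::rtree(6)
    tr$edge.length <- tr$edge.length + 0.1
    D <- additive_distances(tr)
    mine <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), mine), 0,
                 ignore_attr = TRUE)
    # independent cross-check against the reference implementation
    expect_equal(ape::dist.topo(ape::nj(D), mine), 0, ignore_attr = TRUE)
  }
})

test_that("leaf order of the input never changes the topology", {
  set.seed(5)
  tr <- ape::rtree(8); tr$edge.length <- tr$edge.length + 0.1
  D <- additive_distances(tr)
  perm <- sample(8)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports reflect planted signal and resampling", {
  # two clearly separated 3-taxon clades
  core1 <- random_protein_str(60, seed = 61)
  core2 <- random_protein_str(60, seed = 62)
  aln <- c(a1 = core1, a2 = mutate_copy(core1, 0.95, 63),
           a3 = mutate_copy(core1, 0.95, 64),
           b1 = core2, b2 = mutate_copy(core2, 0.95, 65),
           b3 = mutate_copy(core2, 0.95, 66))
  bs <- bootstrap_support(aln, n_replicates = 200, seed = 9)
  central <- bs$supports[bs$supports$bipartition %in%
                           c("b1|b2|b3", "a1|a2|a3"), ]
  expect_gte(max(central$support), 99)
  bs2 <- bootstrap_support(aln, n_replicates = 25, seed = 1)
  bs3 <- bootstrap_support(aln, n_replicates = 25, seed = 1)
  expect_identical(bs2$supports, bs3$supports)
  expect_true(all(bs$supports$flagged == (bs$supports$support <= 50)))
})

test_that("resampling-invariant alignments give 100% support everywhere", {
  base <- c(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT", e = "KKKK")
  # every column identical, so each replicate rebuilds the same tree
  bs <- bootstrap_support(base, n_replicates = 50, seed = 2)
  expect_true(all(bs$supports$support == 100))
})

test_that("newick output round-trips topology, lengths and supports", {
  tf <- tempfile(fileext = ".nwk")
  set.seed(99)
  for (k in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(4:10, 1)))
    write_newick(tr, tf)
    back <- read_newick(tf)
    expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
  t3 <- neighbor_joining(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                                dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C"))))
  write_newick(t3, tf)
  expect_match(readLines(tf), "^\\(A:.*,B:.*,C:.*\\);$")
  unlink(tf)
})
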