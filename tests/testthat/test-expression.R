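test_that("EST eligibility follows the identity and overlap gates", {
  cds <- generate_cds(c("gA", "gB"), len_range = c(500, 600), seed = 2)
  est <- substr(cds[["gA"]], 100, 279)           # error-free substring
  man <- data.frame(est_id = "e1", tissue = "root")
  hit <- map_cds_to_ests(cds, c(e1 = est), man)
  expect_equal(hit$gene_id, "gA")
  expect_equal(hit$identity, 100)
  # 15% scattered substitutions: ineligible at the 90% bar
  b <- strsplit(est, "")[[1]]
  set.seed(5)
  idx <- sample(length(b), round(0.15 * length(b)))
  for (p in idx) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  noisy <- paste(b, collapse = "")
  expect_equal(nrow(map_cds_to_ests(cds, c(e1 = noisy), man)), 0)
  # overlap gate: a 60 bp perfect read is too short
  short <- substr(cds[["gA"]], 1, 60)
  expect_equal(nrow(map_cds_to_ests(cds, c(e1 = short), man)), 0)
  expect_error(map_cds_to_ests(cds, c(e9 = est),
                               data.frame(est_id = "e1",
                                          tissue = "root")),
               "missing tissue")
})

test_that("seeded mapping equals full alignment over all pairs", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  cds <- generate_cds(sprintf("g%02d", 1:12), len_range = c(400, 700),
                      seed = 31)
  means <- matrix(0, 12, 6, dimnames = list(names(cds), tiss))
  set.seed(32)
  means[cbind(1:12, sample(6, 12, TRUE))] <- 6
  lib <- generate_est_library(means, cds, error_rate = 0.01, seed = 33)
  fast <- map_cds_to_ests(cds, lib$ests, lib$manifest, prefilter = TRUE)
  full <- map_cds_to_ests(cds, lib$ests, lib$manifest, prefilter = FALSE)
  expect_equal(fast, full)
  # every eligible hit is assigned to its true source gene
  merged <- merge(fast, lib$truth, by = "est_id")
  expect_true(all(merged$gene_id.x == merged$gene_id.y))
})

test_that("tissue counts conserve hits and ignore hit order", {
  hits <- data.frame(est_id = sprintf("e%d", 1:7),
                     gene_id = c("g1", "g1", "g2", "g2", "g2", "g3", "g3"),
                     identity = 100, overlap = 150, evalue_surrogate = 0,
                     tissue = c("root", "root", "leaf", "seed", "seed",
                                "bud", "silique"))
  tc <- tissue_counts(hits)
  expect_equal(sum(as.matrix(tc[, -1])), nrow(hits))
  perm <- tissue_counts(hits[sample(nrow(hits)), ])
  expect_equal(tc, perm)
  withz <- tissue_counts(hits, all_genes = c("g1", "g2", "g3", "g4"))
  expect_equal(nrow(withz), 4)
  expect_equal(sum(as.matrix(withz[withz$gene_id == "g4", -1])), 0)
})

test_that("tissue totals reproduce printed percentage shares", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  printed <- c(7677, 17288, 26384, 42027, 30120, 8051)
  prof <- data.frame(gene_id = "all", t(setNames(printed, tiss)))
  tot <- tissue_totals(prof)
  expect_equal(tot$percentage[tot$tissue == "root"], 31.95)
  expect_equal(tot$percentage[tot$tissue == "seed"], 22.90)
  expect_equal(tot$percentage[tot$tissue == "leaf"], 20.06)
  expect_equal(tot$percentage[tot$tissue == "flower"], 13.14)
  expect_equal(tot$percentage[tot$tissue == "silique"], 6.12)
  expect_equal(tot$percentage[tot$tissue == "bud"], 5.84)
  single <- data.frame(gene_id = "g", bud = 0, flower = 0, leaf = 0,
                       root = 9, seed = 0, silique = 0)
  expect_equal(tissue_totals(single)$percentage[4], 100)
  zero <- single; zero$root <- 0
  expect_error(tissue_totals(zero), "undefined")
})

test_that("sharing table reproduces printed family percentages", {
  fx <- printed_expression_fixture()
  sh <- sharing_table(fx$profiles, fx$family)
  expect_equal(sh$n_expressed, 174)
  fs <- sh$family_summary
  expect_equal(fs$percentage[fs$type == "ERF"], 55.2)
  expect_equal(fs$percentage[fs$type == "DREB"], 33.3)
  expect_equal(fs$percentage[fs$type == "AP2"], 6.9)
  expect_equal(fs$percentage[fs$type == "RAV"], 4.0)
  expect_equal(fs$percentage[fs$type == "Soloist"], 0.6)
  expect_equal(sum(fs$type_num), 174)
  # published sharing pattern percentages
  subs <- sh$subsets
  all6 <- paste(c("bud", "flower", "leaf", "root", "seed", "silique"),
                collapse = "+")
  expect_equal(subs$percentage[subs$subset == all6], 6.32)
  expect_equal(subs$percentage[subs$subset == "leaf+root+seed"], 13.22)
  expect_equal(subs$percentage[subs$subset == "flower+leaf+root+seed"],
               9.77)
  expect_equal(subs$percentage[subs$subset == "root"], 7.47)
  expect_equal(sum(subs$n_genes), 174)
})

test_that("singleton-subset profiles partition the expressed genes", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  prof <- data.frame(gene_id = sprintf("g%d", 1:6),
                     diag(6) * 5)
  names(prof)[-1] <- tiss
  sh <- sharing_table(prof)
  expect_equal(sort(sh$subsets$subset), sort(tiss))
  expect_true(all(sh$subsets$n_genes == 1))
})

test_that("pcc matches the closed form and refuses zero variance", {
  expect_equal(pcc(1:5, 1:5), 1)
  x <- c(-2, -1, 1, 2)
  expect_equal(pcc(x, -x), -1)
  xx <- c(1, 2, 3, 4); yy <- c(2, 4, 6, 9)
  byhand <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  expect_equal(pcc(xx, yy), byhand, tolerance = 1e-12)
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pcc(1:2, 1:2), "length")
})

test_that("profile clustering merges identical genes first", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  m <- rbind(g1 = c(9, 1, 1, 1, 1, 1), g2 = c(9, 1, 1, 1, 1, 1),
             g3 = c(1, 1, 1, 9, 9, 1), g4 = c(1, 2, 1, 8, 9, 1))
  prof <- data.frame(gene_id = rownames(m), m)
  names(prof)[-1] <- tiss
  cl <- cluster_profiles(prof)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- rownames(m)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("g1", "g2"))
  # merge heights non-decreasing (average linkage)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # constant profile excluded with warning
  prof2 <- rbind(prof, data.frame(gene_id = "flat", t(rep(3, 6))) |>
                   setNames(names(prof)))
  expect_warning(cl2 <- cluster_profiles(prof2), "flat")
  expect_false("flat" %in% cl2$order)
})

test_that("planted two-block expression designs split at the root", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    rootish <- t(replicate(5, c(1, 1, 1, 20, 2, 1) + rpois(6, 1)))
    seedish <- t(replicate(5, c(1, 1, 1, 2, 20, 1) + rpois(6, 1)))
    prof <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       rbind(rootish, seedish))
    names(prof)[-1] <- tiss
    cl <- cluster_profiles(prof)
    top <- cutree(cl$hclust, k = 2)
    if (length(unique(top[1:5])) == 1 &&
        length(unique(top[6:10])) == 1) ok <- ok + 1
  }
  expect_equal(ok, 10)
})
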