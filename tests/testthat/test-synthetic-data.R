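test_that("domain models are normalized, peaked and deterministic", {
  cons <- random_protein_str(29, seed = 5)
  m <- make_domain_model(cons, diversity = 20, seed = 3)
  expect_equal(m$length, 29)
  expect_equal(unname(rowSums(m$pfm)), rep(1, 29), tolerance = 1e-9)
  # degenerate concentration: consensus recoverable from every column
  m_inf <- make_domain_model(cons, diversity = 1e7, seed = 3)
  expect_equal(paste(colnames(m_inf$pfm)[max.col(m_inf$pfm)],
                     collapse = ""), cons)
  m2 <- make_domain_model(cons, diversity = 20, seed = 3)
  expect_identical(m$pfm, m2$pfm)
  expect_error(make_domain_model("ACDEFGHIKB", 20, 1), "non-amino-acid")
  expect_error(make_domain_model(cons, 0, 1), "diversity")
  expect_error(make_domain_model("ACDEF", 20, 1), "length")
})

test_that("generated proteomes carry the planted architecture census", {
  empty <- generate_proteome(c(ERF = 0, AP2 = 0, RAV = 0, Soloist = 0),
                             fix_models, fix_panel, seed = 1)
  expect_length(empty$proteins, 0)
  expect_equal(nrow(empty$truth$family_labels), 0)

  tr <- fix_proteome$truth
  expect_equal(as.integer(table(tr$family_labels$family)[
    c("ERF", "AP2", "RAV", "Soloist")]), c(24L, 6L, 4L, 1L))
  # every truth gene exists in the emitted sequence set
  expect_true(all(tr$family_labels$gene_id %in%
                    names(fix_proteome$proteins)))
  expect_true(all(tr$architectures$gene_id %in%
                    names(fix_proteome$proteins)))
  # AP2-family genes carry two AP2 domains, RAV one AP2 + one B3
  arch <- split(tr$architectures$domain, tr$architectures$gene_id)
  for (g in tr$family_labels$gene_id) {
    fam <- tr$family_labels$family[tr$family_labels$gene_id == g]
    expected <- switch(fam, AP2 = c("AP2", "AP2"), RAV = c("AP2", "B3"),
                       "AP2")
    expect_equal(sort(arch[[g]]), sort(expected))
  }
  expect_error(generate_proteome(c(ERF = 1), list(), seed = 1), "empty")
})

test_that("mutate_copy hits its identity target exactly", {
  s <- random_protein_str(100, seed = 9)
  expect_identical(mutate_copy(s, 1, seed = 1), s)
  m <- mutate_copy(s, 0.95, seed = 2)
  mism <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(mism, 5)
  expect_equal(percent_identity(s, m), 95)
  expect_error(mutate_copy(s, 0, seed = 1), "target_identity")
  # realized divergence matches target within 1/len for lengths >= 20
  for (k in 1:12) {
    len <- sample(20:300, 1)
    ti <- runif(1, 0.6, 1)
    sq <- random_protein_str(len, seed = 100 + k)
    mm <- mutate_copy(sq, ti, seed = 200 + k)
    realized <- mean(strsplit(sq, "")[[1]] == strsplit(mm, "")[[1]])
    expect_lte(abs(realized - ti), 1 / len + 1e-12)
  }
})

test_that("genome layout plants clusters, scaffolds and valid coordinates", {
  expect_equal(nrow(generate_genome_layout(character(0))$loci), 0)
  ids <- sprintf("Br%03d", 1:40)
  spec <- list(ids[5:7])
  lay <- generate_genome_layout(ids, cluster_spec = spec, n_scaffold = 2,
                                seed = 4)
  loci <- lay$loci
  expect_setequal(loci$gene_id, ids)
  expect_true(all(loci$start <= loci$end))
  expect_equal(sum(loci$chrom == "scaffold"), 2)
  # non-overlap within each chromosome
  for (ch in setdiff(unique(loci$chrom), "scaffold")) {
    sub <- loci[loci$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  # the planted run is recovered exactly by the cluster caller
  groups <- data.frame(gene_id = ids, group = "ERF-B3")
  cl <- tandem_clusters(loci, groups, max_intervening = 0,
                        max_span_kb = 25)
  found <- vapply(cl, function(x) paste(sort(x$gene_id), collapse = ","),
                  character(1))
  expect_true(paste(sort(ids[5:7]), collapse = ",") %in% found)
  expect_error(generate_genome_layout(ids[1:2],
                                      cluster_spec = list(ids[1:5])),
               "subset")
})

test_that("EST libraries follow the planted count model", {
  tiss <- c("bud", "flower", "leaf", "root", "seed", "silique")
  cds <- generate_cds("g1", seed = 4)
  means0 <- matrix(0, 1, 6, dimnames = list("g1", tiss))
  lib0 <- generate_est_library(means0, cds, seed = 1)
  expect_length(lib0$ests, 0)

  means <- means0; means["g1", "root"] <- 20
  expect_error(generate_est_library(means, cds, error_rate = 0.2),
               "error_rate")
  bad <- means; colnames(bad) <- c("bud", "flower", "leaf", "root",
                                   "seed", "pod")
  expect_error(generate_est_library(bad, cds), "columns")

  # Monte-Carlo: mean realized count within 5% of the stated mean
  # (600 replicate libraries put the standard error near 1.7%)
  counts <- vapply(1:600, function(s)
    length(generate_est_library(means, cds, error_rate = 0,
                                seed = s)$ests), numeric(1))
  expect_lt(abs(mean(counts) - 20) / 20, 0.05)

  # with zero error, counting the library recovers root-only expression
  lib <- generate_est_library(means, cds, error_rate = 0, seed = 3)
  hits <- map_cds_to_ests(cds, lib$ests, lib$manifest)
  tc <- tissue_counts(hits)
  expect_equal(tc$root, length(lib$ests))
  expect_equal(tc$bud + tc$flower + tc$leaf + tc$seed + tc$silique, 0L)

  # 2% substitution error keeps reads well above the 90% identity bar
  lib2 <- generate_est_library(means, cds, error_rate = 0.02,
                               read_len = c(150, 300), seed = 5)
  hits2 <- map_cds_to_ests(cds, lib2$ests, lib2$manifest)
  expect_gte(nrow(hits2) / length(lib2$ests), 0.99)
})
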