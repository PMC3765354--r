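test_that("the distribution table reproduces printed survey counts", {
  fx <- printed_distribution_fixture()
  dt <- distribution_table(fx$calls, fx$loci)
  expect_equal(dt$grand_total, 288)
  expect_equal(as.matrix(dt$table[rownames(fx$counts),
                                  colnames(fx$counts)]),
               fx$counts, ignore_attr = TRUE)
  expect_equal(dt$table["Total", "Total"], 288)
  expect_equal(unlist(dt$table["Total", colnames(fx$counts)]),
               colSums(fx$counts), ignore_attr = TRUE)
})

test_that("empty inputs, permutations and exclusions are handled", {
  fx <- printed_distribution_fixture()
  empty <- distribution_table(fx$calls[0, ], fx$loci[0, ])
  expect_equal(empty$grand_total, 0)
  perm <- sample(nrow(fx$calls))
  dt2 <- distribution_table(fx$calls[perm, ], fx$loci)
  expect_equal(dt2$table, distribution_table(fx$calls, fx$loci)$table)
  # a locus without a call lands in the exclusions report
  loci2 <- rbind(fx$loci,
                 data.frame(gene_id = "orphan", chrom = "A01",
                            start = 1L, end = 10L, strand = "+"))
  dt3 <- distribution_table(fx$calls, loci2)
  expect_equal(dt3$exclusions, "orphan")
  expect_equal(dt3$grand_total, 288)
  # scaffold genes are reported separately, not in chromosome rows
  loci3 <- fx$loci
  loci3$chrom[1] <- "scaffold"
  dt4 <- distribution_table(fx$calls, loci3)
  expect_equal(dt4$grand_total, 287)
  expect_equal(dt4$scaffold, fx$loci$gene_id[1])
})

make_chrom <- function(genes, groups, starts, chrom = "A01") {
  list(loci = data.frame(gene_id = genes, chrom = chrom, start = starts,
                         end = starts + 999L, strand = "+",
                         stringsAsFactors = FALSE),
       groups = data.frame(gene_id = genes, group = groups,
                           stringsAsFactors = FALSE))
}

test_that("tandem clusters follow the proximity rule", {
  # five consecutive same-group genes: one cluster of five
  cc <- make_chrom(sprintf("g%d", 1:5), rep("ERF-B3", 5),
                   seq(1e5, by = 5e4, length.out = 5))
  cl <- tandem_clusters(cc$loci, cc$groups)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]), 5)
  # same group, different chromosomes: nothing
  cc2 <- make_chrom(c("h1", "h2"), c("ERF-B1", "ERF-B1"), c(1e5, 2e5))
  cc2$loci$chrom <- c("A01", "A02")
  expect_length(tandem_clusters(cc2$loci, cc2$groups), 0)
  # a gap beyond max_span_kb splits the run
  cc3 <- make_chrom(sprintf("k%d", 1:4), rep("DREB-A1", 4),
                    c(1e5, 1.5e5, 5e6, 5.05e6))
  cl3 <- tandem_clusters(cc3$loci, cc3$groups, max_span_kb = 100)
  expect_length(cl3, 2)
  expect_true(all(vapply(cl3, nrow, integer(1)) == 2))
})

test_that("cluster detection equals brute-force run enumeration", {
  set.seed(9)
  for (k in 1:10) {
    n <- sample(6:14, 1)
    cc <- make_chrom(sprintf("g%02d", 1:n),
                     sample(c("ERF-B1", "ERF-B3", "DREB-A1"), n, TRUE),
                     cumsum(sample(c(2e4, 8e4, 2e5), n, TRUE)))
    mine <- lapply(tandem_clusters(cc$loci, cc$groups,
                                   max_intervening = 1,
                                   max_span_kb = 100),
                   function(x) sort(x$gene_id))
    oracle <- brute_runs(cc$loci, cc$groups, 1, 100)
    expect_setequal(vapply(mine, paste, character(1), collapse = ","),
                    vapply(oracle, paste, character(1), collapse = ","))
  }
})

test_that("synteny links keep scaffold pairs and reject unknown ids", {
  lociA <- data.frame(gene_id = c("a1", "a2", "a3"),
                      chrom = c("A01", "scaffold", "A02"),
                      start = c(100L, 5L, 900L), end = c(200L, 50L, 950L),
                      strand = "+")
  lociB <- data.frame(gene_id = c("b1", "b2", "b3"),
                      chrom = c("B01", "B01", "B02"),
                      start = c(1L, 2L, 3L), end = c(9L, 9L, 9L),
                      strand = "+")
  pairs <- data.frame(idA = c("a1", "a2"), idB = c("b1", "b3"))
  links <- synteny_links(pairs, lociA, lociB)
  expect_equal(nrow(links), 2)
  expect_equal(links$scaffold_flag, c(FALSE, TRUE))
  expect_equal(nrow(synteny_links(pairs[0, ], lociA, lociB)), 0)
  bad <- data.frame(idA = "zz", idB = "b1")
  expect_error(synteny_links(bad, lociA, lociB), "zz")
})
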