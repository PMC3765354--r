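#' Generate a synthetic genome layout with planted tandem clusters
#'
#' Assigns each gene a chromosome, strand and non-overlapping 1-based
#' inclusive coordinates.  Genes named in `cluster_spec` are placed as
#' consecutive genes on one chromosome with small intergenic gaps, giving
#' known tandem-cluster truth; `n_scaffold` genes are left unanchored
#' (chrom `"scaffold"`), mirroring assembly gaps.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_chromosomes number of chromosomes (default 10, named
#'   `A01..A10`).
#' @param cluster_spec list of character vectors; each element is a run of
#'   gene ids to be planted consecutively (all must be in `gene_ids`).
#' @param n_scaffold number of non-cluster genes left unplaced.
#' @param cluster_gap_kb range (kb) of intergenic gaps inside planted
#'   clusters.
#' @param gap_kb range (kb) of gaps between unrelated neighbours.
#' @param gene_kb range (kb) of gene lengths.
#' @param seed integer seed.
#' @return list with `loci` (data.frame gene_id, chrom, start, end,
#'   strand) and `clusters` (the planted runs, as given).
#' @export
generate_genome_layout <- function(gene_ids, n_chromosomes = 10,
                                   cluster_spec = list(), n_scaffold = 0,
                                   cluster_gap_kb = c(2, 20),
                                   gap_kb = c(30, 120), gene_kb = c(1, 4),
                                   seed = 3) {
  cl_genes <- unlist(cluster_spec)
  if (anyDuplicated(cl_genes))
    stop("a gene appears in two planted clusters", call. = FALSE)
  if (!all(cl_genes %in% gene_ids))
    stop("cluster members must be a subset of gene_ids", call. = FALSE)
  if (length(cl_genes) > length(gene_ids))
    stop("more planted cluster genes than gene_ids", call. = FALSE)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(gene_ids))
    return(list(loci = empty, clusters = cluster_spec))
  chroms <- sprintf("A%02d", seq_len(n_chromosomes))

  with_seed(seed, {
    free <- setdiff(gene_ids, cl_genes)
    scaff <- character(0)
    if (n_scaffold > 0) {
      scaff <- sample(free, min(n_scaffold, length(free)))
      free <- setdiff(free, scaff)
    }
    # each chromosome gets a shuffled share of free genes plus whole
    # clusters (kept contiguous) spliced in at random positions
    chrom_of_cluster <- sample(chroms, length(cluster_spec), replace = TRUE)
    free_chrom <- sample(chroms, length(free), replace = TRUE)
    rows <- list()
    for (ch in chroms) {
      units <- as.list(sample(free[free_chrom == ch]))
      for (k in which(chrom_of_cluster == ch))
        units <- append(units, list(cluster_spec[[k]]),
                        after = sample(0:length(units), 1))
      pos <- 1L
      for (u in units) {
        first <- TRUE
        for (g in u) {
          gap <- if (first) round(runif(1, gap_kb[1], gap_kb[2]) * 1000)
                 else round(runif(1, cluster_gap_kb[1],
                                  cluster_gap_kb[2]) * 1000)
          len <- round(runif(1, gene_kb[1], gene_kb[2]) * 1000)
          start <- pos + gap
          rows[[length(rows) + 1L]] <-
            data.frame(gene_id = g, chrom = ch, start = start,
                       end = start + len - 1L,
                       strand = sample(c("+", "-"), 1),
                       stringsAsFactors = FALSE)
          pos <- start + len - 1L
          first <- FALSE
        }
      }
    }
    pos <- 1L
    for (g in scaff) {
      len <- round(runif(1, gene_kb[1], gene_kb[2]) * 1000)
      start <- pos + round(runif(1, gap_kb[1], gap_kb[2]) * 1000)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, chrom = "scaffold", start = start,
                   end = start + len - 1L, strand = sample(c("+", "-"), 1),
                   stringsAsFactors = FALSE)
      pos <- start + len - 1L
    }
    loci <- do.call(rbind, rows)
    loci <- loci[match(gene_ids, loci$gene_id), ]
    rownames(loci) <- NULL
    list(loci = validate_loci(loci), clusters = cluster_spec)
  })
}

#' Default planted cluster design for a survey-scale genome
#'
#' Picks runs of same-group genes (sizes 5, 3, 3, 2, 2) from the truth
#' table, the pattern of tandem duplication a chromosome map of this
#' superfamily typically shows.
#'
#' @param family_labels truth data.frame (gene_id, family, group).
#' @param sizes cluster sizes to plant.
#' @param seed integer seed.
#' @return list of gene-id runs usable as `cluster_spec`.
#' @export
default_cluster_spec <- function(family_labels, sizes = c(5, 3, 3, 2, 2),
                                 seed = 3) {
  with_seed(substream(seed, 77), {
    avail <- family_labels
    spec <- list()
    for (s in sizes) {
      tab <- table(avail$group[avail$family == "ERF"])
      ok <- names(tab)[tab >= s]
      if (!length(ok)) next
      g <- sample(ok, 1)
      ids <- sample(avail$gene_id[avail$group == g], s)
      avail <- avail[!avail$gene_id %in% ids, ]
      spec[[length(spec) + 1L]] <- ids
    }
    spec
  })
}
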