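# DNA E-value surrogate, Gumbel-fitted once per session on random decoy
# EST-vs-CDS alignments (fixed internal seed)
dna_evalue_params <- function() {
  if (is.null(.erf_cache$ka_dna)) {
    m0 <- 150L; n0 <- 1000L
    nt <- c("A", "C", "G", "T")
    scores <- with_seed(412709, {
      a <- vapply(seq_len(100), function(i)
        paste(sample(nt, m0, replace = TRUE), collapse = ""), character(1))
      b <- paste(sample(nt, n0, replace = TRUE), collapse = "")
      Biostrings::score(est_align(a, b))
    })
    lambda <- pi / (sd(scores) * sqrt(6))
    mu <- mean(scores) - 0.5772156649 / lambda
    .erf_cache$ka_dna <- list(lambda = lambda, mu = mu, m0 = m0, n0 = n0)
  }
  .erf_cache$ka_dna
}

est_align <- function(est, cds) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unlist(as.character(est))), cds,
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
}

dna_evalue <- function(score, m, n) {
  p <- dna_evalue_params()
  as.numeric(m) * as.numeric(n) / (p$m0 * p$n0) *
    exp(-p$lambda * (score - p$mu))
}

#' Map ESTs to CDS sequences and keep eligible hits
#'
#' Each EST is aligned (whole EST within CDS, exact affine-gap DP) against
#' every CDS sharing at least one `k`-mer seed with it; a hit is eligible
#' when identity >= `min_identity` percent over an overlap of at least
#' `min_overlap_bp` aligned columns and the E-value surrogate is at most
#' `max_e`.  Each EST is assigned to its single best CDS (ties broken by
#' alphabetical CDS id).
#'
#' @param cds named DNA vector.
#' @param ests named DNA vector.
#' @param manifest data.frame (est_id, tissue) covering every EST.
#' @param min_identity percent identity bar (default 90).
#' @param max_e E-value surrogate gate (default 1e-5).
#' @param min_overlap_bp minimum aligned overlap (default 100).
#' @param k seed k-mer length (default 11).
#' @param min_seeds minimum distinct shared k-mers for a CDS to become an
#'   alignment candidate (default 2; an eligible hit at the 90% identity
#'   bar over 100+ bp shares dozens).
#' @param prefilter use the k-mer seed prefilter (TRUE); FALSE aligns all
#'   pairs (slow; used for oracle checks).
#' @return data.frame: est_id, gene_id, identity, overlap,
#'   evalue_surrogate, tissue.
#' @export
map_cds_to_ests <- function(cds, ests, manifest, min_identity = 90,
                            max_e = 1e-5, min_overlap_bp = 100, k = 11,
                            min_seeds = 2, prefilter = TRUE) {
  missing_lab <- setdiff(names(ests), manifest$est_id)
  if (length(missing_lab))
    stop("EST(s) missing tissue label: ",
         paste(head(missing_lab, 5), collapse = ", "), call. = FALSE)
  empty <- data.frame(est_id = character(), gene_id = character(),
                      identity = numeric(), overlap = integer(),
                      evalue_surrogate = numeric(), tissue = character(),
                      stringsAsFactors = FALSE)
  if (!length(ests) || !length(cds)) return(empty)
  cand <- if (prefilter) candidate_partners(ests, cds, k = k,
                                            min_shared = min_seeds)
          else rep(list(seq_along(cds)), length(ests))
  tiss <- setNames(manifest$tissue, manifest$est_id)
  # batch by CDS: one vectorized alignment call per CDS over the ESTs
  # whose seed sets name it
  per_cds <- vector("list", length(cds))
  for (i in seq_along(ests))
    for (j in cand[[i]]) per_cds[[j]] <- c(per_cds[[j]], i)
  best <- vector("list", length(ests))
  for (j in seq_along(cds)) {
    is <- per_cds[[j]]
    if (!length(is)) next
    al <- est_align(ests[is], cds[[j]])
    pa <- as.character(Biostrings::pattern(al))
    pb <- as.character(Biostrings::subject(al))
    sc <- Biostrings::score(al)
    for (q in seq_along(is)) {
      i <- is[q]
      rec <- list(gene = names(cds)[j],
                  idy = aligned_identity(pa[q], pb[q]),
                  ov = nchar(pa[q]), sc = sc[q], cds_len = nchar(cds[[j]]))
      b <- best[[i]]
      if (is.null(b) || rec$sc > b$sc ||
          (rec$sc == b$sc && rec$gene < b$gene)) best[[i]] <- rec
    }
  }
  rows <- list()
  for (i in seq_along(ests)) {
    b <- best[[i]]
    if (is.null(b)) next
    ev <- dna_evalue(b$sc, nchar(ests[[i]]), b$cds_len)
    if (b$idy >= min_identity && b$ov >= min_overlap_bp && ev <= max_e)
      rows[[length(rows) + 1L]] <-
        data.frame(est_id = names(ests)[i], gene_id = b$gene,
                   identity = b$idy, overlap = b$ov,
                   evalue_surrogate = ev, tissue = tiss[[names(ests)[i]]],
                   stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$est_id), ]
  rownames(out) <- NULL
  out
}

#' Per-gene, per-tissue EST counts
#'
#' @param hits eligible hits from [map_cds_to_ests()].
#' @param all_genes optional gene ids to retain as zero rows (the "full
#'   table"); by default only genes with at least one hit appear.
#' @return data.frame: gene_id plus one count column per tissue (bud,
#'   flower, leaf, root, seed, silique).
#' @export
tissue_counts <- function(hits, all_genes = NULL) {
  genes <- if (is.null(all_genes)) sort(unique(hits$gene_id))
           else sort(unique(all_genes))
  m <- matrix(0L, length(genes), 6, dimnames = list(genes, TISSUES))
  if (nrow(hits)) {
    tb <- table(factor(hits$gene_id, levels = genes),
                factor(hits$tissue, levels = TISSUES))
    m[] <- as.integer(tb)
  }
  data.frame(gene_id = genes, as.data.frame.matrix(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[TISSUES])
  rownames(m) <- profiles$gene_id
  m
}

#' Per-tissue transcript totals and percentage shares
#'
#' Percentages are tissue total / grand total x 100, rounded half-up to
#' two decimals (printed-table precision).
#'
#' @param profiles expression profiles (see [tissue_counts()]).
#' @return data.frame: tissue, total, percentage.
#' @export
tissue_totals <- function(profiles) {
  if (!nrow(profiles)) stop("need >= 1 profile", call. = FALSE)
  m <- profile_matrix(profiles)
  tot <- colSums(m)
  if (sum(tot) == 0)
    stop("all counts are zero: percentages undefined", call. = FALSE)
  data.frame(tissue = TISSUES, total = as.numeric(tot),
             percentage = round_half_up(100 * tot / sum(tot), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tissue-sharing table and family-level expression summary
#'
#' A gene belongs to the subset of tissues where its count is positive.
#' Subset percentages are relative to the number of expressed genes
#' (2 decimals, half-up); the family summary gives per-family, per-tissue
#' expressed-gene counts, the number of expressed genes (`type_num`) and
#' its percentage (1 decimal, half-up).
#'
#' @param profiles expression profiles.
#' @param family optional data.frame (gene_id, family) enabling the
#'   family summary.
#' @return list of class `sharing_table`: `subsets` (data.frame subset,
#'   n_genes, percentage), `n_expressed`, and `family_summary` (or NULL).
#' @export
sharing_table <- function(profiles, family = NULL) {
  m <- profile_matrix(profiles)
  expressed <- m[rowSums(m) > 0, , drop = FALSE]
  n_exp <- nrow(expressed)
  subs <- apply(expressed > 0, 1, function(z)
    paste(TISSUES[z], collapse = "+"))
  tab <- table(subs)
  subsets <- data.frame(subset = names(tab), n_genes = as.integer(tab),
                        percentage = round_half_up(
                          100 * as.integer(tab) / n_exp, 2),
                        stringsAsFactors = FALSE)
  subsets <- subsets[order(-subsets$n_genes, subsets$subset), ]
  rownames(subsets) <- NULL
  fam_sum <- NULL
  if (!is.null(family)) {
    fam_of <- setNames(family$family, family$gene_id)
    fams <- c("AP2", "DREB", "ERF", "RAV", "Soloist")
    # the ERF family splits into its subfamilies when given as such
    gf <- fam_of[rownames(expressed)]
    rows <- lapply(fams, function(f) {
      sel <- expressed[which(gf == f), , drop = FALSE]
      data.frame(type = f, t(colSums(sel > 0)), type_num = nrow(sel),
                 percentage = round_half_up(100 * nrow(sel) / n_exp, 1),
                 stringsAsFactors = FALSE)
    })
    fam_sum <- do.call(rbind, rows)
    names(fam_sum) <- c("type", TISSUES, "type_num", "percentage")
  }
  structure(list(subsets = subsets, n_expressed = n_exp,
                 family_summary = fam_sum), class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("tissue sharing over", x$n_expressed, "expressed genes\n")
  print(head(x$subsets, 10))
  if (!is.null(x$family_summary)) {
    cat("family summary:\n"); print(x$family_summary)
  }
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment coefficient; zero variance in either vector is
#' an explicit error (an undefined correlation, never reported as 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return coefficient in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  cor(x, y)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative average-linkage clustering at distance 1 - PCC between
#' gene profiles.  Constant profiles (undefined PCC) are excluded with a
#' warning.  The dendrogram is returned both as an `hclust` and as a
#' newick-exportable `phylo`, together with the leaf-ordered count matrix
#' for heatmap export.
#'
#' @param profiles expression profiles (>= 2 non-constant).
#' @return list of class `expression_clustering`: `hclust`, `dendrogram`
#'   (`ape::phylo`), `order` (gene ids in leaf order), `ordered_matrix`,
#'   `excluded`.
#' @export
cluster_profiles <- function(profiles) {
  m <- profile_matrix(profiles)
  constant <- apply(m, 1, sd) == 0
  if (any(constant))
    warning("excluding constant profile(s): ",
            paste(rownames(m)[constant], collapse = ", "))
  m <- m[!constant, , drop = FALSE]
  if (nrow(m) < 2) stop("need >= 2 profiles with variance", call. = FALSE)
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  list_out <- list(hclust = hc, dendrogram = ape::as.phylo(hc),
                   order = rownames(m)[hc$order],
                   ordered_matrix = m[hc$order, , drop = FALSE],
                   excluded = rownames(profile_matrix(profiles))[constant])
  class(list_out) <- "expression_clustering"
  list_out
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("<expression clustering>  %d genes, average linkage on 1-PCC\n",
              length(x$order)))
  invisible(x)
}
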