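#' Generate synthetic CDS sequences for a gene set
#'
#' Random nucleotide sequences (no codon structure is emulated); ESTs are
#' later drawn as substrings, so mapping truth depends only on sequence
#' identity, not on coding content.
#'
#' @param gene_ids character vector.
#' @param len_range CDS length range in bp.
#' @param seed integer seed.
#' @return named character vector of DNA sequences.
#' @export
generate_cds <- function(gene_ids, len_range = c(600, 1500), seed = 4) {
  with_seed(seed, {
    setNames(vapply(seq_along(gene_ids), function(i) {
      paste(sample(c("A", "C", "G", "T"),
                   sample(len_range[1]:len_range[2], 1),
                   replace = TRUE), collapse = "")
    }, character(1)), gene_ids)
  })
}

#' Draw an expression design for a survey
#'
#' A random subset of genes is expressed; each expressed gene is active in
#' a random subset of the six tissues with negative-binomial mean tag
#' counts drawn uniformly from `mean_range`.
#'
#' @param gene_ids character vector.
#' @param n_expressed number of expressed genes (default 174, a typical
#'   EST-detectable fraction of a ~290-gene family).
#' @param p_tissue probability a tissue is active for an expressed gene.
#' @param mean_range range of per-tissue mean counts.
#' @param seed integer seed.
#' @return gene x tissue numeric matrix of expected EST counts (zero rows
#'   for unexpressed genes are omitted).
#' @export
make_expression_design <- function(gene_ids,
                                   n_expressed = min(174, length(gene_ids)),
                                   p_tissue = 0.6, mean_range = c(3, 30),
                                   seed = 5) {
  with_seed(seed, {
    sel <- sort(sample(length(gene_ids), n_expressed))
    m <- matrix(0, n_expressed, 6,
                dimnames = list(gene_ids[sel], TISSUES))
    for (i in seq_len(n_expressed)) {
      act <- runif(6) < p_tissue
      if (!any(act)) act[sample(6, 1)] <- TRUE
      m[i, act] <- round(runif(sum(act), mean_range[1], mean_range[2]), 1)
    }
    m
  })
}

#' Generate an EST library from expression means
#'
#' Per gene and tissue the read count is drawn from a negative binomial
#' with the stated mean and dispersion (variance = mu + dispersion * mu^2);
#' each read is a contiguous CDS substring with per-base substitution
#' errors at `error_rate`.  The manifest maps every read to its tissue.
#'
#' @param expression_means gene x tissue matrix (colnames must be the six
#'   tissue types; rownames must have a CDS).
#' @param cds named DNA vector.
#' @param read_len read length range in bp.
#' @param error_rate per-base substitution probability (< 0.1).
#' @param dispersion negative-binomial dispersion (default 0.3).
#' @param seed integer seed.
#' @return list with `ests` (named DNA vector), `manifest` (est_id,
#'   tissue) and `truth` (est_id, gene_id).
#' @export
generate_est_library <- function(expression_means, cds,
                                 read_len = c(150, 400), error_rate = 0.01,
                                 dispersion = 0.3, seed = 6) {
  if (error_rate >= 0.1) stop("error_rate must be < 0.1", call. = FALSE)
  if (!identical(colnames(expression_means), TISSUES))
    stop("expression_means columns must be exactly: ",
         paste(TISSUES, collapse = ", "), call. = FALSE)
  missing_cds <- setdiff(rownames(expression_means), names(cds))
  if (length(missing_cds))
    stop("no CDS for gene(s): ", paste(missing_cds, collapse = ", "),
         call. = FALSE)
  nt <- c("A", "C", "G", "T")
  with_seed(seed, {
    acc <- vector("list", 2048L); n_acc <- 0L
    for (g in rownames(expression_means)) {
      s <- cds[[g]]; slen <- nchar(s)
      for (t in TISSUES) {
        mu <- expression_means[g, t]
        if (mu <= 0) next
        cnt <- rnbinom(1, mu = mu, size = 1 / dispersion)
        if (cnt == 0) next
        for (k in seq_len(cnt)) {
          rl <- min(sample(read_len[1]:read_len[2], 1), slen)
          st <- sample(slen - rl + 1L, 1)
          read <- substr(s, st, st + rl - 1L)
          if (error_rate > 0) {
            b <- strsplit(read, "")[[1]]
            hit <- which(runif(rl) < error_rate)
            for (p in hit) b[p] <- sample(setdiff(nt, b[p]), 1)
            read <- paste(b, collapse = "")
          }
          n_acc <- n_acc + 1L
          if (n_acc > length(acc)) acc <- c(acc, vector("list",
                                                        length(acc)))
          acc[[n_acc]] <- c(read, t, g)
        }
      }
    }
    acc <- acc[seq_len(n_acc)]
    ests <- vapply(acc, `[`, character(1), 1)
    tissue <- vapply(acc, `[`, character(1), 2)
    src <- vapply(acc, `[`, character(1), 3)
    ids <- sprintf("EST%06d", seq_along(ests))
    list(ests = setNames(ests, ids),
         manifest = data.frame(est_id = ids, tissue = tissue,
                               stringsAsFactors = FALSE),
         truth = data.frame(est_id = ids, gene_id = src,
                            stringsAsFactors = FALSE))
  })
}

#' Generate an alignment with a planted conserved block
#'
#' Columns outside the block are independent uniform residues per
#' sequence; inside the block, `round(conservation * n_seq)` sequences
#' carry the consensus residue and the rest a random alternative, so every
#' block column has a known, deterministic conservation score.  An
#' optional short element (e.g. `WLG` or its `HLG` variant) can replace
#' part of the block consensus in every sequence that carries it.
#'
#' @param n_seq number of sequences.
#' @param block_len planted block length.
#' @param conservation per-column fraction of consensus residues.
#' @param flank columns of unconserved sequence on each side.
#' @param element optional residue string written into the block consensus.
#' @param seed integer seed.
#' @return named character vector (an aligned set, no gaps).
#' @export
generate_motif_alignment <- function(n_seq = 10, block_len = 50,
                                     conservation = 0.95, flank = 35,
                                     element = NULL, seed = 7) {
  with_seed(seed, {
    cons <- sample(AA20, block_len, replace = TRUE)
    if (!is.null(element)) {
      el <- strsplit(element, "")[[1]]
      if (length(el) > block_len) stop("element longer than block")
      cons[seq_along(el) + 2L] <- el
    }
    k <- max(1L, round(conservation * n_seq))
    m <- matrix("", n_seq, 2 * flank + block_len)
    for (j in seq_len(flank))
      m[, j] <- sample(AA20, n_seq, replace = TRUE)
    for (j in seq_len(block_len)) {
      col <- rep(cons[j], n_seq)
      off <- sample(n_seq, n_seq - k)
      for (i in off) col[i] <- sample(setdiff(AA20, cons[j]), 1)
      m[, flank + j] <- col
    }
    for (j in seq_len(flank))
      m[, flank + block_len + j] <- sample(AA20, n_seq, replace = TRUE)
    setNames(apply(m, 1, paste, collapse = ""),
             sprintf("seq%02d", seq_len(n_seq)))
  })
}
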