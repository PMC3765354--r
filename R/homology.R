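# k-mer sets used to prefilter candidate pairs before full alignment;
# homologs above the survey's identity bars always share exact k-mers,
# unrelated background pairs essentially never do
kmer_set <- function(seq, k = 6) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

candidate_partners <- function(a_seqs, b_seqs, k = 6, min_shared = 1) {
  kb <- lapply(b_seqs, kmer_set, k = k)
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seq_along(kb)) {
    for (km in kb[[j]]) {
      index[[km]] <- c(index[[km]], j)
    }
  }
  lapply(a_seqs, function(s) {
    hits <- unlist(lapply(kmer_set(s, k), function(km) index[[km]]),
                   use.names = FALSE)
    if (!length(hits)) return(integer(0))
    tab <- tabulate(hits, nbins = length(b_seqs))
    which(tab >= min_shared)
  })
}

best_hit_pairs <- function(a_seqs, b_seqs, min_identity, max_e, relation,
                           exclude_self = FALSE) {
  empty <- data.frame(idA = character(), idB = character(),
                      relation = character(), identity = numeric(),
                      evalue_surrogate = numeric(), stringsAsFactors = FALSE)
  if (!length(a_seqs) || !length(b_seqs)) return(empty)
  cand <- candidate_partners(a_seqs, b_seqs)
  rows <- list()
  for (i in seq_along(a_seqs)) {
    js <- cand[[i]]
    if (exclude_self)
      js <- js[names(b_seqs)[js] != names(a_seqs)[i]]
    if (!length(js)) next
    al <- align_batch_aa(b_seqs[js], a_seqs[[i]])
    k <- order(-al$score, names(b_seqs)[js])[1]
    ev <- alignment_evalue(al$score[k], nchar(a_seqs[[i]]),
                           nchar(b_seqs[[js[k]]]))
    if (al$identity[k] >= min_identity && ev <= max_e)
      rows[[length(rows) + 1L]] <-
        data.frame(idA = names(a_seqs)[i], idB = names(b_seqs)[js[k]],
                   relation = relation, identity = al$identity[k],
                   evalue_surrogate = ev, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species ortholog calling by best hit above an identity bar
#'
#' For each gene of species A the best-scoring species-B gene is kept when
#' global-alignment identity reaches `min_identity` (inclusive) and the
#' E-value surrogate is at most `max_e`.  The map is best-hit, not
#' reciprocal, so several A genes may share one B partner (the expected
#' pattern after whole-genome triplication).
#'
#' @param speciesA,speciesB named protein vectors with disjoint id
#'   namespaces.
#' @param min_identity percent identity bar (default 75).
#' @param max_e E-value surrogate gate (default 1e-10).
#' @return data.frame: idA, idB, relation, identity, evalue_surrogate.
#' @export
find_orthologs <- function(speciesA, speciesB, min_identity = 75,
                           max_e = 1e-10) {
  if (length(intersect(names(speciesA), names(speciesB))))
    stop("species id namespaces must be disjoint", call. = FALSE)
  best_hit_pairs(speciesA, speciesB, min_identity, max_e, "ortholog")
}

#' Within-species paralog calling
#'
#' Every gene's best-scoring partner (self excluded) is retained when
#' identity reaches `min_identity`; both orientations of a reciprocal pair
#' are reported.
#'
#' @param species named protein vector.
#' @param min_identity percent identity bar (default 80).
#' @param max_e E-value surrogate gate (default 1e-10).
#' @export
find_paralogs <- function(species, min_identity = 80, max_e = 1e-10) {
  best_hit_pairs(species, species, min_identity, max_e, "paralog",
                 exclude_self = TRUE)
}

#' Near-identical duplicate calling
#'
#' As [find_paralogs()] with the stricter near-identity bar (default 95).
#' `dedupe = TRUE` collapses the two orientations of a reciprocal pair to
#' one row (idA < idB).
#'
#' @inheritParams find_paralogs
#' @param dedupe collapse reciprocal orientations.
#' @export
find_duplicates <- function(species, min_identity = 95, max_e = 1e-10,
                            dedupe = FALSE) {
  out <- best_hit_pairs(species, species, min_identity, max_e, "duplicate",
                        exclude_self = TRUE)
  if (dedupe && nrow(out)) {
    key <- ifelse(out$idA < out$idB, paste(out$idA, out$idB),
                  paste(out$idB, out$idA))
    out <- out[!duplicated(key), , drop = FALSE]
    swap <- out$idA > out$idB
    tmp <- out$idA[swap]
    out$idA[swap] <- out$idB[swap]
    out$idB[swap] <- tmp
    out <- out[order(out$idA), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
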