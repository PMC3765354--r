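# Shared fixtures, built once per test session.  Everything is generated
# in code at fixed seeds; no data files.

fix_models <- default_domain_models(seed = 97)
fix_panel <- make_reference_panel(fix_models, seed = 97)
fix_calibrated <- lapply(fix_models, calibrate_threshold, n_decoys = 2000,
                         seed = 1)

fix_proteome <- generate_proteome(c(ERF = 24, AP2 = 6, RAV = 4, Soloist = 1),
                                  fix_models, fix_panel, seed = 1)
fix_hits <- scan_proteome(fix_proteome$proteins, fix_calibrated)
fix_calls <- classify_proteins(fix_proteome$proteins, fix_hits, fix_panel)

# independently written affine-gap alignment scorer (plain R dynamic
# program over explicit match/insert/delete states) used as the oracle for
# the C alignment engine
oracle_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  sm <- erfsurvey:::get_submat("BLOSUM62")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    Ix[i + 1, 1] <- -gap_open - i * gap_extend
  }
  for (j in seq_len(m)) {
    Iy[1, j + 1] <- -gap_open - j * gap_extend
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[x[i], y[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# exhaustive enumeration of every gapped alignment (monotone path in the
# edit grid), scoring gap runs with the affine rule; feasible for very
# short sequences only -- validates the R dynamic program itself
enumerate_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  sm <- erfsurvey:::get_submat("BLOSUM62")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(x) && j > length(y)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(x) && j <= length(y))
      rec(i + 1, j + 1, score + sm[x[i], y[j]], "M")
    if (i <= length(x))
      rec(i + 1, j, score - (if (state == "Ix") gap_extend
                             else gap_open + gap_extend), "Ix")
    if (j <= length(y))
      rec(i, j + 1, score - (if (state == "Iy") gap_extend
                             else gap_open + gap_extend), "Iy")
  }
  rec(1, 1, 0, "M")
  best
}

random_protein_str <- function(len, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# printed chromosome-distribution counts of a ten-chromosome survey,
# expanded into per-gene calls + loci (used to exercise the table op on a
# published-shape input)
printed_distribution_fixture <- function() {
  counts <- rbind(
    A01 = c(9, 16, 3, 0, 0),  A02 = c(10, 16, 5, 2, 0),
    A03 = c(16, 20, 5, 0, 0), A04 = c(9, 6, 0, 0, 0),
    A05 = c(7, 9, 3, 2, 0),   A06 = c(6, 11, 3, 6, 0),
    A07 = c(15, 15, 4, 0, 0), A08 = c(12, 15, 2, 2, 1),
    A09 = c(18, 18, 2, 2, 0), A10 = c(5, 11, 2, 0, 0))
  colnames(counts) <- c("DREB", "ERF", "AP2", "RAV", "Soloist")
  gene_id <- character(0); chrom <- character(0)
  family <- character(0); subfam <- character(0)
  n <- 0
  for (ch in rownames(counts)) {
    for (ty in colnames(counts)) {
      k <- counts[ch, ty]
      if (k == 0) next
      ids <- sprintf("g%03d", n + seq_len(k)); n <- n + k
      gene_id <- c(gene_id, ids); chrom <- c(chrom, rep(ch, k))
      family <- c(family, rep(if (ty %in% c("DREB", "ERF")) "ERF" else ty, k))
      subfam <- c(subfam, rep(if (ty %in% c("DREB", "ERF")) ty else "n/a", k))
    }
  }
  calls <- data.frame(gene_id = gene_id, family = family,
                      subfamily = subfam, stringsAsFactors = FALSE)
  loci <- data.frame(gene_id = gene_id, chrom = chrom,
                     start = seq_along(gene_id) * 10000L,
                     end = seq_along(gene_id) * 10000L + 2000L,
                     strand = "+", stringsAsFactors = FALSE)
  list(calls = calls, loci = loci, counts = counts)
}

# profiles matching a printed six-tissue family expression summary:
# 174 expressed genes, 12 AP2 / 58 DREB / 96 ERF / 7 RAV / 1 Soloist
printed_expression_fixture <- function() {
  fam <- rep(c("AP2", "DREB", "ERF", "RAV", "Soloist"),
             c(12, 58, 96, 7, 1))
  ids <- sprintf("e%03d", seq_along(fam))
  prof <- data.frame(gene_id = ids, bud = 0L, flower = 0L, leaf = 0L,
                     root = 0L, seed = 0L, silique = 0L,
                     stringsAsFactors = FALSE)
  # subset membership of a published sharing pattern: 11 genes in all six
  # tissues, 23 in leaf+root+seed, 17 in flower+leaf+root+seed, 13 root
  # only, remainder spread over other subsets
  prof[1:11, c("bud", "flower", "leaf", "root", "seed", "silique")] <- 1L
  prof[12:34, c("leaf", "root", "seed")] <- 1L
  prof[35:51, c("flower", "leaf", "root", "seed")] <- 1L
  prof[52:64, "root"] <- 1L
  prof[65:174, "bud"] <- 1L
  list(profiles = prof,
       family = data.frame(gene_id = ids, family = fam,
                           stringsAsFactors = FALSE))
}

# brute-force enumeration of maximal qualifying same-group runs, the
# oracle for the tandem-cluster caller
brute_runs <- function(loci, groups, max_intervening, max_span_kb) {
  m <- merge(loci, groups, by = "gene_id")
  out <- list()
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]; sub <- sub[order(sub$start), ]
    for (g in unique(sub$group)) {
      pos <- which(sub$group == g)
      if (length(pos) < 2) next
      valid <- function(run) all(
        diff(run) - 1 <= max_intervening &
          (sub$start[run[-1]] - sub$end[run[-length(run)]]) / 1000 <=
            max_span_kb)
      runs <- list()
      for (a in seq_len(length(pos) - 1)) for (b in (a + 1):length(pos)) {
        r <- pos[a:b]
        if (valid(r)) runs[[length(runs) + 1]] <- r
      }
      if (!length(runs)) next
      keep <- vapply(runs, function(r) !any(vapply(runs, function(s)
        length(s) > length(r) && all(r %in% s), logical(1))),
        logical(1))
      for (r in runs[keep])
        out[[length(out) + 1]] <- sort(sub$gene_id[r])
    }
  }
  out
}
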