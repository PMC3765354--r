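#' Substitute residues to reach a target identity
#'
#' Returns a copy of `seq` with `round(len * (1 - target_identity))`
#' positions substituted (no indels); substitutions are drawn uniformly
#' from the 19 alternative residues, so realized identity equals the target
#' within 1/len.
#'
#' @param seq protein sequence.
#' @param target_identity fraction in (0, 1].
#' @param seed integer seed.
#' @return mutated sequence of the same length.
#' @export
mutate_copy <- function(seq, target_identity, seed) {
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]", call. = FALSE)
  res <- strsplit(check_protein(seq), "")[[1]]
  n_sub <- round(length(res) * (1 - target_identity))
  if (n_sub == 0) return(paste(res, collapse = ""))
  with_seed(seed, {
    pos <- sample(length(res), n_sub)
    for (p in pos) res[p] <- sample(setdiff(AA20, res[p]), 1)
    paste(res, collapse = "")
  })
}

# deterministic largest-remainder allocation of n items to weighted bins
alloc_counts <- function(n, weights) {
  if (n == 0) return(setNames(rep(0L, length(weights)), names(weights)))
  q <- n * weights / sum(weights)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(-(q - k), seq_along(q))
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(k), names(weights))
}

#' Build the labelled reference panel of group exemplars
#'
#' One exemplar AP2-domain sequence per group (DREB-A1..A6, ERF-B1..B6,
#' AP2-R1, AP2-R2, RAV, Soloist), sampled from the AP2 domain model; the
#' Soloist exemplar is sampled at elevated temperature so it remains
#' detectable but diverges from every ERF group.  Full-length AP2-family
#' reference proteins (two domains each) support the single-domain rescue
#' rule, and a B3 exemplar supports RAV gene construction.
#'
#' @param models list with `AP2` and `B3` domain models
#'   (see [default_domain_models()]).
#' @param seed integer seed.
#' @param soloist_temperature sampling temperature for the Soloist
#'   exemplar, default 1.3.
#' @return list of class `reference_panel`: `domains` (named vector, 15
#'   groups), `ap2_second` (second AP2 domain per AP2 group), `ap2_full`
#'   (full-length AP2-family references), `b3`, `soloist_reference`.
#' @export
make_reference_panel <- function(models = default_domain_models(),
                                 seed = 97, soloist_temperature = 1.3) {
  if (!all(c("AP2", "B3") %in% names(models)))
    stop("models must contain AP2 and B3", call. = FALSE)
  doms <- setNames(character(length(GROUPS_ALL)), GROUPS_ALL)
  for (i in seq_along(GROUPS_ALL)) {
    g <- GROUPS_ALL[i]
    if (g == "Soloist") {
      doms[g] <- sample_soloist(models$AP2, substream(seed, 100 + i),
                                soloist_temperature)
    } else {
      doms[g] <- sample_exemplar(models$AP2, substream(seed, 100 + i))
    }
  }
  ap2_second <- setNames(c(sample_exemplar(models$AP2,
                                           substream(seed, 201)),
                           sample_exemplar(models$AP2,
                                           substream(seed, 202))),
                         c("AP2-R1", "AP2-R2"))
  b3 <- sample_exemplar(models$B3, substream(seed, 301))
  ap2_full <- setNames(vapply(c("AP2-R1", "AP2-R2"), function(g) {
    with_seed(substream(seed, 401 + match(g, c("AP2-R1", "AP2-R2"))), {
      paste0(random_protein(40), doms[g], random_protein(20),
             ap2_second[g], random_protein(40))
    })
  }, character(1)), c("AP2-R1", "AP2-R2"))
  structure(list(domains = doms, ap2_second = ap2_second,
                 ap2_full = ap2_full, b3 = b3,
                 soloist_reference = "Soloist"),
            class = "reference_panel")
}

# Group exemplars represent strongly conserved real domain instances, so
# an unconstrained PFM sample that happens to pick rare residues at many
# positions is rejected: resample (deterministic seed sequence) until the
# self-score reaches 1.15 bits per column (an average draw scores ~1.3)
sample_exemplar <- function(model, seed, min_bits_per_col = 1.15,
                            max_tries = 60) {
  lo <- min_bits_per_col * model$length
  for (k in seq_len(max_tries)) {
    s <- sample_domain(model, substream(seed, 4000 + k))
    if (score_window(model, s) >= lo) return(s)
  }
  s
}

# Soloist exemplar: sampled at elevated temperature, accepted when its
# self-score lands in a band that keeps it detectable by a calibrated scan
# yet well below a typical within-group hit (0.70-1.00 bits per column;
# deterministic retry sequence)
sample_soloist <- function(model, seed, temperature, max_tries = 60) {
  lo <- 0.70 * model$length
  hi <- 1.00 * model$length
  for (k in seq_len(max_tries)) {
    s <- sample_domain(model, substream(seed, 7000 + k), temperature)
    sc <- score_window(model, s)
    if (sc >= lo && sc <= hi) return(s)
  }
  s
}

#' Generate a synthetic proteome with planted domain architectures
#'
#' Emulates the domain-architecture composition of an AP2/ERF superfamily
#' survey: ERF-family genes carry one AP2 domain, AP2-family genes two,
#' RAV genes one AP2 plus one B3, and the Soloist a single divergent AP2.
#' Each gene's domain(s) are mutated copies (at `divergence`) of its
#' group's panel exemplar, embedded in uniform-background flanks.  Near
#' identical duplicate pairs and high-identity paralog pairs are planted
#' inside the family counts.
#'
#' @param n_per_family named counts for ERF, AP2, RAV, Soloist.  The
#'   default mirrors the survey census this generator emulates:
#'   248/29/14/1.
#' @param models domain models (AP2, B3).
#' @param panel a `reference_panel`; built from `models` when NULL.
#' @param divergence fraction of domain residues mutated away from the
#'   exemplar (default 0.1).
#' @param background_len range of flank lengths.
#' @param duplicate_identities identities (percent) of planted duplicate
#'   pairs, carved out of the ERF count.
#' @param paralog_identities identities (percent) of additional planted
#'   paralog pairs.
#' @param seed integer seed.
#' @return list with `proteins` (named character vector) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_proteome <- function(n_per_family = c(ERF = 248, AP2 = 29,
                                               RAV = 14, Soloist = 1),
                              models = default_domain_models(),
                              panel = NULL,
                              divergence = 0.1,
                              background_len = c(30, 120),
                              duplicate_identities = c(100, 100, 100, 97.65,
                                                       99.2, 95.6, 100),
                              paralog_identities = c(85, 88, 90, 92),
                              seed = 1) {
  if (!length(models)) stop("empty model set", call. = FALSE)
  if (any(n_per_family < 0)) stop("counts must be >= 0", call. = FALSE)
  if (is.null(panel)) panel <- make_reference_panel(models, seed = seed)
  fams <- c("ERF", "AP2", "RAV", "Soloist")
  n <- setNames(rep(0L, 4), fams)
  n[names(n_per_family)] <- as.integer(n_per_family)

  # per-group allocation: DREB and ERF-subfamily groups share the ERF count
  erf_groups <- alloc_counts(n[["ERF"]],
                             setNames(c(rep(109 / 6, 6), rep(139 / 6, 6)),
                                      c(GROUPS_DREB, GROUPS_ERF)))
  ap2_groups <- alloc_counts(n[["AP2"]], setNames(c(1, 1),
                                                  c("AP2-R1", "AP2-R2")))
  group_of <- c(rep(names(erf_groups), erf_groups),
                rep(names(ap2_groups), ap2_groups),
                rep("RAV", n[["RAV"]]), rep("Soloist", n[["Soloist"]]))
  total <- length(group_of)
  if (total == 0) {
    return(list(proteins = setNames(character(0), character(0)),
                truth = empty_truth(seed)))
  }
  ids <- sprintf("Br%03d", seq_len(total))

  proteins <- setNames(character(total), ids)
  arch <- vector("list", total)
  for (i in seq_len(total)) {
    g <- group_of[i]
    s <- substream(seed, 1000 + i)
    dom1 <- mutate_copy(panel$domains[[g]], 1 - divergence, s)
    parts <- with_seed(substream(seed, 5000 + i), {
      lf <- sample(background_len[1]:background_len[2], 2, replace = TRUE)
      lk <- sample(10:30, 1)
      list(f1 = random_protein(lf[1]), f2 = random_protein(lf[2]), link = lk)
    })
    if (g %in% c("AP2-R1", "AP2-R2")) {
      dom2 <- mutate_copy(panel$ap2_second[[g]], 1 - divergence,
                          substream(seed, 2000 + i))
      linker <- with_seed(substream(seed, 6000 + i),
                          random_protein(parts$link))
      seqs <- paste0(parts$f1, dom1, linker, dom2, parts$f2)
      a1 <- nchar(parts$f1) + 1L
      a2 <- a1 + nchar(dom1) + nchar(linker)
      arch[[i]] <- data.frame(gene_id = ids[i], domain = c("AP2", "AP2"),
                              start = c(a1, a2),
                              end = c(a1 + nchar(dom1) - 1L,
                                      a2 + nchar(dom2) - 1L))
    } else if (g == "RAV") {
      domb <- mutate_copy(panel$b3, 1 - divergence, substream(seed, 3000 + i))
      linker <- with_seed(substream(seed, 6000 + i),
                          random_protein(parts$link))
      seqs <- paste0(parts$f1, dom1, linker, domb, parts$f2)
      a1 <- nchar(parts$f1) + 1L
      a2 <- a1 + nchar(dom1) + nchar(linker)
      arch[[i]] <- data.frame(gene_id = ids[i], domain = c("AP2", "B3"),
                              start = c(a1, a2),
                              end = c(a1 + nchar(dom1) - 1L,
                                      a2 + nchar(domb) - 1L))
    } else {
      seqs <- paste0(parts$f1, dom1, parts$f2)
      a1 <- nchar(parts$f1) + 1L
      arch[[i]] <- data.frame(gene_id = ids[i], domain = "AP2",
                              start = a1, end = a1 + nchar(dom1) - 1L)
    }
    proteins[i] <- seqs
  }

  # plant duplicate pairs (and extra paralog pairs) inside the ERF groups:
  # overwrite the second member of a pair with a mutated copy of the first
  erf_idx <- which(group_of %in% c(GROUPS_DREB, GROUPS_ERF))
  dup <- plant_pairs(proteins, arch, group_of, erf_idx,
                     duplicate_identities, seed, 7000)
  proteins <- dup$proteins; arch <- dup$arch
  par <- plant_pairs(dup$proteins, dup$arch, group_of,
                     setdiff(erf_idx, dup$used), paralog_identities,
                     seed, 8000)
  proteins <- par$proteins; arch <- par$arch

  truth <- structure(list(
    architectures = do.call(rbind, arch),
    family_labels = data.frame(gene_id = ids,
                               family = group_to_family(group_of),
                               group = group_of, stringsAsFactors = FALSE),
    ortholog_pairs = NULL,
    duplicate_pairs = dup$pairs,
    paralog_pairs = rbind(dup$pairs, par$pairs),
    tandem_clusters = NULL,
    expression_means = NULL,
    rng_seed = seed), class = "synthetic_truth")
  list(proteins = proteins, truth = truth)
}

empty_truth <- function(seed) {
  structure(list(architectures = data.frame(gene_id = character(),
                                            domain = character(),
                                            start = integer(),
                                            end = integer()),
                 family_labels = data.frame(gene_id = character(),
                                            family = character(),
                                            group = character()),
                 ortholog_pairs = NULL, duplicate_pairs = NULL,
                 paralog_pairs = NULL, tandem_clusters = NULL,
                 expression_means = NULL, rng_seed = seed),
            class = "synthetic_truth")
}

plant_pairs <- function(proteins, arch, group_of, pool, identities,
                        seed, offset) {
  pairs <- data.frame(idA = character(), idB = character(),
                      planted_identity = numeric())
  used <- integer(0)
  if (!length(identities) || length(pool) < 2 * length(identities))
    return(list(proteins = proteins, arch = arch, pairs = pairs, used = used))
  ids <- names(proteins)
  picks <- with_seed(substream(seed, offset), {
    # pairs must share a group so cluster/group truth stays coherent
    out <- list()
    avail <- pool
    for (k in seq_along(identities)) {
      gcounts <- table(group_of[avail])
      gs <- names(gcounts)[gcounts >= 2]
      g <- sample(gs, 1)
      cand <- avail[group_of[avail] == g]
      ij <- sample(cand, 2)
      avail <- setdiff(avail, ij)
      out[[k]] <- ij
    }
    out
  })
  for (k in seq_along(identities)) {
    i <- picks[[k]][1]; j <- picks[[k]][2]
    proteins[j] <- mutate_copy(proteins[i], identities[k] / 100,
                               substream(seed, offset + 10 + k))
    a <- arch[[i]]; a$gene_id <- ids[j]
    arch[[j]] <- a
    pairs <- rbind(pairs, data.frame(idA = ids[i], idB = ids[j],
                                     planted_identity = identities[k]))
    used <- c(used, i, j)
  }
  list(proteins = proteins, arch = arch, pairs = pairs, used = used)
}

#' Generate a diverged second species with known ortholog pairs
#'
#' Each selected gene is copied at `identity` (substitutions only) and
#' renamed into a disjoint id namespace, giving a one-to-one planted
#' ortholog map.
#'
#' @param proteins named protein vector (species A).
#' @param n number of genes to mirror (default all, capped at 214 to match
#'   a realistic cross-species recovery set).
#' @param identity planted identity fraction (default 0.85).
#' @param prefix id prefix for the new species.
#' @param seed integer seed.
#' @return list with `proteins` (species B) and `pairs` (idA, idB,
#'   planted_identity).
#' @export
generate_ortholog_set <- function(proteins, n = min(214, length(proteins)),
                                  identity = 0.85, prefix = "At", seed = 2) {
  n <- min(n, length(proteins))
  sel <- with_seed(substream(seed, 1), sort(sample(length(proteins), n)))
  ids_a <- names(proteins)[sel]
  ids_b <- sprintf("%s%03d", prefix, seq_len(n))
  out <- setNames(vapply(seq_len(n), function(k)
    mutate_copy(proteins[[sel[k]]], identity, substream(seed, 100 + k)),
    character(1)), ids_b)
  list(proteins = out,
       pairs = data.frame(idA = ids_a, idB = ids_b,
                          planted_identity = identity * 100,
                          stringsAsFactors = FALSE))
}
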