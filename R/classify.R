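#' Provisional family from domain architecture
#'
#' Two AP2 domains define the AP2 family; one AP2 plus one B3 the RAV
#' family; exactly one AP2 an ERF candidate; no AP2 means the protein is
#' outside the superfamily.  Three or more AP2 hits are returned as AP2
#' with a review flag.
#'
#' @param hits data.frame of domain hits for one protein (see
#'   [scan_protein()]).
#' @return list with `family` and `evidence` (rule identifier).
#' @export
classify_architecture <- function(hits) {
  if (nrow(hits) && length(unique(hits$protein_id)) > 1)
    stop("hits must belong to one protein", call. = FALSE)
  n_ap2 <- sum(hits$domain == "AP2")
  n_b3 <- sum(hits$domain == "B3")
  if (n_ap2 >= 3)
    return(list(family = "AP2", evidence = "arch:>=3xAP2:review"))
  if (n_ap2 == 2) return(list(family = "AP2", evidence = "arch:2xAP2"))
  if (n_ap2 == 1 && n_b3 >= 1)
    return(list(family = "RAV", evidence = "arch:AP2+B3"))
  if (n_ap2 == 1)
    return(list(family = "ERF-candidate", evidence = "arch:1xAP2"))
  list(family = "none", evidence = "arch:no-AP2")
}

#' Single-domain AP2 rescue rule
#'
#' A protein with a single AP2 domain is reassigned from ERF candidate to
#' the AP2 family when its best full-length global-alignment identity
#' against any AP2-family reference reaches `min_identity` (inclusive).
#'
#' @param protein full-length protein sequence.
#' @param ap2_family_refs named character vector of full-length AP2-family
#'   reference proteins.
#' @param min_identity percent identity threshold (default 60).
#' @return logical.
#' @export
rescue_single_domain_ap2 <- function(protein, ap2_family_refs,
                                     min_identity = 60) {
  if (!length(ap2_family_refs))
    stop("empty AP2 reference set", call. = FALSE)
  best <- max(align_batch_aa(ap2_family_refs, protein)$identity)
  best >= min_identity
}

#' Soloist detection
#'
#' An ERF candidate is the Soloist when the Soloist panel exemplar is its
#' best hit among all group exemplars and the identity reaches the floor.
#'
#' @param domain_seq the protein's AP2-domain region sequence.
#' @param panel a `reference_panel`.
#' @param min_identity identity floor (default 50).
#' @return logical.
#' @export
detect_soloist <- function(domain_seq, panel, min_identity = 50) {
  idy <- setNames(align_batch_aa(panel$domains, domain_seq)$identity,
                  names(panel$domains))
  best <- names(idy)[order(-idy, names(idy))][1]
  best == panel$soloist_reference && idy[best] >= min_identity
}

#' Nearest-exemplar group assignment
#'
#' Best global-alignment identity of the domain region against every panel
#' exemplar; ties broken by higher alignment score, then lexicographic
#' exemplar id.  Below `floor`, the gene stays unassigned.
#'
#' @param domain_seq domain-region sequence.
#' @param panel a `reference_panel`.
#' @param family restrict candidate exemplars to this family's groups
#'   (`"ERF"` considers the twelve DREB/ERF groups, `"AP2"` the two AP2
#'   groups); `NULL` considers all fifteen.
#' @param floor minimum identity, default 40.
#' @return list with `group`, `subfamily`, `identity`.
#' @export
assign_group <- function(domain_seq, panel, family = NULL, floor = 40) {
  cand <- switch(if (is.null(family)) "all" else family,
                 ERF = c(GROUPS_DREB, GROUPS_ERF),
                 AP2 = c("AP2-R1", "AP2-R2"),
                 RAV = "RAV",
                 Soloist = "Soloist",
                 GROUPS_ALL)
  res <- align_batch_aa(panel$domains[cand], domain_seq)
  idy <- setNames(res$identity, cand)
  sc <- setNames(res$score, cand)
  ord <- order(-idy, -sc, names(idy))
  best <- names(idy)[ord[1]]
  if (idy[best] < floor)
    return(list(group = "unassigned", subfamily = "n/a",
                identity = unname(idy[best])))
  list(group = best, subfamily = group_to_subfamily(best),
       identity = unname(idy[best]))
}

#' Classify a scanned proteome into families and groups
#'
#' Applies the rule cascade in fixed precedence: domain architecture,
#' Soloist check, single-domain AP2 rescue, then nearest-exemplar group
#' assignment.  Exactly one call per protein.
#'
#' @param proteins named protein vector.
#' @param hits data.frame of domain hits (see [scan_proteome()]).
#' @param panel a `reference_panel`.
#' @param rescue_identity full-length identity for the AP2 rescue
#'   (default 60).
#' @param soloist_floor Soloist identity floor (default 50).
#' @param group_floor group-assignment identity floor (default 40).
#' @return data.frame: gene_id, family, subfamily, group, evidence,
#'   identity.
#' @export
classify_proteins <- function(proteins, hits, panel, rescue_identity = 60,
                              soloist_floor = 50, group_floor = 40) {
  ids <- sort(names(proteins))
  rows <- lapply(ids, function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    arch <- classify_architecture(h)
    fam <- arch$family; evid <- arch$evidence
    if (fam == "none")
      return(data.frame(gene_id = id, family = "none", subfamily = "n/a",
                        group = "unassigned", evidence = evid,
                        identity = NA_real_, stringsAsFactors = FALSE))
    ap2h <- h[h$domain == "AP2", , drop = FALSE]
    domseq <- substr(proteins[[id]], ap2h$start[1], ap2h$end[1])
    if (fam == "ERF-candidate") {
      if (detect_soloist(domseq, panel, soloist_floor)) {
        g <- assign_group(domseq, panel, family = "Soloist",
                          floor = group_floor)
        return(data.frame(gene_id = id, family = "Soloist",
                          subfamily = "n/a", group = "Soloist",
                          evidence = "soloist:best-hit",
                          identity = g$identity, stringsAsFactors = FALSE))
      }
      if (rescue_single_domain_ap2(proteins[[id]], panel$ap2_full,
                                   rescue_identity)) {
        fam <- "AP2"; evid <- "rescue:ap2-similarity"
      }
    }
    if (fam %in% c("AP2", "ERF-candidate")) {
      gfam <- if (fam == "AP2") "AP2" else "ERF"
      g <- assign_group(domseq, panel, family = gfam, floor = group_floor)
      fam_final <- if (fam == "AP2") "AP2" else "ERF"
      return(data.frame(gene_id = id, family = fam_final,
                        subfamily = g$subfamily, group = g$group,
                        evidence = paste0(evid, "+group:",
                                          format(round(g$identity, 1))),
                        identity = g$identity, stringsAsFactors = FALSE))
    }
    # RAV
    g <- assign_group(domseq, panel, family = "RAV", floor = group_floor)
    data.frame(gene_id = id, family = "RAV", subfamily = "n/a",
               group = if (g$group == "unassigned") "unassigned" else "RAV",
               evidence = evid, identity = g$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family / subfamily / group census
#'
#' @param calls data.frame of family calls (one per gene).
#' @return list of class `erf_census`: `families`, `subfamilies`,
#'   `groups` (named counts) and `total`.
#' @export
census <- function(calls) {
  if (anyDuplicated(calls$gene_id))
    stop("more than one call per gene", call. = FALSE)
  fams <- c("ERF", "AP2", "RAV", "Soloist", "none")
  fam <- setNames(vapply(fams, function(f)
    sum(calls$family == f), integer(1)), fams)
  subs <- c("DREB", "ERF")
  sub <- setNames(vapply(subs, function(s)
    sum(calls$subfamily == s), integer(1)), subs)
  grp <- setNames(vapply(GROUPS_ALL, function(g)
    sum(calls$group == g), integer(1)), GROUPS_ALL)
  structure(list(families = fam, subfamilies = sub, groups = grp,
                 total = nrow(calls)), class = "erf_census")
}

#' @export
print.erf_census <- function(x, ...) {
  cat("AP2/ERF census:", x$total, "genes\n")
  print(x$families)
  cat("ERF subfamilies:\n"); print(x$subfamilies)
  cat("groups:\n"); print(x$groups)
  invisible(x)
}
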