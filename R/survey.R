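#' Survey configuration: every numeric gate in one place
#'
#' Defaults are the survey's standard printed thresholds: domain-scan
#' E-value 1e-4; EST eligibility E 1e-5 at identity 90 over >= 100 bp;
#' ortholog E 1e-10 at identity 75; paralog identity 80; duplicate
#' identity 95; 1000 bootstrap replicates with a 50 percent display floor;
#' AP2 rescue identity 60; group floor 40; tandem cluster rule 1
#' intervening gene / 100 kb.  Identity thresholds are inclusive (>=)
#' throughout.
#'
#' @param seed global RNG seed; all stage substreams derive from it.
#' @param scan_evalue,scan_decoys,database_size domain-scan calibration.
#' @param est_evalue,est_identity,est_overlap EST eligibility gates.
#' @param ortholog_evalue,ortholog_identity,paralog_identity,duplicate_identity
#'   homology gates.
#' @param bootstrap_replicates,bootstrap_floor bootstrap settings.
#' @param rescue_identity,soloist_floor,group_floor classification gates.
#' @param cluster_max_intervening,cluster_max_span_kb tandem-cluster rule.
#' @param motif_score_threshold,motif_max_gap conserved-block rule.
#' @param tree_taxa_cap build the display tree on at most this many
#'   domain sequences (a seeded subsample keeps at least one gene per
#'   group); `Inf` uses all.
#' @return object of class `survey_config`.
#' @export
survey_config <- function(seed = 1,
                          scan_evalue = 1e-4, scan_decoys = 2000,
                          database_size = 1e5,
                          est_evalue = 1e-5, est_identity = 90,
                          est_overlap = 100,
                          ortholog_evalue = 1e-10, ortholog_identity = 75,
                          paralog_identity = 80, duplicate_identity = 95,
                          bootstrap_replicates = 1000, bootstrap_floor = 50,
                          rescue_identity = 60, soloist_floor = 50,
                          group_floor = 40,
                          cluster_max_intervening = 1,
                          cluster_max_span_kb = 100,
                          motif_score_threshold = 0.8, motif_max_gap = 0.2,
                          tree_taxa_cap = 80) {
  cfg <- list(seed = seed, scan_evalue = scan_evalue,
              scan_decoys = scan_decoys, database_size = database_size,
              est_evalue = est_evalue, est_identity = est_identity,
              est_overlap = est_overlap,
              ortholog_evalue = ortholog_evalue,
              ortholog_identity = ortholog_identity,
              paralog_identity = paralog_identity,
              duplicate_identity = duplicate_identity,
              bootstrap_replicates = bootstrap_replicates,
              bootstrap_floor = bootstrap_floor,
              rescue_identity = rescue_identity,
              soloist_floor = soloist_floor, group_floor = group_floor,
              cluster_max_intervening = cluster_max_intervening,
              cluster_max_span_kb = cluster_max_span_kb,
              motif_score_threshold = motif_score_threshold,
              motif_max_gap = motif_max_gap,
              tree_taxa_cap = tree_taxa_cap)
  stopifnot(cfg$scan_evalue > 0, cfg$est_evalue > 0,
            cfg$ortholog_evalue > 0,
            cfg$est_identity >= 0, cfg$est_identity <= 100,
            cfg$ortholog_identity >= 0, cfg$ortholog_identity <= 100,
            cfg$paralog_identity >= 0, cfg$paralog_identity <= 100,
            cfg$duplicate_identity >= 0, cfg$duplicate_identity <= 100,
            cfg$bootstrap_replicates >= 1,
            cfg$motif_score_threshold >= 0, cfg$motif_score_threshold <= 1,
            cfg$motif_max_gap >= 0, cfg$motif_max_gap <= 1)
  structure(cfg, class = "survey_config")
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write / read a survey configuration (YAML, lossless round-trip)
#' @param config a `survey_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(survey_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config), precision = 15)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% 4294967291)
}

#' Generate a complete synthetic survey input bundle
#'
#' Builds every input the pipeline consumes, with ground truth: domain
#' models, reference panel, proteome with planted architectures and
#' duplicate/paralog pairs, a diverged second species with planted
#' orthologs, a 10-chromosome layout with planted tandem clusters and
#' unanchored scaffold genes, CDS sequences, an expression design and an
#' EST library.
#'
#' @param seed integer seed.
#' @param scale `"full"` (survey-scale census 248/29/14/1) or `"small"`
#'   (a fast miniature with the same structure).
#' @return list with `inputs` (everything [run_survey()] needs) and
#'   `truth` (a `synthetic_truth`).
#' @export
generate_survey_inputs <- function(seed = 1, scale = c("full", "small")) {
  scale <- match.arg(scale)
  n_fam <- if (scale == "full") c(ERF = 248, AP2 = 29, RAV = 14, Soloist = 1)
           else c(ERF = 24, AP2 = 6, RAV = 4, Soloist = 1)
  models <- default_domain_models(seed = substream(seed, 1))
  panel <- make_reference_panel(models, seed = substream(seed, 2))
  dup_ids <- if (scale == "full") c(100, 100, 100, 97.65, 99.2, 95.6, 100)
             else c(100, 97.65)
  par_ids <- if (scale == "full") c(85, 88, 90, 92) else 88
  prot <- generate_proteome(n_fam, models, panel,
                            duplicate_identities = dup_ids,
                            paralog_identities = par_ids,
                            seed = substream(seed, 3))
  orth <- generate_ortholog_set(prot$proteins,
                                n = if (scale == "full") 214
                                    else min(10, length(prot$proteins)),
                                seed = substream(seed, 4))
  cl_spec <- default_cluster_spec(prot$truth$family_labels,
                                  sizes = if (scale == "full")
                                    c(5, 3, 3, 2, 2) else c(2, 2),
                                  seed = substream(seed, 5))
  layout <- generate_genome_layout(names(prot$proteins),
                                   cluster_spec = cl_spec,
                                   n_scaffold = if (scale == "full") 3 else 1,
                                   seed = substream(seed, 6))
  layout_b <- generate_genome_layout(names(orth$proteins),
                                     n_chromosomes = 5,
                                     seed = substream(seed, 7))
  cds <- generate_cds(names(prot$proteins), seed = substream(seed, 8))
  means <- make_expression_design(names(prot$proteins),
                                  n_expressed = if (scale == "full") 174
                                                else min(8, length(cds)),
                                  seed = substream(seed, 9))
  lib <- generate_est_library(means, cds, seed = substream(seed, 10))
  truth <- prot$truth
  truth$ortholog_pairs <- orth$pairs
  truth$tandem_clusters <- layout$clusters
  truth$expression_means <- means
  list(inputs = list(proteins = prot$proteins, speciesB = orth$proteins,
                     loci = layout$loci, lociB = layout_b$loci,
                     cds = cds, ests = lib$ests, manifest = lib$manifest,
                     models = models, panel = panel),
       truth = truth, est_truth = lib$truth)
}

#' Run the end-to-end AP2/ERF survey
#'
#' Chains every stage: model calibration, domain scan, family/group
#' classification, homology calling (orthologs, paralogs, duplicates),
#' neighbor-joining phylogeny with bootstrap, per-group conserved motif
#' blocks, chromosome distribution with tandem clusters and synteny
#' links, and EST tissue expression profiling.  All randomness derives
#' from `config$seed`; two runs with the same inputs and config produce
#' identical reports.
#'
#' @param inputs list as produced by [generate_survey_inputs()] (fields
#'   `proteins`, `models`, `panel` required; `speciesB`, `loci`, `lociB`,
#'   `cds`, `ests`, `manifest` optional).
#' @param config a `survey_config`.
#' @return object of class `erf_survey`.
#' @export
run_survey <- function(inputs, config = survey_config()) {
  need <- c("proteins", "models", "panel")
  miss <- need[vapply(need, function(k) is.null(inputs[[k]]),
                      logical(1))]
  if (length(miss))
    stop("survey inputs missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  seed <- config$seed

  models <- lapply(inputs$models, calibrate_threshold,
                   n_decoys = config$scan_decoys,
                   target_evalue = config$scan_evalue,
                   database_size = config$database_size,
                   seed = substream(seed, 21))
  hits <- scan_proteome(inputs$proteins, models)
  calls <- classify_proteins(inputs$proteins, hits, inputs$panel,
                             rescue_identity = config$rescue_identity,
                             soloist_floor = config$soloist_floor,
                             group_floor = config$group_floor)
  cens <- census(calls)

  orthologs <- NULL
  if (!is.null(inputs$speciesB))
    orthologs <- find_orthologs(inputs$proteins, inputs$speciesB,
                                min_identity = config$ortholog_identity,
                                max_e = config$ortholog_evalue)
  paralogs <- find_paralogs(inputs$proteins,
                            min_identity = config$paralog_identity,
                            max_e = config$ortholog_evalue)
  duplicates <- find_duplicates(inputs$proteins,
                                min_identity = config$duplicate_identity,
                                max_e = config$ortholog_evalue)

  # domain-region sequences (first AP2 hit per gene) double as the
  # fixed-length alignment the tree and motif stages consume
  ap2 <- hits[hits$domain == "AP2", ]
  ap2 <- ap2[!duplicated(ap2$protein_id), ]
  domseqs <- setNames(substr(inputs$proteins[ap2$protein_id],
                             ap2$start, ap2$end), ap2$protein_id)
  phylo <- NULL
  if (length(domseqs) >= 4) {
    taxa <- names(domseqs)
    if (length(taxa) > config$tree_taxa_cap) {
      grp <- setNames(calls$group, calls$gene_id)[taxa]
      taxa <- with_seed(substream(seed, 22), {
        keep <- unlist(lapply(split(taxa, grp), function(g)
          sample(g, 1)))
        extra <- setdiff(taxa, keep)
        c(keep, sample(extra, max(0, min(length(extra),
                                         config$tree_taxa_cap -
                                           length(keep)))))
      })
      taxa <- sort(taxa)
    }
    phylo <- bootstrap_support(domseqs[taxa],
                               n_replicates = config$bootstrap_replicates,
                               seed = substream(seed, 23),
                               display_floor = config$bootstrap_floor)
  }

  groups_present <- setdiff(unique(calls$group), "unassigned")
  motif_blocks <- lapply(setNames(nm = sort(groups_present)), function(g) {
    ids <- calls$gene_id[calls$group == g]
    ids <- intersect(ids, names(domseqs))
    if (length(ids) < 2) return(NULL)
    prof <- column_conservation(domseqs[ids])
    suppressMessages(conserved_block(prof,
                                     config$motif_score_threshold,
                                     config$motif_max_gap))
  })

  distribution <- clusters <- links <- NULL
  if (!is.null(inputs$loci)) {
    distribution <- distribution_table(calls, inputs$loci)
    clusters <- tandem_clusters(inputs$loci, calls,
                                max_intervening =
                                  config$cluster_max_intervening,
                                max_span_kb = config$cluster_max_span_kb)
    if (!is.null(orthologs) && !is.null(inputs$lociB))
      links <- synteny_links(orthologs, inputs$loci, inputs$lociB)
  }

  expression <- NULL
  if (!is.null(inputs$ests) && length(inputs$ests)) {
    est_hits <- map_cds_to_ests(inputs$cds, inputs$ests, inputs$manifest,
                                min_identity = config$est_identity,
                                max_e = config$est_evalue,
                                min_overlap_bp = config$est_overlap)
    profiles <- tissue_counts(est_hits)
    # Table-3-style types: ERF genes split into their subfamilies
    type_of <- ifelse(calls$family == "ERF", calls$subfamily, calls$family)
    fam_map <- data.frame(gene_id = calls$gene_id, family = type_of,
                          stringsAsFactors = FALSE)
    expression <- list(
      hits = est_hits, profiles = profiles,
      totals = if (nrow(profiles)) tissue_totals(profiles) else NULL,
      sharing = if (nrow(profiles)) sharing_table(profiles, fam_map)
                else NULL,
      clustering = if (nrow(profiles) >= 2)
        suppressWarnings(tryCatch(cluster_profiles(profiles),
                                  error = function(e) NULL)) else NULL)
  }

  structure(list(census = cens, calls = calls, hits = hits,
                 orthologs = orthologs, paralogs = paralogs,
                 duplicates = duplicates, phylogeny = phylo,
                 motif_blocks = motif_blocks,
                 distribution = distribution, clusters = clusters,
                 synteny = links, expression = expression,
                 config = config,
                 provenance = list(seed = seed,
                                   config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "erfsurvey")))),
            class = "erf_survey")
}

#' @export
print.erf_survey <- function(x, ...) {
  cat("== AP2/ERF survey report ==\n")
  cat(sprintf("genes surveyed: %d  (seed %s, config %s)\n",
              x$census$total, format(x$provenance$seed),
              x$provenance$config_hash))
  print(x$census$families)
  if (!is.null(x$orthologs))
    cat("ortholog pairs:", nrow(x$orthologs), "\n")
  cat("paralog calls:", nrow(x$paralogs),
      " duplicate calls:", nrow(x$duplicates), "\n")
  if (!is.null(x$distribution))
    cat("placed genes:", x$distribution$grand_total,
        " scaffold:", length(x$distribution$scaffold),
        " tandem clusters:", length(x$clusters), "\n")
  if (!is.null(x$expression) && !is.null(x$expression$totals))
    cat("expressed genes:", nrow(x$expression$profiles), "\n")
  invisible(x)
}

#' @method summary erf_survey
#' @export
summary.erf_survey <- function(object, ...) {
  print(object)
  cat("\ngroup census:\n")
  print(object$census$groups)
  if (!is.null(object$expression) && !is.null(object$expression$sharing)) {
    cat("\nfamily expression summary:\n")
    print(object$expression$sharing$family_summary)
  }
  invisible(object)
}
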