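#' Chromosome-by-family distribution table
#'
#' Counts placed genes per chromosome per column (DREB, ERF, AP2, RAV,
#' Soloist) with row and column totals.  Scaffold genes are excluded from
#' chromosome rows but reported separately; genes with a locus but no
#' family call go to an exclusions report rather than being dropped.
#'
#' @param calls data.frame of family calls (gene_id, family, subfamily).
#' @param loci data.frame of gene loci.
#' @return list of class `distribution_table`: `table` (data.frame with a
#'   Total row and column), `scaffold` (gene ids), `exclusions` (gene ids
#'   without calls), `grand_total` (placed, called genes).
#' @export
distribution_table <- function(calls, loci) {
  cols <- c("DREB", "ERF", "AP2", "RAV", "Soloist")
  merged <- merge(loci, calls, by = "gene_id", all.x = TRUE)
  exclusions <- merged$gene_id[is.na(merged$family)]
  merged <- merged[!is.na(merged$family) & merged$family != "none", ]
  # split the ERF family into its two subfamilies for the table columns
  colname <- ifelse(merged$family == "ERF", merged$subfamily, merged$family)
  scaffold <- merged$gene_id[merged$chrom == "scaffold"]
  placed <- merged[merged$chrom != "scaffold", ]
  pcol <- colname[merged$chrom != "scaffold"]
  chroms <- sort(unique(loci$chrom[loci$chrom != "scaffold"]))
  tab <- matrix(0L, length(chroms), length(cols),
                dimnames = list(chroms, cols))
  for (k in seq_len(nrow(placed))) {
    if (pcol[k] %in% cols)
      tab[placed$chrom[k], pcol[k]] <- tab[placed$chrom[k], pcol[k]] + 1L
  }
  df <- as.data.frame(tab)
  df$Total <- rowSums(tab)
  total_row <- c(colSums(tab), sum(tab))
  df <- rbind(df, Total = total_row)
  structure(list(table = df, scaffold = scaffold,
                 exclusions = exclusions, grand_total = sum(tab)),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  print(x$table)
  if (length(x$scaffold))
    cat("unanchored (scaffold):", paste(x$scaffold, collapse = ", "), "\n")
  if (length(x$exclusions))
    cat("excluded (no family call):",
        paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Tandem cluster detection
#'
#' Same-group genes on one chromosome form a cluster when each consecutive
#' pair (in coordinate order) is separated by at most `max_intervening`
#' other surveyed genes and at most `max_span_kb` kilobases; maximal
#' qualifying runs of two or more genes are reported.
#'
#' @param loci gene loci (scaffold genes are ignored).
#' @param group_calls data.frame with gene_id and group.
#' @param max_intervening allowed surveyed genes between cluster
#'   neighbours (default 1).
#' @param max_span_kb allowed gap between cluster neighbours, kb
#'   (default 100).
#' @return list of clusters; each element is a data.frame of the member
#'   loci with their group, in coordinate order.
#' @export
tandem_clusters <- function(loci, group_calls, max_intervening = 1,
                            max_span_kb = 100) {
  merged <- merge(loci, group_calls[c("gene_id", "group")], by = "gene_id")
  merged <- merged[merged$chrom != "scaffold", ]
  clusters <- list()
  for (ch in unique(merged$chrom)) {
    sub <- merged[merged$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    for (g in unique(sub$group)) {
      if (g %in% c("unassigned", NA)) next
      pos <- which(sub$group == g)
      if (length(pos) < 2) next
      # break the group's genes into maximal qualifying runs
      run <- pos[1]
      flush <- function(run) {
        if (length(run) >= 2)
          clusters[[length(clusters) + 1L]] <<- sub[run, ]
      }
      for (k in pos[-1]) {
        prev <- run[length(run)]
        gap_genes <- k - prev - 1L
        gap_kb <- (sub$start[k] - sub$end[prev]) / 1000
        if (gap_genes <= max_intervening && gap_kb <= max_span_kb) {
          run <- c(run, k)
        } else {
          flush(run)
          run <- k
        }
      }
      flush(run)
    }
  }
  clusters
}

#' Synteny link table for homology pairs
#'
#' One row per pair with both members' coordinates -- the data a circular
#' synteny plot would draw.  Pairs with a scaffold member are flagged, not
#' dropped; an unknown gene id is a named error.
#'
#' @param pairs homology pairs (idA, idB, ...).
#' @param lociA,lociB locus tables covering idA and idB respectively.
#' @return data.frame: idA, chromA, startA, idB, chromB, startB,
#'   scaffold_flag.
#' @export
synteny_links <- function(pairs, lociA, lociB = lociA) {
  empty <- data.frame(idA = character(), chromA = character(),
                      startA = integer(), idB = character(),
                      chromB = character(), startB = integer(),
                      scaffold_flag = logical(), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  ia <- match(pairs$idA, lociA$gene_id)
  ib <- match(pairs$idB, lociB$gene_id)
  if (anyNA(ia))
    stop("unknown gene id in pairs: ", pairs$idA[which(is.na(ia))[1]],
         call. = FALSE)
  if (anyNA(ib))
    stop("unknown gene id in pairs: ", pairs$idB[which(is.na(ib))[1]],
         call. = FALSE)
  data.frame(idA = pairs$idA, chromA = lociA$chrom[ia],
             startA = lociA$start[ia], idB = pairs$idB,
             chromB = lociB$chrom[ib], startB = lociB$start[ib],
             scaffold_flag = lociA$chrom[ia] == "scaffold" |
                             lociB$chrom[ib] == "scaffold",
             stringsAsFactors = FALSE)
}
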