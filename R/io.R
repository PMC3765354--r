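#' Read a protein or nucleotide FASTA file strictly
#'
#' Wraps the Biostrings readers with the pipeline's strictness rules:
#' duplicate sequence ids are rejected (they would make truth tables and
#' hit assignment ambiguous) and ids are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  out <- as.character(set)
  names(out) <- ids
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (length(seqs) && is.null(names(seqs)))
    stop("sequences must be named", call. = FALSE)
  set <- if (type == "AA") Biostrings::AAStringSet(unlist(as.character(seqs)))
         else Biostrings::DNAStringSet(unlist(as.character(seqs)))
  if (length(seqs)) names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a 5-column gene locus table
#'
#' Columns: gene_id, chrom, start, end, strand.  Coordinates are 1-based
#' inclusive.  Unplaced genes carry chrom `"scaffold"`.
#'
#' @param path TSV file with header.
#' @return data.frame of loci.
#' @export
read_loci <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("locus table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_loci(df[need])
}

validate_loci <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in locus table", call. = FALSE)
  if (nrow(df) && any(df$start > df$end))
    stop("locus with start > end: ",
         df$gene_id[which(df$start > df$end)[1]], call. = FALSE)
  if (nrow(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  df
}

#' Read gene loci from a GFF3 file
#'
#' Only `gene` features are used; the `ID` attribute becomes the gene id.
#' Features on sequence names not in `chromosomes` (when given) are kept
#' with chrom set to `"scaffold"` rather than dropped.
#'
#' @param path GFF3 file.
#' @param chromosomes optional character vector of recognized chromosome
#'   names.
#' @return data.frame of loci (see [read_loci()]).
#' @export
read_loci_gff3 <- function(path, chromosomes = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9L))
    stop(sprintf("malformed GFF3 line %d: expected 9 fields, found %d",
                 which(nf != 9L)[1], nf[nf != 9L][1]), call. = FALSE)
  m <- do.call(rbind, f)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  id <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  chrom <- m[, 1]
  if (!is.null(chromosomes)) chrom[!chrom %in% chromosomes] <- "scaffold"
  validate_loci(data.frame(gene_id = id, chrom = chrom,
                           start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                           strand = m[, 7], stringsAsFactors = FALSE))
}

#' Write a locus table
#' @param loci data.frame of loci.
#' @param path output TSV.
#' @export
write_loci <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EST tissue manifest
#'
#' Two tab-separated columns, `est_id` and `tissue`; tissues must be among
#' the six surveyed types (bud, flower, leaf, root, seed, silique).
#'
#' @param path TSV file with header.
#' @return data.frame with columns est_id, tissue.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("est_id", "tissue") %in% names(df)))
    stop("manifest must have columns est_id, tissue", call. = FALSE)
  bad <- setdiff(unique(df$tissue), TISSUES)
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df[c("est_id", "tissue")]
}

#' @rdname read_manifest
#' @param manifest data.frame with est_id, tissue.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree to newick
#'
#' Branch lengths are retained and integer bootstrap supports, when present
#' as node labels, are written as internal node labels.  The companion
#' supports table flags bipartitions at or below the display floor.
#'
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
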