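#' Per-column conservation profile of an alignment
#'
#' For each column, score = frequency of the modal non-gap residue among
#' non-gap entries (all-gap columns score 0); the gap fraction is reported
#' alongside.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, >= 2.
#' @return data.frame: column, score, gap_fraction, modal residue.
#' @export
column_conservation <- function(alignment) {
  if (length(alignment) < 2) stop("need >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1)
    stop("ragged alignment", call. = FALSE)
  chm <- do.call(rbind, strsplit(toupper(alignment), ""))
  n <- nrow(chm)
  out <- lapply(seq_len(ncol(chm)), function(j) {
    col <- chm[, j]
    ng <- col[col != "-"]
    if (!length(ng))
      return(data.frame(column = j, score = 0, gap_fraction = 1,
                        modal = NA_character_))
    tab <- sort(table(ng), decreasing = TRUE)
    data.frame(column = j, score = as.numeric(tab[1]) / length(ng),
               gap_fraction = 1 - length(ng) / n,
               modal = names(tab)[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Longest conserved block of an alignment profile
#'
#' The longest contiguous run of columns with conservation score >=
#' `score_threshold` and gap fraction <= `max_gap_fraction` (ties:
#' leftmost).  The consensus is the modal residue of each block column.
#'
#' @param profile output of [column_conservation()].
#' @param score_threshold minimum column conservation (default 0.8).
#' @param max_gap_fraction maximum column gap fraction (default 0.2).
#' @return list of class `motif_block`: start, length, consensus,
#'   mean_conservation; or NULL (with a message) when no column qualifies.
#' @export
conserved_block <- function(profile, score_threshold = 0.8,
                            max_gap_fraction = 0.2) {
  if (!nrow(profile)) stop("empty profile", call. = FALSE)
  ok <- profile$score >= score_threshold &
        profile$gap_fraction <= max_gap_fraction
  if (!any(ok)) {
    message("no column meets the conservation thresholds")
    return(NULL)
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max: leftmost tie
  span <- starts[best]:ends[best]
  structure(list(start = starts[best], length = length(span),
                 consensus = paste(profile$modal[span], collapse = ""),
                 mean_conservation = mean(profile$score[span])),
            class = "motif_block")
}

#' @export
print.motif_block <- function(x, ...) {
  cat(sprintf("<motif block>  columns %d-%d (length %d)  mean cons %.3f\n%s\n",
              x$start, x$start + x$length - 1L, x$length,
              x$mean_conservation, x$consensus))
  invisible(x)
}

#' Presence of short signature elements (e.g. WLG, AYD) in an alignment
#'
#' For each element, the fraction of (ungapped) sequences containing it as
#' a substring, plus the modal variant observed at the element's aligned
#' position.  The aligned position is the window of alignment columns
#' where the element occurs most often; when the element is absent
#' everywhere, the window whose modal string is most similar to the
#' element is reported (so a converted variant, e.g. WLG -> HLG, is still
#' surfaced).
#'
#' @param alignment named aligned sequences.
#' @param elements character vector of residue strings of length 2-6.
#' @return data.frame: element, fraction, modal_variant.
#' @export
element_presence <- function(alignment, elements) {
  if (!length(elements))
    return(data.frame(element = character(), fraction = numeric(),
                      modal_variant = character(), stringsAsFactors = FALSE))
  if (any(nchar(elements) < 2 | nchar(elements) > 6))
    stop("elements must be 2-6 residues long", call. = FALSE)
  ungapped <- gsub("-", "", alignment, fixed = TRUE)
  chm <- do.call(rbind, strsplit(toupper(alignment), ""))
  rows <- lapply(elements, function(el) {
    w <- nchar(el)
    frac <- mean(vapply(ungapped, function(s)
      grepl(el, s, fixed = TRUE), logical(1)))
    best <- list(n_el = -1, sim = -1, modal = NA_character_)
    for (j in seq_len(ncol(chm) - w + 1L)) {
      win <- chm[, j:(j + w - 1L), drop = FALSE]
      strs <- apply(win, 1, paste, collapse = "")
      strs <- strs[!grepl("-", strs, fixed = TRUE)]
      if (!length(strs)) next
      tab <- sort(table(strs), decreasing = TRUE)
      modal <- names(tab)[1]
      n_el <- sum(strs == el)
      sim <- sum(strsplit(modal, "")[[1]] == strsplit(el, "")[[1]])
      if (n_el > best$n_el ||
          (n_el == best$n_el && sim > best$sim)) {
        best <- list(n_el = n_el, sim = sim, modal = modal)
      }
    }
    data.frame(element = el, fraction = frac, modal_variant = best$modal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
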