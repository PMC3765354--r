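#' Score one window against a domain model
#'
#' Sum over model columns of the log-odds (bits) of the observed residue.
#' Unknown residues (`X`) contribute 0 bits per column.
#'
#' @param model a `domain_model`.
#' @param subseq protein segment whose length equals the model length.
#' @return bit score (numeric scalar).
#' @export
score_window <- function(model, subseq) {
  subseq <- check_protein(subseq, "window")
  res <- strsplit(subseq, "")[[1]]
  if (length(res) != model$length)
    stop(sprintf("window length %d != model length %d",
                 length(res), model$length), call. = FALSE)
  idx <- match(res, AA20)
  sc <- model$log_odds[cbind(seq_len(model$length), idx)]
  sc[is.na(idx)] <- 0                     # 'X' is neutral
  sum(sc)
}

# all window scores for one protein, vectorized over start positions
window_scores <- function(model, protein) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res); L <- model$length
  if (n < L) return(numeric(0))
  idx <- match(res, AA20)
  # per-position contribution for every model column, then banded sum
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- unname(model$log_odds[j, idx[j:(j + nw - 1L)]])
    v[is.na(idx[j:(j + nw - 1L)])] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan a protein for domain hits
#'
#' Slides the model across every window, keeps windows scoring at or above
#' the bit threshold, and resolves overlaps greedily by descending score
#' (ties: leftmost start).  Coordinates are 1-based inclusive.
#'
#' @param protein residue string (length >= 1).
#' @param model a `domain_model`.
#' @param bit_threshold minimum reported bit score; defaults to the model's
#'   calibrated threshold.
#' @param protein_id id used in the output rows.
#' @return data.frame with columns protein_id, domain, start, end, bits,
#'   evalue_surrogate (NA when the model is uncalibrated), sorted by start.
#' @export
scan_protein <- function(protein, model, bit_threshold = model$bit_threshold,
                         protein_id = "protein") {
  if (is.null(bit_threshold))
    stop("no bit_threshold given and model is uncalibrated", call. = FALSE)
  protein <- check_protein(protein, "protein")
  empty <- data.frame(protein_id = character(), domain = character(),
                      start = integer(), end = integer(), bits = numeric(),
                      evalue_surrogate = numeric(), stringsAsFactors = FALSE)
  sc <- window_scores(model, protein)
  keep <- which(sc >= bit_threshold)
  if (!length(keep)) return(empty)
  # greedy overlap resolution: best score first, ties leftmost
  ord <- keep[order(-sc[keep], keep)]
  chosen <- integer(0)
  for (s in ord) {
    if (!any(abs(s - chosen) < model$length)) chosen <- c(chosen, s)
  }
  chosen <- sort(chosen)
  data.frame(protein_id = protein_id, domain = model$name,
             start = chosen, end = chosen + model$length - 1L,
             bits = sc[chosen],
             evalue_surrogate = score_evalue(model, sc[chosen]),
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome with a set of models
#'
#' @param proteins named character vector of protein sequences.
#' @param models list of calibrated `domain_model`s.
#' @return data.frame of hits over all proteins and models.
#' @export
scan_proteome <- function(proteins, models) {
  if (!length(proteins)) return(scan_protein("A", models[[1]],
                                             bit_threshold = Inf)[0, ])
  rows <- lapply(names(proteins), function(id) {
    do.call(rbind, lapply(models, function(m)
      scan_protein(proteins[[id]], m, protein_id = id)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), ]
}

# expected decoy count in a database of `database_size` windows for scores
# at or above x, from the stored Gaussian null calibration
score_evalue <- function(model, x) {
  cal <- model$calibration
  if (is.null(cal)) return(rep(NA_real_, length(x)))
  p <- stats::pnorm(x, cal$mean, cal$sd, lower.tail = FALSE)
  pmin(cal$database_size * p, cal$database_size)
}

#' Calibrate a model's bit threshold from shuffled decoys
#'
#' Scores `n_decoys` random background windows and fits a Gaussian null to
#' the decoy scores (a window score is the sum of per-column scores, so
#' the decoy law is very close to normal); the threshold is the score
#' whose expected decoy count in a database of `database_size` windows
#' equals `target_evalue`.  The calibration (null parameters, decoy
#' quantiles) is stored on the returned model.
#'
#' @param model a `domain_model`.
#' @param n_decoys number of decoy windows (>= 1000).
#' @param target_evalue expected false hits per database, default 1e-4.
#' @param database_size number of windows the E-value refers to.
#' @param seed integer seed.
#' @return the model with `bit_threshold` and `calibration` filled in.
#' @export
calibrate_threshold <- function(model, n_decoys = 2000, target_evalue = 1e-4,
                                database_size = 1e5, seed = 1) {
  if (n_decoys < 1000) stop("n_decoys must be >= 1000", call. = FALSE)
  if (max(model$log_odds) - min(model$log_odds) < 1e-8)
    stop("degenerate model: zero-information columns, cannot calibrate",
         call. = FALSE)
  scores <- with_seed(seed, {
    idx <- matrix(sample.int(20, n_decoys * model$length, replace = TRUE),
                  n_decoys, model$length)
    rowSums(matrix(model$log_odds[cbind(rep(seq_len(model$length),
                                            each = n_decoys),
                                        as.vector(idx))],
                   n_decoys, model$length))
  })
  if (sd(scores) <= 0)
    stop("calibration failure: no decoy score spread", call. = FALSE)
  # solve database_size * P(S > t) = target_evalue under the normal null
  thr <- mean(scores) +
    stats::qnorm(target_evalue / database_size, lower.tail = FALSE) *
    sd(scores)
  model$bit_threshold <- thr
  model$calibration <- list(n_decoys = n_decoys, mean = mean(scores),
                            sd = sd(scores),
                            database_size = database_size,
                            target_evalue = target_evalue,
                            decoy_quantiles = quantile(scores,
                                                       c(.5, .9, .99, 1)),
                            max_decoy = max(scores))
  model
}
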