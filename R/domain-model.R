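#' Build a position-frequency domain model around a consensus
#'
#' Emulates a profile of a DNA-binding domain (AP2 or B3) as a
#' position-frequency matrix: each column is a Dirichlet draw concentrated
#' on the consensus residue.  `diversity` is the Dirichlet concentration on
#' the consensus (off-consensus residues have concentration 1); larger
#' values give sharper, more conserved columns.  The log-odds matrix is in
#' bits against a uniform 20-residue background.
#'
#' @param consensus residue string, length >= 10, standard amino acids only.
#' @param diversity concentration parameter, > 0.
#' @param seed integer seed; models are deterministic given (consensus,
#'   diversity, seed).
#' @param name model name, e.g. `"AP2"` or `"B3"`.
#' @return an object of class `domain_model` with elements `name`,
#'   `consensus`, `length`, `pfm` (length x 20, rows sum to 1), `log_odds`
#'   (bits), `background`, and (after calibration) `bit_threshold` and
#'   `calibration`.
#' @export
make_domain_model <- function(consensus, diversity, seed, name = "AP2") {
  consensus <- check_protein(consensus, "consensus")
  res <- strsplit(consensus, "")[[1]]
  if (any(res == "X") || any(res == "-"))
    stop("consensus must contain only the 20 standard residues",
         call. = FALSE)
  if (length(res) < 10) stop("consensus length must be >= 10", call. = FALSE)
  if (!is.numeric(diversity) || diversity <= 0)
    stop("diversity must be > 0", call. = FALSE)
  L <- length(res)
  pfm <- with_seed(seed, {
    m <- matrix(0, L, 20, dimnames = list(NULL, AA20))
    for (i in seq_len(L)) {
      alpha <- rep(1, 20)
      alpha[match(res[i], AA20)] <- diversity
      g <- rgamma(20, shape = alpha)      # Dirichlet via gamma draws
      m[i, ] <- g / sum(g)
    }
    m
  })
  pfm <- pmax(pfm, 1e-6)
  pfm <- pfm / rowSums(pfm)
  bg <- rep(1 / 20, 20)
  structure(list(name = name, consensus = consensus, length = L,
                 pfm = pfm, log_odds = log2(pfm / rep(bg, each = L)),
                 background = bg, bit_threshold = NULL, calibration = NULL),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model '%s'>  length %d", x$name, x$length))
  if (!is.null(x$bit_threshold))
    cat(sprintf("  bit threshold %.2f (calibrated on %d decoys)",
                x$bit_threshold, x$calibration$n_decoys))
  cat("\n")
  invisible(x)
}

#' Sample a domain sequence from a model
#'
#' Draws one residue per column from the position-frequency matrix.
#' `temperature` flattens (`> 1`) or sharpens (`< 1`) the column
#' distributions; elevated temperature yields a divergent but still
#' recognizable domain (used for the Soloist family).
#'
#' @param model a `domain_model`.
#' @param seed integer seed.
#' @param temperature sampling temperature, default 1.
#' @return a residue string of the model's length.
#' @export
sample_domain <- function(model, seed, temperature = 1) {
  stopifnot(inherits(model, "domain_model"), temperature > 0)
  with_seed(seed, {
    res <- vapply(seq_len(model$length), function(i) {
      p <- model$pfm[i, ]^(1 / temperature)
      sample(AA20, 1, prob = p / sum(p))
    }, character(1))
    paste(res, collapse = "")
  })
}

#' Write / read the plain-text domain model format
#'
#' Header lines (`# name`, `# length`, `# background`, `# bit_threshold`)
#' followed by one tab-separated probability row per model column.
#'
#' @param model a `domain_model`.
#' @param path file path.
#' @export
write_domain_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name\t%s", model$name),
               sprintf("# length\t%d", model$length),
               sprintf("# background\t%s",
                       paste(format(model$background, digits = 12),
                             collapse = "\t")),
               sprintf("# bit_threshold\t%s",
                       if (is.null(model$bit_threshold)) "NA"
                       else format(model$bit_threshold, digits = 12)),
               paste(AA20, collapse = "\t")), con)
  write.table(format(model$pfm, digits = 12), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_domain_model
#' @export
read_domain_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) stop("model file missing header: ", key, call. = FALSE)
    strsplit(ln, "\t")[[1]][-1]
  }
  name <- get("name")
  L <- as.integer(get("length"))
  bg <- as.numeric(get("background"))
  thr <- get("bit_threshold")
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]                       # residue header row
  pfm <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  colnames(pfm) <- AA20
  pfm <- pfm / rowSums(pfm)
  if (nrow(pfm) != L) stop("model file row count != declared length",
                           call. = FALSE)
  cons <- paste(AA20[max.col(pfm)], collapse = "")
  structure(list(name = name, consensus = cons, length = L, pfm = pfm,
                 log_odds = log2(pfm / rep(bg, each = L)), background = bg,
                 bit_threshold = if (identical(thr, "NA")) NULL
                                 else as.numeric(thr),
                 calibration = NULL),
            class = "domain_model")
}

# default consensus strings for the two domain types; lengths reflect the
# ~60-aa AP2 DNA-binding domain and a compact B3 domain
default_consensus <- function(type = c("AP2", "B3"), seed = 97) {
  type <- match.arg(type)
  len <- if (type == "AP2") 60L else 50L
  off <- if (type == "AP2") 0L else 1L
  with_seed(substream(seed, off), random_protein(len))
}

#' Construct the default AP2 and B3 domain models
#'
#' @param diversity Dirichlet concentration (default 20, a strongly
#'   conserved domain).
#' @param seed integer seed.
#' @return named list with elements `AP2` and `B3`.
#' @export
default_domain_models <- function(diversity = 20, seed = 97) {
  list(AP2 = make_domain_model(default_consensus("AP2", seed), diversity,
                               substream(seed, 11), name = "AP2"),
       B3 = make_domain_model(default_consensus("B3", seed), diversity,
                              substream(seed, 12), name = "B3"))
}
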