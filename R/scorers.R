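#' Splice-site scorer contract
#'
#' A site scorer stands in for a neural splice predictor: given a nucleotide
#' sequence it returns, for every position, an acceptor-site score and a
#' donor-site score in [0,1]. The position convention is the annotated-site
#' convention used throughout: the donor score at position p rates p as the
#' first intronic base of a donor junction (9-base window p-3..p+5); the
#' acceptor score rates p as the last intronic base of an acceptor junction
#' (23-base window p-19..p+3). Positions whose window falls off the sequence
#' or contains an unknown base score 0.
#'
#' \code{site_scorer()} wraps a function \code{f(seq, chrom, start)} that
#' must return \code{list(acceptor=, donor=)}, both the same length as the
#' input sequence; \code{chrom}/\code{start} give the genomic coordinates of
#' the sequence for scorers backed by positional lookups and may be NA for
#' sequence-only scorers.
#'
#' @param f Scoring function.
#' @param label Description used in printing.
#' @return Object of class \code{"site_scorer"} (callable).
#' @export
site_scorer <- function(f, label = "custom") {
  stopifnot(is.function(f))
  structure(f, class = c("site_scorer", "function"), label = label)
}

#' @export
print.site_scorer <- function(x, ...) {
  cat("<site_scorer> ", attr(x, "label"), "\n", sep = "")
  invisible(x)
}

score_sequence <- function(scorer, seq, chrom = NA, start = NA) {
  out <- scorer(seq, chrom, start)
  n <- nchar(seq)
  stopifnot(length(out$acceptor) == n, length(out$donor) == n)
  out
}

#' PWM-based splice-site scorer
#'
#' Scans a sequence with the donor and acceptor tables of a [motif_model()]
#' and converts window log-odds to [0,1] site scores via the model's cap:
#' \code{min(max(bits,0),C)/C}.
#'
#' @param model A [motif_model()].
#' @return A [site_scorer()].
#' @export
pwm_site_scorer <- function(model = default_motif_model()) {
  force(model)
  f <- function(seq, chrom = NA, start = NA) {
    idx <- seq_to_idx(seq)
    n <- length(idx)
    don <- acc <- numeric(n)
    ds <- scan_windows(idx, model, "donor")      # window starts
    if (length(ds)) {
      p <- seq_along(ds) + 3L                    # site = start + 3
      don[p] <- norm_bits(ds, model$cap)
    }
    as <- scan_windows(idx, model, "acceptor")
    if (length(as)) {
      p <- seq_along(as) + 19L                   # site = start + 19
      acc[p] <- norm_bits(as, model$cap)
    }
    list(acceptor = acc, donor = don)
  }
  site_scorer(f, label = "PWM motif scanner")
}

#' Precomputed per-position splice-site scorer
#'
#' Loads a TSV of per-position site scores (columns chrom, pos, acc, don;
#' 1-based positions) such as exported output of a neural splice predictor,
#' and serves them by genomic coordinate. The sequence content is ignored;
#' calls must supply \code{chrom} and \code{start}. Positions absent from
#' the table score 0. Because the lookup is positional, this scorer only
#' applies to reference-frame sequences (alternate frames of indels shift
#' coordinates); use it for SNV-dominated inputs or reference scans.
#'
#' @param path TSV file with header columns chrom, pos, acc, don.
#' @return A [site_scorer()].
#' @export
tsv_site_scorer <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "acc", "don") %in% names(tab)))
  key <- paste(tab$chrom, tab$pos)
  acc <- setNames(as.numeric(tab$acc), key)
  don <- setNames(as.numeric(tab$don), key)
  f <- function(seq, chrom = NA, start = NA) {
    n <- nchar(seq)
    if (is.na(chrom) || is.na(start))
      stop("tsv_site_scorer requires chrom and start coordinates")
    k <- paste(chrom, start + seq_len(n) - 1L)
    a <- acc[k]; d <- don[k]
    a[is.na(a)] <- 0; d[is.na(d)] <- 0
    list(acceptor = unname(a), donor = unname(d))
  }
  site_scorer(f, label = sprintf("precomputed scores (%s)", basename(path)))
}
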