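DONOR_W <- 9L     # 3 exonic + 6 intronic bases around the donor junction
ACCEPTOR_W <- 23L # 20 intronic + 3 exonic bases around the acceptor junction
BASES <- c("A", "C", "G", "T")

#' Construct a splice-motif model
#'
#' A first-order (independent-position) maximum-entropy-style motif model:
#' per-position base probability tables for the 9-base donor window and the
#' 23-base acceptor window, a background base distribution, and a
#' normalization cap C in bits. Window log-odds are
#' \eqn{\sum_i \log_2 p_i(b_i)/q(b_i)}; the [0,1] site score used by the
#' PWM site scorer and the motif variant feature is
#' \code{min(max(bits, 0), C) / C}.
#'
#' @param donor 9 x 4 matrix of base probabilities (columns A,C,G,T).
#' @param acceptor 23 x 4 matrix of base probabilities.
#' @param background Length-4 base probability vector (default uniform).
#' @param cap Normalization cap C in bits (default 12).
#' @return Object of class \code{"motif_model"}.
#' @export
motif_model <- function(donor, acceptor, background = rep(0.25, 4),
                        cap = 12) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  if (!all(dim(donor) == c(DONOR_W, 4L)))
    stop("donor table must be 9 x 4")
  if (!all(dim(acceptor) == c(ACCEPTOR_W, 4L)))
    stop("acceptor table must be 23 x 4")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be a proper probability distribution")
  donor <- donor / rowSums(donor)
  acceptor <- acceptor / rowSums(acceptor)
  colnames(donor) <- colnames(acceptor) <- BASES
  structure(list(donor = donor, acceptor = acceptor,
                 background = background, cap = cap),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> donor 9x4, acceptor 23x4, cap =", x$cap, "bits\n")
  invisible(x)
}

row_mat <- function(rows) do.call(rbind, rows)

#' Default splice-motif model
#'
#' Probability tables shaped on the canonical human donor (CAG|GTAAGT) and
#' acceptor (pyrimidine tract + CAG|) consensus. These are package defaults
#' for desk-scale work, not tables fit to a reference motif collection.
#'
#' @param cap Normalization cap in bits.
#' @return A [motif_model()].
#' @export
default_motif_model <- function(cap = 12) {
  donor <- row_mat(list(
    c(.35, .35, .18, .12),  # -3
    c(.60, .13, .14, .13),  # -2
    c(.08, .04, .80, .08),  # -1
    c(.01, .01, .97, .01),  # +1 G
    c(.01, .01, .01, .97),  # +2 T
    c(.55, .02, .40, .03),  # +3
    c(.70, .08, .12, .10),  # +4
    c(.07, .05, .84, .04),  # +5
    c(.16, .17, .19, .48))) # +6
  pyr <- c(.18, .28, .14, .40)
  acceptor <- row_mat(c(
    rep(list(pyr), 17),
    list(c(.06, .65, .01, .28),   # -4 (C-rich)
         c(.97, .01, .01, .01),   # -2 A
         c(.01, .01, .97, .01),   # -1 G (last intronic base)
         c(.25, .20, .40, .15),   # +1 exonic
         c(.25, .25, .25, .25),
         c(.25, .25, .25, .25))))
  motif_model(donor, acceptor, cap = cap)
}

motif_width <- function(kind) if (kind == "donor") DONOR_W else ACCEPTOR_W

log_odds <- function(model, kind) {
  p <- model[[kind]]
  log2(sweep(p, 2, model$background, "/"))
}

#' Score one motif window in log-odds bits
#'
#' @param window Sequence of length 9 (donor) or 23 (acceptor).
#' @param model A [motif_model()].
#' @param kind "donor" or "acceptor".
#' @return Log2 odds of the window under the motif vs background model
#'   (bits; may be negative).
#' @export
mes_score <- function(window, model, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  w <- motif_width(kind)
  if (nchar(window) != w)
    stop(kind, " window must have length ", w)
  idx <- match(strsplit(toupper(window), "")[[1]], BASES)
  if (anyNA(idx)) stop("non-ACGT base in motif window")
  L <- log_odds(model, kind)
  sum(L[cbind(seq_len(w), idx)])
}

# all window log-odds over an integer-coded sequence; positions with unknown
# bases give -Inf. Returns a vector over window start positions.
scan_windows <- function(idx, model, kind) {
  w <- motif_width(kind)
  n <- length(idx)
  if (n < w) return(numeric(0))
  L <- log_odds(model, kind)
  ns <- n - w + 1L
  s <- numeric(ns)
  bad <- logical(ns)
  for (o in seq_len(w)) {
    b <- idx[o:(o + ns - 1L)]
    miss <- is.na(b)
    bad <- bad | miss
    b[miss] <- 1L
    s <- s + L[o, b]
  }
  s[bad] <- -Inf
  s
}

seq_to_idx <- function(s) match(strsplit(toupper(s), "")[[1]], BASES)

norm_bits <- function(bits, cap) pmin(pmax(bits, 0), cap) / cap

#' Motif-based variant-effect feature
#'
#' Enumerates every donor 9-mer and acceptor 23-mer window overlapping the
#' variant in the reference and alternate frames. Per site kind, with
#' \code{a} the best alternate window score and \code{r} the best reference
#' window score (bits): a gain-creating variant contributes
#' \code{min(a, C)/C} when \code{a > r} and \code{a > 0}, else 0. The feature
#' is the larger of the donor and acceptor contributions.
#'
#' @param ref_seq,alt_seq Reference and variant-substituted sequences
#'   covering all windows that overlap the variant.
#' @param var_offset 1-based offset of the variant's first base in both
#'   frames (frames agree left of the variant).
#' @param model A [motif_model()].
#' @param ref_len,alt_len Allele lengths within the two frames.
#' @return Feature score in [0,1].
#' @export
mes_variant_feature <- function(ref_seq, alt_seq, var_offset, model,
                                ref_len = 1L, alt_len = 1L) {
  ridx <- seq_to_idx(ref_seq); aidx <- seq_to_idx(alt_seq)
  best <- 0
  for (kind in c("donor", "acceptor")) {
    w <- motif_width(kind)
    r <- best_overlapping(ridx, model, kind, var_offset, ref_len, w)
    a <- best_overlapping(aidx, model, kind, var_offset, alt_len, w)
    contrib <- if (a <= r || a <= 0) 0 else norm_bits(a, model$cap)
    best <- max(best, contrib)
  }
  best
}

best_overlapping <- function(idx, model, kind, var_offset, len, w) {
  lo <- max(1L, var_offset - w + 1L)
  hi <- min(length(idx) - w + 1L, var_offset + len - 1L)
  if (hi < lo) return(-Inf)
  scores <- scan_windows(idx, model, kind)
  max(scores[lo:hi])
}
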