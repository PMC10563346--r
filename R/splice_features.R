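#' Masked splice-gain features for one variant
#'
#' The splice-gain features compare a site scorer's output on the
#' variant-substituted (alternate) sequence against the reference sequence.
#' For each site kind (acceptor, donor), over alternate-frame positions
#' within \code{d} bases of the variant:
#' \itemize{
#'   \item raw gain = the maximum alternate-frame site score (no subtraction,
#'     no mask);
#'   \item delta at a position = alternate score minus the reference score at
#'     the corresponding reference-frame position (an inserted base has no
#'     reference counterpart and its reference score is 0);
#'   \item deltas at annotated splice sites of the same kind are forced to 0
#'     (extended masking over all annotated sites supplied);
#'   \item delta gain = the maximum masked delta, floored at 0.
#' }
#' Derived aggregates: \code{delta_gain_max}, \code{delta_gain_mean} over the
#' two kinds, and \code{raw_gain_mean} / \code{raw_gain_max}.
#'
#' @param scorer A [site_scorer()].
#' @param ref_seq,alt_seq Reference and variant-substituted sequences
#'   covering the variant +/- \code{d} (clipped at contig ends).
#' @param var_offset 1-based offset of the variant's first base in both
#'   frames.
#' @param annotated_sites NULL or data.frame with columns \code{offset}
#'   (reference-frame offset) and \code{kind} ("donor"/"acceptor").
#' @param d Maximum distance from the variant considered (default 300).
#' @param ref_len,alt_len Allele lengths in the two frames (SNV: 1 and 1).
#' @param chrom,ref_start Optional genomic coordinates of \code{ref_seq}
#'   (passed through to positional scorers).
#' @return List of class \code{"splice_gain"} with elements
#'   \code{acc_delta_gain}, \code{don_delta_gain}, \code{acc_raw_gain},
#'   \code{don_raw_gain}, \code{delta_gain_max}, \code{delta_gain_mean},
#'   \code{raw_gain_mean}, \code{raw_gain_max}.
#' @export
masked_gain_features <- function(scorer, ref_seq, alt_seq, var_offset,
                                 annotated_sites = NULL, d = 300L,
                                 ref_len = 1L, alt_len = NULL,
                                 chrom = NA, ref_start = NA) {
  nr <- nchar(ref_seq); na <- nchar(alt_seq)
  L <- na - nr                       # indel length shift (alt minus ref)
  if (is.null(alt_len)) alt_len <- ref_len + L
  if (alt_len != ref_len + L)
    stop("allele lengths inconsistent with sequence lengths")
  if (var_offset < 1L || var_offset + alt_len - 1L > na ||
      var_offset + ref_len - 1L > nr)
    stop("window shorter than the variant extent")

  sc_ref <- score_sequence(scorer, ref_seq, chrom, ref_start)
  sc_alt <- score_sequence(scorer, alt_seq, chrom, ref_start)

  # alternate positions within d of the variant's allele span
  p <- seq_len(na)
  span_lo <- var_offset; span_hi <- var_offset + max(alt_len, 1L) - 1L
  dist <- pmax(0L, span_lo - p, p - span_hi)
  sel <- dist <= d

  # alt -> ref frame position map (NA for inserted bases)
  rp <- ifelse(p < var_offset, p,
        ifelse(p > span_hi, p - L,
               ifelse(p - var_offset < ref_len, p, NA_integer_)))
  rp[!is.na(rp) & (rp < 1L | rp > nr)] <- NA_integer_

  # reference-frame mask offsets mapped into the alt frame
  mask_alt <- function(kind) {
    if (is.null(annotated_sites) || nrow(annotated_sites) == 0)
      return(integer(0))
    s <- annotated_sites$offset[annotated_sites$kind == kind]
    m <- ifelse(s < var_offset, s,
         ifelse(s >= var_offset + ref_len, s + L,
                ifelse(s - var_offset < alt_len, s, NA_integer_)))
    m[!is.na(m) & m >= 1L & m <= na]
  }

  out <- list()
  for (kind in c("acceptor", "donor")) {
    alt_sc <- sc_alt[[kind]]
    ref_sc <- ifelse(is.na(rp), 0, sc_ref[[kind]][ifelse(is.na(rp), 1L, rp)])
    delta <- alt_sc - ref_sc
    delta[mask_alt(kind)] <- 0
    pre <- if (kind == "acceptor") "acc" else "don"
    out[[paste0(pre, "_raw_gain")]] <-
      if (any(sel)) max(alt_sc[sel]) else 0
    out[[paste0(pre, "_delta_gain")]] <-
      max(0, if (any(sel)) max(delta[sel]) else 0)
  }
  out$delta_gain_max <- max(out$acc_delta_gain, out$don_delta_gain)
  out$delta_gain_mean <- (out$acc_delta_gain + out$don_delta_gain) / 2
  out$raw_gain_mean <- (out$acc_raw_gain + out$don_raw_gain) / 2
  out$raw_gain_max <- max(out$acc_raw_gain, out$don_raw_gain)
  class(out) <- "splice_gain"
  out
}

#' @export
print.splice_gain <- function(x, ...) {
  cat(sprintf(paste0("<splice_gain> delta acc/don %.3f/%.3f ",
                     "raw acc/don %.3f/%.3f\n"),
              x$acc_delta_gain, x$don_delta_gain,
              x$acc_raw_gain, x$don_raw_gain))
  invisible(x)
}

#' Assemble the five-feature vector for one variant
#'
#' A vector is complete only when all five features are present; scores are
#' computed downstream only for complete vectors.
#'
#' @param gains A [masked_gain_features()] result.
#' @param mes Motif variant feature in [0,1].
#' @param constraint Constraint score in [0,1] or NA.
#' @param raw_gain_agg Which raw-gain aggregate feeds the third feature:
#'   "mean" (default, per the method description) or "max".
#' @return One-row data.frame with the [pdivas_features()] columns and a
#'   logical \code{complete}.
#' @export
assemble_features <- function(gains, mes, constraint,
                              raw_gain_agg = c("mean", "max")) {
  raw_gain_agg <- match.arg(raw_gain_agg)
  raw <- if (raw_gain_agg == "mean") gains$raw_gain_mean else
    gains$raw_gain_max
  df <- data.frame(
    spliceai_del_gain_mean = gains$delta_gain_mean,
    spliceai_del_gain_max = gains$delta_gain_max,
    spliceai_raw_gain_mean = raw,
    consplice = if (is.null(constraint)) NA_real_ else as.numeric(constraint),
    maxentscan = if (is.null(mes)) NA_real_ else as.numeric(mes))
  df$complete <- !anyNA(df[1, PDIVAS_FEATURES])
  df
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Extract features for a variant table against a reference
#'
#' The full feature-extraction pipeline: per variant, locate its transcript,
#' classify its region, cut the variant +/- \code{d} sequence window out of
#' the genome, build the alternate window, orient minus-strand windows by
#' reverse complement, compute masked splice-gain features (masking every
#' annotated splice site of the transcript inside the window), the motif
#' variant feature, and the constraint lookup.
#'
#' @param v A [variants()] table (gene assignment is done here if absent).
#' @param txs Named list of [transcript_model()].
#' @param genome A \code{Biostrings::DNAStringSet} keyed by chromosome.
#' @param scorer A [site_scorer()].
#' @param model A [motif_model()] for the motif feature.
#' @param track A [constraint_track()].
#' @param d Scan distance (default 300).
#' @param raw_gain_agg "mean" or "max" (see [assemble_features()]).
#' @return data.frame: variant key, gene, zone, distance, the five features,
#'   and \code{complete}.
#' @export
annotate_variants <- function(v, txs, genome, scorer,
                              model = default_motif_model(), track = NULL,
                              d = 300L, raw_gain_agg = "mean") {
  v <- assign_genes(v, txs)
  constraint <- if (is.null(track)) rep(NA_real_, nrow(v)) else
    constraint_lookup(v, track)
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    vi <- v[i, , drop = FALSE]
    t <- if (!is.na(vi$gene_id)) txs[[vi$gene_id]] else NULL
    if (is.null(t)) {
      reg <- data.frame(zone = "outside_gene", distance_bp = NA_integer_)
      feat <- assemble_features(empty_gain(), NA_real_, NA_real_)
    } else {
      reg <- classify_region(vi, t)
      feat <- variant_features(vi, t, genome, scorer, model,
                               constraint[i], d, raw_gain_agg)
    }
    rows[[i]] <- cbind(
      data.frame(key = variant_key(vi), chrom = vi$chrom, pos = vi$pos,
                 gene_id = vi$gene_id, stringsAsFactors = FALSE),
      reg, feat)
  }
  do.call(rbind, rows)
}

empty_gain <- function() {
  structure(list(acc_delta_gain = NA_real_, don_delta_gain = NA_real_,
                 acc_raw_gain = NA_real_, don_raw_gain = NA_real_,
                 delta_gain_max = NA_real_, delta_gain_mean = NA_real_,
                 raw_gain_mean = NA_real_, raw_gain_max = NA_real_),
            class = "splice_gain")
}

variant_features <- function(vi, t, genome, scorer, model, constraint,
                             d, raw_gain_agg) {
  chrom <- vi$chrom
  if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
  contig <- genome[[chrom]]
  clen <- length(contig)
  ref_len <- nchar(vi$ref); alt_len <- nchar(vi$alt)
  pad <- d + ACCEPTOR_W + 2L
  win_lo <- max(1L, vi$pos - pad)
  win_hi <- min(clen, vi$pos + ref_len - 1L + pad)
  ref_seq <- as.character(Biostrings::subseq(contig, win_lo, win_hi))
  off <- vi$pos - win_lo + 1L
  obs <- substr(ref_seq, off, off + ref_len - 1L)
  if (obs != vi$ref)
    stop("reference allele mismatch at ", variant_key(vi),
         " (genome has ", obs, ")")
  alt_seq <- paste0(substr(ref_seq, 1L, off - 1L), vi$alt,
                    substr(ref_seq, off + ref_len, nchar(ref_seq)))

  ss <- splice_sites(t)
  ss <- ss[ss$pos >= win_lo & ss$pos <= win_hi, , drop = FALSE]
  sites <- data.frame(offset = ss$pos - win_lo + 1L, kind = ss$kind,
                      stringsAsFactors = FALSE)

  pos_coords <- list(chrom = chrom, start = win_lo)
  if (t$strand == "-") {
    nr <- nchar(ref_seq)
    ref_rc <- revcomp(ref_seq)
    alt_rc <- revcomp(alt_seq)
    off_rc <- nr - (off + ref_len - 1L) + 1L
    sites$offset <- nr - sites$offset + 1L
    ref_seq <- ref_rc; alt_seq <- alt_rc; off <- off_rc
    pos_coords <- list(chrom = NA, start = NA)  # coordinates no longer linear
  }
  gains <- masked_gain_features(scorer, ref_seq, alt_seq, off,
                                annotated_sites = sites, d = d,
                                ref_len = ref_len, alt_len = alt_len,
                                chrom = pos_coords$chrom,
                                ref_start = pos_coords$start)
  mes <- mes_variant_feature(ref_seq, alt_seq, off, model,
                             ref_len = ref_len, alt_len = alt_len)
  assemble_features(gains, mes, constraint, raw_gain_agg)
}
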