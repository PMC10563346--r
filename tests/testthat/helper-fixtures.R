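# Shared fixtures and independent brute-force oracles.

toy_tx <- function(strand = "+") {
  transcript_model("G1", "T1", "chr1", strand,
                   cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# ---- average precision: naive step-sum over descending unique thresholds
ap_oracle <- function(labels, scores) {
  y <- as.integer(labels)
  ts <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in ts) {
    pred <- scores >= t
    p <- sum(y[pred]) / sum(pred)
    r <- sum(y[pred]) / sum(y)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# ---- max MCC: exhaustive confusion-matrix enumeration over the full grid
mcc_oracle <- function(labels, scores, step = 0.001) {
  y <- as.integer(labels)
  ts <- seq.int(0L, round(1 / step)) * step
  pred <- outer(scores, ts, ">=")
  tp <- colSums(pred & y == 1)
  fp <- colSums(pred & y == 0)
  fn <- sum(y == 1) - tp
  tn <- sum(y == 0) - fp
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / sqrt(den))
  # same float tolerance for ties as the implementation contract
  list(threshold = ts[min(which(mcc >= max(mcc) - 1e-12))], mcc = max(mcc))
}

# best MCC over all distinct-score cutoffs (grid-free, rank-based; invariant
# under monotone transforms of the scores)
mcc_rank_oracle <- function(labels, scores) {
  y <- as.integer(labels)
  best <- 0
  for (t in unique(scores)) {
    pred <- scores >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(y == 1) - tp; tn <- sum(y == 0) - fp
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) best <- max(best, (tp * tn - fp * fn) / sqrt(den))
  }
  best
}

# ---- motif feature: exhaustive enumeration of every overlapping window
mes_feature_oracle <- function(ref_seq, alt_seq, var_offset, model,
                               ref_len = 1L, alt_len = 1L) {
  best_kind <- function(s, len, kind) {
    w <- if (kind == "donor") 9L else 23L
    best <- -Inf
    for (st in seq_len(max(0L, nchar(s) - w + 1L))) {
      if (st > var_offset + len - 1L || st + w - 1L < var_offset) next
      best <- max(best, mes_score(substr(s, st, st + w - 1L), model, kind))
    }
    best
  }
  out <- 0
  for (kind in c("donor", "acceptor")) {
    a <- best_kind(alt_seq, alt_len, kind)
    r <- best_kind(ref_seq, ref_len, kind)
    if (a > r && a > 0) out <- max(out, min(a, model$cap) / model$cap)
  }
  out
}

# ---- masked gain features: independent position-mapping implementation
gain_oracle <- function(scorer, ref_seq, alt_seq, var_offset, sites, d,
                        ref_len, alt_len) {
  sr <- scorer(ref_seq, NA, NA)
  sa <- scorer(alt_seq, NA, NA)
  L <- alt_len - ref_len
  na <- nchar(alt_seq)
  out <- list()
  for (kind in c("acceptor", "donor")) {
    raw <- 0; dg <- 0
    for (p in seq_len(na)) {
      dist <- max(0L, var_offset - p, p - (var_offset + alt_len - 1L))
      if (dist > d) next
      raw <- max(raw, sa[[kind]][p])
      # reference counterpart by explicit alignment
      rp <- if (p < var_offset) p
            else if (p >= var_offset + alt_len) p - L
            else if (p - var_offset < ref_len) p else NA
      rs <- if (is.na(rp) || rp < 1 || rp > nchar(ref_seq)) 0
            else sr[[kind]][rp]
      delta <- sa[[kind]][p] - rs
      masked <- FALSE
      if (!is.null(sites) && nrow(sites) > 0)
        for (i in seq_len(nrow(sites))) {
          if (sites$kind[i] != kind) next
          s <- sites$offset[i]
          m <- if (s < var_offset) s
               else if (s >= var_offset + ref_len) s + L
               else if (s - var_offset < alt_len) s else NA
          if (!is.na(m) && m == p) masked <- TRUE
        }
      if (masked) delta <- 0
      dg <- max(dg, delta)
    }
    pre <- if (kind == "acceptor") "acc" else "don"
    out[[paste0(pre, "_raw_gain")]] <- raw
    out[[paste0(pre, "_delta_gain")]] <- dg
  }
  out
}

# deterministic per-position probe scorer: pseudo-random but a pure function
# of (position, sequence length parity) so ref/alt frames genuinely differ
probe_scorer <- function() {
  site_scorer(function(seq, chrom = NA, start = NA) {
    n <- nchar(seq)
    idx <- utf8ToInt(seq)
    list(acceptor = ((seq_len(n) * 37 + idx) %% 101) / 101,
         donor = ((seq_len(n) * 17 + idx * 3) %% 89) / 89)
  }, label = "probe")
}

small_feature_world <- function(seed = 11) {
  spec <- synthetic_spec(seed = seed, n_genes = 8, n_samples = 6,
                         n_path = 30, n_benign = 200)
  ref <- gen_reference(spec)
  list(spec = spec, ref = ref)
}
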