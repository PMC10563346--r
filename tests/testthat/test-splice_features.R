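# Handcrafted scorer whose outputs we position explicitly: donor score 0.9
# at offset 10 of the alt frame, 0.1 at the matching ref position.
fixed_scorer <- function(alt_seq, hot = 10L, ref_val = 0.1, alt_val = 0.9) {
  site_scorer(function(seq, chrom = NA, start = NA) {
    n <- nchar(seq)
    don <- numeric(n)
    don[hot] <- if (identical(seq, alt_seq)) alt_val else ref_val
    list(acceptor = numeric(n), donor = don)
  })
}

test_that("delta/raw gain arithmetic and annotated-site masking", {
  ref <- rand_seq(30); alt <- ref
  substr(alt, 15, 15) <- if (substr(ref, 15, 15) == "A") "C" else "A"
  sc <- fixed_scorer(alt)
  g <- masked_gain_features(sc, ref, alt, var_offset = 15, d = 300)
  expect_equal(g$don_delta_gain, 0.8)
  expect_equal(g$don_raw_gain, 0.9)
  expect_equal(g$acc_delta_gain, 0)
  # masking the hot position as an annotated donor zeroes the delta only
  g2 <- masked_gain_features(sc, ref, alt, var_offset = 15,
                             annotated_sites = data.frame(offset = 10L,
                                                          kind = "donor"),
                             d = 300)
  expect_equal(g2$don_delta_gain, 0)
  expect_equal(g2$don_raw_gain, 0.9)       # raw gain ignores the mask
  # acceptor-kind mask does not touch the donor delta
  g3 <- masked_gain_features(sc, ref, alt, var_offset = 15,
                             annotated_sites = data.frame(offset = 10L,
                                                          kind = "acceptor"),
                             d = 300)
  expect_equal(g3$don_delta_gain, 0.8)
})

test_that("identity variant yields zero deltas and reference raw maxima", {
  set.seed(1)
  ref <- rand_seq(80)
  sc <- pwm_site_scorer()
  g <- masked_gain_features(sc, ref, ref, var_offset = 40, d = 300)
  expect_equal(g$don_delta_gain, 0)
  expect_equal(g$acc_delta_gain, 0)
  ss <- sc(ref, NA, NA)
  expect_equal(g$don_raw_gain, max(ss$donor))
  expect_equal(g$acc_raw_gain, max(ss$acceptor))
})

test_that("aggregate definitions: max, mean, raw mean", {
  sc <- site_scorer(function(seq, chrom = NA, start = NA) {
    n <- nchar(seq)
    alt <- grepl("GGG", seq)  # crude frame marker
    list(acceptor = rep(if (alt) 0.3 else 0, n),
         donor = rep(if (alt) 0.7 else 0, n))
  })
  ref <- paste(rep("A", 20), collapse = "")
  alt <- sub("AAA$", "GGG", ref)
  g <- masked_gain_features(sc, ref, alt, var_offset = 18, ref_len = 3,
                            alt_len = 3)
  expect_equal(g$acc_delta_gain, 0.3)
  expect_equal(g$don_delta_gain, 0.7)
  expect_equal(g$delta_gain_max, 0.7)
  expect_equal(g$delta_gain_mean, 0.5)
  expect_equal(g$raw_gain_mean, 0.5)
  expect_equal(g$raw_gain_max, 0.7)
})

test_that("gains match a brute-force position-mapping oracle on indels", {
  set.seed(5)
  sc <- probe_scorer()
  for (rep in 1:25) {
    n <- sample(40:70, 1)
    ref <- rand_seq(n)
    type <- sample(c("snv", "ins", "del"), 1)
    off <- sample(12:(n - 12), 1)
    if (type == "snv") {
      ref_len <- 1L; alt_allele <- sample(c("A", "C", "G", "T"), 1)
    } else if (type == "ins") {
      ref_len <- 1L
      alt_allele <- paste0(substr(ref, off, off), rand_seq(sample(1:4, 1)))
    } else {
      ref_len <- sample(2:4, 1)
      alt_allele <- substr(ref, off, off)
    }
    alt <- paste0(substr(ref, 1, off - 1), alt_allele,
                  substr(ref, off + ref_len, n))
    sites <- data.frame(offset = sample(n, 3),
                        kind = sample(c("donor", "acceptor"), 3,
                                      replace = TRUE))
    d <- sample(c(5L, 15L, 300L), 1)
    got <- masked_gain_features(sc, ref, alt, off, sites, d = d,
                                ref_len = ref_len,
                                alt_len = nchar(alt_allele))
    want <- gain_oracle(sc, ref, alt, off, sites, d, ref_len,
                        nchar(alt_allele))
    expect_equal(got$acc_raw_gain, want$acc_raw_gain)
    expect_equal(got$don_raw_gain, want$don_raw_gain)
    expect_equal(got$acc_delta_gain, max(0, want$acc_delta_gain))
    expect_equal(got$don_delta_gain, max(0, want$don_delta_gain))
  }
})

test_that("masking is monotone: more annotated sites never raise deltas", {
  set.seed(9)
  sc <- pwm_site_scorer()
  for (rep in 1:10) {
    ref <- rand_seq(120)
    alt <- ref
    substr(alt, 60, 60) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(ref, 60, 60)), 1)
    sites <- data.frame(offset = sample(120, 12),
                        kind = sample(c("donor", "acceptor"), 12,
                                      replace = TRUE))
    prev_max <- Inf; prev_mean <- Inf
    for (k in c(0, 4, 8, 12)) {
      g <- masked_gain_features(sc, ref, alt, 60,
                                sites[seq_len(k), , drop = FALSE], d = 300)
      expect_lte(g$delta_gain_max, prev_max)
      expect_lte(g$delta_gain_mean, prev_mean)
      prev_max <- g$delta_gain_max; prev_mean <- g$delta_gain_mean
    }
  }
})

test_that("window shorter than the variant extent errors", {
  expect_error(masked_gain_features(probe_scorer(), "ACGT", "ACG", 4,
                                    ref_len = 2, alt_len = 1), "extent")
})

test_that("mes_score is a per-position log-odds sum", {
  bg <- motif_model(matrix(0.25, 9, 4), matrix(0.25, 23, 4))
  expect_equal(mes_score(rand_seq(9), bg, "donor"), 0)
  expect_equal(mes_score(rand_seq(23), bg, "acceptor"), 0)
  m <- default_motif_model()
  w <- "CAGGTAAGT"
  idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
  hand <- sum(log2(m$donor[cbind(1:9, idx)] / 0.25))
  expect_equal(mes_score(w, m, "donor"), hand)
  expect_error(mes_score("ACGTACGT", m, "donor"), "length")
  expect_error(mes_score("ACGTNACGT", m, "donor"), "non-ACGT")
})

test_that("motif variant feature: identity, clamp, and enumeration oracle", {
  m <- default_motif_model()
  s <- rand_seq(60)
  expect_equal(mes_variant_feature(s, s, 30, m), 0)     # a == r
  # a strong created site above the cap clamps to 1
  ref <- paste0(rand_seq(20), "CAGGAAAGT", rand_seq(20))
  alt <- ref; substr(alt, 25, 25) <- "T"                 # completes GTAAGT
  if (mes_score(substr(alt, 21, 29), m, "donor") >= m$cap)
    expect_equal(mes_variant_feature(ref, alt, 25, m), 1.0)
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(30:60, 1)
    ref <- rand_seq(n)
    off <- sample(5:(n - 5), 1)
    type <- sample(c("snv", "ins", "del"), 1)
    if (type == "snv") { ref_len <- 1L
      alt_allele <- sample(c("A", "C", "G", "T"), 1)
    } else if (type == "ins") { ref_len <- 1L
      alt_allele <- paste0(substr(ref, off, off), rand_seq(2))
    } else { ref_len <- 3L; alt_allele <- substr(ref, off, off) }
    alt <- paste0(substr(ref, 1, off - 1), alt_allele,
                  substr(ref, off + ref_len, n))
    got <- mes_variant_feature(ref, alt, off, m, ref_len,
                               nchar(alt_allele))
    want <- mes_feature_oracle(ref, alt, off, m, ref_len,
                               nchar(alt_allele))
    expect_equal(got, want)
  }
})

test_that("feature vectors are complete only with all five features", {
  g <- masked_gain_features(probe_scorer(), rand_seq(30), rand_seq(30), 15)
  f1 <- assemble_features(g, mes = 0.4, constraint = 0.7)
  expect_true(f1$complete)
  f2 <- assemble_features(g, mes = 0.4, constraint = NA)
  expect_false(f2$complete)
  f0 <- assemble_features(g, mes = 0, constraint = 0)  # all-zero is valid
  expect_true(f0$complete)
  # raw aggregate switch
  expect_equal(assemble_features(g, 0, 0, "max")$spliceai_raw_gain_mean,
               g$raw_gain_max)
})

test_that("PWM site scorer obeys the scorer contract", {
  sc <- pwm_site_scorer()
  s <- rand_seq(200)
  out <- sc(s, NA, NA)
  expect_length(out$donor, 200)
  expect_length(out$acceptor, 200)
  expect_true(all(out$donor >= 0 & out$donor <= 1))
  expect_true(all(out$acceptor >= 0 & out$acceptor <= 1))
  expect_identical(out, sc(s, NA, NA))   # deterministic
})

test_that("precomputed TSV scorer serves scores by coordinate", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "chr1", pos = c(100, 102),
                         acc = c(0.4, 0), don = c(0, 0.8)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- tsv_site_scorer(p)
  out <- sc("ACGTA", "chr1", 99)
  expect_equal(out$acceptor, c(0, 0.4, 0, 0, 0))
  expect_equal(out$donor, c(0, 0, 0, 0.8, 0))
  expect_error(sc("ACGT", NA, NA), "coordinates")
})

test_that("minus-strand annotation equals the mirrored plus-strand case", {
  # same physical locus annotated on both strands: the donor created on the
  # minus strand must be found via reverse complement
  set.seed(21)
  world <- small_feature_world()
  ref <- world$ref
  cr <- ref$cryptic[1, ]
  tx <- ref$transcripts[[cr$gene_id]]
  v <- variants(cr$chrom, cr$pos, cr$ref, cr$alt,
                af = list(gnomAD = 0, KGP = 0))
  plus <- annotate_variants(v, ref$transcripts, ref$genome,
                            pwm_site_scorer(), track = ref$constraint)
  expect_true(plus$complete)
  expect_gt(plus$spliceai_del_gain_max, 0.3)
  # flip the transcript to minus: the planted plus-orientation motif is no
  # longer seen in transcript orientation, so the gain drops
  txs_minus <- ref$transcripts
  txs_minus[[cr$gene_id]] <- transcript_model(
    tx$gene_id, tx$transcript_id, tx$chrom, "-", tx$exons)
  minus <- annotate_variants(v, txs_minus, ref$genome, pwm_site_scorer(),
                             track = ref$constraint)
  expect_lt(minus$spliceai_del_gain_max, plus$spliceai_del_gain_max)
})
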