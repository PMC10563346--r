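# Toy transcript: exons 101-200, 301-400, 501-600; introns 201-300, 401-500.

test_that("nearest_splice_distance counts intronic bases inclusively", {
  t <- toy_tx()
  expect_equal(nearest_splice_distance(201, t), 1L)   # first intronic base
  expect_equal(nearest_splice_distance(250, t), 50L)  # min(50, 51)
  expect_equal(nearest_splice_distance(150, t), 0L)   # exonic
  expect_equal(nearest_splice_distance(300, t), 1L)   # last intronic base
  expect_true(is.na(nearest_splice_distance(50, t)))  # outside gene span
})

test_that("deep-intron boundary is inclusive at 50 bases", {
  t <- toy_tx()
  v <- variants(rep("chr1", 4), c(249L, 250L, 150L, 251L),
                rep("A", 4), rep("G", 4))
  r <- classify_region(v, t)
  expect_equal(r$zone, c("near_splice_intronic", "deep_intronic", "exonic",
                         "deep_intronic"))
  expect_equal(r$distance_bp, c(49L, 50L, NA, 50L))  # 251: min(51, 50)
})

test_that("deletions use the most splice-proximal deleted base", {
  t <- toy_tx()
  # deletion spanning 248..252: closest base 248 is at distance 48
  v <- variants("chr1", 248L, "AAAAA", "A")
  expect_equal(classify_region(v, t)$zone, "near_splice_intronic")
  # wholly deep deletion stays deep
  v2 <- variants("chr1", 250L, "AA", "A")
  expect_equal(classify_region(v2, t)$zone, "deep_intronic")
})

test_that("intronic zones partition at the 50-base boundary on random genes", {
  set.seed(42)
  for (rep in 1:20) {
    ne <- sample(2:5, 1)
    widths <- sample(80:200, ne, replace = TRUE)
    gaps <- sample(120:400, ne - 1, replace = TRUE)
    starts <- cumsum(c(sample(50:200, 1), widths[-ne] + gaps))
    t <- transcript_model("G", "T", "chr1", sample(c("+", "-"), 1),
                          cbind(starts, starts + widths - 1L))
    span <- c(starts[1], starts[ne] + widths[ne] - 1L)
    pos <- sample(span[1]:span[2], 40)
    d <- nearest_splice_distance(pos, t)
    zone <- classify_region(variants(rep("chr1", 40), pos, "A", "G"), t)$zone
    intronic <- d > 0
    expect_true(all(zone[intronic] %in%
                    c("deep_intronic", "near_splice_intronic")))
    expect_equal(zone[intronic] == "deep_intronic", d[intronic] >= 50)
    expect_true(all(zone[!intronic] == "exonic"))
  }
})

test_that("motif-region windows follow the 9/23-base MaxEntScan geometry", {
  # donor on + strand at site s: window s-3 .. s+5
  expect_equal(classify_motif_region(201, 201, "donor", "+"), "donor_motif")
  expect_equal(classify_motif_region(206, 201, "donor", "+"), "donor_motif")
  expect_equal(classify_motif_region(207, 201, "donor", "+"), "outside")
  expect_equal(classify_motif_region(198, 201, "donor", "+"), "donor_motif")
  expect_equal(classify_motif_region(197, 201, "donor", "+"), "outside")
  # acceptor on + strand at site s: window s-19 .. s+3
  expect_equal(classify_motif_region(281, 300, "acceptor", "+"),
               "acceptor_motif")
  expect_equal(classify_motif_region(280, 300, "acceptor", "+"), "outside")
  expect_equal(classify_motif_region(303, 300, "acceptor", "+"),
               "acceptor_motif")
  # minus strand mirrors the windows
  expect_equal(classify_motif_region(196, 201, "donor", "-"), "donor_motif")
  expect_equal(classify_motif_region(195, 201, "donor", "-"), "outside")
  expect_equal(classify_motif_region(319, 300, "acceptor", "-"),
               "acceptor_motif")
  expect_equal(classify_motif_region(320, 300, "acceptor", "-"), "outside")
})

test_that("splice sites derive from internal boundaries, strand-aware", {
  plus <- splice_sites(toy_tx("+"))
  expect_equal(plus$pos, c(201L, 300L, 401L, 500L))
  expect_equal(plus$kind, c("donor", "acceptor", "donor", "acceptor"))
  minus <- splice_sites(toy_tx("-"))
  expect_equal(minus$kind, c("acceptor", "donor", "acceptor", "donor"))
  expect_equal(nrow(splice_sites(transcript_model("G", "T", "c", "+",
                                                  cbind(1, 100)))), 0)
})

test_that("rarity and commonness filters use every source, missing AF = 0", {
  v <- variants(rep("chr1", 4), 1:4 * 100L, rep("A", 4), rep("G", 4),
                af = list(gnomAD = c(0.02, 0.005, NA, 0.06),
                          KGP = c(0.01, 0.0, NA, 0.05)))
  src <- c("gnomAD", "KGP")
  expect_equal(passes_rare_filter(v, src), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(passes_common_filter(v, src), c(FALSE, FALSE, FALSE, TRUE))
  # inclusive >= 5% boundary; 5% + 1% mix fails the common filter
  v2 <- variants(rep("c", 2), c(1L, 2L), "A", "G",
                 af = list(KGP = c(0.05, 0.05), gnomAD = c(0.06, 0.01)))
  expect_equal(passes_common_filter(v2, src), c(TRUE, FALSE))
})

test_that("rare and common filters are mutually exclusive at defaults", {
  set.seed(7)
  af1 <- runif(200); af2 <- runif(200)
  af1[sample(200, 30)] <- NA; af2[sample(200, 30)] <- NA
  v <- variants(rep("chr1", 200), seq_len(200), "A", "G",
                af = list(gnomAD = af1, KGP = af2))
  both <- passes_rare_filter(v, c("gnomAD", "KGP")) &
    passes_common_filter(v, c("gnomAD", "KGP"))
  expect_false(any(both))
})
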