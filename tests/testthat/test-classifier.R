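beta_table <- function(n_path, n_benign, seed) {
  set.seed(seed)
  mk <- function(n, a, b) data.frame(
    spliceai_del_gain_mean = rbeta(n, a, b),
    spliceai_del_gain_max = rbeta(n, a, b),
    spliceai_raw_gain_mean = rbeta(n, a, b),
    consplice = rbeta(n, a, b),
    maxentscan = rbeta(n, a, b))
  rbind(cbind(mk(n_path, 8, 2), label = "pathogenic"),
        cbind(mk(n_benign, 2, 8), label = "benign"))
}

test_that("tuning: one-point grid, determinism, and interaction depth", {
  tab <- beta_table(30, 60, 1)
  one <- data.frame(ntree = 50, max_depth = 4, sample_frac = 1, mtry = 2)
  got <- tune_hyperparameters(tab, tab$label, one, k = 3, seed = 5)
  expect_equal(got$best, one, ignore_attr = TRUE)
  expect_error(tune_hyperparameters(tab, tab$label, one[0, ]), "empty")

  # XOR-structured labels: depth-1 stumps cannot express the interaction
  set.seed(2)
  n <- 240
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  xor_tab <- data.frame(
    spliceai_del_gain_mean = x1 + runif(n, 0, .05),
    spliceai_del_gain_max = x2 + runif(n, 0, .05),
    spliceai_raw_gain_mean = runif(n), consplice = runif(n),
    maxentscan = runif(n))
  xor_tab$spliceai_del_gain_mean <- xor_tab$spliceai_del_gain_mean / 1.05
  xor_tab$spliceai_del_gain_max <- xor_tab$spliceai_del_gain_max / 1.05
  y <- as.integer(xor(x1 == 1, x2 == 1))
  grid <- data.frame(ntree = 100, max_depth = c(1, 8), sample_frac = 1,
                     mtry = 5)
  pick <- tune_hyperparameters(xor_tab, y, grid, k = 5, seed = 3)
  expect_equal(pick$best$max_depth, 8)
  expect_gt(pick$cv$mean_ap[2], pick$cv$mean_ap[1])

  # fixed seed: identical selection twice
  again <- tune_hyperparameters(xor_tab, y, grid, k = 5, seed = 3)
  expect_identical(pick, again)
})

test_that("near-separable training recovers the classes", {
  tab <- beta_table(60, 140, 4)
  tr <- c(1:40, 61:160)
  te <- setdiff(seq_len(nrow(tab)), tr)
  fit <- pdivas(tab[tr, ], hp = list(ntree = 300, max_depth = NA,
                                     sample_frac = 1, mtry = 2), seed = 9)
  s <- predict(fit, tab[te, ])
  y <- as.integer(tab$label[te] == "pathogenic")
  expect_gte(average_precision(y, s), 0.99)
})

test_that("scores obey the fraction-of-trees contract", {
  tab <- beta_table(25, 50, 6)
  fit <- pdivas(tab, hp = list(ntree = 73, max_depth = 8, sample_frac = .8,
                               mtry = 2), seed = 2)
  s <- predict(fit, tab)
  expect_true(all(s >= 0 & s <= 1))
  # granularity: every score is an integer multiple of 1/T
  expect_equal(round(s * 73), s * 73, tolerance = 1e-12)
  # bit-stable under a fixed seed
  fit2 <- pdivas(tab, hp = fit$hp, seed = 2)
  expect_identical(predict(fit2, tab), s)
  # incomplete vector: unscorable signal, never a numeric score
  bad <- tab[1, ]; bad$consplice <- NA
  expect_true(is.na(predict(fit, bad)))
  # single-class training set errors
  expect_error(pdivas(tab[tab$label == "benign", ]), "both classes")
})

test_that("identical feature rows vote by bootstrap majority", {
  one <- data.frame(spliceai_del_gain_mean = .5, spliceai_del_gain_max = .5,
                    spliceai_raw_gain_mean = .5, consplice = .5,
                    maxentscan = .5)
  rows <- one[rep(1, 100), ]
  hp <- list(ntree = 400, max_depth = 4, sample_frac = 1, mtry = 2)
  # 30% pathogenic: almost every bootstrap majority is benign
  f30 <- pdivas(rows, rep(c(1, 0), c(30, 70)), hp = hp, seed = 3)
  expect_lt(predict(f30, one), 0.05)
  # 50/50 mix: majorities split close to evenly (ties vote benign)
  f50 <- pdivas(rows, rep(c(1, 0), c(50, 50)), hp = hp, seed = 3)
  expect_gt(predict(f50, one), 0.25)
  expect_lt(predict(f50, one), 0.55)
})

test_that("feature importances are normalized and track the signal", {
  tab <- beta_table(40, 80, 8)
  # keep only one informative feature
  set.seed(8)
  for (f in setdiff(pdivas_features(), "spliceai_del_gain_mean"))
    tab[[f]] <- runif(nrow(tab))
  fit <- pdivas(tab, hp = list(ntree = 200, max_depth = 8, sample_frac = 1,
                               mtry = 2), seed = 1)
  imp <- feature_importances(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "spliceai_del_gain_mean")
})

test_that("cumulative-feature analysis reuses one split and orders signal", {
  set.seed(10)
  n <- 300
  tab <- data.frame(
    spliceai_del_gain_mean = runif(n),   # pure noise
    spliceai_del_gain_max = runif(n),    # pure noise
    spliceai_raw_gain_mean = runif(n),
    consplice = runif(n), maxentscan = runif(n))
  y <- rbinom(n, 1, 0.3)
  tab$consplice <- ifelse(y == 1, rbeta(n, 8, 2), rbeta(n, 2, 8))
  tr <- sample(n, 200); te <- setdiff(seq_len(n), tr)
  hp <- list(ntree = 150, max_depth = 8, sample_frac = 1, mtry = 1)

  one <- cumulative_feature_analysis(tab[tr, ], tab[te, ], y[tr], y[te],
                                     "consplice", hp = hp, seed = 2)
  expect_equal(nrow(one), 1)

  res <- cumulative_feature_analysis(
    tab[tr, ], tab[te, ], y[tr], y[te],
    c("spliceai_del_gain_mean", "consplice", "spliceai_del_gain_max"),
    hp = hp, seed = 2)
  expect_equal(res$n_features, 1:3)
  # adding the informative feature to a noise-only prefix helps sharply
  expect_gt(res$average_precision[2], res$average_precision[1] + 0.2)
  # adding another pure-noise feature stays within stochastic tolerance
  expect_lt(abs(res$average_precision[3] - res$average_precision[2]), 0.08)
})
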