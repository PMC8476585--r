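test_that("masked reconstruction error matches hand-computed values", {
  Y <- encode_ss3("HEC", L_max = 5)
  expect_identical(masked_mse(Y, Y), 0)
  # three real positions, per-position channel-sum squared error 0.25 each:
  # (1/3) * 0.75 = 0.25
  Yhat <- unclass(Y)
  Yhat[1, ] <- Y[1, ] + c(0.3, 0.4, 0)     # 0.09 + 0.16 = 0.25
  Yhat[2, ] <- Y[2, ] + c(0, 0.5, 0)       # 0.25
  Yhat[3, ] <- Y[3, ] + c(0.5, 0, 0)       # 0.25
  expect_equal(masked_mse(Y, Yhat), 0.25, tolerance = 1e-12)
  # perturbing only padding rows changes nothing
  Yhat2 <- Yhat
  Yhat2[4:5, ] <- 99
  expect_identical(masked_mse(Y, Yhat), masked_mse(Y, Yhat2))
  expect_error(masked_mse(Y, Yhat[1:3, ]), "shape mismatch")
})

test_that("masked form reduces to the plain mean square without padding", {
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- sample(3:20, 1)
      s <- paste(sample(c("H", "E", "C"), n, replace = TRUE), collapse = "")
      Y <- encode_ss3(s, L_max = n)  # no padding at all
      Yhat <- unclass(Y) + matrix(rnorm(n * 3, 0, 0.2), n, 3)
      expect_equal(masked_mse(Y, Yhat), sum((Y - Yhat)^2) / n,
                   tolerance = 1e-12)
    }
  })
})

test_that("fold assignment score reproduces worked examples exactly", {
  st <- cluster_stats("c1", RE_b = 0.05, OOC_b = 0.10, OOF_b = 0.15)
  # zero numerator forces -100 * thres
  expect_equal(fas(0.10, st, thres = 0.014), -1.4, tolerance = 1e-12)
  # direct arithmetic: (0.05 * 0.05 / 0.10 - 0.014) * 100 = 1.1
  expect_equal(fas(0.05, st, thres = 0.014), 1.1, tolerance = 1e-12)
})

test_that("the score is affine and strictly decreasing in the family RE", {
  st <- cluster_stats("c1", RE_b = 0.04, OOC_b = 0.09, OOF_b = 0.16)
  slope_expected <- -100 * (st$OOF_b - st$OOC_b) / (st$OOF_b - st$RE_b)
  grid <- seq(0, 0.3, by = 0.01)
  vals <- vapply(grid, fas, 0, stats = st)
  slopes <- diff(vals) / diff(grid)
  expect_equal(slopes, rep(slope_expected, length(slopes)),
               tolerance = 1e-9)
  expect_true(all(diff(vals) < 0))
  bad <- suppressWarnings(cluster_stats("c2", 0.05, 0.10, 0.05))
  expect_error(fas(0.02, bad), "OOF_b equals RE_b")
})

test_that("implausible cluster statistics are warned about but kept", {
  expect_warning(cluster_stats("w", RE_b = 0.10, OOC_b = 0.05, OOF_b = 0.2),
                 "RE_b <= OOC_b <= OOF_b")
})

test_that("gumbel fit recovers known parameters from 20,000 samples", {
  x <- withr::with_seed(100, rgumbel(20000, loc = 0.05, scale = 0.01))
  cal <- calibrate(x)
  expect_lt(abs(cal$loc - 0.05), 0.001)
  expect_lt(abs(cal$scale - 0.01), 0.001)
  expect_equal(cal$mid_threshold, (cal$ci95_upper + cal$ci99_upper) / 2)
  expect_lte(cal$ci95_upper, cal$ci99_upper)
})

test_that("calibration edge cases behave as specified", {
  x <- withr::with_seed(101, rgumbel(200, 0.05, 0.01))
  # q95 = q99 collapses the midpoint onto that single quantile
  cal <- calibrate(x, q95 = 0.95, q99 = 0.95)
  expect_equal(cal$mid_threshold, cal$ci95_upper)
  expect_equal(cal$ci95_upper, cal$ci99_upper)
  # two-sided reading uses the wider quantiles
  cal2 <- calibrate(x, two_sided = TRUE)
  expect_gt(cal2$ci95_upper, calibrate(x)$ci95_upper)
  expect_error(calibrate(x[1:10]), "at least 50")
  expect_error(calibrate(rep(0.05, 60)), "degenerate")
})

paper_calibration <- function() re_calibration(0.107, 0.147)

test_that("the published calibration reproduces the published thresholds", {
  cal <- paper_calibration()
  expect_equal(cal$mid_threshold, 0.127)
  # the high-confidence bound maps back to 0.1 under this calibration
  expect_equal(known_high_bound(cal), 0.1, tolerance = 1e-12)
})

test_that("the decision table is total and hits every branch once", {
  cal <- paper_calibration()
  fas_pos <- c(a = 1.5, b = -2)
  fas_small <- c(a = 0.5, b = -2)
  fas_neg <- c(a = -0.5, b = -2)
  cases <- list(
    # (i) below the 95% limit: known; high needs low mRE and FAS > 1
    list(0.090, fas_pos, "known", "high", "a"),
    list(0.090, fas_small, "known", "medium", "a"),
    list(0.105, fas_pos, "known", "medium", "a"),   # above the 0.1 bound
    list(0.050, fas_neg, "known", "medium", "a"),
    # (ii) between the 95% limit and the midpoint
    list(0.110, fas_small, "known", "low", "a"),
    list(0.110, fas_neg, "variant", "low", NA_character_),
    list(0.120, fas_neg, "variant", "medium", NA_character_),
    # (iii) at or above the midpoint: novel, confidence grows with mRE
    list(0.130, fas_neg, "novel", "low", NA_character_),
    list(0.150, fas_neg, "novel", "medium", NA_character_),
    list(0.281, fas_neg, "novel", "high", NA_character_))
  for (cs in cases) {
    fc <- call_family(cs[[1]], cs[[2]], cal)
    expect_equal(fc$verdict, cs[[3]], info = paste("mRE", cs[[1]]))
    expect_equal(fc$confidence, cs[[4]], info = paste("mRE", cs[[1]]))
    expect_equal(fc$fold, cs[[5]], info = paste("mRE", cs[[1]]))
  }
})

test_that("a family like GT108 is called a novel fold with high confidence", {
  fc <- call_family(0.281, c(A0 = -3, B0 = -8, C0 = -12, lyso = -20),
                    paper_calibration())
  expect_equal(fc$verdict, "novel")
  expect_equal(fc$confidence, "high")
})

test_that("anomalies and ties are flagged", {
  cal <- paper_calibration()
  fc <- call_family(0.2, c(a = 2, b = -1), cal)
  expect_true("positive_fas_above_threshold" %in% fc$flags)
  expect_warning(tie <- call_family(0.05, c(b = 1, a = 1), cal), "tie")
  expect_equal(tie$fold, "a")  # lexicographically first of the tied set
  fc5 <- call_family(0.05, c(a = 2), cal, n_seqs = 3L)
  expect_true("low_reliability" %in% fc5$flags)
})

test_that("the out-of-cluster holdout is a seeded disjoint partition", {
  tbl <- ss3_tbl(sprintf("s%03d", 1:100), rep(strrep("HEC", 10), 100),
                 family = "F")
  sp <- build_ooc_holdout(tbl, fraction = 0.20, seed = 5L)
  expect_equal(nrow(sp$holdout), 20L)
  expect_equal(nrow(sp$train), 80L)
  expect_length(intersect(sp$train$id, sp$holdout$id), 0L)
  expect_setequal(c(sp$train$id, sp$holdout$id), tbl$id)
  sp2 <- build_ooc_holdout(tbl, fraction = 0.20, seed = 5L)
  expect_identical(sp$holdout$id, sp2$holdout$id)
  expect_error(build_ooc_holdout(tbl[1:4, ]), "at least 5")
})

test_that("autoencoder training freezes the encoder and separates novelty", {
  toy <- get_toy()
  ae <- get_toy_ae()
  verify_frozen(ae)
  pre <- toy$model$params[grep("^b1_", names(toy$model$params))]
  post <- ae$classifier$params[grep("^b1_", names(ae$classifier$params))]
  expect_identical(pre, post)  # bit-for-bit
  # training sequences reconstruct better than held-out novel archetypes
  re_novel <- reconstruction_errors(ae, toy$data$novel[1:50, ])
  expect_lt(median(ae$re_train), median(re_novel))
})

test_that("a per-cluster decoder reconstructs its own archetype best", {
  toy <- get_toy()
  own <- toy$data$train[toy$data$train$fold == "rossmann", ]
  other <- toy$data$train[toy$data$train$fold != "rossmann", ]
  ae_own <- train_autoencoder(toy$model, own[1:60, ],
                              decoder_filters = c(24L, 16L, 12L),
                              epochs = 10L, lr = 3e-3, seed = 51L)
  re_own <- reconstruction_errors(ae_own, own[61:100, ])
  re_other <- reconstruction_errors(ae_own, other[1:40, ])
  # paired comparison at matched sample size
  expect_lt(median(re_own), median(re_other))
  expect_gt(mean(re_other > median(re_own)), 0.8)
})

test_that("families from training archetypes score as known, novel as novel", {
  toy <- get_toy()
  os <- suppressWarnings(
    fit_openset(toy$model, toy$data$train[-toy$val_idx, ],
                decoder_filters = c(24L, 16L, 12L), epochs = 10L,
                lr = 3e-3, seed = 61L))
  known_scores <- score_unknown_families(os, toy$data$train[toy$val_idx, ])
  expect_true(all(known_scores$verdict == "known"))
  expect_gte(mean(known_scores$best_cluster ==
                    sub("_f[0-9]+$", "", known_scores$family)), 0.5)
  novel_scores <- score_unknown_families(os, toy$data$novel)
  expect_gte(mean(novel_scores$verdict == "novel"), 0.5)
  # empty input gives an empty result
  empty <- toy$data$novel[0, ]
  expect_equal(nrow(score_unknown_families(os, empty)), 0L)
  .fixture_cache$toy_os <- os
})
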