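test_that("model construction follows the configured architecture", {
  cfg <- model_config()
  expect_equal(cfg$block1_kernels, c(3L, 7L, 15L))
  expect_equal(cfg$block1_filters, c(256L, 512L, 512L))
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$weight_decay, 1e-5)
  small <- model_config(L_max = 32L, block1_filters = c(4L, 6L, 6L),
                        block2_filters = c(6L, 6L, 5L),
                        attention_reduction = 2L)
  m <- build_model(small, folds = c("A", "B"), families = c("f1", "f2"))
  expect_equal(dim(m$params$b1_1_W), c(3L * 3L, 4L))
  expect_equal(dim(m$params$b1_2_W), c(7L * 4L, 6L))
  expect_equal(dim(m$params$b1_3_W), c(15L * 6L, 6L))
  expect_equal(dim(m$params$head_fold_W), c(5L, 2L))
  expect_error(build_model(small, folds = "A", families = c("f1", "f2")),
               "at least 2 fold classes")
  expect_error(build_model(small, folds = c("A", "B"), families = "f1"),
               "at least 2 family classes")
})

test_that("Block 1 preserves spatial length and all-padding input stays finite", {
  small <- model_config(L_max = 16L, block1_filters = c(4L, 5L, 5L),
                        block2_filters = c(5L, 5L, 4L), bridge_window = 2L,
                        attention_reduction = 2L)
  m <- build_model(small, folds = c("A", "B"), families = c("f1", "f2"))
  x <- matrix(0, 16L, 3L)        # a fully padded "sequence"
  mask <- rep(FALSE, 16L)
  fw <- nn_forward(m, x, mask, 16L, 1L, train = FALSE)
  expect_true(all(is.finite(fw$logits_fold)))
  expect_true(all(is.finite(fw$logits_fam)))
  for (j in 1:3) {
    expect_equal(nrow(fw$caches$b1[[j]]$A_out), 16L)  # stride-1 contract
  }
})

test_that("spatial fidelity: perturbations stay within the receptive field", {
  small <- model_config(L_max = 32L, block1_filters = c(4L, 5L, 5L),
                        block2_filters = c(5L, 5L, 4L), bridge_window = 2L,
                        attention_reduction = 2L, sa_kernel = 7L, seed = 8L)
  m <- build_model(small, folds = c("A", "B"), families = c("f1", "f2"))
  s1 <- strrep("HEC", 10)
  s2 <- paste0(substr(s1, 1, 14), "H", substr(s1, 16, 30))  # flip pos 15
  e1 <- encode_set(ss3_tbl("a", s1), 32L)
  e2 <- encode_set(ss3_tbl("a", s2), 32L)
  f1 <- nn_forward(m, e1$x, e1$mask, 32L, 1L, train = FALSE)
  f2 <- nn_forward(m, e2$x, e2$mask, 32L, 1L, train = FALSE)
  # layer-1 convolution (kernel 3): pre-attention maps change within radius 1
  pre1 <- relu(f1$caches$b1[[1]]$bn$out)
  pre2 <- relu(f2$caches$b1[[1]]$bn$out)
  changed <- which(rowSums(abs(pre1 - pre2)) > 1e-12)
  expect_true(all(abs(changed - 15L) <= 1L))
  # post-attention maps add the spatial-attention radius (kernel 7 -> +3)
  post1 <- f1$caches$b1[[1]]$A_out
  post2 <- f2$caches$b1[[1]]$A_out
  changed_post <- which(rowSums(abs(post1 - post2)) > 1e-12)
  expect_true(all(abs(changed_post - 15L) <= 4L))
})

test_that("a separable two-archetype grammar is learned to high accuracy", {
  toy <- get_toy()
  expect_gte(max(toy$model$log$val_fold_acc), 0.99)
  expect_lte(toy$model$best_epoch, 20L)
})

test_that("posteriors are normalized, deterministic, and memorize toy labels", {
  toy <- get_toy()
  sub <- toy$data$train[1:40, ]
  pr <- predict(toy$model, sub)
  expect_true(all(abs(rowSums(pr$fold_posterior) - 1) < 1e-6))
  expect_true(all(abs(rowSums(pr$family_posterior) - 1) < 1e-6))
  # memorization oracle on training sequences of a converged model
  expect_gte(mean(pr$calls$fold_call == sub$fold), 0.99)
  # duplicated input rows yield identical posteriors
  dup <- sub[c(1, 1, 2), ]
  dup$id <- c("d1", "d2", "d3")
  pd <- predict(toy$model, dup)
  expect_identical(pd$fold_posterior[1, ], pd$fold_posterior[2, ])
  # encoding mismatch is an error, never silent truncation
  long <- ss3_tbl("too_long", strrep("H", toy$model$config$L_max + 1L))
  expect_error(predict(toy$model, long), "L_max")
})

test_that("embeddings have the contracted shape and ignore padding entirely", {
  toy <- get_toy()
  sub <- toy$data$train[1:10, ]
  em <- embed_sequences(toy$model, sub)
  expect_equal(ncol(em$embedding),
               tail(toy$model$config$block2_filters, 1))
  expect_true(all(is.finite(em$embedding)))
  # identical sequences -> identical vectors
  dup <- sub[c(1, 1), ]
  dup$id <- c("d1", "d2")
  ed <- embed_sequences(toy$model, dup)
  expect_identical(ed$embedding[1, ], ed$embedding[2, ])
  # appending extra padding leaves the embedding bit-for-bit unchanged
  em_wide <- embed_sequences(toy$model, sub,
                             L_max = toy$model$config$L_max + 64L)
  expect_identical(em$embedding, em_wide$embedding)
})

test_that("embeddings separate archetypes (cosine-similarity oracle)", {
  toy <- get_toy()
  sub <- toy$data$train[toy$data$train$id %in%
                          toy$data$train$id[c(1:15, 101:115)], ]
  em <- embed_sequences(toy$model, sub)
  V <- em$embedding / sqrt(rowSums(em$embedding^2))
  S <- tcrossprod(V)
  fam <- sub$family
  fold <- sub$fold
  same_fam <- outer(fam, fam, "==") & !diag(nrow(S))
  diff_fold <- outer(fold, fold, "!=")
  expect_gt(mean(S[same_fam]), mean(S[diff_fold]))
})

test_that("family predictions are consistent with the fold head", {
  toy <- get_toy()
  sub <- toy$data$train[seq(1, 200, by = 5), ]
  pr <- predict(toy$model, sub)
  fam2fold <- unique(toy$data$train[c("family", "fold")])
  implied <- fam2fold$fold[match(pr$calls$family_call, fam2fold$family)]
  expect_lt(mean(implied != pr$calls$fold_call), 0.10)
})

test_that("an untrained model warns but still embeds and predicts", {
  small <- model_config(L_max = 16L, block1_filters = c(4L, 5L, 5L),
                        block2_filters = c(5L, 5L, 4L), bridge_window = 2L,
                        attention_reduction = 2L)
  m <- build_model(small, folds = c("A", "B"), families = c("f1", "f2"))
  tbl <- ss3_tbl("a", "HECHEC")
  expect_warning(em <- embed_sequences(m, tbl), "untrained")
  expect_equal(dim(em$embedding), c(1L, 4L))
  expect_warning(predict(m, tbl), "untrained")
})
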