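test_that("grad-cam normalizes to max 1 and zero-gradient maps are all zero", {
  toy <- get_toy()
  sub <- toy$data$train[1:5, ]
  prof <- grad_cam(toy$model, sub, layer = 2L,
                   target_class = toy$model$fold_vocab[1], task = "fold")
  for (p in prof) {
    expect_length(p$values, nchar(p$states))
    expect_true(all(p$values >= 0 & p$values <= 1))
    if (any(p$values > 0)) expect_equal(max(p$values), 1)
  }
  # constant logits (zeroed head) give an identically zero rectified map
  m0 <- toy$model
  m0$params$head_fold_W[] <- 0
  prof0 <- grad_cam(m0, sub[1, ], layer = 2L,
                    target_class = m0$fold_vocab[1], task = "fold")
  expect_true(all(prof0[[1]]$values == 0))
})

test_that("grad-cam values are invariant to extra padding", {
  toy <- get_toy()
  sub <- toy$data$train[1:3, ]
  p1 <- grad_cam(toy$model, sub, layer = 2L,
                 target_class = toy$model$fold_vocab[1], task = "fold")
  m_wide <- toy$model
  m_wide$config$L_max <- toy$model$config$L_max + 32L
  p2 <- grad_cam(m_wide, sub, layer = 2L,
                 target_class = toy$model$fold_vocab[1], task = "fold")
  for (i in seq_along(p1)) expect_equal(p1[[i]]$values, p2[[i]]$values)
})

test_that("grad-cam rejects unknown target classes", {
  toy <- get_toy()
  expect_error(grad_cam(toy$model, toy$data$train[1, ], layer = 2L,
                        target_class = "no-such-fold", task = "fold"),
               "not in fold vocabulary")
})

test_that("family CAM averaging matches hand computation on a built map", {
  mk <- function(id, vals, states) {
    structure(list(id = id, layer = 2L, target_class = "A", task = "fold",
                   states = states, values = vals), class = "cam_profile")
  }
  profiles <- list(mk("s1", c(1, 0.5, 0), "HEC"),
                   mk("s2", c(0.2, 0.8), "HC"),
                   mk("s3", c(0.4, 0.6, 1), "EEC"))
  # 4 alignment columns; s2 skips column 2; column 4 is s3-only
  column_map <- data.frame(
    id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    position = c(1L, 2L, 3L, 1L, 2L, 1L, 2L, 3L),
    column = c(1L, 2L, 3L, 1L, 3L, 1L, 2L, 4L))
  avg <- family_cam(profiles, column_map)
  expect_equal(avg$values,
               c((1 + 0.2 + 0.4) / 3, (0.5 + 0.6) / 2, (0 + 0.8) / 2, 1))
  # consensus: col1 H/H/E -> H, col2 E/E -> E, col3 C/C -> C, col4 C
  expect_equal(avg$states, "HECC")
  expect_equal(avg$coverage, c(3L, 2L, 2L, 1L))
  # permutation invariance in the profile list
  avg2 <- family_cam(rev(profiles), column_map)
  expect_equal(avg2$values, avg$values)
  # single sequence with the identity map passes through unchanged
  one <- family_cam(profiles[1],
                    data.frame(id = "s1", position = 1:3, column = 1:3))
  expect_equal(one$values, profiles[[1]]$values)
  # empty column yields a missing value
  gap <- family_cam(profiles[1],
                    data.frame(id = "s1", position = 1:3,
                               column = c(1L, 2L, 4L)))
  expect_true(is.na(gap$values[3]))
})

test_that("family CAM refuses mixed layers", {
  p1 <- structure(list(id = "a", layer = 1L, target_class = "A",
                       task = "fold", states = "H", values = 1),
                  class = "cam_profile")
  p2 <- structure(list(id = "b", layer = 2L, target_class = "A",
                       task = "fold", states = "H", values = 1),
                  class = "cam_profile")
  expect_error(family_cam(list(p1, p2),
                          data.frame(id = "a", position = 1, column = 1)),
               "different layers")
})

test_that("projection scan emits the full parameter grid deterministically", {
  X <- withr::with_seed(3, matrix(rnorm(40 * 6), 40, 6))
  scan <- umap_scan(X, repeats = 3L, seed = 5L, method = "pca")
  expect_equal(nrow(scan), 3L * 4L * 3L * 40L)  # grid x repeats x points
  expect_equal(length(unique(paste(scan$n_neighbors, scan$min_dist,
                                   scan$rep))), 36L)
  single <- umap_scan(X, n_neighbors_list = 15L, min_dist_list = 0.1,
                      repeats = 1L, seed = 5L, method = "pca")
  expect_equal(nrow(single), 40L)
  expect_error(umap_scan(X[1:5, ], method = "pca"), "at least 10")
})

test_that("the umap backend reproduces projections under a fixed master seed", {
  X <- withr::with_seed(4, rbind(matrix(rnorm(60, 0), 30, 2),
                                 matrix(rnorm(60, 6), 30, 2)))
  s1 <- umap_scan(X, n_neighbors_list = 10L, min_dist_list = 0.1,
                  repeats = 1L, seed = 11L, method = "umap")
  s2 <- umap_scan(X, n_neighbors_list = 10L, min_dist_list = 0.1,
                  repeats = 1L, seed = 11L, method = "umap")
  expect_equal(nrow(s1), 60L)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
})

test_that("well-separated mixture components are recovered by the GMM", {
  withr::with_seed(6, {
    P <- rbind(cbind(rnorm(100, 0, 0.1), rnorm(100, 0, 0.1)),
               cbind(rnorm(100, 10, 0.1), rnorm(100, 10, 0.1)))
  })
  out <- gmm_cluster(P, n_components_range = 1:4)
  expect_equal(attr(out, "n_components"), 2L)
  truth <- rep(1:2, each = 100)
  assigned <- !is.na(out$cluster)
  agree <- max(mean(out$cluster[assigned] == truth[assigned]),
               mean(out$cluster[assigned] != truth[assigned]))
  expect_gte(agree, 0.99)
  # a cutoff above every score unassigns everything
  out2 <- gmm_cluster(P, n_components_range = 2L,
                      score_cutoff = max(out$gmm_score) + 1)
  expect_true(all(is.na(out2$cluster)))
  # degenerate inputs
  expect_warning(one <- gmm_cluster(matrix(1, 30, 2)), "identical")
  expect_true(all(one$cluster == 1L))
  expect_error(gmm_cluster(P[1:3, ], n_components_range = 4L),
               "fewer points")
})

test_that("gmm clusters of scan projections recover archetypes above chance", {
  toy <- get_toy()
  sub_idx <- seq(1, 200, by = 4)
  sub <- toy$data$train[sub_idx, ]
  em <- embed_sequences(toy$model, sub)
  scan <- umap_scan(em$embedding, n_neighbors_list = 15L,
                    min_dist_list = 0.1, repeats = 1L, seed = 7L,
                    method = "pca")
  cl <- gmm_cluster(scan[c("x", "y")], n_components_range = 1:5)
  keep <- !is.na(cl$cluster)
  obs <- mclust::adjustedRandIndex(cl$cluster[keep], sub$fold[keep])
  perm <- withr::with_seed(8, replicate(999, {
    mclust::adjustedRandIndex(cl$cluster[keep], sample(sub$fold[keep]))
  }))
  p <- (1 + sum(perm >= obs)) / 1000
  expect_lt(p, 0.01)
})

test_that("CAM TSV export is tidy per residue", {
  toy <- get_toy()
  prof <- grad_cam(toy$model, toy$data$train[1:2, ], layer = 1L,
                   target_class = toy$model$fold_vocab[1], task = "fold")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cam(prof, f)
  got <- utils::read.delim(f)
  expect_equal(names(got), c("id", "layer", "position", "state", "cam"))
  expect_equal(nrow(got), sum(vapply(prof, function(p) length(p$values), 0L)))
  expect_true(all(got$state %in% c("H", "E", "C")))
})
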