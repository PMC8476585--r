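test_that("archetype construction is deterministic and pairwise distinct", {
  cfg <- sim_config(n_archetypes = 5L, novel_archetypes = 2L, seed = 13L)
  a1 <- make_archetypes(cfg)
  a2 <- make_archetypes(cfg)
  expect_identical(a1, a2)
  expect_length(a1$train, 5L)
  expect_length(a1$novel, 2L)
  sigs <- vapply(c(a1$train, a1$novel),
                 function(a) paste(vapply(a$template, `[[`, "", 1L),
                                   collapse = ""), "")
  expect_equal(anyDuplicated(sigs), 0L)
})

test_that("a single-archetype config degenerates the classifier task", {
  cfg <- sim_config(n_archetypes = 1L, novel_archetypes = 0L,
                    seqs_per_family = 2L, seed = 1L)
  d <- sample_dataset(cfg)
  expect_equal(unique(d$train$fold), "rossmann")
  expect_error(build_model(model_config(L_max = 64L),
                           folds = unique(d$train$fold),
                           families = unique(d$train$family)),
               "at least 2 fold classes")
})

test_that("zero noise and zero length-jitter give identical family members", {
  arch <- fold_archetype("flat", list(list("H", 10L, 0), list("E", 6L, 0),
                                      list("C", 8L, 0)))
  cfg <- sim_config(n_archetypes = 1L, families_per_archetype = 2L,
                    seqs_per_family = 8L, insertion_rate = 0,
                    noise_rate = 0, novel_archetypes = 0L, seed = 5L)
  d <- sample_dataset(cfg, archetypes = list(train = list(arch),
                                             novel = list()))
  for (f in unique(d$train$family)) {
    expect_length(unique(d$train$states[d$train$family == f]), 1L)
  }
})

test_that("realized noise matches the configured rate (binomial oracle)", {
  arch <- fold_archetype("flat", list(list("H", 40L, 0), list("E", 30L, 0),
                                      list("C", 30L, 0)))
  rate <- 0.05
  cfg <- sim_config(n_archetypes = 1L, families_per_archetype = 1L,
                    seqs_per_family = 100L, insertion_rate = 0,
                    noise_rate = rate, novel_archetypes = 0L, seed = 17L)
  d <- sample_dataset(cfg, archetypes = list(train = list(arch),
                                             novel = list()))
  consensus <- strsplit(d$consensus[[1]], "")[[1]]
  diffs <- vapply(d$train$states, function(s) {
    sum(strsplit(s, "")[[1]] != consensus)
  }, 0)
  n_pos <- length(consensus) * nrow(d$train)  # 10,000 positions
  phat <- sum(diffs) / n_pos
  se <- sqrt(rate * (1 - rate) / n_pos)
  expect_lt(abs(phat - rate), 3 * se)
})

test_that("novel archetypes are held out and empty when not requested", {
  d0 <- sample_dataset(sim_config(novel_archetypes = 0L,
                                  seqs_per_family = 2L, seed = 3L))
  expect_equal(nrow(d0$novel), 0L)
  d1 <- sample_dataset(sim_config(seqs_per_family = 2L, seed = 3L))
  expect_equal(length(intersect(d1$train$fold, d1$novel$fold)), 0L)
  expect_true(all(d1$truth$novel[match(d1$novel$id, d1$truth$id)]))
})

test_that("emitted sequences satisfy container invariants and the max length", {
  cfg <- sim_config(seqs_per_family = 10L, seed = 23L)
  d <- sample_dataset(cfg)
  expect_s3_class(validate_ss3(d$train), "ss3_tbl")
  expect_true(all(d$train$n <= cfg$max_len))
  expect_true(all(d$novel$n <= cfg$max_len))
  expect_true(all(grepl("^[HEC]+$", d$train$states)))
})

test_that("fixed seed reproduces the dataset exactly; seeds change it", {
  cfg <- sim_config(seqs_per_family = 5L, seed = 29L)
  d1 <- sample_dataset(cfg)
  d2 <- sample_dataset(cfg)
  expect_identical(d1$train$states, d2$train$states)
  expect_identical(d1$novel$states, d2$novel$states)
  d3 <- sample_dataset(sim_config(seqs_per_family = 5L, seed = 30L))
  expect_false(identical(d1$train$states, d3$train$states))
})

test_that("within-family identity exceeds between-archetype identity", {
  d <- sample_dataset(sim_config(seqs_per_family = 20L, seed = 37L))
  ident <- function(s1, s2) {
    n <- min(nchar(s1), nchar(s2))
    mean(strsplit(substr(s1, 1, n), "")[[1]] ==
           strsplit(substr(s2, 1, n), "")[[1]])
  }
  withr::with_seed(11, {
    fams <- unique(d$train$family)
    within <- replicate(20, {
      f <- sample(fams, 1)
      s <- sample(d$train$states[d$train$family == f], 2)
      ident(s[1], s[2])
    })
    folds <- unique(d$train$fold)
    between <- replicate(20, {
      fd <- sample(folds, 2)
      ident(sample(d$train$states[d$train$fold == fd[1]], 1),
            sample(d$train$states[d$train$fold == fd[2]], 1))
    })
  })
  expect_gt(mean(within), mean(between))
})
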