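#' Model configuration for the fold/family classifier
#'
#' Defaults are the reference architecture: three spatially resolved
#' convolution+attention layers (Block 1, kernel sizes 3/7/15 with 256/512/512
#' filters, stride 1, no pooling so activations stay mapped to residues), a
#' local average-pooling bridge, three further convolution blocks with local
#' max pooling (Block 2) ending in per-channel global max pooling, and two
#' fully connected heads (fold and family) sharing a dropout layer.
#'
#' @param L_max Fixed input width (default 798).
#' @param block1_kernels,block1_filters Kernel sizes and filter counts of the
#'   three Block 1 layers.
#' @param block2_kernels,block2_filters Same for Block 2.
#' @param bridge_window Window (= stride) of the masked local average pooling
#'   between the blocks.
#' @param pool_window Window of the masked local max pooling after each
#'   Block 2 layer.
#' @param attention_reduction Bottleneck reduction ratio of the channel
#'   attention.
#' @param sa_kernel Kernel size of the spatial-attention convolution.
#' @param dropout Dropout rate on the embedding before the heads.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param batch_size,max_epochs,patience Training loop controls; early
#'   stopping monitors validation fold accuracy.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `ss3_model_config`.
#' @export
model_config <- function(L_max = 798L,
                         block1_kernels = c(3L, 7L, 15L),
                         block1_filters = c(256L, 512L, 512L),
                         block2_kernels = c(3L, 3L, 3L),
                         block2_filters = c(512L, 512L, 512L),
                         bridge_window = 4L,
                         pool_window = 2L,
                         attention_reduction = 8L,
                         sa_kernel = 7L,
                         dropout = 0.5,
                         lr = 1e-4,
                         weight_decay = 1e-5,
                         batch_size = 32L,
                         max_epochs = 100L,
                         patience = 10L,
                         seed = 1L) {
  cfg <- list(L_max = as.integer(L_max),
              block1_kernels = as.integer(block1_kernels),
              block1_filters = as.integer(block1_filters),
              block2_kernels = as.integer(block2_kernels),
              block2_filters = as.integer(block2_filters),
              bridge_window = as.integer(bridge_window),
              pool_window = as.integer(pool_window),
              attention_reduction = as.integer(attention_reduction),
              sa_kernel = as.integer(sa_kernel),
              dropout = dropout, lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              seed = as.integer(seed))
  stopifnot(length(cfg$block1_kernels) == 3L, length(cfg$block1_filters) == 3L,
            length(cfg$block2_kernels) == 3L, length(cfg$block2_filters) == 3L,
            all(cfg$block1_kernels %% 2L == 1L),
            all(cfg$block2_kernels %% 2L == 1L),
            cfg$sa_kernel %% 2L == 1L,
            all(unlist(cfg[c("L_max", "block1_filters", "block2_filters",
                             "bridge_window", "pool_window", "batch_size",
                             "max_epochs", "patience")]) >= 1L),
            cfg$dropout >= 0, cfg$dropout < 1, cfg$lr > 0)
  class(cfg) <- "ss3_model_config"
  cfg
}

#' Build an untrained fold/family classifier
#'
#' @param config A [model_config()].
#' @param folds Character vector of fold labels (the fold vocabulary).
#' @param families Character vector of family labels.
#' @return An object of class `ss3_classifier` holding initialized weights,
#'   batch-norm statistics, the vocabularies and the channel order.
#' @export
build_model <- function(config, folds, families) {
  stopifnot(inherits(config, "ss3_model_config"))
  folds <- sort(unique(as.character(folds)))
  families <- sort(unique(as.character(families)))
  if (length(folds) < 2L) stop("build_model: need at least 2 fold classes")
  if (length(families) < 2L) stop("build_model: need at least 2 family classes")
  withr::with_seed(config$seed, {
    params <- list()
    bn <- list()
    cin <- 3L
    for (j in 1:3) {
      k <- config$block1_kernels[j]
      f <- config$block1_filters[j]
      r <- max(1L, f %/% config$attention_reduction)
      params[[paste0("b1_", j, "_W")]] <- init_w(k * cin, f)
      params[[paste0("b1_", j, "_b")]] <- numeric(f)
      params[[paste0("b1_", j, "_gamma")]] <- rep(1, f)
      params[[paste0("b1_", j, "_beta")]] <- numeric(f)
      params[[paste0("b1_", j, "_ca_W1")]] <- init_w(f, r)
      params[[paste0("b1_", j, "_ca_b1")]] <- numeric(r)
      params[[paste0("b1_", j, "_ca_W2")]] <- init_w(r, f)
      params[[paste0("b1_", j, "_ca_b2")]] <- numeric(f)
      params[[paste0("b1_", j, "_sa_W")]] <- init_w(config$sa_kernel * 2L, 1L)
      params[[paste0("b1_", j, "_sa_b")]] <- numeric(1L)
      bn[[paste0("b1_", j, "_mean")]] <- numeric(f)
      bn[[paste0("b1_", j, "_var")]] <- rep(1, f)
      cin <- f
    }
    for (j in 1:3) {
      k <- config$block2_kernels[j]
      f <- config$block2_filters[j]
      params[[paste0("b2_", j, "_W")]] <- init_w(k * cin, f)
      params[[paste0("b2_", j, "_b")]] <- numeric(f)
      params[[paste0("b2_", j, "_gamma")]] <- rep(1, f)
      params[[paste0("b2_", j, "_beta")]] <- numeric(f)
      bn[[paste0("b2_", j, "_mean")]] <- numeric(f)
      bn[[paste0("b2_", j, "_var")]] <- rep(1, f)
      cin <- f
    }
    params$head_fold_W <- init_w(cin, length(folds))
    params$head_fold_b <- numeric(length(folds))
    params$head_fam_W <- init_w(cin, length(families))
    params$head_fam_b <- numeric(length(families))
    structure(list(config = config, channels = ss3_channels(),
                   fold_vocab = folds, family_vocab = families,
                   params = params, bn = bn, trained = FALSE,
                   log = NULL),
              class = "ss3_classifier")
  })
}

#' @export
print.ss3_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0(
    "ss3 fold/family classifier (%s)\n",
    "  L_max %d | block1 %s filters, kernels %s | block2 %s filters\n",
    "  %d folds, %d families, %s parameters\n"),
    if (x$trained) "trained" else "untrained",
    x$config$L_max,
    paste(x$config$block1_filters, collapse = "/"),
    paste(x$config$block1_kernels, collapse = "/"),
    paste(x$config$block2_filters, collapse = "/"),
    length(x$fold_vocab), length(x$family_vocab), format(np, big.mark = ",")))
  invisible(x)
}

attn_params <- function(params, j, sa_k) {
  list(ca_W1 = params[[paste0("b1_", j, "_ca_W1")]],
       ca_b1 = params[[paste0("b1_", j, "_ca_b1")]],
       ca_W2 = params[[paste0("b1_", j, "_ca_W2")]],
       ca_b2 = params[[paste0("b1_", j, "_ca_b2")]],
       sa_W = params[[paste0("b1_", j, "_sa_W")]],
       sa_b = params[[paste0("b1_", j, "_sa_b")]],
       sa_k = sa_k)
}

# Full forward pass over one batch. x: (N*L) x 3 stacked input, mask: logical.
# Returns logits, the embedding, and the caches needed for backward and for
# Grad-CAM (post-attention Block 1 maps).
nn_forward <- function(model, x, mask, L, N, train = FALSE,
                       drop_mask = NULL) {
  cfg <- model$config
  p <- model$params
  bn <- model$bn
  caches <- list(L0 = L, N = N, b1 = vector("list", 3L),
                 b2 = vector("list", 3L))
  A <- x
  cur_mask <- mask
  for (j in 1:3) {
    k <- cfg$block1_kernels[j]
    cin <- ncol(A)
    cv <- conv1d_fwd(A, p[[paste0("b1_", j, "_W")]],
                     p[[paste0("b1_", j, "_b")]], k, L, N)
    bnc <- bn_fwd(cv$Z, p[[paste0("b1_", j, "_gamma")]],
                  p[[paste0("b1_", j, "_beta")]],
                  bn[[paste0("b1_", j, "_mean")]],
                  bn[[paste0("b1_", j, "_var")]], train)
    bn[[paste0("b1_", j, "_mean")]] <- bnc$run_mean
    bn[[paste0("b1_", j, "_var")]] <- bnc$run_var
    R <- relu(bnc$out)
    at <- attn_fwd(R, cur_mask, L, N, attn_params(p, j, cfg$sa_kernel))
    caches$b1[[j]] <- list(cv = cv, bn = bnc, relu_pos = bnc$out > 0,
                           at = at, cin = cin, A_out = at$out)
    A <- at$out
  }
  caches$b1_mask <- cur_mask
  br <- avgpool_fwd(A, cur_mask, L, N, cfg$bridge_window)
  caches$bridge <- br
  A <- br$out
  cur_mask <- br$mask2
  L <- br$L2
  for (j in 1:3) {
    k <- cfg$block2_kernels[j]
    cin <- ncol(A)
    cv <- conv1d_fwd(A, p[[paste0("b2_", j, "_W")]],
                     p[[paste0("b2_", j, "_b")]], k, L, N)
    bnc <- bn_fwd(cv$Z, p[[paste0("b2_", j, "_gamma")]],
                  p[[paste0("b2_", j, "_beta")]],
                  bn[[paste0("b2_", j, "_mean")]],
                  bn[[paste0("b2_", j, "_var")]], train)
    bn[[paste0("b2_", j, "_mean")]] <- bnc$run_mean
    bn[[paste0("b2_", j, "_var")]] <- bnc$run_var
    R <- relu(bnc$out)
    mp <- maxpool_fwd(R, cur_mask, L, N, cfg$pool_window)
    caches$b2[[j]] <- list(cv = cv, bn = bnc, relu_pos = bnc$out > 0,
                           mp = mp, cin = cin, L_in = L,
                           mask_in = cur_mask)
    A <- mp$out
    cur_mask <- mp$mask2
    L <- as.integer(ceiling(L / cfg$pool_window))
  }
  gm <- gmaxpool_fwd(A, cur_mask, L, N)
  caches$gm <- gm
  caches$L_gm <- L
  emb <- gm$out
  if (train && cfg$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(
        (stats::runif(length(emb)) >= cfg$dropout) / (1 - cfg$dropout),
        nrow(emb), ncol(emb))
    }
    embd <- emb * drop_mask
  } else {
    drop_mask <- NULL
    embd <- emb
  }
  caches$drop_mask <- drop_mask
  caches$embd <- embd
  logits_fold <- embd %*% p$head_fold_W + rep(p$head_fold_b, each = N)
  logits_fam <- embd %*% p$head_fam_W + rep(p$head_fam_b, each = N)
  list(logits_fold = logits_fold, logits_fam = logits_fam,
       embedding = emb, caches = caches, bn = bn)
}

# Full backward pass. Returns the flat gradient list and, for Grad-CAM, the
# gradients with respect to each Block 1 post-attention map.
nn_backward <- function(model, fw, mask, dl_fold, dl_fam) {
  cfg <- model$config
  p <- model$params
  caches <- fw$caches
  N <- caches$N
  grads <- list()
  grads$head_fold_W <- crossprod(caches$embd, dl_fold)
  grads$head_fold_b <- colSums(dl_fold)
  grads$head_fam_W <- crossprod(caches$embd, dl_fam)
  grads$head_fam_b <- colSums(dl_fam)
  dE <- tcrossprod(dl_fold, p$head_fold_W) +
    tcrossprod(dl_fam, p$head_fam_W)
  if (!is.null(caches$drop_mask)) dE <- dE * caches$drop_mask
  L <- caches$L_gm
  C <- ncol(dE)
  dA <- gmaxpool_bwd(dE, caches$gm, L, N, C)
  for (j in 3:1) {
    cj <- caches$b2[[j]]
    L_in <- cj$L_in
    dR <- maxpool_bwd(dA, cj$mp, N * L_in, ncol(dA))
    dBN <- dR * cj$relu_pos
    bb <- bn_bwd(dBN, cj$bn, p[[paste0("b2_", j, "_gamma")]])
    grads[[paste0("b2_", j, "_gamma")]] <- bb$dgamma
    grads[[paste0("b2_", j, "_beta")]] <- bb$dbeta
    cb <- conv1d_bwd(bb$dZ, cj$cv, p[[paste0("b2_", j, "_W")]],
                     cfg$block2_kernels[j], L_in, N, cj$cin)
    grads[[paste0("b2_", j, "_W")]] <- cb$dW
    grads[[paste0("b2_", j, "_b")]] <- cb$db
    dA <- cb$dA
  }
  L <- caches$L0
  dA <- avgpool_bwd(dA, caches$bridge, caches$b1_mask)
  dA_b1 <- vector("list", 3L)
  for (j in 3:1) {
    cj <- caches$b1[[j]]
    dA_b1[[j]] <- dA  # gradient w.r.t. layer j's post-attention output
    ab <- attn_bwd(dA, cj$at, caches$b1_mask, L, N,
                   attn_params(p, j, cfg$sa_kernel))
    for (nm in names(ab$grads)) {
      grads[[paste0("b1_", j, "_", nm)]] <- ab$grads[[nm]]
    }
    dBN <- ab$dA * cj$relu_pos
    bb <- bn_bwd(dBN, cj$bn, p[[paste0("b1_", j, "_gamma")]])
    grads[[paste0("b1_", j, "_gamma")]] <- bb$dgamma
    grads[[paste0("b1_", j, "_beta")]] <- bb$dbeta
    cb <- conv1d_bwd(bb$dZ, cj$cv, p[[paste0("b1_", j, "_W")]],
                     cfg$block1_kernels[j], L, N, cj$cin, need_dA = j > 1L)
    grads[[paste0("b1_", j, "_W")]] <- cb$dW
    grads[[paste0("b1_", j, "_b")]] <- cb$db
    dA <- cb$dA
  }
  list(grads = grads, dA_b1 = dA_b1)
}

# Slice rows of the stacked layout for a subset of sequences.
stack_rows <- function(seq_idx, L) {
  as.vector(outer(seq_len(L), (seq_idx - 1L) * L, `+`))
}

encode_labels <- function(tbl, model) {
  fold_y <- match(tbl$fold, model$fold_vocab)
  fam_y <- match(tbl$family, model$family_vocab)
  if (anyNA(fold_y)) stop("train: fold label outside model vocabulary: ",
                          tbl$fold[which(is.na(fold_y))[1]])
  if (anyNA(fam_y)) stop("train: family label outside model vocabulary: ",
                         tbl$family[which(is.na(fam_y))[1]])
  list(fold = fold_y, family = fam_y)
}

#' Train the classifier
#'
#' Minimizes the unweighted sum of the fold and family cross-entropies with
#' Adam (L2 weight decay), with early stopping on validation fold accuracy.
#'
#' @param model An `ss3_classifier` from [build_model()].
#' @param train_tbl,val_tbl Labeled [ss3_tbl()] partitions.
#' @param verbose Print per-epoch progress.
#' @return The trained model (best checkpoint by validation fold accuracy),
#'   with a per-epoch `log` tibble.
#' @export
train_classifier <- function(model, train_tbl, val_tbl, verbose = FALSE) {
  cfg <- model$config
  enc_tr <- encode_set(train_tbl, cfg$L_max)
  enc_va <- encode_set(val_tbl, cfg$L_max)
  y_tr <- encode_labels(train_tbl, model)
  if (length(unique(y_tr$fold)) < 2L || length(unique(y_tr$family)) < 2L) {
    stop("train: need at least 2 classes per task in the training set")
  }
  y_va <- encode_labels(val_tbl, model)
  N_tr <- nrow(train_tbl)
  L <- cfg$L_max
  best <- list(acc = -Inf, params = model$params, bn = model$bn, epoch = 0L)
  wait <- 0L
  log_rows <- vector("list", cfg$max_epochs)
  opt <- adam_init(model$params)
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(N_tr)
      starts <- seq(1L, N_tr, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, N_tr)]
        rows <- stack_rows(bi, L)
        fw <- nn_forward(model, enc_tr$x[rows, , drop = FALSE],
                         enc_tr$mask[rows], L, length(bi), train = TRUE)
        model$bn <- fw$bn
        lf <- softmax_xent(fw$logits_fold, y_tr$fold[bi])
        lm <- softmax_xent(fw$logits_fam, y_tr$family[bi])
        epoch_loss <- epoch_loss + (lf$loss + lm$loss) * length(bi)
        bw <- nn_backward(model, fw, enc_tr$mask[rows], lf$dlogits,
                          lm$dlogits)
        upd <- adam_step(model$params, bw$grads, opt, lr = cfg$lr,
                         weight_decay = cfg$weight_decay)
        model$params <- upd$params
        opt <- upd$state
      }
      epoch_loss <- epoch_loss / N_tr
      pv <- predict_posteriors(model, enc_va)
      acc_fold <- mean(max.col(pv$fold) == y_va$fold)
      acc_fam <- mean(max.col(pv$family) == y_va$family)
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss,
        val_fold_acc = acc_fold, val_family_acc = acc_fam)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val fold %.3f  val family %.3f",
                        epoch, epoch_loss, acc_fold, acc_fam))
      }
      if (acc_fold > best$acc + 1e-12) {
        best <- list(acc = acc_fold, params = model$params, bn = model$bn,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (wait >= cfg$patience || best$epoch == 0L) {
    if (best$epoch == 0L) {
      warning("train: validation accuracy never improved; returning best-so-far")
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$trained <- TRUE
  model$log <- dplyr::bind_rows(log_rows)
  model$best_epoch <- best$epoch
  model
}

# Batched eval-mode posteriors over an encoded set.
predict_posteriors <- function(model, enc, batch_size = 64L) {
  L <- enc$L_max
  N <- length(enc$n)
  Pf <- matrix(NA_real_, N, length(model$fold_vocab))
  Pm <- matrix(NA_real_, N, length(model$family_vocab))
  emb <- NULL
  for (s in seq(1L, N, by = batch_size)) {
    bi <- s:min(s + batch_size - 1L, N)
    rows <- stack_rows(bi, L)
    fw <- nn_forward(model, enc$x[rows, , drop = FALSE], enc$mask[rows],
                     L, length(bi), train = FALSE)
    Pf[bi, ] <- softmax_rows(fw$logits_fold)
    Pm[bi, ] <- softmax_rows(fw$logits_fam)
    if (is.null(emb)) emb <- matrix(NA_real_, N, ncol(fw$embedding))
    emb[bi, ] <- fw$embedding
  }
  list(fold = Pf, family = Pm, embedding = emb)
}

#' Predict fold and family posteriors
#'
#' @param object A trained `ss3_classifier`.
#' @param tbl An [ss3_tbl()] of sequences to classify; must be encodable at
#'   the model's recorded `L_max` (an encoding mismatch is an error, never a
#'   silent truncation).
#' @param ... Unused.
#' @return A list with `calls` (tibble: id, fold_call, fold_prob,
#'   family_call, family_prob), `fold_posterior` and `family_posterior`
#'   (row-stochastic matrices with vocabulary column names).
#' @export
predict.ss3_classifier <- function(object, tbl, ...) {
  if (!object$trained) warning("predict: model is untrained")
  tbl <- validate_ss3(tbl)
  if (any(tbl$n > object$config$L_max)) {
    stop("predict: sequence(s) longer than the model's L_max = ",
         object$config$L_max, "; encoding mismatch")
  }
  enc <- encode_set(tbl, object$config$L_max)
  pv <- predict_posteriors(object, enc)
  colnames(pv$fold) <- object$fold_vocab
  colnames(pv$family) <- object$family_vocab
  i_f <- max.col(pv$fold, ties.method = "first")
  i_m <- max.col(pv$family, ties.method = "first")
  calls <- tibble::tibble(
    id = tbl$id,
    fold_call = object$fold_vocab[i_f],
    fold_prob = pv$fold[cbind(seq_len(nrow(tbl)), i_f)],
    family_call = object$family_vocab[i_m],
    family_prob = pv$family[cbind(seq_len(nrow(tbl)), i_m)])
  list(calls = calls, fold_posterior = pv$fold, family_posterior = pv$family)
}

#' Extract Block 2 embeddings
#'
#' The embedding is the per-channel global maximum over real positions of the
#' last Block 2 feature map, so its dimension equals the last Block 2 filter
#' count and padding never influences it.
#'
#' @param model A (trained) `ss3_classifier`.
#' @param tbl An [ss3_tbl()].
#' @param L_max Optional encoding width override (defaults to the model's);
#'   the architecture is length-agnostic, so embeddings are unchanged under
#'   extra padding.
#' @return A tibble with `id` and an `embedding` matrix column.
#' @export
embed_sequences <- function(model, tbl, L_max = model$config$L_max) {
  if (!model$trained) {
    warning("embed_sequences: model is untrained; embeddings are from random weights")
  }
  tbl <- validate_ss3(tbl)
  enc <- encode_set(tbl, L_max)
  pv <- predict_posteriors(model, enc)
  tibble::tibble(id = tbl$id, embedding = pv$embedding)
}

#' Stratified k-fold cross-validation
#'
#' Splits sequences into k disjoint partitions stratified by family (falling
#' back to fold-level strata for families with fewer than k members, with a
#' warning), trains one model per partition and reports fold/family accuracy.
#'
#' @param config A [model_config()].
#' @param tbl A labeled [ss3_tbl()].
#' @param k Number of folds (default 10).
#' @param balance_target If non-NULL, training partitions (never test
#'   partitions) are balanced to this per-family size by coil-mutation
#'   augmentation.
#' @param verbose Print training progress.
#' @return A list with `per_fold` (tibble: cv_fold, fold_acc, family_acc),
#'   `mean_fold_acc`, `sd_fold_acc`, `mean_family_acc`, `sd_family_acc`,
#'   and `assignments` (the partition index of every sequence).
#' @export
cross_validate <- function(config, tbl, k = 10L, balance_target = NULL,
                           verbose = FALSE) {
  tbl <- validate_ss3(tbl)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  assign_cv <- withr::with_seed(config$seed, {
    out <- integer(nrow(tbl))
    small <- names(which(table(tbl$family) < k))
    if (length(small) > 0L) {
      warning("cross_validate: families with < k members stratified by fold: ",
              paste(small, collapse = ", "))
    }
    for (f in unique(tbl$family)) {
      idx <- which(tbl$family == f)
      if (length(idx) >= k) {
        out[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    for (fd in unique(tbl$fold)) {  # leftover small-family members
      idx <- which(tbl$fold == fd & out == 0L)
      if (length(idx) > 0L) out[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    out
  })
  per_fold <- vector("list", k)
  for (ki in seq_len(k)) {
    test_tbl <- tbl[assign_cv == ki, ]
    train_tbl <- tbl[assign_cv != ki, ]
    if (!is.null(balance_target)) {
      train_tbl <- balance_dataset(train_tbl, target = balance_target,
                                   rng_seed = stage_seed(config$seed,
                                                         paste0("cv", ki)))
    }
    # inner 90/10 split: early stopping must not see the test partition
    inner_val <- withr::with_seed(
      stage_seed(config$seed, paste0("cv-val", ki)),
      sample.int(nrow(train_tbl), max(1L, nrow(train_tbl) %/% 10L)))
    model <- build_model(config, folds = unique(tbl$fold),
                         families = unique(tbl$family))
    model <- train_classifier(model, train_tbl[-inner_val, ],
                              train_tbl[inner_val, ], verbose = verbose)
    pr <- predict(model, test_tbl)
    per_fold[[ki]] <- tibble::tibble(
      cv_fold = ki,
      fold_acc = mean(pr$calls$fold_call == test_tbl$fold),
      family_acc = mean(pr$calls$family_call == test_tbl$family))
  }
  per_fold <- dplyr::bind_rows(per_fold)
  list(per_fold = per_fold,
       mean_fold_acc = mean(per_fold$fold_acc),
       sd_fold_acc = stats::sd(per_fold$fold_acc),
       mean_family_acc = mean(per_fold$family_acc),
       sd_family_acc = stats::sd(per_fold$family_acc),
       assignments = assign_cv)
}
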