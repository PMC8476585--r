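#' Masked mean squared reconstruction error
#'
#' The reconstruction error of one sequence: per-position squared error
#' summed over the three channels, averaged over the real (unpadded)
#' residues only, so padding can never dilute or inflate the error.
#'
#' @param Y Encoded input matrix (`L x 3`, see [encode_ss3()]).
#' @param Yhat Reconstruction of the same shape.
#' @param mask Logical vector of real positions; defaults to `Y`'s
#'   `pad_mask` attribute.
#' @return A non-negative scalar; 0 iff the reconstruction matches the
#'   input at every real position.
#' @export
#' @examples
#' Y <- encode_ss3("HEC", L_max = 5)
#' masked_mse(Y, Y)  # 0
masked_mse <- function(Y, Yhat, mask = attr(Y, "pad_mask")) {
  if (!all(dim(Y) == dim(Yhat))) {
    stop("masked_mse: shape mismatch (", paste(dim(Y), collapse = "x"),
         " vs ", paste(dim(Yhat), collapse = "x"), ")")
  }
  if (is.null(mask)) stop("masked_mse: no pad mask available")
  d <- Y - Yhat
  sum(rowSums(d * d)[mask]) / sum(mask)
}

default_decoder_filters <- function(cfg) {
  c(cfg$block1_filters[2], cfg$block1_filters[1],
    max(8L, cfg$block1_filters[1] %/% 4L))
}

# Eval-mode Block 1 forward (the frozen encoder): conv -> batch norm
# (running statistics) -> ReLU -> attention, three times.
encoder_features <- function(classifier, x, mask, L, N) {
  cfg <- classifier$config
  p <- classifier$params
  bn <- classifier$bn
  A <- x
  for (j in 1:3) {
    cv <- conv1d_fwd(A, p[[paste0("b1_", j, "_W")]],
                     p[[paste0("b1_", j, "_b")]],
                     cfg$block1_kernels[j], L, N)
    bnc <- bn_fwd(cv$Z, p[[paste0("b1_", j, "_gamma")]],
                  p[[paste0("b1_", j, "_beta")]],
                  bn[[paste0("b1_", j, "_mean")]],
                  bn[[paste0("b1_", j, "_var")]], train = FALSE)
    A <- attn_fwd(relu(bnc$out), mask, L, N,
                  attn_params(p, j, cfg$sa_kernel))$out
  }
  A
}

dec_param_names <- function() {
  c(sprintf("d%d_%s", rep(1:3, each = 4), c("W", "b", "gamma", "beta")),
    "out_W", "out_b")
}

init_decoder <- function(enc_channels, kernels, filters, seed) {
  withr::with_seed(seed, {
    params <- list()
    cin <- enc_channels
    for (j in 1:3) {
      params[[paste0("d", j, "_W")]] <- init_w(kernels[j] * cin, filters[j])
      params[[paste0("d", j, "_b")]] <- numeric(filters[j])
      params[[paste0("d", j, "_gamma")]] <- rep(1, filters[j])
      params[[paste0("d", j, "_beta")]] <- numeric(filters[j])
      cin <- filters[j]
    }
    params$out_W <- init_w(cin, 3L)
    params$out_b <- numeric(3L)
    params
  })
}

dec_fwd <- function(Feat, mask, L, N, params, kernels) {
  A <- Feat
  caches <- vector("list", 3L)
  for (j in 1:3) {
    cv <- conv1d_fwd(A, params[[paste0("d", j, "_W")]],
                     params[[paste0("d", j, "_b")]], kernels[j], L, N)
    inn <- in_fwd(cv$Z, mask, L, N, params[[paste0("d", j, "_gamma")]],
                  params[[paste0("d", j, "_beta")]])
    R <- relu(inn$out)
    caches[[j]] <- list(cv = cv, inn = inn, relu_pos = inn$out > 0,
                        cin = ncol(A))
    A <- R
  }
  NL <- N * L
  Yhat <- A %*% params$out_W + rep(params$out_b, each = NL)
  list(Yhat = Yhat, A_last = A, caches = caches)
}

dec_bwd <- function(dYhat, fw, mask, L, N, params, kernels) {
  grads <- list(out_W = crossprod(fw$A_last, dYhat),
                out_b = colSums(dYhat))
  dA <- tcrossprod(dYhat, params$out_W)
  for (j in 3:1) {
    cj <- fw$caches[[j]]
    dIN <- dA * cj$relu_pos
    ib <- in_bwd(dIN, cj$inn, mask, params[[paste0("d", j, "_gamma")]])
    grads[[paste0("d", j, "_gamma")]] <- ib$dgamma
    grads[[paste0("d", j, "_beta")]] <- ib$dbeta
    cb <- conv1d_bwd(ib$dZ, cj$cv, params[[paste0("d", j, "_W")]],
                     kernels[j], L, N, cj$cin, need_dA = j > 1L)
    grads[[paste0("d", j, "_W")]] <- cb$dW
    grads[[paste0("d", j, "_b")]] <- cb$db
    dA <- cb$dA
  }
  grads
}

#' Train an autoencoder on top of a frozen classifier encoder
#'
#' The encoder is Block 1 of the trained classifier with weights frozen
#' (bit-identical before and after training, which is asserted). The
#' decoder mirrors Block 1's kernel sizes in reverse (15/7/3 by default)
#' as stride-1 transposed convolutions with instance normalization, ending
#' in a linear three-channel output; it is trained to minimize the masked
#' reconstruction error.
#'
#' @param classifier A trained `ss3_classifier`.
#' @param tbl Training sequences ([ss3_tbl()]).
#' @param decoder_filters Filter counts of the three decoder blocks
#'   (default mirrors Block 1).
#' @param epochs,batch_size,lr Decoder training controls.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return An `ss3_autoencoder` holding the frozen classifier, decoder
#'   weights and the training-set reconstruction errors (`re_train`).
#' @export
train_autoencoder <- function(classifier, tbl, decoder_filters = NULL,
                              epochs = 15L, batch_size = 32L, lr = 1e-3,
                              seed = 1L, verbose = FALSE) {
  stopifnot(inherits(classifier, "ss3_classifier"))
  if (!classifier$trained) {
    warning("train_autoencoder: classifier encoder is untrained")
  }
  cfg <- classifier$config
  kernels <- rev(cfg$block1_kernels)
  filters <- as.integer(decoder_filters %||% default_decoder_filters(cfg))
  stopifnot(length(filters) == 3L)
  tbl <- validate_ss3(tbl)
  enc <- encode_set(tbl, cfg$L_max)
  L <- cfg$L_max
  N <- length(enc$n)
  enc_snapshot <- classifier$params[grep("^b1_", names(classifier$params))]
  # the encoder is frozen: extract features once, then train only the decoder
  Feat <- matrix(NA_real_, N * L, cfg$block1_filters[3])
  for (s in seq(1L, N, by = 64L)) {
    bi <- s:min(s + 63L, N)
    rows <- stack_rows(bi, L)
    Feat[rows, ] <- encoder_features(classifier, enc$x[rows, , drop = FALSE],
                                     enc$mask[rows], L, length(bi))
  }
  params <- init_decoder(cfg$block1_filters[3], kernels, filters,
                         stage_seed(seed, "decoder-init"))
  opt <- adam_init(params)
  withr::with_seed(stage_seed(seed, "decoder-train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(N)
      epoch_loss <- 0
      for (s in seq(1L, N, by = batch_size)) {
        bi <- ord[s:min(s + batch_size - 1L, N)]
        rows <- stack_rows(bi, L)
        msk <- enc$mask[rows]
        fw <- dec_fwd(Feat[rows, , drop = FALSE], msk, L, length(bi),
                      params, kernels)
        D <- fw$Yhat - enc$x[rows, , drop = FALSE]
        D[!msk, ] <- 0
        # per-sequence masked MSE, averaged over the batch
        wpos <- rep(1 / (enc$n[bi] * length(bi)), each = L)
        loss <- sum(rowSums(D * D) * wpos)
        epoch_loss <- epoch_loss + loss * length(bi)
        dYhat <- 2 * D * wpos
        grads <- dec_bwd(dYhat, fw, msk, L, length(bi), params, kernels)
        upd <- adam_step(params, grads, opt, lr = lr, weight_decay = 0)
        params <- upd$params
        opt <- upd$state
      }
      if (verbose) {
        message(sprintf("decoder epoch %3d  loss %.5f", epoch,
                        epoch_loss / N))
      }
    }
  })
  post <- classifier$params[grep("^b1_", names(classifier$params))]
  if (!identical(enc_snapshot, post)) {
    stop("train_autoencoder: encoder weights drifted during training")
  }
  ae <- structure(list(classifier = classifier, params = params,
                       kernels = kernels, filters = filters,
                       encoder_snapshot = enc_snapshot,
                       L_max = cfg$L_max, trained = TRUE),
                  class = "ss3_autoencoder")
  ae$re_train <- reconstruction_errors(ae, tbl)
  ae
}

#' Verify the autoencoder's encoder is still bit-identical to its classifier
#' @param ae An `ss3_autoencoder`.
#' @return `TRUE` invisibly; error if any encoder weight drifted.
#' @export
verify_frozen <- function(ae) {
  now <- ae$classifier$params[grep("^b1_", names(ae$classifier$params))]
  if (!identical(now, ae$encoder_snapshot)) {
    stop("verify_frozen: encoder weights differ from the training-time snapshot")
  }
  invisible(TRUE)
}

#' Per-sequence reconstruction errors under an autoencoder
#'
#' @param ae An `ss3_autoencoder`.
#' @param tbl An [ss3_tbl()].
#' @return Named numeric vector of masked reconstruction errors (names =
#'   ids).
#' @export
reconstruction_errors <- function(ae, tbl) {
  tbl <- validate_ss3(tbl)
  enc <- encode_set(tbl, ae$L_max)
  L <- ae$L_max
  N <- length(enc$n)
  re <- numeric(N)
  for (s in seq(1L, N, by = 64L)) {
    bi <- s:min(s + 63L, N)
    rows <- stack_rows(bi, L)
    msk <- enc$mask[rows]
    Feat <- encoder_features(ae$classifier, enc$x[rows, , drop = FALSE],
                             msk, L, length(bi))
    fw <- dec_fwd(Feat, msk, L, length(bi), ae$params, ae$kernels)
    D <- enc$x[rows, , drop = FALSE] - fw$Yhat
    sq <- rowSums(D * D)
    for (b in seq_along(bi)) {
      real <- (b - 1L) * L + seq_len(enc$n[bi[b]])
      re[bi[b]] <- sum(sq[real]) / enc$n[bi[b]]
    }
  }
  stats::setNames(re, enc$ids)
}

# ---- extreme-value (Gumbel) calibration -------------------------------------

#' Gumbel (type-I extreme value) distribution functions
#'
#' Density, distribution function, quantile function and random generation
#' for the right-skewed Gumbel distribution with location `loc` and scale
#' `scale`.
#'
#' @param x,q,p Numeric vectors.
#' @param n Number of draws.
#' @param loc,scale Location and scale (`scale > 0`).
#' @param log,lower.tail Usual distribution-function switches.
#' @return Numeric vector.
#' @name gumbel
NULL

#' @rdname gumbel
#' @export
dgumbel <- function(x, loc = 0, scale = 1, log = FALSE) {
  z <- (x - loc) / scale
  ll <- -z - exp(-z) - base::log(scale)
  if (log) ll else exp(ll)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, loc = 0, scale = 1, lower.tail = TRUE) {
  p <- exp(-exp(-(q - loc) / scale))
  if (lower.tail) p else 1 - p
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, loc = 0, scale = 1) {
  loc - scale * base::log(-base::log(p))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, loc = 0, scale = 1) {
  qgumbel(stats::runif(n), loc, scale)
}

# Maximum-likelihood Gumbel fit (BFGS on the closed-form log-likelihood,
# moment-based start).
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 2L)
  if (stats::sd(x) < .Machine$double.eps) {
    stop("fit_gumbel: degenerate (zero-variance) sample")
  }
  b0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772156649 * b0
  nll <- function(par) -sum(dgumbel(x, par[1], exp(par[2]), log = TRUE))
  fit <- stats::optim(c(m0, base::log(b0)), nll, method = "BFGS")
  list(loc = fit$par[1], scale = exp(fit$par[2]),
       loglik = -fit$value, convergence = fit$convergence)
}

#' Calibrate novelty thresholds from training reconstruction errors
#'
#' Fits a right-skewed type-I extreme value (Gumbel) distribution to the
#' training reconstruction errors by maximum likelihood, takes the fitted
#' quantiles at the 95% and 99% levels as the confidence-interval upper
#' limits, and sets the novelty threshold at their midpoint.
#'
#' @param re_values Numeric vector of training reconstruction errors
#'   (at least 50).
#' @param q95,q99 Coverage levels (defaults 0.95 and 0.99).
#' @param two_sided If `TRUE`, read the levels as two-sided intervals and
#'   use the 0.975/0.995 fitted quantiles instead of 0.95/0.99.
#' @return An object of class `re_calibration`: `loc`, `scale`,
#'   `ci95_upper`, `ci99_upper`, `mid_threshold`, `n`.
#' @export
calibrate <- function(re_values, q95 = 0.95, q99 = 0.99, two_sided = FALSE) {
  re_values <- as.numeric(re_values)
  if (length(re_values) < 50L) {
    stop("calibrate: need at least 50 reconstruction errors")
  }
  fit <- fit_gumbel(re_values)
  p95 <- if (two_sided) 1 - (1 - q95) / 2 else q95
  p99 <- if (two_sided) 1 - (1 - q99) / 2 else q99
  ci95 <- qgumbel(p95, fit$loc, fit$scale)
  ci99 <- qgumbel(p99, fit$loc, fit$scale)
  structure(list(loc = fit$loc, scale = fit$scale,
                 ci95_upper = ci95, ci99_upper = ci99,
                 mid_threshold = (ci95 + ci99) / 2,
                 n = length(re_values), q95 = q95, q99 = q99,
                 two_sided = two_sided),
            class = "re_calibration")
}

#' @export
print.re_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "EVD calibration (n = %d): loc %.4f, scale %.4f\n",
    "  CI upper limits: %.4f (95%%), %.4f (99%%); midpoint threshold %.4f\n"),
    x$n, x$loc, x$scale, x$ci95_upper, x$ci99_upper, x$mid_threshold))
  invisible(x)
}

#' Manually construct a calibration (e.g. from published thresholds)
#'
#' @param ci95_upper,ci99_upper Upper limits of the 95% and 99% intervals.
#' @param loc,scale Optional fitted parameters.
#' @return An `re_calibration`.
#' @export
re_calibration <- function(ci95_upper, ci99_upper, loc = NA_real_,
                           scale = NA_real_) {
  stopifnot(ci95_upper <= ci99_upper)
  structure(list(loc = loc, scale = scale, ci95_upper = ci95_upper,
                 ci99_upper = ci99_upper,
                 mid_threshold = (ci95_upper + ci99_upper) / 2,
                 n = NA_integer_, q95 = 0.95, q99 = 0.99,
                 two_sided = FALSE),
            class = "re_calibration")
}

# ---- fold assignment score --------------------------------------------------

#' Per-cluster reference statistics for the fold-assignment score
#'
#' @param cluster Cluster name.
#' @param RE_b Median reconstruction error of the cluster's own members
#'   under the cluster autoencoder.
#' @param OOC_b Mean error of same-fold, out-of-cluster sequences (for a
#'   single-cluster fold: of a held-out split of the cluster).
#' @param OOF_b Mean error of different-fold sequences.
#' @return A list of class `cluster_stats`. A calibration with
#'   `RE_b <= OOC_b <= OOF_b` is meaningful; violations are warned about
#'   but kept.
#' @export
cluster_stats <- function(cluster, RE_b, OOC_b, OOF_b) {
  stopifnot(RE_b >= 0, OOC_b >= 0, OOF_b >= 0)
  if (!(RE_b <= OOC_b && OOC_b <= OOF_b)) {
    warning(sprintf(
      "cluster_stats('%s'): expected RE_b <= OOC_b <= OOF_b, got %.4f / %.4f / %.4f",
      cluster, RE_b, OOC_b, OOF_b))
  }
  structure(list(cluster = cluster, RE_b = RE_b, OOC_b = OOC_b,
                 OOF_b = OOF_b),
            class = "cluster_stats")
}

#' Fold assignment score
#'
#' `FAS = ((OOC_b - RE_a) * (OOF_b - OOC_b) / (OOF_b - RE_b) - thres) * 100`:
#' a signed, normalized measure of how much better a family reconstructs
#' under a cluster's autoencoder than sequences outside that cluster do.
#' Positive means assignable to the cluster.
#'
#' @param RE_a Median reconstruction error of the query family under the
#'   cluster's autoencoder.
#' @param stats A [cluster_stats()].
#' @param thres Score threshold absorbing between-cluster differences in
#'   baseline error (default 0.014).
#' @return The score (scalar).
#' @export
#' @examples
#' st <- cluster_stats("c1", RE_b = 0.05, OOC_b = 0.10, OOF_b = 0.15)
#' fas(0.05, st)  # 1.1
fas <- function(RE_a, stats, thres = 0.014) {
  stopifnot(inherits(stats, "cluster_stats"))
  if (abs(stats$OOF_b - stats$RE_b) < .Machine$double.eps) {
    stop("fas: undefined, OOF_b equals RE_b")
  }
  ((stats$OOC_b - RE_a) * (stats$OOF_b - stats$OOC_b) /
      (stats$OOF_b - stats$RE_b) - thres) * 100
}

# ---- decision table ---------------------------------------------------------

# The published high-confidence bound (0.1) and tier widths expressed in
# units of the calibration interval width w = ci99 - ci95, so they transfer
# to recalibrated datasets: ci95 - 0.175*w reproduces 0.1 exactly under the
# reference calibration (0.107/0.147).
known_high_bound <- function(calib) {
  w <- calib$ci99_upper - calib$ci95_upper
  calib$ci95_upper - 0.175 * w
}

#' Call a family's fold status from its median RE and FAS scores
#'
#' The decision table: below the 95% limit the family is a known fold
#' (assigned to the highest-FAS cluster; high confidence when the median RE
#' is low and the best FAS exceeds 1). Between the 95% limit and the
#' midpoint threshold, a positive FAS still assigns a known fold with low
#' confidence, while all-negative FAS means a variant of a known fold.
#' At or above the midpoint threshold the family is a novel fold;
#' confidence increases with the median RE.
#'
#' @param mRE Median reconstruction error of the family under the main
#'   autoencoder.
#' @param fas_scores Named numeric vector of FAS scores, one per cluster.
#' @param calib An `re_calibration`.
#' @param family Optional family name carried through.
#' @param n_seqs Optional sequence count; families with fewer than 5 are
#'   flagged low-reliability.
#' @return A list of class `fold_call`: `family`, `mRE`, `verdict`
#'   (`"known"`, `"variant"` or `"novel"`), `fold` (assigned cluster or
#'   `NA`), `best_fas`, `confidence` (`"low"`, `"medium"`, `"high"`),
#'   `fas`, `flags`.
#' @export
call_family <- function(mRE, fas_scores, calib, family = NA_character_,
                        n_seqs = NA_integer_) {
  stopifnot(inherits(calib, "re_calibration"), length(fas_scores) >= 1L)
  if (is.null(names(fas_scores))) {
    names(fas_scores) <- paste0("cluster", seq_along(fas_scores))
  }
  w <- calib$ci99_upper - calib$ci95_upper
  flags <- character(0)
  if (!is.na(n_seqs) && n_seqs < 5L) flags <- c(flags, "low_reliability")
  best <- max(fas_scores)
  tied <- names(fas_scores)[fas_scores == best]
  if (length(tied) > 1L) {
    warning("call_family: FAS tie between ", paste(tied, collapse = ", "),
            "; picking the lexicographically first")
    flags <- c(flags, paste0("fas_tie:", paste(sort(tied), collapse = "+")))
  }
  best_cluster <- sort(tied)[1]
  if (mRE < calib$ci95_upper) {
    verdict <- "known"
    fold <- best_cluster
    confidence <- if (mRE < known_high_bound(calib) && best > 1) "high" else "medium"
  } else if (mRE < calib$mid_threshold) {
    if (best > 0) {
      verdict <- "known"
      fold <- best_cluster
      confidence <- "low"
    } else {
      verdict <- "variant"
      fold <- NA_character_
      confidence <- if (mRE < calib$ci95_upper + w / 4) "low" else "medium"
    }
  } else {
    verdict <- "novel"
    fold <- NA_character_
    confidence <- if (mRE < calib$ci99_upper) "low"
      else if (mRE < calib$ci99_upper + w) "medium" else "high"
    if (best > 0) flags <- c(flags, "positive_fas_above_threshold")
  }
  structure(list(family = family, mRE = mRE, verdict = verdict, fold = fold,
                 best_fas = best, confidence = confidence, fas = fas_scores,
                 flags = flags),
            class = "fold_call")
}

#' @export
print.fold_call <- function(x, ...) {
  cat(sprintf("fold call%s: %s (%s confidence), mRE %.4f, best FAS %.2f%s%s\n",
              if (is.na(x$family)) "" else paste0(" [", x$family, "]"),
              x$verdict, x$confidence, x$mRE, x$best_fas,
              if (is.na(x$fold)) "" else paste0(" -> ", x$fold),
              if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ";"),
                                          ")") else ""))
  invisible(x)
}

#' Disjoint train/holdout split of a cluster (out-of-cluster surrogate)
#'
#' For a fold with a single cluster there are no same-fold out-of-cluster
#' sequences, so a held-out fraction of the cluster itself (unseen by the
#' cluster autoencoder) stands in for them.
#'
#' @param tbl The cluster's sequences ([ss3_tbl()], at least 5 rows).
#' @param fraction Holdout fraction (default 0.20).
#' @param seed Integer seed.
#' @return A list with `train` and `holdout` (`ss3_tbl`s partitioning the
#'   input).
#' @export
build_ooc_holdout <- function(tbl, fraction = 0.20, seed = 1L) {
  tbl <- validate_ss3(tbl)
  n <- nrow(tbl)
  if (n < 5L) stop("build_ooc_holdout: need at least 5 members")
  stopifnot(fraction > 0, fraction < 1)
  idx <- withr::with_seed(seed,
                          sample.int(n, max(1L, round(fraction * n))))
  list(train = tbl[-idx, ], holdout = tbl[idx, ])
}

#' Fit the full open-set recognition model
#'
#' Trains the main autoencoder on all training sequences (per-family cap
#' applied), one autoencoder per cluster, computes per-cluster RE/OOC/OOF
#' statistics, and calibrates the extreme-value novelty thresholds from the
#' main autoencoder's training reconstruction errors.
#'
#' @param classifier A trained `ss3_classifier`.
#' @param tbl Training sequences with fold labels.
#' @param cluster Per-sequence cluster assignment (defaults to the fold
#'   label, i.e. one cluster per fold).
#' @param per_family_cap Max sequences per family used for autoencoder
#'   training (default 200).
#' @param holdout_fraction Held-out fraction for single-cluster folds
#'   (default 0.20).
#' @param thres FAS threshold (default 0.014).
#' @param epochs,lr Decoder training controls.
#' @param decoder_filters Optional decoder filter counts.
#' @param seed Master seed.
#' @param verbose Print progress.
#' @return An `ss3_openset` object: `main_ae`, `cluster_aes` (named list),
#'   `cluster_stats` (named list), `calib`, `thres`.
#' @export
fit_openset <- function(classifier, tbl, cluster = NULL,
                        per_family_cap = 200L, holdout_fraction = 0.20,
                        thres = 0.014, epochs = 15L, lr = 1e-3,
                        decoder_filters = NULL, seed = 1L,
                        verbose = FALSE) {
  tbl <- validate_ss3(tbl)
  if (is.null(cluster)) cluster <- tbl$fold
  stopifnot(length(cluster) == nrow(tbl))
  cap <- function(x, seed_tag) {
    keep <- withr::with_seed(stage_seed(seed, seed_tag), {
      unlist(lapply(split(seq_len(nrow(x)), x$family), function(ii) {
        if (length(ii) > per_family_cap) sample(ii, per_family_cap) else ii
      }))
    })
    x[sort(keep), ]
  }
  main_tbl <- cap(tbl, "cap-main")
  if (verbose) message("training main autoencoder on ", nrow(main_tbl),
                       " sequences")
  main_ae <- train_autoencoder(classifier, main_tbl,
                               decoder_filters = decoder_filters,
                               epochs = epochs, lr = lr,
                               seed = stage_seed(seed, "ae-main"),
                               verbose = verbose)
  calib <- calibrate(main_ae$re_train)
  clusters <- sort(unique(cluster))
  fold_of <- vapply(clusters, function(b) {
    unique(tbl$fold[cluster == b])[1]
  }, "")
  cluster_aes <- list()
  stats_list <- list()
  for (b in clusters) {
    members <- cap(tbl[cluster == b, ], paste0("cap-", b))
    same_fold_other <- tbl[tbl$fold == fold_of[[b]] & cluster != b, ]
    single_cluster_fold <- nrow(same_fold_other) == 0L
    if (single_cluster_fold) {
      sp <- build_ooc_holdout(members, holdout_fraction,
                              seed = stage_seed(seed, paste0("holdout-", b)))
      fit_tbl <- sp$train
      ooc_tbl <- sp$holdout
    } else {
      fit_tbl <- members
      ooc_tbl <- cap(same_fold_other, paste0("cap-ooc-", b))
    }
    if (verbose) message("training cluster autoencoder '", b, "' on ",
                         nrow(fit_tbl), " sequences")
    ae_b <- train_autoencoder(classifier, fit_tbl,
                              decoder_filters = decoder_filters,
                              epochs = epochs, lr = lr,
                              seed = stage_seed(seed, paste0("ae-", b)),
                              verbose = verbose)
    oof_tbl <- cap(tbl[tbl$fold != fold_of[[b]], ], paste0("cap-oof-", b))
    stats_list[[b]] <- cluster_stats(
      cluster = b,
      RE_b = stats::median(ae_b$re_train),
      OOC_b = mean(reconstruction_errors(ae_b, ooc_tbl)),
      OOF_b = mean(reconstruction_errors(ae_b, oof_tbl)))
    cluster_aes[[b]] <- ae_b
  }
  structure(list(main_ae = main_ae, cluster_aes = cluster_aes,
                 cluster_stats = stats_list, calib = calib, thres = thres),
            class = "ss3_openset")
}

#' Score families of unknown fold against the open-set model
#'
#' For every family: the median reconstruction error under the main
#' autoencoder gives mRE; the median error under each cluster autoencoder
#' gives that cluster's FAS; the decision table then yields a verdict with
#' a confidence tier.
#'
#' @param openset An `ss3_openset` from [fit_openset()].
#' @param families_tbl An [ss3_tbl()]; rows are grouped by their `family`
#'   column.
#' @return A tibble: `family`, `n_seqs`, `mRE`, `best_cluster`, `best_FAS`,
#'   `verdict`, `confidence`, `flags`; the full `fold_call` objects are in
#'   the `calls` attribute.
#' @export
score_unknown_families <- function(openset, families_tbl) {
  stopifnot(inherits(openset, "ss3_openset"))
  families_tbl <- validate_ss3(families_tbl)
  fams <- unique(families_tbl$family)
  calls <- list()
  rows <- list()
  for (a in fams) {
    sub <- families_tbl[families_tbl$family == a, ]
    if (nrow(sub) == 0L) {
      warning("score_unknown_families: empty family ", a, "; skipped")
      next
    }
    mre <- stats::median(reconstruction_errors(openset$main_ae, sub))
    fscores <- vapply(names(openset$cluster_aes), function(b) {
      re_a <- stats::median(
        reconstruction_errors(openset$cluster_aes[[b]], sub))
      fas(re_a, openset$cluster_stats[[b]], thres = openset$thres)
    }, 0)
    fc <- call_family(mre, fscores, openset$calib, family = a,
                      n_seqs = nrow(sub))
    calls[[a]] <- fc
    rows[[a]] <- tibble::tibble(
      family = a, n_seqs = nrow(sub), mRE = mre,
      best_cluster = if (is.na(fc$fold)) names(which.max(fscores)) else fc$fold,
      best_FAS = fc$best_fas, verdict = fc$verdict,
      confidence = fc$confidence,
      flags = paste(fc$flags, collapse = ";"))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "calls") <- calls
  out
}
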