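#' Per-residue Grad-CAM profiles from Block 1
#'
#' For each sequence, takes the gradient of the target class's contrastive
#' score (its logit minus the mean of the other logits — the quantity the
#' softmax actually discriminates on, so class-shared activation is
#' cancelled instead of lighting up the whole map) with respect to the
#' chosen Block 1 layer's post-attention feature maps, averages it
#' spatially over real residues to get per-channel weights, forms the
#' rectified weighted sum over channels, and min-max normalizes over real
#' residues. Because Block 1 is stride-1 with no pooling, the map is
#' already at residue resolution.
#'
#' @param model A trained `ss3_classifier`.
#' @param tbl An [ss3_tbl()] of sequences.
#' @param layer Block 1 layer to map (1, 2 or 3).
#' @param target_class Label to take the gradient for; must be in the
#'   relevant vocabulary.
#' @param task `"fold"` or `"family"`: which head's logit to use.
#' @return A list of `cam_profile` objects (id, layer, target_class, states,
#'   values in `[0,1]`, one value per residue).
#' @export
grad_cam <- function(model, tbl, layer = 2L, target_class,
                     task = c("fold", "family")) {
  task <- match.arg(task)
  stopifnot(layer %in% 1:3)
  if (!model$trained) warning("grad_cam: model is untrained")
  vocab <- if (task == "fold") model$fold_vocab else model$family_vocab
  ci <- match(target_class, vocab)
  if (is.na(ci)) stop("grad_cam: target class '", target_class,
                      "' not in ", task, " vocabulary")
  tbl <- validate_ss3(tbl)
  enc <- encode_set(tbl, model$config$L_max)
  L <- enc$L_max
  N <- length(enc$n)
  profiles <- vector("list", N)
  batch <- 32L
  for (s in seq(1L, N, by = batch)) {
    bi <- s:min(s + batch - 1L, N)
    rows <- stack_rows(bi, L)
    msk <- enc$mask[rows]
    fw <- nn_forward(model, enc$x[rows, , drop = FALSE], msk, L,
                     length(bi), train = FALSE)
    nb <- length(bi)
    # contrastive score: +1 on the target logit, -1/(K-1) on the rest
    d_one <- matrix(-1 / (length(vocab) - 1), nb, length(vocab))
    d_one[, ci] <- 1
    zero_other <- matrix(0, nb, length(
      if (task == "fold") model$family_vocab else model$fold_vocab))
    bw <- if (task == "fold") {
      nn_backward(model, fw, msk, d_one, zero_other)
    } else {
      nn_backward(model, fw, msk, zero_other, d_one)
    }
    dA <- bw$dA_b1[[layer]]
    A <- fw$caches$b1[[layer]]$A_out
    for (b in seq_along(bi)) {
      i <- bi[b]
      real <- (b - 1L) * L + seq_len(enc$n[i])
      alpha <- colMeans(dA[real, , drop = FALSE])
      raw <- pmax(A[real, , drop = FALSE] %*% alpha, 0)[, 1L]
      if (max(raw) > 0) raw <- (raw - min(raw)) / (max(raw) - min(raw))
      if (all(!msk[(b - 1L) * L + seq_len(L)])) {
        warning("grad_cam: padding-only input for id ", enc$ids[i])
      }
      profiles[[i]] <- structure(
        list(id = enc$ids[i], layer = as.integer(layer),
             target_class = target_class, task = task,
             states = tbl$states[i], values = raw),
        class = "cam_profile")
    }
  }
  profiles
}

#' @export
print.cam_profile <- function(x, ...) {
  cat(sprintf("CAM profile '%s' (layer %d, target %s): %d residues, mean %.3f\n",
              x$id, x$layer, x$target_class, length(x$values),
              mean(x$values)))
  invisible(x)
}

#' Family-average CAM over alignment columns
#'
#' Averages per-residue CAM values across a family using a caller-supplied
#' residue-to-alignment-column map, and reports the per-column majority
#' (consensus) secondary-structure state. Columns with no aligned residue
#' carry `NA`.
#'
#' @param profiles List of `cam_profile` objects, all from the same layer.
#' @param column_map Data frame with columns `id`, `position` (1-based
#'   residue index) and `column` (alignment column, `NA` = unaligned).
#' @return A `cam_profile` whose `values` are per-column means and whose
#'   `states` string is the per-column consensus (`-` where empty).
#' @export
family_cam <- function(profiles, column_map) {
  stopifnot(length(profiles) >= 1L,
            all(c("id", "position", "column") %in% names(column_map)))
  layers <- vapply(profiles, `[[`, 0L, "layer")
  if (length(unique(layers)) != 1L) {
    stop("family_cam: profiles come from different layers")
  }
  ids <- vapply(profiles, `[[`, "", "id")
  ncol_aln <- max(column_map$column, na.rm = TRUE)
  sums <- numeric(ncol_aln)
  counts <- integer(ncol_aln)
  state_votes <- matrix(0L, ncol_aln, 3L,
                        dimnames = list(NULL, ss3_channels()))
  for (p in profiles) {
    cm <- column_map[column_map$id == p$id & !is.na(column_map$column), ]
    if (nrow(cm) == 0L) next
    if (any(cm$position < 1L | cm$position > length(p$values))) {
      stop("family_cam: column map position out of range for id ", p$id)
    }
    sums[cm$column] <- sums[cm$column] + p$values[cm$position]
    counts[cm$column] <- counts[cm$column] + 1L
    st <- substring(p$states, cm$position, cm$position)
    for (ch in ss3_channels()) {
      hit <- cm$column[st == ch]
      state_votes[hit, ch] <- state_votes[hit, ch] + 1L
    }
  }
  vals <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  cons <- rep("-", ncol_aln)
  filled <- counts > 0L
  cons[filled] <- ss3_channels()[max.col(state_votes[filled, , drop = FALSE],
                                         ties.method = "first")]
  structure(list(id = paste0("family:", paste(unique(ids), collapse = ",")),
                 layer = layers[1], target_class = profiles[[1]]$target_class,
                 task = profiles[[1]]$task,
                 states = paste(cons, collapse = ""), values = vals,
                 n_sequences = length(profiles), coverage = counts),
            class = "cam_profile")
}

#' UMAP parameter scan over Block 2 embeddings
#'
#' Runs 2-D UMAP for every combination of `n_neighbors` and `min_dist`,
#' repeated `repeats` times with deterministically derived seeds, matching
#' the reproducibility scan used to inspect embedding stability. The
#' default backend shells out to the Python `umap-learn` implementation;
#' `method = "pca"` substitutes a deterministic principal-component
#' projection when Python is unavailable.
#'
#' @param embeddings Numeric matrix (sequences x dimensions) or the tibble
#'   from [embed_sequences()].
#' @param n_neighbors_list,min_dist_list Parameter grids
#'   (defaults 5/15/20 and 0.001/0.01/0.1/0.5).
#' @param repeats Projections per parameter pair (default 3).
#' @param seed Master seed; per-projection seeds are derived from it.
#' @param method `"umap"` (Python umap-learn) or `"pca"`.
#' @return A tibble with one row per (n_neighbors, min_dist, repeat,
#'   sequence): columns `n_neighbors`, `min_dist`, `rep`, `row`, `x`, `y`.
#' @export
umap_scan <- function(embeddings, n_neighbors_list = c(5L, 15L, 20L),
                      min_dist_list = c(0.001, 0.01, 0.1, 0.5),
                      repeats = 3L, seed = 1L,
                      method = c("umap", "pca")) {
  method <- match.arg(method)
  if (is.data.frame(embeddings)) embeddings <- embeddings$embedding
  X <- as.matrix(embeddings)
  if (nrow(X) < 10L) stop("umap_scan: need at least 10 embeddings")
  grid <- expand.grid(rep = seq_len(repeats), min_dist = min_dist_list,
                      n_neighbors = n_neighbors_list)
  grid$seed <- mapply(function(nn, md, r) {
    stage_seed(seed, sprintf("umap-%d-%g-%d", nn, md, r))
  }, grid$n_neighbors, grid$min_dist, grid$rep)
  if (method == "pca") {
    pc <- stats::prcomp(X, rank. = 2L)$x
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      tibble::tibble(n_neighbors = grid$n_neighbors[g],
                     min_dist = grid$min_dist[g], rep = grid$rep[g],
                     row = seq_len(nrow(X)), x = pc[, 1L], y = pc[, 2L])
    }))
    return(tibble::as_tibble(out))
  }
  run_umap_python(X, grid)
}

# One Python process computes the whole scan (umap-learn's numba JIT cost is
# paid once); interchange is CSV + JSON in a temp directory.
run_umap_python <- function(X, grid) {
  td <- tempfile("umapscan")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  in_csv <- file.path(td, "X.csv")
  out_csv <- file.path(td, "proj.csv")
  cfg_json <- file.path(td, "cfg.json")
  utils::write.table(X, in_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(input = in_csv, output = out_csv,
                            grid = grid), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  script <- c(
    "import json, sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import numpy as np, umap",
    "cfg = json.load(open(sys.argv[1]))",
    "X = np.loadtxt(cfg['input'], delimiter=',')",
    "rows = []",
    "for g in cfg['grid']:",
    "    m = umap.UMAP(n_neighbors=int(g['n_neighbors']),",
    "                  min_dist=float(g['min_dist']), n_components=2,",
    "                  random_state=int(g['seed'])).fit_transform(X)",
    "    for i in range(m.shape[0]):",
    "        rows.append((g['n_neighbors'], g['min_dist'], g['rep'],",
    "                     i + 1, m[i, 0], m[i, 1]))",
    "with open(cfg['output'], 'w') as fh:",
    "    fh.write('n_neighbors,min_dist,rep,row,x,y\\n')",
    "    for r in rows:",
    "        fh.write(','.join(map(repr, r)) + '\\n')")
  py_file <- file.path(td, "scan.py")
  writeLines(script, py_file)
  status <- system2("python", c(py_file, cfg_json), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L || !file.exists(out_csv)) {
    stop("umap_scan: python umap-learn backend failed (status ", status,
         "); use method = 'pca' if Python is unavailable")
  }
  tibble::as_tibble(utils::read.csv(out_csv))
}

#' Gaussian-mixture clustering of a 2-D projection
#'
#' Fits Gaussian mixtures over a range of component counts, selects the
#' count by BIC, and assigns each point its mixture log-density as a GMM
#' score; points scoring below the cutoff are labeled unassigned.
#'
#' @param projection Two-column matrix or data frame of 2-D coordinates.
#' @param n_components_range Candidate component counts (default 1:6).
#' @param score_cutoff Log-density cutoff below which a point is unassigned;
#'   default is the 1st percentile of scores.
#' @return A tibble: `row`, `x`, `y`, `cluster` (integer or `NA` =
#'   unassigned), `gmm_score`; attributes `n_components` and `score_cutoff`.
#' @export
gmm_cluster <- function(projection, n_components_range = 1:6,
                        score_cutoff = NULL) {
  P <- as.matrix(projection)[, 1:2, drop = FALSE]
  storage.mode(P) <- "double"
  if (nrow(P) < max(n_components_range)) {
    stop("gmm_cluster: fewer points than the largest requested component count")
  }
  degenerate <- all(abs(sweep(P, 2L, P[1L, ])) < 1e-12)
  if (degenerate) {
    warning("gmm_cluster: all points identical; returning a single cluster")
    out <- tibble::tibble(row = seq_len(nrow(P)), x = P[, 1L], y = P[, 2L],
                          cluster = 1L, gmm_score = 0)
    attr(out, "n_components") <- 1L
    attr(out, "score_cutoff") <- -Inf
    return(out)
  }
  fit <- mclust::Mclust(P, G = n_components_range, verbose = FALSE)
  if (is.null(fit)) stop("gmm_cluster: mixture fit failed")
  score <- mclust::dens(modelName = fit$modelName, data = P,
                        parameters = fit$parameters, logarithm = TRUE)
  if (is.null(score_cutoff)) {
    score_cutoff <- stats::quantile(score, 0.01, names = FALSE)
  }
  cl <- as.integer(fit$classification)
  cl[score < score_cutoff] <- NA_integer_
  out <- tibble::tibble(row = seq_len(nrow(P)), x = P[, 1L], y = P[, 2L],
                        cluster = cl, gmm_score = as.numeric(score))
  attr(out, "n_components") <- fit$G
  attr(out, "score_cutoff") <- score_cutoff
  out
}

#' Write CAM profiles to a TSV file
#'
#' Columns: id, layer, position (1-based), state, cam.
#'
#' @param profiles List of `cam_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cam <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    tibble::tibble(id = p$id, layer = p$layer,
                   position = seq_along(p$values),
                   state = strsplit(p$states, "")[[1]][seq_along(p$values)],
                   cam = p$values)
  })
  utils::write.table(dplyr::bind_rows(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
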