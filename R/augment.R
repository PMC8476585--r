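#' Mutate-to-coil data augmentation of a single sequence
#'
#' Draws `k = max(1, floor(rate * n))` residue positions uniformly without
#' replacement and sets them to coil (`C`). If every drawn position was
#' already coil (no effective change), the whole draw is retried; a sequence
#' consisting entirely of coil can never be changed and raises an error.
#' Padding is never touched because augmentation operates on the unpadded
#' state string.
#'
#' @param states A single H/E/C string.
#' @param rate Fraction of positions to set to coil (default 0.05).
#' @param rng_seed Optional integer seed making the draw reproducible.
#' @param max_retries Retry budget for all-coil draws (default 100).
#' @return The augmented state string (same length).
#' @export
#' @examples
#' mutate_to_coil("HHHHHHHHHH", rate = 0.2, rng_seed = 1)
mutate_to_coil <- function(states, rate = 0.05, rng_seed = NULL,
                           max_retries = 100L) {
  n <- nchar(states)
  stopifnot(n >= 1L, rate > 0, rate <= 1)
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  if (all(ch == "C")) {
    stop("mutate_to_coil: augmentation impossible, sequence is entirely coil")
  }
  k <- max(1L, as.integer(floor(rate * n)))
  draw <- function() {
    for (i in seq_len(max_retries)) {
      pos <- sample.int(n, k)
      if (any(ch[pos] != "C")) return(pos)
    }
    stop("mutate_to_coil: no effective change after ", max_retries, " retries")
  }
  pos <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  ch[pos] <- "C"
  paste(ch, collapse = "")
}

#' Balance one family to a target size by augmentation or subsampling
#'
#' Families larger than `target` are uniformly subsampled to `target`;
#' smaller families keep all original records and are topped up with
#' mutate-to-coil copies of uniformly drawn parents. Augmented records carry
#' `augmented = TRUE` and an `_augNNN` id suffix.
#'
#' @param family An [ss3_tbl()] holding one family's sequences.
#' @param target Desired family size (default 2000).
#' @param rate Mutation rate passed to [mutate_to_coil()].
#' @param rng_seed Integer seed for reproducibility.
#' @return An `ss3_tbl` with exactly `target` rows.
#' @export
balance_family <- function(family, target = 2000L, rate = 0.05,
                           rng_seed = 1L) {
  family <- validate_ss3(family)
  family <- family[order(family$id), ]  # input-order invariance
  target <- as.integer(target)
  if (target < 1L) stop("balance_family: target must be >= 1")
  n0 <- nrow(family)
  stopifnot(n0 >= 1L)
  withr::with_seed(rng_seed, {
    if (n0 >= target) {
      keep <- sort(sample.int(n0, target))
      return(validate_ss3(family[keep, ]))
    }
    n_new <- target - n0
    parents <- sample.int(n0, n_new, replace = TRUE)
    aug <- family[parents, ]
    aug$states <- vapply(aug$states, mutate_to_coil, "", rate = rate,
                         USE.NAMES = FALSE)
    aug$id <- sprintf("%s_aug%03d", aug$id, seq_len(n_new))
    aug$augmented <- TRUE
    aug$n <- nchar(aug$states)
    validate_ss3(dplyr::bind_rows(family, aug))
  })
}

#' Balance every family of a dataset to a common size
#'
#' Applies [balance_family()] per family; intended for training partitions
#' only (evaluation splits are never augmented).
#'
#' @param tbl An [ss3_tbl()] with family labels.
#' @param target Per-family target size.
#' @param rate Mutation rate.
#' @param rng_seed Master seed; per-family seeds are derived from it so the
#'   result does not depend on family order.
#' @return The balanced `ss3_tbl`.
#' @export
balance_dataset <- function(tbl, target = 2000L, rate = 0.05, rng_seed = 1L) {
  tbl <- validate_ss3(tbl)
  fams <- sort(unique(tbl$family))
  out <- lapply(fams, function(f) {
    balance_family(tbl[tbl$family == f, ], target = target, rate = rate,
                   rng_seed = stage_seed(rng_seed, f))
  })
  validate_ss3(dplyr::bind_rows(out))
}
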