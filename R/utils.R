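#' Derive a per-stage seed from a master seed and a stage name
#'
#' A small polynomial hash of the stage name is folded into the master seed,
#' so adding or reordering pipeline stages never perturbs the random draws
#' of other stages. The result always fits in a 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 1000003
  as.integer((as.numeric(master) + h * 1009) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-softmax with the usual max-shift for stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
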