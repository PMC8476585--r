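#' Construct a table of three-state secondary-structure sequences
#'
#' The central data container of the package: one row per protein, holding a
#' per-residue secondary-structure string over the alphabet H (helix),
#' E (strand), C (coil/loop), together with family and fold labels.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param states Character vector of H/E/C strings, one per sequence.
#' @param family Character vector of family labels (default `"unknown"`).
#' @param fold Character vector of fold labels (default `"unknown"`).
#' @param augmented Logical vector flagging records created by data
#'   augmentation (default `FALSE`).
#'
#' @return A tibble of class `ss3_tbl` with columns `id`, `family`, `fold`,
#'   `states`, `n` (residue count) and `augmented`.
#' @export
#' @examples
#' ss3_tbl("s1", "HHEECC", family = "F1", fold = "A")
ss3_tbl <- function(id, states, family = "unknown", fold = "unknown",
                    augmented = FALSE) {
  tbl <- tibble::tibble(
    id = as.character(id),
    family = rep_len(as.character(family), length(id)),
    fold = rep_len(as.character(fold), length(id)),
    states = as.character(states),
    n = nchar(states),
    augmented = rep_len(as.logical(augmented), length(id))
  )
  validate_ss3(tbl)
}

#' Validate an `ss3_tbl`
#'
#' Checks the container invariants: states only over H/E/C, at least one
#' residue per sequence, ids unique.
#'
#' @param tbl A tibble with at least `id` and `states` columns.
#' @return The validated tibble with class `ss3_tbl` (invisibly usable in
#'   pipelines).
#' @export
validate_ss3 <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("id", "states") %in% names(tbl)))
  if (!"family" %in% names(tbl)) tbl$family <- "unknown"
  if (!"fold" %in% names(tbl)) tbl$fold <- "unknown"
  if (!"n" %in% names(tbl)) tbl$n <- nchar(tbl$states)
  if (!"augmented" %in% names(tbl)) tbl$augmented <- FALSE
  if (any(tbl$n < 1L)) {
    stop("ss3 validation: empty states string for id ",
         tbl$id[which(tbl$n < 1L)[1]])
  }
  bad <- regexpr("[^HEC]", tbl$states)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("ss3 validation: illegal character '%s' in id '%s' at position %d",
                 substr(tbl$states[i], bad[i], bad[i]), tbl$id[i], bad[i]))
  }
  if (anyDuplicated(tbl$id)) {
    stop("ss3 validation: duplicated id '",
         tbl$id[duplicated(tbl$id)][1], "'")
  }
  class(tbl) <- unique(c("ss3_tbl", class(tbl)))
  tbl
}

#' Read secondary-structure sequences from an ss3-FASTA file
#'
#' The on-disk format is FASTA-like: a header line `>id|family|fold`
#' (family and fold optional, defaulting to `"unknown"`) followed by one or
#' more lines of H/E/C characters.
#'
#' @param path Path to the text file.
#' @return An [ss3_tbl()].
#' @export
#' @examples
#' f <- system.file("extdata", "example.ss3.fasta", package = "ss3fold")
#' read_ss3(f)
read_ss3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_ss3: empty file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("read_ss3: line 1 is not a header (expected '>')")
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  fields <- strsplit(headers, "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 1L | nf > 3L)) {
    stop("read_ss3: malformed header at line ",
         which(hdr)[which(nf < 1L | nf > 3L)[1]])
  }
  id <- vapply(fields, `[`, "", 1L)
  fam <- vapply(fields, function(f) if (length(f) >= 2 && nzchar(f[2])) f[2] else "unknown", "")
  fld <- vapply(fields, function(f) if (length(f) >= 3 && nzchar(f[3])) f[3] else "unknown", "")
  body <- vapply(split(lines[!hdr], rec[!hdr]), paste0, "", collapse = "")
  if (length(body) != length(id)) stop("read_ss3: record with no sequence body")
  ss3_tbl(id = id, states = unname(body), family = fam, fold = fld)
}

#' Write secondary-structure sequences to an ss3-FASTA file
#'
#' Canonical writer: `>id|family|fold` headers and 60-character wrapped
#' bodies, so `write_ss3(read_ss3(f))` round-trips canonical files
#' byte-identically.
#'
#' @param tbl An [ss3_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss3 <- function(tbl, path) {
  tbl <- validate_ss3(tbl)
  wrap <- function(s) {
    n <- nchar(s)
    starts <- seq(1L, n, by = 60L)
    substring(s, starts, pmin(starts + 59L, n))
  }
  con <- file(path, open = "wb")  # fixed "\n" endings on every platform
  on.exit(close(con))
  for (i in seq_len(nrow(tbl))) {
    writeLines(c(sprintf(">%s|%s|%s", tbl$id[i], tbl$family[i], tbl$fold[i]),
                 wrap(tbl$states[i])), con, sep = "\n")
  }
  invisible(path)
}

#' Read a labels table (id, family, fold) from TSV
#'
#' @param path Path to a tab-separated file with a header row and columns
#'   `id`, `family`, `fold`.
#' @return A tibble with those three character columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("id", "family", "fold")
  if (!all(need %in% names(df))) {
    stop("read_labels: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  tibble::as_tibble(df[need])
}

#' Write a labels table to TSV
#' @param tbl A data frame with `id`, `family`, `fold` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(tbl, path) {
  utils::write.table(tbl[c("id", "family", "fold")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length statistics and the mu + k*sigma length cutoff
#'
#' Models the sequence-length distribution as Gaussian and reports the
#' maximum-length cutoff `round(mu + k_sigma * sigma)` used to choose the
#' fixed encoding width.
#'
#' @param lengths Integer vector of residue counts (at least 2).
#' @param k_sigma Number of standard deviations above the mean (default 3).
#' @return A list with `mu`, `sigma`, `cutoff` (class `ss3_length_stats`).
#' @export
#' @examples
#' length_cutoff(c(280, 300, 320))
length_cutoff <- function(lengths, k_sigma = 3) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) stop("length_cutoff: need at least 2 lengths")
  mu <- mean(lengths)
  # population sd: the cutoff describes the realized set, not an estimator
  sigma <- sqrt(mean((lengths - mu)^2))
  cutoff <- as.integer(floor(mu + k_sigma * sigma + 0.5))  # round half up
  structure(list(mu = mu, sigma = sigma, cutoff = cutoff),
            class = "ss3_length_stats")
}

#' @export
print.ss3_length_stats <- function(x, ...) {
  cat(sprintf("length stats: mu = %.2f, sigma = %.2f, cutoff = %d\n",
              x$mu, x$sigma, x$cutoff))
  invisible(x)
}

# Fixed channel order for one-hot encoding; recorded in all model metadata.
ss3_channels <- function() c("H", "E", "C")

#' One-hot encode a secondary-structure string to a fixed-width matrix
#'
#' Encodes a state string into an `L_max x 3` matrix in channel order
#' (H, E, C). Positions beyond the sequence end are padding rows `[0,0,0]`;
#' the attached `pad_mask` attribute is `TRUE` exactly on real residues.
#'
#' @param states A single H/E/C string.
#' @param L_max Fixed encoding width (default 798).
#' @return A numeric `L_max x 3` matrix with attributes `pad_mask`
#'   (logical, length `L_max`) and `channels`.
#' @export
#' @examples
#' m <- encode_ss3("HEC", L_max = 5)
#' colSums(m)  # one residue per channel
encode_ss3 <- function(states, L_max = 798L) {
  n <- nchar(states)
  if (n > L_max) {
    stop(sprintf(paste0(
      "encode_ss3: sequence length %d exceeds L_max %d; ",
      "trim to the domain of interest first (see trim_to_domain)"), n, L_max))
  }
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  idx <- match(ch, ss3_channels())
  if (anyNA(idx)) stop("encode_ss3: illegal state character")
  m <- matrix(0, nrow = L_max, ncol = 3L,
              dimnames = list(NULL, ss3_channels()))
  m[cbind(seq_len(n), idx)] <- 1
  attr(m, "pad_mask") <- c(rep(TRUE, n), rep(FALSE, L_max - n))
  attr(m, "channels") <- ss3_channels()
  m
}

#' Decode an encoded matrix back to a state string
#'
#' Inverse of [encode_ss3()]: argmax over channels on unmasked rows.
#'
#' @param m A matrix produced by [encode_ss3()] (or any `L x 3` matrix with a
#'   `pad_mask` attribute).
#' @return The H/E/C string.
#' @export
decode_ss3 <- function(m) {
  mask <- attr(m, "pad_mask")
  if (is.null(mask)) mask <- rowSums(m != 0) > 0
  rows <- m[mask, , drop = FALSE]
  paste0(ss3_channels()[max.col(rows, ties.method = "first")], collapse = "")
}

#' Encode a dataset of sequences into the stacked model-input layout
#'
#' Internal model-facing layout: sequences are stacked row-wise so that row
#' `(i-1)*L_max + t` holds residue `t` of sequence `i`. This keeps every
#' network operation a plain matrix op.
#'
#' @param tbl An [ss3_tbl()].
#' @param L_max Fixed width.
#' @return A list with `x` (`(N*L_max) x 3` matrix), `mask` (logical vector),
#'   `ids`, `n` (lengths), `L_max`, `channels`.
#' @export
encode_set <- function(tbl, L_max = 798L) {
  tbl <- validate_ss3(tbl)
  if (any(tbl$n > L_max)) {
    stop("encode_set: ", sum(tbl$n > L_max), " sequence(s) exceed L_max = ",
         L_max, "; raise L_max or trim domains")
  }
  N <- nrow(tbl)
  x <- matrix(0, nrow = N * L_max, ncol = 3L)
  mask <- logical(N * L_max)
  all_states <- strsplit(tbl$states, "", fixed = TRUE)
  for (i in seq_len(N)) {
    idx <- match(all_states[[i]], ss3_channels())
    off <- (i - 1L) * L_max
    x[cbind(off + seq_along(idx), idx)] <- 1
    mask[off + seq_along(idx)] <- TRUE
  }
  list(x = x, mask = mask, ids = tbl$id, n = tbl$n, L_max = as.integer(L_max),
       channels = ss3_channels())
}

#' Trim a sequence to a domain interval
#'
#' Restricts a record to a 1-based inclusive residue interval (e.g. a domain
#' called by an external domain mapper) and annotates the id with the
#' interval.
#'
#' @param tbl An [ss3_tbl()] (one or more rows).
#' @param start,end 1-based inclusive bounds (scalars, recycled across rows).
#' @return The trimmed `ss3_tbl`; ids become `id/start-end`.
#' @export
#' @examples
#' trim_to_domain(ss3_tbl("s1", "HHEECC"), 3, 4)$states
trim_to_domain <- function(tbl, start, end) {
  tbl <- validate_ss3(tbl)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L) || any(end < start) || any(end > tbl$n)) {
    stop("trim_to_domain: interval out of range (need 1 <= start <= end <= n)")
  }
  out <- tbl
  out$states <- substr(tbl$states, start, end)
  out$id <- sprintf("%s/%d-%d", tbl$id, start, end)
  out$n <- nchar(out$states)
  validate_ss3(out)
}
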