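#' Configuration for the synthetic fold-grammar simulator
#'
#' The simulator emulates the statistical structure that the classifier and
#' the open-set detector assume about real folds: a fold is a *grammar* of
#' secondary-structure elements (an ordered template of H/E/C runs with
#' characteristic lengths), families within a fold share the grammar but
#' carry family-specific element-length offsets and fixed hypervariable-slot
#' insertions, and individual sequences add length jitter and per-position
#' state noise. Held-out "novel" archetypes emulate folds unseen in
#' training.
#'
#' @param n_archetypes Number of training fold archetypes.
#' @param families_per_archetype Families simulated per archetype.
#' @param seqs_per_family Sequences per family.
#' @param insertion_rate Probability that a family carries an insertion motif
#'   at each hypervariable slot.
#' @param noise_rate Per-position probability that a state is flipped to one
#'   of the other two states.
#' @param novel_archetypes Archetypes held out of training entirely.
#' @param max_len Maximum emitted sequence length (longer draws are
#'   truncated); matches the encoding width used downstream.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_archetypes = 3L, families_per_archetype = 4L,
                       seqs_per_family = 150L, insertion_rate = 0.3,
                       noise_rate = 0.05, novel_archetypes = 1L,
                       max_len = 256L, seed = 1L) {
  cfg <- list(n_archetypes = as.integer(n_archetypes),
              families_per_archetype = as.integer(families_per_archetype),
              seqs_per_family = as.integer(seqs_per_family),
              insertion_rate = insertion_rate,
              noise_rate = noise_rate,
              novel_archetypes = as.integer(novel_archetypes),
              max_len = as.integer(max_len),
              seed = as.integer(seed))
  stopifnot(cfg$n_archetypes >= 1L, cfg$families_per_archetype >= 1L,
            cfg$seqs_per_family >= 1L, cfg$novel_archetypes >= 0L,
            cfg$max_len >= 10L,
            insertion_rate >= 0, insertion_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# The three canonical archetypes mimic, at toy scale, the secondary-structure
# architectures of the major glycosyltransferase folds: a single Rossmann-like
# beta/alpha repeat, a doubled (two-domain) variant, and a membrane-like
# grammar of long helices separated by long loops.
canonical_archetypes <- function() {
  rossmann_unit <- list(
    list("E", 6L, 1), list("C", 4L, 1), list("H", 10L, 2), list("C", 4L, 1),
    list("E", 5L, 1), list("C", 3L, 1), list("H", 9L, 2), list("C", 5L, 2),
    list("E", 5L, 1), list("C", 6L, 2))
  dual <- c(rossmann_unit, list(list("C", 10L, 3)), rossmann_unit)
  membrane <- list(
    list("H", 18L, 2), list("C", 8L, 3), list("H", 16L, 2), list("C", 12L, 4),
    list("H", 18L, 2), list("C", 6L, 2), list("H", 17L, 2), list("C", 10L, 3),
    list("H", 16L, 2))
  list(
    fold_archetype("rossmann", rossmann_unit, hv_slots = c(4L, 8L)),
    fold_archetype("dual-rossmann", dual, hv_slots = c(8L, 11L, 18L)),
    fold_archetype("membrane", membrane, hv_slots = c(2L, 4L, 8L))
  )
}

#' Construct a fold archetype (a grammar of secondary-structure elements)
#'
#' @param name Archetype (fold) name.
#' @param template List of elements, each `list(state, mean_len, sd_len)`.
#' @param hv_slots Integer template positions that admit hypervariable
#'   insertions.
#' @return A list of class `fold_archetype`.
#' @export
fold_archetype <- function(name, template, hv_slots = integer()) {
  stopifnot(length(template) >= 1L)
  for (el in template) {
    stopifnot(el[[1]] %in% c("H", "E", "C"), el[[2]] >= 1L, el[[3]] >= 0)
  }
  structure(list(name = name, template = template,
                 hv_slots = as.integer(hv_slots)),
            class = "fold_archetype")
}

archetype_state_string <- function(a) {
  paste(vapply(a$template, `[[`, "", 1L), collapse = "")
}

# Random grammar for archetypes beyond the three canonical ones (and for
# held-out novel archetypes): 8-14 elements, no two consecutive elements in
# the same state, element lengths typical of secondary-structure runs.
random_archetype <- function(name) {
  n_el <- sample(8:14, 1L)
  states <- character(n_el)
  states[1] <- sample(c("H", "E", "C"), 1L)
  for (j in 2:n_el) {
    states[j] <- sample(setdiff(c("H", "E", "C"), states[j - 1L]), 1L)
  }
  template <- lapply(states, function(s) {
    mean_len <- switch(s,
      H = sample(8:16, 1L), E = sample(4:8, 1L), C = sample(3:10, 1L))
    list(s, as.integer(mean_len), stats::runif(1, 0.5, 2.5))
  })
  hv <- which(states == "C")
  if (length(hv) > 3L) hv <- sort(sample(hv, 3L))
  fold_archetype(name, template, hv_slots = hv)
}

#' Build the set of fold archetypes for a simulation
#'
#' The first three training archetypes are fixed canonical grammars
#' (Rossmann-like, dual-domain, membrane-like); any further training
#' archetypes and all held-out novel archetypes are random grammars drawn
#' deterministically from the configured seed. Archetypes are guaranteed
#' pairwise distinct in their element state order.
#'
#' @param config A [sim_config()].
#' @return Named list with `train` and `novel`, each a list of
#'   [fold_archetype()] objects.
#' @export
make_archetypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    canon <- canonical_archetypes()
    total <- config$n_archetypes + config$novel_archetypes
    arch <- list()
    seen <- character()
    i <- 0L
    while (length(arch) < total) {
      i <- i + 1L
      if (i > 100L * total) stop("make_archetypes: could not build distinct grammars")
      cand <- if (length(arch) < config$n_archetypes && length(arch) < 3L) {
        canon[[length(arch) + 1L]]
      } else {
        nm <- if (length(arch) < config$n_archetypes) {
          sprintf("arch%02d", length(arch) + 1L)
        } else {
          sprintf("novel%02d", length(arch) - config$n_archetypes + 1L)
        }
        random_archetype(nm)
      }
      sig <- archetype_state_string(cand)
      if (!sig %in% seen) {
        arch <- c(arch, list(cand))
        seen <- c(seen, sig)
      }
    }
    list(train = arch[seq_len(config$n_archetypes)],
         novel = if (config$novel_archetypes > 0L) {
           arch[config$n_archetypes + seq_len(config$novel_archetypes)]
         } else list())
  })
}

# Draw one family's realization of an archetype: per-element mean-length
# offsets plus fixed insertion motifs at hypervariable slots.
draw_family_grammar <- function(archetype, insertion_rate) {
  template <- lapply(archetype$template, function(el) {
    # family offset scales with the element's own length sd, so rigid
    # (sd = 0) elements keep exact positions across families
    off <- if (el[[3]] > 0) round(stats::rnorm(1, 0, el[[3]])) else 0L
    list(el[[1]], max(1L, as.integer(el[[2]] + off)), el[[3]])
  })
  inserts <- vector("list", length(template))
  for (slot in archetype$hv_slots) {
    if (stats::runif(1) < insertion_rate) {
      len <- sample(4:12, 1L)
      st <- character(len)
      st[1] <- sample(c("H", "E", "C"), 1L)
      for (j in seq_len(len - 1L)) {
        st[j + 1L] <- if (stats::runif(1) < 0.8) st[j] else
          sample(setdiff(c("H", "E", "C"), st[j]), 1L)
      }
      inserts[[slot]] <- paste(st, collapse = "")
    }
  }
  list(template = template, inserts = inserts)
}

sample_family_sequence <- function(grammar, noise_rate, max_len) {
  parts <- character(0)
  for (j in seq_along(grammar$template)) {
    el <- grammar$template[[j]]
    len <- max(1L, as.integer(round(stats::rnorm(1, el[[2]], el[[3]]))))
    parts <- c(parts, strrep(el[[1]], len))
    if (!is.null(grammar$inserts[[j]])) parts <- c(parts, grammar$inserts[[j]])
  }
  s <- paste(parts, collapse = "")
  if (nchar(s) > max_len) s <- substr(s, 1L, max_len)
  if (noise_rate > 0) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    flip <- stats::runif(length(ch)) < noise_rate
    if (any(flip)) {
      # a flip always changes the state, so the realized mismatch fraction
      # against the noiseless consensus is the configured noise rate
      alt <- list(H = c("E", "C"), E = c("H", "C"), C = c("H", "E"))
      ch[flip] <- vapply(ch[flip], function(x) sample(alt[[x]], 1L), "")
      s <- paste(ch, collapse = "")
    }
  }
  s
}

# Noiseless, jitter-free realization of a family grammar (its consensus).
family_consensus <- function(grammar, max_len) {
  parts <- character(0)
  for (j in seq_along(grammar$template)) {
    el <- grammar$template[[j]]
    parts <- c(parts, strrep(el[[1]], el[[2]]))
    if (!is.null(grammar$inserts[[j]])) parts <- c(parts, grammar$inserts[[j]])
  }
  s <- paste(parts, collapse = "")
  if (nchar(s) > max_len) s <- substr(s, 1L, max_len)
  s
}

#' Sample a complete synthetic dataset
#'
#' Generates training sequences for every (archetype, family) stratum plus
#' held-out sequences from novel archetypes, all deterministic under the
#' configured seed.
#'
#' @param config A [sim_config()].
#' @param archetypes Optional archetype set from [make_archetypes()]
#'   (rebuilt from `config` when omitted).
#' @return A list with `train` (an [ss3_tbl()]), `novel` (an `ss3_tbl`,
#'   possibly empty), `truth` (tibble id/family/fold/novel) and
#'   `consensus` (named list family -> noiseless consensus string).
#' @export
#' @examples
#' d <- sample_dataset(sim_config(seqs_per_family = 5, seed = 7))
#' table(d$train$fold)
sample_dataset <- function(config, archetypes = make_archetypes(config)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    emit <- function(arch_list, novel) {
      rows <- list()
      consensus <- list()
      for (a in arch_list) {
        for (f in seq_len(config$families_per_archetype)) {
          fam <- sprintf("%s_f%d", a$name, f)
          grammar <- draw_family_grammar(a, config$insertion_rate)
          consensus[[fam]] <- family_consensus(grammar, config$max_len)
          states <- vapply(seq_len(config$seqs_per_family), function(s) {
            sample_family_sequence(grammar, config$noise_rate, config$max_len)
          }, "")
          rows[[fam]] <- tibble::tibble(
            id = sprintf("%s_s%03d", fam, seq_len(config$seqs_per_family)),
            family = fam, fold = a$name, states = states,
            n = nchar(states), augmented = FALSE)
        }
      }
      list(tbl = validate_ss3(dplyr::bind_rows(rows)), consensus = consensus)
    }
    tr <- emit(archetypes$train, FALSE)
    nv <- if (length(archetypes$novel) > 0L) emit(archetypes$novel, TRUE) else
      list(tbl = ss3_tbl(character(0), character(0))[0, ], consensus = list())
    truth <- dplyr::bind_rows(
      tibble::tibble(id = tr$tbl$id, family = tr$tbl$family,
                     fold = tr$tbl$fold, novel = FALSE),
      if (nrow(nv$tbl) > 0L) {
        tibble::tibble(id = nv$tbl$id, family = nv$tbl$family,
                       fold = nv$tbl$fold, novel = TRUE)
      })
    list(train = tr$tbl, novel = nv$tbl, truth = truth,
         consensus = c(tr$consensus, nv$consensus))
  })
}
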