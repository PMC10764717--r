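#' Specify a synthetic KS-like family
#'
#' A family is a seeded recipe for a profile HMM of `M` match states in
#' which every column concentrates `conservation` probability mass on one
#' preferred residue (drawn uniformly under `seed`) and spreads the rest in
#' proportion to the background. Insertions/deletions open at
#' `indel_rate / 2` each per node.
#'
#' @param name Family name (single token).
#' @param M Match-state count. 120 is the desk-scale default; 420 matches a
#'   typical KS domain length.
#' @param conservation Probability mass on each column's preferred residue,
#'   in `(0.05, 1]` (at most 1/20 would be indistinguishable from
#'   background).
#' @param indel_rate Total probability of opening an insertion or deletion
#'   at a node, in `[0, 0.2]`.
#' @param seed Integer seed fixing the preferred-residue draws.
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, M = 120, conservation = 0.7, indel_rate = 0.02,
                        seed = 0) {
  if (!is.numeric(M) || M < 1) abort("`M` must be a positive integer.")
  if (!is.numeric(conservation) || conservation <= 1 / 20 || conservation > 1) {
    abort("`conservation` must lie in (0.05, 1].")
  }
  if (!is.numeric(indel_rate) || indel_rate < 0 || indel_rate > 0.2) {
    abort("`indel_rate` must lie in [0, 0.2].")
  }
  structure(list(name = as.character(name)[1], M = as.integer(M),
                 conservation = conservation, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Materialize a family specification as a profile HMM
#'
#' @param spec A [family_spec()].
#' @param background `"uniform"` or a 20-vector of probabilities.
#' @return A `profile_hmm`, deterministic given `spec$seed`.
#' @export
make_family_hmm <- function(spec, background = "uniform") {
  if (!inherits(spec, "family_spec")) abort("`spec` must be a `family_spec`.")
  bg <- resolve_background(background)
  pref <- withr::with_seed(spec$seed,
                           sample.int(20, spec$M, replace = TRUE))
  c0 <- spec$conservation
  me <- matrix(0, spec$M, 20)
  for (k in seq_len(spec$M)) {
    rest <- bg
    rest[pref[k]] <- 0
    me[k, ] <- (1 - c0) * rest / sum(rest)
    me[k, pref[k]] <- me[k, pref[k]] + c0
  }
  ir <- spec$indel_rate
  tr_row <- c(1 - ir, ir / 2, ir / 2, 0.6, 0.4, 0.6, 0.4)
  tr <- matrix(rep(tr_row, spec$M + 1), spec$M + 1, 7, byrow = TRUE)
  new_profile_hmm(name = spec$name, match_emissions = me,
                  insert_emissions = bg, transitions = tr, background = bg)
}

#' Interpolate two profile HMMs
#'
#' Every emission and transition probability of the result is the convex
#' combination `(1 - lambda) * a + lambda * b`, renormalized to machine
#' precision. This produces a controllable "intermediate" family emulating
#' the score continuum observed between FAS-like and PKS-like KS domains.
#'
#' @param a,b `profile_hmm` objects with equal `M`.
#' @param lambda Fraction of `b`, in `[0, 1]`.
#' @return A `profile_hmm` named after its parents and `lambda`.
#' @export
interpolate_models <- function(a, b, lambda) {
  validate_profile_hmm(a)
  validate_profile_hmm(b)
  if (a$M != b$M) {
    abort(paste0("Model length mismatch: ", a$M, " vs ", b$M, " match states."))
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  mix <- function(x, y) (1 - lambda) * x + lambda * y
  renorm_rows <- function(m) m / rowSums(m)
  me <- renorm_rows(mix(a$match_emissions, b$match_emissions))
  ie <- mix(a$insert_emissions, b$insert_emissions)
  ie <- ie / sum(ie)
  bg <- mix(a$background, b$background)
  bg <- bg / sum(bg)
  tr <- mix(a$transitions, b$transitions)
  for (g in list(1:3, 4:5, 6:7)) tr[, g] <- tr[, g, drop = FALSE] / rowSums(tr[, g, drop = FALSE])
  new_profile_hmm(name = sprintf("%s:%s:l%.3g", a$name, b$name, lambda),
                  match_emissions = me, insert_emissions = ie,
                  transitions = tr, background = bg)
}

#' Mutate a sequence by random substitution
#'
#' Each position is independently substituted with probability `rate` by a
#' uniform draw from the 19 other residues (`X` positions are resampled
#' uniformly from all 20).
#'
#' @param residues A single residue string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The mutated residue string.
#' @export
mutate_sequence <- function(residues, rate, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) abort("`rate` must lie in [0, 1].")
  if (length(residues) != 1) abort("`residues` must be a single string.")
  run <- function() {
    chars <- strsplit(residues, "")[[1]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(ch) {
        pool <- setdiff(AA_ALPHABET, ch)
        pool[sample.int(length(pool), 1)]
      }, character(1), USE.NAMES = FALSE)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Specify an interpolated (intermediate) family
#'
#' @param parent_a,parent_b Names of two [family_spec()] families.
#' @param lambda Fraction of `parent_b` in `[0, 1]`.
#' @param name Optional class label; defaults to
#'   `"<parent_a>:<parent_b>:l<lambda>"`.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(parent_a, parent_b, lambda, name = NULL) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  if (is.null(name)) name <- sprintf("%s:%s:l%.3g", parent_a, parent_b, lambda)
  structure(list(parent_a = parent_a, parent_b = parent_b,
                 lambda = lambda, name = name),
            class = "mixture_spec")
}

#' Generate a labeled synthetic dataset
#'
#' Builds each family model, each mixture model by [interpolate_models()],
#' samples `n_per_class` sequences per class with [sample_sequence()], and
#' applies [mutate_sequence()] at `noise_rate`. Fully deterministic given
#' `seed`.
#'
#' @param families List of [family_spec()]s.
#' @param mixtures List of [mixture_spec()]s (may be empty).
#' @param n_per_class Sequences per class (>= 1).
#' @param noise_rate Per-site substitution rate applied after sampling.
#' @param seed Integer master seed.
#' @return A list of class `ks_dataset`: `$sequences` (tibble with `id`,
#'   `description`, `residues`, `label`, `lambda`), `$models` (named list of
#'   `profile_hmm`s, one per class) and `$seed`.
#' @export
generate_labeled_dataset <- function(families, mixtures = list(),
                                     n_per_class, noise_rate = 0.05,
                                     seed = 0) {
  if (length(families) == 0) abort("At least one family is required.")
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be >= 1.")
  }
  fam_models <- list()
  for (f in families) {
    if (!inherits(f, "family_spec")) abort("`families` must contain `family_spec`s.")
    fam_models[[f$name]] <- make_family_hmm(f)
  }
  class_models <- fam_models
  lambda_of <- setNames(rep(0, length(fam_models)), names(fam_models))
  for (m in mixtures) {
    if (!inherits(m, "mixture_spec")) abort("`mixtures` must contain `mixture_spec`s.")
    for (p in c(m$parent_a, m$parent_b)) {
      if (!p %in% names(fam_models)) {
        abort(paste0("Mixture references unknown family: ", p))
      }
    }
    mod <- interpolate_models(fam_models[[m$parent_a]], fam_models[[m$parent_b]],
                              m$lambda)
    mod$name <- m$name
    class_models[[m$name]] <- mod
    lambda_of[m$name] <- m$lambda
  }

  rows <- withr::with_seed(seed, {
    purrr::imap(class_models, function(mod, label) {
      s <- sample_sequence(mod, n = n_per_class, prefix = label)
      if (noise_rate > 0) {
        s$residues <- vapply(s$residues, mutate_sequence, character(1),
                             rate = noise_rate, USE.NAMES = FALSE)
      }
      s$label <- label
      s$lambda <- lambda_of[[label]]
      s
    })
  })
  sequences <- dplyr::bind_rows(rows)
  structure(list(sequences = sequences, models = class_models, seed = seed),
            class = "ks_dataset")
}

#' @export
print.ks_dataset <- function(x, ...) {
  cat("<ks_dataset> ", nrow(x$sequences), " sequences, ",
      length(x$models), " classes (seed ", x$seed, ")\n", sep = "")
  print(dplyr::count(x$sequences, .data$label))
  invisible(x)
}
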