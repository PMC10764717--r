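#' Construct a profile HMM object
#'
#' Low-level constructor for the `profile_hmm` class: a Plan7-like profile
#' with M match states, per-state match emissions, one shared insert-emission
#' vector, per-node transition 7-tuples `(MM, MI, MD, IM, II, DM, DD)` for
#' nodes `0..M` (node 0 is the begin state; node M's `MM`/`MD` mass routes to
#' the end state), and a background composition. All probability rows must be
#' positive and normalized.
#'
#' @param name Model name (single token).
#' @param match_emissions `M x 20` matrix of match-emission probabilities,
#'   columns in alphabet order.
#' @param insert_emissions Length-20 insert-emission probability vector,
#'   shared across insert states.
#' @param transitions `(M+1) x 7` matrix, columns `MM, MI, MD, IM, II, DM, DD`.
#' @param background Length-20 background probability vector.
#' @return A `profile_hmm` object.
#' @export
new_profile_hmm <- function(name, match_emissions, insert_emissions,
                            transitions, background) {
  hmm <- structure(
    list(
      name = as.character(name)[1],
      M = nrow(match_emissions),
      match_emissions = unname(as.matrix(match_emissions)),
      insert_emissions = unname(as.numeric(insert_emissions)),
      transitions = unname(as.matrix(transitions)),
      background = unname(as.numeric(background))
    ),
    class = "profile_hmm"
  )
  validate_profile_hmm(hmm)
}

TRANSITION_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Validate a profile HMM
#'
#' Checks normalization (each emission row, the background, and each node's
#' `MM+MI+MD`, `IM+II`, `DM+DD` groups sum to 1 within 1e-9) and positivity
#' of emissions.
#'
#' @param hmm A `profile_hmm`.
#' @return `hmm`, invisibly; aborts on violation.
#' @export
validate_profile_hmm <- function(hmm) {
  if (!inherits(hmm, "profile_hmm")) abort("Not a `profile_hmm` object.")
  M <- hmm$M
  if (is.null(M) || M < 1) abort("Profile must have at least one match state.")
  me <- hmm$match_emissions
  if (!is.matrix(me) || nrow(me) != M || ncol(me) != 20) {
    abort("`match_emissions` must be an M x 20 matrix.")
  }
  if (any(me <= 0)) abort("Match emissions must be strictly positive.")
  if (any(abs(rowSums(me) - 1) > 1e-9)) abort("Match emission rows must sum to 1.")
  ie <- hmm$insert_emissions
  if (length(ie) != 20 || any(ie <= 0) || abs(sum(ie) - 1) > 1e-9) {
    abort("`insert_emissions` must be 20 positive probabilities summing to 1.")
  }
  tr <- hmm$transitions
  if (!is.matrix(tr) || nrow(tr) != M + 1 || ncol(tr) != 7) {
    abort("`transitions` must be an (M+1) x 7 matrix.")
  }
  if (any(tr < 0)) abort("Transition probabilities must be non-negative.")
  grp <- cbind(rowSums(tr[, 1:3, drop = FALSE]),
               rowSums(tr[, 4:5, drop = FALSE]),
               rowSums(tr[, 6:7, drop = FALSE]))
  if (any(abs(grp - 1) > 1e-9)) {
    abort("Each node's MM+MI+MD, IM+II and DM+DD must sum to 1.")
  }
  bg <- hmm$background
  if (length(bg) != 20 || any(bg <= 0) || abs(sum(bg) - 1) > 1e-9) {
    abort("`background` must be 20 positive probabilities summing to 1.")
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$name, "\n", sep = "")
  cat("  match states: ", x$M, "\n", sep = "")
  cons <- consensus_sequence(x)
  cat("  consensus:    ",
      if (nchar(cons) > 60) paste0(substr(cons, 1, 57), "...") else cons,
      "\n", sep = "")
  invisible(x)
}

#' @describeIn new_profile_hmm Per-match-state emission table in long form
#'   (`state`, `residue`, `probability`).
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @export
tidy.profile_hmm <- function(x, ...) {
  tibble(
    state = rep(seq_len(x$M), each = 20),
    residue = rep(AA_ALPHABET, times = x$M),
    probability = as.numeric(t(x$match_emissions))
  )
}

#' @describeIn new_profile_hmm One-row model summary (name, number of match
#'   states, mean match-column information content in bits).
#' @export
glance.profile_hmm <- function(x, ...) {
  rel_ent <- rowSums(x$match_emissions *
                       log2(sweep(x$match_emissions, 2, x$background, "/")))
  tibble(name = x$name, m = x$M, mean_information_bits = mean(rel_ent))
}

#' Consensus sequence of a profile
#'
#' The highest-probability residue of each match state.
#'
#' @param hmm A `profile_hmm`.
#' @return A residue string of length `M`.
#' @export
consensus_sequence <- function(hmm) {
  paste(AA_ALPHABET[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

# Fixed transition priors blended with observed counts in build_profile().
TRANSITION_PRIOR <- c(MM = 0.90, MI = 0.05, MD = 0.05,
                      IM = 0.60, II = 0.40, DM = 0.60, DD = 0.40)

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is at most `gap_threshold` become match states.
#' Match emissions are pseudocount-smoothed observed frequencies:
#' `(count(a) + w * bg(a)) / (n + w)` with `w = pseudocount_weight`, where
#' `n` counts non-gap, non-`X` residues in the column (`X` contributes to no
#' count). Transition probabilities blend observed state-path counts with
#' fixed priors (`MM .90, MI .05, MD .05, IM .60, II .40, DM .60, DD .40`)
#' through the same pseudocount weight. Insert emissions equal the
#' background.
#'
#' @param msa An alignment tibble from [read_alignment()].
#' @param gap_threshold Maximum gap fraction for a match column (default 0.5,
#'   ties inclusive).
#' @param pseudocount_weight Pseudocount mass `w` (default 5).
#' @param background `"uniform"` or a 20-vector of probabilities.
#' @param name Model name (default `"profile"`).
#' @return A `profile_hmm`.
#' @export
build_profile <- function(msa, gap_threshold = 0.5, pseudocount_weight = 5.0,
                          background = "uniform", name = "profile") {
  if (!is.data.frame(msa) || !all(c("id", "aligned") %in% names(msa))) {
    abort("`msa` must be a data frame with columns `id` and `aligned`.")
  }
  if (!is.numeric(gap_threshold) || gap_threshold < 0 || gap_threshold > 1) {
    abort("`gap_threshold` must lie in [0, 1].")
  }
  if (!is.numeric(pseudocount_weight) || pseudocount_weight <= 0) {
    abort("`pseudocount_weight` must be positive.")
  }
  bg <- resolve_background(background)
  w <- pseudocount_weight

  chars <- do.call(rbind, strsplit(msa$aligned, ""))
  L <- ncol(chars)
  n_rows <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  is_match <- gap_frac <= gap_threshold
  M <- sum(is_match)
  if (M == 0) abort("No alignment column qualifies as a match state.")

  # Emissions
  me <- matrix(0, M, 20)
  match_cols <- which(is_match)
  for (k in seq_len(M)) {
    col <- chars[, match_cols[k]]
    col <- col[col != "-" & col != "X"]
    counts <- tabulate(match(col, AA_ALPHABET), nbins = 20)
    me[k, ] <- (counts + w * bg) / (sum(counts) + w)
  }

  # Transition counts from per-row state paths. Node index = number of match
  # columns passed; residues in insert columns occupy I at the current node.
  tc <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANSITION_NAMES))
  node_of_col <- cumsum(is_match)
  for (r in seq_len(n_rows)) {
    prev_state <- "M"; prev_node <- 0           # begin acts as M_0
    for (c in seq_len(L)) {
      if (is_match[c]) {
        st <- if (chars[r, c] == "-") "D" else "M"
        nd <- node_of_col[c]
      } else if (chars[r, c] != "-") {
        st <- "I"; nd <- node_of_col[c]
      } else next
      key <- paste0(prev_state, st)
      if (key %in% c("MI", "II") && nd == prev_node) {
        tc[prev_node + 1, key] <- tc[prev_node + 1, key] + 1
      } else if (key %in% c("MM", "MD", "IM", "DM", "DD") && nd == prev_node + 1) {
        tc[prev_node + 1, key] <- tc[prev_node + 1, key] + 1
      }
      # D->I and I->D have no slot in the 7-tuple and are skipped.
      prev_state <- st; prev_node <- nd
    }
    # exit into the end state from node M
    key <- paste0(prev_state, "M")
    if (prev_node == M && key %in% c("MM", "IM", "DM")) {
      tc[M + 1, key] <- tc[M + 1, key] + 1
    }
  }

  tr <- matrix(0, M + 1, 7)
  groups <- list(1:3, 4:5, 6:7)
  for (k in seq_len(M + 1)) {
    for (g in groups) {
      tot <- sum(tc[k, g])
      tr[k, g] <- (tc[k, g] + w * TRANSITION_PRIOR[g]) / (tot + w)
    }
  }

  new_profile_hmm(name = name, match_emissions = me, insert_emissions = bg,
                  transitions = tr, background = bg)
}

# --- scoring ---------------------------------------------------------------

residue_indices <- function(residues) {
  idx <- match(strsplit(residues, "")[[1]], AA_ALPHABET)  # X and friends -> NA
  idx
}

# Precompute log-odds pieces shared across sequences for one model.
hmm_log_odds <- function(hmm) {
  lbg <- log(hmm$background)
  list(
    lom = log(hmm$match_emissions) - matrix(lbg, hmm$M, 20, byrow = TRUE),
    li = log(hmm$insert_emissions) - lbg,
    logT = suppressWarnings(log(hmm$transitions))
  )
}

seq_log_matrices <- function(pieces, idx) {
  L <- length(idx)
  logE <- matrix(0, nrow(pieces$lom), L)
  known <- !is.na(idx)
  if (any(known)) logE[, known] <- pieces$lom[, idx[known], drop = FALSE]
  logEins <- numeric(L)
  logEins[known] <- pieces$li[idx[known]]
  list(logE = logE, logEins = logEins)
}

#' Forward-algorithm bit score
#'
#' The log2 odds of a sequence under the profile versus an i.i.d. background
#' null, with the numerator summed over all state paths by the forward
#' algorithm. In `"glocal"` mode the whole model is traversed and the whole
#' sequence emitted; in `"local"` mode a single best-supported contiguous
#' model/sequence fragment is scored (unihit), with flanking residues
#' emitted by the null. `X` residues emit at background in both numerator
#' and denominator and so contribute 0 bits.
#'
#' @param hmm A `profile_hmm`.
#' @param residues A character vector of residue strings.
#' @param mode `"glocal"` (default) or `"local"`.
#' @return A numeric vector of bit scores (possibly negative).
#' @examples
#' spec <- family_spec("toy", M = 5, conservation = 0.9, seed = 1)
#' hmm <- make_family_hmm(spec)
#' forward_bitscore(hmm, consensus_sequence(hmm))
#' @export
forward_bitscore <- function(hmm, residues, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  validate_profile_hmm(hmm)
  if (length(residues) == 0) abort("No sequences supplied.")
  if (any(!nzchar(residues))) abort("Empty sequence: cannot score.")
  pieces <- hmm_log_odds(hmm)
  vapply(residues, function(r) {
    mats <- seq_log_matrices(pieces, residue_indices(r))
    lo <- if (mode == "glocal") {
      cpp_forward_glocal(mats$logE, mats$logEins, pieces$logT)
    } else {
      cpp_forward_local(mats$logE, mats$logEins, pieces$logT)
    }
    lo / log(2)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Locate the best-scoring domain window
#'
#' Runs local-mode Viterbi (single best path) and reports the
#' maximal-scoring window as a one-row tibble if its bit score reaches
#' `threshold`, else `NULL`. Intervals are 0-based half-open on the query,
#' matching common domain-coordinate conventions.
#'
#' @param hmm A `profile_hmm`.
#' @param residues A single residue string.
#' @param threshold Bit-score gate for reporting a hit (default 180, the
#'   KS-hit gate used when mining full-scale models; lower it for toy
#'   profiles).
#' @return A tibble with columns `start`, `end`, `bits`, or `NULL`.
#' @export
locate_domain <- function(hmm, residues, threshold = 180) {
  validate_profile_hmm(hmm)
  if (length(residues) != 1) abort("`residues` must be a single sequence string.")
  if (!nzchar(residues)) abort("Empty sequence: cannot score.")
  pieces <- hmm_log_odds(hmm)
  mats <- seq_log_matrices(pieces, residue_indices(residues))
  v <- cpp_viterbi_local(mats$logE, mats$logEins, pieces$logT)
  bits <- v$log_odds / log(2)
  if (!is.finite(bits) || bits < threshold) return(NULL)
  tibble(start = v$start, end = v$end, bits = bits)
}

#' Sample sequences from a profile HMM
#'
#' Stochastic traversal begin -> ... -> end, emitting from match and insert
#' states. Deterministic for a given `seed`.
#'
#' @param hmm A `profile_hmm`.
#' @param n Number of sequences (default 1).
#' @param seed Optional integer seed; when `NULL`, the current RNG stream is
#'   used (callers managing their own seed).
#' @param prefix Id prefix (default the model name).
#' @return A sequence tibble (`id`, `description`, `residues`).
#' @export
sample_sequence <- function(hmm, n = 1, seed = NULL, prefix = NULL) {
  validate_profile_hmm(hmm)
  if (is.null(prefix)) prefix <- hmm$name
  draw <- function() {
    vapply(seq_len(n), function(i) sample_one_path(hmm), character(1))
  }
  residues <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(id = sprintf("%s_%03d", prefix, seq_len(n)),
         description = paste0("sampled from ", hmm$name),
         residues = residues)
}

sample_one_path <- function(hmm) {
  tr <- hmm$transitions
  me <- hmm$match_emissions
  ie <- hmm$insert_emissions
  M <- hmm$M
  out <- character(0)
  state <- "M"; node <- 0                       # begin acts as M_0
  repeat {
    if (state == "M" || state == "B") {
      p <- tr[node + 1, 1:3]
      nxt <- sample(c("MM", "MI", "MD"), 1, prob = p)
    } else if (state == "I") {
      p <- tr[node + 1, 4:5]
      nxt <- sample(c("IM", "II"), 1, prob = p)
    } else {
      p <- tr[node + 1, 6:7]
      nxt <- sample(c("DM", "DD"), 1, prob = p)
    }
    to <- substr(nxt, 2, 2)
    if (to == "I") {
      out <- c(out, sample(AA_ALPHABET, 1, prob = ie))
      state <- "I"                              # node unchanged
    } else {
      if (node == M) break                      # M/D advance out of node M = end
      node <- node + 1
      if (to == "M") out <- c(out, sample(AA_ALPHABET, 1, prob = me[node, ]))
      state <- to
    }
  }
  paste(out, collapse = "")
}
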