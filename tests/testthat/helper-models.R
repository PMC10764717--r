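# Shared fixtures: hand-built toy profiles and an exhaustive path-enumeration
# oracle for the forward algorithm. The oracle is independent of the package's
# DP implementation: it literally enumerates every begin->end state path that
# emits the query and sums path probabilities.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

uniform_bg <- rep(1 / 20, 20)

# A profile whose transitions route begin -> M1 -> ... -> M_M -> end with no
# inserts or deletes unless asked for.
toy_hmm <- function(match_emissions, mm = 1, mi = 0, md = 0,
                    im = 0.6, dm = 0.6, insert = uniform_bg, bg = uniform_bg,
                    name = "toy") {
  M <- nrow(match_emissions)
  tr <- matrix(rep(c(mm, mi, md, im, 1 - im, dm, 1 - dm), M + 1),
               M + 1, 7, byrow = TRUE)
  new_profile_hmm(name, match_emissions, insert, tr, bg)
}

# Emission matrix concentrating `p` on one residue per state.
peaked_emissions <- function(residues, p = 0.9) {
  idx <- match(strsplit(residues, "")[[1]], AA)
  M <- length(idx)
  me <- matrix((1 - p) / 19, M, 20)
  for (k in seq_len(M)) me[k, idx[k]] <- p
  me
}

# Random valid toy profile over the full alphabet (Dirichlet-ish rows).
random_toy_hmm <- function(M, seed) {
  withr::with_seed(seed, {
    me <- matrix(rgamma(M * 20, 1), M, 20)
    me <- me / rowSums(me)
    ie <- rgamma(20, 1); ie <- ie / sum(ie)
    tr <- matrix(0, M + 1, 7)
    for (k in seq_len(M + 1)) {
      a <- rgamma(3, 1); tr[k, 1:3] <- a / sum(a)
      b <- rgamma(2, 1); tr[k, 4:5] <- b / sum(b)
      d <- rgamma(2, 1); tr[k, 6:7] <- d / sum(d)
    }
    new_profile_hmm("rand", me, ie, tr, uniform_bg)
  })
}

# Exhaustive glocal forward: sum of P(path, seq) over every explicit path.
# States are (kind, node); begin behaves like M at node 0. Returns log2 odds
# against the i.i.d. background null, like forward_bitscore(mode = "glocal").
oracle_forward_glocal <- function(hmm, residues) {
  idx <- match(strsplit(residues, "")[[1]], AA)
  L <- length(idx)
  M <- hmm$M
  tr <- hmm$transitions
  me <- hmm$match_emissions
  ie <- hmm$insert_emissions
  bg <- hmm$background
  emit_m <- function(k, i) if (is.na(idx[i])) 1 else me[k, idx[i]]
  emit_i <- function(i) if (is.na(idx[i])) 1 else ie[idx[i]]
  total <- 0
  # `state` is the state just arrived in (emission already applied), `i` the
  # number of residues consumed, `p` the path probability so far.
  go <- function(state, node, i, p) {
    if (p == 0) return()
    if (state %in% c("M", "B")) {
      pmm <- tr[node + 1, 1]; pmi <- tr[node + 1, 2]; pmd <- tr[node + 1, 3]
      if (node == M) {
        if (i == L) total <<- total + p * (pmm + pmd)   # M_M -> E
        if (i < L) go("I", node, i + 1, p * pmi * emit_i(i + 1))
      } else {
        if (i < L) go("M", node + 1, i + 1, p * pmm * emit_m(node + 1, i + 1))
        if (i < L) go("I", node, i + 1, p * pmi * emit_i(i + 1))
        go("D", node + 1, i, p * pmd)
      }
    } else if (state == "I") {
      pim <- tr[node + 1, 4]; pii <- tr[node + 1, 5]
      if (node == M) {
        if (i == L) total <<- total + p * pim           # I_M -> E
      } else if (i < L) {
        go("M", node + 1, i + 1, p * pim * emit_m(node + 1, i + 1))
      }
      if (i < L) go("I", node, i + 1, p * pii * emit_i(i + 1))
    } else {                                            # D
      pdm <- tr[node + 1, 6]; pdd <- tr[node + 1, 7]
      if (node == M) {
        if (i == L) total <<- total + p                 # D_M -> E, prob 1
      } else {
        if (i < L) go("M", node + 1, i + 1, p * pdm * emit_m(node + 1, i + 1))
        go("D", node + 1, i, p * pdd)
      }
    }
  }
  go("B", 0, 0, 1)
  null_p <- prod(ifelse(is.na(idx), 1, bg[idx]))
  log2(total / null_p)
}

# Random residue strings over a reduced 4-letter alphabet (keeps the oracle's
# path count small while exercising mismatches).
random_reduced_seq <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "D", "E"), len, replace = TRUE),
                               collapse = ""))
}

default_fas_pks_models <- function(M = 120) {
  list(
    fas = make_family_hmm(family_spec("FAS", M = M, conservation = 0.55,
                                      indel_rate = 0.02, seed = 101)),
    pks = make_family_hmm(family_spec("PKS", M = M, conservation = 0.95,
                                      indel_rate = 0.02, seed = 102)),
    fasii = make_family_hmm(family_spec("FASII", M = M, conservation = 0.75,
                                        indel_rate = 0.02, seed = 103))
  )
}
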