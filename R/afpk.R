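#' Normalize a score matrix per model column
#'
#' Column-wise z-scoring (population standard deviation) of a
#' sequences-by-models bit-score table, making scores against models of
#' different lengths and information content comparable before embedding.
#' Constant columns map to all-zero.
#'
#' @param scores A wide score tibble (`seq_id` + numeric model columns).
#' @return A tibble of the same shape.
#' @export
normalize_scores <- function(scores) {
  if (!is.data.frame(scores) || names(scores)[1] != "seq_id" || ncol(scores) < 2) {
    abort("`scores` must be a wide score table: `seq_id` plus model columns.")
  }
  out <- as_tibble(scores)
  n <- nrow(out)
  for (j in names(out)[-1]) {
    v <- out[[j]]
    mu <- mean(v)
    s <- sqrt(sum((v - mu)^2) / n)            # population sd
    out[[j]] <- if (s == 0) rep(0, n) else (v - mu) / s
  }
  out
}

#' Embed a score matrix in two dimensions
#'
#' t-SNE (the default, mirroring the published workflow) or PCA of a
#' (normalized) score matrix. t-SNE is deterministic for a fixed `seed`;
#' the PCA mode is fully deterministic by construction: the top-2 principal
#' components of the input, with each component's sign fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param scores A wide score tibble, normally from [normalize_scores()].
#' @param method `"tsne"` or `"pca"`.
#' @param perplexity t-SNE perplexity (default 30); values of at least
#'   `(n - 1) / 3` are shrunk with a warning.
#' @param seed Integer seed for the t-SNE initialization and optimization.
#' @return A `ks_embedding` tibble with columns `seq_id`, `x`, `y` and
#'   attributes `method`, `perplexity`, `seed`.
#' @export
embed_2d <- function(scores, method = c("tsne", "pca"), perplexity = 30,
                     seed = 0) {
  method <- match.arg(method)
  if (!is.data.frame(scores) || names(scores)[1] != "seq_id") {
    abort("`scores` must be a wide score table: `seq_id` plus model columns.")
  }
  X <- as.matrix(scores[, -1, drop = FALSE])
  n <- nrow(X)
  if (n < 4) abort("At least 4 rows are required for a 2D embedding.")
  if (method == "tsne") {
    max_perp <- (n - 1) / 3
    if (perplexity >= max_perp) {
      perplexity <- max(1, floor(max_perp) - 1e-9)
      if (perplexity >= max_perp) perplexity <- max_perp * 0.9
      warn(sprintf("Perplexity too large for %d rows; shrunk to %.6g.",
                   n, perplexity))
    }
    coords <- withr::with_seed(as.integer(seed), {
      Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = 0,
                   pca = FALSE, check_duplicates = FALSE,
                   max_iter = 1000, verbose = FALSE)$Y
    })
  } else {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    k <- ncol(pc$x)
    coords <- matrix(0, n, 2)
    for (d in seq_len(min(2, k))) {
      rot <- pc$rotation[, d]
      flip <- sign(rot[which.max(abs(rot))])
      coords[, d] <- pc$x[, d] * ifelse(flip == 0, 1, flip)
    }
  }
  structure(
    tibble(seq_id = scores$seq_id, x = coords[, 1], y = coords[, 2]),
    method = method,
    perplexity = if (method == "tsne") perplexity else NA_real_,
    seed = seed,
    class = c("ks_embedding", class(tibble()))
  )
}

#' Density-based clustering of a 2D embedding
#'
#' DBSCAN semantics: a core point has at least `min_pts` neighbours
#' (itself included) within `eps`; clusters are the connected regions of
#' core points plus their border points; everything else is noise
#' (cluster `-1`). When `eps` is not given it defaults to three times the
#' median 4th-nearest-neighbour distance.
#'
#' @param emb A `ks_embedding` (or any tibble with `seq_id`, `x`, `y`).
#' @param eps Neighbourhood radius; must be positive when supplied.
#' @param min_pts Core-point neighbour count (default 5).
#' @return `emb` with an added integer `cluster` column (`-1` = noise).
#' @export
cluster_embedding <- function(emb, eps = NULL, min_pts = 5) {
  if (!is.data.frame(emb) || !all(c("seq_id", "x", "y") %in% names(emb))) {
    abort("`emb` must contain seq_id, x and y columns.")
  }
  pts <- cbind(emb$x, emb$y)
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  if (is.null(eps)) {
    if (n < 5) abort("Need at least 5 points to choose a default eps.")
    knn4 <- apply(D, 1, function(row) sort(row)[5])  # 4th neighbour (self at rank 1)
    eps <- 3 * median(knn4)
    if (eps == 0) eps <- .Machine$double.eps         # all points coincide
  }
  if (!is.numeric(eps) || eps <= 0) abort("`eps` must be positive.")
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (labels[k] == -1L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  out <- as_tibble(emb)
  out$cluster <- labels
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency table. 1 for identical
#' partitions (up to label names), about 0 for independent ones; can be
#' negative for partitions that disagree more than chance.
#'
#' @param a,b Vectors of group labels of equal length.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("Label vectors must have equal length.")
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  # common-denominator form: exact for small integer contingency tables
  num <- sum_ij * tot - sum_a * sum_b
  den <- tot * (sum_a + sum_b) / 2 - sum_a * sum_b
  if (den == 0) return(1)                     # both partitions trivial and equal
  num / den
}

#' Congruence between clusters and reference clades
#'
#' Adjusted Rand index between a cluster assignment and a reference clade
#' partition, over their shared sequence ids only. Noise points
#' (cluster `-1`) are treated as singleton groups so that failing to
#' cluster is penalized rather than pooled.
#'
#' @param clusters A tibble with `seq_id` and `cluster` columns (from
#'   [cluster_embedding()]).
#' @param reference A tibble with `seq_id` and `clade` columns.
#' @return The ARI, in `[-1, 1]`.
#' @export
congruence <- function(clusters, reference) {
  if (!is.data.frame(clusters) || !all(c("seq_id", "cluster") %in% names(clusters))) {
    abort("`clusters` must contain seq_id and cluster columns.")
  }
  if (!is.data.frame(reference) || !all(c("seq_id", "clade") %in% names(reference))) {
    abort("`reference` must contain seq_id and clade columns.")
  }
  shared <- dplyr::inner_join(clusters[, c("seq_id", "cluster")],
                              reference[, c("seq_id", "clade")],
                              by = "seq_id")
  if (nrow(shared) < 2) {
    abort("Fewer than 2 ids are shared between clusters and reference.")
  }
  cl <- as.character(shared$cluster)
  noise <- shared$cluster == -1
  cl[noise] <- paste0("noise_", shared$seq_id[noise])  # singleton groups
  adjusted_rand_index(cl, shared$clade)
}

#' Select a discriminative model panel
#'
#' Draws `trials` seeded random subsets of `panel_size` candidate models,
#' runs the full pipeline (score, normalize, embed, cluster) on the
#' training sequences for each subset, and keeps the subset whose clusters
#' are most congruent (highest ARI) with the reference clades; ties keep
#' the first subset drawn. Candidate scores are computed once and subset
#' per trial.
#'
#' @param candidates Named list of `profile_hmm`s (>= `panel_size`).
#' @param training A sequence tibble of training sequences.
#' @param reference A tibble with `seq_id` and `clade` for the training
#'   sequences.
#' @param panel_size Panel size (default 30).
#' @param trials Number of random subsets to evaluate.
#' @param seed Integer seed driving the subset draws and embeddings.
#' @param method,perplexity Passed to [embed_2d()].
#' @param eps,min_pts Passed to [cluster_embedding()].
#' @return A list of class `ks_panel_selection`: `$panel` (the selected
#'   named list of models), `$ari` (its congruence), and `$trials` (a
#'   per-trial tibble of panels and ARIs).
#' @export
select_panel <- function(candidates, training, reference, panel_size = 30,
                         trials = 10, seed = 0, method = "tsne",
                         perplexity = 30, eps = NULL, min_pts = 5) {
  if (length(candidates) < panel_size) {
    abort("`panel_size` exceeds the number of candidate models.")
  }
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- vapply(candidates, function(h) h$name, character(1))
  }
  training <- as_sequence_tbl(training)
  all_scores <- score_panel(training, candidates)
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(trials), function(i) sort(sample.int(length(candidates), panel_size)))
  })
  aris <- numeric(trials)
  for (i in seq_len(trials)) {
    sub <- all_scores[, c(1, 1 + draws[[i]]), drop = FALSE]
    emb <- embed_2d(normalize_scores(sub), method = method,
                    perplexity = perplexity, seed = seed + i)
    cls <- cluster_embedding(emb, eps = eps, min_pts = min_pts)
    aris[i] <- congruence(cls, reference)
  }
  best <- which.max(aris)                      # ties: first drawn
  trial_tbl <- tibble(
    trial = seq_len(trials),
    ari = aris,
    models = vapply(draws, function(d) paste(names(candidates)[d], collapse = ","),
                    character(1))
  )
  structure(list(panel = candidates[draws[[best]]], ari = aris[best],
                 trials = trial_tbl),
            class = "ks_panel_selection")
}

#' @export
print.ks_panel_selection <- function(x, ...) {
  cat("<ks_panel_selection> ", length(x$panel), " models, ARI ",
      format(x$ari, digits = 4), " over ", nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

#' Classify embedded queries by reference neighbours
#'
#' Labels each query point by majority vote of its `k` nearest reference
#' points in embedding space (Euclidean); vote ties are broken by the
#' single nearest reference neighbour. Confidence is the winning vote
#' fraction.
#'
#' @param emb A `ks_embedding` containing both reference and query ids.
#' @param reference A tibble with `seq_id` and `clade`; ids must appear in
#'   `emb`.
#' @param query_ids Character vector of query ids present in `emb`.
#' @param k Number of neighbours (default 5; capped at the reference size).
#' @return A tibble with columns `seq_id`, `clade`, `confidence`.
#' @export
classify_by_reference <- function(emb, reference, query_ids, k = 5) {
  if (!is.data.frame(emb) || !all(c("seq_id", "x", "y") %in% names(emb))) {
    abort("`emb` must contain seq_id, x and y columns.")
  }
  unknown <- setdiff(query_ids, emb$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("Query id(s) absent from the embedding: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ref <- dplyr::inner_join(reference[, c("seq_id", "clade")], emb, by = "seq_id")
  if (nrow(ref) == 0) abort("No reference ids are present in the embedding.")
  if (k > nrow(ref)) abort("`k` exceeds the number of embedded reference points.")
  qry <- emb[match(query_ids, emb$seq_id), ]
  out <- purrr::map_dfr(seq_len(nrow(qry)), function(i) {
    d <- sqrt((ref$x - qry$x[i])^2 + (ref$y - qry$y[i])^2)
    ord <- order(d)
    nn <- ord[seq_len(k)]
    votes <- table(ref$clade[nn])
    top <- votes[votes == max(votes)]
    winner <- if (length(top) == 1) names(top) else {
      # tie: the clade of the single nearest neighbour among the tied ones
      cand <- names(top)
      ref$clade[nn][match(TRUE, ref$clade[nn] %in% cand)]
    }
    tibble(seq_id = qry$seq_id[i], clade = winner,
           confidence = as.numeric(max(votes)) / k)
  })
  out
}

#' Run the full AFPK-Finder embedding pipeline
#'
#' Convenience wrapper chaining [score_panel()], [normalize_scores()],
#' [embed_2d()] and [cluster_embedding()], optionally evaluating
#' [congruence()] against a reference.
#'
#' @param seqs A sequence tibble.
#' @param panel A named list of `profile_hmm`s.
#' @param reference Optional tibble with `seq_id` and `clade`.
#' @param method,perplexity,seed Passed to [embed_2d()].
#' @param eps,min_pts Passed to [cluster_embedding()].
#' @return A list with `$scores`, `$embedding` (with `cluster` column) and,
#'   when a reference is given, `$ari`.
#' @export
run_afpk_finder <- function(seqs, panel, reference = NULL,
                            method = "tsne", perplexity = 30, seed = 0,
                            eps = NULL, min_pts = 5) {
  scores <- score_panel(seqs, panel)
  emb <- embed_2d(normalize_scores(scores), method = method,
                  perplexity = perplexity, seed = seed)
  cls <- cluster_embedding(emb, eps = eps, min_pts = min_pts)
  out <- list(scores = scores, embedding = cls)
  if (!is.null(reference)) out$ari <- congruence(cls, reference)
  out
}
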