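# Small embedded score matrices and clouds used across the embedding tests.
two_clouds <- function(n_each = 20, gap = 100, spread = 1, seed = 4) {
  withr::with_seed(seed, tibble::tibble(
    seq_id = sprintf("p%02d", seq_len(2 * n_each)),
    x = c(rnorm(n_each, 0, spread), rnorm(n_each, gap, spread)),
    y = c(rnorm(n_each, 0, spread), rnorm(n_each, 0, spread))
  ))
}

test_that("normalize_scores z-scores columns with population sd", {
  m <- tibble::tibble(seq_id = c("a", "b", "c"),
                      h1 = c(1, 2, 3), h2 = c(5, 5, 5))
  z <- normalize_scores(m)
  expect_equal(z$h1, c(-1.224745, 0, 1.224745), tolerance = 1e-5)
  expect_equal(z$h2, c(0, 0, 0))
  expect_equal(dim(z), dim(m))
  # idempotence
  expect_equal(normalize_scores(z)$h1, z$h1, tolerance = 1e-9)
})

test_that("embeddings are seed-deterministic and size-checked", {
  withr::with_seed(9, {
    m <- tibble::tibble(seq_id = sprintf("s%02d", 1:30))
    for (j in 1:5) m[[paste0("h", j)]] <- rnorm(30)
  })
  e1 <- embed_2d(m, method = "tsne", perplexity = 5, seed = 3)
  e2 <- embed_2d(m, method = "tsne", perplexity = 5, seed = 3)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$y, e2$y)

  expect_warning(embed_2d(m, method = "tsne", perplexity = 50, seed = 3),
                 "[Pp]erplexity")
  expect_error(embed_2d(m[1:3, ], seed = 1), "4 rows")
})

test_that("PCA puts a rank-1 matrix entirely on the first axis", {
  v <- seq(-2, 2, length.out = 12)
  m <- tibble::tibble(seq_id = sprintf("s%02d", 1:12),
                      h1 = v, h2 = 2 * v, h3 = -v)
  e <- embed_2d(m, method = "pca")
  expect_gt(stats::sd(e$x), 0)
  expect_equal(max(abs(e$y)), 0, tolerance = 1e-9)
})

test_that("well-separated families separate in the embedding", {
  fams <- lapply(1:3, function(i) {
    make_family_hmm(family_spec(paste0("f", i), M = 60, conservation = 0.75,
                                seed = 130 + i))
  })
  names(fams) <- paste0("f", 1:3)
  seqs <- dplyr::bind_rows(lapply(names(fams), function(nm) {
    s <- sample_sequence(fams[[nm]], n = 12, seed = 140 + match(nm, names(fams)),
                         prefix = nm)
    s$family <- nm
    s
  }))
  emb <- embed_2d(normalize_scores(score_panel(seqs, fams)),
                  method = "tsne", perplexity = 8, seed = 0)
  emb$family <- seqs$family
  cen <- dplyr::summarise(dplyr::group_by(emb, .data$family),
                          cx = mean(x), cy = mean(y))
  inter <- mean(stats::dist(as.matrix(cen[, c("cx", "cy")])))
  intra <- mean(vapply(split(emb, emb$family), function(g) {
    mean(sqrt((g$x - mean(g$x))^2 + (g$y - mean(g$y))^2))
  }, numeric(1)))
  expect_gt(inter, 3 * intra)
})

test_that("DBSCAN clustering matches its definition on forced geometries", {
  emb <- two_clouds()
  cl <- cluster_embedding(emb, eps = 5, min_pts = 5)
  expect_equal(length(setdiff(unique(cl$cluster), -1)), 2)
  expect_false(any(cl$cluster == -1))
  # each cloud is one cluster
  expect_equal(length(unique(cl$cluster[1:20])), 1)
  expect_equal(length(unique(cl$cluster[21:40])), 1)

  same <- tibble::tibble(seq_id = sprintf("s%d", 1:8), x = 1, y = 2)
  cl_same <- cluster_embedding(same, min_pts = 5)
  expect_equal(unique(cl_same$cluster), 1)

  expect_error(cluster_embedding(emb, eps = -1), "eps")
})

test_that("a hand-run 6-point DBSCAN configuration is reproduced", {
  # Points: a(0,0) b(1,0) c(2,0) form a chain; d(10,0) e(11,0) border pair;
  # f(30,0) isolated. eps = 1.5, min_pts = 3.
  # Neighborhoods: a{a,b}, b{a,b,c}, c{b,c}, d{d,e}, e{d,e}, f{f}.
  # Only b is core (3 neighbors) -> cluster {a, b, c}; d, e, f noise.
  emb <- tibble::tibble(seq_id = letters[1:6],
                        x = c(0, 1, 2, 10, 11, 30), y = 0)
  cl <- cluster_embedding(emb, eps = 1.5, min_pts = 3)
  expect_equal(cl$cluster, c(1, 1, 1, -1, -1, -1))
})

test_that("adjusted Rand index matches hand arithmetic and the mclust oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # {a,b}{c,d} vs {a,c}{b,d}: contingency all-ones, ARI = -0.5
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)

  skip_if_not_installed("mclust")
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- sample(1:4, 40, replace = TRUE)
      b <- sample(1:3, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})

test_that("congruence works on shared ids and penalizes noise as singletons", {
  clusters <- tibble::tibble(seq_id = c("a", "b", "c", "d", "zzz"),
                             cluster = c(1, 1, 2, 2, 9))
  ref <- tibble::tibble(seq_id = c("a", "b", "c", "d"),
                        clade = c("x", "y", "x", "y"))
  expect_equal(congruence(clusters, ref), -0.5)
  ref2 <- tibble::tibble(seq_id = c("a", "b", "c", "d"),
                         clade = c("x", "x", "y", "y"))
  expect_equal(congruence(clusters, ref2), 1)

  # noise points split an otherwise perfect match
  noisy <- tibble::tibble(seq_id = c("a", "b", "c", "d"),
                          cluster = c(1, 1, -1, -1))
  expect_lt(congruence(noisy, ref2), 1)

  expect_error(congruence(clusters[5, ], ref), "shared")
})

test_that("panel selection prefers panels containing the family models", {
  fams <- lapply(1:3, function(i) {
    make_family_hmm(family_spec(paste0("fam", i), M = 50, conservation = 0.8,
                                seed = 150 + i))
  })
  names(fams) <- paste0("fam", 1:3)
  # distractor models never seen by any training sequence
  cands <- fams
  for (i in 1:9) {
    cands[[paste0("bg", i)]] <-
      make_family_hmm(family_spec(paste0("bg", i), M = 50, conservation = 0.8,
                                  seed = 200 + i))
  }
  train <- dplyr::bind_rows(lapply(names(fams), function(nm) {
    s <- sample_sequence(fams[[nm]], n = 8, seed = 210 + match(nm, names(fams)),
                         prefix = nm)
    s
  }))
  ref <- tibble::tibble(seq_id = train$id, clade = sub("_[0-9]+$", "", train$id))
  sel <- select_panel(cands, train, ref, panel_size = 4, trials = 8, seed = 5,
                      method = "pca", min_pts = 3)
  expect_s3_class(sel, "ks_panel_selection")
  expect_equal(nrow(sel$trials), 8)
  expect_equal(sel$ari, max(sel$trials$ari))
  # panels that include all three family models dominate those missing them
  has_all <- vapply(strsplit(sel$trials$models, ","), function(nms) {
    all(names(fams) %in% nms)
  }, logical(1))
  if (any(has_all) && any(!has_all)) {
    expect_gte(max(sel$trials$ari[has_all]), max(sel$trials$ari[!has_all]))
  }
  expect_true(any(names(fams) %in% names(sel$panel)))

  # determinism and trials = 1 degenerate case
  sel2 <- select_panel(cands, train, ref, panel_size = 4, trials = 8, seed = 5,
                       method = "pca", min_pts = 3)
  expect_identical(names(sel$panel), names(sel2$panel))
  one <- select_panel(cands, train, ref, panel_size = 4, trials = 1, seed = 6,
                      method = "pca", min_pts = 3)
  expect_equal(nrow(one$trials), 1)
  expect_error(select_panel(cands, train, ref, panel_size = 99), "panel_size")
})

test_that("reference kNN voting labels queries as specified", {
  emb <- structure(tibble::tibble(
    seq_id = c("r1", "r2", "r3", "r4", "r5", "q1", "q2"),
    x = c(0, 0.1, 0.2, 10, 10.1, 0, 10),
    y = 0
  ), class = c("ks_embedding", class(tibble::tibble())))
  ref <- tibble::tibble(seq_id = paste0("r", 1:5),
                        clade = c("A", "A", "A", "B", "B"))
  calls <- classify_by_reference(emb, ref, c("q1", "q2"), k = 3)
  expect_equal(calls$clade, c("A", "B"))
  expect_equal(calls$confidence[1], 1)
  expect_gte(calls$confidence[2], 2 / 3 - 1e-12)

  k1 <- classify_by_reference(emb, ref, "q2", k = 1)
  expect_equal(k1$clade, "B")
  expect_error(classify_by_reference(emb, ref, "nope"), "absent")
})

test_that("synthetic queries recover their family by reference voting", {
  fams <- lapply(1:3, function(i) {
    make_family_hmm(family_spec(paste0("f", i), M = 60, conservation = 0.75,
                                seed = 160 + i))
  })
  names(fams) <- paste0("f", 1:3)
  ref_seqs <- dplyr::bind_rows(lapply(names(fams), function(nm) {
    sample_sequence(fams[[nm]], n = 10, seed = 170 + match(nm, names(fams)),
                    prefix = nm)
  }))
  queries <- sample_sequence(fams$f1, n = 20, seed = 180, prefix = "query")
  all_seqs <- dplyr::bind_rows(ref_seqs, queries)
  emb <- embed_2d(normalize_scores(score_panel(all_seqs, fams)),
                  method = "tsne", perplexity = 10, seed = 1)
  ref <- tibble::tibble(seq_id = ref_seqs$id, clade = sub("_[0-9]+$", "", ref_seqs$id))
  calls <- classify_by_reference(emb, ref, queries$id, k = 5)
  expect_gte(mean(calls$clade == "f1"), 0.9)
})

test_that("the PCA pipeline commutes with row permutation", {
  withr::with_seed(19, {
    m <- tibble::tibble(seq_id = sprintf("s%02d", 1:24))
    for (j in 1:6) m[[paste0("h", j)]] <- rnorm(24, mean = j)
  })
  e <- embed_2d(normalize_scores(m), method = "pca")
  perm <- withr::with_seed(20, sample(nrow(m)))
  e_perm <- embed_2d(normalize_scores(m[perm, ]), method = "pca")
  expect_equal(e_perm$x, e$x[perm], tolerance = 1e-9)
  expect_equal(e_perm$y, e$y[perm], tolerance = 1e-9)
})
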