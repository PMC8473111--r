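test_that("distance table matches the frozen-weight geometry and BMU search", {
  fx <- make_features(15, seed = 31)
  m <- som_train(fx$features, train_config(seed = 2, max_iters = 1500),
                 labels = fx$labels)
  d <- recompute_distances(m, fx$features)
  expect_equal(dim(d), c(nrow(fx$features), 6L))
  expect_true(all(d >= 0))
  xn <- normalize_rows(fx$features)
  for (i in seq_len(nrow(d))) {
    bmu <- find_bmu(xn[i, ], m)
    expect_equal(which.min(d[i, ]), bmu$index, ignore_attr = TRUE)
    expect_equal(min(d[i, ]), bmu$distance, tolerance = 1e-10)
  }
  # a sample equal to a node weight has a zero in that column
  d0 <- recompute_distances(m, m$weights[3, , drop = FALSE])
  expect_equal(d0[1, 3], 0, tolerance = 1e-12)
})

test_that("differentiation degree follows |d_ij - d_ik| / (d_ij + d_ik)", {
  # hand-built model and distance rows exercising the closed form
  w <- normalize_rows(matrix(withr::with_seed(32, rnorm(6 * 8)), 6, 8))
  m <- structure(list(grid = hex_grid(), weights = w), class = "som_model")

  recs_of <- function(drow) {
    differentiation_records(m, samples = NULL,
                            distances = matrix(drow, nrow = 1L))
  }
  # bmu node 1 (0.2), best adjacent rival node 2 (0.6): r = 0.4/0.8 = 0.5
  r <- recs_of(c(0.2, 0.6, 2, 2, 2, 2))
  expect_equal(r$bmu, 1L)
  expect_equal(r$rival, 2L)
  expect_equal(r$e_jk, -0.4)
  expect_equal(r$r_jk, 0.5)
  # equidistant bmu and rival -> 0
  expect_equal(recs_of(c(0.5, 0.5, 2, 2, 2, 2))$r_jk, 0)
  # zero BMU distance with a positive rival -> perfectly differentiated
  expect_equal(recs_of(c(0, 0.7, 2, 2, 2, 2))$r_jk, 1)
  # both distances zero -> defined as 0 (maximally ambiguous)
  expect_equal(recs_of(c(0, 0, 2, 2, 2, 2))$r_jk, 0)
  # rival must be hex-adjacent to the bmu: node 1 adjoins only nodes 2 and
  # 4, so the non-adjacent node 3 is skipped even when it is closer
  r13 <- recs_of(c(0.1, 0.9, 0.2, 0.8, 0.8, 0.8))
  expect_equal(r13$rival, 4L)
  expect_equal(r13$d_ik, 0.8)
})

test_that("filtering is a strict-threshold partition, monotone in r_min", {
  fx <- make_features(20, seed = 33)
  m <- som_train(fx$features, train_config(seed = 5), labels = fx$labels)
  recs <- differentiation_records(m, fx$features)
  expect_true(all(recs$r_jk >= 0 & recs$r_jk <= 1))
  expect_true(all(recs$d_ij >= 0 & recs$d_ik >= 0))
  expect_true(all(recs$d_ij <= recs$d_ik))

  part <- filter_samples(recs, 0.15)
  expect_setequal(c(part$kept, part$removed), recs$sample_index)
  expect_length(intersect(part$kept, part$removed), 0L)
  expect_true(all(recs$r_jk[part$removed] < 0.15))
  expect_true(all(recs$r_jk[part$kept] >= 0.15))

  # strict inequality: r_min = 0 removes nothing
  expect_length(filter_samples(recs, 0)$removed, 0L)

  # removed-set size non-decreasing in r_min
  sizes <- sapply(seq(0, 1, by = 0.05),
                  function(r) length(filter_samples(recs, r)$removed))
  expect_true(all(diff(sizes) >= 0))
})

test_that("midpoints between adjacent prototypes are filtered out", {
  fx <- make_features(20, seed = 34)
  m <- som_train(fx$features, train_config(seed = 6), labels = fx$labels)
  adj <- which(abs(m$grid$dist - 1) < 1e-6 & upper.tri(m$grid$dist),
               arr.ind = TRUE)
  mids <- t(apply(adj, 1L, function(p) {
    normalize_vec(m$weights[p[1], ] + m$weights[p[2], ])
  }))
  recs <- differentiation_records(m, mids)
  # a midpoint whose BMU is one of its two parents and whose strongest
  # rival is the other parent is exactly equidistant: r = 0
  pair_scored <- (recs$bmu == adj[, 1] & recs$rival == adj[, 2]) |
    (recs$bmu == adj[, 2] & recs$rival == adj[, 1])
  expect_true(any(pair_scored))
  expect_equal(recs$r_jk[pair_scored], rep(0, sum(pair_scored)),
               tolerance = 1e-9)
  # and the bulk of prototype midpoints falls below the default threshold
  part <- filter_samples(recs, 0.15)
  expect_gt(length(part$removed), length(part$kept))
})

test_that("improved training filters, retrains, and stays deterministic", {
  fx <- make_features(25, seed = 35)
  inj <- inject_midpoints(fx$features, fx$labels, fraction = 0.1, seed = 36)
  cfg <- train_config(seed = 7)
  m1 <- isom_train(inj$features, inj$labels, cfg)
  m2 <- isom_train(inj$features, inj$labels, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$kept, m2$kept)
  expect_s3_class(m1, "isom_model")
  expect_equal(nrow(m1$filter), nrow(inj$features))
  expect_true(all(m1$filter$kept == (m1$filter$sample_index %in% m1$kept)))

  # injected midpoints are removed at a far higher rate than clean samples
  rem_rate_inj <- mean(!m1$filter$kept[inj$injected])
  rem_rate_clean <- mean(!m1$filter$kept[-inj$injected])
  expect_gt(rem_rate_inj, rem_rate_clean)

  expect_error(isom_train(matrix(numeric(0), 0, 5), character(0)),
               "non-empty")
})

test_that("a filter no-op reduces improved training to a plain refit", {
  # with r_min = 0 nothing is removed (strict inequality), so the retrain
  # sees the full sample set and must equal a plain fit with the same seed
  fx <- make_features(10, seed = 37)
  cfg <- train_config(seed = 8, r_min = 0, max_iters = 1500)
  mi <- isom_train(fx$features, fx$labels, cfg)
  ms <- som_train(fx$features, cfg, labels = fx$labels)
  expect_length(mi$kept, nrow(fx$features))
  expect_identical(mi$weights, ms$weights)
  expect_identical(mi$node_labels, ms$node_labels)
})
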