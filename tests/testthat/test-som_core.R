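test_that("hex lattice has unit spacing between all adjacent nodes", {
  g <- hex_grid()
  expect_equal(g$n_nodes, 6L)
  adj <- abs(g$dist - 1) < 1e-9
  # within-row links and the between-row diagonals
  expect_true(adj[1, 2] && adj[2, 3] && adj[4, 5] && adj[5, 6])
  expect_true(adj[1, 4] && adj[2, 4] && adj[2, 5] && adj[3, 5] && adj[3, 6])
  expect_false(adj[1, 3])
  expect_false(adj[1, 6])
  # rows sqrt(3)/2 apart, second row offset +0.5
  expect_equal(g$positions[4, ], c(0.5, sqrt(3) / 2))
})

test_that("normalization produces unit vectors and rejects zero input", {
  expect_equal(normalize_vec(c(3, 4, rep(0, 254))),
               c(0.6, 0.8, rep(0, 254)))
  u <- normalize_vec(withr::with_seed(1, rnorm(256)))
  expect_equal(normalize_vec(u), u)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_error(normalize_vec(rep(0, 256)), "zero")
})

test_that("decay schedules start at the configured values and decay exponentially", {
  cfg <- train_config()
  expect_equal(sigma_at(0, cfg), 10)
  expect_equal(sigma_at(cfg$tau_sigma, cfg), 10 / exp(1))
  expect_equal(eta_at(0, cfg), 0.6)
  expect_equal(eta_at(1000, cfg), 0.6 / exp(1))
  t <- seq(0, 50, by = 1)
  expect_true(all(diff(sigma_at(t, cfg)) < 0))
  expect_true(all(diff(eta_at(t, cfg)) < 0) && all(eta_at(t, cfg) > 0))
})

test_that("Gaussian neighborhood is 1 at the winner and decays with lattice distance", {
  g <- hex_grid()
  expect_equal(neighborhood(2, 2, 5, g), 1)
  expect_equal(neighborhood(1, 2, 1, g), exp(-0.5))
  # monotone in distance at fixed width: d(1,2) = 1 < d(1,3) = 2 < d(1,6)
  h <- c(neighborhood(1, 1, 2, g), neighborhood(1, 2, 2, g),
         neighborhood(1, 3, 2, g), neighborhood(1, 6, 2, g))
  expect_true(all(diff(h) < 0))
})

test_that("BMU search matches an exhaustive scan and breaks ties low", {
  w <- normalize_rows(matrix(withr::with_seed(2, rnorm(6 * 256)), 6, 256))
  model <- structure(list(grid = hex_grid(), weights = w), class = "som_model")
  expect_equal(find_bmu(w[3, ], model)$index, 3L)
  expect_equal(find_bmu(w[3, ], model)$distance, 0)
  for (s in 1:20) {
    x <- normalize_vec(withr::with_seed(100 + s, rnorm(256)))
    got <- find_bmu(x, model)
    want <- oracle_bmu(x, w)
    expect_equal(got$index, want$index)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
  # exact tie between two equidistant nodes -> lower index
  w2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  m2 <- structure(list(grid = hex_grid(), weights = w2), class = "som_model")
  x <- normalize_vec(c(1, 1, 0))
  expect_equal(find_bmu(x, m2)$index, 1L)
})

test_that("weight updates move the neighborhood and keep weights unit-norm", {
  w <- normalize_rows(matrix(withr::with_seed(3, rnorm(6 * 256)), 6, 256))
  model <- structure(list(grid = hex_grid(), weights = w,
                          node_labels = rep(NA_character_, 6)),
                     class = "som_model")
  x <- normalize_vec(withr::with_seed(4, rnorm(256)))

  # full step (eta = 1, h = 1 at the winner) replaces the winner with x
  cfg1 <- train_config(eta0 = 1)
  up <- update_weights(model, x, 2L, t = 0, cfg = cfg1)
  expect_equal(up$weights[2, ], x, tolerance = 1e-12)

  # vanishing learning rate leaves the model untouched
  cfg <- train_config()
  up0 <- update_weights(model, x, 2L, t = 1e7, cfg = cfg)
  expect_equal(up0$weights, model$weights, tolerance = 1e-12)

  # a partial step strictly shrinks the winner's distance to x and all
  # updated weights stay unit-norm
  for (s in 1:10) {
    xs <- normalize_vec(withr::with_seed(200 + s, rnorm(256)))
    c_idx <- find_bmu(xs, model)$index
    upd <- update_weights(model, xs, c_idx, t = 10, cfg = cfg)
    expect_lt(sqrt(sum((xs - upd$weights[c_idx, ])^2)),
              sqrt(sum((xs - model$weights[c_idx, ])^2)))
    expect_equal(sqrt(rowSums(upd$weights^2)), rep(1, 6), tolerance = 1e-9)
  }
})

test_that("training is deterministic, converges on repeats, separates orthogonal inputs", {
  # orthogonal inputs end up with bijective BMUs
  x6 <- diag(6)
  cfg <- train_config(seed = 42, max_iters = 600)
  m <- som_train(x6, cfg)
  bmus <- apply(x6, 1L, function(v) find_bmu(v, m)$index)
  expect_setequal(bmus, 1:6)
  expect_equal(sqrt(rowSums(m$weights^2)), rep(1, 6), tolerance = 1e-9)

  # same seed twice -> identical weights; different seed -> different
  m2 <- som_train(x6, cfg)
  expect_identical(m$weights, m2$weights)
  m3 <- som_train(x6, train_config(seed = 43, max_iters = 600))
  expect_false(identical(m$weights, m3$weights))

  # a single repeated sample is a fixed point: BMU distance -> 0
  one <- matrix(rep(normalize_vec(withr::with_seed(5, rnorm(256))), 3),
                3, 256, byrow = TRUE)
  mfix <- som_train(one, train_config(seed = 1, max_iters = 2000))
  expect_lt(find_bmu(one[1, ], mfix)$distance, 1e-3)

  expect_error(som_train(matrix(numeric(0), 0, 5)), "non-empty")
})

test_that("quantization error shrinks as training proceeds", {
  fx <- make_features(30, seed = 8)
  short <- som_train(fx$features, train_config(seed = 1, max_iters = 20))
  long <- som_train(fx$features, train_config(seed = 1, max_iters = 3000))
  qe <- function(m) mean(apply(normalize_rows(fx$features), 1L,
                               function(v) find_bmu(v, m)$distance))
  expect_lt(qe(long), qe(short) + 1e-6)
})

test_that("node labeling uses majority vote with canonical-order ties and fills empty nodes", {
  w <- diag(6)
  model <- structure(list(grid = hex_grid(), weights = w,
                          node_labels = rep(NA_character_, 6),
                          config = train_config()),
                     class = "som_model")
  # node 1 hit only by LL; node 2 by 3 LL vs 5 LC; node 3 tied 2-2 WB/SS
  samples <- rbind(
    matrix(rep(w[1, ], 4), 4, 6, byrow = TRUE),
    matrix(rep(w[2, ], 8), 8, 6, byrow = TRUE),
    matrix(rep(w[3, ], 4), 4, 6, byrow = TRUE),
    w[4, ], w[5, ], w[6, ])
  labels <- c(rep("LL", 4),
              c(rep("LL", 3), rep("LC", 5)),
              c("WB", "SS", "SS", "WB"),
              "LR", "WB", "SS")
  lab_model <- assign_labels(model, samples, labels)
  expect_equal(lab_model$node_labels[1], "LL")
  expect_equal(lab_model$node_labels[2], "LC")   # majority 5 > 3
  expect_equal(lab_model$node_labels[3], "WB")   # tie -> earlier class order
  expect_error(assign_labels(model, samples, NULL), "labels")

  # an unhit node inherits the nearest labeled node's class
  samples2 <- samples[1:16, ]
  labels2 <- labels[1:16]
  lab2 <- assign_labels(model, samples2, labels2)
  expect_false(any(is.na(lab2$node_labels)))
})

test_that("prediction routes through BMU labels deterministically", {
  fx <- make_features(20, seed = 12)
  m <- som_train(fx$features, train_config(seed = 3, max_iters = 2000),
                 labels = fx$labels)
  p1 <- predict(m, fx$features)
  p2 <- predict(m, fx$features)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% posture_classes()))
  # a feature vector equal to a node weight gets that node's label
  expect_equal(predict(m, m$weights[4, ]), m$node_labels[4])
  # node indices agree with per-sample BMU search
  nodes <- predict(m, fx$features, type = "node")
  expect_equal(nodes[1],
               find_bmu(normalize_vec(fx$features[1, ]), m)$index)
  unlabeled <- som_train(fx$features, train_config(seed = 3, max_iters = 50))
  expect_error(predict(unlabeled, fx$features), "no node labels")
})

test_that("similar postures land on adjacent nodes more often than distal ones", {
  adj_count <- 0L
  distal_count <- 0L
  for (s in 1:10) {
    fx <- make_features(40, seed = 300 + s)
    m <- som_train(fx$features, train_config(seed = 600 + s),
                   labels = fx$labels)
    wb <- which(m$node_labels == "WB")[1]
    ss <- which(m$node_labels == "SS")[1]
    if (is.na(wb) || is.na(ss) || wb == ss) next
    if (abs(m$grid$dist[wb, ss] - 1) < 1e-6) {
      adj_count <- adj_count + 1L
    } else {
      distal_count <- distal_count + 1L
    }
  }
  expect_gt(adj_count, distal_count)
})
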