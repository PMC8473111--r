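#' Hexagonal output lattice
#'
#' Node coordinates for a hexagonally packed grid laid out in offset rows:
#' odd rows at integer x, even rows shifted by +0.5 with rows sqrt(3)/2
#' apart, so every adjacent pair (within-row neighbors and the diagonal
#' links between rows) is at distance exactly 1. The default 2 x 3 layout
#' gives the six output nodes.
#'
#' @param nrows,ncols Lattice rows and columns (default 2 x 3).
#' @return Object of class `hex_grid`: list with `n_nodes`, `positions`
#'   (n x 2 matrix, node order row-major), and `dist` (n x n lattice
#'   distance matrix).
#' @export
hex_grid <- function(nrows = 2L, ncols = 3L) {
  stopifnot(nrows >= 1, ncols >= 1)
  pos <- matrix(0, nrows * ncols, 2L)
  i <- 0L
  for (r in seq_len(nrows)) {
    for (c in seq_len(ncols)) {
      i <- i + 1L
      pos[i, ] <- c((c - 1) + if (r %% 2L == 0L) 0.5 else 0,
                    (r - 1) * sqrt(3) / 2)
    }
  }
  structure(list(n_nodes = nrows * ncols, positions = pos,
                 dist = as.matrix(stats::dist(pos))),
            class = "hex_grid")
}

# Adjacency on the hex lattice: distance 1 within tolerance.
hex_adjacent <- function(grid, tol = 1e-6) {
  abs(grid$dist - 1) < tol
}

#' Training configuration
#'
#' Bundles the training parameters: initial learning rate `eta0` with time
#' constant `tau_eta`, learning gain `sigma0` (initial neighborhood width)
#' with time constant `tau_sigma`, initial neighborhood size cap `nc0`,
#' differentiation threshold `r_min` for the improved-SOM filter, and the
#' stopping rule (iteration budget `max_iters`, or learning rate below
#' `eta_stop`). Defaults are the method's published operating point.
#'
#' @param eta0 Initial learning rate in (0, 1] (default 0.6).
#' @param tau_eta Learning-rate time constant in iterations (default 1000).
#' @param sigma0 Learning gain: initial neighborhood width (default 10).
#' @param tau_sigma Neighborhood-width time constant in iterations (default 2).
#' @param nc0 Initial neighborhood radius cap on the lattice (default 3).
#' @param r_min Differentiation threshold for sample filtering (default 0.15).
#' @param max_iters Iteration budget, counted per sample update (default 5000).
#' @param eta_stop Stop once the learning rate decays below this (default 1e-3).
#' @param seed Integer seed for initialization and sample order (default 1).
#' @param init Weight initialization: `"maximin"` (default) seeds the nodes
#'   with mutually far-apart training samples (farthest-point traversal from
#'   a random start), `"sample"` draws distinct training samples uniformly,
#'   `"random"` draws random unit vectors.
#' @return Object of class `train_config`.
#' @export
train_config <- function(eta0 = 0.6, tau_eta = 1000, sigma0 = 10,
                         tau_sigma = 2, nc0 = 3, r_min = 0.15,
                         max_iters = 5000L, eta_stop = 1e-3, seed = 1L,
                         init = c("maximin", "sample", "random")) {
  stopifnot(eta0 > 0, eta0 <= 1, tau_eta > 0, sigma0 > 0, tau_sigma > 0,
            nc0 > 0, r_min >= 0, max_iters >= 1, eta_stop > 0)
  structure(list(eta0 = eta0, tau_eta = tau_eta, sigma0 = sigma0,
                 tau_sigma = tau_sigma, nc0 = nc0, r_min = r_min,
                 max_iters = as.integer(max_iters), eta_stop = eta_stop,
                 seed = as.integer(seed), init = match.arg(init)),
            class = "train_config")
}

#' Normalize a vector to unit Euclidean length
#'
#' @param v Numeric vector; must be non-zero.
#' @return `v / ||v||`.
#' @export
normalize_vec <- function(v) {
  n <- l2(v)
  if (!is.finite(n) || n == 0) {
    stop("cannot normalize a zero (or non-finite) vector", call. = FALSE)
  }
  v / n
}

# Normalize each row of a matrix; errors on zero rows.
normalize_rows <- function(m) {
  norms <- sqrt(rowSums(m * m))
  if (any(!is.finite(norms)) || any(norms == 0)) {
    stop("cannot normalize zero or non-finite sample vectors", call. = FALSE)
  }
  m / norms
}

#' Neighborhood width at iteration t
#'
#' Exponential decay `sigma(t) = sigma0 * exp(-t / tau_sigma)`.
#'
#' @param t Iteration (>= 0).
#' @param cfg A [train_config()].
#' @return Positive width.
#' @export
sigma_at <- function(t, cfg = train_config()) {
  stopifnot(all(t >= 0))
  cfg$sigma0 * exp(-t / cfg$tau_sigma)
}

#' Learning rate at iteration t
#'
#' Exponential decay `eta(t) = eta0 * exp(-t / tau_eta)`.
#'
#' @param t Iteration (>= 0).
#' @param cfg A [train_config()].
#' @return Learning rate in (0, eta0].
#' @export
eta_at <- function(t, cfg = train_config()) {
  stopifnot(all(t >= 0))
  cfg$eta0 * exp(-t / cfg$tau_eta)
}

#' Gaussian neighborhood weight between the winner and another node
#'
#' `h = exp(-D^2 / (2 sigma_t^2))` where `D` is the lattice distance between
#' the winning node `c` and node `j`.
#'
#' @param c,j Node indices.
#' @param sigma_t Current neighborhood width (> 0).
#' @param grid A [hex_grid()].
#' @return Weight in (0, 1]; 1 iff `j == c`.
#' @export
neighborhood <- function(c, j, sigma_t, grid = hex_grid()) {
  stopifnot(sigma_t > 0)
  d <- grid$dist[c, j]
  exp(-d^2 / (2 * sigma_t^2))
}

#' Best-matching unit for an input vector
#'
#' Exhaustive Euclidean nearest-weight search; ties go to the lowest node
#' index.
#'
#' @param x Unit-norm input vector.
#' @param model A `som_model`, or a weight matrix (nodes x dim).
#' @return List with `index` (winning node) and `distance`.
#' @export
find_bmu <- function(x, model) {
  w <- if (inherits(model, "som_model")) model$weights else model
  d2 <- rowSums(sweep(w, 2L, x)^2)
  c_idx <- which.min(d2)
  list(index = c_idx, distance = sqrt(d2[c_idx]))
}

# Nodes inside the winning neighborhood at iteration t: lattice distance to
# the winner at most min(sigma(t), nc0); the winner itself always qualifies.
neighborhood_members <- function(c_idx, t, cfg, grid) {
  radius <- min(sigma_at(t, cfg), cfg$nc0)
  which(grid$dist[c_idx, ] <= radius)
}

#' One competitive-learning weight update
#'
#' Moves every node in the winning neighborhood toward the input by
#' `eta(t) * h_cj(t) * (x - w_j)` and renormalizes the moved weights to unit
#' length; nodes outside the neighborhood are untouched.
#'
#' @param model A `som_model`.
#' @param x Unit-norm input vector.
#' @param c_idx Winning node index for `x`.
#' @param t Iteration (drives both schedules).
#' @param cfg A [train_config()].
#' @return The updated model.
#' @export
update_weights <- function(model, x, c_idx, t, cfg = train_config()) {
  eta <- eta_at(t, cfg)
  if (eta <= 0) return(model)
  sig <- sigma_at(t, cfg)
  members <- neighborhood_members(c_idx, t, cfg, model$grid)
  for (j in members) {
    d <- model$grid$dist[c_idx, j]
    # at zero lattice distance h is 1 even once sigma underflows to 0
    h <- if (d == 0) 1 else exp(-d^2 / (2 * sig^2))
    w <- model$weights[j, ] + eta * h * (x - model$weights[j, ])
    n <- l2(w)
    if (n > 0) model$weights[j, ] <- w / n
  }
  model
}

# Construct an untrained model with seeded initial unit-norm weights.
init_som <- function(samples, cfg, grid) {
  n_nodes <- grid$n_nodes
  d <- ncol(samples)
  if (cfg$init == "maximin" && nrow(samples) >= n_nodes) {
    # farthest-point traversal: random start, then greedily add the sample
    # farthest from the chosen set, so prototypes start mutually far apart
    idx <- sample.int(nrow(samples), 1L)
    mind2 <- colSums((t(samples) - samples[idx, ])^2)
    while (length(idx) < n_nodes) {
      nxt <- which.max(mind2)
      idx <- c(idx, nxt)
      mind2 <- pmin(mind2, colSums((t(samples) - samples[nxt, ])^2))
    }
    w <- samples[idx, , drop = FALSE]
  } else if (cfg$init %in% c("sample", "maximin")) {
    if (nrow(samples) >= n_nodes) {
      idx <- sample.int(nrow(samples), n_nodes)
    } else {
      idx <- sample.int(nrow(samples), n_nodes, replace = TRUE)
    }
    w <- samples[idx, , drop = FALSE]
  } else {
    w <- matrix(stats::rnorm(n_nodes * d), n_nodes, d)
  }
  structure(list(grid = grid, weights = normalize_rows(w),
                 node_labels = rep(NA_character_, n_nodes),
                 config = cfg, n_iter = 0L),
            class = "som_model")
}

#' Train a self-organizing map
#'
#' Competitive learning over the (row-)normalized samples: per iteration one
#' sample is presented (order reshuffled every epoch under the seed), its
#' best-matching unit found, and the winning neighborhood pulled toward it
#' with the decaying learning rate and Gaussian neighborhood. Training stops
#' at `max_iters` updates or once `eta(t) < eta_stop`. Fully deterministic
#' given `cfg$seed`.
#'
#' @param samples M x d numeric matrix, one feature vector per row (d = 256
#'   for the posture pipeline).
#' @param cfg A [train_config()].
#' @param labels Optional character labels (length M); when given, node
#'   labels are assigned by majority vote after training.
#' @param grid Output lattice (default the 2 x 3 [hex_grid()]).
#' @return A `som_model`: list with `grid`, `weights` (nodes x d, unit rows),
#'   `node_labels`, `config`, `n_iter`.
#' @export
som_train <- function(samples, cfg = train_config(), labels = NULL,
                      grid = hex_grid()) {
  if (!is.matrix(samples) || nrow(samples) < 1L) {
    stop("'samples' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  x <- normalize_rows(samples)
  m <- nrow(x)
  with_seed(cfg$seed, {
    model <- init_som(x, cfg, grid)
    t <- 0L
    done <- FALSE
    while (!done) {
      ord <- sample.int(m)
      for (i in ord) {
        if (t >= cfg$max_iters || eta_at(t, cfg) < cfg$eta_stop) {
          done <- TRUE
          break
        }
        bmu <- find_bmu(x[i, ], model)
        model <- update_weights(model, x[i, ], bmu$index, t, cfg)
        t <- t + 1L
      }
      if (m == 0L) done <- TRUE
    }
    model$n_iter <- t
    if (!is.null(labels)) model <- assign_labels(model, samples, labels)
    model
  })
}

#' Label map nodes by majority vote of their training samples
#'
#' Each node receives the most frequent class among training samples whose
#' best-matching unit it is; ties break by the canonical class order
#' LC < RC < LL < LR < WB < SS. A node that wins no sample inherits the
#' label of the nearest (weight-space) labeled node.
#'
#' @param model A trained `som_model`.
#' @param samples The training feature matrix (rows normalized internally).
#' @param labels Character class labels, one per sample row.
#' @return The model with `node_labels` filled in.
#' @export
assign_labels <- function(model, samples, labels) {
  if (is.null(labels) || length(labels) != nrow(samples)) {
    stop("labels must match the number of sample rows", call. = FALSE)
  }
  x <- normalize_rows(samples)
  order_ref <- posture_classes()
  extra <- setdiff(unique(labels), order_ref)
  order_ref <- c(order_ref, sort(extra))
  bmus <- apply(x, 1L, function(v) find_bmu(v, model)$index)
  n_nodes <- model$grid$n_nodes
  node_labels <- rep(NA_character_, n_nodes)
  for (j in seq_len(n_nodes)) {
    hit <- labels[bmus == j]
    if (length(hit) == 0L) next
    counts <- table(factor(hit, levels = order_ref))
    node_labels[j] <- names(counts)[which.max(counts)]
  }
  empty <- which(is.na(node_labels))
  filled <- which(!is.na(node_labels))
  if (length(filled) == 0L) stop("no labeled samples", call. = FALSE)
  for (j in empty) {
    d2 <- rowSums(sweep(model$weights[filled, , drop = FALSE], 2L,
                        model$weights[j, ])^2)
    node_labels[j] <- node_labels[filled[which.min(d2)]]
  }
  model$node_labels <- node_labels
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d nodes, dim %d, %d iterations\n",
              x$grid$n_nodes, ncol(x$weights), x$n_iter))
  if (!all(is.na(x$node_labels))) {
    cat("  node labels:", paste(x$node_labels, collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict posture classes from feature vectors
#'
#' @param object A labeled `som_model`.
#' @param newdata Feature matrix (rows = samples) or a single feature vector.
#' @param type `"class"` (default) for labels, `"node"` for winning node
#'   indices.
#' @param ... Unused.
#' @return Character labels or integer node indices.
#' @export
predict.som_model <- function(object, newdata, type = c("class", "node"),
                              ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  x <- normalize_rows(newdata)
  nodes <- apply(x, 1L, function(v) find_bmu(v, object)$index)
  if (type == "node") return(as.integer(nodes))
  if (all(is.na(object$node_labels))) {
    stop("model has no node labels; train with labels or call assign_labels()",
         call. = FALSE)
  }
  object$node_labels[nodes]
}

#' Classify raw pressure frames with a trained map
#'
#' Convenience composition: reduce each frame, flatten, normalize, find the
#' best-matching unit, return its label.
#'
#' @param model A labeled `som_model`.
#' @param frames A single 32 x 32 matrix, a list of them, or an
#'   `spr_dataset`.
#' @param k Components used in the reduction (default 8; must match
#'   training).
#' @param mode Reduction mode passed to [frames_to_features()].
#' @param basis_frames Optional frames for a pooled basis.
#' @param spec A [sensor_spec()].
#' @return Character vector of predicted classes.
#' @export
spr_predict <- function(model, frames, k = 8L, mode = "perframe",
                        basis_frames = NULL, spec = sensor_spec()) {
  if (is.matrix(frames)) frames <- list(frames)
  feats <- frames_to_features(frames, k = k, mode = mode,
                              basis_frames = basis_frames, spec = spec)
  predict(model, feats)
}

#' Mean pairwise distance between node weight vectors
#'
#' A scalar summary of how far apart the map's prototypes sit; the
#' improved-SOM retraining step is expected to increase it.
#'
#' @param model A `som_model`.
#' @return Mean Euclidean distance over all node pairs.
#' @export
internode_distance <- function(model) {
  mean(stats::dist(model$weights))
}
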