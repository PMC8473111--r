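#' Distances from every sample to every node of a frozen map
#'
#' Recomputes the Euclidean distance table between the (normalized) training
#' samples and the trained map's fixed weight vectors.
#'
#' @param model A trained `som_model`.
#' @param samples M x d feature matrix.
#' @return M x n_nodes matrix of non-negative distances.
#' @export
recompute_distances <- function(model, samples) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  x <- normalize_rows(samples)
  w <- model$weights
  out <- matrix(0, nrow(x), nrow(w))
  for (j in seq_len(nrow(w))) {
    out[, j] <- sqrt(rowSums(sweep(x, 2L, w[j, ])^2))
  }
  out
}

#' Differentiation records for training samples
#'
#' For each sample, takes its best-matching node `j` and the hex-adjacent
#' rival `k` of `j` with the smallest distance (the strongest competing
#' node), and scores how decisively the sample prefers `j`:
#' `e_jk = d_ij - d_ik` and `r_jk = |e_jk| / (d_ij + d_ik)`, a scale-free
#' degree of differentiation in `[0, 1]` (defined as 0 when both distances
#' are zero). Low `r_jk` marks samples that sit ambiguously between two
#' adjacent nodes.
#'
#' @param model A trained `som_model`.
#' @param samples M x d feature matrix, or a precomputed distance table via
#'   `distances`.
#' @param distances Optional M x n_nodes distance table from
#'   [recompute_distances()].
#' @return A data.frame with columns `sample_index`, `bmu`, `rival`, `d_ij`,
#'   `d_ik`, `e_jk`, `r_jk`.
#' @export
differentiation_records <- function(model, samples, distances = NULL) {
  if (is.null(distances)) distances <- recompute_distances(model, samples)
  adj <- hex_adjacent(model$grid)
  m <- nrow(distances)
  out <- data.frame(sample_index = seq_len(m), bmu = NA_integer_,
                    rival = NA_integer_, d_ij = NA_real_, d_ik = NA_real_,
                    e_jk = NA_real_, r_jk = NA_real_)
  for (i in seq_len(m)) {
    d <- distances[i, ]
    j <- which.min(d)
    nb <- which(adj[j, ])
    k <- nb[which.min(d[nb])]
    dij <- d[j]
    dik <- d[k]
    e <- dij - dik
    r <- if (dij + dik > 0) abs(e) / (dij + dik) else 0
    out$bmu[i] <- j
    out$rival[i] <- k
    out$d_ij[i] <- dij
    out$d_ik[i] <- dik
    out$e_jk[i] <- e
    out$r_jk[i] <- r
  }
  out
}

#' Partition samples by differentiation threshold
#'
#' A sample is removed iff its differentiation degree falls strictly below
#' `r_min`; the kept/removed index sets are disjoint and exhaustive.
#'
#' @param records Data.frame from [differentiation_records()].
#' @param r_min Threshold in `[0, 1]` (default 0.15).
#' @return List with integer vectors `kept` and `removed`.
#' @export
filter_samples <- function(records, r_min = 0.15) {
  stopifnot(is.data.frame(records), r_min >= 0)
  removed <- records$sample_index[records$r_jk < r_min]
  kept <- setdiff(records$sample_index, removed)
  list(kept = kept, removed = removed)
}

#' Train the improved SOM (filter-and-retrain)
#'
#' Runs a first SOM fit, recomputes sample-to-node distances against the
#' frozen weights, scores every training sample's differentiation degree,
#' drops samples below `cfg$r_min`, and retrains from scratch on the kept
#' subset with fresh schedules under the same seed. Node labels come from a
#' majority vote of the kept samples. Unless `strict = TRUE`, a class the
#' filter would wipe out keeps its highest-differentiation samples (10% of
#' the class, at least one) so every posture stays represented.
#'
#' @param samples M x d feature matrix.
#' @param labels Character class labels, one per row.
#' @param cfg A [train_config()]; `r_min` and `seed` govern the filter and
#'   both fits.
#' @param grid Output lattice (default 2 x 3 [hex_grid()]).
#' @param strict Disable the class-retention guard (default FALSE).
#' @param warm_start Initialize the retrain from the first fit's weights
#'   instead of restarting (default FALSE).
#' @return An `isom_model` (inherits `som_model`) with extra fields
#'   `filter` (the differentiation records plus a `kept` flag),
#'   `initial_model` (the first fit), and `kept` (indices retrained on).
#' @export
isom_train <- function(samples, labels, cfg = train_config(),
                       grid = hex_grid(), strict = FALSE,
                       warm_start = FALSE) {
  if (!is.matrix(samples) || nrow(samples) < 1L) {
    stop("'samples' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (length(labels) != nrow(samples)) {
    stop("labels must match the number of sample rows", call. = FALSE)
  }
  first <- som_train(samples, cfg, labels = labels, grid = grid)
  rec <- differentiation_records(first, samples)
  part <- filter_samples(rec, cfg$r_min)
  kept <- part$kept
  if (!strict) {
    for (cls in unique(labels)) {
      cls_idx <- which(labels == cls)
      if (!any(cls_idx %in% kept)) {
        n_keep <- max(1L, floor(0.1 * length(cls_idx)))
        top <- cls_idx[order(rec$r_jk[cls_idx], decreasing = TRUE)][
          seq_len(n_keep)]
        kept <- sort(union(kept, top))
      }
    }
  }
  if (length(kept) == 0L) {
    stop("differentiation filter removed every sample; lower r_min",
         call. = FALSE)
  }
  if (warm_start) {
    model <- with_seed(cfg$seed, {
      x <- normalize_rows(samples[kept, , drop = FALSE])
      m <- nrow(x)
      mdl <- first
      t <- 0L
      done <- FALSE
      while (!done) {
        ord <- sample.int(m)
        for (i in ord) {
          if (t >= cfg$max_iters || eta_at(t, cfg) < cfg$eta_stop) {
            done <- TRUE
            break
          }
          bmu <- find_bmu(x[i, ], mdl)
          mdl <- update_weights(mdl, x[i, ], bmu$index, t, cfg)
          t <- t + 1L
        }
      }
      mdl$n_iter <- t
      assign_labels(mdl, samples[kept, , drop = FALSE], labels[kept])
    })
  } else {
    model <- som_train(samples[kept, , drop = FALSE], cfg,
                       labels = labels[kept], grid = grid)
  }
  rec$kept <- rec$sample_index %in% kept
  model$filter <- rec
  model$initial_model <- first
  model$kept <- kept
  class(model) <- c("isom_model", class(model))
  model
}

#' @export
print.isom_model <- function(x, ...) {
  cat(sprintf(
    "<isom_model> %d nodes, dim %d; filter kept %d/%d samples (r_min = %g)\n",
    x$grid$n_nodes, ncol(x$weights), length(x$kept), nrow(x$filter),
    x$config$r_min))
  if (!all(is.na(x$node_labels))) {
    cat("  node labels:", paste(x$node_labels, collapse = " "), "\n")
  }
  invisible(x)
}
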