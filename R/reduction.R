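#' Column covariance matrix of a pressure frame
#'
#' Treats the 32 columns of one frame as variables observed over the 32 rows
#' and returns their sample covariance matrix (divisor n - 1 = 31), via
#' [stats::cov()].
#'
#' @param frame A 32 x 32 pressure matrix.
#' @param spec A [sensor_spec()] giving the expected shape.
#' @return A 32 x 32 symmetric covariance matrix.
#' @export
column_covariance <- function(frame, spec = sensor_spec()) {
  if (!is.matrix(frame) || nrow(frame) != spec$rows ||
      ncol(frame) != spec$cols) {
    stop(sprintf("frame must be %d x %d", spec$rows, spec$cols),
         call. = FALSE)
  }
  stats::cov(frame)
}

#' Leading eigenvectors of a covariance matrix
#'
#' Returns the top `k` eigenvectors ordered by decreasing eigenvalue, as
#' columns of an orthonormal matrix. The sign of each eigenvector is fixed by
#' forcing its largest-magnitude entry positive, so identical inputs always
#' yield identical bases. When the matrix has rank below `k` the
#' eigendecomposition still supplies an orthonormal completion; the result
#' then carries attribute `degenerate = TRUE` as a diagnostic.
#'
#' @param cov_mat Symmetric covariance matrix.
#' @param k Number of leading eigenvectors (default 8).
#' @param tol Symmetry tolerance (default 1e-8, relative to the largest
#'   entry).
#' @return A `nrow(cov_mat) x k` matrix with orthonormal columns; attributes
#'   `eigenvalues` (the k leading eigenvalues) and `degenerate`.
#' @export
top_eigenvectors <- function(cov_mat, k = 8L, tol = 1e-8) {
  stopifnot(is.matrix(cov_mat), nrow(cov_mat) == ncol(cov_mat))
  if (k < 1L || k > nrow(cov_mat)) {
    stop("k must be between 1 and nrow(cov_mat)", call. = FALSE)
  }
  asym <- max(abs(cov_mat - t(cov_mat)))
  scale_ref <- max(abs(cov_mat), 1)
  if (asym > tol * scale_ref) {
    stop(sprintf("matrix is not symmetric (max asymmetry %.3g)", asym),
         call. = FALSE)
  }
  es <- eigen((cov_mat + t(cov_mat)) / 2, symmetric = TRUE)
  vals <- es$values[seq_len(k)]
  vecs <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    idx <- which.max(abs(vecs[, j]))
    if (vecs[idx, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rank_tol <- max(abs(es$values)) * 1e-10
  degenerate <- sum(es$values > rank_tol) < k
  structure(vecs, eigenvalues = vals, degenerate = degenerate)
}

#' Reduce a frame to its 32 x 8 principal-component projection
#'
#' Projects the frame onto the top `k` eigenvectors of its own column
#' covariance (per-frame reduction): `P_r = P A`. With `basis` supplied, the
#' projection uses that fixed basis instead (pooled mode; see
#' [pooled_basis()]).
#'
#' @param frame A 32 x 32 pressure matrix.
#' @param k Number of components retained (default 8).
#' @param basis Optional fixed 32 x k basis to project onto.
#' @param spec A [sensor_spec()].
#' @return A 32 x k matrix of class `reduced_frame`.
#' @export
reduce_frame <- function(frame, k = 8L, basis = NULL, spec = sensor_spec()) {
  if (!is.matrix(frame) || nrow(frame) != spec$rows ||
      ncol(frame) != spec$cols) {
    stop(sprintf("frame must be %d x %d", spec$rows, spec$cols),
         call. = FALSE)
  }
  if (is.null(basis)) {
    basis <- top_eigenvectors(column_covariance(frame, spec), k = k)
  } else {
    stopifnot(nrow(basis) == spec$cols, ncol(basis) == k)
  }
  structure(unclass(frame) %*% basis, class = "reduced_frame")
}

#' Shared projection basis fitted on a set of frames
#'
#' Averages the per-frame column covariances over `frames` and extracts the
#' top `k` eigenvectors, giving one basis under which feature vectors are
#' directly comparable across frames.
#'
#' @param frames List of 32 x 32 matrices.
#' @param k Number of components (default 8).
#' @param spec A [sensor_spec()].
#' @return A 32 x k orthonormal matrix.
#' @export
pooled_basis <- function(frames, k = 8L, spec = sensor_spec()) {
  stopifnot(length(frames) >= 1L)
  acc <- matrix(0, spec$cols, spec$cols)
  for (fr in frames) acc <- acc + column_covariance(fr, spec)
  top_eigenvectors(acc / length(frames), k = k)
}

#' Flatten a reduced frame head-to-tail into a feature vector
#'
#' Row-major concatenation: entry (m, n) of the 32 x 8 matrix lands at
#' position `8 * (m - 1) + n` of the 256-element vector.
#'
#' @param reduced A 32 x 8 (`reduced_frame`) matrix.
#' @return Numeric vector of length `nrow * ncol` (256 by default).
#' @export
flatten_to_vector <- function(reduced) {
  if (!is.matrix(reduced)) stop("input must be a matrix", call. = FALSE)
  as.vector(t(unclass(reduced)))
}

#' Reassemble a feature vector into its reduced-frame matrix
#'
#' Inverse of [flatten_to_vector()].
#'
#' @param v Feature vector of length `rows * cols`.
#' @param rows,cols Target shape (default 32 x 8).
#' @return A `rows x cols` matrix.
#' @export
unflatten_vector <- function(v, rows = 32L, cols = 8L) {
  if (length(v) != rows * cols) {
    stop(sprintf("vector length %d does not match %d x %d", length(v),
                 rows, cols), call. = FALSE)
  }
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Feature matrix for a list of frames
#'
#' Applies [reduce_frame()] then [flatten_to_vector()] to each frame. In
#' `"perframe"` mode every frame is projected onto its own eigenbasis (with
#' the deterministic sign convention); in `"pooled"` mode one basis is fitted
#' on `basis_frames` (default: the frames themselves) and shared.
#'
#' @param frames List of 32 x 32 matrices, or an `spr_dataset`.
#' @param k Components retained per frame (default 8).
#' @param mode `"perframe"` (default) or `"pooled"`.
#' @param basis_frames Frames used to fit the pooled basis.
#' @param spec A [sensor_spec()].
#' @return An M x (32 k) numeric matrix, one feature vector per row.
#' @export
frames_to_features <- function(frames, k = 8L,
                               mode = c("perframe", "pooled"),
                               basis_frames = NULL, spec = sensor_spec()) {
  mode <- match.arg(mode)
  if (inherits(frames, "spr_dataset")) frames <- frames$frames
  stopifnot(length(frames) >= 1L)
  basis <- NULL
  if (mode == "pooled") {
    basis <- pooled_basis(if (is.null(basis_frames)) frames else basis_frames,
                          k = k, spec = spec)
  }
  out <- matrix(0, length(frames), spec$rows * k)
  for (i in seq_along(frames)) {
    out[i, ] <- flatten_to_vector(
      reduce_frame(frames[[i]], k = k, basis = basis, spec = spec))
  }
  out
}
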