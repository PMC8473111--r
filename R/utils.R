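#' Posture class labels in canonical order
#'
#' The six sitting-posture classes recognized by the pipeline, in the fixed
#' order used everywhere (confusion-matrix axes, tie-breaking, reports):
#' left cross-legs (LC), right cross-legs (RC), lean left (LL),
#' lean right (LR), waist bow (WB), standard sitting (SS).
#'
#' @return Character vector of length 6.
#' @export
posture_classes <- function() {
  c("LC", "RC", "LL", "LR", "WB", "SS")
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# seed = NULL means "use the current RNG stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# L2 norm
l2 <- function(v) sqrt(sum(v * v))

# Half-up rounding used for printing percentages (matches the reported tables).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
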