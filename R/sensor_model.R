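#' Sensor array specification
#'
#' Describes the flexible resistive seat sensor: a 32 x 32 array of
#' strain-gauge induction units read through a voltage divider. Per-point
#' resistance `R_ij` maps to output voltage `u_o = V_ref * R_ij / (R_ij +
#' R_IM)` and to pressure through the calibration fit `p = fit_a / R - fit_b`.
#'
#' @param rows,cols Array dimensions (default 32 x 32, i.e. 1024 points).
#' @param v_ref Reference voltage in V (default 5).
#' @param r_im Impedance-matching resistance in kilo-ohm (default 200).
#' @param fit_a,fit_b Coefficients of the measured pressure-resistance fit
#'   `p = fit_a / R - fit_b`, with `R` in kilo-ohm (defaults 1690 and 3.379).
#' @param collection_threshold Pressure below which readings are discarded at
#'   acquisition time, to reject seat-foam deformation. Default 0 (keep all).
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(rows = 32L, cols = 32L, v_ref = 5, r_im = 200,
                        fit_a = 1690, fit_b = 3.379,
                        collection_threshold = 0) {
  stopifnot(rows >= 1, cols >= 1)
  stop_if_not_scalar_number(v_ref, "v_ref")
  stop_if_not_scalar_number(r_im, "r_im")
  if (v_ref <= 0) stop("'v_ref' must be positive", call. = FALSE)
  if (r_im <= 0) stop("'r_im' must be positive", call. = FALSE)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         v_ref = v_ref, r_im = r_im, fit_a = fit_a, fit_b = fit_b,
         collection_threshold = collection_threshold),
    class = "sensor_spec"
  )
}

#' Voltage-divider output for a sensing-point resistance
#'
#' @param r_ij Resistance(s) in kilo-ohm; must be strictly positive.
#' @param spec A [sensor_spec()].
#' @return Output voltage(s) in V, strictly increasing in `r_ij` and bounded
#'   in `(0, v_ref)`.
#' @export
resistance_to_voltage <- function(r_ij, spec = sensor_spec()) {
  if (any(!is.finite(r_ij)) || any(r_ij <= 0)) {
    stop("resistance must be positive and finite", call. = FALSE)
  }
  spec$v_ref * r_ij / (r_ij + spec$r_im)
}

#' Pressure from a sensing-point resistance via the calibration fit
#'
#' Evaluates `p = fit_a / R - fit_b`. Large resistances (no contact) give a
#' negative fit value; by the frame non-negativity contract these are clamped
#' to 0 unless `clamp = FALSE`.
#'
#' @param r_ij Resistance(s) in kilo-ohm; strictly positive.
#' @param spec A [sensor_spec()].
#' @param clamp Clamp negative fit outputs to 0 (default TRUE).
#' @return Pressure(s) in the fit's units.
#' @export
resistance_to_pressure <- function(r_ij, spec = sensor_spec(), clamp = TRUE) {
  if (any(!is.finite(r_ij)) || any(r_ij <= 0)) {
    stop("resistance must be positive and finite", call. = FALSE)
  }
  p <- spec$fit_a / r_ij - spec$fit_b
  if (clamp) p <- pmax(p, 0)
  p
}

#' Resistance implied by a pressure (inverse of the calibration fit)
#'
#' @param p Pressure(s); must exceed `-fit_b`.
#' @param spec A [sensor_spec()].
#' @return Resistance(s) in kilo-ohm.
#' @export
pressure_to_resistance <- function(p, spec = sensor_spec()) {
  if (any(!is.finite(p)) || any(p <= -spec$fit_b)) {
    stop("pressure must be finite and exceed -fit_b", call. = FALSE)
  }
  spec$fit_a / (p + spec$fit_b)
}

#' Zero out sub-threshold readings of a frame
#'
#' Emulates acquisition-time filtering: entries below the spec's
#' `collection_threshold` are set to 0, entries at or above it pass
#' unchanged. Idempotent.
#'
#' @param frame A 32 x 32 non-negative pressure matrix.
#' @param spec A [sensor_spec()].
#' @return The thresholded frame (attributes preserved).
#' @export
apply_collection_threshold <- function(frame, spec = sensor_spec()) {
  check_frame(frame, spec)
  out <- frame
  out[out < spec$collection_threshold] <- 0
  out
}

# Validate a pressure frame: numeric matrix of spec dimensions, non-negative.
check_frame <- function(frame, spec = sensor_spec()) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix", call. = FALSE)
  }
  if (nrow(frame) != spec$rows || ncol(frame) != spec$cols) {
    stop(sprintf("frame must be %d x %d, got %d x %d",
                 spec$rows, spec$cols, nrow(frame), ncol(frame)),
         call. = FALSE)
  }
  if (any(!is.finite(frame)) || any(frame < 0)) {
    stop("frame entries must be finite and non-negative", call. = FALSE)
  }
  invisible(frame)
}

#' Spatial load template for a posture class
#'
#' Each posture is modeled as a mixture of 2-D Gaussian load components on
#' the 32 x 32 grid: two ischial (sit-bone) peaks plus two broader thigh
#' regions. Rows run back (1) to front (32); columns run left (1) to
#' right (32). Class geometry:
#' \itemize{
#'   \item SS: symmetric two-peak pattern.
#'   \item LL / LR: all centers shifted toward the named side, with load
#'     share moved to that side.
#'   \item LC / RC: the crossed leg's thigh region nearly unloaded and the
#'     contralateral ischial load raised.
#'   \item WB: load shifted forward and concentrated (smaller spreads).
#' }
#'
#' @param class_id One of `posture_classes()`.
#' @return A list with `class_id`, `centers` (4 x 2 matrix of (row, col)),
#'   `spreads` (length 4), and `amplitudes` (length 4, summing to 1).
#' @export
posture_template <- function(class_id) {
  classes <- posture_classes()
  if (!is.character(class_id) || length(class_id) != 1L ||
      !(class_id %in% classes)) {
    stop(sprintf("unknown posture class '%s' (expected one of %s)",
                 paste(class_id, collapse = ","),
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  # base geometry: ischial L, ischial R, thigh L, thigh R
  centers <- rbind(c(13, 12), c(13, 21), c(22, 12), c(22, 21))
  spreads <- c(2.6, 2.6, 3.4, 3.4)
  amps <- switch(class_id,
    SS = c(0.30, 0.30, 0.20, 0.20),
    LL = c(0.38, 0.22, 0.26, 0.14),
    LR = c(0.22, 0.38, 0.14, 0.26),
    LC = c(0.24, 0.42, 0.04, 0.30),
    RC = c(0.42, 0.24, 0.30, 0.04)
  )
  if (class_id == "LL") centers[, 2] <- centers[, 2] - 3
  if (class_id == "LR") centers[, 2] <- centers[, 2] + 3
  if (class_id == "WB") {
    centers[, 1] <- centers[, 1] + 4
    spreads <- spreads * 0.8
    amps <- c(0.26, 0.26, 0.24, 0.24)
  }
  if (is.null(amps)) amps <- c(0.30, 0.30, 0.20, 0.20)
  list(class_id = class_id, centers = centers, spreads = spreads,
       amplitudes = amps / sum(amps))
}

#' Noise model for the synthetic generator
#'
#' @param center_shift_sd Whole-body placement jitter, grid cells (default 0.6).
#' @param center_jitter_sd Per-component center jitter, grid cells (default 0.3).
#' @param amplitude_jitter_sd Log-normal sd of component load shares (default 0.08).
#' @param spread_jitter_sd Log-normal sd of component spatial scales (default 0.05).
#' @param additive_sd_frac Additive Gaussian noise sd, as a fraction of the
#'   clean frame's peak value (default 0.02).
#' @return A list of class `gen_noise`.
#' @export
gen_noise <- function(center_shift_sd = 0.6, center_jitter_sd = 0.3,
                      amplitude_jitter_sd = 0.08, spread_jitter_sd = 0.05,
                      additive_sd_frac = 0.02) {
  structure(list(center_shift_sd = center_shift_sd,
                 center_jitter_sd = center_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 spread_jitter_sd = spread_jitter_sd,
                 additive_sd_frac = additive_sd_frac),
            class = "gen_noise")
}

#' Generate one synthetic pressure frame for a posture class
#'
#' Draws a jittered instance of the class template, adds sensor noise, clamps
#' to non-negative values, applies the acquisition threshold, and rescales so
#' the total load is proportional to subject weight (`load_scale` pressure
#' units per kg). Deterministic for a fixed `(class_id, weight_kg, seed)`.
#'
#' @param class_id One of [posture_classes()].
#' @param weight_kg Subject weight in kg (default: drawn uniformly from
#'   `weight_range`).
#' @param seed Integer seed, or NULL to consume the current RNG stream.
#' @param spec A [sensor_spec()].
#' @param noise A [gen_noise()].
#' @param weight_range Plausible subject-weight range in kg (default 45-80).
#' @param load_scale Total frame load per kg of body weight (default 10).
#' @param subject_id Optional subject tag stored as an attribute.
#' @return A 32 x 32 non-negative matrix with attributes `label`,
#'   `weight_kg`, and `subject_id`.
#' @export
generate_frame <- function(class_id, weight_kg = NULL, seed = NULL,
                           spec = sensor_spec(), noise = gen_noise(),
                           weight_range = c(45, 80), load_scale = 10,
                           subject_id = NA_character_) {
  tpl <- posture_template(class_id)
  with_seed(seed, {
    if (is.null(weight_kg)) {
      weight_kg <- stats::runif(1L, weight_range[1L], weight_range[2L])
    }
    stopifnot(weight_kg > 0)
    ncomp <- nrow(tpl$centers)
    shift <- stats::rnorm(2L, 0, noise$center_shift_sd)
    centers <- tpl$centers +
      matrix(stats::rnorm(2L * ncomp, 0, noise$center_jitter_sd),
             ncol = 2L) +
      matrix(shift, nrow = ncomp, ncol = 2L, byrow = TRUE)
    amps <- tpl$amplitudes *
      exp(stats::rnorm(ncomp, 0, noise$amplitude_jitter_sd))
    amps <- amps / sum(amps)
    spreads <- tpl$spreads *
      exp(stats::rnorm(ncomp, 0, noise$spread_jitter_sd))

    rr <- seq_len(spec$rows)
    cc <- seq_len(spec$cols)
    field <- matrix(0, spec$rows, spec$cols)
    for (k in seq_len(ncomp)) {
      dr2 <- (rr - centers[k, 1L])^2
      dc2 <- (cc - centers[k, 2L])^2
      field <- field + amps[k] *
        outer(exp(-dr2 / (2 * spreads[k]^2)),
              exp(-dc2 / (2 * spreads[k]^2)))
    }
    if (noise$additive_sd_frac > 0) {
      field <- field + stats::rnorm(length(field), 0,
                                    noise$additive_sd_frac * max(field))
    }
    field <- pmax(field, 0)
    field[field < spec$collection_threshold] <- 0
    tot <- sum(field)
    if (tot > 0) field <- field * (weight_kg * load_scale / tot)
    structure(field, label = class_id, weight_kg = weight_kg,
              subject_id = subject_id)
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' @param n_per_class Frames per posture class (>= 1).
#' @param seed Integer seed driving all randomness (weights and frame noise).
#' @param classes Classes to generate (default all six).
#' @param ... Passed to [generate_frame()] (`spec`, `noise`, `weight_range`,
#'   `load_scale`).
#' @return A list of class `spr_dataset` with `frames` (list of matrices) and
#'   `meta` (data.frame with `label`, `subject_id`, `weight_kg`).
#' @export
generate_dataset <- function(n_per_class, seed = 1L,
                             classes = posture_classes(), ...) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    n <- n_per_class * length(classes)
    frames <- vector("list", n)
    label <- character(n)
    weight <- numeric(n)
    subject <- character(n)
    i <- 0L
    for (cls in classes) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        sid <- sprintf("sim-%s-%03d", cls, j)
        fr <- generate_frame(cls, weight_kg = NULL, seed = NULL,
                             subject_id = sid, ...)
        frames[[i]] <- fr
        label[i] <- cls
        weight[i] <- attr(fr, "weight_kg")
        subject[i] <- sid
      }
    }
    structure(list(frames = frames,
                   meta = data.frame(label = label, subject_id = subject,
                                     weight_kg = weight,
                                     stringsAsFactors = FALSE)),
              class = "spr_dataset")
  })
}

#' @export
print.spr_dataset <- function(x, ...) {
  cat(sprintf("<spr_dataset> %d frames (%s)\n", length(x$frames),
              paste(sprintf("%s:%d", names(table(x$meta$label)),
                            as.integer(table(x$meta$label))),
                    collapse = ", ")))
  invisible(x)
}

#' Inject between-class midpoint samples into a feature set
#'
#' Builds deliberately ambiguous training samples by averaging the feature
#' vectors of randomly paired samples from two different classes. Used to
#' exercise the differentiation filter: midpoints sit near the boundary
#' between two map nodes and receive low differentiation degrees.
#'
#' @param features M x d feature matrix.
#' @param labels Character labels of length M.
#' @param fraction Number of midpoints to add, as a fraction of M (default 0.1).
#' @param seed Integer seed.
#' @return A list with `features` (rows appended), `labels` (midpoints keep
#'   the label of the first parent), and `injected` (indices of added rows).
#' @export
inject_midpoints <- function(features, labels, fraction = 0.1, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  n_add <- max(1L, round(fraction * nrow(features)))
  with_seed(seed, {
    add <- matrix(0, n_add, ncol(features))
    lab <- character(n_add)
    for (i in seq_len(n_add)) {
      cls2 <- sample(unique(labels), 2L)
      a <- sample(which(labels == cls2[1L]), 1L)
      b <- sample(which(labels == cls2[2L]), 1L)
      add[i, ] <- (features[a, ] + features[b, ]) / 2
      lab[i] <- cls2[1L]
    }
    list(features = rbind(features, add),
         labels = c(labels, lab),
         injected = nrow(features) + seq_len(n_add))
  })
}
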