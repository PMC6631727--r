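# Sensor-log reading, feature magnitudes, min-max scaling, observation
# windowing and fold splitting.

# canonical feature order: gyro x/y/z, gyro magnitude, accel x/y/z, accel
# magnitude
ldmf_features <- c("wx", "wy", "wz", "wT", "ax", "ay", "az", "aT")
ldmf_raw_channels <- c("wx", "wy", "wz", "ax", "ay", "az")

#' Euclidean magnitudes of angular velocity and acceleration
#'
#' Computes the two intensity features appended to the six raw IMU channels:
#' the square root of the sum of squares of the gyroscope components and of
#' the accelerometer components.
#'
#' @param omega_xyz numeric 3-vector (rad/s) or n x 3 matrix.
#' @param a_xyz numeric 3-vector (m/s^2) or n x 3 matrix.
#' @return List with elements \code{omega_T} and \code{A_T}.
#' @examples
#' compute_magnitudes(c(3, 4, 0), c(0, 0, 9.81))
#' @export
compute_magnitudes <- function(omega_xyz, a_xyz) {
  as_mat3 <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3L)
  W <- as_mat3(omega_xyz)
  A <- as_mat3(a_xyz)
  stopifnot(ncol(W) == 3L, ncol(A) == 3L, all(is.finite(W)), all(is.finite(A)))
  list(omega_T = sqrt(rowSums(W * W)), A_T = sqrt(rowSums(A * A)))
}

#' Construct a validated feature sequence
#'
#' A feature sequence holds one recording: a frame per sample with the
#' 8-dimensional feature vector (3-axis angular velocity, its magnitude,
#' 3-axis acceleration, its magnitude) plus timestamps.
#'
#' @param frames data frame with columns \code{t} and the six raw channels
#'   \code{wx, wy, wz, ax, ay, az}; magnitude columns \code{wT, aT} are
#'   computed if absent.
#' @param sampling_rate nominal sampling rate in Hz.
#' @param subject_id,motion identifiers; \code{motion} is "walk" or "run".
#' @return Object of class \code{feature_sequence}.
#' @export
feature_sequence <- function(frames, sampling_rate = 30,
                             subject_id = NA_character_, motion = "walk") {
  stopifnot(is.data.frame(frames))
  missing_cols <- setdiff(c("t", ldmf_raw_channels), names(frames))
  if (length(missing_cols) > 0) {
    stop("missing channel column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(vapply(frames[c("t", ldmf_raw_channels)],
                  function(x) all(is.finite(x)), TRUE))) {
    stop("non-finite values in sensor log")
  }
  if (nrow(frames) > 1 && any(diff(frames$t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!("wT" %in% names(frames)) || !("aT" %in% names(frames))) {
    mg <- compute_magnitudes(as.matrix(frames[c("wx", "wy", "wz")]),
                             as.matrix(frames[c("ax", "ay", "az")]))
    frames$wT <- mg$omega_T
    frames$aT <- mg$A_T
  }
  structure(
    list(frames = frames[c("t", ldmf_features)],
         sampling_rate = sampling_rate,
         subject_id = subject_id, motion = motion),
    class = "feature_sequence"
  )
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> subject=%s motion=%s frames=%d rate=%g Hz\n",
              x$subject_id, x$motion, nrow(x$frames), x$sampling_rate))
  invisible(x)
}

# 8-column feature matrix of a sequence
feature_matrix <- function(seq) {
  as.matrix(seq$frames[ldmf_features])
}

#' Read a delimited sensor log
#'
#' Parses a comma-separated log with a header row naming the timestamp column
#' \code{t} and the six raw channels \code{wx, wy, wz} (rad/s) and
#' \code{ax, ay, az} (m/s^2), then appends the two magnitude features.
#'
#' @param path path to the CSV file.
#' @inheritParams feature_sequence
#' @return A \code{\link{feature_sequence}}.
#' @export
read_sensor_log <- function(path, sampling_rate = 30,
                            subject_id = NA_character_, motion = "walk") {
  df <- utils::read.csv(path)
  feature_sequence(df, sampling_rate = sampling_rate,
                   subject_id = subject_id, motion = motion)
}

#' Write a feature sequence back to the CSV dialect read_sensor_log expects
#'
#' @param seq a \code{\link{feature_sequence}}.
#' @param path output path.
#' @export
write_sensor_log <- function(seq, path) {
  utils::write.csv(seq$frames[c("t", ldmf_raw_channels)], path,
                   row.names = FALSE)
}

# --- min-max scaling --------------------------------------------------------

#' Fit per-feature min-max scaling over a cohort
#'
#' The interval for each of the 8 features is the envelope over every frame of
#' every provided sequence, so that scaled values from the fitted cohort lie
#' in [0, 1].
#'
#' @param sequences a \code{feature_sequence} or list of them.
#' @return Object of class \code{minmax_spec}: data frame with columns
#'   \code{feature}, \code{min}, \code{max}.
#' @export
fit_minmax <- function(sequences) {
  if (inherits(sequences, "feature_sequence")) sequences <- list(sequences)
  stopifnot(length(sequences) > 0)
  X <- do.call(rbind, lapply(sequences, feature_matrix))
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  if (any(hi <= lo)) {
    stop("degenerate scaling: constant feature(s) ",
         paste(ldmf_features[hi <= lo], collapse = ", "))
  }
  structure(data.frame(feature = ldmf_features, min = lo, max = hi,
                       row.names = NULL),
            class = c("minmax_spec", "data.frame"))
}

#' Apply (or invert) min-max scaling
#'
#' Maps each feature to \code{(v - min) / (max - min)}; values outside the
#' fitted interval are clipped to [0, 1] to keep the emitter's support
#' bounded. \code{invert_minmax} maps scaled values back to feature units.
#'
#' @param x an 8-vector, an n x 8 matrix, or a \code{feature_sequence}.
#' @param spec a \code{minmax_spec} from \code{\link{fit_minmax}}.
#' @return Scaled matrix (n x 8) in [0, 1], or its preimage.
#' @export
apply_minmax <- function(x, spec) {
  X <- scale_input_matrix(x)
  lo <- matrix(spec$min, nrow(X), 8L, byrow = TRUE)
  hi <- matrix(spec$max, nrow(X), 8L, byrow = TRUE)
  out <- (X - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  colnames(out) <- ldmf_features
  out
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(x, spec) {
  X <- scale_input_matrix(x)
  lo <- matrix(spec$min, nrow(X), 8L, byrow = TRUE)
  hi <- matrix(spec$max, nrow(X), 8L, byrow = TRUE)
  out <- X * (hi - lo) + lo
  colnames(out) <- ldmf_features
  out
}

scale_input_matrix <- function(x) {
  if (inherits(x, "feature_sequence")) return(feature_matrix(x))
  if (!is.matrix(x)) x <- matrix(x, ncol = 8L, byrow = FALSE)
  stopifnot(ncol(x) == 8L)
  x
}

#' Serialise a scaling specification as YAML text
#'
#' @param spec a \code{minmax_spec}.
#' @param path file path; \code{read_minmax} reads it back.
#' @export
write_minmax <- function(spec, path) {
  obj <- list(features = as.list(stats::setNames(
    lapply(seq_len(nrow(spec)), function(i) {
      list(min = spec$min[i], max = spec$max[i])
    }), spec$feature)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- obj$features
  structure(data.frame(
    feature = names(feats),
    min = vapply(feats, function(f) as.numeric(f$min), 0),
    max = vapply(feats, function(f) as.numeric(f$max), 0),
    row.names = NULL
  ), class = c("minmax_spec", "data.frame"))
}

# --- observation windows ----------------------------------------------------

#' Build stacked observation windows from a feature sequence
#'
#' The observation at time t concatenates the scaled feature vectors of the
#' current and past two frames, \code{[x_t, x_{t-1}, x_{t-2}]}, giving a
#' 24-dimensional vector (8 features x 3 frames). The first full window is
#' re-indexed to time 0; a sequence of n frames yields n - 2 windows.
#' Consecutive windows share 16 of their 24 entries.
#'
#' @param seq a \code{\link{feature_sequence}} with at least 3 frames.
#' @param spec a \code{minmax_spec}.
#' @return Object of class \code{obs_seq}: an (n-2) x 24 matrix with
#'   attributes \code{subject_id} and \code{motion}.
#' @export
build_observations <- function(seq, spec) {
  X <- apply_minmax(seq, spec)
  n <- nrow(X)
  if (n < 3L) stop("insufficient data: need at least 3 frames, got ", n)
  Y <- cbind(X[3:n, , drop = FALSE],
             X[2:(n - 1L), , drop = FALSE],
             X[1:(n - 2L), , drop = FALSE])
  colnames(Y) <- c(ldmf_features,
                   paste0(ldmf_features, "_lag1"),
                   paste0(ldmf_features, "_lag2"))
  structure(Y, class = c("obs_seq", class(Y)),
            subject_id = seq$subject_id, motion = seq$motion)
}

obs_matrix <- function(y) {
  if (is.matrix(y)) unclass(y) else as.matrix(y)
}

# --- fold splitting ---------------------------------------------------------

#' Consecutive k-fold split
#'
#' Splits indices 1..n into k consecutive, disjoint, jointly exhaustive folds
#' (the first \code{n %% k} folds hold one extra index). Each fold in turn is
#' the test set; the remaining k - 1 folds form the training set, so with the
#' default k = 5 each test fold holds 20\% of the data.
#'
#' @param n number of samples (or recordings).
#' @param k number of folds, default 5.
#' @return List of length k; each element has \code{fold_id},
#'   \code{train_indices} and \code{test_indices}.
#' @export
kfold_split <- function(n, k = 5L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop("cannot split n = ", n, " samples into k = ", k, " folds")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, stops[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- seq.int(starts[i], stops[i])
    list(fold_id = i, train_indices = setdiff(seq_len(n), test),
         test_indices = test)
  })
}

#' Shipped subject-profile fixture
#'
#' Loads the bundled cohort profile table (20 subjects: gender, age, height,
#' weight) used by loader tests and summary examples.
#'
#' @return Data frame with columns \code{subject}, \code{gender},
#'   \code{age_yr}, \code{height_cm}, \code{weight_kg}.
#' @export
read_subject_profiles <- function() {
  utils::read.csv(system.file("extdata", "subject_profiles.csv",
                              package = "ldmf"))
}
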