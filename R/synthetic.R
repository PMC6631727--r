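# Synthetic gait-signal generator and linear-Gaussian state-space instances.
#
# The IMU generator emulates quasi-periodic walking/running: each raw channel
# is a sum of three harmonics of the subject's gait fundamental frequency
# plus white Gaussian noise, with per-subject amplitudes and phases. It is
# deliberately a 1-D limit-cycle signal family, not a biomechanical model.

#' Draw a synthetic subject profile
#'
#' A profile fixes everything that characterises one subject: the gait
#' fundamental frequency for walking (1.4--2.0 Hz) and running (2.4--3.2 Hz),
#' harmonic amplitudes and phases for the six raw channels, per-channel DC
#' offsets (gravity on the vertical accelerometer axis) and noise levels.
#' Running doubles the oscillation amplitudes, reflecting movement intensity.
#' Uses the current RNG state.
#'
#' @param subject_id identifier.
#' @return Object of class \code{subject_profile}.
#' @export
draw_subject_profile <- function(subject_id) {
  # channel scales: gyro in rad/s, accel oscillation in m/s^2
  ch_scale <- c(stats::runif(3, 0.5, 2.0), stats::runif(3, 1.0, 3.0))
  rel <- c(1, 0.4, 0.15)             # relative harmonic amplitudes
  amp <- outer(rel, ch_scale)        # 3 harmonics x 6 channels
  structure(list(
    subject_id = subject_id,
    f0_walk = stats::runif(1, 1.4, 2.0),
    f0_run = stats::runif(1, 2.4, 3.2),
    amp = amp,
    phase = matrix(stats::runif(18, 0, 2 * pi), 3L, 6L),
    dc = c(0, 0, 0, stats::runif(2, -0.5, 0.5), 9.81 + stats::runif(1, -0.3, 0.3)),
    noise_sd = 0.1 * ch_scale,
    age_yr = NA_real_, height_cm = NA_real_, weight_kg = NA_real_
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s walk %.2f Hz run %.2f Hz\n",
              x$subject_id, x$f0_walk, x$f0_run))
  invisible(x)
}

#' Generate one synthetic IMU recording
#'
#' Each of the six raw channels is a sum of three harmonics of the gait
#' fundamental plus Gaussian noise; the two magnitude features are computed
#' from the components so the feature-frame invariants hold by construction.
#' Recordings of the same subject differ only through the start phase,
#' small per-channel phase jitter and the noise draw.
#'
#' @param profile a \code{\link{draw_subject_profile}} object.
#' @param motion "walk" or "run".
#' @param duration recording length in seconds.
#' @param rate sampling rate in Hz (default 30).
#' @param seed integer seed for reproducibility.
#' @return A \code{\link{feature_sequence}} of \code{duration * rate} frames.
#' @export
generate_subject_sequence <- function(profile, motion = c("walk", "run"),
                                      duration = 60, rate = 30, seed = 1L) {
  motion <- match.arg(motion)
  stopifnot(duration > 0)
  set.seed(seed)
  f0 <- if (motion == "walk") profile$f0_walk else profile$f0_run
  gain <- if (motion == "walk") 1 else 2
  n <- as.integer(round(duration * rate))
  t <- seq.int(0L, n - 1L) / rate
  phase0 <- stats::runif(1, 0, 2 * pi)
  jitter <- matrix(stats::rnorm(18, sd = 0.2), 3L, 6L)
  X <- matrix(0, n, 6L)
  for (ch in 1:6) {
    sig <- profile$dc[ch]
    for (k in 1:3) {
      sig <- sig + gain * profile$amp[k, ch] *
        sin(2 * pi * k * f0 * t + profile$phase[k, ch] + jitter[k, ch] + phase0)
    }
    X[, ch] <- sig + stats::rnorm(n, sd = profile$noise_sd[ch])
  }
  df <- data.frame(t = t, wx = X[, 1], wy = X[, 2], wz = X[, 3],
                   ax = X[, 4], ay = X[, 5], az = X[, 6])
  feature_sequence(df, sampling_rate = rate,
                   subject_id = profile$subject_id, motion = motion)
}

#' Generate a synthetic cohort of recordings
#'
#' Draws one profile per subject, then generates
#' \code{recordings_per_subject} recordings per subject and motion. Within a
#' subject, recordings share the profile (fundamental frequency, amplitudes)
#' and differ only in start phase, phase jitter and noise, emulating the
#' train/test similarity that makes per-subject cross-validation meaningful.
#'
#' @param n_subjects number of subjects.
#' @param recordings_per_subject recordings per subject and motion (default 5,
#'   one per cross-validation fold).
#' @param seed master seed; every draw derives from it.
#' @param motions character vector, subset of c("walk", "run").
#' @param duration,rate recording length (s) and sampling rate (Hz).
#' @return List with \code{profiles} (list of \code{subject_profile}) and
#'   \code{recordings} (list of \code{feature_sequence}, each carrying
#'   \code{subject_id} and \code{motion}).
#' @export
generate_cohort <- function(n_subjects, recordings_per_subject = 5L,
                            seed = 1L, motions = "walk",
                            duration = 60, rate = 30) {
  stopifnot(n_subjects >= 1, all(motions %in% c("walk", "run")))
  set.seed(seed)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    draw_subject_profile(sprintf("S%02d", i))
  })
  recordings <- list()
  rec_seed <- seed
  for (i in seq_len(n_subjects)) {
    for (m in motions) {
      for (r in seq_len(recordings_per_subject)) {
        rec_seed <- rec_seed + 1L
        s <- generate_subject_sequence(profiles[[i]], m, duration = duration,
                                       rate = rate, seed = rec_seed)
        s$recording <- r
        recordings[[length(recordings) + 1L]] <- s
      }
    }
  }
  list(profiles = profiles, recordings = recordings)
}

# --- linear-Gaussian state-space instances ----------------------------------

#' Generate a linear-Gaussian state-space instance
#'
#' Simulates \code{z_t = A z_{t-1} + w_t}, \code{y_t = C z_t + v_t} with
#' diagonal process/observation noise, used as ground truth against the
#' closed-form Kalman recursions when validating the neural filter.
#'
#' @param d latent dimension.
#' @param obs_dim observation dimension.
#' @param T_len number of time steps after the initial state (sequence length
#'   is \code{T_len + 1}).
#' @param seed integer seed.
#' @param a transition coefficient(s), recycled to length d; must satisfy
#'   |a| < 1.
#' @param q_sd,r_sd process and observation noise standard deviations.
#' @param mu0,p0_sd initial mean and standard deviation.
#' @param C emission matrix (obs_dim x d); default random.
#' @return Object of class \code{ssm_instance} with the model matrices and
#'   simulated \code{z} ((T+1) x d) and \code{y} ((T+1) x obs_dim).
#' @export
generate_linear_gaussian_ssm <- function(d = 1L, obs_dim = 1L, T_len = 50L,
                                         seed = 1L, a = 0.9, q_sd = 0.5,
                                         r_sd = 0.5, mu0 = 0, p0_sd = 1,
                                         C = NULL) {
  a <- rep_len(a, d)
  if (any(abs(a) >= 1)) stop("unstable transition coefficient: |a| must be < 1")
  stopifnot(q_sd > 0, r_sd > 0, p0_sd > 0)
  set.seed(seed)
  if (is.null(C)) C <- matrix(stats::rnorm(obs_dim * d), obs_dim, d)
  mu0 <- rep_len(mu0, d)
  z <- matrix(0, T_len + 1L, d)
  y <- matrix(0, T_len + 1L, obs_dim)
  z[1L, ] <- mu0 + stats::rnorm(d, sd = p0_sd)
  y[1L, ] <- C %*% z[1L, ] + stats::rnorm(obs_dim, sd = r_sd)
  if (T_len > 0) for (t in 2:(T_len + 1L)) {
    z[t, ] <- a * z[t - 1L, ] + stats::rnorm(d, sd = q_sd)
    y[t, ] <- C %*% z[t, ] + stats::rnorm(obs_dim, sd = r_sd)
  }
  structure(list(a = a, q_var = rep(q_sd^2, d), C = C,
                 r_var = rep(r_sd^2, obs_dim),
                 mu0 = mu0, p0_var = rep(p0_sd^2, d),
                 z = z, y = y),
            class = "ssm_instance")
}

#' Express a linear-Gaussian state-space model as backbone parameters
#'
#' Builds \code{\link{generative_params}} whose (linear, K = 1) transition
#' and emitter reproduce the given state-space instance exactly: the
#' transition mean is \code{a * z} with variance \code{q_var}, the emitter
#' mean is \code{C z} with variance \code{r_var}, and the initial prior
#' matches \code{mu0}, \code{p0_var}. Useful for validating the neural
#' filter against the closed-form Kalman recursions with a known backbone.
#'
#' @param ssm an \code{ssm_instance}.
#' @return A \code{generative_params} object with linear networks.
#' @export
ssm_to_params <- function(ssm) {
  d <- length(ssm$a)
  p <- nrow(ssm$C)
  params <- generative_params(latent_dim = d, obs_dim = p, mixture_K = 1L,
                              hidden = integer(0))
  # transition head layout: [logit, mean(d), pre-variance(d)]
  W <- matrix(0, d, 1L + 2L * d)
  W[, 1L + seq_len(d)] <- diag(ssm$a, d, d)
  params$trans$W$W1 <- W
  params$trans$b$b1 <- matrix(c(0, rep(0, d),
                                softplus_inv(ssm$q_var - VAR_FLOOR)), 1L)
  We <- matrix(0, d, 2L * p)
  We[, seq_len(p)] <- t(ssm$C)
  params$emit$W$W1 <- We
  params$emit$b$b1 <- matrix(c(rep(0, p),
                               softplus_inv(ssm$r_var - VAR_FLOOR)), 1L)
  params$prior$mu <- matrix(ssm$mu0, 1L)
  params$prior$rho <- matrix(softplus_inv(ssm$p0_var - VAR_FLOOR), 1L)
  params
}

#' Kalman filter for a linear-Gaussian state-space instance
#'
#' Exact filtering recursions (predict and correct) with the log-likelihood
#' from the prediction-error decomposition. Used as the closed-form reference
#' when assessing the learned combiner filter; it is not on the package's
#' neural filtering path.
#'
#' @param ssm an \code{ssm_instance} (its matrices; \code{y} may be
#'   overridden).
#' @param y optional (T+1) x obs_dim observation matrix.
#' @return List with filtered means \code{mu} ((T+1) x d), filtered variances
#'   \code{P} (list of d x d matrices), and \code{loglik}.
#' @export
kalman_filter <- function(ssm, y = NULL) {
  if (is.null(y)) y <- ssm$y
  d <- length(ssm$a)
  A <- diag(ssm$a, d, d)
  Q <- diag(ssm$q_var, d, d)
  C <- ssm$C
  R <- diag(ssm$r_var, nrow(C), nrow(C))
  n <- nrow(y)
  mu <- matrix(0, n, d)
  P <- vector("list", n)
  loglik <- 0
  m_pred <- ssm$mu0
  P_pred <- diag(ssm$p0_var, d, d)
  for (t in seq_len(n)) {
    if (t > 1L) {
      m_pred <- A %*% m_prev
      P_pred <- A %*% P_prev %*% t(A) + Q
    }
    S <- C %*% P_pred %*% t(C) + R
    innov <- y[t, ] - C %*% m_pred
    K <- P_pred %*% t(C) %*% solve(S)
    m_prev <- m_pred + K %*% innov
    P_prev <- P_pred - K %*% C %*% P_pred
    loglik <- loglik - 0.5 * (length(innov) * log(2 * pi) +
                              determinant(S, logarithm = TRUE)$modulus[1] +
                              t(innov) %*% solve(S, innov))
    mu[t, ] <- m_prev
    P[[t]] <- P_prev
  }
  list(mu = mu, P = P, loglik = as.numeric(loglik))
}
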