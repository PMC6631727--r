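# End-to-end orchestration: load or simulate recordings, scale, window,
# train both stages, filter, fit the latent density, and evaluate against
# the IPCA baseline.

#' Default pipeline configuration
#'
#' @return Named list of every tunable consumed by
#'   \code{\link{run_full_pipeline}}: cohort size, network sizes, epochs per
#'   stage, batch size (64), fold count (5), emitter family, density mass
#'   level and the master seed.
#' @export
pipeline_config <- function() {
  list(
    simulate = TRUE, n_subjects = 2L, recordings_per_subject = 5L,
    motions = "walk", duration = 20, rate = 30,
    latent_dim = 2L, mixture_K = 1L, hidden = c(16L, 16L), rnn_hidden = 16L,
    emitter_family = "gaussian", batch_size = 64L,
    epochs1 = 5L, epochs2 = 5L, lr1 = 1e-3, lr2 = 1e-3,
    subseq_len = 100L, stride = 50L, k = 5L,
    density_mass = 0.95, density_iter = 200L,
    seed = 1L, input_dir = NULL, output_dir = "ldmf-output"
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  stopifnot(cfg$latent_dim >= 1, cfg$k >= 2, cfg$batch_size >= 1)
  cfg
}

pipe_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Write / read a cohort directory
#'
#' A cohort directory holds one CSV per recording (the dialect of
#' \code{\link{read_sensor_log}}) plus a YAML manifest naming subject,
#' motion and recording index for each file.
#'
#' @param cohort list with \code{recordings} (see
#'   \code{\link{generate_cohort}}).
#' @param dir directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    fn <- sprintf("%s_%s_%02d.csv", r$subject_id, r$motion,
                  r$recording %||% i)
    write_sensor_log(r, file.path(dir, fn))
    entries[[length(entries) + 1L]] <- list(
      file = fn, subject = r$subject_id, motion = r$motion,
      recording = r$recording %||% i, rate = r$sampling_rate)
  }
  yaml::write_yaml(list(recordings = entries), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir)
  man <- yaml::read_yaml(mf)
  recordings <- lapply(man$recordings, function(e) {
    s <- read_sensor_log(file.path(dir, e$file),
                         sampling_rate = e$rate %||% 30,
                         subject_id = e$subject, motion = e$motion)
    s$recording <- e$recording
    s
  })
  list(recordings = recordings)
}

#' Run the full training-and-evaluation pipeline
#'
#' Executes, in order: load (or simulate) recordings; fit and save the
#' min-max scaling; window every recording; per-subject cross-validated
#' two-stage training with the IPCA comparison; a pooled two-stage fit on
#' all recordings; causal filtering of every recording to latent-trajectory
#' CSVs; continuous-flow density fitting on the pooled filtered means and a
#' thresholded normal region. Every random draw derives from
#' \code{config$seed}.
#'
#' @param config list or path to a YAML file; see
#'   \code{\link{pipeline_config}} for keys and defaults.
#' @return (Invisibly) the output directory, which contains
#'   \code{scaling.yaml}, \code{eval_report.csv}, \code{eval_summary.csv},
#'   \code{checkpoint.rds}, \code{latents/*.csv}, \code{density_grid.csv}
#'   and \code{region.yaml}.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)

  if (!is.null(cfg$input_dir)) {
    pipe_log("load", paste("reading cohort from", cfg$input_dir))
    cohort <- read_cohort(cfg$input_dir)
  } else if (isTRUE(cfg$simulate)) {
    pipe_log("simulate", sprintf("%d subjects x %d recordings (%s)",
                                 cfg$n_subjects, cfg$recordings_per_subject,
                                 paste(cfg$motions, collapse = "+")))
    cohort <- generate_cohort(cfg$n_subjects, cfg$recordings_per_subject,
                              seed = cfg$seed, motions = cfg$motions,
                              duration = cfg$duration, rate = cfg$rate)
  } else {
    stop("no input_dir given and simulate is FALSE")
  }

  pipe_log("scale", "fitting cohort min-max interval")
  spec <- fit_minmax(cohort$recordings)
  write_minmax(spec, out("scaling.yaml"))

  obs <- lapply(cohort$recordings, build_observations, spec = spec)

  pipe_log("evaluate", "cross-validated two-stage training vs IPCA")
  report <- run_cross_validation(cohort, list(
    latent_dim = cfg$latent_dim, mixture_K = cfg$mixture_K,
    hidden = cfg$hidden, rnn_hidden = cfg$rnn_hidden,
    batch_size = cfg$batch_size, epochs1 = cfg$epochs1,
    epochs2 = cfg$epochs2, lr1 = cfg$lr1, lr2 = cfg$lr2,
    subseq_len = cfg$subseq_len, stride = cfg$stride, k = cfg$k,
    seed = cfg$seed))
  utils::write.csv(report, out("eval_report.csv"), row.names = FALSE)
  smry <- summarize_cv(report)
  utils::write.csv(smry$by_subject, out("eval_summary.csv"), row.names = FALSE)

  pipe_log("train", "pooled two-stage fit on all recordings")
  fit <- ldmf(obs, latent_dim = cfg$latent_dim, mixture_K = cfg$mixture_K,
              hidden = cfg$hidden, rnn_hidden = cfg$rnn_hidden,
              emitter_family = cfg$emitter_family,
              epochs = c(cfg$epochs1, cfg$epochs2), lr = c(cfg$lr1, cfg$lr2),
              batch_size = cfg$batch_size, subseq_len = cfg$subseq_len,
              stride = cfg$stride, seed = cfg$seed, scaling = spec)
  saveRDS(fit, out("checkpoint.rds"))

  pipe_log("filter", "latent trajectories for every recording")
  dir.create(out("latents"), showWarnings = FALSE)
  lat_all <- list()
  for (i in seq_along(obs)) {
    traj <- filter_sequence(obs[[i]], fit$params, fit$combiner)
    d <- ncol(traj$mu)
    df <- data.frame(t = seq_len(nrow(traj$mu)) - 1L, traj$mu, traj$var)
    names(df) <- c("t", paste0("mu_", seq_len(d)), paste0("var_", seq_len(d)))
    r <- cohort$recordings[[i]]
    utils::write.csv(df, out("latents", sprintf("%s_%s_%02d.csv",
                                                r$subject_id, r$motion,
                                                r$recording %||% i)),
                     row.names = FALSE)
    lat_all[[i]] <- traj$mu
  }

  pipe_log("density", "continuous-flow fit on pooled filtered means")
  lat <- do.call(rbind, lat_all)
  dm <- fit_density(lat, list(n_iter = cfg$density_iter, seed = cfg$seed))
  region <- normal_region(dm, cfg$density_mass, seed = cfg$seed)
  if (fit$params$latent_dim == 2L) {
    utils::write.csv(density_grid(dm, lim = max(abs(lat)) + 2, n = 60L),
                     out("density_grid.csv"), row.names = FALSE)
  }
  yaml::write_yaml(list(mass = region$mass, threshold = region$c),
                   out("region.yaml"))
  saveRDS(dm, out("density.rds"))

  pipe_log("done", cfg$output_dir)
  invisible(cfg$output_dir)
}
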