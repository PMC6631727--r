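# Sensor-log parsing, magnitudes, scaling, windowing and fold splitting.

test_that("magnitudes are Euclidean norms of the component triples", {
  expect_equal(compute_magnitudes(c(3, 4, 0), c(0, 0, 0)),
               list(omega_T = 5, A_T = 0))
  expect_equal(compute_magnitudes(c(0, 0, 0), c(0, 0, 0)),
               list(omega_T = 0, A_T = 0))
  # sqrt(0.09 + 0.16 + 1.44) = 1.3
  expect_close(compute_magnitudes(c(0.3, 0.4, 1.2), c(1, 2, 2))$omega_T, 1.3,
               tol = 1e-12)
  expect_close(compute_magnitudes(c(0.3, 0.4, 1.2), c(1, 2, 2))$A_T, 3,
               tol = 1e-12)
})

test_that("read_sensor_log parses the CSV dialect and validates it", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = 0:2 / 30, wx = 0, wy = 0, wz = 0, ax = 0, ay = 0, az = 0)
  write.csv(df, f, row.names = FALSE)
  s <- read_sensor_log(f)
  expect_s3_class(s, "feature_sequence")
  expect_equal(nrow(s$frames), 3L)
  expect_true(all(as.matrix(s$frames[ldmf:::ldmf_features]) == 0))

  df2 <- df; df2$wx <- 3; df2$wy <- 4
  write.csv(df2, f, row.names = FALSE)
  s2 <- read_sensor_log(f)
  expect_equal(s2$frames$wT, rep(5, 3))
  expect_equal(s2$frames$aT, rep(0, 3))

  write.csv(df[, -2], f, row.names = FALSE)
  expect_error(read_sensor_log(f), "missing channel")

  df3 <- df; df3$t <- c(0, 2, 1)
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_sensor_log(f), "strictly increasing")
})

test_that("a 60 s log at 30 Hz round-trips as 1800 frames", {
  set.seed(1)
  prof <- draw_subject_profile("S1")
  s <- generate_subject_sequence(prof, "walk", duration = 60, rate = 30,
                                 seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(s, f)
  s2 <- read_sensor_log(f)
  expect_equal(nrow(s2$frames), 1800L)
  expect_close(as.matrix(s2$frames), as.matrix(s$frames), tol = 1e-9)
})

test_that("min-max scaling covers the cohort envelope and round-trips", {
  mk <- function(vals) {
    n <- length(vals)
    feature_sequence(data.frame(t = seq_len(n), wx = vals, wy = 1:n,
                                ax = -vals, ay = 0:(n - 1), az = 2 * vals + 1,
                                wz = vals + 2))
  }
  s1 <- mk(c(0, 1, 0.5)); s2 <- mk(c(-1, 2, 0))
  spec <- fit_minmax(list(s1, s2))
  expect_s3_class(spec, "minmax_spec")
  expect_equal(spec$min[spec$feature == "wx"], -1)
  expect_equal(spec$max[spec$feature == "wx"], 2)

  # brute-force elementwise oracle over a random 4-sequence cohort
  set.seed(9)
  cohort <- lapply(1:4, function(i) {
    generate_subject_sequence(draw_subject_profile(paste0("S", i)), "walk",
                              duration = 2, seed = i)
  })
  spec2 <- fit_minmax(cohort)
  X <- do.call(rbind, lapply(cohort, ldmf:::feature_matrix))
  for (j in 1:8) {
    expect_equal(spec2$min[j], min(X[, j]))
    expect_equal(spec2$max[j], max(X[, j]))
  }

  # constant feature is degenerate
  sc <- feature_sequence(data.frame(t = 1:3, wx = 1:3, wy = 1:3, wz = 1:3,
                                    ax = 1:3, ay = 1:3, az = 5))
  expect_error(fit_minmax(sc), "degenerate")

  # endpoints, midpoint, clipping, inverse
  sp <- spec2
  v_min <- apply_minmax(matrix(sp$min, 1), sp)
  v_max <- apply_minmax(matrix(sp$max, 1), sp)
  v_mid <- apply_minmax(matrix((sp$min + sp$max) / 2, 1), sp)
  expect_close(v_min, rep(0, 8), tol = 1e-12)
  expect_close(v_max, rep(1, 8), tol = 1e-12)
  expect_close(v_mid, rep(0.5, 8), tol = 1e-12)
  out_of_range <- apply_minmax(matrix(sp$max + 10, 1), sp)
  expect_equal(as.numeric(out_of_range), rep(1, 8))

  Z <- apply_minmax(X, sp)
  expect_close(invert_minmax(Z, sp), X, tol = 1e-9)

  # YAML round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  write_minmax(sp, f)
  sp2 <- read_minmax(f)
  expect_equal(sp$min, sp2$min)
  expect_equal(sp$max, sp2$max)
})

test_that("observation windows stack three scaled frames", {
  set.seed(4)
  s <- generate_subject_sequence(draw_subject_profile("S1"), "walk",
                                 duration = 1, seed = 5)
  spec <- fit_minmax(s)
  y <- build_observations(s, spec)
  expect_equal(ncol(y), 24L)
  expect_equal(nrow(y), nrow(s$frames) - 2L)
  X <- apply_minmax(s, spec)
  expect_close(y[1, ], c(X[3, ], X[2, ], X[1, ]), tol = 1e-12)
  # consecutive windows share 16 of 24 entries
  for (t in 2:nrow(y)) {
    expect_identical(unname(y[t, 9:24]), unname(y[t - 1, 1:16]))
  }
  # five frames give three windows; two frames are insufficient
  s5 <- s; s5$frames <- s5$frames[1:5, ]
  expect_equal(nrow(build_observations(s5, spec)), 3L)
  s2 <- s; s2$frames <- s2$frames[1:2, ]
  expect_error(build_observations(s2, spec), "insufficient")
})

test_that("consecutive k-fold split is disjoint, exhaustive and sized", {
  f <- kfold_split(100, 5)
  expect_length(f, 5L)
  for (fd in f) expect_length(fd$test_indices, 20L)

  f10 <- kfold_split(10, 5)
  expect_true(all(vapply(f10, function(x) length(x$test_indices), 1L) == 2L))

  # consecutive-fold convention: the first n %% k folds hold one extra index
  f7 <- kfold_split(7, 5)
  expect_equal(vapply(f7, function(x) length(x$test_indices), 1L),
               c(2L, 2L, 1L, 1L, 1L))

  expect_error(kfold_split(4, 5), "cannot split")

  for (n in c(7, 23, 100)) {
    f <- kfold_split(n, 5)
    tests <- lapply(f, `[[`, "test_indices")
    expect_equal(sort(unlist(tests)), 1:n)
    expect_equal(sum(lengths(tests)), n) # disjoint + exhaustive
    for (fd in f) {
      expect_equal(sort(c(fd$train_indices, fd$test_indices)), 1:n)
      # consecutive
      expect_equal(fd$test_indices, seq(min(fd$test_indices),
                                        max(fd$test_indices)))
    }
  }
})

test_that("shipped subject profile table has 20 rows with known averages", {
  prof <- read_subject_profiles()
  expect_equal(nrow(prof), 20L)
  expect_equal(sum(prof$gender == "Male"), 10L)
  expect_equal(sum(prof$gender == "Female"), 10L)
  expect_equal(mean(prof$age_yr), 33.85)
  expect_equal(mean(prof$height_cm), 167.15)
})
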