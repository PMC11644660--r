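# Small deterministic fixture: a cohort plus per-subject video features
# extracted from synthetic traces at each subject's reference heart rate.
make_fixture <- function(n = 40, duration = 20, trace_noise = 0.003,
                         cohort = cohort_spec(n_subjects = n, seed = 101),
                         seed0 = 500) {
  co <- sample_cohort(cohort)
  feats <- purrr::map_dfr(seq_len(n), function(i) {
    tr <- synth_rgb_trace(trace_spec(duration = duration,
                                     hr = co$hr_reference[i],
                                     noise_sd = trace_noise,
                                     seed = seed0 + i))
    dplyr::bind_cols(tibble::tibble(subject_id = co$subject_id[i]),
                     extract_features(bandpass(pos_project(tr))))
  })
  list(cohort = co, features = feats)
}

fx <- make_fixture()

test_that("BMI derivation matches hand arithmetic and validates inputs", {
  expect_equal(derive_bmi(70, 175), 70 / 1.75^2)
  expect_equal(round(derive_bmi(70, 175), 3), 22.857)
  expect_equal(derive_bmi(55, 100), 55)
  expect_error(derive_bmi(0, 170), "positive")
  expect_error(derive_bmi(70, -2), "positive")
})

test_that("the feature table carries the expected modality columns", {
  video <- assemble_table(fx$features, fx$cohort, video = TRUE, physical = FALSE)
  phys <- assemble_table(fx$features, fx$cohort, video = FALSE, physical = TRUE)
  both <- assemble_table(fx$features, fx$cohort)
  n_pred <- function(t) ncol(t) - 2L  # minus subject_id and hr_reference
  expect_equal(n_pred(video), 11)
  expect_equal(n_pred(phys), 5)
  expect_equal(n_pred(both), 16)
  expect_setequal(setdiff(names(phys), c("subject_id", "hr_reference")),
                  c("age", "gender_code", "height", "weight", "bmi"))
  expect_true(all(both$gender_code %in% c(0, 1)))
  expect_equal(both$bmi, derive_bmi(fx$cohort$weight, fx$cohort$height))
  expect_error(assemble_table(fx$features[-1, ], fx$cohort), "ids")
})

test_that("error metrics reproduce hand-computed values", {
  y <- c(100, 50); yh <- c(90, 60)
  m <- compute_metrics(y, yh)
  expect_equal(m$mae, 10)
  expect_equal(m$rmse, 10)
  expect_equal(m$mape, 15)

  m2 <- compute_metrics(c(80), c(76))
  expect_equal(unlist(m2), c(mae = 4, rmse = 4, mape = 5))

  ident <- compute_metrics(c(70, 80, 90), c(70, 80, 90))
  expect_equal(unlist(ident), c(mae = 0, rmse = 0, mape = 0))

  expect_error(compute_metrics(c(0, 1), c(1, 1)), "undefined")

  # RMSE >= MAE always; metrics are permutation invariant
  set.seed(9)
  for (i in 1:20) {
    y <- runif(15, 50, 100); yh <- y + rnorm(15, 0, 5)
    m <- compute_metrics(y, yh)
    expect_gte(m$rmse, m$mae)
    p <- sample(15)
    expect_equal(compute_metrics(y[p], yh[p]), m)
  }
})

test_that("fold partitions are disjoint, exhaustive and seed-reproducible", {
  f1 <- make_folds(60, k = 5, seed = 4)
  f2 <- make_folds(60, k = 5, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  expect_equal(as.vector(table(f1)), rep(12, 5))
  expect_false(identical(make_folds(60, 5, seed = 5), f1))
  expect_error(make_folds(3, k = 5), "folds")
})

test_that("grid search selects within the declared grids and is deterministic", {
  tab <- assemble_table(fx$features, fx$cohort)
  cv_rf <- run_grid_search_cv(tab, "rf", seed = 7)
  expect_true(nrow(dplyr::semi_join(cv_rf$best_params, rf_grid(),
                                    by = names(rf_grid()))) == 1)
  cv_svr <- run_grid_search_cv(tab, "svr", seed = 7)
  expect_true(nrow(dplyr::semi_join(cv_svr$best_params, svr_grid(),
                                    by = names(svr_grid()))) == 1)

  # fixed seed: identical folds, selection and metrics on a repeated run
  cv_rf2 <- run_grid_search_cv(tab, "rf", seed = 7)
  expect_identical(cv_rf$folds, cv_rf2$folds)
  expect_identical(cv_rf$best_params, cv_rf2$best_params)
  expect_equal(cv_rf$metrics, cv_rf2$metrics)

  # report invariants
  expect_gte(cv_rf$metrics$rmse, cv_rf$metrics$mae)
  expect_equal(nrow(tidy(cv_rf)), nrow(rf_grid()))
  expect_equal(sum(tidy(cv_rf)$selected), 1)
  expect_equal(nrow(glance(cv_rf)), 1)
})

test_that("the forest recovers a known linear generative model", {
  set.seed(42)
  n <- 200
  bmi <- runif(n, 18, 35)
  tab <- tibble::tibble(
    subject_id = sprintf("T%03d", 1:n),
    bmi = bmi,
    filler = rnorm(n),
    hr_reference = 2 * bmi + rnorm(n, 0, 0.5)
  )
  cv <- run_grid_search_cv(tab, "rf",
                           grid = rf_grid(n_trees = 200, max_depth = NA,
                                          min_samples_split = c(2, 5)),
                           seed = 3)
  expect_lt(cv$metrics$mae, 1.5)
})

test_that("the ablation study produces the six-row method-by-modality table", {
  small_rf <- rf_grid(n_trees = 100, max_depth = c(NA, 10), min_samples_split = 2)
  small_svr <- svr_grid(C = c(1, 10), gamma = 1, epsilon = 0.1)
  ab <- ablation_study(fx$features, fx$cohort, seed = 2,
                       rf_grid = small_rf, svr_grid = small_svr)
  expect_equal(nrow(ab), 6)
  expect_equal(ab$method, rep(c("rf", "svr"), each = 3))
  expect_equal(ab$video, rep(c(TRUE, FALSE, TRUE), 2))
  expect_equal(ab$physical, rep(c(FALSE, TRUE, TRUE), 2))
  expect_true(all(ab$rmse >= ab$mae))
  td <- tidy(ab)
  expect_named(td, c("index", "method", "video", "physical",
                     "mae", "rmse", "mape", "hyperparameters"))
})

test_that("feature importances are normalized and find a planted signal", {
  set.seed(11)
  n <- 150
  tab <- tibble::tibble(
    subject_id = sprintf("T%03d", 1:n),
    signal = runif(n, 0, 10),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  tab$hr_reference <- 60 + 4 * tab$signal + rnorm(n, 0, 0.5)
  cv <- run_grid_search_cv(tab, "rf",
                           grid = rf_grid(100, NA, 2), seed = 5)
  imp <- feature_importance(cv)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$feature[1], "signal")

  # the permutation variant agrees on the dominant feature
  pimp <- permutation_importance(cv, seed = 1)
  expect_equal(pimp$feature[1], "signal")

  expect_error(feature_importance(run_grid_search_cv(
    tab, "svr", grid = svr_grid(C = 1, gamma = 1, epsilon = 0.1), seed = 1
  )), "random forest")
})

test_that("partial dependence reflects the model's functional form", {
  tab <- assemble_table(fx$features, fx$cohort)
  cv <- run_grid_search_cv(tab, "rf", grid = rf_grid(50, NA, 2), seed = 1)

  # exact linear response: the PDP is the line itself
  cv_lin <- cv
  cv_lin$predict_fn <- function(d) 2 * d$bmi + 1
  pd <- partial_dependence(cv_lin, "bmi", grid_points = 15)
  expect_equal(nrow(pd), 15)
  slope <- diff(pd$prediction) / diff(pd$value)
  expect_equal(slope, rep(2, 14))

  # constant model: flat curve
  cv_const <- cv
  cv_const$predict_fn <- function(d) rep(72, nrow(d))
  pd2 <- partial_dependence(cv_const, "age", grid_points = 8)
  expect_equal(pd2$prediction, rep(72, 8))

  expect_error(partial_dependence(cv, "not_a_feature"), "unknown")
})

test_that("the baseline comparison has the expected rows and clean-signal accuracy", {
  co <- sample_cohort(cohort_spec(n_subjects = 8, seed = 33))
  traces <- lapply(seq_len(8), function(i) {
    synth_rgb_trace(trace_spec(duration = 30, hr = co$hr_reference[i],
                               noise_sd = 0, drift_amplitude = 0, seed = 600 + i))
  })
  res <- compare_baselines(traces, co, seed = 1, include_models = FALSE)
  expect_setequal(res$method, c("green+fft", "ica+fft", "chrom+fft", "pos+fft"))
  expect_true(all(res$mae <= 2))

  res_full <- compare_baselines(traces, co, seed = 1, include_models = TRUE,
                                rf_grid = rf_grid(50, NA, 2), k = 4)
  expect_setequal(res_full$method,
                  c("green+fft", "ica+fft", "chrom+fft", "pos+fft",
                    "rf+video", "rf+multimodal"))
})
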