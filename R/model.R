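#' Body mass index from weight and height
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' derive_bmi(70, 175)  # 22.857
#' @export
derive_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight / (height / 100)^2
}

PHYSICAL_FEATURE_NAMES <- c("age", "gender_code", "height", "weight", "bmi")

#' Assemble the multimodal feature table
#'
#' Joins per-subject video signal features with physical attributes into
#' the regression table. Gender is encoded male = 0, female = 1; BMI is
#' recomputed from height and weight so the column is always consistent.
#'
#' @param features A data frame with `subject_id` plus the eleven signal
#'   feature columns (see [extract_features()]).
#' @param attrs A data frame with `subject_id`, `age`, `gender`, `height`,
#'   `weight` and `hr_reference` (e.g. a [sample_cohort()] output).
#' @param video,physical Logical modality flags: include the video feature
#'   block and/or the physical attribute block.
#' @return A tibble with `subject_id`, the selected predictor columns and
#'   the `hr_reference` target.
#' @export
assemble_table <- function(features, attrs, video = TRUE, physical = TRUE) {
  if (!video && !physical) stop("at least one modality must be included", call. = FALSE)
  if (!all(c("subject_id", SIGNAL_FEATURE_NAMES) %in% names(features))) {
    stop("`features` must contain subject_id and the 11 signal feature columns",
         call. = FALSE)
  }
  need <- c("subject_id", "age", "gender", "height", "weight", "hr_reference")
  if (!all(need %in% names(attrs))) {
    stop("`attrs` must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!setequal(features$subject_id, attrs$subject_id)) {
    stop("subject ids in `features` and `attrs` do not match", call. = FALSE)
  }
  tab <- dplyr::inner_join(features, attrs, by = "subject_id") |>
    dplyr::mutate(
      gender_code = ifelse(.data$gender == "female", 1, 0),
      bmi = derive_bmi(.data$weight, .data$height)
    )
  cols <- c(
    if (video) SIGNAL_FEATURE_NAMES,
    if (physical) PHYSICAL_FEATURE_NAMES
  )
  out <- dplyr::select(tab, "subject_id", dplyr::all_of(cols), "hr_reference")
  if (anyNA(out)) stop("feature table contains missing values", call. = FALSE)
  out
}

#' Regression error metrics
#'
#' Mean absolute error, root mean squared error and mean absolute
#' percentage error (in percent) between observed and predicted values.
#'
#' @param y Observed values (strictly positive for MAPE).
#' @param y_hat Predicted values, same length.
#' @return A one-row tibble: `mae`, `rmse`, `mape` (percent).
#' @examples
#' compute_metrics(c(100, 50), c(90, 60))  # mae 10, rmse 10, mape 15
#' @export
compute_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1L) {
    stop("`y` and `y_hat` must be equal-length, nonempty", call. = FALSE)
  }
  if (any(y == 0)) stop("MAPE is undefined when any observed value is zero", call. = FALSE)
  err <- y - y_hat
  tibble::tibble(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err) / abs(y))
  )
}

#' Hyperparameter grids
#'
#' The default search grids: for support-vector regression, kernel in
#' \{linear, rbf\}, `C` and `gamma` in \{0.01, 0.1, 1, 10, 100\} and
#' `epsilon` in \{0.001, 0.01, 0.1, 1, 10\} (`gamma` is inapplicable to the
#' linear kernel and collapsed there); for random forests, 50/100/200
#' trees, max depth none/5/10/20 and minimum samples per split
#' 2/5/10/20. Rows are in canonical order; grid-search ties resolve to the
#' first row.
#'
#' @param C,gamma,epsilon,kernel SVR grid values.
#' @return A tibble, one row per configuration.
#' @export
svr_grid <- function(kernel = c("linear", "rbf"),
                     C = c(0.01, 0.1, 1, 10, 100),
                     gamma = c(0.01, 0.1, 1, 10, 100),
                     epsilon = c(0.001, 0.01, 0.1, 1, 10)) {
  g <- tidyr::expand_grid(kernel = kernel, C = C, gamma = gamma, epsilon = epsilon)
  # gamma plays no role in the linear kernel: collapse to a single NA entry
  lin <- g$kernel == "linear"
  g$gamma[lin] <- NA_real_
  dplyr::distinct(g)
}

#' @rdname svr_grid
#' @param n_trees,max_depth,min_samples_split Random-forest grid values
#'   (`NA` depth means unlimited).
#' @export
rf_grid <- function(n_trees = c(50, 100, 200),
                    max_depth = c(NA, 5, 10, 20),
                    min_samples_split = c(2, 5, 10, 20)) {
  tidyr::expand_grid(n_trees = n_trees, max_depth = max_depth,
                     min_samples_split = min_samples_split)
}

.predictor_names <- function(table) {
  setdiff(names(table), c("subject_id", "hr_reference"))
}

# Fit one model on `train` and return a prediction closure; handles the
# z-score standardization SVR needs (training-fold statistics only).
.fit_model <- function(train, model, params, seed) {
  preds <- .predictor_names(train)
  if (model == "rf") {
    fit <- ranger::ranger(
      x = as.data.frame(train[preds]), y = train$hr_reference,
      num.trees = params$n_trees,
      max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
      min.node.size = params$min_samples_split,
      importance = "impurity",
      seed = seed, num.threads = 1
    )
    predict_fn <- function(newdata) {
      stats::predict(fit, data = as.data.frame(newdata[preds]),
                     num.threads = 1)$predictions
    }
  } else {
    mu <- vapply(train[preds], mean, numeric(1))
    sigma <- vapply(train[preds], stats::sd, numeric(1))
    sigma[sigma == 0 | is.na(sigma)] <- 1
    scale_x <- function(d) {
      scale(as.matrix(d[preds]), center = mu, scale = sigma)
    }
    svm_args <- list(
      x = scale_x(train), y = train$hr_reference,
      type = "eps-regression", scale = FALSE, fitted = FALSE,
      kernel = if (params$kernel == "rbf") "radial" else "linear",
      cost = params$C, epsilon = params$epsilon
    )
    if (params$kernel == "rbf") svm_args$gamma <- params$gamma
    fit <- do.call(e1071::svm, svm_args)
    y_mean <- mean(train$hr_reference)
    predict_fn <- function(newdata) {
      # an epsilon tube wide enough to cover the data leaves no support
      # vectors; such a model predicts the training mean
      if (fit$tot.nSV == 0L) return(rep(y_mean, nrow(newdata)))
      as.numeric(stats::predict(fit, scale_x(newdata)))
    }
  }
  list(fit = fit, predict_fn = predict_fn, model = model, params = params)
}

#' Seeded k-fold partition
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An integer vector of fold labels in `1..k`; folds are disjoint,
#'   exhaustive and of near-equal size.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (k > n) stop("more folds than rows", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Grid-searched regression under k-fold cross-validation
#'
#' For every grid configuration, fits the model on each of `k` seeded folds'
#' training portions and scores the held-out fold; the configuration with
#' the lowest mean cross-validated MAE (ties: first in canonical grid
#' order) is selected and its fold-averaged MAE/RMSE/MAPE reported. A final
#' model at the selected configuration is refit on all rows for
#' interpretability (importances, partial dependence).
#'
#' @param table An [assemble_table()] output (predictors + `hr_reference`).
#' @param model `"rf"` or `"svr"`.
#' @param grid A grid tibble ([rf_grid()] / [svr_grid()]); defaults by model.
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold partition and forest
#'   randomness.
#' @param select_metric Criterion minimized across the grid (`"mae"` or
#'   `"rmse"`).
#' @return An object of class `pulsemodal_cv`: a list with `metrics`
#'   (fold-averaged, at the selected configuration), `best_params`,
#'   `per_fold`, `grid_results`, `folds`, `fit`, `predict_fn`, `model`,
#'   `seed`. Supports [tidy()], [glance()] and [feature_importance()].
#' @export
run_grid_search_cv <- function(table, model = c("rf", "svr"), grid = NULL,
                               k = 5L, seed = 1L,
                               select_metric = c("mae", "rmse")) {
  model <- match.arg(model)
  select_metric <- match.arg(select_metric)
  if (is.null(grid)) grid <- if (model == "rf") rf_grid() else svr_grid()
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  n <- nrow(table)
  folds <- make_folds(n, k = k, seed = seed)

  fold_metrics <- function(params) {
    purrr::map_dfr(seq_len(k), function(fold) {
      tr <- table[folds != fold, , drop = FALSE]
      te <- table[folds == fold, , drop = FALSE]
      m <- .fit_model(tr, model, params, seed = seed)
      dplyr::bind_cols(tibble::tibble(fold = fold),
                       compute_metrics(te$hr_reference, m$predict_fn(te)))
    })
  }

  per_config <- purrr::map(seq_len(nrow(grid)), function(i) fold_metrics(grid[i, ]))
  grid_results <- dplyr::bind_cols(
    grid,
    purrr::map_dfr(per_config, function(pf) {
      tibble::tibble(mae = mean(pf$mae), rmse = mean(pf$rmse), mape = mean(pf$mape))
    })
  )
  best_i <- which.min(grid_results[[select_metric]])
  best_params <- grid[best_i, ]
  final <- .fit_model(table, model, best_params, seed = seed)

  structure(list(
    metrics = grid_results[best_i, c("mae", "rmse", "mape")],
    best_params = best_params,
    per_fold = per_config[[best_i]],
    grid_results = grid_results,
    folds = folds,
    fit = final$fit,
    predict_fn = final$predict_fn,
    predictors = .predictor_names(table),
    table = table,
    model = model, k = k, seed = seed,
    select_metric = select_metric
  ), class = "pulsemodal_cv")
}

#' @export
print.pulsemodal_cv <- function(x, ...) {
  cat(sprintf("<pulsemodal_cv: %s, %d-fold CV over %d configurations>\n",
              toupper(x$model), x$k, nrow(x$grid_results)))
  cat("  selected:", .format_params(x$best_params), "\n")
  cat(sprintf("  MAE %.3f  RMSE %.3f  MAPE %.2f%%\n",
              x$metrics$mae, x$metrics$rmse, x$metrics$mape))
  invisible(x)
}

.format_params <- function(p) {
  vals <- vapply(names(p), function(nm) {
    v <- p[[nm]]
    if (is.na(v)) paste0(nm, "=none") else paste0(nm, "=", format(v))
  }, character(1))
  paste(vals, collapse = ", ")
}

#' Modality ablation study
#'
#' Runs the grid-searched cross-validation for random forest and SVR under
#' three modality configurations each: video features only, physical
#' attributes only, and both. The six rows mirror the standard ablation
#' layout (method, modality flags, MAE/RMSE/MAPE, selected
#' hyperparameters).
#'
#' @param features,attrs As in [assemble_table()].
#' @param k,seed As in [run_grid_search_cv()].
#' @param rf_grid,svr_grid Grid tibbles; package defaults if omitted.
#' @return A tibble of class `pulsemodal_ablation` with columns `index`,
#'   `method`, `video`, `physical`, `mae`, `rmse`, `mape`,
#'   `hyperparameters` (string) and a `report` list-column of the
#'   underlying `pulsemodal_cv` objects.
#' @export
ablation_study <- function(features, attrs, k = 5L, seed = 1L,
                           rf_grid = pulsemodal::rf_grid(),
                           svr_grid = pulsemodal::svr_grid()) {
  configs <- tibble::tibble(
    index = 1:6,
    method = rep(c("rf", "svr"), each = 3),
    video = rep(c(TRUE, FALSE, TRUE), 2),
    physical = rep(c(FALSE, TRUE, TRUE), 2)
  )
  reports <- purrr::pmap(configs, function(index, method, video, physical) {
    tab <- assemble_table(features, attrs, video = video, physical = physical)
    run_grid_search_cv(tab, model = method,
                       grid = if (method == "rf") rf_grid else svr_grid,
                       k = k, seed = seed)
  })
  out <- dplyr::bind_cols(
    configs,
    purrr::map_dfr(reports, function(r) r$metrics),
    tibble::tibble(
      hyperparameters = vapply(reports, function(r) .format_params(r$best_params),
                               character(1)),
      report = I(reports)
    )
  )
  class(out) <- c("pulsemodal_ablation", class(out))
  out
}

#' Impurity-based feature importances
#'
#' Importances of a fitted random forest, normalized to sum to one and
#' sorted descending.
#'
#' @param x A `pulsemodal_cv` fitted with `model = "rf"` (or a `ranger`
#'   fit with impurity importances).
#' @return A tibble with columns `feature`, `importance`.
#' @export
feature_importance <- function(x) {
  fit <- if (inherits(x, "pulsemodal_cv")) x$fit else x
  if (!inherits(fit, "ranger") || is.null(fit$variable.importance) ||
      length(fit$variable.importance) == 0L) {
    stop("feature importances require a fitted random forest", call. = FALSE)
  }
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  tibble::tibble(feature = names(imp), importance = imp / sum(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Permutation feature importances
#'
#' Model-agnostic importance: the increase in MAE when one predictor
#' column is randomly permuted, averaged over `n_rep` permutations.
#'
#' @param x A `pulsemodal_cv`.
#' @param n_rep Permutations per feature.
#' @param seed Integer seed.
#' @return A tibble with columns `feature`, `delta_mae`, sorted descending.
#' @export
permutation_importance <- function(x, n_rep = 5L, seed = 1L) {
  stopifnot(inherits(x, "pulsemodal_cv"))
  tab <- x$table
  base <- compute_metrics(tab$hr_reference, x$predict_fn(tab))$mae
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  deltas <- vapply(x$predictors, function(f) {
    mean(vapply(seq_len(n_rep), function(r) {
      perm <- tab
      perm[[f]] <- sample(perm[[f]])
      compute_metrics(perm$hr_reference, x$predict_fn(perm))$mae - base
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(feature = x$predictors, delta_mae = deltas) |>
    dplyr::arrange(dplyr::desc(.data$delta_mae))
}

#' Partial dependence of one feature
#'
#' Sweeps a single predictor over a grid of values and, at each value,
#' averages the model prediction over the table with that predictor
#' overwritten — revealing how the model's output depends on the feature
#' with the others held at their observed joint distribution.
#'
#' @param x A `pulsemodal_cv`.
#' @param feature Predictor name.
#' @param grid_points Number of grid values (range of the observed data).
#' @return A tibble of class `pulsemodal_pdp` with columns `value`,
#'   `prediction`, length `grid_points`.
#' @export
partial_dependence <- function(x, feature, grid_points = 20L) {
  stopifnot(inherits(x, "pulsemodal_cv"))
  if (!feature %in% x$predictors) {
    stop(sprintf("unknown feature `%s`", feature), call. = FALSE)
  }
  rng <- range(x$table[[feature]])
  grid <- if (rng[1] == rng[2]) rep(rng[1], grid_points) else {
    seq(rng[1], rng[2], length.out = grid_points)
  }
  preds <- vapply(grid, function(v) {
    tab <- x$table
    tab[[feature]] <- v
    mean(x$predict_fn(tab))
  }, numeric(1))
  out <- tibble::tibble(value = grid, prediction = preds)
  attr(out, "feature") <- feature
  class(out) <- c("pulsemodal_pdp", class(out))
  out
}

#' Compare pulse-extraction baselines and learned models
#'
#' For each subject trace, estimates heart rate with the four
#' signal-processing pipelines (green / ICA / CHROM / POS, each followed by
#' the bandpass filter and FFT dominant-frequency estimate) and scores them
#' against the reference heart rates. Optionally adds the cross-validated
#' random-forest rows (video features only, and video + physical) for the
#' full comparison table.
#'
#' @param traces A list of [rgb_trace()], one per row of `attrs` (same
#'   order as `attrs$subject_id`).
#' @param attrs Cohort attribute tibble with `hr_reference`.
#' @param seed Integer seed (ICA, CV folds, forests).
#' @param methods Signal-only pipelines to include.
#' @param include_models Add the RF video-only and RF multimodal rows.
#' @param filter Bandpass applied to every extracted pulse.
#' @param rf_grid Grid for the RF rows.
#' @param k Folds for the RF rows.
#' @return A tibble with columns `method`, `mae`, `rmse`, `mape`.
#' @export
compare_baselines <- function(traces, attrs, seed = 1L,
                              methods = c("green", "ica", "chrom", "pos"),
                              include_models = TRUE,
                              filter = filter_spec(),
                              rf_grid = pulsemodal::rf_grid(), k = 5L) {
  stopifnot(length(traces) == nrow(attrs), nrow(attrs) >= 2L)
  y <- attrs$hr_reference

  rows <- purrr::map_dfr(methods, function(m) {
    est <- vapply(traces, function(tr) {
      estimate_hr(extract_pulse(tr, method = m, filter = filter, seed = seed),
                  band = filter)$bpm
    }, numeric(1))
    dplyr::bind_cols(tibble::tibble(method = paste0(m, "+fft")),
                     compute_metrics(y, est))
  })

  if (include_models) {
    feats <- purrr::map_dfr(seq_along(traces), function(i) {
      p <- extract_pulse(traces[[i]], method = "pos", filter = filter)
      dplyr::bind_cols(tibble::tibble(subject_id = attrs$subject_id[i]),
                       extract_features(p))
    })
    for (phys in c(FALSE, TRUE)) {
      tab <- assemble_table(feats, attrs, video = TRUE, physical = phys)
      cvr <- run_grid_search_cv(tab, model = "rf", grid = rf_grid, k = k, seed = seed)
      rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
        tibble::tibble(method = if (phys) "rf+multimodal" else "rf+video"),
        cvr$metrics
      ))
    }
  }
  rows
}
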