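#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validated model
#'
#' @param x A `pulsemodal_cv`.
#' @param ... Unused.
#' @return One row per grid configuration with its fold-averaged metrics
#'   and a `selected` flag.
#' @method tidy pulsemodal_cv
#' @export
tidy.pulsemodal_cv <- function(x, ...) {
  out <- x$grid_results
  best_i <- which.min(out[[x$select_metric]])
  out$selected <- seq_len(nrow(out)) == best_i
  out
}

#' @rdname tidy.pulsemodal_cv
#' @return `glance()`: a one-row summary (model, folds, selected
#'   hyperparameters, MAE/RMSE/MAPE, seed).
#' @method glance pulsemodal_cv
#' @export
glance.pulsemodal_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model, k = x$k,
                   hyperparameters = .format_params(x$best_params)),
    x$metrics,
    tibble::tibble(seed = x$seed)
  )
}

#' Tidy an ablation study
#'
#' @param x A `pulsemodal_ablation`.
#' @param ... Unused.
#' @return The six-row metric table without the report list-column.
#' @method tidy pulsemodal_ablation
#' @export
tidy.pulsemodal_ablation <- function(x, ...) {
  tibble::as_tibble(x)[, c("index", "method", "video", "physical",
                           "mae", "rmse", "mape", "hyperparameters")]
}
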