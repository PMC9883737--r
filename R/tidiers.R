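# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x A `detector_model`, `feature_model` or `corrector_model`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @method tidy detector_model
#' @export
tidy.detector_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.detector_model
#' @method tidy feature_model
#' @export
tidy.feature_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.detector_model
#' @method tidy corrector_model
#' @export
tidy.corrector_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' Tidy a feature prediction into long form
#'
#' @param x A `feature_prediction`.
#' @param ... Unused.
#' @return A tibble with `feature`, `class`, `probability`.
#' @method tidy feature_prediction
#' @export
tidy.feature_prediction <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature = "shape", class = names(x$shape_probs),
                   probability = as.numeric(x$shape_probs)),
    tibble::tibble(feature = "color", class = names(x$color_probs),
                   probability = as.numeric(x$color_probs)),
    tibble::tibble(feature = "form", class = names(x$form_probs),
                   probability = as.numeric(x$form_probs))
  )
}

n_params <- function(params) sum(vapply(params, length, integer(1)))

#' One-row fit summaries
#'
#' @param x A fitted model object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance detector_model
#' @export
glance.detector_model <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss_history),
                 initial_loss = x$loss_history[1],
                 final_loss = utils::tail(x$loss_history, 1),
                 n_parameters = n_params(x$params))
}

#' @rdname glance.detector_model
#' @method glance feature_model
#' @export
glance.feature_model <- glance.detector_model

#' @rdname glance.detector_model
#' @method glance corrector_model
#' @export
glance.corrector_model <- glance.detector_model

#' @rdname glance.detector_model
#' @method glance pillid_evaluation
#' @export
glance.pillid_evaluation <- function(x, ...) {
  out <- tibble::tibble(n_queries = nrow(x$per_query))
  for (i in seq_len(nrow(x$metrics))) {
    out[[paste0("top", x$metrics$k[i])]] <- x$metrics$accuracy[i]
  }
  out
}
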