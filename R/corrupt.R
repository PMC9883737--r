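#' Detector-noise configuration
#'
#' Describes the corruption model used to emulate a real character detector's
#' failure modes on ground-truth boxes: visually confusable symbol swaps
#' (detectors habitually confuse letters with digits, `O` with `0`, `I` with
#' `1`), missed characters, coordinate jitter, and loss of reading order
#' (detector output carries no order semantics). The defaults are the
#' corruption benchmark used throughout the package: confusion 0.3, drop
#' 0.05, jitter 0.01 of the image size, shuffling on.
#'
#' @param confusion_rate Probability that an eligible character (one with a
#'   confusion partner) is replaced by its partner.
#' @param drop_rate Probability that a character is missed entirely.
#' @param coord_jitter_sd Standard deviation of Gaussian coordinate noise, as
#'   a fraction of the image extent.
#' @param shuffle Whether to scramble the output order.
#' @param seed Integer seed.
#' @param confusion_pairs List of length-2 character vectors of mutually
#'   confusable symbols (applied symmetrically).
#' @return A `noise_config` list.
#' @export
noise_config <- function(confusion_rate = 0.3,
                         drop_rate = 0.05,
                         coord_jitter_sd = 0.01,
                         shuffle = TRUE,
                         seed = 1L,
                         confusion_pairs = list(c("O", "0"), c("I", "1"),
                                                c("B", "8"), c("S", "5"),
                                                c("Z", "2"))) {
  for (p in list(confusion_rate, drop_rate)) {
    if (p < 0 || p > 1) stop("noise probabilities must lie in [0,1]", call. = FALSE)
  }
  stopifnot(coord_jitter_sd >= 0)
  structure(
    list(confusion_rate = confusion_rate, drop_rate = drop_rate,
         coord_jitter_sd = coord_jitter_sd, shuffle = isTRUE(shuffle),
         seed = as.integer(seed), confusion_pairs = confusion_pairs),
    class = "noise_config"
  )
}

confusion_map <- function(pairs) {
  map <- character(0)
  for (p in pairs) {
    map[p[1]] <- p[2]
    map[p[2]] <- p[1]
  }
  map
}

#' Corrupt ground-truth character boxes into noisy detections
#'
#' Applies the detector-noise model of a [noise_config()] to ground-truth
#' character boxes: each character survives with probability
#' `1 - drop_rate`; surviving characters with a confusion partner are swapped
#' with probability `confusion_rate`; coordinates receive Gaussian jitter and
#' are clamped to `[0,1]`; the order is scrambled when `shuffle` is set.
#' Deterministic given the config's seed.
#'
#' @param boxes A tibble of character boxes (`char` plus either
#'   `x_center`/`y_center` or `x`/`y` columns), e.g. the `boxes` of
#'   [render_pill()].
#' @param noise A [noise_config()].
#' @return A tibble of detections with columns `char`, `x`, `y`,
#'   `confidence`.
#' @export
corrupt_detections <- function(boxes, noise = noise_config()) {
  stopifnot(inherits(noise, "noise_config"))
  x <- if ("x" %in% names(boxes)) boxes$x else boxes$x_center
  y <- if ("y" %in% names(boxes)) boxes$y else boxes$y_center
  chars <- boxes$char
  n <- length(chars)
  empty <- tibble::tibble(char = character(0), x = numeric(0), y = numeric(0),
                          confidence = numeric(0))
  if (n == 0L) return(empty)
  withr::with_seed(noise$seed, {
    keep <- stats::runif(n) >= noise$drop_rate
    chars <- chars[keep]; x <- x[keep]; y <- y[keep]
    m <- length(chars)
    if (m == 0L) return(empty)
    map <- confusion_map(noise$confusion_pairs)
    eligible <- chars %in% names(map)
    swap <- eligible & stats::runif(m) < noise$confusion_rate
    chars[swap] <- unname(map[chars[swap]])
    x <- pmin(pmax(x + stats::rnorm(m, 0, noise$coord_jitter_sd), 0), 1)
    y <- pmin(pmax(y + stats::rnorm(m, 0, noise$coord_jitter_sd), 0), 1)
    conf <- stats::runif(m, 0.5, 1)
    ord <- if (noise$shuffle) sample.int(m) else seq_len(m)
    tibble::tibble(char = chars[ord], x = x[ord], y = y[ord],
                   confidence = conf[ord])
  })
}
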