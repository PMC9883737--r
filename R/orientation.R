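#' Rotate a pill image so its major axis is horizontal
#'
#' Reference photographs are taken at arbitrary angles, so before character
#' detection the pill is levelled: the foreground silhouette is segmented
#' against the neutral background, its second-moment (principal-axis)
#' orientation is computed, and the image is rotated so the major axis lies
#' horizontal. Near-circular silhouettes have no defined major axis: when the
#' square root of the moment-eigenvalue ratio is within `circular_tol` of 1
#' the image is returned unchanged with rotation 0.
#'
#' @param image An `h x w x 3` array in `[0,1]` containing one pill
#'   silhouette on the neutral rendering background.
#' @param background Background intensity used for segmentation.
#' @param circular_tol Axis-ratio tolerance below which the silhouette counts
#'   as circular.
#' @return A list with `image` (the levelled image) and `rotation_applied`
#'   (degrees, in `(-90, 90]`; the angle passed to [rotate_image()]).
#' @export
normalize_orientation <- function(image, background = 0.7,
                                  circular_tol = 0.05) {
  mask <- foreground_mask(image, background)
  if (!any(mask)) stop("no foreground silhouette found in image", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  yy <- idx[, 1]; xx <- idx[, 2]
  mx <- mean(xx); my <- mean(yy)
  mu20 <- mean((xx - mx)^2)
  mu02 <- mean((yy - my)^2)
  mu11 <- mean((xx - mx) * (yy - my))
  common <- sqrt(4 * mu11^2 + (mu20 - mu02)^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l2 <= 0 || sqrt(l1 / max(l2, 1e-12)) - 1 < circular_tol) {
    return(list(image = image, rotation_applied = 0))
  }
  # angle of the major axis in y-down pixel coordinates
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  deg <- -theta * 180 / pi
  if (deg <= -90) deg <- deg + 180
  if (deg > 90) deg <- deg - 180
  list(image = rotate_image(image, deg, fill = background),
       rotation_applied = deg)
}

foreground_mask <- function(image, background = 0.7, tol = 0.08) {
  d <- abs(image - background)
  (d[, , 1] > tol) | (d[, , 2] > tol) | (d[, , 3] > tol)
}

# Level a two-face reference image by normalizing each half independently.
normalize_reference <- function(image, background = 0.7) {
  h <- dim(image)[1]; w <- dim(image)[2]
  half <- w %/% 2
  left <- image[, seq_len(half), , drop = FALSE]
  right <- image[, (half + 1):w, , drop = FALSE]
  nl <- tryCatch(normalize_orientation(left, background),
                 error = function(e) list(image = left, rotation_applied = 0))
  nr <- tryCatch(normalize_orientation(right, background),
                 error = function(e) list(image = right, rotation_applied = 0))
  out <- image
  out[, seq_len(half), ] <- nl$image
  out[, (half + 1):w, ] <- nr$image
  list(image = out, rotation_front = nl$rotation_applied,
       rotation_back = nr$rotation_applied)
}
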