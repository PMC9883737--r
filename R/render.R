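# Synthetic reference-image renderer. A reference image shows the pill's
# front face on the left half and its back face on the right half, the way
# regulatory pill databases photograph one pill per record. Shapes are filled
# silhouettes on a neutral background; capsules are two-tone with the record
# colour as the dominant (larger) half; imprints are drawn with the built-in
# bitmap face so every character box is exact by construction.

.render_bg <- 0.7

pill_palette <- function() {
  list(
    "white"       = c(0.95, 0.95, 0.95),
    "yellow"      = c(0.95, 0.85, 0.20),
    "orange"      = c(0.95, 0.55, 0.15),
    "pink"        = c(0.95, 0.60, 0.70),
    "red"         = c(0.85, 0.15, 0.15),
    "brown"       = c(0.50, 0.30, 0.15),
    "light green" = c(0.60, 0.90, 0.55),
    "green"       = c(0.15, 0.60, 0.25),
    "cyan"        = c(0.30, 0.85, 0.90),
    "blue"        = c(0.20, 0.40, 0.85),
    "navy"        = c(0.10, 0.15, 0.45),
    "purple"      = c(0.55, 0.25, 0.70),
    "gray"        = c(0.52, 0.52, 0.52),
    "black"       = c(0.12, 0.12, 0.12),
    "violet"      = c(0.75, 0.50, 0.90),
    "transparent" = c(0.76, 0.83, 0.86)
  )
}

.mask_env <- new.env(parent = emptyenv())

# Logical size x size silhouette mask for one face (row = y down, col = x).
shape_mask <- function(shape, size) {
  key <- paste0(shape, "|", size)
  if (!is.null(.mask_env[[key]])) return(.mask_env[[key]])
  cc <- (seq_len(size) - 0.5) / size
  x <- matrix(cc, size, size, byrow = TRUE) - 0.5
  y <- matrix(cc, size, size, byrow = FALSE) - 0.5
  m <- switch(shape,
    round     = x^2 + y^2 <= 0.41^2,
    oval      = (x / 0.44)^2 + (y / 0.30)^2 <= 1,
    oblong    = {
      dx <- pmax(abs(x) - 0.20, 0); dy <- abs(y)
      dx^2 + dy^2 <= 0.24^2
    },
    triangle  = tri_mask(x, y, 0.46),
    square    = abs(x) <= 0.34 & abs(y) <= 0.34,
    rectangle = abs(x) <= 0.42 & abs(y) <= 0.28,
    diamond   = abs(x) + abs(y) <= 0.45,
    pentagon  = ngon_mask(x, y, 5L, 0.44),
    hexagon   = ngon_mask(x, y, 6L, 0.44),
    octagon   = ngon_mask(x, y, 8L, 0.43),
    others    = (x^2 + (y - 0.18)^2 <= 0.44^2) & y <= 0.18,  # semicircle dome
    stop("unknown shape '", shape, "'", call. = FALSE)
  )
  .mask_env[[key]] <- m
  m
}

tri_mask <- function(x, y, R) {
  # point-up triangle, base at the bottom
  v <- list(c(0, -R), c(R * sin(2 * pi / 3), -R * cos(2 * pi / 3)),
            c(-R * sin(2 * pi / 3), -R * cos(2 * pi / 3)))
  inside <- rep(TRUE, length(x))
  for (k in 1:3) {
    a <- v[[k]]; b <- v[[k %% 3 + 1]]
    inside <- inside & ((b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1]) >= 0)
  }
  matrix(inside, nrow(x), ncol(x))
}

ngon_mask <- function(x, y, n, R) {
  a <- R * cos(pi / n)
  inside <- rep(TRUE, length(x))
  for (k in seq_len(n)) {
    phi <- 2 * pi * (k - 0.5) / n
    inside <- inside & (x * cos(phi) + y * sin(phi) <= a)
  }
  matrix(inside, nrow(x), ncol(x))
}

# Longest horizontal interval of columns that are inside the mask for every
# row of the band [y0, y1] (1-based pixel rows). Returns c(start, end) or NULL.
usable_interval <- function(mask, y0, y1) {
  if (y0 < 1 || y1 > nrow(mask)) return(NULL)
  cols <- apply(mask[y0:y1, , drop = FALSE], 2, all)
  if (!any(cols)) return(NULL)
  r <- rle(cols)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(starts[best], ends[best])
}

# Place tokens on a face: contiguous rows, centered, row widths constrained
# by the silhouette's usable width at each row's vertical band. Returns a
# data frame of glyph placements (0-based pixel coords) or NULL on overflow.
layout_face <- function(tokens, mask, size, scale) {
  nt <- length(tokens)
  if (nt == 0L) {
    return(data.frame(token = character(0), x0 = numeric(0), y0 = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  widths <- vapply(tokens, function(t) glyph_size(t, scale)[["width"]], numeric(1))
  sp <- scale
  gh <- 7L * scale
  rowpitch <- 9L * scale
  margin <- 2L * scale
  for (r in seq_len(min(4L, nt))) {
    cuts <- round(seq(0, nt, length.out = r + 1))
    counts <- diff(cuts)
    if (any(counts < 1)) next
    ycs <- size / 2 + (seq_len(r) - (r + 1) / 2) * rowpitch
    placement <- vector("list", r)
    ok <- TRUE
    idx0 <- 0L
    for (i in seq_len(r)) {
      grp <- (idx0 + 1L):(idx0 + counts[i])
      idx0 <- idx0 + counts[i]
      y_top <- round(ycs[i] - gh / 2)
      run <- usable_interval(mask, y_top + 1L, y_top + gh)
      if (is.null(run)) { ok <- FALSE; break }
      usable <- (run[2] - run[1] + 1L) - 2L * margin
      roww <- sum(widths[grp]) + sp * (counts[i] - 1L)
      if (roww > usable) { ok <- FALSE; break }
      x <- (run[1] - 1L + run[2]) / 2 - roww / 2  # 0-based left edge
      rows <- data.frame(token = tokens[grp], x0 = NA_real_, y0 = y_top,
                         w = widths[grp], h = gh, stringsAsFactors = FALSE)
      for (j in seq_along(grp)) {
        rows$x0[j] <- round(x)
        x <- x + widths[grp[j]] + sp
      }
      placement[[i]] <- rows
    }
    if (ok) return(do.call(rbind, placement))
  }
  NULL
}

draw_face <- function(shape, color, form, tokens, size, glyph_scale = 2L) {
  pal <- pill_palette()
  main <- pal[[color]]
  if (is.null(main)) stop("unknown color '", color, "'", call. = FALSE)
  img <- array(.render_bg, dim = c(size, size, 3L))
  mask <- shape_mask(shape, size)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- main[ch]
    img[, , ch] <- plane
  }
  if (form == "capsule") {
    # two-tone body; the record colour is the dominant (larger, left) half
    secondary <- if (color %in% c("white", "transparent")) pal[["red"]] else pal[["white"]]
    split_col <- round(0.55 * size)
    right <- mask & matrix(seq_len(size) > split_col, size, size, byrow = TRUE)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[right] <- secondary[ch]
      img[, , ch] <- plane
    }
  }

  lay <- layout_face(tokens, mask, size, glyph_scale)
  scale_used <- glyph_scale
  if (is.null(lay) && glyph_scale > 1L) {
    lay <- layout_face(tokens, mask, size, 1L)
    scale_used <- 1L
  }
  if (is.null(lay)) {
    stop("imprint '", paste(tokens, collapse = ""),
         "' does not fit inside a ", shape, " face at image size ", size,
         call. = FALSE)
  }
  if (nrow(lay) > 0) {
    lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (j in seq_len(nrow(lay))) {
      bm <- scale_bitmap(glyph_bitmap(lay$token[j]), scale_used)
      rr <- lay$y0[j] + seq_len(nrow(bm))
      cc <- lay$x0[j] + seq_len(ncol(bm))
      ink <- ifelse(lum[rr, cc][bm] > 0.45, 0.18, 0.92)
      for (ch in 1:3) {
        plane <- img[rr, cc, ch]
        plane[bm] <- ink
        img[rr, cc, ch] <- plane
      }
    }
  }
  boxes <- data.frame(
    char = lay$token,
    cx = lay$x0 + lay$w / 2,
    cy = lay$y0 + lay$h / 2,
    w = lay$w, h = lay$h,
    stringsAsFactors = FALSE
  )
  list(img = img, boxes = boxes)
}

#' Render a reference image for a pill record
#'
#' Draws the front face on the left half and the back face on the right half
#' of an `image_size` x `2 * image_size` RGB image, and returns the exact
#' per-character ground-truth boxes. The underscore separator is not a
#' printed character: it only routes tokens to the two faces, so it never
#' appears in the boxes. An imprint that cannot be placed inside the
#' silhouette raises an explicit overflow error rather than being truncated.
#' Rendering is deterministic given its arguments.
#'
#' @param record One pill record: a one-row data frame or list with `shape`,
#'   `color`, `form`, `imprint` (and optionally `pill_id`).
#' @param image_size Height in pixels (>= 64); the image is twice as wide.
#' @param rotation_deg Rotation applied to each face about its own centre, in
#'   degrees (positive rotates the content clockwise on screen).
#' @param seed Unused randomness hook kept for interface stability; rendering
#'   is fully deterministic.
#' @return An object of class `pill_render`: a list with `image` (an
#'   `image_size x 2*image_size x 3` array in `[0,1]`), `boxes` (a tibble with
#'   `char`, `x_center`, `y_center`, `width`, `height`, `face`, coordinates
#'   normalized to the full image, origin top-left, y down), and the call
#'   metadata.
#' @export
#' @examples
#' r <- render_pill(list(shape = "round", color = "white", form = "tablet",
#'                       imprint = "M10_KI"))
#' r$boxes
render_pill <- function(record, image_size = 96L, rotation_deg = 0, seed = 1L) {
  stopifnot(image_size >= 64)
  rec <- as.list(record)
  validate_imprint(rec$imprint)
  faces <- split_faces(rec$imprint)

  half <- as.integer(image_size)
  width <- 2L * half
  img <- array(.render_bg, dim = c(half, width, 3L))
  boxes <- list()
  for (side in c("front", "back")) {
    fr <- draw_face(rec$shape, rec$color, rec$form, faces[[side]], half)
    fimg <- fr$img
    fb <- fr$boxes
    if (rotation_deg != 0) {
      fimg <- rotate_image(fimg, rotation_deg, fill = .render_bg)
      if (nrow(fb) > 0) {
        th <- rotation_deg * pi / 180
        ctr <- half / 2
        dx <- fb$cx - ctr; dy <- fb$cy - ctr
        fb$cx <- ctr + dx * cos(th) - dy * sin(th)
        fb$cy <- ctr + dx * sin(th) + dy * cos(th)
        w2 <- abs(fb$w * cos(th)) + abs(fb$h * sin(th))
        h2 <- abs(fb$w * sin(th)) + abs(fb$h * cos(th))
        fb$w <- w2; fb$h <- h2
      }
    }
    off <- if (side == "front") 0L else half
    img[, off + seq_len(half), ] <- fimg
    if (nrow(fb) > 0) {
      boxes[[side]] <- tibble::tibble(
        char = fb$char,
        x_center = (fb$cx + off) / width,
        y_center = fb$cy / half,
        width = fb$w / width,
        height = fb$h / half,
        face = side
      )
    }
  }
  boxes <- if (length(boxes)) dplyr::bind_rows(boxes) else
    tibble::tibble(char = character(0), x_center = numeric(0),
                   y_center = numeric(0), width = numeric(0),
                   height = numeric(0), face = character(0))
  structure(
    list(image = img, boxes = boxes, record = rec,
         image_size = half, rotation_deg = rotation_deg),
    class = "pill_render"
  )
}

# Rotate image content by `deg` (clockwise on screen, y-down pixel coords)
# about the image centre, bilinear sampling, constant fill outside.
rotate_image <- function(img, deg, fill = .render_bg) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- deg * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h), h, w, byrow = FALSE) - cy
  # inverse map: source = R(-th) * dest
  sx <- cx + xs * cos(th) + ys * sin(th)
  sy <- cy - xs * sin(th) + ys * cos(th)
  out <- array(fill, dim = d)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- bilinear_sample(img[, , ch], sx, sy, fill)
  }
  out
}

bilinear_sample <- function(plane, sx, sy, fill) {
  h <- nrow(plane); w <- ncol(plane)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  gv <- function(xx, yy) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- matrix(fill, nrow(xx), ncol(xx))
    v[ok] <- plane[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gv(x0, y0); v10 <- gv(x0 + 1, y0)
  v01 <- gv(x0, y0 + 1); v11 <- gv(x0 + 1, y0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Write a rendered pill image and its annotations to disk
#'
#' Images are written as RGB PNG; annotations as a JSON array of character
#' boxes with coordinates normalized to `[0,1]` (x right-positive, y
#' down-positive, origin top-left).
#'
#' @param render A `pill_render` object.
#' @param png_path Path for the PNG image.
#' @param json_path Optional path for the JSON annotations.
#' @return `png_path` invisibly.
#' @export
write_pill_image <- function(render, png_path, json_path = NULL) {
  png::writePNG(render$image, png_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(render$boxes, json_path, auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(png_path)
}

#' @rdname write_pill_image
#' @param path Path to a PNG written by [write_pill_image()].
#' @export
read_pill_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @export
print.pill_render <- function(x, ...) {
  cat("<pill_render> ", dim(x$image)[1], "x", dim(x$image)[2],
      " image, ", nrow(x$boxes), " character boxes (",
      x$record$shape, " ", x$record$color, " ", x$record$form, ", imprint '",
      x$record$imprint, "')\n", sep = "")
  invisible(x)
}
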