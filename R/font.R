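# Built-in 5x7 bitmap face used to render imprints. Glyph boxes are taken
# from these exact metrics, so ground-truth annotations are exact by
# construction rather than re-detected. "mg" is a single 11-column ligature.

.font_raw <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".###.", "#...#", "#....", ".###.", "....#", "#...#", ".###."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  "m" = c(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#...#"),
  "g" = c(".....", ".....", ".####", "#...#", ".####", "....#", ".###.")
)

.font_env <- new.env(parent = emptyenv())

# 7 x width logical matrix for one token at scale 1. "mg" is m ++ gap ++ g.
glyph_bitmap <- function(token) {
  if (!is.null(.font_env[[token]])) return(.font_env[[token]])
  bm <- if (token == "mg") {
    m <- glyph_bitmap_single("m")
    g <- glyph_bitmap_single("g")
    cbind(m, matrix(FALSE, 7, 1), g)
  } else {
    glyph_bitmap_single(token)
  }
  .font_env[[token]] <- bm
  bm
}

glyph_bitmap_single <- function(ch) {
  rows <- .font_raw[[ch]]
  if (is.null(rows)) stop("no glyph for symbol '", ch, "'", call. = FALSE)
  do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
}

# Pixel width/height of a token glyph at an integer scale.
glyph_size <- function(token, scale = 2L) {
  bm <- glyph_bitmap(token)
  c(width = ncol(bm) * scale, height = nrow(bm) * scale)
}

# Upscale a logical bitmap by an integer factor.
scale_bitmap <- function(bm, scale) {
  if (scale == 1L) return(bm)
  bm[rep(seq_len(nrow(bm)), each = scale), rep(seq_len(ncol(bm)), each = scale)]
}
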