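# Database generation, rendering and detector-noise corruption.

test_that("degenerate frequencies force a single pill type", {
  freqs <- nlm_class_frequencies()
  freqs$shape[] <- 0; freqs$shape["round"] <- 1
  freqs$color[] <- 0; freqs$color["white"] <- 1
  freqs$form[] <- 0; freqs$form["tablet"] <- 1
  db <- generate_pill_database(1, class_frequencies = freqs, seed = 42)
  expect_identical(db$shape, "round")
  expect_identical(db$color, "white")
  expect_identical(db$form, "tablet")
})

test_that("invalid frequency tables are rejected with the feature named", {
  freqs <- nlm_class_frequencies()
  freqs$color["white"] <- -0.1
  expect_error(generate_pill_database(10, class_frequencies = freqs),
               "color")
  freqs <- nlm_class_frequencies()
  freqs$shape["round"] <- freqs$shape[["round"]] + 0.2
  expect_error(generate_pill_database(10, class_frequencies = freqs),
               "shape")
})

test_that("the generator is deterministic and records satisfy the contract", {
  db1 <- generate_pill_database(500, seed = 7)
  db2 <- generate_pill_database(500, seed = 7)
  expect_identical(db1, db2)
  expect_false(identical(db1, generate_pill_database(500, seed = 8)))
  expect_identical(anyDuplicated(db1$pill_id), 0L)
  expect_true(all(db1$shape %in% pill_shapes()))
  expect_true(all(db1$color %in% pill_colors()))
  expect_true(all(db1$form %in% pill_forms()))
  for (im in db1$imprint) {
    toks <- tokenize_imprint(im)
    expect_lte(sum(toks == "_"), 1)
    expect_true(all(toks %in% pill_vocabulary()))
  }
})

test_that("empirical class frequencies recover the NLM marginals", {
  db <- generate_pill_database(10000, seed = 7)
  expect_equal(mean(db$form == "capsule"), 0.15, tolerance = 0.02 / 0.15)
  expect_lt(abs(mean(db$form == "capsule") - 0.15), 0.02)
  freqs <- nlm_class_frequencies()
  for (feat in c("shape", "color")) {
    emp <- table(factor(db[[feat]], levels = names(freqs[[feat]]))) / nrow(db)
    expect_true(all(abs(emp - freqs[[feat]]) < 0.02),
                info = paste("marginals of", feat))
  }
})

test_that("at least 10% of records share features with a different imprint", {
  db <- generate_pill_database(300, seed = 17)
  key <- paste(db$shape, db$color, db$form)
  tab <- table(key)
  dup_frac <- sum(tab[tab >= 2]) / nrow(db)
  expect_gte(dup_frac, 0.10)
  expect_identical(anyDuplicated(paste(key, db$imprint)), 0L)
})

test_that("database CSV round-trips byte-identically", {
  db <- generate_pill_database(40, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pill_database(db, path)
  expect_identical(utils::read.csv(path, colClasses = "character")[[1]],
                   db$pill_id)
  expect_equal(as.data.frame(read_pill_database(path)), as.data.frame(db))
})

test_that("rendering lays out faces and boxes per the contract", {
  rec <- list(shape = "round", color = "white", form = "tablet",
              imprint = "M10_KI")
  r <- render_pill(rec)
  expect_identical(dim(r$image), c(96L, 192L, 3L))
  expect_identical(nrow(r$boxes), 5L)   # "_" is not a printed character
  expect_identical(sum(r$boxes$face == "front"), 3L)
  expect_identical(sum(r$boxes$face == "back"), 2L)
  expect_true(all(r$boxes$x_center[r$boxes$face == "front"] < 0.5))
  expect_true(all(r$boxes$x_center[r$boxes$face == "back"] >= 0.5))
  # boxes fully inside the unit square
  expect_true(all(r$boxes$x_center - r$boxes$width / 2 >= 0))
  expect_true(all(r$boxes$x_center + r$boxes$width / 2 <= 1))
  expect_true(all(r$boxes$y_center - r$boxes$height / 2 >= 0))
  expect_true(all(r$boxes$y_center + r$boxes$height / 2 <= 1))

  empty <- render_pill(list(shape = "oval", color = "red", form = "tablet",
                            imprint = ""))
  expect_identical(nrow(empty$boxes), 0L)
})

test_that("render round-trip recovers the imprint in face reading order", {
  db <- generate_pill_database(60, seed = 31)
  for (i in seq_len(20)) {
    r <- render_pill(db[i, ])
    b <- r$boxes[order(r$boxes$face == "back", r$boxes$y_center,
                       r$boxes$x_center), ]
    rebuilt <- paste0(
      paste0(b$char[b$face == "front"], collapse = ""), "_",
      paste0(b$char[b$face == "back"], collapse = ""))
    expect_identical(rebuilt, db$imprint[i])
  }
})

test_that("an imprint that cannot fit raises an explicit overflow error", {
  rec <- list(shape = "triangle", color = "white", form = "tablet",
              imprint = paste(rep("W", 40), collapse = ""))
  expect_error(render_pill(rec), "does not fit")
})

test_that("rendering is deterministic and capsules are two-tone", {
  rec <- list(shape = "oblong", color = "blue", form = "capsule",
              imprint = "AB_CD")
  r1 <- render_pill(rec); r2 <- render_pill(rec)
  expect_identical(r1$image, r2$image)
  left <- r1$image[48, 20:40, ]    # dominant half carries the record colour
  right <- r1$image[48, 60:80, ]
  expect_false(identical(left, right))
})

test_that("identity noise returns the input characters and coordinates", {
  r <- render_pill(list(shape = "round", color = "white", form = "tablet",
                        imprint = "M10_KI"))
  nz <- noise_config(confusion_rate = 0, drop_rate = 0, coord_jitter_sd = 0,
                     shuffle = FALSE, seed = 1)
  d <- corrupt_detections(r$boxes, nz)
  expect_identical(d$char, r$boxes$char)
  expect_equal(d$x, r$boxes$x_center)
  expect_equal(d$y, r$boxes$y_center)
  expect_identical(nrow(corrupt_detections(r$boxes[0, ], nz)), 0L)
})

test_that("confusion counts follow the binomial law", {
  n <- 10000
  boxes <- tibble::tibble(char = rep("O", n), x_center = runif(n),
                          y_center = runif(n))
  nz <- noise_config(confusion_rate = 0.5, drop_rate = 0,
                     coord_jitter_sd = 0, shuffle = FALSE, seed = 99)
  d <- corrupt_detections(boxes, nz)
  swapped <- sum(d$char == "0")
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(swapped, ci[1])
  expect_lte(swapped, ci[2])
})

test_that("the worked-example corruption yields the scrambled confused set", {
  r <- render_pill(list(shape = "round", color = "white", form = "tablet",
                        imprint = "M10_KI"))
  # seed pinned so that "1" and "0" flip while "I" survives: the detector
  # reads the scrambled confused string "IKOIM"
  nz <- noise_config(confusion_rate = 0.5, drop_rate = 0,
                     coord_jitter_sd = 0, shuffle = TRUE, seed = 9)
  d <- corrupt_detections(r$boxes, nz)
  expect_identical(paste0(d$char, collapse = ""), "IKOIM")
  expect_identical(sort(d$char), sort(c("M", "I", "O", "K", "I")))
})

test_that("corruption is deterministic given its seed", {
  r <- render_pill(list(shape = "square", color = "pink", form = "tablet",
                        imprint = "AB12_CD"))
  nz <- noise_config(seed = 7)
  expect_identical(corrupt_detections(r$boxes, nz),
                   corrupt_detections(r$boxes, nz))
})

test_that("drop rate removes roughly the configured fraction", {
  n <- 5000
  boxes <- tibble::tibble(char = rep("A", n), x_center = runif(n),
                          y_center = runif(n))
  nz <- noise_config(confusion_rate = 0, drop_rate = 0.3,
                     coord_jitter_sd = 0, shuffle = FALSE, seed = 2)
  d <- corrupt_detections(boxes, nz)
  expect_lt(abs(nrow(d) / n - 0.7), 0.03)
})

test_that("PNG and JSON annotation output round-trips", {
  r <- render_pill(list(shape = "hexagon", color = "green", form = "tablet",
                        imprint = "A1_B2"))
  png_path <- withr::local_tempfile(fileext = ".png")
  json_path <- withr::local_tempfile(fileext = ".json")
  write_pill_image(r, png_path, json_path)
  img <- read_pill_image(png_path)
  expect_identical(dim(img), dim(r$image))
  expect_lt(max(abs(img - r$image)), 1 / 255)
  ann <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_identical(ann$char, r$boxes$char)
  expect_equal(ann$x_center, r$boxes$x_center, tolerance = 1e-9)
})
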