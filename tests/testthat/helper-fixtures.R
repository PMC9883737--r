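# Shared fixtures. Heavy trained models are built once per test run and
# cached so several test files can probe the same fit.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# Exhaustive recursive Levenshtein oracle (tokens), independent of the DP.
edit_distance_oracle <- function(ta, tb) {
  if (length(ta) == 0L) return(length(tb))
  if (length(tb) == 0L) return(length(ta))
  sub <- edit_distance_oracle(ta[-1], tb[-1]) + (ta[1] != tb[1])
  del <- edit_distance_oracle(ta[-1], tb) + 1L
  ins <- edit_distance_oracle(ta, tb[-1]) + 1L
  min(sub, del, ins)
}

random_imprint_string <- function(len, alphabet = c(LETTERS[1:6], "0", "1", "_")) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Desk-scale render/detect fixture: 320 pills, 300 train / 20 held out.
detector_fixture <- function() {
  cached("detector_fixture", {
    db <- generate_pill_database(320, seed = 5)
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    images <- lapply(renders, `[[`, "image")
    boxes <- lapply(renders, `[[`, "boxes")
    model <- train_detector(
      images[1:300], boxes[1:300],
      detector_config(epochs = 40L, hidden = 128L, learning_rate = 0.05,
                      aug_per_positive = 4L, seed = 1L))
    list(db = db, images = images, boxes = boxes, model = model,
         held_out = 301:320)
  })
}

# Match detections against ground truth by centre distance and character.
detection_scores <- function(model, images, boxes, idx, conf = 0.5) {
  tp <- 0L; fp <- 0L; fn <- 0L; errs <- c()
  for (i in idx) {
    det <- detect_characters(model, images[[i]], conf)
    gt <- boxes[[i]]
    used <- rep(FALSE, nrow(gt))
    for (j in seq_len(nrow(det))) {
      d <- sqrt((gt$x_center - det$x[j])^2 * 4 + (gt$y_center - det$y[j])^2)
      cand <- which(!used & d < 0.06 & gt$char == det$char[j])
      if (length(cand) > 0) {
        k <- cand[which.min(d[cand])]
        used[k] <- TRUE
        tp <- tp + 1L
        errs <- c(errs, abs(gt$x_center[k] - det$x[j]))
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       mean_x_err = mean(errs))
}

# Feature-recognition fixture: 360 pills, 300 train / 60 held out.
features_fixture <- function() {
  cached("features_fixture", {
    db <- generate_pill_database(360, seed = 9)
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    images <- lapply(renders, `[[`, "image")
    model <- suppressWarnings(train_features(
      images[1:300], db[1:300, c("shape", "color", "form")],
      feature_config(hidden_dim = 64L, epochs = 60L, seed = 1L),
      oversample = TRUE))
    list(db = db, images = images, model = model, held_out = 301:360)
  })
}

feature_accuracy <- function(model, images, labels, idx) {
  ok <- c(shape = 0L, color = 0L, form = 0L)
  for (i in idx) {
    p <- predict_features(model, images[[i]])
    ok["shape"] <- ok["shape"] + (p$shape_label == labels$shape[i])
    ok["color"] <- ok["color"] + (p$color_label == labels$color[i])
    ok["form"] <- ok["form"] + (p$form_label == labels$form[i])
  }
  ok / length(idx)
}

# Corruption-pair builder shared by the corrector fixtures.
corruption_pairs <- function(db, renders, reps, seed0,
                             noise_template = noise_config()) {
  pairs <- list()
  k <- 0L
  for (i in seq_len(nrow(db))) {
    for (r in seq_len(reps)) {
      nz <- noise_template
      nz$seed <- seed0 + i * 1000L + r
      k <- k + 1L
      pairs[[k]] <- list(source = corrupt_detections(renders[[i]]$boxes, nz),
                         target = db$imprint[i])
    }
  }
  pairs
}

# Corrector fixture: 60 pills x 84 corruptions (~5,000 pairs) under the
# benchmark noise.
corrector_fixture <- function() {
  cached("corrector_fixture", {
    db <- generate_pill_database(60, imprint_length_range = c(2, 5), seed = 4)
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    pairs <- corruption_pairs(db, renders, reps = 84L, seed0 = 0L)
    model <- train_corrector(
      pairs, config = corrector_config(hidden_size = 64L, epochs = 12L,
                                       seed = 1L))
    list(db = db, renders = renders, model = model)
  })
}

corrector_heldout_pairs <- function(fx, reps = 5L) {
  corruption_pairs(fx$db, fx$renders, reps = reps, seed0 = 777000L)
}

# End-to-end fixture: a 150-pill study (including confusable imprint
# siblings), all three models trained at desk scale, evaluated with the
# benchmark noise injected between detection and correction.
pipeline_fixture <- function() {
  cached("pipeline_fixture", {
    db <- generate_pill_database(150, imprint_length_range = c(2, 5),
                                 seed = 101)
    cfg <- pillid_config(
      detector = detector_config(epochs = 40L, hidden = 128L,
                                 learning_rate = 0.05, aug_per_positive = 4L,
                                 seed = 1L),
      features = feature_config(hidden_dim = 64L, epochs = 40L, seed = 1L),
      corrector = corrector_config(hidden_size = 64L, epochs = 15L, seed = 1L),
      corruptions_per_pill = 25L,
      seed = 1L)
    models <- suppressWarnings(pillid_train(db, cfg))
    list(db = db, cfg = cfg, models = models)
  })
}
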