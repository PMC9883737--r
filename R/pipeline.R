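# End-to-end orchestration: generate -> train (detector, features,
# corrector) -> identify -> evaluate, with one global seed propagated to
# every stage. Evaluation injects the configured detector-noise corruption
# between detection and correction: on clean synthetic renders the toy
# detector is near-exact, so the corruption model supplies the confusion,
# drop and order-scrambling errors that a full-scale detector exhibits on
# real photographs, and the corrector is measured against exactly that
# benchmark.

#' Pipeline configuration
#'
#' Bundles the per-module configurations with the global seed. `desk_scale`
#' keeps every stage small enough for interactive CPU use (fewer epochs,
#' modest hidden sizes); full-scale defaults follow the per-module
#' configuration objects.
#'
#' @param image_size Rendered image height in pixels.
#' @param detector A [detector_config()].
#' @param features A [feature_config()].
#' @param corrector A [corrector_config()].
#' @param noise A [noise_config()] applied between detection and correction
#'   during evaluation.
#' @param corruptions_per_pill Noisy training variants generated per pill
#'   for the corrector.
#' @param seed Global integer seed, propagated to every module.
#' @param desk_scale If `TRUE`, shrink epochs and hidden sizes for CPU use.
#' @return A `pillid_config` list.
#' @export
pillid_config <- function(image_size = 96L,
                          detector = NULL, features = NULL, corrector = NULL,
                          noise = noise_config(),
                          corruptions_per_pill = 20L,
                          seed = 1L,
                          desk_scale = TRUE) {
  seed <- as.integer(seed)
  if (is.null(detector)) {
    detector <- if (desk_scale) {
      detector_config(epochs = 40L, hidden = 128L, learning_rate = 0.05,
                      aug_per_positive = 4L, seed = seed)
    } else {
      detector_config(seed = seed)
    }
  }
  if (is.null(features)) {
    features <- feature_config(hidden_dim = if (desk_scale) 64L else 128L,
                               epochs = if (desk_scale) 40L else 100L,
                               seed = seed)
  }
  if (is.null(corrector)) {
    corrector <- corrector_config(hidden_size = if (desk_scale) 64L else 256L,
                                  epochs = if (desk_scale) 15L else 100L,
                                  seed = seed)
  }
  noise$seed <- seed
  structure(list(image_size = as.integer(image_size), detector = detector,
                 features = features, corrector = corrector, noise = noise,
                 corruptions_per_pill = as.integer(corruptions_per_pill),
                 seed = seed, desk_scale = isTRUE(desk_scale)),
            class = "pillid_config")
}

derive_seed <- function(seed, ...) {
  k <- seed
  for (x in c(...)) k <- (k * 131L + as.integer(x)) %% 2147483629L
  as.integer(abs(k)) + 1L
}

#' Split a pill database by species
#'
#' Train/test splits are disjoint by pill (species), mirroring evaluation on
#' pills never seen in training — the setting a retrieval (rather than
#' classification) system is built for.
#'
#' @param database Pill-database tibble.
#' @param test_fraction Fraction of species assigned to the test split.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
pillid_split <- function(database, test_fraction = 0.5, seed = 1L) {
  n <- nrow(database)
  withr::with_seed(seed, {
    test_idx <- sort(sample.int(n, round(test_fraction * n)))
  })
  list(train = database[setdiff(seq_len(n), test_idx), ],
       test = database[test_idx, ])
}

#' Train all three recognition models on a pill database
#'
#' Renders one reference image per record, then trains the character
#' detector on the ground-truth boxes, the multitask feature classifier on
#' the (shape, colour, form) labels (with inverse-frequency oversampling),
#' and the imprint corrector on `corruptions_per_pill` noisy variants of
#' each pill's ground-truth boxes under the configured detector-noise model.
#'
#' @param database Pill-database tibble (the training species).
#' @param config A [pillid_config()].
#' @param verbose Print stage progress.
#' @return A `pillid_models` list with `detector`, `features`, `corrector`,
#'   the training `database` and the `config`.
#' @export
pillid_train <- function(database, config = pillid_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pillid_config"), nrow(database) >= 1L)
  say <- function(...) if (verbose) message(...)
  say("rendering ", nrow(database), " reference images")
  renders <- lapply(seq_len(nrow(database)), function(i) {
    render_pill(database[i, ], image_size = config$image_size)
  })
  images <- lapply(renders, `[[`, "image")
  boxes <- lapply(renders, `[[`, "boxes")

  say("training detector")
  detector <- train_detector(images, boxes, config$detector)
  say("training feature classifier")
  features <- train_features(images, database[, c("shape", "color", "form")],
                             config$features, oversample = TRUE)
  say("training corrector")
  pairs <- list()
  ctx <- list()
  k <- 0L
  for (i in seq_len(nrow(database))) {
    for (rep in seq_len(config$corruptions_per_pill)) {
      nz <- config$noise
      nz$seed <- derive_seed(config$seed, i, rep)
      k <- k + 1L
      pairs[[k]] <- list(source = corrupt_detections(boxes[[i]], nz),
                         target = database$imprint[i])
      ctx[[k]] <- database[i, c("shape", "color", "form")]
    }
  }
  feature_context <- if (config$corrector$context_mode == "features") {
    dplyr::bind_rows(ctx)
  }
  corrector <- train_corrector(pairs, feature_context, config$corrector)

  structure(list(detector = detector, features = features,
                 corrector = corrector, database = database,
                 config = config),
            class = "pillid_models")
}

# Reading-order string straight from the detector, the "without language
# model" baseline: front-face characters by (y, x), an underscore, then the
# back-face characters.
uncorrected_imprint <- function(detections) {
  if (nrow(detections) == 0L) return("")
  d <- sort_detections(detections)
  front <- d$char[d$x < 0.5]
  back <- d$char[d$x >= 0.5]
  paste0(paste0(front, collapse = ""), "_", paste0(back, collapse = ""))
}

#' Identify one pill image against a database
#'
#' Runs the full recognition-and-retrieval pipeline on one reference image:
#' orientation normalization per face, character detection, feature
#' classification, imprint correction, then similarity ranking against the
#' database. A query with no detected characters proceeds on features and an
#' empty imprint and is flagged low-confidence.
#'
#' @param models A `pillid_models` object from [pillid_train()].
#' @param image An `h x 2h x 3` reference-image array.
#' @param database Database to retrieve from (defaults to the training
#'   database).
#' @param top_k Candidates to return.
#' @param noise Optional [noise_config()] injected between detection and
#'   correction (the evaluation benchmark); `NULL` for none.
#' @return A `pillid_result`: list with `query` (predicted characteristics),
#'   `ranking` (a `pill_ranking` tibble), `detections`, `corrected`,
#'   `uncorrected` and `low_confidence`.
#' @export
pillid_identify <- function(models, image, database = models$database,
                            top_k = 3L, noise = NULL) {
  stopifnot(inherits(models, "pillid_models"))
  norm <- normalize_reference(image)
  det <- detect_characters(models$detector, norm$image)
  if (!is.null(noise)) det <- corrupt_detections(det, noise)
  feats <- predict_features(models$features, norm$image)
  corrected <- correct_imprint(models$corrector, det, feats)
  query <- list(shape = feats$shape_label, color = feats$color_label,
                form = feats$form_label, imprint = corrected)
  ranking <- rank_database(query, database, k = top_k)
  structure(list(query = query, ranking = ranking, detections = det,
                 corrected = corrected,
                 uncorrected = uncorrected_imprint(det),
                 features = feats,
                 low_confidence = nrow(det) == 0L),
            class = "pillid_result")
}

#' @export
print.pillid_result <- function(x, ...) {
  cat("<pillid_result> predicted [", x$query$shape, ", ", x$query$color, ", ",
      x$query$form, ", ", x$query$imprint, "]",
      if (x$low_confidence) " (low confidence: no characters detected)",
      "\n", sep = "")
  print(as.data.frame(x$ranking), row.names = FALSE)
  invisible(x)
}

#' Evaluate the pipeline on a set of pills
#'
#' Renders an evaluation image for every pill in `test_database`, runs the
#' pipeline with the configured detector-noise corruption injected between
#' detection and correction, retrieves from `retrieval_database`, and
#' reports top-k accuracy. `ablate` switches off parts of the system:
#' `"corrector"` scores the raw detector reading-order string instead of the
#' corrected imprint; `"shape"`, `"color"`, `"form"`, `"imprint"` drop score
#' terms from the similarity.
#'
#' @param models A `pillid_models` object.
#' @param test_database Pills to query (one rendered image each).
#' @param retrieval_database Database to retrieve from (defaults to
#'   `test_database`).
#' @param ablate `NULL` or a character vector from `"corrector"`, `"shape"`,
#'   `"color"`, `"form"`, `"imprint"`.
#' @param top_ks Accuracy cutoffs.
#' @param noise The injected [noise_config()]; defaults to the models'
#'   configured benchmark noise. `NULL` disables injection.
#' @return A `pillid_evaluation`: list with `metrics` (tibble `k`,
#'   `accuracy`) and `per_query` (one row per pill with the predicted
#'   characteristics, the top candidate and hit indicators).
#' @export
pillid_evaluate <- function(models, test_database,
                            retrieval_database = test_database,
                            ablate = NULL, top_ks = c(1L, 3L),
                            noise = models$config$noise) {
  stopifnot(inherits(models, "pillid_models"), nrow(test_database) >= 1L)
  if (!is.null(ablate)) {
    ablate <- match.arg(ablate,
                        c("corrector", "shape", "color", "form", "imprint"),
                        several.ok = TRUE)
  }
  score_ablate <- setdiff(ablate, "corrector")
  if (length(score_ablate) == 0L) score_ablate <- NULL
  rows <- vector("list", nrow(test_database))
  rankings <- vector("list", nrow(test_database))
  kmax <- max(top_ks)
  for (i in seq_len(nrow(test_database))) {
    rec <- test_database[i, ]
    img <- render_pill(rec, image_size = models$config$image_size)$image
    norm <- normalize_reference(img)
    det <- detect_characters(models$detector, norm$image)
    if (!is.null(noise)) {
      nz <- noise
      nz$seed <- derive_seed(models$config$seed, 900000L, i)
      det <- corrupt_detections(det, nz)
    }
    feats <- predict_features(models$features, norm$image)
    imprint <- if ("corrector" %in% ablate) {
      uncorrected_imprint(det)
    } else {
      correct_imprint(models$corrector, det, feats)
    }
    query <- list(shape = feats$shape_label, color = feats$color_label,
                  form = feats$form_label, imprint = imprint)
    rk <- rank_database(query, retrieval_database, k = kmax,
                        ablate = score_ablate)
    rankings[[i]] <- rk
    hit <- match(rec$pill_id, rk$pill_id)
    rows[[i]] <- tibble::tibble(
      pill_id = rec$pill_id, true_imprint = rec$imprint,
      predicted_imprint = imprint,
      predicted_shape = query$shape, predicted_color = query$color,
      predicted_form = query$form,
      top1_id = rk$pill_id[1],
      rank = if (is.na(hit)) NA_integer_ else rk$rank[hit]
    )
  }
  metrics <- evaluate_topk(rankings, test_database$pill_id, ks = top_ks)
  structure(list(metrics = metrics, per_query = dplyr::bind_rows(rows),
                 ablate = ablate),
            class = "pillid_evaluation")
}

#' @export
print.pillid_evaluation <- function(x, ...) {
  cat("<pillid_evaluation>",
      if (length(x$ablate)) paste0(" (ablated: ",
                                   paste(x$ablate, collapse = ", "), ")"),
      "\n", sep = "")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}
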