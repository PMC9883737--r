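# Coordinate encoding and the seq2seq corrector.

test_that("coordinate encoding is one-hot plus trailing coordinates", {
  d <- tibble::tibble(char = "M", x = 0.2, y = 0.5)
  enc <- encode_sequence(d)
  V <- length(pill_vocabulary())
  expect_identical(dim(enc), c(1L, V + 2L))
  expect_equal(sum(enc[1, seq_len(V)]), 1)
  expect_equal(enc[1, match("M", pill_vocabulary())], 1)
  expect_equal(enc[1, V + 1:2], c(0.2, 0.5))
  expect_identical(nrow(encode_sequence(d[0, ])), 0L)
  expect_error(encode_sequence(tibble::tibble(char = "?", x = 0, y = 0)),
               "\\?")
})

test_that("the one-hot part round-trips every vocabulary symbol", {
  V <- pill_vocabulary()
  withr::with_seed(2, {
    d <- tibble::tibble(char = sample(V, 200, replace = TRUE),
                        x = runif(200), y = runif(200))
    enc <- encode_sequence(d)
    rec <- V[apply(enc[, seq_along(V)], 1, which.max)]
    expect_identical(rec, d$char)
    expect_equal(enc[, length(V) + 1], d$x)
  })
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- corrector_config(embedding_size = 7L, hidden_size = 5L,
                          context_mode = "features", epochs = 1L, seed = 1)
  withr::with_seed(42, {
    params <- pillidr:::corrector_init_params(cfg)
    mk <- function(chars, xs, ys) tibble::tibble(char = chars, x = xs, y = ys)
    pairs <- list(
      list(source = mk(c("M", "1", "0"), c(.1, .2, .3), c(.5, .5, .5)),
           target = "M10_K"),
      list(source = mk(c("A", "B"), c(.6, .7), c(.4, .4)), target = "AB"),
      list(source = mk(character(0), numeric(0), numeric(0)), target = "Z"))
    prep <- lapply(pairs, function(p)
      pillidr:::prepare_pair(p$source, p$target, cfg))
    ctx <- pillidr:::ctx_indices(tibble::tibble(
      shape = c("round", "oval", "square"),
      color = c("white", "red", "blue"),
      form = c("tablet", "capsule", "tablet")))
    batch <- pillidr:::make_batch(prep, ctx)
    out <- pillidr:::seq2seq_batch(params, batch, cfg, compute_grads = TRUE)
    f <- function(p) pillidr:::seq2seq_batch(p, batch, cfg,
                                             compute_grads = FALSE)$loss
    eps <- 1e-6
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
      for (ii in idx) {
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
        num <- (f(pp) - f(pm)) / (2 * eps)
        ana <- out$grads[[nm]][ii]
        expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)),
                  label = paste("gradient of", nm))
      }
    }
  })
})

test_that("targets beyond the configured maximum are rejected at load", {
  cfg <- corrector_config(max_target_len = 5L, epochs = 1L)
  pairs <- list(list(source = tibble::tibble(char = "A", x = .1, y = .1),
                     target = "ABCDEFG_H"))
  expect_error(train_corrector(pairs, config = cfg), "max_target_len")
  expect_error(train_corrector(list(), config = cfg), "no training pairs")
})

test_that("feature context is required for every pair when enabled", {
  cfg <- corrector_config(context_mode = "features", epochs = 1L)
  pairs <- list(list(source = tibble::tibble(char = "A", x = .1, y = .1),
                     target = "A"))
  expect_error(train_corrector(pairs, config = cfg), "feature_context")
})

test_that("an identity copy task is learned almost perfectly", {
  model <- cached("copy_corrector", {
    db <- generate_pill_database(25, imprint_length_range = c(2, 4), seed = 8)
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    nz <- noise_config(confusion_rate = 0, drop_rate = 0,
                       coord_jitter_sd = 0, shuffle = FALSE)
    pairs <- corruption_pairs(db, renders, reps = 25L, seed0 = 0L,
                              noise_template = nz)
    list(db = db, renders = renders,
         model = train_corrector(pairs,
                                 config = corrector_config(hidden_size = 48L,
                                                           epochs = 30L,
                                                           seed = 1L)))
  })
  db <- model$db
  hits <- 0L
  for (i in seq_len(nrow(db))) {
    det <- corrupt_detections(model$renders[[i]]$boxes,
                              noise_config(confusion_rate = 0, drop_rate = 0,
                                           coord_jitter_sd = 0,
                                           shuffle = FALSE, seed = i))
    hits <- hits + (correct_imprint(model$model, det) == db$imprint[i])
  }
  expect_gte(hits / nrow(db), 0.98)
})

test_that("the corrector decodes the worked example from IKOIM", {
  fx <- cached("worked_example_corrector", {
    # a corpus containing the pill M10_KI among visually similar pills
    db <- tibble::tibble(
      pill_id = sprintf("P%02d", 1:12),
      shape = "round", color = "white", form = "tablet",
      imprint = c("M10_KI", "M20_KI", "B12_X", "A5_C3", "M100_K", "E4_F7",
                  "10B_Z", "OK_10", "IK_OM", "M1_O", "50mg_A", "7Q_RS"))
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    pairs <- corruption_pairs(db, renders, reps = 60L, seed0 = 0L)
    model <- train_corrector(pairs,
                             config = corrector_config(hidden_size = 48L,
                                                       epochs = 15L,
                                                       seed = 1L))
    list(db = db, renders = renders, model = model)
  })
  # the detector read "IKOIM": scrambled, 1->I and 0->O confused, with the
  # true coordinates of each character on the pill
  r <- fx$renders[[1]]
  b <- r$boxes       # M 1 0 | K I
  det <- tibble::tibble(
    char = c("I", "K", "O", "I", "M"),
    x = b$x_center[c(2, 4, 3, 5, 1)],
    y = b$y_center[c(2, 4, 3, 5, 1)])
  expect_identical(correct_imprint(fx$model, det), "M10_KI")
})

test_that("decoding respects the contract on empty and bounded output", {
  fx <- corrector_fixture()
  empty <- tibble::tibble(char = character(0), x = numeric(0), y = numeric(0))
  expect_identical(correct_imprint(fx$model, empty), "")
  withr::with_seed(99, {
    for (rep in seq_len(20)) {
      n <- sample(1:10, 1)
      det <- tibble::tibble(
        char = sample(setdiff(pill_vocabulary(), "_"), n, replace = TRUE),
        x = runif(n), y = runif(n))
      out <- correct_imprint(fx$model, det)
      toks <- tokenize_imprint(out)
      expect_lte(length(toks), fx$model$config$max_target_len)
      expect_lte(sum(toks == "_"), 1)
    }
  })
})

test_that("training NLL is non-increasing over the final epochs", {
  fx <- corrector_fixture()
  lh <- fx$model$loss_history
  tail10 <- utils::tail(lh, 10)
  expect_true(all(diff(tail10) <= 0.05 * tail10[-length(tail10)]))
  expect_lt(utils::tail(lh, 1), lh[1])
})

test_that("held-out exact match is high under the corruption benchmark", {
  fx <- corrector_fixture()
  held <- corrector_heldout_pairs(fx, reps = 5L)
  hits <- vapply(held, function(p) {
    correct_imprint(fx$model, p$source) == p$target
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("correction strictly improves edit similarity over raw detections", {
  fx <- corrector_fixture()
  held <- corrector_heldout_pairs(fx, reps = 5L)
  sim_corrected <- numeric(0); sim_raw <- numeric(0)
  for (p in held) {
    out <- correct_imprint(fx$model, p$source)
    raw <- pillidr:::uncorrected_imprint(p$source)
    sim_corrected <- c(sim_corrected,
                       normalized_edit_similarity(out, p$target))
    sim_raw <- c(sim_raw, normalized_edit_similarity(raw, p$target))
  }
  expect_gt(mean(sim_corrected), mean(sim_raw))
})

test_that("zeroing coordinates hurts exact match on shuffled inputs", {
  # Anagram pairs: every pill shares its character multiset with a partner
  # whose front face is reversed, so once the order is scrambled the
  # coordinates are the only signal that separates the two. The coordinate
  # ablation zeroes (x, y) at train and test and removes the coordinate
  # sort (sorting by position is itself coordinate use).
  res <- cached("coordinate_ablation", {
    letters_safe <- setdiff(LETTERS, c("O", "I", "B", "S", "Z"))
    withr::with_seed(31, {
      fronts <- replicate(8, paste0(sample(letters_safe, 3), collapse = ""))
      backs <- replicate(8, sample(letters_safe, 1))
    })
    rev3 <- vapply(fronts, function(f)
      paste(rev(strsplit(f, "")[[1]]), collapse = ""), character(1))
    db <- tibble::tibble(
      pill_id = sprintf("P%02d", 1:16),
      shape = "round", color = "white", form = "tablet",
      imprint = c(paste0(fronts, "_", backs), paste0(rev3, "_", backs)))
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    pairs <- corruption_pairs(db, renders, reps = 30L, seed0 = 0L)
    with_c <- train_corrector(pairs,
                              config = corrector_config(hidden_size = 48L,
                                                        epochs = 12L,
                                                        seed = 1L))
    no_c <- train_corrector(pairs,
                            config = corrector_config(hidden_size = 48L,
                                                      epochs = 12L,
                                                      use_coords = FALSE,
                                                      seed = 1L))
    held <- corruption_pairs(db, renders, reps = 5L, seed0 = 444000L)
    acc <- function(model) mean(vapply(held, function(p)
      correct_imprint(model, p$source) == p$target, logical(1)))
    c(with_coords = acc(with_c), without_coords = acc(no_c))
  })
  expect_gt(res[["with_coords"]], res[["without_coords"]])
})

test_that("feature context helps when imprints correlate with colour", {
  res <- cached("context_comparison", {
    # two colour groups whose imprints share a confusable core: only the
    # colour context disambiguates which canonical form to emit
    withr::with_seed(5, {
      n <- 24
      half <- n / 2
      core <- replicate(n, paste0(sample(c("O", "0", "I", "1", "B", "8"), 3,
                                         replace = TRUE), collapse = ""))
      db <- tibble::tibble(
        pill_id = sprintf("P%03d", 1:n),
        shape = "round",
        color = rep(c("white", "blue"), each = half),
        form = "tablet",
        imprint = paste0(core, "_", rep(c("A", "Z"), each = half)))
    })
    renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
    pairs <- corruption_pairs(db, renders, reps = 40L, seed0 = 0L)
    ctx <- db[rep(seq_len(nrow(db)), each = 40L), c("shape", "color", "form")]
    m_ctx <- train_corrector(pairs, feature_context = ctx,
                             config = corrector_config(
                               hidden_size = 48L, epochs = 12L,
                               context_mode = "features", seed = 1L))
    m_none <- train_corrector(pairs,
                              config = corrector_config(hidden_size = 48L,
                                                        epochs = 12L,
                                                        seed = 1L))
    held <- corruption_pairs(db, renders, reps = 5L, seed0 = 555000L)
    acc_ctx <- mean(vapply(seq_along(held), function(k) {
      i <- (k - 1L) %/% 5L + 1L
      correct_imprint(m_ctx, held[[k]]$source,
                      features = as.list(db[i, c("shape", "color", "form")])) ==
        held[[k]]$target
    }, logical(1)))
    acc_none <- mean(vapply(seq_along(held), function(k)
      correct_imprint(m_none, held[[k]]$source) == held[[k]]$target,
      logical(1)))
    c(ctx = acc_ctx, none = acc_none)
  })
  expect_gte(res[["ctx"]], res[["none"]])
})

test_that("training is deterministic given the seed", {
  db <- generate_pill_database(6, imprint_length_range = c(2, 3), seed = 19)
  renders <- lapply(seq_len(nrow(db)), function(i) render_pill(db[i, ]))
  pairs <- corruption_pairs(db, renders, reps = 4L, seed0 = 0L)
  cfg <- corrector_config(hidden_size = 16L, epochs = 2L, seed = 77)
  m1 <- train_corrector(pairs, config = cfg)
  m2 <- train_corrector(pairs, config = cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})
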