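#' Class inventories for pill features
#'
#' The closed categorical inventories for the three pill features: 11 shapes
#' (the ten standard shapes plus `rectangle`, which US reference data maps to
#' `square` during fine-tuning but which we keep as its own value; unusual
#' shapes such as semicircles fall in `others`), 16 colours, and the two
#' physical forms. A capsule carries a single colour label, the dominant
#' (larger) half of its two-tone body.
#'
#' @return Character vector of levels.
#' @export
pill_shapes <- function() {
  c("round", "oblong", "oval", "triangle", "square", "diamond",
    "pentagon", "hexagon", "octagon", "rectangle", "others")
}

#' @rdname pill_shapes
#' @export
pill_colors <- function() {
  c("white", "yellow", "orange", "pink", "red", "brown", "light green",
    "green", "cyan", "blue", "navy", "purple", "gray", "black", "violet",
    "transparent")
}

#' @rdname pill_shapes
#' @export
pill_forms <- function() {
  c("tablet", "capsule")
}

#' Marginal class frequencies of the NLM reference database
#'
#' The published marginal distributions of the US National Library of
#' Medicine pill database: shapes round 46.18%, oval 35.01%, oblong 15.46%
#' (remainder spread over the rare shapes); colours white 42.27%, yellow
#' 12.68%, pink 8.93%, orange 8.64%, blue 8.44%, brown 5.76%, green 5.53%
#' (remainder spread over the rare colours); 85% tablets and 15% capsules.
#' These are the default sampling frequencies of [generate_pill_database()].
#'
#' @return Named list with elements `shape`, `color`, `form`, each a named
#'   probability vector over the corresponding inventory, summing to 1.
#' @export
nlm_class_frequencies <- function() {
  shape <- stats::setNames(numeric(11), pill_shapes())
  shape[c("round", "oval", "oblong")] <- c(0.4618, 0.3501, 0.1546)
  rest <- setdiff(pill_shapes(), c("round", "oval", "oblong"))
  shape[rest] <- (1 - sum(shape)) / length(rest)

  color <- stats::setNames(numeric(16), pill_colors())
  color[c("white", "yellow", "pink", "orange", "blue", "brown", "green")] <-
    c(0.4227, 0.1268, 0.0893, 0.0864, 0.0844, 0.0576, 0.0553)
  rest <- setdiff(pill_colors(),
                  c("white", "yellow", "pink", "orange", "blue", "brown", "green"))
  color[rest] <- (1 - sum(color)) / length(rest)

  form <- c(tablet = 0.85, capsule = 0.15)
  list(shape = shape, color = color, form = form)
}

check_frequencies <- function(freqs) {
  levels <- list(shape = pill_shapes(), color = pill_colors(), form = pill_forms())
  for (feat in c("shape", "color", "form")) {
    f <- freqs[[feat]]
    if (is.null(f)) stop("class_frequencies is missing the '", feat, "' table",
                         call. = FALSE)
    if (is.null(names(f)) || !setequal(names(f), levels[[feat]])) {
      stop("frequency table for '", feat, "' must be named over its full ",
           "class inventory", call. = FALSE)
    }
    if (any(f < 0)) stop("frequency table for '", feat,
                         "' contains negative values", call. = FALSE)
    if (abs(sum(f) - 1) > 1e-9) stop("frequency table for '", feat,
                                     "' does not sum to 1", call. = FALSE)
  }
  invisible(freqs)
}

#' Generate a synthetic pill database
#'
#' Draws `n` pill records with shape, colour and form sampled independently
#' from the supplied marginal frequencies (by default the NLM marginals,
#' [nlm_class_frequencies()]) and random imprints over the closed vocabulary:
#' per face a uniform number of tokens in `imprint_length_range`, each token
#' an uppercase letter or digit, occasionally the `"mg"` token, with the two
#' faces joined by `"_"`. Because many real pills are visually
#' near-identical (white round tablets above all), at least
#' `duplicate_feature_min` of the records are forced to share their full
#' (shape, colour, form) triple with another record while carrying a
#' different imprint, so that retrieval cannot succeed on features alone.
#'
#' The generator is a pure function of its arguments: the same seed yields a
#' byte-identical database.
#'
#' @param n Number of records (>= 1).
#' @param class_frequencies Named list of per-feature probability tables; see
#'   [nlm_class_frequencies()].
#' @param imprint_length_range Integer pair: min/max tokens per face.
#' @param seed Integer seed.
#' @param mg_rate Probability that a token is the `"mg"` ligature.
#' @param duplicate_feature_min Minimum fraction of records sharing their
#'   feature triple with at least one other record.
#' @param confusable_sibling_rate Fraction of records generated as
#'   "siblings" of an earlier record: same imprint except one position
#'   swapped to a different detector-confusable symbol (O/0, I/1, B/8, S/5,
#'   Z/2), emulating the dosage families and look-alike codes (M10 vs MIO)
#'   that make real imprint retrieval hard.
#' @return A tibble with columns `pill_id`, `shape`, `color`, `form`,
#'   `imprint`.
#' @export
#' @examples
#' generate_pill_database(5, seed = 1)
generate_pill_database <- function(n,
                                   class_frequencies = nlm_class_frequencies(),
                                   imprint_length_range = c(2L, 8L),
                                   seed = 1L,
                                   mg_rate = 0.06,
                                   duplicate_feature_min = 0.10,
                                   confusable_sibling_rate = 0.15) {
  stopifnot(length(n) == 1L, n >= 1)
  check_frequencies(class_frequencies)
  stopifnot(length(imprint_length_range) == 2L,
            imprint_length_range[1] >= 1,
            imprint_length_range[1] <= imprint_length_range[2])

  withr::with_seed(seed, {
    shape <- sample(names(class_frequencies$shape), n, replace = TRUE,
                    prob = class_frequencies$shape)
    color <- sample(names(class_frequencies$color), n, replace = TRUE,
                    prob = class_frequencies$color)
    form <- sample(names(class_frequencies$form), n, replace = TRUE,
                   prob = class_frequencies$form)

    imprints <- vapply(seq_len(n), function(i) {
      random_imprint(imprint_length_range, mg_rate)
    }, character(1))

    # Force the feature-duplicate floor: records in a feature group of size
    # >= 2 count as duplicates. Copy features from earlier records until the
    # floor is met (imprints stay distinct, re-drawn on collision).
    if (n >= 2) {
      feat_key <- function() paste(shape, color, form, sep = "|")
      dup_frac <- function() {
        tab <- table(feat_key())
        sum(tab[tab >= 2]) / n
      }
      guard <- 0L
      while (dup_frac() < duplicate_feature_min && guard < 10L * n) {
        i <- sample.int(n, 1L)
        j <- sample.int(n, 1L)
        if (i != j) {
          shape[i] <- shape[j]
          color[i] <- color[j]
          form[i] <- form[j]
        }
        guard <- guard + 1L
      }
    }

    # Confusable siblings: overwrite a fraction of imprints with a one-token
    # confusable flip of another record's imprint, so the database contains
    # the near-collisions (M10 vs MIO) that imprint retrieval must resolve.
    confusables <- c("O", "0", "I", "1", "B", "8", "S", "5", "Z", "2")
    if (n >= 4 && confusable_sibling_rate > 0) {
      n_sib <- round(confusable_sibling_rate * n)
      if (n_sib >= 1) {
        children <- sample.int(n, n_sib)
        for (i in children) {
          j <- sample(setdiff(seq_len(n), i), 1L)
          toks <- tokenize_imprint(imprints[j])
          cand <- which(toks != "_")
          conf_pos <- cand[toks[cand] %in% confusables]
          pos <- if (length(conf_pos) > 0) resample(conf_pos, 1L) else resample(cand, 1L)
          repl <- resample(setdiff(confusables, toks[pos]), 1L)
          toks[pos] <- repl
          imprints[i] <- detokenize_imprint(toks)
        }
      }
    }

    # Distinct (features, imprint) combinations: re-draw colliding imprints.
    key <- paste(shape, color, form, imprints, sep = "|")
    guard <- 0L
    while (anyDuplicated(key) && guard < 100L) {
      idx <- which(duplicated(key))
      for (i in idx) {
        imprints[i] <- random_imprint(imprint_length_range, mg_rate)
      }
      key <- paste(shape, color, form, imprints, sep = "|")
      guard <- guard + 1L
    }

    tibble::tibble(
      pill_id = sprintf("P%05d", seq_len(n)),
      shape = shape,
      color = color,
      form = form,
      imprint = imprints
    )
  })
}

resample <- function(x, k) x[sample.int(length(x), k)]

random_imprint <- function(len_range, mg_rate) {
  alphabet <- c(LETTERS, as.character(0:9))
  face <- function() {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    toks <- vapply(seq_len(len), function(k) {
      if (stats::runif(1) < mg_rate) "mg" else sample(alphabet, 1L)
    }, character(1))
    paste0(toks, collapse = "")
  }
  paste0(face(), "_", face())
}

#' Read or write a pill database CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `pill_id,shape,color,form,imprint` and no quoting (the closed vocabularies
#' contain no commas).
#'
#' @param database A pill-database tibble.
#' @param path File path.
#' @return `read_pill_database()` returns a tibble; `write_pill_database()`
#'   returns `path` invisibly.
#' @export
write_pill_database <- function(database, path) {
  stopifnot(all(c("pill_id", "shape", "color", "form", "imprint") %in%
                  names(database)))
  utils::write.csv(as.data.frame(database), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pill_database
#' @export
read_pill_database <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  tibble::as_tibble(df)
}
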