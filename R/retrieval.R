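# Retrieval: rank every database pill against the predicted characteristics
# with a five-term additive similarity — 1/3 per exactly matching feature
# (shape, colour, form), plus two imprint terms in [0,1]: normalized edit
# similarity (order-sensitive) and multiset character overlap (order-free).
# All terms are exact small rationals; decimals appear only on display.

#' Edit distance between two imprints
#'
#' Levenshtein distance with unit-cost insertion, deletion and substitution,
#' computed over imprint tokens: `"_"` and the `"mg"` ligature each count as
#' one ordinary symbol.
#'
#' @param a,b Imprint strings.
#' @return Non-negative integer.
#' @export
#' @examples
#' edit_distance("M10_KI", "M10SPC_")  # 4: 3 substitutions + 1 insertion
edit_distance <- function(a, b) {
  ned_dp(tokenize_imprint(a), tokenize_imprint(b))$dist
}

# DP over (cost, -matches) lexicographically: among minimum-cost edit
# scripts, prefer the one with the most aligned matches.
ned_dp <- function(ta, tb) {
  n <- length(ta); m <- length(tb)
  D <- matrix(0L, n + 1L, m + 1L)   # cost
  M <- matrix(0L, n + 1L, m + 1L)   # matches under the preferred script
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n > 0 && m > 0) {
    for (i in seq_len(n)) {
      eq <- ta[i] == tb
      for (j in seq_len(m)) {
        csub <- D[i, j] + (!eq[j])
        msub <- M[i, j] + eq[j]
        cdel <- D[i, j + 1L] + 1L
        mdel <- M[i, j + 1L]
        cins <- D[i + 1L, j] + 1L
        mins <- M[i + 1L, j]
        best_c <- csub; best_m <- msub
        if (cdel < best_c || (cdel == best_c && mdel > best_m)) {
          best_c <- cdel; best_m <- mdel
        }
        if (cins < best_c || (cins == best_c && mins > best_m)) {
          best_c <- cins; best_m <- mins
        }
        D[i + 1L, j + 1L] <- best_c
        M[i + 1L, j + 1L] <- best_m
      }
    }
  }
  list(dist = D[n + 1L, m + 1L], matches = M[n + 1L, m + 1L],
       len = n + m)
}

#' Normalized edit similarity between two imprints
#'
#' Rescales the edit distance into `[0,1]` as
#' `2 * matches / (|a| + |b|)`, where `matches` is the number of aligned
#' equal tokens in a minimum-cost edit script chosen (lexicographically) to
#' maximize matches. Equivalently `(|a| + |b| - d - x) / (|a| + |b|)` with
#' `d` the edit distance and `x` the substitutions in that script. Two empty
#' strings have similarity 1.
#'
#' @param a,b Imprint strings.
#' @return Similarity in `[0,1]`.
#' @export
#' @examples
#' normalized_edit_similarity("M10_KI", "M10SPC_")  # 6/13
normalized_edit_similarity <- function(a, b) {
  f <- ned_fraction(a, b)
  f[["num"]] / f[["den"]]
}

ned_fraction <- function(a, b) {
  r <- ned_dp(tokenize_imprint(a), tokenize_imprint(b))
  if (r$len == 0L) return(c(num = 1L, den = 1L))
  c(num = 2L * r$matches, den = r$len)
}

#' Multiset character-overlap similarity
#'
#' The order-free imprint term: `2 * |multiset intersection| / (|a| + |b|)`
#' over imprint tokens, with `"_"` participating as an ordinary symbol. Two
#' empty strings have similarity 1.
#'
#' @param a,b Imprint strings.
#' @return Similarity in `[0,1]`.
#' @export
#' @examples
#' overlap_similarity("M10_KI", "M10SPC_")  # 8/13
overlap_similarity <- function(a, b) {
  f <- overlap_fraction(a, b)
  f[["num"]] / f[["den"]]
}

overlap_fraction <- function(a, b) {
  ta <- tokenize_imprint(a); tb <- tokenize_imprint(b)
  len <- length(ta) + length(tb)
  if (len == 0L) return(c(num = 1L, den = 1L))
  cta <- table(ta); ctb <- table(tb)
  common <- intersect(names(cta), names(ctb))
  inter <- sum(pmin(as.integer(cta[common]), as.integer(ctb[common])))
  c(num = 2L * inter, den = len)
}

#' Feature similarity between predicted and target features
#'
#' 1/3 per exactly matching label among shape, colour and form; labels must
#' belong to their class inventories.
#'
#' @param pred,target Feature triples: character vectors
#'   `c(shape, color, form)` or lists/one-row data frames with those names.
#' @return One of 0, 1/3, 2/3, 1.
#' @export
#' @examples
#' feature_similarity(c("square", "orange", "tablet"),
#'                    c("square", "pink", "tablet"))   # 2/3
feature_similarity <- function(pred, target) {
  p <- as_feature_triple(pred)
  t <- as_feature_triple(target)
  sum(p == t) / 3
}

as_feature_triple <- function(x) {
  if (is.character(x) && length(x) == 3L && is.null(names(x))) {
    x <- list(shape = x[1], color = x[2], form = x[3])
  } else {
    x <- as.list(x)
  }
  lv <- feature_levels()
  out <- character(3)
  for (i in seq_along(c("shape", "color", "form"))) {
    feat <- c("shape", "color", "form")[i]
    val <- as.character(x[[feat]])
    if (length(val) != 1L || !(val %in% lv[[feat]])) {
      stop("unknown ", feat, " label '", val, "'", call. = FALSE)
    }
    out[i] <- val
  }
  out
}

#' Five-term similarity breakdown against one database pill
#'
#' Computes the three feature-match terms (1/3 each), the normalized edit
#' similarity and the multiset overlap similarity between the predicted
#' characteristics and one database record, with their exact rational values
#' and the total.
#'
#' @param query Predicted characteristics: list/one-row data frame with
#'   `shape`, `color`, `form`, `imprint`.
#' @param target One database record (same fields, plus optionally
#'   `pill_id`).
#' @return A one-row tibble with `shape_term`, `color_term`, `form_term`,
#'   `edit_sim`, `overlap_sim`, `total`, and the exact integer
#'   numerator/denominator columns `edit_num`, `edit_den`, `overlap_num`,
#'   `overlap_den`.
#' @export
#' @examples
#' total_score(list(shape = "square", color = "orange", form = "tablet",
#'                  imprint = "M10_KI"),
#'             list(shape = "square", color = "pink", form = "tablet",
#'                  imprint = "M10_KI"))
total_score <- function(query, target) {
  q <- as.list(query); t <- as.list(target)
  qf <- as_feature_triple(q)
  tf <- as_feature_triple(t)
  terms <- (qf == tf) / 3
  ef <- ned_fraction(q$imprint, t$imprint)
  of <- overlap_fraction(q$imprint, t$imprint)
  edit_sim <- ef[["num"]] / ef[["den"]]
  overlap_sim <- of[["num"]] / of[["den"]]
  tibble::tibble(
    pill_id = if (!is.null(t$pill_id)) t$pill_id else NA_character_,
    shape_term = terms[1], color_term = terms[2], form_term = terms[3],
    edit_sim = edit_sim, overlap_sim = overlap_sim,
    total = terms[1] + terms[2] + terms[3] + edit_sim + overlap_sim,
    edit_num = ef[["num"]], edit_den = ef[["den"]],
    overlap_num = of[["num"]], overlap_den = of[["den"]]
  )
}

#' Rank a pill database against predicted characteristics
#'
#' Scores every database record with [total_score()] (optionally ablating
#' score terms) and returns the top `k` by total, ties broken by `pill_id`
#' ascending, so the ranking is deterministic.
#'
#' @param query Predicted characteristics (`shape`, `color`, `form`,
#'   `imprint`).
#' @param database Pill-database tibble.
#' @param k Number of candidates to return (capped at the database size).
#' @param ablate Optional character vector of terms to drop from the total:
#'   any of `"shape"`, `"color"`, `"form"`, `"imprint"`.
#' @return A `pill_ranking` tibble: `pill_id`, `rank`, the five terms and
#'   `total`.
#' @export
rank_database <- function(query, database, k = 3L, ablate = NULL) {
  stopifnot(nrow(database) >= 1L, k >= 1L)
  if (!is.null(ablate)) {
    ablate <- match.arg(ablate, c("shape", "color", "form", "imprint"),
                        several.ok = TRUE)
  }
  q <- as.list(query)
  qf <- as_feature_triple(q)
  qt <- tokenize_imprint(q$imprint)
  qtab <- table(qt)
  n <- nrow(database)
  shape_term <- (database$shape == qf[1]) / 3
  color_term <- (database$color == qf[2]) / 3
  form_term <- (database$form == qf[3]) / 3
  edit_sim <- numeric(n)
  overlap_sim <- numeric(n)
  for (i in seq_len(n)) {
    tt <- tokenize_imprint(database$imprint[i])
    len <- length(qt) + length(tt)
    if (len == 0L) {
      edit_sim[i] <- 1; overlap_sim[i] <- 1
    } else {
      r <- ned_dp(qt, tt)
      edit_sim[i] <- 2 * r$matches / len
      ttab <- table(tt)
      common <- intersect(names(qtab), names(ttab))
      overlap_sim[i] <- 2 * sum(pmin(as.integer(qtab[common]),
                                     as.integer(ttab[common]))) / len
    }
  }
  if ("shape" %in% ablate) shape_term[] <- 0
  if ("color" %in% ablate) color_term[] <- 0
  if ("form" %in% ablate) form_term[] <- 0
  if ("imprint" %in% ablate) {
    edit_sim[] <- 0; overlap_sim[] <- 0
  }
  total <- shape_term + color_term + form_term + edit_sim + overlap_sim
  ord <- order(-total, database$pill_id)
  k <- min(k, n)
  top <- ord[seq_len(k)]
  out <- tibble::tibble(
    pill_id = database$pill_id[top], rank = seq_len(k),
    shape_term = shape_term[top], color_term = color_term[top],
    form_term = form_term[top], edit_sim = edit_sim[top],
    overlap_sim = overlap_sim[top], total = total[top])
  class(out) <- c("pill_ranking", class(out))
  out
}

#' Top-k retrieval accuracy
#'
#' The fraction of queries whose true pill appears within the first `k`
#' ranked candidates. A truth id absent from a ranked list counts as a miss.
#'
#' @param ranked_lists List of `pill_ranking` tibbles (one per query).
#' @param truth_ids Character vector of true pill ids, one per query.
#' @param ks Integer vector of cutoffs.
#' @return A tibble with columns `k` and `accuracy`.
#' @export
evaluate_topk <- function(ranked_lists, truth_ids, ks = c(1L, 3L)) {
  stopifnot(length(ranked_lists) == length(truth_ids))
  n <- length(ranked_lists)
  ranks <- vapply(seq_len(n), function(i) {
    r <- ranked_lists[[i]]
    hit <- match(truth_ids[i], r$pill_id)
    if (is.na(hit)) Inf else r$rank[hit]
  }, numeric(1))
  tibble::tibble(
    k = as.integer(ks),
    accuracy = vapply(ks, function(k) mean(ranks <= k), numeric(1))
  )
}
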