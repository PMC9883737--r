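#' Imprint vocabulary
#'
#' The closed symbol inventory used on pill surfaces: the uppercase letters
#' `A`-`Z`, the digits `0`-`9`, the lowercase milligram token `"mg"` (the one
#' lowercase exception, treated as a single token throughout), and the
#' underscore `"_"` that separates the front-face imprint from the back-face
#' imprint.
#'
#' @return Character vector of vocabulary tokens.
#' @export
#' @examples
#' pill_vocabulary()
pill_vocabulary <- function() {
  c(LETTERS, as.character(0:9), "mg", "_")
}

#' Tokenize an imprint string
#'
#' Splits an imprint into tokens: single characters, except that the exact
#' lowercase bigram `"mg"` is kept as one token. Tokenization is permissive:
#' symbols outside [pill_vocabulary()] are kept as single-character tokens so
#' that retrieval can score arbitrary database imprints; the strict vocabulary
#' is enforced only where a model consumes the tokens (see
#' [encode_sequence()]).
#'
#' @param x A single imprint string.
#' @return Character vector of tokens (length 0 for the empty string).
#' @export
#' @examples
#' tokenize_imprint("M10_KI")
#' tokenize_imprint("50mg_A")
tokenize_imprint <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || nchar(x) == 0L) return(character(0))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (i < n && chars[i] == "m" && chars[i + 1L] == "g") {
      out <- c(out, "mg")
      i <- i + 2L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  out
}

#' Reassemble tokens into an imprint string
#'
#' @param tokens Character vector of tokens as produced by
#'   [tokenize_imprint()].
#' @return A single string.
#' @export
detokenize_imprint <- function(tokens) {
  paste0(tokens, collapse = "")
}

# Split an imprint into per-face token lists at the first underscore.
# Imprints without an underscore are treated as front-only.
split_faces <- function(imprint) {
  toks <- tokenize_imprint(imprint)
  sep <- which(toks == "_")
  if (length(sep) == 0L) {
    list(front = toks, back = character(0))
  } else {
    s <- sep[1L]
    list(
      front = toks[seq_len(s - 1L)],
      back  = if (s < length(toks)) toks[(s + 1L):length(toks)] else character(0)
    )
  }
}

# Validate an imprint against the ImprintString contract: at most one "_",
# all other tokens in the closed vocabulary.
validate_imprint <- function(x) {
  toks <- tokenize_imprint(x)
  if (sum(toks == "_") > 1L) {
    stop("imprint '", x, "' contains more than one '_' separator", call. = FALSE)
  }
  bad <- setdiff(toks, pill_vocabulary())
  if (length(bad) > 0L) {
    stop("imprint '", x, "' contains out-of-vocabulary symbol(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
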