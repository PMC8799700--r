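# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a global seed plus a character key (stage name,
#' dyad id, reservoir index, ...) to a new integer seed. All randomness in
#' the package flows through keys derived this way, so execution order and
#' parallel scheduling cannot change results.
#'
#' @param seed integer global seed.
#' @param ... key components identifying the consumer (coerced to character).
#' @return a single integer in `[1, 2^31)`.
#' @examples
#' derive_seed(1, "esn", 3)
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(
    c(format(seed, scientific = FALSE),
      vapply(list(...), function(x) paste(format(x, scientific = FALSE), collapse = ","), "")),
    collapse = "/"
  )
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483587
  as.integer(h %% 2147483587) + 1L
}

# z-score with an explicit degenerate flag instead of NaN propagation
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(structure(rep(NA_real_, length(x)), degenerate = TRUE))
  }
  (x - mean(x)) / s
}

is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# full-precision numeric formatting so CSV round trips are bit-identical
fmt17 <- function(x) sprintf("%.17g", x)

write_precise_table <- function(df, path, sep = ",") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt17(out[[j]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
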