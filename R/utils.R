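# Internal helpers shared across modules.

#' Stop with a classed validation error
#' @noRd
rr_abort <- function(msg, class = "radiorobust_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that simulation helpers never perturb user-level randomness.
#' @noRd
with_rr_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rr_abort("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a substream seed from a master seed
#'
#' Deterministic, collision-poor mapping from (master seed, stream label) to
#' an integer seed below 2^31, so every stage/group/level of a pipeline run
#' draws from its own named stream.
#' @noRd
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(paste(label, collapse = "/")) *
             (31^(seq_along(utf8ToInt(paste(label, collapse = "/"))) %% 8)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483587) + 1L
}

#' Case-insensitive, trimmed categorical match
#' @noRd
match_label <- function(x, choices, what = "label") {
  key <- tolower(trimws(as.character(x)))
  hit <- match(key, tolower(choices))
  if (anyNA(hit)) {
    rr_abort(sprintf(
      "unknown %s: %s (expected one of: %s)", what,
      paste(sQuote(x[is.na(hit)]), collapse = ", "),
      paste(choices, collapse = ", ")
    ), class = "radiorobust_validation_error")
  }
  choices[hit]
}
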