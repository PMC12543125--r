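# The eight candidate response functions f(x) = alpha * g(x) + beta used both
# to model mean feature-parameter relationships and, rearranged as
# (f(x) - beta) / g(x), to correct per-region feature values. Natural
# logarithms throughout (the base only rescales alpha).

#' Candidate model families
#'
#' The eight parametric forms `f(x) = alpha * g(x) + beta` fitted to the mean
#' relationship between a feature and an acquisition/reconstruction
#' parameter, in fixed complexity order (used for AIC tie-breaking): `x`,
#' `x^2`, `x^3`, `1/x`, `1/x^2`, `1/x^3`, `log(x)`, `1/log(x)`.
#'
#' @return Character vector of the eight family names.
#' @examples
#' model_families()
#' @export
model_families <- function() {
  c("a*x+b", "a*x^2+b", "a*x^3+b", "a/x+b", "a/x^2+b", "a/x^3+b",
    "a*log(x)+b", "a/log(x)+b")
}

#' Evaluate the transform g(x) of a model family
#'
#' @param family One of [model_families()].
#' @param x Positive numeric values (already rescaled via [rescale_x()]).
#' @return `g(x)` such that the family is `alpha * g(x) + beta`.
#' @examples
#' family_transform("a/x+b", 10)  # 0.1
#' @export
family_transform <- function(family, x) {
  family <- match_label(family, model_families(), "model family")
  switch(family,
    "a*x+b"      = x,
    "a*x^2+b"    = x^2,
    "a*x^3+b"    = x^3,
    "a/x+b"      = 1 / x,
    "a/x^2+b"    = 1 / x^2,
    "a/x^3+b"    = 1 / x^3,
    "a*log(x)+b" = log(x),
    "a/log(x)+b" = 1 / log(x)
  )
}
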