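#' Response transformations for decay modelling
#'
#' The decay models are fitted on a transformed scale chosen per metric to
#' linearise the relationship with log10 distance and stabilise variance:
#' log10 for turbidity-derived suspended sediment concentrations, square root
#' for daily light integrals, and logit for quantities bounded in (0, 1)
#' (the sediment deposition index and cover/exceedance proportions).
#'
#' `transform_tag()` builds a small object holding the forward and inverse
#' mappings together with the transform name; `fit_decay()` and the
#' effect-distance functions carry it along so that predictions can always be
#' returned on the natural scale.
#'
#' @param name one of `"identity"`, `"log10"`, `"sqrt"`, `"logit"`.
#' @return An object of class `transform_tag`: a list with elements `name`,
#'   `forward` and `inverse`.
#' @examples
#' tg <- transform_tag("logit")
#' tg$forward(0.5)      # 0
#' tg$inverse(0)        # 0.5
#' @export
transform_tag <- function(name = c("identity", "log10", "sqrt", "logit")) {
  if (inherits(name, "transform_tag")) return(name)
  name <- match.arg(name)
  fwd <- switch(name,
    identity = function(x) x,
    log10    = function(x) log10(x),
    sqrt     = function(x) sqrt(x),
    logit    = function(x) log(x / (1 - x))
  )
  inv <- switch(name,
    identity = function(x) x,
    log10    = function(x) 10^x,
    sqrt     = function(x) x^2,
    logit    = function(x) 1 / (1 + exp(-x))
  )
  structure(list(name = name, forward = fwd, inverse = inv),
            class = "transform_tag")
}

#' @export
print.transform_tag <- function(x, ...) {
  cat("<transform_tag:", x$name, ">\n")
  invisible(x)
}

#' Apply a response transformation
#'
#' Element-wise forward transformation with domain validation. For the logit
#' of observed proportions an empirical-logit correction is available: when
#' exact 0 or 1 occur and the denominator `n` is supplied, every value is
#' shrunk as `(x * n + c) / (n + 2 * c)` with `c = correction` before taking
#' logits, the standard empirical logit for binomial proportions.
#'
#' @param values numeric vector on the natural scale.
#' @param transform a `transform_tag` or its name.
#' @param n optional denominator count(s) behind proportion values (scalar or
#'   vector recycled against `values`); required for the logit when exact 0/1
#'   are present.
#' @param correction empirical-logit pseudo-count (default 0.5).
#' @return numeric vector on the transformed scale.
#' @examples
#' apply_transform(c(0.25, 0.5), "logit")
#' apply_transform(c(0, 0.5, 1), "logit", n = 20)
#' @export
apply_transform <- function(values, transform, n = NULL, correction = 0.5) {
  tg <- transform_tag(transform)
  if (!is.numeric(values)) stop("`values` must be numeric")
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (tg$name == "log10" && any(v[ok] <= 0))
    stop("log10 transform requires strictly positive values")
  if (tg$name == "sqrt" && any(v[ok] < 0))
    stop("sqrt transform requires non-negative values")
  if (tg$name == "logit") {
    if (any(v[ok] < 0 | v[ok] > 1))
      stop("logit transform requires proportions in [0, 1]")
    boundary <- any(v[ok] <= 0 | v[ok] >= 1)
    if (boundary) {
      if (is.null(n))
        stop("exact 0/1 proportions need the empirical-logit correction: supply `n`")
      if (any(n <= 0)) stop("`n` must be positive")
      v <- (v * n + correction) / (n + 2 * correction)
    }
  }
  tg$forward(v)
}

#' Invert a response transformation
#'
#' @param values numeric vector on the transformed scale.
#' @param transform a `transform_tag` or its name.
#' @return numeric vector on the natural scale. For the sqrt transform,
#'   negative transformed values (possible for a linear predictor evaluated
#'   far from the data) are truncated at 0 before squaring so the natural
#'   scale stays non-negative and monotone in the linear predictor.
#' @export
invert_transform <- function(values, transform) {
  tg <- transform_tag(transform)
  v <- as.numeric(values)
  if (tg$name == "sqrt") v <- pmax(v, 0)
  tg$inverse(v)
}
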