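#' Effect distance of a fitted decay curve (point version)
#'
#' The decay curve on the natural scale is
#' `f(d) = inverse_transform(beta0 + beta1 * log10(d))` with random effects
#' at zero. The effect distance at retention level `q` is the unique
#' distance in `[d_near, d_far]` where only the fraction `q` of the total
#' effect (the difference between the predictions at the nearest and
#' farthest monitored distances) remains:
#' `f(ED_q) = f(d_far) + q * (f(d_near) - f(d_far))`. ED10 (`q = 0.1`) is
#' the distance at which 90% of the effect has dissipated; ED50 the
#' half-effect distance.
#'
#' Under the identity transform the solution has the closed form
#' `log10(ED) = log10(d_far) + q * (log10(d_near) - log10(d_far))`,
#' independent of the coefficients; for the other transforms a monotone
#' bisection on the log10-distance axis is used (tolerance 1e-9 on
#' log10 d). The definition is direction-symmetric, so metrics that
#' increase with distance (e.g. light) are handled with `beta1 > 0`.
#'
#' @param beta0,beta1 coefficient value(s) on the transformed scale;
#'   vectors are recycled against each other. `beta1` must be non-zero.
#' @param transform transform tag or name.
#' @param q effect-remaining fraction, `0 < q < 1`.
#' @param d_near_km,d_far_km interval endpoints (defaults 0.19 and 34.8 km).
#' @return effect distance(s) in km, always within `[d_near_km, d_far_km]`.
#' @examples
#' ed_point(0, -1, "identity", q = 0.1)   # 20.67 km, whatever the slope
#' ed_point(0, -2, "logit", q = 0.5)
#' @export
ed_point <- function(beta0, beta1, transform, q,
                     d_near_km = 0.19, d_far_km = 34.8) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (d_near_km <= 0 || d_near_km >= d_far_km)
    stop("need 0 < d_near_km < d_far_km")
  if (any(beta1 == 0)) stop("ED is undefined for beta1 = 0 (no gradient)")
  tg <- transform_tag(transform)
  tn <- log10(d_near_km)
  tf <- log10(d_far_km)
  if (tg$name == "identity")
    return(rep_len(10^(tf + q * (tn - tf)), max(length(beta0), length(beta1))))
  nb <- max(length(beta0), length(beta1))
  b0 <- rep_len(beta0, nb)
  b1 <- rep_len(beta1, nb)
  f <- function(t) invert_transform(b0 + b1 * t, tg)
  f_near <- f(tn)
  f_far <- f(tf)
  target <- f_far + q * (f_near - f_far)
  lo <- rep(tn, nb)
  hi <- rep(tf, nb)
  increasing <- f_near < f_far      # per-draw direction of f on the interval
  flat <- f_near == f_far           # fully saturated transform: any point works
  for (i in seq_len(60)) {          # 60 halvings: width < 1e-9 on log10 d
    mid <- (lo + hi) / 2
    fm <- f(mid)
    go_right <- ifelse(increasing, fm < target, fm > target)
    lo <- ifelse(go_right, mid, lo)
    hi <- ifelse(go_right, hi, mid)
  }
  t_ed <- (lo + hi) / 2
  t_ed[flat] <- tf + q * (tn - tf)  # continuity limit
  10^t_ed
}

#' Posterior effect distance with 95% credible band
#'
#' Applies [ed_point()] to every posterior draw of `(beta0, beta1)` and
#' summarises: the point estimate is the posterior median of the per-draw
#' effect distances (the mean is also reported) with the 2.5th and 97.5th
#' percentiles as the credible interval. Draws whose slope has the wrong
#' sign (relative to the posterior-median direction) or is numerically zero
#' have no dissipation point in the monitored direction; they are clipped
#' to the nearest interval endpoint (`d_far` for `q <= 0.5`, `d_near`
#' otherwise, the endpoint adjacent to the zero-slope limit on the log
#' axis) and counted in `n_clipped`.
#'
#' @param fit a `decay_fit`, or a matrix/data.frame of draws with columns
#'   `beta0` and `beta1` (then `transform` must be given).
#' @param q effect-remaining fraction (0.10 for ED10, 0.50 for ED50).
#' @param d_near_km,d_far_km interval endpoints.
#' @param transform required when `fit` is a plain draw matrix.
#' @param metric optional metric label carried into the result.
#' @return list of class `ed_result`: `metric, q, ed_km` (posterior
#'   median), `ed_mean_km`, `ci95_km`, `n_draws`, `n_clipped`,
#'   `d_near_km`, `d_far_km`, `transform`.
#' @export
ed_posterior <- function(fit, q, d_near_km = 0.19, d_far_km = 34.8,
                         transform = NULL, metric = NULL) {
  if (inherits(fit, "decay_fit")) {
    b <- posterior_draws(fit, c("beta0", "beta1"))
    transform <- fit$transform
  } else {
    b <- as.matrix(fit)
    if (!all(c("beta0", "beta1") %in% colnames(b)))
      stop("draws must have columns beta0 and beta1")
    if (is.null(transform)) stop("supply `transform` with a plain draw matrix")
  }
  tg <- transform_tag(transform)
  b0 <- b[, "beta0"]
  b1 <- b[, "beta1"]
  tol <- 1e-10
  ref_sign <- sign(stats::median(b1))
  if (ref_sign == 0) stop("posterior slope is centred on zero; no gradient")
  degenerate <- abs(b1) < tol | sign(b1) != ref_sign
  if (mean(degenerate) > 0.5)
    stop("more than half of the posterior draws carry no gradient in the ",
         "reference direction; effect distance is not estimable")
  ed <- rep(NA_real_, length(b1))
  clip_to <- if (q <= 0.5) d_far_km else d_near_km
  ed[degenerate] <- clip_to
  if (any(!degenerate))
    ed[!degenerate] <- ed_point(b0[!degenerate], b1[!degenerate], tg, q,
                                d_near_km, d_far_km)
  out <- list(metric = metric %||% "response", q = q,
              ed_km = stats::median(ed),
              ed_mean_km = mean(ed),
              ci95_km = unname(stats::quantile(ed, c(0.025, 0.975))),
              n_draws = length(ed),
              n_clipped = sum(degenerate),
              d_near_km = d_near_km, d_far_km = d_far_km,
              transform = tg$name)
  class(out) <- "ed_result"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ed_result <- function(x, ...) {
  cat(sprintf("ED%d for %s: %.3g km (95%% CI %.3g-%.3g km, %d draws, %d clipped)\n",
              round(100 * x$q), x$metric, x$ed_km, x$ci95_km[1], x$ci95_km[2],
              x$n_draws, x$n_clipped))
  invisible(x)
}

#' Tabulate effect distances across metrics
#'
#' Builds a summary table of ED10 and ED50 with credible intervals, one row
#' per metric, values formatted to 2 significant figures in km.
#'
#' @param results list of `ed_result` objects (mixed q levels; typically
#'   0.1 and 0.5 per metric).
#' @return data.frame with columns `metric, ed10_km, ed10_ci95, ed50_km,
#'   ed50_ci95` (numeric ED columns; interval columns formatted strings).
#'   Levels other than 0.1/0.5 get their own column pair.
#' @export
ed_table <- function(results) {
  if (length(results) == 0L) stop("no effect-distance results supplied")
  if (inherits(results, "ed_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "ed_result")))
  metrics <- unique(vapply(results, `[[`, character(1), "metric"))
  qs <- sort(unique(vapply(results, `[[`, numeric(1), "q")))
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (q in qs) {
    lab <- paste0("ed", round(100 * q))
    ed <- ci <- rep(NA, length(metrics))
    for (r in results) {
      if (r$q == q) {
        i <- match(r$metric, metrics)
        ed[i] <- signif(r$ed_km, 2)
        ci[i] <- sprintf("%.2g-%.2g", r$ci95_km[1], r$ci95_km[2])
      }
    }
    out[[paste0(lab, "_km")]] <- as.numeric(ed)
    out[[paste0(lab, "_ci95")]] <- ci
  }
  out
}
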