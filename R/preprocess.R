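#' Preprocessing configuration
#'
#' Parameters converting raw daily logger records into the fortnightly
#' pressure metrics the decay models consume: suspended sediment
#' concentration (SSC) derived from turbidity with a fixed NTU-to-SSC factor,
#' the daily light integral (DLI), and the unit-less sediment deposition
#' index. Each daily series is smoothed with a trailing running mean (14 d
#' for SSC and DLI, 60 d for the deposition index) and summarised per
#' fortnight by the maximum of the smoothed values.
#'
#' @param ntu_to_ssc_factor multiplicative NTU to mg/L factor (default 1.8).
#' @param ssc_window_days,dli_window_days,depo_window_days trailing
#'   running-mean windows in days (defaults 14, 14, 60).
#' @param fortnight_length_days fortnight bin width (default 14).
#' @param dli_stat fortnightly summary for DLI: `"max"` (as for the pressure
#'   metrics) or `"min"` (light minima as the pressure reading).
#' @param min_window_coverage minimum fraction of non-missing days a running
#'   window must contain before a value is emitted (default 0.5; loggers are
#'   fouled and serviced, so gaps are expected).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(ntu_to_ssc_factor = 1.8,
                              ssc_window_days = 14,
                              dli_window_days = 14,
                              depo_window_days = 60,
                              fortnight_length_days = 14,
                              dli_stat = c("max", "min"),
                              min_window_coverage = 0.5) {
  if (ntu_to_ssc_factor <= 0) stop("ntu_to_ssc_factor must be positive")
  if (any(c(ssc_window_days, dli_window_days, depo_window_days,
            fortnight_length_days) <= 0))
    stop("window lengths must be positive")
  if (min_window_coverage <= 0 || min_window_coverage > 1)
    stop("min_window_coverage must be in (0, 1]")
  structure(list(ntu_to_ssc_factor = ntu_to_ssc_factor,
                 ssc_window_days = as.integer(ssc_window_days),
                 dli_window_days = as.integer(dli_window_days),
                 depo_window_days = as.integer(depo_window_days),
                 fortnight_length_days = as.integer(fortnight_length_days),
                 dli_stat = match.arg(dli_stat),
                 min_window_coverage = min_window_coverage),
            class = "preprocess_config")
}

#' Convert turbidity to suspended sediment concentration
#'
#' @param ntu turbidity in nephelometric turbidity units (>= 0).
#' @param factor NTU-to-SSC conversion factor in mg/L per NTU (default 1.8).
#' @return SSC in mg/L, `factor * ntu`.
#' @examples
#' ntu_to_ssc(1.0)    # 1.8 mg/L
#' @export
ntu_to_ssc <- function(ntu, factor = 1.8) {
  if (factor <= 0) stop("conversion factor must be positive")
  if (any(ntu < 0, na.rm = TRUE)) stop("NTU values must be non-negative")
  factor * ntu
}

#' Daily light integral from quantum-flux samples
#'
#' Integrates photosynthetically active radiation over one civil day:
#' `DLI = sum(flux * interval_s) / 1e6` mol photons m^-2 d^-1 for flux in
#' umol m^-2 s^-1. For a constant flux the result is independent of the
#' sampling interval.
#'
#' @param flux vector of quantum-flux samples (umol m^-2 s^-1) covering one
#'   day; `NA` samples are dropped and the remaining samples rescaled to the
#'   day (equivalent to mean-imputation of the gaps).
#' @param interval_s sampling interval in seconds (default 1).
#' @return DLI in mol m^-2 d^-1; `NA` (with a warning) for an empty day.
#' @examples
#' dli_from_flux(rep(100, 86400))          # 8.64
#' dli_from_flux(rep(100, 144), 600)       # same day at 10-min sampling
#' @export
dli_from_flux <- function(flux, interval_s = 1) {
  if (interval_s <= 0) stop("interval_s must be positive")
  flux <- flux[!is.na(flux)]
  if (length(flux) == 0L) {
    warning("no flux samples for the day; DLI is missing")
    return(NA_real_)
  }
  if (any(flux < 0)) stop("quantum flux must be non-negative")
  mean(flux) * 86400 / 1e6
}

#' Unit-less sediment deposition index
#'
#' Per-site min-max normalisation of daily-mean deposition-sensor output to
#' the 0-1 range: `(x - min) / (max - min)`. Because the optical-backscatter
#' sensors are uncalibrated, only this relative index is comparable across
#' sites; the index is invariant to affine rescaling of the raw units.
#'
#' @param depo_raw daily-mean raw sensor values for one site.
#' @return Values in `[0, 1]`. A constant series returns all zeros with a
#'   warning (the normalisation is undefined).
#' @examples
#' deposition_index(c(2, 4, 6))   # 0 0.5 1
#' @export
deposition_index <- function(depo_raw) {
  x <- as.numeric(depo_raw)
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 daily values to normalise")
  rng <- range(x[ok])
  if (diff(rng) == 0) {
    warning("constant deposition series; index set to 0")
    x[ok] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Trailing running mean with a coverage rule
#'
#' Mean over the trailing window ending at each day (the pressure
#' experienced up to that day), using whatever values are available; the
#' result is emitted only where the fraction of non-missing days in the
#' window reaches `min_coverage`, and is `NA` otherwise. Early days with a
#' partial window count the missing lead-in against coverage.
#'
#' @param x daily series on a regular grid (may contain `NA`).
#' @param window_days window length in days.
#' @param min_coverage minimum available/window fraction (default 0.5).
#' @return numeric vector, same length as `x`.
#' @examples
#' running_mean(1:14, 14)[14]    # 7.5
#' @export
running_mean <- function(x, window_days, min_coverage = 0.5) {
  n <- length(x)
  w <- as.integer(window_days)
  if (w <= 0) stop("window_days must be positive")
  xs <- ifelse(is.na(x), 0, x)
  pres <- as.numeric(!is.na(x))
  cs <- cumsum(xs)
  cp <- cumsum(pres)
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)
  tot <- cs[idx] - c(0, cs)[lo + 1L]
  cnt <- cp[idx] - c(0, cp)[lo + 1L]
  out <- ifelse(cnt / w >= min_coverage & cnt > 0, tot / cnt, NA_real_)
  out
}

#' Fortnight index of a day
#'
#' Days are binned into non-overlapping fortnights anchored at the start of
#' dredging: `floor(day / length)`. Day 0 (dredging start) opens fortnight 0;
#' baseline days (negative indices) fall into negative fortnights.
#'
#' @param day integer day index (0 = dredging start).
#' @param length_days fortnight length (default 14).
#' @return integer fortnight index.
#' @export
fortnight_of <- function(day, length_days = 14L) {
  as.integer(floor(day / length_days))
}

#' Fortnightly summary of a smoothed daily series
#'
#' Bins a (site, day, value) running-mean series into fortnights and takes
#' the chosen statistic (maximum by default) of the non-missing values in
#' each bin; fortnights with no values yield no row.
#'
#' @param site_id,day,value parallel vectors: site code, integer day index,
#'   smoothed daily value.
#' @param stat summary statistic, `"max"` or `"min"`.
#' @param length_days fortnight length (default 14).
#' @return data.frame `site_id, fortnight, value`.
#' @export
fortnight_summary <- function(site_id, day, value, stat = c("max", "min"),
                              length_days = 14L) {
  stat <- match.arg(stat)
  stopifnot(length(site_id) == length(day), length(day) == length(value))
  keep <- !is.na(value)
  if (!any(keep))
    return(data.frame(site_id = character(), fortnight = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  df <- data.frame(site_id = site_id[keep],
                   fortnight = fortnight_of(day[keep], length_days),
                   value = value[keep], stringsAsFactors = FALSE)
  f <- if (stat == "max") max else min
  agg <- stats::aggregate(value ~ site_id + fortnight, data = df, FUN = f)
  agg <- agg[order(agg$site_id, agg$fortnight), c("site_id", "fortnight", "value")]
  rownames(agg) <- NULL
  agg
}

#' Full water-quality preprocessing chain
#'
#' Converts a daily record table (`site_id, day, ntu, dli, depo_raw`) into
#' the fortnightly pressure metrics: `ssc` (fortnightly max of the 14 d
#' running-mean SSC), `dli` (fortnightly max -- or min, by configuration --
#' of the 14 d running-mean DLI) and `depo_index` (fortnightly max of the
#' 60 d running-mean deposition index).
#'
#' @param records data.frame with columns `site_id, day, ntu, dli, depo_raw`,
#'   one row per site-day.
#' @param config a [preprocess_config()].
#' @return data.frame `site_id, fortnight, metric, value` in long format.
#' @export
preprocess_water_quality <- function(records, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  need <- c("site_id", "day", "ntu", "dli", "depo_raw")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(records[c("site_id", "day")]))
    stop("records must contain one row per (site, day)")
  out <- list()
  for (sid in unique(records$site_id)) {
    r <- records[records$site_id == sid, ]
    r <- r[order(r$day), ]
    # regularise onto the full day grid so windows count real gaps
    grid <- seq.int(min(r$day), max(r$day))
    m <- match(grid, r$day)
    ssc_d <- ntu_to_ssc(r$ntu, config$ntu_to_ssc_factor)[m]
    dli_d <- r$dli[m]
    depo_d <- suppressWarnings(deposition_index(r$depo_raw))[m]
    cov <- config$min_window_coverage
    chains <- list(
      ssc = list(x = running_mean(ssc_d, config$ssc_window_days, cov),
                 stat = "max"),
      dli = list(x = running_mean(dli_d, config$dli_window_days, cov),
                 stat = config$dli_stat),
      depo_index = list(x = running_mean(depo_d, config$depo_window_days, cov),
                        stat = "max"))
    for (metric in names(chains)) {
      fs <- fortnight_summary(rep(sid, length(grid)), grid,
                              chains[[metric]]$x, chains[[metric]]$stat,
                              config$fortnight_length_days)
      if (nrow(fs)) {
        fs$metric <- metric
        out[[length(out) + 1L]] <- fs
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("site_id", "fortnight", "metric", "value")]
  res <- res[order(res$metric, res$site_id, res$fortnight), ]
  rownames(res) <- NULL
  res
}
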