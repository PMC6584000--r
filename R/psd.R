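#' Particle size class boundaries
#'
#' The four-class scheme for seabed surficial sediment: gravel (> 2 mm),
#' sand (2000-62.5 um), silt (62.5-4 um) and clay (< 4 um). The classes
#' partition the positive size axis.
#'
#' @return data.frame `class, lower_um, upper_um` with strictly decreasing
#'   boundaries.
#' @export
size_class_scheme <- function() {
  data.frame(class = c("gravel", "sand", "silt", "clay"),
             lower_um = c(2000, 62.5, 4, 0),
             upper_um = c(Inf, 2000, 62.5, 4),
             stringsAsFactors = FALSE)
}

#' Classify a binned mass distribution into the four size classes
#'
#' Aggregates laboratory grain-size output (mass per size bin) into gravel /
#' sand / silt / clay percentages. Bins straddling a class boundary are
#' split pro-rata on the log-size axis, matching the log-binned output of
#' laser-diffraction instruments.
#'
#' @param mass non-negative mass (or volume) per bin.
#' @param bin_edges_um bin edges in micrometres, length `length(mass) + 1`,
#'   strictly monotone (either direction).
#' @return named numeric vector of percentages
#'   `(gravel, sand, silt, clay)` summing to 100.
#' @examples
#' classify_fractions(1, c(90, 110))              # all sand
#' classify_fractions(c(1, 1), c(0.9, 1.1, 11))   # clay plus a straddling bin
#' @export
classify_fractions <- function(mass, bin_edges_um) {
  if (length(bin_edges_um) != length(mass) + 1L)
    stop("bin_edges_um must have length(mass) + 1 entries")
  if (any(mass < 0)) stop("bin masses must be non-negative")
  if (sum(mass) <= 0) stop("total mass must be positive")
  if (any(bin_edges_um <= 0)) stop("bin edges must be positive sizes (um)")
  e <- as.numeric(bin_edges_um)
  if (is.unsorted(e, strictly = TRUE)) {
    if (is.unsorted(rev(e), strictly = TRUE))
      stop("bin edges must be strictly monotone")
    e <- rev(e); mass <- rev(mass)
  }
  scheme <- size_class_scheme()
  out <- stats::setNames(numeric(4), scheme$class)
  le <- log(e)
  for (k in seq_len(4)) {
    lo <- log(max(scheme$lower_um[k], .Machine$double.xmin))
    hi <- log(scheme$upper_um[k])
    # overlap of each bin with the class, on the log-size axis
    ov <- pmax(0, pmin(le[-1], hi) - pmax(le[-length(le)], lo))
    width <- le[-1] - le[-length(le)]
    out[k] <- sum(mass * ov / width)
  }
  100 * out / sum(out)
}

#' Combined silt and clay fraction of a composition
#'
#' @param sample named numeric vector or one-row data.frame holding the
#'   percentages `gravel, sand, silt, clay` (summing to 100).
#' @return proportion in `[0, 1]`: `(silt% + clay%) / 100`.
#' @examples
#' silt_clay_fraction(c(gravel = 10, sand = 40, silt = 30, clay = 20)) # 0.5
#' @export
silt_clay_fraction <- function(sample) {
  f <- psd_fractions(sample)
  (f[["silt"]] + f[["clay"]]) / 100
}

# Pull the four class percentages out of a vector or data.frame row.
psd_fractions <- function(sample) {
  cls <- c("gravel", "sand", "silt", "clay")
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    sample <- unlist(sample[cls])
  }
  if (!all(cls %in% names(sample)))
    stop("sample must contain named fractions: ", paste(cls, collapse = ", "))
  f <- as.numeric(sample[cls])
  names(f) <- cls
  if (any(f < 0)) stop("fractions must be non-negative")
  if (abs(sum(f) - 100) > 1e-6) stop("fractions must sum to 100")
  f
}

#' Silt+clay enrichment of a post-dredging sample over its baseline
#'
#' @param after_sample,before_sample matched compositions for the same site
#'   (see [silt_clay_fraction()] for the accepted forms); if both carry a
#'   `site_id` the ids must agree.
#' @return ratio `silt_clay(after) / silt_clay(before)`; `NA` with a warning
#'   when the baseline fraction is zero.
#' @export
enrichment_ratio <- function(after_sample, before_sample) {
  sid <- function(s) {
    if (is.data.frame(s) && "site_id" %in% names(s)) s$site_id[1]
    else if ("site_id" %in% names(s)) as.character(s[["site_id"]])
    else NA_character_
  }
  a_id <- sid(after_sample); b_id <- sid(before_sample)
  if (!is.na(a_id) && !is.na(b_id) && a_id != b_id)
    stop("after/before samples are from different sites: ", a_id, " vs ", b_id)
  before <- silt_clay_fraction(before_sample)
  if (before == 0) {
    warning("baseline silt+clay fraction is zero; enrichment undefined")
    return(NA_real_)
  }
  silt_clay_fraction(after_sample) / before
}

#' Ternary-plot coordinates of a composition
#'
#' Pools silt and clay and renormalises to the three-part composition
#' (gravel, sand, silt+clay) used for ternary display.
#'
#' @inheritParams silt_clay_fraction
#' @return named numeric triple summing to 1.
#' @export
ternary_coords <- function(sample) {
  f <- psd_fractions(sample)
  out <- c(gravel = f[["gravel"]], sand = f[["sand"]],
           silt_clay = f[["silt"]] + f[["clay"]]) / 100
  out / sum(out)
}
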