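#' The 7-category percent-cover score scale
#'
#' Sediment and mucous-sheet cover of a colony is scored on an ordered
#' categorical scale: 1 = 0%, 2 = 1-5%, 3 = 6-33%, 4 = 34-65%, 5 = 66-95%,
#' 6 = 96-99%, 7 = 100%. The printed integer band edges leave gaps for
#' fractional cover values; these are closed by the half-open convention
#' `(previous upper, upper]`, so e.g. 5.5% falls in category 3.
#'
#' @return data.frame `score, lower, upper, label`: category bands on the
#'   percent scale, contiguous and covering `[0, 100]`.
#' @export
score_scale <- function() {
  data.frame(score = 1:7,
             lower = c(-Inf, 0, 5, 33, 65, 95, 99),
             upper = c(0, 5, 33, 65, 95, 99, 100),
             label = c("0%", "1-5%", "6-33%", "34-65%", "66-95%", "96-99%",
                       "100%"),
             stringsAsFactors = FALSE)
}

#' Score a percent cover on the 1-7 categorical scale
#'
#' @param percent_cover percent of the colony surface covered, in `[0, 100]`.
#' @return integer category 1-7; monotone non-decreasing in the input.
#' @examples
#' score_from_percent(c(0, 5.5, 20, 100))   # 1 3 3 7
#' @export
score_from_percent <- function(percent_cover) {
  p <- as.numeric(percent_cover)
  if (any(p < 0 | p > 100, na.rm = TRUE))
    stop("percent cover must be within [0, 100]")
  sc <- score_scale()
  # half-open bands (lower, upper]; category 1 is exactly 0
  idx <- findInterval(p, sc$upper, left.open = TRUE) + 1L
  idx[!is.na(p) & p == 0] <- 1L
  as.integer(idx)
}

#' Percent-cover band of a score
#'
#' @param score integer category 1-7.
#' @return data.frame `score, lower, upper` of the covered percent band
#'   (`lower` is exclusive except for category 1).
#' @export
band_from_score <- function(score) {
  if (any(!score %in% 1:7)) stop("scores must be integers in 1..7")
  sc <- score_scale()
  out <- sc[match(score, sc$score), c("score", "lower", "upper")]
  out$lower[out$score == 1] <- 0
  rownames(out) <- NULL
  out
}

#' Classify tissue fate under sediment cover from a surface-state timeline
#'
#' For a chronologically ordered per-survey timeline of surface states
#' (`clear_live`, `covered`, `clear_dead`) the underlying tissue of each
#' maximal covered episode is labelled by the episode's outcome: if the
#' sediment is ultimately washed off to reveal live tissue, the covered
#' surveys are labelled `live`; if the cover ends in a dead surface, or the
#' record ends while still covered, the tissue is labelled `dead` from the
#' first covered survey of that episode. Clear surveys are labelled by their
#' own state. The same rule applies to mucous-sheet cover.
#'
#' @param surface_state character vector of states in chronological order.
#' @param day optional survey days used to check ordering.
#' @return character vector of per-survey labels `"live"` / `"dead"`.
#' @examples
#' classify_fate(c("clear_live", "covered", "covered", "clear_live"))
#' classify_fate(c("clear_live", "covered", "covered", "clear_dead"))
#' @export
classify_fate <- function(surface_state, day = NULL) {
  states <- c("clear_live", "covered", "clear_dead")
  if (!all(surface_state %in% states))
    stop("surface_state must be one of: ", paste(states, collapse = ", "))
  if (!is.null(day)) {
    if (length(day) != length(surface_state))
      stop("day and surface_state lengths differ")
    if (is.unsorted(day, strictly = TRUE))
      stop("timeline must be in strictly increasing day order")
  }
  n <- length(surface_state)
  out <- ifelse(surface_state == "clear_dead", "dead", "live")
  i <- 1L
  while (i <= n) {
    if (surface_state[i] == "covered") {
      j <- i
      while (j < n && surface_state[j + 1L] == "covered") j <- j + 1L
      ends_dead <- j == n || surface_state[j + 1L] == "clear_dead"
      out[i:j] <- if (ends_dead) "dead" else "live"
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Exclude dislodged colonies from a survey panel
#'
#' A colony flagged as moved or dislodged at any survey is removed from all
#' further analyses, including its earlier observations (whole-colony
#' removal).
#'
#' @param observations data.frame with at least `colony_id` and `dislodged`.
#' @return The observations of never-dislodged colonies; a warning if
#'   nothing remains.
#' @export
exclude_dislodged <- function(observations) {
  stopifnot(all(c("colony_id", "dislodged") %in% names(observations)))
  bad <- unique(observations$colony_id[observations$dislodged])
  out <- observations[!observations$colony_id %in% bad, , drop = FALSE]
  if (nrow(out) == 0L && nrow(observations) > 0L)
    warning("all colonies were flagged as dislodged; no observations remain")
  rownames(out) <- NULL
  out
}

#' Per-site score-exceedance proportions
#'
#' Proportion of observations (colony x survey) whose score reaches the
#' threshold, per site -- e.g. the fraction of surveys showing a sediment or
#' mucous cover score of 3 or more (>5% cover). With
#' `denominator = "colonies"` the proportion of colonies that ever exceed
#' the threshold is returned instead.
#'
#' @param observations filtered observation table (see
#'   [exclude_dislodged()]); must contain `site_id`, `colony_id` and the
#'   score column.
#' @param score_field name of the score column (e.g. `"sediment_score"`);
#'   may also name a logical column (e.g. `mortality_nonzero`), in which
#'   case `TRUE` counts as exceedance.
#' @param threshold minimum score counted as exceedance (default 3).
#' @param sites optional site table used to attach `distance_km`.
#' @param denominator `"observations"` (default) or `"colonies"`.
#' @return data.frame `site_id[, distance_km], metric, n_obs, proportion`;
#'   sites with no scored observations yield no row. Observation order does
#'   not affect the result.
#' @export
site_exceedance <- function(observations, score_field, threshold = 3,
                            sites = NULL,
                            denominator = c("observations", "colonies")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("site_id", "colony_id", score_field) %in% names(observations)))
  v <- observations[[score_field]]
  ex <- if (is.logical(v)) v else v >= threshold
  keep <- !is.na(ex)
  df <- data.frame(site_id = observations$site_id[keep],
                   colony_id = observations$colony_id[keep],
                   ex = ex[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(site_id = character(), metric = character(),
                      n_obs = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE))
  if (denominator == "colonies") {
    agg <- stats::aggregate(ex ~ site_id + colony_id, data = df, FUN = any)
    df <- data.frame(site_id = agg$site_id, colony_id = agg$colony_id,
                     ex = agg$ex, stringsAsFactors = FALSE)
  }
  n <- stats::aggregate(ex ~ site_id, data = df, FUN = length)
  k <- stats::aggregate(ex ~ site_id, data = df, FUN = sum)
  out <- data.frame(site_id = n$site_id,
                    metric = score_field,
                    n_obs = as.integer(n$ex),
                    proportion = k$ex / n$ex,
                    stringsAsFactors = FALSE)
  if (!is.null(sites))
    out$distance_km <- sites$distance_km[match(out$site_id, sites$site_id)]
  out <- out[order(out$site_id),
             c("site_id", intersect("distance_km", names(out)), "metric",
               "n_obs", "proportion")]
  rownames(out) <- NULL
  out
}
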