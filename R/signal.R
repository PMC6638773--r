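# Daily surveillance signals: aggregation, smoothing, correlation.

#' Daily signal from a classified post stream
#'
#' Aggregates classified posts to one value per calendar date (UTC):
#' either the count of relevant posts, or that count as a proportion of
#' all posts that day. The returned series is gap-free from the first to
#' the last observed date; dates with no posts get 0 (with a warning in
#' proportion mode, where the proportion is undefined).
#'
#' @param tweets data.frame with a `timestamp` column (POSIXct or Date)
#'   and a `label` column (`"relevant"`/`"irrelevant"`).
#' @param mode `"proportion"` or `"count"`.
#' @param label_col name of the label column.
#' @return data.frame of class `signal_series` with columns `date` and
#'   `value`.
#' @export
daily_signal <- function(tweets, mode = c("proportion", "count"),
                         label_col = "label") {
  mode <- match.arg(mode)
  if (nrow(tweets) == 0) {
    out <- data.frame(date = as.Date(character(0)), value = numeric(0))
    class(out) <- c("signal_series", "data.frame")
    return(out)
  }
  day <- as.Date(tweets$timestamp, tz = "UTC")
  lab <- as.character(tweets[[label_col]])
  dates <- seq(min(day), max(day), by = "day")
  n_all <- as.numeric(table(factor(day, levels = as.character(dates))))
  n_rel <- as.numeric(table(factor(day[lab == "relevant"],
                                   levels = as.character(dates))))
  value <- if (mode == "count") {
    n_rel
  } else {
    if (any(n_all == 0))
      warning(sum(n_all == 0),
              " day(s) with no posts: proportion undefined, set to 0")
    ifelse(n_all == 0, 0, n_rel / n_all)
  }
  out <- data.frame(date = dates, value = value)
  class(out) <- c("signal_series", "data.frame")
  out
}

#' Moving-average smoothing
#'
#' Smooths a daily series with a `window`-day moving average. The
#' default trailing alignment assigns to day `d` the mean of days
#' `d - window + 1 ... d`, the retrospective convention of surveillance
#' reporting; early days with less history use the mean of the days
#' available, so the output has the input's length. Centred alignment
#' shrinks the window symmetrically at both edges.
#'
#' @param s a [daily_signal()] series (data.frame with `date`, `value`).
#' @param window window length in days (default 7).
#' @param align `"trailing"` or `"centred"`.
#' @return a `signal_series` of the same length.
#' @export
moving_average <- function(s, window = 7,
                           align = c("trailing", "centred")) {
  align <- match.arg(align)
  stopifnot(window >= 1)
  n <- nrow(s)
  if (window > n) stop("window longer than the series")
  v <- s$value
  out <- numeric(n)
  half <- (window - 1) %/% 2
  for (i in seq_len(n)) {
    rng <- if (align == "trailing") {
      max(1, i - window + 1):i
    } else {
      max(1, i - half):min(n, i + half)
    }
    out[i] <- mean(v[rng])
  }
  res <- data.frame(date = s$date, value = out)
  class(res) <- c("signal_series", "data.frame")
  res
}

#' Pearson correlation of two daily series
#'
#' Intersects the two series on date, then computes the Pearson
#' correlation coefficient with its two-sided p-value. No interpolation
#' is done for missing dates. Correlation is symmetric in its arguments
#' and invariant to affine rescaling of either series.
#'
#' @param a,b `signal_series` data.frames (columns `date`, `value`).
#' @return list with `r`, `p`, `n` (overlapping days) and `degenerate`
#'   (`TRUE`, with an `NA` coefficient, when either series has zero
#'   variance on the overlap).
#' @export
correlate <- function(a, b) {
  m <- merge(as.data.frame(a), as.data.frame(b), by = "date",
             suffixes = c("_a", "_b"))
  n <- nrow(m)
  if (n < 3) stop("need at least 3 overlapping days")
  if (sd(m$value_a) == 0 || sd(m$value_b) == 0) {
    warning("zero variance in a series: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- cor.test(m$value_a, m$value_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       degenerate = FALSE)
}
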