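# Corpus input/output and stream cleaning.

url_pattern <- paste0(
  "(https?://[^[:space:]]+)",                       # scheme URLs
  "|(\\bwww\\.[^[:space:]]+)",                      # www. domains
  "|(\\b[a-zA-Z0-9-]+\\.[a-z]{2,6}/[^[:space:]]+)"  # bare domain-with-path
)

#' Replace URLs with a placeholder token
#'
#' Every URL substring (http/https scheme, `www.` prefix, or bare
#' domain-with-path) is replaced with the literal token `<URL>`. Texts
#' differing only in their URLs therefore normalise to the same string,
#' which is what makes duplicate detection robust to appended links.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' replace_urls("wheezing all day http://t.co/abc")
#' @export
replace_urls <- function(text) {
  gsub(url_pattern, "<URL>", text, perl = TRUE)
}

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  if (is.numeric(x))
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  is_epoch <- !is.na(num) & grepl("^[0-9]+(\\.[0-9]+)?$", x)
  out[is_epoch] <- as.POSIXct(num[is_epoch], origin = "1970-01-01",
                              tz = "UTC")
  # formats are tried per element, so one corpus may mix conventions
  formats <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS%z",
               "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%a %b %d %H:%M:%S %z %Y", "%Y-%m-%d")
  for (f in formats) {
    todo <- !is_epoch & is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

#' Load a corpus of posts
#'
#' Reads a line-delimited JSON (one object per line) or headed CSV corpus
#' into a data frame of posts. Each record must carry `id`, `text` and
#' `timestamp`; `user_id`, `timezone`, `place_country`, `coordinates`
#' (lat, lon) and `source` are optional. Records missing a mandatory field
#' or with an unparseable timestamp are skipped with a warning; the number
#' skipped is recorded in the `n_malformed` attribute. Timestamps
#' (ISO-8601 or epoch seconds) are normalised to UTC.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return data.frame with columns `id`, `text`, `timestamp` (POSIXct,
#'   UTC), `user_id`, `timezone`, `place_country`, `lat`, `lon`, `source`;
#'   attribute `n_malformed` counts skipped records.
#' @export
load_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    raw <- data.frame(
      id        = vapply(recs, function(r) as.character(r$id %||% NA), ""),
      text      = vapply(recs, function(r) as.character(r$text %||% NA), ""),
      timestamp = vapply(recs, function(r) as.character(r$timestamp %||% NA), ""),
      user_id   = vapply(recs, function(r) as.character(r$user_id %||% NA), ""),
      timezone  = vapply(recs, function(r) as.character(r$timezone %||% NA), ""),
      place_country = vapply(recs, function(r) as.character(r$place_country %||% NA), ""),
      lat = vapply(recs, function(r) {
        co <- r$coordinates; if (is.null(co) || length(co) < 2) NA_real_ else as.numeric(co[[1]])
      }, 0),
      lon = vapply(recs, function(r) {
        co <- r$coordinates; if (is.null(co) || length(co) < 2) NA_real_ else as.numeric(co[[2]])
      }, 0),
      source = vapply(recs, function(r) as.character(r$source %||% NA), ""),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    for (col in c("user_id", "timezone", "place_country", "source"))
      if (is.null(raw[[col]])) raw[[col]] <- NA_character_
    raw$lat <- if (is.null(raw$lat)) NA_real_ else as.numeric(raw$lat)
    raw$lon <- if (is.null(raw$lon)) NA_real_ else as.numeric(raw$lon)
  }
  ts <- parse_timestamps(raw$timestamp)
  ok <- !is.na(raw$id) & !is.na(raw$text) & nzchar(raw$text) & !is.na(ts)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " malformed record(s) skipped (missing id/text or ",
            "unparseable timestamp)")
  out <- raw[ok, c("id", "text", "user_id", "timezone", "place_country",
                   "lat", "lon", "source"), drop = FALSE]
  out$timestamp <- ts[ok]
  out <- out[, c("id", "text", "timestamp", "user_id", "timezone",
                 "place_country", "lat", "lon", "source")]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write a corpus as line-delimited JSON
#'
#' @param tweets data.frame as returned by [load_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(tweets, path) {
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    rec <- as.list(tweets[i, , drop = FALSE])
    rec <- lapply(rec, function(v) if (is.factor(v)) as.character(v) else v)
    if (inherits(rec$timestamp, "POSIXct"))
      rec$timestamp <- format(rec$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
    rec <- rec[!vapply(rec, function(v) all(is.na(v)), TRUE)]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bot/news posting heuristics
#'
#' The cleaning step can drop accounts that behave like automated or
#' news-feed posters. Three configurable rules, each of which can be
#' disabled: a `source` blocklist (substring match), a per-user daily
#' posting cap, and a "link with no first person" rule (text contains the
#' `<URL>` token and no first-person pronoun).
#'
#' @param source_blocklist character vector of source substrings.
#' @param max_daily_posts drop all posts of a user exceeding this many
#'   posts on a single UTC calendar day (`Inf` disables).
#' @param drop_impersonal_links if `TRUE`, drop posts containing `<URL>`
#'   and no first-person pronoun. Off by default: genuine personal posts
#'   do sometimes carry links, so this rule is opt-in.
#' @return a `bot_rules` list.
#' @export
bot_rules <- function(source_blocklist = character(0),
                      max_daily_posts = 10,
                      drop_impersonal_links = FALSE) {
  structure(list(source_blocklist = source_blocklist,
                 max_daily_posts = max_daily_posts,
                 drop_impersonal_links = drop_impersonal_links),
            class = "bot_rules")
}

first_person_pattern <- "\\b(i|i'm|i've|me|my|mine|we|our|us)\\b"

#' Clean a raw post stream
#'
#' Applies, in order: (1) retweet removal (text starting `"RT "`),
#' (2) URL tokenisation of all surviving texts via [replace_urls()],
#' (3) exact-text duplicate removal on the normalised text (lower-cased,
#' URL-tokenised, whitespace-collapsed; the earliest record of each group
#' survives), (4) bot/news heuristics (see [bot_rules()]), and (5)
#' per-user same-calendar-day deduplication (first post of the day kept).
#' Duplication is removed because repeated content inflates the daily
#' signal and can fabricate outbreaks.
#'
#' @param tweets data.frame of posts ([load_corpus()] layout).
#' @param rules a [bot_rules()] object.
#' @return list with `tweets` (the cleaned data.frame, URL-tokenised
#'   texts) and `report`, a `clean_report` with counts
#'   `n_input`, `n_retweets_removed`, `n_duplicates_removed`,
#'   `n_bots_removed`, `n_location_removed`, `n_output`.
#' @export
clean_corpus <- function(tweets, rules = bot_rules()) {
  n_input <- nrow(tweets)
  report <- list(n_input = n_input, n_retweets_removed = 0L,
                 n_duplicates_removed = 0L, n_bots_removed = 0L,
                 n_location_removed = 0L, n_output = 0L)
  if (n_input == 0) {
    report$n_output <- 0L
    return(list(tweets = tweets, report = structure(report,
                                                    class = "clean_report")))
  }
  tw <- tweets

  is_rt <- startsWith(tw$text, "RT ")
  report$n_retweets_removed <- sum(is_rt)
  tw <- tw[!is_rt, , drop = FALSE]

  tw$text <- replace_urls(tw$text)
  norm <- tolower(gsub("[[:space:]]+", " ", trimws(tw$text)))
  dup <- duplicated(norm)
  report$n_duplicates_removed <- sum(dup)
  tw <- tw[!dup, , drop = FALSE]

  # bot heuristics
  day <- as.Date(tw$timestamp, tz = "UTC")
  bot <- rep(FALSE, nrow(tw))
  if (length(rules$source_blocklist) > 0 && any(!is.na(tw$source))) {
    pat <- paste(rules$source_blocklist, collapse = "|")
    bot <- bot | (!is.na(tw$source) & grepl(pat, tw$source,
                                            ignore.case = TRUE))
  }
  if (is.finite(rules$max_daily_posts) && any(!is.na(tw$user_id))) {
    key <- paste(tw$user_id, day)
    counts <- table(key[!is.na(tw$user_id)])
    heavy <- names(counts)[counts > rules$max_daily_posts]
    bot <- bot | (!is.na(tw$user_id) & key %in% heavy)
  }
  if (isTRUE(rules$drop_impersonal_links)) {
    bot <- bot | (grepl("<URL>", tw$text, fixed = TRUE) &
                  !grepl(first_person_pattern, tolower(tw$text), perl = TRUE))
  }
  report$n_bots_removed <- sum(bot)
  tw <- tw[!bot, , drop = FALSE]
  day <- day[!bot]

  # per-user same-day repeats beyond the first
  has_user <- !is.na(tw$user_id)
  ukey <- paste(tw$user_id, day)
  rep_same_day <- has_user & duplicated(ukey)
  report$n_duplicates_removed <- report$n_duplicates_removed +
    sum(rep_same_day)
  tw <- tw[!rep_same_day, , drop = FALSE]

  report$n_output <- nrow(tw)
  rownames(tw) <- NULL
  list(tweets = tw, report = structure(report, class = "clean_report"))
}

#' @export
print.clean_report <- function(x, ...) {
  cat("corpus cleaning report\n")
  cat("  input:              ", x$n_input, "\n")
  cat("  retweets removed:   ", x$n_retweets_removed, "\n")
  cat("  duplicates removed: ", x$n_duplicates_removed, "\n")
  cat("  bots removed:       ", x$n_bots_removed, "\n")
  cat("  location removed:   ", x$n_location_removed, "\n")
  cat("  output:             ", x$n_output, "\n")
  invisible(x)
}

#' Define an acceptance region for coarse location filtering
#'
#' @param timezones accepted timezone strings (case-insensitive exact
#'   match).
#' @param countries accepted country codes/names (case-insensitive).
#' @param bbox numeric `c(lat_min, lat_max, lon_min, lon_max)` bounding
#'   box for point coordinates.
#' @return a `region_spec` list. `uk_region()` is a ready-made region for
#'   the United Kingdom.
#' @export
region_spec <- function(timezones = character(0), countries = character(0),
                        bbox = c(-90, 90, -180, 180)) {
  stopifnot(length(bbox) == 4)
  structure(list(timezones = tolower(timezones),
                 countries = tolower(countries), bbox = bbox),
            class = "region_spec")
}

#' @rdname region_spec
#' @export
uk_region <- function() {
  region_spec(
    timezones = c("london", "edinburgh", "dublin", "united kingdom", "uk"),
    countries = c("gb", "uk", "united kingdom", "great britain"),
    bbox = c(49.8, 60.9, -8.7, 1.8)
  )
}

#' Coarse location filtering
#'
#' A post is retained if at least one populated geolocation field
#' (timezone, place country, coordinates) matches the region. Posts with
#' all three fields absent are retained by default (`keep_nogeo = TRUE`):
#' geo fields are sparse on social platforms and dropping every bare post
#' empties the stream. Malformed coordinates are treated as absent with a
#' warning.
#'
#' @param tweets data.frame of posts.
#' @param region a [region_spec()].
#' @param keep_nogeo keep posts with no populated geo field?
#' @return the retained subset of `tweets`.
#' @export
filter_location <- function(tweets, region = uk_region(),
                            keep_nogeo = TRUE) {
  n <- nrow(tweets)
  if (n == 0) return(tweets)
  tz_ok <- !is.na(tweets$timezone) &
    tolower(tweets$timezone) %in% region$timezones
  co_ok <- !is.na(tweets$place_country) &
    tolower(tweets$place_country) %in% region$countries
  lat <- suppressWarnings(as.numeric(tweets$lat))
  lon <- suppressWarnings(as.numeric(tweets$lon))
  bad_coord <- (!is.na(tweets$lat) & is.na(lat)) |
    (!is.na(tweets$lon) & is.na(lon)) |
    (!is.na(lat) & (lat < -90 | lat > 90)) |
    (!is.na(lon) & (lon < -180 | lon > 180))
  if (any(bad_coord)) {
    warning(sum(bad_coord), " post(s) with malformed coordinates treated ",
            "as having none")
    lat[bad_coord] <- NA_real_
    lon[bad_coord] <- NA_real_
  }
  xy_ok <- !is.na(lat) & !is.na(lon) &
    lat >= region$bbox[1] & lat <= region$bbox[2] &
    lon >= region$bbox[3] & lon <= region$bbox[4]
  has_geo <- (!is.na(tweets$timezone)) | (!is.na(tweets$place_country)) |
    (!is.na(lat) & !is.na(lon))
  keep <- tz_ok | co_ok | xy_ok | (!has_geo & keep_nogeo)
  out <- tweets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
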