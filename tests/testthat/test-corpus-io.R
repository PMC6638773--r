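test_that("jsonl corpora parse, with malformed records skipped", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","text":"first post","timestamp":"2016-06-15T10:00:00Z"}',
    '{"id":"b","text":"second post","timestamp":1466000000}',
    '{"id":"c","text":"third post","timestamp":"2016-06-17 09:30:00"}'
  ), f)
  tw <- load_corpus(f, "jsonl")
  expect_equal(nrow(tw), 3)
  expect_equal(tw$id, c("a", "b", "c"))
  expect_equal(attr(tw, "n_malformed"), 0)

  # independent datetime oracles
  expect_equal(as.numeric(tw$timestamp[2]), 1466000000)
  expect_equal(tw$timestamp[1],
               as.POSIXct(strptime("2016-06-15 10:00:00", "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC")))

  writeLines(c(
    '{"id":"a","text":"ok","timestamp":"2016-06-15T10:00:00Z"}',
    '{"id":"b","timestamp":"2016-06-15T10:00:00Z"}'
  ), f)
  expect_warning(tw2 <- load_corpus(f, "jsonl"), "malformed")
  expect_equal(nrow(tw2), 1)
  expect_equal(attr(tw2, "n_malformed"), 1)

  expect_error(load_corpus(file.path(tempdir(), "nope.jsonl")), "cannot read")
})

test_that("URL replacement tokenises every URL and nothing else", {
  expect_equal(replace_urls("wheezing all day http://t.co/abc"),
               "wheezing all day <URL>")
  expect_equal(replace_urls("no links here"), "no links here")
  # texts differing only in URLs normalise identically
  set.seed(31)
  for (i in 1:20) {
    stem <- paste(sample(letters, 5), collapse = " ")
    u1 <- paste0("http://t.co/", paste(sample(c(letters, 0:9), 6), collapse = ""))
    u2 <- paste0("https://example.com/", i, "/x")
    expect_equal(replace_urls(paste(stem, u1)),
                 replace_urls(paste(stem, u2)))
  }
})

test_that("cleaning removes exactly the injected junk and reconciles", {
  corp <- generate_corpus(corpus_spec(n_tweets = 250, dup_rate = 0.08,
                                      rt_rate = 0.04, bot_rate = 0.05,
                                      seed = 12))
  ann <- corp$annotations
  cl <- clean_corpus(corp$tweets)
  r <- cl$report
  expect_equal(r$n_retweets_removed, sum(ann$is_retweet))
  expect_equal(r$n_duplicates_removed, sum(ann$is_duplicate))
  expect_equal(r$n_bots_removed, sum(ann$is_bot))
  expect_equal(r$n_output, sum(ann$is_base))
  expect_equal(r$n_output,
               r$n_input - r$n_retweets_removed - r$n_duplicates_removed -
                 r$n_bots_removed - r$n_location_removed)
  # all surviving texts URL-tokenised
  expect_false(any(grepl("https?://", cl$tweets$text)))
})

test_that("cleaning is idempotent and duplicate removal order-stable", {
  tw <- data.frame(
    id = c("x1", "x2", "x3", "x4"),
    text = c("my chest hurts http://t.co/aa",
             "placeholder",
             "my chest hurts http://t.co/bb",
             "unrelated post"),
    timestamp = as.POSIXct("2016-06-15 10:00:00", tz = "UTC") + 1:4,
    user_id = paste0("u", 1:4), timezone = NA, place_country = NA,
    lat = NA_real_, lon = NA_real_, source = "web",
    stringsAsFactors = FALSE
  )
  tw$text[2] <- "RT my chest hurts http://t.co/aa"
  cl1 <- clean_corpus(tw)
  expect_equal(cl1$tweets$id, c("x1", "x4"))  # first duplicate survives
  expect_equal(cl1$report$n_retweets_removed, 1)
  expect_equal(cl1$report$n_duplicates_removed, 1)
  cl2 <- clean_corpus(cl1$tweets)
  expect_equal(cl2$tweets, cl1$tweets)
  expect_equal(cl2$report$n_output, cl2$report$n_input)

  # empty input
  cl0 <- clean_corpus(tw[0, , drop = FALSE])
  expect_equal(cl0$report$n_input, 0)
  expect_equal(cl0$report$n_output, 0)
})

test_that("per-user same-day repeats are deduplicated to the first", {
  tw <- data.frame(
    id = paste0("p", 1:3),
    text = c("first today", "second today", "different day"),
    timestamp = as.POSIXct(c("2016-06-15 08:00:00", "2016-06-15 20:00:00",
                             "2016-06-16 08:00:00"), tz = "UTC"),
    user_id = "u1", timezone = NA, place_country = NA,
    lat = NA_real_, lon = NA_real_, source = "web",
    stringsAsFactors = FALSE
  )
  cl <- clean_corpus(tw)
  expect_equal(cl$tweets$id, c("p1", "p3"))
})

test_that("location filtering honours any matching geo field", {
  base <- data.frame(id = "t", text = "x",
                     timestamp = as.POSIXct("2016-06-15", tz = "UTC"),
                     user_id = "u", timezone = NA_character_,
                     place_country = NA_character_, lat = NA_real_,
                     lon = NA_real_, source = "web",
                     stringsAsFactors = FALSE)
  tz_lon <- transform(base, timezone = "London")
  paris <- transform(base, lat = 48.85, lon = 2.35)
  expect_equal(nrow(filter_location(tz_lon, uk_region())), 1)
  expect_equal(nrow(filter_location(paris, uk_region())), 0)
  expect_equal(nrow(filter_location(base, uk_region(), keep_nogeo = TRUE)), 1)
  expect_equal(nrow(filter_location(base, uk_region(), keep_nogeo = FALSE)), 0)

  # ground-truth recovery on a generated assignment
  set.seed(99)
  n <- 400
  in_uk <- runif(n) < 0.6
  tw <- do.call(rbind, replicate(n, base, simplify = FALSE))
  tw$id <- paste0("g", 1:n)
  mode <- sample(1:3, n, replace = TRUE)
  tw$timezone[mode == 1 & in_uk] <- "London"
  tw$timezone[mode == 1 & !in_uk] <- "Paris"
  tw$place_country[mode == 2 & in_uk] <- "GB"
  tw$place_country[mode == 2 & !in_uk] <- "FR"
  tw$lat[mode == 3] <- ifelse(in_uk[mode == 3], 52.5, 48.85)
  tw$lon[mode == 3] <- ifelse(in_uk[mode == 3], -1.9, 2.35)
  kept <- filter_location(tw, uk_region(), keep_nogeo = FALSE)
  expect_setequal(kept$id, tw$id[in_uk])

  # malformed coordinates treated as absent with a warning
  bad <- transform(base, lat = 500, lon = 10)
  expect_warning(out <- filter_location(bad, uk_region(),
                                        keep_nogeo = TRUE), "malformed")
  expect_equal(nrow(out), 1)
})

test_that("corpus round-trips through jsonl", {
  corp <- generate_corpus(corpus_spec(n_tweets = 30, seed = 3))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp$tweets, f)
  back <- load_corpus(f, "jsonl")
  expect_equal(back$id, corp$tweets$id)
  expect_equal(back$text, corp$tweets$text)
  expect_equal(round(as.numeric(back$timestamp)),
               round(as.numeric(corp$tweets$timestamp)))
})
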