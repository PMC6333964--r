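# The four-scenario time-point extractor, its validation rules, and the
# err-by-excess resolution policy.

test_that("time-unit spellings normalize case-insensitively", {
  expect_equal(normalize_time_unit("hr")$unit, "hour")
  expect_equal(normalize_time_unit("Hours")$unit, "hour")
  expect_equal(normalize_time_unit("wks")$unit, "week")
  expect_equal(normalize_time_unit("passages")$unit, "stage-ordinal")
  expect_null(normalize_time_unit("banana"))
  d <- normalize_time_unit("D")
  expect_equal(d$unit, "day")
  expect_true(d$single_letter)
  expect_false(normalize_time_unit("day")$single_letter)
})

test_that("explicit statements yield the stated count, erring by excess", {
  expect_equal(extract_explicit("we profiled 12 time points")$count, 12L)
  expect_equal(extract_explicit("7 developmental stages")$count, 7L)
  expect_equal(extract_explicit("samples span twelve time-points")$count, 12L)
  expect_null(extract_explicit("time points were sparse"))
  multi <- extract_explicit("4 time points in mice and 9 time points in rats")
  expect_equal(multi$count, 9L)
  expect_length(multi$evidence, 2L)
  expect_equal(multi$scenario, "EXPLICIT")
})

test_that("listings bind runs of numerals to their unit and dedupe", {
  five <- extract_listings("harvest at 6, 12 hours and 1, 3, 5 days")
  expect_equal(five$count, 5L)
  expect_equal(nrow(five$values), 5L)
  six <- extract_listings("0, 0.25, 1, 3, 6, and 24 h")
  expect_equal(six$count, 6L)
  before <- extract_listings("sampled on days 1, 3 and 7")
  expect_equal(before$count, 3L)
  pervalue <- extract_listings("latencies of 4 min, 8 min, 9 min and 13.5 min")
  expect_equal(pervalue$count, 4L)
  # unit identity across runs: 24 h duplicates 1 day
  dup <- extract_listings("measured at 6, 24 hours and 1, 3 days")
  expect_equal(dup$count, 3L)
})

test_that("descending and unit-less runs are not listings", {
  expect_null(extract_listings("12, 6, 3 hours"))
  expect_null(extract_listings("groups of 3, 5, 8 mice"))
  expect_null(extract_listings("incubated for 24 h"))  # lone value, no list
})

test_that("ranges contribute only their endpoints", {
  call <- extract_listings("sampled over 0-24 h and 3, 5 days")
  expect_equal(call$count, 4L)
})

test_that("approximate statements flag but never count", {
  call <- extract_approximate("at early stage and late stage of infection")
  expect_equal(call$scenario, "APPROXIMATE")
  expect_true(is.na(call$count))
  expect_length(call$evidence, 2L)
  expect_false(is.null(extract_approximate("middle age mice")))
  expect_null(extract_approximate("staged surgery"))
})

test_that("title candidates record unit form and positional context", {
  cand <- extract_title_candidates(c("ctrl d1 r1", "ctrl d3 r1", "ctrl d7 r1"))
  expect_equal(sort(cand$magnitude), c(1, 3, 7))
  expect_true(all(cand$unit == "day"))
  expect_true(all(cand$single_letter))
  expect_equal(cand$title_index, 1:3)
  expect_length(unique(cand$unit_offset), 1L)
  full <- extract_title_candidates(c("day 1 rep", "10 hr rep"))
  expect_equal(full$unit, c("day", "hour"))
  expect_false(any(full$single_letter))
  expect_equal(nrow(extract_title_candidates(c("sample A", "sample B"))), 0L)
})

test_that("rule i drops single-letter candidates echoed as cohort sizes", {
  meta <- series_metadata("G", summary = "45 patients enrolled in this study",
                          sample_titles = c("biopsy 45y a", "biopsy 52y b"))
  v <- validate_title_candidates(extract_title_candidates(meta$sample_titles),
                                 meta)
  expect_equal(nrow(v$accepted), 0L)
  expect_true(all(v$rejections$rule == "rule-i"))
  # same titles with a clean summary pass (two values, rule iii vacuous)
  clean <- series_metadata("G", summary = "gene expression in biopsies",
                           sample_titles = c("biopsy 45y a", "biopsy 52y b"))
  v2 <- validate_title_candidates(extract_title_candidates(clean$sample_titles),
                                  clean)
  expect_equal(nrow(v2$accepted), 2L)
})

test_that("rule ii drops slots shared with non-time letters", {
  meta <- series_metadata("G", sample_titles = c("ctrl d1 r1", "ctrl d3 r1",
                                                 "ctrl x9 r1"))
  v <- validate_title_candidates(extract_title_candidates(meta$sample_titles),
                                 meta)
  expect_equal(nrow(v$accepted), 0L)
  expect_true("rule-ii" %in% v$rejections$rule)
  # an aligned grid of unit letters is untouched
  grid <- series_metadata("G", sample_titles = c("ctrl d1 r1", "ctrl d2 r1",
                                                 "ctrl d4 r1"))
  v2 <- validate_title_candidates(extract_title_candidates(grid$sample_titles),
                                  grid)
  expect_equal(nrow(v2$accepted), 3L)
})

test_that("rule iii requires a 3-term progression among >= 3 values", {
  no_prog <- series_metadata("G", sample_titles = c("a d1", "a d5", "a d12"))
  v <- validate_title_candidates(
    extract_title_candidates(no_prog$sample_titles), no_prog)
  expect_equal(nrow(v$accepted), 0L)
  expect_true(all(v$rejections$rule == "rule-iii"))
  gp <- series_metadata("G", sample_titles = c("a d1", "a d2", "a d4", "a d8"))
  v2 <- validate_title_candidates(extract_title_candidates(gp$sample_titles),
                                  gp)
  expect_equal(nrow(v2$accepted), 4L)
  expect_equal(nrow(v2$rejections), 0L)
})

test_that("progression detection agrees with exhaustive enumeration", {
  expect_true(has_progression(c(0, 3, 6)))
  expect_true(has_progression(c(1, 2, 4)))
  expect_false(has_progression(c(1, 5, 12)))
  set.seed(101)
  for (i in 1:300) {
    v <- unique(sample(c(0:24, 2^(0:6), seq(0, 36, by = 3)),
                       sample(3:8, 1L)))
    expect_equal(has_progression(v), oracle_has_progression(v),
                 info = paste(v, collapse = ","))
  }
})

test_that("canonical deduplication merges equivalent units", {
  expect_equal(nrow(dedupe_time_values(
    time_values(c(24, 1), c("hour", "day")))), 1L)
  expect_equal(nrow(dedupe_time_values(
    time_values(c(0, 0), c("hour", "day")))), 1L)
  expect_equal(nrow(dedupe_time_values(
    time_values(c(6, 12, 1, 3, 5), c("hour", "hour", "day", "day", "day")))),
    5L)
  # stage ordinals never merge with temporal values
  mixed <- rbind(time_values(3, "stage-ordinal"), time_values(3, "hour"))
  expect_equal(nrow(dedupe_time_values(mixed)), 2L)
})

test_that("resolution takes the maximum count with scenario precedence", {
  meta <- series_metadata(
    "GSE1", summary = "we profiled 12 time points",
    sample_titles = c("cond d1 r1", "cond d2 r1", "cond d4 r1"))
  res <- resolve_series(meta)
  expect_equal(res$final_count, 12L)
  expect_equal(res$scenario, "EXPLICIT")
  # err-by-excess: final count >= every counted call
  counts <- vapply(res$calls, `[[`, integer(1), "count")
  expect_true(all(res$final_count >= counts[!is.na(counts)]))
})

test_that("series without temporal cues default to one time point", {
  res <- resolve_series(series_metadata("GSE1", summary = "plain study",
                                        sample_titles = c("a", "b")))
  expect_equal(res$final_count, 1L)
  expect_equal(res$scenario, "DEFAULT")
  expect_equal(nrow(res$final_values), 0L)
})

test_that("super-series are excluded from detection", {
  res <- resolve_series(series_metadata("GSE1", series_type = "SuperSeries",
                                        summary = "5 time points"))
  expect_true(res$excluded)
  expect_equal(res$final_count, 0L)
  expect_length(res$calls, 0L)
})

test_that("resolution is deterministic and unit-invariant", {
  meta <- series_metadata("GSE1",
                          summary = "harvest at 6, 12 hours and 1, 3, 5 days")
  expect_identical(resolve_series(meta), resolve_series(meta))
  # rewriting values in equivalent units leaves the count unchanged
  rewritten <- series_metadata("GSE1",
                               summary = "harvest at 6, 12, 24, 72, 120 hours")
  expect_equal(resolve_series(rewritten)$final_count,
               resolve_series(meta)$final_count)
})

test_that("approximate phrases set the flag without affecting the count", {
  meta <- series_metadata("GSE1",
                          summary = "tumors at early stage and late stage")
  res <- resolve_series(meta)
  expect_true(res$approximate_flag)
  expect_equal(res$final_count, 1L)
})

test_that("counted calls keep count equal to distinct values", {
  set.seed(202)
  for (i in 1:100) {
    cs <- gen_listing_case()
    call <- extract_listings(cs$text)
    if (!is.null(call)) {
      expect_equal(call$count, nrow(dedupe_time_values(call$values)))
    }
  }
})
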