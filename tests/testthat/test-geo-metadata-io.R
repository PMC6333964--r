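# Metadata container, SOFT and tabular parsing, super-series detection,
# and the restructured-record writer.

soft_fixture <- function(eol = "\n") {
  paste(c(
    "^SERIES = GSE1",
    "!Series_title = Test series",
    "!Series_geo_accession = GSE1",
    "!Series_summary = A.",
    "!Series_summary = B.",
    "!Series_overall_design = Design text",
    "!Series_type = Expression profiling by array",
    "!Series_platform_id = GPL570",
    "^SAMPLE = GSM1",
    "!Sample_title = t0",
    "^SAMPLE = GSM2",
    "!Sample_title = t1",
    "^SAMPLE = GSM3",
    "!Sample_title = t2"
  ), collapse = eol)
}

test_that("SOFT parsing concatenates repeated summaries and keeps sample order", {
  meta <- parse_soft_series(soft_fixture())
  expect_s3_class(meta, "series_metadata")
  expect_equal(meta$accession, "GSE1")
  expect_equal(meta$summary, "A. B.")
  expect_equal(meta$sample_titles, c("t0", "t1", "t2"))
  expect_equal(meta$aux$platform_id, "GPL570")
})

test_that("SOFT parsing is insensitive to line endings and trailing blanks", {
  lf <- parse_soft_series(soft_fixture("\n"))
  crlf <- parse_soft_series(soft_fixture("\r\n"))
  padded <- parse_soft_series(paste0(soft_fixture("\n"), "   \n\n"))
  expect_identical(lf, crlf)
  expect_identical(lf, padded)
})

test_that("streams without a series block raise a malformed-input error", {
  expect_error(parse_soft_series(character()), "no \\^SERIES")
  expect_error(parse_soft_series("just some text\nno records here"),
               "bytes")
})

test_that("tabular parsing matches columns case-insensitively and keeps aux", {
  rows <- data.frame(gse = "GSE1", title = "x", PUBMED_ID = "123",
                     platform_taxid = "9606", custom_col = "kept",
                     stringsAsFactors = FALSE)
  metas <- parse_tabular(rows)
  expect_length(metas, 1L)
  expect_equal(metas[[1]]$accession, "GSE1")
  expect_equal(metas[[1]]$pubmed_id, "123")
  expect_equal(metas[[1]]$aux$platform_taxid, "9606")
  expect_equal(metas[[1]]$aux$custom_col, "kept")
})

test_that("duplicate accessions in tabular input are a validation error", {
  rows <- data.frame(gse = c("GSE1", "GSE2", "GSE1"), title = "x")
  expect_error(parse_tabular(rows), "GSE1")
})

test_that("super-series detection uses type and summary boilerplate only", {
  plain <- series_metadata("GSE1", series_type = "Expression profiling by array")
  by_type <- series_metadata("GSE2", series_type = "SuperSeries")
  by_summary <- series_metadata(
    "GSE3",
    summary = "This SuperSeries is composed of the SubSeries listed below.")
  empty <- series_metadata("GSE4")
  expect_false(is_superseries(plain))
  expect_true(is_superseries(by_type))
  expect_true(is_superseries(by_summary))
  expect_false(is_superseries(empty))
  # pure function of type/summary: titles and design are irrelevant
  noisy <- series_metadata("GSE5", title = "SuperSeries of everything",
                           overall_design = "SuperSeries design")
  expect_false(is_superseries(noisy))
})

test_that("missing fields default to empty strings, never NA", {
  meta <- series_metadata("GSE1")
  for (f in c("title", "summary", "overall_design", "series_type",
              "organism", "pubmed_id", "abstract")) {
    expect_identical(meta[[f]], "")
  }
  expect_true(all(unlist(meta$aux) == ""))
  expect_error(series_metadata(""), "non-empty")
})

fixture_results <- function() {
  obo <- system.file("extdata", "mini_do.obo", package = "timegeo")
  idx <- load_ontology(obo)
  metas <- list(
    series_metadata("GSE1", title = "influenza and breast cancer study",
                    summary = "harvest at 6, 12 hours and 1, 3, 5 days",
                    aux = list(platform_id = "GPL570", contact = "a@b.c")),
    series_metadata("GSE2", summary = "no time information"),
    series_metadata("GSE3", series_type = "SuperSeries")
  )
  lapply(metas, function(m) {
    list(meta = m, time = resolve_series(m), tags = tag_series(idx, m))
  })
}

test_that("records round-trip bit-exactly through jsonl and csv", {
  records <- restructured_records(fixture_results())
  expect_equal(nrow(records), 3L)
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_restructured(records, path, format = fmt)
    back <- read_restructured(path, format = fmt)
    expect_identical(back, records, label = fmt)
  }
})

test_that("records carry pipe-joined DOID fields in tag order", {
  records <- restructured_records(fixture_results())
  r1 <- records[records$gse == "GSE1", ]
  expect_equal(r1$DOID_termIDs, "8469|1612")
  expect_equal(r1$DOID_termName, "influenza|breast cancer")
  expect_equal(r1$n_timepoints, 5L)
  expect_match(r1$time_values, "^6 hour;12 hour;1 day;3 day;5 day$")
  # tagless series have empty DOID fields; excluded series count 0
  r2 <- records[records$gse == "GSE2", ]
  expect_equal(r2$DOID_termIDs, "")
  r3 <- records[records$gse == "GSE3", ]
  expect_true(r3$is_superseries)
  expect_equal(r3$n_timepoints, 0L)
})
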