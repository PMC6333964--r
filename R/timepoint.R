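# Rule-based time-point extraction. Four scenarios are evaluated per
# series: an explicit statement of the number of time points, listings of
# time values in the summary / overall-design text, approximate temporal
# phrases, and number+unit tokens in sample titles. Candidates from sample
# titles pass through three validation rules before they are trusted, and
# conflicting scenario counts resolve to the maximum (the engine prefers
# to over-count rather than miss time points, since false extra time
# points are easy to discard downstream).

.word_numbers <- stats::setNames(
  1:20,
  c("one", "two", "three", "four", "five", "six", "seven", "eight", "nine",
    "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen", "sixteen",
    "seventeen", "eighteen", "nineteen", "twenty")
)

.explicit_keywords <-
  "time[ -]?points?|time[ -]?series|(?:developmental\\s+)?stages?|phases?"

.approximate_qualifiers <- c("early", "middle", "late", "terminal")
.approximate_heads <- "stages?|phases?|ages?|time[ -]?points?"

#' A scenario's extraction result
#'
#' @param scenario One of `"EXPLICIT"`, `"LISTING"`, `"APPROXIMATE"`,
#'   `"SAMPLE_TITLES"`.
#' @param count Non-negative integer, or `NA` for APPROXIMATE calls (which
#'   never contribute a numeric count).
#' @param values Time-value data frame (may have zero rows for EXPLICIT).
#' @param field_source `"summary"`, `"overall_design"` or `"sample_titles"`.
#' @param evidence Character vector of verbatim matched spans.
#' @return An object of class `timepoint_call`.
#' @export
timepoint_call <- function(scenario, count, values = empty_time_values(),
                           field_source = "summary", evidence = character()) {
  scenario <- match.arg(scenario,
                        c("EXPLICIT", "LISTING", "APPROXIMATE", "SAMPLE_TITLES"))
  if (!is.na(count) && length(evidence) == 0L) {
    stop("a counted call must carry evidence spans")
  }
  structure(
    list(scenario = scenario,
         count = if (is.na(count)) NA_integer_ else as.integer(count),
         values = values, field_source = field_source, evidence = evidence),
    class = "timepoint_call"
  )
}

#' @export
print.timepoint_call <- function(x, ...) {
  cat(sprintf("<timepoint_call> %s [%s] count=%s values=%d\n",
              x$scenario, x$field_source,
              ifelse(is.na(x$count), "-", x$count), nrow(x$values)))
  invisible(x)
}

# ---- scenario 1: explicit statement --------------------------------------

#' Extract an explicitly stated number of time points
#'
#' Matches phrases of the form "<N> time points" / "time-points" /
#' "time series" / "stages" / "developmental stages" / "phases", where N
#' is a numeral or a number word from one to twenty. When several such
#' statements occur, the maximum N wins (err-by-excess) and every matched
#' span is kept as evidence.
#'
#' @param text Summary or overall-design text.
#' @param field_source Label recorded on the call.
#' @return A `timepoint_call` of scenario EXPLICIT, or `NULL`.
#' @examples
#' extract_explicit("we profiled 12 time points")$count      # 12
#' extract_explicit("across 7 developmental stages")$count   # 7
#' @export
extract_explicit <- function(text, field_source = "summary") {
  txt <- normalize_text(text)
  num_alt <- paste0(.num_re, "|", paste(names(.word_numbers), collapse = "|"))
  pat <- paste0("\\b(", num_alt, ")[ -]+(?:different\\s+)?(?:",
                .explicit_keywords, ")\\b")
  m <- gregexpr(pat, txt, perl = TRUE, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(NULL)
  }
  spans <- regmatches(txt, list(m))[[1L]]
  nums <- vapply(spans, function(s) {
    tok <- tolower(regmatches(s, regexpr(paste0("^(?:", num_alt, ")"), s,
                                         perl = TRUE, ignore.case = TRUE)))
    if (grepl("^[0-9]", tok)) as.numeric(tok) else
      as.numeric(.word_numbers[[tok]])
  }, numeric(1))
  timepoint_call("EXPLICIT", count = as.integer(round(max(nums))),
                 field_source = field_source, evidence = unname(spans))
}

# ---- scenario 2: listings of time values ---------------------------------

# Tokenize text into NUM / RANGE / UNIT / SEP / OTHER tokens with positions.
.listing_tokens <- function(txt) {
  pat <- paste0(.num_re, "\\s?-\\s?", .num_re, "|", .num_re,
                "|[A-Za-z]+|,|&")
  m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(NULL)
  }
  toks <- regmatches(txt, list(m))[[1L]]
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  type <- character(length(toks))
  unit <- rep(NA_character_, length(toks))
  single <- logical(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[i]
    if (grepl(paste0("^", .num_re, "$"), tk)) {
      type[i] <- "NUM"
    } else if (grepl(paste0("^", .num_re, "\\s?-\\s?", .num_re, "$"), tk)) {
      type[i] <- "RANGE"
    } else if (tk == "," || tolower(tk) == "and" || tk == "&") {
      type[i] <- "SEP"
    } else {
      u <- normalize_time_unit(tk)
      if (!is.null(u)) {
        type[i] <- "UNIT"
        unit[i] <- u$unit
        single[i] <- u$single_letter
      } else {
        type[i] <- "OTHER"
      }
    }
  }
  data.frame(token = toks, type = type, unit = unit, single = single,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

# numbers carried by a NUM or RANGE token (a range contributes endpoints)
.token_numbers <- function(token) {
  as.numeric(regmatches(token, gregexpr(.num_re, token, perl = TRUE))[[1L]])
}

# Partition a chain of NUM/RANGE/UNIT/SEP tokens into listing groups:
# runs of numbers bound to a unit written after them, before them, or on
# every number (consecutive single-number groups merge into a per-value
# group).
.chain_groups <- function(tok) {
  groups <- list()
  pending <- list() # list of (nums, token index)
  prefix_unit <- NULL
  flush <- function(unit_row, style) {
    if (length(pending) == 0L) return()
    idx <- c(vapply(pending, `[[`, integer(1), "i"),
             if (!is.null(unit_row)) unit_row$i)
    groups[[length(groups) + 1L]] <<- list(
      nums = unlist(lapply(pending, `[[`, "nums")),
      unit = unit_row$unit, single = unit_row$single,
      style = style, from = min(idx), to = max(idx),
      span_start = min(tok$start[idx]), span_end = max(tok$end[idx])
    )
    pending <<- list()
  }
  last_type <- ""
  for (i in seq_len(nrow(tok))) {
    ty <- tok$type[i]
    if (ty %in% c("NUM", "RANGE")) {
      if (last_type %in% c("NUM", "RANGE")) {
        pending <- list() # juxtaposed numbers without separator: restart run
      }
      pending[[length(pending) + 1L]] <-
        list(nums = .token_numbers(tok$token[i]), i = i)
    } else if (ty == "UNIT") {
      u <- list(unit = tok$unit[i], single = tok$single[i], i = i)
      if (length(pending) > 0L) {
        flush(u, "after")
        prefix_unit <- NULL
      } else {
        prefix_unit <- u
      }
    }
    # SEP tokens just continue the chain
    last_type <- ty
  }
  if (length(pending) > 0L && !is.null(prefix_unit)) {
    flush(prefix_unit, "before")
  }
  groups
}

# merge maximal runs of >= 2 consecutive single-number "after"-style groups
# into per-value-unit groups (a list of numbers each with its own unit)
.merge_pervalue <- function(groups) {
  if (length(groups) == 0L) return(groups)
  singleton <- vapply(groups, function(g) {
    length(g$nums) == 1L && g$style == "after"
  }, logical(1))
  out <- list()
  i <- 1L
  while (i <= length(groups)) {
    j <- i
    while (j < length(groups) && singleton[j] && singleton[j + 1L]) j <- j + 1L
    if (j > i) {
      run <- groups[i:j]
      out[[length(out) + 1L]] <- list(
        nums = vapply(run, `[[`, numeric(1), "nums"),
        unit = vapply(run, `[[`, character(1), "unit"),
        single = vapply(run, `[[`, logical(1), "single"),
        style = "pervalue",
        span_start = min(vapply(run, `[[`, integer(1), "span_start")),
        span_end = max(vapply(run, `[[`, integer(1), "span_end"))
      )
    } else {
      out[[length(out) + 1L]] <- groups[[i]]
    }
    i <- j + 1L
  }
  out
}

#' Extract listings of time values
#'
#' Detects comma/"and"-separated runs of numerals bound to a time unit:
#' either one unit for the whole run, written before or after it
#' ("harvest at 6, 12 hours", "days 1, 3, 5"), or one unit per numeral
#' ("4 min, 8 min, 9 min"). A shared-unit run is accepted only if it is
#' strictly ascending; a per-value-unit run must be non-decreasing in
#' canonical hours. Several runs in the same sentence are unioned
#' ("harvest at 6, 12 hours and 1, 3, 5 days"), and the count is the
#' number of distinct canonical values after deduplication. Numeric
#' ranges ("0-24 h") contribute only their endpoints.
#'
#' @param text Summary or overall-design text.
#' @param field_source Label recorded on the call.
#' @return A `timepoint_call` of scenario LISTING, or `NULL` when no valid
#'   listing is present.
#' @examples
#' extract_listings("harvest at 6, 12 hours and 1, 3, 5 days")$count  # 5
#' extract_listings("0, 0.25, 1, 3, 6, and 24 h")$count               # 6
#' extract_listings("12, 6, 3 hours")                                 # NULL
#' @export
extract_listings <- function(text, field_source = "summary") {
  txt <- tolower(normalize_text(text))
  tok <- .listing_tokens(txt)
  if (is.null(tok)) {
    return(NULL)
  }
  chain_break <- tok$type == "OTHER"
  chain_id <- cumsum(chain_break)
  all_values <- empty_time_values()
  evidence <- character()
  for (cid in unique(chain_id[!chain_break])) {
    sel <- chain_id == cid & !chain_break
    chain <- tok[sel, , drop = FALSE]
    chain$i <- seq_len(nrow(chain))
    if (!any(chain$type %in% c("NUM", "RANGE")) || !any(chain$type == "UNIT")) {
      next
    }
    groups <- .merge_pervalue(.chain_groups(chain))
    for (g in groups) {
      nums <- g$nums
      if (length(nums) < 2L) next # a lone number+unit is not a listing
      ok <- if (identical(g$style, "pervalue")) {
        tv <- time_values(nums, g$unit)
        keys <- .value_keys(tv)
        all(diff(keys) >= -1e-12)
      } else {
        all(diff(nums) > 0)
      }
      if (!ok) next
      span <- substr(txt, g$span_start, g$span_end)
      tv <- time_values(nums, g$unit, source_text = span,
                        single_letter = g$single)
      all_values <- rbind(all_values, tv)
      evidence <- c(evidence, span)
    }
  }
  if (nrow(all_values) == 0L) {
    return(NULL)
  }
  vals <- dedupe_time_values(all_values)
  timepoint_call("LISTING", count = nrow(vals), values = vals,
                 field_source = field_source, evidence = unique(evidence))
}

# ---- scenario 3: approximate statements ----------------------------------

#' Detect approximate temporal statements
#'
#' Matches a small fixed lexicon of qualitative temporal phrases
#' ("early stage", "late phase", "middle age", ...). Such phrases flag a
#' series as temporally structured but never yield a numeric count; the
#' call's count is `NA` and it never contributes to the resolved count.
#'
#' @param text Summary or overall-design text.
#' @param field_source Label recorded on the call.
#' @return A `timepoint_call` of scenario APPROXIMATE, or `NULL`.
#' @export
extract_approximate <- function(text, field_source = "summary") {
  txt <- normalize_text(text)
  pat <- paste0("\\b(?:", paste(.approximate_qualifiers, collapse = "|"),
                ")[ -](?:", .approximate_heads, ")\\b")
  m <- gregexpr(pat, txt, perl = TRUE, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(NULL)
  }
  spans <- regmatches(txt, list(m))[[1L]]
  timepoint_call("APPROXIMATE", count = NA_integer_,
                 field_source = field_source, evidence = unname(spans))
}

# ---- scenario 4: sample titles -------------------------------------------

#' Extract time-value candidates from sample titles
#'
#' Scans each title for number+unit and unit+number tokens, with or
#' without a separator ("day 1", "day1", "10 hr", "10h", "d3"). Full-word
#' and abbreviated unit spellings are matched first; single-letter units
#' are matched last and flagged, since they are the ambiguous forms the
#' validation rules scrutinize. Every candidate records its title index,
#' match offset, and the character offset of the unit token, because the
#' validation rules need positional context; duplicates across titles are
#' kept.
#'
#' @param titles Character vector of sample titles.
#' @return A time-value data frame, one row per candidate.
#' @examples
#' extract_title_candidates(c("ctrl d1 r1", "ctrl d3 r1", "ctrl d7 r1"))
#' @export
extract_title_candidates <- function(titles) {
  multi <- unlist(lapply(.unit_synonyms, function(x) x[nchar(x) > 1L]),
                  use.names = FALSE)
  multi <- multi[order(-nchar(multi))]
  multi_alt <- paste(multi, collapse = "|")
  sl_alt <- paste(.single_letter_units, collapse = "")
  passes <- list(
    list(pat = paste0("\\b(", .num_re, ")[ _-]?(", multi_alt, ")\\b"),
         order = c("num", "unit")),
    list(pat = paste0("\\b(", multi_alt, ")[ _-]?(", .num_re, ")\\b"),
         order = c("unit", "num")),
    list(pat = paste0("\\b(", .num_re, ")[ _-]?([", sl_alt, "])\\b"),
         order = c("num", "unit")),
    list(pat = paste0("\\b([", sl_alt, "])[ _-]?(", .num_re, ")\\b"),
         order = c("unit", "num"))
  )
  out <- empty_time_values()
  for (ti in seq_along(titles)) {
    title <- normalize_text(titles[ti])
    claimed <- integer(0) # character positions already matched
    for (p in passes) {
      m <- gregexpr(p$pat, title, perl = TRUE, ignore.case = TRUE)[[1L]]
      if (m[1L] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      spans <- regmatches(title, list(m))[[1L]]
      for (k in seq_along(starts)) {
        pos <- seq(starts[k], starts[k] + lens[k] - 1L)
        if (any(pos %in% claimed)) next
        span <- spans[k]
        num_m <- regexpr(.num_re, span, perl = TRUE)
        magnitude <- as.numeric(regmatches(span, num_m))
        unit_tok <- trimws(gsub(.num_re, "", gsub("[ _-]", " ", span)))
        u <- normalize_time_unit(unit_tok)
        if (is.null(u)) next
        unit_in_span <- regexpr(unit_tok, span, ignore.case = TRUE)
        unit_offset <- starts[k] + as.integer(unit_in_span) - 1L
        claimed <- c(claimed, pos)
        out <- rbind(out, time_values(
          magnitude, u$unit, source_text = span,
          single_letter = u$single_letter, title_index = ti,
          offset = starts[k], unit_offset = unit_offset))
      }
    }
  }
  out
}

# numbers occurring within `window` tokens of a sample/patient keyword
.protected_numbers <- function(text, vocab, window = 2L) {
  txt <- tolower(normalize_text(text))
  toks <- regmatches(txt, gregexpr(paste0(.num_re, "|[a-z]+"), txt,
                                   perl = TRUE))[[1L]]
  if (length(toks) == 0L) {
    return(numeric())
  }
  kw <- which(toks %in% vocab)
  hits <- numeric()
  for (i in kw) {
    near <- toks[max(1L, i - window):min(length(toks), i + window)]
    nums <- suppressWarnings(as.numeric(near[grepl("^[0-9]", near)]))
    hits <- c(hits, nums[!is.na(nums)])
  }
  unique(hits)
}

#' Validate sample-title candidates
#'
#' Applies the three validation rules for time points found in sample
#' titles. Rules i and ii apply only to candidates with single-letter
#' units (full-word units are trusted):
#'
#' * rule i — the whole single-letter candidate set is dropped if any
#'   candidate magnitude also appears within a two-token window of a
#'   sample/patient/subject keyword in the summary or overall design
#'   (the number is then a cohort size, not a time point);
#' * rule ii — single-letter candidates at a given unit-letter offset are
#'   dropped when, at the same offset in other titles, letters occur that
#'   do not belong to the time-unit alphabet `s h d w m y` (the slot is
#'   then an arbitrary code, not a time unit);
#' * rule iii — if the deduplicated surviving set has three or more
#'   distinct canonical values, some three of them must form an
#'   arithmetic or geometric progression, otherwise all candidates are
#'   rejected; sets of at most two distinct values pass vacuously.
#'
#' @param candidates Data frame from [extract_title_candidates()].
#' @param meta The series' [series_metadata()] (for rule i context and the
#'   titles for rule ii).
#' @param sample_vocab Keywords for rule i.
#' @param window Token window for rule i.
#' @param tol Progression tolerance for rule iii.
#' @return A list with `accepted` (deduplicated time-value data frame) and
#'   `rejections` (data frame with columns `source_text`, `magnitude`,
#'   `unit`, `rule`).
#' @export
validate_title_candidates <- function(candidates, meta,
                                      sample_vocab = c("sample", "samples",
                                                       "patient", "patients",
                                                       "subject", "subjects"),
                                      window = 2L, tol = 1e-6) {
  rejections <- data.frame(source_text = character(), magnitude = numeric(),
                           unit = character(), rule = character(),
                           stringsAsFactors = FALSE)
  reject <- function(rows, rule) {
    rejections <<- rbind(rejections, data.frame(
      source_text = rows$source_text, magnitude = rows$magnitude,
      unit = rows$unit, rule = rule, stringsAsFactors = FALSE))
  }
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(accepted = empty_time_values(), rejections = rejections))
  }
  cand <- candidates
  titles <- normalize_text(meta$sample_titles)

  # rule i: magnitudes echoed near sample/patient counts kill the whole
  # single-letter set
  sl <- cand$single_letter
  if (any(sl)) {
    protected <- .protected_numbers(paste(meta$summary, meta$overall_design),
                                    sample_vocab, window)
    if (any(cand$magnitude[sl] %in% protected)) {
      reject(cand[sl, , drop = FALSE], "rule-i")
      cand <- cand[!sl, , drop = FALSE]
    }
  }

  # rule ii: non-time letters in the same slot of other titles
  sl <- which(cand$single_letter)
  if (length(sl) > 0L) {
    drop <- logical(nrow(cand))
    for (off in unique(cand$unit_offset[sl])) {
      in_group <- cand$single_letter & cand$unit_offset == off
      group_titles <- unique(cand$title_index[in_group])
      others <- setdiff(seq_along(titles), group_titles)
      others <- others[nchar(titles[others]) >= off]
      ch <- tolower(substr(titles[others], off, off))
      foreign <- grepl("[a-z]", ch) & !ch %in% .single_letter_units
      if (any(foreign)) {
        drop <- drop | in_group
      }
    }
    if (any(drop)) {
      reject(cand[drop, , drop = FALSE], "rule-ii")
      cand <- cand[!drop, , drop = FALSE]
    }
  }

  # rule iii: >= 3 distinct values must contain a 3-term AP or GP
  deduped <- dedupe_time_values(cand)
  if (nrow(deduped) >= 3L && !has_progression(.value_keys(deduped), tol)) {
    reject(cand, "rule-iii")
    cand <- cand[0L, , drop = FALSE]
    deduped <- empty_time_values()
  }
  list(accepted = deduped, rejections = rejections)
}

# ---- resolution -----------------------------------------------------------

#' Resolve the time-point count of a series
#'
#' Runs all four extraction scenarios on a series and resolves them into a
#' final count. Super-series are excluded (count 0, no calls). Otherwise
#' the explicit and listing extractors run on the summary and the overall
#' design, the approximate detector on both, and the sample-title pathway
#' on the titles. The final count is the maximum over all counted calls
#' (err-by-excess); ties are broken by scenario precedence
#' EXPLICIT > LISTING > SAMPLE_TITLES, then field precedence
#' summary > overall_design. A series with no counted call is a
#' single-time-point series (count 1, no values).
#'
#' @param meta A [series_metadata()] object.
#' @param sample_vocab,window,tol Passed to [validate_title_candidates()].
#' @return An object of class `series_time_result` with fields
#'   `accession`, `final_count`, `final_values`, `scenario`, `calls`,
#'   `excluded`, `approximate_flag`, `rejections`.
#' @export
resolve_series <- function(meta, sample_vocab = c("sample", "samples",
                                                  "patient", "patients",
                                                  "subject", "subjects"),
                           window = 2L, tol = 1e-6) {
  stopifnot(inherits(meta, "series_metadata"))
  empty_rej <- data.frame(source_text = character(), magnitude = numeric(),
                          unit = character(), rule = character(),
                          stringsAsFactors = FALSE)
  if (is_superseries(meta)) {
    return(structure(
      list(accession = meta$accession, final_count = 0L,
           final_values = empty_time_values(), scenario = "EXCLUDED",
           calls = list(), excluded = TRUE, approximate_flag = FALSE,
           rejections = empty_rej),
      class = "series_time_result"))
  }
  calls <- list()
  for (field in c("summary", "overall_design")) {
    txt <- meta[[field]]
    for (f in list(extract_explicit, extract_listings, extract_approximate)) {
      call <- f(txt, field_source = field)
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  cand <- extract_title_candidates(meta$sample_titles)
  val <- validate_title_candidates(cand, meta, sample_vocab = sample_vocab,
                                   window = window, tol = tol)
  if (nrow(val$accepted) > 0L) {
    calls[[length(calls) + 1L]] <- timepoint_call(
      "SAMPLE_TITLES", count = nrow(val$accepted), values = val$accepted,
      field_source = "sample_titles", evidence = val$accepted$source_text)
  }
  counts <- vapply(calls, `[[`, integer(1), "count")
  counted <- which(!is.na(counts))
  approximate_flag <- any(vapply(calls, function(x) {
    x$scenario == "APPROXIMATE"
  }, logical(1)))
  if (length(counted) == 0L) {
    final_count <- 1L
    final_values <- empty_time_values()
    scenario <- "DEFAULT"
  } else {
    final_count <- max(counts[counted])
    best <- counted[counts[counted] == final_count]
    scen_rank <- c(EXPLICIT = 1L, LISTING = 2L, SAMPLE_TITLES = 3L)
    field_rank <- c(summary = 1L, overall_design = 2L, sample_titles = 3L)
    ord <- order(
      scen_rank[vapply(calls[best], `[[`, character(1), "scenario")],
      field_rank[vapply(calls[best], `[[`, character(1), "field_source")])
    win <- calls[[best[ord[1L]]]]
    final_values <- win$values
    scenario <- win$scenario
  }
  structure(
    list(accession = meta$accession, final_count = final_count,
         final_values = final_values, scenario = scenario, calls = calls,
         excluded = FALSE, approximate_flag = approximate_flag,
         rejections = val$rejections),
    class = "series_time_result")
}

#' @export
print.series_time_result <- function(x, ...) {
  cat(sprintf("<series_time_result> %s: %d time point(s) [%s]%s\n",
              x$accession, x$final_count, x$scenario,
              if (x$approximate_flag) " +approximate" else ""))
  if (nrow(x$final_values) > 0L) {
    cat("  values: ", format_time_value(x$final_values), "\n", sep = "")
  }
  if (nrow(x$rejections) > 0L) {
    cat("  rejections: ",
        paste(sprintf("%s (%s)", x$rejections$source_text, x$rejections$rule),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
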