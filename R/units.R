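# Canonical time-unit handling: every temporal magnitude is converted to
# hours so that values written in different units (24 h vs 1 day) compare
# as the same time point. Stage/passage ordinals have no duration and are
# compared by their bare magnitude.

.unit_factors <- c(
  second = 1 / 3600,
  minute = 1 / 60,
  hour   = 1,
  day    = 24,
  week   = 168,
  month  = 720,   # 30-day months, fixed for determinism
  year   = 8760
)

.unit_synonyms <- list(
  second            = c("s", "sec", "secs", "second", "seconds"),
  minute            = c("min", "mins", "minute", "minutes"),
  hour              = c("h", "hr", "hrs", "hour", "hours"),
  day               = c("d", "day", "days"),
  week              = c("w", "wk", "wks", "week", "weeks"),
  month             = c("m", "mo", "mos", "month", "months"),
  year              = c("y", "yr", "yrs", "year", "years"),
  "stage-ordinal"   = c("stage", "stages", "passage", "passages")
)

.unit_lookup <- local({
  u <- rep(names(.unit_synonyms), lengths(.unit_synonyms))
  names(u) <- unlist(.unit_synonyms, use.names = FALSE)
  u
})

# single-letter spellings get extra scrutiny in the sample-title rules
.single_letter_units <- c("s", "h", "d", "w", "m", "y")

.num_re <- "[0-9]+(?:\\.[0-9]+)?"

#' Normalize a time-unit token
#'
#' Maps the common spellings of time units (`"hr"`, `"hours"`, `"d"`,
#' `"wks"`, ...) onto canonical unit names, case-insensitively. Stage and
#' passage tokens map to the pseudo-unit `"stage-ordinal"`, which carries
#' no duration. Single-letter spellings (`s h d w m y`) are flagged,
#' because they are the ambiguous forms that the sample-title validation
#' rules treat with suspicion.
#'
#' @param token A single word.
#' @return `NULL` if the token is not a time unit, otherwise a list with
#'   elements `unit` (canonical name) and `single_letter` (logical).
#' @examples
#' normalize_time_unit("hr")     # hour
#' normalize_time_unit("D")      # day, single-letter
#' normalize_time_unit("banana") # NULL
#' @export
normalize_time_unit <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- tolower(trimws(token))
  unit <- unname(.unit_lookup[tok])
  if (is.na(unit)) {
    return(NULL)
  }
  list(unit = unit, single_letter = tok %in% .single_letter_units)
}

#' Construct a table of time values
#'
#' A time value is a magnitude plus a unit; temporal units also get a
#' canonical magnitude in hours (`canonical_hours`), which is what all
#' identity and progression checks operate on. Stage ordinals have
#' `canonical_hours = NA` and compare by magnitude.
#'
#' @param magnitude Numeric vector of non-negative magnitudes.
#' @param unit Character vector of canonical unit names (recycled).
#' @param source_text Verbatim matched spans (recycled).
#' @param single_letter Whether the unit was spelled as a single letter.
#' @param title_index,offset,unit_offset Positional context for candidates
#'   extracted from sample titles (1-based title index, character offset of
#'   the match, character offset of the unit letter); `NA` elsewhere.
#' @return A data frame with one row per value.
#' @export
time_values <- function(magnitude, unit, source_text = paste(magnitude, unit),
                        single_letter = FALSE, title_index = NA_integer_,
                        offset = NA_integer_, unit_offset = NA_integer_) {
  n <- length(magnitude)
  if (n == 0L) {
    return(empty_time_values())
  }
  unit <- rep_len(unit, n)
  bad <- !unit %in% c(names(.unit_factors), "stage-ordinal")
  if (any(bad)) {
    stop("unknown canonical unit(s): ", paste(unique(unit[bad]), collapse = ", "))
  }
  canonical <- ifelse(unit == "stage-ordinal", NA_real_,
                      magnitude * unname(.unit_factors[unit]))
  data.frame(
    magnitude = as.numeric(magnitude),
    unit = unit,
    canonical_hours = canonical,
    source_text = rep_len(as.character(source_text), n),
    single_letter = rep_len(as.logical(single_letter), n),
    title_index = rep_len(as.integer(title_index), n),
    offset = rep_len(as.integer(offset), n),
    unit_offset = rep_len(as.integer(unit_offset), n),
    stringsAsFactors = FALSE
  )
}

empty_time_values <- function() {
  data.frame(
    magnitude = numeric(), unit = character(), canonical_hours = numeric(),
    source_text = character(), single_letter = logical(),
    title_index = integer(), offset = integer(), unit_offset = integer(),
    stringsAsFactors = FALSE
  )
}

# comparison key: canonical hours for temporal values, magnitude for
# stage ordinals (kept on a separate branch so 3 h never equals stage 3)
.value_keys <- function(values) {
  ifelse(is.na(values$canonical_hours), values$magnitude, values$canonical_hours)
}

.same_value <- function(key1, stage1, key2, stage2, tol = 1e-9) {
  if (stage1 != stage2) {
    return(FALSE)
  }
  abs(key1 - key2) <= tol * max(abs(key1), abs(key2), 1e-300) ||
    (key1 == 0 && key2 == 0)
}

#' Deduplicate time values by canonical identity
#'
#' Two temporal values are the same time point when their canonical hours
#' agree within a relative tolerance of 1e-9 (so 24 h and 1 day collapse,
#' and 0 h equals 0 days). Stage ordinals compare by magnitude and never
#' merge with temporal values. The first-seen representative is kept, in
#' input order.
#'
#' @param values A time-value data frame (see [time_values()]).
#' @return The subset of `values` with duplicates removed.
#' @export
dedupe_time_values <- function(values) {
  if (is.null(values) || nrow(values) == 0L) {
    return(empty_time_values())
  }
  keys <- .value_keys(values)
  stage <- is.na(values$canonical_hours)
  keep <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (.same_value(keys[i], stage[i], keys[j], stage[j])) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  values[keep, , drop = FALSE]
}

#' Test for an arithmetic or geometric progression among time values
#'
#' Returns `TRUE` when some subset of at least three of the given values
#' forms an arithmetic progression (constant successive difference) or a
#' geometric progression (constant successive ratio, all values positive),
#' at relative tolerance `tol`. Since every progression of length >= 3
#' contains a three-term progression among its first three sorted
#' elements, scanning all three-element subsets decides the question
#' exactly for any set size.
#'
#' @param values Numeric vector of deduplicated comparison values.
#' @param tol Relative tolerance on the difference of differences/ratios.
#' @return Logical flag.
#' @examples
#' has_progression(c(0, 3, 6))    # AP, step 3
#' has_progression(c(1, 2, 4))    # GP, ratio 2
#' has_progression(c(1, 5, 12))   # neither
#' @export
has_progression <- function(values, tol = 1e-6) {
  v <- sort(unique(as.numeric(values)))
  n <- length(v)
  if (n < 3L) {
    return(FALSE)
  }
  triples <- utils::combn(n, 3L)
  for (j in seq_len(ncol(triples))) {
    a <- v[triples[1L, j]]
    b <- v[triples[2L, j]]
    c <- v[triples[3L, j]]
    d1 <- b - a
    d2 <- c - b
    if (abs(d2 - d1) <= tol * max(abs(d1), abs(d2))) {
      return(TRUE)
    }
    if (a > 0) {
      r1 <- b / a
      r2 <- c / b
      if (abs(r2 - r1) <= tol * max(r1, r2)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# shared text normalization: dashes to hyphens, nbsp to space, squeeze CR
normalize_text <- function(x) {
  x <- gsub("–|—", "-", x)
  x <- gsub(" ", " ", x)
  gsub("\r", "", x)
}
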