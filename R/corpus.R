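# Synthetic metadata corpus with known ground truth. The generator
# fabricates GEO-like series records whose time-point structure is known
# by construction, stratified by true count (1 / 2-7 / >7, matching the
# strata of a 200-series curated benchmark), rendered through one of the
# extraction scenarios, and optionally contaminated with the confounders
# that cause real-world extraction failures: patient ages in sample
# titles, short treatment durations (latencies) in the running text, and
# cohort sizes echoed in the summary.

#' Specification of a synthetic corpus
#'
#' @param n_series Number of series to generate.
#' @param strata_weights Proportions of series with true count 1, 2-7, and
#'   >7; must sum to 1. The default mirrors a 200-series curated test set
#'   (159/33/8).
#' @param scenario_mix Proportions over the rendering scenarios EXPLICIT,
#'   LISTING, SAMPLE_TITLES and mixed (explicit + listing); applies to
#'   multi-time-point strata only.
#' @param confounder_rates Per-series injection probabilities for the
#'   three confounders `patient_age_in_title`, `latency_duration_in_text`
#'   and `sample_count_echo`.
#' @param seed Integer seed; fully determines the corpus.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_series = 200L,
                        strata_weights = c(`1` = 159 / 200,
                                           `2-7` = 33 / 200,
                                           `>7` = 8 / 200),
                        scenario_mix = c(EXPLICIT = 0.25, LISTING = 0.35,
                                         SAMPLE_TITLES = 0.25, mixed = 0.15),
                        confounder_rates = c(patient_age_in_title = 0.10,
                                             latency_duration_in_text = 0.10,
                                             sample_count_echo = 0.10),
                        seed = 42L) {
  stopifnot(n_series >= 0L)
  if (abs(sum(strata_weights) - 1) > 1e-9) {
    stop("strata_weights must sum to 1")
  }
  if (abs(sum(scenario_mix) - 1) > 1e-9) {
    stop("scenario_mix must sum to 1")
  }
  if (any(confounder_rates < 0 | confounder_rates > 1)) {
    stop("confounder_rates must lie in [0, 1]")
  }
  structure(list(n_series = as.integer(n_series),
                 strata_weights = strata_weights,
                 scenario_mix = scenario_mix,
                 confounder_rates = confounder_rates,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

.fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

.listing_phrase <- function(mags, unit_word) {
  k <- length(mags)
  nums <- .fmt_num(mags)
  listing <- if (k == 2L) {
    paste(nums, collapse = " and ")
  } else {
    paste0(paste(nums[-k], collapse = ", "), ", and ", nums[k])
  }
  paste0(listing, " ", unit_word)
}

# draw the true time grid for a multi-time-point series: an arithmetic or
# geometric progression in a single unit, integer magnitudes
.draw_time_grid <- function(k) {
  unit <- sample(c("minute", "hour", "day", "week"), 1L)
  if (stats::runif(1) < 0.5 || k > 10L) {
    start <- sample(c(0L, 1L, 2L, 3L, 6L), 1L)
    step <- sample(c(1L, 2L, 3L, 4L, 6L, 12L), 1L)
    mags <- start + step * (seq_len(k) - 1L)
  } else {
    start <- sample(c(1L, 2L, 3L), 1L)
    mags <- start * 2L^(seq_len(k) - 1L)
  }
  list(magnitudes = mags, unit = unit)
}

.unit_letter <- c(minute = "m", hour = "h", day = "d", week = "w")
.unit_plural <- c(minute = "minutes", hour = "hours", day = "days",
                  week = "weeks")

.neutral_summaries <- c(
  "Expression profiling of %s tissue under treatment and control conditions.",
  "Transcriptional response of %s cells to drug exposure was profiled.",
  "Gene expression was compared between treated and untreated %s samples.",
  "Genome-wide expression profiling of %s biopsies."
)
.tissues <- c("liver", "lung", "kidney", "muscle", "blood", "brain")
.organisms <- c("Homo sapiens", "Mus musculus", "Rattus norvegicus")

#' Generate one synthetic series
#'
#' @param spec A [corpus_spec()].
#' @param stratum `"1"`, `"2-7"` or `">7"`.
#' @param accession Series identifier to use.
#' @return An object of class `synthetic_series` with components `meta`
#'   ([series_metadata()]), `truth_count`, `truth_values` (time-value data
#'   frame), `scenario`, and `confounders` (character vector of injected
#'   confounder labels). Uses the current RNG state; see
#'   [generate_corpus()] for seeded generation.
#' @export
generate_series <- function(spec, stratum = c("1", "2-7", ">7"),
                            accession = "GSE000001") {
  stratum <- match.arg(stratum)
  tissue <- sample(.tissues, 1L)
  organism <- sample(.organisms, 1L)
  summary <- sprintf(sample(.neutral_summaries, 1L), tissue)
  overall_design <- "Biological replicates were collected for each condition."
  titles <- character()
  scenario <- "NONE"
  truth_values <- empty_time_values()

  if (stratum == "1") {
    truth_count <- 1L
    titles <- paste(tissue, "replicate", seq_len(sample(3:6, 1L)))
  } else {
    truth_count <- if (stratum == "2-7") sample(2:7, 1L) else sample(8:15, 1L)
    grid <- .draw_time_grid(truth_count)
    truth_values <- time_values(grid$magnitudes, grid$unit)
    scenario <- sample(names(spec$scenario_mix), 1L,
                       prob = spec$scenario_mix)
    unit_word <- .unit_plural[[grid$unit]]
    if (scenario %in% c("EXPLICIT", "mixed")) {
      summary <- paste(summary, sprintf(
        "Gene expression was measured at %d time points.", truth_count))
    }
    if (scenario %in% c("LISTING", "mixed")) {
      summary <- paste(summary, sprintf(
        "Samples were harvested at %s after treatment.",
        .listing_phrase(grid$magnitudes, unit_word)))
    }
    if (scenario == "SAMPLE_TITLES") {
      ul <- .unit_letter[[grid$unit]]
      titles <- as.vector(vapply(grid$magnitudes, function(v) {
        sprintf("cond %s%s rep%d", ul, .fmt_num(v), 1:2)
      }, character(2)))
    } else {
      titles <- paste(tissue, "replicate", seq_len(min(truth_count * 2L, 12L)))
    }
  }

  confounders <- character()
  rates <- spec$confounder_rates
  if (stats::runif(1) < rates[["patient_age_in_title"]] && length(titles) > 0L) {
    ages <- sample(35:78, length(titles), replace = TRUE)
    titles <- sprintf("%s patient %dy", titles, ages)
    confounders <- c(confounders, "patient-age-in-title")
  }
  if (stats::runif(1) < rates[["latency_duration_in_text"]]) {
    summary <- paste(summary,
                     "Seizure latency lengths of 4 min, 8 min, 9 min and",
                     "13.5 min were recorded in the treatment groups.")
    confounders <- c(confounders, "latency-duration-in-text")
  }
  if (stats::runif(1) < rates[["sample_count_echo"]]) {
    summary <- paste(summary, sprintf("A total of %d samples were analyzed.",
                                      length(titles)))
    confounders <- c(confounders, "sample-count-echo")
  }

  meta <- series_metadata(
    accession = accession,
    title = sprintf("Expression profiling of %s (%s)", tissue, organism),
    summary = summary,
    overall_design = overall_design,
    series_type = "Expression profiling by array",
    organism = organism,
    sample_titles = titles
  )
  structure(list(meta = meta, truth_count = truth_count,
                 truth_values = truth_values, scenario = scenario,
                 stratum = stratum, confounders = confounders),
            class = "synthetic_series")
}

#' Generate a synthetic corpus
#'
#' Seeds the RNG from the spec and generates exactly `n_series` series
#' whose per-stratum counts equal the rounded strata weights (largest
#' remainder rounding, so counts always sum to `n_series`). The same spec
#' yields a byte-identical corpus.
#'
#' @param spec A [corpus_spec()].
#' @return A list of `synthetic_series` objects.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_series
  raw <- spec$strata_weights * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1L
  }
  strata <- rep(c("1", "2-7", ">7"), times = counts)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)
  lapply(seq_along(strata), function(i) {
    generate_series(spec, strata[i], accession = sprintf("GSE%06d", i))
  })
}

#' Write a synthetic corpus as SOFT-like files plus a ground-truth table
#'
#' One SOFT file per series (parsable by [parse_soft_series()]) and a
#' `truth.csv` with columns accession, truth_count, truth_values,
#' scenario, stratum, confounders.
#'
#' @param corpus Output of [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return The path of the truth table, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  rows <- lapply(corpus, function(s) {
    meta <- s$meta
    lines <- c(
      paste0("^SERIES = ", meta$accession),
      paste0("!Series_title = ", meta$title),
      paste0("!Series_geo_accession = ", meta$accession),
      paste0("!Series_summary = ", meta$summary),
      paste0("!Series_overall_design = ", meta$overall_design),
      paste0("!Series_type = ", meta$series_type),
      paste0("!Series_organism = ", meta$organism)
    )
    for (i in seq_along(meta$sample_titles)) {
      lines <- c(lines,
                 sprintf("^SAMPLE = GSM%s_%d", meta$accession, i),
                 paste0("!Sample_title = ", meta$sample_titles[i]))
    }
    writeLines(lines, file.path(dir, paste0(meta$accession, ".soft")))
    data.frame(accession = meta$accession, truth_count = s$truth_count,
               truth_values = format_time_value(s$truth_values),
               scenario = s$scenario, stratum = s$stratum,
               confounders = paste(s$confounders, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(do.call(rbind, rows), truth_path, row.names = FALSE)
  invisible(truth_path)
}
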