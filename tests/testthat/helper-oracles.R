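# Independent oracles used to check the extraction engine. These are
# deliberately simple re-derivations from first principles (their own
# unit table, exhaustive enumeration) and share no code with the package
# internals they check.

# hours per unit, written down independently of the package table
.oracle_factors <- c(second = 1 / 3600, minute = 1 / 60, hour = 1,
                     day = 24, week = 7 * 24, month = 30 * 24,
                     year = 365 * 24)

oracle_distinct_canonical <- function(magnitudes, units) {
  key <- ifelse(units == "stage",
                paste0("stage:", magnitudes),
                as.character(signif(magnitudes * .oracle_factors[units], 12)))
  length(unique(key))
}

# exhaustive subset enumeration: does any subset of size >= 3 form a full
# arithmetic or geometric progression?
oracle_has_progression <- function(values, tol = 1e-6) {
  v <- sort(unique(values))
  n <- length(v)
  if (n < 3L) return(FALSE)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 3L) next
    s <- v[idx]
    d <- diff(s)
    if (all(abs(d - d[1L]) <= tol * max(abs(d)))) return(TRUE)
    if (all(s > 0)) {
      r <- s[-1L] / s[-length(s)]
      if (all(abs(r - r[1L]) <= tol * max(r))) return(TRUE)
    }
  }
  FALSE
}

# exhaustive enumeration of all simple is_a paths from a term to the root
oracle_root_distance <- function(index, doid) {
  if (identical(doid, index$root)) return(0L)
  best <- Inf
  walk <- function(id, depth, seen) {
    if (identical(id, index$root)) {
      best <<- min(best, depth)
      return()
    }
    for (p in index$terms[[id]]$parents) {
      if (!is.null(index$terms[[p]]) && !p %in% seen) {
        walk(p, depth + 1L, c(seen, p))
      }
    }
  }
  walk(doid, 0L, doid)
  if (is.infinite(best)) -1L else as.integer(best)
}

# ---- listing grammar generator -------------------------------------------
# Produces sentences inside the engine's declared listing grammar together
# with the ground-truth value set. Runs are ascending and distinct; when a
# sentence has several runs they are unit-after or per-value style (the
# form listings take in real summaries).

.grammar_spellings <- list(
  second = c("s", "sec", "secs", "seconds"),
  minute = c("min", "mins", "minutes"),
  hour = c("h", "hr", "hrs", "hours"),
  day = c("d", "days"),
  week = c("w", "wk", "wks", "weeks"),
  month = c("months", "mos"),
  year = c("y", "yr", "yrs", "years"),
  stage = c("stages")
)

gen_listing_case <- function() {
  n_runs <- sample(1:2, 1L)
  mags_all <- numeric()
  units_all <- character()
  run_texts <- character()
  # two adjacent per-value runs would be indistinguishable from one long
  # per-value listing, so at most one run per sentence is per-value
  run_styles <- if (n_runs == 1L) {
    sample(c("after", "before", "pervalue"), 1L)
  } else {
    sample(list(c("after", "after"), c("after", "pervalue"),
                c("pervalue", "after")), 1L)[[1L]]
  }
  for (r in seq_len(n_runs)) {
    unit <- sample(names(.grammar_spellings), 1L)
    spelling <- sample(.grammar_spellings[[unit]], 1L)
    k <- sample(2:6, 1L)
    pool <- if (unit == "stage") 1:12 else c(0, 0.25, 0.5, 1:30)
    mags <- sort(sample(pool, k))
    style <- run_styles[r]
    nums <- format(mags, trim = TRUE, scientific = FALSE,
                   drop0trailing = TRUE)
    txt <- if (style == "pervalue") {
      parts <- paste(nums, spelling)
      paste0(paste(parts[-k], collapse = ", "),
             if (k > 1L) paste0(" and ", parts[k]) else "")
    } else if (style == "after") {
      paste0(paste(nums[-k], collapse = ", "),
             if (k > 2L) ", and " else " and ", nums[k], " ", spelling)
    } else {
      # unit-before reads naturally only with a full spelling
      full <- sample(setdiff(.grammar_spellings[[unit]],
                             c("s", "h", "d", "w", "m", "y")), 1L)
      paste0(full, " ", paste(nums[-k], collapse = ", "),
             if (k > 2L) ", and " else " and ", nums[k])
    }
    run_texts <- c(run_texts, txt)
    mags_all <- c(mags_all, mags)
    units_all <- c(units_all, rep(unit, k))
  }
  sentence <- paste0("Samples were collected at ",
                     paste(run_texts, collapse = " and "),
                     " following stimulation.")
  list(text = sentence,
       expected = oracle_distinct_canonical(mags_all, units_all))
}
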