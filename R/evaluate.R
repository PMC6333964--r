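# Scoring of predicted time-point counts against curated ground truth.
# A prediction is exactly correct when it equals the true count, and
# within-one correct when it differs by at most one time point (baseline
# time points are reported inconsistently even between human curators, so
# a one-point discrepancy is tolerated). Error rates are additionally
# reported per stratum of the true count: single time point, 2-7, and
# more than 7 (i.e. >= 8).

.stratum_of <- function(count) {
  ifelse(count <= 1L, "1", ifelse(count <= 7L, "2-7", ">7"))
}

#' Score predicted time-point counts
#'
#' @param truth Named integer vector: accession -> true count.
#' @param predicted Named integer vector: accession -> predicted count.
#'   Must cover exactly the same accessions as `truth`. Predictions for
#'   excluded series (super-series, count 0 by convention) should be
#'   dropped by the caller before scoring; [score_timepoints()] refuses
#'   mismatched key sets and reports the difference.
#' @return An object of class `evaluation_report`: `n`, `exact_correct`,
#'   `within_one_correct`, `exact_accuracy`, `within_one_accuracy`, and
#'   `strata`, a data frame with per-stratum `n`, `errors_within_one`
#'   (predictions off by more than one) and `error_rate`.
#' @examples
#' truth <- c(GSE1 = 6, GSE2 = 1)
#' pred <- c(GSE1 = 7, GSE2 = 1)
#' score_timepoints(truth, pred)$within_one_accuracy # 1
#' @export
score_timepoints <- function(truth, predicted) {
  if (is.null(names(truth)) || is.null(names(predicted))) {
    stop("truth and predicted must be named by accession")
  }
  missing_pred <- setdiff(names(truth), names(predicted))
  extra_pred <- setdiff(names(predicted), names(truth))
  if (length(missing_pred) > 0L || length(extra_pred) > 0L) {
    stop("accession sets differ; missing predictions: ",
         paste(missing_pred, collapse = ", "),
         "; unexpected predictions: ",
         paste(extra_pred, collapse = ", "))
  }
  predicted <- predicted[names(truth)]
  n <- length(truth)
  err <- abs(as.numeric(predicted) - as.numeric(truth))
  exact_correct <- sum(err == 0)
  within_one_correct <- sum(err <= 1)
  strat <- .stratum_of(as.numeric(truth))
  strata <- do.call(rbind, lapply(c("1", "2-7", ">7"), function(s) {
    in_s <- strat == s
    ns <- sum(in_s)
    errs <- sum(err[in_s] > 1)
    data.frame(stratum = s, n = ns, errors_within_one = errs,
               error_rate = if (ns > 0L) errs / ns else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(n = n, exact_correct = exact_correct,
         within_one_correct = within_one_correct,
         exact_accuracy = if (n > 0L) exact_correct / n else NA_real_,
         within_one_accuracy = if (n > 0L) within_one_correct / n else NA_real_,
         strata = strata),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d\n", x$n))
  cat(sprintf("  exact:      %d/%d (%.1f%%)\n", x$exact_correct, x$n,
              100 * x$exact_accuracy))
  cat(sprintf("  within +/-1: %d/%d (%.1f%%)\n", x$within_one_correct, x$n,
              100 * x$within_one_accuracy))
  for (i in seq_len(nrow(x$strata))) {
    s <- x$strata[i, ]
    cat(sprintf("  stratum %-4s n=%-4d errors=%-3d rate=%s\n", s$stratum,
                s$n, s$errors_within_one,
                ifelse(is.na(s$error_rate), "-",
                       sprintf("%.1f%%", 100 * s$error_rate))))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An [score_timepoints()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(
    n = report$n, exact_correct = report$exact_correct,
    within_one_correct = report$within_one_correct,
    exact_accuracy = report$exact_accuracy,
    within_one_accuracy = report$within_one_accuracy,
    strata = report$strata
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
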