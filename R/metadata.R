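# Series metadata container and I/O: GEO SOFT family files, GEOmetadb-style
# tables, super-series detection, and the restructured-record writer.

# GEOmetadb-style auxiliary columns carried through to the output record
.aux_fields <- c(
  "platform_id", "platform_organism", "platform_taxid",
  "sample_organism", "sample_taxid", "contributor", "contact",
  "last_update_date", "submission_date"
)

#' Series metadata record
#'
#' Holds one series' unstructured and structured metadata: the free-text
#' title/summary/overall-design fields the extractor mines, the sample
#' titles, and GEOmetadb-style auxiliary columns. Missing text fields are
#' empty strings, never `NA`, so downstream regexes need not branch on
#' absence.
#'
#' @param accession Series identifier, e.g. `"GSE28435"`. Required,
#'   non-empty.
#' @param title,summary,overall_design,series_type,organism Free-text
#'   fields; default `""`.
#' @param pubmed_id,abstract Optional text; default `""`.
#' @param sample_titles Character vector of sample titles, in order.
#' @param aux Named list of auxiliary fields (platform_id,
#'   platform_organism, platform_taxid, sample_organism, sample_taxid,
#'   contributor, contact, last_update_date, submission_date); missing
#'   entries are filled with `""`.
#' @return An object of class `series_metadata`.
#' @export
series_metadata <- function(accession, title = "", summary = "",
                            overall_design = "", series_type = "",
                            organism = "", pubmed_id = "", abstract = "",
                            sample_titles = character(), aux = list()) {
  accession <- as.character(accession)
  if (length(accession) != 1L || is.na(accession) || !nzchar(accession)) {
    stop("accession must be a single non-empty string")
  }
  chr1 <- function(x) {
    x <- as.character(x)
    if (length(x) == 0L || is.na(x[1L])) "" else x[1L]
  }
  full_aux <- stats::setNames(as.list(rep("", length(.aux_fields))), .aux_fields)
  for (nm in names(aux)) {
    full_aux[[tolower(nm)]] <- chr1(aux[[nm]])
  }
  structure(
    list(
      accession = accession,
      title = chr1(title),
      summary = chr1(summary),
      overall_design = chr1(overall_design),
      series_type = chr1(series_type),
      organism = chr1(organism),
      pubmed_id = chr1(pubmed_id),
      abstract = chr1(abstract),
      sample_titles = as.character(sample_titles),
      aux = full_aux
    ),
    class = "series_metadata"
  )
}

#' @export
print.series_metadata <- function(x, ...) {
  cat("<series_metadata> ", x$accession, "\n", sep = "")
  cat("  title:   ", substr(x$title, 1, 60), "\n", sep = "")
  cat("  type:    ", x$series_type, "\n", sep = "")
  cat("  samples: ", length(x$sample_titles), "\n", sep = "")
  invisible(x)
}

#' Parse one series from a SOFT-format stream
#'
#' Reads GEO's line-oriented SOFT dialect: a `^SERIES` block with
#' `!Series_*` attribute lines, optionally followed by `^SAMPLE` blocks
#' whose `!Sample_title` lines become the sample titles, in file order.
#' Repeated attribute lines (typically `!Series_summary`) are concatenated
#' with a single space. All other line kinds are ignored. CRLF and LF
#' input parse identically.
#'
#' @param con A file path, connection, or character vector of lines.
#' @return A [series_metadata()] object.
#' @export
parse_soft_series <- function(con) {
  lines <- if (is.character(con)) {
    if (length(con) == 1L && !grepl("\n", con) && file.exists(con)) {
      readLines(con, warn = FALSE)
    } else if (length(con) == 1L) {
      strsplit(con, "\n", fixed = TRUE)[[1L]]
    } else {
      con
    }
  } else {
    tryCatch(readLines(con, warn = FALSE),
             error = function(e) stop("cannot read SOFT input: ",
                                      conditionMessage(e)))
  }
  lines <- sub("\r$", "", lines)
  lines <- sub("[ \t]+$", "", lines)

  series_at <- grep("^\\^SERIES\\b", lines, ignore.case = TRUE)
  if (length(series_at) == 0L) {
    consumed <- sum(nchar(lines, type = "bytes")) + length(lines)
    stop(sprintf(
      "malformed SOFT input: no ^SERIES line found (scanned %d bytes)",
      consumed))
  }
  start <- series_at[1L]
  acc_from_caret <- sub("^\\^SERIES\\s*=\\s*", "", lines[start],
                        ignore.case = TRUE)
  if (identical(acc_from_caret, lines[start])) acc_from_caret <- ""

  fields <- list()
  sample_titles <- character()
  aux <- list()
  for (ln in lines[seq(start + 1L, length.out = max(0L, length(lines) - start))]) {
    if (grepl("^\\^SERIES\\b", ln, ignore.case = TRUE)) {
      break # one series per stream; further blocks ignored
    }
    m <- regmatches(ln, regexec("^!Series_([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      key <- tolower(m[2L])
      val <- m[3L]
      fields[[key]] <- if (is.null(fields[[key]])) val else
        paste(fields[[key]], val)
      next
    }
    m <- regmatches(ln, regexec("^!Sample_title\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 2L) {
      sample_titles <- c(sample_titles, m[2L])
    }
  }
  fld <- function(key, default = "") {
    v <- fields[[key]]
    if (is.null(v)) default else v
  }
  for (nm in .aux_fields) {
    if (!is.null(fields[[nm]])) aux[[nm]] <- fields[[nm]]
  }
  accession <- fld("geo_accession", acc_from_caret)
  if (!nzchar(accession)) {
    stop("malformed SOFT input: series block carries no accession")
  }
  series_metadata(
    accession = accession,
    title = fld("title"),
    summary = fld("summary"),
    overall_design = fld("overall_design"),
    series_type = fld("type"),
    organism = fld("organism", fld("platform_organism")),
    pubmed_id = fld("pubmed_id"),
    abstract = fld("abstract"),
    sample_titles = sample_titles,
    aux = aux
  )
}

#' Parse a GEOmetadb-style table into series metadata records
#'
#' Column names are matched case-insensitively against the GEOmetadb
#' vocabulary (`gse`, `title`, `summary`, `overall_design`, `type`,
#' `organism`, `pubmed_id`, ...). Unrecognized columns are preserved in
#' `aux`. `sample_titles`, if present, is a `";"`-joined string.
#'
#' @param rows A data frame with at least an accession (`gse`) column.
#' @return A list of [series_metadata()] objects, one per row.
#' @export
parse_tabular <- function(rows) {
  stopifnot(is.data.frame(rows))
  nms <- tolower(names(rows))
  pick <- function(i, key, default = "") {
    j <- match(key, nms)
    if (is.na(j)) return(default)
    v <- rows[[j]][i]
    if (is.na(v)) "" else as.character(v)
  }
  acc_col <- match(c("gse", "accession"), nms)
  acc_col <- acc_col[!is.na(acc_col)][1]
  if (is.na(acc_col)) {
    stop("tabular input has no accession column (expected 'gse')")
  }
  accs <- as.character(rows[[acc_col]])
  dups <- unique(accs[duplicated(accs)])
  if (length(dups) > 0L) {
    stop("duplicate accessions in tabular input: ",
         paste(dups, collapse = ", "))
  }
  known <- c("gse", "accession", "title", "summary", "overall_design",
             "type", "organism", "pubmed_id", "abstract", "sample_titles")
  lapply(seq_len(nrow(rows)), function(i) {
    aux <- list()
    for (j in seq_along(nms)) {
      if (!nms[j] %in% known) {
        v <- rows[[j]][i]
        aux[[nms[j]]] <- if (is.na(v)) "" else as.character(v)
      }
    }
    st <- pick(i, "sample_titles")
    st <- if (nzchar(st)) strsplit(st, ";", fixed = TRUE)[[1L]] else character()
    series_metadata(
      accession = accs[i],
      title = pick(i, "title"),
      summary = pick(i, "summary"),
      overall_design = pick(i, "overall_design"),
      series_type = pick(i, "type"),
      organism = pick(i, "organism"),
      pubmed_id = pick(i, "pubmed_id"),
      abstract = pick(i, "abstract"),
      sample_titles = st,
      aux = aux
    )
  })
}

#' Detect a super-series
#'
#' Super-series bundle several sub-series and are excluded from time-point
#' detection (they are still disease-tagged). Detection is a pure function
#' of the type field and the summary: either the series type contains a
#' "SuperSeries" token, or the summary carries GEO's standard boilerplate
#' ("This SuperSeries is composed of the SubSeries listed below").
#'
#' @param meta A [series_metadata()] object.
#' @return Logical flag.
#' @export
is_superseries <- function(meta) {
  stopifnot(inherits(meta, "series_metadata"))
  pat <- "super[ -]?series"
  grepl(pat, meta$series_type, ignore.case = TRUE) ||
    grepl(pat, meta$summary, ignore.case = TRUE)
}

# ---- restructured-record output ------------------------------------------

.record_columns <- c(
  "gse", "title", "type", "organism", "pubmed_id", "submission_date",
  "last_update_date", "platform_id", "platform_organism", "platform_taxid",
  "sample_organism", "sample_taxid", "contributor", "contact",
  "n_timepoints", "time_values", "timepoint_scenario", "is_superseries",
  "DOID_termIDs", "DOID_termName", "DOID_isLeaf", "DOID_distancefromRoot",
  "DOID_isObsolete"
)

format_time_value <- function(values) {
  if (is.null(values) || nrow(values) == 0L) return("")
  keys <- .value_keys(values)
  values <- values[order(keys), , drop = FALSE]
  paste(paste(values$magnitude, values$unit), collapse = ";")
}

#' Assemble restructured records
#'
#' Flattens (metadata, time-point result, disease tags) triples into the
#' output table: one row per series, auxiliary fields as columns, the
#' resolved time-point count, the time values as a canonical-order
#' semicolon-joined string, and the five `DOID_*` annotation columns as
#' parallel pipe-joined strings in tag order.
#'
#' @param results A list; each element a list with components `meta`
#'   ([series_metadata()]), `time` ([resolve_series()] result or `NULL`),
#'   and `tags` (data frame from [tag_series()] or `NULL`).
#' @return A data frame with one row per series.
#' @export
restructured_records <- function(results) {
  rows <- lapply(results, function(res) {
    meta <- res$meta
    tim <- res$time
    tags <- res$tags
    stopifnot(inherits(meta, "series_metadata"))
    pipe <- function(x) paste(as.character(x), collapse = "|")
    tag_cols <- if (is.null(tags) || nrow(tags) == 0L) {
      list(ids = "", names = "", leaf = "", dist = "", obs = "")
    } else {
      list(ids = pipe(tags$doid), names = pipe(tags$term_name),
           leaf = pipe(tags$is_leaf), dist = pipe(tags$distance_from_root),
           obs = pipe(tags$is_obsolete))
    }
    data.frame(
      gse = meta$accession, title = meta$title, type = meta$series_type,
      organism = meta$organism, pubmed_id = meta$pubmed_id,
      submission_date = meta$aux$submission_date,
      last_update_date = meta$aux$last_update_date,
      platform_id = meta$aux$platform_id,
      platform_organism = meta$aux$platform_organism,
      platform_taxid = meta$aux$platform_taxid,
      sample_organism = meta$aux$sample_organism,
      sample_taxid = meta$aux$sample_taxid,
      contributor = meta$aux$contributor, contact = meta$aux$contact,
      n_timepoints = if (is.null(tim)) NA_integer_ else as.integer(tim$final_count),
      time_values = if (is.null(tim)) "" else format_time_value(tim$final_values),
      timepoint_scenario = if (is.null(tim)) "" else tim$scenario,
      is_superseries = if (is.null(tim)) is_superseries(meta) else tim$excluded,
      DOID_termIDs = tag_cols$ids, DOID_termName = tag_cols$names,
      DOID_isLeaf = tag_cols$leaf, DOID_distancefromRoot = tag_cols$dist,
      DOID_isObsolete = tag_cols$obs,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[, .record_columns]
}

#' Write restructured records
#'
#' Serializes the output table as JSON-lines or CSV. [read_restructured()]
#' reproduces the records exactly (bit-exact round trip).
#'
#' @param records Data frame from [restructured_records()], or the list
#'   accepted by it.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_restructured <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    records <- restructured_records(records)
  }
  ok <- tryCatch({
    if (format == "jsonl") {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      jsonlite::stream_out(records, con, verbose = FALSE, digits = NA)
    } else {
      utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
    }
    TRUE
  }, error = function(e) {
    stop("cannot write restructured records to '", path, "': ",
         conditionMessage(e))
  })
  invisible(path)
}

#' Read restructured records back
#'
#' @param path File written by [write_restructured()].
#' @param format `"jsonl"` or `"csv"`.
#' @return The records data frame.
#' @export
read_restructured <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  out <- if (format == "jsonl") {
    con <- file(path, open = "r", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_in(con, verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = stats::setNames(
                      c(rep("character", 14L), "integer", rep("character", 3L),
                        rep("character", 5L)),
                      .record_columns),
                    fileEncoding = "UTF-8")
  }
  if (is.character(out$is_superseries)) {
    out$is_superseries <- as.logical(out$is_superseries)
  }
  out$n_timepoints <- as.integer(out$n_timepoints)
  out[, .record_columns]
}
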