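# Disease Ontology loading and dictionary-based tagging. The tagger scans
# metadata text for DO term names and synonyms (greedy longest match over
# word boundaries, case-insensitive, singular/plural tolerant) and
# attaches hierarchy metrics (leaf status, distance from the root
# "disease" term, obsolete flag) so that a search for a non-leaf disease
# can also return series tagged with its descendants.

.stop_words <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "in",
  "is", "it", "of", "on", "or", "the", "to", "with", "was", "were",
  "all", "acute", "chronic", "human", "type"
)

.norm_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9' ]", " ", x)
  trimws(gsub("\\s+", " ", x))
}

.singularize <- function(word) {
  if (nchar(word) > 3L && grepl("ses$", word)) {
    sub("ses$", "sis", word) # metastases -> metastasis
  } else if (nchar(word) > 3L && grepl("ies$", word)) {
    sub("ies$", "y", word)
  } else if (nchar(word) > 3L && grepl("s$", word) && !grepl("ss$", word)) {
    sub("s$", "", word)
  } else {
    word
  }
}

#' Load a Disease Ontology snapshot from an OBO file
#'
#' Parses OBO 1.2 `[Term]` stanzas (tags `id`, `name`, `synonym`, `is_a`,
#' `is_obsolete`) and builds a lookup index over term names and EXACT /
#' RELATED synonyms. Surface strings shorter than three characters after
#' normalization are excluded, so ambiguous short abbreviations never
#' match. Terms with an `id` but no `name` are skipped with a warning; a
#' cyclic `is_a` graph is a validation error.
#'
#' @param path An OBO file path or a character vector of OBO lines.
#' @return An object of class `ontology_index` with components `terms`
#'   (named list: DOID -> list(id, name, synonyms, parents, obsolete)),
#'   `name_index` (normalized surface string -> character vector of
#'   DOIDs), and `root` (the DOID of the term named "disease", or the
#'   unique parentless non-obsolete term).
#' @export
load_ontology <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (length(path) == 1L) {
    strsplit(path, "\n", fixed = TRUE)[[1L]]
  } else {
    path
  }
  lines <- sub("\r$", "", lines)

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  commit <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$name)) {
      if (!is.null(cur$id)) {
        warning("skipping OBO stanza without a name: ", cur$id)
      }
    } else if (!is.null(cur$id)) {
      terms[[cur$id]] <<- cur
    }
  }
  for (ln in lines) {
    if (grepl("^\\[Term\\]", ln)) {
      commit()
      cur <- list(id = NULL, name = NULL, synonyms = character(),
                  parents = character(), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {
      commit()
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) next
    tag <- m[2L]
    val <- trimws(m[3L])
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "synonym") {
      sm <- regmatches(val, regexec('^"(.*)"\\s*([A-Z]*)', val))[[1L]]
      if (length(sm) == 3L && sm[3L] %in% c("", "EXACT", "RELATED")) {
        cur$synonyms <- c(cur$synonyms, sm[2L])
      }
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, trimws(sub("!.*$", "", val)))
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  commit()

  if (length(terms) == 0L) {
    warning("empty ontology: no [Term] stanzas found")
  }

  # cycle check over is_a
  state <- stats::setNames(rep(0L, length(terms)), names(terms))
  visit <- function(id) {
    if (is.na(state[id])) return()
    if (state[id] == 1L) stop("cyclic is_a hierarchy at ", id)
    if (state[id] == 2L) return()
    state[id] <<- 1L
    for (p in terms[[id]]$parents) {
      if (!is.null(terms[[p]])) visit(p)
    }
    state[id] <<- 2L
  }
  for (id in names(terms)) visit(id)

  root <- NULL
  for (id in names(terms)) {
    if (identical(tolower(terms[[id]]$name), "disease")) root <- id
  }
  if (is.null(root)) {
    parentless <- names(terms)[vapply(terms, function(t) {
      length(t$parents) == 0L && !t$obsolete
    }, logical(1))]
    if (length(parentless) == 1L) root <- parentless
  }

  name_index <- list()
  for (id in names(terms)) {
    t <- terms[[id]]
    if (t$obsolete) next
    for (surface in c(t$name, t$synonyms)) {
      key <- .norm_term(surface)
      if (nchar(key) < 3L) next
      name_index[[key]] <- unique(c(name_index[[key]], id))
    }
  }

  structure(list(terms = terms, name_index = name_index, root = root),
            class = "ontology_index")
}

#' @export
print.ontology_index <- function(x, ...) {
  cat(sprintf("<ontology_index> %d terms, %d surface forms, root %s\n",
              length(x$terms), length(x$name_index),
              if (is.null(x$root)) "<none>" else x$root))
  invisible(x)
}

doid_number <- function(id) {
  sub("^DOID:0*", "", id)
}

#' Hierarchy metrics for an ontology term
#'
#' @param index An [load_ontology()] index.
#' @param doid A term identifier (`"DOID:8469"`).
#' @return A list with `is_leaf` (no term has this one as an `is_a`
#'   parent), `distance_from_root` (shortest `is_a` path to the root;
#'   -1 for terms detached from the root, e.g. obsolete terms without
#'   recorded parents), and `is_obsolete`.
#' @export
hierarchy_metrics <- function(index, doid) {
  stopifnot(inherits(index, "ontology_index"))
  if (is.null(index$terms[[doid]])) {
    stop("unknown term: ", doid)
  }
  term <- index$terms[[doid]]
  children_of <- unlist(lapply(index$terms, `[[`, "parents"), use.names = FALSE)
  is_leaf <- !doid %in% children_of
  dist <- if (is.null(index$root)) {
    -1L
  } else if (doid == index$root) {
    0L
  } else {
    # BFS up the is_a graph
    depth <- 0L
    frontier <- doid
    seen <- character()
    found <- -1L
    while (length(frontier) > 0L) {
      depth <- depth + 1L
      nxt <- unique(unlist(lapply(frontier, function(id) {
        index$terms[[id]]$parents
      })))
      nxt <- setdiff(nxt, seen)
      if (index$root %in% nxt) {
        found <- depth
        break
      }
      seen <- c(seen, frontier)
      frontier <- nxt[nxt %in% names(index$terms)]
    }
    found
  }
  list(is_leaf = is_leaf, distance_from_root = dist,
       is_obsolete = isTRUE(term$obsolete))
}

#' All descendants of a term
#'
#' Transitive closure of the child relation (inverse `is_a`). Used to
#' answer searches for a non-leaf disease: a series tagged with any
#' descendant should satisfy a query for the ancestor.
#'
#' @param index An [load_ontology()] index.
#' @param doid A term identifier.
#' @return Character vector of descendant DOIDs (excluding `doid`).
#' @export
doid_descendants <- function(index, doid) {
  stopifnot(inherits(index, "ontology_index"))
  kids_map <- list()
  for (id in names(index$terms)) {
    for (p in index$terms[[id]]$parents) {
      kids_map[[p]] <- c(kids_map[[p]], id)
    }
  }
  out <- character()
  frontier <- doid
  while (length(frontier) > 0L) {
    kids <- unique(unlist(kids_map[frontier]))
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Tag disease mentions in one text field
#'
#' Greedy longest-match scan over word boundaries: at each word position
#' the longest n-gram present in the ontology's surface index wins, and
#' shorter matches inside an accepted span are suppressed. Matching is
#' case-insensitive and tolerant of plural surface forms; stop words never
#' match on their own. Each distinct DOID is reported once per field, with
#' the first matched span.
#'
#' @param index An [load_ontology()] index.
#' @param text The field text.
#' @param field_source Label recorded on each tag.
#' @return A data frame of tags with columns `doid` (numeric part),
#'   `term_name`, `is_leaf`, `distance_from_root`, `is_obsolete`,
#'   `matched_text`, `field_source`.
#' @export
tag_text <- function(index, text, field_source = "summary") {
  stopifnot(inherits(index, "ontology_index"))
  empty <- data.frame(doid = character(), term_name = character(),
                      is_leaf = logical(), distance_from_root = integer(),
                      is_obsolete = logical(), matched_text = character(),
                      field_source = character(), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text) || length(index$name_index) == 0L) {
    return(empty)
  }
  txt <- normalize_text(text)
  m <- gregexpr("[A-Za-z0-9']+", txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(empty)
  }
  words <- regmatches(txt, list(m))[[1L]]
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  max_ngram <- max(vapply(strsplit(names(index$name_index), " ", fixed = TRUE),
                          length, integer(1)))
  hits <- list()
  i <- 1L
  n <- length(words)
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_ngram, n - i + 1L), 1L)) {
      gram_words <- words[i:(i + len - 1L)]
      key <- .norm_term(paste(gram_words, collapse = " "))
      ids <- index$name_index[[key]]
      if (is.null(ids)) {
        # plural-tolerant retry on the last word
        gw <- gram_words
        gw[len] <- .singularize(tolower(gw[len]))
        key2 <- .norm_term(paste(gw, collapse = " "))
        if (!identical(key2, key)) ids <- index$name_index[[key2]]
      }
      if (!is.null(ids)) {
        if (len == 1L && tolower(gram_words) %in% .stop_words) next
        span <- substr(txt, starts[i], ends[i + len - 1L])
        for (id in ids) {
          hits[[length(hits) + 1L]] <- list(id = id, span = span)
        }
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(hits) == 0L) {
    return(empty)
  }
  seen <- character()
  rows <- list()
  for (h in hits) {
    if (h$id %in% seen) next
    seen <- c(seen, h$id)
    hm <- hierarchy_metrics(index, h$id)
    rows[[length(rows) + 1L]] <- data.frame(
      doid = doid_number(h$id), term_name = index$terms[[h$id]]$name,
      is_leaf = hm$is_leaf, distance_from_root = hm$distance_from_root,
      is_obsolete = hm$is_obsolete, matched_text = h$span,
      field_source = field_source, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Tag a series' metadata with Disease Ontology terms
#'
#' Runs [tag_text()] over the title, summary, overall design, citation
#' abstract and organism fields, then deduplicates by DOID keeping the
#' highest-precedence field (title > summary > overall_design > abstract >
#' organism).
#'
#' @param index An [load_ontology()] index.
#' @param meta A [series_metadata()] object.
#' @return A tag data frame (see [tag_text()]), one row per distinct DOID.
#' @export
tag_series <- function(index, meta) {
  stopifnot(inherits(meta, "series_metadata"))
  fields <- c("title", "summary", "overall_design", "abstract", "organism")
  tags <- do.call(rbind, lapply(fields, function(f) {
    tag_text(index, meta[[f]], field_source = f)
  }))
  tags[!duplicated(tags$doid), , drop = FALSE]
}
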