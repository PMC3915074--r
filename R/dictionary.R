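#' Controlled-vocabulary dictionaries
#'
#' Dictionaries are CSV files with at least three columns -- \code{ID},
#' \code{TERM} and \code{DESCRIPTION} -- plus optional extra columns holding
#' scalar attributes, boolean flags, or links into other dictionaries
#' (foreign-key style columns conventionally named \code{<TARGET>_ID}).
#' A dictionary set groups the individual dictionaries so cross-dictionary
#' links (e.g. a QM method's class, a class's family) can be resolved.
#'
#' @name dictionaries
NULL

MANDATORY_COLS <- c("ID", "TERM", "DESCRIPTION")

#' Load one dictionary from a CSV term listing
#'
#' @param source path to a CSV file, or a data.frame with the same columns.
#' @param name dictionary name; defaults to the file name without extension.
#' @param schema optional data.frame with columns \code{COLUMN}, \code{KIND}
#'   (\code{"extra"}, \code{"boolean"} or \code{"link"}) and \code{TARGET}
#'   (target dictionary for links). When omitted, columns ending in
#'   \code{_ID} are treated as links to the dictionary named by the
#'   lower-cased prefix, and all other extra columns as scalars.
#' @return an object of class \code{simdex_dictionary}: entries keyed by id,
#'   each retaining term, description, citation, extras and links.
#' @export
load_dictionary <- function(source, name = NULL, schema = NULL) {
  if (is.character(source)) {
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(source))
    df <- read_simdex_csv(source)
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
    if (is.null(name)) stopf("simdex_usage_error", "name is required for data.frame input")
  }
  missing <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing) > 0) {
    stopf("simdex_schema_error", "dictionary '%s' is missing mandatory column(s): %s",
          name, paste(missing, collapse = ", "))
  }
  dup <- df$ID[duplicated(df$ID)]
  if (length(dup) > 0) {
    stopf("simdex_load_error", "duplicate id(s) in dictionary '%s': %s",
          name, paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(trimws(df$TERM)))) {
    stopf("simdex_load_error", "dictionary '%s' contains an entry with an empty term", name)
  }

  extra_cols <- setdiff(names(df), MANDATORY_COLS)
  col_spec <- infer_column_spec(extra_cols, schema)

  entries <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    extras <- list()
    links <- list()
    for (col in extra_cols) {
      val <- df[[col]][i]
      kind <- col_spec$KIND[col_spec$COLUMN == col]
      if (kind == "link") {
        if (nzchar(trimws(val))) {
          links[[col]] <- list(id = trimws(val),
                               target = col_spec$TARGET[col_spec$COLUMN == col])
        }
      } else if (kind == "boolean") {
        extras[[col]] <- is_flag_true(val)
      } else if (nzchar(val)) {
        extras[[col]] <- val
      }
    }
    entries[[i]] <- structure(
      list(id = df$ID[i], term = df$TERM[i], description = df$DESCRIPTION[i],
           citation = if ("CITATION" %in% names(extras)) extras[["CITATION"]] else NULL,
           extras = extras[setdiff(names(extras), "CITATION")],
           links = links, dictionary = name),
      class = "simdex_dict_entry")
  }
  names(entries) <- df$ID
  structure(list(name = name, entries = entries,
                 schema = col_spec, columns = names(df)),
            class = "simdex_dictionary")
}

infer_column_spec <- function(extra_cols, schema) {
  if (length(extra_cols) == 0) {
    return(data.frame(COLUMN = character(), KIND = character(),
                      TARGET = character(), stringsAsFactors = FALSE))
  }
  if (!is.null(schema)) {
    schema <- as.data.frame(schema, stringsAsFactors = FALSE)
    spec <- schema[schema$COLUMN %in% extra_cols, c("COLUMN", "KIND", "TARGET")]
    rest <- setdiff(extra_cols, spec$COLUMN)
    if (length(rest) > 0) {
      spec <- rbind(spec, infer_column_spec(rest, NULL))
    }
    return(spec[match(extra_cols, spec$COLUMN), , drop = FALSE])
  }
  kind <- ifelse(grepl("_ID$", extra_cols), "link", "extra")
  target <- ifelse(kind == "link", tolower(sub("_ID$", "", extra_cols)), "")
  data.frame(COLUMN = extra_cols, KIND = kind, TARGET = target,
             stringsAsFactors = FALSE)
}

#' Load a directory of dictionary CSV files as a dictionary set
#'
#' Reads every \code{*.csv} file in \code{dir} (one dictionary per file,
#' named after the file) plus an optional \code{_schema.csv} declaring the
#' kind and link target of extra columns.
#'
#' @param dir directory of CSV files; defaults to the dictionaries packaged
#'   with simdex.
#' @return a named list of dictionaries of class \code{simdex_dictionary_set}.
#' @export
load_dictionary_set <- function(dir = simdex_dictionary_dir()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!startsWith(basename(files), "_")]
  schema_path <- file.path(dir, "_schema.csv")
  schema_all <- if (file.exists(schema_path)) read_simdex_csv(schema_path) else NULL
  dicts <- lapply(files, function(f) {
    nm <- tools::file_path_sans_ext(basename(f))
    sch <- if (!is.null(schema_all)) schema_all[schema_all$DICTIONARY == nm, ] else NULL
    load_dictionary(f, name = nm, schema = sch)
  })
  names(dicts) <- vapply(dicts, function(d) d$name, character(1))
  structure(dicts, class = "simdex_dictionary_set")
}

#' Path to the dictionary CSV files shipped with simdex
#' @export
simdex_dictionary_dir <- function() {
  system.file("extdata", "dictionaries", package = "simdex", mustWork = TRUE)
}

#' Look up a term in a dictionary
#'
#' Matching is case-insensitive and whitespace-normalized.
#'
#' @param dictionary a \code{simdex_dictionary}.
#' @param term the display term to look up (e.g. \code{"QM/MM"}).
#' @return the matching entry, or \code{NULL} when the term is absent.
#' @export
lookup_term <- function(dictionary, term) {
  assert_string(term, "term")
  terms <- vapply(dictionary$entries, function(e) fold_term(e$term), character(1))
  hit <- which(terms == fold_term(term))
  if (length(hit) == 0) return(NULL)
  dictionary$entries[[hit[1]]]
}

#' Build a term index over a dictionary set
#'
#' The index is a flat posting table over all entries of all dictionaries
#' (or one dictionary), rebuilt deterministically from the CSV content.
#'
#' @param dictionaries a \code{simdex_dictionary_set} or single dictionary.
#' @return a \code{simdex_term_index}.
#' @export
build_term_index <- function(dictionaries) {
  if (inherits(dictionaries, "simdex_dictionary")) {
    dictionaries <- structure(stats::setNames(list(dictionaries), dictionaries$name),
                              class = "simdex_dictionary_set")
  }
  rows <- list()
  for (d in dictionaries) {
    for (e in d$entries) {
      rows[[length(rows) + 1L]] <- data.frame(
        dictionary = d$name, id = e$id, term = e$term,
        folded = fold_term(e$term), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dictionary, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 source = sprintf("%d dictionaries / %d entries",
                                  length(dictionaries), nrow(tab)),
                 dictionaries = dictionaries),
            class = "simdex_term_index")
}

#' Does a term match a query under the index matching rules?
#'
#' A term matches when, after case folding and whitespace normalization,
#' the query equals the term (exact), the term starts with the query
#' (prefix), or every query token is a prefix of some term token (token
#' match). Exported so callers (and independent checks) share one predicate.
#'
#' @param term,query display strings.
#' @return logical.
#' @export
term_matches <- function(term, query) {
  t <- fold_term(term)
  q <- fold_term(query)
  if (t == q || startsWith(t, q)) return(TRUE)
  ttok <- strsplit(t, " ", fixed = TRUE)[[1]]
  qtok <- strsplit(q, " ", fixed = TRUE)[[1]]
  all(vapply(qtok, function(qt) any(startsWith(ttok, qt)), logical(1)))
}

#' Search dictionary terms
#'
#' Results are ranked exact match first, then raw-term prefix matches, then
#' token matches, ties broken by term lexicographic order (then dictionary
#' and id, so ranking is total and deterministic).
#'
#' @param index a \code{simdex_term_index}.
#' @param query non-empty query string.
#' @param max_n maximum number of entries to return (\code{-n} semantics).
#' @param dictionary optional dictionary name to restrict the search.
#' @return a list of matching entries, at most \code{max_n} long.
#' @export
search_terms <- function(index, query, max_n = 10L, dictionary = NULL) {
  assert_string(query, "query")
  if (!is.numeric(max_n) || length(max_n) != 1 || max_n < 1) {
    stopf("simdex_usage_error", "max_n must be a positive integer")
  }
  tab <- index$table
  if (!is.null(dictionary)) tab <- tab[tab$dictionary == dictionary, , drop = FALSE]
  if (nrow(tab) == 0) return(list())
  q <- fold_term(query)
  keep <- vapply(tab$term, term_matches, logical(1), query = query)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) return(list())
  tier <- ifelse(tab$folded == q, 0L, ifelse(startsWith(tab$folded, q), 1L, 2L))
  ord <- order(tier, tab$folded, tab$dictionary, tab$id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab <- utils::head(tab, as.integer(max_n))
  lapply(seq_len(nrow(tab)), function(i) {
    index$dictionaries[[tab$dictionary[i]]]$entries[[tab$id[i]]]
  })
}

#' Resolve a link column of an entry to its target entry
#'
#' @param entry a dictionary entry.
#' @param link_name the link column name (e.g. \code{"CLASS_ID"}).
#' @param dictionaries the dictionary set containing the target dictionary.
#' @return the linked entry in the target dictionary.
#' @export
resolve_link <- function(entry, link_name, dictionaries) {
  if (!link_name %in% names(entry$links)) {
    stopf("simdex_usage_error", "entry '%s' declares no link named '%s'",
          entry$id, link_name)
  }
  ln <- entry$links[[link_name]]
  target <- dictionaries[[ln$target]]
  if (is.null(target)) {
    stopf("simdex_integrity_error", "link '%s' of entry '%s' targets unknown dictionary '%s'",
          link_name, entry$id, ln$target)
  }
  hit <- target$entries[[ln$id]]
  if (is.null(hit)) {
    stopf("simdex_integrity_error", "entry '%s': link %s=%s has no match in dictionary '%s'",
          entry$id, link_name, ln$id, ln$target)
  }
  hit
}

#' Check referential integrity of a dictionary set
#'
#' @param dictionaries a \code{simdex_dictionary_set}.
#' @return data.frame of violations (dictionary, id, link, target, reason);
#'   zero rows when every declared link of every entry resolves.
#' @export
validate_dictionary_set <- function(dictionaries) {
  out <- list()
  for (d in dictionaries) {
    for (e in d$entries) {
      for (ln_name in names(e$links)) {
        ok <- tryCatch({resolve_link(e, ln_name, dictionaries); TRUE},
                       simdex_integrity_error = function(c) FALSE)
        if (!ok) {
          ln <- e$links[[ln_name]]
          out[[length(out) + 1L]] <- data.frame(
            dictionary = d$name, id = e$id, link = ln_name,
            target = ln$target, reason = "unresolved link id",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(dictionary = character(), id = character(),
                      link = character(), target = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify a computational method name through the dictionaries
#'
#' Looks the specific name up in the \code{qm_method} dictionary and, when a
#' definition exists, follows its class and family links: e.g. MP2 is a
#' Moller-Plesset method of the ab initio family, B3LYP a DFT method. The
#' specific name is always retained, matched or not, so unmapped methods can
#' still be published and queried.
#'
#' @param name method name as found in an input or output file.
#' @param dictionaries a \code{simdex_dictionary_set}.
#' @return a \code{simdex_method_classification} with fields
#'   \code{specific_name}, \code{method}, \code{method_class},
#'   \code{method_family} (the last three \code{NULL} when unmapped).
#' @export
classify_method <- function(name, dictionaries) {
  assert_string(name, "name")
  out <- list(specific_name = name, method = NULL,
              method_class = NULL, method_family = NULL)
  md <- dictionaries[["qm_method"]]
  if (!is.null(md)) {
    entry <- lookup_term(md, name)
    if (!is.null(entry)) {
      out$method <- entry
      if ("CLASS_ID" %in% names(entry$links)) {
        cls <- resolve_link(entry, "CLASS_ID", dictionaries)
        out$method_class <- cls$term
        if ("FAMILY_ID" %in% names(cls$links)) {
          out$method_family <- resolve_link(cls, "FAMILY_ID", dictionaries)$term
        }
      }
    }
  }
  structure(out, class = "simdex_method_classification")
}

#' @export
print.simdex_dictionary <- function(x, ...) {
  cat(sprintf("<simdex dictionary '%s': %d entries, columns %s>\n",
              x$name, length(x$entries), paste(x$columns, collapse = "/")))
  invisible(x)
}

#' @export
print.simdex_dictionary_set <- function(x, ...) {
  cat(sprintf("<simdex dictionary set: %d dictionaries, %d entries>\n",
              length(x), sum(vapply(x, function(d) length(d$entries), integer(1)))))
  invisible(x)
}

#' @export
print.simdex_dict_entry <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$id, x$term, x$description))
  invisible(x)
}
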