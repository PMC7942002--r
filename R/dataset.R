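# Datasets of compositions and the two on-disk encodings.
#
# nested-records: newline-delimited JSON, one composition per line:
#   {"template_id": "...", "root": {"name": ..., "node_id": ..., "unit": ...,
#    "value": ... | "children": [ ... ]}}
# flat-table: RFC-4180 CSV whose column headers are leaf paths; every row
#   becomes a composition built from the headers' shared root segment.
#
# Missing semantics: a value is missing iff the node is absent from the
# tree or its text form is one of the dataset's missing tokens (default
# "", "NA", "ND" — real-world feeds use varying null flavors).

DEFAULT_MISSING_TOKENS <- c("", "NA", "ND")

new_dataset <- function(rows, missing_tokens = DEFAULT_MISSING_TOKENS,
                        schema = NULL) {
  ds <- structure(
    list(rows = rows, variables = NULL, missing_tokens = missing_tokens),
    class = "dq_dataset")
  ds$variables <- list_variables(ds, schema = schema)
  ds
}

#' @export
print.dq_dataset <- function(x, ...) {
  cat(sprintf("<dq_dataset> %d rows, %d variables\n",
              length(x$rows), nrow(x$variables)))
  invisible(x)
}

n_rows <- function(dataset) length(dataset$rows)

is_missing_token <- function(x, tokens) {
  is.character(x) & !is.na(x) & x %in% tokens
}

node_from_json <- function(obj, row_index) {
  bad <- function(msg) dq_error("PARSE", sprintf("row %d: %s", row_index, msg))
  if (!is.list(obj) || is.null(obj$name)) bad("node without a name")
  has_value <- !is.null(obj$value)
  has_children <- !is.null(obj$children)
  if (has_value && has_children) {
    bad(sprintf("node '%s' has both value and children", obj$name))
  }
  children <- NULL
  if (has_children) {
    children <- lapply(obj$children, node_from_json, row_index = row_index)
  }
  dq_node(name = obj$name,
          value = if (has_value) obj$value else NULL,
          unit = obj$unit,
          children = children,
          node_id = obj$node_id,
          archetype_id = obj$archetype_id,
          display_name = obj$display_name)
}

normalize_missing_node <- function(node, tokens) {
  if (node_is_leaf(node)) {
    if (!is.null(node$value) && is_missing_token(node$value, tokens)) {
      node$value <- NA
    }
    return(node)
  }
  node$children <- lapply(node$children, normalize_missing_node, tokens = tokens)
  node
}

load_nested_records <- function(lines, missing_tokens) {
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) dq_error("PARSE", sprintf(
        "row %d: malformed record (%s)", i - 1L, conditionMessage(e))))
    if (is.null(obj$root)) {
      dq_error("PARSE", sprintf("row %d: record without 'root'", i - 1L))
    }
    root <- node_from_json(obj$root, row_index = i - 1L)
    root <- normalize_missing_node(root, missing_tokens)
    rows[[i]] <- dq_dataset_row(i - 1L, dq_composition(root),
                                template_id = obj$template_id)
  }
  rows
}

# Insert one leaf value into a tree under construction (environment of
# mutable nodes), creating intermediate containers as needed.
insert_path_value <- function(tree, segments, value, unit = NULL) {
  if (length(segments) == 0L) return(tree)
  seg <- segments[[1L]]
  key <- paste(seg$name, seg$node_id %||% "", sep = "\r")
  child <- tree$children[[key]]
  if (is.null(child)) {
    child <- new.env(parent = emptyenv())
    child$name <- seg$name
    child$node_id <- seg$node_id
    child$display <- seg$display
    child$children <- list()
    child$order <- length(tree$children) + 1L
    tree$children[[key]] <- child
  }
  if (length(segments) == 1L) {
    child$value <- value
    child$unit <- unit
  } else {
    insert_path_value(child, segments[-1L], value, unit)
  }
  tree
}

freeze_tree <- function(env_node) {
  kids <- env_node$children
  if (length(kids) == 0L) {
    return(dq_node(env_node$name, value = env_node$value %||% NA,
                   unit = env_node$unit,
                   node_id = env_node$node_id,
                   display_name = env_node$display))
  }
  ord <- order(vapply(kids, function(k) k$order, numeric(1L)))
  dq_node(env_node$name,
          children = lapply(kids[ord], freeze_tree),
          node_id = env_node$node_id,
          display_name = env_node$display)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build one composition from a named list path -> scalar (NULL entries are
# skipped entirely, i.e. the subtree is absent). Values may be wrapped as
# list(value=, unit=) to attach a unit attribute.
composition_from_cells <- function(cells) {
  parsed <- lapply(names(cells), parse_path)
  firsts <- vapply(parsed, function(p) p$segments[[1L]]$name, character(1L))
  dq_assert(length(unique(firsts)) == 1L, "FORMAT",
            "all paths must share a single root segment")
  root <- new.env(parent = emptyenv())
  root$name <- firsts[[1L]]
  root$node_id <- parsed[[1L]]$segments[[1L]]$node_id
  root$display <- NULL
  root$children <- list()
  root$order <- 1L
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (is.null(cell)) next
    unit <- NULL
    value <- cell
    if (is.list(cell)) {
      value <- cell$value
      unit <- cell$unit
    }
    insert_path_value(root, parsed[[i]]$segments[-1L], value, unit)
  }
  dq_composition(freeze_tree(root))
}

load_flat_table <- function(source, missing_tokens) {
  df <- utils::read.csv(source, check.names = FALSE,
                        colClasses = "character", na.strings = NULL,
                        blank.lines.skip = FALSE,
                        stringsAsFactors = FALSE)
  headers <- names(df)
  if (anyDuplicated(headers)) {
    dq_error("FORMAT", sprintf("duplicate column header(s): %s",
      paste(unique(headers[duplicated(headers)]), collapse = ", ")))
  }
  parsed <- lapply(headers, parse_path)  # validates headers
  # Columns whose non-missing cells all parse as numbers become numeric.
  typed <- lapply(seq_along(headers), function(j) {
    col <- df[[j]]
    col[is_missing_token(col, missing_tokens)] <- NA
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == is.na(col)) && any(!is.na(col))) num else col
  })
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cells <- stats::setNames(
      lapply(typed, function(col) {
        v <- col[[i]]
        if (is.na(v)) NA else v
      }),
      headers)
    rows[[i]] <- dq_dataset_row(i - 1L, composition_from_cells(cells))
  }
  rows
}

#' Load a dataset of compositions
#'
#' @param source File path (or readable connection for nested records).
#' @param format `"nested-records"` (JSON lines) or `"flat-table"` (CSV with
#'   path headers).
#' @param missing_tokens Text values normalized to the missing marker at
#'   load time. Defaults cover the common null flavors "", "NA" and "ND".
#' @param schema Optional [constraint_schema()] whose declared types
#'   override inference when listing variables.
#' @return A `dq_dataset`.
#' @export
load_dataset <- function(source,
                         format = c("nested-records", "flat-table"),
                         missing_tokens = DEFAULT_MISSING_TOKENS,
                         schema = NULL) {
  format <- match.arg(format)
  if (format == "nested-records") {
    lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- load_nested_records(lines, missing_tokens)
  } else {
    first <- readLines(source, n = 1L, warn = FALSE)
    rows <- if (length(first) == 0L) list() else
      load_flat_table(source, missing_tokens)
  }
  new_dataset(rows, missing_tokens = missing_tokens, schema = schema)
}

ISO_DATETIME_RE <-
  "^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?)?$"

# Reference-type inference (used when no schema covers the path):
# NUMERIC if every non-missing value parses as a number, DATE_TIME if all
# are ISO-8601, BOOLEAN if all in {true,false}, else CODED_TEXT while the
# distinct-value count stays small (<= 50), else TEXT.
infer_reference_type <- function(values) {
  vals <- values[!vapply(values, function(v) length(v) == 0L || is.na(v),
                         logical(1L))]
  if (length(vals) == 0L) return("TEXT")
  if (all(vapply(vals, is.numeric, logical(1L)))) return("NUMERIC")
  if (all(vapply(vals, is.logical, logical(1L)))) return("BOOLEAN")
  chr <- vapply(vals, as.character, character(1L))
  if (all(!is.na(suppressWarnings(as.numeric(chr))))) return("NUMERIC")
  if (all(grepl(ISO_DATETIME_RE, chr))) return("DATE_TIME")
  if (all(tolower(chr) %in% c("true", "false"))) return("BOOLEAN")
  if (length(unique(chr)) <= 50L) return("CODED_TEXT")
  "TEXT"
}

#' List the variables of a dataset
#'
#' Discovers every distinct resolvable leaf path occurring in the rows and
#' infers each variable's reference type (schema-declared types take
#' precedence). Output is ordered lexicographically by path.
#'
#' @param dataset A `dq_dataset`.
#' @param schema Optional [constraint_schema()].
#' @return `data.frame` with columns `path`, `reference_type`,
#'   `observed_in_rows` (rows with at least one non-missing value).
#' @export
list_variables <- function(dataset, schema = NULL) {
  per_row_paths <- lapply(dataset$rows, function(row) {
    unique(composition_leaf_paths(row$composition))
  })
  all_paths <- unlist(per_row_paths, use.names = FALSE)
  all_paths <- if (length(all_paths) == 0L) character(0) else
    sort(unique(all_paths), method = "radix")
  declared <- list()
  if (!is.null(schema)) {
    for (v in schema$variables) declared[[v$path]] <- v$reference_type
  }
  out <- lapply(all_paths, function(p) {
    parsed <- parse_path(p)
    vals <- list()
    observed <- 0L
    for (row in dataset$rows) {
      rv <- resolve_path(row, parsed)
      present <- Filter(function(v) !is.na(v), rv)
      if (length(present) > 0L) observed <- observed + 1L
      vals <- c(vals, rv)
    }
    type <- declared[[p]] %||% infer_reference_type(vals)
    data.frame(path = p, reference_type = type,
               observed_in_rows = observed, stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(path = character(0), reference_type = character(0),
                      observed_in_rows = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

node_to_json <- function(node) {
  out <- list(name = node$name)
  if (!is.null(node$node_id)) out$node_id <- node$node_id
  if (!is.null(node$archetype_id)) out$archetype_id <- node$archetype_id
  if (!is.null(node$display_name)) out$display_name <- node$display_name
  if (node_is_leaf(node)) {
    out$value <- if (is.null(node$value) || is.na(node$value)) NULL else node$value
    if (!is.null(node$unit)) out$unit <- node$unit
    if (is.null(out$value)) out["value"] <- list(NULL)
  } else {
    out$children <- lapply(node$children, node_to_json)
  }
  out
}

#' Write a dataset to disk
#'
#' @param dataset A `dq_dataset`.
#' @param path Output file.
#' @param format `"nested-records"` or `"flat-table"`. The flat table
#'   contains one column per discovered leaf variable (first match per row);
#'   missing cells are written with `na_token`.
#' @param na_token Token used for missing cells in the flat table.
#' @export
write_dataset <- function(dataset, path,
                          format = c("nested-records", "flat-table"),
                          na_token = "NA") {
  format <- match.arg(format)
  if (format == "nested-records") {
    lines <- vapply(dataset$rows, function(row) {
      jsonlite::toJSON(
        list(template_id = row$template_id,
             root = node_to_json(row$composition$root)),
        auto_unbox = TRUE, null = "null", digits = NA)
    }, character(1L))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  } else {
    vars <- dataset$variables$path
    cols <- lapply(vars, function(p) {
      parsed <- parse_path(p)
      vapply(dataset$rows, function(row) {
        rv <- resolve_path(row, parsed)
        if (length(rv) == 0L || is.na(rv[[1L]])) na_token else
          as.character(rv[[1L]])
      }, character(1L))
    })
    df <- as.data.frame(stats::setNames(cols, vars), check.names = FALSE,
                        stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
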