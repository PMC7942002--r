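# Measurement methods (MMs).
#
# An MM is a 5-tuple: (A) tags, (B) domain paths binding named input items,
# (C) an optional constraint check applied to each input row, (D) an
# optional grouping assigning each row to a group, and (E) a
# characterization summarizing each group into the MM result. Only these
# five parts differ between MMs; everything else is fixed scaffolding.
#
# Domain paths are written in the grammar
#
#   # itemN (type) = dataset-row/<archetype-path>[.instruction]
#   # itemN (type) = other_data_input: <tag filter> .<selector>
#
# where type is numeric|string|text|boolean|datetime and selector is
# resultsValue | resultsGroupLabels | tags. Dataset bindings pull values
# from the dataset rows; filter bindings pull attributes from other MMs'
# results, enabling multi-layered MMs.

ITEM_TYPES <- c("numeric", "text", "boolean", "datetime")
FILTER_SELECTORS <- c("resultsValue", "resultsGroupLabels", "tags")

CHARACTERIZATION_BUILTINS <- c(
  "count_present", "count_total", "count_missing",
  "min", "max", "mean", "median", "sd", "variance",
  "frequency_table", "relative_frequency_table",
  "mean_density", "histogram", "barplot")

#' Construct a domain path binding
#'
#' @param item_name `"item0"`, `"item1"`, ...
#' @param declared_type One of numeric, text, boolean, datetime.
#' @param path Dataset path (for dataset bindings).
#' @param filter Tag filter text or `dq_filter` (for MM-filter bindings).
#' @param selector Attribute selected from matched MM results.
#' @return A `dq_domain_path`.
#' @export
domain_path <- function(item_name, declared_type,
                        path = NULL, filter = NULL,
                        selector = c("resultsValue", "resultsGroupLabels",
                                     "tags")) {
  dq_assert(grepl("^item\\d+$", item_name), "SPEC",
            sprintf("item name '%s' must match 'itemN'", item_name))
  declared_type <- match.arg(declared_type, ITEM_TYPES)
  if (is.null(path) == is.null(filter)) {
    dq_error("SPEC", "exactly one of path/filter must be given")
  }
  if (!is.null(path)) {
    parsed <- parse_path(path)  # validates, incl. dataset-row/ prefix
    structure(list(item_name = item_name, declared_type = declared_type,
                   kind = "dataset", path = path, parsed = parsed),
              class = "dq_domain_path")
  } else {
    selector <- match.arg(selector)
    f <- if (inherits(filter, "dq_filter")) filter else
      parse_filter_expression(filter)
    structure(list(item_name = item_name, declared_type = declared_type,
                   kind = "filter", filter = f, selector = selector),
              class = "dq_domain_path")
  }
}

#' Parse a domain-path declaration
#'
#' @param text Declaration in the grammar `"# itemN (type) = <binding>"`.
#' @return A `dq_domain_path`.
#' @export
parse_domain_path <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*#\\s*(item\\d+)\\s*\\(([A-Za-z_]+)\\)\\s*=\\s*(.*?)\\s*$",
    text))[[1L]]
  if (length(m) == 0L) {
    dq_error("PARSE", sprintf(
      "domain path '%s' does not match '# itemN (type) = <binding>'", text))
  }
  item <- m[2L]
  type_kw <- m[3L]
  type <- switch(type_kw,
    numeric = "numeric", string = "text", text = "text",
    boolean = "boolean", datetime = "datetime",
    dq_error("PARSE", sprintf("unknown type keyword '%s' in '%s'",
                              type_kw, text)))
  binding <- m[4L]
  if (startsWith(binding, "other_data_input:")) {
    rest <- trimws(substring(binding, nchar("other_data_input:") + 1L))
    sm <- regmatches(rest, regexec(
      sprintf("^(.*?)\\s*\\.(%s)$", paste(FILTER_SELECTORS, collapse = "|")),
      rest))[[1L]]
    if (length(sm) == 0L) {
      dq_error("PARSE", sprintf(
        "filter binding '%s' must end with a selector (.%s)",
        text, paste(FILTER_SELECTORS, collapse = "/.")))
    }
    domain_path(item, type, filter = sm[2L], selector = sm[3L])
  } else {
    domain_path(item, type, path = binding)
  }
}

render_domain_path <- function(dp) {
  type_kw <- if (dp$declared_type == "text") "string" else dp$declared_type
  binding <- if (dp$kind == "dataset") dp$path else
    sprintf("other_data_input: %s .%s", dp$filter$source, dp$selector)
  sprintf("# %s (%s) = %s", dp$item_name, type_kw, binding)
}

#' Construct a characterization
#'
#' Either a named builtin from the registry (with optional parameters, e.g.
#' `breaks` for histograms) or a custom dialect expression over the item
#' vectors (plus `check` when the MM defines a check).
#'
#' @param builtin Registry name, or `NULL` when `expr` is given.
#' @param expr Custom expression text, or `NULL`.
#' @param params Named list of builtin parameters.
#' @export
characterization <- function(builtin = NULL, expr = NULL, params = list()) {
  if (is.null(builtin) == is.null(expr)) {
    dq_error("SPEC", "exactly one of builtin/expr must be given")
  }
  if (!is.null(builtin)) {
    dq_assert(builtin %in% CHARACTERIZATION_BUILTINS, "REGISTRY",
              sprintf("unknown characterization builtin '%s'", builtin))
    structure(list(kind = "builtin", builtin = builtin, params = params),
              class = "dq_characterization")
  } else {
    structure(list(kind = "custom", expr = parse_expression(expr)),
              class = "dq_characterization")
  }
}

#' Construct a measurement method
#'
#' @param tags Non-empty character vector of descriptive keywords.
#' @param domain_paths List of [domain_path()] objects (or declaration
#'   strings), named item0, item1, ... consecutively.
#' @param characterization A [characterization()] or a builtin name.
#' @param check Optional check expression (text or `dq_expr`).
#' @param grouping Optional grouping expression (text or `dq_expr`).
#' @param description Optional free text.
#' @param id Stable identifier; defaults to a content hash of the 5-tuple.
#' @return A `dq_mm`.
#' @export
measurement_method <- function(tags, domain_paths, characterization,
                               check = NULL, grouping = NULL,
                               description = NULL, id = NULL) {
  dps <- lapply(domain_paths, function(dp) {
    if (inherits(dp, "dq_domain_path")) dp else parse_domain_path(dp)
  })
  if (is.character(characterization)) {
    characterization <- characterization(builtin = characterization)
  }
  as_expr <- function(e) {
    if (is.null(e) || inherits(e, "dq_expr")) e else parse_expression(e)
  }
  mm <- structure(
    list(id = id, tags = as.character(tags), domain_paths = dps,
         check = as_expr(check), grouping = as_expr(grouping),
         characterization = characterization,
         description = description),
    class = "dq_mm")
  if (is.null(id)) mm$id <- mm_content_id(mm)
  mm
}

#' @export
print.dq_mm <- function(x, ...) {
  cat(sprintf("<dq_mm> %s [%s]\n", x$id, paste(x$tags, collapse = ", ")))
  for (dp in x$domain_paths) cat(" ", render_domain_path(dp), "\n")
  if (!is.null(x$check)) cat("  check:", x$check$source, "\n")
  if (!is.null(x$grouping)) cat("  grouping:", x$grouping$source, "\n")
  ch <- x$characterization
  cat("  characterization:",
      if (ch$kind == "builtin") ch$builtin else ch$expr$source, "\n")
  invisible(x)
}

mm_binding_kind <- function(mm) {
  kinds <- unique(vapply(mm$domain_paths, function(dp) dp$kind, character(1L)))
  if (length(kinds) == 1L) kinds else "mixed"
}

mm_to_document <- function(mm, with_id = TRUE) {
  ch <- mm$characterization
  doc <- list()
  if (with_id) doc$id <- mm$id
  doc$tags <- as.list(mm$tags)
  doc$domain_paths <- lapply(mm$domain_paths, render_domain_path)
  doc$check <- if (is.null(mm$check)) NULL else mm$check$source
  doc$grouping <- if (is.null(mm$grouping)) NULL else mm$grouping$source
  doc$characterization <- if (ch$kind == "builtin") {
    c(list(builtin = ch$builtin),
      if (length(ch$params) > 0L) list(params = ch$params))
  } else {
    list(expr = ch$expr$source)
  }
  doc$description <- mm$description
  doc
}

mm_from_document <- function(doc) {
  ch <- doc$characterization
  chr <- if (!is.null(ch$builtin)) {
    characterization(builtin = ch$builtin, params = ch$params %||% list())
  } else {
    characterization(expr = ch$expr)
  }
  measurement_method(
    tags = unlist(doc$tags),
    domain_paths = lapply(doc$domain_paths, parse_domain_path),
    characterization = chr,
    check = doc$check,
    grouping = doc$grouping,
    description = doc$description,
    id = doc$id)
}

render_mm_yaml <- function(mm, with_id = TRUE) {
  yaml::as.yaml(mm_to_document(mm, with_id = with_id))
}

# Content-hash identity: the id is a digest of the rendered 5-tuple (id
# excluded), so identical MMs share identity across knowledge-base
# round-trips and version-control history.
mm_content_id <- function(mm) {
  paste0("mm_", substr(
    digest::digest(render_mm_yaml(mm, with_id = FALSE), algo = "sha256",
                   serialize = FALSE),
    1L, 16L))
}

mm_issue <- function(code, message) list(code = code, message = message)

#' Validate a measurement method
#'
#' Checks the structural invariants of the 5-tuple: non-empty tags,
#' consecutive item names from item0, expressions referencing only declared
#' items, a single binding kind, and a known characterization builtin.
#'
#' @param mm A `dq_mm`.
#' @return List of issues (empty when valid); each issue has `$code` and
#'   `$message`.
#' @export
validate_mm <- function(mm) {
  issues <- list()
  add <- function(code, msg) {
    issues[[length(issues) + 1L]] <<- mm_issue(code, msg)
  }
  if (length(mm$tags) == 0L || all(!nzchar(mm$tags))) {
    add("EMPTY_TAGS", "tags must be non-empty")
  }
  if (length(mm$domain_paths) == 0L) {
    add("EMPTY_DOMAIN_PATHS", "at least one domain path is required")
  } else {
    names_seen <- vapply(mm$domain_paths, function(dp) dp$item_name,
                         character(1L))
    expected <- paste0("item", seq_along(names_seen) - 1L)
    if (!identical(names_seen, expected)) {
      add("BAD_ITEM_NUMBERING", sprintf(
        "item names must be %s, found %s",
        paste(expected, collapse = ","), paste(names_seen, collapse = ",")))
    }
    if (anyDuplicated(names_seen)) {
      add("DUPLICATE_ITEM", "duplicate item names")
    }
    if (mm_binding_kind(mm) == "mixed") {
      add("MIXED_BINDING_KINDS",
          "domain paths must be all dataset bindings or all MM filters")
    }
  }
  declared <- vapply(mm$domain_paths, function(dp) dp$item_name, character(1L))
  check_vars <- function(expr, where, extra = character(0)) {
    if (is.null(expr)) return()
    for (v in setdiff(expr_free_vars(expr), c(declared, extra))) {
      add("UNDECLARED_ITEM",
          sprintf("%s references undeclared item '%s'", where, v))
    }
  }
  check_vars(mm$check, "check")
  check_vars(mm$grouping, "grouping")
  ch <- mm$characterization
  if (ch$kind == "custom") {
    check_vars(ch$expr, "characterization", extra = "check")
  } else if (!ch$builtin %in% CHARACTERIZATION_BUILTINS) {
    add("UNKNOWN_BUILTIN",
        sprintf("unknown characterization builtin '%s'", ch$builtin))
  }
  issues
}

## ---- characterization builtins ---------------------------------------

freq_table <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(structure(numeric(0), names = character(0)))
  }
  tab <- table(as.character(v))
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  counts[order(names(counts), method = "radix")]
}

plot_data <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "dq_plot_data")
}

minmax_builtin <- function(v, num, first) {
  x <- v[!is.na(v)]
  if (is.character(x)) {
    if (length(x) == 0L) return(NA_character_)
    s <- sort(x, method = "radix")
    return(if (first) s[1L] else s[length(s)])
  }
  x <- num()
  if (length(x) == 0L) return(NA_real_)
  if (first) min(x) else max(x)
}

# Apply a builtin to one group's vector. Builtins skip missing values,
# except count_total/count_missing (completeness bookkeeping).
apply_builtin <- function(builtin, v, params = list()) {
  num <- function() {
    x <- v[!is.na(v)]
    if (is.logical(x)) x <- as.numeric(x)
    if (!is.numeric(x)) {
      if (length(x) == 0L) return(numeric(0))
      x2 <- suppressWarnings(as.numeric(as.character(x)))
      if (anyNA(x2)) {
        dq_error("EVAL", sprintf(
          "builtin '%s' needs numeric input", builtin))
      }
      x <- x2
    }
    x
  }
  switch(builtin,
    count_present = sum(!is.na(v)),
    count_total = length(v),
    count_missing = sum(is.na(v)),
    # min/max of text (e.g. ISO dates) is byte-order, locale-independent
    min = minmax_builtin(v, num, first = TRUE),
    max = minmax_builtin(v, num, first = FALSE),
    mean = if (length(num()) == 0L) NA_real_ else mean(num()),
    median = if (length(num()) == 0L) NA_real_ else stats::median(num()),
    sd = if (length(num()) < 2L) NA_real_ else stats::sd(num()),
    variance = if (length(num()) < 2L) NA_real_ else stats::var(num()),
    frequency_table = freq_table(v),
    relative_frequency_table = {
      tab <- freq_table(v)
      if (length(tab) == 0L) tab else tab / sum(tab)
    },
    mean_density = {
      x <- num()
      if (length(x) < 2L) NA_real_ else mean(abs(diff(x)))
    },
    histogram = {
      x <- num()
      if (length(x) == 0L) {
        plot_data("histogram", breaks = numeric(0), counts = numeric(0))
      } else {
        h <- graphics::hist(x, breaks = params$breaks %||% "Sturges",
                            plot = FALSE)
        plot_data("histogram", breaks = h$breaks, counts = h$counts)
      }
    },
    barplot = {
      tab <- freq_table(v)
      plot_data("barplot", labels = names(tab), counts = unname(tab))
    },
    dq_error("REGISTRY", sprintf("unknown builtin '%s'", builtin)))
}
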