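# Composition trees and the archetype-path dialect.
#
# A composition is one nested clinical record: a tree of named nodes where a
# node carries either a scalar payload (optionally with a unit attribute) or
# an ordered list of children, never both. Nodes may be annotated with a
# node id (e.g. "at0001"), an archetype id and a human-readable display name.
#
# Paths address nodes inside a composition:
#
#   dataset-row/<seg>/<seg>/...[.<attr>][.countChildnodes(<mode>)]
#
# where each segment is `name`, `name[id]`, `name[id,'display']` or `[id]`
# (id matches the node id or the archetype id), the optional trailing
# `.value` / `.magnitude` / `.unit` / `.code` projects an attribute of the
# matched payload, and the optional `.countChildnodes(only_child|all)`
# instruction asks for the number of child nodes instead of the contents.

PATH_PREFIX <- "dataset-row/"
PATH_ATTRIBUTES <- c("value", "magnitude", "unit", "code")

#' Construct a composition node
#'
#' @param name Element name (non-empty string).
#' @param value Scalar payload; mutually exclusive with `children`.
#' @param unit Optional unit attribute of the payload (e.g. "kg").
#' @param children Ordered list of child nodes; mutually exclusive with
#'   `value`.
#' @param node_id Optional node-id annotation (e.g. "at0001").
#' @param archetype_id Optional archetype identifier.
#' @param display_name Optional human-readable name used by
#'   `[id,'display']` predicates.
#' @return A `dq_node`.
#' @export
dq_node <- function(name, value = NULL, unit = NULL, children = NULL,
                    node_id = NULL, archetype_id = NULL,
                    display_name = NULL) {
  dq_assert(is.character(name) && length(name) == 1L && nzchar(name),
            "SPEC", "node name must be a non-empty string")
  if (!is.null(value) && !is.null(children)) {
    dq_error("SPEC", sprintf(
      "node '%s' has both a payload and children; a node carries one or the other",
      name))
  }
  if (!is.null(value)) {
    dq_assert(length(value) == 1L, "SPEC",
              sprintf("payload of node '%s' must be scalar", name))
  }
  structure(
    list(name = name, value = value, unit = unit,
         children = children, node_id = node_id,
         archetype_id = archetype_id, display_name = display_name),
    class = "dq_node")
}

#' Wrap a root node as a composition
#'
#' @param root The root `dq_node` of the record.
#' @export
dq_composition <- function(root) {
  dq_assert(inherits(root, "dq_node"), "SPEC", "root must be a dq_node")
  structure(list(root = root), class = "dq_composition")
}

#' Construct a dataset row
#'
#' @param row_index 0-based ordinal of the row within its dataset.
#' @param composition The row's `dq_composition`.
#' @param template_id Optional template identifier.
#' @export
dq_dataset_row <- function(row_index, composition, template_id = NULL) {
  dq_assert(inherits(composition, "dq_composition"), "SPEC",
            "composition must be a dq_composition")
  structure(list(row_index = as.integer(row_index),
                 composition = composition,
                 template_id = template_id),
            class = "dq_dataset_row")
}

node_is_leaf <- function(node) is.null(node$children)

path_syntax_error <- function(path, msg) {
  dq_error("PATH_SYNTAX", sprintf("invalid path '%s': %s", path, msg))
}

# Split a path body on "/" outside brackets and quotes.
split_segments_raw <- function(body, full) {
  chars <- strsplit(body, "", fixed = TRUE)[[1L]]
  segs <- character(0)
  buf <- character(0)
  depth <- 0L
  in_quote <- FALSE
  for (ch in chars) {
    if (ch == "'" && depth > 0L) in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") {
        depth <- depth - 1L
        if (depth < 0L) path_syntax_error(full, "unbalanced ']'")
      }
    }
    if (ch == "/" && depth == 0L && !in_quote) {
      segs <- c(segs, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
  }
  if (depth != 0L) path_syntax_error(full, "unbalanced '['")
  if (in_quote) path_syntax_error(full, "unterminated quote")
  c(segs, paste(buf, collapse = ""))
}

parse_segment <- function(seg, full) {
  m <- regmatches(seg, regexec("^([^][]*)([[]([^]]*)[]])?$", seg))[[1L]]
  if (length(m) == 0L) path_syntax_error(full, sprintf("bad segment '%s'", seg))
  name <- m[2L]
  pred <- if (nzchar(m[3L])) m[4L] else NULL
  if (!nzchar(name) && is.null(pred)) {
    path_syntax_error(full, "empty segment")
  }
  node_id <- NULL
  display <- NULL
  if (!is.null(pred)) {
    pm <- regmatches(pred,
      regexec("^\\s*([^,']+?)\\s*(,\\s*'(.*)'\\s*)?$", pred))[[1L]]
    if (length(pm) == 0L || !nzchar(pm[2L])) {
      path_syntax_error(full, sprintf("bad predicate '[%s]'", pred))
    }
    node_id <- pm[2L]
    if (nzchar(pm[3L])) display <- pm[4L]
  }
  list(name = name, node_id = node_id, display = display)
}

#' Parse a path expression
#'
#' @param path Path text in the dialect described above.
#' @return A `dq_path`: list of segments plus optional `projection` and
#'   `count_mode`.
#' @export
parse_path <- function(path) {
  dq_assert(is.character(path) && length(path) == 1L, "PATH_SYNTAX",
            "path must be a single string")
  text <- trimws(path)
  if (!startsWith(text, PATH_PREFIX)) {
    path_syntax_error(path, sprintf("must start with '%s'", PATH_PREFIX))
  }
  body <- substring(text, nchar(PATH_PREFIX) + 1L)

  count_mode <- NULL
  m <- regmatches(body, regexec("\\.countChildnodes\\(([^)]*)\\)\\s*$", body))[[1L]]
  if (length(m) > 0L) {
    count_mode <- m[2L]
    if (!count_mode %in% c("only_child", "all")) {
      path_syntax_error(path, sprintf("unknown countChildnodes mode '%s'", count_mode))
    }
    body <- sub("\\.countChildnodes\\([^)]*\\)\\s*$", "", body)
  } else if (grepl("countChildnodes", body, fixed = TRUE)) {
    path_syntax_error(path, "malformed countChildnodes instruction")
  }

  segs <- split_segments_raw(body, path)
  if (length(segs) == 0L || !any(nzchar(segs))) {
    path_syntax_error(path, "no segments")
  }

  # A trailing ".attr" on the last segment (outside any bracket) is a
  # payload projection, not part of the element name.
  projection <- NULL
  last <- segs[length(segs)]
  pm <- regmatches(last, regexec(
    sprintf("^(.*?)\\.(%s)$", paste(PATH_ATTRIBUTES, collapse = "|")), last))[[1L]]
  if (length(pm) > 0L) {
    dot_pos <- nchar(pm[2L]) + 1L
    close_pos <- regexpr("\\][^\\]]*$", last)
    if (close_pos < 0L || dot_pos > close_pos) {
      projection <- pm[3L]
      segs[length(segs)] <- pm[2L]
      if (!nzchar(pm[2L])) path_syntax_error(path, "projection without a segment")
    }
  }

  structure(
    list(segments = lapply(segs, parse_segment, full = path),
         projection = projection,
         count_mode = count_mode,
         source = path),
    class = "dq_path")
}

segment_matches <- function(node, seg) {
  if (nzchar(seg$name) && !identical(node$name, seg$name)) return(FALSE)
  if (!is.null(seg$node_id)) {
    ids <- c(node$node_id, node$archetype_id)
    if (!(seg$node_id %in% ids)) return(FALSE)
  }
  if (!is.null(seg$display) && !identical(node$display_name, seg$display)) {
    return(FALSE)
  }
  TRUE
}

# All nodes matched by the parsed path, in document order.
match_nodes <- function(row, parsed) {
  root <- row$composition$root
  current <- if (segment_matches(root, parsed$segments[[1L]])) list(root) else list()
  if (length(parsed$segments) > 1L) {
    for (seg in parsed$segments[-1L]) {
      nxt <- list()
      for (node in current) {
        for (child in node$children) {
          if (segment_matches(child, seg)) nxt[[length(nxt) + 1L]] <- child
        }
      }
      current <- nxt
      if (length(current) == 0L) break
    }
  }
  current
}

project_payload <- function(node, projection) {
  if (is.null(projection) || projection %in% c("value", "code")) {
    v <- node$value
    if (is.null(v)) NA else v
  } else if (projection == "magnitude") {
    v <- suppressWarnings(as.numeric(node$value))
    if (length(v) == 0L) NA_real_ else v
  } else if (projection == "unit") {
    if (is.null(node$unit)) NA_character_ else node$unit
  }
}

#' Resolve a path against one dataset row
#'
#' Returns the payloads of all matched leaf nodes in document order; an
#' empty list when nothing matches. A path carrying a
#' `.countChildnodes(mode)` instruction instead returns a single child-node
#' count (see [count_child_nodes()]).
#'
#' @param row A `dq_dataset_row`.
#' @param path Path text or a pre-parsed `dq_path`.
#' @return List of scalar values (possibly `NA` for missing payloads).
#' @export
resolve_path <- function(row, path) {
  parsed <- if (inherits(path, "dq_path")) path else parse_path(path)
  if (!is.null(parsed$count_mode)) {
    return(list(count_matched_children(row, parsed, parsed$count_mode)))
  }
  matched <- match_nodes(row, parsed)
  out <- list()
  for (node in matched) {
    if (node_is_leaf(node)) {
      out[[length(out) + 1L]] <- project_payload(node, parsed$projection)
    }
  }
  out
}

count_matched_children <- function(row, parsed, mode) {
  matched <- match_nodes(row, parsed)
  if (mode == "only_child") {
    if (length(matched) > 1L) {
      dq_error("AMBIGUITY", sprintf(
        "countChildnodes(only_child) on '%s': %d parents matched, expected at most one",
        parsed$source, length(matched)))
    }
    if (length(matched) == 0L) return(0L)
    length(matched[[1L]]$children)
  } else {
    sum(vapply(matched, function(n) length(n$children), integer(1L)))
  }
}

#' Count child nodes under a path
#'
#' Mode `"only_child"` requires at most one matched parent and fails loudly
#' on ambiguity; an absent parent counts as 0. Mode `"all"` sums child
#' counts over every matched parent.
#'
#' @inheritParams resolve_path
#' @param mode `"only_child"` or `"all"`.
#' @return Non-negative integer.
#' @export
count_child_nodes <- function(row, path, mode = c("only_child", "all")) {
  mode <- match.arg(mode)
  parsed <- if (inherits(path, "dq_path")) path else parse_path(path)
  parsed$count_mode <- NULL
  count_matched_children(row, parsed, mode)
}

# Canonical leaf paths occurring in a composition; a segment renders its
# node-id predicate when the node carries one, so discovered paths resolve
# identically on nested-record and flat-table encodings.
leaf_paths <- function(node, prefix = "") {
  seg <- node$name
  if (!is.null(node$node_id)) seg <- sprintf("%s[%s]", seg, node$node_id)
  here <- if (nzchar(prefix)) paste(prefix, seg, sep = "/") else seg
  if (node_is_leaf(node)) return(here)
  unlist(lapply(node$children, leaf_paths, prefix = here), use.names = FALSE)
}

composition_leaf_paths <- function(composition) {
  lp <- leaf_paths(composition$root)
  if (length(lp) == 0L) return(character(0))
  paste0(PATH_PREFIX, lp)
}

# Drop the final segment (used to address the parent container of a
# variable for cardinality checks). Projections/instructions are dropped.
parent_path <- function(path) {
  parsed <- if (inherits(path, "dq_path")) path else parse_path(path)
  n <- length(parsed$segments)
  dq_assert(n >= 2L, "PATH_SYNTAX",
            sprintf("path '%s' has no parent", parsed$source))
  render_segments <- vapply(parsed$segments[seq_len(n - 1L)], function(seg) {
    out <- seg$name
    if (!is.null(seg$node_id)) {
      pred <- if (is.null(seg$display)) seg$node_id else
        sprintf("%s,'%s'", seg$node_id, seg$display)
      out <- sprintf("%s[%s]", out, pred)
    }
    out
  }, character(1L))
  paste0(PATH_PREFIX, paste(render_segments, collapse = "/"))
}
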