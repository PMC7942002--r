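# MM execution: input assembly, check, grouping, characterization, and
# dependency resolution for multi-layered MMs.
#
# Input assembly follows two alignment rules. Dataset bindings produce one
# input row per dataset row; when a path matches several nodes inside one
# composition (repeated elements), each matched node contributes its own
# input row with the originating row index kept as provenance. Filter
# bindings produce one input row per (matched MM, group) pair. Mixing the
# two kinds within one MM is rejected — their row semantics are
# incomparable.

coerce_item_values <- function(values, declared_type) {
  switch(declared_type,
    numeric = vapply(values, function(v) {
      if (is.na(v)) return(NA_real_)
      if (is.numeric(v)) return(as.numeric(v))
      if (is.logical(v)) return(as.numeric(v))
      suppressWarnings(as.numeric(as.character(v)))
    }, numeric(1L)),
    boolean = vapply(values, function(v) {
      if (is.na(v)) return(NA)
      if (is.logical(v)) return(v)
      tolower(as.character(v)) %in% "true"
    }, logical(1L)),
    # text and datetime are carried as character
    vapply(values, function(v) {
      if (is.na(v)) NA_character_ else as.character(v)
    }, character(1L)))
}

assemble_dataset_input <- function(mm, dataset) {
  items <- mm$domain_paths
  n_items <- length(items)
  cols <- stats::setNames(rep(list(list()), n_items),
                          vapply(items, `[[`, character(1L), "item_name"))
  row_prov <- integer(0)
  for (row in dataset$rows) {
    per_item <- lapply(items, function(dp) resolve_path(row, dp$parsed))
    lens <- lengths(per_item)
    m <- max(lens, 1L)
    bad <- lens[lens > 1L]
    if (length(unique(bad)) > 1L) {
      dq_error("ALIGNMENT", sprintf(
        "row %d: items match differing numbers of nodes (%s) for MM %s",
        row$row_index, paste(lens, collapse = ","), mm$id))
    }
    for (j in seq_len(n_items)) {
      vals <- per_item[[j]]
      vals <- if (lens[j] == 0L) rep(list(NA), m)
              else if (lens[j] == m) vals
              else rep(vals, m)  # length 1 recycled over matched nodes
      cols[[j]] <- c(cols[[j]], vals)
    }
    row_prov <- c(row_prov, rep(row$row_index, m))
  }
  typed <- lapply(seq_len(n_items), function(j) {
    coerce_item_values(cols[[j]], items[[j]]$declared_type)
  })
  names(typed) <- names(cols)
  list(items = typed, provenance = data.frame(row_index = row_prov))
}

select_result_attribute <- function(mm_entry, group, selector) {
  switch(selector,
    resultsValue = {
      v <- group$value
      if (is.numeric(v) && length(v) == 1L) v else NA_real_
    },
    resultsGroupLabels = group$group_label,
    tags = paste(mm_entry$tags, collapse = ";"))
}

assemble_filter_input <- function(mm, prior) {
  items <- mm$domain_paths
  filters <- vapply(items, function(dp) dp$filter$source, character(1L))
  if (length(unique(filters)) > 1L) {
    dq_error("UNSUPPORTED_COMBINATION", sprintf(
      "MM %s: all filter bindings must share one filter expression", mm$id))
  }
  flt <- items[[1L]]$filter
  matched <- Filter(function(res) {
    identical(res$status, "ok") && eval_filter(flt, res$tags)
  }, prior)
  # canonical row order (by MM id): results are then independent of which
  # valid topological order produced `prior`
  matched <- matched[order(vapply(matched, `[[`, character(1L), "mm_id"),
                           method = "radix")]
  if (length(matched) == 0L) {
    dq_error("EMPTY_FILTER", sprintf(
      "MM %s: filter '%s' matches no executed MM", mm$id, flt$source))
  }
  rows <- list()
  for (res in matched) {
    for (grp in res$groups) {
      rows[[length(rows) + 1L]] <- list(res = res, grp = grp)
    }
  }
  typed <- lapply(items, function(dp) {
    vals <- lapply(rows, function(r) {
      select_result_attribute(r$res, r$grp, dp$selector)
    })
    coerce_item_values(vals, dp$declared_type)
  })
  names(typed) <- vapply(items, `[[`, character(1L), "item_name")
  prov <- data.frame(
    source_mm = vapply(rows, function(r) r$res$mm_id, character(1L)),
    group_label = vapply(rows, function(r) r$grp$group_label, character(1L)),
    stringsAsFactors = FALSE)
  list(items = typed, provenance = prov)
}

#' Assemble the input table for an MM
#'
#' @param mm A `dq_mm`.
#' @param dataset A `dq_dataset` (required for dataset bindings).
#' @param prior Named list of `dq_mm_result` from already-executed MMs
#'   (required for filter bindings).
#' @return List with `items` (named, equal-length, typed vectors) and
#'   `provenance` (one row per input row).
#' @export
assemble_input <- function(mm, dataset = NULL, prior = list()) {
  kind <- mm_binding_kind(mm)
  if (kind == "mixed") {
    dq_error("UNSUPPORTED_COMBINATION", sprintf(
      "MM %s mixes dataset and filter domain paths", mm$id))
  }
  if (kind == "dataset") {
    dq_assert(inherits(dataset, "dq_dataset"), "SPEC",
              "dataset bindings require a dataset")
    assemble_dataset_input(mm, dataset)
  } else {
    assemble_filter_input(mm, prior)
  }
}

#' Apply an MM's check to an assembled input
#'
#' @param mm A `dq_mm` with a check expression.
#' @param input Result of [assemble_input()].
#' @return One check result per input row (missing inputs propagate).
#' @export
apply_check <- function(mm, input) {
  dq_assert(!is.null(mm$check), "SPEC", "MM has no check")
  n <- input_length(input)
  out <- evaluate_expression(mm$check, input$items)
  recycle_to(out, max(n, length(out)))
}

#' Apply an MM's grouping to an assembled input
#'
#' @inheritParams apply_check
#' @return Character vector of group labels; `"ALL"` when the MM defines no
#'   grouping, `"MISSING"` where the grouping value is missing.
#' @export
apply_grouping <- function(mm, input) {
  n <- input_length(input)
  if (is.null(mm$grouping)) return(rep("ALL", n))
  labels <- evaluate_expression(mm$grouping, input$items)
  labels <- as.character(recycle_to(labels, max(n, length(labels))))
  labels[is.na(labels)] <- "MISSING"
  labels
}

input_length <- function(input) {
  if (length(input$items) == 0L) return(0L)
  max(lengths(input$items))
}

#' Apply an MM's characterization per group
#'
#' When the MM defines a check the characterization consumes the check
#' vector; otherwise it consumes item0 (further items serve grouping and
#' conditions). Groups are ordered lexicographically.
#'
#' @inheritParams apply_check
#' @param check Check vector from [apply_check()] (or `NULL`).
#' @param groups Label vector from [apply_grouping()].
#' @return A `dq_mm_result`.
#' @export
apply_characterization <- function(mm, input, check = NULL, groups = NULL) {
  n <- input_length(input)
  if (is.null(groups)) groups <- rep("ALL", n)
  target <- if (!is.null(check)) check else input$items[[1L]]
  labels <- sort(unique(groups), method = "radix")
  ch <- mm$characterization
  out_groups <- lapply(labels, function(lb) {
    sel <- groups == lb
    value <- if (ch$kind == "builtin") {
      apply_builtin(ch$builtin, target[sel], ch$params)
    } else {
      bindings <- lapply(input$items, function(col) col[sel])
      if (!is.null(check)) bindings$check <- check[sel]
      evaluate_expression(ch$expr, bindings)
    }
    list(group_label = lb, value = value)
  })
  check_counts <- NULL
  if (!is.null(check) && is.logical(check)) {
    check_counts <- c(n_true = sum(check, na.rm = TRUE),
                      n_false = sum(!check, na.rm = TRUE),
                      n_missing = sum(is.na(check)))
  }
  structure(
    list(mm_id = mm$id, tags = mm$tags, groups = out_groups,
         check_counts = check_counts, n_input_rows = n,
         status = "ok", error = NULL),
    class = "dq_mm_result")
}

#' @export
print.dq_mm_result <- function(x, ...) {
  cat(sprintf("<dq_mm_result> %s (%s)\n", x$mm_id, x$status))
  for (g in x$groups) {
    v <- g$value
    vtxt <- if (inherits(v, "dq_plot_data")) sprintf("<%s>", v$type)
            else if (length(v) > 1L) paste0("{", paste(names(v), round(v, 4),
                                            sep = ":", collapse = ", "), "}")
            else format(v)
    cat(sprintf("  %s: %s\n", g$group_label, vtxt))
  }
  invisible(x)
}

failed_result <- function(mm, err) {
  structure(
    list(mm_id = mm$id, tags = mm$tags, groups = list(),
         check_counts = NULL, n_input_rows = NA_integer_,
         status = "failed", error = conditionMessage(err)),
    class = "dq_mm_result")
}

#' Execute one MM
#'
#' @inheritParams assemble_input
#' @return A `dq_mm_result`.
#' @export
execute_mm <- function(mm, dataset = NULL, prior = list()) {
  input <- assemble_input(mm, dataset = dataset, prior = prior)
  check <- if (!is.null(mm$check)) apply_check(mm, input) else NULL
  groups <- apply_grouping(mm, input)
  apply_characterization(mm, input, check = check, groups = groups)
}

mm_filter_of <- function(mm) {
  for (dp in mm$domain_paths) {
    if (dp$kind == "filter") return(dp$filter)
  }
  NULL
}

#' Resolve the execution order of a set of MMs
#'
#' Builds the dependency graph (an edge from MM x to MM y whenever y's
#' filter matches x's tags) and returns a stable topological order:
#' independent MMs keep their input order.
#'
#' @param mms List of `dq_mm`.
#' @return The same MMs, reordered so dependencies execute first.
#' @export
resolve_execution_order <- function(mms) {
  n <- length(mms)
  if (n == 0L) return(mms)
  filters <- lapply(mms, mm_filter_of)
  depends_on <- lapply(seq_len(n), function(y) {
    f <- filters[[y]]
    if (is.null(f)) return(integer(0))
    which(vapply(seq_len(n), function(x) {
      x != y && eval_filter(f, mms[[x]]$tags)
    }, logical(1L)))
  })
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(y) {
      all(placed[depends_on[[y]]])
    }, logical(1L)))
    if (length(ready) == 0L) break
    take <- ready[1L]  # stable: first in input order
    placed[take] <- TRUE
    order_out <- c(order_out, take)
  }
  if (any(!placed)) {
    ids <- vapply(mms[!placed], `[[`, character(1L), "id")
    dq_error("CYCLE", sprintf(
      "dependency cycle among MMs: %s", paste(ids, collapse = ", ")))
  }
  mms[order_out]
}

#' Execute a set of MMs against a dataset
#'
#' MMs run in dependency order; a failing MM is recorded as a failed result
#' and never aborts the batch, so DQ reports surface partial results.
#'
#' @param mms List of `dq_mm`.
#' @param dataset A `dq_dataset` (may be `NULL` when all MMs are
#'   filter-only, which only makes sense with non-empty `prior`).
#' @param prior Optional pre-existing results made available to filters.
#' @return Named list `mm_id -> dq_mm_result` in execution order.
#' @export
execute_all <- function(mms, dataset = NULL, prior = list()) {
  ordered <- resolve_execution_order(mms)
  results <- prior
  for (mm in ordered) {
    res <- tryCatch({
      issues <- validate_mm(mm)
      if (length(issues) > 0L) {
        dq_error("VALIDATION", paste(
          vapply(issues, `[[`, character(1L), "code"), collapse = ", "))
      }
      execute_mm(mm, dataset = dataset, prior = results)
    }, dq_error = function(e) failed_result(mm, e),
       error = function(e) failed_result(mm, e))
    results[[mm$id]] <- res
  }
  results[vapply(ordered, `[[`, character(1L), "id")]
}

## ---- results export --------------------------------------------------

scalarize_value <- function(v) {
  if (inherits(v, "dq_plot_data")) {
    return(as.character(jsonlite::toJSON(unclass(v), auto_unbox = TRUE,
                                         digits = NA)))
  }
  if (length(v) > 1L || !is.null(names(v))) {
    return(as.character(jsonlite::toJSON(as.list(v), auto_unbox = TRUE,
                                         digits = NA)))
  }
  if (length(v) == 0L) return(NA_character_)
  as.character(v)
}

#' Flatten execution results to a table
#'
#' @param results Named list of `dq_mm_result`.
#' @return `data.frame` with columns mm_id, tags, status, group_label,
#'   value (non-scalar values JSON-encoded).
#' @export
results_to_table <- function(results) {
  rows <- list()
  for (res in results) {
    if (length(res$groups) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        mm_id = res$mm_id, tags = paste(res$tags, collapse = ";"),
        status = res$status, group_label = NA_character_,
        value = NA_character_, stringsAsFactors = FALSE)
    }
    for (g in res$groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        mm_id = res$mm_id, tags = paste(res$tags, collapse = ";"),
        status = res$status, group_label = g$group_label,
        value = scalarize_value(g$value), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mm_id = character(0), tags = character(0),
                      status = character(0), group_label = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write execution results to disk
#'
#' Writes both a structured document (`results.json`: MM id, tags, groups,
#' values) and a flat delimited table (`results.csv`) for downstream tools.
#'
#' @param results Named list of `dq_mm_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- lapply(results, function(res) {
    list(mm_id = res$mm_id, tags = as.list(res$tags), status = res$status,
         error = res$error,
         groups = lapply(res$groups, function(g) {
           v <- g$value
           list(group_label = g$group_label,
                value = if (inherits(v, "dq_plot_data")) unclass(v)
                        else if (length(v) > 1L || !is.null(names(v)))
                          as.list(v)
                        else v)
         }))
  })
  jsonlite::write_json(doc, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  utils::write.csv(results_to_table(results),
                   file.path(dir, "results.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(dir)
}
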