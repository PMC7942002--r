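# The three adapted HDQF measures, built as ordinary (multi-layered) MMs:
#
# RepresentationComplete — fraction of non-missing entries per variable,
#   with the dataset row count as denominator (an absent subtree counts as
#   missing).
# TaskComplete — per mandatory variable, the count of rows whose mandatory
#   value is missing or absent (cardinality via child-node counting); 0 is
#   the all-good value.
# TDConstraints — one multi-layered MM summarizing all executed constraint
#   checks: it selects check MMs via the tag filter
#   has_tag('check') and lacks_tag('per_*') and reports, per variable, the
#   unweighted mean of that variable's check-MM pass fractions. Because
#   the filter only speaks about tags, the same TDConstraints MM applies
#   unchanged to check MMs derived from any constraint schema.

HDQF_MEASURES <- c("RepresentationComplete", "TaskComplete", "TDConstraints")

#' Build RepresentationComplete MMs
#'
#' One MM per variable computing count_present / count_total over the
#' variable's values (one input row per dataset row, so the denominator is
#' the row count).
#'
#' @param variables `data.frame` as returned by [list_variables()].
#' @return List of `dq_mm`.
#' @export
build_representation_complete <- function(variables) {
  lapply(seq_len(nrow(variables)), function(i) {
    path <- variables$path[i]
    measurement_method(
      tags = c("hdqf", "representation_complete", path),
      domain_paths = list(
        domain_path("item0", item_type_for(variables$reference_type[i]),
                    path = path)),
      characterization = characterization(
        expr = "count_present(item0) / count_total(item0)"),
      description = sprintf("Fraction of non-missing entries in %s", path))
  })
}

#' Build TaskComplete MMs
#'
#' One MM per mandatory schema variable counting the rows in which the
#' mandatory value is missing/absent, via a child-node-count cardinality
#' check on the variable's parent container.
#'
#' @param schema A `dq_schema`.
#' @return List of `dq_mm` (empty when no variable is mandatory).
#' @export
build_task_complete <- function(schema) {
  mandatory <- Filter(function(v) v$mandatory, schema$variables)
  lapply(mandatory, function(v) {
    bounds <- cardinality_bounds(v)
    count_path <- paste0(parent_path(v$path), ".countChildnodes(only_child)")
    measurement_method(
      tags = c("hdqf", "task_complete", v$path),
      domain_paths = list(
        domain_path("item0", "numeric", path = count_path)),
      check = sprintf("item0 >= %d", as.integer(bounds[1L])),
      characterization = characterization(
        expr = "count_total(check) - sum(if (check) 1.0 else 0.0)"),
      description = sprintf("Count of missing mandatory values in %s", v$path))
  })
}

#' Build the TDConstraints MM
#'
#' A single multi-layered MM whose inputs are the pass fractions of all
#' ungrouped check MMs (filter `has_tag('check') and lacks_tag('per_*')`),
#' grouped by the contributing MM's variable-path tag and averaged. It
#' assumes nothing about the schema the checks came from.
#'
#' @return A `dq_mm`.
#' @export
build_td_constraints <- function() {
  flt <- "has_tag('check') and lacks_tag('per_*')"
  measurement_method(
    tags = c("hdqf", "td_constraints"),
    domain_paths = list(
      domain_path("item0", "numeric", filter = flt,
                  selector = "resultsValue"),
      domain_path("item1", "text", filter = flt, selector = "tags")),
    grouping = "extract_match(item1, 'dataset-row/[^;]*')",
    characterization = characterization(builtin = "mean"),
    description = paste(
      "Per-variable mean of constraint-check pass fractions over all",
      "ungrouped check MMs"))
}

#' Build all HDQF MMs for a dataset/schema pair
#'
#' @param variables `data.frame` from [list_variables()].
#' @param schema Optional `dq_schema` (enables TaskComplete; TDConstraints
#'   is always included and finds whatever check MMs were executed).
#' @return List of `dq_mm`.
#' @export
build_hdqf_mms <- function(variables, schema = NULL) {
  c(build_representation_complete(variables),
    if (!is.null(schema)) build_task_complete(schema),
    list(build_td_constraints()))
}

single_value <- function(res, label = "ALL") {
  for (g in res$groups) {
    if (identical(g$group_label, label)) return(g$value)
  }
  NA_real_
}

#' Assemble the HDQF heatmap table
#'
#' One row per assessed variable, one column per measure. TaskComplete is
#' reported both as the raw missing count and as a normalized goodness
#' score 1 - count/row_count used for coloring. Variables without
#' contributing results get not-applicable (`NA`) cells, rendered white.
#'
#' @param results Named list of `dq_mm_result` (from [execute_all()]).
#' @param row_count Dataset row count (TaskComplete normalization).
#' @param variable_name_map Optional named character vector mapping domain
#'   paths to short display names.
#' @return A `dq_heatmap`: `data.frame` plus a parallel matrix of colors.
#' @export
build_heatmap <- function(results, row_count, variable_name_map = NULL) {
  rc <- list(); tc <- list(); td <- list()
  for (res in results) {
    if (res$status != "ok" || !"hdqf" %in% res$tags) next
    if ("representation_complete" %in% res$tags) {
      path <- grep("^dataset-row/", res$tags, value = TRUE)[1L]
      rc[[path]] <- single_value(res)
    } else if ("task_complete" %in% res$tags) {
      path <- grep("^dataset-row/", res$tags, value = TRUE)[1L]
      tc[[path]] <- single_value(res)
    } else if ("td_constraints" %in% res$tags) {
      for (g in res$groups) {
        if (startsWith(g$group_label, "dataset-row/")) {
          td[[g$group_label]] <- g$value
        }
      }
    }
  }
  paths <- sort(unique(c(names(rc), names(tc), names(td))), method = "radix")
  get_or_na <- function(lst, p) {
    v <- lst[[p]]
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }
  tab <- data.frame(
    path = paths,
    variable = vapply(paths, function(p) {
      unname(variable_name_map[p] %||% NA_character_) %||% p
    }, character(1L)),
    RepresentationComplete = vapply(paths, get_or_na, numeric(1L),
                                    lst = rc),
    TaskComplete_count = vapply(paths, get_or_na, numeric(1L), lst = tc),
    TDConstraints = vapply(paths, get_or_na, numeric(1L), lst = td),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$variable <- ifelse(is.na(tab$variable), shorten_path(tab$path),
                         tab$variable)
  tab$TaskComplete_score <- 1 - tab$TaskComplete_count / row_count
  score_cols <- c("RepresentationComplete", "TaskComplete_score",
                  "TDConstraints")
  colors <- vapply(score_cols, function(cn) {
    vapply(tab[[cn]], heatmap_color, character(1L))
  }, character(nrow(tab)))
  colors <- matrix(colors, nrow = nrow(tab),
                   dimnames = list(tab$variable, score_cols))
  structure(list(table = tab, colors = colors, row_count = row_count),
            class = "dq_heatmap")
}

shorten_path <- function(path) {
  vapply(strsplit(sub("\\.[A-Za-z_]+$", "", path), "/"), function(segs) {
    segs <- sub("\\[.*\\]$", "", segs)
    # generic leaf names (value/name) are uninformative; use the container
    informative <- setdiff(segs, c("dataset-row", "composition", "value"))
    if (length(informative) == 0L) return(segs[length(segs)])
    last <- informative[length(informative)]
    if (last == "name" && length(informative) > 1L) {
      last <- informative[length(informative) - 1L]
    }
    last
  }, character(1L))
}

#' Heatmap color scale
#'
#' Continuous green (1.0) through yellow (0.8) to red (0.0);
#' not-applicable values are white.
#'
#' @param value Goodness score in \[0, 1\] or `NA`.
#' @return Hex color string.
#' @export
heatmap_color <- function(value) {
  if (is.na(value)) return("#FFFFFF")
  value <- min(max(value, 0), 1)
  if (value >= 0.8) {
    f <- (value - 0.8) / 0.2
    ramp <- grDevices::colorRamp(c("#FFFF00", "#00A000"))(f)
  } else {
    f <- value / 0.8
    ramp <- grDevices::colorRamp(c("#D00000", "#FFFF00"))(f)
  }
  grDevices::rgb(ramp[1L], ramp[2L], ramp[3L], maxColorValue = 255)
}

#' @export
print.dq_heatmap <- function(x, ...) {
  cat(sprintf("<dq_heatmap> %d variables x %d measures\n",
              nrow(x$table), length(HDQF_MEASURES)))
  print(x$table[, c("variable", "RepresentationComplete",
                    "TaskComplete_count", "TDConstraints")], ...)
  invisible(x)
}

#' Export a heatmap table
#'
#' Writes the heatmap as a delimited table (values plus hex colors) and
#' optionally renders a raster image.
#'
#' @param heatmap A `dq_heatmap`.
#' @param path Output CSV path.
#' @param image Optional PNG path for a rendered heatmap.
#' @export
export_heatmap <- function(heatmap, path, image = NULL) {
  tab <- heatmap$table
  out <- cbind(tab,
               stats::setNames(as.data.frame(heatmap$colors,
                                             stringsAsFactors = FALSE),
                               paste0("color_", colnames(heatmap$colors))))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(image)) render_heatmap(heatmap, image)
  invisible(path)
}

#' Render a heatmap image
#'
#' @param heatmap A `dq_heatmap`.
#' @param file PNG output path.
#' @export
render_heatmap <- function(heatmap, file) {
  tab <- heatmap$table
  nr <- nrow(tab)
  if (nr == 0L) return(invisible(NULL))
  grDevices::png(file, width = 900, height = 120 + 40 * nr)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 16, 6, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NULL, xlim = c(0, 3), ylim = c(0, nr), axes = FALSE,
                 xlab = "", ylab = "")
  vals <- cbind(tab$RepresentationComplete, tab$TaskComplete_score,
                tab$TDConstraints)
  raw <- cbind(tab$RepresentationComplete, tab$TaskComplete_count,
               tab$TDConstraints)
  for (i in seq_len(nr)) {
    for (j in 1:3) {
      graphics::rect(j - 1, nr - i, j, nr - i + 1,
                     col = heatmap$colors[i, j], border = "grey40")
      if (!is.na(raw[i, j])) {
        graphics::text(j - 0.5, nr - i + 0.5,
                       format(round(raw[i, j], 3)), cex = 0.9)
      }
    }
  }
  graphics::axis(2, at = seq_len(nr) - 0.5, labels = rev(tab$variable),
                 las = 2, tick = FALSE, cex.axis = 0.9)
  graphics::axis(3, at = (1:3) - 0.5,
                 labels = c("RepresentationComplete", "TaskComplete",
                            "TDConstraints"),
                 tick = FALSE, cex.axis = 0.9)
  invisible(file)
}
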