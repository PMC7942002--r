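# Automatic MM derivation.
#
# Two generation sources mirror how DQ knowledge arrives in practice:
# (1) the variables present in a dataset and their reference model types
#     yield profiling MMs (distribution measures for numerics, frequencies
#     for categorical data, simple visualizations);
# (2) a constraint schema — the information content of a clinical
#     information model: types, ranges, value sets, cardinalities,
#     patterns — yields one check MM per constraint, each reporting the
#     fraction of rows passing the check.

#' Construct a constraint schema
#'
#' A purpose-built document emulating the constraint content of clinical
#' information models. Each variable entry may declare: `mandatory`,
#' occurrence bounds `min_occurs`/`max_occurs`, a numeric `range`
#' `c(lo, hi)`, per-unit ranges `unit_ranges` (named list unit -> c(lo, hi),
#' requires `unit_path`), a `value_set`, and a regular-expression `pattern`.
#'
#' @param schema_id Identifier.
#' @param variables List of variable entries; each needs at least `path`
#'   and `reference_type`.
#' @return A `dq_schema`.
#' @export
constraint_schema <- function(schema_id, variables) {
  paths <- vapply(variables, `[[`, character(1L), "path")
  dq_assert(!anyDuplicated(paths), "SCHEMA", "variable paths must be unique")
  variables <- lapply(variables, function(v) {
    parse_path(v$path)  # validate
    dq_assert(v$reference_type %in% c("NUMERIC", "TEXT", "CODED_TEXT",
                                      "DATE_TIME", "BOOLEAN", "COUNT"),
              "SCHEMA", sprintf("unknown reference type for '%s'", v$path))
    v$mandatory <- isTRUE(v$mandatory)
    if (!is.null(v$range)) {
      dq_assert(length(v$range) == 2L && v$range[1L] <= v$range[2L],
                "SCHEMA", sprintf("range lo > hi for '%s'", v$path))
    }
    if (!is.null(v$unit_ranges)) {
      dq_assert(!is.null(v$unit_path), "SCHEMA",
                sprintf("per-unit ranges for '%s' require unit_path", v$path))
      for (r in v$unit_ranges) {
        dq_assert(length(r) == 2L && r[1L] <= r[2L], "SCHEMA",
                  sprintf("unit range lo > hi for '%s'", v$path))
      }
    }
    v
  })
  structure(list(schema_id = schema_id, variables = variables),
            class = "dq_schema")
}

#' Read / write constraint schemas
#'
#' Schemas are stored as YAML documents with keys `schema_id` and
#' `variables`.
#'
#' @param path File path.
#' @return [read_schema()] returns a `dq_schema`.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  dq_assert(!is.null(doc$schema_id) && !is.null(doc$variables), "SCHEMA",
            sprintf("'%s' is not a schema document", path))
  vars <- lapply(doc$variables, function(v) {
    if (!is.null(v$range)) v$range <- as.numeric(unlist(v$range))
    if (!is.null(v$unit_ranges)) {
      v$unit_ranges <- lapply(v$unit_ranges, function(r) as.numeric(unlist(r)))
    }
    if (!is.null(v$value_set)) v$value_set <- as.character(unlist(v$value_set))
    v
  })
  constraint_schema(doc$schema_id, vars)
}

#' @rdname read_schema
#' @param schema A `dq_schema`.
#' @export
write_schema <- function(schema, path) {
  doc <- list(
    schema_id = schema$schema_id,
    variables = lapply(schema$variables, function(v) {
      out <- list(path = v$path, reference_type = v$reference_type,
                  mandatory = v$mandatory)
      for (k in c("min_occurs", "max_occurs", "unit_path", "pattern",
                  "role")) {
        if (!is.null(v[[k]])) out[[k]] <- v[[k]]
      }
      if (!is.null(v$range)) out$range <- as.list(v$range)
      if (!is.null(v$unit_ranges)) {
        out$unit_ranges <- lapply(v$unit_ranges, as.list)
      }
      if (!is.null(v$value_set)) out$value_set <- as.list(v$value_set)
      out
    }))
  writeLines(enc2utf8(yaml::as.yaml(doc)), path, useBytes = TRUE)
  invisible(path)
}

#' Default type-to-characterization generation matrix
#'
#' Maps each reference model type to the profiling builtins generated for
#' variables of that type. The mapping is pinned for reproducibility and
#' can be overridden by passing a modified copy to [generate_type_mms()].
#'
#' @return Named list reference_type -> character vector of builtins.
#' @export
default_generation_matrix <- function() {
  numeric_set <- c("count_present", "min", "max", "mean", "median", "sd",
                   "histogram")
  categorical_set <- c("count_present", "frequency_table",
                       "relative_frequency_table", "barplot")
  list(
    NUMERIC = numeric_set,
    COUNT = numeric_set,
    TEXT = categorical_set,
    CODED_TEXT = categorical_set,
    BOOLEAN = c("count_present", "frequency_table",
                "relative_frequency_table"),
    DATE_TIME = c("count_present", "min", "max")
  )
}

item_type_for <- function(reference_type) {
  switch(reference_type,
    NUMERIC = "numeric", COUNT = "numeric",
    BOOLEAN = "boolean", DATE_TIME = "datetime",
    "text")
}

#' Generate profiling MMs from variable reference types
#'
#' One MM per (variable, builtin) pair of the generation matrix, tagged
#' with the builtin name, the variable path, `"generated"` and
#' `"type_based"`. Output order is deterministic: variables in input
#' order, builtins in matrix order; ids are content hashes.
#'
#' @param variables `data.frame` as returned by [list_variables()].
#' @param matrix Generation matrix (default [default_generation_matrix()]).
#' @return List of `dq_mm`.
#' @export
generate_type_mms <- function(variables, matrix = default_generation_matrix()) {
  for (entry in matrix) {
    dq_assert(all(entry %in% CHARACTERIZATION_BUILTINS), "REGISTRY",
              "generation matrix names an unknown builtin")
  }
  out <- list()
  for (i in seq_len(nrow(variables))) {
    path <- variables$path[i]
    rtype <- variables$reference_type[i]
    builtins <- matrix[[rtype]] %||% character(0)
    for (b in builtins) {
      out[[length(out) + 1L]] <- measurement_method(
        tags = c(b, path, "generated", "type_based"),
        domain_paths = list(
          domain_path("item0", item_type_for(rtype), path = path)),
        characterization = characterization(builtin = b),
        description = sprintf("%s of values in %s", b, path))
    }
  }
  out
}

range_check_expr <- function(lo, hi) {
  sprintf("item0 >= %s and item0 <= %s", format(lo, digits = 15),
          format(hi, digits = 15))
}

quote_expr_str <- function(x) sprintf("'%s'", gsub("'", "\\\\'", x))

unit_range_check_expr <- function(unit_ranges) {
  clauses <- character(0)
  for (unit in names(unit_ranges)) {
    r <- unit_ranges[[unit]]
    clauses <- c(clauses, sprintf("if (item1 == %s) %s",
                                  quote_expr_str(unit),
                                  range_check_expr(r[1L], r[2L])))
  }
  paste(clauses, collapse = " else ")
}

value_set_check_expr <- function(value_set) {
  sprintf("in_list(item0, [%s])",
          paste(vapply(value_set, quote_expr_str, character(1L)),
                collapse = ", "))
}

cardinality_bounds <- function(v) {
  lo <- v$min_occurs %||% (if (v$mandatory) 1L else 0L)
  hi <- v$max_occurs %||% 1L
  c(lo, hi)
}

check_mm <- function(kind, path, domain_paths, check, description) {
  measurement_method(
    tags = c("check", kind, path, "generated", "cim_based"),
    domain_paths = domain_paths,
    check = check,
    characterization = characterization(builtin = "mean"),
    description = description)
}

#' Generate constraint-check MMs from a schema
#'
#' One check MM per declared constraint, each with characterization
#' `mean` over the Boolean check vector (the pass fraction), ungrouped,
#' tagged `"check"`, the constraint kind, the variable path, `"generated"`
#' and `"cim_based"`.
#'
#' Cardinality checks count the child nodes of the variable's parent
#' container via `.countChildnodes(only_child)` and test the occurrence
#' bounds; the fixture convention is one dedicated container per variable.
#'
#' @param schema A `dq_schema`.
#' @return List of `dq_mm`.
#' @export
generate_constraint_mms <- function(schema) {
  out <- list()
  add <- function(mm) out[[length(out) + 1L]] <<- mm
  for (v in schema$variables) {
    item_type <- item_type_for(v$reference_type)
    if (v$mandatory || !is.null(v$min_occurs) || !is.null(v$max_occurs)) {
      bounds <- cardinality_bounds(v)
      count_path <- paste0(parent_path(v$path), ".countChildnodes(only_child)")
      check <- if (is.finite(bounds[2L])) {
        sprintf("item0 >= %d and item0 <= %d",
                as.integer(bounds[1L]), as.integer(bounds[2L]))
      } else {
        sprintf("item0 >= %d", as.integer(bounds[1L]))
      }
      add(check_mm("cardinality", v$path,
        list(domain_path("item0", "numeric", path = count_path)),
        check,
        sprintf("Cardinality check (%s..%s occurrences) for %s",
                bounds[1L], bounds[2L], v$path)))
    }
    if (!is.null(v$unit_ranges)) {
      add(check_mm("unit_range", v$path,
        list(domain_path("item0", "numeric", path = v$path),
             domain_path("item1", "text", path = v$unit_path)),
        unit_range_check_expr(v$unit_ranges),
        sprintf("Unit-conditional range check for %s", v$path)))
    } else if (!is.null(v$range)) {
      add(check_mm("range", v$path,
        list(domain_path("item0", "numeric", path = v$path)),
        range_check_expr(v$range[1L], v$range[2L]),
        sprintf("Range check [%s, %s] for %s",
                v$range[1L], v$range[2L], v$path)))
    }
    if (!is.null(v$value_set)) {
      add(check_mm("value_set", v$path,
        list(domain_path("item0", "text", path = v$path)),
        value_set_check_expr(v$value_set),
        sprintf("Value-set check for %s", v$path)))
    }
    if (!is.null(v$pattern)) {
      add(check_mm("pattern", v$path,
        list(domain_path("item0", "text", path = v$path)),
        sprintf("matches(item0, %s)", quote_expr_str(v$pattern)),
        sprintf("Pattern check for %s", v$path)))
    }
  }
  out
}

#' Define a grouping dimension
#'
#' @param name Dimension name (becomes the `per_<name>` tag).
#' @param path Dataset path of the grouping variable.
#' @param derive Optional date derivation applied to the variable:
#'   `"year"`, `"month"`, `"quarter"`, `"day"` or `"weekday"`.
#' @export
dimension <- function(name, path, derive = NULL) {
  if (!is.null(derive)) {
    dq_assert(derive %in% c("year", "month", "quarter", "day", "weekday"),
              "SPEC", sprintf("unknown derivation '%s'", derive))
  }
  parse_path(path)
  list(name = name, path = path, derive = derive)
}

#' Create grouped (dimension) variants of MMs
#'
#' For each MM with dataset bindings and each dimension, emits a copy with
#' an appended grouping item, the grouping expression set, and an added
#' `per_<dimension>` tag. Originals are returned unchanged ahead of the
#' variants. Dimensions whose path is absent from the dataset's variables
#' are skipped with a warning.
#'
#' @param mms List of `dq_mm`.
#' @param dimensions List of [dimension()] specs.
#' @param dataset Optional `dq_dataset` used to verify dimension paths.
#' @return List of `dq_mm`: originals followed by variants.
#' @export
generate_dimension_variants <- function(mms, dimensions, dataset = NULL) {
  variants <- list()
  for (dim in dimensions) {
    if (!is.null(dataset) && !dim$path %in% dataset$variables$path) {
      warning(sprintf("dimension '%s': path %s absent from dataset; skipped",
                      dim$name, dim$path))
      next
    }
    for (mm in mms) {
      if (mm_binding_kind(mm) != "dataset") next
      item <- paste0("item", length(mm$domain_paths))
      dim_type <- if (is.null(dim$derive)) "text" else "datetime"
      grouping <- if (is.null(dim$derive)) item else
        sprintf("%s(%s)", dim$derive, item)
      variants[[length(variants) + 1L]] <- measurement_method(
        tags = c(mm$tags, paste0("per_", dim$name)),
        domain_paths = c(mm$domain_paths,
                         list(domain_path(item, dim_type, path = dim$path))),
        characterization = mm$characterization,
        check = mm$check,
        grouping = grouping,
        description = paste0(mm$description %||% "", " per ", dim$name))
    }
  }
  c(mms, variants)
}

#' Filter MMs by a tag predicate
#'
#' @param mms List of `dq_mm`.
#' @param predicate Filter text or `dq_filter`.
#' @return The MMs whose tags satisfy the predicate, order preserved.
#' @export
filter_mms <- function(mms, predicate) {
  f <- if (inherits(predicate, "dq_filter")) predicate else
    parse_filter_expression(predicate)
  Filter(function(mm) eval_filter(f, mm$tags), mms)
}
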