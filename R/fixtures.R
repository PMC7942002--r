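# Synthetic fixtures with known ground truth.
#
# The study data this package's methods were designed around (a multi-site
# kidney-transplant study) is restricted, so testing relies on synthetic
# datasets whose data-quality defects are injected by construction: clean
# values are drawn inside the schema's constraints, then cells are
# independently flipped to missing (with a configurable mix of null-flavor
# tokens for text encodings) or to constraint-violating values. A cell is
# never both missing and violated — missing wins — which keeps
# completeness and correctness measures separable in the ground truth.
#
# Cardinality violations (and missing values) manifest as an absent
# subtree: the variable's container node is simply not emitted for that
# row, which is exactly what child-node-count checks detect.

#' Specify a synthetic fixture
#'
#' @param schema A `dq_schema`; fixture variables may carry an extra
#'   `role` field (`"site"` or `"patient"`) marking the site and patient
#'   identifier variables.
#' @param n_rows Number of dataset rows.
#' @param n_sites Number of clinical sites.
#' @param n_patients Number of distinct patients.
#' @param missing_rate Scalar or named (by path) per-variable missing
#'   probability in \[0, 1\].
#' @param violation_rate Scalar or named per-constraint violation
#'   probability in \[0, 1\].
#' @param null_flavors Named numeric vector of null-flavor tokens and
#'   mixture weights used for missing cells in flat-table encodings.
#' @param seed Integer seed; fully determines the output.
#' @return A `dq_fixture_spec`.
#' @export
fixture_spec <- function(schema, n_rows, n_sites = 2L,
                         n_patients = max(1L, n_rows %/% 2L),
                         missing_rate = 0, violation_rate = 0,
                         null_flavors = stats::setNames(
                           c(0.5, 0.3, 0.2), c("NA", "ND", "")),
                         seed = 1L) {
  check_rate <- function(r, what) {
    vals <- unlist(r)
    dq_assert(all(vals >= 0 & vals <= 1), "SPEC",
              sprintf("%s must lie in [0, 1]", what))
  }
  check_rate(missing_rate, "missing_rate")
  check_rate(violation_rate, "violation_rate")
  dq_assert(n_rows >= 0 && n_sites >= 1 && n_patients >= 1, "SPEC",
            "n_rows/n_sites/n_patients out of range")
  structure(
    list(schema = schema, n_rows = as.integer(n_rows),
         n_sites = as.integer(n_sites), n_patients = as.integer(n_patients),
         missing_rate = missing_rate, violation_rate = violation_rate,
         null_flavors = null_flavors, seed = as.integer(seed)),
    class = "dq_fixture_spec")
}

rate_for <- function(rates, path) {
  v <- unlist(rates)
  if (is.null(names(v))) return(as.numeric(v)[1L])
  if (path %in% names(v)) as.numeric(v[[path]]) else 0
}

# Constraints declared for a variable, in injection precedence order.
variable_constraints <- function(v) {
  kinds <- character(0)
  if (v$mandatory || !is.null(v$min_occurs) || !is.null(v$max_occurs)) {
    kinds <- c(kinds, "cardinality")
  }
  if (!is.null(v$unit_ranges)) kinds <- c(kinds, "unit_range")
  else if (!is.null(v$range)) kinds <- c(kinds, "range")
  if (!is.null(v$value_set)) kinds <- c(kinds, "value_set")
  if (!is.null(v$pattern)) kinds <- c(kinds, "pattern")
  kinds
}

DATE_WINDOW <- c("2020-01-01", "2022-12-31")

random_date <- function() {
  lo <- as.Date(DATE_WINDOW[1L])
  hi <- as.Date(DATE_WINDOW[2L])
  format(lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L, "%Y-%m-%d")
}

clean_value <- function(v, sites, patients) {
  role <- v$role %||% ""
  if (role == "site") return(sample(sites, 1L))
  if (role == "patient") return(sample(patients, 1L))
  switch(v$reference_type,
    NUMERIC = , COUNT = {
      if (!is.null(v$unit_ranges)) {
        unit <- sample(names(v$unit_ranges), 1L)
        r <- v$unit_ranges[[unit]]
        list(value = stats::runif(1L, r[1L], r[2L]), unit = unit)
      } else {
        r <- v$range %||% c(0, 100)
        stats::runif(1L, r[1L], r[2L])
      }
    },
    CODED_TEXT = , TEXT = {
      if (!is.null(v$value_set)) sample(v$value_set, 1L)
      else sprintf("txt_%03d", sample.int(20L, 1L))
    },
    DATE_TIME = random_date(),
    BOOLEAN = sample(c(TRUE, FALSE), 1L))
}

violated_value <- function(v, kind) {
  switch(kind,
    cardinality = NULL,  # absent subtree
    range = {
      r <- v$range
      r[2L] + stats::runif(1L, 1, (r[2L] - r[1L]) + 1)
    },
    unit_range = {
      unit <- sample(names(v$unit_ranges), 1L)
      r <- v$unit_ranges[[unit]]
      list(value = r[2L] + stats::runif(1L, 1, (r[2L] - r[1L]) + 1),
           unit = unit)
    },
    value_set = "INVALID_CODE",
    pattern = "##INVALID##")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws clean values inside the schema's constraints, then independently
#' flips cells to missing or to constraint-violating values at the
#' specified rates (missing wins; see module header). Deterministic given
#' the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `dataset` (a `dq_dataset`) and `ground_truth` (a
#'   `dq_ground_truth`: per-cell injected status plus realized per-variable
#'   missing and per-constraint violation counts).
#' @export
generate_dataset <- function(spec) {
  dq_assert(inherits(spec, "dq_fixture_spec"), "SPEC",
            "spec must be a dq_fixture_spec")
  vars <- spec$schema$variables
  for (v in vars) {
    # a scalar rate silently skips constraint-less variables; an explicit
    # per-path request for one is a contradictory spec
    explicit <- !is.null(names(spec$violation_rate)) &&
      v$path %in% names(spec$violation_rate)
    if (explicit && rate_for(spec$violation_rate, v$path) > 0 &&
        length(variable_constraints(v)) == 0L) {
      dq_error("SPEC", sprintf(
        "violation requested for '%s' but it declares no constraint",
        v$path))
    }
    if (!is.null(v$value_set) && length(v$value_set) == 0L) {
      dq_error("SPEC", sprintf("empty value set for '%s'", v$path))
    }
  }
  with_seed(spec$seed, {
    sites <- paste0("Site", LETTERS[seq_len(spec$n_sites)])
    patients <- sprintf("P%04d", seq_len(spec$n_patients))
    rows <- vector("list", spec$n_rows)
    cells_log <- vector("list", spec$n_rows * max(length(vars), 1L))
    k <- 0L
    for (i in seq_len(spec$n_rows)) {
      cells <- list()
      for (v in vars) {
        status <- "ok"
        kind <- NA_character_
        token <- NA_character_
        value <- clean_value(v, sites, patients)
        if (stats::runif(1L) < rate_for(spec$missing_rate, v$path)) {
          status <- "missing"
          value <- NULL
          token <- sample(names(spec$null_flavors), 1L,
                          prob = spec$null_flavors)
        } else {
          for (ck in variable_constraints(v)) {
            if (stats::runif(1L) < rate_for(spec$violation_rate, v$path)) {
              status <- "violated"
              kind <- ck
              value <- violated_value(v, ck)
              break
            }
          }
        }
        cells[v$path] <- list(value)
        k <- k + 1L
        cells_log[[k]] <- data.frame(
          row_index = i - 1L, path = v$path, status = status,
          kind = kind, token = token, stringsAsFactors = FALSE)
      }
      rows[[i]] <- dq_dataset_row(i - 1L, composition_from_cells(cells))
    }
    cell_df <- if (k > 0L) do.call(rbind, cells_log[seq_len(k)]) else
      data.frame(row_index = integer(0), path = character(0),
                 status = character(0), kind = character(0),
                 token = character(0), stringsAsFactors = FALSE)
    gt <- ground_truth(cell_df)
    dataset <- new_dataset(rows, schema = spec$schema)
    list(dataset = dataset, ground_truth = gt)
  })
}

ground_truth <- function(cells) {
  miss <- table(cells$path[cells$status == "missing"])
  viol <- cells[cells$status == "violated", c("path", "kind")]
  viol_counts <- if (nrow(viol) > 0L) {
    stats::aggregate(list(count = rep(1L, nrow(viol))),
                     by = list(path = viol$path, kind = viol$kind), FUN = sum)
  } else {
    data.frame(path = character(0), kind = character(0), count = integer(0))
  }
  structure(
    list(cells = cells,
         missing_counts = stats::setNames(as.integer(miss), names(miss)),
         violation_counts = viol_counts),
    class = "dq_ground_truth")
}

#' Write a fixture dataset as a flat table with null-flavor tokens
#'
#' Missing cells are written with the null-flavor token sampled for them at
#' generation time (e.g. "ND"), emulating source systems with non-standard
#' missing encodings.
#'
#' @param dataset A `dq_dataset` from [generate_dataset()].
#' @param ground_truth The matching `dq_ground_truth`.
#' @param path Output CSV path.
#' @export
write_fixture_flat_table <- function(dataset, ground_truth, path) {
  vars <- dataset$variables$path
  cells <- ground_truth$cells
  cols <- lapply(vars, function(p) {
    parsed <- parse_path(p)
    vapply(dataset$rows, function(row) {
      rv <- resolve_path(row, parsed)
      if (length(rv) > 0L && !is.na(rv[[1L]])) {
        return(as.character(rv[[1L]]))
      }
      tok <- cells$token[cells$row_index == row$row_index & cells$path == p]
      tok <- tok[!is.na(tok)]
      if (length(tok) > 0L) tok[[1L]] else "NA"
    }, character(1L))
  })
  df <- as.data.frame(stats::setNames(cols, vars), check.names = FALSE,
                      stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

STUDY_PREFIX <- "dataset-row/composition"

study_path <- function(...) paste(STUDY_PREFIX, ..., sep = "/")

#' The study constraint schema
#'
#' A compact schema emulating a two-template multi-site transplant study:
#' a mandatory healthcare facility, patient identifier, gender with a
#' three-code value set, recipient and donor ages with plausibility
#' ranges, a weight with unit-conditional ranges (kg/g), transplant and
#' biopsy dates, and months since transplantation.
#'
#' @return A `dq_schema`.
#' @export
study_schema <- function() {
  constraint_schema("transplant_study", list(
    list(path = study_path("context", "health_care_facility", "name"),
         reference_type = "TEXT", mandatory = TRUE, role = "site"),
    list(path = study_path("context", "patient_id", "value"),
         reference_type = "TEXT", role = "patient"),
    list(path = study_path("content", "demographics", "gender", "value"),
         reference_type = "CODED_TEXT",
         value_set = c("Weiblich", "Männlich", "Divers")),
    list(path = study_path("content", "demographics", "recipient_age",
                           "value"),
         reference_type = "NUMERIC", range = c(0, 120)),
    list(path = study_path("content", "donor", "donor_age", "value"),
         reference_type = "NUMERIC", range = c(0, 120)),
    list(path = study_path("content", "anthropometry", "weight", "value"),
         reference_type = "NUMERIC",
         unit_ranges = list(kg = c(0, 1000), g = c(0, 1000000)),
         unit_path = paste0(
           study_path("content", "anthropometry", "weight", "value"),
           ".unit")),
    list(path = study_path("content", "transplantation", "transplant_date",
                           "value"),
         reference_type = "DATE_TIME"),
    list(path = study_path("content", "biopsy", "biopsy_date", "value"),
         reference_type = "DATE_TIME"),
    list(path = study_path("content", "follow_up",
                           "months_since_transplant", "value"),
         reference_type = "NUMERIC", range = c(0, 360))
  ))
}

#' Generate the study fixture
#'
#' A small two-site dataset (200 rows by default) shaped like the
#' transplant study the method was applied to, together with the matching
#' constraint schema. Clean by default; missingness and violations can be
#' injected at chosen rates.
#'
#' @param seed Integer seed.
#' @param n_rows Number of rows.
#' @param missing_rate,violation_rate Passed to [fixture_spec()].
#' @return List with `dataset`, `schema` and `ground_truth`.
#' @export
make_study_fixture <- function(seed = 1L, n_rows = 200L,
                               missing_rate = 0, violation_rate = 0) {
  schema <- study_schema()
  spec <- fixture_spec(schema, n_rows = n_rows, n_sites = 2L,
                       n_patients = max(1L, n_rows %/% 2L),
                       missing_rate = missing_rate,
                       violation_rate = violation_rate,
                       seed = seed)
  gen <- generate_dataset(spec)
  list(dataset = gen$dataset, schema = schema,
       ground_truth = gen$ground_truth)
}
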