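test_that("dataset bindings align one input row per dataset row", {
  ds <- tiny_dataset(list(1, 2, 3, 4, 5))
  mm <- measurement_method(
    tags = "t",
    domain_paths = list(
      domain_path("item0", "numeric", path = "dataset-row/composition/x"),
      domain_path("item1", "numeric", path = "dataset-row/composition/x")),
    characterization = "count_total")
  input <- assemble_input(mm, ds)
  expect_equal(length(input$items), 2L)
  expect_equal(lengths(input$items), c(item0 = 5L, item1 = 5L))
  expect_equal(input$provenance$row_index, 0:4)
})

test_that("multi-match paths flatten to one input row per matched node with
           provenance", {
  rows <- list(dq_dataset_row(0L, dq_composition(
    branch("composition",
      branch("panel", leaf("v", 1)),
      branch("panel", leaf("v", 2))))),
    dq_dataset_row(1L, dq_composition(
      branch("composition", branch("panel", leaf("v", 7))))))
  ds <- dqmm:::new_dataset(rows)
  mm <- measurement_method(
    tags = "t",
    domain_paths = list(domain_path("item0", "numeric",
                                    path = "dataset-row/composition/panel/v")),
    characterization = "count_present")
  input <- assemble_input(mm, ds)
  expect_equal(input$items$item0, c(1, 2, 7))
  expect_equal(input$provenance$row_index, c(0L, 0L, 1L))
})

test_that("filter bindings yield one row per (matched MM, group) pair and
           empty filters error", {
  prior <- list(
    a = structure(list(mm_id = "a", tags = c("check", "p1"),
      groups = list(list(group_label = "ALL", value = 0.9)),
      status = "ok"), class = "dq_mm_result"),
    b = structure(list(mm_id = "b", tags = c("check", "p2"),
      groups = list(list(group_label = "SiteA", value = 1.0),
                    list(group_label = "SiteB", value = 0.5)),
      status = "ok"), class = "dq_mm_result"),
    c = structure(list(mm_id = "c", tags = c("check", "per_site"),
      groups = list(list(group_label = "ALL", value = 0.1)),
      status = "ok"), class = "dq_mm_result"))
  mm <- measurement_method(
    tags = "agg",
    domain_paths = list(
      domain_path("item0", "numeric",
                  filter = "has_tag('check') and lacks_tag('per_*')",
                  selector = "resultsValue")),
    characterization = "mean")
  input <- assemble_input(mm, prior = prior)
  # 2 matching MMs, one with two groups -> 3 rows (c excluded by per_*)
  expect_equal(input$items$item0, c(0.9, 1.0, 0.5))
  expect_equal(input$provenance$source_mm, c("a", "b", "b"))

  mm_none <- measurement_method(
    tags = "agg",
    domain_paths = list(
      domain_path("item0", "numeric", filter = "has_tag('nothing')")),
    characterization = "mean")
  expect_error(assemble_input(mm_none, prior = prior),
               class = "dq_empty_filter_error")
})

test_that("mixing dataset and filter bindings is rejected", {
  mm <- measurement_method(
    tags = "bad",
    domain_paths = list(
      domain_path("item0", "numeric", path = "dataset-row/composition/x"),
      domain_path("item1", "numeric", filter = "has_tag('check')")),
    characterization = "mean")
  expect_error(assemble_input(mm, tiny_dataset(list(1))),
               class = "dq_unsupported_combination_error")
})

test_that("checks, groupings and their degenerate forms behave as specified", {
  ds <- tiny_dataset(list(1, 2, 3))
  mm <- measurement_method(
    tags = "t",
    domain_paths = list(domain_path("item0", "numeric",
                                    path = "dataset-row/composition/x")),
    check = "item0 >= 2",
    characterization = "mean")
  input <- assemble_input(mm, ds)
  expect_equal(apply_check(mm, input), c(FALSE, TRUE, TRUE))
  expect_equal(apply_grouping(mm, input), rep("ALL", 3))

  # grouping by a second item; missing keys pool under MISSING
  rows <- lapply(list(c("A", "1"), c("B", "2"), c("A", "3"),
                      c(NA, "4")), function(vv) {
    dq_dataset_row(0L, dq_composition(branch("composition",
      if (is.na(vv[1])) dq_node("pad", value = 0) else leaf("site", vv[1]),
      leaf("x", as.numeric(vv[2])))))
  })
  for (i in seq_along(rows)) rows[[i]]$row_index <- i - 1L
  ds2 <- dqmm:::new_dataset(rows)
  mm2 <- measurement_method(
    tags = "t",
    domain_paths = list(
      domain_path("item0", "numeric", path = "dataset-row/composition/x"),
      domain_path("item1", "text", path = "dataset-row/composition/site")),
    grouping = "item1",
    characterization = "count_present")
  input2 <- assemble_input(mm2, ds2)
  expect_equal(apply_grouping(mm2, input2), c("A", "B", "A", "MISSING"))

  res <- execute_mm(mm2, ds2)
  expect_equal(vapply(res$groups, `[[`, character(1), "group_label"),
               c("A", "B", "MISSING"))  # lexicographic
  expect_equal(vapply(res$groups, `[[`, numeric(1), "value"), c(2, 1, 1))
})

test_that("combined grouping keys concatenate like the species_antibiotic
           idiom", {
  labels <- evaluate_expression("format('%s_%s', item1, item2)",
                                list(item1 = c("E. coli", "S. aureus"),
                                     item2 = c("ampicillin", "oxacillin")))
  expect_equal(labels, c("E. coli_ampicillin", "S. aureus_oxacillin"))
})

test_that("characterization builtins match naive reference implementations", {
  set.seed(13)
  for (k in 1:25) {
    v <- round(runif(40, -50, 50), 3)
    v[sample(40, 5)] <- NA
    ref <- naive_stats(v)
    for (b in c("min", "max", "mean", "median", "sd")) {
      expect_equal(dqmm:::apply_builtin(b, v), ref[[b]], tolerance = 1e-9,
                   info = b)
    }
    codes <- sample(letters[1:5], 30, replace = TRUE)
    codes[sample(30, 4)] <- NA
    expect_equal(dqmm:::apply_builtin("frequency_table", codes),
                 naive_freq(codes))
    rel <- dqmm:::apply_builtin("relative_frequency_table", codes)
    expect_equal(sum(rel), 1)
    expect_equal(rel, naive_freq(codes) / sum(naive_freq(codes)))
  }
  expect_equal(dqmm:::apply_builtin("count_present", c(1, NA, 3)), 2)
  expect_equal(dqmm:::apply_builtin("count_missing", c(1, NA, 3)), 1)
  expect_equal(dqmm:::apply_builtin("mean_density", c(1, 3, 6)), 2.5)
  h <- dqmm:::apply_builtin("histogram", c(1, 2, 2, 9))
  expect_s3_class(h, "dq_plot_data")
  expect_equal(sum(h$counts), 4)
  bp <- dqmm:::apply_builtin("barplot", c("a", "a", "b"))
  expect_equal(bp$labels, c("a", "b"))
  expect_equal(bp$counts, c(2, 1))
})

test_that("check means are bounded and equal 1 minus the brute-force
           violation fraction", {
  set.seed(5)
  vals <- as.list(round(runif(60, -20, 120), 1))
  ds <- tiny_dataset(vals)
  mm <- range_check_mm_for_test(0, 100, "dataset-row/composition/x")
  res <- execute_mm(mm, ds)
  m <- res$groups[[1]]$value
  expect_true(m >= 0 && m <= 1)
  brute <- mean(vapply(vals, function(v) v >= 0 && v <= 100, TRUE))
  expect_equal(m, brute)
})

test_that("execution order places dependencies first, is stable, and any
           topological order gives identical results", {
  ds <- tiny_dataset(list(1, 2, 3, 11))
  checks <- list(
    range_check_mm_for_test(0, 10, "pA"),
    range_check_mm_for_test(0, 100, "pB"),
    range_check_mm_for_test(2, 20, "pC"))
  td <- build_td_constraints()
  mms <- c(list(td), checks)
  ordered <- resolve_execution_order(mms)
  ids <- vapply(ordered, `[[`, character(1), "id")
  expect_equal(ids[4], td$id)  # checks first, aggregate last
  # independent MMs keep input order
  expect_equal(ids[1:3], vapply(checks, `[[`, character(1), "id"))

  r1 <- execute_all(mms, ds)
  r2 <- execute_all(rev(mms), ds)
  expect_identical(r1[sort(names(r1))], r2[sort(names(r2))])

  # no filters anywhere -> input order preserved
  plain <- resolve_execution_order(checks)
  expect_identical(vapply(plain, `[[`, character(1), "id"),
                   vapply(checks, `[[`, character(1), "id"))
})

test_that("mutually-matching filters raise a cycle error naming the MMs", {
  mk <- function(tag, other) measurement_method(
    tags = tag,
    domain_paths = list(domain_path("item0", "numeric",
                                    filter = sprintf("has_tag('%s')", other))),
    characterization = "mean")
  expect_error(resolve_execution_order(list(mk("a", "b"), mk("b", "a"))),
               class = "dq_cycle_error")
})

test_that("execution is fail-soft: one failing MM never aborts the batch", {
  ds <- tiny_dataset(list("a", "b"))
  bad <- measurement_method(
    tags = "bad",
    domain_paths = list(domain_path("item0", "text",
                                    path = "dataset-row/composition/x")),
    check = "item0 < 3",  # type mismatch at evaluation
    characterization = "mean")
  good <- measurement_method(
    tags = "good",
    domain_paths = list(domain_path("item0", "text",
                                    path = "dataset-row/composition/x")),
    characterization = "count_present")
  res <- execute_all(list(bad, good), ds)
  expect_equal(res[[bad$id]]$status, "failed")
  expect_match(res[[bad$id]]$error, "type mismatch")
  expect_equal(res[[good$id]]$status, "ok")
  expect_equal(res[[good$id]]$groups[[1]]$value, 2)
  expect_equal(length(execute_all(list(), ds)), 0L)
})

test_that("group decomposition: count characterizations sum over groups to
           the ungrouped total", {
  fx <- make_study_fixture(seed = 21, n_rows = 60, missing_rate = 0.1)
  ds <- fx$dataset
  num_vars <- ds$variables[ds$variables$reference_type == "NUMERIC", ,
                           drop = FALSE]
  base <- generate_type_mms(num_vars,
                            matrix = list(NUMERIC = "count_present"))
  site_dim <- dimension("site",
    "dataset-row/composition/context/health_care_facility/name")
  both <- generate_dimension_variants(base, list(site_dim), dataset = ds)
  res <- execute_all(both, ds)
  n_base <- length(base)
  for (i in seq_len(n_base)) {
    plain <- res[[both[[i]]$id]]$groups[[1]]$value
    variant <- res[[both[[n_base + i]]$id]]
    expect_equal(sum(vapply(variant$groups, `[[`, numeric(1), "value")),
                 plain)
  }
})

test_that("results flatten to a stable table and export both formats", {
  ds <- tiny_dataset(list(1, 2))
  mm <- range_check_mm_for_test(0, 10, "p")
  res <- execute_all(list(mm), ds)
  tab <- results_to_table(res)
  expect_equal(tab$mm_id, mm$id)
  expect_equal(tab$group_label, "ALL")
  expect_equal(as.numeric(tab$value), 1)
  out <- withr::local_tempdir()
  export_results(res, out)
  expect_true(file.exists(file.path(out, "results.json")))
  expect_true(file.exists(file.path(out, "results.csv")))
  doc <- jsonlite::read_json(file.path(out, "results.json"))
  expect_equal(doc[[1]]$groups[[1]]$value, 1)
})
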