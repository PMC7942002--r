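test_that("RepresentationComplete is the fraction of non-missing entries and
           complements the missing fraction exactly", {
  ds <- tiny_dataset(list(1, 2, NULL, 4))  # 3 of 4 present
  mms <- build_representation_complete(ds$variables)
  res <- execute_all(mms, ds)
  expect_equal(res[[1]]$groups[[1]]$value, 0.75)

  # a fully-missing variable (explicit NA payloads) scores 0
  rows <- lapply(0:1, function(i) dq_dataset_row(i, dq_composition(
    branch("composition", dq_node("x", value = NA)))))
  ds2 <- dqmm:::new_dataset(rows)
  res2 <- execute_all(build_representation_complete(ds2$variables), ds2)
  expect_equal(res2[[1]]$groups[[1]]$value, 0)

  fx <- make_study_fixture(seed = 31, n_rows = 50, missing_rate = 0.2)
  res3 <- execute_all(build_representation_complete(fx$dataset$variables),
                      fx$dataset)
  for (r in res3) {
    p <- grep("^dataset-row/", r$tags, value = TRUE)[1]
    missing_frac <- mean(vapply(fx$dataset$rows, function(row) {
      rv <- resolve_path(row, p)
      length(rv) == 0L || all(vapply(rv, is.na, TRUE))
    }, logical(1)))
    expect_equal(r$groups[[1]]$value + missing_frac, 1, info = p)
  }
})

test_that("RepresentationComplete recovers an injected missing rate within
           binomial bounds", {
  n <- 1000L
  rate <- 0.1
  fx <- make_study_fixture(seed = 101, n_rows = n, missing_rate = rate)
  res <- execute_all(build_representation_complete(fx$dataset$variables),
                     fx$dataset)
  p <- "dataset-row/composition/content/demographics/recipient_age/value"
  r <- Filter(function(x) p %in% x$tags, res)[[1]]
  bound <- 3 * sqrt(rate * (1 - rate) / n)
  expect_lt(abs(r$groups[[1]]$value - (1 - rate)), bound)
})

test_that("TaskComplete counts missing mandatory values and is 0 on clean
           data", {
  fx <- make_study_fixture(seed = 8, n_rows = 40)
  tc <- build_task_complete(fx$schema)
  expect_equal(length(tc), 1L)  # one mandatory variable in the study schema
  res <- execute_all(tc, fx$dataset)
  expect_equal(res[[1]]$groups[[1]]$value, 0)

  site_path <- "dataset-row/composition/context/health_care_facility/name"
  fx2 <- make_study_fixture(seed = 8, n_rows = 200,
                            missing_rate = stats::setNames(0.15, site_path))
  res2 <- execute_all(build_task_complete(fx2$schema), fx2$dataset)
  injected <- fx2$ground_truth$missing_counts[[site_path]]
  expect_gt(injected, 0)
  expect_equal(res2[[1]]$groups[[1]]$value, injected)

  no_mandatory <- constraint_schema("nm", list(
    list(path = "dataset-row/composition/x", reference_type = "NUMERIC")))
  expect_equal(length(build_task_complete(no_mandatory)), 0L)
})

test_that("TDConstraints averages per-variable check pass fractions", {
  # two checks on the same variable with pass fractions 1.0 and 0.8
  ds <- tiny_dataset(list(1, 2, 3, 4, 11))
  mm_loose <- range_check_mm_for_test(0, 100, "dataset-row/composition/x")
  mm_tight <- range_check_mm_for_test(0, 10, "dataset-row/composition/x")
  td <- build_td_constraints()
  res <- execute_all(list(mm_loose, mm_tight, td), ds)
  expect_equal(res[[mm_loose$id]]$groups[[1]]$value, 1.0)
  expect_equal(res[[mm_tight$id]]$groups[[1]]$value, 0.8)
  td_res <- res[[td$id]]
  expect_equal(td_res$groups[[1]]$group_label, "dataset-row/composition/x")
  expect_equal(td_res$groups[[1]]$value, 0.9)

  # per_* checks are excluded by the filter
  mm_site <- range_check_mm_for_test(0, 100, "dataset-row/composition/x",
                                     extra_tags = "per_site")
  res2 <- execute_all(list(mm_loose, mm_tight, mm_site, td), ds)
  expect_equal(res2[[td$id]]$groups[[1]]$value, 0.9)

  # zero matching checks -> EMPTY_FILTER recorded as failure (fail-soft)
  res3 <- execute_all(list(td), ds)
  expect_equal(res3[[td$id]]$status, "failed")
  expect_match(res3[[td$id]]$error, "filter")
})

test_that("the same TDConstraints MM applies unchanged to checks from a
           different schema", {
  td <- build_td_constraints()
  other_schema <- constraint_schema("other", list(
    list(path = "dataset-row/composition/x", reference_type = "NUMERIC",
         range = c(0, 3))))
  ds <- tiny_dataset(list(1, 2, 9))
  res <- execute_all(c(generate_constraint_mms(other_schema), list(td)), ds)
  td_res <- res[[td$id]]
  expect_equal(td_res$status, "ok")
  expect_equal(td_res$groups[[1]]$group_label, "dataset-row/composition/x")
  expect_equal(td_res$groups[[1]]$value, 2 / 3)
})

test_that("TDConstraints values stay in [0,1] and match the unweighted mean
           rule on the study fixture", {
  fx <- make_study_fixture(seed = 77, n_rows = 150, missing_rate = 0.05,
                           violation_rate = 0.1)
  checks <- generate_constraint_mms(fx$schema)
  td <- build_td_constraints()
  res <- execute_all(c(checks, list(td)), fx$dataset)
  td_res <- res[[td$id]]
  by_var <- list()
  for (mm in checks) {
    p <- mm$tags[3]
    by_var[[p]] <- c(by_var[[p]], res[[mm$id]]$groups[[1]]$value)
  }
  for (g in td_res$groups) {
    expect_true(g$value >= 0 && g$value <= 1)
    expect_equal(g$value, mean(by_var[[g$group_label]]),
                 info = g$group_label)
  }
})

test_that("heatmap cells are pure functions of results and equal
           independently computed fractions", {
  n <- 120L
  fx <- make_study_fixture(seed = 19, n_rows = n, missing_rate = 0.1,
                           violation_rate = 0.15)
  mms <- c(generate_constraint_mms(fx$schema),
           build_hdqf_mms(fx$dataset$variables, fx$schema))
  res <- execute_all(mms, fx$dataset)
  hm <- build_heatmap(res, row_count = n)
  hm2 <- build_heatmap(res, row_count = n)
  expect_identical(hm$table, hm2$table)

  tab <- hm$table
  for (i in seq_len(nrow(tab))) {
    p <- tab$path[i]
    present <- sum(vapply(fx$dataset$rows, function(row) {
      rv <- resolve_path(row, p)
      length(rv) > 0L && !all(vapply(rv, is.na, TRUE))
    }, logical(1)))
    expect_equal(tab$RepresentationComplete[i], present / n, info = p)
  }
  # variables without constraint checks get not-applicable TDConstraints
  no_check <- "dataset-row/composition/context/patient_id/value"
  expect_true(is.na(tab$TDConstraints[tab$path == no_check]))
  # normalized TaskComplete score complements the raw count
  site <- "dataset-row/composition/context/health_care_facility/name"
  i <- which(tab$path == site)
  expect_equal(tab$TaskComplete_score[i],
               1 - tab$TaskComplete_count[i] / n)
})

test_that("heatmap colors follow the green-yellow-red scale with white for
           not-applicable", {
  expect_equal(heatmap_color(NA), "#FFFFFF")
  expect_equal(heatmap_color(1), "#00A000")
  expect_equal(heatmap_color(0.8), "#FFFF00")
  expect_equal(heatmap_color(0), "#D00000")
  n <- 40L
  fx <- make_study_fixture(seed = 3, n_rows = n)
  res <- execute_all(build_hdqf_mms(fx$dataset$variables, fx$schema),
                     fx$dataset)
  hm <- build_heatmap(res, row_count = n)
  # all-clean fixture: RepresentationComplete cells are all green
  expect_true(all(hm$colors[, "RepresentationComplete"] == "#00A000"))
  f <- withr::local_tempfile(fileext = ".csv")
  export_heatmap(hm, f)
  expect_true(file.exists(f))
})
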