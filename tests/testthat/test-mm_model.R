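test_that("domain-path declarations parse and round-trip", {
  dp <- parse_domain_path(
    "# item1 (string) = dataset-row/composition/context/health_care_facility/name")
  expect_equal(dp$item_name, "item1")
  expect_equal(dp$declared_type, "text")
  expect_equal(dp$kind, "dataset")

  dp2 <- parse_domain_path(paste(
    "# item0 (numeric) = other_data_input:",
    "has_tag('check') and lacks_tag('per_*') .resultsValue"))
  expect_equal(dp2$kind, "filter")
  expect_equal(dp2$selector, "resultsValue")

  dp3 <- parse_domain_path(paste0(
    "# item0 (numeric) = dataset-row/composition/panel",
    ".countChildnodes(only_child)"))
  expect_equal(dp3$parsed$count_mode, "only_child")

  for (d in list(dp, dp2, dp3)) {
    rendered <- dqmm:::render_domain_path(d)
    reparsed <- parse_domain_path(rendered)
    expect_equal(dqmm:::render_domain_path(reparsed), rendered)
  }

  expect_error(parse_domain_path("# item0 = dataset-row/x"),
               class = "dq_parse_error")
  expect_error(parse_domain_path("# item0 (volume) = dataset-row/x"),
               class = "dq_parse_error")
})

test_that("the printed constraint rules evaluate correctly on a boundary battery", {
  # cardinality rule for a mandatory single-occurrence variable
  card <- "item0 >= 1 and item0 <= 1"
  expect_equal(evaluate_expression(card, list(item0 = c(1, 0, 2))),
               c(TRUE, FALSE, FALSE))

  # value-set rule for the three gender codes
  vs <- "in_list(item0, ['Weiblich', 'Männlich', 'Divers'])"
  expect_equal(
    evaluate_expression(vs, list(
      item0 = c("Weiblich", "Männlich", "Divers", "divers", "X",
                NA_character_))),
    c(TRUE, TRUE, TRUE, FALSE, FALSE, NA))

  # unit-conditional range rule: kg in [0, 1000], g in [0, 1000000]
  ur <- paste("if (item1 == 'kg') item0 >= 0.0 and item0 <= 1000.0",
              "else if (item1 == 'g') item0 >= 0.0 and item0 <= 1000000.0")
  eps <- 1e-9
  battery <- list(
    list(u = "kg", x = 0, ok = TRUE),       # lo
    list(u = "kg", x = 1000, ok = TRUE),    # hi
    list(u = "kg", x = -eps, ok = FALSE),   # lo - eps
    list(u = "kg", x = 1000 + eps, ok = FALSE),
    list(u = "kg", x = 1500000, ok = FALSE),
    list(u = "g", x = 0, ok = TRUE),
    list(u = "g", x = 1000000, ok = TRUE),
    list(u = "g", x = -eps, ok = FALSE),
    list(u = "g", x = 1000000 + eps, ok = FALSE),
    list(u = "g", x = 1500000, ok = FALSE))
  for (b in battery) {
    expect_equal(
      evaluate_expression(ur, list(item0 = b$x, item1 = b$u)), b$ok,
      info = sprintf("%s %s", b$x, b$u))
  }
  # unknown unit -> no branch applies -> missing; missing value -> missing
  expect_true(is.na(evaluate_expression(ur, list(item0 = 5, item1 = "lb"))))
  expect_true(is.na(evaluate_expression(ur, list(item0 = NA_real_,
                                                 item1 = "kg"))))
})

test_that("any missing operand makes the result missing", {
  exprs <- c("item0 + 1", "item0 > 3", "item0 == item0",
             "not (item0 > 1)", "item0 > 1 and true",
             "false and item0 > 1",  # full propagation, not 3-valued logic
             "concat('a', item0)")
  for (e in exprs) {
    expect_true(is.na(evaluate_expression(e, list(item0 = NA))), info = e)
  }
})

test_that("evaluation errors identify unbound variables and type mismatches", {
  expect_error(evaluate_expression("item7 > 1", list(item0 = 1)),
               "item7", class = "dq_eval_error")
  expect_error(evaluate_expression("item0 < 3", list(item0 = "a")),
               class = "dq_eval_error")
  expect_error(evaluate_expression("item0 and true", list(item0 = 2)),
               class = "dq_eval_error")
  expect_error(parse_expression("item0 >="), class = "dq_expr_error")
  expect_error(parse_expression(""), class = "dq_expr_error")
})

test_that("dialect builtins: strings, dates, membership", {
  expect_equal(evaluate_expression("concat(item0, '_', item1)",
                                   list(item0 = "E. coli",
                                        item1 = "ampicillin")),
               "E. coli_ampicillin")
  expect_equal(evaluate_expression("format('%s_%s', item0, item1)",
                                   list(item0 = "a", item1 = "b")), "a_b")
  b <- list(item0 = "2021-05-04")
  expect_equal(evaluate_expression("year(item0)", b), 2021)
  expect_equal(evaluate_expression("month(item0)", b), 5)
  expect_equal(evaluate_expression("quarter(item0)", b), 2)
  expect_equal(evaluate_expression("weekday(item0)", b), "Tue")
  expect_true(evaluate_expression("matches(item0, '^P[0-9]+$')",
                                  list(item0 = "P0042")))
  expect_equal(
    evaluate_expression("extract_match(item0, 'at[0-9]+')",
                        list(item0 = "x;at0098;y")), "at0098")
})

test_that("vectorized evaluation agrees with a direct scalar interpreter on
           random expressions", {
  set.seed(41)
  n_cases <- 60L
  for (k in seq_len(n_cases)) {
    tree <- gen_expr(3L)
    text <- render_expr(tree)
    bindings <- list(a = round(runif(8, -5, 5), 2),
                     b = round(runif(8, -5, 5), 2),
                     c = round(runif(8, -5, 5), 2))
    # inject some missings
    bindings$a[sample(8, 2)] <- NA
    got <- rep(as.numeric(evaluate_expression(text, bindings)),
               length.out = 8)  # constant expressions stay scalar
    expected <- vapply(seq_len(8), function(i) {
      as.numeric(ref_eval(tree, list(a = bindings$a[i], b = bindings$b[i],
                                     c = bindings$c[i])))
    }, numeric(1))
    expect_equal(as.numeric(got), expected, tolerance = 1e-12, info = text)
  }
})

test_that("filter atoms match tag lists exactly, with * as prefix match", {
  set.seed(7)
  pool <- c("check", "per_site", "per_patient", "mean", "generated", "hdqf")
  f <- parse_filter_expression("has_tag('check') and lacks_tag('per_*')")
  for (k in 1:50) {
    tags <- sample(pool, sample(1:5, 1))
    expected <- ("check" %in% tags) && !any(startsWith(tags, "per_"))
    expect_equal(eval_filter(f, tags), expected,
                 info = paste(tags, collapse = ","))
  }
  expect_true(eval_filter("has_tag('per_*')", c("per_site")))
  expect_false(eval_filter("has_tag('per_*')", c("persite_x")))
  expect_true(eval_filter("not has_tag('a') or has_tag('b')", "b"))
  expect_error(parse_filter_expression("has_tag('a') + 1"),
               class = "dq_expr_error")
})

test_that("validate_mm flags structural defects and accepts the range-check
           example MM", {
  good <- measurement_method(
    tags = c("check", "range", "example"),
    domain_paths = list(
      domain_path("item0", "numeric",
                  path = "dataset-row/composition/content/biopsy/biopsy_date/value"),
      domain_path("item1", "text",
                  path = "dataset-row/composition/context/health_care_facility/name")),
    check = "item0 >= 0.0 and item0 <= 1000.0",
    grouping = "item1",
    characterization = "mean")
  expect_equal(validate_mm(good), list())

  bad <- measurement_method(
    tags = character(0),
    domain_paths = list(domain_path("item1", "numeric",
                                    path = "dataset-row/composition/x")),
    check = "item3 > 0",
    characterization = "mean")
  codes <- vapply(validate_mm(bad), `[[`, character(1), "code")
  expect_true("EMPTY_TAGS" %in% codes)
  expect_true("BAD_ITEM_NUMBERING" %in% codes)
  expect_true("UNDECLARED_ITEM" %in% codes)
})

test_that("MM documents round-trip through YAML with stable ids", {
  mm <- measurement_method(
    tags = c("check", "value_set", "demo"),
    domain_paths = list(domain_path("item0", "text",
                                    path = "dataset-row/composition/g")),
    check = "in_list(item0, ['Weiblich', 'Männlich', 'Divers'])",
    characterization = "mean",
    description = "gender value-set check")
  text <- dqmm:::render_mm_yaml(mm)
  back <- dqmm:::mm_from_document(yaml::yaml.load(text))
  expect_equal(dqmm:::render_mm_yaml(back), text)
  expect_equal(back$id, mm$id)
  # id is a content hash: changing the 5-tuple changes it
  mm2 <- measurement_method(
    tags = mm$tags,
    domain_paths = mm$domain_paths,
    check = "in_list(item0, ['Weiblich'])",
    characterization = "mean")
  expect_false(identical(mm2$id, mm$id))
})
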