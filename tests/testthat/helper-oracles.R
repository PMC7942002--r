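# Independent reference implementations used as oracles. These deliberately
# take the naive route (loops, per-scalar recursion) so they share no code
# path with the package's vectorized implementations.

naive_freq <- function(v) {
  v <- v[!is.na(v)]
  out <- numeric(0)
  for (x in as.character(v)) {
    if (is.na(out[x])) out[x] <- 0
    out[x] <- out[x] + 1
  }
  out[order(names(out), method = "radix")]
}

naive_stats <- function(v) {
  v <- as.numeric(v[!is.na(v)])
  list(
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_,
    mean = if (length(v)) sum(v) / length(v) else NA_real_,
    median = if (length(v)) {
      s <- sort(v); n <- length(s)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    } else NA_real_,
    sd = if (length(v) >= 2) {
      m <- sum(v) / length(v)
      sqrt(sum((v - m)^2) / (length(v) - 1))
    } else NA_real_)
}

# --- random expression ASTs with a direct scalar interpreter -------------
# gen_expr() builds a random tree over numeric variables a, b, c;
# render_expr() prints it in the MM dialect; ref_eval() interprets the tree
# directly, one scalar binding at a time, with full missing propagation.

gen_expr <- function(depth = 3L) {
  if (depth <= 0L || runif(1) < 0.3) {
    choice <- sample(3L, 1L)
    if (choice == 1L) return(list(op = "num", v = round(runif(1, -5, 5), 2)))
    return(list(op = "var", v = sample(c("a", "b", "c"), 1L)))
  }
  op <- sample(c("+", "-", "*", "cmp", "and", "or", "not", "if"), 1L)
  if (op == "not") {
    return(list(op = "not", x = gen_bool(depth - 1L)))
  }
  if (op %in% c("and", "or")) {
    return(list(op = op, x = gen_bool(depth - 1L), y = gen_bool(depth - 1L)))
  }
  if (op == "cmp") {
    return(list(op = sample(c("<", "<=", ">", ">=", "==", "!="), 1L),
                x = gen_expr(depth - 1L), y = gen_expr(depth - 1L)))
  }
  if (op == "if") {
    return(list(op = "if", c = gen_bool(depth - 1L),
                x = gen_expr(depth - 1L), y = gen_expr(depth - 1L)))
  }
  list(op = op, x = gen_expr(depth - 1L), y = gen_expr(depth - 1L))
}

gen_bool <- function(depth) {
  if (depth <= 0L) {
    return(list(op = sample(c("<", ">"), 1L),
                x = list(op = "var", v = sample(c("a", "b", "c"), 1L)),
                y = list(op = "num", v = round(runif(1, -5, 5), 2))))
  }
  node <- gen_expr(depth)
  if (node$op %in% c("<", "<=", ">", ">=", "==", "!=", "and", "or",
                     "not")) return(node)
  list(op = "<", x = node, y = list(op = "num", v = round(runif(1, -5, 5), 2)))
}

render_expr <- function(n) {
  switch(n$op,
    num = format(n$v, digits = 15),
    var = n$v,
    not = sprintf("not (%s)", render_expr(n$x)),
    "and" = sprintf("(%s) and (%s)", render_expr(n$x), render_expr(n$y)),
    "or" = sprintf("(%s) or (%s)", render_expr(n$x), render_expr(n$y)),
    "if" = sprintf("if (%s) (%s) else (%s)", render_expr(n$c),
                   render_expr(n$x), render_expr(n$y)),
    sprintf("(%s) %s (%s)", render_expr(n$x), n$op, render_expr(n$y)))
}

ref_eval <- function(n, env) {
  miss <- function(x) length(x) != 1L || is.na(x)
  switch(n$op,
    num = n$v,
    var = env[[n$v]],
    not = { x <- ref_eval(n$x, env); if (miss(x)) NA else !x },
    "and" = {
      x <- ref_eval(n$x, env); y <- ref_eval(n$y, env)
      if (miss(x) || miss(y)) NA else x && y
    },
    "or" = {
      x <- ref_eval(n$x, env); y <- ref_eval(n$y, env)
      if (miss(x) || miss(y)) NA else x || y
    },
    "if" = {
      c_ <- ref_eval(n$c, env)
      if (miss(c_)) NA else if (c_) ref_eval(n$x, env) else ref_eval(n$y, env)
    },
    {
      x <- ref_eval(n$x, env); y <- ref_eval(n$y, env)
      if (miss(x) || miss(y)) return(NA)
      switch(n$op,
        "+" = x + y, "-" = x - y, "*" = x * y,
        "<" = x < y, "<=" = x <= y, ">" = x > y, ">=" = x >= y,
        "==" = x == y, "!=" = x != y)
    })
}

# --- tiny hand-built datasets -------------------------------------------

leaf <- function(name, value, unit = NULL, node_id = NULL) {
  dq_node(name, value = value, unit = unit, node_id = node_id)
}

branch <- function(name, ..., node_id = NULL, display = NULL) {
  dq_node(name, children = list(...), node_id = node_id,
          display_name = display)
}

tiny_dataset <- function(values, path_name = "x") {
  # one leaf variable dataset-row/composition/<path_name>; NULL = absent
  rows <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    kids <- if (is.null(v)) list() else list(dq_node(path_name, value = v))
    dq_dataset_row(i - 1L, dq_composition(dq_node("composition",
                                                  children = kids)))
  })
  dqmm:::new_dataset(rows)
}

range_check_mm_for_test <- function(lo, hi, tag_path, extra_tags = character(0)) {
  measurement_method(
    tags = c("check", "range", tag_path, extra_tags),
    domain_paths = list(domain_path("item0", "numeric",
                                    path = "dataset-row/composition/x")),
    check = sprintf("item0 >= %s and item0 <= %s", lo, hi),
    characterization = "mean")
}
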