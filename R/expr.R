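# The MM expression dialect.
#
# Checks, groupings and custom characterizations are written in a small,
# closed, side-effect-free expression language rather than a general
# scripting language, so that MMs stay portable, diffable and safe to run
# on third-party knowledge bases. The dialect offers:
#
#   literals        42, 1.5, 'text', "text", true, false, missing
#   lists           ['Weiblich', 'Männlich', 'Divers']
#   arithmetic      + - * / %        (% is modulo)
#   comparison      == != < <= > >=
#   boolean         and or not
#   conditional     if (cond) expr else expr     (else optional -> missing)
#   functions       in_list(x, [..]), concat(..), format(fmt, ..),
#                   matches(x, re), extract_match(x, re),
#                   year(d), month(d), quarter(d), day(d), weekday(d),
#                   abs(x), round(x[, digits]), floor(x), ceiling(x),
#                   is_missing(x),
#                   aggregates: sum, mean, min, max, median, sd,
#                   count_present, count_total, count_missing
#
# Missing propagation: any missing operand makes the result missing
# (including `false and missing`), mirroring the convention that
# completeness and correctness measures must stay orthogonal. Aggregates
# skip missing values, except count_total/count_missing.
#
# Evaluation is vectorized: bindings may be whole columns; scalars recycle.

expr_error <- function(msg, pos = NULL, src = NULL) {
  loc <- if (!is.null(pos)) sprintf(" at position %d", pos) else ""
  ctx <- if (!is.null(src)) sprintf(" in '%s'", src) else ""
  dq_error("EXPR", sprintf("expression error%s%s: %s", loc, ctx, msg))
}

eval_error <- function(msg) dq_error("EVAL", msg)

## ---- tokenizer -------------------------------------------------------

TOKEN_PATTERNS <- list(
  c("WS",    "^\\s+"),
  c("NUM",   "^\\d+\\.?\\d*([eE][+-]?\\d+)?"),
  c("STR",   "^'([^'\\\\]|\\\\.)*'|^\"([^\"\\\\]|\\\\.)*\""),
  c("IDENT", "^[A-Za-z_][A-Za-z0-9_]*"),
  c("OP",    "^(==|!=|<=|>=|<|>|\\+|-|\\*|/|%|\\(|\\)|\\[|\\]|,)")
)

KEYWORDS <- c("and", "or", "not", "if", "else", "true", "false", "missing")

tokenize_expr <- function(text) {
  tokens <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    matched <- FALSE
    for (tp in TOKEN_PATTERNS) {
      m <- regexpr(tp[[2L]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        lex <- substr(rest, 1L, len)
        if (tp[[1L]] != "WS") {
          type <- tp[[1L]]
          if (type == "IDENT" && lex %in% KEYWORDS) type <- toupper(lex)
          tokens[[length(tokens) + 1L]] <-
            list(type = type, lex = lex, pos = pos)
        }
        pos <- pos + len
        rest <- substring(rest, len + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      expr_error(sprintf("unexpected character '%s'", substr(rest, 1L, 1L)),
                 pos = pos, src = text)
    }
  }
  tokens[[length(tokens) + 1L]] <- list(type = "EOF", lex = "", pos = pos)
  tokens
}

## ---- parser (recursive descent) --------------------------------------

new_parser_state <- function(tokens, src) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$src <- src
  env
}

peek_tok <- function(st) st$tokens[[st$i]]
next_tok <- function(st) {
  t <- st$tokens[[st$i]]
  st$i <- st$i + 1L
  t
}
expect_tok <- function(st, type, what = type) {
  t <- next_tok(st)
  if (t$type != type) {
    expr_error(sprintf("expected %s but found '%s'", what,
                       if (t$type == "EOF") "end of expression" else t$lex),
               pos = t$pos, src = st$src)
  }
  t
}

ast <- function(kind, ...) c(list(kind = kind), list(...))

parse_expr_inner <- function(st) {
  if (peek_tok(st)$type == "IF") return(parse_if(st))
  parse_or(st)
}

parse_if <- function(st) {
  expect_tok(st, "IF")
  expect_op(st, "(")
  cond <- parse_expr_inner(st)
  expect_op(st, ")")
  then <- parse_expr_inner(st)
  alt <- NULL
  if (peek_tok(st)$type == "ELSE") {
    next_tok(st)
    alt <- parse_expr_inner(st)
  }
  ast("if", cond = cond, then = then, alt = alt)
}

expect_op <- function(st, lex) {
  t <- next_tok(st)
  if (t$type != "OP" || t$lex != lex) {
    expr_error(sprintf("expected '%s' but found '%s'", lex,
                       if (t$type == "EOF") "end of expression" else t$lex),
               pos = t$pos, src = st$src)
  }
  t
}

peek_op <- function(st, lexes) {
  t <- peek_tok(st)
  t$type == "OP" && t$lex %in% lexes
}

parse_or <- function(st) {
  left <- parse_and(st)
  while (peek_tok(st)$type == "OR") {
    next_tok(st)
    left <- ast("or", left = left, right = parse_and(st))
  }
  left
}

parse_and <- function(st) {
  left <- parse_not(st)
  while (peek_tok(st)$type == "AND") {
    next_tok(st)
    left <- ast("and", left = left, right = parse_not(st))
  }
  left
}

parse_not <- function(st) {
  if (peek_tok(st)$type == "NOT") {
    next_tok(st)
    return(ast("not", operand = parse_not(st)))
  }
  parse_comparison(st)
}

parse_comparison <- function(st) {
  left <- parse_additive(st)
  if (peek_op(st, c("==", "!=", "<", "<=", ">", ">="))) {
    op <- next_tok(st)$lex
    right <- parse_additive(st)
    return(ast("cmp", op = op, left = left, right = right))
  }
  left
}

parse_additive <- function(st) {
  left <- parse_multiplicative(st)
  while (peek_op(st, c("+", "-"))) {
    op <- next_tok(st)$lex
    left <- ast("arith", op = op, left = left,
                right = parse_multiplicative(st))
  }
  left
}

parse_multiplicative <- function(st) {
  left <- parse_unary(st)
  while (peek_op(st, c("*", "/", "%"))) {
    op <- next_tok(st)$lex
    left <- ast("arith", op = op, left = left, right = parse_unary(st))
  }
  left
}

parse_unary <- function(st) {
  if (peek_op(st, "-")) {
    next_tok(st)
    return(ast("neg", operand = parse_unary(st)))
  }
  parse_primary(st)
}

unquote_string <- function(lex) {
  inner <- substr(lex, 2L, nchar(lex) - 1L)
  gsub("\\\\(.)", "\\1", inner)
}

parse_primary <- function(st) {
  t <- peek_tok(st)
  if (t$type == "NUM") {
    next_tok(st)
    return(ast("num", value = as.numeric(t$lex)))
  }
  if (t$type == "STR") {
    next_tok(st)
    return(ast("str", value = unquote_string(t$lex)))
  }
  if (t$type %in% c("TRUE", "FALSE")) {
    next_tok(st)
    return(ast("bool", value = t$type == "TRUE"))
  }
  if (t$type == "MISSING") {
    next_tok(st)
    return(ast("missing"))
  }
  if (t$type == "IF") return(parse_if(st))
  if (t$type == "IDENT") {
    next_tok(st)
    if (peek_op(st, "(")) {
      next_tok(st)
      args <- list()
      if (!peek_op(st, ")")) {
        repeat {
          args[[length(args) + 1L]] <- parse_expr_inner(st)
          if (peek_op(st, ",")) next_tok(st) else break
        }
      }
      expect_op(st, ")")
      return(ast("call", fn = t$lex, args = args))
    }
    return(ast("var", name = t$lex))
  }
  if (t$type == "OP" && t$lex == "(") {
    next_tok(st)
    inner <- parse_expr_inner(st)
    expect_op(st, ")")
    return(inner)
  }
  if (t$type == "OP" && t$lex == "[") {
    next_tok(st)
    items <- list()
    if (!peek_op(st, "]")) {
      repeat {
        items[[length(items) + 1L]] <- parse_expr_inner(st)
        if (peek_op(st, ",")) next_tok(st) else break
      }
    }
    expect_op(st, "]")
    return(ast("list", items = items))
  }
  expr_error(sprintf("unexpected token '%s'",
                     if (t$type == "EOF") "end of expression" else t$lex),
             pos = t$pos, src = st$src)
}

#' Parse an MM expression
#'
#' @param text Expression text in the MM dialect.
#' @return A `dq_expr` holding the source text and parsed tree.
#' @export
parse_expression <- function(text) {
  dq_assert(is.character(text) && length(text) == 1L && nzchar(trimws(text)),
            "EXPR", "expression must be a non-empty string")
  st <- new_parser_state(tokenize_expr(text), text)
  tree <- parse_expr_inner(st)
  t <- peek_tok(st)
  if (t$type != "EOF") {
    expr_error(sprintf("trailing input starting at '%s'", t$lex),
               pos = t$pos, src = text)
  }
  structure(list(source = text, ast = tree), class = "dq_expr")
}

#' @export
print.dq_expr <- function(x, ...) {
  cat("<dq_expr>", x$source, "\n")
  invisible(x)
}

# Free variables referenced by an expression (for MM validation).
expr_free_vars <- function(expr) {
  node <- if (inherits(expr, "dq_expr")) expr$ast else expr
  walk <- function(n) {
    switch(n$kind,
      var = n$name,
      `if` = c(walk(n$cond), walk(n$then),
               if (!is.null(n$alt)) walk(n$alt)),
      or = , and = , cmp = , arith = c(walk(n$left), walk(n$right)),
      not = , neg = walk(n$operand),
      call = unlist(lapply(n$args, walk)),
      list = unlist(lapply(n$items, walk)),
      NULL)
  }
  unique(walk(node) %||% character(0))
}

## ---- evaluator -------------------------------------------------------

is_numeric_vec <- function(x) is.numeric(x)
is_text_vec <- function(x) is.character(x)
all_na <- function(x) all(is.na(x))

coerce_num <- function(x, what) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  if (all_na(x)) return(rep(NA_real_, length(x)))
  eval_error(sprintf("type mismatch: %s requires numeric operands", what))
}

recycle_to <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  eval_error(sprintf("cannot align vector of length %d with length %d",
                     length(x), n))
}

# Binary dispatch with common length and full missing propagation.
binary_common <- function(a, b, f) {
  n <- max(length(a), length(b))
  a <- recycle_to(a, n)
  b <- recycle_to(b, n)
  out <- f(a, b)
  out[is.na(a) | is.na(b)] <- NA
  out
}

eval_cmp <- function(op, a, b) {
  ok_pair <-
    (is_numeric_vec(a) || is.logical(a) || all_na(a)) &&
      (is_numeric_vec(b) || is.logical(b) || all_na(b)) ||
    (is_text_vec(a) || all_na(a)) && (is_text_vec(b) || all_na(b))
  if (!ok_pair) {
    eval_error(sprintf(
      "type mismatch: cannot compare %s with %s using '%s'",
      class(a)[1L], class(b)[1L], op))
  }
  f <- switch(op,
    "==" = `==`, "!=" = `!=`, "<" = `<`, "<=" = `<=`,
    ">" = `>`, ">=" = `>=`)
  binary_common(a, b, f)
}

merge_branches <- function(cond, then_v, alt_v) {
  n <- max(length(cond), length(then_v), length(alt_v))
  cond <- recycle_to(cond, n)
  then_v <- recycle_to(then_v, n)
  alt_v <- recycle_to(alt_v, n)
  proto <- if (!all_na(then_v)) then_v else alt_v
  if (!all_na(then_v) && !all_na(alt_v) &&
      is_text_vec(then_v) != is_text_vec(alt_v)) {
    eval_error("type mismatch: if/else branches have incompatible types")
  }
  out <- rep(proto[NA_integer_], n)
  take_then <- !is.na(cond) & cond
  take_alt <- !is.na(cond) & !cond
  out[take_then] <- then_v[take_then]
  out[take_alt] <- alt_v[take_alt]
  out
}

agg_skip_na <- function(f) function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  f(v)
}

EXPR_FUNCTIONS <- list(
  in_list = function(x, lst) {
    out <- x %in% lst
    out[is.na(x)] <- NA
    out
  },
  concat = function(...) {
    args <- lapply(list(...), as.character)
    out <- do.call(paste0, args)
    nas <- Reduce(`|`, lapply(args, is.na))
    out[nas] <- NA_character_
    out
  },
  format = function(fmt, ...) {
    args <- list(...)
    out <- do.call(sprintf, c(list(fmt), args))
    nas <- Reduce(`|`, lapply(args, is.na), init = is.na(fmt))
    out[nas] <- NA_character_
    out
  },
  matches = function(x, pattern) {
    out <- grepl(pattern[[1L]], as.character(x))
    out[is.na(x)] <- NA
    out
  },
  extract_match = function(x, pattern) {
    x <- as.character(x)
    m <- regexpr(pattern[[1L]], x)
    out <- rep(NA_character_, length(x))
    hit <- !is.na(x) & m > 0L
    out[hit] <- regmatches(x, m)
    out
  },
  year = function(d) date_part(d, "year"),
  month = function(d) date_part(d, "month"),
  quarter = function(d) date_part(d, "quarter"),
  day = function(d) date_part(d, "day"),
  weekday = function(d) date_part(d, "weekday"),
  abs = function(x) abs(coerce_num(x, "abs")),
  round = function(x, digits = 0) round(coerce_num(x, "round"), digits[[1L]]),
  floor = function(x) floor(coerce_num(x, "floor")),
  ceiling = function(x) ceiling(coerce_num(x, "ceiling")),
  is_missing = function(x) is.na(x),
  sum = agg_skip_na(sum),
  mean = agg_skip_na(mean),
  min = agg_skip_na(min),
  max = agg_skip_na(max),
  median = agg_skip_na(stats::median),
  sd = agg_skip_na(stats::sd),
  count_present = function(v) sum(!is.na(v)),
  count_total = function(v) length(v),
  count_missing = function(v) sum(is.na(v))
)

date_part <- function(d, part) {
  d <- as.character(d)
  dates <- as.Date(substr(d, 1L, 10L), format = "%Y-%m-%d")
  bad <- !is.na(d) & is.na(dates)
  if (any(bad)) {
    eval_error(sprintf("not an ISO-8601 date: '%s'", d[which(bad)[1L]]))
  }
  switch(part,
    year = as.numeric(format(dates, "%Y")),
    month = as.numeric(format(dates, "%m")),
    day = as.numeric(format(dates, "%d")),
    quarter = (as.numeric(format(dates, "%m")) - 1) %/% 3 + 1,
    weekday = {
      # Stable English labels regardless of locale.
      c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
        "Sun")[as.integer(format(dates, "%u"))]
    })
}

eval_node <- function(node, env) {
  switch(node$kind,
    num = node$value,
    str = node$value,
    bool = node$value,
    missing = NA,
    var = {
      if (!node$name %in% names(env$bindings)) {
        eval_error(sprintf("unbound variable '%s'", node$name))
      }
      env$bindings[[node$name]]
    },
    list = unlist(lapply(node$items, eval_node, env = env)),
    neg = -coerce_num(eval_node(node$operand, env), "unary '-'"),
    not = {
      v <- eval_node(node$operand, env)
      if (!is.logical(v) && !all_na(v)) {
        eval_error("type mismatch: 'not' requires a boolean operand")
      }
      !v
    },
    and = eval_bool2(node, env, `&`),
    or = eval_bool2(node, env, `|`),
    cmp = eval_cmp(node$op,
                   eval_node(node$left, env),
                   eval_node(node$right, env)),
    arith = {
      a <- coerce_num(eval_node(node$left, env), node$op)
      b <- coerce_num(eval_node(node$right, env), node$op)
      f <- switch(node$op, "+" = `+`, "-" = `-`, "*" = `*`,
                  "/" = `/`, "%" = `%%`)
      binary_common(a, b, f)
    },
    `if` = {
      cond <- eval_node(node$cond, env)
      if (!is.logical(cond) && !all_na(cond)) {
        eval_error("type mismatch: if() condition must be boolean")
      }
      then_v <- eval_node(node$then, env)
      alt_v <- if (is.null(node$alt)) NA else eval_node(node$alt, env)
      merge_branches(cond, then_v, alt_v)
    },
    call = {
      fn <- EXPR_FUNCTIONS[[node$fn]]
      if (is.null(fn)) {
        eval_error(sprintf("unknown function '%s'", node$fn))
      }
      args <- lapply(node$args, eval_node, env = env)
      do.call(fn, args)
    },
    eval_error(sprintf("unknown AST node kind '%s'", node$kind)))
}

# `false and missing` is missing by design (D-style full propagation),
# unlike R's three-valued logic.
eval_bool2 <- function(node, env, f) {
  a <- eval_node(node$left, env)
  b <- eval_node(node$right, env)
  for (v in list(a, b)) {
    if (!is.logical(v) && !all_na(v)) {
      eval_error("type mismatch: and/or require boolean operands")
    }
  }
  binary_common(as.logical(a), as.logical(b), f)
}

#' Evaluate an MM expression against bindings
#'
#' @param expr Expression text or a parsed `dq_expr`.
#' @param bindings Named list mapping item names to scalar values or
#'   equal-length vectors (length-1 values recycle).
#' @return The evaluated value; vectorized over the binding length. Any
#'   missing operand yields a missing result.
#' @export
evaluate_expression <- function(expr, bindings = list()) {
  parsed <- if (inherits(expr, "dq_expr")) expr else parse_expression(expr)
  env <- new.env(parent = emptyenv())
  env$bindings <- bindings
  eval_node(parsed$ast, env)
}

## ---- tag filter expressions ------------------------------------------

# Filters select MMs by their tags only: has_tag('x') / lacks_tag('x')
# combined with and/or/not. A trailing "*" makes the tag atom a prefix
# match, expressing "no tag starting with per_" as lacks_tag('per_*').

#' Parse a tag-filter expression
#'
#' @param text Filter text, e.g. `"has_tag('check') and lacks_tag('per_*')"`.
#' @return A `dq_filter`.
#' @export
parse_filter_expression <- function(text) {
  parsed <- parse_expression(text)
  check_filter_ast(parsed$ast, text)
  structure(list(source = text, ast = parsed$ast), class = "dq_filter")
}

check_filter_ast <- function(node, src) {
  ok <- switch(node$kind,
    and = , or = {
      check_filter_ast(node$left, src)
      check_filter_ast(node$right, src)
      TRUE
    },
    not = {
      check_filter_ast(node$operand, src)
      TRUE
    },
    call = {
      if (!node$fn %in% c("has_tag", "lacks_tag")) {
        expr_error(sprintf("filters allow only has_tag/lacks_tag, found '%s'",
                           node$fn), src = src)
      }
      if (length(node$args) != 1L || node$args[[1L]]$kind != "str") {
        expr_error(sprintf("%s() takes exactly one string literal", node$fn),
                   src = src)
      }
      TRUE
    },
    expr_error(sprintf(
      "filters are boolean combinations of tag atoms; found a '%s' node",
      node$kind), src = src))
  invisible(ok)
}

tag_atom_matches <- function(tag_spec, tags) {
  if (endsWith(tag_spec, "*")) {
    prefix <- substr(tag_spec, 1L, nchar(tag_spec) - 1L)
    any(startsWith(tags, prefix))
  } else {
    tag_spec %in% tags
  }
}

#' Evaluate a tag filter against a tag list
#'
#' @param filter A `dq_filter` or filter text.
#' @param tags Character vector of MM tags.
#' @return `TRUE` or `FALSE`.
#' @export
eval_filter <- function(filter, tags) {
  f <- if (inherits(filter, "dq_filter")) filter else
    parse_filter_expression(filter)
  walk <- function(node) {
    switch(node$kind,
      and = walk(node$left) && walk(node$right),
      or = walk(node$left) || walk(node$right),
      not = !walk(node$operand),
      call = {
        hit <- tag_atom_matches(node$args[[1L]]$value, tags)
        if (node$fn == "has_tag") hit else !hit
      })
  }
  walk(f$ast)
}
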