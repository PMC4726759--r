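# Small symbolic layer on top of R language objects.
#
# Expressions are plain R calls/symbols/numbers.  The helpers below build
# arithmetic with constant folding and algebraic identities (0+x, 1*x, 0*x,
# x^0, x^1) so that derived systems stay readable and structural zeros
# (e.g. vanishing expansion corrections for linear propensities) are real
# zeros, not unsimplified calls.

is_num1 <- function(e) is.numeric(e) && length(e) == 1L

e_clean <- function(e) if (is.numeric(e)) unname(e) else e

e_add <- function(a, b) {
  a <- e_clean(a); b <- e_clean(b)
  if (is_num1(a) && is_num1(b)) return(a + b)
  if (is_num1(a) && a == 0) return(b)
  if (is_num1(b) && b == 0) return(a)
  call("+", a, b)
}

e_sub <- function(a, b) {
  a <- e_clean(a); b <- e_clean(b)
  if (is_num1(a) && is_num1(b)) return(a - b)
  if (is_num1(b) && b == 0) return(a)
  if (is_num1(a) && a == 0) return(e_neg(b))
  call("-", a, b)
}

e_neg <- function(a) {
  a <- e_clean(a)
  if (is_num1(a)) return(-a)
  call("-", a)
}

e_mul <- function(a, b) {
  a <- e_clean(a); b <- e_clean(b)
  if (is_num1(a) && is_num1(b)) return(a * b)
  if (is_num1(a)) {
    if (a == 0) return(0)
    if (a == 1) return(b)
  }
  if (is_num1(b)) {
    if (b == 0) return(0)
    if (b == 1) return(a)
  }
  call("*", a, b)
}

e_div <- function(a, b) {
  a <- e_clean(a); b <- e_clean(b)
  if (is_num1(b)) {
    if (b == 1) return(a)
    if (is_num1(a)) return(a / b)
  }
  if (is_num1(a) && a == 0) return(0)
  call("/", a, b)
}

e_pow <- function(a, n) {
  a <- e_clean(a); n <- e_clean(n)
  if (is_num1(n)) {
    if (n == 0) return(1)
    if (n == 1) return(a)
    if (is_num1(a)) return(a^n)
  }
  call("^", a, n)
}

#' Substitute symbols in an expression
#'
#' @param e a language object (call, symbol, or number)
#' @param map named list mapping symbol names to replacement expressions or
#'   numbers
#' @return the expression with every occurrence substituted
#' @keywords internal
subst_expr <- function(e, map) {
  if (length(map) == 0L) return(e)
  eval(call("substitute", e, map))
}

# Recursive constant folding: evaluates numeric subtrees of the safe
# arithmetic/function vocabulary and re-applies the identity-aware builders.
fold_expr <- function(e) {
  if (is_num1(e) || is.symbol(e)) return(e)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  args <- lapply(as.list(e)[-1L], fold_expr)
  if (op == "(") return(args[[1L]])
  if (op == "+" && length(args) == 2L) return(e_add(args[[1L]], args[[2L]]))
  if (op == "-" && length(args) == 2L) return(e_sub(args[[1L]], args[[2L]]))
  if (op == "-" && length(args) == 1L) return(e_neg(args[[1L]]))
  if (op == "+" && length(args) == 1L) return(args[[1L]])
  if (op == "*") return(e_mul(args[[1L]], args[[2L]]))
  if (op == "/") return(e_div(args[[1L]], args[[2L]]))
  if (op == "^") return(e_pow(args[[1L]], args[[2L]]))
  out <- as.call(c(e[[1L]], args))
  if (all(vapply(args, is_num1, logical(1L))) &&
      op %in% c("exp", "log", "sin", "cos", "tan", "sqrt", "abs")) {
    return(eval(out, baseenv()))
  }
  out
}

# Parse a single expression from character / formula / language input.
as_lang <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(str2lang(x))
  }
  if (inherits(x, "formula")) return(x[[length(x)]])
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.language(x)) return(x)
  stop("cannot interpret object of class '", class(x)[1L], "' as an expression")
}

deparse_one <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = " ")

## ---- common-subexpression elimination -------------------------------------

# Collect repeated non-trivial subexpressions (post-order, so children are
# listed before parents) and rewrite the expression list with temporaries.
# Returns list(assign = list(name = expr), exprs = rewritten exprs).
cse_exprs <- function(exprs, min_size = 10L) {
  counts <- new.env(parent = emptyenv())
  order_seen <- character(0L)
  visit <- function(e) {
    if (!is.call(e)) return(invisible())
    for (a in as.list(e)[-1L]) visit(a)
    key <- deparse_one(e)
    # very large subtrees are not worth hashing (and env keys cap at 10 kB)
    if (nchar(key) < min_size || nchar(key) > 1500L) return(invisible())
    n <- if (is.null(counts[[key]])) 0L else counts[[key]]
    if (n == 0L) order_seen <<- c(order_seen, key)
    counts[[key]] <- n + 1L
    invisible()
  }
  for (e in exprs) visit(e)
  shared <- order_seen[vapply(order_seen, function(k) counts[[k]] > 1L, logical(1L))]
  if (length(shared) == 0L) return(list(assign = list(), exprs = exprs))
  tmp_names <- paste0(".cse", seq_along(shared))
  names(tmp_names) <- shared
  rewrite <- function(e, skip_key = NULL) {
    if (!is.call(e)) return(e)
    key <- deparse_one(e)
    if (!identical(key, skip_key) && !is.null(tmp_names[key]) && !is.na(tmp_names[key])) {
      return(as.symbol(tmp_names[[key]]))
    }
    as.call(c(e[[1L]], lapply(as.list(e)[-1L], rewrite)))
  }
  assigns <- list()
  for (key in shared) {
    e <- str2lang(key)
    # rewrite the definition itself in terms of earlier temporaries
    e <- as.call(c(e[[1L]], lapply(as.list(e)[-1L], rewrite)))
    assigns[[tmp_names[[key]]]] <- e
  }
  list(assign = assigns, exprs = lapply(exprs, rewrite))
}

## ---- numeric lowering ------------------------------------------------------

# Build an R function (t, y, p) -> numeric vector evaluating `exprs`, with
# state symbols bound positionally from y and parameter symbols from p.
build_eval_fun <- function(exprs, state_names, param_names, use_cse = TRUE) {
  lowered <- if (use_cse) cse_exprs(exprs) else list(assign = list(), exprs = exprs)
  lines <- character(0L)
  if (length(state_names)) {
    lines <- c(lines, sprintf("%s <- y[[%dL]]", state_names, seq_along(state_names)))
  }
  if (length(param_names)) {
    lines <- c(lines, sprintf("%s <- p[[\"%s\"]]", param_names, param_names))
  }
  for (nm in names(lowered$assign)) {
    lines <- c(lines, paste0(nm, " <- ", deparse_one(lowered$assign[[nm]])))
  }
  body_txt <- paste0(
    "{\n",
    paste(lines, collapse = "\n"), "\n",
    "as.double(c(",
    paste(vapply(lowered$exprs, deparse_one, character(1L)), collapse = ",\n  "),
    "))\n}"
  )
  f <- function(t, y, p) NULL
  body(f) <- str2lang(body_txt)
  environment(f) <- baseenv()
  f
}

# Symbolic partial derivative with a friendlier error than stats::D's.
d_expr <- function(e, var) {
  if (is_num1(e)) return(0)
  out <- tryCatch(stats::D(e, var),
                  error = function(err) stop("cannot differentiate '", deparse_one(e),
                                             "' with respect to '", var, "': ",
                                             conditionMessage(err), call. = FALSE))
  fold_expr(out)
}
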