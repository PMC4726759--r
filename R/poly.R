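# Sparse multivariate polynomials over a fixed, ordered variable set, with
# coefficients that are themselves R expressions (in parameters, inputs and
# time).  This is the workhorse behind the CME generator, the moment
# equations and the closure schemes: monomials in species symbols are kept
# exactly, everything else lives in the coefficient.
#
# Representation: list(vars = character(), terms = named list keyed by the
# exponent vector pasted with "_"; each entry list(expo = integer vector,
# coef = expression-or-number)).

p_key <- function(expo) {
  if (length(expo) == 0L) return("0")       # the constant index of a 0-variable ring
  paste(expo, collapse = "_")
}

p_zero <- function(vars) {
  structure(list(vars = vars, terms = list()), class = "spoly")
}

p_term <- function(vars, expo, coef) {
  p <- p_zero(vars)
  if (is.numeric(coef)) coef <- unname(coef)
  expo <- unname(expo)
  if (is_num1(coef) && coef == 0) return(p)
  p$terms[[p_key(expo)]] <- list(expo = as.integer(expo), coef = coef)
  p
}

p_const <- function(coef, vars) p_term(vars, integer(length(vars)) * 0L, coef)

p_var <- function(v, vars) {
  expo <- integer(length(vars))
  i <- match(v, vars)
  if (is.na(i)) stop("unknown polynomial variable: ", v)
  expo[i] <- 1L
  p_term(vars, expo, 1)
}

p_is_zero <- function(p) length(p$terms) == 0L

p_add <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  out <- a
  for (key in names(b$terms)) {
    tb <- b$terms[[key]]
    ta <- out$terms[[key]]
    if (is.null(ta)) {
      out$terms[[key]] <- tb
    } else {
      cf <- e_add(ta$coef, tb$coef)
      if (is_num1(cf) && cf == 0) out$terms[[key]] <- NULL
      else out$terms[[key]] <- list(expo = ta$expo, coef = cf)
    }
  }
  out
}

p_scale <- function(p, coef) {
  if (is_num1(coef) && coef == 0) return(p_zero(p$vars))
  out <- p
  for (key in names(out$terms)) {
    out$terms[[key]]$coef <- e_mul(out$terms[[key]]$coef, coef)
  }
  out
}

p_neg <- function(p) p_scale(p, -1)

p_sub <- function(a, b) p_add(a, p_neg(b))

p_mul <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  out <- p_zero(a$vars)
  for (ka in names(a$terms)) {
    ta <- a$terms[[ka]]
    for (kb in names(b$terms)) {
      tb <- b$terms[[kb]]
      expo <- ta$expo + tb$expo
      key <- p_key(expo)
      cf <- e_mul(ta$coef, tb$coef)
      prev <- out$terms[[key]]
      if (is.null(prev)) {
        if (!(is_num1(cf) && cf == 0)) out$terms[[key]] <- list(expo = expo, coef = cf)
      } else {
        cf2 <- e_add(prev$coef, cf)
        if (is_num1(cf2) && cf2 == 0) out$terms[[key]] <- NULL
        else out$terms[[key]] <- list(expo = expo, coef = cf2)
      }
    }
  }
  out
}

p_pow <- function(p, n) {
  stopifnot(n >= 0, n == round(n))
  out <- p_const(1, p$vars)
  n <- as.integer(n)
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) out <- p_mul(out, base)
    base_needed <- n %/% 2L > 0L
    n <- n %/% 2L
    if (n > 0L) base <- p_mul(base, base)
  }
  out
}

# Formal partial derivative with respect to one polynomial variable.
p_deriv <- function(p, v) {
  i <- match(v, p$vars)
  stopifnot(!is.na(i))
  out <- p_zero(p$vars)
  for (key in names(p$terms)) {
    tm <- p$terms[[key]]
    if (tm$expo[i] > 0L) {
      expo <- tm$expo
      k <- expo[i]
      expo[i] <- expo[i] - 1L
      out <- p_add(out, p_term(p$vars, expo, e_mul(tm$coef, k)))
    }
  }
  out
}

# Substitute variable v by polynomial q (same ring).
p_subst_var <- function(p, v, q) {
  i <- match(v, p$vars)
  stopifnot(!is.na(i))
  out <- p_zero(p$vars)
  for (key in names(p$terms)) {
    tm <- p$terms[[key]]
    expo <- tm$expo
    k <- expo[i]
    expo[i] <- 0L
    piece <- p_term(p$vars, expo, tm$coef)
    if (k > 0L) piece <- p_mul(piece, p_pow(q, k))
    out <- p_add(out, piece)
  }
  out
}

p_total_degree <- function(p) {
  if (p_is_zero(p)) return(0L)
  max(vapply(p$terms, function(tm) sum(tm$expo), integer(1L)))
}

# Split by total degree: returns list of polynomials indexed by degree+1.
p_degree_parts <- function(p) {
  d <- p_total_degree(p)
  parts <- lapply(0:d, function(i) p_zero(p$vars))
  for (key in names(p$terms)) {
    tm <- p$terms[[key]]
    deg <- sum(tm$expo) + 1L
    parts[[deg]] <- p_add(parts[[deg]], p_term(p$vars, tm$expo, tm$coef))
  }
  parts
}

# Convert polynomial to a plain R expression.
p_to_expr <- function(p) {
  if (p_is_zero(p)) return(0)
  keys <- names(p$terms)
  # canonical ordering: total degree, then lexicographic on the exponent key
  degs <- vapply(p$terms, function(tm) sum(tm$expo), integer(1L))
  keys <- keys[order(degs, keys)]
  out <- NULL
  for (key in keys) {
    tm <- p$terms[[key]]
    mono <- NULL
    for (i in seq_along(p$vars)) {
      if (tm$expo[i] > 0L) {
        fac <- e_pow(as.symbol(p$vars[i]), tm$expo[i])
        mono <- if (is.null(mono)) fac else e_mul(mono, fac)
      }
    }
    term <- if (is.null(mono)) tm$coef else e_mul(tm$coef, mono)
    out <- if (is.null(out)) term else e_add(out, term)
  }
  out
}

# Parse an R expression into a polynomial in `vars`; every subexpression free
# of `vars` becomes a coefficient atom.  Non-polynomial structure (division
# by, or transcendental functions of, the variables) raises an error.
parse_poly <- function(e, vars) {
  e <- as_lang(e)
  uses_vars <- function(x) any(all.vars(x) %in% vars)
  rec <- function(x) {
    if (!uses_vars(x)) return(p_const(fold_expr(x), vars))
    if (is.symbol(x)) return(p_var(as.character(x), vars))
    if (!is.call(x)) stop("cannot interpret '", deparse_one(x), "' as polynomial")
    op <- as.character(x[[1L]])
    args <- as.list(x)[-1L]
    if (op == "(") return(rec(args[[1L]]))
    if (op == "+" && length(args) == 2L) return(p_add(rec(args[[1L]]), rec(args[[2L]])))
    if (op == "+" && length(args) == 1L) return(rec(args[[1L]]))
    if (op == "-" && length(args) == 2L) return(p_sub(rec(args[[1L]]), rec(args[[2L]])))
    if (op == "-" && length(args) == 1L) return(p_neg(rec(args[[1L]])))
    if (op == "*") return(p_mul(rec(args[[1L]]), rec(args[[2L]])))
    if (op == "/") {
      if (uses_vars(args[[2L]])) {
        stop("expression '", deparse_one(x), "' is not polynomial in (",
             paste(vars, collapse = ", "), "): division by a variable")
      }
      return(p_scale(rec(args[[1L]]), e_div(1, fold_expr(args[[2L]]))))
    }
    if (op == "^") {
      n <- args[[2L]]
      if (!is_num1(n) || n < 0 || n != round(n)) {
        stop("non-integer power of a variable in '", deparse_one(x), "'")
      }
      return(p_pow(rec(args[[1L]]), n))
    }
    stop("expression '", deparse_one(x), "' is not polynomial in (",
         paste(vars, collapse = ", "), ")")
  }
  rec(e)
}

# Shift variables: substitute x_i -> x_i + shift_i (integer vector).
p_shift <- function(p, shift) {
  out <- p
  shift <- unname(shift)
  for (i in seq_along(p$vars)) {
    if (shift[i] != 0) {
      q <- p_add(p_var(p$vars[i], p$vars), p_const(shift[i], p$vars))
      out <- p_subst_var(out, p$vars[i], q)
    }
  }
  out
}

## ---- multi-index utilities -------------------------------------------------

# All multi-indices over n variables with total order between lo and hi,
# canonical order: by total order, then lexicographic.
moment_indices <- function(n, hi, lo = 1L) {
  if (lo > hi) return(list())
  out <- list()
  gen <- function(prefix, remaining_slots, remaining_total) {
    if (remaining_slots == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in remaining_total:0L) {
      gen(c(prefix, v), remaining_slots - 1L, remaining_total - v)
    }
  }
  idx <- list()
  for (ord in lo:hi) {
    out <- list()
    gen(integer(0L), n, ord)
    keep <- Filter(function(I) sum(I) == ord, out)
    keep <- keep[order(vapply(keep, p_key, character(1L)), decreasing = TRUE)]
    # lexicographic ascending on the vector itself
    mat <- do.call(rbind, keep)
    o <- do.call(order, as.data.frame(mat))
    idx <- c(idx, keep[o])
  }
  idx
}

choose_prod <- function(I, J) prod(choose(I, J))

# All J with 0 <= J <= I elementwise.
sub_indices <- function(I) {
  grids <- lapply(I, function(k) 0:k)
  mat <- as.matrix(expand.grid(grids))
  lapply(seq_len(nrow(mat)), function(r) as.integer(mat[r, ]))
}
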