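#' Construct a symbolic ODE/DAE system
#'
#' A derived description (reaction rate equations, moment equations, system
#' size expansion, conditional moments, sensitivities) is represented as a
#' set of right-hand-side expressions over state symbols, parameters and time
#' `t`, together with initial-condition expressions in the parameters and an
#' optional constant mass matrix for DAEs.
#'
#' @param state_symbols character vector of state names (syntactic symbols)
#' @param rhs list of expressions, one per state
#' @param initial_condition list of expressions (in parameters) or numbers,
#'   one per state
#' @param parameter_symbols character vector of parameter names
#' @param mass_matrix `NULL` for a plain ODE, otherwise an n x n constant
#'   matrix (singular rows mark algebraic constraints)
#' @param kind `"ode"` or `"dae"`; inferred from the mass matrix by default
#' @param metadata free-form list recording the derivation provenance
#'   (method, order, closure, ...)
#' @return a `ck_system` object
#' @export
symbolic_system <- function(state_symbols, rhs, initial_condition,
                            parameter_symbols, mass_matrix = NULL,
                            kind = NULL, metadata = list(),
                            jacobian_exprs = NULL) {
  stopifnot(length(rhs) == length(state_symbols),
            length(initial_condition) == length(state_symbols))
  rhs <- lapply(rhs, as_lang)
  initial_condition <- lapply(initial_condition, as_lang)
  if (is.null(kind)) {
    kind <- if (!is.null(mass_matrix) &&
                abs(det(mass_matrix)) < .Machine$double.eps^0.5) "dae" else "ode"
  }
  structure(list(state_symbols = state_symbols, rhs = rhs,
                 initial_condition = initial_condition,
                 parameter_symbols = parameter_symbols,
                 mass_matrix = mass_matrix, kind = kind,
                 metadata = metadata, jacobian_exprs = jacobian_exprs),
            class = "ck_system")
}

#' @export
print.ck_system <- function(x, ...) {
  cat("<ck_system> ", length(x$state_symbols), " states (", x$kind, ")",
      if (!is.null(x$metadata$method)) paste0(", method = ", x$metadata$method),
      "\n", sep = "")
  invisible(x)
}

#' Write the equations of a derived system to a text file
#'
#' One `d<state>/dt = <expression>` line per state, for inspection.
#'
#' @param sys a `ck_system`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_system_equations <- function(sys, path) {
  lines <- vapply(seq_along(sys$state_symbols), function(i) {
    paste0("d", sys$state_symbols[i], "/dt = ", deparse_one(sys$rhs[[i]]))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Apply the master-equation generator to a polynomial test function
#'
#' For a test function `f(x)` polynomial in the species counts, returns the
#' fully expanded expression `sum_j a_j(x, t) * (f(x + nu_j) - f(x))`, i.e.
#' the exact time derivative of `E[f(X_t)]` implied by the master equation
#' before expectations are taken.
#'
#' @param f polynomial expression in the species symbols (character, formula
#'   or language)
#' @param net a `ck_network`
#' @return an expanded expression in species, parameters, inputs and `t`
#' @export
apply_generator <- function(f, net) {
  p_to_expr(apply_generator_poly(f, net))
}

# Polynomial-valued version used internally by the moment engine.
apply_generator_poly <- function(f, net) {
  sn <- species_names(net)
  fp <- if (inherits(f, "spoly")) f else parse_poly(f, sn)
  S <- stoichiometry_matrix(net)
  acc <- p_zero(sn)
  for (j in seq_len(n_reactions(net))) {
    prop <- parse_poly(propensity_expr(net, j), sn)
    diff <- p_sub(p_shift(fp, S[, j]), fp)
    if (p_is_zero(diff)) next
    acc <- p_add(acc, p_mul(prop, diff))
  }
  acc
}

#' Multivariate Taylor expansion of a propensity
#'
#' Expands a smooth propensity about a center point, truncating at the given
#' total degree.  Used to polynomialize non-mass-action kinetics (Hill terms
#' etc.) before moment or conditional-moment derivation; the natural center
#' is the current (conditional) mean, passed as a symbol so the resulting
#' moment equations stay autonomous.
#'
#' @param prop propensity expression
#' @param center named list mapping each expanded variable to its center
#'   (number, symbol or expression)
#' @param order truncation total degree (>= 0)
#' @return the Taylor polynomial as an expression
#' @export
taylor_expand_propensity <- function(prop, center, order) {
  stopifnot(order >= 0, order == round(order))
  prop <- as_lang(prop)
  vars <- names(center)
  center <- lapply(center, as_lang)
  idx <- c(list(integer(length(vars))),
           if (order >= 1) moment_indices(length(vars), order))
  out <- NULL
  for (I in idx) {
    dI <- prop
    for (i in seq_along(vars)) {
      for (r in seq_len(I[i])) dI <- d_expr(dI, vars[i])
    }
    coef <- fold_expr(subst_expr(dI, center))
    if (is_num1(coef) && coef == 0) next
    term <- e_div(coef, prod(factorial(I)))
    for (i in seq_along(vars)) {
      if (I[i] > 0L) {
        term <- e_mul(term, e_pow(call("-", as.symbol(vars[i]), center[[i]]),
                                  I[i]))
      }
    }
    out <- if (is.null(out)) term else e_add(out, term)
  }
  if (is.null(out)) 0 else out
}

#' Compile a symbolic system to numeric callables
#'
#' Lowers the right-hand-side expressions (after common-subexpression
#' elimination) into an R function `(t, state, theta) -> dstate`, and builds
#' the analytic Jacobian by symbolic differentiation.
#'
#' @param sys a `ck_system`
#' @param jacobian build the symbolic Jacobian (`TRUE` for systems up to a
#'   few dozen states; larger systems fall back to the integrator's internal
#'   finite-difference Jacobian, unless the derivation supplied one)
#' @param theta optional named numeric parameter values; when given, they
#'   are folded into the compiled expressions (substantially faster
#'   evaluation for large derived systems; the compiled object is then
#'   specific to these values)
#' @return a `ck_compiled` object with elements `rhs_fn`, `jac_fn` (or
#'   `NULL`), `init_fn`, and the originating system
#' @export
compile_system <- function(sys, jacobian = length(sys$state_symbols) <= 40L,
                           theta = NULL) {
  states <- sys$state_symbols
  params <- sys$parameter_symbols
  if (!is.null(theta)) {
    theta <- unlist(theta)
    missing <- setdiff(params, names(theta))
    if (length(missing)) stop("missing parameter value(s) for inlining: ",
                              paste(missing, collapse = ", "))
    map <- as.list(theta[params])
    sys$rhs <- lapply(sys$rhs, function(e) fold_expr(subst_expr(e, map)))
    sys$initial_condition <- lapply(sys$initial_condition,
                                    function(e) fold_expr(subst_expr(e, map)))
    if (!is.null(sys$jacobian_exprs)) {
      sys$jacobian_exprs <- lapply(sys$jacobian_exprs,
                                   function(e) fold_expr(subst_expr(e, map)))
    }
    sys$parameter_symbols <- character(0L)
    params <- character(0L)
  }
  known <- c(states, params, "t", "pi")
  stray <- setdiff(unique(unlist(lapply(sys$rhs, all.vars))), known)
  if (length(stray)) {
    stop("cannot compile system: unresolved symbol(s) ",
         paste(stray, collapse = ", "))
  }
  stray0 <- setdiff(unique(unlist(lapply(sys$initial_condition, all.vars))),
                    c(params, "pi"))
  if (length(stray0)) {
    stop("cannot compile initial condition: unresolved symbol(s) ",
         paste(stray0, collapse = ", "))
  }
  rhs_fn <- build_eval_fun(sys$rhs, states, params)
  jac_fn <- NULL
  if (!is.null(sys$jacobian_exprs)) {
    # pre-derived Jacobian (column-major list of n*n expressions)
    jfun <- build_eval_fun(sys$jacobian_exprs, states, params)
    jac_fn <- function(t, y, p) matrix(jfun(t, y, p), nrow = length(states))
  } else if (jacobian) {
    n <- length(states)
    jac_exprs <- vector("list", n * n)
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        jac_exprs[[(k - 1L) * n + i]] <- d_expr(sys$rhs[[i]], states[k])
      }
    }
    jfun <- build_eval_fun(jac_exprs, states, params)
    jac_fn <- function(t, y, p) matrix(jfun(t, y, p), nrow = length(states))
  }
  init_fn <- build_eval_fun(sys$initial_condition, character(0L), params)
  structure(list(rhs_fn = rhs_fn, jac_fn = jac_fn, init_fn = init_fn,
                 system = sys, metadata = sys$metadata),
            class = "ck_compiled")
}

#' Integrate a compiled (or symbolic) system
#'
#' Stiff integration via deSolve: `lsoda` for ODEs, `radau` with the constant
#' mass matrix for DAEs.  Default tolerances are tight (relative `1e-8`,
#' absolute `1e-10`) because derived moment systems are routinely stiff and
#' downstream comparisons are made at the `1e-6` level.
#'
#' @param sys a `ck_compiled` or `ck_system`
#' @param t_grid strictly increasing output times
#' @param theta named parameter values (missing entries are an error)
#' @param rtol,atol integration tolerances
#' @param y0 optional numeric initial state overriding the system's
#'   initial-condition expressions
#' @return matrix of states on `t_grid` (times in rows), with a `times`
#'   attribute
#' @export
integrate_system <- function(sys, t_grid, theta, rtol = 1e-8, atol = 1e-10,
                             y0 = NULL) {
  if (inherits(sys, "ck_system")) {
    # numeric parameters are known here: fold them into the compiled code
    sys <- compile_system(sys, theta = theta)
  }
  stopifnot(inherits(sys, "ck_compiled"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  theta <- as.list(theta)
  missing <- setdiff(sys$system$parameter_symbols, names(theta))
  if (length(missing)) stop("missing parameter value(s): ",
                            paste(missing, collapse = ", "))
  states <- sys$system$state_symbols
  if (is.null(y0)) y0 <- sys$init_fn(0, numeric(0L), theta)
  names(y0) <- states
  if (length(t_grid) == 1L) {
    out <- matrix(y0, nrow = 1L, dimnames = list(NULL, states))
    attr(out, "times") <- t_grid
    return(out)
  }
  f <- sys$rhs_fn
  func <- function(t, y, parms) list(f(t, y, parms))
  jac <- NULL
  if (!is.null(sys$jac_fn)) {
    jf <- sys$jac_fn
    jac <- function(t, y, parms) jf(t, y, parms)
  }
  M <- sys$system$mass_matrix
  sol <- if (!is.null(M) && sys$system$kind == "dae") {
    deSolve::radau(y = y0, times = t_grid, func = func, parms = theta,
                   mass = M, rtol = rtol, atol = atol)
  } else if (!is.null(jac)) {
    deSolve::lsoda(y = y0, times = t_grid, func = func, parms = theta,
                   jacfunc = jac, jactype = "fullusr",
                   rtol = rtol, atol = atol, maxsteps = 50000L)
  } else {
    deSolve::lsoda(y = y0, times = t_grid, func = func, parms = theta,
                   rtol = rtol, atol = atol, maxsteps = 50000L)
  }
  if (nrow(sol) < length(t_grid) || anyNA(sol[, -1L])) {
    stop("integration failed at t = ", sol[nrow(sol), 1L],
         "; last state: ", paste(signif(sol[nrow(sol), -1L], 6), collapse = ", "))
  }
  out <- unname(sol[, -1L, drop = FALSE])
  colnames(out) <- states
  attr(out, "times") <- t_grid
  out
}
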