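# Forward (order 1 and 2) and adjoint sensitivity analysis for any derived
# ODE/DAE description, plus gradients of weighted least-squares objectives.
#
# Forward: the augmented system carries n*(1+n_theta) states at order 1
# (plus n*n_theta*(n_theta+1)/2 second-order states at order 2).
# Adjoint: one backward system of n adjoint states independent of n_theta,
# integrated segment-wise between measurement times with jump updates, the
# state co-integrated backward alongside (no interpolation error).

sens_sym <- function(state, par) paste0("sn_", state, "_", par)
sens2_sym <- function(state, p1, p2) {
  pp <- sort(c(p1, p2))
  paste0("sn2_", state, "_", pp[1L], "_", pp[2L])
}

#' Derive forward sensitivity equations
#'
#' Augments a symbolic system with first-order sensitivities
#' `s_ip = d x_i / d theta_p` (and optionally the symmetric second-order
#' sensitivities) by symbolic differentiation of the right-hand side.  DAE
#' bases propagate their mass matrix to every sensitivity block.
#'
#' @param sys a `ck_system`
#' @param theta_subset parameters to differentiate with respect to
#'   (default: all parameters of the system)
#' @param order 1 or 2
#' @return a `ck_sens_system`; `$system` is the augmented `ck_system`
#' @export
derive_forward_sensitivities <- function(sys, theta_subset = NULL, order = 1L) {
  stopifnot(order %in% c(1L, 2L))
  pars <- if (is.null(theta_subset)) sys$parameter_symbols else theta_subset
  stopifnot(all(pars %in% sys$parameter_symbols))
  states <- sys$state_symbols
  n <- length(states)
  np <- length(pars)
  J <- matrix(list(0), n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    J[[i, k]] <- d_expr(sys$rhs[[i]], states[k])
  }
  ftheta <- matrix(list(0), n, np)
  for (i in seq_len(n)) for (p in seq_len(np)) {
    ftheta[[i, p]] <- d_expr(sys$rhs[[i]], pars[p])
  }
  aug_states <- states
  aug_rhs <- sys$rhs
  aug_ic <- sys$initial_condition
  for (p in seq_len(np)) {
    for (i in seq_len(n)) {
      acc <- ftheta[[i, p]]
      for (k in seq_len(n)) {
        acc <- e_add(acc, e_mul(J[[i, k]], as.symbol(sens_sym(states[k], pars[p]))))
      }
      aug_states <- c(aug_states, sens_sym(states[i], pars[p]))
      aug_rhs[[length(aug_rhs) + 1L]] <- acc
      aug_ic[[length(aug_ic) + 1L]] <- d_expr(sys$initial_condition[[i]], pars[p])
    }
  }
  if (order == 2L) {
    # d/dt s2_{i,pq} = J s2_pq + (dJ/dx . s_q + dJ/dtheta_q) s_p
    #                 + df_theta_p/dx . s_q + d2 f / dtheta_p dtheta_q
    Jx <- array(list(0), c(n, n, n))
    for (i in seq_len(n)) for (k in seq_len(n)) for (l in seq_len(n)) {
      Jx[[i, k, l]] <- d_expr(J[[i, k]], states[l])
    }
    Jth <- array(list(0), c(n, n, np))
    for (i in seq_len(n)) for (k in seq_len(n)) for (p in seq_len(np)) {
      Jth[[i, k, p]] <- d_expr(J[[i, k]], pars[p])
    }
    fthth <- array(list(0), c(n, np, np))
    for (i in seq_len(n)) for (p in seq_len(np)) for (q in seq_len(np)) {
      fthth[[i, p, q]] <- d_expr(ftheta[[i, p]], pars[q])
    }
    for (p in seq_len(np)) for (q in p:np) {
      for (i in seq_len(n)) {
        acc <- fthth[[i, p, q]]
        for (k in seq_len(n)) {
          acc <- e_add(acc, e_mul(J[[i, k]],
                                  as.symbol(sens2_sym(states[k], pars[p], pars[q]))))
          acc <- e_add(acc, e_mul(Jth[[i, k, q]],
                                  as.symbol(sens_sym(states[k], pars[p]))))
          acc <- e_add(acc, e_mul(Jth[[i, k, p]],
                                  as.symbol(sens_sym(states[k], pars[q]))))
          for (l in seq_len(n)) {
            acc <- e_add(acc, e_mul(Jx[[i, k, l]],
                                    e_mul(as.symbol(sens_sym(states[k], pars[p])),
                                          as.symbol(sens_sym(states[l], pars[q])))))
          }
        }
        aug_states <- c(aug_states, sens2_sym(states[i], pars[p], pars[q]))
        aug_rhs[[length(aug_rhs) + 1L]] <- acc
        ic2 <- d_expr(d_expr(sys$initial_condition[[i]], pars[p]), pars[q])
        aug_ic[[length(aug_ic) + 1L]] <- ic2
      }
    }
  }
  M <- NULL
  if (!is.null(sys$mass_matrix)) {
    blocks <- 1L + np + if (order == 2L) np * (np + 1L) / 2L else 0L
    M <- matrix(0, n * blocks, n * blocks)
    for (b in seq_len(blocks)) {
      idx <- (b - 1L) * n + seq_len(n)
      M[idx, idx] <- sys$mass_matrix
    }
  }
  aug <- symbolic_system(aug_states, aug_rhs, aug_ic, sys$parameter_symbols,
                         mass_matrix = M, kind = sys$kind,
                         metadata = c(sys$metadata,
                                      list(sensitivity_order = order,
                                           sensitivity_parameters = pars)))
  structure(list(base = sys, parameters = pars, order = order, system = aug,
                 n_base = n),
            class = "ck_sens_system")
}

#' @export
print.ck_sens_system <- function(x, ...) {
  cat("<ck_sens_system> order ", x$order, ", ", length(x$parameters),
      " parameters, ", length(x$system$state_symbols), " augmented states\n",
      sep = "")
  invisible(x)
}

#' Define a weighted least-squares objective
#'
#' `J(theta) = sum_k sum_o w_ko * (y_o(t_k; theta) - d_ko)^2` with
#' observables `y_o` given as expressions in the state symbols of the system
#' the objective will be evaluated on.
#'
#' @param observables named list of expressions in the state symbols (and
#'   parameters)
#' @param times measurement times
#' @param data matrix (length(times) x length(observables)) of measured
#'   values
#' @param weights positive weights, recycled to the shape of `data`
#' @return a `ck_objective`
#' @export
objective_function <- function(observables, times, data, weights = 1) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(times), ncol(data) == length(observables),
            !anyNA(data), all(weights > 0))
  W <- matrix(weights, nrow(data), ncol(data))
  structure(list(observables = lapply(observables, as_lang),
                 obs_names = names(observables), times = times,
                 data = data, weights = W),
            class = "ck_objective")
}

# Forward solve at the union of t0 and measurement times; returns rows
# aligned with obj$times.
solve_at_measurements <- function(comp, obj, theta, rtol, atol, t0 = 0) {
  tt <- sort(unique(c(t0, obj$times)))
  tr <- integrate_system(comp, tt, theta, rtol = rtol, atol = atol)
  tr[match(obj$times, tt), , drop = FALSE]
}

eval_obs <- function(obj, states_row, theta) {
  env <- c(as.list(states_row), as.list(theta), list(pi = pi))
  vapply(obj$observables, function(e) eval(e, env), numeric(1L))
}

#' Objective value and gradient
#'
#' @param obj a `ck_objective`
#' @param sys a `ck_system` (the model the observables refer to)
#' @param theta named parameter values
#' @param method `"forward"` (first-order forward sensitivities),
#'   `"adjoint"` (backward adjoint states; ODE systems only), or
#'   `"finite_differences"` (central differences)
#' @param theta_subset parameters in the gradient (default: all)
#' @param fd_step relative finite-difference step (absolute floor `1e-8`)
#' @param rtol,atol integration tolerances
#' @return list with `value` (the objective) and `gradient` (named vector)
#' @export
objective_gradient <- function(obj, sys, theta,
                               method = c("forward", "adjoint",
                                          "finite_differences"),
                               theta_subset = NULL, fd_step = 1e-6,
                               rtol = 1e-10, atol = 1e-12) {
  method <- match.arg(method)
  pars <- if (is.null(theta_subset)) sys$parameter_symbols else theta_subset
  theta <- unlist(theta)[sys$parameter_symbols]
  states <- sys$state_symbols
  value_of <- function(th) {
    comp <- compile_system(sys, jacobian = length(states) <= 40L)
    tr <- solve_at_measurements(comp, obj, th, rtol, atol)
    v <- 0
    for (k in seq_along(obj$times)) {
      y <- eval_obs(obj, tr[k, ], th)
      v <- v + sum(obj$weights[k, ] * (y - obj$data[k, ])^2)
    }
    v
  }
  if (method == "finite_differences") {
    grad <- numeric(length(pars))
    names(grad) <- pars
    for (p in pars) {
      h <- max(fd_step * abs(theta[[p]]), 1e-8)
      tp <- theta; tp[[p]] <- tp[[p]] + h
      tm <- theta; tm[[p]] <- tm[[p]] - h
      grad[[p]] <- (value_of(tp) - value_of(tm)) / (2 * h)
    }
    return(list(value = value_of(theta), gradient = grad))
  }
  if (method == "forward") {
    sens <- derive_forward_sensitivities(sys, pars, order = 1L)
    comp <- compile_system(sens$system,
                           jacobian = length(sens$system$state_symbols) <= 40L)
    tr <- solve_at_measurements(comp, obj, theta, rtol, atol)
    grad <- numeric(length(pars)); names(grad) <- pars
    value <- 0
    dobs_dx <- lapply(obj$observables, function(e) {
      lapply(states, function(s) d_expr(e, s))
    })
    dobs_dth <- lapply(obj$observables, function(e) {
      lapply(pars, function(p) d_expr(e, p))
    })
    for (k in seq_along(obj$times)) {
      env <- c(as.list(tr[k, ]), as.list(theta), list(pi = pi))
      y <- vapply(obj$observables, function(e) eval(e, env), numeric(1L))
      res <- y - obj$data[k, ]
      value <- value + sum(obj$weights[k, ] * res^2)
      for (p in seq_along(pars)) {
        for (o in seq_along(obj$observables)) {
          dy <- eval(dobs_dth[[o]][[p]], env)
          for (i in seq_along(states)) {
            gx <- dobs_dx[[o]][[i]]
            if (is_num1(gx) && gx == 0) next
            dy <- dy + eval(gx, env) * tr[k, sens_sym(states[i], pars[p])]
          }
          grad[[p]] <- grad[[p]] + 2 * obj$weights[k, o] * res[o] * dy
        }
      }
    }
    return(list(value = value, gradient = grad))
  }
  # adjoint
  ad <- derive_adjoint(sys, obj)
  ad$gradient(theta, pars, rtol = rtol, atol = atol)
}

#' Derive the adjoint sensitivity system
#'
#' Backward adjoint ODE `dlambda/dt = -J' lambda` between measurement times
#' with jump updates `lambda <- lambda + dg_k/dx` at each measurement, and
#' gradient assembly
#' `dJ/dtheta = int lambda' df/dtheta dt + lambda(0)' dx0/dtheta +
#' sum_k dg_k/dtheta`.  The adjoint dimension equals the state dimension
#' regardless of the number of parameters.  Only ODE bases are supported;
#' DAE descriptions must use forward sensitivities.
#'
#' @param sys a `ck_system` with `kind = "ode"`
#' @param obj a `ck_objective`
#' @return a `ck_adjoint` with a `$gradient(theta, pars, ...)` function and
#'   the symbolic adjoint right-hand side
#' @export
derive_adjoint <- function(sys, obj) {
  if (sys$kind != "ode") {
    stop("adjoint sensitivities are available for ODE systems only; ",
         "DAE descriptions require forward sensitivity analysis")
  }
  states <- sys$state_symbols
  n <- length(states)
  J <- matrix(list(0), n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    J[[i, k]] <- d_expr(sys$rhs[[i]], states[k])
  }
  # adjoint RHS: dlambda_i/dt = -sum_k J_ki lambda_k
  lam_sym <- paste0("adj_", states)
  adj_rhs <- lapply(seq_len(n), function(i) {
    acc <- 0
    for (k in seq_len(n)) {
      acc <- e_add(acc, e_mul(e_neg(J[[k, i]]), as.symbol(lam_sym[k])))
    }
    acc
  })
  dobs_dx <- lapply(obj$observables, function(e) {
    lapply(states, function(s) d_expr(e, s))
  })
  gradient <- function(theta, pars = sys$parameter_symbols,
                       rtol = 1e-10, atol = 1e-12) {
    theta <- unlist(theta)[sys$parameter_symbols]
    np <- length(pars)
    ftheta <- matrix(list(0), n, np)
    for (i in seq_len(n)) for (p in seq_len(np)) {
      ftheta[[i, p]] <- d_expr(sys$rhs[[i]], pars[p])
    }
    comp <- compile_system(sys, jacobian = n <= 40L)
    tmeas <- obj$times
    tr <- solve_at_measurements(comp, obj, theta, rtol, atol)
    value <- 0
    resid <- matrix(0, length(tmeas), length(obj$observables))
    for (k in seq_along(tmeas)) {
      y <- eval_obs(obj, tr[k, ], theta)
      resid[k, ] <- y - obj$data[k, ]
      value <- value + sum(obj$weights[k, ] * resid[k, ]^2)
    }
    # combined backward system: x (recomputed), lambda, quadratures q
    comb_rhs_fn <- local({
      ffun <- comp$rhs_fn
      adj_fun <- build_eval_fun(adj_rhs, c(states, lam_sym),
                                sys$parameter_symbols)
      fth_fun <- build_eval_fun(as.list(ftheta), states, sys$parameter_symbols)
      function(t, y, parms) {
        x <- y[seq_len(n)]
        lam <- y[n + seq_len(n)]
        dx <- ffun(t, x, parms)
        dlam <- adj_fun(t, c(x, lam), parms)
        fth <- matrix(fth_fun(t, x, parms), n, np)
        dq <- as.numeric(crossprod(fth, lam))
        list(c(dx, dlam, dq))
      }
    })
    lam <- numeric(n)
    q <- numeric(np)
    grad_meas <- numeric(np); names(grad_meas) <- pars
    # walk measurement times backward, applying jumps
    ord <- order(tmeas, decreasing = TRUE)
    t_hi <- NULL
    x_hi <- NULL
    for (k in ord) {
      tk <- tmeas[k]
      if (!is.null(t_hi) && t_hi > tk) {
        y0 <- c(x_hi, lam, q)
        sol <- deSolve::lsoda(y = y0, times = c(t_hi, tk), func = comb_rhs_fn,
                              parms = as.list(theta), rtol = rtol, atol = atol,
                              maxsteps = 50000L)
        yv <- sol[nrow(sol), -1L]
        lam <- yv[n + seq_len(n)]
        q <- yv[2L * n + seq_len(np)]
      }
      x_hi <- tr[k, ]   # re-anchor on the stored forward solution
      env <- c(as.list(setNames(x_hi, states)), as.list(theta), list(pi = pi))
      for (o in seq_along(obj$observables)) {
        w2r <- 2 * obj$weights[k, o] * resid[k, o]
        for (i in seq_len(n)) {
          gx <- dobs_dx[[o]][[i]]
          if (is_num1(gx) && gx == 0) next
          lam[i] <- lam[i] + w2r * eval(gx, env)
        }
        for (p in seq_len(np)) {
          gth <- d_expr(obj$observables[[o]], pars[p])
          if (!(is_num1(gth) && gth == 0)) {
            grad_meas[p] <- grad_meas[p] + w2r * eval(gth, env)
          }
        }
      }
      t_hi <- tk
    }
    # integrate from the earliest measurement back to t = 0
    if (t_hi > 0) {
      y0 <- c(x_hi, lam, q)
      sol <- deSolve::lsoda(y = y0, times = c(t_hi, 0), func = comb_rhs_fn,
                            parms = as.list(theta), rtol = rtol, atol = atol,
                            maxsteps = 50000L)
      yv <- sol[nrow(sol), -1L]
      lam <- yv[n + seq_len(n)]
      q <- yv[2L * n + seq_len(np)]
    }
    # q accumulated backward: q(0) = -int_0^T lambda' f_theta dt, flip sign
    grad <- -q
    names(grad) <- pars
    # initial-condition term
    for (p in seq_len(np)) {
      dx0 <- vapply(sys$initial_condition, function(e) {
        de <- d_expr(e, pars[p])
        if (is_num1(de)) de else eval(de, c(as.list(theta), list(pi = pi)))
      }, numeric(1L))
      grad[p] <- grad[p] + sum(lam * dx0)
    }
    grad <- grad + grad_meas
    list(value = value, gradient = grad)
  }
  structure(list(system = sys, objective = obj, adjoint_rhs = adj_rhs,
                 adjoint_states = lam_sym, gradient = gradient),
            class = "ck_adjoint")
}

#' @export
print.ck_adjoint <- function(x, ...) {
  cat("<ck_adjoint> ", length(x$adjoint_states),
      " adjoint states (independent of the parameter count)\n", sep = "")
  invisible(x)
}

#' Gradient report as a data frame / CSV
#'
#' @param obj,sys,theta as in [objective_gradient()]
#' @param methods methods to tabulate
#' @param path optional CSV path
#' @param ... passed to [objective_gradient()]
#' @return data frame with columns `parameter`, `method`, `gradient`
#' @export
gradient_report <- function(obj, sys, theta,
                            methods = c("forward", "adjoint",
                                        "finite_differences"),
                            path = NULL, ...) {
  rows <- list()
  for (m in methods) {
    g <- objective_gradient(obj, sys, theta, method = m, ...)
    rows[[m]] <- data.frame(parameter = names(g$gradient), method = m,
                            gradient = unname(g$gradient))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
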