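# Method of conditional moments: exact marginal probabilities for the
# low-copy species ("modes" y) coupled to conditional moments of the
# high-copy species z, derived from the CME via test functions
# 1{y = y0} * z^I.  The primary integration form uses unnormalized weighted
# moments w_{y,I} = p(y) * E[z^I | y], which turns the DAE into an ODE and
# avoids division by vanishing mode probabilities; the normalized DAE view
# (probabilities + conditional moments with a p-weighted mass matrix) is
# retained and solved with an implicit DAE solver for cross-checking.
#
# Weighted-moment symbols: wm<mode>_<I> (I = exponents over the high-copy
# species, order 0 = the marginal probability itself).

wm_sym <- function(mode, I) paste0("wm", mode, "_", p_key(I))
wm_order <- function(name) sum(wm_index(name)$I)
wm_index <- function(name) {
  parts <- strsplit(sub("^wm", "", name), "_")[[1L]]
  list(mode = as.integer(parts[1L]), I = as.integer(parts[-1L]))
}

#' Partition species into low- and high-copy sets
#'
#' The automatic rule marks as low-copy every species whose reachable range
#' is provably finite from a nonnegative conservation law and no larger than
#' `cap` states (the default 2 covers promoter-occupancy indicators);
#' everything else stays high-copy.  If no species qualifies, a manual
#' partition is required.
#'
#' @param net a `ck_network`
#' @param rule `"auto"` or `"manual"`
#' @param low_copy character vector of species names (manual rule)
#' @param low_bounds named integer vector of bounds for manual low-copy
#'   species lacking a conservation law
#' @param cap maximum number of reachable states for the auto rule
#' @return a `ck_partition` with elements `low`, `high`, `low_bounds`
#' @export
partition_species <- function(net, rule = c("auto", "manual"),
                              low_copy = NULL, low_bounds = c(), cap = 2L) {
  rule <- match.arg(rule)
  sn <- species_names(net)
  laws <- conservation_laws(net)
  law_bound <- rep(NA_integer_, length(sn))
  names(law_bound) <- sn
  for (law in laws) {
    b <- floor(law$total / pmax(law$coef, 1))
    take <- law$coef > 0 & (is.na(law_bound) | law_bound > b)
    law_bound[take] <- b[take]
  }
  if (rule == "auto") {
    low <- sn[!is.na(law_bound) & law_bound + 1L <= cap]
    if (length(low) == 0L) {
      stop("automatic partition found no species with a provably finite ",
           "reachable range; supply a manual partition")
    }
  } else {
    stopifnot(all(low_copy %in% sn))
    low <- low_copy
  }
  bounds <- law_bound[low]
  for (s in names(low_bounds)) bounds[s] <- low_bounds[[s]]
  if (anyNA(bounds)) {
    stop("no finite range for manual low-copy species: ",
         paste(low[is.na(bounds)], collapse = ", "),
         " (give low_bounds)")
  }
  structure(list(low = low, high = setdiff(sn, low), low_bounds = bounds),
            class = "ck_partition")
}

#' @export
print.ck_partition <- function(x, ...) {
  cat("<ck_partition> low: {", paste(x$low, collapse = ", "), "} high: {",
      paste(x$high, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Enumerate the low-copy mode states (reuses the FSP enumeration restricted
# to the low-copy coordinates).
enumerate_modes <- function(net, partition) {
  sn <- species_names(net)
  if (length(partition$low) == 0L) {
    return(matrix(integer(0L), nrow = 1L, ncol = 0L))
  }
  grid <- as.matrix(expand.grid(lapply(partition$low_bounds, function(b) 0:b),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- partition$low
  laws <- conservation_laws(net)
  for (law in laws) {
    w <- law$coef
    names(w) <- sn
    if (any(w[partition$high] != 0)) next   # law involves high species: skip
    wl <- w[partition$low]
    grid <- grid[drop(grid %*% wl) == law$total, , drop = FALSE]
  }
  storage.mode(grid) <- "integer"
  grid
}

#' Derive the method of conditional moments
#'
#' @param net a `ck_network`
#' @param partition a `ck_partition` (see [partition_species()]); empty-high
#'   partitions reduce the MCM to the FSP over the modes, empty-low
#'   partitions reduce it to the plain moment equations
#' @param order conditional-moment truncation order `m >= 1`
#' @param closure closure scheme applied per mode to conditional moments
#'   above `m` (same vocabulary as [apply_closure()])
#' @param eps regularization added to mode probabilities inside closure
#'   denominators (reported conditional moments use a separate reporting
#'   threshold)
#' @return a `ck_mcm_system` carrying the weighted-moment `ck_system`
#' @export
derive_mcm <- function(net, partition, order = 2L,
                       closure = c("low_dispersion", "mean_field",
                                   "zero_cumulants", "derivative_matching"),
                       eps = 1e-10) {
  closure <- match.arg(closure)
  stopifnot(order >= 1L)
  m <- as.integer(order)
  sn <- species_names(net)
  low <- partition$low
  high <- partition$high
  nh <- length(high)
  modes <- enumerate_modes(net, partition)
  n_modes <- nrow(modes)
  if (n_modes == 0L) stop("mode enumeration is empty")
  mode_key <- apply(modes, 1L, paste, collapse = ",")
  mode_of <- function(y) match(paste(y, collapse = ","), mode_key)
  S <- stoichiometry_matrix(net)
  nuL <- S[low, , drop = FALSE]
  nuH <- S[high, , drop = FALSE]
  idx_all <- c(list(integer(nh)), if (nh > 0L && m >= 1L) moment_indices(nh, m))
  states <- character(0L)
  for (mi in seq_len(n_modes)) {
    for (I in idx_all) states <- c(states, wm_sym(mi, I))
  }
  maxdeg_z <- 1L
  prop_by_mode <- vector("list", n_modes)
  for (mi in seq_len(n_modes)) {
    y <- modes[mi, ]
    subs <- as.list(as.numeric(y))
    names(subs) <- low
    prop_by_mode[[mi]] <- lapply(seq_len(n_reactions(net)), function(j) {
      e <- fold_expr(subst_expr(propensity_expr(net, j), subs))
      pol <- tryCatch(parse_poly(e, high), error = function(err) {
        stop("propensity of reaction ", j, " is not polynomial in the ",
             "high-copy species (", conditionMessage(err),
             "); Taylor-expand first", call. = FALSE)
      })
      maxdeg_z <<- max(maxdeg_z, p_total_degree(pol))
      pol
    })
  }
  # mode-changing reactions contribute a_j(z) * (z + nu)^I without the
  # leading-order cancellation of the single-mode case, so the weighted
  # equations reference moments up to m + deg_z(a)
  maxord <- m + maxdeg_z
  # ring of weighted-moment symbols, all modes, orders 0..maxord
  ring <- character(0L)
  idx_ring <- c(list(integer(nh)), if (nh > 0L) moment_indices(nh, maxord))
  for (mi in seq_len(n_modes)) for (I in idx_ring) ring <- c(ring, wm_sym(mi, I))
  # weighted expectation of a z-polynomial under mode mi
  wexpect <- function(pol, mi) {
    out <- p_zero(ring)
    for (key in names(pol$terms)) {
      tm <- pol$terms[[key]]
      out <- p_add(out, p_scale(p_var(wm_sym(mi, tm$expo), ring), tm$coef))
    }
    out
  }
  rhs_polys <- list()
  for (mi in seq_len(n_modes)) {
    y <- modes[mi, ]
    for (I in idx_all) {
      acc <- p_zero(ring)
      for (j in seq_len(n_reactions(net))) {
        # loss: reaction fires while in mode mi
        loss <- p_mul(prop_by_mode[[mi]][[j]], p_term(high, I, 1))
        acc <- p_sub(acc, wexpect(loss, mi))
        # gain: reaction fires in mode y - nuL and lands in mi
        y_src <- y - nuL[, j]
        src <- if (length(low)) mode_of(y_src) else mi
        if (length(low) && any(y_src < 0)) src <- NA_integer_
        if (!is.na(src)) {
          zsh <- p_shift(p_term(high, I, 1), nuH[, j])
          gain <- p_mul(prop_by_mode[[src]][[j]], zsh)
          acc <- p_add(acc, wexpect(gain, src))
        }
      }
      rhs_polys[[wm_sym(mi, I)]] <- acc
    }
  }
  # per-mode closure of weighted moments above order m:
  # wm_{y,J} ~ (p+eps) * close_raw(J)[ mom_K -> wm_{y,K}/(p+eps) ]
  subst_map <- list()
  if (nh > 0L && maxord > m) {
    raw_ring <- vapply(moment_indices(nh, maxord), mom_sym, character(1L))
    raw_map <- close_raw_map(nh, m, maxord, closure, raw_ring)$exprs
    for (mi in seq_len(n_modes)) {
      psym <- as.symbol(wm_sym(mi, integer(nh)))
      preg <- call("+", psym, eps)
      mom_to_w <- list()
      for (K in moment_indices(nh, m)) {
        mom_to_w[[mom_sym(K)]] <- call("/", as.symbol(wm_sym(mi, K)), preg)
      }
      ords <- vapply(names(raw_map), sym_order, integer(1L))
      local_map <- raw_map
      for (key in names(local_map)[order(-ords)]) {
        e <- local_map[[key]]
        for (k2 in names(local_map)) {
          if (sym_order(k2) < sym_order(key)) {
            e <- subst_expr(e, setNames(list(local_map[[k2]]), k2))
          }
        }
        local_map[[key]] <- e
      }
      for (key in names(local_map)) {
        e <- subst_expr(local_map[[key]], mom_to_w)
        subst_map[[wm_sym(mi, sym_index(key))]] <- e_mul(preg, e)
      }
    }
  }
  rhs <- lapply(rhs_polys, p_to_expr)
  rhs <- lapply(rhs, function(e) fold_expr(subst_expr(e, subst_map)))
  # initial condition: point mass at the initial mode, deterministic z0
  x0 <- initial_state(net)
  mi0 <- if (length(low)) mode_of(x0[low]) else 1L
  if (is.na(mi0)) stop("initial low-copy state is outside the enumerated modes")
  z0 <- x0[high]
  ic <- lapply(states, function(s) {
    info <- wm_index(s)
    if (info$mode != mi0) return(0)
    prod(z0^info$I)
  })
  sys <- symbolic_system(states, rhs, ic, names(net$parameters),
                         metadata = list(method = "MCM", order = m,
                                         closure = closure,
                                         network = net$name))
  structure(list(net = net, partition = partition, order = m,
                 closure = closure, modes = modes, states = states,
                 system = sys, high = high, low = low, eps = eps,
                 initial_mode = mi0),
            class = "ck_mcm_system")
}

#' @export
print.ck_mcm_system <- function(x, ...) {
  cat("<ck_mcm_system> ", nrow(x$modes), " modes x order ", x$order,
      " (closure ", x$closure, "), ", length(x$states), " states\n", sep = "")
  invisible(x)
}

#' Simulate the method of conditional moments
#'
#' Integrates the weighted-moment ODE form (default) or the normalized DAE
#' view via the implicit solver `deSolve::daspk` (residual formulation with
#' mode-probability-weighted moment rows; requires all initial mode
#' probabilities positive).
#'
#' @param mcm a `ck_mcm_system`
#' @param t_grid output times
#' @param theta parameter values
#' @param form `"weighted"` (ODE) or `"normalized_dae"`
#' @param p0 optional initial distribution over the modes (defaults to a
#'   point mass at the network's initial low-copy state)
#' @param report_eps conditional moments are reported only where the mode
#'   probability exceeds this threshold; below it they are `NA`
#' @param rtol,atol integration tolerances
#' @return a `ck_mcm_result`: mode marginals `p` (times x modes),
#'   conditional moments `conditional[[mode]]` (times x indices), plus grid
#'   and metadata
#' @export
simulate_mcm <- function(mcm, t_grid, theta = mcm$net$parameters,
                         form = c("weighted", "normalized_dae"), p0 = NULL,
                         report_eps = 1e-10, rtol = 1e-8, atol = 1e-10) {
  form <- match.arg(form)
  n_modes <- nrow(mcm$modes)
  nh <- length(mcm$high)
  idx_all <- c(list(integer(nh)), if (nh > 0L) moment_indices(nh, mcm$order))
  comp <- compile_system(mcm$system, jacobian = length(mcm$states) <= 40L,
                         theta = theta)
  y0 <- comp$init_fn(0, numeric(0L), as.list(theta))
  names(y0) <- mcm$states
  if (!is.null(p0)) {
    stopifnot(length(p0) == n_modes, abs(sum(p0) - 1) < 1e-12)
    x0 <- initial_state(mcm$net)
    z0 <- x0[mcm$high]
    for (mi in seq_len(n_modes)) {
      for (I in idx_all) y0[wm_sym(mi, I)] <- p0[mi] * prod(z0^I)
    }
  }
  if (form == "weighted") {
    tr <- integrate_system(comp, t_grid, theta, rtol = rtol, atol = atol,
                           y0 = y0)
  } else {
    tr <- mcm_solve_dae(mcm, comp, t_grid, theta, y0, rtol, atol)
  }
  p <- matrix(0, nrow(tr), n_modes)
  mode_labels <- apply(mcm$modes, 1L, function(y) {
    paste(paste0(colnames(mcm$modes), "=", y), collapse = ",")
  })
  colnames(p) <- mode_labels
  for (mi in seq_len(n_modes)) p[, mi] <- tr[, wm_sym(mi, integer(nh))]
  conditional <- vector("list", n_modes)
  names(conditional) <- mode_labels
  if (nh > 0L) {
    for (mi in seq_len(n_modes)) {
      cm <- matrix(NA_real_, nrow(tr), length(idx_all) - 1L)
      colnames(cm) <- vapply(idx_all[-1L], p_key, character(1L))
      ok <- p[, mi] > report_eps
      for (ii in seq_along(idx_all[-1L])) {
        I <- idx_all[[ii + 1L]]
        cm[ok, ii] <- tr[ok, wm_sym(mi, I)] / p[ok, mi]
      }
      conditional[[mi]] <- cm
    }
  }
  structure(list(times = t_grid, p = p, conditional = conditional,
                 modes = mcm$modes, mcm = mcm, weighted = tr,
                 form = form),
            class = "ck_mcm_result")
}

# Normalized DAE view: states (p_y, nu_{y,I} = E[z^I|y]); residuals
#   p rows:      dp/dt - f_p(w(p, nu)) = 0
#   moment rows: p * dnu/dt + nu * dp/dt - f_w(w(p, nu)) = 0
# solved with deSolve::daspk.  Requires p_y(0) > 0 for consistency.
mcm_solve_dae <- function(mcm, comp, t_grid, theta, w0, rtol, atol) {
  n_modes <- nrow(mcm$modes)
  nh <- length(mcm$high)
  idx_all <- c(list(integer(nh)), if (nh > 0L) moment_indices(nh, mcm$order))
  n_per <- length(idx_all)
  p_idx <- vapply(seq_len(n_modes), function(mi) {
    match(wm_sym(mi, integer(nh)), mcm$states)
  }, integer(1L))
  if (any(w0[p_idx] <= 0)) {
    stop("the normalized DAE view needs all initial mode probabilities ",
         "positive; use the weighted form or supply p0")
  }
  to_norm <- function(w) {
    y <- numeric(length(w))
    for (mi in seq_len(n_modes)) {
      base <- (mi - 1L) * n_per
      pv <- w[base + 1L]
      y[base + 1L] <- pv
      if (n_per > 1L) y[base + (2L:n_per)] <- w[base + (2L:n_per)] / pv
    }
    y
  }
  to_weighted <- function(y) {
    w <- numeric(length(y))
    for (mi in seq_len(n_modes)) {
      base <- (mi - 1L) * n_per
      pv <- y[base + 1L]
      w[base + 1L] <- pv
      if (n_per > 1L) w[base + (2L:n_per)] <- y[base + (2L:n_per)] * pv
    }
    w
  }
  res_fn <- function(t, y, dy, parms) {
    w <- to_weighted(y)
    f <- comp$rhs_fn(t, w, parms)
    r <- numeric(length(y))
    for (mi in seq_len(n_modes)) {
      base <- (mi - 1L) * n_per
      pv <- y[base + 1L]
      dp <- dy[base + 1L]
      r[base + 1L] <- dp - f[base + 1L]
      if (n_per > 1L) {
        for (k in 2L:n_per) {
          r[base + k] <- pv * dy[base + k] + y[base + k] * dp - f[base + k]
        }
      }
    }
    list(r)
  }
  y0 <- to_norm(w0)
  f0 <- comp$rhs_fn(t_grid[1L], w0, as.list(theta))
  dy0 <- numeric(length(y0))
  for (mi in seq_len(n_modes)) {
    base <- (mi - 1L) * n_per
    pv <- y0[base + 1L]
    dy0[base + 1L] <- f0[base + 1L]
    if (n_per > 1L) {
      for (k in 2L:n_per) {
        dy0[base + k] <- (f0[base + k] - y0[base + k] * f0[base + 1L]) / pv
      }
    }
  }
  sol <- deSolve::daspk(y = y0, dy = dy0, times = t_grid, res = res_fn,
                        parms = as.list(theta), rtol = rtol, atol = atol)
  if (nrow(sol) < length(t_grid)) {
    stop("MCM DAE integration failed at t = ", sol[nrow(sol), 1L])
  }
  out <- t(apply(unname(sol[, -1L, drop = FALSE]), 1L, to_weighted))
  colnames(out) <- mcm$states
  attr(out, "times") <- t_grid
  out
}

#' Reconstruct unconditional moments from an MCM result
#'
#' Law of total expectation/variance over the modes: unconditional means are
#' probability-weighted conditional means, variances add the between-mode
#' term, and low-copy species moments come from the marginal itself.
#'
#' @param result a `ck_mcm_result`
#' @return a `ck_moments` over all species of the network
#' @export
reconstruct_overall_moments <- function(result) {
  mcm <- result$mcm
  net <- mcm$net
  sn <- species_names(net)
  n <- length(sn)
  nh <- length(mcm$high)
  nt <- length(result$times)
  n_modes <- nrow(mcm$modes)
  tr <- result$weighted
  mean_mat <- matrix(0, nt, n, dimnames = list(NULL, sn))
  cov_arr <- array(NA_real_, dim = c(nt, n, n), dimnames = list(NULL, sn, sn))
  # low-copy species from the marginal
  for (s in mcm$low) {
    vals <- as.numeric(result$p %*% mcm$modes[, s])
    mean_mat[, s] <- vals
    raw2 <- as.numeric(result$p %*% mcm$modes[, s]^2)
    cov_arr[, s, s] <- raw2 - vals^2
  }
  for (s1i in seq_along(mcm$low)) {
    for (s2i in seq_along(mcm$low)) {
      if (s2i <= s1i) next
      s1 <- mcm$low[s1i]; s2 <- mcm$low[s2i]
      raw <- as.numeric(result$p %*% (mcm$modes[, s1] * mcm$modes[, s2]))
      cc <- raw - mean_mat[, s1] * mean_mat[, s2]
      cov_arr[, s1, s2] <- cc; cov_arr[, s2, s1] <- cc
    }
  }
  if (nh > 0L) {
    wsum <- function(I) {
      acc <- numeric(nt)
      for (mi in seq_len(n_modes)) acc <- acc + tr[, wm_sym(mi, I)]
      acc
    }
    for (a in seq_len(nh)) {
      ea <- integer(nh); ea[a] <- 1L
      mean_mat[, mcm$high[a]] <- wsum(ea)
    }
    if (mcm$order >= 2L) {
      for (a in seq_len(nh)) for (b in a:nh) {
        eab <- integer(nh); eab[a] <- eab[a] + 1L; eab[b] <- eab[b] + 1L
        raw2 <- wsum(eab)
        cc <- raw2 - mean_mat[, mcm$high[a]] * mean_mat[, mcm$high[b]]
        cov_arr[, mcm$high[a], mcm$high[b]] <- cc
        cov_arr[, mcm$high[b], mcm$high[a]] <- cc
      }
      # low-high cross covariances: E[y_s * z_a] = sum_y y_s w_{y,e_a}
      for (s in mcm$low) for (a in seq_len(nh)) {
        ea <- integer(nh); ea[a] <- 1L
        raw <- numeric(nt)
        for (mi in seq_len(n_modes)) {
          raw <- raw + mcm$modes[mi, s] * tr[, wm_sym(mi, ea)]
        }
        cc <- raw - mean_mat[, s] * mean_mat[, mcm$high[a]]
        cov_arr[, s, mcm$high[a]] <- cc
        cov_arr[, mcm$high[a], s] <- cc
      }
    }
  }
  new_moments(times = result$times, species = sn, mean = mean_mat,
              cov = cov_arr, method = "MCM", order = mcm$order,
              closure = mcm$closure, units = "molecule_numbers",
              extra = list(p_drift = abs(rowSums(result$p) - 1)))
}

#' Export MCM marginals and conditional moments as a long table
#'
#' @param result a `ck_mcm_result`
#' @param path optional CSV path
#' @return data frame with columns `mode`, `time`, `quantity`, `value`
#' @export
mcm_to_table <- function(result, path = NULL) {
  rows <- list()
  labs <- colnames(result$p)
  for (mi in seq_along(labs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      mode = labs[mi], time = result$times, quantity = "probability",
      value = result$p[, mi])
    cm <- result$conditional[[mi]]
    if (!is.null(cm)) {
      for (cc in colnames(cm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mode = labs[mi], time = result$times,
          quantity = paste0("cond_moment_", cc), value = cm[, cc])
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
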