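# Exact sampling of the reaction-network CTMC: Gillespie's direct method,
# the next-reaction method (Gibson-Bruck reuse of tentative firing times),
# and the modified next-reaction method in internal time, which handles
# time-dependent propensities (exactly, when closed-form antiderivatives are
# supplied; otherwise by tolerance-controlled quadrature) and fixed delays.
#
# Reproducibility contract: one L'Ecuyer-CMRG substream per path, derived
# from the master seed, so ensembles are bit-identical for a given
# (seed, method, n_paths) regardless of execution order; the per-path RNG
# states are recorded in the ensemble.

# Per-reaction propensity evaluator with parameters inlined numerically.
make_propensity_evaluator <- function(net, theta) {
  sn <- species_names(net)
  exprs <- lapply(seq_len(n_reactions(net)), function(j) {
    fold_expr(subst_expr(propensity_expr(net, j), as.list(theta)))
  })
  f <- build_eval_fun(exprs, sn, character(0L), use_cse = FALSE)
  function(x, t) f(t, x, NULL)
}

path_seed_streams <- function(seed, n_paths) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n_paths)
  for (i in seq_len(n_paths)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_path_stream <- function(stream, code) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  assign(".Random.seed", stream, globalenv())
  code()
}

time_dependent_reactions <- function(net) {
  which(vapply(seq_len(n_reactions(net)), function(j) {
    "t" %in% all.vars(propensity_expr(net, j))
  }, logical(1L)))
}

new_ensemble <- function(t_grid, paths, seeds, method, species, events = NULL) {
  structure(list(t_grid = t_grid, paths = paths, seeds = seeds,
                 method = method, species = species, events = events),
            class = "ck_ensemble")
}

#' @export
print.ck_ensemble <- function(x, ...) {
  cat("<ck_ensemble> ", dim(x$paths)[1L], " paths x ", dim(x$paths)[2L],
      " times x ", dim(x$paths)[3L], " species (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Simulate sample paths of the reaction network
#'
#' Front end for the three exact stochastic simulation variants.  States are
#' recorded by zero-order hold on `t_grid`; set `record_events = TRUE` to
#' keep the full event sequences as well.
#'
#' @param net a `ck_network`
#' @param t_grid output times (first entry is the initial time)
#' @param n_paths number of sample paths
#' @param seed master seed; each path gets its own RNG substream
#' @param method `"direct"`, `"next_reaction"`, or
#'   `"modified_next_reaction"`; only the last supports time-dependent
#'   propensities and delays
#' @param theta parameter values (defaults to the network's)
#' @param antiderivatives optional named/indexed list of closed-form
#'   antiderivatives `F_j(t)` of each time-dependent propensity's time
#'   factor is not assumed -- each entry must be an expression in `t` and
#'   the state symbols such that `dF_j/dt = a_j(x, t)` holds for fixed state
#'   `x`; used by the modified next-reaction method to make firing times
#'   exact.  Reactions without an entry fall back to adaptive quadrature
#'   with absolute tolerance `quad_tol`.
#' @param quad_tol absolute tolerance of the quadrature fallback
#' @param record_events keep per-path event lists (time, reaction index)
#' @return a `ck_ensemble`
#' @export
simulate_ssa <- function(net, t_grid, n_paths, seed,
                         method = c("direct", "next_reaction",
                                    "modified_next_reaction"),
                         theta = net$parameters, antiderivatives = NULL,
                         quad_tol = 1e-10, record_events = FALSE) {
  method <- match.arg(method)
  stopifnot(n_paths >= 1L, !is.unsorted(t_grid, strictly = TRUE))
  tdep <- time_dependent_reactions(net)
  delays <- vapply(net$reactions, `[[`, numeric(1L), "delay")
  if (method != "modified_next_reaction" && (length(tdep) || any(delays > 0))) {
    stop("time-dependent propensities or delays require method = ",
         "\"modified_next_reaction\"")
  }
  sn <- species_names(net)
  x0 <- initial_state(net)
  prop <- make_propensity_evaluator(net, theta)
  S <- stoichiometry_matrix(net)
  streams <- path_seed_streams(seed, n_paths)
  nt <- length(t_grid)
  paths <- array(0L, dim = c(n_paths, nt, length(sn)),
                 dimnames = list(NULL, NULL, sn))
  events <- if (record_events) vector("list", n_paths) else NULL
  stepper <- switch(method,
                    direct = ssa_path_direct,
                    next_reaction = ssa_path_nrm,
                    modified_next_reaction = function(...) {
                      ssa_path_mnrm(..., antiderivatives = antiderivatives,
                                    delays = delays, quad_tol = quad_tol,
                                    net = net, theta = theta)
                    })
  for (i in seq_len(n_paths)) {
    res <- with_path_stream(streams[[i]], function() {
      stepper(x0, t_grid, prop, S, record_events)
    })
    paths[i, , ] <- res$states
    if (record_events) events[[i]] <- res$events
  }
  new_ensemble(t_grid, paths, streams, method, sn, events)
}

# Zero-order-hold recording helper: fill output rows with current state for
# all grid times in [t_prev, t_now).
zoh_record <- function(states, t_grid, gi, t_now, x) {
  while (gi <= length(t_grid) && t_grid[gi] < t_now) {
    states[gi, ] <- x
    gi <- gi + 1L
  }
  list(states = states, gi = gi)
}

ssa_path_direct <- function(x0, t_grid, prop, S, record_events) {
  nt <- length(t_grid)
  n_r <- ncol(S)
  states <- matrix(0, nt, nrow(S))
  x <- x0
  t_now <- t_grid[1L]
  gi <- 1L
  ev_t <- numeric(0L); ev_j <- integer(0L)
  repeat {
    a <- prop(x, t_now)
    a0 <- sum(a)
    if (a0 <= 0) break
    t_next <- t_now + stats::rexp(1L, a0)
    r <- zoh_record(states, t_grid, gi, t_next, x)
    states <- r$states; gi <- r$gi
    if (t_next > t_grid[nt]) { t_now <- t_next; break }
    j <- 1L + sum(stats::runif(1L) * a0 > cumsum(a))
    j <- min(j, n_r)
    x <- x + S[, j]
    t_now <- t_next
    if (record_events) { ev_t <- c(ev_t, t_now); ev_j <- c(ev_j, j) }
    if (gi > nt) break
  }
  while (gi <= nt) { states[gi, ] <- x; gi <- gi + 1L }
  list(states = states,
       events = if (record_events) data.frame(time = ev_t, reaction = ev_j))
}

# Next-reaction method with Gibson-Bruck reuse: absolute tentative firing
# times per reaction; unfired reactions rescale their remaining waiting time
# when their propensity changes.  Ties are broken toward the lowest reaction
# index (which.min's convention).
ssa_path_nrm <- function(x0, t_grid, prop, S, record_events) {
  nt <- length(t_grid)
  n_r <- ncol(S)
  states <- matrix(0, nt, nrow(S))
  x <- x0
  t_now <- t_grid[1L]
  gi <- 1L
  ev_t <- numeric(0L); ev_j <- integer(0L)
  a <- prop(x, t_now)
  tau <- ifelse(a > 0, t_now + stats::rexp(n_r) / a, Inf)
  repeat {
    j <- which.min(tau)
    t_next <- tau[j]
    if (!is.finite(t_next)) break
    r <- zoh_record(states, t_grid, gi, t_next, x)
    states <- r$states; gi <- r$gi
    if (t_next > t_grid[nt]) { t_now <- t_next; break }
    x <- x + S[, j]
    t_prev <- t_now
    t_now <- t_next
    if (record_events) { ev_t <- c(ev_t, t_now); ev_j <- c(ev_j, j) }
    a_new <- prop(x, t_now)
    for (k in seq_len(n_r)) {
      if (k == j) {
        tau[k] <- if (a_new[k] > 0) t_now + stats::rexp(1L) / a_new[k] else Inf
      } else if (a_new[k] != a[k]) {
        tau[k] <- if (a_new[k] > 0) {
          if (is.finite(tau[k])) t_now + (a[k] / a_new[k]) * (tau[k] - t_now)
          else t_now + stats::rexp(1L) / a_new[k]
        } else Inf
      }
    }
    a <- a_new
    if (gi > nt) break
  }
  while (gi <= nt) { states[gi, ] <- x; gi <- gi + 1L }
  list(states = states,
       events = if (record_events) data.frame(time = ev_t, reaction = ev_j))
}

# Modified next-reaction method (internal-time formulation): each reaction
# carries a unit-exponential budget P_j and consumed internal time T_j; the
# next firing of j solves int_t^s a_j(x, u) du = P_j - T_j.  Fixed delays
# put the state change into a completion queue executed at firing + delay.
ssa_path_mnrm <- function(x0, t_grid, prop, S, record_events,
                          antiderivatives, delays, quad_tol, net, theta) {
  nt <- length(t_grid)
  n_r <- ncol(S)
  sn <- rownames(S)
  states <- matrix(0, nt, nrow(S))
  # closed-form antiderivative evaluators (state symbols + t)
  anti_fn <- vector("list", n_r)
  if (!is.null(antiderivatives)) {
    keys <- names(antiderivatives)
    for (k in seq_along(antiderivatives)) {
      j <- if (!is.null(keys) && nzchar(keys[k])) as.integer(keys[k]) else k
      e <- fold_expr(subst_expr(as_lang(antiderivatives[[k]]), as.list(theta)))
      f <- build_eval_fun(list(e), sn, character(0L), use_cse = FALSE)
      anti_fn[[j]] <- function(x, t) f(t, x, NULL)
      # force binding of f per iteration
      environment(anti_fn[[j]]) <- list2env(list(f = f), parent = baseenv())
    }
  }
  tdep_j <- time_dependent_reactions(net)
  prop_j <- function(j, x, t) {
    a <- prop(x, t)[j]
    if (a < 0) stop("negative propensity for reaction ", j, " at t = ", t)
    a
  }
  # integral of a_j(x, .) over [t1, t2] at fixed x
  int_aj <- function(j, x, t1, t2) {
    if (!(j %in% tdep_j)) return(prop_j(j, x, t1) * (t2 - t1))
    if (!is.null(anti_fn[[j]])) return(anti_fn[[j]](x, t2) - anti_fn[[j]](x, t1))
    stats::integrate(function(u) vapply(u, function(uu) prop_j(j, x, uu),
                                        numeric(1L)),
                     t1, t2, abs.tol = quad_tol, rel.tol = quad_tol * 10)$value
  }
  # solve int_t^(s) a_j = budget for s > t (Inf if unreachable on the horizon)
  solve_firing <- function(j, x, t, budget, horizon) {
    if (!(j %in% tdep_j)) {
      a <- prop_j(j, x, t)
      return(if (a > 0) t + budget / a else Inf)
    }
    total <- int_aj(j, x, t, horizon)
    if (total < budget) return(Inf)
    g <- function(s) int_aj(j, x, t, s) - budget
    stats::uniroot(g, lower = t, upper = horizon, tol = 1e-12)$root
  }
  x <- x0
  t_now <- t_grid[1L]
  gi <- 1L
  Tj <- numeric(n_r)                  # consumed internal time
  Pj <- stats::rexp(n_r)              # next internal firing levels
  queue_t <- numeric(0L); queue_j <- integer(0L)
  ev_t <- numeric(0L); ev_j <- integer(0L)
  horizon <- t_grid[nt] + max(delays) + 1
  repeat {
    cand <- vapply(seq_len(n_r), function(j) {
      solve_firing(j, x, t_now, Pj[j] - Tj[j], horizon)
    }, numeric(1L))
    t_fire <- min(cand)
    j_fire <- if (is.finite(t_fire)) which.min(cand) else NA_integer_
    t_compl <- if (length(queue_t)) min(queue_t) else Inf
    t_next <- min(t_fire, t_compl)
    if (!is.finite(t_next) || t_next > t_grid[nt]) break
    r <- zoh_record(states, t_grid, gi, t_next, x)
    states <- r$states; gi <- r$gi
    # consume internal time for all reactions up to t_next
    for (j in seq_len(n_r)) Tj[j] <- Tj[j] + int_aj(j, x, t_now, t_next)
    if (t_compl <= t_fire) {
      # a delayed reaction completes: apply its state change
      qi <- which.min(queue_t)
      jq <- queue_j[qi]
      x <- x + S[, jq]
      queue_t <- queue_t[-qi]; queue_j <- queue_j[-qi]
      if (record_events) { ev_t <- c(ev_t, t_next); ev_j <- c(ev_j, jq) }
    } else {
      j <- j_fire
      Pj[j] <- Pj[j] + stats::rexp(1L)
      if (delays[j] > 0) {
        queue_t <- c(queue_t, t_next + delays[j])
        queue_j <- c(queue_j, j)
      } else {
        x <- x + S[, j]
        if (record_events) { ev_t <- c(ev_t, t_next); ev_j <- c(ev_j, j) }
      }
    }
    t_now <- t_next
    if (gi > nt && length(queue_t) == 0L) break
  }
  while (gi <= nt) { states[gi, ] <- x; gi <- gi + 1L }
  list(states = states,
       events = if (record_events) data.frame(time = ev_t, reaction = ev_j))
}

#' Sample moments of a trajectory ensemble
#'
#' Unbiased Monte-Carlo estimators of the raw and central moments per output
#' time, with central-limit standard errors (the variance of the variance
#' estimator uses fourth moments).
#'
#' @param ens a `ck_ensemble`
#' @param order maximum moment order (>= 1)
#' @return a `ck_moment_estimate`: per-species arrays `mean`, `se_mean`,
#'   `variance`, `se_variance`, raw moments up to `order`, plus the
#'   cross-species covariance array
#' @export
ensemble_moments <- function(ens, order = 2L) {
  stopifnot(order >= 1L)
  np <- dim(ens$paths)[1L]
  nt <- dim(ens$paths)[2L]
  ns <- dim(ens$paths)[3L]
  mean_m <- matrix(0, nt, ns, dimnames = list(NULL, ens$species))
  se_mean <- var_m <- se_var <- mean_m
  cov_arr <- array(0, dim = c(nt, ns, ns),
                   dimnames = list(NULL, ens$species, ens$species))
  raw <- list()
  for (k in seq_len(order)) raw[[k]] <- mean_m
  for (ti in seq_len(nt)) {
    Xt <- matrix(as.numeric(ens$paths[, ti, ]), nrow = np, ncol = ns)
    mu <- colMeans(Xt)
    mean_m[ti, ] <- mu
    if (np > 1L) {
      cv <- stats::cov(Xt)
      cov_arr[ti, , ] <- cv
      var_m[ti, ] <- diag(cv)
      se_mean[ti, ] <- sqrt(diag(cv) / np)
      ctr <- sweep(Xt, 2L, mu)
      m4 <- colMeans(ctr^4)
      se_var[ti, ] <- sqrt(pmax(m4 - diag(cv)^2 * (np - 3) / (np - 1), 0) / np)
    }
    for (k in seq_len(order)) raw[[k]][ti, ] <- colMeans(Xt^k)
  }
  structure(list(times = ens$t_grid, species = ens$species, n_paths = np,
                 mean = mean_m, se_mean = se_mean, variance = var_m,
                 se_variance = se_var, cov = cov_arr, raw = raw,
                 order = order),
            class = "ck_moment_estimate")
}

#' @export
print.ck_moment_estimate <- function(x, ...) {
  cat("<ck_moment_estimate> ", x$n_paths, " paths, ", length(x$times),
      " times\n", sep = "")
  invisible(x)
}

#' Empirical state distribution of an ensemble at one time
#'
#' @param ens a `ck_ensemble`
#' @param t a time on the ensemble grid (no interpolation of distributions)
#' @param species_subset species to keep (default: all)
#' @return data frame of observed states and their relative frequencies;
#'   frequencies sum to 1
#' @export
empirical_distribution <- function(ens, t, species_subset = ens$species) {
  ti <- match(t, ens$t_grid)
  if (is.na(ti)) stop("t = ", t, " is not on the ensemble time grid")
  cols <- match(species_subset, ens$species)
  stopifnot(!anyNA(cols))
  X <- matrix(ens$paths[, ti, cols], nrow = dim(ens$paths)[1L])
  key <- apply(X, 1L, paste, collapse = ",")
  tab <- table(key)
  states <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  colnames(states) <- species_subset
  out <- data.frame(states, probability = as.numeric(tab) / sum(tab))
  out[do.call(order, as.data.frame(states)), , drop = FALSE]
}

#' Write an ensemble to CSV files
#'
#' Persists the paths (long format), the per-path RNG states, and a metadata
#' header so a run can be reproduced exactly.
#'
#' @param ens a `ck_ensemble`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_ensemble_csv <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- dim(ens$paths)[1L]; nt <- dim(ens$paths)[2L]
  long <- data.frame(path = rep(seq_len(np), each = nt),
                     time = rep(ens$t_grid, times = np))
  for (s in seq_along(ens$species)) {
    long[[ens$species[s]]] <- as.vector(t(ens$paths[, , s]))
  }
  utils::write.csv(long, file.path(dir, "paths.csv"), row.names = FALSE)
  seeds <- do.call(rbind, ens$seeds)
  utils::write.csv(data.frame(path = seq_len(np), seeds),
                   file.path(dir, "seeds.csv"), row.names = FALSE)
  meta <- data.frame(field = c("method", "n_paths", "n_times", "species"),
                     value = c(ens$method, np, nt,
                               paste(ens$species, collapse = ";")))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
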