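# Finite state projection of the chemical master equation: truncate the
# state space, integrate dp/dt = A(t) p with a sparse stiff solver, and track
# the mass defect 1 - sum(p) as the certified approximation error.  The FSP
# solution is the in-package reference oracle for every moment-based method.

#' Enumerate a truncated state space
#'
#' Hyper-rectangle enumeration `0:bound` per species, intersected with the
#' nonnegative-integer conservation laws detected from the left null space of
#' the stoichiometry matrix (so, e.g., a conserved promoter pair contributes
#' two states, not four).  Species covered by a conservation law are bounded
#' automatically and may be omitted from `bounds`.
#'
#' @param net a `ck_network`
#' @param bounds named integer vector of per-species upper bounds
#' @param max_states size cap; enumeration beyond it is an error that reports
#'   the attempted count
#' @return a `ck_statespace` with the state matrix (rows = states), a
#'   state-to-row index, and the bounds used
#' @export
enumerate_states <- function(net, bounds = c(), max_states = 2e5) {
  sn <- species_names(net)
  x0 <- initial_state(net)
  laws <- conservation_laws(net)
  ub <- rep(NA_real_, length(sn))
  names(ub) <- sn
  ub[names(bounds)] <- bounds
  for (law in laws) {
    covered <- law$coef > 0
    auto <- floor(law$total / pmax(law$coef, 1))
    take <- covered & (is.na(ub) | ub > auto)
    ub[take] <- auto[take]
  }
  if (anyNA(ub)) {
    stop("no bound (explicit or conservation-implied) for species: ",
         paste(sn[is.na(ub)], collapse = ", "))
  }
  count <- prod(ub + 1)
  if (count > 20 * max_states) {
    stop("truncated state space exceeds the size cap before conservation ",
         "filtering (", format(count, scientific = TRUE), " states, cap ",
         max_states, ")")
  }
  grid <- as.matrix(expand.grid(lapply(ub, function(b) 0:b),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- sn
  for (law in laws) {
    grid <- grid[drop(grid %*% law$coef) == law$total, , drop = FALSE]
  }
  if (nrow(grid) > max_states) {
    stop("truncated state space exceeds the size cap: ", nrow(grid),
         " states (cap ", max_states, ")")
  }
  storage.mode(grid) <- "integer"
  key <- apply(grid, 1L, paste, collapse = ",")
  index <- seq_len(nrow(grid))
  names(index) <- key
  if (!(paste(x0, collapse = ",") %in% key)) {
    stop("initial state is outside the truncated state space")
  }
  structure(list(states = grid, index = index, bounds = ub, net_name = net$name),
            class = "ck_statespace")
}

#' @export
print.ck_statespace <- function(x, ...) {
  cat("<ck_statespace> ", nrow(x$states), " states over (",
      paste(colnames(x$states), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Evaluate propensity j on all rows of the state matrix at time t (vectorized
# over states).
propensity_on_space <- function(net, space, theta) {
  sn <- species_names(net)
  cols <- lapply(seq_along(sn), function(i) as.numeric(space$states[, i]))
  names(cols) <- sn
  env0 <- c(cols, as.list(theta), list(pi = pi))
  exprs <- lapply(seq_len(n_reactions(net)), function(j) propensity_expr(net, j))
  function(t) {
    env <- c(env0, list(t = t))
    vapply(exprs, function(e) {
      v <- eval(e, env)
      if (length(v) == 1L) v <- rep(v, nrow(space$states))
      v
    }, numeric(nrow(space$states)))
  }
}

#' Build the truncated master-equation generator
#'
#' Sparse rate matrix `A` with `A[y, x] = a_j(x)` for transitions
#' `y = x + nu_j` inside the space and `A[x, x] = -sum_j a_j(x)` including
#' flow out of the space, so column sums are `<= 0` with deficit equal to the
#' outflow rate (the source of the mass defect).
#'
#' @param net a `ck_network`
#' @param space a `ck_statespace`
#' @param theta parameter values (defaults to the network's)
#' @return for time-independent propensities a `dgCMatrix`; otherwise a
#'   function `A(t)` returning one
#' @export
build_generator <- function(net, space, theta = net$parameters) {
  S <- stoichiometry_matrix(net)
  N <- nrow(space$states)
  prop_t <- propensity_on_space(net, space, theta)
  targets <- vector("list", n_reactions(net))
  for (j in seq_len(n_reactions(net))) {
    shifted <- sweep(space$states, 2L, -S[, j])
    key <- apply(shifted, 1L, paste, collapse = ",")
    tg <- unname(space$index[key])
    targets[[j]] <- tg                      # NA = outside the space
  }
  assemble <- function(aval) {
    ii <- integer(0L); jj <- integer(0L); vv <- numeric(0L)
    for (j in seq_len(ncol(aval))) {
      tg <- targets[[j]]
      keep <- !is.na(tg) & aval[, j] != 0
      ii <- c(ii, tg[keep]); jj <- c(jj, which(keep)); vv <- c(vv, aval[keep, j])
    }
    diag_out <- rowSums(aval)
    Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                         x = c(vv, -diag_out), dims = c(N, N))
  }
  tdep <- any(vapply(seq_len(n_reactions(net)), function(j) {
    "t" %in% all.vars(propensity_expr(net, j))
  }, logical(1L)))
  if (!tdep) return(assemble(prop_t(0)))
  function(t) assemble(prop_t(t))
}

#' Solve the finite state projection
#'
#' Integrates `dp/dt = A(t) p` over the truncated space with the sparse
#' stiff solver (`deSolve::lsodes`).  The solution is a pointwise lower bound
#' on the true distribution (up to integration tolerance); lost mass is
#' tracked per output time as the defect `1 - sum(p)`.
#'
#' @param net a `ck_network`
#' @param space a `ck_statespace` (or named bounds vector, passed to
#'   [enumerate_states()])
#' @param t_grid output times (first entry is the initial time)
#' @param theta parameter values (defaults to the network's)
#' @param p0 initial distribution over the space; defaults to a point mass at
#'   the network's initial state
#' @param rtol,atol integration tolerances
#' @return a `ck_fsp` with probability matrix `p` (times x states),
#'   `mass_defect`, the space, and the grid
#' @export
solve_fsp <- function(net, space, t_grid, theta = net$parameters, p0 = NULL,
                      rtol = 1e-8, atol = 1e-10) {
  if (!inherits(space, "ck_statespace")) space <- enumerate_states(net, space)
  N <- nrow(space$states)
  if (is.null(p0)) {
    p0 <- numeric(N)
    p0[space$index[[paste(initial_state(net), collapse = ",")]]] <- 1
  }
  stopifnot(length(p0) == N)
  A <- build_generator(net, space, theta)
  if (length(t_grid) == 1L) {
    p <- matrix(p0, nrow = 1L)
  } else {
    func <- if (is.function(A)) {
      function(t, y, parms) list(as.numeric(A(t) %*% y))
    } else {
      function(t, y, parms) list(as.numeric(A %*% y))
    }
    sol <- deSolve::lsodes(y = p0, times = t_grid, func = func, parms = NULL,
                           rtol = rtol, atol = atol, maxsteps = 100000L)
    if (nrow(sol) < length(t_grid)) {
      stop("FSP integration failed at t = ", sol[nrow(sol), 1L])
    }
    p <- unname(sol[, -1L, drop = FALSE])
  }
  structure(list(p = p, times = t_grid, space = space,
                 mass_defect = 1 - rowSums(p), atol = atol),
            class = "ck_fsp")
}

#' @export
print.ck_fsp <- function(x, ...) {
  cat("<ck_fsp> ", nrow(x$p), " times x ", ncol(x$p), " states; final mass defect ",
      signif(x$mass_defect[length(x$mass_defect)], 3), "\n", sep = "")
  invisible(x)
}

#' Mass-defect error bound of an FSP solution
#'
#' @param sol a `ck_fsp`
#' @return numeric vector `1 - sum_x p(x|t)` per output time
#' @export
fsp_error_bound <- function(sol) sol$mass_defect

#' Marginalize an FSP solution
#'
#' @param sol a `ck_fsp`
#' @param species_subset character vector of species to keep
#' @return a list with the marginal state matrix and the marginal probability
#'   matrix (times x marginal states); marginal rows sum to `1 - mass_defect`
#' @export
marginalize_fsp <- function(sol, species_subset) {
  stopifnot(length(species_subset) >= 1L)
  sn <- colnames(sol$space$states)
  stopifnot(all(species_subset %in% sn))
  sub <- sol$space$states[, species_subset, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = ",")
  groups <- match(key, unique(key))
  marg_states <- sub[!duplicated(key), , drop = FALSE]
  pm <- t(apply(sol$p, 1L, function(row) {
    as.numeric(rowsum(row, groups))
  }))
  if (nrow(marg_states) == 1L) pm <- matrix(pm, ncol = 1L)
  list(states = marg_states, p = pm, times = sol$times)
}

#' Moments of an FSP solution
#'
#' Raw and central moments of the truncated distribution, renormalized by
#' `1 - mass_defect`; the defect is carried along so consumers can judge the
#' truncation bias.
#'
#' @param sol a `ck_fsp`
#' @param order maximum moment order
#' @return a `ck_moments` trajectory (means, covariances, and raw moments up
#'   to `order`), with the mass defect in `$mass_defect`
#' @export
fsp_moments <- function(sol, order = 2L) {
  X <- sol$space$states
  sn <- colnames(X)
  n <- ncol(X)
  nt <- nrow(sol$p)
  norm <- pmax(1 - sol$mass_defect, .Machine$double.eps)
  mean_mat <- (sol$p %*% X) / norm
  colnames(mean_mat) <- sn
  cov_arr <- array(0, dim = c(nt, n, n), dimnames = list(NULL, sn, sn))
  for (i in seq_len(n)) {
    for (j in i:n) {
      raw <- (sol$p %*% (X[, i] * X[, j])) / norm
      cc <- raw - mean_mat[, i] * mean_mat[, j]
      cov_arr[, i, j] <- cc
      cov_arr[, j, i] <- cc
    }
  }
  raw_moments <- list()
  if (order >= 1L) {
    for (I in moment_indices(n, order)) {
      mono <- apply(X, 1L, function(x) prod(x^I))
      raw_moments[[p_key(I)]] <- as.numeric((sol$p %*% mono) / norm)
    }
  }
  new_moments(times = sol$times, species = sn, mean = mean_mat, cov = cov_arr,
              raw = raw_moments, method = "FSP", order = order,
              closure = "none", units = "molecule_numbers",
              extra = list(mass_defect = sol$mass_defect))
}
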