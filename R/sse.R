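# System size expansion of the master equation about the macroscopic limit,
# via the ansatz x = Omega*phi + sqrt(Omega)*xi.  Successive order tags add
# states to a single nested ODE system (corrections never feed back into
# lower orders):
#
#   RRE :  dphi/dt = S f(phi)
#   LNA :  + covariance C of xi:        dC = A C + C A' + D
#   EMRE:  + mean shift h (order 1/Omega in counts):
#            dh_i = A_ik h_k + 1/2 A2_ikl C_kl + (S g)_i
#   IOS :  + leading third cumulant T and covariance correction Z
#
# with A the RRE Jacobian, A2/A3 its higher derivatives, D = S diag(f) S',
# and g the sub-leading (discreteness) part of mass-action propensities.
# Count-scale outputs: mean = Omega*phi (+ h for EMRE/IOS), covariance =
# Omega*C (+ Z for IOS).  The equations themselves are Omega-free; the
# system size enters only through this output assembly, because propensities
# are count-based at Omega = 1 and mass-action rate constants scale as
# Omega^(1-order) across volumes.

# Leading (macroscopic) and sub-leading parts of every propensity.  For
# mass-action reactions the combinatorial corrections of order
# reactants-1, reactants-2 feed the g/w parts; general kinetics are taken
# as already macroscopic (documented assumption).
macroscopic_parts <- function(net) {
  sn <- species_names(net)
  f <- list(); g <- list()
  for (j in seq_len(n_reactions(net))) {
    rxn <- net$reactions[[j]]
    pol <- tryCatch(parse_poly(propensity_expr(net, j), sn),
                    error = function(e) {
                      stop("reaction ", j, if (!is.null(rxn$name)) paste0(" ('", rxn$name, "')"),
                           " has no macroscopic rate form: ", conditionMessage(e),
                           call. = FALSE)
                    })
    if (rxn$kinetics == "mass_action") {
      d <- sum(rxn$reactants)
      parts <- p_degree_parts(pol)
      pad <- function(k) if (k >= 1L && k <= length(parts)) parts[[k]] else p_zero(sn)
      f[[j]] <- pad(d + 1L)
      g[[j]] <- pad(d)
    } else {
      f[[j]] <- pol
      g[[j]] <- p_zero(sn)
    }
  }
  list(f = f, g = g)
}

sse_state_names <- function(sn, order_tag) {
  n <- length(sn)
  states <- sn
  blocks <- list(phi = sn)
  if (order_tag == "RRE") return(list(states = states, blocks = blocks))
  cv <- character(0L)
  for (i in 1:n) for (j in i:n) cv <- c(cv, paste0("covC_", i, "_", j))
  states <- c(states, cv); blocks$C <- cv
  if (order_tag == "LNA") return(list(states = states, blocks = blocks))
  h <- paste0("emh_", 1:n)
  states <- c(states, h); blocks$h <- h
  if (order_tag == "EMRE") return(list(states = states, blocks = blocks))
  tc <- character(0L)
  for (i in 1:n) for (j in i:n) for (k in j:n) tc <- c(tc, paste0("tc_", i, "_", j, "_", k))
  zc <- character(0L)
  for (i in 1:n) for (j in i:n) zc <- c(zc, paste0("zc_", i, "_", j))
  states <- c(states, tc, zc); blocks$T <- tc; blocks$Z <- zc
  list(states = states, blocks = blocks)
}

#' Derive the system size expansion
#'
#' @param net a `ck_network` with polynomial propensities (Taylor-expand
#'   general kinetics first if needed)
#' @param order_tag `"RRE"`, `"LNA"`, `"EMRE"`, or `"IOS"`; each tag
#'   contains the previous one as a closed subsystem
#' @return a `ck_sse` carrying the derived `ck_system`
#' @export
derive_sse <- function(net, order_tag = c("LNA", "RRE", "EMRE", "IOS")) {
  order_tag <- match.arg(order_tag)
  sn <- species_names(net)
  n <- length(sn)
  S <- stoichiometry_matrix(net)
  mp <- macroscopic_parts(net)
  f_ex <- lapply(mp$f, p_to_expr)
  g_ex <- lapply(mp$g, p_to_expr)
  # RRE right-hand side and its derivatives
  Sf <- lapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(ncol(S))) if (S[i, j] != 0L) acc <- e_add(acc, e_mul(S[i, j], f_ex[[j]]))
    acc
  })
  Sg <- lapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(ncol(S))) if (S[i, j] != 0L) acc <- e_add(acc, e_mul(S[i, j], g_ex[[j]]))
    acc
  })
  A <- matrix(list(0), n, n)
  for (i in 1:n) for (k in 1:n) A[[i, k]] <- d_expr(Sf[[i]], sn[k])
  needA2 <- order_tag %in% c("EMRE", "IOS")
  A2 <- if (needA2) {
    arr <- array(list(0), c(n, n, n))
    for (i in 1:n) for (k in 1:n) for (l in k:n) {
      v <- d_expr(A[[i, k]], sn[l])
      arr[[i, k, l]] <- v; arr[[i, l, k]] <- v
    }
    arr
  }
  A3 <- if (order_tag == "IOS") {
    arr <- array(list(0), c(n, n, n, n))
    for (i in 1:n) for (k in 1:n) for (l in k:n) for (q in l:n) {
      v <- d_expr(A2[[i, k, l]], sn[q])
      for (pp in unique(list(c(k,l,q), c(k,q,l), c(l,k,q), c(l,q,k), c(q,k,l), c(q,l,k)))) {
        arr[[i, pp[1L], pp[2L], pp[3L]]] <- v
      }
    }
    arr
  }
  f1 <- if (order_tag == "IOS") {
    m <- matrix(list(0), ncol(S), n)
    for (r in seq_len(ncol(S))) for (k in 1:n) m[[r, k]] <- d_expr(f_ex[[r]], sn[k])
    m
  }
  f2 <- if (order_tag == "IOS") {
    arr <- array(list(0), c(ncol(S), n, n))
    for (r in seq_len(ncol(S))) for (k in 1:n) for (l in k:n) {
      v <- d_expr(f1[[r, k]], sn[l])
      arr[[r, k, l]] <- v; arr[[r, l, k]] <- v
    }
    arr
  }
  nm <- sse_state_names(sn, order_tag)
  csym <- function(i, j) as.symbol(paste0("covC_", min(i, j), "_", max(i, j)))
  hsym <- function(i) as.symbol(paste0("emh_", i))
  tsym <- function(i, j, k) {
    s <- sort(c(i, j, k))
    as.symbol(paste0("tc_", s[1L], "_", s[2L], "_", s[3L]))
  }
  zsym <- function(i, j) as.symbol(paste0("zc_", min(i, j), "_", max(i, j)))
  Dij <- function(i, j) {
    acc <- 0
    for (r in seq_len(ncol(S))) {
      w <- S[i, r] * S[j, r]
      if (w != 0L) acc <- e_add(acc, e_mul(w, f_ex[[r]]))
    }
    acc
  }
  rhs <- list()
  for (i in 1:n) rhs[[sn[i]]] <- Sf[[i]]
  if (order_tag != "RRE") {
    for (i in 1:n) for (j in i:n) {
      acc <- Dij(i, j)
      for (k in 1:n) {
        acc <- e_add(acc, e_mul(A[[i, k]], csym(k, j)))
        acc <- e_add(acc, e_mul(A[[j, k]], csym(k, i)))
      }
      rhs[[as.character(csym(i, j))]] <- acc
    }
  }
  if (order_tag %in% c("EMRE", "IOS")) {
    for (i in 1:n) {
      acc <- Sg[[i]]
      for (k in 1:n) {
        acc <- e_add(acc, e_mul(A[[i, k]], hsym(k)))
        for (l in 1:n) {
          acc <- e_add(acc, e_mul(e_mul(0.5, A2[[i, k, l]]), csym(k, l)))
        }
      }
      rhs[[as.character(hsym(i))]] <- acc
    }
  }
  if (order_tag == "IOS") {
    Bijk <- function(i, j, k) {
      acc <- 0
      for (r in seq_len(ncol(S))) {
        w <- S[i, r] * S[j, r]
        if (w != 0L) acc <- e_add(acc, e_mul(w, f1[[r, k]]))
      }
      acc
    }
    B2ijkl <- function(i, j, k, l) {
      acc <- 0
      for (r in seq_len(ncol(S))) {
        w <- S[i, r] * S[j, r]
        if (w != 0L) acc <- e_add(acc, e_mul(w, f2[[r, k, l]]))
      }
      acc
    }
    Eijk <- function(i, j, k) {
      acc <- 0
      for (r in seq_len(ncol(S))) {
        w <- S[i, r] * S[j, r] * S[k, r]
        if (w != 0L) acc <- e_add(acc, e_mul(w, f_ex[[r]]))
      }
      acc
    }
    Gij <- function(i, j) {
      acc <- 0
      for (r in seq_len(ncol(S))) {
        w <- S[i, r] * S[j, r]
        if (w != 0L) acc <- e_add(acc, e_mul(w, g_ex[[r]]))
      }
      acc
    }
    Ag <- matrix(list(0), n, n)
    for (i in 1:n) for (k in 1:n) Ag[[i, k]] <- d_expr(Sg[[i]], sn[k])
    for (i in 1:n) for (j in i:n) for (k in j:n) {
      acc <- Eijk(i, j, k)
      for (l in 1:n) {
        acc <- e_add(acc, e_mul(A[[i, l]], tsym(l, j, k)))
        acc <- e_add(acc, e_mul(A[[j, l]], tsym(i, l, k)))
        acc <- e_add(acc, e_mul(A[[k, l]], tsym(i, j, l)))
        acc <- e_add(acc, e_mul(Bijk(i, j, l), csym(l, k)))
        acc <- e_add(acc, e_mul(Bijk(i, k, l), csym(l, j)))
        acc <- e_add(acc, e_mul(Bijk(j, k, l), csym(l, i)))
        for (q in 1:n) {
          acc <- e_add(acc, e_mul(A2[[i, l, q]], e_mul(csym(l, j), csym(q, k))))
          acc <- e_add(acc, e_mul(A2[[j, l, q]], e_mul(csym(l, i), csym(q, k))))
          acc <- e_add(acc, e_mul(A2[[k, l, q]], e_mul(csym(l, i), csym(q, j))))
        }
      }
      rhs[[as.character(tsym(i, j, k))]] <- acc
    }
    for (i in 1:n) for (j in i:n) {
      acc <- Gij(i, j)
      for (k in 1:n) {
        acc <- e_add(acc, e_mul(A[[i, k]], zsym(k, j)))
        acc <- e_add(acc, e_mul(A[[j, k]], zsym(k, i)))
        acc <- e_add(acc, e_mul(Bijk(i, j, k), hsym(k)))
        acc <- e_add(acc, e_mul(Ag[[i, k]], csym(k, j)))
        acc <- e_add(acc, e_mul(Ag[[j, k]], csym(k, i)))
        for (l in 1:n) {
          acc <- e_add(acc, e_mul(e_mul(0.5, A2[[i, k, l]]), tsym(k, l, j)))
          acc <- e_add(acc, e_mul(e_mul(0.5, A2[[j, k, l]]), tsym(k, l, i)))
          acc <- e_add(acc, e_mul(A2[[i, k, l]], e_mul(hsym(k), csym(l, j))))
          acc <- e_add(acc, e_mul(A2[[j, k, l]], e_mul(hsym(k), csym(l, i))))
          acc <- e_add(acc, e_mul(e_mul(0.5, B2ijkl(i, j, k, l)), csym(k, l)))
          for (q in 1:n) {
            acc <- e_add(acc, e_mul(e_mul(0.5, A3[[i, k, l, q]]),
                                    e_mul(csym(k, l), csym(q, j))))
            acc <- e_add(acc, e_mul(e_mul(0.5, A3[[j, k, l, q]]),
                                    e_mul(csym(k, l), csym(q, i))))
          }
        }
      }
      rhs[[as.character(zsym(i, j))]] <- acc
    }
  }
  x0 <- initial_state(net)
  ic <- lapply(nm$states, function(s) {
    if (s %in% sn) unname(x0[[s]]) else 0
  })
  sys <- symbolic_system(nm$states, rhs[nm$states], ic, names(net$parameters),
                         metadata = list(method = order_tag,
                                         network = net$name))
  structure(list(net = net, order_tag = order_tag, system = sys,
                 blocks = nm$blocks),
            class = "ck_sse")
}

#' @export
print.ck_sse <- function(x, ...) {
  cat("<ck_sse> ", x$order_tag, ": ", length(x$system$state_symbols),
      " states\n", sep = "")
  invisible(x)
}

#' Simulate a system size expansion
#'
#' Integrates the derived expansion and assembles mean and covariance time
#' courses.  On the count scale the mean is `Omega*phi` plus the EMRE shift
#' `h` (tags EMRE/IOS) and the covariance `Omega*C` plus the correction `Z`
#' (tag IOS); concentrations divide by `Omega` per index.
#'
#' @param sse a `ck_sse` from [derive_sse()]
#' @param t_grid output times
#' @param theta parameter values (defaults to the network's)
#' @param omega system size; the initial species amounts are interpreted as
#'   concentrations on the `omega = 1` reference volume
#' @param units `"molecule_numbers"` or `"concentrations"`
#' @param rtol,atol integration tolerances
#' @return a `ck_moments` trajectory (covariances absent for tag RRE)
#' @export
simulate_sse <- function(sse, t_grid, theta = sse$net$parameters, omega = 1,
                         units = c("molecule_numbers", "concentrations"),
                         rtol = 1e-8, atol = 1e-10) {
  units <- match.arg(units)
  stopifnot(omega > 0)
  tr <- integrate_system(sse$system, t_grid, theta, rtol = rtol, atol = atol)
  sn <- species_names(sse$net)
  n <- length(sn)
  nt <- nrow(tr)
  tag <- sse$order_tag
  mean_mat <- matrix(0, nt, n, dimnames = list(NULL, sn))
  for (i in 1:n) {
    mean_mat[, i] <- omega * tr[, sn[i]]
    if (tag %in% c("EMRE", "IOS")) {
      mean_mat[, i] <- mean_mat[, i] + tr[, paste0("emh_", i)]
    }
  }
  cov_arr <- array(0, dim = c(nt, n, n), dimnames = list(NULL, sn, sn))
  if (tag != "RRE") {
    for (i in 1:n) for (j in i:n) {
      v <- omega * tr[, paste0("covC_", i, "_", j)]
      if (tag == "IOS") v <- v + tr[, paste0("zc_", i, "_", j)]
      cov_arr[, i, j] <- v; cov_arr[, j, i] <- v
    }
  }
  if (units == "concentrations") {
    mean_mat <- mean_mat / omega
    cov_arr <- cov_arr / omega^2
  }
  new_moments(times = t_grid, species = sn, mean = mean_mat, cov = cov_arr,
              method = tag, order = if (tag == "RRE") 1L else 2L,
              closure = "none", units = units,
              extra = list(omega = omega, states = tr))
}
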