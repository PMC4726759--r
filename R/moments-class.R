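# Shared container for moment time courses produced by FSP, the moment
# equations, the system size expansion and the method of conditional moments.

new_moments <- function(times, species, mean, cov, raw = list(),
                        central = list(), method, order, closure, units,
                        extra = list()) {
  structure(c(list(times = times, species = species, mean = mean, cov = cov,
                   raw = raw, central = central, method = method,
                   order = order, closure = closure, units = units),
              extra),
            class = "ck_moments")
}

#' @export
print.ck_moments <- function(x, ...) {
  cat("<ck_moments> ", x$method, " (order ", x$order,
      if (!is.null(x$closure) && x$closure != "none") paste0(", closure ", x$closure),
      "), ", length(x$times), " times, species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean time courses of a moment trajectory
#' @param traj a `ck_moments`
#' @return matrix times x species
#' @export
moment_means <- function(traj) traj$mean

#' Covariance time courses of a moment trajectory
#' @param traj a `ck_moments`
#' @param t optionally a single time on the grid; returns that covariance
#'   matrix instead of the full array
#' @return array times x species x species, or one matrix
#' @export
moment_covariances <- function(traj, t = NULL) {
  if (is.null(t)) return(traj$cov)
  i <- match(t, traj$times)
  if (is.na(i)) stop("time ", t, " is not on the trajectory grid")
  m <- traj$cov[i, , ]
  matrix(m, ncol = length(traj$species),
         dimnames = list(traj$species, traj$species))
}

#' Variance time course of one species
#' @param traj a `ck_moments`
#' @param species species name
#' @return numeric vector over the time grid
#' @export
moment_variance <- function(traj, species) {
  i <- match(species, traj$species)
  if (is.na(i)) stop("unknown species: ", species)
  traj$cov[, i, i]
}

#' Export a moment trajectory as a long-format data frame
#'
#' One row per (time, moment index); the multi-index is recorded over the
#' species ordering of the trajectory.
#'
#' @param traj a `ck_moments`
#' @param path optional CSV path; when given, the table is also written there
#' @return data frame with columns `time`, `index`, `kind`, `value`,
#'   `method`, `order`, `closure`
#' @export
moments_to_table <- function(traj, path = NULL) {
  n <- length(traj$species)
  rows <- list()
  add <- function(idx, kind, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time = traj$times, index = p_key(idx), kind = kind, value = values,
      method = traj$method, order = traj$order,
      closure = if (is.null(traj$closure)) "none" else traj$closure)
  }
  for (i in seq_len(n)) {
    e <- integer(n); e[i] <- 1L
    add(e, "mean", traj$mean[, i])
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      e <- integer(n); e[i] <- e[i] + 1L; e[j] <- e[j] + 1L
      add(e, "covariance", traj$cov[, i, j])
    }
  }
  for (key in names(traj$raw)) {
    rows[[length(rows) + 1L]] <- data.frame(
      time = traj$times, index = key, kind = "raw", value = traj$raw[[key]],
      method = traj$method, order = traj$order,
      closure = if (is.null(traj$closure)) "none" else traj$closure)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Correlation and partial-correlation maps
#'
#' Per output time: the correlation matrix (covariance normalized by the
#' standard deviations) and the partial-correlation matrix (negated
#' off-diagonal of the normalized inverse covariance).  Entries that are
#' undefined because a variance vanishes are reported as `NA`, never as 0;
#' a singular covariance yields `NULL` partial correlations with a
#' diagnostic attribute.
#'
#' @param traj a `ck_moments` of order >= 2
#' @return list with one element per time: `list(correlation, partial)`
#' @export
correlation_maps <- function(traj) {
  if (traj$order < 2L) stop("correlation maps require a trajectory of order >= 2")
  n <- length(traj$species)
  lapply(seq_along(traj$times), function(k) {
    C <- matrix(traj$cov[k, , ], n, n,
                dimnames = list(traj$species, traj$species))
    sds <- sqrt(pmax(diag(C), 0))
    corr <- matrix(NA_real_, n, n, dimnames = dimnames(C))
    ok <- sds > 0
    corr[ok, ok] <- C[ok, ok] / outer(sds[ok], sds[ok])
    diag(corr)[ok] <- 1
    partial <- tryCatch({
      P <- solve(C)
      d <- sqrt(diag(P))
      pc <- -P / outer(d, d)
      diag(pc) <- 1
      dimnames(pc) <- dimnames(C)
      pc
    }, error = function(e) {
      structure(list(), diagnostic = paste("singular covariance:",
                                           conditionMessage(e)))
    })
    list(correlation = corr, partial = partial)
  })
}
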