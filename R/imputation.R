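#' Patients-by-schedule trajectory matrix
#'
#' Wide representation of the log-biomarker series: one row per patient, one
#' column per schedule month, `NA` marking missing measurements.  Every row
#' must retain at least one observed entry.
#'
#' @param values numeric matrix (patients x schedule) with `NA` for missing.
#' @param times measurement schedule in months, strictly increasing,
#'   length >= 2.
#' @param ids optional patient identifiers (defaults to row numbers).
#' @return an object of class `trajectory_matrix`.
#' @export
trajectory_matrix <- function(values, times, ids = NULL) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with length >= 2")
  if (ncol(values) != length(times))
    stop("'values' must have one column per schedule time")
  if (any(rowSums(!is.na(values)) == 0L))
    stop("every row must have at least one observed entry")
  if (is.null(ids)) ids <- seq_len(nrow(values))
  structure(list(ids = ids, times = times, values = unname(values),
                 mask = !is.na(values)),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat("<trajectory_matrix>", nrow(x$values), "patients x",
      length(x$times), "times;", sum(!x$mask), "missing\n")
  invisible(x)
}

#' Build a trajectory matrix from a long table
#'
#' @param long data frame with columns `id`, `t`, `y`; times must lie on
#'   `schedule`.
#' @param schedule the measurement schedule in months.
#' @return a [trajectory_matrix()].
#' @export
long_to_trajectory <- function(long, schedule) {
  ids <- sort(unique(long$id))
  vis <- match(long$t, schedule)
  if (anyNA(vis)) stop("longitudinal times must lie on the schedule")
  V <- matrix(NA_real_, length(ids), length(schedule))
  V[cbind(match(long$id, ids), vis)] <- long$y
  trajectory_matrix(V, schedule, ids)
}

#' Convert a trajectory matrix to long format
#'
#' Missing entries are dropped.
#'
#' @param M a [trajectory_matrix()].
#' @return data frame with columns `id`, `t`, `y`.
#' @export
trajectory_to_long <- function(M) {
  obs <- which(t(!is.na(M$values)), arr.ind = TRUE)  # time-major per patient
  data.frame(id = M$ids[obs[, 2]], t = M$times[obs[, 1]],
             y = t(M$values)[obs])
}

## slopes of piecewise-linear series: rows of X over consecutive segments
series_slopes <- function(X, times) {
  dt <- diff(times)
  if (any(dt == 0)) stop("duplicate time points give zero-length segments")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  (X[, -1L, drop = FALSE] - X[, -ncol(X), drop = FALSE]) /
    rep(dt, each = nrow(X))
}

#' Short-time-series (slope) distance
#'
#' Treats both series as piecewise-linear functions on the schedule and
#' returns the Euclidean distance between their segment-slope vectors:
#' \deqn{d^2(x, v) = \sum_k \left(\frac{x_{k+1}-x_k}{t_{k+1}-t_k}
#'       - \frac{v_{k+1}-v_k}{t_{k+1}-t_k}\right)^2.}
#' The distance ignores vertical shifts of a whole series.
#'
#' @param x,v complete numeric series on the schedule.
#' @param times the schedule (months).
#' @return non-negative distance.
#' @export
sts_distance <- function(x, v, times) {
  if (length(x) != length(times) || length(v) != length(times))
    stop("'x', 'v' and 'times' must have equal length")
  if (anyNA(x) || anyNA(v)) stop("series must be complete")
  sqrt(sum((series_slopes(x, times) - series_slopes(v, times))^2))
}

## Deterministic farthest-point seeding on slope vectors.  Ties are broken by
## a canonical (lexicographic) ordering of the slope rows so the result does
## not depend on patient order.
init_prototypes <- function(SX, c) {
  n <- nrow(SX)
  canon <- do.call(order, as.data.frame(SX))
  rank_canon <- order(canon)
  pick_max <- function(d) {
    cand <- which(d >= max(d) - 1e-12)
    cand[which.min(rank_canon[cand])]
  }
  centre <- colMeans(SX)
  d <- rowSums(sweep(SX, 2, centre)^2)
  sel <- pick_max(d)
  while (length(sel) < c) {
    dmin <- apply(SX, 1, function(r)
      min(colSums((t(SX[sel, , drop = FALSE]) - r)^2)))
    dmin[sel] <- -Inf
    sel <- c(sel, pick_max(dmin))
  }
  sel
}

## Membership update of fuzzy c-means on squared distances, with the
## standard singularity rule: an exactly-zero distance receives the whole
## membership (first such cluster).
update_memberships <- function(D2, m_fuzz) {
  c <- nrow(D2); n <- ncol(D2)
  U <- matrix(0, c, n)
  for (k in seq_len(n)) {
    d <- D2[, k]
    zero <- which(d <= .Machine$double.eps)
    if (length(zero)) {
      U[zero[1], k] <- 1
    } else {
      w <- (d / min(d))^(-1 / (m_fuzz - 1))
      U[, k] <- w / sum(w)
    }
  }
  U
}

## One engine behind fsts_cluster() and ocs_impute(): alternating
## minimization over memberships U, prototypes V and (optionally) the
## missing entries of X.  Each step minimizes the common objective
## J = sum_{i,k} u_ik^m d^2(x_k, v_i) exactly, so J is non-increasing.
fsts_engine <- function(M, c, m_fuzz, seed = 1L, tol = 1e-6,
                        max_iter = 500L, impute = FALSE) {
  X <- M$values
  times <- M$times
  n <- nrow(X); Tn <- ncol(X)
  if (c < 1 || c > n) stop("'c' must satisfy 1 <= c <= n")
  if (m_fuzz <= 1) stop("the fuzzifier must exceed 1")
  mask <- M$mask
  if (impute && any(!mask)) {
    ## start missing entries from carry-forward / back-fill
    for (k in seq_len(n)) {
      xi <- X[k, ]
      xi <- locf_fill(xi)
      if (anyNA(xi)) xi[is.na(xi)] <- xi[which(!is.na(xi))[1]]
      X[k, ] <- xi
    }
  } else if (anyNA(X)) {
    stop("fsts_cluster() needs a complete trajectory matrix; use ocs_impute()")
  }
  dt <- diff(times)
  ## slope operator S: (Tn-1) x Tn, S x = segment slopes of x
  S <- matrix(0, Tn - 1L, Tn)
  S[cbind(seq_len(Tn - 1L), seq_len(Tn - 1L))] <- -1 / dt
  S[cbind(seq_len(Tn - 1L), 2:Tn)] <- 1 / dt
  SX <- series_slopes(X, times)
  degenerate <- c > 1L && max(stats::dist(SX)) <= 1e-12
  if (degenerate)
    warning("all series have identical slope patterns; clusters are degenerate")
  V <- X[init_prototypes(SX, c), , drop = FALSE]
  obj_trace <- numeric(0)
  d2 <- function(SX, SV) {
    ## c x n squared slope distances
    cross <- SV %*% t(SX)
    outer(rowSums(SV^2), rowSums(SX^2), "+") - 2 * cross
  }
  for (iter in seq_len(max_iter)) {
    V_old <- V
    X_old <- X
    SV <- series_slopes(V, times)
    D2 <- pmax(d2(SX, SV), 0)
    U <- update_memberships(D2, m_fuzz)
    Um <- U^m_fuzz
    ## prototype update: slope part is the membership-weighted mean slope;
    ## the level is anchored at the membership-weighted mean level.
    wsum <- rowSums(Um)
    empty <- wsum <= .Machine$double.eps
    wsum[empty] <- 1
    SV <- (Um %*% SX) / wsum
    lev <- (Um %*% rowMeans(X)) / wsum
    V <- cbind(0, t(apply(SV * rep(dt, each = c), 1, cumsum)))
    if (Tn == 2L) V <- cbind(0, SV * dt)
    V <- V - rowMeans(V) + as.vector(lev)
    V[empty, ] <- V_old[empty, , drop = FALSE]  # cluster with no weight
    if (impute && any(!mask)) {
      SVn <- series_slopes(V, times)
      for (k in seq_len(n)) {
        mis <- !mask[k, ]
        if (!any(mis)) next
        w <- Um[, k]
        Wk <- sum(w)
        g <- colSums(SVn * w)                       # sum_i w_i S v_i
        Sm <- S[, mis, drop = FALSE]
        So <- S[, !mis, drop = FALSE]
        rhs <- crossprod(Sm, g - Wk * So %*% X[k, !mis])
        A <- Wk * crossprod(Sm)
        X[k, mis] <- solve(A, rhs)
      }
      SX <- series_slopes(X, times)
    }
    D2 <- pmax(d2(SX, series_slopes(V, times)), 0)
    obj_trace <- c(obj_trace, sum(Um * D2))
    if (max(abs(V - V_old)) < tol && max(abs(X - X_old)) < tol) break
  }
  SV <- series_slopes(V, times)
  D2 <- pmax(d2(SX, SV), 0)
  U <- update_memberships(D2, m_fuzz)
  part <- structure(list(c = c, m_fuzz = m_fuzz, U = U, V = V,
                         objective_trace = obj_trace,
                         degenerate = degenerate,
                         n_iter = iter, converged = iter < max_iter),
                    class = "fuzzy_partition")
  list(partition = part,
       matrix = trajectory_matrix(X, times, M$ids))
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat("<fuzzy_partition> c =", x$c, " m =", x$m_fuzz,
      " iterations =", x$n_iter, "\n")
  hard <- colSums(x$U >= 0.75) > 0
  cat("  series with membership >= 0.75 in some cluster:",
      sum(hard), "/", ncol(x$U), "\n")
  invisible(x)
}

#' Fuzzy short-time-series clustering
#'
#' Fuzzy c-means on the slope representation of the series (the STS
#' distance of [sts_distance()]): memberships follow the standard fuzzy
#' c-means update, prototypes minimize the membership-weighted sum of
#' squared slope distances (their slopes are membership-weighted mean
#' slopes) and are anchored so that each prototype's mean level equals the
#' membership-weighted mean level of the data.  Defaults follow the
#' bone-metastasis analysis: `c = 6` clusters, fuzzifier `m_fuzz = 1.3`.
#'
#' @param M a complete [trajectory_matrix()].
#' @param c number of clusters.
#' @param m_fuzz fuzzifier, > 1.
#' @param seed accepted for interface stability; the procedure is
#'   deterministic (farthest-point seeding with canonical tie-breaks).
#' @param tol convergence tolerance on the maximum absolute prototype
#'   change.
#' @param max_iter iteration cap.
#' @return a `fuzzy_partition` with memberships `U` (c x n), prototypes `V`
#'   (c x T) and the per-iteration objective trace.
#' @export
fsts_cluster <- function(M, c = 6L, m_fuzz = 1.3, seed = 1L,
                         tol = 1e-6, max_iter = 500L) {
  fsts_engine(M, c, m_fuzz, seed, tol, max_iter, impute = FALSE)$partition
}

#' Impute missing trajectory entries by the optimal completion strategy
#'
#' Runs the fuzzy short-time-series clustering of [fsts_cluster()] while
#' treating the missing entries as free variables of the clustering
#' objective: each cycle updates memberships, prototypes and then the
#' missing values exactly (a small linear solve per patient), so the
#' objective never increases.  Observed entries are never altered.  With no
#' missing entries the result coincides with [fsts_cluster()].
#'
#' @inheritParams fsts_cluster
#' @param M a [trajectory_matrix()]; every row needs at least one observed
#'   entry.
#' @return list with `matrix` (the completed [trajectory_matrix()]) and
#'   `partition` (the final `fuzzy_partition`).
#' @export
ocs_impute <- function(M, c = 6L, m_fuzz = 1.3, seed = 1L,
                       tol = 1e-6, max_iter = 500L) {
  fsts_engine(M, c, m_fuzz, seed, tol, max_iter, impute = TRUE)
}

locf_fill <- function(x) {
  obs <- !is.na(x)
  if (!any(obs)) return(x)
  idx <- cummax(ifelse(obs, seq_along(x), 0L))
  out <- ifelse(idx > 0L, x[pmax(idx, 1L)], NA_real_)
  out
}

#' Write a trajectory matrix as a wide CSV
#'
#' One row per patient: an `id` column plus one column per schedule month
#' (named `m<month>`); missing entries become empty fields.
#'
#' @param M a [trajectory_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(M, path) {
  df <- data.frame(id = M$ids, M$values)
  names(df)[-1] <- paste0("m", M$times)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide-grid trajectory CSV
#'
#' Inverse of [write_trajectory()]: expects an `id` column and one column
#' per schedule month named `m<month>`.
#'
#' @param path CSV file path.
#' @return a [trajectory_matrix()].
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  mcols <- grep("^m", names(df), value = TRUE)
  times <- as.numeric(sub("^m", "", mcols))
  ord <- order(times)
  trajectory_matrix(as.matrix(df[, mcols[ord], drop = FALSE]),
                    times[ord], ids = df$id)
}

#' Last-observation-carried-forward imputation
#'
#' Replaces each missing entry by the most recent observed value at an
#' earlier schedule time for the same patient.  Entries before a patient's
#' first observation stay missing (no backward fill) and are dropped when
#' converting to long format.
#'
#' @param M a [trajectory_matrix()].
#' @return the imputed [trajectory_matrix()].
#' @export
locf_impute <- function(M) {
  V <- t(apply(M$values, 1, locf_fill))
  trajectory_matrix(V, M$times, M$ids)
}
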