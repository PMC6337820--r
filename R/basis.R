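#' Longitudinal mean-structure basis specification
#'
#' Describes one of the mean structures used for the log-biomarker
#' trajectory: a two-parameter rational decay \eqn{1/(t+\delta)^\eta}, an
#' exponential decay \eqn{\exp(-\delta t)}, a natural cubic spline with
#' interior knots, or a constant (intercept-only) structure.  The same basis
#' is used for the fixed and the random effects (the \eqn{z = x} convention),
#' so the basis dimension equals both the length of the fixed-effects vector
#' and the random-effects dimension.
#'
#' @param kind one of `"rational"`, `"exponential"`, `"spline"`, `"constant"`.
#' @param delta positive tuning parameter (rational and exponential kinds),
#'   in 1/months for the exponential rate and months for the rational shift.
#' @param eta positive exponent of the rational form.
#' @param knots interior knot locations in months (spline kind), strictly
#'   increasing and strictly inside `boundary`.
#' @param boundary length-2 boundary knots `(t0, tf)` in months (spline kind).
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("rational", "exponential", "spline", "constant"),
                       delta = NULL, eta = NULL,
                       knots = NULL, boundary = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("rational", "exponential")) {
    if (is.null(delta) || !is.finite(delta) || delta <= 0)
      stop("'delta' must be a positive number for the ", kind, " basis")
  }
  if (kind == "rational") {
    if (is.null(eta) || !is.finite(eta) || eta <= 0)
      stop("'eta' must be a positive number for the rational basis")
  }
  if (kind == "spline") {
    if (is.null(boundary) || length(boundary) != 2L || diff(boundary) <= 0)
      stop("'boundary' must be an increasing pair (t0, tf)")
    if (is.null(knots) || length(knots) < 1L)
      stop("spline basis needs at least one interior knot")
    knots <- sort(as.numeric(knots))
    if (any(diff(knots) <= 0)) stop("interior knots must be strictly increasing")
    if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
      stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(list(kind = kind, delta = delta, eta = eta,
                 knots = knots, boundary = boundary),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec>", x$kind, "- dimension", basis_dim(x), "\n")
  if (x$kind == "rational")
    cat("  delta =", x$delta, " eta =", x$eta, "\n")
  if (x$kind == "exponential")
    cat("  delta =", x$delta, "\n")
  if (x$kind == "spline")
    cat("  knots =", paste(x$knots, collapse = ", "),
        " boundary = (", x$boundary[1], ",", x$boundary[2], ")\n")
  invisible(x)
}

#' Dimension of a basis
#'
#' @param spec a [basis_spec()].
#' @return integer basis dimension (columns of the design matrix).
#' @export
basis_dim <- function(spec) {
  switch(spec$kind,
         constant = 1L,
         rational = 2L,
         exponential = 2L,
         spline = length(spec$knots) + 2L)
}

#' Evaluate a parametric (rational or exponential) basis
#'
#' Returns the design rows \eqn{(1, (t+\delta)^{-\eta})} for the rational
#' kind or \eqn{(1, e^{-\delta t})} for the exponential kind.
#'
#' @param t vector of times in months.
#' @param spec a [basis_spec()] of kind `"rational"` or `"exponential"`.
#' @return numeric matrix, `length(t)` rows by 2 columns.
#' @export
parametric_basis <- function(t, spec) {
  if (!spec$kind %in% c("rational", "exponential"))
    stop("parametric_basis() needs a rational or exponential basis_spec")
  t <- as.numeric(t)
  col2 <- switch(spec$kind,
                 rational = (t + spec$delta)^(-spec$eta),
                 exponential = exp(-spec$delta * t))
  cbind(1, col2, deparse.level = 0)
}

#' Evaluate the natural cubic spline basis
#'
#' Intercept column plus `length(knots) + 1` natural cubic spline basis
#' functions (linear beyond the boundary knots, continuous second
#' derivatives).  Evaluation outside the boundary knots extrapolates
#' linearly, with a warning.
#'
#' @param t vector of times in months.
#' @param spec a [basis_spec()] of kind `"spline"`.
#' @return numeric matrix, `length(t)` rows by `length(knots) + 2` columns.
#' @export
natural_cubic_basis <- function(t, spec) {
  if (spec$kind != "spline")
    stop("natural_cubic_basis() needs a spline basis_spec")
  t <- as.numeric(t)
  if (any(t < spec$boundary[1] - 1e-9 | t > spec$boundary[2] + 1e-9))
    warning("evaluating the natural cubic basis outside its boundary knots; ",
            "extrapolating linearly")
  B <- splines::ns(t, knots = spec$knots, Boundary.knots = spec$boundary)
  unname(cbind(1, B[, , drop = FALSE]))
}

#' Design matrix for any basis kind
#'
#' @param t vector of times in months.
#' @param spec a [basis_spec()].
#' @return numeric matrix with [basis_dim()] columns.
#' @export
basis_matrix <- function(t, spec) {
  switch(spec$kind,
         constant = matrix(1, length(t), 1L),
         rational = parametric_basis(t, spec),
         exponential = parametric_basis(t, spec),
         spline = natural_cubic_basis(t, spec))
}
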