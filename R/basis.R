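#' Cubic M-spline basis for baseline-hazard estimation
#'
#' Builds a non-negative M-spline basis on the interval spanned by the
#' finite positive observed survival times. Each basis function
#' \eqn{\psi_u} is normalised to integrate to one over the support, so the
#' baseline hazard \eqn{h_0(t) = \sum_u \theta_u \psi_u(t)} is non-negative
#' whenever every coefficient \eqn{\theta_u \ge 0}, and the cumulative
#' basis \eqn{\Psi_u(t) = \int_0^t \psi_u(s)\,ds} (an I-spline) increases
#' from \eqn{\Psi_u(a) = 0} to \eqn{\Psi_u(b) = 1}.
#'
#' The basis dimension defaults to the cube-root rule
#' \eqn{m = \max(\mathrm{order}, \mathrm{round}(n_0^{1/3}))} where
#' \eqn{n_0} is the number of non-right-censored subjects; interior knots
#' are placed at equally spaced quantiles of the observed times and the
#' boundary knots at the minimum and maximum finite observed times.
#' Evaluation outside \eqn{[a, b]} clamps to the nearest boundary.
#'
#' The curvature penalty matrix \eqn{R} with entries
#' \eqn{r_{uv} = \int \psi_u''(t)\psi_v''(t)\,dt} is stored in the object;
#' for cubic splines the integrand is piecewise quadratic, so two-point
#' Gauss-Legendre quadrature per inter-knot segment integrates it exactly.
#'
#' @param times numeric vector of observed interval endpoints; zeros and
#'   non-finite values are dropped before use.
#' @param n0 number of non-right-censored subjects (drives the basis
#'   dimension rule). Required unless `m` is given.
#' @param order spline order (4 = cubic, the default). Must be >= 3 so
#'   that second derivatives exist piecewise.
#' @param m optional override for the total number of basis functions;
#'   must be at least `order` (the `m = order` basis has no interior
#'   knots).
#' @return An object of class `mspline_basis` with elements `a`, `b`,
#'   `order`, `m`, `knots` (interior knots), and penalty matrix `R`.
#' @examples
#' b <- mspline_basis(c(0.4, 1.2, 2.0, 3.5), n0 = 27)
#' colSums(basis_psi(b, seq(b$a, b$b, length.out = 5)))
#' @export
mspline_basis <- function(times, n0 = NULL, order = 4L, m = NULL) {
  order <- as.integer(order)
  if (order < 3L)
    stop("unsupported order: need order >= 3 for a curvature penalty")
  tt <- times[is.finite(times) & times > 0]
  if (length(tt) == 0L)
    stop("no finite positive times available to build a basis")
  a <- min(tt)
  b <- max(tt)
  if (a == b)
    stop("degenerate support: all observed times are identical")
  if (is.null(m)) {
    if (is.null(n0)) stop("either 'n0' or 'm' must be supplied")
    if (n0 < 1) stop("'n0' must be at least 1")
    m <- max(order, as.integer(round(n0^(1 / 3))))
  } else {
    m <- as.integer(m)
    if (is.na(m) || m < 1L) stop("invalid 'm': need a positive integer")
    if (m < order)
      stop("'m' must be at least the spline order (", order, ")")
  }
  n_int <- m - order
  if (n_int > 0L) {
    probs <- seq_len(n_int) / (n_int + 1)
    kn <- unname(stats::quantile(tt, probs, type = 7))
    kn <- unique(kn[kn > a & kn < b])
    if (length(kn) < n_int) {
      # ties in the observed times collapsed some quantiles; shrink m
      m <- order + length(kn)
      n_int <- length(kn)
    }
  } else {
    kn <- numeric(0)
  }
  obj <- structure(
    list(a = a, b = b, order = order, m = m, knots = kn,
         aug = c(rep(a, order), kn, rep(b, order)),
         breaks = c(a, kn, b)),
    class = "mspline_basis")
  obj$Psi_breaks <- .psi_cum_breaks(obj)
  obj$R <- .penalty_matrix(obj)
  obj
}

#' Evaluate the M-spline basis functions
#'
#' @param basis an [mspline_basis()] object.
#' @param t numeric vector of times; values outside the support are
#'   clamped to the nearest boundary.
#' @param deriv derivative order (0, 1 or 2).
#' @return a `length(t)` by `m` matrix of \eqn{\psi_u^{(deriv)}(t)}.
#' @export
basis_psi <- function(basis, t, deriv = 0L) {
  x <- pmin(pmax(t, basis$a), basis$b)
  D <- splines::splineDesign(basis$aug, x, ord = basis$order,
                             derivs = rep(as.integer(deriv), length(x)))
  sc <- basis$order /
    (basis$aug[seq_len(basis$m) + basis$order] - basis$aug[seq_len(basis$m)])
  D * rep(sc, each = nrow(D))
}

#' Evaluate the cumulative (I-spline) basis functions
#'
#' Returns \eqn{\Psi_u(t) = \int_a^t \psi_u(s) ds}; since \eqn{\psi_u}
#' vanishes below the support and each basis function integrates to one,
#' \eqn{\Psi_u} runs from 0 at `basis$a` to 1 at `basis$b` and is held at
#' those values beyond the boundaries.
#'
#' @inheritParams basis_psi
#' @return a `length(t)` by `m` matrix of \eqn{\Psi_u(t)}.
#' @export
basis_Psi <- function(basis, t) {
  x <- pmin(pmax(t, basis$a), basis$b)
  j <- findInterval(x, basis$breaks, rightmost.closed = TRUE)
  basis$Psi_breaks[j, , drop = FALSE] + .seg_integral(basis, basis$breaks[j], x)
}

# Exact integral of each psi_u over [lo, hi] where no knot lies strictly
# inside (lo, hi): two-point Gauss-Legendre, exact for cubics.
.seg_integral <- function(basis, lo, hi) {
  half <- (hi - lo) / 2
  mid <- (lo + hi) / 2
  off <- half / sqrt(3)
  half * (basis_psi(basis, mid - off) + basis_psi(basis, mid + off))
}

.psi_cum_breaks <- function(basis) {
  nb <- length(basis$breaks)
  out <- matrix(0, nb, basis$m)
  for (j in seq_len(nb - 1L)) {
    out[j + 1L, ] <- out[j, ] +
      .seg_integral(basis, basis$breaks[j], basis$breaks[j + 1L])
  }
  out
}

# r_uv = int psi_u'' psi_v'': psi'' is piecewise linear for cubic splines,
# hence the integrand is piecewise quadratic and 2-point Gauss-Legendre per
# inter-knot segment is exact.
.penalty_matrix <- function(basis) {
  m <- basis$m
  R <- matrix(0, m, m)
  nb <- length(basis$breaks)
  for (j in seq_len(nb - 1L)) {
    lo <- basis$breaks[j]; hi <- basis$breaks[j + 1L]
    half <- (hi - lo) / 2
    mid <- (lo + hi) / 2
    off <- half / sqrt(3)
    d1 <- basis_psi(basis, mid - off, deriv = 2L)
    d2 <- basis_psi(basis, mid + off, deriv = 2L)
    R <- R + half * (crossprod(d1) + crossprod(d2))
  }
  (R + t(R)) / 2
}

#' @export
print.mspline_basis <- function(x, ...) {
  cat("M-spline basis (order ", x$order, ", m = ", x$m, ")\n", sep = "")
  cat("  support: [", format(x$a), ", ", format(x$b), "]\n", sep = "")
  if (length(x$knots))
    cat("  interior knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  else
    cat("  interior knots: none\n")
  invisible(x)
}

# JSON-serialisable summary (knots, order, m) for reproducibility records.
basis_summary <- function(basis) {
  list(order = basis$order, m = basis$m, a = basis$a, b = basis$b,
       interior_knots = as.numeric(basis$knots))
}

.basis_from_summary <- function(s) {
  kn <- as.numeric(s$interior_knots)
  obj <- structure(
    list(a = s$a, b = s$b, order = as.integer(s$order), m = as.integer(s$m),
         knots = kn,
         aug = c(rep(s$a, s$order), kn, rep(s$b, s$order)),
         breaks = c(s$a, kn, s$b)),
    class = "mspline_basis")
  obj$Psi_breaks <- .psi_cum_breaks(obj)
  obj$R <- .penalty_matrix(obj)
  obj
}
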