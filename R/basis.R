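#' B-spline basis over the dementia-severity axis
#'
#' Builds the spline basis used to represent severity-varying coefficient
#' functions \eqn{\beta_j(t) = \sum_l \gamma_{jl} B_l(t)}.  With the default
#' configuration (`L = 4`, cubic) there are no interior knots, so the basis
#' spans the cubic polynomials on the observed severity range expressed in the
#' Bernstein-like B-spline form.
#'
#' @param t_values numeric vector of severities (CDR-SB units) whose range
#'   defines the domain, unless `domain` is given explicitly.
#' @param L number of basis functions.
#' @param degree spline degree (3 = cubic).
#' @param domain optional length-2 numeric, the closed severity interval.
#' @return object of class `bspline_basis` with fields `degree`, `knots`
#'   (full knot vector with boundary multiplicity `degree + 1`), `L`, `domain`.
#' @examples
#' b <- bspline_basis(c(0, 3, 18))
#' rowSums(eval_basis(b, c(0, 5.5, 18)))  # partition of unity
#' @export
bspline_basis <- function(t_values = NULL, L = 4L, degree = 3L,
                          domain = NULL) {
  if (is.null(domain)) {
    if (is.null(t_values) || !length(t_values)) {
      stop("either 't_values' or 'domain' must be supplied")
    }
    domain <- range(t_values)
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) ||
      domain[2] <= domain[1]) {
    stop("severity values span a degenerate interval; need t_max > t_min")
  }
  L <- as.integer(L)
  degree <- as.integer(degree)
  if (L < degree + 1L) stop("need L >= degree + 1")
  n_interior <- L - degree - 1L
  interior <- if (n_interior > 0L) {
    seq(domain[1], domain[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  knots <- c(rep(domain[1], degree + 1L), interior, rep(domain[2], degree + 1L))
  structure(list(degree = degree, knots = knots, L = L, domain = domain),
            class = "bspline_basis")
}

#' Evaluate a B-spline basis
#'
#' @param basis a [bspline_basis()].
#' @param t numeric severities inside the basis domain.
#' @return numeric matrix, `length(t)` rows by `basis$L` columns.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "bspline_basis"))
  t <- as.numeric(t)
  eps <- 1e-9 * max(1, abs(basis$domain))
  if (any(t < basis$domain[1] - eps | t > basis$domain[2] + eps)) {
    stop("severity grid extends outside the basis domain [",
         basis$domain[1], ", ", basis$domain[2], "]")
  }
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  B <- splines::splineDesign(basis$knots, t, ord = basis$degree + 1L)
  colnames(B) <- paste0("B", seq_len(basis$L))
  B
}

#' Gauss-Legendre nodes and weights on an interval
#'
#' Golub-Welsch computation from the Jacobi matrix of the Legendre
#' recurrence; used for exact integration of spline products.
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with `nodes` and `weights`.
#' @export
gauss_legendre <- function(n, a = -1, b = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1L, b > a)
  if (n == 1L) {
    x <- 0
    w <- 2
  } else {
    i <- seq_len(n - 1L)
    off <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- off
    J[cbind(i + 1L, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1L, ]^2
    ord <- order(x)
    x <- x[ord]
    w <- w[ord]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Penalty Gram matrix of a basis
#'
#' Computes \eqn{\Omega_{lm} = \int B_l(t) B_m(t)\,dt} (Lebesgue measure on
#' the basis domain) by per-knot-span Gauss-Legendre quadrature, which is
#' exact for the polynomial integrand.  For any coefficient vector
#' \eqn{\gamma}, \eqn{\gamma^\top \Omega \gamma = \int \beta^2(t) dt}, the
#' quantity inside the functional group-LASSO penalty.
#'
#' @param basis a [bspline_basis()].
#' @return list of class `penalty_gram` with `omega` (L x L, positive
#'   definite) and its upper-triangular Cholesky factor `R` (`omega = R'R`).
#' @export
penalty_gram <- function(basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  kn <- unique(basis$knots)
  L <- basis$L
  omega <- matrix(0, L, L)
  n_gl <- basis$degree + 1L  # exact for degree 2*degree polynomials
  for (s in seq_len(length(kn) - 1L)) {
    gl <- gauss_legendre(n_gl, kn[s], kn[s + 1L])
    B <- eval_basis(basis, gl$nodes)
    omega <- omega + crossprod(B * sqrt(gl$weights))
  }
  omega <- (omega + t(omega)) / 2
  R <- chol(omega)
  structure(list(omega = omega, R = R), class = "penalty_gram")
}
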