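#' Polyexponential curve
#'
#' A finite sum of scaled exponentials \eqn{g(t) = \sum_j \lambda_j e^{\mu_j t}},
#' the standard parametrization of the arterial plasma input function
#' \eqn{C_P} in compartmental PET modelling. The degree-0 curve is the zero
#' function.
#'
#' @param lambdas numeric vector of coefficients (activity-concentration units).
#' @param mus numeric vector of exponents (1/min); must be pairwise distinct.
#' @return An object of class `petkin_polyexp` with fields `lambdas`, `mus`,
#'   `degree`.
#' @examples
#' cp <- polyexp(c(-10.9136, 9.545, 0.7331, 0.6355),
#'               c(-13.4522, -3.2672, -0.1532, -0.0106))
#' eval_polyexp(cp, 0)  # coefficients sum to ~0
#' @export
polyexp <- function(lambdas = numeric(0), mus = numeric(0)) {
  lambdas <- as.numeric(lambdas)
  mus <- as.numeric(mus)
  if (length(lambdas) != length(mus)) {
    stop("`lambdas` and `mus` must have equal length", call. = FALSE)
  }
  if (length(mus) > 1) {
    d <- abs(outer(mus, mus, "-"))
    tol <- 1e-12 * max(1, abs(mus))
    if (any(d[upper.tri(d)] <= tol)) {
      stop("exponents `mus` must be pairwise distinct", call. = FALSE)
    }
  }
  structure(list(lambdas = lambdas, mus = mus, degree = length(lambdas)),
            class = "petkin_polyexp")
}

#' @export
print.petkin_polyexp <- function(x, ...) {
  if (x$degree == 0) {
    cat("<polyexp> degree 0 (zero function)\n")
  } else {
    cat("<polyexp> degree", x$degree, "\n")
    for (j in seq_len(x$degree)) {
      cat(sprintf("  %+.6g * exp(%+.6g t)\n", x$lambdas[j], x$mus[j]))
    }
  }
  invisible(x)
}

#' Parent plasma fraction parameters (biexponential model)
#'
#' The biexponential parent-fraction model
#' \eqn{f(t) = A e^{\xi_1 t} + (1-A) e^{\xi_2 t}} with \eqn{f(0) = 1} by
#' construction. Its uniqueness degree is 4, i.e. four whole-blood samples
#' suffice to pin the model within its family.
#'
#' @param A amplitude in `[0, Inf)` (dimensionless).
#' @param xi1,xi2 exponents in `(-Inf, 0]` (1/min).
#' @return An object of class `petkin_fraction`.
#' @export
plasma_fraction <- function(A, xi1, xi2) {
  if (A < 0) stop("`A` must be >= 0", call. = FALSE)
  if (xi1 > 0 || xi2 > 0) stop("`xi1` and `xi2` must be <= 0", call. = FALSE)
  structure(list(A = as.numeric(A), xi1 = as.numeric(xi1),
                 xi2 = as.numeric(xi2)),
            class = "petkin_fraction")
}

#' Kinetic rate constants of one tissue region
#'
#' Rates of the irreversible two-tissue compartment model: `K1`
#' (plasma to free tissue), `k2` (free tissue to plasma), `k3` (free to
#' bound/trapped), all in 1/min; the model has no `k4`.
#'
#' @param K1,k2,k3 positive rates (1/min).
#' @param epsilon lower domain bound; rates below it are rejected.
#' @return An object of class `petkin_kinetics`.
#' @export
kinetic_params <- function(K1, k2, k3, epsilon = 1e-3) {
  v <- c(K1 = as.numeric(K1), k2 = as.numeric(k2), k3 = as.numeric(k3))
  if (any(!is.finite(v))) stop("kinetic rates must be finite", call. = FALSE)
  if (any(v < epsilon)) {
    stop(sprintf("kinetic rates must be >= epsilon = %g", epsilon),
         call. = FALSE)
  }
  structure(as.list(v), class = "petkin_kinetics")
}

#' Joint parameter vector of the forward model
#'
#' Bundles the arterial input parameters \eqn{(\lambda, \mu)}, the parent
#' fraction parameters \eqn{m = (A, \xi_1, \xi_2)} and the kinetic rates of
#' each region. The packed ordering is
#' \eqn{(\lambda_1..\lambda_p, \mu_1..\mu_p, m_1..m_3,
#' K_1^1, k_2^1, k_3^1, \dots)}; for p = 4 and n = 4 regions the packed
#' length is 23.
#'
#' @param polyexp a [polyexp()] input curve.
#' @param fraction a [plasma_fraction()] object.
#' @param regions named list of [kinetic_params()].
#' @return An object of class `petkin_params`.
#' @export
param_vector <- function(polyexp, fraction, regions) {
  stopifnot(inherits(polyexp, "petkin_polyexp"),
            inherits(fraction, "petkin_fraction"),
            length(regions) >= 1,
            all(vapply(regions, inherits, TRUE, "petkin_kinetics")))
  if (is.null(names(regions))) {
    names(regions) <- paste0("region", seq_along(regions))
  }
  structure(list(polyexp = polyexp, fraction = fraction, regions = regions),
            class = "petkin_params")
}

#' @export
print.petkin_params <- function(x, ...) {
  cat(sprintf("<petkin_params> p = %d input terms, %d regions (packed length %d)\n",
              x$polyexp$degree, length(x$regions),
              2 * x$polyexp$degree + 3 + 3 * length(x$regions)))
  cat(sprintf("  fraction: A = %g, xi1 = %g, xi2 = %g\n",
              x$fraction$A, x$fraction$xi1, x$fraction$xi2))
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %-12s K1 = %.4f  k2 = %.4f  k3 = %.4f\n",
                nm, r$K1, r$k2, r$k3))
  }
  invisible(x)
}

#' Pack a parameter vector into a plain numeric vector
#'
#' @param pv a [param_vector()].
#' @param mode `"full"` packs all 2p + 3 + 3n entries; `"reduced"` omits the
#'   fraction block (the parent fraction is frozen at a known value), giving
#'   2p + 3n entries.
#' @return numeric vector in the canonical packing order.
#' @export
pack_params <- function(pv, mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  kin <- unlist(lapply(pv$regions, function(r) c(r$K1, r$k2, r$k3)),
                use.names = FALSE)
  m <- if (mode == "full") {
    c(pv$fraction$A, pv$fraction$xi1, pv$fraction$xi2)
  } else {
    numeric(0)
  }
  c(pv$polyexp$lambdas, pv$polyexp$mus, m, kin)
}

#' Unpack a plain numeric vector into a parameter vector
#'
#' Inverse of [pack_params()]; `pack_params(unpack_params(x, ...))` round-trips
#' exactly.
#'
#' @param x packed numeric vector.
#' @param p degree of the input-curve parametrization.
#' @param n number of regions.
#' @param mode `"full"` or `"reduced"` (see [pack_params()]).
#' @param fraction a [plasma_fraction()] supplying the frozen fraction block in
#'   reduced mode; ignored in full mode.
#' @param region_names optional character vector of region names.
#' @return A [param_vector()].
#' @export
unpack_params <- function(x, p, n, mode = c("full", "reduced"),
                          fraction = NULL, region_names = NULL) {
  mode <- match.arg(mode)
  want <- if (mode == "full") 2 * p + 3 + 3 * n else 2 * p + 3 * n
  if (length(x) != want) {
    stop(sprintf("packed length %d does not match expected %d", length(x), want),
         call. = FALSE)
  }
  lambdas <- x[seq_len(p)]
  mus <- x[p + seq_len(p)]
  if (mode == "full") {
    m <- x[2 * p + 1:3]
    frac <- structure(list(A = m[1], xi1 = m[2], xi2 = m[3]),
                      class = "petkin_fraction")
    kin <- x[(2 * p + 3 + 1):want]
  } else {
    if (is.null(fraction)) stop("reduced mode requires `fraction`", call. = FALSE)
    frac <- fraction
    kin <- x[(2 * p + 1):want]
  }
  regions <- lapply(seq_len(n), function(i) {
    structure(list(K1 = kin[3 * i - 2], k2 = kin[3 * i - 1], k3 = kin[3 * i]),
              class = "petkin_kinetics")
  })
  names(regions) <- region_names %||% paste0("region", seq_len(n))
  param_vector(polyexp(lambdas, mus), frac, regions)
}

#' Measurement schedule
#'
#' Tissue measurement times `t` (length T) and whole-blood sample times `s`
#' (length q), both in minutes and strictly increasing.
#'
#' @param t tissue measurement times (min).
#' @param s whole-blood sample times (min); defaults to `t`.
#' @return An object of class `petkin_schedule`.
#' @export
measurement_schedule <- function(t, s = t) {
  t <- as.numeric(t); s <- as.numeric(s)
  if (any(t < 0) || any(s < 0)) stop("times must be >= 0", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (length(s) > 1 && any(diff(s) <= 0)) {
    stop("`s` must be strictly increasing", call. = FALSE)
  }
  structure(list(t = t, s = s), class = "petkin_schedule")
}

#' Measurement set
#'
#' Tissue values per region (an n x T matrix, one row per region), q
#' whole-blood samples and the discrepancy noise level `delta_y`. The stacked
#' data vector used by the inversion is `(CT entries row-major, 0, ..., 0)`:
#' the whole-blood samples enter the forward operator as data, not as a data
#' block to be matched, so their block of the measurement vector is zero.
#'
#' @param ct_matrix n x T matrix of tissue activity values (rows = regions).
#' @param cwb whole-blood samples at the schedule's `s` times.
#' @param delta_y discrepancy noise level (Y-norm units), `>= 0`.
#' @param schedule the [measurement_schedule()] the values live on.
#' @return An object of class `petkin_measurements`.
#' @export
measurement_set <- function(ct_matrix, cwb, delta_y = 0, schedule = NULL) {
  ct_matrix <- as.matrix(ct_matrix)
  if (delta_y < 0) stop("`delta_y` must be >= 0", call. = FALSE)
  if (!is.null(schedule)) {
    stopifnot(ncol(ct_matrix) == length(schedule$t),
              length(cwb) == length(schedule$s))
  }
  structure(list(ct_matrix = ct_matrix, cwb = as.numeric(cwb),
                 delta_y = as.numeric(delta_y), schedule = schedule),
            class = "petkin_measurements")
}

#' Stack a measurement set into the data vector y
#'
#' @param ms a [measurement_set()].
#' @return numeric vector of length `n*T + q` (tissue block row-major by
#'   region, then a zero block for the whole-blood consistency equations).
#' @export
stack_measurements <- function(ms) {
  c(as.vector(t(ms$ct_matrix)), rep(0, length(ms$cwb)))
}

#' Canonicalize the term order of a packed parameter vector
#'
#' A polyexponential input curve is unique only up to re-indexing of its
#' terms, and the inversion can legitimately return a term-permuted copy of
#' the configuration it started from. This sorts the `(lambda, mu)` pairs by
#' increasing exponent `mu` so that parameter vectors can be compared in the
#' X-norm without spurious permutation error. All other entries are left
#' untouched.
#'
#' @param theta packed parameter vector (see [pack_params()]).
#' @param p degree of the input-curve parametrization.
#' @return the packed vector with input terms in canonical order.
#' @export
canonicalize_terms <- function(theta, p) {
  ord <- order(theta[p + seq_len(p)])
  theta[seq_len(p)] <- theta[ord]
  theta[p + seq_len(p)] <- theta[p + ord]
  theta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

norm2 <- function(v) sqrt(sum(v^2))
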