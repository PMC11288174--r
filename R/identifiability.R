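# Checkable sufficient conditions for unique recovery of the kinetic
# parameters from tissue curves (up to a global scale on K1 and the input
# amplitude), and for pinning that scale with whole-blood data.

rate_distinct <- function(a, b, tol = 1e-9) {
  abs(a - b) > tol * max(1, abs(a), abs(b))
}

rate_margin <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))

#' Region-distinctness condition for unique identifiability
#'
#' Checks, for each input-curve exponent index `j0`, whether at least three
#' regions exist whose `k3` and `k2 + k3` values are pairwise distinct, with
#' `mu_j0 + k3 != 0`, and where either `mu_j0 + k2 + k3 = 0` or the sum
#' \eqn{\sum_{j: \mu_j + k_2 + k_3 \neq 0} \lambda_j / (k_2 + k_3 + \mu_j)}
#' is nonzero. Together with enough tissue time points this guarantees that
#' the kinetic rates are uniquely determined by noiseless tissue curves, with
#' the K1 block determined up to one global scale.
#'
#' Nonzero/distinctness decisions use the relative tolerance `tol`; margins
#' below 1e-4 are flagged in `notes` as practically non-identifiable.
#'
#' @param cp a [polyexp()] input curve (all coefficients nonzero).
#' @param regions list of [kinetic_params()], or a [param_vector()] (in which
#'   case `cp` may be omitted).
#' @param tol relative tolerance for "distinct" and "nonzero" decisions.
#' @param fraction_model registered parent-fraction family, for the reported
#'   minimum number of blood samples.
#' @return An object of class `petkin_identifiability`: fields `passes_A`,
#'   `witnesses` (per `j0`, indices of a passing region triple), `counts`,
#'   `distinct_region_count`, `required_T`, `required_q`, `notes`.
#' @export
check_assumption_A <- function(cp, regions = NULL, tol = 1e-9,
                               fraction_model = "biexponential") {
  if (inherits(cp, "petkin_params")) {
    regions <- cp$regions
    cp <- cp$polyexp
  }
  stopifnot(inherits(cp, "petkin_polyexp"))
  p <- cp$degree
  n <- length(regions)
  if (p < 1 || n < 1) stop("need p >= 1 and at least one region", call. = FALSE)
  if (any(cp$lambdas == 0)) {
    stop("assumption check requires all lambda coefficients nonzero",
         call. = FALSE)
  }
  k3 <- vapply(regions, function(r) r$k3, 0)
  kap <- vapply(regions, function(r) r$k2 + r$k3, 0)
  lam <- cp$lambdas
  mu <- cp$mus

  notes <- character(0)
  min_margin <- Inf
  # does region i satisfy the per-region clauses for exponent j0?
  region_ok <- function(i, j0) {
    if (!rate_distinct(mu[j0] + k3[i], 0, tol)) return(FALSE)
    if (!rate_distinct(mu[j0] + kap[i], 0, tol)) return(TRUE)  # first disjunct
    keep <- vapply(mu, function(m) rate_distinct(m + kap[i], 0, tol), TRUE)
    terms <- lam[keep] / (kap[i] + mu[keep])
    s <- sum(terms)
    abs(s) > tol * max(sum(abs(terms)), .Machine$double.eps)
  }

  triples <- if (n >= 3) utils::combn(n, 3) else matrix(numeric(0), 3, 0)
  witnesses <- vector("list", p)
  for (j0 in seq_len(p)) {
    found <- NULL
    for (c0 in seq_len(ncol(triples))) {
      idx <- triples[, c0]
      d3 <- c(rate_margin(k3[idx[1]], k3[idx[2]]),
              rate_margin(k3[idx[1]], k3[idx[3]]),
              rate_margin(k3[idx[2]], k3[idx[3]]))
      dk <- c(rate_margin(kap[idx[1]], kap[idx[2]]),
              rate_margin(kap[idx[1]], kap[idx[3]]),
              rate_margin(kap[idx[2]], kap[idx[3]]))
      if (any(d3 <= tol) || any(dk <= tol)) next
      if (all(vapply(idx, region_ok, TRUE, j0 = j0))) {
        found <- idx
        min_margin <- min(min_margin, d3, dk)
        break
      }
    }
    witnesses[[j0]] <- found
  }
  passes <- !any(vapply(witnesses, is.null, TRUE))
  if (passes && min_margin < 1e-4) {
    notes <- c(notes, sprintf(
      "smallest distinctness margin %.2e < 1e-4: practically non-identifiable",
      min_margin))
  }
  l11 <- check_lemma11(regions, p, tol = tol)
  structure(list(passes_A = passes,
                 witnesses = witnesses,
                 distinct_region_count = l11$count,
                 required_T = as.integer(2 * (p + 3)),
                 required_q = min_blood_samples(fraction_model),
                 notes = notes),
            class = "petkin_identifiability")
}

#' @export
print.petkin_identifiability <- function(x, ...) {
  cat("<identifiability report>\n")
  cat("  assumption (A) satisfied:", x$passes_A, "\n")
  cat("  largest region subset with distinct k3 and k2+k3:",
      x$distinct_region_count, "\n")
  cat("  required tissue time points T >=", x$required_T, "\n")
  cat("  required whole-blood samples q >=", x$required_q, "\n")
  for (s in x$notes) cat("  note:", s, "\n")
  invisible(x)
}

#' Sufficient region count for the distinctness assumption
#'
#' TRUE when some subset of at least `p + 3` regions has pairwise-distinct
#' `k3` values and pairwise-distinct `k2 + k3` values; this implies the
#' condition tested by [check_assumption_A()].
#'
#' @param regions list of [kinetic_params()].
#' @param p degree of the input-curve parametrization, `>= 1`.
#' @param tol relative distinctness tolerance.
#' @return list with `ok` (logical) and `count`, the size of the largest
#'   subset with both families pairwise distinct.
#' @export
check_lemma11 <- function(regions, p, tol = 1e-9) {
  stopifnot(p >= 1)
  n <- length(regions)
  k3 <- vapply(regions, function(r) r$k3, 0)
  kap <- vapply(regions, function(r) r$k2 + r$k3, 0)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (!rate_distinct(k3[i], k3[j], tol) ||
                  !rate_distinct(kap[i], kap[j], tol))) {
      conflict[i, j] <- conflict[j, i] <- TRUE
    }
  }
  subset_ok <- function(idx) {
    !any(conflict[idx, idx, drop = FALSE])
  }
  count <- 0
  for (size in rev(seq_len(n))) {
    if (choose(n, size) > 1e5) next  # regions are few in practice
    sets <- utils::combn(n, size)
    hit <- FALSE
    for (c0 in seq_len(ncol(sets))) {
      if (subset_ok(sets[, c0])) { hit <- TRUE; break }
    }
    if (hit) { count <- size; break }
  }
  list(ok = count >= p + 3, count = count)
}

#' Minimum number of tissue time points for unique identifiability
#'
#' The identifiability theorem requires `T >= 2(p + 3)` distinct tissue
#' measurement times for an input parametrization of degree `p` (14 for the
#' standard degree-4 input model).
#'
#' @param p degree of the input-curve parametrization.
#' @return integer, `2 * (p + 3)`.
#' @export
min_timepoints <- function(p) {
  if (p < 0) stop("`p` must be >= 0", call. = FALSE)
  if (p < 3) warning("the bound is established for p >= 3", call. = FALSE)
  as.integer(2 * (p + 3))
}

#' Minimum number of whole-blood samples to pin the parent fraction
#'
#' Returns the uniqueness degree of a registered parent-fraction family: the
#' number of distinct blood-sample times at which agreement of two family
#' members (up to a scale) forces them to coincide with scale 1.
#'
#' @param fraction_model family identifier; only `"biexponential"` is
#'   registered (uniqueness degree 4).
#' @return integer uniqueness degree.
#' @export
min_blood_samples <- function(fraction_model = "biexponential") {
  registry <- c(biexponential = 4L)
  if (!fraction_model %in% names(registry)) {
    stop(sprintf("unknown parent-fraction family '%s'", fraction_model),
         call. = FALSE)
  }
  registry[[fraction_model]]
}

#' Align two parameter vectors over the K1/input-amplitude scale ambiguity
#'
#' Tissue curves alone determine the `K1` block and the input amplitudes only
#' up to a common factor zeta: `(lambda, K1) -> (lambda/zeta, zeta*K1)`
#' leaves every tissue value unchanged. This estimates zeta between a
#' reference `x_a` and a candidate `x_b` as the median of the per-region
#' ratios `K1_a / K1_b` (robust to one outlier region) and returns `x_b`
#' rescaled onto `x_a`'s scale.
#'
#' @param x_a,x_b [param_vector()]s sharing `p` and `n`; `x_b` must have
#'   nonzero `K1` entries.
#' @return list with `zeta`, the per-region `ratios`, `spread` (max relative
#'   deviation of the ratios from zeta; ~0 iff `x_b` lies on `x_a`'s scale
#'   manifold) and `aligned`, the rescaled copy of `x_b`.
#' @export
align_scale <- function(x_a, x_b) {
  stopifnot(inherits(x_a, "petkin_params"), inherits(x_b, "petkin_params"),
            x_a$polyexp$degree == x_b$polyexp$degree,
            length(x_a$regions) == length(x_b$regions))
  K1a <- vapply(x_a$regions, function(r) r$K1, 0)
  K1b <- vapply(x_b$regions, function(r) r$K1, 0)
  if (any(K1b == 0)) stop("`x_b` has zero K1 entries", call. = FALSE)
  ratios <- K1a / K1b
  zeta <- stats::median(ratios)
  spread <- max(abs(ratios / zeta - 1))
  aligned <- x_b
  aligned$polyexp$lambdas <- x_b$polyexp$lambdas / zeta
  aligned$regions <- lapply(x_b$regions, function(r) {
    r$K1 <- r$K1 * zeta
    r
  })
  list(zeta = zeta, ratios = ratios, spread = spread, aligned = aligned)
}

#' Root-count bound for generalized polyexponential functions
#'
#' A nonzero function \eqn{\sum_j P_j(t) e^{\mu_j t}} with polynomial factors
#' of degrees \eqn{m_j - 1} has at most \eqn{\sum_j m_j - 1} real roots.
#'
#' @param m_list integer multiplicities, all `>= 1`.
#' @return the integer bound \eqn{\sum m_j - 1}.
#' @export
generalized_polyexp_root_bound <- function(m_list) {
  m_list <- as.integer(m_list)
  if (length(m_list) == 0) stop("`m_list` must be nonempty", call. = FALSE)
  if (any(m_list < 1)) stop("multiplicities must be >= 1", call. = FALSE)
  as.integer(sum(m_list) - 1L)
}
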