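# The fitting engine: parametrized forward problem, analytic Jacobian,
# Tikhonov objective, iteratively regularized Gauss-Newton (IRGNM) iteration
# with block regularization schedules, domain projection and discrepancy
# stopping.

#' Geometric regularization schedule
#'
#' The decaying sequence \eqn{\alpha_i = a \, 2^{-i/c}} (equivalently
#' \eqn{a e^{-b i}} with \eqn{b = \ln 2 / c}). The ratio
#' \eqn{\alpha_i/\alpha_{i+1} = 2^{1/c}} is constant and bounded, and
#' \eqn{\alpha_i \to 0}, as the iteratively regularized Gauss-Newton theory
#' requires.
#'
#' @param a initial level, `> 0`.
#' @param c halving constant, `> 0`: the level halves every `c` iterations.
#' @return An object of class `petkin_schedule_reg`.
#' @export
reg_schedule <- function(a, c) {
  if (a <= 0 || c <= 0) stop("`a` and `c` must be > 0", call. = FALSE)
  structure(list(a = a, c = c), class = "petkin_schedule_reg")
}

#' Evaluate a regularization schedule
#'
#' @param s a [reg_schedule()].
#' @param i iteration index, `>= 0` (vectorized).
#' @return \eqn{a \, 2^{-i/c}}.
#' @export
schedule_value <- function(s, i) {
  stopifnot(inherits(s, "petkin_schedule_reg"))
  s$a * 2^(-i / s$c)
}

#' Define a parameter-identification problem
#'
#' Binds the measurement schedule, whole-blood data and estimation mode into
#' a problem object with packed-vector `forward`, `jacobian`, `project`,
#' `pack`/`unpack` closures and a `blocks` labelling of the packed entries
#' (`"input"` for lambda/mu, `"fraction"` for the parent-fraction parameters,
#' `"kinetic"` for the rate constants).
#'
#' Modes: `"full"` estimates all `2p + 3 + 3n` parameters against the stacked
#' data `(F1, F2)`; `"reduced"` freezes the parent fraction at
#' `fraction_fixed` (known-fraction setting, `2p + 3n` unknowns) but keeps
#' the whole-blood consistency block `F2`, which pins the K1/input scale;
#' `"tissue"` also drops `F2`, fitting tissue curves only, and therefore
#' determines the K1 block and input amplitude only up to a common scale.
#'
#' @param mode one of `"full"`, `"reduced"`, `"tissue"`.
#' @param p input-curve degree.
#' @param region_names character vector of region names (length n).
#' @param schedule a [measurement_schedule()].
#' @param cwb_data whole-blood samples at `schedule$s` (measured data; ignored
#'   in tissue mode).
#' @param fraction_fixed a [plasma_fraction()]; required in reduced and
#'   tissue modes.
#' @param epsilon lower domain bound for the kinetic rates.
#' @param mu_upper_bound optional: clip the input exponents to
#'   `(-Inf, -mu_upper_bound]` in the projection (off when `NULL`).
#' @param pin_cp_origin if TRUE the projection re-imposes
#'   \eqn{C_P(0) = 0} by setting \eqn{\lambda_p = -\sum_{j<p} \lambda_j}.
#' @return An object of class `petkin_problem`.
#' @export
fit_problem <- function(mode = c("full", "reduced", "tissue"), p, region_names,
                        schedule, cwb_data = NULL, fraction_fixed = NULL,
                        epsilon = 1e-3, mu_upper_bound = NULL,
                        pin_cp_origin = FALSE) {
  mode <- match.arg(mode)
  n <- length(region_names)
  has_f2 <- mode != "tissue"
  has_m <- mode == "full"
  if (!has_m && is.null(fraction_fixed)) {
    stop("reduced/tissue modes require `fraction_fixed`", call. = FALSE)
  }
  if (has_f2 && (is.null(cwb_data) ||
                 length(cwb_data) != length(schedule$s))) {
    stop("modes with a whole-blood block require `cwb_data` at every s",
         call. = FALSE)
  }
  pack_mode <- if (has_m) "full" else "reduced"
  npar <- 2 * p + has_m * 3 + 3 * n
  blocks <- c(rep("input", 2 * p),
              rep("fraction", if (has_m) 3 else 0),
              rep("kinetic", 3 * n))
  Tn <- length(schedule$t)
  q <- length(schedule$s)

  unpack <- function(theta) {
    unpack_params(theta, p, n, pack_mode, fraction = fraction_fixed,
                  region_names = region_names)
  }
  forward <- function(theta) {
    pv <- unpack(theta)
    if (has_f2) {
      forward_operator(pv, schedule, cwb_data)
    } else {
      unlist(lapply(pv$regions, function(K) {
        ct_closed_form(K, pv$polyexp, schedule$t)
      }), use.names = FALSE)
    }
  }
  project <- function(theta) {
    kin_start <- 2 * p + has_m * 3
    kin <- theta[(kin_start + 1):npar]
    theta[(kin_start + 1):npar] <- pmax(kin, epsilon)
    if (has_m) {
      theta[2 * p + 1] <- max(theta[2 * p + 1], 0)     # A >= 0
      theta[2 * p + 2] <- min(theta[2 * p + 2], 0)     # xi1 <= 0
      theta[2 * p + 3] <- min(theta[2 * p + 3], 0)     # xi2 <= 0
    }
    if (!is.null(mu_upper_bound)) {
      mu_idx <- p + seq_len(p)
      theta[mu_idx] <- pmin(theta[mu_idx], -mu_upper_bound)
    }
    if (pin_cp_origin && p >= 1) {
      theta[p] <- -sum(theta[seq_len(p - 1)])
    }
    theta
  }
  jac <- function(theta) {
    jacobian_packed(theta, p, n, has_m, schedule, cwb_data, fraction_fixed,
                    has_f2)
  }
  structure(list(mode = mode, p = p, n = n, npar = npar,
                 region_names = region_names, schedule = schedule,
                 cwb_data = cwb_data, fraction_fixed = fraction_fixed,
                 epsilon = epsilon, blocks = blocks, n_obs = n * Tn +
                   if (has_f2) q else 0,
                 forward = forward, jacobian = jac, project = project,
                 pack_mode = pack_mode, unpack = unpack),
            class = "petkin_problem")
}

# Analytic Jacobian of the packed forward map, assembled from closed-form
# derivatives of the exponential integral primitives E and D.
jacobian_packed <- function(theta, p, n, has_m, schedule, cwb_data,
                            fraction_fixed, has_f2) {
  npar <- 2 * p + has_m * 3 + 3 * n
  t <- schedule$t; s <- schedule$s
  Tn <- length(t); q <- length(s)
  lambdas <- theta[seq_len(p)]
  mus <- theta[p + seq_len(p)]
  m_off <- 2 * p
  kin_off <- 2 * p + has_m * 3
  nrow_out <- n * Tn + if (has_f2) q else 0
  J <- matrix(0, nrow_out, npar)

  Em <- lapply(mus, exp_int, t = t)          # E(mu_j, t)
  Dm <- lapply(mus, exp_int_s, t = t)        # D(mu_j, t)
  for (i in seq_len(n)) {
    K1 <- theta[kin_off + 3 * i - 2]
    k2 <- theta[kin_off + 3 * i - 1]
    k3 <- theta[kin_off + 3 * i]
    kap <- k2 + k3
    ekt <- exp(-kap * t)
    rows <- (i - 1) * Tn + seq_len(Tn)
    S1 <- numeric(Tn); S2 <- numeric(Tn); dS1 <- numeric(Tn)
    for (j in seq_len(p)) {
      z <- kap + mus[j]
      Ez <- exp_int(z, t)
      Dz <- exp_int_s(z, t)
      Gj <- ekt * Ez
      S1 <- S1 + lambdas[j] * Gj
      S2 <- S2 + lambdas[j] * Em[[j]]
      dS1 <- dS1 + lambdas[j] * ekt * (Dz - t * Ez)
      # d/d lambda_j and d/d mu_j
      J[rows, j] <- K1 * (k2 / kap * Gj + k3 / kap * Em[[j]])
      J[rows, p + j] <- K1 * lambdas[j] *
        (k2 / kap * ekt * Dz + k3 / kap * Dm[[j]])
    }
    ct <- K1 * (k2 / kap * S1 + k3 / kap * S2)
    J[rows, kin_off + 3 * i - 2] <- ct / K1
    J[rows, kin_off + 3 * i - 1] <- K1 *
      (k3 / kap^2 * S1 + k2 / kap * dS1 - k3 / kap^2 * S2)
    J[rows, kin_off + 3 * i] <- K1 *
      (-k2 / kap^2 * S1 + k2 / kap * dS1 + k2 / kap^2 * S2)
  }
  if (has_f2) {
    rows <- n * Tn + seq_len(q)
    for (j in seq_len(p)) {
      e <- exp(mus[j] * s)
      J[rows, j] <- -e
      J[rows, p + j] <- -lambdas[j] * s * e
    }
    if (has_m) {
      A <- theta[m_off + 1]; xi1 <- theta[m_off + 2]; xi2 <- theta[m_off + 3]
      e1 <- exp(xi1 * s); e2 <- exp(xi2 * s)
      J[rows, m_off + 1] <- cwb_data * (e1 - e2)
      J[rows, m_off + 2] <- cwb_data * A * s * e1
      J[rows, m_off + 3] <- cwb_data * (1 - A) * s * e2
    }
  }
  J
}

#' Project a packed vector onto the problem domain
#'
#' Euclidean projection onto the closed convex domain: kinetic rates are
#' clipped to `[epsilon, Inf)`, the fraction amplitude to `[0, Inf)` and the
#' fraction exponents to `(-Inf, 0]`; the input-curve parameters are left
#' free unless the optional constraints of the problem are active.
#'
#' @param theta packed parameter vector.
#' @param problem a [fit_problem()].
#' @return the projected packed vector.
#' @export
project_domain <- function(theta, problem) {
  stopifnot(inherits(problem, "petkin_problem"))
  problem$project(theta)
}

#' Tikhonov objective value
#'
#' Squared data misfit plus `alpha` times the squared Euclidean distance of
#' the packed parameters to a prior center:
#' \deqn{\|F(x) - y\|_Y^2 + \alpha \|x - \bar x\|_X^2.}
#'
#' @param theta packed parameter vector (in the problem's domain).
#' @param y_delta stacked data vector.
#' @param alpha regularization weight, `>= 0`.
#' @param theta_bar packed prior center.
#' @param problem a [fit_problem()].
#' @return scalar objective value.
#' @export
tikhonov_objective <- function(theta, y_delta, alpha, theta_bar, problem) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  r <- problem$forward(theta) - y_delta
  sum(r^2) + alpha * sum((theta - theta_bar)^2)
}

#' One iteratively regularized Gauss-Newton step
#'
#' Solves the regularized normal equations
#' \deqn{(J^T J + \mathrm{diag}(w)) \Delta = J^T (y - F(x_k)) + w (x_0 - x_k)}
#' by a dense Cholesky factorization (with a symmetric solve fallback) and
#' projects the update onto the problem domain. With uniform weights
#' `w = alpha_k` this is exactly the textbook iteratively regularized
#' Gauss-Newton update followed by projection; block-constant weights carry
#' the per-parameter-type schedules.
#'
#' @param theta_k current packed iterate.
#' @param theta_0 packed initial guess (the regularization center).
#' @param y_delta stacked data vector.
#' @param w positive per-entry weight vector (recycled if scalar).
#' @param problem a [fit_problem()].
#' @return the projected next iterate.
#' @export
irgnm_step <- function(theta_k, theta_0, y_delta, w, problem) {
  w <- rep_len(w, length(theta_k))
  if (any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  J <- problem$jacobian(theta_k)
  r <- y_delta - problem$forward(theta_k)
  H <- crossprod(J)
  diag(H) <- diag(H) + w
  rhs <- drop(crossprod(J, r)) + w * (theta_0 - theta_k)
  delta <- tryCatch({
    R <- chol(H)
    backsolve(R, forwardsolve(t(R), rhs))
  }, error = function(e) solve(H, rhs))
  if (any(!is.finite(delta))) {
    stop("non-finite Gauss-Newton step", call. = FALSE)
  }
  problem$project(theta_k + delta)
}

#' Run the iteratively regularized Gauss-Newton method
#'
#' Iterates [irgnm_step()] with per-block geometric schedules and stops at
#' the first iterate `N` whose residual satisfies the discrepancy principle
#' \eqn{\|F(x_N) - y^\delta\|_Y \le \tau \delta_y}, or at `max_iter`. With
#' noiseless data (`delta_y = 0`) the guard never fires and a small residual
#' floor plus the iteration cap terminate the run. No line search or damping
#' is applied; divergence is diagnosed at the experiment level.
#'
#' @param theta_0 packed initial guess (projected into the domain first).
#' @param y_delta stacked data vector.
#' @param delta_y noise level for the discrepancy principle, `>= 0`.
#' @param problem a [fit_problem()].
#' @param config list with entries `alpha`, `beta` and (full mode) `gamma`
#'   ([reg_schedule()]s for the kinetic, input-curve and fraction blocks),
#'   `tau` (`> 1`), `max_iter`, and optionally `residual_floor`
#'   (default `1e-10`).
#' @return An object of class `petkin_fit`: `iterates` (list, first entry is
#'   the projected start), `residual_norms`, `stop_iteration` (`NA` when the
#'   cap was hit), `stopped_by`, final `x` (packed) and `params`
#'   (a [param_vector()]).
#' @export
run_irgnm <- function(theta_0, y_delta, delta_y, problem, config) {
  stopifnot(inherits(problem, "petkin_problem"))
  if (delta_y < 0) stop("`delta_y` must be >= 0", call. = FALSE)
  if (config$tau <= 1) stop("`tau` must be > 1", call. = FALSE)
  floor_ <- config$residual_floor %||% 1e-10
  threshold <- max(config$tau * delta_y, floor_)
  need_gamma <- any(problem$blocks == "fraction")
  if (need_gamma && is.null(config$gamma)) {
    stop("full-mode config requires a `gamma` schedule", call. = FALSE)
  }
  weights_at <- function(i) {
    w <- numeric(problem$npar)
    w[problem$blocks == "kinetic"] <- schedule_value(config$alpha, i)
    w[problem$blocks == "input"] <- schedule_value(config$beta, i)
    if (need_gamma) {
      w[problem$blocks == "fraction"] <- schedule_value(config$gamma, i)
    }
    w
  }
  x <- problem$project(theta_0)
  iterates <- vector("list", config$max_iter + 1)
  iterates[[1]] <- x
  residuals <- numeric(config$max_iter + 1)
  residuals[1] <- norm2(y_delta - problem$forward(x))
  stopped_by <- "max_iter"
  N <- NA_integer_
  n_done <- 0
  for (i in 0:config$max_iter) {
    rn <- residuals[i + 1]
    if (!is.finite(rn)) {
      stopped_by <- "non_finite"
      break
    }
    if (rn <= threshold) {
      stopped_by <- "discrepancy"
      N <- i
      break
    }
    if (i == config$max_iter) break
    x_new <- tryCatch(irgnm_step(x, iterates[[1]], y_delta, weights_at(i),
                                 problem),
                      error = function(e) NULL)
    if (is.null(x_new)) {
      # the linearized step left the numerically representable range
      # (exponential overflow); keep the trajectory up to the last finite
      # iterate and surface the abort
      stopped_by <- "aborted"
      break
    }
    x <- x_new
    iterates[[i + 2]] <- x
    residuals[i + 2] <- tryCatch(norm2(y_delta - problem$forward(x)),
                                 error = function(e) Inf)
    n_done <- i + 1
  }
  iterates <- iterates[seq_len(n_done + 1)]
  residuals <- residuals[seq_len(n_done + 1)]
  x_final <- if (stopped_by == "discrepancy") iterates[[N + 1]] else
    iterates[[n_done + 1]]
  structure(list(iterates = iterates, residual_norms = residuals,
                 stop_iteration = N, stopped_by = stopped_by,
                 x = x_final, params = problem$unpack(x_final),
                 threshold = threshold),
            class = "petkin_fit")
}

#' @export
print.petkin_fit <- function(x, ...) {
  cat(sprintf("<petkin_fit> %d iterates, stopped by %s", length(x$iterates),
              x$stopped_by))
  if (!is.na(x$stop_iteration)) cat(" at N =", x$stop_iteration)
  cat(sprintf("; final residual %.3e\n",
              x$residual_norms[length(x$residual_norms)]))
  invisible(x)
}
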