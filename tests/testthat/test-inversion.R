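gt <- ground_truth_config()
sched <- frame_schedule()
sim <- simulate_ground_truth(gt, sched)

make_reduced <- function() {
  fit_problem("reduced", 4, names(gt$regions), sched, cwb_data = sim$cwb,
              fraction_fixed = gt$fraction)
}
make_full <- function() {
  fit_problem("full", 4, names(gt$regions), sched, cwb_data = sim$cwb)
}

test_that("regularization schedules decay geometrically", {
  s <- reg_schedule(10, 5)
  expect_equal(schedule_value(s, 0), 10)
  expect_equal(schedule_value(s, 5), 5)
  i <- 0:20
  ratios <- schedule_value(s, i) / schedule_value(s, i + 1)
  expect_equal(ratios, rep(2^(1 / 5), 21))
  expect_error(reg_schedule(-1, 5), "> 0")
})

test_that("domain projection clips exactly the constrained blocks", {
  prob <- make_full()
  th <- pack_params(gt$params, "full")
  expect_equal(project_domain(th, prob), th)  # interior point untouched
  bad <- th
  bad[13] <- -0.5                              # frontal k2
  bad[9] <- -0.1                               # A
  bad[10] <- 0.2                               # xi1
  pr <- project_domain(bad, prob)
  expect_equal(pr[13], 1e-3)
  expect_equal(pr[9], 0)
  expect_equal(pr[10], 0)
  expect_equal(pr[c(1:8, 11:12, 14:23)], th[c(1:8, 11:12, 14:23)])
})

test_that("optional input-curve constraints act through the projection", {
  prob <- fit_problem("full", 4, names(gt$regions), sched,
                      cwb_data = sim$cwb, mu_upper_bound = 1e-3,
                      pin_cp_origin = TRUE)
  th <- pack_params(gt$params, "full")
  th[8] <- 0.5                                  # mu_4 pushed positive
  th[4] <- th[4] + 1                            # break C_P(0) = 0
  pr <- project_domain(th, prob)
  expect_equal(pr[8], -1e-3)
  expect_equal(sum(pr[1:4]), 0)
})

test_that("Tikhonov objective reduces to its limiting cases", {
  prob <- make_full()
  th <- pack_params(gt$params, "full")
  y <- stack_measurements(sim$measurements)
  expect_lt(tikhonov_objective(th, y, 1, th, prob), 1e-20)
  x <- th * 1.05
  misfit <- sum((prob$forward(x) - y)^2)
  expect_equal(tikhonov_objective(x, y, 0, th, prob), misfit)
  expect_equal(tikhonov_objective(x, y, 1, x, prob), misfit)
  expect_equal(tikhonov_objective(x, y, 2, th, prob),
               misfit + 2 * sum((x - th)^2))
})

test_that("analytic Jacobian matches central finite differences", {
  prob <- make_full()
  th <- pack_params(gt$params, "full")
  for (s in 1:10) {
    x <- prob$project(perturb_initialization(th, 0.2, seed = 600 + s))
    J <- prob$jacobian(x)
    Jfd <- matrix(0, nrow(J), ncol(J))
    for (j in seq_along(x)) {
      h <- 1e-6 * max(1, abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      Jfd[, j] <- (prob$forward(xp) - prob$forward(xm)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }
})

test_that("Jacobian has the structural zero and homogeneity patterns", {
  prob <- make_full()
  th <- pack_params(gt$params, "full")
  J <- prob$jacobian(th)
  # tissue block does not depend on the fraction parameters
  expect_equal(J[1:100, 9:11], matrix(0, 100, 3))
  # dCT/dK1 = CT/K1 entrywise
  y <- prob$forward(th)
  for (i in 1:4) {
    rows <- (i - 1) * 25 + 1:25
    expect_equal(J[rows, 11 + 3 * i - 2], y[rows] / th[11 + 3 * i - 2],
                 tolerance = 1e-12)
  }
  # kinetic parameters of region i do not touch other regions' rows
  expect_equal(J[26:100, 12:14], matrix(0, 75, 3))
})

test_that("the regularized step solves the augmented least-squares problem", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  y <- stack_measurements(sim$measurements)
  for (s in 1:10) {
    x <- prob$project(perturb_initialization(th, 0.2, seed = 700 + s))
    set.seed(700 + s)
    w <- stats::runif(length(x), 0.01, 5)
    got <- irgnm_step(x, th, y, w, prob)
    # independent oracle: dense QR on the stacked system
    J <- prob$jacobian(x)
    A <- rbind(J, diag(sqrt(w)))
    b <- c(y - prob$forward(x), sqrt(w) * (th - x))
    want <- prob$project(x + qr.solve(A, b))
    expect_lt(norm2(got - want) / norm2(want), 1e-8)
  }
})

test_that("uniform weights reproduce the textbook update", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  y <- stack_measurements(sim$measurements)
  x <- prob$project(perturb_initialization(th, 0.15, seed = 42))
  alpha <- 0.37
  got <- irgnm_step(x, th, y, rep(alpha, length(x)), prob)
  J <- prob$jacobian(x)
  step <- solve(crossprod(J) + alpha * diag(length(x)),
                drop(crossprod(J, y - prob$forward(x))) + alpha * (th - x))
  expect_equal(got, prob$project(x + step), tolerance = 1e-10)
})

test_that("a consistent iterate with matching center is a fixed point", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  y <- prob$forward(th)
  expect_equal(irgnm_step(th, th, y, rep(1, 20), prob), th, tolerance = 1e-12)
})

test_that("the dominant-penalty limit returns the center", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  y <- stack_measurements(sim$measurements)
  x <- prob$project(perturb_initialization(th, 0.2, seed = 9))
  x0 <- prob$project(perturb_initialization(th, 0.1, seed = 10))
  nxt <- irgnm_step(x, x0, y, rep(1e12, 20), prob)
  expect_lt(norm2(nxt - x0) / norm2(x0), 1e-4)
})

test_that("iteration cap and discrepancy guard shape the trajectory", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  setting <- count_setting("normal")
  noisy <- generate_noisy_data(sim, setting, seed = 314)
  y <- stack_measurements(noisy)
  cfg <- c(setup_defaults("reduced"), list(max_iter = 200))
  x0 <- prob$project(perturb_initialization(th, 0.2, seed = 315))
  fit <- run_irgnm(x0, y, setting$delta_y, prob, cfg)
  expect_s3_class(fit, "petkin_fit")
  expect_equal(fit$iterates[[1]], x0)
  expect_identical(fit$stopped_by, "discrepancy")
  expect_lte(fit$residual_norms[fit$stop_iteration + 1],
             cfg$tau * setting$delta_y)
  # a zero-iteration cap returns the start only
  cfg0 <- c(setup_defaults("reduced"), list(max_iter = 0))
  fit0 <- run_irgnm(x0, y, setting$delta_y, prob, cfg0)
  expect_length(fit0$iterates, 1)
  expect_identical(fit0$stopped_by, "max_iter")
})

test_that("noiseless recovery from a moderate perturbation is accurate", {
  prob <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  y <- stack_measurements(sim$measurements)
  cfg <- c(setup_defaults("reduced"), list(max_iter = 300))
  x0 <- prob$project(perturb_initialization(th, 0.1, seed = 2024))
  fit <- run_irgnm(x0, y, 0, prob, cfg)
  err <- norm2(canonicalize_terms(fit$x, 4) - th) / norm2(th)
  expect_lt(err, 1e-3)
})

test_that("every iterate satisfies the domain constraints", {
  prob <- make_full()
  th <- pack_params(gt$params, "full")
  setting <- count_setting("low")
  noisy <- generate_noisy_data(sim, setting, noisy_cwb = TRUE, seed = 55)
  prob <- fit_problem("full", 4, names(gt$regions), sched,
                      cwb_data = noisy$cwb)
  cfg <- c(setup_defaults("full_noisy_cwb"), list(max_iter = 60))
  x0 <- prob$project(perturb_initialization(th, 0.3, seed = 56))
  fit <- run_irgnm(x0, stack_measurements(noisy), setting$delta_y, prob, cfg)
  for (x in fit$iterates) {
    expect_true(all(x[12:23] >= 1e-3 - 1e-15))
    expect_gte(x[9], 0)
    expect_lte(x[10], 0)
    expect_lte(x[11], 0)
  }
})

test_that("final error decreases with the noise level", {
  # empirical consistency: median final error over seeds shrinks as the
  # count setting improves
  prob0 <- make_reduced()
  th <- pack_params(gt$params, "reduced")
  med_err <- vapply(c("low", "normal", "high", "noiseless"), function(cnt) {
    setting <- count_setting(cnt)
    errs <- vapply(1:5, function(s) {
      noisy <- generate_noisy_data(sim, setting, seed = 8100 + s)
      cfg <- c(setup_defaults("reduced"),
               list(max_iter = if (cnt == "noiseless") 300 else 200))
      x0 <- prob0$project(perturb_initialization(th, 0.2, seed = 8200 + s))
      fit <- run_irgnm(x0, stack_measurements(noisy), setting$delta_y,
                       prob0, cfg)
      norm2(canonicalize_terms(fit$x, 4) - th) / norm2(th)
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) <= 1e-10))
})
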