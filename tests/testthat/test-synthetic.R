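gt <- ground_truth_config()
sched <- frame_schedule()
sim <- simulate_ground_truth(gt, sched)

test_that("frame schedule matches the acquisition protocol", {
  expect_length(sched$t, 25)
  expect_identical(sched$s, sched$t)
  expect_equal(attr(sched, "frame_end")[25], 62.5)
  expect_equal(sched$t[1], 2.5 / 60)
  expect_equal(sched$t[25], (3750 - 300) / 60)
  expect_true(all(diff(sched$t) > 0))
})

test_that("ground-truth configuration is internally consistent", {
  expect_equal(sum(gt$cp$lambdas), 0, tolerance = 1e-4)
  expect_true(all(vapply(gt$regions, function(r) {
    min(r$K1, r$k2, r$k3) >= 1e-3
  }, TRUE)))
  expect_true(check_assumption_A(gt$params)$passes_A)
  expect_equal(gt$vb, 0.05)
})

test_that("simulation produces a consistent forward chain", {
  expect_equal(sim$cwb, sim$cp / sim$f, tolerance = 1e-14)
  # stacked truth has an exactly zero whole-blood block
  expect_equal(sim$y_true[101:125], rep(0, 25))
  expect_equal(sim$y_true[1:100], as.vector(t(sim$ct_matrix)))
  # blood-volume mixing inverts exactly
  back <- t(apply(sim$cpet_matrix, 1, pet_to_tissue,
                  cwb_values = sim$cwb, VB = gt$vb))
  dimnames(back) <- dimnames(sim$ct_matrix)
  expect_equal(back, sim$ct_matrix, tolerance = 1e-13)
  # frame averaging changes the early frames most
  sim_avg <- simulate_ground_truth(gt, sched, frame_average = TRUE)
  expect_false(isTRUE(all.equal(sim_avg$ct_matrix, sim$ct_matrix)))
  expect_equal(sim_avg$ct_matrix[, 25], sim$ct_matrix[, 25], tolerance = 0.01)
})

test_that("calibrated noise realizes the requested discrepancy exactly", {
  expect_equal(generate_noisy_data(sim, count_setting("noiseless"))$ct_matrix,
               sim$ct_matrix)
  for (cnt in c("high", "normal", "low")) {
    setting <- count_setting(cnt)
    for (noisy_cwb in c(FALSE, TRUE)) {
      ms <- generate_noisy_data(sim, setting, noisy_cwb, seed = 99)
      realized <- sqrt(sum((ms$ct_matrix - sim$ct_matrix)^2) +
                         sum((sim$f * (ms$cwb - sim$cwb))^2))
      expect_equal(realized, setting$delta_y, tolerance = 1e-12)
      if (!noisy_cwb) expect_equal(ms$cwb, sim$cwb)
    }
  }
  a <- generate_noisy_data(sim, count_setting("normal"), seed = 1)
  b <- generate_noisy_data(sim, count_setting("normal"), seed = 2)
  expect_false(isTRUE(all.equal(a$ct_matrix, b$ct_matrix)))
  expect_equal(a$delta_y, b$delta_y)
  # same seed reproduces the same draw
  expect_equal(generate_noisy_data(sim, count_setting("normal"), seed = 1),
               a)
})

test_that("initialization perturbation has the stated statistics", {
  th <- pack_params(gt$params, "full")
  expect_equal(perturb_initialization(th, 0, seed = 5), th)
  # Monte-Carlo check of the expected squared relative deviation
  # delta_x/4 + delta_x^2 (small-sample version; the acceptance suite runs
  # the full-size check)
  for (dx in c(0.1, 0.3)) {
    set.seed(31)
    n_draw <- 20000
    vals <- vapply(seq_len(n_draw), function(i) {
      sigma <- sample(c(-1, 1), 23, replace = TRUE)
      gamma <- stats::rnorm(23, dx, sqrt(dx) / 2)
      sum((th * sigma * gamma)^2) / sum(th^2)
    }, 0)
    want <- dx / 4 + dx^2
    se <- stats::sd(vals) / sqrt(n_draw)
    expect_lt(abs(mean(vals) - want), 3 * se)
  }
  # signs are balanced
  set.seed(77)
  draws <- replicate(4000, sign(perturb_initialization(th, 0.2)[1] - th[1]))
  expect_lt(abs(mean(draws)), 0.06)
})

test_that("improvement metrics follow their definitions", {
  th <- pack_params(gt$params, "full")
  x0 <- th * 1.2
  expect_equal(rho_metrics(list(x0, th), th, N = 1),
               list(rho_opt = 100, rho_d = 100))
  expect_equal(rho_metrics(list(x0, x0), th)$rho_opt, 0)
  halfway <- th + 0.5 * (x0 - th)
  expect_equal(rho_metrics(list(x0, halfway), th, N = 1)$rho_d, 50)
  expect_true(is.na(rho_metrics(list(x0, halfway), th)$rho_d))
  expect_error(rho_metrics(list(th), th), "coincides")
})

test_that("relative error curve is the normalized distance per iterate", {
  th <- pack_params(gt$params, "full")
  expect_equal(relative_error_curve(list(th), th), 0)
  expect_equal(relative_error_curve(list(2 * th), th), 1)
  expect_equal(relative_error_curve(list(th, 2 * th, th), th), c(0, 1, 0))
})

test_that("replicated experiments summarize non-divergent recoveries", {
  res <- run_experiment("reduced", "normal", delta_x = 0.2, n_reps = 4,
                        master_seed = 7)
  expect_s3_class(res, "petkin_experiment")
  expect_length(res$replicates, 4)
  expect_identical(nrow(res$summary), 12L)  # 4 regions x 3 parameters
  expect_true(all(res$summary$mean > 0))
  # summary excludes divergent/unstopped replicates by construction
  keep <- res$kept
  k1 <- vapply(res$replicates[keep], function(x) x$kinetics["frontal", "K1"], 0)
  expect_equal(res$summary$mean[res$summary$region == "frontal" &
                                  res$summary$parameter == "K1"], mean(k1))
  # best-iterate improvement bounds the stopped-iterate improvement
  for (rep in res$replicates) {
    if (!is.na(rep$rho_d)) expect_gte(rep$rho_opt, rep$rho_d)
  }
  # reproducibility from the master seed
  res2 <- run_experiment("reduced", "normal", delta_x = 0.2, n_reps = 4,
                         master_seed = 7)
  expect_equal(res2$summary, res$summary)
  # reference-based bias correction is a small, well-behaved rescaling
  res3 <- run_experiment("reduced", "normal", delta_x = 0.2, n_reps = 4,
                         master_seed = 7, bias_correction = TRUE)
  expect_identical(nrow(res3$summary), 12L)
  expect_lt(max(abs(res3$summary$mean - res$summary$mean)), 0.05)
})

test_that("knowing more about the input improves kinetic recovery", {
  # median final kinetic error over paired seeds: reduced setup (input
  # effectively known) <= full with noiseless whole blood <= full with
  # noisy whole blood
  seeds <- 1:5
  setting <- count_setting("normal")
  err_for <- function(setup, s) {
    mode <- if (setup == "reduced") "reduced" else "full"
    noisy <- generate_noisy_data(sim, setting,
                                 noisy_cwb = setup == "full_noisy_cwb",
                                 seed = 61000 + s)
    prob <- fit_problem(mode, 4, names(gt$regions), sched,
                        cwb_data = noisy$cwb,
                        fraction_fixed = if (mode == "reduced") gt$fraction)
    th <- pack_params(gt$params, prob$pack_mode)
    x0 <- prob$project(perturb_initialization(th, 0.3, seed = 62000 + s))
    fit <- run_irgnm(x0, stack_measurements(noisy), setting$delta_y, prob,
                     c(setup_defaults(setup), list(max_iter = 200)))
    kb <- prob$blocks == "kinetic"
    norm2(fit$x[kb] - th[kb]) / norm2(th[kb])
  }
  med <- vapply(c("reduced", "full_noiseless_cwb", "full_noisy_cwb"),
                function(st) {
                  stats::median(vapply(seeds, function(s) err_for(st, s), 0))
                }, 0)
  expect_lte(med[["reduced"]], med[["full_noiseless_cwb"]] + 1e-12)
  expect_lte(med[["full_noiseless_cwb"]], med[["full_noisy_cwb"]] + 1e-12)
})
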