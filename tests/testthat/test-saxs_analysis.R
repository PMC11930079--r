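test_that("read_saxs_profile parses the .dat dialect and cleans rows", {
  path <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.002, 1.0, length.out = 500)
  writeLines(c("# header one", "# header two",
               sprintf("%.6e %.6e %.6e", q, exp(-q), 0.01 * exp(-q))),
             path)
  p <- read_saxs_profile(path)
  expect_s3_class(p, "saxs_profile")
  expect_equal(nrow(p), 500)
  expect_true("sigma" %in% names(p))

  # two-column variant: no sigma
  path2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.6e %.6e", q, exp(-q)), path2)
  expect_false("sigma" %in% names(read_saxs_profile(path2)))

  # rows with q <= 0 dropped with a message
  path3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.6e %.6e", c(-0.01, 0, q), exp(-c(-0.01, 0, q))), path3)
  expect_message(p3 <- read_saxs_profile(path3), "dropped 2")
  expect_equal(nrow(p3), 500)
})

test_that("read_saxs_profile rejects degenerate files", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.4f %.4f", c(0.01, 0.02, 0.02, 0.03, seq(0.04, 0.2, 0.01)),
                     1:21), path)
  expect_error(read_saxs_profile(path), "non-monotone q")
  path2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.4f %.4f", seq(0.01, 0.05, 0.01), 1:5), path2)
  expect_error(read_saxs_profile(path2), "fewer than 10")
  expect_error(read_saxs_profile(file.path(tempdir(), "nope.dat")), "cannot read")
})

test_that("profile writer round-trips through the reader", {
  p <- sphere_profile()
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(p, path)
  p2 <- read_saxs_profile(path)
  expect_equal(p2$q, p$q, tolerance = 1e-7)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-7)
})

test_that("guinier_fit recovers its own generating form exactly", {
  fit <- guinier_fit(exact_guinier_profile(rg = 55.4, i0 = 7))
  expect_equal(fit$rg, 55.4, tolerance = 1e-6)
  expect_equal(fit$i0, 7, tolerance = 1e-6)
  expect_lte(fit$q_range_used[2], 1.3 + 1e-8)
})

test_that("guinier_fit recovers the closed-form sphere Rg within 2%", {
  fit <- guinier_fit(sphere_profile(radius = 30))
  expect_equal(fit$rg, sqrt(3 / 5) * 30, tolerance = 0.02)
})

test_that("guinier_fit of a Debye profile matches coordinate-space Rg", {
  set.seed(31)
  coords <- matrix(rnorm(300, sd = 8), ncol = 3)  # compact cloud
  rg_true <- compute_rg(coords)
  prof <- debye_profile(coords, seq(0.004, 0.1, length.out = 80))
  fit <- guinier_fit(prof)
  expect_equal(fit$rg, rg_true, tolerance = 0.02)
})

test_that("guinier_fit refuses profiles without a decaying low-q region", {
  q <- seq(0.01, 0.1, length.out = 40)
  expect_error(guinier_fit(saxs_profile(q, exp(q^2 * 100))), "slope")
})

test_that("tidy and glance summarize a guinier fit", {
  fit <- guinier_fit(exact_guinier_profile())
  td <- tidy(fit)
  expect_equal(td$term, c("rg", "i0"))
  gl <- glance(fit)
  expect_true(all(c("rg", "i0", "r_squared", "n_points") %in% names(gl)))
})

test_that("dimensionless Kratky curve has the analytic globular optimum", {
  prof <- exact_guinier_profile(rg = 30, i0 = 2,
                                q = seq(0.001, 0.12, length.out = 4000))
  fit <- guinier_fit(prof)
  k <- dimensionless_kratky(prof, fit)
  expect_equal(k$x[which.max(k$y)], sqrt(3), tolerance = 1e-3)
  expect_equal(max(k$y), 3 / exp(1), tolerance = 1e-3)
})

test_that("Kratky curve is invariant under intensity scaling", {
  prof <- sphere_profile()
  scaled <- saxs_profile(prof$q, prof$intensity * 137.5)
  k1 <- dimensionless_kratky(prof, guinier_fit(prof))
  k2 <- dimensionless_kratky(scaled, guinier_fit(scaled))
  expect_equal(k1$x, k2$x, tolerance = 1e-9)
  expect_equal(k1$y, k2$y, tolerance = 1e-9)
})

test_that("flexible dumbbell ensembles show the monotonic Kratky rise", {
  tpl <- small_template()
  conf <- sample_conformers(tpl, sampler_config(30, 5, linker_stiffness = 1))
  prof <- ensemble_average_profile(conf, seq(0.004, 0.4, by = 0.004))
  fit <- guinier_fit(prof)
  k <- dimensionless_kratky(prof, fit)
  y_at <- function(x0) k$y[which.min(abs(k$x - x0))]
  expect_gt(y_at(6), y_at(4))
})

test_that("compute_pr recovers the uniform sphere closed forms", {
  pr <- compute_pr(sphere_profile(radius = 30), dmax_trial = 90)
  expect_equal(pr$dmax, 60, tolerance = 2 / 60)
  expect_equal(pr$rg_real, sqrt(3 / 5) * 30, tolerance = 0.5 / 23.2)
  # P(r) invariants
  expect_true(all(pr$curve$p >= 0))
  expect_equal(pr$curve$p[1], 0)
  expect_equal(pracma::trapz(pr$curve$r, pr$curve$p), 1, tolerance = 1e-6)
  second_moment_rg <- sqrt(pracma::trapz(pr$curve$r, pr$curve$r^2 * pr$curve$p) / 2)
  expect_equal(pr$rg_real, second_moment_rg, tolerance = 1e-6)
})

test_that("compute_pr locates a dumbbell separation peak", {
  prof <- debye_profile(rbind(c(0, 0, 0), c(0, 0, 100)),
                        seq(0.005, 0.35, by = 0.002))
  pr <- compute_pr(prof, dmax_trial = 150, background = 2)
  expect_equal(pr$curve$r[which.max(pr$curve$p)], 100, tolerance = 2 / 100)
})

test_that("compute_pr real-space Rg matches ensemble coordinate Rg", {
  tpl <- small_template()
  conf <- sample_conformers(tpl, sampler_config(25, 9, linker_stiffness = 1))
  prof <- ensemble_average_profile(conf, seq(0.004, 0.3, by = 0.002))
  rg_ens <- sqrt(mean(conf$rg^2))
  pr <- suppressWarnings(compute_pr(prof, dmax_trial = max(conf$dmax_model) * 1.15,
                                    background = nrow(tpl$coords)))
  expect_equal(pr$rg_real, rg_ens, tolerance = 0.05)
})

test_that("compute_pr warns when Dmax exceeds the data resolution limit", {
  prof <- sphere_profile(radius = 30, q = seq(0.05, 0.35, by = 0.002))
  expect_warning(compute_pr(prof, dmax_trial = 90), "resolution")
})

test_that("debye_profile obeys its closed forms", {
  q <- seq(0.01, 0.5, by = 0.01)
  one <- debye_profile(matrix(c(1, 2, 3), 1), q)
  expect_equal(one$intensity, rep(1, length(q)))
  d <- 42
  two <- debye_profile(rbind(c(0, 0, 0), c(d, 0, 0)), q)
  expect_equal(two$intensity, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  expect_equal(debye_profile(rbind(c(0, 0, 0), c(d, 0, 0)), c(0, q))$intensity[1], 4)
})

test_that("debye profiles of random clouds agree with coordinate Rg", {
  set.seed(77)
  coords <- matrix(rnorm(150, sd = 10), ncol = 3)
  fit <- guinier_fit(debye_profile(coords, seq(0.003, 0.08, length.out = 60)))
  expect_equal(fit$rg, compute_rg(coords), tolerance = 0.02)
})

test_that("ensemble_average_profile is the mean of member profiles", {
  tpl <- small_template()
  conf <- sample_conformers(tpl, sampler_config(2, 3))
  q <- seq(0.01, 0.2, by = 0.01)
  single <- debye_profile(conf$coords[[1]], q)
  expect_equal(ensemble_average_profile(conf[1, ], q)$intensity,
               single$intensity)
  # two identical conformers
  twin <- list(conf$coords[[1]], conf$coords[[1]])
  expect_equal(ensemble_average_profile(twin, q)$intensity, single$intensity)
  expect_error(ensemble_average_profile(list(), q), "empty")
})

test_that("mixed ensembles have Guinier Rg bracketed by the members", {
  compact <- matrix(rnorm(240, sd = 5), ncol = 3)
  extended <- compact * 4
  q <- seq(0.002, 0.05, length.out = 60)
  rg_mix <- guinier_fit(ensemble_average_profile(list(compact, extended), q))$rg
  rg_c <- guinier_fit(debye_profile(compact, q))$rg
  rg_e <- guinier_fit(debye_profile(extended, q))$rg
  expect_gt(rg_mix, rg_c)
  expect_lt(rg_mix, rg_e)
})
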