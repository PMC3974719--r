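test_that("unfished equilibrium matches the closed form and scales with R0", {
  lh <- tiny_lh()
  lh$ages <- 0:2
  lh$length_bins <- seq(8, 44, by = 4)
  lh$M <- 0.2
  lh$R0 <- 1
  eq <- unfished_equilibrium(lh)
  expect_equal(unname(eq$N0),
               c(1, exp(-0.2), exp(-0.4) / (1 - exp(-0.2))))
  lh2 <- lh
  lh2$R0 <- 2
  expect_equal(unfished_equilibrium(lh2)$SSB0, 2 * eq$SSB0)
  bad <- lh
  bad$M <- 0
  expect_error(unfished_equilibrium(bad), "degenerate")
})

test_that("unfished SSB0 equals the long-run SSB of an independent 500-year projection", {
  lh <- get_builtin("cod")$om
  eq <- unfished_equilibrium(lh)
  # independent recursion: start well away from equilibrium, no fishing,
  # deterministic Beverton-Holt recruitment, iterate to stationarity
  ages <- lh$ages
  na <- length(ages)
  L <- lh$Linf * (1 - exp(-lh$k * (ages - lh$t0)))
  w <- lh$w_alpha * L^lh$w_beta
  mat <- 1 / (1 + exp(-lh$mat_slope * (ages - lh$mat_a50)))
  mat[1] <- 0
  N <- rep(lh$R0, na)            # far from the equilibrium age structure
  ssb <- NA_real_
  for (t in 1:500) {
    ssb <- sum(N * w * mat)
    R <- 4 * lh$h * lh$R0 * ssb /
      (eq$SSB0 * (1 - lh$h) + ssb * (5 * lh$h - 1))
    Nn <- numeric(na)
    Nn[1] <- R
    Nn[2:na] <- N[1:(na - 1)] * exp(-lh$M)
    Nn[na] <- Nn[na] + N[na] * exp(-lh$M)
    N <- Nn
  }
  expect_equal(ssb, eq$SSB0, tolerance = 1e-8)
})

test_that("Beverton-Holt recruitment honours its normalization and steepness", {
  lh <- tiny_lh()
  ssb0 <- unfished_equilibrium(lh)$SSB0
  expect_equal(beverton_holt(ssb0, lh), lh$R0)
  expect_equal(beverton_holt(0.2 * ssb0, lh), lh$h * lh$R0)
  lh1 <- lh
  lh1$h <- 1
  for (s in c(0.1, 0.5, 2)) {
    expect_equal(beverton_holt(s * ssb0, lh1, ssb0 = ssb0), lh1$R0)
  }
  expect_error(beverton_holt(-1, lh), "ssb")
})

test_that("Baranov catch matches its limits and an ODE integration", {
  N <- c(100, 80, 60)
  expect_equal(baranov_catch(N, 0.2, 0, c(1, 1, 1)), c(0, 0, 0))
  expect_equal(baranov_catch(N, 0, 0.3, c(1, 1, 1)), N * (1 - exp(-0.3)))
  # generic inputs vs numerical integration of the competing-mortality ODE
  M <- 0.25; F <- 0.4; sel <- c(0.2, 0.7, 1.0)
  got <- baranov_catch(N, M, F, sel)
  for (a in 1:3) {
    out <- deSolve::ode(
      y = c(N = N[a], C = 0), times = c(0, 1),
      func = function(t, y, p) {
        list(c(-(M + sel[a] * F) * y[["N"]], sel[a] * F * y[["N"]]))
      }, parms = NULL, method = "ode45", atol = 1e-12, rtol = 1e-12)
    expect_equal(got[a], out[2, "C"], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("time-varying injection is additive, per-year, and validated", {
  cod <- get_builtin("cod")$om
  expect_identical(apply_tv(cod, list()), cod)
  bump <- apply_tv(cod, list(M = c("1990" = 0.1)))
  expect_equal(bump$M[cod$years == 1990], 0.3)
  expect_equal(bump$M[cod$years == 1991], 0.2)
  expect_equal(cod$M, 0.2)   # original untouched
  expect_error(apply_tv(cod, list(xyzzy = 0.1)), "unknown time-varying")
  expect_error(apply_tv(cod, list(M = c("1900" = 0.1))), "outside")
  sel_bump <- apply_tv(cod, list(sel_a50_f1 = c("2000" = 1)))
  expect_equal(length(sel_bump$fleets[[1]]$sel_a50), length(cod$years))
  expect_equal(sel_bump$fleets[[2]]$sel_a50, cod$fleets[[2]]$sel_a50)
})

test_that("an unfished, deviation-free projection sits at equilibrium", {
  # the lognormal mean-bias correction exp(-sigma_R^2/2) makes a zero-dev
  # run the median trajectory; exact equilibrium holds as sigma_R -> 0
  lh <- tiny_lh(sigma_R = 1e-8)
  tr <- project(lh, rep(0, length(lh$years)), rep(0, length(lh$years)))
  expect_equal(unname(tr$SSB), rep(tr$SSB0, length(lh$years)))
  expect_equal(unname(tr$depletion), rep(1, length(lh$years)))
  expect_true(all(unlist(lapply(tr$C, sum)) == 0))
  # at sigma_R = 0.4 the zero-dev run drifts below SSB0 by at most the
  # correction factor, never above
  lh4 <- tiny_lh(sigma_R = 0.4)
  tr4 <- project(lh4, rep(0, length(lh4$years)), rep(0, length(lh4$years)))
  expect_true(all(tr4$depletion <= 1 + 1e-12))
  expect_true(all(tr4$depletion > exp(-lh4$sigma_R^2 / 2) - 0.05))
})

test_that("the projection recursion matches an independent hand recursion", {
  # 3 ages x 3 years, all pieces recomputed from first principles
  lh <- tiny_lh()
  lh$ages <- 0:2
  lh$years <- 2001:2003
  lh$length_bins <- seq(8, 44, by = 4)
  f <- c(0.1, 0.3, 0.2)
  dev <- c(0.2, -0.1, 0.05)
  tr <- project(lh, f, dev)

  L <- pmax(lh$Linf * (1 - exp(-lh$k * (lh$ages - lh$t0))), 1e-4 * lh$Linf)
  w <- lh$w_alpha * L^lh$w_beta
  mat <- 1 / (1 + exp(-lh$mat_slope * (lh$ages - lh$mat_a50)))
  mat[1] <- 0
  sel <- 1 / (1 + exp(-lh$fleets[[1]]$sel_slope *
                        (lh$ages - lh$fleets[[1]]$sel_a50)))
  N0 <- lh$R0 * exp(-lh$M * lh$ages)
  N0[3] <- N0[3] / (1 - exp(-lh$M))
  ssb0 <- sum(N0 * w * mat)
  N <- matrix(0, 3, 3)
  N[, 1] <- N0
  for (y in 1:3) {
    ssb <- sum(N[, y] * w * mat)
    bh <- 4 * lh$h * lh$R0 * ssb / (ssb0 * (1 - lh$h) + ssb * (5 * lh$h - 1))
    N[1, y] <- bh * exp(dev[y] - lh$sigma_R^2 / 2)
    Z <- lh$M + sel * f[y]
    if (y < 3) {
      N[2:3, y + 1] <- N[1:2, y] * exp(-Z[1:2])
      N[3, y + 1] <- N[3, y + 1] + N[3, y] * exp(-Z[3])
    }
  }
  expect_equal(unname(tr$N), N, tolerance = 1e-12)
})

test_that("cohorts survive consistently and decline with age", {
  lh <- tiny_lh()
  tr <- project(lh, tiny_f(lh), make_rec_devs(0.4, lh$years, seed = 3))
  na <- length(lh$ages)
  ny <- length(lh$years)
  # cohort identity N[a+1, y+1] * e^{Z[a, y]} = N[a, y] below the plus group
  for (y in 1:(ny - 1)) {
    for (a in 1:(na - 2)) {
      expect_equal(tr$N[a + 1, y + 1] * exp(tr$Z[a, y]), tr$N[a, y],
                   tolerance = 1e-10)
    }
  }
  # monotone decline along each cohort below the plus group (which
  # accumulates several cohorts and may grow)
  for (y in 1:(ny - 1)) {
    expect_true(all(tr$N[2:(na - 1), y + 1] < tr$N[1:(na - 2), y] + 1e-12))
  }
})

test_that("catch never exceeds available deaths and proportions sum to one", {
  lh <- tiny_lh()
  tr <- project(lh, tiny_f(lh, f_max = 0.6),
                make_rec_devs(0.4, lh$years, seed = 11))
  deaths <- tr$N * (1 - exp(-tr$Z))
  total_catch <- Reduce(`+`, tr$C)
  expect_true(all(total_catch <= deaths + 1e-12))
  for (id in names(tr$expected_agecomp)) {
    expect_equal(unname(colSums(tr$expected_agecomp[[id]])),
                 rep(1, length(lh$years)), tolerance = 1e-10)
    expect_equal(unname(colSums(tr$expected_lencomp[[id]])),
                 rep(1, length(lh$years)), tolerance = 1e-10)
  }
  expect_true(all(tr$N >= 0) && all(total_catch >= 0))
})

test_that("recruitment is mean-unbiased around the stock-recruit curve", {
  lh <- tiny_lh()
  ssb0 <- unfished_equilibrium(lh)$SSB0
  ssb <- 0.4 * ssb0
  bh <- beverton_holt(ssb, lh, ssb0 = ssb0)
  set.seed(42)
  n <- 1e5
  draws <- bh * exp(rnorm(n, 0, lh$sigma_R) - lh$sigma_R^2 / 2)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - bh), 3 * se)
})

test_that("depletion stays in (0, 1] under fishing without deviations", {
  lh <- tiny_lh()
  for (fm in c(0, 0.2, 0.8)) {
    tr <- project(lh, tiny_f(lh, f_max = fm), rep(0, length(lh$years)))
    expect_true(all(tr$depletion > 0 & tr$depletion <= 1 + 1e-12))
  }
})

test_that("projection inputs must cover every year", {
  lh <- tiny_lh()
  expect_error(project(lh, rep(0.1, 3), rep(0, length(lh$years))),
               "cover all")
  short_devs <- stats::setNames(rep(0, 5), lh$years[1:5])
  expect_error(project(lh, tiny_f(lh), short_devs), "missing years")
})
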