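tiny_truth <- function(seed = 9, sigma_R = 0.4) {
  lh <- tiny_lh(sigma_R = sigma_R)
  devs <- make_rec_devs(lh$sigma_R, lh$years, seed = seed)
  list(lh = lh, devs = devs, truth = project(lh, tiny_f(lh), devs))
}

test_that("likelihood components match independent hand computations", {
  # lognormal index kernel: one point with log-residual 0.1 at se 0.1
  expect_equal(nll_index_component(obs = exp(0.1), pred = 1, se_log = 0.1),
               0.5)
  # multinomial kernel for a printed 3-bin toy
  p_obs <- c(0.5, 0.3, 0.2); p_pred <- c(0.4, 0.4, 0.2)
  hand <- -100 * (0.5 * log(0.4) + 0.3 * log(0.4) + 0.2 * log(0.2))
  expect_equal(nll_multinomial_component(p_obs, p_pred, 100), hand)
})

test_that("the total objective decomposes into the R-side component oracles", {
  tt <- tiny_truth()
  dat <- exact_dataset(tt$truth, svy_years = seq(2001, 2015, 2))
  cfg <- em_config(tt$lh)
  v <- nll(true_params(tt$lh, tt$devs), dat, cfg)
  comp <- attr(v, "components")
  # noise-free data at the true parameters: index component at its 0 minimum
  expect_equal(unname(comp["index"]), 0, tolerance = 1e-8)
  # composition components equal the oracle evaluated at p_pred = p_obs
  oracle_comp <- function(tbl) {
    sum(vapply(split(tbl, paste(tbl$fleet, tbl$year)), function(d) {
      nll_multinomial_component(d$prop, d$prop, d$Nsamp[1])
    }, numeric(1)))
  }
  expect_equal(unname(comp["agecomp"]), oracle_comp(dat$agecomp),
               tolerance = 1e-8)
  expect_equal(unname(comp["lencomp"]), oracle_comp(dat$lencomp),
               tolerance = 1e-8)
  # deviation penalty: sum dev^2 / (2 sigma^2) + n log sigma
  pen <- sum(tt$devs^2) / (2 * tt$lh$sigma_R^2) +
    length(tt$devs) * log(tt$lh$sigma_R)
  expect_equal(unname(comp["rec_devs"]), pen, tolerance = 1e-8)
  expect_equal(as.numeric(v), sum(comp), tolerance = 1e-10)
})

test_that("the estimation model reproduces the operating model at the truth", {
  tt <- tiny_truth()
  dat <- exact_dataset(tt$truth, svy_years = seq(2001, 2015, 2))
  cfg <- em_config(tt$lh)
  pred <- em_predictions(true_params(tt$lh, tt$devs), dat, cfg)
  expect_equal(unname(pred$SSB), unname(tt$truth$SSB), tolerance = 1e-6)
  expect_equal(unname(pred$R), unname(tt$truth$R), tolerance = 1e-6)
  expect_equal(pred$SSB0, tt$truth$SSB0, tolerance = 1e-6)
  # the catch-conditioned Newton solve recovers the true F series
  expect_equal(as.numeric(pred$F), unname(tt$truth$F[["1"]]),
               tolerance = 1e-6)
})

test_that("fixed parameters pass through exactly and carry no standard error", {
  tt <- tiny_truth(seed = 31)
  dat <- simulate_dataset(tiny_lh(), seed = 600)$data
  ft <- fit(em_config(tiny_lh(), toggles = list(M = "fixed")), dat)
  row <- ft$estimates[ft$estimates$term == "M", ]
  expect_identical(row$estimate, 0.35)   # the template value, exactly
  expect_true(is.na(row$se))
  expect_false(row$estimated)
  ft2 <- fit(em_config(tiny_lh(), toggles = list(M = 0.28)), dat)
  expect_identical(ft2$estimates$estimate[ft2$estimates$term == "M"], 0.28)
  expect_error(em_config(tiny_lh(), toggles = list(banana = "fixed")),
               "unknown estimation toggle")
})

test_that("a self-test fit converges and its gradient is the true sup-norm", {
  sim <- simulate_dataset(tiny_lh(), seed = 801)
  cfg <- em_config(tiny_lh(), toggles = list(M = "estimated"))
  ft <- fit(cfg, sim$data)
  expect_true(ft$converged)
  expect_true(ft$covariance_ok)
  expect_lt(ft$max_gradient, cfg$grad_tol)
  expect_identical(ft$n_params_on_bounds, 0L)
  # finite-difference check of the reported gradient at the solution
  built <- scaloop:::make_em_obj(cfg, sim$data)
  fd <- vapply(seq_along(ft$opt_par), function(i) {
    h <- 1e-5 * (1 + abs(ft$opt_par[i]))
    xp <- xm <- ft$opt_par
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (built$obj$fn(xp) - built$obj$fn(xm)) / (2 * h)
  }, numeric(1))
  expect_lt(abs(max(abs(fd)) - ft$max_gradient), 0.05)
  # tidy/glance surfaces
  td <- tidy(ft)
  expect_tibble_cols(td, c("term", "estimate", "se", "estimated"))
  gl <- glance(ft)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})

test_that("structurally broken input yields a diagnosed failure, not an error", {
  sim <- simulate_dataset(tiny_lh(), seed = 900)
  dat <- sim$data
  dat$catch$value <- dat$catch$value * 1e8   # impossible catches
  ft <- fit(em_config(tiny_lh()), dat)
  expect_s3_class(ft, "fit_result")
  expect_false(ft$converged)
})

test_that("derived quantities honour their limits and a brute-force oracle", {
  lh <- tiny_lh(sigma_R = 1e-8)   # deterministic recruitment limit
  bio <- scaloop:::em_biology(lh)
  ff <- lh$fleets[[1]]
  sel <- logistic_age(lh$ages, ff$sel_a50, ff$sel_slope)
  msy <- msy_reference_points(lh$ages, lh$M, lh$h, lh$R0, bio$w_a,
                              bio$mat_a, sel)
  expect_gt(msy$F_MSY, 0)
  expect_lt(msy$SSB_MSY, msy$SSB0)
  # long-horizon projection at fixed F_MSY reaches SSB_MSY
  lh500 <- lh
  lh500$years <- 1:500
  tr <- project(lh500, rep(msy$F_MSY, 500), rep(0, 500))
  expect_equal(unname(tr$SSB[500]), msy$SSB_MSY, tolerance = 1e-3)
  expect_equal(sum(Reduce(`+`, tr$C)[, 500] * tr$weight_at_age[, 500]),
               msy$MSY, tolerance = 1e-3)
  # h = 1: equilibrium recruitment R0 wherever SPR > 0, yield = YPR * R0
  msy1 <- msy_reference_points(lh$ages, lh$M, 1, lh$R0, bio$w_a, bio$mat_a,
                               sel)
  ypr_at <- function(F) scaloop:::per_recruit(lh$ages, lh$M, F, sel,
                                              bio$w_a, bio$mat_a)$ypr
  expect_equal(msy1$MSY, ypr_at(msy1$F_MSY) * lh$R0, tolerance = 1e-6)
  # zero-F, zero-dev history has depletion exactly 1
  dq <- derive_quantities(list(M = lh$M, h = lh$h, R0 = lh$R0,
                               sel_a50 = ff$sel_a50, sel_slope = ff$sel_slope,
                               SSB = rep(msy$SSB0, 10)),
                          em_config(lh))
  expect_equal(dq$depletion, 1)
  # steepness at the lower limit: no sustainable yield
  flat <- msy_reference_points(lh$ages, lh$M, 0.2 + 1e-9, lh$R0, bio$w_a,
                               bio$mat_a, sel)
  expect_true(is.na(flat$SSB_MSY))
  expect_identical(attr(flat, "flag"), "zero_yield_curve")
})

test_that("retrospective peeling truncates data correctly", {
  lh <- tiny_lh()
  sim <- simulate_dataset(lh, seed = 950)
  cfg <- em_config(lh)
  retro <- run_retrospective(cfg, sim$data, 2)
  expect_length(retro, 3)
  # peel 0 equals a plain fit
  ft <- fit(cfg, sim$data)
  expect_equal(retro[[1]]$ssb$est, ft$ssb$est, tolerance = 1e-8)
  expect_equal(max(retro[[2]]$ssb$year), 2014)
  expect_equal(max(retro[[3]]$ssb$year), 2013)
  # with a survey every 2nd year starting 2001, peel 2 retains odd years
  # only up to 2013
  expect_error(run_retrospective(cfg, sim$data, 8), ">= 10 model years")
  expect_type(mohns_rho(retro), "double")
})

test_that("retrospective peels drop later survey years per the filtering rule", {
  # survey every 2nd year 1974-2012: peel 2 retains survey years <= 2010
  svy <- seq(1974, 2012, by = 2)
  expect_identical(max(svy[svy <= 2012 - 2]), 2010)
  lh <- tiny_lh()
  sim <- simulate_dataset(lh, seed = 951)
  retro <- run_retrospective(em_config(lh), sim$data, 3)
  svy_tiny <- seq(2001, 2015, by = 2)
  # deepest peel: terminal year 2012, so survey years retained <= 2011
  deepest <- retro[[4]]
  expect_lte(max(deepest$ssb$year), 2012)
})

test_that("a matched model shows no retrospective pattern", {
  # Monte-Carlo null for Mohn's rho on the fast sardine-like configuration:
  # with no OM/EM misspecification the central rho should sit near zero
  lh <- get_builtin("sardine")$om
  yrs <- lh$years
  svy <- seq(min(yrs), max(yrs), 2)
  f <- build_f_series(list(pattern = "ramp_constant", f_max = 0.48,
                           ramp_years = 10), yrs)
  rhos <- vapply(1:12, function(i) {
    devs <- make_rec_devs(lh$sigma_R, yrs, seed = hash_seed(55, i, "p"))
    truth <- project(lh, f, devs)
    dat <- observed_dataset(
      sample_index(truth, index_spec(2, svy, 0.1), hash_seed(55, i, "oi")),
      sample_agecomp(truth, comp_spec(c(1, 2), list(yrs, svy), 100),
                     hash_seed(55, i, "oa")),
      lencomp = NULL, catch = catch_series(truth))
    mohns_rho(run_retrospective(em_config(lh), dat, 5))
  }, numeric(1))
  expect_lt(abs(median(rhos)), 0.05)
})

test_that("bias-adjustment factors move towards the information limits", {
  lh <- tiny_lh()
  yrs <- lh$years
  late <- tail(yrs, 6)
  devs <- make_rec_devs(lh$sigma_R, yrs, seed = 321)
  truth <- project(lh, tiny_f(lh), devs)
  fixed_all <- list(M = "fixed", h = "fixed", R0 = "fixed", q = "fixed",
                    sel_fishery = "fixed", sel_survey = "fixed")
  # weak data only in recent years: early b_y small, late b_y larger
  dat_weak <- observed_dataset(
    sample_index(truth, index_spec(2, late, 0.1), 1),
    sample_agecomp(truth, comp_spec(2, list(late), 50), 2),
    lencomp = NULL, catch = catch_series(truth))
  cfg_w <- run_bias_adjust(em_config(lh, toggles = fixed_all), dat_weak)
  expect_true(all(cfg_w$b_y >= 0 & cfg_w$b_y <= 1))
  expect_lt(mean(cfg_w$b_y[1:6]), 0.5)
  expect_gt(mean(cfg_w$b_y[yrs %in% late]) - mean(cfg_w$b_y[1:6]), 0.1)
  # near noise-free, data-rich observations: b_y approaches 1
  dat_rich <- observed_dataset(
    sample_index(truth, index_spec(2, yrs, 0.01), 3),
    sample_agecomp(truth, comp_spec(c(1, 2), list(yrs, yrs), 5000), 4),
    lencomp = NULL, catch = catch_series(truth))
  cfg_r <- run_bias_adjust(em_config(lh, toggles = fixed_all), dat_rich)
  expect_gt(mean(cfg_r$b_y), 0.9)
})
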