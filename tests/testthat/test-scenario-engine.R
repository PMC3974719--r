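# One small engine run shared across blocks in this file.
engine_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    case_dir <- file.path(tempdir(), "tiny-cases")
    dir.create(case_dir, showWarnings = FALSE)
    write_tiny_cases(case_dir)
    out <- file.path(tempdir(), "tiny-run")
    unlink(out, recursive = TRUE)
    rc <- run_config(iterations = 1:2,
                     scenarios = c("D0-E0-F0-M0-R0-tiny",
                                   "D1-E0-F0-M0-R0-tiny"),
                     case_folder = case_dir, om = tiny_lh(), em = tiny_lh(),
                     base_seed = 11, output_dir = out)
    report <- run_simulation(rc)
    cache <<- list(rc = rc, report = report, out = out,
                   case_dir = case_dir)
    cache
  }
})

test_that("a run produces the scenario/iteration folder layout", {
  fx <- engine_fixture()
  expect_true(all(fx$report$status == "ok"))
  for (scn in fx$rc$scenarios) {
    for (it in 1:2) {
      d <- file.path(fx$out, scn, it)
      expect_true(dir.exists(d))
      for (f in c("om_truth.csv", "om_ts.csv", "om_scalars.txt",
                  "em_data.csv", "em_ts.csv", "em_scalars.txt",
                  "config.txt", "log.txt")) {
        expect_true(file.exists(file.path(d, f)), info = file.path(scn, it, f))
      }
    }
  }
})

test_that("process error is paired across scenarios at fixed iteration", {
  fx <- engine_fixture()
  for (it in 1:2) {
    a <- readLines(file.path(fx$out, fx$rc$scenarios[1], it, "om_ts.csv"))
    b <- readLines(file.path(fx$out, fx$rc$scenarios[2], it, "om_ts.csv"))
    expect_identical(a, b)   # same truth under D0 and D1
  }
  # but different iterations draw different process error
  a1 <- readLines(file.path(fx$out, fx$rc$scenarios[1], 1, "om_ts.csv"))
  a2 <- readLines(file.path(fx$out, fx$rc$scenarios[1], 2, "om_ts.csv"))
  expect_false(identical(a1, a2))
  # observation error differs across scenarios
  d0 <- readLines(file.path(fx$out, fx$rc$scenarios[1], 1, "em_data.csv"))
  d1 <- readLines(file.path(fx$out, fx$rc$scenarios[2], 1, "em_data.csv"))
  expect_false(identical(d0, d1))
})

test_that("re-running an identical configuration is byte-identical", {
  fx <- engine_fixture()
  out2 <- file.path(tempdir(), "tiny-run-2")
  unlink(out2, recursive = TRUE)
  rc2 <- fx$rc
  rc2$output_dir <- out2
  run_simulation(rc2)
  get_results_all(fx$out)
  get_results_all(out2)
  for (f in c("ss3sim_scalars.csv", "ss3sim_ts.csv")) {
    expect_identical(readLines(file.path(fx$out, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("parallel execution reproduces the serial outputs byte-for-byte", {
  fx <- engine_fixture()
  out3 <- file.path(tempdir(), "tiny-run-par")
  unlink(out3, recursive = TRUE)
  rc3 <- fx$rc
  rc3$output_dir <- out3
  rc3$parallel_workers <- 2L
  run_simulation(rc3)
  skip_runtime <- function(x) x[!grepl("^runtime", x)]
  for (scn in fx$rc$scenarios) {
    for (it in 1:2) {
      for (f in c("om_ts.csv", "em_data.csv", "em_scalars.txt")) {
        expect_identical(
          skip_runtime(readLines(file.path(out3, scn, it, f))),
          skip_runtime(readLines(file.path(fx$out, scn, it, f))))
      }
    }
  }
})

test_that("base_run with equivalent bundles matches the case-file route", {
  fx <- engine_fixture()
  cases <- list(
    D = list(index = parse_case_file(file.path(fx$case_dir,
                                               "index0-tiny.txt")),
             agecomp = parse_case_file(file.path(fx$case_dir,
                                                 "agecomp0-tiny.txt")),
             lcomp = parse_case_file(file.path(fx$case_dir,
                                               "lcomp0-tiny.txt"))),
    E = parse_case_file(file.path(fx$case_dir, "E0-tiny.txt")),
    F = parse_case_file(file.path(fx$case_dir, "F0-tiny.txt")),
    M = parse_case_file(file.path(fx$case_dir, "M0-tiny.txt")),
    R = parse_case_file(file.path(fx$case_dir, "R0-tiny.txt")))
  out4 <- file.path(tempdir(), "tiny-base")
  unlink(out4, recursive = TRUE)
  base_run(om = tiny_lh(), em = tiny_lh(), cases = cases, iterations = 1:2,
           scenario_id = "D0-E0-F0-M0-R0-tiny", output_dir = out4,
           base_seed = 11)
  skip_runtime <- function(x) x[!grepl("^runtime", x)]
  for (it in 1:2) {
    for (f in c("om_ts.csv", "em_data.csv", "em_scalars.txt", "em_ts.csv")) {
      expect_identical(
        skip_runtime(readLines(file.path(out4, "D0-E0-F0-M0-R0-tiny", it, f))),
        skip_runtime(readLines(file.path(fx$out, "D0-E0-F0-M0-R0-tiny", it, f))))
    }
  }
})

test_that("missing argument bundles are reported by name", {
  expect_error(base_run(om = tiny_lh(), cases = list(D = list()),
                        iterations = 1),
               "missing argument bundle\\(s\\): F")
  expect_error(base_run(om = tiny_lh(),
                        cases = list(D = list(index = list()),
                                     F = list(pattern = "vector")),
                        iterations = 1),
               "'agecomp'")
})

test_that("direct survey-year vectors restrict the observations", {
  fx <- engine_fixture()
  dat <- readr::read_csv(
    file.path(fx$out, "D0-E0-F0-M0-R0-tiny", 1, "em_data.csv"),
    show_col_types = FALSE)
  idx_years <- sort(unique(dat$year[dat$section == "index"]))
  expect_identical(idx_years, seq(2001, 2015, by = 2))
})

test_that("a failing iteration is isolated and reported with its stage", {
  case_dir <- file.path(tempdir(), "bad-cases")
  dir.create(case_dir, showWarnings = FALSE)
  write_tiny_cases(case_dir)
  # survey years outside the projection -> sampling stage failure
  writeLines(c("fleets; 2", "years; list(seq(1990, 1999, by = 1))",
               "sds_obs; list(0.1)"),
             file.path(case_dir, "index0-tiny.txt"))
  out <- file.path(tempdir(), "bad-run")
  unlink(out, recursive = TRUE)
  rc <- run_config(iterations = 1:2, scenarios = "D0-E0-F0-M0-R0-tiny",
                   case_folder = case_dir, om = tiny_lh(), em = tiny_lh(),
                   base_seed = 3, output_dir = out)
  rep <- run_simulation(rc)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$status == "failed"))
  expect_true(all(rep$stage == "sampling"))
  expect_match(rep$message[1], "1990")
})

test_that("scenarios missing required case letters are rejected", {
  fx <- engine_fixture()
  rc <- fx$rc
  rc$scenarios <- "D0-E0-tiny"
  expect_error(run_simulation(rc), "missing case letter")
})
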