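test_that("shipped fixtures parse to the captioned parameter sets with defaults applied", {
  sc <- nc_scenario("fig1a")
  expect_equal(sc$params$r1, 1)
  expect_equal(sc$params$r2, 10)
  expect_equal(sc$params$rs, 0)
  expect_equal(sc$params$A, 1.001)
  expect_identical(sc$policy$mode, "none")
  expect_equal(unlist(sc$init[c("n1", "n2", "K")]), c(n1 = 2, n2 = 2, K = 5))
  expect_equal(sc$options$rtol, 1e-9)      # default applied
  expect_equal(sc$options$atol, 1e-9)
  expect_identical(sc$capacity_mode, "unbounded")

  sc3 <- nc_scenario("fig3")
  expect_identical(sc3$policy$mode, "adaptive")
  expect_equal(sc3$init$n1, 0)

  sc6 <- nc_scenario("fig6a")
  expect_identical(sc6$capacity_mode, "bounded")
  expect_equal(sc6$params$Kmax, 20)
  expect_true(length(sc6$assumed) > 0)
})

test_that("scenario validation rejects malformed configurations with field paths", {
  write_cfg <- function(x) {
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(x, f, auto_unbox = TRUE)
    f
  }
  base <- list(params = list(r1 = 1, r2 = 10, rs = 0, A = 1.001),
               policy = list(mode = "none"),
               init = list(n1 = 2, n2 = 2, K = 5))

  bad <- base; bad$params$bogus <- 1
  expect_error(load_scenario(write_cfg(bad)), "unknown keys.*bogus")

  bad <- base; bad$policy <- list(mode = "fixed", L1 = 4, L2 = 3)
  expect_error(load_scenario(write_cfg(bad)), "L1")

  bad <- base; bad$init <- NULL
  expect_error(load_scenario(write_cfg(bad)), "missing block: init")

  bad <- base; bad$capacity_mode <- "bounded"
  expect_error(load_scenario(write_cfg(bad)), "Kmax")

  bad <- base; bad$extra_top <- 1
  expect_error(load_scenario(write_cfg(bad)), "unknown top-level")
})

test_that("trajectory files round-trip exactly and empty event logs keep their header", {
  # truncated horizon: the run has not converged, so classification warns
  res <- suppressWarnings(run_scenario("fig1b", t_end = 5))
  dir <- file.path(tempdir(), "nc-roundtrip")
  write_trajectory(res$trajectory, dir, name = "fig1b")
  back <- read_trajectory(dir)

  expect_identical(back$trajectory$t, res$trajectory$times)
  expect_identical(back$trajectory$n1, res$trajectory$n1)
  expect_identical(back$trajectory$n2, res$trajectory$n2)
  expect_identical(back$trajectory$K, res$trajectory$K)
  expect_identical(nrow(back$events), 0L)            # rs = 0: header only
  expect_identical(back$manifest$name, "fig1b")
  expect_equal(back$manifest$params$r2, 10)

  res2 <- run_scenario("fig2b", t_end = 10)
  dir2 <- file.path(tempdir(), "nc-roundtrip2")
  write_trajectory(res2$trajectory, dir2)
  back2 <- read_trajectory(dir2)
  expect_identical(back2$events$t, res2$trajectory$events$time)
  expect_true(all(c("K_crossed_L1_down", "K_crossed_L2_up") %in%
                    back2$events$event_type))
})

test_that("the level sweep classifies both sides of the threshold pair", {
  sw <- sweep_scenario("fig2b", vary = "L2", values = c(4, 4.5))
  expect_identical(sw$regime, c("periodic_survival", "extinct_with_switching"))
})

test_that("the CLI dispatches theory and run subcommands", {
  out <- capture.output(status <- nc_cli(c("theory", "--A", "1.001",
                                           "--L1", "3", "--r1", "1", "--json")))
  expect_identical(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(parsed$B, critical_from_allee(1.001), tolerance = 1e-8)
  expect_gt(parsed$L2_max, 4)

  cfg <- system.file("extdata", "scenarios", "fig1a.json",
                     package = "nomadcolony")
  dir <- file.path(tempdir(), "nc-cli-run")
  out <- capture.output(status <- nc_cli(c("run", "--config", cfg,
                                           "--out", dir, "--t-end", "5")))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  expect_message(status <- nc_cli("no-such-command"), "unknown subcommand")
  expect_identical(status, 1L)
})
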