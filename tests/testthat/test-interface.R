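write_tmp_csv <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("p-value tables are validated on read", {
  path <- write_tmp_csv(data.frame(index = 1:3, p_value = c(0.2, 0.5, 0.01)),
                        "p.csv")
  tbl <- read_pvalue_table(path)
  expect_equal(tbl$p_value, c(0.2, 0.5, 0.01))
  bad <- write_tmp_csv(data.frame(index = 1:2, p_value = c(0.2, 1.2)),
                       "bad.csv")
  expect_error(read_pvalue_table(bad), "row 2")
  expect_error(read_pvalue_table("does-not-exist.csv"), "not found")
})

test_that("conflict and timeline CSV schemas round-trip", {
  lag_path <- write_tmp_csv(data.frame(i = 1:4, lag = c(0, 1, 2, 0)),
                            "lags.csv")
  cs <- read_lag_csv(lag_path)
  expect_equal(lags_of(cs), c(0L, 1L, 2L, 0L))

  pair_path <- write_tmp_csv(data.frame(i = c(2, 3, 3), j = c(1, 1, 2)),
                             "pairs.csv")
  cs2 <- read_conflict_pairs(pair_path)
  expect_equal(cs2$sets[[3]], c(1L, 2L))

  tl_path <- write_tmp_csv(
    data.frame(arm_id = c("a", "b", "c"), entry = c(0, 2, 6),
               exit = c(3, 5, 9)), "tl.csv")
  tl <- read_timeline_csv(tl_path)
  expect_equal(conflicts_from_timeline(tl)$sets[[2]], 1L)
})

test_that("flat dotted-key configs parse values and comments", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "run.cfg")
  writeLines(c("# run settings", "procedure = graph-conf",
               "alpha = 0.05", "gamma.family = geometric",
               "gamma.q = 0.5  # decay"), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$procedure, "graph-conf")
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$`gamma.q`, 0.5)
})

test_that("decisions CSV round-trips losslessly at 12 significant digits", {
  g <- make_gamma("geometric", q = 0.5)
  res <- addis_graph(c(0.1, 0.5, 0.5), g, alpha = 0.05, tau = 0.8, lam = 0.3)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "dec.csv")
  write_decisions(res, out)
  back <- utils::read.csv(out)
  expect_equal(back$level, res$level, tolerance = 1e-11)
  expect_equal(back$rejected, res$rejected)
  expect_true(all(diff(back$spent_so_far) >= 0))
  expect_true(all(back$remaining_budget >= 0))
})

test_that("cli test subcommand reproduces the worked levels at alpha 0.05", {
  dir <- withr::local_tempdir()
  p_path <- file.path(dir, "p.csv")
  utils::write.csv(data.frame(index = 1:3, p_value = c(0.1, 0.5, 0.5)),
                   p_path, row.names = FALSE)
  cfg_path <- file.path(dir, "run.cfg")
  writeLines(c("procedure = graph", "alpha = 0.05", "tau = 0.8", "lam = 0.3",
               "gamma.family = geometric", "gamma.q = 0.5"), cfg_path)
  out <- file.path(dir, "dec.csv")
  status <- run_cli(c("test", "--pvalues", p_path, "--config", cfg_path,
                      "--out", out))
  expect_identical(status, 0L)
  dec <- utils::read.csv(out)
  expect_equal(dec$level, c(0.0125, 0.0125, 0.00625), tolerance = 1e-10)
})

test_that("cli budget subcommand prints the full level before any test", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "run.cfg")
  writeLines(c("alpha = 0.05", "gamma.family = geometric", "gamma.q = 0.7"),
             cfg_path)
  out <- capture.output(status <- run_cli(c("budget", "--config", cfg_path)))
  expect_identical(status, 0L)
  expect_equal(as.numeric(out[1]), 0.05)
})

test_that("cli simulate is byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "sim.cfg")
  writeLines(c("sim.n = 20", "sim.b = 5", "sim.piA = 0.3", "sim.reps = 5",
               "sim.alpha = 0.2", "seed = 4", "gamma.family = quadratic"),
             cfg_path)
  out1 <- file.path(dir, "r1.csv"); out2 <- file.path(dir, "r2.csv")
  expect_identical(run_cli(c("simulate", "--config", cfg_path,
                             "--out", out1)), 0L)
  expect_identical(run_cli(c("simulate", "--config", cfg_path,
                             "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("cli weights subcommand writes a valid transfer table", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "w.cfg")
  writeLines(c("gamma.family = geometric", "gamma.q = 0.5", "weights.n = 6"),
             cfg_path)
  out <- file.path(dir, "w.csv")
  expect_identical(run_cli(c("weights", "--config", cfg_path, "--out", out)),
                   0L)
  w <- utils::read.csv(out)
  expect_true(all(w$weight >= 0))
  expect_true(all(tapply(w$weight, w$j, sum) <= 1 + 1e-9))
  # table reloads as a usable custom transfer
  tw <- transfer_table(w)
  expect_equal(tw$w(1, 2), w$weight[w$j == 1 & w$i == 2][1])
})

test_that("cli failures exit nonzero with a message", {
  expect_message(status <- run_cli(c("frobnicate")), "unknown subcommand")
  expect_identical(status, 1L)
  expect_message(status2 <- run_cli(c("test", "--out")), "requires a value")
  expect_identical(status2, 1L)
})
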