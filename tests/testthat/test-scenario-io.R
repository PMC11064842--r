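test_that("scenario files round-trip through YAML and JSON", {
  sc <- synth_scenario(seed = 3)
  tmp <- withr::local_tempdir()

  y <- file.path(tmp, "scenario.yaml")
  write_scenario(sc, y)
  back <- load_scenario(y)
  expect_equal(back$economics, sc$economics, tolerance = 1e-12)
  expect_equal(back$transition$recurrence_by_year,
               sc$transition$recurrence_by_year)
  expect_equal(back$transition$death_hr_by_mrs,
               sc$transition$death_hr_by_mrs, tolerance = 1e-12)
  expect_equal(as.numeric(back$trials$SELECT2$EVT$dist),
               as.numeric(sc$trials$SELECT2$EVT$dist), tolerance = 1e-12)
  expect_equal(back$simulation, sc$simulation)

  j <- file.path(tmp, "scenario.json")
  write_scenario(sc, j)
  backj <- load_scenario(j)
  expect_equal(backj$economics, sc$economics, tolerance = 1e-12)
  expect_equal(backj$transition$life_table$qx, sc$transition$life_table$qx,
               tolerance = 1e-12)

  # external life-table CSV reference, resolved relative to the config
  y2 <- file.path(tmp, "scenario2.yaml")
  write_scenario(sc, y2, life_table_csv = "lt.csv")
  expect_true(file.exists(file.path(tmp, "lt.csv")))
  back2 <- load_scenario(y2)
  expect_equal(back2$transition$life_table$qx, sc$transition$life_table$qx,
               tolerance = 1e-12)
})

test_that("validation failures name the offending key", {
  sc <- synth_scenario(seed = 3)
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.yaml")

  raw <- yaml::read_yaml(write_scenario(sc, file.path(tmp, "ok.yaml")))

  bad <- raw
  bad$transition$recurrent_outcome_dist <- c(0.1, 0.2, 0.2, 0.2, 0.1, 0.1)
  yaml::write_yaml(bad, p, precision = 15)
  expect_error(load_scenario(p), "recurrent_outcome_dist.*sum to 1")

  bad <- raw
  bad$economics$evt_procedure_cost <- -5
  yaml::write_yaml(bad, p, precision = 15)
  expect_error(load_scenario(p), "economics.*evt_procedure_cost")

  bad <- raw
  bad$trials[[1]]$arms[[1]]$dist <- rep(0.2, 7)
  yaml::write_yaml(bad, p, precision = 15)
  expect_error(load_scenario(p), "trials\\.ANGEL-ASPECT")

  bad <- raw
  bad$trials[[2]]$arms <- bad$trials[[2]]$arms[1]
  yaml::write_yaml(bad, p, precision = 15)
  expect_error(load_scenario(p), "EVT and a BMC arm")

  bad <- raw
  bad$simulation <- NULL
  yaml::write_yaml(bad, p, precision = 15)
  expect_error(load_scenario(p), "simulation")

  # published utilities row is accepted as-is
  ok <- raw
  ok$economics$utilities <- c(1.0, 0.91, 0.76, 0.65, 0.33, 0.0)
  yaml::write_yaml(ok, p, precision = 15)
  expect_equal(load_scenario(p)$economics$utilities,
               c(1.0, 0.91, 0.76, 0.65, 0.33, 0.0))

  expect_error(load_scenario(file.path(tmp, "missing.yaml")), "missing.yaml")
})

test_that("result files are complete, manifest-listed and byte-stable", {
  sc <- synth_scenario(seed = 5)
  an <- run_scenario(sc)
  pooled <- an$comparisons$Pooled
  psa <- run_psa(pool_arms(unname(lapply(sc$trials, `[[`, "EVT"))),
                 pool_arms(unname(lapply(sc$trials, `[[`, "BMC"))),
                 sc$transition, sc$economics, n = 10,
                 seed = sc$simulation$seed)
  dsa <- one_way_dsa(pool_arms(unname(lapply(sc$trials, `[[`, "EVT"))),
                     pool_arms(unname(lapply(sc$trials, `[[`, "BMC"))),
                     sc$transition, sc$economics)
  tmp <- withr::local_tempdir()
  out1 <- file.path(tmp, "run1")
  out2 <- file.path(tmp, "run2")
  m1 <- write_results(an, out1, psa = psa, dsa = dsa)
  m2 <- write_results(an, out2, psa = psa, dsa = dsa)

  expected <- c("cea_table.csv", "trace_EVT.csv", "trace_BMC.csv",
                "psa_points.csv", "ceac.csv", "tornado.csv")
  expect_true(all(file.exists(file.path(out1, expected))))
  expect_true(file.exists(file.path(out1, "run_manifest.json")))
  # every output is listed in the manifest with a content hash
  expect_setequal(names(m1$files), expected)
  expect_true(all(nchar(unlist(m1$files)) == 32))
  # identical rerun gives identical hashes
  expect_equal(unname(unlist(m1$files)), unname(unlist(m2$files)))

  # PSA omitted: files skipped, manifest notes the omission
  m3 <- write_results(an, file.path(tmp, "run3"))
  expect_false(file.exists(file.path(tmp, "run3", "psa_points.csv")))
  expect_true(all(c("psa_points.csv", "ceac.csv", "tornado.csv") %in%
                    unlist(m3$omitted)))

  # a dominant pooled comparison surfaces the sentinel in the table CSV
  tab <- utils::read.csv(file.path(out1, "cea_table.csv"))
  expect_true(all(tab$icer[tab$classification == "cost_saving_dominant"] ==
                    "cost saving"))
})

test_that("published-style tables are checked, not silently corrected", {
  # per-strategy totals and printed incrementals of the published comparison
  printed <- data.frame(
    cohort = c("Pooled", "ANGEL-ASPECT", "SELECT2", "RESCUE-Japan LIMIT"),
    cost_bmc = c(403044, 420443, 336473, 444711),
    cost_evt = c(385726, 382679, 325753, 446856),
    incr_cost = c(-17318, -37763, -8610, 2145),
    qaly_bmc = c(2.44, 3.25, 2.06, 1.98),
    qaly_evt = c(3.76, 4.38, 3.31, 3.58),
    incr_qalys = c(1.32, 1.12, 1.25, 1.61))
  chk <- check_cea_table(printed)
  # pooled row is internally consistent
  expect_false(chk$cost_mismatch[1])
  expect_false(chk$qaly_mismatch[1])
  # SELECT2 printed incremental cost disagrees with its totals by $2,110
  expect_true(chk$cost_mismatch[chk$cohort == "SELECT2"])
  expect_equal(chk$incr_cost_recomputed[chk$cohort == "SELECT2"], -10720)
  # ANGEL-ASPECT disagrees by $1 (within the $1 tolerance: not flagged)
  expect_equal(chk$incr_cost_recomputed[chk$cohort == "ANGEL-ASPECT"], -37764)
  expect_false(chk$cost_mismatch[chk$cohort == "ANGEL-ASPECT"])
  # RESCUE-Japan LIMIT QALY gain prints 1.61 vs 1.60 from totals
  expect_equal(chk$incr_qalys_recomputed[chk$cohort == "RESCUE-Japan LIMIT"],
               1.60)
  expect_false(chk$qaly_mismatch[chk$cohort == "RESCUE-Japan LIMIT"])
  # a clear inconsistency is flagged
  broken <- printed
  broken$incr_qalys[1] <- 1.00
  expect_true(check_cea_table(broken)$qaly_mismatch[1])
  expect_error(check_cea_table(printed[, -2]), "cost_bmc")
})

test_that("the command-line layer runs synth, run, psa and validate end to end", {
  tmp <- withr::local_tempdir()
  synth_dir <- file.path(tmp, "cfg")
  expect_equal(cea_cli(c("synth", "--seed", "7", "--outdir", synth_dir,
                         "--log-level", "error")), 0L)
  cfg <- file.path(synth_dir, "scenario.yaml")
  expect_true(file.exists(cfg))
  expect_true(file.exists(file.path(synth_dir, "life_table.csv")))

  run_dir <- file.path(tmp, "out")
  expect_equal(cea_cli(c("run", "--config", cfg, "--outdir", run_dir,
                         "--log-level", "error")), 0L)
  expect_true(file.exists(file.path(run_dir, "cea_table.csv")))

  # psa twice with the same seed: identical point files
  p1 <- file.path(tmp, "psa1"); p2 <- file.path(tmp, "psa2")
  for (d in c(p1, p2)) {
    expect_equal(cea_cli(c("psa", "--config", cfg, "--iterations", "8",
                           "--seed", "1", "--outdir", d,
                           "--log-level", "error")), 0L)
  }
  expect_identical(readLines(file.path(p1, "psa_points.csv")),
                   readLines(file.path(p2, "psa_points.csv")))

  expect_equal(cea_cli(c("validate", "--config", cfg,
                         "--log-level", "error")), 0L)

  # failure paths exit non-zero
  expect_equal(cea_cli(c("run", "--config", file.path(tmp, "missing.yaml"),
                         "--log-level", "error")), 1L)
  expect_equal(cea_cli(c("frobnicate")), 1L)
  expect_equal(cea_cli(c("run", "--bogus-flag", "1",
                         "--log-level", "error")), 1L)
})
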