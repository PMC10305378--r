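test_that("parameter constructors validate their invariants by name", {
  expect_error(tube_params(inner_diameter = -4), "inner_diameter")
  expect_error(tube_params(wall_thickness = 5), "wall_thickness")
  expect_error(pump_params(heart_rate = 0), "heart_rate")
  expect_error(acquisition_params(analog_band = c(10, 1)), "analog_band")
  expect_error(acquisition_params(fs = 15), "band")
  expect_error(pressure_setpoint(80, 120), "sbp")
})

test_that("an empty config file yields the documented defaults", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", path)
  sc <- load_scenario(path)
  expect_equal(sc$tube$inner_diameter, 4)
  expect_equal(sc$tube$wall_thickness, 1)
  expect_equal(sc$tube$modulus_zero, 1428.7)
  expect_equal(sc$tube$stiffness_coeff, 0.031)
  expect_equal(sc$tube$sensor_distance, 4)
  expect_equal(sc$acq$fs, 5000)
  expect_equal(sc$acq$analog_band, c(0.6, 10.6))
  expect_equal(sc$acq$digital_band, c(0.7, 9.5))
  expect_equal(sc$pump$heart_rate, 75)
  expect_equal(nrow(sc$setpoints), 9)
  expect_equal(sc$duration_s, 60)
})

test_that("configs round-trip through files and reject bad fields", {
  sc <- fast_scenario(seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(scenario_to_list(sc), path, auto_unbox = TRUE,
                       digits = NA)
  back <- load_scenario(path)
  expect_equal(scenario_to_list(back), scenario_to_list(sc))

  # YAML too
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(scenario_to_list(sc), ypath)
  expect_equal(scenario_to_list(load_scenario(ypath)),
               scenario_to_list(sc))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"tube": {"inner_diameter": -1}}', bad)
  expect_error(load_scenario(bad), "inner_diameter")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"frobnicate": 1}', bad2)
  expect_error(load_scenario(bad2), "frobnicate")
})

test_that("trace CSVs round-trip with their sidecar metadata", {
  s <- synth_pressure_series(duty_to_setpoint(0.5, 80), duration = 2,
                             fs = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(s, path, provenance = list(seed = 3))
  back <- read_trace_csv(path)
  expect_equal(back$samples, s$samples, tolerance = 1e-12)
  expect_equal(back$fs, 250)
  expect_equal(attr(back, "provenance")$seed, 3)

  rec <- propagate(s, 3, L = 4)
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_record_csv(rec, rpath)
  rback <- read_record_csv(rpath)
  expect_equal(rback$true_delay, rec$true_delay)
  expect_equal(rback$distal$samples, rec$distal$samples, tolerance = 1e-12)
})

test_that("CLI commands run the pipeline and fail loudly on bad input", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.json")
  sc <- fast_scenario(setpoints = data.frame(duty = c(0.3, 0.5, 0.7, 0.9),
                                             base_pressure = 80),
                      duration_s = 4, seed = 5)
  jsonlite::write_json(scenario_to_list(sc), cfg, auto_unbox = TRUE,
                       digits = NA)

  tdir <- file.path(dir, "traces")
  pwsim_cli(c("simulate", "--config", cfg, "--out", tdir))
  expect_length(list.files(tdir, pattern = "^trace_.*csv$"), 4)

  mdir <- file.path(dir, "meas")
  pwsim_cli(c("measure", "--config", cfg, "--in", tdir, "--out", mdir))
  summ <- read.csv(file.path(mdir, "summaries.csv"))
  expect_equal(nrow(summ), 4)
  expect_true(all(summ$n_beats >= 4))

  model_json <- file.path(dir, "model.json")
  pwsim_cli(c("calibrate", "--config", cfg, "--in",
              file.path(mdir, "summaries.csv"), "--out", model_json))
  model <- jsonlite::read_json(model_json)
  expect_true(all(c("beta0", "beta1", "beta2") %in% names(model)))

  report_json <- file.path(dir, "report.json")
  pwsim_cli(c("report", "--config", cfg, "--out", report_json))
  rep <- jsonlite::read_json(report_json)
  expect_lte(rep$after$mae, rep$before$mae)
  expect_equal(rep$provenance$seed, 5)
  expect_match(rep$provenance$config_hash, "^[0-9a-f]{32}$")

  # missing inputs: nonzero-style errors naming the problem
  expect_error(pwsim_cli(c("measure", "--config", cfg, "--in",
                           file.path(dir, "nowhere"), "--out", mdir)),
               "no trace CSVs")
  expect_error(pwsim_cli(c("unknown")), "unknown command")
  empty_trace <- file.path(dir, "empty", "trace_01.csv")
  dir.create(dirname(empty_trace))
  writeLines("time_s,pressure_mmHg", empty_trace)
  expect_error(pwsim_cli(c("measure", "--config", cfg, "--in",
                           dirname(empty_trace), "--out", mdir)),
               "trace_01")
})

test_that("identical config and seed give byte-identical outputs", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.json")
  sc <- fast_scenario(setpoints = data.frame(duty = c(0.3, 0.6, 0.9),
                                             base_pressure = 80),
                      duration_s = 4, seed = 11,
                      dut_bias = list(a = 0.95, b = 0.5, noise_sd = 0.03))
  jsonlite::write_json(scenario_to_list(sc), cfg, auto_unbox = TRUE,
                       digits = NA)
  t1 <- file.path(dir, "t1"); t2 <- file.path(dir, "t2")
  pwsim_cli(c("simulate", "--config", cfg, "--out", t1))
  pwsim_cli(c("simulate", "--config", cfg, "--out", t2))
  for (f in list.files(t1)) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  }
  r1 <- file.path(dir, "r1.json"); r2 <- file.path(dir, "r2.json")
  pwsim_cli(c("report", "--config", cfg, "--out", r1))
  pwsim_cli(c("report", "--config", cfg, "--out", r2))
  expect_identical(unname(tools::md5sum(r1)), unname(tools::md5sum(r2)))
})
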