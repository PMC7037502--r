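test_that("dataset CSV round trip is the identity to float-text precision", {
  ds <- generate_dataset(tiny_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_lt(max(abs(back$absorbance - ds$absorbance)), 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$split, ds$split)
  expect_equal(as.numeric(back$grid), as.numeric(ds$grid))
  expect_identical(back$class_names, ds$class_names)
  expect_identical(back$config$seed, ds$config$seed)
})

test_that("column count must match the wavenumber grid", {
  ds <- generate_dataset(tiny_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  expect_error(read_spectra(path, grid = wavenumber_grid(119L)),
               "119")
})

test_that("degenerate and malformed files are rejected with locations", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_spectra(empty))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_1,wavenumber_2,label,split",
               "0.1,0.2,1,train",
               "0.3,oops,2,test"), bad)
  expect_error(read_spectra(bad), "wavenumber_2")

  badlab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_1,wavenumber_2,label,split",
               "0.1,0.2,1,train",
               "0.3,0.4,0,test"), badlab)
  expect_error(read_spectra(badlab), "row 2")

  expect_error(read_spectra(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("evaluation reports serialize and read back unchanged", {
  rep <- evaluate(rep(1:13, each = 80L), rep(1:13, each = 80L), 13L)
  expect_equal(rep$accuracy, 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$confusion, rep$confusion)
  expect_equal(back$per_class_accuracy, rep$per_class_accuracy)

  # confusion is stored row-major in class order: rows = true class
  rep2 <- evaluate(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L), 2L)
  write_report(rep2, path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(unlist(raw$confusion[[1L]]), c(1L, 1L))
  expect_equal(unlist(raw$confusion[[2L]]), c(0L, 2L))
  expect_equal(raw$accuracy, 75)
})

test_that("run configurations are validated strictly", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectra(generate_dataset(tiny_cfg()), csv)
  good <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(data = csv, seed = 3L,
                        training = list(batch_size = 8L)), good)
  cfg <- read_run_config(good)
  expect_equal(cfg$seed, 3L)
  expect_equal(cfg$monitor, "validation")

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(data = csv, bogus = 1), bad)
  expect_error(read_run_config(bad), "bogus")

  bad2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(data = csv, training = list(typo = 2)), bad2)
  expect_error(read_run_config(bad2), "typo")

  bad3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(data = "/nonexistent/file.csv"), bad3)
  expect_error(read_run_config(bad3), "not found")
})
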