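make_spot_dir <- function(n = 5, seed = 1, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  set.seed(seed)
  for (i in seq_len(n)) {
    sp <- render_spot(64, 64, n_nuclei = 20, dab_fraction = runif(1))
    write_spot_image(sp$image, file.path(dir, sprintf("spot%02d.png", i)))
  }
  dir
}

test_that("run_analyze writes one row per image with a config header", {
  dir <- make_spot_dir(5)
  out <- file.path(dir, "spots.csv")
  res <- suppressMessages(run_analyze(dir, out))
  expect_equal(nrow(res), 5)
  expect_true(all(res$status == "ok"))
  hdr <- readLines(out, n = 5)
  expect_true(any(grepl("^# threshold_dab: 200", hdr)))
  expect_true(any(grepl("^# stain_h:", hdr)))
  back <- read.csv(out, comment.char = "#")
  expect_equal(back$extent, res$extent)
})

test_that("a corrupt file is logged but does not abort the batch", {
  dir <- make_spot_dir(4)
  writeLines("this is not a png", file.path(dir, "corrupt.png"))
  out <- file.path(dir, "spots.csv")
  expect_warning(res <- suppressMessages(run_analyze(dir, out)),
                 "corrupt")
  expect_equal(nrow(res), 5)
  expect_equal(sum(res$status == "ok"), 4)
  expect_equal(sum(res$status == "failed"), 1)
  # missing statistics are blank fields, not zeros
  raw <- readLines(out)
  expect_true(any(grepl("^\"?corrupt\"?,,,,,,\"?failed\"?$", raw)))
})

test_that("run_analyze is deterministic and errors on empty input", {
  dir <- make_spot_dir(3)
  o1 <- file.path(dir, "a.csv"); o2 <- file.path(dir, "b.csv")
  suppressMessages(run_analyze(dir, o1, pattern = "spot.*png$"))
  suppressMessages(run_analyze(dir, o2, pattern = "spot.*png$"))
  expect_identical(readLines(o1), readLines(o2))

  empty <- withr::local_tempdir()
  expect_error(run_analyze(empty, file.path(empty, "x.csv")), "no images")
})

test_that("run_aggregate on a single-core cohort passes spot values through", {
  dir <- withr::local_tempdir()
  spots <- data.frame(spot_id = c("s1", "s2", "s3"),
                      n_h_only = 1, n_dab = 1, n_union = 2,
                      extent = c(10, 50, 90), intensity = c(40, 50, 60),
                      status = "ok")
  write.csv(spots, file.path(dir, "spots.csv"), row.names = FALSE)
  write.csv(data.frame(spot_id = c("s1", "s2", "s3"),
                       patient_id = c("p1", "p2", "p3")),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  pat <- run_aggregate(file.path(dir, "spots.csv"),
                       file.path(dir, "manifest.csv"),
                       file.path(dir, "patients.csv"))
  expect_equal(pat$extent, c(10, 50, 90))
  expect_equal(pat$extent_group, c("low", "moderate", "high"))

  # missing manifest column is named in the error
  write.csv(data.frame(spot_id = "s1"), file.path(dir, "bad.csv"),
            row.names = FALSE)
  expect_error(run_aggregate(file.path(dir, "spots.csv"),
                             file.path(dir, "bad.csv"),
                             file.path(dir, "p2.csv")),
               "missing column: patient_id")
})

test_that("run_agreement on identical ratings gives kappa 1", {
  dir <- withr::local_tempdir()
  pat <- data.frame(patient_id = sprintf("p%d", 1:9),
                    extent_group = rep(c("low", "moderate", "high"), each = 3))
  vis <- data.frame(patient_id = pat$patient_id,
                    visual_category = rep(c("negative", "moderate", "high"),
                                          each = 3))
  write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(vis, file.path(dir, "visual.csv"), row.names = FALSE)
  res <- withr::with_output_sink(
    file.path(dir, "log.txt"),
    run_agreement(file.path(dir, "patients.csv"), file.path(dir, "visual.csv"),
                  file.path(dir, "agree")))
  expect_equal(res$stats$kappa_weighted, 1)
  expect_true(file.exists(file.path(dir, "agree_stats.json")))
  js <- jsonlite::read_json(file.path(dir, "agree_stats.json"))
  expect_equal(js$kappa_weighted, 1)
})

test_that("the simulated pipeline closes end to end with high agreement", {
  dir <- withr::local_tempdir()
  run_simulate(dir, n_patients = 40, seed = 99, width = 96, height = 96,
               n_nuclei = 40)
  suppressMessages(run_analyze(dir, file.path(dir, "spots.csv"),
                               pattern = "_c\\d+\\.png$"))
  pat <- run_aggregate(file.path(dir, "spots.csv"),
                       file.path(dir, "manifest.csv"),
                       file.path(dir, "patients.csv"))
  expect_equal(nrow(pat), 40)
  res <- withr::with_output_sink(
    file.path(dir, "log.txt"),
    run_agreement(file.path(dir, "patients.csv"), file.path(dir, "visual.csv"),
                  file.path(dir, "agree")))
  expect_gte(res$stats$kappa_weighted, 0.8)
})
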