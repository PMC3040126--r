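test_that("aggregate_patients takes the highest core per variable independently", {
  spots <- data.frame(spot_id = c("a", "b", "c"),
                      patient_id = c("p1", "p1", "p2"),
                      extent = c(2.0, 5.5, 7.0),
                      intensity = c(40.0, 38.0, 50.0))
  pat <- aggregate_patients(spots)
  expect_equal(pat$extent[pat$patient_id == "p1"], 5.5)
  expect_equal(pat$intensity[pat$patient_id == "p1"], 40.0)
  expect_equal(pat$extent[pat$patient_id == "p2"], 7.0)   # single core passthrough

  # max over non-missing, per variable; different cores may win each
  spots2 <- data.frame(spot_id = c("a", "b"), patient_id = "p1",
                       extent = c(NA, 3.0), intensity = c(40.0, NA))
  pat2 <- aggregate_patients(spots2)
  expect_equal(pat2$extent, 3.0)
  expect_equal(pat2$intensity, 40.0)

  # all-missing stays missing
  spots3 <- data.frame(spot_id = "a", patient_id = "p1",
                       extent = NA_real_, intensity = NA_real_)
  expect_true(is.na(aggregate_patients(spots3)$extent))
})

test_that("aggregation uses the manifest and rejects unmapped spots", {
  spots <- data.frame(spot_id = c("a", "b"), extent = c(1, 2),
                      intensity = c(10, 20))
  manifest <- data.frame(spot_id = "a", patient_id = "p1")
  expect_error(aggregate_patients(spots, manifest), "unknown patient.*b")

  manifest2 <- data.frame(spot_id = c("a", "b"), patient_id = c("p1", "p1"))
  expect_equal(aggregate_patients(spots, manifest2)$extent, 2)
})

test_that("aggregation is permutation-invariant and idempotent", {
  set.seed(5)
  spots <- data.frame(spot_id = sprintf("s%02d", 1:20),
                      patient_id = sample(sprintf("p%d", 1:7), 20, replace = TRUE),
                      extent = runif(20, 0, 95),
                      intensity = runif(20, 30, 70))
  a <- aggregate_patients(spots)
  b <- aggregate_patients(spots[sample(20), ])
  expect_equal(a, b)
  # re-aggregating the patient table (one row per patient) changes nothing
  again <- aggregate_patients(
    data.frame(spot_id = a$patient_id, patient_id = a$patient_id,
               extent = a$extent, intensity = a$intensity))
  expect_equal(again$extent, a$extent)
})

test_that("tertile_split cuts at the 1/3 and 2/3 inverse-CDF quantiles", {
  s <- tertile_split(1:9)
  expect_equal(unname(s$thresholds), c(3, 6))
  expect_equal(unname(s$counts), c(3, 3, 3))

  expect_error(tertile_split(c(1, 2)), "at least 3")
  expect_error(tertile_split(rep(5, 10)), "no variation")
})

test_that("splits match the sort-and-cut oracle on tie-free lists", {
  set.seed(31)
  x300 <- sample(seq(0.1, 100, by = 0.1), 300)
  s <- tertile_split(x300)
  o <- sort_cut_oracle(x300, rep(1, 3) / 3)
  expect_equal(unname(s$thresholds), unname(o$cuts))
  expect_equal(unname(s$counts), c(100, 100, 100))
  expect_equal(as.character(assign_groups(x300, s$thresholds)), o$groups)

  x1000 <- sample(seq(0.1, 400, by = 0.1), 1000)
  p <- c(0.077, 0.557, 0.366)
  sp <- proportion_split(x1000, p)
  op <- sort_cut_oracle(x1000, p)
  expect_equal(unname(sp$thresholds), unname(op$cuts))
  expect_true(all(abs(sp$counts - c(77, 557, 366)) <= 1))
})

test_that("proportion_split reduces to tertile_split and handles edge proportions", {
  set.seed(8)
  for (i in 1:10) {
    x <- runif(sample(10:200, 1), 0, 100)
    expect_equal(proportion_split(x, rep(1, 3) / 3)$thresholds,
                 tertile_split(x)$thresholds)
  }
  x <- runif(50, 0, 100)
  s <- proportion_split(x, c(1, 0, 0))
  expect_equal(unname(s$counts), c(50, 0, 0))   # everything low
  expect_error(proportion_split(x, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("group assignment respects one-decimal closed-interval boundaries", {
  g <- assign_groups(c(2.3, 2.4, 6.3, 6.4, 0.0, 100), c(2.3, 6.3))
  expect_equal(as.character(g),
               c("low", "moderate", "moderate", "high", "low", "high"))
  expect_true(is.na(assign_groups(NA_real_, c(2.3, 6.3))))
  # rounding happens before comparison: 2.34 -> 2.3 -> low
  expect_equal(as.character(assign_groups(2.34, c(2.3, 6.3))), "low")
  expect_error(assign_groups(1, c(6.3, 2.3)), "lower < upper")
})

test_that("group assignment partitions all non-missing patients", {
  set.seed(13)
  v <- c(runif(97, 0, 100), NA, NA, NA)
  s <- tertile_split(v)
  g <- assign_groups(v, s$thresholds)
  expect_equal(sum(!is.na(g)), 97)
  expect_equal(sum(table(g)), 97)
})
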