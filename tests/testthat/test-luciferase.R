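make_plate <- function(firefly, renilla, roles, conditions = NULL) {
  n <- length(firefly)
  if (is.null(conditions)) conditions <- roles
  out <- data.frame(
    well_id = paste0("W", seq_len(n)),
    condition = conditions,
    role = roles,
    replicate = 1L,
    firefly_raw = firefly,
    renilla_raw = renilla,
    stringsAsFactors = FALSE
  )
  class(out) <- c("luciferase_plate", "data.frame")
  out
}

test_that("background subtraction uses channel means and floors with a flag", {
  plate <- make_plate(
    firefly = c(80, 120, 600, 90),
    renilla = c(50, 50, 250, 500),
    roles = c("background", "background", "sample", "sample"),
    conditions = c("bg", "bg", "a", "b")
  )
  out <- subtract_background(plate)
  expect_equal(out$firefly[3], 600 - 100) # mean of 80 and 120
  expect_equal(out$renilla[3], 250 - 50)
  expect_equal(out$firefly[4], 0) # 90 - 100 floored
  expect_true(out$floored[4])
  expect_false(out$floored[3])
  expect_error(subtract_background(plate[plate$role != "background", ]),
    "background")
})

test_that("normalization endpoints and hand arithmetic are exact", {
  # duplicate ratios {5, 7}, controls 10 and 2 -> E = (6-2)/(10-2) = 0.5
  plate <- make_plate(
    firefly = c(0, 1000, 1000, 200, 200, 500, 700),
    renilla = c(0, 100, 100, 100, 100, 100, 100),
    roles = c(
      "background", "positive_control", "positive_control",
      "negative_control", "negative_control", "sample", "sample"
    ),
    conditions = c("bg", "pos", "pos", "neg", "neg", "cond", "cond")
  )
  eff <- editing_efficiency(plate)
  expect_equal(eff$efficiency, 0.5)
  expect_equal(eff$raw_ratio, 6)
  # wells identical to positive controls -> 1; to negative -> 0
  plate$firefly_raw[plate$role == "sample"] <- 1000
  expect_equal(editing_efficiency(plate)$efficiency, 1.0)
  plate$firefly_raw[plate$role == "sample"] <- 200
  expect_equal(editing_efficiency(plate)$efficiency, 0.0)
})

test_that("efficiency is invariant to a common luminescence rescaling", {
  layout <- plate_layout(c("g1", "g2"))
  plate <- simulate_plate(
    layout, c(g1 = 0.38, g2 = 0.8),
    noise_cv = 0.05, seed = 4
  )
  e1 <- editing_efficiency(plate)
  plate2 <- plate
  plate2$firefly_raw <- plate2$firefly_raw * 3.7
  plate2$renilla_raw <- plate2$renilla_raw * 3.7
  e2 <- editing_efficiency(plate2)
  expect_equal(e2$efficiency, e1$efficiency, tolerance = 1e-12)
})

test_that("noiseless simulated plates round-trip the generative truths exactly", {
  layout <- plate_layout(c("a", "b", "c"))
  truths <- c(a = 0.5, b = 1.0, c = 0.0)
  plate <- simulate_plate(layout, truths, noise_cv = 0, seed = 1)
  eff <- editing_efficiency(plate)
  expect_equal(
    stats::setNames(eff$efficiency, eff$condition), truths,
    tolerance = 1e-12
  )
  # efficiency 1 wells equal the positive-control wells
  expect_equal(
    plate$firefly_raw[plate$condition == "b"],
    rep(plate$firefly_raw[plate$role == "positive_control"][1], 2)
  )
})

test_that("noisy plates recover the generative truth on average", {
  layout <- plate_layout("g")
  recovered <- vapply(1:100, function(i) {
    plate <- simulate_plate(layout, c(g = 0.38), noise_cv = 0.05, seed = i)
    editing_efficiency(plate)$efficiency
  }, numeric(1))
  mc_sem <- stats::sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - 0.38), 3 * mc_sem + 0.005)
})

test_that("raising Firefly in a condition never lowers its efficiency", {
  layout <- plate_layout("g")
  plate <- simulate_plate(layout, c(g = 0.3), noise_cv = 0.02, seed = 2)
  e0 <- editing_efficiency(plate)$efficiency
  plate$firefly_raw[plate$condition == "g"] <-
    plate$firefly_raw[plate$condition == "g"] * 1.5
  expect_gte(editing_efficiency(plate)$efficiency, e0)
})

test_that("degenerate plates are rejected and flags are set, not clamped", {
  plate <- make_plate(
    firefly = c(0, 500, 500, 900),
    renilla = c(0, 100, 100, 100),
    roles = c("background", "positive_control", "negative_control", "sample"),
    conditions = c("bg", "pos", "neg", "cond")
  )
  expect_error(editing_efficiency(plate), "degenerate dynamic range")
  expect_error(
    simulate_plate(
      plate[plate$role != "background", ], c(cond = 0.5)
    ),
    "background"
  )
  plate$firefly_raw[2] <- 1000
  plate$firefly_raw[4] <- 2000
  eff <- editing_efficiency(plate)
  expect_gt(eff$efficiency, 1.05)
  expect_true(eff$out_of_range)
})

test_that("plate TSV round trip preserves raw values", {
  layout <- plate_layout("g")
  plate <- simulate_plate(layout, c(g = 0.4), noise_cv = 0.05, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_plate_tsv(plate, tf)
  back <- read_plate_tsv(tf)
  expect_equal(back$firefly_raw, plate$firefly_raw, tolerance = 1e-9)
  expect_identical(back$role, plate$role)
})
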