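test_that("the band-pass assay is deterministic and handles the all-pass window", {
  b1 <- bandpass_assay(max_steps = 50)
  b2 <- bandpass_assay(max_steps = 50)
  expect_identical(b1$mask, b2$mask)
  expect_identical(b1$steps_to_stability, b2$steps_to_stability)
  expect_identical(b1$conc, b2$conc)

  # window [0, Inf): every receiver fluoresces from the first step
  all_pass <- bandpass_assay(window = c(0, Inf), max_steps = 20)
  expect_equal(all_pass$steps_to_stability, 1L)
  expect_equal(sum(all_pass$mask), 21 * 21 - 4)
})

test_that("ring geometry: a strong central source carves an annulus with inner <= outer", {
  bp <- bandpass_assay(secretion_rate = 1.6, max_steps = 120,
                       stability_window = 1000)   # inspect a fixed horizon
  expect_false(bp$stable)
  expect_gt(sum(bp$mask), 0)
  expect_lte(bp$inner_extent_blocks, bp$outer_extent_blocks)
  expect_gt(bp$inner_extent_blocks, 0)     # over-threshold core is dark
  expect_equal(bp$outer_extent_mm, bp$outer_extent_blocks * 3)
  # sender squares are never part of the fluorescence mask
  expect_false(any(bp$mask[cbind(bp$senders$y + 1, bp$senders$x + 1)]))
})

test_that("widening the band-pass window never shrinks the fluorescing set", {
  narrow <- bandpass_assay(secretion_rate = 1.6, window = c(10, 200),
                           max_steps = 80, stability_window = 1000)
  wide <- bandpass_assay(secretion_rate = 1.6, window = c(5, 400),
                         max_steps = 80, stability_window = 1000)
  expect_true(all(wide$mask[narrow$mask]))
  expect_gte(sum(wide$mask), sum(narrow$mask))
})

test_that("two separated sender clusters produce a union of rings", {
  senders <- data.frame(x = c(5, 15), y = c(10, 10))
  bp <- bandpass_assay(senders = senders, secretion_rate = 1.6,
                       max_steps = 100, stability_window = 1000)
  idx <- which(bp$mask, arr.ind = TRUE)
  d1 <- sqrt((idx[, 1] - 11)^2 + (idx[, 2] - 6)^2)
  d2 <- sqrt((idx[, 1] - 11)^2 + (idx[, 2] - 16)^2)
  # fluorescence surrounds both clusters
  expect_gt(sum(d1 < d2), 0)
  expect_gt(sum(d2 < d1), 0)
  # and the pattern is mirror-symmetric about the midline between them
  expect_identical(bp$mask, bp$mask[, rev(seq_len(ncol(bp$mask)))])
})

test_that("single-sender layout places one central block", {
  bp <- bandpass_assay(senders = "single", max_steps = 10, stability_window = 1000)
  expect_equal(nrow(bp$senders), 1L)
  expect_equal(bp$senders$x, 10)
})

test_that("directional classification partitions all division events", {
  pg <- preferential_growth_assay(n_runs = 6, n_steps = 10, seed = 11)
  expect_equal(nrow(pg$per_run), 12L)           # 6 runs x 2 strains
  # recompute totals from an independent engine run for one replicate
  cons <- make_consortium(2)
  pat <- seed_parallel_lines(c("S1", "S2"), length = 8, separation = 10)
  cfg <- simulation_config(create_grid(21, 21), cons$strains, pat,
                           n_steps = 10, seed = quorumCA:::derive_seed(11, 3))
  tr <- run_simulation(cfg)
  for (s in c("S1", "S2")) {
    row <- pg$per_run[pg$per_run$run == 3 & pg$per_run$strain == s, ]
    expect_equal(row$toward + row$away + row$neutral,
                 sum(tr$events$strain == s))
  }
})

test_that("the assay geometry is validated", {
  expect_error(preferential_growth_assay(n_runs = 1), "two runs")
  expect_error(preferential_growth_assay(
    n_runs = 2, pattern = seed_random(c("S1", "S2"), 4, seed = 1)),
    "parallel_lines")
  expect_error(preferential_growth_assay(n_runs = 2,
                                         overrides = list(SX = list(threshold = 1))),
               "unknown strain")
})

test_that("a single-iteration sweep equals a direct engine run with the derived seed", {
  sw <- single_parameter_sweep("secretion_rate", values = 5e-2, n_strains = 2,
                               n_iter = 1, n_steps = 8, seed = 9)
  cons <- make_consortium(2)
  cons$strains[[1]]$secretion_rate <- 5e-2
  rs <- quorumCA:::derive_seed(9, 1)
  cfg <- simulation_config(create_grid(21, 21), cons$strains,
                           seed_random(c("S1", "S2"), 4, seed = rs),
                           n_steps = 8, seed = rs)
  fc <- final_counts(run_simulation(cfg))
  got <- sw$runs[order(sw$runs$strain), ]
  expect_equal(got$count, as.integer(fc[order(names(fc))]))
})

test_that("sweep means are robust to the root seed (within 3 standard errors)", {
  a <- single_parameter_sweep("fitness_gain", values = 0.05, n_iter = 15,
                              n_steps = 10, seed = 1)
  b <- single_parameter_sweep("fitness_gain", values = 0.05, n_iter = 15,
                              n_steps = 10, seed = 999)
  for (s in c("S1", "S2")) {
    ma <- a$summary$mean_count[a$summary$strain == s]
    mb <- b$summary$mean_count[b$summary$strain == s]
    se <- sqrt(a$summary$sd_count[a$summary$strain == s]^2 / 15 +
               b$summary$sd_count[b$summary$strain == s]^2 / 15)
    expect_lt(abs(ma - mb), 3 * se)
  }
})

test_that("sweeps validate their inputs", {
  expect_error(single_parameter_sweep("colour", 1), "arg")
  expect_error(single_parameter_sweep("threshold", numeric(0)), "at least one")
  expect_error(grid_search(secretion_values = numeric(0), n_iter = 1), "empty")
})

test_that("three-strain sweeps carry the ring topology into the engine", {
  sw <- single_parameter_sweep("threshold", values = 5, n_strains = 3,
                               n_iter = 2, n_steps = 5, seed = 4)
  expect_setequal(unique(sw$runs$strain), c("S1", "S2", "S3"))
  expect_equal(nrow(sw$summary), 3L)
})

test_that("the default source saturates far below the band-pass window", {
  # constant default-rate secretion against first-order decay plateaus near
  # 3.4 nM at the sender cluster: the 10 nM window floor is out of reach
  bp <- bandpass_assay(max_steps = 1000, stability_window = 2000)
  peak <- max(bp$conc)
  expect_gt(peak, 3)
  expect_lt(peak, 3.6)
  expect_equal(sum(bp$mask), 0)
})
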