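test_that("window plans are evenly spaced with the protocol arithmetic", {
  # 64 windows at 4-degree intervals from 0 end at 252 degrees
  w <- make_windows(0, 4, 64, 0.183)
  expect_length(w, 64)
  expect_equal(w[[64]]$center, 252)
  expect_equal(vapply(w, function(x) x$k, numeric(1)), rep(0.183, 64))

  expect_equal(make_windows(10, 5, 1, 1)[[1]]$center, 10)
  expect_equal(vapply(make_windows(0, 4, 3, 1), `[[`, numeric(1), "center"),
               c(0, 4, 8))
  expect_error(make_windows(0, -1, 3, 1), "spacing")
})

test_that("bias energy uses the restraint convention k*dtheta^2", {
  b <- bias_potential(100, 0.183)
  expect_equal(bias_energy(b, 100), 0)
  expect_equal(bias_energy(b, 104), 0.183 * 16)  # 2.928 kcal/mol
  expect_equal(bias_energy(b, 104), bias_energy(b, 96))
  expect_equal(bias_energy(b, 104, half = TRUE), 0.5 * 0.183 * 16)
})

test_that("an unbiased uniform window unbiases to a flat PMF", {
  set.seed(31)
  w <- umbrella_window(bias_potential(0, 0), runif(50000, 0, 50))
  p <- anchor_zero(wham(list(w), bin_width = 2), 25)
  ok <- !is.na(p$G) & p$counts >= 200
  expect_gt(sum(ok), 15)
  expect_lt(max(abs(p$G[ok])), 0.1)
})

test_that("a single harmonic window on a flat landscape recovers flat G", {
  cfg <- sampler_config(n_samples = 200000, burn_in = 2000, step_sd = 3, seed = 32)
  w <- sample_window(make_landscape("flat"), bias_potential(50, 0.183), cfg)
  # thin the chain so per-bin counts are effectively independent draws
  w <- umbrella_window(w$bias, w$samples[seq(1, 200000, by = 10)])
  p <- anchor_zero(wham(list(w)), 50)
  ok <- !is.na(p$G) & p$counts >= 200
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(p$G[ok])), 0.1)
})

test_that("WHAM is invariant to window order, duplication, and splitting", {
  ls <- make_landscape("double_well")
  wins <- make_windows(40, 4, 31, 0.183)
  windows <- lapply(seq_along(wins), function(i) {
    sample_window(ls, wins[[i]], sampler_config(n_samples = 1500, seed = 100 + i))
  })
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  p0 <- anchor_zero(wham(windows, range = rng), 60)

  p_rev <- anchor_zero(wham(rev(windows), range = rng), 60)
  expect_equal(p_rev$G, p0$G, tolerance = 1e-10)

  p_dup <- anchor_zero(wham(c(windows, windows), range = rng), 60)
  expect_equal(p_dup$G, p0$G, tolerance = 1e-8)

  # split one window's samples into two windows with the same bias
  w1 <- windows[[1]]
  h1 <- umbrella_window(w1$bias, w1$samples[1:750])
  h2 <- umbrella_window(w1$bias, w1$samples[751:1500])
  p_split <- anchor_zero(wham(c(list(h1, h2), windows[-1]), range = rng), 60)
  expect_equal(p_split$G, p0$G, tolerance = 1e-8)
})

test_that("WHAM recovers a known double-well landscape from biased windows", {
  ls <- make_landscape("double_well")
  wins <- make_windows(30, 4, 46, 0.183)
  two_runs <- lapply(c(300, 900), function(base) {
    lapply(seq_along(wins), function(i) {
      sample_window(ls, wins[[i]],
                    sampler_config(n_samples = 3000, seed = base + i))
    })
  })
  rng <- range(unlist(lapply(two_runs, lapply, `[[`, "samples")))
  profs <- lapply(two_runs, function(ws) anchor_zero(wham(ws, range = rng), 60))
  comb <- two_run_error(profs[[1]], profs[[2]])
  expect_lt(recovery_rms(ls, comb), 0.25)
})

test_that("disconnected window coverage and non-convergence are reported", {
  set.seed(33)
  w1 <- umbrella_window(bias_potential(0, 0.183), rnorm(500, 0, 1))
  w2 <- umbrella_window(bias_potential(50, 0.183), rnorm(500, 50, 1))
  expect_error(wham(list(w1, w2)), "coverage|overlap")
  w3 <- umbrella_window(bias_potential(2, 0.183), rnorm(500, 2, 1))
  expect_error(wham(list(w1, w3), max_iter = 1L, tol = 1e-300), "converge")
})

test_that("anchoring shifts by a constant and preserves differences", {
  set.seed(34)
  w <- umbrella_window(bias_potential(10, 0.183), rnorm(5000, 10, 1.5))
  p <- wham(list(w))
  a1 <- anchor_zero(p, 10)
  expect_equal(a1$G[baseflip:::.anchor_bin(a1, 10)], 0)
  # anchoring an already-zero profile is a no-op
  expect_equal(anchor_zero(a1, 10)$G, a1$G)
  # adding a constant then re-anchoring recovers the profile
  shifted <- a1; shifted$G <- shifted$G + 5
  expect_equal(anchor_zero(shifted, 10)$G, a1$G, tolerance = 1e-12)
  # two different anchors differ by a constant only
  a2 <- anchor_zero(p, 11)
  d <- a1$G - a2$G
  d <- d[!is.na(d)]
  expect_lt(diff(range(d)), 1e-10)
})

test_that("two-run combination averages G and halves the run difference", {
  set.seed(35)
  w1 <- umbrella_window(bias_potential(10, 0.183), rnorm(4000, 10, 1.5), run_id = 1)
  w2 <- umbrella_window(bias_potential(10, 0.183), rnorm(4000, 10, 1.5), run_id = 2)
  rng <- range(c(w1$samples, w2$samples))
  p1 <- anchor_zero(wham(list(w1), range = rng), 10)
  p2 <- anchor_zero(wham(list(w2), range = rng), 10)

  same <- two_run_error(p1, p1)
  expect_equal(same$error[!is.na(same$error)],
               rep(0, sum(!is.na(same$error))))

  p2b <- p1
  p2b$G <- p1$G + 1  # runs differing by +1 kcal/mol everywhere
  comb <- two_run_error(p1, p2b)
  ok <- !is.na(comb$G)
  expect_equal(comb$error[ok], rep(0.5, sum(ok)))
  expect_equal(comb$G[ok], p1$G[ok] + 0.5)

  real <- two_run_error(p1, p2)
  expect_true(all(real$error[!is.na(real$error)] >= 0))
  expect_error(two_run_error(p1, wham(list(w1), bin_width = 2)), "anchored|binning")
})

test_that("barrier and endpoint statistics follow the profile shape", {
  bins <- seq(0.5, 99.5, by = 1)
  mono <- baseflip:::new_pmf_profile(bins, bins / 10, rep(NA_real_, 100),
                                     rep(100L, 100))
  s <- barrier_and_endpoint_stats(mono, c(0, 100))
  expect_equal(s$dG_endpoints, (99.5 - 0.5) / 10)
  expect_equal(s$barrier, s$dG_endpoints)  # crest at segment end

  flat <- baseflip:::new_pmf_profile(bins, rep(0, 100), rep(NA_real_, 100),
                                     rep(100L, 100))
  sf <- barrier_and_endpoint_stats(flat, c(0, 100))
  expect_equal(sf$dG_endpoints, 0)
  expect_equal(sf$barrier, 0)

  # symmetric double well with a constructed crest height
  crest <- landscape(4.5, 50, 10)
  prof <- analytic_profile(crest, bins)
  sc <- barrier_and_endpoint_stats(prof, c(0.5, 99.5))
  expect_equal(sc$barrier, 4.5, tolerance = 1e-2)  # crest sits between bins
  expect_equal(sc$dG_endpoints, 0, tolerance = 1e-3)

  masked <- mono; masked$G[50] <- NA
  expect_error(barrier_and_endpoint_stats(masked, c(0, 100)), "masked")
  si <- barrier_and_endpoint_stats(masked, c(0, 100), interpolate = TRUE)
  expect_equal(si$dG_endpoints, s$dG_endpoints)
})
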