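test_that("active-enzyme normalization scales the effective concentration", {
  ds <- kinetics_dataset(S = c(2, 10, 50), v0 = c(0.1, 0.3, 0.5),
                         E_total = 2, active_fraction = 0.5)
  expect_equal(normalize_active(ds), 1)
  ds2 <- kinetics_dataset(S = c(2, 10, 50), v0 = c(0.1, 0.3, 0.5),
                          E_total = 2, active_fraction = 1)
  expect_equal(normalize_active(ds2), 2)
  expect_error(kinetics_dataset(S = 1, v0 = 1, E_total = 1, active_fraction = 1.2),
               "active_fraction")
})

test_that("halving the active fraction doubles the fitted k_cat", {
  S <- c(2, 5, 10, 20, 35, 50, 75, 100)
  v0 <- 1.7 * 0.5 * 1 * S / (8.1 + S)
  ds_hi <- kinetics_dataset(S, v0, E_total = 1, active_fraction = 0.5)
  ds_lo <- kinetics_dataset(S, v0, E_total = 1, active_fraction = 0.25)
  f_hi <- mm_fit(ds_hi); f_lo <- mm_fit(ds_lo)
  expect_equal(f_lo$k_cat, 2 * f_hi$k_cat, tolerance = 1e-8)
  expect_equal(f_lo$K_M, f_hi$K_M, tolerance = 1e-8)
})

test_that("noiseless Michaelis-Menten data are recovered to 1e-6 relative", {
  for (km in c(3, 8.1, 40)) {
    ds <- generate_kinetics_data(K_M = km, k_cat = 1.7, E_total = 1,
                                 active_fraction = 0.6, noise_sd = 0,
                                 replicates = 2, seed = 51)
    fit <- mm_fit(ds)
    expect_equal(fit$K_M, km, tolerance = 1e-6)
    expect_equal(fit$k_cat, 1.7, tolerance = 1e-6)
    expect_equal(fit$k_sp, fit$k_cat / fit$K_M, tolerance = 1e-12)
  }
  # v0 at [S] = K_M equals half of k_cat [E]_active
  ds <- generate_kinetics_data(K_M = 10, k_cat = 2, E_total = 1,
                               active_fraction = 0.5, S = c(2, 5, 10, 50),
                               noise_sd = 0, replicates = 1, seed = 52)
  expect_equal(ds$records$v0[ds$records$S == 10], 2 * 0.5 * 1 / 2)
})

test_that("wild-type parameters imply k_sp = 0.21 after 2-sf rounding", {
  ds <- generate_kinetics_data(K_M = 8.1, k_cat = 1.7, E_total = 1,
                               active_fraction = 1, noise_sd = 0,
                               replicates = 3, seed = 53)
  fit <- mm_fit(ds)
  expect_equal(signif(fit$k_sp, 2), 0.21)
})

test_that("linear-slope k_sp matches its generating slope and scaling law", {
  S <- c(2, 5, 10, 20)
  E <- 1
  ds <- kinetics_dataset(S, 0.0039 * E * S, E_total = E, active_fraction = 1,
                         enzyme = "R108K")
  fit <- linear_ksp(ds)
  expect_equal(fit$k_sp, 0.0039, tolerance = 1e-12)
  expect_equal(fit$mode, "linear-slope")
  expect_true(is.na(fit$K_M) && is.na(fit$k_cat))

  # doubling [E] at fixed k_sp doubles the raw slope, leaving k_sp fixed
  ds2 <- kinetics_dataset(S, 0.0039 * 2 * E * S, E_total = 2 * E,
                          active_fraction = 1)
  expect_equal(linear_ksp(ds2)$k_sp, 0.0039, tolerance = 1e-12)

  ds0 <- kinetics_dataset(S, rep(0, 4), E_total = E, active_fraction = 1)
  expect_error(linear_ksp(ds0), "slope")
})

test_that("linear k_sp agrees with the saturable k_cat/K_M limit", {
  km <- 100
  S <- c(0.5, 1, 2, 5)  # max[S] = K_M/20
  v0 <- 1.2 * 1 * S / (km + S)
  ds <- kinetics_dataset(S, v0, E_total = 1, active_fraction = 1)
  lin <- linear_ksp(ds)
  expect_equal(lin$k_sp, 1.2 / km, tolerance = 0.02)
})

test_that("k_sp is invariant to joint rescaling of v0 and [E]", {
  ds <- generate_kinetics_data(K_M = 8.1, k_cat = 1.7, E_total = 1,
                               active_fraction = 1, noise_sd = 0.03,
                               replicates = 3, seed = 54)
  fit <- mm_fit(ds)
  ds_scaled <- kinetics_dataset(ds$records$S, 10 * ds$records$v0,
                                ds$records$replicate, E_total = 10,
                                active_fraction = 1)
  fit2 <- mm_fit(ds_scaled)
  expect_equal(fit2$k_sp, fit$k_sp, tolerance = 1e-8)
})

test_that("relative activity ratios the reported k_sp values", {
  expect_equal(relative_activity(0.21, 0.21), 100)
  # mutant entries against the wild type
  expect_equal(relative_activity(0.070 / 18.0, 1.7 / 8.1), 1.9)
  expect_equal(relative_activity(0.16 / 8.1, 1.7 / 8.1), 9.5)
  expect_error(relative_activity(0.1, 0), "k_sp")
})

test_that("the report table reproduces a full published-style kinetics table", {
  sat <- list("Wild-type" = c(8.1, 1.7), "R108K" = c(18.0, 0.070),
              "N168Q" = c(8.1, 0.16), "R258Q" = c(6.3, 0.08))
  lin <- list("R108L" = 6.4e-4, "R108Q" = 6.4e-4, "N168D" = 4.7e-4,
              "R258A" = 7.6e-4, "R258K" = 6.0e-4)
  fits <- c(
    lapply(names(sat), function(nm) {
      ds <- generate_kinetics_data(K_M = sat[[nm]][1], k_cat = sat[[nm]][2],
                                   E_total = 1, noise_sd = 0, replicates = 3,
                                   seed = 55, enzyme = nm)
      mm_fit(ds)
    }),
    lapply(names(lin), function(nm) {
      S <- c(2, 5, 10, 20)
      linear_ksp(kinetics_dataset(S, lin[[nm]] * S, E_total = 1,
                                  active_fraction = 1, enzyme = nm))
    })
  )
  tab <- table_report(fits, wildtype = "Wild-type")
  rownames(tab) <- tab$enzyme
  expect_equal(tab["Wild-type", "k_sp_per_nM_s"], "0.21")
  expect_equal(tab["R108K", "k_sp_per_nM_s"], "0.0039")
  expect_equal(tab["N168Q", "k_sp_per_nM_s"], "0.02")
  expect_equal(tab["R258Q", "k_sp_per_nM_s"], "0.013")
  expect_equal(tab["R108L", "K_M_nM"], "n/d")
  expect_equal(tab["R108L", "k_cat_per_s"], "n/d")
  expect_equal(tab[c("Wild-type", "R108K", "R108L", "R108Q", "N168D",
                     "N168Q", "R258A", "R258Q", "R258K"),
                   "relative_activity_pct"],
               c(100, 1.9, 0.3, 0.3, 0.2, 9.5, 0.4, 6.2, 0.3))

  expect_error(table_report(fits[c(1, 1)]), "duplicate")
  expect_error(table_report(fits[-1]), "not found")
})

test_that("kinetics CSV round-trips into datasets", {
  f <- withr::local_tempfile(fileext = ".csv")
  ds <- generate_kinetics_data(K_M = 8.1, k_cat = 1.7, E_total = 1,
                               active_fraction = 0.4, noise_sd = 0.05,
                               replicates = 2, seed = 56, enzyme = "WT")
  write_kinetics_csv(ds, f)
  back <- read_kinetics_csv(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$records$v0, ds$records$v0, tolerance = 1e-9)
  expect_equal(back[[1]]$active_fraction, 0.4)
})
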