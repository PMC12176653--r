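test_that("single-dose tables reproduce the closed form -ln(F_neg)/d", {
  tab <- data.frame(dose_cells = 1L, n_wells = 100L, n_responding = 61L)
  f <- fit_single_hit(tab)
  expect_equal(f$frequency, -log(0.39), tolerance = 1e-8)
  expect_equal(f$potency * f$frequency, 1)
  expect_true(f$ci_lower <= f$potency && f$potency <= f$ci_upper)

  tab2 <- data.frame(dose_cells = 5L, n_wells = 60L, n_responding = 45L)
  f2 <- fit_single_hit(tab2)
  expect_equal(f2$frequency, -log(15 / 60) / 5, tolerance = 1e-8)
})

test_that("boundary tables are flagged as non-estimable, never silent", {
  allpos <- data.frame(dose_cells = c(20L, 1L), n_wells = 8L,
                       n_responding = 8L)
  expect_warning(f <- fit_single_hit(allpos), "upper boundary")
  expect_equal(f$boundary, "all_responding")
  expect_true(is.na(f$frequency))

  allneg <- data.frame(dose_cells = c(20L, 1L), n_wells = 8L,
                       n_responding = 0L)
  expect_warning(f2 <- fit_single_hit(allneg), "lower boundary")
  expect_equal(f2$boundary, "none_responding")
})

test_that("the GLM solution matches a brute-force likelihood grid", {
  # extreme but estimable: everything responds at dose 20, nothing at 1
  tab <- data.frame(dose_cells = c(20L, 1L), n_wells = c(8L, 8L),
                    n_responding = c(8L, 0L))
  loglik <- function(f) {
    p <- 1 - exp(-f * tab$dose_cells)
    sum(dbinom(tab$n_responding, tab$n_wells, p, log = TRUE))
  }
  fgrid <- exp(seq(log(1e-4), log(1), length.out = 20000))
  fstar <- fgrid[which.max(vapply(fgrid, loglik, numeric(1)))]
  fit <- fit_single_hit(tab)
  expect_gt(fit$frequency, 1 / 20)
  expect_lte(fit$frequency, 1)
  expect_equal(fit$frequency, fstar, tolerance = 1e-3)
  expect_equal(fit$log_lik, loglik(fstar), tolerance = 1e-4)
})

test_that("adding responding wells never decreases the estimated frequency", {
  for (s in 1:12) {
    tab <- generate_limiting_dilution(0.3, wells_per_dose = 10L, seed = s)
    base <- suppressWarnings(fit_single_hit(tab))
    if (base$boundary != "none") next
    i <- which(tab$n_responding < tab$n_wells)[1]
    if (is.na(i)) next
    tab2 <- tab
    tab2$n_responding[i] <- tab2$n_responding[i] + 1L
    more <- suppressWarnings(fit_single_hit(tab2))
    if (more$boundary != "none") next
    expect_gte(more$frequency, base$frequency - 1e-10)
  }
})

test_that("profile-likelihood intervals are available and ordered", {
  tab <- generate_limiting_dilution(1 / 3, seed = 4)
  w <- fit_single_hit(tab, ci = "wald")
  p <- fit_single_hit(tab, ci = "profile")
  expect_true(p$ci_lower <= p$potency && p$potency <= p$ci_upper)
  expect_equal(w$frequency, p$frequency)
})

test_that("the slope test accepts exact single-hit expectations", {
  d <- c(20L, 10L, 3L, 1L)
  n <- 96L
  exp_resp <- round(n * (1 - exp(-d / 3)))
  tab <- data.frame(dose_cells = d, n_wells = n, n_responding = exp_resp)
  st <- slope_test(tab)
  expect_gt(st$p_value, 0.5)
  expect_equal(st$slope, 1, tolerance = 0.1)

  one <- data.frame(dose_cells = 5L, n_wells = 8L, n_responding = 4L)
  expect_error(slope_test(one), "2 distinct doses")
})
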