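test_that("initial rates are exact on linear traces and skip the plateau", {
  tr <- kinetic_trace(0:20, 5 * (0:20))
  r <- initial_rate(tr)
  expect_equal(r$slope, 5)
  expect_equal(r$se, 0)
  expect_equal(r$quality, "ok")
  # line then plateau: the window excludes the plateau and recovers the
  # generating rate exactly, while a whole-trace fit underestimates it
  trp <- simulate_trace(5, noise = 0, seed = 1, plateau_at = 2000)
  rp <- initial_rate(trp)
  expect_equal(rp$slope, 5, tolerance = 1e-9)
  full <- lm(trp$rfu ~ trp$times)
  expect_lt(coef(full)[[2]], 4.9)
  expect_lt(rp$window[2], length(trp$times))
  # window selection never includes points below the background threshold
  bg_level <- 100; bg_sd <- 5
  rfu <- c(rep(bg_level, 6), bg_level + 3 * bg_sd + 10 * (1:20))
  trb <- kinetic_trace(seq_along(rfu), rfu)
  rb <- initial_rate(trb, background = c(bg_level, bg_sd))
  expect_gte(rb$window[1], 7L)
  expect_equal(rb$slope, 10)
  # a flat trace yields a flagged estimate with a warning, never silence
  expect_warning(rf <- initial_rate(kinetic_trace(1:10, rep(3, 10))),
                 "initial_rate")
  expect_false(rf$quality == "ok")
})

test_that("regression SE agrees with a residual-bootstrap oracle", {
  set.seed(71)
  n <- 50
  t <- seq(0, 300, length.out = n)
  y <- 40 + 2.5 * t + rnorm(n, sd = 12)
  r <- initial_rate(kinetic_trace(t, y), r2_min = 0.9)
  fit <- lm(y ~ t)
  res <- residuals(fit)
  boot <- replicate(2000, {
    yb <- fitted(fit) + sample(res, n, replace = TRUE)
    coef(lm(yb ~ t))[[2]]
  })
  expect_lt(abs(r$se - sd(boot)) / sd(boot), 0.15)
  expect_equal(r$slope, coef(fit)[[2]], tolerance = 1e-6)
})

test_that("fold changes propagate errors and honour the reciprocal convention", {
  mk <- function(s, e) structure(list(slope = s, se = e, window = c(1, 10),
                                      r2 = 1, quality = "ok", well = "",
                                      variant = ""), class = "iflc_rate")
  eq <- fold_change(list(mk(3, 0.1), mk(3, 0.1)), list(mk(3, 0.1), mk(3, 0.1)))
  expect_equal(eq$ratio, 1)
  # OFF-switch: reported as fold repression >= 1
  off <- fold_change(mk(1, 0.05), mk(8, 0.2), variant = "2-A5")
  expect_equal(off$direction, "OFF")
  expect_equal(off$ratio, 8)
  # propagated SE matches a Monte-Carlo oracle within 10%
  set.seed(72)
  fc <- fold_change(mk(10, 0.3), mk(2, 0.1))
  mc <- replicate(10000, (10 + 0.3 * rnorm(1)) / (2 + 0.1 * rnorm(1)))
  expect_lt(abs(fc$se - sd(mc)) / sd(mc), 0.10)
  # an OFF-state rate indistinguishable from background becomes a bound
  bd <- fold_change(mk(8, 0.2), mk(0.05, 0.04), variant = "1-A9")
  expect_true(bd$is_bound)
  expect_true(is.na(bd$se))
  expect_gt(bd$ratio, 1)
  expect_error(fold_change(list(), mk(1, 0.1)), "non-empty")
})

test_that("KD fitting recovers tight-binding constants and degrades loudly", {
  # tight-binding activation at E comparable to KD
  ds <- simulate_dose_series("kd-tight", true_K = 20e-9, enzyme_conc = 20e-9,
                             noise = 0)
  fit <- fit_kd(ds$doses, ds$rates, enzyme_conc = 20e-9)
  expect_equal(fit$model_id, "KD-tight-binding")
  expect_lt(abs(fit$estimate - 20e-9) / 20e-9, 0.05)
  # the tight-binding form reduces to the hyperbola as E/K -> 0
  K <- 5e-6
  dsh <- simulate_dose_series("kd-tight", K, enzyme_conc = K * 1e-3, noise = 0)
  fh <- fit_kd(dsh$doses, dsh$rates, enzyme_conc = K * 1e-3,
               model = "hyperbolic")
  ft <- fit_kd(dsh$doses, dsh$rates, enzyme_conc = K * 1e-3, model = "tight")
  expect_lt(abs(fh$estimate - ft$estimate) / ft$estimate, 0.01)
  # no curvature in the dosed range: explicit non-identifiability failure
  flat <- simulate_dose_series("kd-hyperbolic", true_K = 10, enzyme_conc = 1e-9,
                               noise = 0)
  expect_error(fit_kd(flat$doses, flat$rates, 1e-9), class = "iflc_fit_error")
  # design preconditions
  expect_error(fit_kd(c(1e-6, 2e-6, 4e-6), c(1, 2, 3), 1e-9),
               class = "iflc_fit_error")
})

test_that("Ki fitting recovers inhibition constants and flags null designs", {
  ds <- simulate_dose_series("ki-hyperbolic", true_K = 4.5e-6,
                             enzyme_conc = 20e-9, noise = 0)
  fit <- fit_ki(ds$doses, ds$rates, enzyme_conc = 20e-9)
  expect_equal(fit$model_id, "Ki-competitive")
  expect_lt(abs(fit$estimate - 4.5e-6) / 4.5e-6, 0.05)
  # zero-noise series lies exactly on the fitted curve
  expect_equal(predict(fit), ds$rates, tolerance = 1e-6)
  # IC50 from the fitted curve is consistent with Ki under the model's own
  # conversion (root-finding on the curve; hyperbolic: IC50 == Ki)
  expect_lt(abs(ic50(fit) - fit$estimate) / fit$estimate, 1e-3)
  # all inhibitor doses zero: failure flag
  expect_error(fit_ki(rep(0, 8), rep(5, 8), 20e-9), class = "iflc_fit_error")
  # no measurable inhibition
  expect_error(fit_ki(ds$doses, rep(5, 12), 20e-9), class = "iflc_fit_error")
})

test_that("switch ranking reproduces the screening order and hit rule", {
  mkf <- function(v, ratio, bound = FALSE)
    structure(list(ratio = ratio, se = if (bound) NA_real_ else 0.5,
                   direction = "OFF", is_bound = bound, variant = v),
              class = "iflc_fold")
  # the affinity-clamp lysate screen, entered verbatim
  lys <- list(mkf("2-H7", 7.9), mkf("5-H8", 16.6), mkf("5-C6", 3.4),
              mkf("2-A5", 6.1), mkf("5-F7", 10.3), mkf("2-F6", 5.2),
              mkf("5-A12", 5.5))
  rk <- rank_switches(lys)
  expect_equal(rk$variant,
               c("5-H8", "5-F7", "2-H7", "2-A5", "5-A12", "2-F6", "5-C6"))
  expect_equal(sum(rk$hit), 6L)  # six variants repressed > 5-fold
  # bounds rank by their bound value, flagged
  rk2 <- rank_switches(c(lys, list(mkf("X", 80, bound = TRUE))))
  expect_equal(rk2$variant[1], "X")
  expect_true(rk2$is_bound[1])
  expect_equal(nrow(rank_switches(list())), 0L)
})

test_that("plate screening wires traces, layout and ranking together", {
  set.seed(73)
  wells <- c("A1", "A2", "B1", "B2", "C1")
  rates <- c(12, 12.3, 0.9, 1.0, 0)
  traces <- do.call(rbind, lapply(seq_along(wells), function(i) {
    tr <- simulate_trace(rates[i], noise = 0.01, seed = 100 + i,
                         well = wells[i], background = 40)
    data.frame(well = wells[i], time_s = tr$times, rfu = tr$rfu)
  }))
  layout <- data.frame(
    well = wells,
    variant = c("v1", "v1", "v1", "v1", "blank"),
    ligand = c("rapamycin", "rapamycin", "", "", ""),
    concentration_M = c(5e-6, 5e-6, NA, NA, NA))
  res <- screen_plate(traces, layout)
  expect_equal(nrow(res$folds), 1L)
  expect_equal(res$folds$variant, "v1")
  expect_equal(res$folds$direction, "ON")
  expect_equal(res$folds$ratio, 12.15 / 0.95, tolerance = 0.15)
})
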