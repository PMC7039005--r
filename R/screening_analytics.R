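## Screening analytics: initial rates from plate-reader kinetics, fold
## induction/repression with propagated standard errors, and dose-response
## fits for KD (activation) and Ki (inhibition) in hyperbolic or
## tight-binding (Morrison) form.

#' Construct a kinetic trace
#'
#' @param times seconds, strictly increasing.
#' @param rfu relative fluorescence units, same length.
#' @param well,variant labels.
#' @param ligand ligand identity (`NA` for the minus-ligand condition).
#' @param concentration molar ligand concentration (`NA` if none).
#' @return an object of class `iflc_trace`.
#' @export
kinetic_trace <- function(times, rfu, well = "", variant = "",
                          ligand = NA_character_, concentration = NA_real_) {
  stopifnot(length(times) == length(rfu), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), rfu = as.numeric(rfu), well = well,
                 variant = variant, ligand = ligand,
                 concentration = concentration),
            class = "iflc_trace")
}

#' @export
print.iflc_trace <- function(x, ...) {
  cat(sprintf("<iflc_trace> %s/%s: %d points over %.0f s%s\n", x$variant, x$well,
              length(x$times), diff(range(x$times)),
              if (!is.na(x$ligand)) sprintf(" (+%s %.3g M)", x$ligand,
                                            x$concentration) else ""))
  invisible(x)
}

#' @export
plot.iflc_trace <- function(x, ...) {
  plot(x$times, x$rfu, xlab = "time (s)", ylab = "RFU",
       main = sprintf("%s %s", x$variant, x$well), ...)
}

# closed-form OLS slope with standard error (avoids lm()'s perfect-fit
# chatter on noiseless traces); returns c(slope, se, r2)
ols_slope <- function(t, y) {
  n <- length(t)
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  sxy <- sum((t - mt) * (y - my))
  sst <- sum((y - my)^2)
  slope <- sxy / sxx
  sse <- max(sst - slope * sxy, 0)
  se <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else NA_real_
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  c(slope = slope, se = se, r2 = r2)
}

ols_residuals <- function(t, y) {
  mt <- mean(t); my <- mean(y)
  slope <- sum((t - mt) * (y - my)) / sum((t - mt)^2)
  y - (my + slope * (t - mt))
}

#' Initial rate of a kinetic trace
#'
#' Ordinary least-squares slope over an automatically selected linear window:
#' starting at the first point whose signal exceeds the background level plus
#' `noise_mult` background SDs, the longest prefix window of at least
#' `min_points` points with r-squared >= `r2_min` is used. Deterministic. If
#' no window qualifies, a flagged estimate over the eligible range is
#' returned with a quality warning (never silently).
#'
#' @param trace an `iflc_trace`.
#' @param background optional: an `iflc_trace` of a blank well, or numeric
#'   `c(level, sd)` in RFU.
#' @param r2_min linearity criterion (default 0.99).
#' @param min_points minimum window size (default 5).
#' @param noise_mult background-SD multiplier (default 3).
#' @return an object of class `iflc_rate`: `slope` and `se` in RFU/s,
#'   `window` (index range), `r2`, `quality`.
#' @export
initial_rate <- function(trace, background = NULL, r2_min = 0.99,
                         min_points = 5L, noise_mult = 3) {
  stopifnot(inherits(trace, "iflc_trace"))
  if (length(trace$times) < min_points)
    stop(sprintf("rate fitting needs at least %d points", min_points), call. = FALSE)
  if (is.null(background)) {
    thr <- -Inf
  } else if (inherits(background, "iflc_trace")) {
    thr <- mean(background$rfu) + noise_mult * sd(background$rfu)
  } else {
    thr <- background[1] + noise_mult * background[2]
  }
  start <- which(trace$rfu >= thr)
  mk <- function(slope, se, window, r2, quality) {
    structure(list(slope = unname(slope), se = unname(se), window = window,
                   r2 = unname(r2), quality = quality, well = trace$well,
                   variant = trace$variant), class = "iflc_rate")
  }
  if (!length(start)) {
    warning("initial_rate: trace never exceeds background threshold")
    o <- ols_slope(trace$times, trace$rfu)
    return(mk(o["slope"], o["se"], c(1L, length(trace$times)), o["r2"],
              "below_background"))
  }
  i0 <- start[1]
  n <- length(trace$times)
  avail <- n - i0 + 1L
  if (avail < min_points) {
    warning("initial_rate: fewer than min_points above background")
    o <- ols_slope(trace$times, trace$rfu)
    return(mk(o["slope"], o["se"], c(1L, n), o["r2"], "short_window"))
  }
  best_k <- 0L
  for (k in seq(min_points, avail)) {
    idx <- i0:(i0 + k - 1L)
    o <- ols_slope(trace$times[idx], trace$rfu[idx])
    if (!is.na(o["r2"]) && o["r2"] >= r2_min) best_k <- k
  }
  if (best_k == 0L) {
    warning("initial_rate: no linear window with r2 >= ", r2_min)
    o <- ols_slope(trace$times[i0:n], trace$rfu[i0:n])
    return(mk(o["slope"], o["se"], c(i0, n), o["r2"], "no_linear_window"))
  }
  # trim trailing departures from linearity (plateau onset): drop the last
  # point while it deviates from the fit of the remaining window by more
  # than 5 within-window residual SDs
  i1 <- i0 + best_k - 1L
  while (i1 - i0 + 1L > min_points) {
    idx <- i0:(i1 - 1L)
    res <- ols_residuals(trace$times[idx], trace$rfu[idx])
    o <- ols_slope(trace$times[idx], trace$rfu[idx])
    pred_last <- mean(trace$rfu[idx]) +
      o["slope"] * (trace$times[i1] - mean(trace$times[idx]))
    tol <- max(5 * sd(res), 1e-9 * max(abs(trace$rfu)))
    if (abs(trace$rfu[i1] - pred_last) > tol) i1 <- i1 - 1L else break
  }
  idx <- i0:i1
  o <- ols_slope(trace$times[idx], trace$rfu[idx])
  mk(o["slope"], o["se"], c(i0, i1), o["r2"], "ok")
}

#' @export
print.iflc_rate <- function(x, ...) {
  cat(sprintf("<iflc_rate> %s/%s: %.4g +/- %.2g RFU/s (window %d..%d, r2=%.4f, %s)\n",
              x$variant, x$well, x$slope, x$se, x$window[1], x$window[2],
              if (is.na(x$r2)) NaN else x$r2, x$quality))
  invisible(x)
}

rate_slopes <- function(rates) {
  if (inherits(rates, "iflc_rate")) rates <- list(rates)
  list(slopes = vapply(rates, `[[`, numeric(1), "slope"),
       ses = vapply(rates, `[[`, numeric(1), "se"))
}

#' Fold change between plus- and minus-ligand rates
#'
#' Replicate rates are averaged (mean of rates, not of traces); the reported
#' ratio is mean(+ligand)/mean(-ligand) for ON-switches and its reciprocal
#' for OFF-switches, so the number is always >= 1 (fold induction /
#' fold repression). The standard error propagates the regression SEs of the
#' means with relative errors added in quadrature. When the OFF-state
#' (denominator) rate is within `bound_mult` SE of the background rate the
#' result is reported as a lower bound (">X-fold").
#'
#' @param rates_plus,rates_minus `iflc_rate` objects or lists of them.
#' @param background optional background rate as `c(level, se)` in RFU/s
#'   (default 0, 0).
#' @param bound_mult SE multiplier for the bound trigger (default 2).
#' @param variant label.
#' @return an object of class `iflc_fold`: `ratio`, `se`, `direction`
#'   (`"ON"`/`"OFF"`), `is_bound`.
#' @export
fold_change <- function(rates_plus, rates_minus, background = c(0, 0),
                        bound_mult = 2, variant = "") {
  p <- rate_slopes(rates_plus)
  m <- rate_slopes(rates_minus)
  if (!length(p$slopes) || !length(m$slopes))
    stop("both rate sets must be non-empty", call. = FALSE)
  mp <- mean(p$slopes); sp <- sqrt(sum(p$ses^2)) / length(p$slopes)
  mm <- mean(m$slopes); sm <- sqrt(sum(m$ses^2)) / length(m$slopes)
  on <- mp >= mm
  num <- if (on) mp else mm;  se_num <- if (on) sp else sm
  den <- if (on) mm else mp;  se_den <- if (on) sm else sp
  se_tot <- sqrt(se_den^2 + background[2]^2)
  is_bound <- den <= 0 || (den - background[1]) <= bound_mult * se_tot
  if (is_bound) {
    floor_den <- max(den, background[1], 0) + bound_mult * max(se_tot, se_den)
    ratio <- num / floor_den
    se <- NA_real_
  } else {
    ratio <- num / den
    se <- ratio * sqrt((se_num / num)^2 + (se_den / den)^2)
  }
  structure(list(ratio = unname(ratio), se = unname(se),
                 direction = if (on) "ON" else "OFF", is_bound = is_bound,
                 variant = variant), class = "iflc_fold")
}

#' @export
print.iflc_fold <- function(x, ...) {
  cat(sprintf("<iflc_fold> %s: %s%.1f-fold %s%s\n", x$variant,
              if (x$is_bound) ">" else "", x$ratio,
              if (x$direction == "ON") "induction" else "repression",
              if (x$is_bound) " (bound)" else sprintf(" +/- %.1f", x$se)))
  invisible(x)
}

## ---- dose-response models ---------------------------------------------------

# fraction of receptor/enzyme bound at free-ligand approximation (hyperbola)
f_hyperbolic <- function(L, K) L / (K + L)

# Morrison tight-binding fraction bound (quadratic isotherm, total ligand)
f_tight <- function(L, K, E) {
  b <- E + L + K
  (b - sqrt(b^2 - 4 * E * L)) / (2 * E)
}

binding_fraction <- function(L, K, E, tight) {
  if (tight) f_tight(L, K, E) else f_hyperbolic(L, K)
}

# plate-reader rate noise scales with the signal (constant CV), so the NLS is
# weighted by the inverse squared observation; floored to keep near-zero
# rates from dominating
cv_weights <- function(rates) {
  floor_r <- 0.05 * max(abs(rates))
  1 / pmax(abs(rates), floor_r)^2
}

new_fit <- function(model_id, K, se, params, converged, doses, rates, curve) {
  structure(list(model_id = model_id, estimate = K, se = se, params = params,
                 converged = converged, doses = doses, rates = rates,
                 curve = curve), class = "iflc_fit")
}

fit_fail <- function(msg) {
  stop(structure(class = c("iflc_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_dose_design <- function(doses, rates) {
  if (length(doses) != length(rates)) fit_fail("doses and rates differ in length")
  if (length(doses) < 6L) fit_fail("need at least 6 dose points")
  pos <- doses[doses > 0]
  if (!length(pos) || max(pos) / min(pos) < 100)
    fit_fail("dose range must span at least two decades")
}

check_identifiability <- function(K, se_K, amp, se_amp, doses, what) {
  if (!is.finite(K) || !is.finite(se_K) || K <= 0)
    fit_fail(sprintf("%s fit did not yield a finite positive estimate", what))
  if (se_K > abs(K))
    fit_fail(sprintf("%s not identifiable: relative SE exceeds 100%%", what))
  if (K > 50 * max(doses))
    fit_fail(sprintf("%s not identifiable: estimate far above the dosed range", what))
  if (is.finite(se_amp) && se_amp > 0 && abs(amp) < 2 * se_amp)
    fit_fail(sprintf("%s fit amplitude indistinguishable from zero", what))
}

#' Fit an activation dose-response (apparent KD)
#'
#' Fits `rate(L) = v0 + (vmax - v0) * f_bound(L; KD, E)` to initial rates
#' across a ligand titration. `f_bound` is the single-site hyperbolic
#' isotherm by default; when the receptor (switch) concentration is within an
#' order of magnitude of the KD estimate (`E >= KD/10`) the tight-binding
#' Morrison quadratic replaces it and the fit is rerun. Non-convergence,
#' non-identifiability (no curvature in the dosed range) or an amplitude
#' indistinguishable from zero raise an explicit `iflc_fit_error`.
#'
#' @param doses molar ligand concentrations (>= 6 points spanning >= 2
#'   decades).
#' @param rates initial rates (numeric, or list of `iflc_rate`).
#' @param enzyme_conc molar switch concentration E.
#' @param model `"auto"` (default), `"hyperbolic"` or `"tight"`.
#' @return an object of class `iflc_fit` with `model_id`
#'   `"KD-hyperbolic"` or `"KD-tight-binding"`, `estimate` (molar), `se`,
#'   baseline/amplitude `params` and convergence info.
#' @export
fit_kd <- function(doses, rates, enzyme_conc, model = c("auto", "hyperbolic", "tight")) {
  model <- match.arg(model)
  if (is.list(rates)) rates <- rate_slopes(rates)$slopes
  check_dose_design(doses, rates)
  E <- enzyme_conc

  run <- function(tight) {
    K0 <- stats::approx(rates, doses, xout = mean(range(rates)), ties = "ordered",
                        rule = 2)$y
    if (!is.finite(K0) || K0 <= 0) K0 <- exp(mean(log(doses[doses > 0])))
    fit <- try(minpack.lm::nlsLM(
      r ~ v0 + (vmax - v0) * binding_fraction(L, K, E, tight),
      data = list(r = rates, L = doses, E = E, tight = tight),
      start = list(v0 = min(rates), vmax = max(rates), K = K0),
      lower = c(v0 = -Inf, vmax = -Inf, K = 1e-15),
      weights = cv_weights(rates),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) fit_fail("KD fit did not converge")
    fit
  }
  finish <- function(fit, tight) {
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    amp <- cf[["vmax"]] - cf[["v0"]]
    se_amp <- sqrt(vcov(fit)["vmax", "vmax"] + vcov(fit)["v0", "v0"] -
                     2 * vcov(fit)["vmax", "v0"])
    check_identifiability(cf[["K"]], se[["K"]], amp, se_amp, doses, "KD")
    new_fit(if (tight) "KD-tight-binding" else "KD-hyperbolic",
            cf[["K"]], se[["K"]],
            c(v0 = cf[["v0"]], vmax = cf[["vmax"]]), TRUE, doses, rates,
            function(L) cf[["v0"]] + amp * binding_fraction(L, cf[["K"]], E, tight))
  }
  if (model == "hyperbolic") return(finish(run(FALSE), FALSE))
  if (model == "tight") return(finish(run(TRUE), TRUE))
  first <- finish(run(FALSE), FALSE)
  if (E >= first$estimate / 10) finish(run(TRUE), TRUE) else first
}

#' Fit an inhibition dose-response (Ki)
#'
#' Fits `rate(I) = v0 * (1 - f_inhibited(I; Ki, E))` to initial rates across
#' an inhibitor titration, with the same hyperbolic default and automatic
#' tight-binding (Morrison) switch as [fit_kd()]. No measurable inhibition in
#' the dosed range raises an explicit `iflc_fit_error`.
#'
#' @param doses molar inhibitor concentrations.
#' @param rates initial rates.
#' @param enzyme_conc molar protease concentration E.
#' @param model `"auto"`, `"hyperbolic"` or `"tight"`.
#' @return an `iflc_fit` with `model_id` `"Ki-competitive"` or
#'   `"Ki-tight-binding"`.
#' @export
fit_ki <- function(doses, rates, enzyme_conc, model = c("auto", "hyperbolic", "tight")) {
  model <- match.arg(model)
  if (is.list(rates)) rates <- rate_slopes(rates)$slopes
  check_dose_design(doses, rates)
  if (all(doses == 0)) fit_fail("Ki fit needs non-zero inhibitor doses")
  E <- enzyme_conc
  rel_drop <- (max(rates) - min(rates)) / max(rates)
  if (!is.finite(rel_drop) || rel_drop < 0.05)
    fit_fail("no measurable inhibition across the dosed range")

  run <- function(tight) {
    K0 <- stats::approx(-rates, doses, xout = mean(range(-rates)), ties = "ordered",
                        rule = 2)$y
    if (!is.finite(K0) || K0 <= 0) K0 <- exp(mean(log(doses[doses > 0])))
    fit <- try(minpack.lm::nlsLM(
      r ~ v0 * (1 - binding_fraction(I, K, E, tight)),
      data = list(r = rates, I = doses, E = E, tight = tight),
      start = list(v0 = max(rates), K = K0),
      lower = c(v0 = 0, K = 1e-15),
      weights = cv_weights(rates),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) fit_fail("Ki fit did not converge")
    fit
  }
  finish <- function(fit, tight) {
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    check_identifiability(cf[["K"]], se[["K"]], cf[["v0"]], se[["v0"]], doses, "Ki")
    new_fit(if (tight) "Ki-tight-binding" else "Ki-competitive",
            cf[["K"]], se[["K"]], c(v0 = cf[["v0"]]), TRUE, doses, rates,
            function(I) cf[["v0"]] * (1 - binding_fraction(I, cf[["K"]], E, tight)))
  }
  if (model == "hyperbolic") return(finish(run(FALSE), FALSE))
  if (model == "tight") return(finish(run(TRUE), TRUE))
  first <- finish(run(FALSE), FALSE)
  if (E >= first$estimate / 10) finish(run(TRUE), TRUE) else first
}

#' @export
print.iflc_fit <- function(x, ...) {
  cat(sprintf("<iflc_fit> %s: K = %.4g +/- %.2g M (n = %d doses)\n",
              x$model_id, x$estimate, x$se, length(x$doses)))
  invisible(x)
}

#' @export
coef.iflc_fit <- function(object, ...) c(K = object$estimate, object$params)

#' @export
summary.iflc_fit <- function(object, ...) {
  out <- list(model_id = object$model_id, estimate = object$estimate,
              se = object$se, params = object$params,
              converged = object$converged,
              residual_sd = sd(object$rates - object$curve(object$doses)))
  class(out) <- "summary.iflc_fit"
  out
}

#' @export
print.summary.iflc_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s)\n", x$model_id))
  cat(sprintf("  K        = %.4g +/- %.2g M\n", x$estimate, x$se))
  for (nm in names(x$params))
    cat(sprintf("  %-8s = %.4g RFU/s\n", nm, x$params[[nm]]))
  cat(sprintf("  residual sd = %.3g RFU/s; converged: %s\n",
              x$residual_sd, x$converged))
  invisible(x)
}

#' @export
predict.iflc_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$doses
  else if (is.list(newdata)) newdata[[1]] else newdata
  object$curve(L)
}

#' @export
plot.iflc_fit <- function(x, ...) {
  plot(x$doses, x$rates, log = "x", xlab = "concentration (M)",
       ylab = "initial rate (RFU/s)", main = x$model_id, ...)
  L <- exp(seq(log(min(x$doses[x$doses > 0])), log(max(x$doses)), length.out = 200))
  lines(L, x$curve(L))
}

#' @importFrom graphics lines
NULL

#' IC50 implied by a fitted inhibition curve
#'
#' Root of `rate(I) = rate(0)/2` on the fitted curve; for the hyperbolic
#' competitive model this equals Ki analytically, for the tight-binding model
#' it exceeds Ki by about E/2.
#'
#' @param fit an `iflc_fit` from [fit_ki()].
#' @return molar IC50.
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "iflc_fit"), grepl("^Ki", fit$model_id))
  target <- fit$curve(0) / 2
  upper <- max(fit$doses) * 1e3
  stats::uniroot(function(I) fit$curve(I) - target, c(1e-15, upper),
                 tol = 1e-12 * upper)$root
}

#' Rank switches by fold change
#'
#' Descending by ratio; lower bounds (">X") rank by their bound value and are
#' flagged. The hit filter reproduces the screening rule of keeping variants
#' changed by more than `threshold`-fold (default 5).
#'
#' @param results list of `iflc_fold` objects.
#' @param threshold hit-picking fold threshold (default 5).
#' @return data.frame ordered by ratio with columns `variant`, `ratio`, `se`,
#'   `direction`, `is_bound`, `hit`.
#' @export
rank_switches <- function(results, threshold = 5) {
  if (!length(results))
    return(data.frame(variant = character(0), ratio = numeric(0),
                      se = numeric(0), direction = character(0),
                      is_bound = logical(0), hit = logical(0)))
  df <- data.frame(
    variant = vapply(results, `[[`, character(1), "variant"),
    ratio = vapply(results, `[[`, numeric(1), "ratio"),
    se = vapply(results, `[[`, numeric(1), "se"),
    direction = vapply(results, `[[`, character(1), "direction"),
    is_bound = vapply(results, `[[`, logical(1), "is_bound"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$ratio), , drop = FALSE]
  df$hit <- df$ratio > threshold
  rownames(df) <- NULL
  df
}

## ---- plate I/O --------------------------------------------------------------

#' Read long-format plate-reader traces
#'
#' @param path CSV with columns `well`, `time_s`, `rfu`.
#' @return data.frame.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "rfu")
  if (!all(need %in% names(df)))
    stop("trace file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a plate layout
#'
#' @param path CSV with columns `well`, `variant`, `ligand`,
#'   `concentration_M` (empty ligand = minus-ligand condition).
#' @return data.frame.
#' @export
read_layout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "variant", "ligand", "concentration_M")
  if (!all(need %in% names(df)))
    stop("layout file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Screen a plate: rates and fold changes per variant
#'
#' Computes [initial_rate()] for every well and [fold_change()] per variant
#' between its plus-ligand and minus-ligand wells; wells whose variant is
#' `background_variant` define the background level.
#'
#' @param traces long-format trace data.frame (see [read_traces()]).
#' @param layout plate layout data.frame (see [read_layout()]).
#' @param background_variant variant label of blank wells (default
#'   `"blank"`).
#' @param ... passed to [initial_rate()].
#' @return list with `rates` (per well) and `folds` (ranked data.frame).
#' @export
screen_plate <- function(traces, layout, background_variant = "blank", ...) {
  bg_wells <- layout$well[layout$variant == background_variant]
  bg <- NULL
  if (length(bg_wells)) {
    bgr <- traces$rfu[traces$well %in% bg_wells]
    bg <- c(mean(bgr), sd(bgr))
  }
  rates <- list()
  for (w in setdiff(unique(layout$well), bg_wells)) {
    tw <- traces[traces$well == w, , drop = FALSE]
    if (!nrow(tw)) next
    lw <- layout[layout$well == w, , drop = FALSE][1, ]
    has_lig <- !is.na(lw$ligand) && nzchar(lw$ligand)
    tr <- kinetic_trace(tw$time_s, tw$rfu, well = w, variant = lw$variant,
                        ligand = if (has_lig) lw$ligand else NA_character_,
                        concentration = lw$concentration_M)
    rates[[w]] <- initial_rate(tr, background = bg, ...)
  }
  folds <- list()
  for (v in setdiff(unique(layout$variant), background_variant)) {
    wells_v <- layout[layout$variant == v, , drop = FALSE]
    lig <- wells_v$ligand
    lig[is.na(lig)] <- ""
    plus <- wells_v$well[nzchar(lig)]
    minus <- setdiff(wells_v$well, plus)
    rp <- rates[intersect(plus, names(rates))]
    rm_ <- rates[intersect(minus, names(rates))]
    if (length(rp) && length(rm_))
      folds[[v]] <- fold_change(unname(rp), unname(rm_), variant = v)
  }
  list(rates = rates, folds = rank_switches(unname(folds)))
}
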