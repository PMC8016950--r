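# Binding-assay machinery: ELISA equilibrium curves, single-cycle SPR
# kinetics (1:1 model), cell-surface saturation binding, and the Lindmo
# immunoreactive-fraction extrapolation. All simulators are pure functions of
# (parameters, seed).

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Assay dataset container
#'
#' @param x predictor values (concentration, time, or cell concentration).
#' @param y measured signal / response / bound fraction.
#' @param x_unit,y_unit unit strings for reporting.
#' @param provenance `"measured"` or `"simulated"`.
#' @param truth for simulated data, the named list of true parameters.
#' @param seed the seed used for simulation (if any).
#' @return list of class `assay_dataset`.
#' @export
assay_dataset <- function(x, y, x_unit = "", y_unit = "",
                          provenance = "measured", truth = NULL, seed = NULL) {
  stopifnot(length(x) == length(y))
  structure(list(x = as.numeric(x), y = as.numeric(y), x_unit = x_unit,
                 y_unit = y_unit, provenance = provenance, truth = truth,
                 seed = seed),
            class = "assay_dataset")
}

#' Read an assay dataset from CSV
#'
#' @param path CSV with columns `x`, `y` (extra columns ignored).
#' @param ... passed to [assay_dataset()].
#' @export
read_assay_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  assay_dataset(d$x, d$y, ...)
}

# --- ELISA ------------------------------------------------------------------

#' Fit an ELISA equilibrium binding curve
#'
#' Least-squares fit of `y = background + a_max * c / (k_d + c)` with
#' positivity bounds (Levenberg-Marquardt). The initial `k_d` is the
#' concentration nearest the half-maximal signal. Concentration and `k_d`
#' share the unit of `data$x`.
#'
#' @param data an [assay_dataset()] (concentration vs signal, >= 5 distinct
#'   concentrations).
#' @return list of class `elisa_fit`: `k_d`, `a_max`, `background`,
#'   standard errors `se`, covariance `vcov`, `no_plateau` flag, and the
#'   underlying `nls` fit.
#' @export
fit_elisa <- function(data) {
  stopifnot(inherits(data, "assay_dataset"))
  x <- data$x
  y <- data$y
  if (length(unique(x)) < 5) stop("need >= 5 distinct concentrations")
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    stop("fit error: constant signal, k_d not identifiable")
  }
  bg0 <- min(y)
  amax0 <- max(y) - bg0
  half <- bg0 + amax0 / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bg + amax * x / (kd + x),
                      start = list(bg = bg0, amax = amax0, kd = kd0),
                      lower = c(-Inf, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(k_d = unname(cf["kd"]), a_max = unname(cf["amax"]),
                 background = unname(cf["bg"]),
                 se = c(k_d = unname(se["kd"]), a_max = unname(se["amax"]),
                        background = unname(se["bg"])),
                 vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 no_plateau = unname(cf["kd"]) > max(x),
                 fit = fit, x_unit = data$x_unit),
            class = "elisa_fit")
}

#' @export
print.elisa_fit <- function(x, ...) {
  cat(sprintf("ELISA fit: K_D = %.4g +/- %.2g %s (a_max %.4g, background %.4g)%s\n",
              x$k_d, x$se["k_d"], x$x_unit, x$a_max, x$background,
              if (x$no_plateau) " [warning: no plateau reached]" else ""))
  invisible(x)
}

#' Simulate an ELISA dilution series
#'
#' Multiplicative Gaussian noise: `y = mu * (1 + noise_sd * eps)`.
#'
#' @param k_d,a_max,background true curve parameters.
#' @param concentrations analyte concentrations.
#' @param noise_sd relative noise level (0 = exact model values).
#' @param seed RNG seed.
#' @return an [assay_dataset()] with recorded truth.
#' @export
simulate_elisa <- function(k_d, a_max, background = 0, concentrations,
                           noise_sd = 0, seed = 0) {
  stopifnot(k_d > 0, a_max > 0)
  mu <- background + a_max * concentrations / (k_d + concentrations)
  y <- .with_seed(seed, mu * (1 + noise_sd * stats::rnorm(length(mu))))
  assay_dataset(concentrations, y, provenance = "simulated",
                truth = list(k_d = k_d, a_max = a_max, background = background,
                             noise_sd = noise_sd),
                seed = seed)
}

# --- saturation binding -----------------------------------------------------

#' Fit a saturation binding curve
#'
#' Least-squares fit of specific binding `B = b_max * c / (k_d + c)`.
#'
#' @param data an [assay_dataset()] (>= 5 concentrations).
#' @return list of class `saturation_fit` with `k_d`, `b_max`, `se`.
#' @export
fit_saturation <- function(data) {
  stopifnot(inherits(data, "assay_dataset"))
  x <- data$x
  y <- data$y
  if (length(unique(x)) < 5) stop("need >= 5 distinct concentrations")
  if (stats::sd(y) == 0) stop("fit error: constant signal")
  bmax0 <- max(y)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(x)
  fit <- minpack.lm::nlsLM(y ~ bmax * x / (kd + x),
                           start = list(bmax = bmax0, kd = kd0),
                           lower = c(0, 0))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  structure(list(k_d = unname(cf["kd"]), b_max = unname(cf["bmax"]),
                 se = c(k_d = unname(se["kd"]), b_max = unname(se["bmax"])),
                 fit = fit, x_unit = data$x_unit),
            class = "saturation_fit")
}

#' Simulate a saturation binding assay
#'
#' @inheritParams simulate_elisa
#' @param b_max maximal specific binding.
#' @export
simulate_saturation <- function(k_d, b_max, concentrations, noise_sd = 0,
                                seed = 0) {
  stopifnot(k_d > 0, b_max > 0)
  mu <- b_max * concentrations / (k_d + concentrations)
  y <- .with_seed(seed, mu * (1 + noise_sd * stats::rnorm(length(mu))))
  assay_dataset(concentrations, y, provenance = "simulated",
                truth = list(k_d = k_d, b_max = b_max, noise_sd = noise_sd),
                seed = seed)
}

# --- single-cycle SPR -------------------------------------------------------

#' Integrate the 1:1 interaction model over an injection schedule
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' `dR/dt = k_on * C(t) * (r_max - R) - k_off * R` with the analyte
#' concentration piecewise-constant per schedule segment and `R` continuous
#' across segment boundaries. Mass-transport and bulk-refractive terms are
#' not modelled.
#'
#' @param times observation times (seconds, ascending, starting inside the
#'   schedule).
#' @param k_on association rate (1/(M*s)).
#' @param k_off dissociation rate (1/s).
#' @param r_max surface capacity (response units).
#' @param schedule data.frame with columns `t_start`, `t_end`, `conc`
#'   (molar; 0 during dissociation).
#' @param r0 response at the start of the first segment.
#' @param step maximum integration step (s; default 0.1).
#' @return numeric response at `times`.
#' @export
spr_response <- function(times, k_on, k_off, r_max, schedule, r0 = 0,
                         step = 0.1) {
  stopifnot(all(diff(times) >= 0), step > 0)
  deriv <- function(R, C) k_on * C * (r_max - R) - k_off * R
  out <- numeric(length(times))
  R <- r0
  t_cur <- schedule$t_start[1]
  ti <- 1
  for (s in seq_len(nrow(schedule))) {
    C <- schedule$conc[s]
    t_end <- schedule$t_end[s]
    while (t_cur < t_end - 1e-12) {
      # report observations that fall before the next sub-step
      h <- min(step, t_end - t_cur)
      while (ti <= length(times) && times[ti] <= t_cur + 1e-9) {
        out[ti] <- R
        ti <- ti + 1
      }
      if (ti <= length(times) && times[ti] < t_cur + h) h <- times[ti] - t_cur
      k1 <- deriv(R, C)
      k2 <- deriv(R + h / 2 * k1, C)
      k3 <- deriv(R + h / 2 * k2, C)
      k4 <- deriv(R + h * k3, C)
      R <- R + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + h
    }
    t_cur <- t_end
  }
  while (ti <= length(times)) {
    out[ti] <- R
    ti <- ti + 1
  }
  out
}

#' Simulate a single-cycle SPR trace
#'
#' Additive Gaussian noise on the response.
#'
#' @inheritParams spr_response
#' @param noise_sd additive noise standard deviation (response units).
#' @param seed RNG seed.
#' @param dt observation spacing in seconds.
#' @return an [assay_dataset()] (`x` = time) with the schedule attached.
#' @export
simulate_sck_spr <- function(k_on, k_off, r_max, schedule, noise_sd = 0,
                             seed = 0, dt = 1) {
  times <- seq(schedule$t_start[1], schedule$t_end[nrow(schedule)], by = dt)
  mu <- spr_response(times, k_on, k_off, r_max, schedule)
  y <- .with_seed(seed, mu + noise_sd * stats::rnorm(length(mu)))
  d <- assay_dataset(times, y, x_unit = "s", y_unit = "RU",
                     provenance = "simulated",
                     truth = list(k_on = k_on, k_off = k_off, r_max = r_max,
                                  k_d = k_off / k_on, noise_sd = noise_sd),
                     seed = seed)
  d$schedule <- schedule
  d
}

#' Fit single-cycle SPR kinetics (1:1 model)
#'
#' Whole-trace least squares over (`k_on`, `k_off`, `r_max`) with positivity
#' bounds; the model trace is integrated with [spr_response()]. `k_off` is
#' initialized from the terminal dissociation decay and `k_on` from the
#' initial association slope. The derived `k_d = k_off / k_on` holds exactly
#' in the returned fit.
#'
#' @param data an [assay_dataset()] with `x` = time; if it lacks a
#'   `schedule`, one must be supplied.
#' @param schedule injection schedule (see [spr_response()]).
#' @param step integration step (s).
#' @return list of class `kinetic_fit`: `k_on`, `k_off`, `r_max`, `k_d`,
#'   `se`, `koff_unidentifiable` flag.
#' @export
fit_sck_spr <- function(data, schedule = data$schedule, step = 0.1) {
  stopifnot(inherits(data, "assay_dataset"))
  if (is.null(schedule)) stop("injection schedule required")
  t <- data$x
  y <- data$y
  rmax0 <- max(y) * 1.5
  # dissociation tail: last zero-concentration segment
  zero <- which(schedule$conc == 0)
  koff0 <- 1e-3
  if (length(zero)) {
    zs <- schedule[zero[length(zero)], ]
    sel <- t >= zs$t_start & t <= zs$t_end & y > 0
    if (sum(sel) > 3 && stats::sd(y[sel]) > 0) {
      sl <- stats::coef(stats::lm(log(y[sel]) ~ t[sel]))[2]
      if (is.finite(sl) && sl < 0) koff0 <- -sl
    }
  }
  first <- schedule[schedule$conc > 0, ][1, ]
  sel1 <- t >= first$t_start & t <= first$t_start + (first$t_end - first$t_start) / 4
  slope <- if (sum(sel1) > 2) stats::coef(stats::lm(y[sel1] ~ t[sel1]))[2] else NA
  kon0 <- if (is.finite(slope) && slope > 0) slope / (first$conc * rmax0) else 1e5
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = log(c(kon = kon0, koff = max(koff0, 1e-8), rmax = rmax0)),
      fn = function(p) {
        pp <- exp(p)
        y - spr_response(t, pp[1], pp[2], pp[3], schedule, step = step)
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: ", conditionMessage(e)))
  pp <- exp(fit$par)
  # delta-method standard errors on the natural scale
  se <- tryCatch({
    cv <- tryCatch(solve(fit$hessian) *
                     2 * fit$deviance / max(1, length(y) - 3),
                   error = function(e) matrix(NA, 3, 3))
    sqrt(diag(cv)) * pp
  }, error = function(e) rep(NA_real_, 3))
  koff_flag <- pp[2] < 1e-7 || !is.finite(se[2]) ||
    (is.finite(se[2]) && se[2] > 10 * pp[2])
  structure(list(k_on = unname(pp[1]), k_off = unname(pp[2]),
                 r_max = unname(pp[3]), k_d = unname(pp[2] / pp[1]),
                 se = c(k_on = se[1], k_off = se[2], r_max = se[3]),
                 koff_unidentifiable = koff_flag, fit = fit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: k_on %.3g 1/(M*s), k_off %.3g 1/s, K_D %.3g M%s\n",
              x$k_on, x$k_off, x$k_d,
              if (x$koff_unidentifiable) " [k_off unidentifiable]" else ""))
  invisible(x)
}

# --- Lindmo immunoreactive fraction ----------------------------------------

#' Lindmo immunoreactive-fraction fit
#'
#' Linear regression of total/bound against 1/[cells]; the immunoreactive
#' fraction is the reciprocal of the intercept (extrapolation to infinite
#' antigen excess). Duplicate cell concentrations are averaged before the
#' regression.
#'
#' @param data an [assay_dataset()] with `x` = cell concentration and `y` =
#'   bound fraction in (0, 1), >= 4 concentrations.
#' @return list of class `lindmo_result`: `immunoreactive_fraction`,
#'   `intercept`, `slope`, `flag_above_one` (fraction > 1.05).
#' @export
lindmo_fit <- function(data) {
  stopifnot(inherits(data, "assay_dataset"))
  x <- data$x
  y <- data$y
  if (any(y <= 0) || any(y > 1)) stop("bound fractions must lie in (0, 1]")
  if (length(unique(x)) < 4) stop("need >= 4 cell concentrations")
  agg <- stats::aggregate(list(y = y), by = list(x = x), FUN = mean)
  inv_x <- 1 / agg$x
  ratio <- 1 / agg$y  # total/bound
  lmfit <- stats::lm(ratio ~ inv_x)
  ic <- unname(stats::coef(lmfit)[1])
  sl <- unname(stats::coef(lmfit)[2])
  if (ic <= 0) stop("nonpositive intercept: immunoreactive fraction undefined")
  frac <- 1 / ic
  structure(list(immunoreactive_fraction = frac, intercept = ic, slope = sl,
                 flag_above_one = frac > 1.05, fit = lmfit),
            class = "lindmo_result")
}

#' @export
print.lindmo_result <- function(x, ...) {
  cat(sprintf("Lindmo fit: immunoreactive fraction %.3f%s\n",
              x$immunoreactive_fraction,
              if (x$flag_above_one) " [> 1, check data]" else ""))
  invisible(x)
}

#' Simulate a Lindmo cell-binding series
#'
#' Bound fraction `B/T = f * c / (K + c)` with fractional Gaussian noise,
#' truncated to (0, 1].
#'
#' @param fraction true immunoreactive fraction in (0, 1].
#' @param k_cells cell concentration of half-maximal binding (same unit as
#'   `cells`).
#' @param cells cell concentrations.
#' @param noise_sd relative noise.
#' @param seed RNG seed.
#' @export
simulate_lindmo <- function(fraction, k_cells, cells, noise_sd = 0, seed = 0) {
  stopifnot(fraction > 0, fraction <= 1, k_cells >= 0)
  mu <- fraction * cells / (k_cells + cells)
  y <- .with_seed(seed, mu * (1 + noise_sd * stats::rnorm(length(mu))))
  y <- pmin(pmax(y, 1e-6), 1)
  assay_dataset(cells, y, provenance = "simulated",
                truth = list(fraction = fraction, k_cells = k_cells,
                             noise_sd = noise_sd),
                seed = seed)
}
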