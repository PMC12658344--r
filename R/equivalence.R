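# Lead equivalence: reference lead transmission, attenuation-curve fitting,
# intersection root-finding and areal mass.

#' Transmission of a pure-lead reference slab
#'
#' Computes the transmission of a 0.35 or 0.5 mm (or any other) pure lead
#' slab under the same spectrum, engine and weighting as the composite
#' curves it will be compared against.  The result carries the engine and
#' weighting as attributes so that [solve_t_eq()] can enforce the
#' apples-to-apples contract.
#'
#' @inheritParams build_curve
#' @param pb_thickness_mm Lead reference thickness in mm.
#' @param pb_density Density of lead (g/cm^3), default 11.35.
#' @return A `pb_reference` scalar: the transmission fraction with
#'   attributes `engine`, `weighting`, `pb_thickness_mm` (and `stderr` for
#'   the MC engine).
#' @export
pb_reference_transmission <- function(spectrum, pb_thickness_mm,
                                      engine = "deterministic",
                                      weighting = "fluence",
                                      geometry = geometry_spec(),
                                      mc = mc_config(),
                                      pb_density = 11.35) {
  engine <- arg_match0(engine, c("deterministic", "mc"))
  weighting <- arg_match0(weighting, c("fluence", "kerma"))
  pb <- pb_material(pb_density)
  if (engine == "deterministic") {
    tr <- narrow_beam_transmission(spectrum, pb, pb_thickness_mm, weighting)
    se <- 0
  } else {
    weighting <- if (mc$tally == "energy") "kerma" else "fluence"
    res <- mc_transmission(spectrum, pb, pb_thickness_mm, geometry, mc)
    tr <- res$transmission; se <- res$stderr
  }
  structure(tr, engine = engine, weighting = weighting,
            pb_thickness_mm = pb_thickness_mm, stderr = se,
            class = "pb_reference")
}

#' @export
print.pb_reference <- function(x, ...) {
  cat(sprintf("Pb %.2f mm reference transmission: %.6g (%s, %s)\n",
              attr(x, "pb_thickness_mm"), as.numeric(x),
              attr(x, "engine"), attr(x, "weighting")))
  invisible(x)
}

#' Fit a continuous attenuation curve
#'
#' Turns a discrete transmission curve into a positive, strictly decreasing
#' function of thickness.  The default `"log_interp"` kind is a monotone
#' cubic interpolant of log-transmission (exact at the knots; polyenergetic
#' curves are not single exponentials because of beam hardening).  The
#' exponential kinds reproduce classical exponential-decay fitting:
#' `"exp1"` fits \eqn{A e^{-bt}} and `"exp2"` fits
#' \eqn{A_1 e^{-b_1 t} + A_2 e^{-b_2 t}}, both by least squares on
#' log-transmission.
#'
#' @param curve A `transmission_curve` (at least 3 points, positive
#'   transmissions).
#' @param kind `"log_interp"` (default), `"exp1"` or `"exp2"`.
#' @return An `attenuation_fit` object; use [predict()][predict.attenuation_fit()],
#'   [solve_t_eq()], [tidy()] and [glance()].
#' @export
fit_curve <- function(curve, kind = "log_interp") {
  kind <- arg_match0(kind, c("log_interp", "exp1", "exp2"))
  t <- curve$thickness_mm; tr <- curve$transmission
  se <- if ("stderr" %in% names(curve)) curve$stderr else rep(0, length(t))
  if (length(t) < 3) {
    abort("need at least 3 curve points", class = "leadequiv_fit_error")
  }
  if (any(tr <= 0)) {
    abort("transmissions must be positive", class = "leadequiv_fit_error")
  }
  # reject curves that rise beyond what the per-point noise can explain
  rises <- diff(tr)
  tol <- 3 * sqrt(se[-1]^2 + se[-length(se)]^2) * tr[-1] + 1e-12
  if (any(rises > tol)) {
    abort("curve is non-monotone beyond noise tolerance",
          class = "leadequiv_fit_error")
  }
  y <- log(tr)
  if (kind == "log_interp") {
    ys <- y
    if (any(diff(ys) >= 0)) {
      # pool small noise-induced inversions, then keep strict monotonicity
      iso <- -isoreg(t, -ys)$yf
      eps <- 1e-9 * seq_along(ys)
      ys <- iso - eps
    }
    f_log <- splinefun(t, ys, method = "hyman")
    fun <- function(tt) exp(f_log(tt))
    params <- tibble(term = character(), estimate = numeric())
  } else if (kind == "exp1") {
    fit <- lm(y ~ t)
    a <- exp(coef(fit)[[1]]); b <- -coef(fit)[[2]]
    fun <- function(tt) a * exp(-b * tt)
    params <- tibble(term = c("A", "rate"), estimate = c(a, b))
  } else {
    start <- .exp2_start(t, y)
    df <- data.frame(t = t, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ log(a1 * exp(-b1 * t) + a2 * exp(-b2 * t)),
      data = df, start = start,
      lower = c(a1 = 1e-8, b1 = 1e-8, a2 = 1e-8, b2 = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    p <- coef(fit)
    # order components by decay rate (fast first)
    if (p[["b2"]] > p[["b1"]]) p <- p[c("a2", "b2", "a1", "b1")]
    fun <- function(tt) p[[1]] * exp(-p[[2]] * tt) + p[[3]] * exp(-p[[4]] * tt)
    params <- tibble(term = c("A1", "rate1", "A2", "rate2"),
                     estimate = as.numeric(p))
  }
  resid <- tr - fun(t)
  structure(list(kind = kind, fun = fun, params = params,
                 thickness_range = range(t),
                 residuals = tibble(thickness_mm = t, transmission = tr,
                                    stderr = se, residual = resid),
                 curve_attrs = list(material = attr(curve, "material"),
                                    density = attr(curve, "density"),
                                    kvp = attr(curve, "kvp"),
                                    engine = attr(curve, "engine"),
                                    weighting = attr(curve, "weighting"))),
            class = "attenuation_fit")
}

# starting values for the bi-exponential: slow component from the tail,
# fast component from the head residual
.exp2_start <- function(t, y) {
  n <- length(t)
  tail_i <- max(3, n - 3):n
  tail_fit <- lm(y[tail_i] ~ t[tail_i])
  b2 <- max(-coef(tail_fit)[[2]], 1e-3)
  a2 <- min(exp(coef(tail_fit)[[1]]), 0.95)
  resid_head <- exp(y) - a2 * exp(-b2 * t)
  pos <- which(resid_head > 0)
  if (length(pos) >= 2) {
    hf <- lm(log(resid_head[pos]) ~ t[pos])
    b1 <- max(-coef(hf)[[2]], b2 * 1.5)
    a1 <- max(exp(coef(hf)[[1]]), 1e-3)
  } else {
    b1 <- b2 * 5; a1 <- max(1 - a2, 0.05)
  }
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
}

#' @export
print.attenuation_fit <- function(x, ...) {
  ca <- x$curve_attrs
  cat(sprintf("<attenuation_fit> kind=%s material=%s kvp=%s [%g, %g] mm\n",
              x$kind, ca$material %||% "?", ca$kvp %||% "?",
              x$thickness_range[1], x$thickness_range[2]))
  if (nrow(x$params)) print(x$params)
  invisible(x)
}

#' Evaluate a fitted attenuation curve
#'
#' @param object An `attenuation_fit`.
#' @param thickness_mm Thickness values in mm.
#' @param ... Unused.
#' @return Transmission fractions.
#' @export
predict.attenuation_fit <- function(object, thickness_mm, ...) {
  object$fun(thickness_mm)
}

#' @export
tidy.attenuation_fit <- function(x, ...) x$params

#' @export
glance.attenuation_fit <- function(x, ...) {
  r <- x$residuals
  within_3se <- if (any(r$stderr > 0)) {
    all(abs(r$residual) <= 3 * r$stderr * r$transmission + 1e-12)
  } else {
    all(abs(r$residual) < 1e-9)
  }
  tibble(kind = x$kind, n_points = nrow(r),
         rmse = sqrt(mean(r$residual^2)),
         max_abs_residual = max(abs(r$residual)),
         within_3se = within_3se)
}

#' Solve for the equivalent thickness at a target transmission
#'
#' Finds the thickness at which the fitted attenuation curve equals the
#' target transmission by bracketed root-finding on the fitted thickness
#' range; extrapolation outside the curve is refused.  When the target is a
#' [pb_reference_transmission()] object, the engine and weighting of curve
#' and reference must match.
#'
#' @param fit An `attenuation_fit`.
#' @param target_transmission Target transmission fraction (plain number or
#'   `pb_reference` object).
#' @return Equivalent thickness in mm.
#' @export
solve_t_eq <- function(fit, target_transmission) {
  stopifnot(inherits(fit, "attenuation_fit"))
  if (inherits(target_transmission, "pb_reference")) {
    ca <- fit$curve_attrs
    if (!is.null(ca$engine) &&
        (!identical(ca$engine, attr(target_transmission, "engine")) ||
         !identical(ca$weighting, attr(target_transmission, "weighting")))) {
      abort(paste0("engine/weighting mismatch between curve (",
                   ca$engine, "/", ca$weighting, ") and lead reference (",
                   attr(target_transmission, "engine"), "/",
                   attr(target_transmission, "weighting"), ")"),
            class = "leadequiv_engine_mismatch")
    }
  }
  target <- as.numeric(target_transmission)
  lo <- fit$thickness_range[1]; hi <- fit$thickness_range[2]
  f_lo <- fit$fun(lo); f_hi <- fit$fun(hi)
  if (target > f_lo) {
    abort(sprintf(paste0("target transmission %.4g exceeds the curve value %.4g at ",
                         "the thinnest point (%g mm); extrapolation below the ",
                         "curve range is not performed"), target, f_lo, lo),
          class = "leadequiv_bracket_error")
  }
  if (target < f_hi) {
    abort(sprintf(paste0("target transmission %.4g is below the curve value %.4g at ",
                         "the thickest point (%g mm); extrapolation beyond the ",
                         "curve range is not performed"), target, f_hi, hi),
          class = "leadequiv_bracket_error")
  }
  uniroot(function(tt) fit$fun(tt) - target, lower = lo, upper = hi,
          tol = 1e-12)$root
}

#' Areal mass of an equivalent-thickness shield
#'
#' Mass per unit area in kg/m^2; numerically `density (g/cm^3) x
#' thickness (mm)` since 1 g/cm^3 x 1 mm = 1 kg/m^2.
#'
#' @param material A [composite()]/[toy_material()], or a plain density in
#'   g/cm^3.
#' @param t_eq_mm Equivalent thickness in mm.
#' @return Areal mass in kg/m^2.
#' @examples
#' areal_mass(3.46, 2.07)
#' @export
areal_mass <- function(material, t_eq_mm) {
  stopifnot(all(t_eq_mm >= 0))
  density <- if (is.numeric(material)) material else material$density
  density * t_eq_mm
}

#' Lead equivalence of one composite under one spectrum
#'
#' The full single-cell pipeline: build the transmission curve, build the
#' lead reference under the same engine and weighting, fit the curve and
#' solve for the intersection thickness, then convert to areal mass.
#'
#' @inheritParams build_curve
#' @param pb_target_mm Lead reference thickness (mm), e.g. 0.35 or 0.5.
#' @param fit_kind Curve model passed to [fit_curve()].
#' @return One-row tibble: `material`, `kvp`, `pb_target_mm`,
#'   `target_transmission`, `t_eq_mm`, `areal_mass_kg_m2`, `density_g_cm3`.
#' @examples
#' \donttest{
#' lead_equivalence(reference_spectrum(100), registry_composite("W-Sn-Gd"), 0.5)
#' }
#' @export
lead_equivalence <- function(spectrum, material, pb_target_mm,
                             engine = "deterministic", weighting = "fluence",
                             thicknesses = .DEFAULT_THICKNESS_GRID,
                             fit_kind = "log_interp",
                             geometry = geometry_spec(), mc = mc_config()) {
  curve <- build_curve(spectrum, material, thicknesses, engine = engine,
                       weighting = weighting, geometry = geometry, mc = mc)
  ref <- pb_reference_transmission(spectrum, pb_target_mm, engine = engine,
                                   weighting = attr(curve, "weighting"),
                                   geometry = geometry, mc = mc)
  fit <- fit_curve(curve, kind = fit_kind)
  t_eq <- solve_t_eq(fit, ref)
  mass <- areal_mass(material, t_eq)
  dens <- material$density
  label <- material$abbreviation %||% material$name
  tibble(material = label,
         kvp = attr(spectrum, "kvp"),
         pb_target_mm = pb_target_mm,
         target_transmission = as.numeric(ref),
         t_eq_mm = t_eq,
         areal_mass_kg_m2 = mass,
         density_g_cm3 = dens)
}
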