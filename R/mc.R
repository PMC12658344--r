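# Analog Monte Carlo broad-beam photon transport through a laterally
# extended slab.  Histories are fully vectorised: at each generation the
# surviving photon set is advanced together (free-path sampling, interaction
# selection, Klein-Nishina or Thomson angular sampling, direction rotation).
#
# Physics scope: photoelectric absorption, incoherent (Compton) scattering
# with exact Klein-Nishina energy/angle sampling via Kahn's method, and
# optional coherent scattering with a form-factor-free Thomson angular law
# (a documented approximation that overestimates large-angle coherent
# deflections).  No electron transport: the energy tally is an air-kerma
# weighting of the photons reaching the detector, adequate below 150 keV.
# The slab is treated as laterally infinite; the field cone is set by the
# shield half-width.

#' Monte Carlo broad-beam transmission
#'
#' Simulates analog photon histories from a point source through a composite
#' slab to a detector disc and tallies the detector signal relative to a
#' no-shield run with the same seed protocol.  Reproducible for a fixed
#' seed and configuration.
#'
#' @inheritParams narrow_beam_transmission
#' @param thickness_mm Slab thickness in mm (scalar).
#' @param geometry A [geometry_spec()].
#' @param mc An [mc_config()].
#' @param primaries_only Discard photons that scatter (narrow-beam
#'   emulation; the Beer-Lambert oracle for validation).
#' @return List with `transmission`, `stderr` (relative standard error of
#'   the shielded tally) and `n_histories`.
#' @export
mc_transmission <- function(spectrum, material, thickness_mm,
                            geometry = geometry_spec(), mc = mc_config(),
                            primaries_only = FALSE) {
  stopifnot(inherits(geometry, "geometry_spec"), inherits(mc, "mc_config"))
  if (length(thickness_mm) != 1 || thickness_mm < 0) {
    abort("thickness_mm must be a non-negative scalar",
          class = "leadequiv_config_error")
  }
  open_run <- .mc_run(spectrum, material, 0, geometry, mc, primaries_only)
  if (open_run$sum_w <= 0) {
    abort("no photons reach the detector in the open-field run; check geometry",
          class = "leadequiv_config_error")
  }
  shield <- if (thickness_mm == 0) open_run else
    .mc_run(spectrum, material, thickness_mm, geometry, mc, primaries_only)
  transmission <- shield$sum_w / open_run$sum_w
  # relative standard error of the shielded tally (open-field run shares the
  # seed protocol and is treated as the normalisation constant)
  n <- mc$n_histories
  var_num <- shield$sum_w2 - shield$sum_w^2 / n
  rel_se <- if (shield$sum_w > 0) sqrt(max(var_num, 0)) / shield$sum_w else Inf
  list(transmission = transmission, stderr = rel_se, n_histories = n)
}

# one full run; returns detector tally sums
.mc_run <- function(spectrum, material, thickness_mm, geometry, mc,
                    primaries_only) {
  set.seed(mc$seed)
  n <- mc$n_histories
  t_cm <- thickness_mm / 10
  D <- geometry$source_to_shield_cm
  z_exit <- D + t_cm
  z_det <- z_exit + geometry$shield_to_detector_cm
  r_det2 <- geometry$detector_radius_cm^2
  cos_max <- D / sqrt(D^2 + geometry$shield_lateral_halfwidth_cm^2)

  keep <- spectrum$fluence > 0
  e_bins <- spectrum$energy_keV[keep]
  p_bins <- spectrum$fluence[keep]

  # source sampling: energy from the spectrum, direction uniform in the cone
  E <- e_bins[sample.int(length(e_bins), n, replace = TRUE, prob = p_bins)]
  mu_z <- 1 - runif(n) * (1 - cos_max)
  phi <- runif(n, 0, 2 * pi)
  sin_t <- sqrt(pmax(1 - mu_z^2, 0))
  dx <- sin_t * cos(phi); dy <- sin_t * sin(phi); dz <- mu_z

  # advance through vacuum to the slab front face
  s0 <- D / dz
  x <- dx * s0; y <- dy * s0; z <- rep(D, n)
  scattered <- rep(FALSE, n)
  alive <- rep(t_cm > 0, n)       # photons needing in-slab transport
  exited <- !alive                # zero thickness: all photons pass through

  mus <- .material_mu_funs(material, coherent_enabled = mc$coherent_enabled)

  guard <- 0L
  while (any(alive)) {
    guard <- guard + 1L
    if (guard > 1000L) abort("MC transport failed to terminate")
    i <- which(alive)
    Ei <- E[i]
    mu_tot <- mus$total(Ei)
    s <- rexp(length(i)) / mu_tot
    # distance to the slab boundary along the flight direction
    dzi <- dz[i]
    s_bound <- ifelse(dzi > 0, (z_exit - z[i]) / dzi,
                      ifelse(dzi < 0, (D - z[i]) / dzi, Inf))
    leaves <- s >= s_bound
    adv <- pmin(s, s_bound)
    x[i] <- x[i] + dx[i] * adv
    y[i] <- y[i] + dy[i] * adv
    z[i] <- z[i] + dzi * adv
    # photons crossing a face leave the slab
    out <- i[leaves]
    if (length(out)) {
      fwd <- dz[out] > 0
      exited[out[fwd]] <- TRUE
      alive[out] <- FALSE          # backward leavers are lost
    }
    ii <- i[!leaves]               # interacting photons
    if (!length(ii)) next
    Ei <- E[ii]
    p_pe <- mus$photoelectric(Ei) / mus$total(Ei)
    p_inc <- mus$incoherent(Ei) / mus$total(Ei)
    u <- runif(length(ii))
    absorb <- u < p_pe
    compton <- !absorb & u < p_pe + p_inc
    coher <- !absorb & !compton
    alive[ii[absorb]] <- FALSE
    if (primaries_only) {
      alive[ii[compton | coher]] <- FALSE
      next
    }
    if (any(compton)) {
      j <- ii[compton]
      kn <- .sample_klein_nishina(E[j])
      E[j] <- kn$energy
      low <- E[j] < mc$energy_cutoff_keV
      alive[j[low]] <- FALSE
      j2 <- j[!low]
      if (length(j2)) {
        rot <- .rotate_direction(dx[j2], dy[j2], dz[j2],
                                 kn$cos_theta[!low],
                                 runif(length(j2), 0, 2 * pi))
        dx[j2] <- rot$x; dy[j2] <- rot$y; dz[j2] <- rot$z
        scattered[j2] <- TRUE
      }
    }
    if (any(coher)) {
      j <- ii[coher]
      ct <- .sample_thomson(length(j))
      rot <- .rotate_direction(dx[j], dy[j], dz[j], ct,
                               runif(length(j), 0, 2 * pi))
      dx[j] <- rot$x; dy[j] <- rot$y; dz[j] <- rot$z
      scattered[j] <- TRUE
    }
  }

  # propagate exiting photons to the detector plane and tally disc hits
  k <- which(exited & dz > 0)
  if (length(k)) {
    sd <- (z_det - z[k]) / dz[k]
    xd <- x[k] + dx[k] * sd
    yd <- y[k] + dy[k] * sd
    hit <- xd^2 + yd^2 <= r_det2
    k <- k[hit]
  }
  if (!length(k)) return(list(sum_w = 0, sum_w2 = 0))
  w <- if (mc$tally == "energy") E[k] * air_muen_rho(E[k]) else rep(1, length(k))
  list(sum_w = sum(w), sum_w2 = sum(w^2))
}

# component linear attenuation interpolators for one material (1/cm);
# built on a fine log-spaced grid once per run
.material_mu_funs <- function(material, coherent_enabled = TRUE) {
  eg <- exp(seq(log(.E_MIN), log(.E_MAX), length.out = 600))
  pe <- linear_mu(material, eg, "photoelectric")
  inc <- linear_mu(material, eg, "incoherent")
  coh <- if (coherent_enabled) linear_mu(material, eg, "coherent") else 0 * eg
  mk <- function(v) {
    lf <- stats::approxfun(log(eg), log(pmax(v, 1e-300)), rule = 2)
    function(E) exp(lf(log(E)))
  }
  list(photoelectric = mk(pe), incoherent = mk(inc), coherent = mk(coh),
       total = mk(pe + inc + coh))
}

# Kahn's rejection method for the Klein-Nishina distribution
.sample_klein_nishina <- function(E) {
  a <- E / 510.99895
  n <- length(E)
  r <- numeric(n)                     # E'/E ratio
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 10000L) abort("Klein-Nishina sampling failed to terminate")
    ai <- a[todo]
    u1 <- runif(length(todo)); u2 <- runif(length(todo)); u3 <- runif(length(todo))
    branch <- u1 <= (1 + 2 * ai) / (9 + 2 * ai)
    ri <- numeric(length(todo)); ok <- logical(length(todo))
    # branch 1
    b1 <- which(branch)
    if (length(b1)) {
      x <- 1 + 2 * ai[b1] * u2[b1]
      ok[b1] <- u3[b1] <= 4 * (1 / x - 1 / x^2)
      ri[b1] <- 1 / x
    }
    # branch 2
    b2 <- which(!branch)
    if (length(b2)) {
      x <- (1 + 2 * ai[b2]) / (1 + 2 * ai[b2] * u2[b2])
      ct <- 1 - (x - 1) / ai[b2]
      ok[b2] <- u3[b2] <= 0.5 * (ct^2 + 1 / x)
      ri[b2] <- 1 / x
    }
    done <- which(ok)
    r[todo[done]] <- ri[done]
    todo <- todo[!ok]
  }
  cos_theta <- 1 - (1 / r - 1) / a
  list(energy = E * r, cos_theta = pmin(pmax(cos_theta, -1), 1))
}

# Thomson angular law (1 + cos^2) by rejection
.sample_thomson <- function(n) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    c0 <- runif(length(todo), -1, 1)
    ok <- runif(length(todo)) <= (1 + c0^2) / 2
    out[todo[ok]] <- c0[ok]
    todo <- todo[!ok]
  }
  out
}

# rotate unit vectors (ux,uy,uz) by polar angle acos(ct) about themselves
# with azimuth psi
.rotate_direction <- function(ux, uy, uz, ct, psi) {
  st <- sqrt(pmax(1 - ct^2, 0))
  cp <- cos(psi); sp <- sin(psi)
  near_pole <- abs(uz) > 0.999999
  denom <- sqrt(pmax(1 - uz^2, 1e-24))
  x <- ux * ct + st * (ux * uz * cp - uy * sp) / denom
  y <- uy * ct + st * (uy * uz * cp + ux * sp) / denom
  z <- uz * ct - st * cp * denom
  # degenerate case: direction along +-z
  if (any(near_pole)) {
    s <- sign(uz[near_pole])
    x[near_pole] <- st[near_pole] * cp[near_pole]
    y[near_pole] <- st[near_pole] * sp[near_pole]
    z[near_pole] <- s * ct[near_pole]
  }
  nrm <- sqrt(x^2 + y^2 + z^2)
  list(x = x / nrm, y = y / nrm, z = z / nrm)
}
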