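# Photon-diffusion forward models.
#
# Conventions (documented in the methods vignette):
#   * diffusion coefficient D = 1/(3 musp'), absorption-independent, so that
#     the time-resolved solution depends on mua only through exp(-mua v t);
#     this makes the CW log-derivative, mean time of flight and DPF identities
#     exact rather than approximate.
#   * isotropic source depth z0 = 1/musp'; extrapolated boundary at z = -zb,
#     zb = 2 A D with A from boundary_factor_A().
#   * reflectance is the detected photon flux per unit area (Fick's law at the
#     surface), relative units mm^-2.

diffusion_params <- function(props, n_tissue, n_external) {
  D <- 1 / (3 * props$musp)
  list(D = D,
       mueff = sqrt(props$mua / D),
       z0 = 1 / props$musp,
       zb = 2 * boundary_factor_A(n_tissue, n_external) * D)
}

#' CW diffuse reflectance of a homogeneous semi-infinite medium
#'
#' Steady-state spatially resolved diffuse reflectance at distance `rho` from a
#' pencil source, computed from the extrapolated-boundary image-source solution
#' of the diffusion equation:
#' \deqn{R(\rho) = \frac{1}{4\pi}\left[z_0\left(\mu_{eff}+\frac{1}{r_1}\right)
#'   \frac{e^{-\mu_{eff} r_1}}{r_1^2} + (z_0+2z_b)\left(\mu_{eff}+\frac{1}{r_2}\right)
#'   \frac{e^{-\mu_{eff} r_2}}{r_2^2}\right]}
#' with \eqn{r_1 = \sqrt{\rho^2+z_0^2}}, \eqn{r_2 = \sqrt{\rho^2+(z_0+2z_b)^2}}.
#'
#' This is the model fitted to the short-separation channel, whose photons are
#' assumed to travel only in extra-cerebral tissue.
#'
#' @param rho source-detector distance, mm (> 0). Vectorized.
#' @param props [optical_properties()].
#' @param n_tissue,n_external refractive indices (default 1.4 / 1.0).
#' @return Reflectance, mm^-2 (relative units), same length as `rho`.
#' @examples
#' p <- optical_properties(0.01, 1.0)
#' cw_reflectance_homog(c(10, 30), p)
#' @export
cw_reflectance_homog <- function(rho, props, n_tissue = 1.4, n_external = 1.0) {
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  props <- resolve_props(props)
  dp <- diffusion_params(props, n_tissue, n_external)
  z1 <- dp$z0
  z2 <- dp$z0 + 2 * dp$zb
  r1 <- sqrt(rho^2 + z1^2)
  r2 <- sqrt(rho^2 + z2^2)
  (z1 * (dp$mueff + 1 / r1) * exp(-dp$mueff * r1) / r1^2 +
   z2 * (dp$mueff + 1 / r2) * exp(-dp$mueff * r2) / r2^2) / (4 * pi)
}

# Spatial-frequency (q-space) surface flux for a two-layer medium: finite slab
# (D1, mua1) of thickness s over a semi-infinite layer (D2, mua2), extrapolated
# boundary at -zb, isotropic source at z0 (< s). Vectorized over q and over
# per-sample absorption vectors mua1/mua2 (q in rows, samples in columns).
# Written in overflow-safe scaled form.
two_layer_flux_q <- function(q, mua1, musp1, mua2, musp2, s, zb, z0) {
  D1 <- 1 / (3 * musp1)
  D2 <- 1 / (3 * musp2)
  nq <- length(q); ns <- max(length(mua1), length(mua2))
  mua1 <- rep_len(mua1, ns); mua2 <- rep_len(mua2, ns)
  q2 <- q^2
  k1 <- sqrt(outer(q2, mua1 / D1, `+`))   # nq x ns
  k2 <- sqrt(outer(q2, mua2 / D2, `+`))
  a1 <- D1 * k1
  a2 <- D2 * k2
  E1 <- exp(-2 * k1 * (s + zb))
  E2 <- exp(-2 * k1 * (s - z0))
  num <- a1 * (1 + E2) + a2 * (1 - E2)
  den <- a1 * (1 + E1) + a2 * (1 - E1)
  cosh(k1 * zb) * exp(-k1 * (z0 + zb)) * num / den
}

# q-space flux for the homogeneous medium (used in tests as the transform pair
# of cw_reflectance_homog): cosh(k zb) exp(-k (z0+zb)).
homog_flux_q <- function(q, mua, musp, zb, z0) {
  k <- sqrt(q^2 + 3 * musp * mua)
  cosh(k * zb) * exp(-k * (z0 + zb))
}

# Inverse Hankel transform of a q-space flux by fixed-node Gauss-Legendre
# quadrature on [0, q_max] with node doubling until relative change < rel_tol.
hankel_invert <- function(flux_fun, rho, q_max, n_start = 128L,
                          rel_tol = 1e-6, n_max = 8192L) {
  prev <- NULL
  n <- as.integer(n_start)
  repeat {
    gl <- gauss_legendre(n, 0, q_max)
    q <- gl$nodes
    val <- as.numeric(
      crossprod(gl$weights * q * besselJ(q * rho, 0), flux_fun(q))
    ) / (2 * pi)
    if (!is.null(prev) &&
        all(abs(val - prev) <= rel_tol * pmax(abs(val), .Machine$double.xmin)))
      return(list(value = val, n_nodes = n))
    if (n >= n_max)
      stop(sprintf(paste0("two-layer Hankel quadrature did not converge to rel ",
                          "%g with %d nodes (rho=%g, q_max=%g)"),
                   rel_tol, n, rho, q_max), call. = FALSE)
    prev <- val
    n <- n * 2L
  }
}

#' CW diffuse reflectance of a two-layer medium
#'
#' Solves the diffusion two-point boundary problem per spatial frequency
#' (continuity of fluence and flux at depth `s`, extrapolated boundary at the
#' surface, decay at infinity) and inverts the Hankel transform by
#' Gauss-Legendre quadrature with node doubling to relative tolerance 1e-6.
#' The transform is truncated at `q_max = 30 * musp'` of the upper layer (the
#' q-space flux decays like `exp(-q z0)` with `z0 = 1/musp'`, so the truncated
#' tail is below 1e-10 of the integral).
#'
#' @param rho source-detector distance, mm (> 0); scalar.
#' @param medium [layered_medium()].
#' @param wavelength which wavelength's properties to use when the medium holds
#'   several; may be omitted for a single-wavelength medium.
#' @return Reflectance, mm^-2 (relative units).
#' @examples
#' p <- optical_properties(0.01, 1.0)
#' m <- layered_medium(10, p, optical_properties(0.02, 1.0))
#' cw_reflectance_two_layer(30, m)
#' @export
cw_reflectance_two_layer <- function(rho, medium, wavelength = NULL) {
  if (!inherits(medium, "layered_medium")) stop("`medium` must be a layered_medium",
                                                call. = FALSE)
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive distance", call. = FALSE)
  up <- resolve_props(medium$upper, wavelength)
  lo <- resolve_props(medium$lower, wavelength)
  dp <- diffusion_params(up, medium$n_tissue, medium$n_external)
  if (dp$z0 >= medium$s)
    stop("upper layer thinner than the source depth 1/musp'; model invalid",
         call. = FALSE)
  res <- hankel_invert(
    function(q) two_layer_flux_q(q, up$mua, up$musp, lo$mua, lo$musp,
                                 medium$s, dp$zb, dp$z0),
    rho = rho, q_max = 30 * up$musp)
  res$value
}

# Vectorized two-layer reflectance over per-sample absorptions, with a fixed
# node count (chosen once via two_layer_nodes); used by the inversion and the
# synthetic generator where thousands of samples share one geometry.
two_layer_reflectance_vec <- function(rho, mua1, musp1, mua2, musp2,
                                      s, zb, z0, quad) {
  q <- quad$nodes
  w <- quad$weights * q * besselJ(q * rho, 0) / (2 * pi)
  ns <- max(length(mua1), length(mua2))
  .two_layer_refl_cpp(q, w, rep_len(mua1, ns), musp1, rep_len(mua2, ns),
                      musp2, s, zb, z0)
}

# Pick a converged Gauss-Legendre rule for a given geometry by node doubling at
# the baseline properties (and a perturbed state), then freeze it.
two_layer_nodes <- function(rho, up, lo, s, zb, z0, rel_tol = 1e-6) {
  key <- paste(rho, up$mua, up$musp, lo$mua, lo$musp, s, zb, z0, rel_tol,
               sep = "|")
  cached <- .quad_cache[[key]]
  if (!is.null(cached)) return(cached)
  q_max <- 30 * up$musp
  probe <- function(n) {
    gl <- gauss_legendre(n, 0, q_max)
    two_layer_reflectance_vec(rho, c(up$mua, up$mua * 2), up$musp,
                              c(lo$mua, lo$mua * 2), lo$musp, s, zb, z0, gl)
  }
  n <- 128L
  prev <- probe(n)
  repeat {
    n <- n * 2L
    cur <- probe(n)
    if (all(abs(cur - prev) <= rel_tol * abs(cur))) {
      rule <- gauss_legendre(n, 0, q_max)
      .quad_cache[[key]] <- rule
      return(rule)
    }
    if (n >= 8192L) stop("quadrature rule did not converge", call. = FALSE)
    prev <- cur
  }
}

.quad_cache <- new.env(parent = emptyenv())

#' Forward-model a change in optical density
#'
#' Predicts the decadic optical-density change produced by absorption
#' perturbations of a baseline two-layer medium, with scattering held fixed:
#' \deqn{\Delta OD = \log_{10} \frac{R(\mu_{a0})}{R(\mu_{a0} + \Delta\mu_a)}.}
#' Under `model = "homogeneous"` the medium is the upper layer's properties and
#' only `dmua_up` applies (the short-channel approximation); under
#' `model = "two_layer"` `dmua_up` perturbs the slab and `dmua_down` the
#' semi-infinite lower layer.
#'
#' @param rho source-detector distance, mm.
#' @param model `"homogeneous"` or `"two_layer"`.
#' @param baseline [layered_medium()] at baseline.
#' @param dmua_up,dmua_down absorption changes, mm^-1 (vectorized, recycled to
#'   a common length).
#' @param wavelength selects per-wavelength properties when needed.
#' @return Decadic `delta OD` (dimensionless), one value per perturbation.
#' @export
delta_od_forward <- function(rho, model = c("homogeneous", "two_layer"),
                             baseline, dmua_up = 0, dmua_down = 0,
                             wavelength = NULL) {
  model <- match.arg(model)
  if (is.null(wavelength)) wavelength <- medium_wavelengths(baseline)[1L]
  up <- resolve_props(baseline$upper, wavelength)
  lo <- resolve_props(baseline$lower, wavelength)
  n <- max(length(dmua_up), length(dmua_down))
  dmua_up <- rep_len(dmua_up, n)
  dmua_down <- rep_len(dmua_down, n)
  if (model == "homogeneous") {
    if (any(up$mua + dmua_up <= 0))
      stop("perturbation drives upper-layer mua <= 0", call. = FALSE)
    r0 <- cw_reflectance_homog(rho, up, baseline$n_tissue, baseline$n_external)
    rp <- vapply(dmua_up, function(d) {
      cw_reflectance_homog(rho, optical_properties(up$mua + d, up$musp, up$wavelength),
                           baseline$n_tissue, baseline$n_external)
    }, numeric(1))
    return(log10(r0 / rp))
  }
  if (any(up$mua + dmua_up <= 0) || any(lo$mua + dmua_down <= 0))
    stop("perturbation drives a layer's mua <= 0", call. = FALSE)
  dp <- diffusion_params(up, baseline$n_tissue, baseline$n_external)
  quad <- two_layer_nodes(rho, up, lo, baseline$s, dp$zb, dp$z0)
  r0 <- two_layer_reflectance_vec(rho, up$mua, up$musp, lo$mua, lo$musp,
                                  baseline$s, dp$zb, dp$z0, quad)
  rp <- two_layer_reflectance_vec(rho, up$mua + dmua_up, up$musp,
                                  lo$mua + dmua_down, lo$musp,
                                  baseline$s, dp$zb, dp$z0, quad)
  log10(r0 / rp)
}

#' Time-resolved reflectance of a homogeneous semi-infinite medium
#'
#' Extrapolated-boundary image-source solution for the time-resolved diffuse
#' reflectance (photon flux per unit area and time). Its time integral equals
#' [cw_reflectance_homog()] exactly, and absorption enters only through the
#' factor `exp(-mua v t)`.
#'
#' @param rho source-detector distance, mm.
#' @param t time after the source pulse, ns (> 0). Vectorized.
#' @param props [optical_properties()].
#' @param n_tissue,n_external refractive indices.
#' @return Reflectance rate, mm^-2 ns^-1, same length as `t`.
#' @export
tr_reflectance_homog <- function(rho, t, props, n_tissue = 1.4, n_external = 1.0) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  props <- resolve_props(props)
  dp <- diffusion_params(props, n_tissue, n_external)
  v <- C_LIGHT / n_tissue
  z1 <- dp$z0
  z2 <- dp$z0 + 2 * dp$zb
  s4 <- 4 * dp$D * v * t
  0.5 * (4 * pi * dp$D * v)^(-1.5) * t^(-2.5) *
    exp(-props$mua * v * t - rho^2 / s4) *
    (z1 * exp(-z1^2 / s4) + z2 * exp(-z2^2 / s4))
}

# First moment <t> of the time-resolved reflectance, ns (numerical).
mean_time_of_flight <- function(rho, props, n_tissue = 1.4, n_external = 1.0) {
  f <- function(t) tr_reflectance_homog(rho, t, props, n_tissue, n_external)
  m0 <- integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  m1 <- integrate(function(t) t * f(t), 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  m1 / m0
}

#' Differential pathlength factor
#'
#' `DPF = v <t> / rho`, with `v = c / n_tissue` and `<t>` the first moment of
#' the time-resolved reflectance: the mean photon pathlength divided by the
#' source-detector distance. This is the factor that converts an
#' optical-density change into an absorption change in the modified
#' Beer-Lambert law.
#'
#' @inheritParams tr_reflectance_homog
#' @return Dimensionless DPF (> 1 in diffusive media).
#' @examples
#' dpf(30, optical_properties(0.01, 1.0))
#' @export
dpf <- function(rho, props, n_tissue = 1.4) {
  v <- C_LIGHT / n_tissue
  v * mean_time_of_flight(rho, props, n_tissue) / rho
}

#' Fit optical properties to a photon time-of-flight histogram
#'
#' Least-squares fit of the normalized homogeneous time-resolved diffusion
#' model to a normalized, background-subtracted distribution of photon times
#' of flight (DTOF), as used by time-resolved diffuse spectroscopy to measure
#' baseline `mua` and `musp'`. The fit window runs from the rising edge at
#' `rise_frac` of the peak to the tail at `tail_frac` of the peak; both curves
#' are normalized to unit area inside the window. The instrument response
#' function is not modelled.
#'
#' @param t bin centers, ns.
#' @param counts photon counts per bin (same length as `t`).
#' @param rho source-detector distance, mm.
#' @param n_tissue tissue refractive index.
#' @param init list with starting `mua`, `musp` (defaults 0.01, 1.0).
#' @param rise_frac,tail_frac fit-window fractions of the peak (defaults 0.80
#'   on the rising edge, 0.01 on the tail).
#' @return An [optical_properties()] with the fitted coefficients; attribute
#'   `"fit"` holds optimizer details and the window.
#' @export
fit_dtof <- function(t, counts, rho, n_tissue = 1.4,
                     init = list(mua = 0.01, musp = 1.0),
                     rise_frac = 0.80, tail_frac = 0.01) {
  if (length(t) != length(counts)) stop("t and counts lengths differ", call. = FALSE)
  keep <- is.finite(counts) & counts > 0
  if (sum(keep) < 50L)
    stop("degenerate DTOF: need at least 50 bins with counts", call. = FALSE)
  ipk <- which.max(counts)
  pk <- counts[ipk]
  i0 <- which(counts[seq_len(ipk)] >= rise_frac * pk)[1]
  tail_idx <- which(counts >= tail_frac * pk)
  i1 <- max(tail_idx)
  win <- seq(i0, i1)
  tw <- t[win]
  yw <- counts[win] / sum(counts[win])
  obj <- function(par) {
    mua <- exp(par[1]); musp <- exp(par[2])
    m <- tr_reflectance_homog(rho, tw, optical_properties(mua, musp), n_tissue)
    m <- m / sum(m)
    sum((m - yw)^2)
  }
  fit <- optim(c(log(init$mua), log(init$musp)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  out <- optical_properties(exp(fit$par[1]), exp(fit$par[2]))
  attr(out, "fit") <- list(value = fit$value, convergence = fit$convergence,
                           window = range(tw))
  out
}
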