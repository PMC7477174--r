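#' @useDynLib ovifnirs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate optim rnorm runif sd t.test
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Internal unit conventions: lengths mm, absorption/scattering mm^-1, time ns,
# concentrations uM. Speed of light in vacuum, mm/ns:
C_LIGHT <- 299.792458

#' Baseline optical properties of a tissue at one wavelength
#'
#' Bundles the absorption coefficient \eqn{\mu_a} and reduced scattering
#' coefficient \eqn{\mu_s'} that parameterize the photon-diffusion models.
#'
#' @param mua absorption coefficient, mm^-1 (> 0).
#' @param musp reduced scattering coefficient, mm^-1 (> 0).
#' @param wavelength wavelength in nm (informational label).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mua = 0.015, musp = 1.0, wavelength = 751)
#' @export
optical_properties <- function(mua, musp, wavelength = NA_real_) {
  if (!is.numeric(mua) || length(mua) != 1L || !is.finite(mua) || mua <= 0)
    stop("`mua` must be a single positive number (mm^-1)", call. = FALSE)
  if (!is.numeric(musp) || length(musp) != 1L || !is.finite(musp) || musp <= 0)
    stop("`musp` must be a single positive number (mm^-1)", call. = FALSE)
  structure(list(mua = mua, musp = musp, wavelength = as.numeric(wavelength)),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mua = %g mm^-1, musp = %g mm^-1, lambda = %s nm\n",
              x$mua, x$musp, format(x$wavelength)))
  invisible(x)
}

is_props <- function(x) inherits(x, "optical_properties")

# Accept either a single optical_properties or a list keyed by wavelength;
# returns the entry for `wavelength` (or the single entry).
resolve_props <- function(x, wavelength = NULL) {
  if (is_props(x)) return(x)
  if (is.list(x) && all(vapply(x, is_props, logical(1)))) {
    if (is.null(wavelength)) {
      if (length(x) == 1L) return(x[[1L]])
      stop("wavelength required to select optical properties", call. = FALSE)
    }
    wl <- vapply(x, function(p) p$wavelength, numeric(1))
    i <- match(wavelength, wl)
    if (is.na(i)) stop(sprintf("no optical properties for wavelength %g nm", wavelength),
                       call. = FALSE)
    return(x[[i]])
  }
  stop("expected optical_properties or list of optical_properties", call. = FALSE)
}

#' Two-layer head medium (extra-cerebral slab over semi-infinite cortex)
#'
#' Describes the layered geometry used throughout: a finite upper layer of
#' thickness `s` (scalp, skull, CSF) over a semi-infinite lower layer
#' (cerebral tissue). When upper and lower properties coincide the medium is
#' homogeneous.
#'
#' @param s upper-layer thickness, mm (> 0). Default 10 mm (sheep scalp-to-cortex
#'   distance estimated from MRI).
#' @param upper,lower [optical_properties()] or a list of them (one per
#'   wavelength) for the upper/lower layer.
#' @param n_tissue,n_external refractive indices of tissue and the external
#'   medium.
#' @return An object of class `layered_medium`.
#' @examples
#' p <- optical_properties(0.015, 1.0, 751)
#' layered_medium(s = 10, upper = p, lower = p)
#' @export
layered_medium <- function(s = 10, upper, lower, n_tissue = 1.4, n_external = 1.0) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("`s` must be a single positive thickness in mm", call. = FALSE)
  if (n_tissue <= 0 || n_external <= 0) stop("refractive indices must be > 0", call. = FALSE)
  check_layer <- function(x) {
    ok <- is_props(x) ||
      (is.list(x) && length(x) >= 1L && all(vapply(x, is_props, logical(1))))
    if (!ok) stop("layer must be optical_properties or a list of them", call. = FALSE)
  }
  check_layer(upper); check_layer(lower)
  structure(list(s = s, upper = upper, lower = lower,
                 n_tissue = n_tissue, n_external = n_external),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> s = %g mm, n = %g/%g\n", x$s, x$n_tissue, x$n_external))
  invisible(x)
}

medium_wavelengths <- function(medium) {
  up <- medium$upper
  if (is_props(up)) return(up$wavelength)
  vapply(up, function(p) p$wavelength, numeric(1))
}

#' Probe geometry and acquisition settings
#'
#' @param rho_short,rho_long source-detector distances, mm (0 < short < long).
#'   Defaults 10 and 30 mm.
#' @param wavelengths wavelengths in nm; the standard pipeline uses exactly two
#'   (751 and 839 nm).
#' @param sampling_rate sampling rate, Hz (default 10).
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(rho_short = 10, rho_long = 30,
                         wavelengths = c(751, 839), sampling_rate = 10) {
  if (!(rho_short > 0 && rho_long > rho_short))
    stop("need 0 < rho_short < rho_long", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  structure(list(rho_short = rho_short, rho_long = rho_long,
                 wavelengths = as.numeric(wavelengths),
                 sampling_rate = sampling_rate),
            class = "probe_config")
}

#' Boundary mismatch factor A from Fresnel reflection moments
#'
#' Computes the coefficient `A` of the extrapolated-boundary condition
#' (extrapolation length `zb = 2 A D`) from the angular moments of the Fresnel
#' reflection coefficient for unpolarized light at a tissue/external interface.
#' `A = (1 + R_eff) / (1 - R_eff)` with
#' `R_eff = (R_phi + R_j) / (2 - R_phi + R_j)`.
#' For matched indices `A = 1`; for the tissue/air default 1.4/1.0 `A` is about
#' 2.95.
#'
#' @param n_tissue,n_external refractive indices.
#' @return Scalar boundary factor A (>= 1 for n_tissue >= n_external).
#' @export
boundary_factor_A <- function(n_tissue = 1.4, n_external = 1.0) {
  if (n_tissue == n_external) return(1.0)
  key <- sprintf("%.12g/%.12g", n_tissue, n_external)
  cached <- .A_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- n_tissue / n_external
  fres <- function(ct) { # unpolarized Fresnel reflectance, incidence from tissue
    st <- sqrt(pmax(0, 1 - ct^2))
    st2 <- n * st                      # Snell: n1 sin(t1) = n2 sin(t2)
    r <- numeric(length(ct))
    tir <- st2 >= 1
    r[tir] <- 1
    ok <- !tir
    if (any(ok)) {
      ct2 <- sqrt(1 - st2[ok]^2)
      rs <- ((n * ct[ok] - ct2) / (n * ct[ok] + ct2))^2
      rp <- ((n * ct2 - ct[ok]) / (n * ct2 + ct[ok]))^2
      r[ok] <- (rs + rp) / 2
    }
    r
  }
  # moments over the hemisphere, mu = cos(theta)
  r_phi <- integrate(function(mu) 2 * mu * fres(mu), 0, 1,
                     rel.tol = 1e-10)$value
  r_j <- integrate(function(mu) 3 * mu^2 * fres(mu), 0, 1,
                   rel.tol = 1e-10)$value
  r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
  A <- (1 + r_eff) / (1 - r_eff)
  .A_cache[[key]] <- A
  A
}

.A_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch on the Jacobi
# matrix; rules are cached (the eigen decomposition dominates at large n).
gauss_legendre <- function(n, a = 0, b = 1) {
  key <- sprintf("%d|%.12g|%.12g", n, a, b)
  cached <- .gl_cache[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  rule <- list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
               weights = (b - a) / 2 * w[ord])
  .gl_cache[[key]] <- rule
  rule
}

.gl_cache <- new.env(parent = emptyenv())
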