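#' Analytic shape specification for digital phantoms
#'
#' Describes the ground-truth tumor geometry used by [make_phantom()] and
#' [reference_geometry()]. Supported kinds:
#'
#' * `sphere`: `radius` (mm).
#' * `ellipsoid`: `semi_axes` = c(a, b, c) in mm.
#' * `cuboid`: `edges` = c(lx, ly, lz) in mm.
#' * `perturbed_sphere`: `radius` plus a real-spherical-harmonic radial
#'   perturbation of a single `degree` l with `amplitudes` (length 2l+1,
#'   ordered m = -l..l, mm). The radius field is
#'   r(theta, phi) = radius + sum_m a_m Y_lm(theta, phi), which stays
#'   star-convex around the center as long as the perturbation never
#'   reaches the base radius.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"cuboid"`,
#'   `"perturbed_sphere"`.
#' @param radius sphere / perturbed-sphere base radius in mm.
#' @param semi_axes ellipsoid semi-axes in mm.
#' @param edges cuboid edge lengths in mm.
#' @param amplitudes spherical-harmonic amplitudes (mm), length `2*degree+1`.
#' @param degree spherical-harmonic degree l >= 1.
#' @param center mm coordinates of the shape center.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("sphere", "ellipsoid", "cuboid",
                                "perturbed_sphere"),
                       radius = NULL, semi_axes = NULL, edges = NULL,
                       amplitudes = NULL, degree = NULL,
                       center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, center = as.numeric(center))
  if (kind == "sphere") {
    stopifnot(is.numeric(radius), radius > 0)
    spec$radius <- radius
  } else if (kind == "ellipsoid") {
    stopifnot(length(semi_axes) == 3L, all(semi_axes > 0))
    spec$semi_axes <- as.numeric(semi_axes)
  } else if (kind == "cuboid") {
    stopifnot(length(edges) == 3L, all(edges > 0))
    spec$edges <- as.numeric(edges)
  } else {
    stopifnot(is.numeric(radius), radius > 0,
              is.numeric(degree), degree >= 1,
              length(amplitudes) == 2 * degree + 1)
    spec$radius <- radius
    spec$degree <- as.integer(degree)
    spec$amplitudes <- as.numeric(amplitudes)
    rmin <- min(radial_field(spec, seq(0, pi, length.out = 181),
                             seq(0, 2 * pi, length.out = 361))$r)
    if (rmin <= 0) {
      stop("perturbation reaches the center: shape is not star-convex")
    }
  }
  structure(spec, class = "shape_spec")
}

# real spherical harmonics Y_lm on a (theta, phi) grid; returns matrix
# [length(theta) x length(phi)] for one (l, m); pracma::legendre includes
# the Condon-Shortley phase, matching the usual real-basis normalization
real_sph_harm <- function(l, m, theta, phi) {
  P <- pracma::legendre(l, cos(theta))        # (l+1) x length(theta), rows m=0..l
  am <- abs(m)
  norm <- sqrt((2 * l + 1) / (4 * pi) *
                 factorial(l - am) / factorial(l + am))
  plm <- P[am + 1, ]
  if (m == 0) {
    outer(norm * plm, rep(1, length(phi)))
  } else if (m > 0) {
    outer(sqrt(2) * norm * plm, cos(m * phi))
  } else {
    outer(sqrt(2) * norm * plm, sin(am * phi))
  }
}

# radius field r(theta, phi) of a (perturbed) sphere
radial_field <- function(spec, theta, phi) {
  r <- matrix(spec$radius, length(theta), length(phi))
  if (identical(spec$kind, "perturbed_sphere")) {
    l <- spec$degree
    for (m in -l:l) {
      a <- spec$amplitudes[m + l + 1]
      if (a != 0) r <- r + a * real_sph_harm(l, m, theta, phi)
    }
  }
  list(r = r, theta = theta, phi = phi)
}

# surface/volume of a star-convex radial surface by tensor quadrature:
# Gauss-Legendre in theta, trapezoid in phi (periodic). Derivatives of the
# smooth radius field by central differences.
radial_surface_quadrature <- function(spec, n_theta) {
  gl <- pracma::gaussLegendre(n_theta, 0, pi)
  n_phi <- 2 * n_theta
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  w_phi <- 2 * pi / n_phi
  th <- gl$x
  h <- 1e-5
  r  <- radial_field(spec, th, phi)$r
  rt <- (radial_field(spec, th + h, phi)$r -
           radial_field(spec, th - h, phi)$r) / (2 * h)
  rp <- (radial_field(spec, th, phi + h)$r -
           radial_field(spec, th, phi - h)$r) / (2 * h)
  st <- sin(th)
  integrand_s <- r * sqrt(r^2 * st^2 + rt^2 * st^2 + rp^2)
  integrand_v <- r^3 / 3 * st
  list(
    surface = sum(gl$w * rowSums(integrand_s)) * w_phi,
    volume  = sum(gl$w * rowSums(integrand_v)) * w_phi
  )
}

# exact ellipsoid surface element integrated numerically
ellipsoid_surface_quadrature <- function(axes, n_theta) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  gl <- pracma::gaussLegendre(n_theta, 0, pi)
  n_phi <- 2 * n_theta
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  w_phi <- 2 * pi / n_phi
  th <- gl$x
  st <- sin(th); ct <- cos(th)
  # |X_theta x X_phi| for X = (a st cp, b st sp, c ct)
  cp <- cos(phi); sp <- sin(phi)
  cross_sq <- outer(st^2, rep(1, n_phi)) *
    (outer((b * c * st)^2, cp^2) +
       outer((a * c * st)^2, sp^2) +
       outer((a * b * ct)^2, rep(1, n_phi)))
  sum(gl$w * rowSums(sqrt(cross_sq))) * w_phi
}

#' Reference (analytic) volume and surface of a shape
#'
#' Closed forms for spheres and cuboids; ellipsoid surface by numerical
#' integration of the exact parametric surface element; perturbed spheres
#' by adaptive tensor quadrature over the radial surface, refined until two
#' successive grids agree to better than 0.01% relative.
#'
#' @param shape a [shape_spec()].
#' @return A list with `volume` (mm^3) and `surface` (mm^2).
#' @export
reference_geometry <- function(shape) {
  stopifnot(inherits(shape, "shape_spec"))
  switch(
    shape$kind,
    sphere = list(volume = 4 / 3 * pi * shape$radius^3,
                  surface = 4 * pi * shape$radius^2),
    cuboid = {
      e <- shape$edges
      list(volume = prod(e),
           surface = 2 * (e[1] * e[2] + e[1] * e[3] + e[2] * e[3]))
    },
    ellipsoid = {
      ax <- shape$semi_axes
      s <- refine_quadrature(function(n) {
        ellipsoid_surface_quadrature(ax, n)
      })
      list(volume = 4 / 3 * pi * prod(ax), surface = s)
    },
    perturbed_sphere = {
      res <- refine_quadrature_sv(function(n) {
        radial_surface_quadrature(shape, n)
      })
      list(volume = res$volume, surface = res$surface)
    },
    stop(sprintf("unsupported shape kind '%s'", shape$kind))
  )
}

refine_quadrature <- function(f, n0 = 32, rel_tol = 1e-4, max_n = 2048) {
  n <- n0
  prev <- f(n)
  repeat {
    n <- 2L * n
    cur <- f(n)
    if (abs(cur - prev) <= rel_tol * abs(cur) || n >= max_n) return(cur)
    prev <- cur
  }
}

refine_quadrature_sv <- function(f, n0 = 32, rel_tol = 1e-4, max_n = 2048) {
  n <- n0
  prev <- f(n)
  repeat {
    n <- 2L * n
    cur <- f(n)
    ok <- abs(cur$surface - prev$surface) <= rel_tol * abs(cur$surface) &&
      abs(cur$volume - prev$volume) <= rel_tol * abs(cur$volume)
    if (ok || n >= max_n) return(cur)
    prev <- cur
  }
}

# is each point (rows of xyz, mm relative to center) inside the shape?
shape_contains <- function(spec, xyz) {
  xyz <- sweep(xyz, 2, spec$center)
  switch(
    spec$kind,
    sphere = rowSums(xyz^2) < spec$radius^2,
    ellipsoid = rowSums(sweep(xyz, 2, spec$semi_axes, "/")^2) < 1,
    cuboid = {
      h <- spec$edges / 2
      abs(xyz[, 1]) < h[1] & abs(xyz[, 2]) < h[2] & abs(xyz[, 3]) < h[3]
    },
    perturbed_sphere = {
      d <- sqrt(rowSums(xyz^2))
      theta <- ifelse(d > 0, acos(pmin(1, pmax(-1, xyz[, 3] / pmax(d, 1e-12)))), 0)
      phi <- atan2(xyz[, 2], xyz[, 1])
      l <- spec$degree
      rmax <- rep(spec$radius, nrow(xyz))
      for (m in -l:l) {
        a <- spec$amplitudes[m + l + 1]
        if (a != 0) {
          rmax <- rmax + a * diag_real_sph(l, m, theta, phi)
        }
      }
      d < rmax
    },
    stop(sprintf("unsupported shape kind '%s'", spec$kind))
  )
}

# Y_lm evaluated pointwise at paired (theta_i, phi_i)
diag_real_sph <- function(l, m, theta, phi) {
  P <- pracma::legendre(l, cos(theta))
  am <- abs(m)
  norm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
  plm <- P[am + 1, ]
  if (m == 0) norm * plm
  else if (m > 0) sqrt(2) * norm * plm * cos(m * phi)
  else sqrt(2) * norm * plm * sin(am * phi)
}

# half-extent of the shape's bounding box along each axis (mm, about center)
shape_extent <- function(spec) {
  switch(
    spec$kind,
    sphere = rep(spec$radius, 3),
    ellipsoid = spec$semi_axes,
    cuboid = spec$edges / 2,
    perturbed_sphere = rep(spec$radius + sum(abs(spec$amplitudes)) *
                             sqrt((2 * spec$degree + 1) / (4 * pi)) * 2, 3)
  )
}
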