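#' Diffusion coefficient of the photon diffusion model
#'
#' \eqn{D = 1 / (3 (\mu_s' + \mu_a))} in mm.
#'
#' @param mu_a absorption coefficient (1/mm).
#' @param mu_s_prime reduced scattering coefficient (1/mm).
#' @return diffusion coefficient (mm), vectorized.
#' @export
diffusion_coefficient <- function(mu_a, mu_s_prime) {
  s <- mu_a + mu_s_prime
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("mu_a + mu_s_prime must be positive")
  }
  1 / (3 * s)
}

# speed of light in vacuum, mm per ns
C_VACUUM_MM_NS <- 299.792458

#' Ring-scanning probe geometry
#'
#' \code{n_sources} fibers equally spaced on the phantom boundary; each fiber
#' acts as source in turn while the other \code{n_sources - 1} fibers detect.
#' Detector ordering for a source is increasing angular offset from the
#' source fiber.
#'
#' @param n_sources number of fibers (default 16).
#' @param source_depth_mm depth of the isotropic point source inside the
#'   boundary; \code{NULL} (default) uses one transport mean free path,
#'   1 / mu_s0', of the medium being solved.
#' @return a \code{dot_probe} with fields \code{n_sources},
#'   \code{n_detectors} (= n_sources - 1), \code{fiber_angles_deg},
#'   \code{source_depth_mm}.
#' @export
probe_geometry <- function(n_sources = 16L, source_depth_mm = NULL) {
  stopifnot(n_sources >= 3)
  structure(list(n_sources = as.integer(n_sources),
                 n_detectors = as.integer(n_sources) - 1L,
                 fiber_angles_deg = 360 * (0:(n_sources - 1)) / n_sources,
                 source_depth_mm = source_depth_mm),
            class = "dot_probe")
}

# boundary node index of each fiber; requires the fiber angles to coincide
# with outer-ring vertices (6 * n_rings divisible by n_sources)
fiber_nodes <- function(mesh, probe) {
  nb <- 6L * mesh$n_rings
  step <- nb / probe$n_sources
  if (step != round(step)) {
    stop(sprintf("mesh with %d boundary nodes cannot host %d equally spaced fibers",
                 nb, probe$n_sources))
  }
  mesh$boundary_nodes[1L + step * (0:(probe$n_sources - 1L))]
}

# Element geometry used by both assembly and Jacobians:
# areas (M), stiffness kernels G (M x 9, ints of grad phi_i . grad phi_j),
# mass kernels Mk (M x 9, ints of phi_i phi_j).
element_kernels <- function(mesh) {
  el <- mesh$elements
  co <- mesh$node_coords
  x <- matrix(co[el, 1], ncol = 3); y <- matrix(co[el, 2], ncol = 3)
  area <- 0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                   (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * area)
  c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * area)
  G <- matrix(0, nrow(el), 9)
  Mk <- matrix(0, nrow(el), 9)
  for (i in 1:3) for (j in 1:3) {
    k <- (i - 1) * 3 + j
    G[, k] <- area * (b[, i] * b[, j] + c_[, i] * c_[, j])
    Mk[, k] <- area / 12 * (1 + (i == j))
  }
  list(area = area, G = G, Mk = Mk)
}

# boundary edge list (consecutive outer-ring nodes) and edge lengths
boundary_edges <- function(mesh) {
  bn <- mesh$boundary_nodes
  n1 <- bn
  n2 <- c(bn[-1], bn[1])
  co <- mesh$node_coords
  len <- sqrt((co[n2, 1] - co[n1, 1])^2 + (co[n2, 2] - co[n1, 2])^2)
  list(n1 = n1, n2 = n2, len = len)
}

#' Assemble the frequency-domain diffusion FEM system
#'
#' Linear-triangle Galerkin discretization of
#' \eqn{-\nabla \cdot D \nabla \Phi + (\mu_a + i\omega/c) \Phi = S_0}
#' with the Robin boundary condition \eqn{\Phi + 2 A D \partial\Phi/\partial n = 0}
#' on the outer ring. Element coefficients are the means of the nodal values.
#' The \eqn{e^{-i\omega t}} time convention is used, so the phase of the
#' field lags (grows negative) with distance and \code{-Arg(Phi)} is the
#' nonnegative phase lag.
#'
#' @param mesh a \code{dot_mesh}.
#' @param coeffs nodal coefficients (\code{dot_coeffs}).
#' @param frequency_MHz modulation frequency (MHz, >= 0).
#' @param refractive_index medium refractive index (default 1.4), sets the
#'   wave speed c = 299.792458 / n mm/ns.
#' @param A_robin Robin reflection coefficient (default 1,
#'   refractive-index-matched boundary).
#' @return a \code{dot_system}: real and imaginary sparse parts \code{Sr},
#'   \code{Si} (symmetric N x N), \code{omega_rad_ns}, \code{wave_speed_mm_ns},
#'   and cached element kernels.
#' @export
assemble_fd_system <- function(mesh, coeffs, frequency_MHz,
                               refractive_index = 1.4, A_robin = 1) {
  N <- nrow(mesh$node_coords)
  if (length(coeffs$mu_a) != N || length(coeffs$mu_s) != N) {
    stop("coefficient vectors do not match mesh node count")
  }
  stopifnot(frequency_MHz >= 0)
  ker <- element_kernels(mesh)
  el <- mesh$elements
  Dn <- diffusion_coefficient(coeffs$mu_a, coeffs$mu_s)
  De <- rowMeans(matrix(Dn[el], ncol = 3))
  mae <- rowMeans(matrix(coeffs$mu_a[el], ncol = 3))
  cmed <- C_VACUUM_MM_NS / refractive_index
  omega <- 2 * pi * frequency_MHz * 1e-3   # rad/ns

  ii <- integer(0); jj <- integer(0)
  vr <- numeric(0); vi <- numeric(0)
  for (i in 1:3) for (j in 1:3) {
    k <- (i - 1) * 3 + j
    ii <- c(ii, el[, i]); jj <- c(jj, el[, j])
    vr <- c(vr, De * ker$G[, k] + mae * ker$Mk[, k])
    vi <- c(vi, (omega / cmed) * ker$Mk[, k])
  }
  be <- boundary_edges(mesh)
  # edge mass (L/6)[[2,1],[1,2]] scaled by 1/(2A)
  sc <- 1 / (2 * A_robin)
  ii <- c(ii, be$n1, be$n2, be$n1, be$n2)
  jj <- c(jj, be$n1, be$n2, be$n2, be$n1)
  vr <- c(vr, sc * be$len / 3, sc * be$len / 3, sc * be$len / 6, sc * be$len / 6)
  vi <- c(vi, numeric(4 * length(be$len)))

  Sr <- Matrix::sparseMatrix(i = ii, j = jj, x = vr, dims = c(N, N))
  Si <- Matrix::sparseMatrix(i = ii, j = jj, x = vi, dims = c(N, N))
  structure(list(Sr = Sr, Si = Si, omega_rad_ns = omega,
                 wave_speed_mm_ns = cmed, A_robin = A_robin,
                 kernels = ker, n_nodes = N),
            class = "dot_system")
}

# 2N x 2N real block form [[Sr, -Si], [Si, Sr]] of the complex system
real_block_system <- function(system) {
  rbind(cbind(system$Sr, -system$Si), cbind(system$Si, system$Sr))
}

# solve the complex system for a matrix of complex right-hand sides
solve_complex <- function(system, B) {
  N <- system$n_nodes
  B <- as.matrix(B)
  S2 <- real_block_system(system)
  rhs <- rbind(Re(B), Im(B))
  x <- tryCatch(as.matrix(Matrix::solve(S2, rhs)),
                error = function(e) stop("forward system solve failed (singular?): ",
                                         conditionMessage(e)))
  out <- x[1:N, , drop = FALSE] + 1i * x[(N + 1):(2 * N), , drop = FALSE]
  if (any(!is.finite(Mod(out)))) stop("forward solve produced non-finite field")
  out
}

# unit isotropic point-source load vectors (N x n_sources), sources placed
# source_depth inside the boundary at each fiber angle
source_loads <- function(mesh, probe, source_depth) {
  R <- mesh$diameter_mm / 2
  depth <- min(source_depth, R * 0.5)  # keep sources interior on small disks
  ang <- probe$fiber_angles_deg * pi / 180
  pts <- cbind((R - depth) * cos(ang), (R - depth) * sin(ang))
  loc <- locate_points(mesh, pts)
  N <- nrow(mesh$node_coords)
  B <- matrix(0, N, probe$n_sources)
  for (s in seq_len(probe$n_sources)) {
    e <- loc$element[s]
    if (is.na(e)) stop("source position not representable on mesh")
    B[mesh$elements[e, ], s] <- loc$bary[s, ]
  }
  B
}

#' Solve the forward problem for every source of a probe
#'
#' Places a unit isotropic point source one transport mean free path inside
#' the boundary at each fiber angle (load distributed to the containing
#' element by barycentric weights) and solves the complex system with a
#' single sparse factorization for all sources.
#'
#' @param system a \code{dot_system} from \code{\link{assemble_fd_system}}.
#' @param probe a \code{dot_probe}.
#' @param mesh the \code{dot_mesh} the system was assembled on.
#' @param coeffs the nodal coefficients (used for the default source depth).
#' @return complex N x n_sources matrix of nodal photon-density fields.
#' @export
solve_sources <- function(system, probe, mesh, coeffs = NULL) {
  depth <- probe$source_depth_mm
  if (is.null(depth)) {
    if (is.null(coeffs)) stop("need `coeffs` (or probe$source_depth_mm) to place sources")
    depth <- 1 / min(coeffs$mu_s)
  }
  B <- source_loads(mesh, probe, depth)
  solve_complex(system, B)
}

#' Read boundary detectors into a measurement set
#'
#' Detector reading = field value at the detector fiber's boundary node;
#' \code{log_amplitude = ln |Phi|}, \code{phase_lag = (-Arg(Phi)) mod 2*pi}.
#' For source \code{s} the detectors are the other fibers in increasing
#' angular offset (the source fiber is skipped).
#'
#' @param fields complex N x n_sources nodal fields from
#'   \code{\link{solve_sources}}.
#' @param probe a \code{dot_probe}.
#' @param mesh the mesh.
#' @param frequency_MHz modulation frequency recorded in the set.
#' @return a \code{dot_measurement}: \code{log_amplitude} and
#'   \code{phase_lag}, both n_sources x n_detectors, plus
#'   \code{frequency_MHz} and \code{diameter_mm}.
#' @export
read_detectors <- function(fields, probe, mesh, frequency_MHz) {
  fn <- fiber_nodes(mesh, probe)
  Ns <- probe$n_sources; Nd <- probe$n_detectors
  la <- matrix(0, Ns, Nd); ph <- matrix(0, Ns, Nd)
  for (s in seq_len(Ns)) {
    det <- ((s - 1 + 1:Nd) %% Ns) + 1L
    y <- fields[fn[det], s]
    la[s, ] <- log(Mod(y))
    ph[s, ] <- (-Arg(y)) %% (2 * pi)
  }
  if (any(!is.finite(la))) stop("non-finite log amplitude in detector readout")
  measurement_set(la, ph, frequency_MHz, mesh$diameter_mm)
}

#' Construct a measurement set
#'
#' @param log_amplitude n_sources x n_detectors natural-log amplitudes.
#' @param phase_lag matching matrix of phase lags in [0, 2*pi).
#' @param frequency_MHz modulation frequency.
#' @param diameter_mm phantom diameter.
#' @return a \code{dot_measurement}.
#' @export
measurement_set <- function(log_amplitude, phase_lag, frequency_MHz, diameter_mm) {
  stopifnot(all(dim(log_amplitude) == dim(phase_lag)))
  structure(list(log_amplitude = log_amplitude, phase_lag = phase_lag,
                 frequency_MHz = frequency_MHz, diameter_mm = diameter_mm),
            class = "dot_measurement")
}

#' Forward-model a phantom into a measurement set
#'
#' Convenience wrapper: nodal coefficients, system assembly, all-source
#' solve and detector readout in one call.
#'
#' @param phantom a \code{dot_phantom}.
#' @param mesh a matching \code{dot_mesh}.
#' @param probe a \code{dot_probe} (default 16 fibers).
#' @param refractive_index medium refractive index.
#' @return a \code{dot_measurement}.
#' @export
forward_measure <- function(phantom, mesh, probe = probe_geometry(),
                            refractive_index = 1.4) {
  coeffs <- nodal_coefficients(phantom, mesh)
  sys <- assemble_fd_system(mesh, coeffs, phantom$frequency_MHz, refractive_index)
  fields <- solve_sources(sys, probe, mesh, coeffs)
  read_detectors(fields, probe, mesh, phantom$frequency_MHz)
}

#' Infinite-medium frequency-domain point-source solution (2-D)
#'
#' Closed-form Green's function of the planar diffusion operator,
#' \eqn{K_0(k r) / (2 \pi D)} with the complex wavenumber
#' \eqn{k = \sqrt{(\mu_a + i \omega / c) / D}} (principal root). This is the
#' dimensionally consistent oracle for the 2-D disk FEM; the familiar 3-D
#' analogue is \eqn{\exp(-kr)/(4 \pi D r)}. Used only as an independent test
#' oracle for near-field FEM accuracy away from boundaries.
#'
#' @param mu_a absorption (1/mm).
#' @param mu_s_prime reduced scattering (1/mm).
#' @param frequency_MHz modulation frequency.
#' @param distance_mm source-observer distance (> 0).
#' @param refractive_index medium refractive index.
#' @return complex amplitude.
#' @export
analytic_infinite_medium <- function(mu_a, mu_s_prime, frequency_MHz,
                                     distance_mm, refractive_index = 1.4) {
  stopifnot(all(distance_mm > 0))
  D <- diffusion_coefficient(mu_a, mu_s_prime)
  cmed <- C_VACUUM_MM_NS / refractive_index
  omega <- 2 * pi * frequency_MHz * 1e-3
  k <- sqrt(complex(real = mu_a / D, imaginary = omega / (cmed * D)))
  besselK0_complex(k * distance_mm) / (2 * pi * D)
}

# Modified Bessel function K0 for complex argument with Re(z) > 0.
# Power series for |z| <= 8, asymptotic expansion beyond; ~1e-9 relative
# accuracy over the regime the oracle uses (checked against base besselK
# on the real axis).
besselK0_complex <- function(z) {
  z <- as.complex(z)
  out <- complex(length(z))
  small <- Mod(z) <= 8
  if (any(small)) {
    zs <- z[small]
    q <- zs * zs / 4
    gamma_e <- 0.57721566490153286
    term <- rep(1 + 0i, length(zs))   # (q^m / (m!)^2), m = 0
    i0 <- term
    ksum <- complex(length(zs))       # sum term * H_m, H_0 = 0
    hm <- 0
    for (m in 1:60) {
      term <- term * q / (m * m)
      hm <- hm + 1 / m
      i0 <- i0 + term
      ksum <- ksum + term * hm
      if (all(Mod(term) < 1e-18 * (Mod(i0) + 1))) break
    }
    out[small] <- -(log(zs / 2) + gamma_e) * i0 + ksum
  }
  if (any(!small)) {
    zl <- z[!small]
    ck <- rep(1 + 0i, length(zl))
    s <- ck
    for (k in 1:12) {
      ck <- ck * (-(2 * k - 1)^2) / (8 * k * zl)
      s <- s + ck
    }
    out[!small] <- sqrt(pi / (2 * zl)) * exp(-zl) * s
  }
  out
}
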