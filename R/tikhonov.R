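# stacked data vector: log amplitudes then phase lags, source index fastest
stack_measurements <- function(meas) {
  c(as.vector(meas$log_amplitude), as.vector(meas$phase_lag))
}

# difference calc - meas in the stacked domain, phase wrapped to (-pi, pi]
stacked_residual <- function(meas, calc) {
  dla <- as.vector(meas$log_amplitude) - as.vector(calc$log_amplitude)
  dph <- as.vector(meas$phase_lag) - as.vector(calc$phase_lag)
  dph <- ((dph + pi) %% (2 * pi)) - pi
  c(dla, dph)
}

#' Data-model misfit
#'
#' Sum of squared differences over all measurement components (log amplitude
#' and phase lag stacked); phase differences are wrapped to (-pi, pi].
#'
#' @param calc calculated \code{dot_measurement}.
#' @param meas measured \code{dot_measurement}.
#' @return scalar chi-squared.
#' @export
chi_squared <- function(calc, meas) {
  if (!all(dim(calc$log_amplitude) == dim(meas$log_amplitude))) {
    stop("measurement shapes do not match")
  }
  sum(stacked_residual(meas, calc)^2)
}

#' Adjoint-method Jacobian of the boundary measurements
#'
#' Sensitivities of every source-detector log amplitude and phase lag to the
#' nodal diffusion coefficient D and absorption mu_a, computed with one
#' forward solve per source and one adjoint solve per detector fiber (the
#' system is symmetric, so adjoint fields are plain solves with point loads
#' at the detector nodes). Rows stack log-amplitude then phase sensitivities
#' (source index fastest, matching \code{stack_measurements}); columns stack
#' the D block then the mu_a block.
#'
#' @param mesh a \code{dot_mesh}.
#' @param coeffs nodal coefficients.
#' @param probe a \code{dot_probe}.
#' @param frequency_MHz modulation frequency.
#' @param refractive_index medium refractive index.
#' @return a \code{dot_jacobian}: list with dense \code{matrix}
#'   ((2 Ns Nd) x (2 N)) and bookkeeping fields.
#' @export
compute_jacobian <- function(mesh, coeffs, probe, frequency_MHz,
                             refractive_index = 1.4) {
  sys <- assemble_fd_system(mesh, coeffs, frequency_MHz, refractive_index)
  fields <- solve_sources(sys, probe, mesh, coeffs)
  fn <- fiber_nodes(mesh, probe)
  N <- sys$n_nodes
  # adjoint fields: unit loads at the detector fiber nodes
  L <- matrix(0 + 0i, N, probe$n_sources)
  L[cbind(fn, seq_len(probe$n_sources))] <- 1
  adj <- solve_complex(sys, L)

  Ns <- probe$n_sources; Nd <- probe$n_detectors
  P <- Ns * Nd
  s_of <- rep(seq_len(Ns), times = Nd)                    # source index fastest
  d_of <- rep(seq_len(Nd), each = Ns)
  det_fiber <- ((s_of - 1L + d_of) %% Ns) + 1L
  y <- fields[cbind(fn[det_fiber], s_of)]                 # complex readings

  el <- mesh$elements
  ker <- sys$kernels
  M <- nrow(el)
  QK <- matrix(0 + 0i, M, P)
  QM <- matrix(0 + 0i, M, P)
  for (a in 1:3) for (b in 1:3) {
    k <- (a - 1) * 3 + b
    pa <- adj[el[, a], det_fiber, drop = FALSE]           # M x P
    pb <- fields[el[, b], s_of, drop = FALSE]
    pr <- pa * pb
    QK <- QK + pr * ker$G[, k]
    QM <- QM + pr * ker$Mk[, k]
  }
  # scatter element scalars to nodes with weight 1/3 (element-mean coefficients)
  Tmat <- Matrix::sparseMatrix(i = as.vector(el), j = rep(seq_len(M), 3),
                               x = rep(1 / 3, 3 * M), dims = c(N, M))
  JD <- -(as.matrix(Tmat %*% Re(QK)) + 1i * as.matrix(Tmat %*% Im(QK)))  # N x P
  Jm <- -(as.matrix(Tmat %*% Re(QM)) + 1i * as.matrix(Tmat %*% Im(QM)))
  # dy -> d(ln|y|) = Re(dy/y), d(lag) = -Im(dy/y)
  JD <- t(JD) * (1 / y)   # P x N, rows scaled by 1/y (column-major recycling)
  Jm <- t(Jm) * (1 / y)
  J <- rbind(cbind(Re(JD), Re(Jm)),
             cbind(-Im(JD), -Im(Jm)))
  structure(list(matrix = J, n_nodes = N, n_pairs = P,
                 readings = y, probe = probe),
            class = "dot_jacobian")
}

#' One Tikhonov / Levenberg-Marquardt update step
#'
#' Solves the damped normal equations
#' \eqn{(J^T J + \lambda\,\mathrm{diag}(J^T J)) \Delta X = J^T \Delta\Phi}.
#' The diagonal (Marquardt) damping keeps the D and mu_a blocks on comparable
#' scales.
#'
#' @param J a \code{dot_jacobian} or plain matrix.
#' @param residual stacked measurement difference (measured - calculated).
#' @param lambda regularization parameter (> 0).
#' @return update vector, columns stacked [Delta D | Delta mu_a].
#' @export
tr_step <- function(J, residual, lambda) {
  stopifnot(lambda > 0)
  Jm <- if (inherits(J, "dot_jacobian")) J$matrix else J
  if (nrow(Jm) != length(residual)) stop("residual length does not match Jacobian rows")
  H <- crossprod(Jm)
  dgn <- diag(H)
  floor_d <- max(dgn, .Machine$double.eps) * 1e-12
  dgn <- pmax(dgn, floor_d)
  A <- H + lambda * diag(dgn, nrow(H))
  g <- crossprod(Jm, residual)
  dx <- tryCatch(solve(A, g),
                 error = function(e) stop("normal equations numerically singular; ",
                                          "increase lambda (", conditionMessage(e), ")"))
  as.numeric(dx)
}

#' Iteration options for the Tikhonov reconstruction
#'
#' @param max_iterations iteration cap (default 20).
#' @param chi2_rel_tol relative chi-squared change for convergence.
#' @param lambda0 initial regularization parameter.
#' @param lambda_decay multiplier per accepted step (in (0, 1]).
#' @param lambda_floor lower bound on lambda.
#' @param mu_a_bounds,mu_s_bounds clamp bounds (1/mm).
#' @return a \code{dot_recon_options} list.
#' @export
recon_options <- function(max_iterations = 20L, chi2_rel_tol = 1e-3,
                          lambda0 = 10, lambda_decay = 0.5, lambda_floor = 1e-4,
                          mu_a_bounds = c(1e-4, 0.1), mu_s_bounds = c(0.05, 5)) {
  stopifnot(chi2_rel_tol > 0, lambda0 > 0, lambda_decay > 0, lambda_decay <= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 chi2_rel_tol = chi2_rel_tol, lambda0 = lambda0,
                 lambda_decay = lambda_decay, lambda_floor = lambda_floor,
                 mu_a_bounds = mu_a_bounds, mu_s_bounds = mu_s_bounds),
            class = "dot_recon_options")
}

clamp_coeffs <- function(D, mu_a, opts) {
  mu_a <- pmin(pmax(mu_a, opts$mu_a_bounds[1]), opts$mu_a_bounds[2])
  mu_s <- 1 / (3 * pmax(D, 1e-6)) - mu_a
  mu_s <- pmin(pmax(mu_s, opts$mu_s_bounds[1]), opts$mu_s_bounds[2])
  structure(list(mu_a = mu_a, mu_s = mu_s), class = "dot_coeffs")
}

#' Iterative Tikhonov-regularized reconstruction
#'
#' Classic model-based inversion: starting from an initial coefficient guess,
#' repeat forward solve, chi-squared misfit, adjoint Jacobian and damped
#' normal-equation update until the relative chi-squared change falls below
#' tolerance or the iteration cap is hit. Steps that increase chi-squared are
#' rejected and retried with a 10x larger lambda; accepted steps decay lambda.
#' The update is computed in (D, mu_a) and converted back to (mu_a, mu_s')
#' with clamping.
#'
#' @param meas measured \code{dot_measurement}.
#' @param mesh a \code{dot_mesh} matching the measurement diameter.
#' @param probe a \code{dot_probe}.
#' @param init initial \code{dot_coeffs} (positive).
#' @param opts a \code{dot_recon_options}.
#' @param refractive_index medium refractive index.
#' @return a \code{dot_recon_result}: \code{coefficients} (nodal
#'   \code{dot_coeffs}), \code{chi2_history} (accepted steps, nonincreasing),
#'   \code{iterations_run}, \code{converged}, \code{warning_flag}.
#' @export
reconstruct_tr <- function(meas, mesh, probe = probe_geometry(),
                           init, opts = recon_options(),
                           refractive_index = 1.4) {
  stopifnot(all(init$mu_a > 0), all(init$mu_s > 0))
  mu_a <- init$mu_a
  mu_s <- init$mu_s
  lambda <- opts$lambda0
  chi2_history <- numeric(0)
  warning_flag <- FALSE
  converged <- FALSE
  iterations <- 0L

  forward_eval <- function(coeffs) {
    sys <- assemble_fd_system(mesh, coeffs, meas$frequency_MHz, refractive_index)
    fields <- solve_sources(sys, probe, mesh, coeffs)
    read_detectors(fields, probe, mesh, meas$frequency_MHz)
  }

  coeffs <- structure(list(mu_a = mu_a, mu_s = mu_s), class = "dot_coeffs")
  calc <- forward_eval(coeffs)
  chi2 <- chi_squared(calc, meas)
  chi2_history <- c(chi2_history, chi2)

  for (it in seq_len(opts$max_iterations)) {
    iterations <- it
    if (chi2 < 1e-20) { converged <- TRUE; break }
    J <- compute_jacobian(mesh, coeffs, probe, meas$frequency_MHz, refractive_index)
    resid <- stacked_residual(meas, calc)
    D <- diffusion_coefficient(coeffs$mu_a, coeffs$mu_s)
    N <- length(D)

    accepted <- FALSE
    for (try in 1:6) {
      dx <- tr_step(J, resid, lambda)
      cand <- clamp_coeffs(D + dx[1:N], coeffs$mu_a + dx[(N + 1):(2 * N)], opts)
      calc_new <- tryCatch(forward_eval(cand), error = function(e) NULL)
      if (!is.null(calc_new)) {
        chi2_new <- chi_squared(calc_new, meas)
        if (is.finite(chi2_new) && chi2_new < chi2) {
          coeffs <- cand; calc <- calc_new
          rel <- (chi2 - chi2_new) / chi2
          chi2 <- chi2_new
          chi2_history <- c(chi2_history, chi2)
          lambda <- max(lambda * opts$lambda_decay, opts$lambda_floor)
          accepted <- TRUE
          if (rel < opts$chi2_rel_tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { warning_flag <- TRUE; break }
    if (converged) break
  }

  structure(list(coefficients = coeffs, chi2_history = chi2_history,
                 iterations_run = iterations, converged = converged,
                 warning_flag = warning_flag, lambda_final = lambda),
            class = "dot_recon_result")
}

#' @export
print.dot_recon_result <- function(x, ...) {
  cat(sprintf("<dot_recon_result> %d iteration(s), chi2 %.4g -> %.4g, converged=%s%s\n",
              x$iterations_run, x$chi2_history[1], utils::tail(x$chi2_history, 1),
              x$converged, if (x$warning_flag) " (warning: stalled)" else ""))
  invisible(x)
}

#' Export a Tikhonov reconstruction as images and tables
#'
#' Writes the nodal coefficients as CSV, the interpolated 64 x 64 grids for
#' both coefficients as CSV matrices, and the chi-squared history.
#'
#' @param result a \code{dot_recon_result}.
#' @param mesh the reconstruction mesh.
#' @param prefix output path prefix.
#' @param grid_size image resolution.
#' @return invisibly, the written paths.
#' @export
export_recon <- function(result, mesh, prefix, grid_size = 64L) {
  co <- mesh$node_coords
  nodal <- data.frame(node = seq_len(nrow(co)), x_mm = co[, 1], y_mm = co[, 2],
                      mu_a = result$coefficients$mu_a,
                      mu_s = result$coefficients$mu_s)
  f1 <- paste0(prefix, "_nodal.csv")
  utils::write.csv(nodal, f1, row.names = FALSE)
  ga <- interpolate_to_grid(result$coefficients$mu_a, mesh, grid_size)
  gs <- interpolate_to_grid(result$coefficients$mu_s, mesh, grid_size)
  f2 <- paste0(prefix, "_mu_a_grid.csv"); f3 <- paste0(prefix, "_mu_s_grid.csv")
  utils::write.table(ga, f2, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(gs, f3, sep = ",", row.names = FALSE, col.names = FALSE)
  f4 <- paste0(prefix, "_chi2.csv")
  utils::write.csv(data.frame(iteration = seq_along(result$chi2_history) - 1,
                              chi2 = result$chi2_history), f4, row.names = FALSE)
  invisible(c(f1, f2, f3, f4))
}
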