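#' Kinetic parameters of the coupled dynamics
#'
#' Mobilities and RNA turnover for the coupled equations
#' \deqn{\partial_t \phi_P = M_p \nabla^2 (\delta F / \delta \phi_P)}
#' \deqn{\partial_t \phi_R = M_r \nabla^2 \phi_R + k_p(\vec x)\phi_P
#'   - k_d \phi_R.}
#' Defaults follow the directed-flow scenario (`M_r = 1.0`,
#' `k_d = 0.5`) with unit protein mobility; the biologically relevant
#' regime has RNA no more mobile than protein (`M_r / M_p <= 1`), the
#' condition under which activity-driven nucleation operates.
#'
#' @param M_p protein mobility (>= 0).
#' @param M_r RNA mobility (>= 0).
#' @param k_d first-order RNA degradation rate constant (>= 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(M_p = 1, M_r = 1.0, k_d = 0.5) {
  v <- c(M_p = M_p, M_r = M_r, k_d = k_d)
  if (!all(is.finite(v)) || any(v < 0))
    stop("M_p, M_r and k_d must be finite and >= 0")
  structure(as.list(v), class = "kinetic_params")
}

.new_state <- function(t, phi_P, phi_R, domain) {
  structure(list(t = t, phi_P = phi_P, phi_R = phi_R, domain = domain),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g: %d cells, total protein %.4f, total RNA %.4f\n",
              x$t, x$domain$n,
              sum(x$phi_P) * x$domain$cell_area,
              sum(x$phi_R) * x$domain$cell_area))
  invisible(x)
}

#' Seeded-droplet initial condition
#'
#' A dense protein seed (`phi_in`, default 0.63) of radius `R0` in a
#' dilute background (`phi_out`, default 0.13), the nucleation-and-growth
#' initial condition. The step is smoothed over about two grid cells with
#' a tanh profile. RNA starts at zero everywhere.
#'
#' @param domain a [build_domain()] object.
#' @param center length-2 seed centre.
#' @param R0 seed radius; the seed must lie inside the domain.
#' @param phi_in,phi_out protein concentrations inside / outside the seed.
#' @return A `field_state` at `t = 0`.
#' @export
seed_droplet <- function(domain, center = c(0, 0), R0 = 4,
                         phi_in = 0.63, phi_out = 0.13) {
  if (!(phi_out >= 0 && phi_out < phi_in))
    stop("need 0 <= phi_out < phi_in")
  if (R0 < 0) stop("R0 must be >= 0")
  if (R0 + sqrt(sum(center^2)) > domain$radius)
    stop("seed extends outside the domain")
  if (R0 == 0) {
    phi_P <- rep(phi_out, domain$n)
  } else {
    d <- sqrt((domain$x - center[1])^2 + (domain$y - center[2])^2)
    phi_P <- phi_out + (phi_in - phi_out) *
      0.5 * (1 - tanh((d - R0) / domain$dx))
  }
  .new_state(0, phi_P, numeric(domain$n), domain)
}

#' Uniform initial condition
#'
#' Spatially uniform dilute protein with no pre-nucleated dense phase;
#' RNA starts at zero. Used to test de novo, activity-driven nucleation.
#'
#' @param domain a [build_domain()] object.
#' @param phi_P0 uniform protein concentration (>= 0).
#' @return A `field_state` at `t = 0`.
#' @export
uniform_state <- function(domain, phi_P0 = 0.13) {
  if (!is.finite(phi_P0) || phi_P0 < 0) stop("phi_P0 must be >= 0")
  .new_state(0, rep(phi_P0, domain$n), numeric(domain$n), domain)
}

# ---- semi-implicit stepper ------------------------------------------------
#
# Protein (Model B, conserved): backward Euler solved by Newton sweeps.
# Each sweep linearizes the bulk chemical potential about the current
# iterate (c = d mu_b / d phi_P) and solves
#   [I - dt Mp L c + dt Mp kappa L^2] phi = phi^n
#       + dt Mp L (mu_b(phi*) - c phi*)
# for the new iterate. The linear system is solved matrix-free with
# BiCGSTAB, preconditioned by a cached constant-coefficient SPD operator
#   P = I - dt Mp A L + dt Mp kappa L^2   (sparse Cholesky, reused across
# steps at the same dt); the Jacobian differs from P only by the
# composition-dependent part of c, which is localized to interfaces, so
# a handful of Krylov iterations suffice and dt ~ 0.5 is attainable.
# Column sums of L vanish, so the exact update conserves total protein;
# the small Krylov residual is removed by an exact uniform mass fix per
# accepted step.
#
# RNA (linear): backward Euler with the protein source lagged at the new
# protein field,
#   ((1 + dt kd) I - dt Mr L) phiR^{n+1} = phiR^n + dt k_p phi_P^{n+1},
# solved directly with a cached Cholesky factor (unconditionally stable,
# exactly mass-balanced in the discrete sense).

# right-preconditioned BiCGSTAB; amul: function(x) -> A x, prec:
# function(x) -> P^{-1} x
.bicgstab <- function(amul, b, x0, prec, tol = 1e-10, maxit = 60) {
  x <- x0
  r <- b - amul(x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  if (sqrt(sum(r^2)) / bnorm < tol)
    return(list(x = x, ok = TRUE, iters = 0L))
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    ph <- prec(p)
    v <- amul(ph)
    alpha <- rho / sum(r0 * v)
    if (!is.finite(alpha)) break
    s <- r - alpha * v
    if (sqrt(sum(s^2)) / bnorm < tol) {
      x <- x + alpha * ph
      return(list(x = x, ok = TRUE, iters = it))
    }
    sh <- prec(s)
    t <- amul(sh)
    omega <- sum(t * s) / sum(t * t)
    if (!is.finite(omega) || omega == 0) break
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (sqrt(sum(r^2)) / bnorm < tol)
      return(list(x = x, ok = TRUE, iters = it))
  }
  list(x = x, ok = FALSE, iters = maxit)
}

.solver_cache <- new.env(parent = emptyenv())

.domain_token <- function(domain) {
  tok <- attr(domain, "cache_token")
  if (is.null(tok)) sprintf("d%g_%g_%d", domain$radius, domain$dx, domain$n)
  else tok
}

.get_factor <- function(domain, key, build) {
  full <- paste0(.domain_token(domain), "|", key)
  f <- .solver_cache[[full]]
  if (is.null(f)) {
    # keep the cache from growing without bound across dt adaptation
    if (length(ls(.solver_cache)) > 60) rm(list = ls(.solver_cache),
                                           envir = .solver_cache)
    f <- build()
    assign(full, f, envir = .solver_cache)
  }
  f
}

# stabilization constant: bound on f_pp over the composition range the
# fields visit (protein within the widened well, RNA up to phi_R_max)
.stab_const <- function(fe, phi_R_max = 0.3) {
  s <- fe$beta - fe$alpha
  phis <- seq(fe$alpha - 0.5 * s, fe$beta + 0.5 * s, length.out = 61)
  max(.fe_hessian(phis, 0, fe)$f_pp) + 2 * fe$c_rep * phi_R_max^2
}

#' Advance the coupled fields by one time step
#'
#' One semi-implicit step of the conserved protein dynamics and the RNA
#' reaction-diffusion equation with no-flux boundaries. The nonlinear
#' chemical potential is handled by linearly stabilized Picard sweeps;
#' the step reports whether the sweeps converged so the caller
#' ([evolve()]) can reject the step and halve `dt`.
#'
#' @param state a `field_state` (from [seed_droplet()], [uniform_state()]
#'   or a previous step).
#' @param fe an [fe_params()] object.
#' @param kin a [kinetic_params()] object.
#' @param rate transcription rate-constant field over cells (see
#'   [rate_field()]), or a single number recycled.
#' @param dt time step (> 0).
#' @param sweep_tol Picard sweep tolerance (max norm of the sweep
#'   increment).
#' @param max_sweeps maximum Picard sweeps before the step is flagged
#'   unconverged.
#' @param frozen_protein if `TRUE` the protein field is held fixed and
#'   only the RNA equation is advanced (used for theory comparisons).
#' @return A list: `state` (the advanced `field_state`), `ok` (logical,
#'   sweeps converged and fields finite), `sweeps`, `sweep_residual`,
#'   and `rna_balance` (discrete residual of the RNA mass balance, zero
#'   to round-off for the implicit scheme).
#' @export
step <- function(state, fe, kin, rate, dt,
                 sweep_tol = 1e-6, max_sweeps = 8, frozen_protein = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  domain <- state$domain
  n <- domain$n
  if (length(rate) == 1) rate <- rep(rate, n)
  L <- domain$L
  phiP <- state$phi_P
  phiR <- state$phi_R
  ok <- TRUE; sweeps <- 0L; res <- 0
  if (!frozen_protein && kin$M_p > 0) {
    # preconditioner stabilization constant, quantized to a power-of-two
    # ladder so the cached factorization is reused as the RNA level drifts
    A <- 2^ceiling(log2(.stab_const(fe, max(0.3, max(phiR)))))
    key <- sprintf("P|%.12g|%.6g|%.6g|%.6g", dt, kin$M_p, fe$kappa, A)
    fac <- .get_factor(domain, key, function() {
      S <- Matrix::Diagonal(n) - (dt * kin$M_p * A) * L +
        (dt * kin$M_p * fe$kappa) * (L %*% L)
      Matrix::Cholesky(Matrix::forceSymmetric(S), LDL = FALSE)
    })
    prec <- function(x) as.numeric(Matrix::solve(fac, x))
    dtM <- dt * kin$M_p
    kap <- fe$kappa
    phiS <- phiP
    lin_ok <- TRUE
    for (s in seq_len(max_sweeps)) {
      mu_b <- mu_P(phiS, phiR, fe)
      c_vec <- .fe_hessian(phiS, phiR, fe)$f_pp
      amul <- function(x) {
        Lx <- as.numeric(L %*% x)
        x - dtM * as.numeric(L %*% (c_vec * x)) +
          (dtM * kap) * as.numeric(L %*% Lx)
      }
      rhs <- phiP + dtM * as.numeric(L %*% (mu_b - c_vec * phiS))
      sol <- .bicgstab(amul, rhs, phiS, prec)
      sweeps <- s
      if (!sol$ok || !all(is.finite(sol$x))) { lin_ok <- FALSE; break }
      res <- max(abs(sol$x - phiS))
      phiS <- sol$x
      if (res < sweep_tol) break
    }
    # exact mass fix: remove the (tiny) Krylov residual's mass error
    phiS <- phiS + (sum(phiP) - sum(phiS)) / n
    phiP <- phiS
    ok <- lin_ok && res < sweep_tol && all(is.finite(phiP))
  }
  # RNA update (linear, unconditionally stable)
  rna_balance <- 0
  if (kin$M_r > 0 || kin$k_d > 0 || any(rate > 0)) {
    keyR <- sprintf("R|%.12g|%.6g|%.6g", dt, kin$M_r, kin$k_d)
    facR <- .get_factor(domain, keyR, function() {
      S <- (1 + dt * kin$k_d) * Matrix::Diagonal(n) - (dt * kin$M_r) * L
      Matrix::Cholesky(Matrix::forceSymmetric(S), LDL = FALSE)
    })
    rhsR <- phiR + dt * (rate * phiP)
    phiRN <- as.numeric(Matrix::solve(facR, rhsR))
    rna_balance <- sum(phiRN - phiR) / dt -
      (sum(rate * phiP) - kin$k_d * sum(phiRN))
    phiR <- phiRN
    ok <- ok && all(is.finite(phiR))
  }
  list(state = .new_state(state$t + dt, phiP, phiR, domain),
       ok = ok, sweeps = sweeps, sweep_residual = res,
       rna_balance = rna_balance * domain$cell_area)
}

#' Integrate the coupled dynamics to steady state
#'
#' Adaptive time stepping around [step()]: `dt` grows by a factor on each
#' accepted step (capped at `dt_max`) and is halved when the Picard
#' sweeps fail to converge; repeated rejection below `dt_min` aborts with
#' a diagnostic trajectory. Integration stops when the per-cell rate of
#' change stays below `steady_tol` for `steady_consec` consecutive
#' accepted steps, or at the step budget.
#'
#' An optional small pseudo-random perturbation of the initial protein
#' field (`perturb_amp`, seeded by `perturb_seed`) provides the
#' controlled symmetry-breaking analogue of trajectory-to-trajectory
#' variability: without it, mirror-symmetric problems stay
#' mirror-symmetric to round-off.
#'
#' @inheritParams step
#' @param max_steps accepted-step budget (default 15000).
#' @param t_max optional simulation-time budget.
#' @param dt0,dt_growth,dt_max,dt_min adaptive time-step controls.
#' @param steady_tol,steady_consec steady-state criterion: max per-cell
#'   `|dphi|/dt` below `steady_tol` for `steady_consec` consecutive
#'   accepted steps.
#' @param snapshot_every record a field snapshot every this many accepted
#'   steps (the final state is always recorded).
#' @param perturb_amp,perturb_seed amplitude and seed of the initial
#'   perturbation (0 = none).
#' @param neg_monitor log excursions of `phi_P` below this level; the run
#'   aborts if `phi_P` falls below `abort_below` (no clipping is ever
#'   applied, to preserve conservation).
#' @param abort_below hard lower bound on `phi_P`.
#' @return An object of class `cond_trajectory`: list with `snapshots`
#'   (list of `field_state`s at strictly increasing times), `scalars`
#'   (per accepted step data.frame: `t`, `dt`, `total_P`, `total_R`,
#'   `max_R`, `max_dphi`, `sweeps`, `rna_balance`), and `run_meta`
#'   (termination reason, counts, negative-excursion monitor).
#' @export
evolve <- function(state, fe, kin, rate, max_steps = 15000, t_max = Inf,
                   dt0 = 0.05, dt_growth = 1.1, dt_max = 0.5, dt_min = 1e-4,
                   steady_tol = 1e-6, steady_consec = 50,
                   sweep_tol = 1e-6, max_sweeps = 8,
                   snapshot_every = 200, frozen_protein = FALSE,
                   perturb_amp = 0, perturb_seed = 1,
                   neg_monitor = -1e-3, abort_below = -0.05) {
  domain <- state$domain
  if (perturb_amp > 0) {
    rng <- .with_seed(perturb_seed, stats::runif(domain$n, -1, 1))
    pert <- rng - mean(rng)  # keep total protein unchanged
    state <- .new_state(state$t, state$phi_P + perturb_amp * pert,
                        state$phi_R, domain)
  }
  if (length(rate) == 1) rate <- rep(rate, domain$n)
  a <- domain$cell_area
  dt <- dt0
  snapshots <- list(state)
  nacc <- 0L; nrej <- 0L; consec <- 0L
  neg_excursions <- 0L; min_phi <- min(state$phi_P)
  reason <- "step_budget"
  sc <- vector("list", max_steps)
  while (nacc < max_steps && state$t < t_max) {
    st <- step(state, fe, kin, rate, dt, sweep_tol = sweep_tol,
               max_sweeps = max_sweeps, frozen_protein = frozen_protein)
    if (!st$ok) {
      nrej <- nrej + 1L
      dt <- dt / 2
      if (dt < dt_min) { reason <- "dt_underflow"; break }
      next
    }
    mp <- min(st$state$phi_P)
    if (mp < abort_below) { reason <- "negative_concentration"; break }
    if (mp < neg_monitor) neg_excursions <- neg_excursions + 1L
    min_phi <- min(min_phi, mp)
    dphi <- max(max(abs(st$state$phi_P - state$phi_P)),
                max(abs(st$state$phi_R - state$phi_R))) / dt
    state <- st$state
    nacc <- nacc + 1L
    sc[[nacc]] <- c(t = state$t, dt = dt,
                    total_P = sum(state$phi_P) * a,
                    total_R = sum(state$phi_R) * a,
                    max_R = max(state$phi_R),
                    max_dphi = dphi, sweeps = st$sweeps,
                    rna_balance = st$rna_balance)
    if (nacc %% snapshot_every == 0) snapshots[[length(snapshots) + 1]] <- state
    consec <- if (dphi < steady_tol) consec + 1L else 0L
    if (consec >= steady_consec) { reason <- "steady_state"; break }
    dt <- min(dt * dt_growth, dt_max)
  }
  if (state$t >= t_max && reason == "step_budget") reason <- "t_max"
  last <- snapshots[[length(snapshots)]]
  if (last$t < state$t) snapshots[[length(snapshots) + 1]] <- state
  scalars <- as.data.frame(do.call(rbind, sc[seq_len(nacc)]))
  structure(list(snapshots = snapshots, scalars = scalars,
                 run_meta = list(reason = reason, accepted = nacc,
                                 rejected = nrej, final_dt = dt,
                                 neg_excursions = neg_excursions,
                                 min_phi_P = min_phi,
                                 perturb_amp = perturb_amp,
                                 perturb_seed = perturb_seed)),
            class = "cond_trajectory")
}

#' @export
print.cond_trajectory <- function(x, ...) {
  m <- x$run_meta
  fin <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("Trajectory: %d accepted steps (%d rejected), t = %g, stopped on %s\n",
              m$accepted, m$rejected, fin$t, m$reason))
  cat(sprintf("  %d snapshots; final totals: protein %.4f, RNA %.4f\n",
              length(x$snapshots),
              sum(fin$phi_P) * fin$domain$cell_area,
              sum(fin$phi_R) * fin$domain$cell_area))
  invisible(x)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Export a trajectory's scalar time series to CSV
#'
#' @param traj a `cond_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_scalars <- function(traj, path) {
  utils::write.csv(traj$scalars, path, row.names = FALSE)
  invisible(path)
}
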