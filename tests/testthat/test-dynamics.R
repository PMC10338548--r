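test_that("seeded droplet carries the right mass and zero RNA", {
  d <- small_domain()
  s <- seed_droplet(d, center = c(0, 0), R0 = 4, phi_in = 0.63,
                    phi_out = 0.13)
  expected <- 0.63 * pi * 16 + 0.13 * (pi * d$radius^2 - pi * 16)
  expect_equal(sum(s$phi_P) * d$cell_area, expected, tolerance = 0.02)
  expect_equal(s$phi_R, numeric(d$n))
  expect_equal(s$t, 0)
  # degenerate seed: uniform background
  s0 <- seed_droplet(d, R0 = 0)
  expect_equal(s0$phi_P, rep(0.13, d$n))
  expect_error(seed_droplet(d, center = c(8, 0), R0 = 4), "outside")
  expect_error(seed_droplet(d, R0 = 2, phi_in = 0.1, phi_out = 0.6),
               "phi_out")
})

test_that("uniform state is rotation-symmetric with the right mass", {
  d <- tiny_domain()
  s <- uniform_state(d, 0.2)
  expect_equal(sum(s$phi_P) * d$cell_area, 0.2 * d$n * d$cell_area)
  expect_equal(length(unique(s$phi_P)), 1L)
  expect_equal(s$phi_R, numeric(d$n))
})

test_that("uniform binodal state with no activity is a fixed point", {
  d <- tiny_domain()
  p <- pure_well()
  kin <- kinetic_params(1, 1, 0.5)
  s <- uniform_state(d, p$beta)
  st <- step(s, p, kin, rate = 0, dt = 0.1)
  expect_true(st$ok)
  expect_equal(st$state$phi_P, s$phi_P, tolerance = 1e-12)
  expect_equal(st$state$phi_R, s$phi_R)
})

test_that("a single step conserves protein exactly with no-flux boundaries", {
  d <- tiny_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  s <- seed_droplet(d, R0 = 2.5)
  st <- step(s, p, kin, rate = 0, dt = 0.25)
  expect_true(st$ok)
  expect_lt(abs(sum(st$state$phi_P) - sum(s$phi_P)) / sum(s$phi_P), 1e-10)
})

test_that("protein is conserved and RNA balance closes over a full run", {
  d <- tiny_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  rf <- rate_field(gene_cluster(c(0, 0), 1.5, 2), d)
  tr <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rf, max_steps = 300,
               snapshot_every = 100)
  sc <- tr$scalars
  expect_lt(max(abs(sc$total_P - sc$total_P[1])) / sc$total_P[1], 1e-6)
  # the implicit RNA update satisfies the discrete source/sink balance
  # identically at every accepted step
  expect_lt(max(abs(sc$rna_balance)), 1e-8)
  expect_true(all(diff(sc$t) > 0))
})

test_that("frozen-protein stepping converges to the discrete steady state", {
  # discretization-independent integrator check: the time-stepped RNA
  # field must land on the steady state of the same discrete operator,
  # obtained here by a direct linear solve
  d <- build_domain(12, 0.3)
  p <- fe_params()
  kin <- kinetic_params(M_p = 1, M_r = 0.5, k_d = 1)
  k_p <- 0.04; sigma <- 1.5; phi0 <- 0.6
  rf <- disk_rate_field(c(0, 0), sigma, k_p, d)
  s <- uniform_state(d, phi0)
  tr <- evolve(s, p, kin, rf, max_steps = 400, frozen_protein = TRUE,
               dt_max = 0.5, snapshot_every = 400)
  fin <- tr$snapshots[[length(tr$snapshots)]]
  direct <- as.numeric(Matrix::solve(
    kin$M_r * d$L - kin$k_d * Matrix::Diagonal(d$n), -rf * phi0))
  expect_lt(sqrt(sum((fin$phi_R - direct)^2) / sum(direct^2)), 1e-6)
  expect_identical(fin$phi_P, s$phi_P)  # protein untouched
})

test_that("a droplet with no activity relaxes to a disk", {
  d <- small_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  tr <- evolve(seed_droplet(d, R0 = 3), p, kin, rate = 0, max_steps = 400,
               snapshot_every = 200)
  fin <- tr$snapshots[[length(tr$snapshots)]]
  m <- morphology_report(fin, p)
  expect_equal(m$n_components, 1L)
  expect_lt(m$eccentricity, 0.01)
  expect_gt(m$R_eff, 0)
})

test_that("mirror-symmetric problems stay mirror-symmetric", {
  d <- tiny_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  rf <- rate_field(gene_cluster(c(0, 0), 1.5, 1), d)
  tr <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rf, max_steps = 200,
               snapshot_every = 200)
  fin <- tr$snapshots[[length(tr$snapshots)]]
  # mirror map x -> -x via the index matrix
  m <- field_matrix(d, fin$phi_P)
  asym <- max(abs(m - m[nrow(m):1, ]), na.rm = TRUE)
  expect_lt(asym, 1e-6)
})

test_that("semi-implicit integrator matches an explicit-Euler oracle", {
  # independent oracle: forward Euler on the same spatial discretization
  d <- build_domain(5, 0.5)
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  rf <- rate_field(gene_cluster(c(0, 0), 1.5, 1), d)
  dt <- 5e-4; nsteps <- 200
  L <- d$L
  phiP <- seed_droplet(d, R0 = 2)$phi_P
  phiR <- numeric(d$n)
  for (i in seq_len(nsteps)) {
    mu <- mu_P(phiP, phiR, p) - p$kappa * as.numeric(L %*% phiP)
    phiP2 <- phiP + dt * kin$M_p * as.numeric(L %*% mu)
    phiR2 <- phiR + dt * (kin$M_r * as.numeric(L %*% phiR) +
                            rf * phiP - kin$k_d * phiR)
    phiP <- phiP2; phiR <- phiR2
  }
  st <- seed_droplet(d, R0 = 2)
  for (i in seq_len(nsteps)) st <- step(st, p, kin, rf, dt)$state
  expect_lt(sqrt(sum((st$phi_P - phiP)^2) / sum(phiP^2)), 1e-3)
  expect_lt(sqrt(sum((st$phi_R - phiR)^2) / max(sum(phiR^2), 1e-30)), 1e-3)
})

test_that("initial perturbation is mass-neutral and seed-reproducible", {
  d <- tiny_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  t1 <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rate = 0, max_steps = 5,
               perturb_amp = 1e-3, perturb_seed = 11)
  t2 <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rate = 0, max_steps = 5,
               perturb_amp = 1e-3, perturb_seed = 11)
  t3 <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rate = 0, max_steps = 5,
               perturb_amp = 1e-3, perturb_seed = 12)
  expect_identical(t1$scalars, t2$scalars)
  expect_false(identical(t1$snapshots[[1]]$phi_P, t3$snapshots[[1]]$phi_P))
  s0 <- seed_droplet(d, R0 = 2.5)
  expect_equal(sum(t1$snapshots[[1]]$phi_P), sum(s0$phi_P), tolerance = 1e-12)
})

test_that("steady-state droplet size converges under grid refinement", {
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  R_eff <- vapply(c(0.5, 0.25), function(dx) {
    d <- build_domain(8, dx)
    rf <- rate_field(gene_cluster(c(0, 0), 1.5, 1), d)
    tr <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rf, max_steps = 500,
                 steady_tol = 1e-5, snapshot_every = 500)
    fin <- tr$snapshots[[length(tr$snapshots)]]
    segment_dense(fin$phi_P, d)$components$R_eff[1]
  }, 0)
  expect_lt(abs(R_eff[2] - R_eff[1]) / R_eff[2], 0.02)
})

test_that("adaptive stepping grows dt and records diagnostics", {
  d <- tiny_domain()
  p <- fe_params()
  kin <- kinetic_params(1, 1, 0.5)
  tr <- evolve(seed_droplet(d, R0 = 2.5), p, kin, rate = 0, max_steps = 100,
               snapshot_every = 50)
  expect_gt(max(tr$scalars$dt), 0.05)
  expect_lte(max(tr$scalars$dt), 0.5)
  expect_true(tr$run_meta$reason %in%
                c("step_budget", "steady_state", "t_max"))
  expect_equal(tr$run_meta$accepted, nrow(tr$scalars))
})
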