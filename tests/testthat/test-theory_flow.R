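test_that("RNA profile is continuous, decaying and regular at the origin", {
  pars <- list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1, sigma = 2)
  f <- function(r) do.call(rna_profile, c(list(r = r), pars))
  # continuity at the source edge
  eps <- 1e-9
  expect_equal(f(pars$sigma - eps), f(pars$sigma + eps), tolerance = 1e-8)
  # decay at infinity
  expect_lt(f(40), 1e-10)
  expect_equal(f(1e4), 0)
  # regularity: dphi/dr(0) = 0
  h <- 1e-5
  expect_lt(abs(f(h) - f(0)) / h, 1e-4)
  expect_error(f(-1), "r must be")
})

test_that("profile solves the radial ODE (finite-difference oracle)", {
  # independent solve: second-order FD of
  # Mr (phi'' + phi'/r) + kP(r) phiP0 - kd phi = 0 on (0, R], Neumann at 0,
  # Dirichlet 0 at large R
  pars <- list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1, sigma = 2)
  h <- 0.005
  R <- 30
  r <- seq(h / 2, R, by = h)  # staggered to avoid the r = 0 singularity
  n <- length(r)
  src <- ifelse(r < pars$sigma, pars$k_P * pars$phi_P0, 0)
  # tridiagonal system via Matrix
  rp <- r + h / 2; rm <- r - h / 2
  lo <- pars$M_r * rm[-1] / (r[-1] * h^2)
  up <- pars$M_r * rp[-n] / (r[-n] * h^2)
  di <- -pars$M_r * (rp + rm) / (r * h^2) - pars$k_d
  di[1] <- -pars$M_r * rp[1] / (r[1] * h^2) - pars$k_d  # no-flux inner face
  A <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(lo, di, up))
  num <- as.numeric(Matrix::solve(A, -src))
  ana <- do.call(rna_profile, c(list(r = r), pars))
  sel <- r <= 10 * pars$sigma
  expect_lt(max(abs(num[sel] - ana[sel])) / max(ana), 1e-4)
})

test_that("steady-state production balances degradation", {
  pars <- list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1, sigma = 2)
  intg <- stats::integrate(function(r) {
    phi <- do.call(rna_profile, c(list(r = r), pars))
    src <- ifelse(r < pars$sigma, pars$k_P * pars$phi_P0, 0)
    (src - pars$k_d * phi) * 2 * pi * r
  }, 0, 200, subdivisions = 2000, rel.tol = 1e-10, abs.tol = 1e-12)
  expect_lt(abs(intg$value), 1e-6)
})

test_that("gradient summary matches numerical differentiation at r = sigma", {
  for (pars in list(list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1,
                         sigma = 2),
                    list(k_P = 0.02, phi_P0 = 0.6, k_d = 0.1, M_r = 0.3,
                        sigma = 4))) {
    gs <- do.call(gradient_summary, pars)
    expect_equal(gs$grad_max * gs$L_dr, gs$phi_R0)
    f <- function(r) do.call(rna_profile, c(list(r = r), pars))
    rs <- seq(0.01, 8 * pars$sigma, by = 0.005)
    g <- abs(diff(f(rs)) / diff(rs))
    rmid <- rs[-1] - 0.0025
    expect_equal(rmid[which.max(g)], pars$sigma, tolerance = 0.01)
    # the profile is C^1 at the source edge: a tight central difference
    # there recovers the maximal gradient to high accuracy
    h <- 1e-6
    expect_equal(abs(f(pars$sigma + h) - f(pars$sigma - h)) / (2 * h),
                 gs$grad_max, tolerance = 1e-6)
    expect_equal(max(g), gs$grad_max, tolerance = 1e-2)
  }
})

test_that("gradient decreases with RNA mobility and degradation rate", {
  base <- list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1, sigma = 2)
  g0 <- do.call(gradient_summary, base)$grad_max
  gm <- vapply(c(2, 4, 8), function(m) {
    p <- base; p$M_r <- m
    do.call(gradient_summary, p)$grad_max
  }, 0)
  expect_true(all(diff(c(g0, gm)) < 0))
  gk <- vapply(c(1, 2, 4), function(k) {
    p <- base; p$k_d <- k
    do.call(gradient_summary, p)$grad_max
  }, 0)
  expect_true(all(diff(c(g0, gk)) < 0))
})

test_that("large sigma_tilde evaluation is overflow-safe", {
  gs <- gradient_summary(k_P = 0.01, phi_P0 = 0.7, k_d = 10, M_r = 1e-4,
                         sigma = 5)
  expect_gt(gs$sigma_tilde, 1000)
  expect_true(is.finite(gs$phi_R0) && is.finite(gs$grad_max))
  # deep-source limit: phi_R0 -> k_P phi_P0 / k_d
  expect_equal(gs$phi_R0, 0.01 * 0.7 / 10, tolerance = 1e-3)
  expect_true(is.finite(rna_profile(5.1, 0.01, 0.7, 10, 1e-4, 5)))
})

test_that("small-sigma scalings approach the exact formulas", {
  base <- list(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1)
  l <- sqrt(base$M_r / base$k_d)
  ratios <- vapply(c(0.1, 0.03, 0.01), function(st) {
    s <- st * l
    ex <- do.call(gradient_summary, c(base, sigma = s))
    ap <- suppressWarnings(do.call(scaling_smallsigma, c(base, sigma = s)))
    ap$L_dr / ex$L_dr
  }, 0)
  expect_true(all(abs(ratios - 1) < 0.5))
  # monotone approach to 1
  expect_true(all(diff(abs(ratios - 1)) < 0))
  # L_dr increasing in M_r, decreasing in k_d within the regime
  a1 <- suppressWarnings(scaling_smallsigma(0.05, 0.7, 0.5, 1, 0.1))
  a2 <- suppressWarnings(scaling_smallsigma(0.05, 0.7, 0.5, 2, 0.1))
  a3 <- suppressWarnings(scaling_smallsigma(0.05, 0.7, 1.0, 1, 0.1))
  expect_gt(a2$L_dr, a1$L_dr)
  expect_lt(a3$L_dr, a1$L_dr)
  expect_warning(scaling_smallsigma(0.05, 0.7, 0.5, 1, 2), "small-source")
})

test_that("biological length scales follow the square-root laws", {
  ls <- length_scales(M_r = 10^-3.5, k_d = log(2) / 60, k_p = 0.02)
  expect_equal(ls$l_off, sqrt(10^-3.5 / (log(2) / 60)), tolerance = 1e-12)
  expect_gt(ls$l_off, 0.1); expect_lt(ls$l_off, 1)  # sub-micron band
  # quadrupling the half-life doubles l_off
  ls4 <- length_scales(M_r = 10^-3.5, k_d = log(2) / 240, k_p = 0.02)
  expect_equal(ls4$l_off / ls$l_off, 2, tolerance = 1e-12)
  # l_on < l_off whenever k_p > k_d
  expect_lt(length_scales(1, 0.1, 0.5)$l_on, length_scales(1, 0.1, 0.5)$l_off)
})

test_that("velocity-gradient fit recovers exact proportionality", {
  pts <- data.frame(grad_max = c(0.1, 0.2, 0.5), peak_velocity = c(0.2, 0.4, 1))
  fit <- fit_velocity_constant(pts)
  expect_equal(fit$constant, 2, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # common rescaling of both coordinates leaves the slope unchanged
  fit2 <- fit_velocity_constant(transform(pts, grad_max = grad_max * 3,
                                          peak_velocity = peak_velocity * 3))
  expect_equal(fit2$constant, fit$constant)
  expect_error(fit_velocity_constant(pts[1, ]), "at least 2")
  expect_error(fit_velocity_constant(data.frame(grad_max = c(0, 0),
                                                peak_velocity = c(1, 2))),
               "degenerate")
})

test_that("gradient grid tabulates all combinations", {
  g <- gradient_grid(sigma = c(1, 2), M_r = c(0.5, 1), k_d = 0.5)
  expect_equal(nrow(g), 4)
  expect_true(all(is.finite(g$grad_max)))
})
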