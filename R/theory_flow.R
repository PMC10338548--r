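# scaled modified Bessel helpers: besselI(x)*exp(-x), besselK(x)*exp(x);
# all theory expressions below are ratios in which the exponentials cancel
# or appear as exp(negative), so sigma_tilde up to ~1e4 is safe
.I0s <- function(x) besselI(x, 0, expon.scaled = TRUE)
.I1s <- function(x) besselI(x, 1, expon.scaled = TRUE)
.K0s <- function(x) besselK(x, 0, expon.scaled = TRUE)
.K1s <- function(x) besselK(x, 1, expon.scaled = TRUE)

.check_theory_args <- function(k_P, phi_P0, k_d, M_r, sigma) {
  v <- c(k_P, phi_P0, k_d, M_r, sigma)
  if (!all(is.finite(v)) || any(c(k_d, M_r, sigma) <= 0) ||
      k_P < 0 || phi_P0 < 0)
    stop("need k_d, M_r, sigma > 0 and k_P, phi_P0 >= 0")
}

#' Steady-state RNA profile around a localized transcription site
#'
#' Closed-form solution of the radial steady-state reaction-diffusion
#' balance \eqn{ (M_r/r)\, d/dr (r\, d\phi_R/dr) + k_P(r) \phi_P^0 - k_d
#' \phi_R = 0 } with constant production rate \eqn{k_P} inside a disk of
#' radius \eqn{\sigma} and zero outside, regular at the origin and
#' decaying at infinity. The solution is a combination of modified
#' Bessel functions of the scaled radius \eqn{r\sqrt{k_d/M_r}}:
#' inside the source, \eqn{\phi_R = (k_P \phi_P^0 / k_d)\,\{1 -
#' K_1(\tilde\sigma) I_0(\tilde r)/D\}}; outside,
#' \eqn{\phi_R = (k_P \phi_P^0/k_d)\, I_1(\tilde\sigma) K_0(\tilde r)/D}
#' with \eqn{D = I_0(\tilde\sigma) K_1(\tilde\sigma) +
#' I_1(\tilde\sigma) K_0(\tilde\sigma)} and
#' \eqn{\tilde\sigma = \sigma / \sqrt{M_r/k_d}}. Exponentially scaled
#' Bessel evaluations keep the expression stable at large
#' \eqn{\tilde\sigma}.
#'
#' @param r radial distance(s), >= 0.
#' @param k_P production rate constant inside the site.
#' @param phi_P0 protein concentration at the site (held constant).
#' @param k_d RNA degradation rate constant (> 0).
#' @param M_r RNA mobility (> 0).
#' @param sigma source radius (> 0).
#' @return RNA concentration at `r` (vectorized).
#' @export
rna_profile <- function(r, k_P, phi_P0, k_d, M_r, sigma) {
  .check_theory_args(k_P, phi_P0, k_d, M_r, sigma)
  if (any(r < 0)) stop("r must be >= 0")
  l <- sqrt(M_r / k_d)
  st <- sigma / l
  rt <- r / l
  D <- .I0s(st) * .K1s(st) + .I1s(st) * .K0s(st)
  amp <- k_P * phi_P0 / k_d
  out <- numeric(length(r))
  inside <- r < sigma
  # exp(rt - st) <= 1 inside, exp(st - rt) <= 1 outside: no overflow
  out[inside] <- amp *
    (1 - .K1s(st) * .I0s(rt[inside]) * exp(rt[inside] - st) / D)
  out[!inside] <- amp *
    .I1s(st) * .K0s(rt[!inside]) * exp(st - rt[!inside]) / D
  out
}

#' Peak RNA gradient and decay length of the steady-state profile
#'
#' The steady-state RNA gradient is steepest at the source edge
#' \eqn{r = \sigma}. Its magnitude is \eqn{\nabla\phi_R^{max} =
#' \phi_R^0 / L_{dr}} where the concentration scale and decay length are
#' \deqn{\phi_R^0 = \frac{k_P \phi_P^0}{k_d}\,
#'  \frac{(I_0(\tilde\sigma)-1) K_1(\tilde\sigma) +
#'        I_1(\tilde\sigma) K_0(\tilde\sigma)}{D}, \quad
#'  L_{dr} = \sqrt{M_r/k_d}\left(\frac{I_0(\tilde\sigma)-1}
#'   {I_1(\tilde\sigma)} + \frac{K_0(\tilde\sigma)}
#'   {K_1(\tilde\sigma)}\right).}
#' Both the gradient and, for large mobility, the concentration scale
#' decrease with \eqn{M_r} and \eqn{k_d}: fast diffusion or fast
#' turnover flattens the gradient.
#'
#' @inheritParams rna_profile
#' @return A list of class `gradient_theory`: `phi_R0`, `L_dr`,
#'   `grad_max` (= `phi_R0 / L_dr`), `sigma_tilde`.
#' @export
gradient_summary <- function(k_P, phi_P0, k_d, M_r, sigma) {
  .check_theory_args(k_P, phi_P0, k_d, M_r, sigma)
  l <- sqrt(M_r / k_d)
  st <- sigma / l
  D <- .I0s(st) * .K1s(st) + .I1s(st) * .K0s(st)
  # I0 - 1 in scaled terms: (I0s - exp(-st)) * exp(st); keep exp(-st) form
  I0m1K1 <- (.I0s(st) - exp(-st)) * .K1s(st)
  phi_R0 <- (k_P * phi_P0 / k_d) * (I0m1K1 + .I1s(st) * .K0s(st)) / D
  L_dr <- l * ((.I0s(st) - exp(-st)) / .I1s(st) + .K0s(st) / .K1s(st))
  structure(list(phi_R0 = phi_R0, L_dr = L_dr,
                 grad_max = phi_R0 / L_dr, sigma_tilde = st),
            class = "gradient_theory")
}

#' @export
print.gradient_theory <- function(x, ...) {
  cat(sprintf(
    "RNA gradient theory: sigma_tilde = %.4g, phi_R0 = %.6g, L_dr = %.6g, grad_max = %.6g\n",
    x$sigma_tilde, x$phi_R0, x$L_dr, x$grad_max))
  invisible(x)
}

#' Small-source scaling laws for the RNA gradient
#'
#' Leading-order behaviour of \eqn{\phi_R^0}, \eqn{L_{dr}} and
#' \eqn{\nabla\phi_R^{max}} for a source much smaller than the
#' reaction-diffusion length (\eqn{\tilde\sigma \ll 1}), from the series
#' expansion of the modified Bessel functions:
#' \deqn{\phi_R^0 \propto \phi_P^0 \frac{\sigma^2 k_P}{M_r}
#'   \log\!\Big(\frac{1}{\sigma}\sqrt{M_r/k_d}\Big)
#'   \Big(1 + \sigma^2 \frac{k_d}{M_r}
#'   \log\big(\sigma\sqrt{k_d/M_r}\big)\Big),}
#' \deqn{L_{dr} \propto \sigma
#'   \log\!\Big(\frac{1}{\sigma}\sqrt{M_r/k_d}\Big), \qquad
#'  \nabla\phi_R^{max} \propto \phi_P^0 \frac{\sigma k_P}{M_r}
#'   \Big(1 + \sigma^2 \frac{k_d}{M_r}
#'   \log\big(\sigma\sqrt{k_d/M_r}\big)\Big).}
#' The proportionality constants are fixed by matching the exact
#' ([gradient_summary()]) values at a reference \eqn{\tilde\sigma} of
#' 0.01. A warning is issued when called outside the small-source
#' regime (\eqn{\tilde\sigma > 0.3}).
#'
#' @inheritParams rna_profile
#' @param sigma_tilde_ref reference \eqn{\tilde\sigma} at which the
#'   constants are matched.
#' @return A list with approximate `phi_R0`, `L_dr`, `grad_max` and the
#'   input `sigma_tilde`.
#' @export
scaling_smallsigma <- function(k_P, phi_P0, k_d, M_r, sigma,
                               sigma_tilde_ref = 0.01) {
  .check_theory_args(k_P, phi_P0, k_d, M_r, sigma)
  l <- sqrt(M_r / k_d)
  st <- sigma / l
  if (st > 0.3)
    warning("sigma_tilde = ", signif(st, 3),
            " > 0.3: outside the small-source regime")
  raw <- function(sg) {
    lg <- log(l / sg)
    corr <- 1 + sg^2 * (k_d / M_r) * log(sg / l)
    list(phi_R0 = phi_P0 * sg^2 * k_P / M_r * lg * corr,
         L_dr = sg * lg,
         grad_max = phi_P0 * sg * k_P / M_r * corr)
  }
  sref <- sigma_tilde_ref * l
  ex <- gradient_summary(k_P, phi_P0, k_d, M_r, sref)
  r0 <- raw(sref)
  rs <- raw(sigma)
  list(phi_R0 = rs$phi_R0 * ex$phi_R0 / r0$phi_R0,
       L_dr = rs$L_dr * ex$L_dr / r0$L_dr,
       grad_max = rs$grad_max * ex$grad_max / r0$grad_max,
       sigma_tilde = st)
}

#' Biological RNA gradient length scales
#'
#' Degradation-limited and transcription-limited gradient length scales
#' in physical units: \eqn{l_{off} = \sqrt{M_r/k_d}} and
#' \eqn{l_{on} = \sqrt{M_r/k_p}}. With chromatin-associated RNA
#' mobilities near \eqn{10^{-3.5} \mu m^2/s} and half-lives of minutes,
#' \eqn{l_{off}} lands in the few-tenths-of-a-micron range, comparable
#' to condensate sizes.
#'
#' @param M_r RNA mobility (\eqn{\mu m^2/s}).
#' @param k_d degradation rate constant (1/s).
#' @param k_p transcription rate constant (1/s).
#' @return A list with `l_on` and `l_off` in \eqn{\mu m}.
#' @export
length_scales <- function(M_r, k_d, k_p) {
  if (any(c(M_r, k_d, k_p) <= 0)) stop("rates and mobility must be > 0")
  list(l_on = sqrt(M_r / k_p), l_off = sqrt(M_r / k_d))
}

#' Fit the flow-velocity-vs-gradient proportionality
#'
#' Zero-intercept linear least squares of peak condensate flow velocity
#' against the theoretical maximum RNA gradient, across a parameter
#' sweep. The slope is the single empirical constant linking the
#' gradient theory to the simulated drift velocities.
#'
#' @param sim_points data.frame (or list) with columns/elements
#'   `grad_max` and `peak_velocity` (>= 2 points).
#' @return A list: `constant` (slope), `residuals`, `r_squared`, `fit`
#'   (the `lm` object).
#' @export
fit_velocity_constant <- function(sim_points) {
  df <- as.data.frame(sim_points)
  if (!all(c("grad_max", "peak_velocity") %in% names(df)))
    stop("sim_points needs columns grad_max and peak_velocity")
  df <- df[stats::complete.cases(df[, c("grad_max", "peak_velocity")]), ]
  if (nrow(df) < 2) stop("need at least 2 points")
  if (all(df$grad_max == 0)) stop("degenerate fit: all gradients are zero")
  fit <- stats::lm(peak_velocity ~ 0 + grad_max, data = df)
  ss_tot <- sum(df$peak_velocity^2)  # zero-intercept R^2
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(constant = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)),
       r_squared = r2, fit = fit)
}

#' Tabulate gradient theory over a parameter grid
#'
#' Evaluates [gradient_summary()] over the Cartesian product of the
#' supplied parameter vectors; the result is convenient to write as CSV.
#'
#' @param sigma,M_r,k_d parameter vectors.
#' @param k_P,phi_P0 production rate constant and site protein level.
#' @return A data.frame with one row per combination.
#' @export
gradient_grid <- function(sigma, M_r, k_d, k_P = 0.02, phi_P0 = 0.7) {
  g <- expand.grid(sigma = sigma, M_r = M_r, k_d = k_d)
  res <- lapply(seq_len(nrow(g)), function(i) {
    s <- gradient_summary(k_P, phi_P0, g$k_d[i], g$M_r[i], g$sigma[i])
    data.frame(sigma = g$sigma[i], M_r = g$M_r[i], k_d = g$k_d[i],
               sigma_tilde = s$sigma_tilde, phi_R0 = s$phi_R0,
               L_dr = s$L_dr, grad_max = s$grad_max)
  })
  do.call(rbind, res)
}
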