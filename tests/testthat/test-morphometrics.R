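test_that("segmentation finds nothing below threshold and disks above", {
  d <- small_domain()
  seg0 <- segment_dense(rep(0.13, d$n), d)
  expect_equal(seg0$n_components, 0L)
  expect_equal(nrow(seg0$components), 0L)
  # ideal disk of radius 4
  seg <- segment_dense(disk_field(d, 4), d)
  expect_equal(seg$n_components, 1L)
  expect_equal(seg$components$R_eff, 4, tolerance = d$dx / 4)
  expect_equal(seg$components$cx, 0, tolerance = 1e-9)
  # default threshold is the well midpoint
  expect_equal(formals(segment_dense)$threshold, 0.4)
  expect_equal((fe_params()$alpha + fe_params()$beta) / 2, 0.4)
})

test_that("two separated blobs are labeled separately, ranked by area", {
  d <- small_domain()
  f <- pmax(disk_field(d, 3, center = c(-5, 0)),
            disk_field(d, 1.5, center = c(5, 0)))
  seg <- segment_dense(f, d)
  expect_equal(seg$n_components, 2L)
  expect_gt(seg$components$area[1], seg$components$area[2])
  expect_equal(seg$components$cx[1], -5, tolerance = 0.1)
})

test_that("vacuole radius detects enclosed dilute regions only", {
  d <- small_domain()
  expect_true(is.na(vacuole_radius(disk_field(d, 4), d)))
  expect_true(is.na(vacuole_radius(rep(0.1, d$n), d)))
  ann <- annulus_field(d, 3, 6)
  expect_equal(vacuole_radius(ann, d), 3, tolerance = d$dx / 2)
})

test_that("interface bands count det(J) < 0 crossings along the ray", {
  d <- small_domain()
  p <- fe_params()
  # uniform stable dilute field: no interface
  expect_equal(interface_bands(rep(0.1, d$n), rep(0, d$n), p, d), 0L)
  # smoothed droplet: one interfacial band crossing the spinodal
  r <- sqrt(d$x^2 + d$y^2)
  prof <- 0.1 + 0.6 * 0.5 * (1 - tanh((r - 4) / (2 * d$dx)))
  expect_equal(interface_bands(prof, rep(0, d$n), p, d), 1L)
  # smoothed annulus: two bands (inner and outer interface)
  ann <- 0.1 + 0.6 * 0.5 * (tanh((r - 3) / (2 * d$dx)) -
                              tanh((r - 6) / (2 * d$dx)))
  expect_equal(interface_bands(ann, rep(0, d$n), p, d), 2L)
})

test_that("centroid and eccentricity follow the moment arithmetic", {
  d <- small_domain()
  # radially symmetric: e = 0
  r2 <- d$x^2 + d$y^2
  ce <- centroid_eccentricity(exp(-r2 / 2), d, mode = "raw")
  expect_equal(ce$centroid, c(0, 0), tolerance = 1e-9)
  expect_lt(ce$eccentricity, 1e-12)
  # anisotropic Gaussian with I_xx = 3 I_yy, I_xy = 0: e = (2/4)^2 = 0.25
  w <- exp(-d$x^2 / (2 * 1.2) - d$y^2 / (2 * 0.4))
  ce2 <- centroid_eccentricity(w, d, mode = "raw")
  expect_equal(ce2$I_xx / ce2$I_yy, 3, tolerance = 1e-3)
  expect_equal(ce2$eccentricity, 0.25, tolerance = 1e-3)
  # literal formula coincides with the invariant one when I_xy = 0
  ce2l <- centroid_eccentricity(w, d, mode = "raw", formula = "literal")
  expect_equal(ce2l$eccentricity, ce2$eccentricity, tolerance = 1e-6)
})

test_that("eccentricity is invariant under rotation; centroid translates", {
  d <- small_domain()
  # tilted anisotropic Gaussian (I_xy != 0) and its 90-degree rotation
  u <- (d$x + d$y) / sqrt(2); v <- (d$x - d$y) / sqrt(2)
  w1 <- exp(-u^2 / 2.4 - v^2 / 0.8)
  u2 <- (-d$y + d$x) / sqrt(2); v2 <- (-d$y - d$x) / sqrt(2)
  w2 <- exp(-u2^2 / 2.4 - v2^2 / 0.8)  # field rotated by 90 degrees
  e1 <- centroid_eccentricity(w1, d, mode = "raw")
  e2 <- centroid_eccentricity(w2, d, mode = "raw")
  expect_equal(e1$eccentricity, e2$eccentricity, tolerance = 1e-9)
  expect_gt(abs(e1$I_xy), 1e-3)  # the rotation actually exercises I_xy
  # translation moves the centroid and leaves e unchanged
  w3 <- exp(-(d$x - 2)^2 / (2 * 1.2) - (d$y + 1)^2 / (2 * 0.4))
  w0 <- exp(-d$x^2 / (2 * 1.2) - d$y^2 / (2 * 0.4))
  e3 <- centroid_eccentricity(w3, d, mode = "raw")
  e0 <- centroid_eccentricity(w0, d, mode = "raw")
  expect_equal(e3$centroid, e0$centroid + c(2, -1), tolerance = 0.02)
  expect_equal(e3$eccentricity, e0$eccentricity, tolerance = 0.01)
  expect_error(centroid_eccentricity(rep(0, d$n), d), "zero mass")
})

test_that("flow metrics recover a prescribed drift velocity", {
  d <- small_domain()
  p <- pure_well()
  kin <- kinetic_params(M_p = 1, M_r = 1, k_d = 0.5)
  # synthetic trajectory: smooth droplet translating at 0.39 length/time
  mk <- function(t, cx) {
    r <- sqrt((d$x - cx)^2 + d$y^2)
    phi <- 0.13 + 0.5 * 0.5 * (1 - tanh((r - 3) / 0.5))
    structure(list(t = t, phi_P = phi, phi_R = numeric(d$n), domain = d),
              class = "field_state")
  }
  ts <- seq(0, 8, by = 2)
  traj <- structure(list(snapshots = lapply(ts, function(t)
    mk(t, -4 + 0.39 * t)), scalars = NULL, run_meta = list()),
    class = "cond_trajectory")
  fm <- flow_metrics(traj, p, kin, R_c = 4)
  # v R_c / D_p = 0.39 * 4 / 1.56 = 1
  expect_equal(fm$peak_v_dimless, 1, tolerance = 0.02)
  expect_false(fm$truncated)
  # stationary droplet: zero velocity throughout
  traj0 <- structure(list(snapshots = lapply(ts, function(t) mk(t, 0)),
                          scalars = NULL, run_meta = list()),
                     class = "cond_trajectory")
  fm0 <- flow_metrics(traj0, p, kin, R_c = 4)
  expect_equal(fm0$peak_v_dimless, 0, tolerance = 1e-9)
})

test_that("classification rules sort the canonical outcomes", {
  d <- small_domain()
  p <- fe_params()
  mk <- function(t, phi) structure(
    list(t = t, phi_P = phi, phi_R = numeric(d$n), domain = d),
    class = "field_state")
  traj_of <- function(fields, ts = seq_along(fields) - 1)
    structure(list(snapshots = Map(mk, ts, fields), scalars = NULL,
                   run_meta = list()), class = "cond_trajectory")
  cl0 <- gene_cluster(c(0, 0), sigma = 2, k_T = 0)
  disk <- disk_field(d, 3)
  # stationary droplet on the cluster: spherical, at site
  out <- classify(traj_of(list(disk, disk, disk)), cl0, p)
  expect_equal(out$classification, "spherical")
  expect_equal(out$dynamics_class, "at_site")
  # droplet dissolves: dissolved
  out2 <- classify(traj_of(list(disk, rep(0.1, d$n))), cl0, p)
  expect_equal(out2$classification, "dissolved")
  # annulus at the end: vacuole
  out3 <- classify(traj_of(list(disk, annulus_field(d, 2, 5))), cl0, p)
  expect_equal(out3$classification, "vacuole")
  # distant cluster, droplet vanishes, new blob appears at the cluster:
  # dissolution and renucleation
  clF <- gene_cluster(c(6, 0), sigma = 1.5, k_T = 1)
  far0 <- disk_field(d, 2.5, center = c(-5, 0))
  renuc <- disk_field(d, 2.5, center = c(6, 0))
  out4 <- classify(traj_of(list(far0, rep(0.1, d$n), renuc)), clF, p)
  expect_equal(out4$dynamics_class, "dissolution_renucleation")
})
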