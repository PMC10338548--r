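# connected components of a cell subset on the domain's 4-neighbour graph;
# returns integer labels (0 outside the subset), components numbered by
# decreasing area
.components <- function(domain, sel) {
  labels <- integer(domain$n)
  ids <- which(sel)
  if (!length(ids)) return(labels)
  e <- domain$edges
  keep <- sel[e[, 1]] & sel[e[, 2]]
  remap <- integer(domain$n)
  remap[ids] <- seq_along(ids)
  g <- igraph::graph_from_edgelist(
    cbind(remap[e[keep, 1]], remap[e[keep, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  ord <- order(tabulate(comp), decreasing = TRUE)
  rank <- integer(max(comp)); rank[ord] <- seq_along(ord)
  labels[ids] <- rank[comp]
  labels
}

#' Segment the dense condensate phase
#'
#' Thresholds the protein field at the well midpoint
#' \eqn{(\alpha+\beta)/2} (0.4 for the default well) and labels
#' 4-connected components of the dense region. The effective radius of a
#' component is \eqn{R_{eff} = \sqrt{area/\pi}}.
#'
#' @param phi_P protein field over in-domain cells.
#' @param domain a [build_domain()] object.
#' @param threshold dense-phase threshold (default 0.4).
#' @return A list: `labels` (integer per cell, 0 = dilute, components
#'   numbered by decreasing area), `n_components`, and `components`, a
#'   data.frame with `id`, `area`, `R_eff` and area-centroid `cx`, `cy`.
#' @export
segment_dense <- function(phi_P, domain, threshold = 0.4) {
  labels <- .components(domain, phi_P > threshold)
  k <- max(labels)
  if (k == 0) {
    comps <- data.frame(id = integer(), area = numeric(),
                        R_eff = numeric(), cx = numeric(), cy = numeric())
  } else {
    comps <- do.call(rbind, lapply(seq_len(k), function(i) {
      cells <- labels == i
      area <- sum(cells) * domain$cell_area
      data.frame(id = i, area = area, R_eff = sqrt(area / pi),
                 cx = mean(domain$x[cells]), cy = mean(domain$y[cells]))
    }))
  }
  list(labels = labels, n_components = k, components = comps)
}

#' Radius of a vacuole enclosed in the dense phase
#'
#' A vacuole is a dilute region (\eqn{\phi_P} below the threshold) fully
#' enclosed by the dense condensate. Dilute connected components that do
#' not reach the domain boundary are enclosed; the equivalent radius
#' \eqn{\sqrt{area/\pi}} of the largest such region is returned, or `NA`
#' if none exists.
#'
#' @inheritParams segment_dense
#' @return Vacuole radius (length units) or `NA_real_`.
#' @export
vacuole_radius <- function(phi_P, domain, threshold = 0.4) {
  if (!any(phi_P > threshold)) return(NA_real_)
  lab <- .components(domain, phi_P <= threshold)
  k <- max(lab)
  if (k == 0) return(NA_real_)
  best <- NA_real_
  for (i in seq_len(k)) {
    cells <- lab == i
    if (any(domain$boundary[cells])) next  # open to the outside
    r <- sqrt(sum(cells) * domain$cell_area / pi)
    if (is.na(best) || r > best) best <- r
  }
  best
}

#' Count interface bands along a radial ray
#'
#' Evaluates the local stability determinant ([stability_det()]) along a
#' ray from `center` outward and counts contiguous bands where it is
#' negative. Each band is a composition interval crossed by an interface:
#' a simple droplet centred on the ray shows one band, a vacuolated
#' (core-shell) condensate shows two (inner and outer interface).
#'
#' @param phi_P,phi_R fields over in-domain cells.
#' @param fe an [fe_params()] object.
#' @param domain a [build_domain()] object.
#' @param center ray origin (typically the gene-cluster centre).
#' @param angle ray direction in radians (default 0 = +x).
#' @return Integer count of `det < 0` bands along the ray.
#' @export
interface_bands <- function(phi_P, phi_R, fe, domain,
                            center = c(0, 0), angle = 0) {
  nh <- domain$nx / 2
  rmax <- domain$radius + sqrt(sum(center^2))
  rs <- seq(0, rmax, by = domain$dx / 2)
  px <- center[1] + rs * cos(angle)
  py <- center[2] + rs * sin(angle)
  i <- round(px / domain$dx + nh + 0.5)
  j <- round(py / domain$dx + nh + 0.5)
  inside <- i >= 1 & i <= domain$nx & j >= 1 & j <= domain$nx
  cell <- rep(NA_integer_, length(rs))
  cell[inside] <- domain$idx[cbind(i[inside], j[inside])]
  cell <- cell[!is.na(cell)]
  if (!length(cell)) return(0L)
  neg <- stability_det(phi_P[cell], phi_R[cell], fe) < 0
  runs <- rle(neg)
  sum(runs$values)
}

#' Centroid and eccentricity of the protein distribution
#'
#' Mass-weighted centroid and second central moments of the protein
#' field. By default the mass distribution is the field restricted to
#' the dense region (\eqn{\phi_P >} threshold); `mode = "raw"` uses the
#' full field. The default eccentricity is the rotation-invariant moment
#' combination
#' \deqn{e = \frac{(I_{xx}-I_{yy})^2 + 4 I_{xy}^2}{(I_{xx}+I_{yy})^2},}
#' which is 0 for radially symmetric profiles; `formula = "literal"`
#' uses \eqn{((I_{xx}-I_{yy})^2 - 4 I_{xy}) / (I_{xx}+I_{yy})^2}
#' instead (not rotation-invariant; coincides with the default whenever
#' \eqn{I_{xy} = 0}, e.g. axis-aligned geometries).
#'
#' @inheritParams segment_dense
#' @param mode `"dense"` (default) or `"raw"` mass distribution.
#' @param formula `"invariant"` (default) or `"literal"`.
#' @return A list: `centroid` (length-2), `eccentricity`, and the central
#'   moments `I_xx`, `I_yy`, `I_xy`.
#' @export
centroid_eccentricity <- function(phi_P, domain, mode = c("dense", "raw"),
                                  formula = c("invariant", "literal"),
                                  threshold = 0.4) {
  mode <- match.arg(mode)
  formula <- match.arg(formula)
  w <- if (mode == "dense") phi_P * (phi_P > threshold) else phi_P
  m <- sum(w)
  if (m <= 0) stop("zero mass: no dense region to characterize")
  cx <- sum(w * domain$x) / m
  cy <- sum(w * domain$y) / m
  dx_ <- domain$x - cx
  dy_ <- domain$y - cy
  Ixx <- sum(w * dx_^2) / m
  Iyy <- sum(w * dy_^2) / m
  Ixy <- sum(w * dx_ * dy_) / m
  e <- if (formula == "invariant") {
    ((Ixx - Iyy)^2 + 4 * Ixy^2) / (Ixx + Iyy)^2
  } else {
    ((Ixx - Iyy)^2 - 4 * Ixy) / (Ixx + Iyy)^2
  }
  list(centroid = c(cx, cy), eccentricity = e,
       I_xx = Ixx, I_yy = Iyy, I_xy = Ixy)
}

# track the condensate across snapshots by nearest-centroid matching;
# returns one row per snapshot (NA rows once/while no component matches)
.track_condensate <- function(traj, threshold = 0.4, max_jump = NULL) {
  snaps <- traj$snapshots
  domain <- snaps[[1]]$domain
  out <- data.frame(t = vapply(snaps, function(s) s$t, 0),
                    cx = NA_real_, cy = NA_real_, R_eff = NA_real_,
                    present = FALSE)
  prev <- NULL
  for (i in seq_along(snaps)) {
    seg <- segment_dense(snaps[[i]]$phi_P, domain, threshold)
    if (seg$n_components == 0) { prev <- NULL; next }
    comps <- seg$components
    if (is.null(prev)) {
      pick <- comps[1, ]  # largest
    } else {
      d <- sqrt((comps$cx - prev$cx)^2 + (comps$cy - prev$cy)^2)
      jump <- if (is.null(max_jump)) 2 * max(prev$R_eff, 1) else max_jump
      cand <- which(d <= jump)
      if (!length(cand)) { prev <- NULL; next }
      pick <- comps[cand[which.max(comps$area[cand])], ]
    }
    # centroid refined by protein mass within the tracked component
    cells <- seg$labels == pick$id
    w <- snaps[[i]]$phi_P * cells
    cx <- sum(w * domain$x) / sum(w)
    cy <- sum(w * domain$y) / sum(w)
    out$cx[i] <- cx; out$cy[i] <- cy
    out$R_eff[i] <- pick$R_eff
    out$present[i] <- TRUE
    prev <- list(cx = cx, cy = cy, R_eff = pick$R_eff)
  }
  out
}

#' Condensate drift velocity from a trajectory
#'
#' Tracks the condensate centroid across snapshots (nearest-centroid
#' matching) and differentiates it in time. The drift speed is reported
#' both raw and non-dimensionalized as \eqn{v\, R_c / D_P}, with
#' \eqn{D_P} the dilute-limit protein diffusivity
#' ([protein_diffusivity()], 1.56 \eqn{M_p} for the default well).
#'
#' @param traj a `cond_trajectory` with at least 3 snapshots.
#' @param fe an [fe_params()] object.
#' @param kin a [kinetic_params()] object.
#' @param R_c condensate radius used in the non-dimensionalization
#'   (default 4).
#' @param threshold dense-phase threshold.
#' @return A list: `series` (data.frame `t`, `cx`, `cy`, `speed`,
#'   `v_dimless`, `displacement`), `peak_v_dimless`, `D_p`, and
#'   `truncated` (`TRUE` if the condensate was lost mid-track).
#' @export
flow_metrics <- function(traj, fe, kin, R_c = 4, threshold = 0.4) {
  if (length(traj$snapshots) < 3)
    stop("need at least 3 snapshots to estimate velocities")
  tr <- .track_condensate(traj, threshold)
  ok <- which(tr$present)
  if (length(ok) == 0) stop("no condensate found in any snapshot")
  # keep the first contiguous tracked stretch; flag if the track was lost
  s <- ok[1]
  tail_present <- tr$present[s:nrow(tr)]
  len <- if (any(!tail_present)) which(!tail_present)[1] - 1
         else length(tail_present)
  truncated <- len < length(tail_present)
  tr <- tr[seq(s, length.out = len), , drop = FALSE]
  n <- nrow(tr)
  speed <- rep(NA_real_, n)
  if (n >= 2) {
    dt <- diff(tr$t)
    vx <- diff(tr$cx) / dt
    vy <- diff(tr$cy) / dt
    sp <- sqrt(vx^2 + vy^2)
    speed[2:n] <- sp
  }
  D_p <- protein_diffusivity(fe, kin$M_p)
  disp <- sqrt((tr$cx - tr$cx[1])^2 + (tr$cy - tr$cy[1])^2)
  series <- data.frame(t = tr$t, cx = tr$cx, cy = tr$cy,
                       R_eff = tr$R_eff, speed = speed,
                       v_dimless = speed * R_c / D_p,
                       displacement = disp)
  list(series = series,
       peak_v_dimless = if (all(is.na(speed))) NA_real_
                        else max(series$v_dimless, na.rm = TRUE),
       D_p = D_p, truncated = truncated)
}

#' Per-snapshot morphology report
#'
#' Convenience wrapper computing the standard metrics for one field
#' state: effective radius (largest dense component), vacuole radius,
#' interface-band count along a ray through the cluster centre, centroid,
#' eccentricity and component count.
#'
#' @param state a `field_state`.
#' @param fe an [fe_params()] object.
#' @param cluster_center ray origin for interface counting.
#' @param threshold dense-phase threshold.
#' @return A one-row data.frame.
#' @export
morphology_report <- function(state, fe, cluster_center = c(0, 0),
                              threshold = 0.4) {
  domain <- state$domain
  seg <- segment_dense(state$phi_P, domain, threshold)
  vac <- vacuole_radius(state$phi_P, domain, threshold)
  if (seg$n_components > 0) {
    ce <- centroid_eccentricity(state$phi_P, domain, threshold = threshold)
    cx <- ce$centroid[1]; cy <- ce$centroid[2]; ecc <- ce$eccentricity
    R_eff <- seg$components$R_eff[1]
  } else {
    cx <- cy <- ecc <- NA_real_; R_eff <- 0
  }
  nb <- interface_bands(state$phi_P, state$phi_R, fe, domain,
                        center = cluster_center)
  data.frame(t = state$t, R_eff = R_eff, vacuole_radius = vac,
             n_interfaces = nb, centroid_x = cx, centroid_y = cy,
             eccentricity = ecc, n_components = seg$n_components)
}

#' Classify trajectory outcome (morphology and dynamics)
#'
#' Rule-based classification of a completed run.
#' Morphology (final snapshot): `dissolved` if no dense component
#' remains; `vacuole` if an enclosed dilute region exists; `aspherical`
#' if the eccentricity exceeds `e_threshold`; `spherical` otherwise.
#' Dynamics (tracked centroid vs the nearest gene cluster):
#' `dissolution_renucleation` if the original condensate vanished while
#' a dense component is present at the cluster at the end; `flow` if the
#' original condensate persisted and its net displacement toward the
#' cluster exceeds `R_c/2`; `at_site` if it started overlapping the
#' cluster and moved less than `R_c/4`; `no_effect` otherwise.
#'
#' @param traj a `cond_trajectory`.
#' @param clusters a [gene_cluster()] or list of them.
#' @param fe an [fe_params()] object.
#' @param e_threshold eccentricity threshold for `aspherical`
#'   (default 0.05).
#' @param threshold dense-phase threshold.
#' @return A list with `classification`, `dynamics_class`, and the
#'   supporting numbers (`final_R_eff`, `vacuole_radius`,
#'   `eccentricity`, `displacement_toward`, `R_c`).
#' @export
classify <- function(traj, clusters, fe, e_threshold = 0.05,
                     threshold = 0.4) {
  if (inherits(clusters, "gene_cluster")) clusters <- list(clusters)
  domain <- traj$snapshots[[1]]$domain
  fin <- traj$snapshots[[length(traj$snapshots)]]
  seg <- segment_dense(fin$phi_P, domain, threshold)
  vac <- vacuole_radius(fin$phi_P, domain, threshold)
  ecc <- if (seg$n_components > 0)
    centroid_eccentricity(fin$phi_P, domain,
                          threshold = threshold)$eccentricity else NA_real_
  classification <-
    if (seg$n_components == 0) "dissolved"
    else if (!is.na(vac)) "vacuole"
    else if (ecc > e_threshold) "aspherical"
    else "spherical"

  tr <- .track_condensate(traj, threshold)
  dynamics <- "no_effect"
  disp_toward <- NA_real_
  R_c <- NA_real_
  if (any(tr$present)) {
    i0 <- which(tr$present)[1]
    R_c <- tr$R_eff[i0]
    p0 <- c(tr$cx[i0], tr$cy[i0])
    # nearest cluster to the initial condensate
    cd <- vapply(clusters, function(cl) sqrt(sum((cl$center - p0)^2)), 0)
    cl <- clusters[[which.min(cd)]]
    d0 <- cd[which.min(cd)]
    # did the original track survive to the end?
    alive <- tr$present[nrow(tr)] &&
      !any(!tr$present[i0:nrow(tr)])
    if (alive) {
      pe <- c(tr$cx[nrow(tr)], tr$cy[nrow(tr)])
      de <- sqrt(sum((cl$center - pe)^2))
      disp_toward <- d0 - de
      overlap0 <- d0 < R_c + cl$sigma
      moved <- sqrt(sum((pe - p0)^2))
      if (overlap0 && moved < R_c / 4) dynamics <- "at_site"
      else if (disp_toward > R_c / 2) dynamics <- "flow"
    } else if (seg$n_components > 0) {
      # original lost; is the surviving dense phase at the cluster?
      dc <- sqrt((seg$components$cx - cl$center[1])^2 +
                 (seg$components$cy - cl$center[2])^2)
      if (any(dc < R_c + cl$sigma)) dynamics <- "dissolution_renucleation"
    }
  }
  list(classification = classification, dynamics_class = dynamics,
       final_R_eff = if (seg$n_components > 0) seg$components$R_eff[1] else 0,
       vacuole_radius = vac, eccentricity = ecc,
       displacement_toward = disp_toward, R_c = R_c)
}
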