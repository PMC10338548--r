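# polynomial rolling hash over the serialized object; good enough for
# config provenance stamps (not cryptographic)
.config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (v in b) h <- (h * 257 + v + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Assemble a run configuration
#'
#' Builds the fully resolved configuration for one simulation: domain,
#' free-energy and kinetic parameters, activity field, initial condition
#' and integration controls. All values have defaults, so presets and
#' user configs need only override what differs. Configurations
#' round-trip losslessly through YAML ([write_config()],
#' [read_config()]).
#'
#' @param scenario free-text scenario name.
#' @param domain list with `radius`, `dx`.
#' @param fe named list of [fe_params()] arguments (defaults: calibrated
#'   parameters).
#' @param kin named list of [kinetic_params()] arguments.
#' @param activity list: `type` one of `"clusters"`, `"uniform"`;
#'   `clusters` a list of `{x, y, sigma, k_T}` lists (for
#'   `"clusters"`); `k_T` total activity (for `"uniform"`).
#' @param initial list: `type` one of `"seed_droplet"`, `"uniform"`;
#'   for droplets `center`, `R0`, `phi_in`, `phi_out`; for uniform
#'   `phi_P0`.
#' @param integration named list of [evolve()] control arguments
#'   (`max_steps`, `dt0`, `dt_max`, `steady_tol`, `snapshot_every`,
#'   `perturb_amp`, `perturb_seed`, ...).
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "custom",
                       domain = list(),
                       fe = list(),
                       kin = list(),
                       activity = list(),
                       initial = list(),
                       integration = list()) {
  merge1 <- function(base, over) {
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  cfg <- list(
    scenario = scenario,
    domain = merge1(list(radius = 30, dx = 0.2), domain),
    fe = merge1(unclass(fe_params()), fe),
    kin = merge1(unclass(kinetic_params())[], kin),
    activity = merge1(list(type = "clusters",
                           clusters = list(list(x = 0, y = 0,
                                                sigma = 2, k_T = 1)),
                           k_T = 1), activity),
    initial = merge1(list(type = "seed_droplet", center = c(0, 0),
                          R0 = 4, phi_in = 0.63, phi_out = 0.13,
                          phi_P0 = 0.13), initial),
    integration = merge1(list(max_steps = 15000, dt0 = 0.05,
                              dt_growth = 1.1, dt_max = 0.5,
                              dt_min = 1e-4, steady_tol = 1e-6,
                              steady_consec = 50, sweep_tol = 1e-6,
                              max_sweeps = 8, snapshot_every = 200,
                              perturb_amp = 0, perturb_seed = 1),
                         integration)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every field and returns all violations at once (empty
#' character vector when valid).
#'
#' @param config a [run_config()] object or plain list.
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  probs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) probs <<- c(probs, msg)
  d <- config$domain
  need(is.numeric(d$radius) && d$radius > 0, "domain.radius must be > 0")
  need(is.numeric(d$dx) && d$dx > 0 && d$dx <= d$radius / 10,
       "domain.dx must satisfy 0 < dx <= radius/10")
  fe <- config$fe
  ok_fe <- tryCatch({ do.call(fe_params, fe); TRUE },
                    error = function(e) { probs <<- c(probs,
                      paste0("fe: ", conditionMessage(e))); FALSE })
  tryCatch(do.call(kinetic_params, config$kin),
           error = function(e) probs <<- c(probs,
             paste0("kin: ", conditionMessage(e))))
  act <- config$activity
  need(act$type %in% c("clusters", "uniform"),
       "activity.type must be 'clusters' or 'uniform'")
  if (identical(act$type, "clusters")) {
    for (i in seq_along(act$clusters)) {
      cl <- act$clusters[[i]]
      for (f in c("x", "y", "sigma", "k_T"))
        need(is.numeric(cl[[f]]) && length(cl[[f]]) == 1 &&
               is.finite(cl[[f]]),
             sprintf("activity.clusters[%d].%s missing or not a number",
                     i, f))
      if (is.numeric(cl$sigma) && length(cl$sigma) == 1)
        need(cl$sigma > 0, sprintf("activity.clusters[%d].sigma must be > 0", i))
    }
  } else {
    need(is.numeric(act$k_T) && act$k_T >= 0, "activity.k_T must be >= 0")
  }
  ini <- config$initial
  need(ini$type %in% c("seed_droplet", "uniform"),
       "initial.type must be 'seed_droplet' or 'uniform'")
  if (identical(ini$type, "seed_droplet")) {
    need(is.numeric(ini$R0) && ini$R0 >= 0, "initial.R0 must be >= 0")
    need(is.numeric(ini$phi_in) && is.numeric(ini$phi_out) &&
           ini$phi_out < ini$phi_in,
         "initial: need phi_out < phi_in")
  } else {
    need(is.numeric(ini$phi_P0) && ini$phi_P0 >= 0,
         "initial.phi_P0 must be >= 0")
  }
  it <- config$integration
  need(is.numeric(it$max_steps) && it$max_steps >= 1,
       "integration.max_steps must be >= 1")
  need(is.numeric(it$dt0) && it$dt0 > 0, "integration.dt0 must be > 0")
  probs
}

#' Write / read a configuration as YAML
#'
#' @param config a [run_config()] object.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns the `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Execute one configured simulation
#'
#' Assembles domain, activity field and initial condition from the
#' configuration, integrates to steady state, and analyzes every
#' snapshot. Deterministic given the configuration (including the
#' perturbation seed).
#'
#' @param config a [run_config()] object.
#' @param keep_snapshots keep field snapshots in the returned trajectory
#'   (set `FALSE` to save memory in large sweeps; the final state is
#'   always kept).
#' @return A list of class `cond_run`: `trajectory`, `reports` (one
#'   [morphology_report()] row per snapshot), `outcome` (the
#'   [classify()] result), `summary` (one-row data.frame), `config`
#'   (with its content hash in `config_hash`).
#' @export
run <- function(config, keep_snapshots = TRUE) {
  probs <- validate_config(config)
  if (length(probs))
    stop("invalid config:\n  ", paste(probs, collapse = "\n  "))
  fe <- do.call(fe_params, config$fe)
  kin <- do.call(kinetic_params, config$kin)
  domain <- build_domain(config$domain$radius, config$domain$dx)
  act <- config$activity
  if (identical(act$type, "uniform")) {
    rate <- uniform_rate_field(act$k_T, domain)
    clusters <- list(gene_cluster(c(0, 0), sigma = domain$radius,
                                  k_T = act$k_T))
  } else {
    clusters <- lapply(act$clusters, function(cl)
      gene_cluster(c(cl$x, cl$y), sigma = cl$sigma, k_T = cl$k_T))
    rate <- rate_field(clusters, domain)
  }
  ini <- config$initial
  state <- if (identical(ini$type, "uniform")) {
    uniform_state(domain, ini$phi_P0)
  } else {
    seed_droplet(domain, center = unlist(ini$center), R0 = ini$R0,
                 phi_in = ini$phi_in, phi_out = ini$phi_out)
  }
  it <- config$integration
  traj <- evolve(state, fe, kin, rate,
                 max_steps = it$max_steps, dt0 = it$dt0,
                 dt_growth = it$dt_growth, dt_max = it$dt_max,
                 dt_min = it$dt_min, steady_tol = it$steady_tol,
                 steady_consec = it$steady_consec,
                 sweep_tol = it$sweep_tol, max_sweeps = it$max_sweeps,
                 snapshot_every = it$snapshot_every,
                 perturb_amp = it$perturb_amp,
                 perturb_seed = it$perturb_seed)
  cc <- clusters[[1]]$center
  reports <- do.call(rbind, lapply(traj$snapshots, morphology_report,
                                   fe = fe, cluster_center = cc))
  outcome <- classify(traj, clusters, fe)
  fin <- reports[nrow(reports), ]
  summary <- data.frame(
    scenario = config$scenario,
    final_R_eff = outcome$final_R_eff,
    vacuole_radius = outcome$vacuole_radius,
    eccentricity = outcome$eccentricity,
    n_interfaces = fin$n_interfaces,
    centroid_x = fin$centroid_x, centroid_y = fin$centroid_y,
    classification = outcome$classification,
    dynamics_class = outcome$dynamics_class,
    steps = traj$run_meta$accepted,
    stop_reason = traj$run_meta$reason,
    config_hash = .config_hash(unclass(config))
  )
  if (!keep_snapshots) {
    traj$snapshots <- traj$snapshots[c(1, length(traj$snapshots))]
  }
  structure(list(trajectory = traj, reports = reports, outcome = outcome,
                 summary = summary, config = config,
                 config_hash = summary$config_hash),
            class = "cond_run")
}

#' @export
print.cond_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Run '%s' [%s]: %s / %s, R_eff = %.3f\n",
              s$scenario, s$config_hash, s$classification,
              s$dynamics_class, s$final_R_eff))
  invisible(x)
}

# set a dot-path like "activity.clusters.1.k_T" in a nested list
.set_path <- function(x, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, parts) {
    key <- parts[1]
    ikey <- suppressWarnings(as.integer(key))
    if (!is.na(ikey)) key <- ikey
    if (length(parts) == 1) node[[key]] <- value
    else node[[key]] <- rec(node[[key]], parts[-1])
    node
  }
  rec(x, parts)
}

#' Parameter sweep over a base configuration
#'
#' Runs the Cartesian product of the supplied parameter axes over a base
#' configuration. Axis names are dot-paths into the configuration
#' (numeric components index into lists), e.g.
#' `"activity.clusters.1.k_T"` or `"kin.M_r"`. Each row is independent
#' and reproducible in isolation from its embedded config hash; failures
#' are recorded per row and the sweep continues.
#'
#' @param base a [run_config()] object.
#' @param axes named list of value vectors; names are config dot-paths.
#' @param keep_runs return the full `cond_run` objects alongside the
#'   summary (memory-hungry for large sweeps).
#' @return A data.frame with one row per combination: the axis values,
#'   the run summary columns, and `error` (NA on success). When
#'   `keep_runs = TRUE`, the runs are attached as attribute `"runs"`.
#' @export
sweep_runs <- function(base, axes, keep_runs = FALSE) {
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(axes)
  rows <- vector("list", nrow(grid))
  runs <- if (keep_runs) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    for (ax in names(axes)) cfg <- .set_path(cfg, ax, grid[[ax]][i])
    row <- tryCatch({
      r <- run(cfg, keep_snapshots = keep_runs)
      if (keep_runs) runs[[i]] <- r
      cbind(grid[i, , drop = FALSE], r$summary, error = NA_character_)
    }, error = function(e) {
      cbind(grid[i, , drop = FALSE],
            data.frame(scenario = cfg$scenario, final_R_eff = NA,
                       vacuole_radius = NA, eccentricity = NA,
                       n_interfaces = NA, centroid_x = NA, centroid_y = NA,
                       classification = NA, dynamics_class = NA,
                       steps = NA, stop_reason = NA, config_hash = NA,
                       error = conditionMessage(e)))
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Scenario presets
#'
#' Ready-made configurations for the model's canonical experiments:
#' \describe{
#'   \item{`size_vs_activity_clustered`}{seeded droplet on a
#'     \eqn{\sigma = 2} cluster; sweep `k_T` for the size/stability
#'     curve.}
#'   \item{`size_vs_activity_uniform`}{same but spatially uniform
#'     activity (the control).}
#'   \item{`nucleation`}{uniform dilute protein, no seed; clustered
#'     activity may nucleate a condensate de novo.}
#'   \item{`vacuole`}{seeded droplet on a \eqn{\sigma = 4} cluster at
#'     high activity: droplet-to-vacuole transition.}
#'   \item{`symmetry_break`}{as `vacuole` at higher activity with a
#'     small seeded initial perturbation: aspherical steady states.}
#'   \item{`flow`}{droplet at distance r = 10 from the active site
#'     (\eqn{M_r = 1.0, k_d = 0.5}): directed flow toward the site.}
#'   \item{`two_cluster`}{two clusters flanking a seeded droplet:
#'     competition, elongation and repositioning.}
#' }
#' `scale = "reduced"` (default) uses a radius-15, dx-0.4 domain and a
#' 2000-step budget for affordable exploration and testing; `"full"`
#' uses the radius-30, dx-0.2, 15000-step setting.
#'
#' @param name preset name (see above).
#' @param scale `"reduced"` or `"full"`.
#' @return A [run_config()] object.
#' @export
preset_config <- function(name = c("size_vs_activity_clustered",
                                   "size_vs_activity_uniform",
                                   "nucleation", "vacuole",
                                   "symmetry_break", "flow",
                                   "two_cluster"),
                          scale = c("reduced", "full")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  dom <- if (scale == "full") list(radius = 30, dx = 0.2)
         else list(radius = 15, dx = 0.4)
  it <- if (scale == "full") list(max_steps = 15000)
        else list(max_steps = 2000)
  base <- switch(name,
    size_vs_activity_clustered = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.02),
      activity = list(type = "clusters",
                      clusters = list(list(x = 0, y = 0, sigma = 2,
                                           k_T = 2))),
      initial = list(type = "seed_droplet", center = c(0, 0), R0 = 4)),
    size_vs_activity_uniform = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.02),
      activity = list(type = "uniform", k_T = 2),
      initial = list(type = "seed_droplet", center = c(0, 0), R0 = 4)),
    nucleation = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.02),
      activity = list(type = "clusters",
                      clusters = list(list(x = 0, y = 0, sigma = 2,
                                           k_T = 2))),
      initial = list(type = "uniform", phi_P0 = 0.13)),
    vacuole = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.5),
      activity = list(type = "clusters",
                      clusters = list(list(x = 0, y = 0, sigma = 4,
                                           k_T = 80))),
      initial = list(type = "seed_droplet", center = c(0, 0), R0 = 4)),
    symmetry_break = run_config(
      scenario = name, domain = dom,
      integration = c(it, list(perturb_amp = 1e-3, perturb_seed = 1)),
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.5),
      activity = list(type = "clusters",
                      clusters = list(list(x = 0, y = 0, sigma = 4,
                                           k_T = 240))),
      initial = list(type = "seed_droplet", center = c(0, 0), R0 = 4)),
    flow = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.5),
      activity = list(type = "clusters",
                      clusters = list(list(x = 5, y = 0, sigma = 4,
                                           k_T = 5))),
      initial = list(type = "seed_droplet", center = c(-5, 0), R0 = 4)),
    two_cluster = run_config(
      scenario = name, domain = dom, integration = it,
      kin = list(M_p = 1, M_r = 1.0, k_d = 0.05),
      activity = list(type = "clusters",
                      clusters = list(list(x = -4, y = 0, sigma = 2,
                                           k_T = 1),
                                      list(x = 4, y = 0, sigma = 2,
                                           k_T = 1))),
      initial = list(type = "seed_droplet", center = c(4, 0), R0 = 4))
  )
  base
}
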