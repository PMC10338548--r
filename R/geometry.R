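#' Circular simulation domain on a masked Cartesian grid
#'
#' Builds a 2D circular domain of the given radius, discretized as a
#' regular Cartesian grid of spacing `dx` masked to the disk. In-domain
#' cells are the cells whose centers lie within `radius` of the origin.
#' The no-flux (zero Neumann) boundary condition is built into the
#' discrete Laplacian: faces between an in-domain cell and the outside
#' carry no flux, so conserved dynamics conserve mass exactly.
#'
#' @param radius domain radius (length units), default 30.
#' @param dx grid spacing, default 0.2; must satisfy `dx <= radius/10`
#'   (coarser grids cannot resolve condensate interfaces).
#' @return An object of class `cond_domain`: a list with `radius`, `dx`,
#'   `n` (cell count), cell-center coordinates `x`, `y`, `cell_area`,
#'   the grid shape `nx` and the cell-index matrix `idx` (NA outside the
#'   disk), the cell adjacency `edges` (two-column matrix of in-domain
#'   4-neighbour pairs), `boundary` (logical, cells with fewer than four
#'   in-domain neighbours) and the sparse no-flux Laplacian `L`.
#' @export
#' @examples
#' d <- build_domain(radius = 10, dx = 0.5)
#' d$n * d$cell_area / (pi * 10^2) # ~ 1
build_domain <- function(radius = 30, dx = 0.2) {
  if (radius <= 0) stop("radius must be > 0")
  if (dx <= 0 || dx > radius / 10)
    stop("dx must satisfy 0 < dx <= radius/10 (grid too coarse to ",
         "resolve interfaces)")
  nh <- ceiling(radius / dx)
  coords <- (seq_len(2 * nh) - nh - 0.5) * dx
  nx <- length(coords)
  X <- matrix(coords, nx, nx)         # x varies along rows
  Y <- matrix(coords, nx, nx, byrow = TRUE)
  mask <- X^2 + Y^2 <= radius^2
  n <- sum(mask)
  idx <- matrix(NA_integer_, nx, nx)
  idx[mask] <- seq_len(n)
  x <- X[mask]; y <- Y[mask]
  # 4-neighbour adjacency among in-domain cells
  right <- cbind(as.vector(idx[-nx, ]), as.vector(idx[-1, ]))
  up    <- cbind(as.vector(idx[, -nx]), as.vector(idx[, -1]))
  edges <- rbind(right, up)
  edges <- edges[stats::complete.cases(edges), , drop = FALSE]
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  w <- 1 / dx^2
  L <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2], seq_len(n)),
    j = c(edges[, 2], edges[, 1], seq_len(n)),
    x = c(rep(w, 2 * nrow(edges)), -deg * w),
    dims = c(n, n)
  )
  structure(list(radius = radius, dx = dx, n = n, nx = nx,
                 x = x, y = y, cell_area = dx^2, idx = idx,
                 edges = edges, boundary = deg < 4L, L = L),
            class = "cond_domain")
}

#' @export
print.cond_domain <- function(x, ...) {
  cat(sprintf("Circular domain: radius %g, dx %g, %d cells (%.2f%% of disk area)\n",
              x$radius, x$dx, x$n,
              100 * x$n * x$cell_area / (pi * x$radius^2)))
  invisible(x)
}

#' Embed a cell-valued field into the full grid matrix
#'
#' Utility for plotting and image-based analyses: places a length-`n`
#' field vector into the `nx` x `nx` grid matrix, with `NA` outside the
#' circular domain.
#'
#' @param domain a [build_domain()] object.
#' @param v numeric vector over in-domain cells.
#' @return An `nx` x `nx` matrix.
#' @export
field_matrix <- function(domain, v) {
  stopifnot(length(v) == domain$n)
  m <- matrix(NA_real_, domain$nx, domain$nx)
  m[!is.na(domain$idx)] <- v[domain$idx[!is.na(domain$idx)]]
  m
}

#' A spatially clustered transcription site
#'
#' One localized region of gene activity, modelled as a Gaussian
#' transcription rate-constant field
#' \eqn{k_p(\vec x) = c\, e^{-\|\vec x - \vec x_0\|^2 / 2\sigma^2}}
#' centred at `center` with spatial extent `sigma`. The amplitude is set
#' by the total activity \eqn{k_T = \int k_p\, d\vec x}: on an infinite
#' domain \eqn{c = k_T / (2\pi\sigma^2)}; on the finite disk the
#' amplitude is renormalized by the discrete in-domain integral (see
#' [rate_field()]) so that \eqn{k_T} is conserved exactly across
#' \eqn{\sigma} sweeps.
#'
#' @param center length-2 numeric, cluster centre \eqn{\vec x_0}.
#' @param sigma spatial extent (> 0).
#' @param k_T total transcriptional activity (>= 0), rate x area units.
#' @return An object of class `gene_cluster` with the derived
#'   infinite-domain `amplitude`.
#' @export
gene_cluster <- function(center = c(0, 0), sigma = 2, k_T = 1) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop("center must be a finite length-2 vector")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(k_T) || k_T < 0) stop("k_T must be >= 0")
  structure(list(center = as.numeric(center), sigma = sigma, k_T = k_T,
                 amplitude = k_T / (2 * pi * sigma^2)),
            class = "gene_cluster")
}

#' Transcription rate-constant field from gene clusters
#'
#' Sums the Gaussian rate constants of one or more [gene_cluster()]s
#' evaluated at the cell centres. Each cluster's amplitude is
#' renormalized by its discrete in-domain integral so that the summed
#' field integrates to exactly \eqn{\sum k_T} on the finite disk; for
#' \eqn{\sigma \lesssim} radius/5 this agrees with the infinite-domain
#' normalization \eqn{k_T/(2\pi\sigma^2)} to well under 1%.
#'
#' @param clusters a [gene_cluster()] or a list of them.
#' @param domain a [build_domain()] object.
#' @return Non-negative rate-constant vector over in-domain cells.
#' @export
rate_field <- function(clusters, domain) {
  if (inherits(clusters, "gene_cluster")) clusters <- list(clusters)
  out <- numeric(domain$n)
  for (cl in clusters) {
    if (sqrt(sum(cl$center^2)) > domain$radius)
      stop("cluster centre lies outside the domain")
    d2 <- (domain$x - cl$center[1])^2 + (domain$y - cl$center[2])^2
    g <- exp(-d2 / (2 * cl$sigma^2))
    tot <- sum(g) * domain$cell_area
    if (tot > 0 && cl$k_T > 0) out <- out + (cl$k_T / tot) * g
  }
  out
}

#' Spatially uniform transcription rate field
#'
#' Control case: the same total activity `k_T` spread uniformly over the
#' domain, i.e. a constant rate constant `k_T / (domain area)` whose
#' discrete integral equals `k_T` exactly.
#'
#' @param k_T total transcriptional activity (>= 0).
#' @param domain a [build_domain()] object.
#' @return Constant rate-constant vector over in-domain cells.
#' @export
uniform_rate_field <- function(k_T, domain) {
  if (!is.finite(k_T) || k_T < 0) stop("k_T must be >= 0")
  rep(k_T / (domain$n * domain$cell_area), domain$n)
}

#' Disk (top-hat) transcription rate field
#'
#' Piecewise-constant rate field: rate constant `k_p` inside a disk of
#' radius `sigma` about `center`, zero outside, with the rim cells
#' weighted by their sub-cell coverage (`ns` x `ns` supersampling) to
#' reduce discretization error. This is the activity profile assumed by
#' the closed-form RNA gradient theory ([rna_profile()]), so it is the
#' field to use when comparing simulation against that theory.
#'
#' @param center length-2 disk centre.
#' @param sigma disk radius.
#' @param k_p rate constant inside the disk.
#' @param domain a [build_domain()] object.
#' @param ns rim supersampling factor per axis.
#' @return Rate-constant vector over in-domain cells.
#' @export
disk_rate_field <- function(center, sigma, k_p, domain, ns = 16) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  d <- sqrt((domain$x - center[1])^2 + (domain$y - center[2])^2)
  out <- numeric(domain$n)
  out[d <= sigma - domain$dx] <- k_p
  rim <- which(abs(d - sigma) <= domain$dx)
  if (length(rim)) {
    ss <- (seq_len(ns) - (ns + 1) / 2) / ns * domain$dx
    off <- expand.grid(sx = ss, sy = ss)
    cov <- numeric(length(rim))
    for (k in seq_len(nrow(off))) {
      cov <- cov + (((domain$x[rim] + off$sx[k] - center[1])^2 +
                     (domain$y[rim] + off$sy[k] - center[2])^2) <= sigma^2)
    }
    out[rim] <- k_p * cov / nrow(off)
  }
  out
}
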