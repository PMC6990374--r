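#' Tissue label codes
#'
#' Element labels of the regular 2D grid: `HEALTHY` and `BZ` conduct; `SCAR`
#' and `FIBROTIC` are non-conducting obstacles enforced through no-flux
#' internal boundaries. `FIBROTIC` may only replace `BZ` elements.
#' @export
TISSUE_LABELS <- c(HEALTHY = 0L, SCAR = 1L, BZ = 2L, FIBROTIC = 3L)

#' Build an all-healthy square tissue sheet
#'
#' Elements are squares of side `h_um`; the node grid has one more point per
#' dimension. The origin sits at the bottom-left node, x rightward and y
#' upward (mm); elements are indexed column-major from the bottom-left.
#'
#' @param size_mm sheet side length (mm), or `c(width, height)`.
#' @param h_um element spacing (um); `size_mm * 1000 / h_um` must be an
#'   integer.
#' @return object of class `tissue_grid` with fields `nx`, `ny`, `h_um`,
#'   and the `nx x ny` integer `labels` matrix.
#' @export
build_sheet <- function(size_mm = 40, h_um = 200) {
  if (length(size_mm) == 1) size_mm <- c(size_mm, size_mm)
  n <- size_mm * 1000 / h_um
  if (any(abs(n - round(n)) > 1e-9))
    stop("configuration error: size_mm * 1000 / h_um must be an integer")
  n <- as.integer(round(n))
  structure(list(nx = n[1], ny = n[2], h_um = h_um,
                 labels = matrix(TISSUE_LABELS[["HEALTHY"]], n[1], n[2])),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("tissue_grid: %d x %d elements (%.1f x %.1f mm at %g um)\n",
              x$nx, x$ny, x$nx * x$h_um / 1000, x$ny * x$h_um / 1000, x$h_um))
  tab <- table(factor(x$labels, levels = TISSUE_LABELS,
                      labels = names(TISSUE_LABELS)))
  print(tab)
  invisible(x)
}

# element centre coordinates (mm)
elem_centers <- function(grid) {
  h <- grid$h_um / 1000
  list(x = (seq_len(grid$nx) - 0.5) * h, y = (seq_len(grid$ny) - 0.5) * h)
}

# node coordinates (mm)
node_coords <- function(grid) {
  h <- grid$h_um / 1000
  list(x = (seq_len(grid$nx + 1) - 1) * h, y = (seq_len(grid$ny + 1) - 1) * h)
}

#' Node index on the (nx+1) x (ny+1) node grid
#'
#' @param grid a `tissue_grid`.
#' @param i,j 1-based node column (x) and row (y) indices.
#' @return 1-based linear node index (column-major in x).
#' @export
node_index <- function(grid, i, j) {
  (j - 1L) * (grid$nx + 1L) + i
}

#' Idealized infarct scar specification
#'
#' Two mirror-image scar segments (half-discs with the flat side facing the
#' channel, or full-width rectangular blocks) flank a vertical conducting
#' isthmus of remodeled border-zone tissue.
#'
#' @param isthmus_width_mm channel width (mm).
#' @param scar_half_length_mm vertical half-extent of each scar segment (mm).
#' @param scar_depth_mm horizontal extent of each segment from the channel
#'   edge (half-disc radius) (mm).
#' @param center sheet coordinates of the channel centre (mm); defaults to
#'   the sheet centre.
#' @param style `"semicircular"` for the half-disc segments, `"full_width"`
#'   for rectangular segments reaching the lateral sheet edges (used by the
#'   isthmus-traversal assay, where the channel must be the only
#'   bottom-to-top path).
#' @return object of class `scar_spec`.
#' @export
scar_spec <- function(isthmus_width_mm = 4, scar_half_length_mm = 17,
                      scar_depth_mm = 16, center = NULL,
                      style = c("semicircular", "full_width")) {
  stopifnot(isthmus_width_mm > 0, scar_half_length_mm > 0, scar_depth_mm > 0)
  structure(list(isthmus_width_mm = isthmus_width_mm,
                 scar_half_length_mm = scar_half_length_mm,
                 scar_depth_mm = scar_depth_mm, center = center,
                 style = match.arg(style)),
            class = "scar_spec")
}

#' Add an idealized scar + isthmus to a sheet
#'
#' Labels two scar segments `SCAR` and the vertical channel between them
#' `BZ`. The channel connects healthy tissue below to healthy tissue above.
#' For the `"semicircular"` style a healthy margin of at least 2 mm must
#' remain on all sides; `"full_width"` extends the segments to the lateral
#' edges so the isthmus is the only conducting path across the scar belt.
#'
#' @param grid a `tissue_grid`.
#' @param spec a [scar_spec()].
#' @return the relabelled `tissue_grid` (with the spec attached as
#'   `$scar`).
#' @export
add_idealized_scar <- function(grid, spec = scar_spec()) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(spec, "scar_spec"))
  h <- grid$h_um / 1000
  wmm <- c(grid$nx, grid$ny) * h
  ctr <- spec$center
  if (is.null(ctr)) ctr <- wmm / 2
  cx <- ctr[1]; cy <- ctr[2]
  wch <- spec$isthmus_width_mm
  if (wch < 2 * h)
    stop("isthmus narrower than 2 elements cannot represent a conduction path")
  ce <- elem_centers(grid)
  X <- matrix(ce$x, grid$nx, grid$ny)
  Y <- matrix(ce$y, grid$nx, grid$ny, byrow = TRUE)
  dxc <- abs(X - cx)
  dyc <- abs(Y - cy)
  if (spec$style == "semicircular") {
    margin_x <- wmm[1] / 2 - wch / 2 - spec$scar_depth_mm
    margin_y <- wmm[2] / 2 - spec$scar_half_length_mm
    if (margin_x < 2 || margin_y < 2)
      stop("scar must leave a healthy margin of at least 2 mm on all sides")
    u <- (dxc - wch / 2) / spec$scar_depth_mm
    scar <- dxc >= wch / 2 & u <= 1 &
      (u^2 + (dyc / spec$scar_half_length_mm)^2) <= 1
  } else {
    scar <- dxc >= wch / 2 & dyc <= spec$scar_half_length_mm
  }
  bz <- dxc < wch / 2 & dyc <= spec$scar_half_length_mm
  labels <- grid$labels
  labels[scar] <- TISSUE_LABELS[["SCAR"]]
  labels[bz] <- TISSUE_LABELS[["BZ"]]
  grid$labels <- labels
  grid$scar <- spec
  grid$scar_center <- c(cx, cy)
  grid
}

#' Seed-deterministic random fibrosis in the border zone
#'
#' Relabels `round(density * n_BZ)` uniformly sampled border-zone elements
#' as `FIBROTIC` (non-conducting). Sampling is spatially uncorrelated;
#' identical `(seed, density, grid)` yield identical masks. The caller's
#' RNG state is left untouched.
#'
#' @param grid a `tissue_grid` containing `BZ` elements.
#' @param density fibrosis fraction in `[0, 0.9]`.
#' @param seed integer seed for the mask.
#' @return the relabelled `tissue_grid` (fields `fibrosis_density`,
#'   `fibrosis_seed` attached).
#' @export
generate_fibrosis <- function(grid, density, seed) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (density < 0 || density > 0.9)
    stop("fibrosis density must lie in [0, 0.9]")
  bz_idx <- which(grid$labels == TISSUE_LABELS[["BZ"]])
  if (length(bz_idx) == 0 && density > 0)
    stop("grid has no border-zone elements to make fibrotic")
  n_fib <- round(density * length(bz_idx))
  if (n_fib > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    mask <- sample(bz_idx, n_fib)
    grid$labels[mask] <- TISSUE_LABELS[["FIBROTIC"]]
  }
  grid$fibrosis_density <- density
  grid$fibrosis_seed <- as.integer(seed)
  grid
}

#' Does the border-zone myocyte lattice percolate bottom-to-top?
#'
#' 4-neighbour connectivity check on the conducting (non-fibrotic) elements
#' of the channel: purely structural, used for the percolation property of
#' the fibrosis generator (conduction additionally requires enough
#' source-sink safety, so traversal in simulation can fail earlier).
#'
#' @param grid a `tissue_grid` with a scar/channel.
#' @return logical.
#' @export
bz_percolates <- function(grid) {
  chan <- grid$labels == TISSUE_LABELS[["BZ"]] |
    grid$labels == TISSUE_LABELS[["FIBROTIC"]]
  if (!any(chan)) return(FALSE)
  cr <- range(which(apply(chan, 1, any)))
  rr <- range(which(apply(chan, 2, any)))
  sub <- (grid$labels == TISSUE_LABELS[["BZ"]])[cr[1]:cr[2], rr[1]:rr[2],
                                                drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  visited <- matrix(FALSE, nr, nc)
  visited[, 1] <- sub[, 1]
  if (!any(visited)) return(FALSE)
  # vectorized flood fill over the 4-neighbour lattice
  repeat {
    grow <- visited
    grow[-1, ] <- grow[-1, ] | visited[-nr, ]
    grow[-nr, ] <- grow[-nr, ] | visited[-1, ]
    grow[, -1] <- grow[, -1] | visited[, -nc]
    grow[, -nc] <- grow[, -nc] | visited[, -1]
    grow <- grow & sub
    if (all(grow == visited)) break
    visited <- grow
  }
  any(visited[, nc])
}

#' Summary counts of element labels
#'
#' @param grid a `tissue_grid`.
#' @return named integer vector over the four labels.
#' @export
label_counts <- function(grid) {
  out <- vapply(TISSUE_LABELS, function(l) sum(grid$labels == l), integer(1))
  names(out) <- names(TISSUE_LABELS)
  out
}
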