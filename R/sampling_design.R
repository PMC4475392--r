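#' Generate a grid-plus-infill sampling design
#'
#' Builds a systematic square-grid sampling design with optional infill
#' sites, emulating a landscape survey in which most sites sit on a regular
#' lattice and a handful of extra sites probe variation at distances shorter
#' than the grid spacing.  Grid sites are lattice nodes inside the bounding
#' polygon, taken in row-major order; each infill site is placed uniformly
#' within a randomly chosen lattice cell, so its distance to the nearest grid
#' site is always below the spacing.
#'
#' @param spacing lattice spacing in metres.
#' @param n_grid number of lattice sites.
#' @param n_infill number of infill sites.
#' @param polygon optional matrix of polygon vertices (two columns, metres);
#'   default is a rectangle just large enough to hold `n_grid` lattice nodes.
#' @param seed integer seed (placement of infill sites).
#' @return object of class `sampling_design`: data frame with columns
#'   `site_id`, `x`, `y`, `type` ("grid"/"infill"); spacing and polygon kept
#'   as attributes.
#' @export
generate_sampling_design <- function(spacing, n_grid, n_infill = 0,
                                     polygon = NULL, seed = 1) {
  stop_if_not_scalar_pos(spacing, "spacing")
  stopifnot(n_grid >= 1, n_infill >= 0)
  if (is.null(polygon)) {
    nx <- ceiling(sqrt(n_grid))
    ny <- ceiling(n_grid / nx)
    polygon <- cbind(x = c(-0.5, nx - 0.5, nx - 0.5, -0.5) * spacing,
                     y = c(-0.5, -0.5, ny - 0.5, ny - 0.5) * spacing)
  }
  polygon <- as.matrix(polygon)
  bb <- apply(polygon, 2, range)
  xs <- seq(ceiling(bb[1, 1] / spacing) * spacing, bb[2, 1], by = spacing)
  ys <- seq(ceiling(bb[1, 2] / spacing) * spacing, bb[2, 2], by = spacing)
  lattice <- expand.grid(x = xs, y = ys) # row-major: x fastest
  inside <- point_in_polygon(lattice$x, lattice$y, polygon)
  lattice <- lattice[inside, , drop = FALSE]
  if (nrow(lattice) < n_grid) {
    stop(sprintf(
      "polygon too small: encloses only %d lattice nodes at spacing %g (need %d)",
      nrow(lattice), spacing, n_grid), call. = FALSE)
  }
  grid <- lattice[seq_len(n_grid), , drop = FALSE]
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n_grid)),
                      x = grid$x, y = grid$y, type = "grid",
                      stringsAsFactors = FALSE)
  if (n_infill > 0) {
    # cells whose four corners are all retained grid sites
    key <- paste(round(grid$x / spacing, 6), round(grid$y / spacing, 6))
    has <- function(x, y) paste(round(x / spacing, 6),
                                round(y / spacing, 6)) %in% key
    cell_ok <- has(grid$x + spacing, grid$y) &
      has(grid$x, grid$y + spacing) &
      has(grid$x + spacing, grid$y + spacing)
    cells <- which(cell_ok)
    if (length(cells) == 0L)
      stop("no complete lattice cell available for infill sites",
           call. = FALSE)
    inf <- with_seed(seed, {
      pick <- if (length(cells) >= n_infill) sample(cells, n_infill)
      else sample(cells, n_infill, replace = TRUE)
      data.frame(x = grid$x[pick] + runif(n_infill, 0, spacing),
                 y = grid$y[pick] + runif(n_infill, 0, spacing))
    })
    sites <- rbind(sites, data.frame(
      site_id = sprintf("I%03d", seq_len(n_infill)),
      x = inf$x, y = inf$y, type = "infill", stringsAsFactors = FALSE))
  }
  rownames(sites) <- NULL
  structure(sites, class = c("sampling_design", "data.frame"),
            spacing = spacing, polygon = polygon)
}

# Even-odd ray casting; points exactly on the boundary count as inside.
point_in_polygon <- function(px, py, polygon) {
  nv <- nrow(polygon)
  vx <- polygon[, 1]; vy <- polygon[, 2]
  out <- logical(length(px))
  for (k in seq_along(px)) {
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      on_edge <- FALSE
      # boundary check: point on segment (i, j)
      d <- (vx[j] - vx[i]) * (py[k] - vy[i]) - (px[k] - vx[i]) * (vy[j] - vy[i])
      if (abs(d) < 1e-9 &&
          px[k] >= min(vx[i], vx[j]) - 1e-9 &&
          px[k] <= max(vx[i], vx[j]) + 1e-9 &&
          py[k] >= min(vy[i], vy[j]) - 1e-9 &&
          py[k] <= max(vy[i], vy[j]) + 1e-9) on_edge <- TRUE
      if (on_edge) { inside <- TRUE; break }
      if ((vy[i] > py[k]) != (vy[j] > py[k])) {
        xint <- vx[i] + (py[k] - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
        if (px[k] < xint) inside <- !inside
      }
      j <- i
    }
    out[k] <- inside
  }
  out
}
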