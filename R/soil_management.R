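#' Default land-management cluster layout
#'
#' Six clusters along a cropping-intensity gradient, from undisturbed forest
#' to conventionally tilled cropland.  The per-cluster site counts follow the
#' published landscape survey (44, 7, 22, 57, 33, 104); those counts sum to
#' 267, so the default pads the largest cluster (Conventional tillage) to
#' cover all 278 sites.  For smaller landscapes the counts are rescaled
#' proportionally (largest-remainder rounding).  Counts are free parameters.
#'
#' @param n_sites total number of sites the layout must cover.
#' @return list with `labels` (ordered by cropping intensity) and `counts`.
#' @export
default_cluster_layout <- function(n_sites = 278) {
  labels <- c("Forest", "Perennial", "CatchCrop", "MinimumTillage",
              "MechanicalHoeing", "ConventionalTillage")
  counts <- c(44, 7, 22, 57, 33, 104)
  if (sum(counts) <= n_sites) {
    counts[which.max(counts)] <- counts[which.max(counts)] +
      (n_sites - sum(counts))
  } else {
    # smaller landscapes: rescale the published proportions (largest
    # remainder), so test runs can use reduced site counts
    raw <- counts * n_sites / sum(counts)
    counts <- floor(raw)
    rem <- n_sites - sum(counts)
    if (rem > 0) {
      idx <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
      counts[idx] <- counts[idx] + 1L
    }
  }
  list(labels = labels, counts = as.integer(counts))
}

# Seeded Voronoi growth: clusters grow from random seed sites by repeatedly
# claiming the unassigned site closest to their seed, until each cluster has
# its requested count.  Ties broken by site id (row order).  Produces
# spatially contiguous patches with exact counts.
grow_cluster_patches <- function(xy, labels, counts, seed = 1) {
  n <- nrow(xy)
  stopifnot(length(labels) == length(counts), sum(counts) == n)
  with_seed(seed, {
    active <- which(counts > 0)
    k <- length(active)
    seeds <- sample(n, k)
    d2seed <- matrix(Inf, n, length(labels))
    d2seed[, active] <- cross_dist(xy, xy[seeds, , drop = FALSE])
    assign <- rep(NA_integer_, n)
    remaining <- counts
    assign[seeds] <- active
    remaining[active] <- remaining[active] - 1L
    while (anyNA(assign)) {
      open <- which(remaining > 0L)
      un <- which(is.na(assign))
      d <- d2seed[un, open, drop = FALSE]
      best <- arrayInd(which.min(d), dim(d)) # ties: first in row order
      assign[un[best[1]]] <- open[best[2]]
      remaining[open[best[2]]] <- remaining[open[best[2]]] - 1L
    }
    factor(labels[assign], levels = labels)
  })
}

#' Default soil field specifications
#'
#' Seven physicochemical variables typical of a silty-clay agricultural
#' landscape: pH, organic carbon and total nitrogen (g/kg, target
#' cross-correlation r = 0.92), CaCO3 (g/kg), and the texture fractions clay
#' and sand (%); silt is derived downstream as 100 - clay - sand so that the
#' texture triple is exactly compositional.  All fields use Matern v = 0.5
#' variograms with range parameters giving effective ranges of roughly
#' 600-900 m.
#'
#' @return named list of [field_spec()] objects.
#' @export
default_soil_fields <- function() {
  vg <- function(c0, c1, a) variogram_model(c0, c1, a, v = 0.5)
  list(
    pH = field_spec("pH", vg(0.04, 0.16, 250), mean = 7.7),
    organic_carbon = field_spec("organic_carbon", vg(10, 90, 250), mean = 25),
    total_nitrogen = field_spec("total_nitrogen", vg(0.06, 0.58, 250),
                                mean = 1.8,
                                cross_correlations = c(organic_carbon = 0.92)),
    caco3 = field_spec("caco3", vg(20, 180, 200), mean = 30),
    clay = field_spec("clay", vg(4, 36, 300), mean = 34),
    sand = field_spec("sand", vg(2, 16, 300), mean = 9,
                      cross_correlations = c(clay = -0.3))
  )
}

#' Attach correlated soil fields and land-management clusters to a design
#'
#' Realizes every soil field as a Gaussian random field, imposes the
#' requested cross-correlations by Cholesky mixing of empirically
#' orthonormalized standard fields (so realized correlations match targets to
#' numerical precision at the sampled sites), derives silt as
#' `100 - clay - sand` when both texture fields are present, and assigns each
#' site to one of the land-management clusters by seeded Voronoi growth with
#' exact per-cluster counts.
#'
#' @param design a [generate_sampling_design()] result.
#' @param field_specs named list of [field_spec()]; default
#'   [default_soil_fields()].
#' @param cluster_layout list with `labels` and `counts` (summing to the
#'   number of sites); default [default_cluster_layout()].
#' @param seed integer seed.
#' @param cluster_effects optional named list: for each field, a vector of
#'   per-cluster mean shifts (default none, so that realized
#'   cross-correlations stay at their targets).
#' @return a `site_table` data frame: `site_id`, `x`, `y`, soil columns,
#'   `management`.
#' @export
attach_soil_and_management <- function(design,
                                       field_specs = default_soil_fields(),
                                       cluster_layout =
                                         default_cluster_layout(nrow(design)),
                                       seed = 1,
                                       cluster_effects = NULL) {
  xy <- design_xy(design)
  n <- nrow(xy)
  fields <- names(field_specs)
  if (is.null(fields) || any(!nzchar(fields)))
    stop("`field_specs` must be a named list", call. = FALSE)
  R <- diag(length(fields))
  dimnames(R) <- list(fields, fields)
  for (f in fields) {
    cc <- field_specs[[f]]$cross_correlations
    for (p in names(cc)) {
      if (!p %in% fields)
        stop(sprintf("cross-correlation partner '%s' of field '%s' unknown",
                     p, f), call. = FALSE)
      R[f, p] <- R[p, f] <- cc[[p]]
    }
  }
  L <- tryCatch(t(chol(R)), error = function(e)
    stop("requested cross-correlation matrix is not positive definite",
         call. = FALSE))
  # independent unit-variance fields, one per spec, each with its own
  # variogram; empirically centred, orthonormalized (QR) and rescaled so the
  # Cholesky mixing reproduces the target correlations exactly at the sites
  Z <- sapply(seq_along(fields), function(j) {
    sp <- field_specs[[j]]
    unit <- field_spec(sp$name,
                       variogram_model(sp$variogram$c0, sp$variogram$c1,
                                       sp$variogram$a, sp$variogram$v),
                       mean = 0)
    z <- simulate_gaussian_field(xy, unit, seed = derive_seed(seed, sp$name))
    z / sqrt(sp$variogram$c0 + sp$variogram$c1)
  })
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Zc))
  Q <- sweep(Q, 2, apply(Q, 2, sd), "/")
  # keep each orthonormalized column aligned with its parent field
  for (j in seq_len(ncol(Q))) if (cor(Q[, j], Z[, j]) < 0) Q[, j] <- -Q[, j]
  Y <- Q %*% t(L)
  soil <- sapply(seq_along(fields), function(j) {
    sp <- field_specs[[j]]
    sp$mean + sqrt(sp$variogram$c0 + sp$variogram$c1) * Y[, j]
  })
  colnames(soil) <- fields
  management <- grow_cluster_patches(xy, cluster_layout$labels,
                                     cluster_layout$counts,
                                     seed = derive_seed(seed, "clusters"))
  if (!is.null(cluster_effects)) {
    for (f in names(cluster_effects)) {
      shift <- cluster_effects[[f]]
      soil[, f] <- soil[, f] + shift[as.integer(management)]
    }
  }
  out <- data.frame(site_id = design$site_id, x = xy[, 1], y = xy[, 2],
                    soil, stringsAsFactors = FALSE)
  if (all(c("clay", "sand") %in% fields)) out$silt <- 100 - out$clay - out$sand
  out$management <- management
  structure(out, class = c("site_table", "data.frame"))
}
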