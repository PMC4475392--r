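#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the field-standard
#' defaults: rarefaction depth 10800, 999 permutations, 1000 SSPE
#' simulations, alpha 0.001, vector-fit R2 threshold 0.20.  Each stochastic
#' stage receives a deterministic child seed derived from the master seed
#' (see [derive_seed()]), so stages can be re-run in isolation.
#'
#' @param seed master seed (mandatory).
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of c("simulate", "ordinate", "krige", "pcnm", "varpart").
#' @param n_grid,n_infill,spacing sampling-design parameters.
#' @param rarefaction_depth,n_perm,sspe_simulations,alpha,r2_threshold
#'   analysis thresholds.
#' @param grid_step kriging prediction-grid step in metres.
#' @param taxonomy_rank rank for taxon aggregation.
#' @param paths named list of input paths when simulation is disabled
#'   (site_table, community_table, tree, distance_matrix).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            stages = c("simulate", "ordinate", "krige",
                                       "pcnm", "varpart"),
                            n_grid = 248, n_infill = 30, spacing = 215,
                            rarefaction_depth = 10800, n_perm = 999,
                            sspe_simulations = 1000, alpha = 0.001,
                            r2_threshold = 0.20, grid_step = 100,
                            taxonomy_rank = "phylum_with_proteobacteria_classes",
                            paths = list()) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory in the pipeline config", call. = FALSE)
  known <- c("simulate", "ordinate", "krige", "pcnm", "varpart")
  if (length(stages) && any(!stages %in% known))
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", ")),
         call. = FALSE)
  structure(list(seed = as.integer(seed), stages = stages, n_grid = n_grid,
                 n_infill = n_infill, spacing = spacing,
                 rarefaction_depth = rarefaction_depth, n_perm = n_perm,
                 sspe_simulations = sspe_simulations, alpha = alpha,
                 r2_threshold = r2_threshold, grid_step = grid_step,
                 taxonomy_rank = taxonomy_rank, paths = paths),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON file path.
#' @param config a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$paths <- as.list(raw$paths)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (synthetic
#' landscape + community), ordinate (rarefaction, taxon aggregation,
#' weighted UniFrac, NMDS, vector fitting), krige (normal-scores ordinary
#' kriging of the NMDS axes with SSPE validation), pcnm, varpart (per-taxon
#' partial-regression partitions plus a db-RDA partition of the community
#' distance) — writing each artifact into `out_dir` and a machine-readable
#' `summary.json` listing per-stage key statistics, seeds and thresholds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = unclass(config))
  stages <- config$stages
  if (length(stages) == 0L) {
    write_pipeline_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  site_table <- NULL; community <- NULL; tree <- NULL; dmat <- NULL
  if ("simulate" %in% stages) {
    sseed <- derive_seed(config$seed, "simulate")
    design <- generate_sampling_design(config$spacing, config$n_grid,
                                       config$n_infill, seed = sseed)
    site_table <- attach_soil_and_management(
      design, seed = derive_seed(sseed, "soil"))
    cspec <- default_community_spec(config$rarefaction_depth)
    community <- simulate_community(site_table, cspec,
                                    seed = derive_seed(sseed, "community"))
    tree <- simulate_taxa_tree(community$taxon,
                               seed = derive_seed(sseed, "tree"))
    write_site_table(site_table, file.path(out_dir, "sites.csv"))
    write_community_table(community, file.path(out_dir, "community.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    summary$simulate <- list(seed = sseed, n_sites = nrow(site_table),
                             n_taxa = nrow(community))
  } else {
    if (!is.null(config$paths$site_table))
      site_table <- read_site_table(config$paths$site_table)
    if (!is.null(config$paths$community_table))
      community <- read_community_table(config$paths$community_table)
    if (!is.null(config$paths$tree))
      tree <- read_unifrac_tree(config$paths$tree)
    if (!is.null(config$paths$distance_matrix))
      dmat <- read_distance_matrix(config$paths$distance_matrix)
  }
  ord <- NULL
  if ("ordinate" %in% stages) {
    oseed <- derive_seed(config$seed, "ordinate")
    rare <- rarefy_counts(community, config$rarefaction_depth,
                          seed = derive_seed(oseed, "rarefy"))
    agg <- aggregate_taxonomy(rare, config$taxonomy_rank)
    if (is.null(dmat)) {
      dtab <- if (all(rare$taxon %in% tree$tip.label)) rare else agg
      dmat <- weighted_unifrac(dtab, tree)
    }
    ord <- nmds(dmat, k = 2, seed = derive_seed(oseed, "nmds"))
    soil_cols <- setdiff(names(site_table)[vapply(site_table, is.numeric,
                                                  logical(1))],
                         c("x", "y"))
    keep <- colnames(dmat)
    st_ord <- site_table[match(keep, site_table$site_id), , drop = FALSE]
    vf_vars <- cbind(st_ord[, soil_cols, drop = FALSE],
                     as.data.frame(t(community_matrix(agg,
                                                      proportions = TRUE))))
    vec <- fit_vectors(ord, vf_vars, n_perm = config$n_perm,
                       seed = derive_seed(oseed, "vectors"),
                       r2_threshold = config$r2_threshold,
                       alpha = config$alpha)
    write_distance_matrix(dmat, file.path(out_dir, "unifrac.tsv"))
    sc <- data.frame(site_id = rownames(ord$points), ord$points)
    write.csv(sc, file.path(out_dir, "nmds_scores.csv"), row.names = FALSE)
    write.csv(vec, file.path(out_dir, "fitted_vectors.csv"),
              row.names = FALSE)
    summary$ordinate <- list(seed = oseed, stress = ord$stress,
                             n_retained_vectors = sum(vec$retained),
                             rarefaction_depth = config$rarefaction_depth)
  }
  if ("krige" %in% stages) {
    kseed <- derive_seed(config$seed, "krige")
    keep <- rownames(ord$points)
    st_k <- site_table[match(keep, site_table$site_id), , drop = FALSE]
    xy <- cbind(st_k$x, st_k$y)
    gx <- seq(min(xy[, 1]), max(xy[, 1]), by = config$grid_step)
    gy <- seq(min(xy[, 2]), max(xy[, 2]), by = config$grid_step)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    summary$krige <- list(seed = kseed, axes = list())
    for (ax in colnames(ord$points)) {
      ns <- normal_scores_transform(ord$points[, ax])
      model <- fit_variogram(method = "ml", site_xy = xy,
                             values = ns$scores, v = NA,
                             seed = derive_seed(kseed, ax))
      surf <- ordinary_kriging(xy, ns$scores, model, grid, ns_map = ns$map)
      rep <- sspe_diagnostics(xy, ns$scores, model,
                              M = config$sspe_simulations,
                              seed = derive_seed(kseed, paste0("sspe", ax)))
      write_kriging_surface(surf, file.path(out_dir,
                                            sprintf("surface_%s.csv", ax)))
      emp <- empirical_variogram(xy, ns$scores)
      write.csv(emp, file.path(out_dir, sprintf("variogram_%s.csv", ax)),
                row.names = FALSE)
      jsonlite::write_json(
        list(c0 = model$c0, c1 = model$c1, a = model$a, v = model$v,
             method = model$method, objective = model$objective,
             effective_range = effective_range(model)),
        file.path(out_dir, sprintf("model_%s.json", ax)),
        auto_unbox = TRUE, digits = NA)
      summary$krige$axes[[ax] ] <- list(
        effective_range = effective_range(model),
        sspe_mean = rep$mean, sspe_median = rep$median,
        sspe_mean_within = rep$mean_within,
        sspe_median_within = rep$median_within)
    }
  }
  basis <- NULL
  if ("pcnm" %in% stages) {
    basis <- build_pcnm(cbind(site_table$x, site_table$y))
    write_pcnm_scores(basis, file.path(out_dir, "pcnm.csv"),
                      site_ids = site_table$site_id)
    write.csv(data.frame(axis = colnames(basis$vectors),
                         eigenvalue = basis$values),
              file.path(out_dir, "pcnm_eigenvalues.csv"), row.names = FALSE)
    summary$pcnm <- list(n_vectors = ncol(basis$vectors),
                         truncation = basis$truncation)
  }
  if ("varpart" %in% stages) {
    vseed <- derive_seed(config$seed, "varpart")
    keep <- colnames(dmat)
    st_v <- site_table[match(keep, site_table$site_id), , drop = FALSE]
    bvec <- if (!is.null(basis))
      basis$vectors[match(keep, site_table$site_id), , drop = FALSE]
    else NULL
    blocks <- prepare_blocks(st_v, pcnm = bvec)
    rare <- rarefy_counts(community, config$rarefaction_depth,
                          seed = derive_seed(config$seed, "ordinate.rarefy"))
    agg <- aggregate_taxonomy(rare, config$taxonomy_rank)
    prop <- community_matrix(agg, proportions = TRUE)[, keep, drop = FALSE]
    rows <- lapply(rownames(prop), function(tx) {
      y <- log_transform_abundance(prop[tx, ])
      pr <- partition_abundance(y, blocks, n_perm = 0)
      data.frame(taxon = tx, t(pr$fractions), stringsAsFactors = FALSE)
    })
    part_tab <- do.call(rbind, rows)
    write.csv(part_tab, file.path(out_dir, "taxon_partitions.csv"),
              row.names = FALSE)
    comm_part <- partition_community(dmat, blocks, n_perm = config$n_perm,
                                     seed = vseed)
    jsonlite::write_json(
      list(fractions = as.list(comm_part$fractions),
           p_values = as.list(comm_part$p_values)),
      file.path(out_dir, "community_partition.json"),
      auto_unbox = TRUE, digits = NA)
    summary$varpart <- list(seed = vseed, n_taxa = nrow(part_tab),
                            community = as.list(comm_part$fractions))
  }
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Log-transform relative abundances with a per-taxon zero rule
#'
#' Zeros are replaced by half the smallest positive value of the taxon
#' before taking logs (a documented convention; the transform needs one).
#'
#' @param p numeric vector of relative abundances.
#' @return log-transformed vector.
#' @export
log_transform_abundance <- function(p) {
  pos <- p[p > 0]
  if (!length(pos)) return(rep(NA_real_, length(p)))
  p[p == 0] <- min(pos) / 2
  log(p)
}
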