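#' Specification of a synthetic taxon community
#'
#' Encodes, for each taxon, a baseline log-abundance, responses to soil
#' variables (coefficients on standardized columns), land-management offsets
#' per cluster, an optional Matern variogram for a spatially structured
#' residual on the logit scale, and an overdispersion standard deviation.
#' Per-site relative abundances arise by softmax over taxa
#' (logistic-normal-multinomial forward model).
#'
#' @param taxa data frame with columns `name`, `lineage`; list-columns or
#'   attached lists supply `env_coef` (named numeric per taxon),
#'   `mgmt_offsets` (numeric per cluster level), `variogram`
#'   ([variogram_model()] or NULL) and `overdispersion` (sd, logit scale).
#'   Most easily built with [community_taxon()] + [community_spec()].
#' @param library_size sequencing depth per site (default 10800, mirroring
#'   the common rarefaction depth).
#' @return object of class `community_spec`.
#' @export
community_spec <- function(taxa, library_size = 10800) {
  stopifnot(is.list(taxa), length(taxa) > 0)
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  nm <- vapply(taxa, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate taxon names", call. = FALSE)
  structure(list(taxa = taxa, library_size = library_size),
            class = "community_spec")
}

#' One taxon entry for [community_spec()]
#'
#' @param name taxon name.
#' @param lineage semicolon-separated rank string
#'   (e.g. "Bacteria;Proteobacteria;Alphaproteobacteria").
#' @param baseline baseline logit (log relative-abundance scale).
#' @param env_coef named numeric vector of coefficients on standardized soil
#'   columns (per-SD effects), or NULL.
#' @param mgmt_offsets numeric vector of per-cluster logit offsets (recycled
#'   or named by cluster level), or NULL.
#' @param variogram [variogram_model()] for the spatial residual logit, or
#'   NULL for no spatial structure.
#' @param overdispersion sd of iid extra logit noise (default 0).
#' @return list usable as one element of `taxa` in [community_spec()].
#' @export
community_taxon <- function(name, lineage, baseline = 0, env_coef = NULL,
                            mgmt_offsets = NULL, variogram = NULL,
                            overdispersion = 0) {
  list(name = name, lineage = lineage, baseline = baseline,
       env_coef = env_coef, mgmt_offsets = mgmt_offsets,
       variogram = variogram, overdispersion = overdispersion)
}

#' Simulate a taxon count table over a site table
#'
#' Per-site taxon probabilities are the softmax of
#' \eqn{\text{baseline} + \sum_k \beta_k\,\tilde s_k + \text{cluster offset}
#' + \text{spatial residual} + \text{overdispersion noise}}
#' where \eqn{\tilde s_k} are standardized soil columns; counts are drawn
#' multinomially at the library size.  Deterministic given the seed.
#'
#' @param site_table a site table from [attach_soil_and_management()].
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return a `community_table`: data frame with columns `taxon`, `lineage`,
#'   then one integer count column per site (named by `site_id`).
#' @export
simulate_community <- function(site_table, spec, seed = 1) {
  stopifnot(inherits(spec, "community_spec"))
  n <- nrow(site_table)
  soil_cols <- setdiff(names(site_table),
                       c("site_id", "x", "y", "type", "management"))
  needed <- unique(unlist(lapply(spec$taxa, function(t) names(t$env_coef))))
  missing <- setdiff(needed, names(site_table))
  if (length(missing))
    stop(sprintf("soil columns missing from site table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  S <- scale(as.matrix(site_table[, soil_cols, drop = FALSE]))
  mgmt <- site_table$management
  logits <- sapply(seq_along(spec$taxa), function(j) {
    tx <- spec$taxa[[j]]
    eta <- rep(tx$baseline, n)
    for (v in names(tx$env_coef)) eta <- eta + tx$env_coef[[v]] * S[, v]
    if (!is.null(tx$mgmt_offsets)) {
      off <- tx$mgmt_offsets
      if (!is.null(names(off))) off <- off[levels(mgmt)]
      eta <- eta + off[as.integer(mgmt)]
    }
    if (!is.null(tx$variogram)) {
      fs <- field_spec(tx$name, tx$variogram, mean = 0)
      eta <- eta + simulate_gaussian_field(site_table, fs,
                                           seed = derive_seed(seed, tx$name))
    }
    if (tx$overdispersion > 0) {
      eta <- eta + with_seed(derive_seed(seed, paste0("od:", tx$name)),
                             rnorm(n, 0, tx$overdispersion))
    }
    eta
  })
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  counts <- with_seed(derive_seed(seed, "multinomial"), {
    vapply(seq_len(n), function(i) {
      as.integer(rmultinom(1, spec$library_size, P[i, ]))
    }, integer(length(spec$taxa)))
  })
  out <- data.frame(
    taxon = vapply(spec$taxa, `[[`, character(1), "name"),
    lineage = vapply(spec$taxa, `[[`, character(1), "lineage"),
    counts, stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[-(1:2)] <- site_table$site_id
  structure(out, class = c("community_table", "data.frame"),
            probabilities = P)
}

#' Default 19-taxon community specification
#'
#' Nineteen dominant bacterial and archaeal groups (phyla plus Proteobacteria
#' classes) with baselines set from typical soil relative abundances and
#' effect structure chosen to emulate commonly reported responses: pH drives
#' Alphaproteobacteria and Planctomycetes, organic carbon drives
#' Betaproteobacteria and Chlorobi, and land-management offsets follow a
#' cropping-intensity gradient (positive for e.g. Bacteroidetes and
#' Firmicutes, negative for e.g. Deltaproteobacteria and Verrucomicrobia,
#' hump-backed for Nitrospirae).  Every taxon carries a weak spatially
#' structured residual.
#'
#' @param library_size sequencing depth per site (default 10800).
#' @return a [community_spec()].
#' @export
default_community_spec <- function(library_size = 10800) {
  grad <- seq(-0.5, 0.5, length.out = 6) # Forest .. ConventionalTillage
  hump <- c(-0.4, -0.1, 0.4, 0.4, -0.1, -0.4)
  resid_vg <- variogram_model(0.02, 0.08, 300, v = 0.5)
  row <- function(name, phylum, class = NA, base, pH = 0, oc = 0, clay = 0,
                  mgmt = NULL) {
    lineage <- if (is.na(class)) paste("Bacteria", phylum, sep = ";")
    else paste("Bacteria", phylum, class, sep = ";")
    if (phylum %in% c("Thaumarchaeota", "Crenarchaeota"))
      lineage <- sub("^Bacteria", "Archaea", lineage)
    env <- c(pH = pH, organic_carbon = oc, clay = clay)
    env <- env[env != 0]
    community_taxon(name, lineage, baseline = log(base),
                    env_coef = if (length(env)) env else NULL,
                    mgmt_offsets = mgmt, variogram = resid_vg,
                    overdispersion = 0.05)
  }
  taxa <- list(
    row("Alphaproteobacteria", "Proteobacteria", "Alphaproteobacteria",
        23.6, pH = 0.6, mgmt = -grad * 0.6),
    row("Gammaproteobacteria", "Proteobacteria", "Gammaproteobacteria",
        11.3, pH = 0.2),
    row("Actinobacteria", "Actinobacteria", base = 11.2, clay = 0.3,
        mgmt = grad * 0.3),
    row("Deltaproteobacteria", "Proteobacteria", "Deltaproteobacteria",
        10.8, oc = 0.3, mgmt = -grad * 0.5),
    row("Bacteroidetes", "Bacteroidetes", base = 8.4, mgmt = grad * 0.6),
    row("Acidobacteria", "Acidobacteria", base = 6.0, pH = -0.5),
    row("Firmicutes", "Firmicutes", base = 5.5, mgmt = grad * 0.4),
    row("Betaproteobacteria", "Proteobacteria", "Betaproteobacteria",
        4.5, oc = 0.6),
    row("Verrucomicrobia", "Verrucomicrobia", base = 4.0, mgmt = -grad * 0.4),
    row("Planctomycetes", "Planctomycetes", base = 3.5, pH = 0.5,
        mgmt = -grad * 0.3),
    row("Chloroflexi", "Chloroflexi", base = 3.0, mgmt = grad * 0.4),
    row("Gemmatimonadetes", "Gemmatimonadetes", base = 2.5,
        mgmt = grad * 0.3),
    row("Nitrospirae", "Nitrospirae", base = 1.5, mgmt = hump),
    row("Chlorobi", "Chlorobi", base = 1.0, oc = 0.5),
    row("Cyanobacteria", "Cyanobacteria", base = 1.0),
    row("Thaumarchaeota", "Thaumarchaeota", base = 0.8, mgmt = grad * 0.4),
    row("Crenarchaeota", "Crenarchaeota", base = 0.6, mgmt = grad * 0.3),
    row("Armatimonadetes", "Armatimonadetes", base = 0.5, mgmt = grad * 0.2),
    row("Fibrobacteres", "Fibrobacteres", base = 0.4, mgmt = grad * 0.4)
  )
  community_spec(taxa, library_size = library_size)
}

#' Random coalescent tree for synthetic taxa
#'
#' A coalescent-style random ultrametric tree whose tips are the taxon
#' names, for use with [weighted_unifrac()] when no real phylogeny exists.
#'
#' @param taxa_names character vector of tip labels.
#' @param seed integer seed.
#' @return an [ape::rcoal()] `phylo` object.
#' @export
simulate_taxa_tree <- function(taxa_names, seed = 1) {
  with_seed(seed, ape::rcoal(length(taxa_names), tip.label = taxa_names))
}
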