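#' Assemble and validate a pipeline run configuration
#'
#' @param genotypes path to a genotype CSV (or a `genotype_table`)
#' @param sites path to a site CSV (or a `site_table`)
#' @param rasters named character vector of ASCII-grid paths (or a
#'   `landscape_stack`); optional — the landscape/gravity stages are
#'   skipped without it
#' @param out_dir output directory
#' @param alpha edge-test significance level
#' @param at_site_vars,between_site_vars candidate variable lists for the
#'   gravity stage (raster layer names)
#' @param candidate_specs explicit candidate covariate subsets (default:
#'   each single variable plus the best-at + best-between combination
#'   strategy is left to the caller; singles are always included)
#' @param window percent-cover moving-window width (cells)
#' @param site_radius at-site extraction radius (m)
#' @param edge_width between-site corridor width (m)
#' @param max_reps node-removal replicate ceiling
#' @param latitude latitude for the heat load index (deg)
#' @param seed root seed
#' @return a validated `run_config`
#' @export
run_config <- function(genotypes, sites, rasters = NULL, out_dir,
                       alpha = 0.05, at_site_vars = NULL,
                       between_site_vars = NULL, candidate_specs = NULL,
                       window = 9L, site_radius = 370, edge_width = 30,
                       max_reps = 100L, latitude = 44.5, seed = 1L) {
  for (p in c(if (is.character(genotypes)) genotypes,
              if (is.character(sites)) sites,
              if (is.character(rasters)) rasters))
    if (!file.exists(p)) stop("input file missing: ", p)
  structure(list(genotypes = genotypes, sites = sites, rasters = rasters,
                 out_dir = out_dir, alpha = alpha,
                 at_site_vars = at_site_vars,
                 between_site_vars = between_site_vars,
                 candidate_specs = candidate_specs, window = window,
                 site_radius = site_radius, edge_width = edge_width,
                 max_reps = max_reps, latitude = latitude, seed = seed),
            class = "run_config")
}

#' Run the full connectivity analysis pipeline
#'
#' Stages, in dependency order: genetic distances (D_PS, theta,
#' geographic) -> pruned population graph + cGD -> topology report ->
#' node-removal profile -> landscape covariates -> gravity model
#' selection. Every stage writes its table(s) under `out_dir`; a JSON
#' manifest records seeds and resolved parameters. A stage failure halts
#' downstream stages but retains completed outputs alongside a failure
#' manifest.
#'
#' @param config a `run_config`
#' @return invisible `run_bundle`: list of stage results and file paths
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  bundle <- list(config = config, files = character(0))
  record <- function(bundle, nm) { bundle$files <- c(bundle$files, nm); bundle }
  fail <- function(stage, err) {
    jsonlite::write_json(list(failed_stage = stage,
                              error = conditionMessage(err)),
                         out("FAILED.json"), auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err))
  }

  tab <- if (is.character(config$genotypes))
    read_genotypes(config$genotypes, "csv") else config$genotypes
  sites <- if (is.character(config$sites))
    read_sites(config$sites) else config$sites
  sites_in <- sites[sites$included, , drop = FALSE]

  # --- distances ---
  res <- tryCatch({
    dps <- dps_matrix(tab)
    fst <- fst_matrix(tab)
    geo <- geographic_matrix(sites)
    ord <- match(rownames(dps), rownames(geo))
    geo <- dist_matrix(unclass(geo)[ord, ord], rownames(dps), "geographic")
    write_dist_matrix(dps, out("dps.csv"))
    write_dist_matrix(fst, out("fst.csv"))
    write_dist_matrix(geo, out("geographic.csv"))
    mant <- mantel_test(dps, geo, n_perm = 999,
                        seed = child_seed(config$seed, "mantel"))
    list(dps = dps, fst = fst, geo = geo, mantel = mant)
  }, error = function(e) fail("distances", e))
  bundle$distances <- res
  bundle <- record(bundle, out(c("dps.csv", "fst.csv", "geographic.csv")))

  # --- population graph ---
  bundle$graph <- tryCatch({
    pg <- build_population_graph(tab, alpha = config$alpha)
    write_population_graph(pg, out("popgraph"), sites = sites_in)
    cgd <- cgd_matrix(pg)
    utils::write.csv(as.data.frame(unclass(cgd)), out("cgd.csv"))
    pg
  }, error = function(e) fail("population_graph", e))
  bundle <- record(bundle, out(c("popgraph.graphml", "popgraph_edges.csv",
                                 "cgd.csv")))

  # --- topology ---
  bundle$topology <- tryCatch({
    rep_ <- topology_report(bundle$graph)
    write_topology_report(rep_, out("topology"))
    rep_
  }, error = function(e) fail("topology", e))
  bundle <- record(bundle, out(c("topology_nodes.csv", "topology.json")))

  # --- robustness ---
  bundle$removal <- tryCatch({
    prof <- removal_profile(bundle$graph, max_reps = config$max_reps,
                            seed = child_seed(config$seed, "removal"))
    utils::write.csv(prof, out("removal_profile.csv"), row.names = FALSE)
    prof
  }, error = function(e) fail("robustness", e))
  bundle <- record(bundle, out("removal_profile.csv"))

  # --- landscape covariates + gravity ---
  if (!is.null(config$rasters)) {
    bundle$covariates <- tryCatch({
      stack <- if (inherits(config$rasters, "landscape_stack")) config$rasters
        else landscape_stack(lapply(config$rasters, read_ascii_grid))
      derived <- list(hli = heat_load_index(stack$dem, config$latitude),
                      srr3 = surface_relief_ratio(stack$dem, 3L),
                      srr27 = surface_relief_ratio(stack$dem, 27L))
      masks <- setdiff(names(stack), "dem")
      cover <- lapply(stack[masks], percent_cover, window = config$window)
      full <- landscape_stack(c(stack["dem"], derived, cover))
      at_vars <- config$at_site_vars %||% c("hli", "shrub", "grass")
      bw_vars <- config$between_site_vars %||%
        c("srr3", "srr27", "imperv", "agri", "eph_strm", "per_strm")
      at <- at_site_covariates(full, sites_in, radius = config$site_radius,
                               layers = intersect(at_vars, names(full)))
      bw <- between_site_covariates(full, sites_in, width = config$edge_width,
                                    layers = intersect(bw_vars, names(full)))
      utils::write.csv(at, out("covariates_at_site.csv"), row.names = FALSE)
      utils::write.csv(bw, out("covariates_between.csv"), row.names = FALSE)
      list(at = at, between = bw, at_vars = at_vars, bw_vars = bw_vars)
    }, error = function(e) fail("landscape", e))
    bundle <- record(bundle, out(c("covariates_at_site.csv",
                                   "covariates_between.csv")))

    bundle$gravity <- tryCatch({
      cv <- bundle$covariates
      ft <- build_flow_table(bundle$distances$dps, bundle$distances$geo,
                             at_site = cv$at, between = cv$between)
      specs <- config$candidate_specs %||% {
        singles <- lapply(intersect(c(cv$at_vars, cv$bw_vars), names(ft)),
                          identity)
        c(singles,
          list(intersect(c(cv$at_vars[1], cv$bw_vars[1]), names(ft))))
      }
      sel <- model_selection(ft, specs,
                             at_site_vars = cv$at_vars,
                             between_site_vars = cv$bw_vars)
      utils::write.csv(as.data.frame(sel), out("gravity_ranking.csv"),
                       row.names = FALSE)
      vw <- cumulative_variable_weight(sel)
      utils::write.csv(data.frame(variable = names(vw), weight = vw),
                       out("variable_weights.csv"), row.names = FALSE)
      list(flow_table = ft, selection = sel, variable_weights = vw)
    }, error = function(e) fail("gravity", e))
    bundle <- record(bundle, out(c("gravity_ranking.csv",
                                   "variable_weights.csv")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("popgravity")),
    seed = config$seed, alpha = config$alpha,
    max_reps = config$max_reps, window = config$window,
    site_radius = config$site_radius, edge_width = config$edge_width,
    latitude = config$latitude,
    files = basename(bundle$files))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  class(bundle) <- "run_bundle"
  invisible(bundle)
}

#' Human-readable summary of a pipeline run
#'
#' Markdown summary of the pruned-graph statistics, best community
#' partitions, core-periphery fit, node-removal profile, and (when run)
#' the top gravity models. Every figure is read back from the bundle's
#' stage results; an incomplete bundle yields a partial summary with the
#' gaps flagged.
#'
#' @param bundle a `run_bundle` from [run_pipeline()]
#' @param top_n gravity models to display
#' @return character vector of markdown lines
#' @export
report_summary <- function(bundle, top_n = 5L) {
  lines <- c("# Connectivity analysis summary", "")
  if (!is.null(bundle$graph)) {
    s <- graph_summary(bundle$graph)
    lines <- c(lines, sprintf(
      "Pruned population graph: %d nodes, %d of %d possible edges (%d%% of saturated).",
      s$n_nodes, s$n_edges_pruned, s$n_edges_saturated, s$pct_saturated))
  } else lines <- c(lines, "_population graph stage missing_")
  if (!is.null(bundle$topology)) {
    tp <- bundle$topology
    lines <- c(lines, "",
      sprintf("Leading-eigenvector communities: k = %d, Q = %.2f.",
              tp$eigen$best$k, tp$eigen$best$Q),
      sprintf("Walktrap communities: k = %d, Q = %.2f.",
              tp$walktrap$best$k, tp$walktrap$best$Q),
      sprintf("Core-periphery: %d core nodes (%s), concentration %.2f.",
              tp$core$best_size, paste(tp$core$core_set, collapse = ", "),
              tp$core$concentration))
  } else lines <- c(lines, "_topology stage missing_")
  if (!is.null(bundle$removal)) {
    pr <- bundle$removal
    lines <- c(lines, "", "## Node removal", "",
               "| removed | reps | prop connected | mean LCP | 95% CI |",
               "|---|---|---|---|---|",
               sprintf("| %d | %d | %.2f | %.2f | %.2f-%.2f |",
                       pr$n_removed, pr$n_reps, pr$prop_connected,
                       pr$mean_lcp, pr$ci_lo, pr$ci_hi))
  } else lines <- c(lines, "_robustness stage missing_")
  if (!is.null(bundle$gravity)) {
    sel <- utils::head(as.data.frame(bundle$gravity$selection), top_n)
    lines <- c(lines, "", "## Top gravity models", "",
               "| model | type | dAICc | weight | cond R2 |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.1f | %.2f | %.2f |",
                       sel$model, sel$type, sel$delta_AICc, sel$weight,
                       sel$conditional_r2))
  }
  lines
}
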