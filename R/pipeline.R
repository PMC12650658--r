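# Pipeline orchestration: a validated JSON (or list) config drives the
# analysis stages and writes per-stage CSV/JSON plus a run manifest.

config_schema <- list(
  top = c("output_dir", "seed", "input", "stages"),
  input = c("structure", "titration", "dls"),
  stages = c("fd", "ellipsoid", "pcn", "equilibrium", "dls"),
  fd = c("per_chain", "probes", "n_sphere_points", "chains"),
  ellipsoid = c("atoms", "chains"),
  pcn = c("k", "bc", "cutoffs", "frame", "chains"),
  equilibrium = c("scheme", "n_bootstrap"),
  dls = c("fit_bimodal")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stopf("unknown config key(s) in %s: %s", where, paste(unknown, collapse = ", "))
  }
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at every level before any stage runs.
#'
#' @param config A list, or path to a JSON config file.
#' @return The validated config list, invisibly usable by [run_pipeline()].
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or a JSON file path")
  check_keys(config, config_schema$top, "top level")
  if (is.null(config$stages) || !length(config$stages)) stopf("config must request at least one stage")
  check_keys(config$input, config_schema$input, "input")
  check_keys(config$stages, config_schema$stages, "stages")
  for (st in names(config$stages)) {
    if (is.list(config$stages[[st]])) check_keys(config$stages[[st]], config_schema[[st]], st)
  }
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "oligotopo_run"
  config
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on the configured
#' inputs, writing each stage's tables under `output_dir` together with a
#' `manifest.json` recording the package version, resolved configuration,
#' seeds, radii table and produced files. Re-running an identical config
#' reproduces identical outputs.
#'
#' @param config List or path to a JSON configuration. Recognised stages:
#'   `fd`, `ellipsoid`, `pcn` (need `input$structure`), `equilibrium` (needs
#'   `input$titration`), `dls` (needs `input$dls`).
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  emit <- function(name) outputs <<- c(outputs, name)

  need_structure <- any(c("fd", "ellipsoid", "pcn") %in% names(cfg$stages))
  model <- NULL
  if (need_structure) {
    if (is.null(cfg$input$structure)) stopf("stage requires input$structure")
    traj <- load_structure(cfg$input$structure)
    frame <- cfg$stages$pcn$frame %||% 1L
    model <- traj$frames[[min(frame, length(traj$frames))]]
  }

  if ("fd" %in% names(cfg$stages)) {
    p <- cfg$stages$fd
    m <- if (!is.null(p$chains)) select_chains(model, p$chains) else model
    probes <- p$probes %||% seq(1.0, 2.0, by = 0.2)
    npts <- p$n_sphere_points %||% 960L
    subjects <- list(assembly = fractal_dimension(m, probes, npts))
    if (isTRUE(p$per_chain)) subjects <- c(subjects, per_chain_fd(m, probes, npts))
    tab <- do.call(rbind, lapply(names(subjects), function(nm) {
      s <- subjects[[nm]]
      data.frame(subject = nm, slope = s$slope, fd = s$fd, r_squared = s$r_squared)
    }))
    utils::write.csv(tab, file.path(cfg$output_dir, "fd.csv"), row.names = FALSE)
    emit("fd.csv")
    results$fd <- subjects
  }

  if ("ellipsoid" %in% names(cfg$stages)) {
    p <- cfg$stages$ellipsoid
    m <- if (!is.null(p$chains)) select_chains(model, p$chains) else model
    if (identical(p$atoms, "CA")) {
      pts <- as.matrix(calpha_coordinates(m)[, c("x", "y", "z")])
    } else pts <- m
    fit <- fit_ellipsoid(pts)
    sph <- spheroid_summary(fit)
    out <- list(coefficients = as.list(fit$coefficients), center = fit$center,
                radii = fit$radii, rotation = fit$rotation, rss = fit$rss,
                r_polar = sph$r_polar, r_equatorial = sph$r_equatorial,
                shape_class = sph$shape_class)
    jsonlite::write_json(out, file.path(cfg$output_dir, "ellipsoid.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("ellipsoid.json")
    results$ellipsoid <- list(fit = fit, spheroid = sph)
  }

  if ("pcn" %in% names(cfg$stages)) {
    p <- cfg$stages$pcn
    m <- if (!is.null(p$chains)) select_chains(model, p$chains) else model
    cuts <- p$cutoffs %||% c(4, 8)
    net <- build_network(m, cuts[1], cuts[2])
    edges <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
    el <- data.frame(chain_i = net$nodes$chain[edges[, 1]],
                     res_i = net$nodes$resno[edges[, 1]],
                     chain_j = net$nodes$chain[edges[, 2]],
                     res_j = net$nodes$resno[edges[, 2]],
                     distance = net$distances[edges])
    utils::write.csv(el, file.path(cfg$output_dir, "pcn_edges.csv"), row.names = FALSE)
    emit("pcn_edges.csv")
    part <- spectral_clusters(net, k = p$k %||% 2L, seed = cfg$seed)
    cluster_color_map(part, file.path(cfg$output_dir, "pcn_clusters.csv"))
    emit("pcn_clusters.csv")
    results$pcn <- list(network = net, partition = part)
    if (isTRUE(p$bc)) {
      bc <- betweenness_centrality(net)
      utils::write.csv(bc, file.path(cfg$output_dir, "pcn_bc.csv"), row.names = FALSE)
      emit("pcn_bc.csv")
      results$pcn$bc <- bc
    }
    if (length(unique(net$nodes$chain)) >= 2L) {
      results$pcn$pairing <- interchain_pairing(net)
    }
  }

  if ("equilibrium" %in% names(cfg$stages)) {
    if (is.null(cfg$input$titration)) stopf("equilibrium stage requires input$titration")
    p <- cfg$stages$equilibrium
    dat <- read_titration(cfg$input$titration)
    fit <- fit_dissociation(dat, scheme = p$scheme %||% "T3M",
                            n_bootstrap = p$n_bootstrap %||% 200L,
                            seed = cfg$seed)
    jsonlite::write_json(
      list(scheme = fit$model$scheme, kd = fit$kd,
           ci = as.list(fit$ci), rss = fit$rss,
           residuals_by_technique = as.list(fit$residuals_by_technique)),
      file.path(cfg$output_dir, "equilibrium.json"), auto_unbox = TRUE, digits = NA)
    emit("equilibrium.json")
    cc <- 10^seq(log10(min(dat$c_tot)), log10(max(dat$c_tot)), length.out = 100)
    utils::write.csv(data.frame(c_tot_M = cc,
                                f_monomer = monomer_fraction(fit$model, cc)),
                     file.path(cfg$output_dir, "equilibrium_curve.csv"),
                     row.names = FALSE)
    emit("equilibrium_curve.csv")
    results$equilibrium <- fit
  }

  if ("dls" %in% names(cfg$stages)) {
    if (is.null(cfg$input$dls)) stopf("dls stage requires input$dls")
    p <- cfg$stages$dls
    dist <- read_size_distribution(cfg$input$dls)
    out <- list(mean_d = dist$mean_d, dispersity = dispersity(dist))
    if (isTRUE(p$fit_bimodal)) {
      fit <- fit_bimodal(dist, seed = cfg$seed)
      out$components <- fit$components
      results$dls_fit <- fit
    }
    jsonlite::write_json(out, file.path(cfg$output_dir, "dls.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("dls.json")
    results$dls <- out
  }

  manifest <- list(
    package = "oligotopo",
    version = as.character(utils::packageVersion("oligotopo")),
    seed = cfg$seed,
    radii_table = if (!is.null(model)) model$radii_table else NA,
    config = cfg,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
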