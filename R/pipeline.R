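# Config-driven orchestration: build a set of named network subsets from
# one record table, run modularity + null standardization + roles on each,
# and assemble a network-level report plus role tables and a
# sampling-completeness report for the full network.

#' Build a validated run configuration
#'
#' @param records_path Path to the records CSV (ignored when `records` is
#'   supplied directly to [run_pipeline()]).
#' @param networks A list of network specifications, each a list with a
#'   unique `name` and optional `location`, `year`, `season` filters and a
#'   logical `reduce` (apply [reduce_by_occurrence()]). Defaults to a
#'   single unfiltered network named `"full"`.
#' @param n_nulls Null matrices per network (default 100; at least 2).
#' @param n_restarts Optimizer restarts (default 50).
#' @param z_sig Significance cutoff on Z_Q (default 2).
#' @param role_quantile Quantile for the critical c/z thresholds (default
#'   0.95).
#' @param seed Master seed; per-network seeds are derived from it by a
#'   stable hash of the network name, so adding a network does not perturb
#'   the others.
#' @param output_dir Optional directory for report/role/completeness files.
#' @return A validated `run_config` list.
#' @export
run_config <- function(records_path = NULL, networks = NULL,
                       n_nulls = 100L, n_restarts = 50L, z_sig = 2,
                       role_quantile = 0.95, seed = 1L,
                       output_dir = NULL) {
  if (is.null(networks)) {
    networks <- list(list(name = "full"))
  }
  nm <- vapply(networks, function(x) {
    if (is.null(x$name) || !nzchar(x$name)) {
      abort("every network spec needs a non-empty `name`")
    }
    x$name
  }, character(1))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate network name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (!is.numeric(n_nulls) || n_nulls < 2) {
    abort("`n_nulls` must be >= 2")
  }
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    abort("`n_restarts` must be >= 1")
  }
  if (role_quantile <= 0 || role_quantile >= 1) {
    abort("`role_quantile` must lie strictly between 0 and 1")
  }
  structure(
    list(
      records_path = records_path,
      networks = networks,
      n_nulls = as.integer(n_nulls),
      n_restarts = as.integer(n_restarts),
      z_sig = z_sig,
      role_quantile = role_quantile,
      seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

# Stable polynomial hash of a network name; child seeds depend only on
# (master seed, name), never on the other networks in the config.
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer((as.numeric(seed) + h) %% 2147483563 + 1)
}

#' The paper-style battery of network subsets
#'
#' Builds the standard analysis surface from the domain of one record
#' table: the full and reduced networks, one network per sampling
#' location, one consecutive (rainy-season) network per year, and -- when
#' a dry season is present -- the two seasonal networks of the first
#' dry-season year.
#'
#' @param records A record table.
#' @return A list of network specs for [run_config()].
#' @export
standard_network_specs <- function(records) {
  records <- as_records(records)
  specs <- list(
    list(name = "full"),
    list(name = "reduced", reduce = TRUE)
  )
  for (loc in sort(unique(records$location))) {
    specs[[length(specs) + 1L]] <- list(
      name = paste0("location_", loc), location = loc
    )
  }
  rainy_years <- sort(unique(records$year[records$season == "rainy"]))
  for (yr in rainy_years) {
    specs[[length(specs) + 1L]] <- list(
      name = paste0("rainy_", yr), year = yr, season = "rainy"
    )
  }
  dry_years <- sort(unique(records$year[records$season == "dry"]))
  if (length(dry_years) > 0) {
    yr <- dry_years[1]
    specs[[length(specs) + 1L]] <- list(
      name = paste0("dry_", yr), year = yr, season = "dry"
    )
  }
  specs
}

#' Run the whole multi-network analysis
#'
#' For every configured network: subset (and optionally reduce) the
#' records, build the weighted matrix, optimize modularity, draw the null
#' ensemble, standardize (Z_Q), and -- when at least two modules were
#' found -- assign topological roles against the null-derived thresholds
#' (networks resolving to fewer than two modules get their roles marked
#' not assessed). A sampling-completeness report is computed for the
#' network named `"full"` (or the first network otherwise). Subsets that
#' become empty are skipped with a warning. Reruns with the same config
#' produce identical results.
#'
#' @param config A [run_config()].
#' @param records Optional record table overriding `config$records_path`.
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return A `pipeline_result` list: `report` (one tibble row per network:
#'   plants, pollinators, visits, modules, Q_observed, Q_adjusted, Z_Q,
#'   significant, roles_assessed), `roles` (named list of role tables or
#'   `NULL`), `modularity` / `ensembles` (per-network fit objects),
#'   `completeness`, and `config`.
#' @export
run_pipeline <- function(config, records = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) {
    if (is.null(config$records_path)) {
      abort("config has no records_path and no records were supplied")
    }
    records <- read_records(config$records_path)
  } else {
    records <- as_records(records)
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  rows <- list()
  roles <- list()
  fits <- list()
  ensembles <- list()
  for (spec in config$networks) {
    t0 <- Sys.time()
    sub <- subset_records(
      records,
      location = spec$location, year = spec$year, season = spec$season
    )
    if (isTRUE(spec$reduce)) sub <- reduce_by_occurrence(sub)
    if (nrow(sub) == 0) {
      warn(sprintf("network '%s' is empty after filtering; skipped",
                   spec$name))
      next
    }
    mat <- build_matrix(sub)
    net_seed <- derive_seed(config$seed, spec$name)
    opt <- optimize_modules(mat, n_restarts = config$n_restarts,
                            seed = net_seed)
    ens <- null_ensemble(
      mat, n = config$n_nulls,
      seed = derive_seed(config$seed, paste0(spec$name, "/nulls")),
      n_restarts = config$n_restarts
    )
    zq <- modularity_z_score(opt, ens, z_sig = config$z_sig)
    assessed <- opt$n_modules >= 2
    if (assessed) {
      thr <- critical_thresholds(ens, config$role_quantile)
      roles[[spec$name]] <- assign_roles(
        role_scores(mat, opt$partition, "plant"), thr
      )
    } else {
      roles[spec$name] <- list(NULL)
    }
    rows[[spec$name]] <- tibble::tibble(
      network = spec$name,
      plants = ncol(mat$A),
      pollinators = nrow(mat$A),
      visits = mat$total,
      modules = opt$n_modules,
      Q_observed = opt$Q,
      Q_adjusted = zq$Q_adjusted,
      Z_Q = zq$Z_Q,
      significant = zq$significant,
      roles_assessed = assessed
    )
    fits[[spec$name]] <- opt
    ensembles[[spec$name]] <- ens
    say("network=%s stage=done seed=%d elapsed=%.1fs Q=%.3f Z_Q=%.2f",
        spec$name, net_seed,
        as.numeric(difftime(Sys.time(), t0, units = "secs")),
        opt$Q, zq$Z_Q)
  }
  if (length(rows) == 0) {
    abort("no network produced any interactions")
  }
  report <- dplyr::bind_rows(rows)
  comp_net <- if ("full" %in% names(fits)) "full" else names(fits)[1]
  comp_records <- config$networks[[
    match(comp_net, vapply(config$networks, `[[`, character(1), "name"))
  ]]
  comp_sub <- subset_records(records, location = comp_records$location,
                             year = comp_records$year,
                             season = comp_records$season)
  if (isTRUE(comp_records$reduce)) comp_sub <- reduce_by_occurrence(comp_sub)
  completeness <- completeness_report(build_matrix(comp_sub))
  result <- structure(
    list(
      report = report,
      roles = roles,
      modularity = fits,
      ensembles = ensembles,
      completeness = completeness,
      log = log_lines,
      config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(result, config$output_dir)
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$report, file.path(dir, "report.tsv"),
                   progress = FALSE)
  for (nm in names(result$roles)) {
    if (!is.null(result$roles[[nm]])) {
      write_roles(result$roles[[nm]],
                  file.path(dir, paste0("roles_", nm, ".tsv")))
    }
  }
  write_completeness(result$completeness,
                     file.path(dir, "completeness.json"))
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d network(s)\n", nrow(x$report)))
  print(x$report)
  invisible(x)
}
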