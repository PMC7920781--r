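# Synthetic visitation data with known ground truth: block-modular
# interaction rates with optional planted connector plants, continuous vs
# brief flowering phenology, multi-location / multi-year / seasonal
# sampling and abundance-dependent visitation. Lets every pipeline stage
# be validated against a planted partition and planted roles.

#' Generate a synthetic plant-pollinator community
#'
#' Plants and pollinators are split into `n_modules` blocks of as-even-as-
#' possible size. The per-sample expected visit rate is `lambda_in` for
#' within-block (plant, pollinator) pairs and `lambda_out` otherwise.
#' Planted connector plants instead interact at rate `lambda_in / 2` with
#' *every* pollinator, spreading their strength evenly over all modules (a
#' planted connector role). A configurable number of plants (default up to
#' six, always including the connectors) flower continuously; the rest are
#' brief, flowering only in the rainy season.
#'
#' @param n_plants,n_pollinators Community sizes.
#' @param n_modules Number of planted modules (at most
#'   `min(n_plants, n_pollinators)`).
#' @param lambda_in,lambda_out Within- and between-block expected visits
#'   per (pollinator, plant, sample); `lambda_in > lambda_out >= 0`.
#' @param connector_count Number of planted connector plants (default 0).
#' @param seed Integer seed; the same seed reproduces the community
#'   exactly.
#' @param n_continuous Number of continuously flowering plants (default
#'   `min(6, n_plants)`).
#' @param prop_bee Probability a pollinator species is a bee rather than a
#'   butterfly (default 0.5).
#' @param base_flowers Baseline open-flower count; per-sample floral
#'   abundance is lognormal around it with mean multiplier 1.
#' @param abundance_effect Exponent linking a sample's floral abundance to
#'   its visit rates: rates are scaled by `(flowers / base_flowers) ^
#'   abundance_effect`. 1 (default) gives a linear positive effect, 0
#'   removes abundance dependence.
#' @param activity_sd Lognormal sd (on the log scale) of a per-pollinator
#'   activity multiplier with mean 1 applied to that species' rates.
#'   0 (default) keeps the exact block rates; around 1 emulates the
#'   right-skewed abundance distributions of real insect assemblages, so
#'   rare species exist and completeness estimation is non-trivial.
#' @param overdispersion `NULL` for Poisson visit counts (default), or a
#'   positive negative-binomial size parameter for overdispersed counts.
#' @return A `synthetic_community`: labels, `rate_matrix` (pollinators x
#'   plants), `true_partition` (a [module_partition()]), `guild`,
#'   `phenology` (`"continuous"` or `"brief"` per plant),
#'   `planted_connectors`, and the generator settings.
#' @export
generate_community <- function(n_plants, n_pollinators, n_modules,
                               lambda_in = 2, lambda_out = 0.02,
                               connector_count = 0, seed = 1L,
                               n_continuous = NULL, prop_bee = 0.5,
                               base_flowers = 50,
                               abundance_effect = 1,
                               activity_sd = 0,
                               overdispersion = NULL) {
  if (n_modules > min(n_plants, n_pollinators) || n_modules < 1) {
    abort("`n_modules` must be between 1 and min(n_plants, n_pollinators)")
  }
  if (lambda_in < lambda_out || lambda_out < 0 || lambda_in <= 0) {
    abort("need lambda_in >= lambda_out >= 0 and lambda_in > 0")
  }
  if (connector_count > n_plants) {
    abort("more planted connectors than plants")
  }
  if (is.null(n_continuous)) n_continuous <- min(6L, n_plants)
  n_continuous <- max(n_continuous, connector_count)
  plants <- sprintf("plant_%02d", seq_len(n_plants))
  pols <- sprintf("pol_%03d", seq_len(n_pollinators))
  plant_module <- sort(rep_len(seq_len(n_modules), n_plants))
  pol_module <- sort(rep_len(seq_len(n_modules), n_pollinators))
  rate <- matrix(lambda_out, n_pollinators, n_plants,
                 dimnames = list(pols, plants))
  rate[outer(pol_module, plant_module, "==")] <- lambda_in
  withr::with_seed(seed, {
    connectors <- if (connector_count > 0) {
      sample(plants, connector_count)
    } else {
      character(0)
    }
    non_conn <- setdiff(plants, connectors)
    extra_cont <- n_continuous - length(connectors)
    continuous <- c(connectors,
                    if (extra_cont > 0) sample(non_conn, extra_cont))
    guild <- sample(c("bee", "butterfly"), n_pollinators, replace = TRUE,
                    prob = c(prop_bee, 1 - prop_bee))
    activity <- rlnorm(n_pollinators, -activity_sd^2 / 2, activity_sd)
  })
  rate <- rate * activity
  if (length(connectors) > 0) {
    rate[, connectors] <- lambda_in / 2
  }
  phenology <- ifelse(plants %in% continuous, "continuous", "brief")
  structure(
    list(
      n_plants = n_plants,
      n_pollinators = n_pollinators,
      n_modules = n_modules,
      plants = plants,
      pollinators = pols,
      rate_matrix = rate,
      true_partition = module_partition(
        setNames(pol_module, pols), setNames(plant_module, plants)
      ),
      guild = setNames(guild, pols),
      phenology = setNames(phenology, plants),
      planted_connectors = connectors,
      lambda_in = lambda_in,
      lambda_out = lambda_out,
      base_flowers = base_flowers,
      abundance_effect = abundance_effect,
      activity = setNames(activity, pols),
      activity_sd = activity_sd,
      overdispersion = overdispersion,
      seed = as.integer(seed)
    ),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "Synthetic community: %d plants x %d pollinators, %d modules, %d planted connector(s)\n",
    x$n_plants, x$n_pollinators, x$n_modules, length(x$planted_connectors)
  ))
  invisible(x)
}

#' Describe a sampling design
#'
#' Emulates a multi-location, multi-year field campaign: rainy-season
#' sampling sessions in every year plus (when `"dry"` is among the
#' seasons) one dry-season session in the first year; a set of sampling
#' locations each plant occupies (all of them, a fixed mapping, or a
#' random subset of 1 to `max_locations_per_plant`); a number of 30-min
#' samples per plant, location and session; and a per-guild detection
#' (capture) probability thinning the observed visits.
#'
#' @param locations Location labels (default eight sites).
#' @param years Sampled years (default 2017-2019).
#' @param seasons Seasons in the design (default rainy + dry).
#' @param sessions Optional data frame with columns `year`, `season`
#'   overriding the default session layout.
#' @param samples_per_plant_per_location Samples per plant per location in
#'   each session (default 1).
#' @param detection Named per-guild capture probabilities in (0, 1].
#' @param plant_locations `"random"`, `"all"`, or a named list mapping
#'   plant labels to location vectors.
#' @param max_locations_per_plant Upper bound for random occupancy
#'   (default 2).
#' @return A `sampling_design` list.
#' @export
sampling_design <- function(locations = sprintf("loc_%d", 1:8),
                            years = 2017:2019,
                            seasons = c("rainy", "dry"),
                            sessions = NULL,
                            samples_per_plant_per_location = 1L,
                            detection = c(bee = 0.8, butterfly = 0.8),
                            plant_locations = "random",
                            max_locations_per_plant = 2L) {
  if (samples_per_plant_per_location < 1) {
    abort("`samples_per_plant_per_location` must be >= 1")
  }
  if (any(detection <= 0 | detection > 1)) {
    abort("detection probabilities must lie in (0, 1]")
  }
  if (is.null(sessions)) {
    sessions <- tibble::tibble(year = as.integer(years), season = "rainy")
    if ("dry" %in% seasons) {
      sessions <- dplyr::bind_rows(
        sessions,
        tibble::tibble(year = min(as.integer(years)), season = "dry")
      )
    }
  }
  sessions <- tibble::as_tibble(sessions)
  structure(
    list(
      locations = locations,
      years = as.integer(years),
      seasons = seasons,
      sessions = sessions,
      samples_per_plant_per_location =
        as.integer(samples_per_plant_per_location),
      detection = detection,
      plant_locations = plant_locations,
      max_locations_per_plant = as.integer(max_locations_per_plant)
    ),
    class = "sampling_design"
  )
}

resolve_occupancy <- function(community, design) {
  spec <- design$plant_locations
  if (identical(spec, "all")) {
    return(setNames(
      rep(list(design$locations), community$n_plants), community$plants
    ))
  }
  if (is.list(spec)) {
    missing_p <- setdiff(community$plants, names(spec))
    if (length(missing_p) > 0) {
      abort(paste0("plant_locations mapping is missing: ",
                   paste(head(missing_p, 5), collapse = ", ")))
    }
    return(spec[community$plants])
  }
  # random occupancy, drawn from the current (seeded) RNG stream
  occ <- lapply(seq_len(community$n_plants), function(i) {
    n_loc <- sample.int(design$max_locations_per_plant, 1L)
    sample(design$locations, min(n_loc, length(design$locations)))
  })
  setNames(occ, community$plants)
}

#' Sample visitation records from a synthetic community
#'
#' For every session, location and active plant (brief plants are inactive
#' outside the rainy season), `samples_per_plant_per_location` 30-min
#' samples are drawn. Each sample gets a lognormal floral abundance (mean
#' multiplier 1 around the community's baseline); per-pollinator visit
#' counts are Poisson (or negative binomial when the community has an
#' overdispersion parameter) with mean `rate * floral multiplier`, then
#' thinned by the per-guild detection probability. Rows with zero captures
#' are not emitted.
#'
#' @param community A [generate_community()] result.
#' @param design A [sampling_design()].
#' @param seed Integer seed; identical `(community, design, seed)` yield
#'   identical records.
#' @return A record tibble (see [as_records()]); empty when every rate is
#'   zero or nothing is detected.
#' @export
sample_visits <- function(community, design, seed = 1L) {
  stopifnot(inherits(community, "synthetic_community"),
            inherits(design, "sampling_design"))
  nr <- community$n_pollinators
  det <- design$detection[community$guild]
  det[is.na(det)] <- 1
  out <- list()
  withr::with_seed(seed, {
    occupancy <- resolve_occupancy(community, design)
    for (si in seq_len(nrow(design$sessions))) {
      yr <- design$sessions$year[si]
      se <- design$sessions$season[si]
      for (loc in design$locations) {
        for (p in seq_len(community$n_plants)) {
          plant <- community$plants[p]
          if (!(loc %in% occupancy[[plant]])) next
          if (community$phenology[plant] == "brief" && se != "rainy") next
          lam <- community$rate_matrix[, p]
          for (s in seq_len(design$samples_per_plant_per_location)) {
            flowers <- round(rlnorm(
              1, log(community$base_flowers) - 0.125, 0.5
            ))
            mult <- (flowers / community$base_flowers)^
              community$abundance_effect
            mu <- lam * mult
            raw <- if (is.null(community$overdispersion)) {
              rpois(nr, mu)
            } else {
              stats::rnbinom(nr, size = community$overdispersion, mu = mu)
            }
            kept <- rbinom(nr, raw, det)
            hit <- which(kept > 0)
            if (length(hit) == 0) next
            out[[length(out) + 1L]] <- tibble::tibble(
              plant = plant,
              pollinator = community$pollinators[hit],
              guild = unname(community$guild[hit]),
              location = loc,
              year = yr,
              season = se,
              sample_id = sprintf("%s_%d_%s_%s_s%02d", loc, yr, se, plant, s),
              floral_abundance = flowers,
              count = as.integer(kept[hit])
            )
          }
        }
      }
    }
  })
  if (length(out) == 0) {
    return(as_records(tibble::tibble(
      plant = character(0), pollinator = character(0), guild = character(0),
      location = character(0), year = integer(0), season = character(0),
      sample_id = character(0), floral_abundance = numeric(0),
      count = integer(0)
    )))
  }
  as_records(dplyr::bind_rows(out))
}

#' Write synthetic records plus a ground-truth sidecar
#'
#' Emits the standard records CSV and a JSON sidecar holding the planted
#' partition, planted connectors, rates and seeds, for test harnesses.
#'
#' @param records Records from [sample_visits()].
#' @param community The generating [generate_community()] community.
#' @param path Output CSV path; the sidecar is written as
#'   `<path-sans-ext>_truth.json`.
#' @return `records`, invisibly.
#' @export
write_synthetic <- function(records, community, path) {
  readr::write_csv(as_records(records), path, progress = FALSE)
  truth <- list(
    seed = community$seed,
    n_modules = community$n_modules,
    plant_module = as.list(setNames(
      community$true_partition$col_module, community$plants
    )),
    pollinator_module = as.list(setNames(
      community$true_partition$row_module, community$pollinators
    )),
    planted_connectors = community$planted_connectors,
    lambda_in = community$lambda_in,
    lambda_out = community$lambda_out
  )
  jsonlite::write_json(
    truth, paste0(sub("\\.[[:alnum:]]+$", "", path), "_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(records)
}

#' Agreement between two module partitions (normalized mutual information)
#'
#' NMI over the joint node labels (columns and rows together), using the
#' average-entropy normalization `2 I(a; b) / (H(a) + H(b))`. Equals 1
#' exactly when the partitions are identical up to relabeling (including
#' two trivial one-module partitions) and 0 when the mutual information is
#' zero (e.g. everything-in-one versus all-singletons).
#'
#' @param a,b [module_partition()]s over the same node set. When both
#'   carry node names, nodes are aligned by name.
#' @return NMI in `[0, 1]`.
#' @export
partition_agreement <- function(a, b) {
  stopifnot(inherits(a, "module_partition"), inherits(b, "module_partition"))
  la <- c(a$col_module, a$row_module)
  lb <- c(b$col_module, b$row_module)
  na <- c(names(a$col_module), names(a$row_module))
  nb <- c(names(b$col_module), names(b$row_module))
  if (length(la) != length(lb)) {
    abort("partitions cover different node sets")
  }
  if (!is.null(na) && !is.null(nb) && all(nzchar(na)) && all(nzchar(nb))) {
    if (!setequal(na, nb)) abort("partitions cover different node sets")
    lb <- lb[match(na, nb)]
  }
  n <- length(la)
  joint <- table(la, lb) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- h(pa)
  hb <- h(pb)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  if (ha + hb == 0) return(1)
  if (mi <= 0) return(0)
  min(1, 2 * mi / (ha + hb))
}
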