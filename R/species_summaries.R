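# Descriptive per-plant-species summaries: per-sample pollinator richness
# and abundance (mean +/- SE), degree, normalized degree and strength.
# Model fitting (GLMMs etc.) is deliberately left to general-purpose
# statistics tooling; these functions guarantee the model-ready tables.

#' Per-plant summaries of per-sample richness and abundance
#'
#' For every plant species: the number of 30-min observation samples, the
#' mean and standard error of pollinator species richness per sample
#' (distinct pollinator species captured in that sample) and of pollinator
#' abundance per sample (captured individuals, i.e. summed counts), plus
#' network-level descriptors computed from the same records: degree
#' (number of partner species), normalized degree (degree divided by the
#' number of pollinator species in the network) and species strength.
#' Bees and butterflies are pooled; pass a pre-filtered record table for a
#' per-guild breakdown. Plants observed in a single sample get `se = 0`
#' and are flagged by `single_sample`.
#'
#' @param records A record table with `sample_id` filled in.
#' @param plants Optional character vector restricting the summarised
#'   plant species.
#' @return A tibble with one row per plant: `plant, n_samples,
#'   mean_richness, se_richness, mean_abundance, se_abundance,
#'   single_sample, degree, normalized_degree, strength`.
#' @export
per_sample_stats <- function(records, plants = NULL) {
  records <- as_records(records)
  if (nrow(records) == 0) abort("no records to summarise")
  if (any(is.na(records$sample_id) | records$sample_id == "")) {
    abort("sample_id is required for per-sample summaries")
  }
  mat <- build_matrix(records)
  degree <- colSums(mat$A > 0)
  network_tbl <- tibble::tibble(
    plant = mat$col_labels,
    degree = as.integer(degree),
    normalized_degree = unname(degree) / nrow(mat$A),
    strength = unname(species_strength(mat, "plant"))
  )
  per_sample <- records |>
    dplyr::group_by(.data$plant, .data$sample_id) |>
    dplyr::summarise(
      richness = dplyr::n_distinct(.data$pollinator),
      abundance = sum(.data$count),
      .groups = "drop"
    )
  out <- per_sample |>
    dplyr::group_by(.data$plant) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_richness = mean(.data$richness),
      se_richness = if (dplyr::n() > 1) {
        sd(.data$richness) / sqrt(dplyr::n())
      } else 0,
      mean_abundance = mean(.data$abundance),
      se_abundance = if (dplyr::n() > 1) {
        sd(.data$abundance) / sqrt(dplyr::n())
      } else 0,
      single_sample = dplyr::n() == 1,
      .groups = "drop"
    ) |>
    dplyr::left_join(network_tbl, by = "plant")
  if (!is.null(plants)) {
    out <- dplyr::filter(out, .data$plant %in% plants)
  }
  out
}

#' Model-ready per-sample table of floral abundance effects
#'
#' One row per (plant, sample): the sample's floral abundance, pollinator
#' species richness and pollinator abundance -- the tidy input for
#' external mixed-model fitting of the floral-abundance effect. Samples
#' with missing floral abundance are dropped with a message stating how
#' many; an all-missing input yields an empty table with a warning.
#'
#' @param records A record table.
#' @return A tibble with columns `plant, location, sample_id,
#'   floral_abundance, richness, abundance`.
#' @export
floral_effect_table <- function(records) {
  records <- as_records(records)
  tbl <- records |>
    dplyr::group_by(.data$plant, .data$location, .data$sample_id) |>
    dplyr::summarise(
      floral_abundance = .data$floral_abundance[1],
      richness = dplyr::n_distinct(.data$pollinator),
      abundance = sum(.data$count),
      .groups = "drop"
    )
  dropped <- sum(is.na(tbl$floral_abundance))
  if (dropped > 0 && dropped < nrow(tbl)) {
    message(sprintf(
      "dropped %d sample(s) with missing floral abundance", dropped
    ))
  }
  if (nrow(tbl) > 0 && dropped == nrow(tbl)) {
    warn("all samples are missing floral abundance; returning an empty table")
  }
  dplyr::filter(tbl, !is.na(.data$floral_abundance))
}
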