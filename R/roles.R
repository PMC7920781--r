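# Strength-based weighted c/z topological roles for the lower trophic
# level (plants), with critical thresholds taken as quantiles of the
# pooled null-model c/z distributions.

role_levels <- c("peripheral", "connector", "module_hub", "network_hub")

#' Species strength
#'
#' The strength of a plant is the sum over its pollinator partners of that
#' partner's dependence on it, `s_j = sum_i A_ij / k_i` -- the share of
#' each pollinator's visits that went to the plant. Plant strengths sum to
#' the number of pollinator species (and symmetrically for the pollinator
#' level).
#'
#' @param matrix An [interaction_matrix()].
#' @param level `"plant"` (default, the lower trophic level) or
#'   `"pollinator"`.
#' @return A named numeric vector of strengths.
#' @export
species_strength <- function(matrix, level = c("plant", "pollinator")) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  level <- match.arg(level)
  if (level == "plant") {
    colSums(matrix$A / matrix$k)
  } else {
    rowSums(sweep(matrix$A, 2, matrix$d, "/"))
  }
}

# Strength of each focal-level species decomposed by the partner-level
# module: for plants, rows t are row-module ids, columns are plants.
strength_by_partner_module <- function(matrix, partition,
                                       level = c("plant", "pollinator")) {
  level <- match.arg(level)
  if (level == "plant") {
    dep <- matrix$A / matrix$k                    # pollinator dependence on plants
    rowsum(dep, partition$row_module)
  } else {
    dep <- sweep(matrix$A, 2, matrix$d, "/")      # plant dependence on pollinators
    t(rowsum(t(dep), partition$col_module))
  }
}

#' Weighted among-module connectivity (participation coefficient c)
#'
#' `c_i = 1 - sum_t (s_it / s_i)^2`, where `s_it` is species i's strength
#' restricted to partners in module t. A species whose partners all sit in
#' one module has `c = 0`; strength split equally over T modules gives
#' `c = 1 - 1/T`. Always in `[0, 1)` and invariant to module relabeling.
#'
#' @inheritParams species_strength
#' @param partition A [module_partition()] matching `matrix`.
#' @return Named numeric vector of c values.
#' @export
participation_c <- function(matrix, partition,
                            level = c("plant", "pollinator")) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(partition, "module_partition"))
  level <- match.arg(level)
  check_partition_dims(matrix, partition)
  s <- species_strength(matrix, level)
  if (any(s <= 0)) {
    abort("species with zero strength cannot be scored (drop them upstream)")
  }
  W <- strength_by_partner_module(matrix, partition, level)
  if (level == "plant") {
    1 - colSums((W / rep(s, each = nrow(W)))^2)
  } else {
    1 - rowSums((W / s)^2)
  }
}

#' Weighted within-module connectivity (z)
#'
#' `z_i = (s_im - mean_m) / sd_m`, where `s_im` is species i's strength
#' restricted to partners inside its own module m and the mean and sample
#' standard deviation are taken over the same-level members of m. Within
#' each module the z values have mean 0 and (when defined) sample sd 1.
#' Degenerate modules (a single member, or zero sd) get `z = 0`.
#'
#' @inheritParams participation_c
#' @return Named numeric vector of z values.
#' @export
within_module_z <- function(matrix, partition,
                            level = c("plant", "pollinator")) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(partition, "module_partition"))
  level <- match.arg(level)
  check_partition_dims(matrix, partition)
  W <- strength_by_partner_module(matrix, partition, level)
  if (level == "plant") {
    own <- partition$col_module
    partner_mods <- as.integer(rownames(W))
    w_own <- vapply(seq_along(own), function(j) {
      t <- match(own[j], partner_mods)
      if (is.na(t)) 0 else W[t, j]
    }, numeric(1))
    names(w_own) <- matrix$col_labels
  } else {
    own <- partition$row_module
    partner_mods <- as.integer(colnames(W))
    w_own <- vapply(seq_along(own), function(i) {
      t <- match(own[i], partner_mods)
      if (is.na(t)) 0 else W[i, t]
    }, numeric(1))
    names(w_own) <- matrix$row_labels
  }
  z <- numeric(length(w_own))
  for (m in unique(own)) {
    members <- which(own == m)
    if (length(members) < 2) {
      z[members] <- 0
      next
    }
    mu <- mean(w_own[members])
    sdev <- sd(w_own[members])
    z[members] <- if (!is.finite(sdev) || sdev == 0) {
      0
    } else {
      (w_own[members] - mu) / sdev
    }
  }
  names(z) <- names(w_own)
  z
}

check_partition_dims <- function(matrix, partition) {
  if (length(partition$row_module) != nrow(matrix$A) ||
      length(partition$col_module) != ncol(matrix$A)) {
    abort("partition dimensions do not match the interaction matrix")
  }
  invisible(TRUE)
}

#' Combined role scores for one trophic level
#'
#' Convenience wrapper returning a tibble with strength, among-module
#' connectivity c and within-module connectivity z for every species of
#' the chosen level under a given partition.
#'
#' @inheritParams participation_c
#' @return A tibble with columns `species, module, strength, c, z`.
#' @export
role_scores <- function(matrix, partition, level = c("plant", "pollinator")) {
  level <- match.arg(level)
  s <- species_strength(matrix, level)
  cc <- participation_c(matrix, partition, level)
  zz <- within_module_z(matrix, partition, level)
  module <- if (level == "plant") partition$col_module else partition$row_module
  tibble::tibble(
    species = names(s),
    module = as.integer(module),
    strength = unname(s),
    c = unname(cc),
    z = unname(zz)
  )
}

#' Null-derived critical thresholds for c and z
#'
#' The critical thresholds are quantiles (default the 95% quantile) of the
#' c and z values pooled across all null matrices of a [null_ensemble()].
#' Quantiles use the common sorted-order linear-interpolation definition
#' (R's type 7), recorded in the output for reproducibility.
#'
#' @param ensemble A [null_ensemble()] with non-empty pooled c/z vectors.
#' @param quantile Quantile in (0, 1); default 0.95.
#' @return An object of class `role_thresholds` with `c_critical`,
#'   `z_critical`, `quantile`, `n_nulls` and `quantile_method`.
#' @export
critical_thresholds <- function(ensemble, quantile = 0.95) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      is.na(quantile) || quantile <= 0 || quantile >= 1) {
    abort("`quantile` must be a single number strictly between 0 and 1")
  }
  if (length(ensemble$pooled_c) == 0 || length(ensemble$pooled_z) == 0) {
    abort("ensemble pooled c/z vectors are empty")
  }
  structure(
    list(
      c_critical = unname(stats::quantile(ensemble$pooled_c, quantile,
                                          type = 7, names = FALSE)),
      z_critical = unname(stats::quantile(ensemble$pooled_z, quantile,
                                          type = 7, names = FALSE)),
      quantile = quantile,
      n_nulls = ensemble$n,
      quantile_method = "type7"
    ),
    class = "role_thresholds"
  )
}

#' @export
print.role_thresholds <- function(x, ...) {
  cat(sprintf(
    "Critical thresholds (%.0f%% quantile of %d pooled nulls): c = %.3f, z = %.3f\n",
    100 * x$quantile, x$n_nulls, x$c_critical, x$z_critical
  ))
  invisible(x)
}

#' Assign the four topological roles
#'
#' Classifies each species into exactly one of four roles by comparing its
#' c and z values to the critical thresholds, using strict inequalities
#' (boundary equality falls to the non-exceeding side):
#' * peripheral: `c <= c_critical` and `z <= z_critical` -- weak
#'   interactions, mostly within the own module;
#' * connector: `c > c_critical` and `z <= z_critical` -- binds modules
#'   together;
#' * module hub: `c <= c_critical` and `z > z_critical` -- many
#'   interactions within the own module;
#' * network hub: `c > c_critical` and `z > z_critical` -- highly
#'   connected both within and among modules.
#'
#' @param scores A tibble of role scores (from [role_scores()]), with at
#'   least columns `species`, `c`, `z`.
#' @param thresholds A [critical_thresholds()] object.
#' @return A `role_assignment` tibble: the scores plus `c_critical`,
#'   `z_critical` and a `role` factor.
#' @export
assign_roles <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "role_thresholds"))
  scores <- tibble::as_tibble(scores)
  if (!all(c("species", "c", "z") %in% names(scores))) {
    abort("`scores` must have columns species, c and z")
  }
  if (!all(is.finite(thresholds$c_critical), is.finite(thresholds$z_critical))) {
    abort("thresholds must be finite")
  }
  high_c <- scores$c > thresholds$c_critical
  high_z <- scores$z > thresholds$z_critical
  role <- dplyr::case_when(
    high_c & high_z ~ "network_hub",
    high_c & !high_z ~ "connector",
    !high_c & high_z ~ "module_hub",
    TRUE ~ "peripheral"
  )
  out <- scores |>
    dplyr::mutate(
      c_critical = thresholds$c_critical,
      z_critical = thresholds$z_critical,
      role = factor(role, levels = role_levels)
    )
  class(out) <- c("role_assignment", class(out))
  out
}

#' Write a role-assignment table as TSV
#'
#' @param roles A `role_assignment` tibble from [assign_roles()].
#' @param path Output TSV path.
#' @return `roles`, invisibly.
#' @export
write_roles <- function(roles, path) {
  readr::write_tsv(tibble::as_tibble(roles), path, progress = FALSE)
  invisible(roles)
}
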