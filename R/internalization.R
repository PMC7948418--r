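#' Quantify agonist-induced receptor internalization from Mesna plates
#'
#' For each (receptor, block) stratum the internalized fraction of each
#' agonist is
#' \deqn{\frac{S_{Mesna,ligand} - S_{Mesna,vehicle}}{S_{noMesna} - S_{Mesna,vehicle}}}
#' i.e. the Mesna-protected signal, corrected for nonspecific fluorescence
#' (Mesna + vehicle wells), as a fraction of the specific cleavable surface
#' pool. This convention gives exactly 0 for a ligand causing no
#' internalization and exactly 1 for complete protection.
#' `subtract_background = FALSE` instead divides by the raw no-Mesna signal.
#'
#' @param table Tibble with columns `receptor`, `ligand`, `mesna` (logical),
#'   `intensity`, `block` (e.g. from [simulate_internalization_plate()] or
#'   a well-intensity CSV).
#' @param subtract_background Subtract nonspecific signal from the
#'   denominator as well as the numerator (default TRUE)?
#' @return List with `per_block` (receptor, ligand, block, fraction) and
#'   `summary` (mean ± SEM over blocks), both tibbles.
#' @export
quantify_internalization <- function(table, subtract_background = TRUE) {
  req <- c("receptor", "ligand", "mesna", "intensity", "block")
  if (!all(req %in% names(table))) {
    abort(paste("`table` must have columns:", paste(req, collapse = ", ")))
  }
  if (any(table$intensity < 0)) abort("Intensities must be non-negative.")

  strata <- table |>
    dplyr::group_by(.data$receptor, .data$block) |>
    dplyr::group_modify(function(d, key) {
      s_nomesna <- mean(d$intensity[!d$mesna])
      veh <- d$intensity[d$mesna & d$ligand == "vehicle"]
      if (length(veh) == 0) {
        abort("Each (receptor, block) stratum needs Mesna + vehicle wells.")
      }
      if (!any(!d$mesna)) {
        abort("Each (receptor, block) stratum needs no-Mesna wells.")
      }
      nonspec <- mean(veh)
      denom <- if (subtract_background) s_nomesna - nonspec else s_nomesna
      agonists <- setdiff(unique(d$ligand), "vehicle")
      tibble(
        ligand = agonists,
        fraction = vapply(agonists, function(a) {
          (mean(d$intensity[d$mesna & d$ligand == a]) - nonspec) / denom
        }, 0, USE.NAMES = FALSE),
        denom = denom
      )
    }) |>
    dplyr::ungroup()

  bad <- strata$denom <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d stratum/strata with non-positive denominator.",
                 sum(bad)))
    strata <- strata[!bad, , drop = FALSE]
  }
  per_block <- dplyr::select(strata, "receptor", "ligand", "block", "fraction")
  summary <- per_block |>
    dplyr::group_by(.data$receptor, .data$ligand) |>
    dplyr::summarise(
      sem = sem(.data$fraction), fraction = mean(.data$fraction),
      n_blocks = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::relocate("fraction", .before = "sem")
  list(per_block = per_block, summary = summary)
}

#' Relative receptor surface expression from no-Mesna wells
#'
#' Background-subtracted no-Mesna intensity (nonspecific background taken
#' from the Mesna + vehicle wells) per receptor, expressed relative to the
#' reference receptor within each block, then summarized across blocks.
#'
#' @inheritParams quantify_internalization
#' @param reference_receptor Receptor whose surface signal defines 1.0.
#' @return List with `per_block` and `summary` tibbles of relative surface
#'   expression.
#' @export
surface_expression <- function(table, reference_receptor) {
  if (!reference_receptor %in% table$receptor) {
    abort(sprintf("Reference receptor '%s' absent from `table`.",
                  reference_receptor))
  }
  spec <- table |>
    dplyr::group_by(.data$receptor, .data$block) |>
    dplyr::summarise(
      specific = mean(.data$intensity[!.data$mesna]) -
        mean(.data$intensity[.data$mesna & .data$ligand == "vehicle"]),
      .groups = "drop"
    )
  ref <- spec |>
    dplyr::filter(.data$receptor == reference_receptor) |>
    dplyr::select("block", ref_specific = "specific")
  per_block <- spec |>
    dplyr::inner_join(ref, by = "block") |>
    dplyr::mutate(surface = .data$specific / .data$ref_specific) |>
    dplyr::select("receptor", "block", "surface")
  summary <- per_block |>
    dplyr::group_by(.data$receptor) |>
    dplyr::summarise(sem = sem(.data$surface), surface = mean(.data$surface),
                     n_blocks = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("surface", .before = "sem")
  list(per_block = per_block, summary = summary)
}

#' Cross-receptor log2 fold-change response table
#'
#' Normalizes per-receptor summary responses to a reference receptor within
#' each readout and expresses them as log2 fold changes — the cross-receptor
#' heatmap convention. Responses that are absent or not positive cannot be
#' expressed on the log scale and are flagged `below_range` (the "marked
#' with an X" convention) rather than given a number.
#'
#' @param responses Tibble with columns `receptor`, `readout`, `value`.
#' @param reference_receptor Receptor defining log2 fold change 0.
#' @return Input tibble with `log2_fc` and `below_range` columns.
#' @export
receptor_response_heatmap <- function(responses, reference_receptor) {
  req <- c("receptor", "readout", "value")
  if (!all(req %in% names(responses))) {
    abort(paste("`responses` must have columns:", paste(req, collapse = ", ")))
  }
  ref <- responses |>
    dplyr::filter(.data$receptor == reference_receptor) |>
    dplyr::select("readout", ref_value = "value")
  if (nrow(ref) == 0) abort("Reference receptor absent from `responses`.")
  if (any(!is.finite(ref$ref_value) | ref$ref_value <= 0)) {
    abort("Reference receptor responses must be positive.")
  }
  responses |>
    dplyr::inner_join(ref, by = "readout") |>
    dplyr::mutate(
      below_range = !is.finite(.data$value) | .data$value <= 0,
      log2_fc = dplyr::if_else(.data$below_range, NA_real_,
                               log2(.data$value / .data$ref_value))
    ) |>
    dplyr::select(-"ref_value")
}
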