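#' Per-animal spine morphology summaries
#'
#' Aggregates spine-level STED measurements to per-animal means (the unit
#' of statistical comparison); spine density (spines per 10 um) is only
#' reported when dendrite lengths are provided — it is never inferred.
#' Spines without an animal id are excluded with a message.
#'
#' @param spines Tibble with columns `animal_id`, `genotype`,
#'   `head_width`, `neck_length`, optionally `dendrite_length` (um of
#'   dendrite represented by each spine row).
#' @return Tibble, one row per animal: `genotype`, `n_spines`,
#'   `head_width`, `neck_length`, `density_per10um` (`NA` without
#'   lengths).
#' @export
morph_summary <- function(spines) {
  bad <- is.na(spines$animal_id) | !nzchar(as.character(spines$animal_id))
  if (any(bad)) {
    message(sum(bad), " spine(s) without animal_id excluded")
    spines <- spines[!bad, , drop = FALSE]
  }
  has_len <- "dendrite_length" %in% names(spines) &&
    !all(is.na(spines$dendrite_length))
  spines |>
    dplyr::group_by(.data$animal_id, .data$genotype) |>
    dplyr::summarise(
      n_spines = dplyr::n(),
      head_width = mean(.data$head_width),
      neck_length = mean(.data$neck_length),
      density_per10um = if (has_len)
        10 * dplyr::n() / sum(.data$dendrite_length) else NA_real_,
      .groups = "drop")
}

#' Structure-function regression per genotype
#'
#' Least-squares regression of uEPSC amplitude on spine head width for
#' uncaged, responsive spines, per genotype (spines pooled within
#' genotype), with a sum-of-squares F-test of slope equality between
#' genotypes via [curve_compare_ftest()].
#'
#' @param spines Morphology tibble with `head_width`, `ampa_amp`,
#'   `genotype`, `uncaged` columns.
#' @return List: `per_genotype` tibble (`genotype`, `slope` pA/um,
#'   `intercept`, `r2`, `p`, `n`), `slope_test` ([curve_compare_ftest()]
#'   result).
#' @export
structure_function <- function(spines) {
  sp <- spines[spines$uncaged & !is.na(spines$ampa_amp), , drop = FALSE]
  tab <- split(sp, sp$genotype)
  if (any(vapply(tab, nrow, integer(1)) < 3))
    stop("need at least 3 linked spines per genotype", call. = FALSE)
  per <- dplyr::bind_rows(lapply(names(tab), function(g) {
    f <- stats::lm(ampa_amp ~ head_width, data = tab[[g]])
    sm <- summary(f)
    tibble::tibble(genotype = g, slope = unname(stats::coef(f)[2]),
                   intercept = unname(stats::coef(f)[1]),
                   r2 = sm$r.squared, p = sm$coefficients[2, 4],
                   n = nrow(tab[[g]]))
  }))
  test <- curve_compare_ftest(sp, y = "ampa_amp", x = "head_width",
                              group = "genotype", model = "linear")
  list(per_genotype = per, slope_test = test)
}

#' Multi-innervated-spine incidence per animal
#'
#' Per-animal incidence is the pooled ratio of multi-innervated spines to
#' all spines over that animal's dendrites, times 100; group summaries
#' average over animals (animals, not spines, are the unit). Animals with
#' zero reconstructed spines are excluded.
#'
#' @param records Ultrastructure tibble: `animal_id`, `genotype`,
#'   `dendrite_id`, `n_spines`, `n_mis`.
#' @return List: `per_animal` tibble (`animal_id`, `genotype`,
#'   `n_spines`, `pct_mis`), `group` tibble (`genotype`, `mean_pct`,
#'   `sem`, `n_animals`).
#' @export
mis_incidence <- function(records) {
  stopifnot(all(records$n_mis <= records$n_spines))
  per <- records |>
    dplyr::group_by(.data$animal_id, .data$genotype) |>
    dplyr::summarise(n_spines = sum(.data$n_spines),
                     pct_mis = 100 * sum(.data$n_mis) / sum(.data$n_spines),
                     .groups = "drop") |>
    dplyr::filter(.data$n_spines > 0)
  grp <- per |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(mean_pct = mean(.data$pct_mis),
                     sem = stats::sd(.data$pct_mis) / sqrt(dplyr::n()),
                     n_animals = dplyr::n(), .groups = "drop")
  list(per_animal = per, group = grp)
}
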