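#' Per-cell feature tables from a cohort
#'
#' Each extractor runs the corresponding sweep-level analysis on every
#' cell holding that protocol and returns a tidy tibble (one row per cell
#' or per cell x condition) carrying the nesting ids, ready for
#' [hierarchical_compare()].
#'
#' @param cohort A cohort tibble.
#' @return A tibble of per-cell features.
#' @name extractors
NULL

.meta_cols <- c("cell_id", "genotype", "animal_id", "litter_id", "slice_id")

.rows_for <- function(cohort, protocol) {
  which(cohort$protocol == protocol)
}

#' @rdname extractors
#' @export
extract_intrinsic <- function(cohort) {
  rows <- .rows_for(cohort, "steps")
  out <- lapply(rows, function(i) {
    chirp_i <- which(cohort$cell_id == cohort$cell_id[i] &
                       cohort$protocol == "chirp")
    chirp <- if (length(chirp_i)) cohort$sweeps[[chirp_i]][[1]] else NULL
    dplyr::bind_cols(tibble::as_tibble(cohort[i, .meta_cols]),
                     intrinsic_profile(cohort$sweeps[[i]], chirp))
  })
  dplyr::bind_rows(out)
}

#' @rdname extractors
#' @param response Passed to [fit_activation()].
#' @export
extract_ih_fits <- function(cohort, response = "conductance") {
  rows <- .rows_for(cohort, "vsteps")
  out <- lapply(rows, function(i) {
    curve <- extract_ih(cohort$sweeps[[i]])
    fit <- fit_activation(curve, response = response)
    dplyr::bind_cols(
      tibble::as_tibble(cohort[i, .meta_cols]),
      tibble::tibble(V12 = fit$V12, k = fit$k, I_max = fit$I_max,
                     ih_max_pA = max(curve$ih_amp)))
  })
  dplyr::bind_rows(out)
}

#' @rdname extractors
#' @export
extract_spines <- function(cohort) {
  rows <- .rows_for(cohort, "uncaging")
  out <- lapply(rows, function(i) {
    sp <- spine_results(cohort$sweeps[[i]])
    dplyr::bind_cols(tibble::as_tibble(cohort[i, .meta_cols])[
      rep(1, nrow(sp)), ], sp)
  })
  dplyr::bind_rows(out)
}

#' @rdname extractors
#' @export
extract_summation <- function(cohort) {
  rows <- .rows_for(cohort, "ensemble")
  out <- lapply(rows, function(i) {
    sw <- cohort$sweeps[[i]]
    n1 <- attr(sw, "n_singles")
    singles <- vapply(sw[seq_len(n1)], function(s)
      as.numeric(measure_uepsc(s, window = "uepsp")), numeric(1))
    ens <- sw[(n1 + 1):length(sw)]
    silent <- if ("synapses" %in% names(cohort)) {
      syn <- cohort$synapses[[i]]
      syn$silent[((seq_len(n1) - 1L) %% nrow(syn)) + 1L]
    } else NULL
    sm <- summation_analysis(ens, singles, silent = silent)
    dplyr::bind_cols(
      tibble::as_tibble(cohort[i, .meta_cols]),
      tibble::tibble(norm_slope = sm$norm_slope,
                     linearity_slope = sm$linearity_slope,
                     spines_to_ap = sm$spines_to_ap,
                     spines_to_ap_excl_silent = sm$spines_to_ap_excl_silent,
                     censored = sm$censored))
  })
  dplyr::bind_rows(out)
}

#' @rdname extractors
#' @export
extract_trains <- function(cohort) {
  rows <- .rows_for(cohort, "train")
  out <- lapply(rows, function(i) {
    sw <- cohort$sweeps[[i]]
    fr <- vapply(sw, function(s) attr(s, "train_freq"), numeric(1))
    dplyr::bind_rows(lapply(unique(fr), function(f) {
      dplyr::bind_cols(tibble::as_tibble(cohort[i, .meta_cols]),
                       train_spike_probability(sw[fr == f], freq = f))
    }))
  })
  dplyr::bind_rows(out)
}

#' @rdname extractors
#' @export
extract_mepsc <- function(cohort) {
  rows <- .rows_for(cohort, "mepsc")
  out <- lapply(rows, function(i) {
    sw <- cohort$sweeps[[i]]
    dplyr::bind_rows(lapply(sw, function(s) {
      kind <- if (!is.na(s$holding) && s$holding > 0) "nmda" else "ampa"
      ev <- detect_events(s)
      st <- event_stats(ev, sweep_duration(s))
      dplyr::bind_cols(tibble::as_tibble(cohort[i, .meta_cols]),
                       tibble::tibble(receptor = kind), st)
    }))
  })
  dplyr::bind_rows(out)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic-cohort run with its
#' default; the realised configuration is serialised into the output
#' bundle for provenance.
#'
#' @param n_animals,cells_per_animal Cohort size per genotype.
#' @param protocols Protocols to simulate and analyse.
#' @param seed Master seed.
#' @param outdir Optional output directory for CSV/JSON tables.
#' @param structure_animals Animals per genotype in the morphology /
#'   ultrastructure tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_animals = 3, cells_per_animal = 2,
                            protocols = c("steps", "vsteps", "uncaging"),
                            seed = 1, outdir = NULL,
                            structure_animals = c(WT = 3, KO = 7)) {
  structure(list(n_animals = n_animals,
                 cells_per_animal = cells_per_animal,
                 protocols = protocols, seed = seed, outdir = outdir,
                 structure_animals = structure_animals),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a WT/KO cohort, extracts every feature table implied by the
#' configured protocols, runs the genotype comparisons, and (when
#' `config$outdir` is set) writes the tables as CSV plus a JSON summary.
#' Identical configuration and seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_bundle`: list with `cohort`, `features` (named
#'   list of tibbles), `comparisons` (tibble), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(config$protocols)) stop("no protocols configured",
                                      call. = FALSE)
  cohort <- generate_cohort(n_animals = config$n_animals,
                            cells_per_animal = config$cells_per_animal,
                            protocols = config$protocols,
                            seed = config$seed)
  feats <- list()
  comps <- list()
  add_cmp <- function(name, tab, col, family = "normal", higher_in = NULL) {
    d <- tibble::tibble(value = tab[[col]], genotype = tab$genotype,
                        animal = tab$animal_id, litter = tab$litter_id,
                        slice = tab$slice_id)
    d <- d[is.finite(d$value), ]
    cmp <- tryCatch(hierarchical_compare(d, family = family),
                    error = function(e) NULL)
    if (is.null(cmp)) return(invisible())
    means <- tapply(d$value, d$genotype, mean)
    comps[[length(comps) + 1L]] <<- tibble::tibble(
      contrast = name, mean_WT = unname(means["WT"]),
      mean_KO = unname(means["KO"]), method = cmp$method,
      statistic = cmp$statistic, p_value = cmp$p_value)
  }

  if ("steps" %in% config$protocols) {
    feats$intrinsic <- extract_intrinsic(cohort)
    add_cmp("input_resistance", feats$intrinsic, "R_I", "log-normal")
    add_cmp("rheobase", feats$intrinsic, "rheobase")
    add_cmp("sag_pct", feats$intrinsic, "sag_pct")
  }
  if ("vsteps" %in% config$protocols) {
    feats$ih <- extract_ih_fits(cohort)
    add_cmp("hcn_V12", feats$ih, "V12")
  }
  if ("uncaging" %in% config$protocols) {
    feats$spines <- extract_spines(cohort)
    resp <- feats$spines[feats$spines$call == "responsive", ]
    add_cmp("uepsc_amplitude", resp, "ampa_amp", "log-normal")
    silent <- feats$spines |>
      dplyr::group_by(dplyr::across(dplyr::all_of(.meta_cols))) |>
      dplyr::summarise(value = sum(.data$call == "silent"),
                       trials = dplyr::n(), .groups = "drop")
    cmp <- tryCatch(hierarchical_compare(
      tibble::tibble(value = silent$value, trials = silent$trials,
                     genotype = silent$genotype, animal = silent$animal_id,
                     litter = silent$litter_id),
      family = "binomial"), error = function(e) NULL)
    if (!is.null(cmp)) {
      pf <- tapply(silent$value / silent$trials, silent$genotype, mean)
      comps[[length(comps) + 1L]] <- tibble::tibble(
        contrast = "silent_fraction", mean_WT = unname(pf["WT"]),
        mean_KO = unname(pf["KO"]), method = cmp$method,
        statistic = cmp$statistic, p_value = cmp$p_value)
    }
  }
  if ("ensemble" %in% config$protocols) {
    feats$summation <- extract_summation(cohort)
    add_cmp("spines_to_ap", feats$summation, "spines_to_ap")
    add_cmp("linearity_slope", feats$summation, "linearity_slope")
  }
  if ("train" %in% config$protocols) {
    feats$trains <- extract_trains(cohort)
    for (f in unique(feats$trains$frequency))
      add_cmp(sprintf("p_spike_%gHz", f),
              feats$trains[feats$trains$frequency == f, ], "p_spike")
  }
  if ("mepsc" %in% config$protocols) {
    feats$mepsc <- extract_mepsc(cohort)
    for (r in unique(feats$mepsc$receptor))
      add_cmp(sprintf("mepsc_%s_frequency", r),
              feats$mepsc[feats$mepsc$receptor == r, ], "frequency")
  }
  if ("chirp" %in% config$protocols && !is.null(feats$intrinsic) &&
      "f_res" %in% names(feats$intrinsic))
    add_cmp("resonant_frequency", feats$intrinsic, "f_res")

  # structure tables are sample-level (no sweeps); sizes follow config
  str_wt <- generate_structure(genotype_preset("WT"),
                               config$structure_animals[["WT"]],
                               seed = config$seed + 101L)
  str_ko <- generate_structure(genotype_preset("KO"),
                               config$structure_animals[["KO"]],
                               seed = config$seed + 202L)
  feats$morphology <- dplyr::bind_rows(str_wt$morphology,
                                       str_ko$morphology)
  feats$ultrastructure <- dplyr::bind_rows(str_wt$ultrastructure,
                                           str_ko$ultrastructure)
  mis <- mis_incidence(feats$ultrastructure)
  tt <- stats::t.test(pct_mis ~ genotype, data = mis$per_animal)
  comps[[length(comps) + 1L]] <- tibble::tibble(
    contrast = "mis_incidence",
    mean_WT = mis$group$mean_pct[mis$group$genotype == "WT"],
    mean_KO = mis$group$mean_pct[mis$group$genotype == "KO"],
    method = "Welch t-test (per-animal)", statistic = unname(tt$statistic),
    p_value = tt$p.value)

  comparisons <- dplyr::bind_rows(comps)
  bundle <- structure(list(cohort = cohort, features = feats,
                           comparisons = comparisons, config = config),
                      class = "pipeline_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n  feature tables:",
      paste(names(x$features), collapse = ", "), "\n")
  print(x$comparisons)
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' One CSV per feature table, `comparisons.csv`, and `summary.json`
#' containing the configuration and the comparison table.
#'
#' @param bundle A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$features)) {
    tab <- bundle$features[[nm]]
    tab <- tab[!vapply(tab, is.list, logical(1))]
    utils::write.csv(tab, file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         comparisons = bundle$comparisons),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(outdir)
}
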