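#' Assemble a cohort tibble from cell records
#'
#' A cohort is a tibble with one row per (cell, protocol) group and the
#' sweeps held in a list-column, so it pipes through dplyr verbs directly.
#' Required columns: `cell_id`, `genotype` (factor WT/KO), `animal_id`,
#' `litter_id`, `slice_id`, `protocol`, `sweeps` (list of lists of sweeps).
#' Simulated cohorts additionally carry a `params` list-column with the
#' ground-truth simulator parameters and gain provenance attributes
#' (`seed`, `preset`).
#'
#' @param cells A data frame with the columns above.
#' @param seed,preset Optional provenance recorded as attributes.
#' @return A `spq_cohort` tibble.
#' @export
new_cohort <- function(cells, seed = NULL, preset = NULL) {
  cells <- tibble::as_tibble(cells)
  need <- c("cell_id", "genotype", "animal_id", "litter_id", "slice_id",
            "protocol", "sweeps")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- cells[c("cell_id", "animal_id", "litter_id", "slice_id")]
  if (any(vapply(ids, function(x) any(!nzchar(as.character(x)) | is.na(x)),
                 logical(1))))
    stop("cohort ids must be non-empty and non-missing", call. = FALSE)
  if (anyDuplicated(unique(cells[c("cell_id", "protocol")])))
    stop("each cell may appear at most once per protocol", call. = FALSE)
  out <- structure(cells, class = c("spq_cohort", class(cells)))
  attr(out, "seed") <- seed
  attr(out, "preset") <- preset
  out
}

#' Sweeps of one cell and protocol
#'
#' @param cohort A cohort tibble.
#' @param cell_id,protocol Selectors.
#' @return The list of sweeps for that cell and protocol.
#' @export
cohort_sweeps <- function(cohort, cell_id, protocol) {
  i <- which(cohort$cell_id == cell_id & cohort$protocol == protocol)
  if (!length(i)) stop("no sweeps for cell ", cell_id, " / ", protocol,
                       call. = FALSE)
  cohort$sweeps[[i[1]]]
}

#' Per-cell metadata table of a cohort
#'
#' @param cohort A cohort tibble.
#' @return One row per cell: ids and genotype.
#' @export
cohort_cells <- function(cohort) {
  dplyr::distinct(
    tibble::as_tibble(cohort)[c("cell_id", "genotype", "animal_id",
                                "litter_id", "slice_id")])
}

#' Quality-control gate for a recorded cell
#'
#' Applies the standard whole-cell rejection rules: holding current above
#' 150 pA in voltage clamp, membrane potential depolarised beyond -50 mV,
#' series resistance above 30 MOhm, or series-resistance drift above 20%
#' over the recording. All comparisons are strict (a cell sitting exactly
#' on a limit is accepted). A missing measurement yields an `"unknown"`
#' verdict rather than silent acceptance.
#'
#' @param cells A data frame with one row per cell and (any of) the
#'   measurement columns `i_hold_pA`, `vm_mV`, `rs_MOhm`, `rs_end_MOhm`.
#' @param qc Named list of limits; defaults follow the standard criteria:
#'   `i_hold_max = 150` (pA), `vm_max = -50` (mV), `rs_max = 30` (MOhm),
#'   `rs_drift_max = 0.20` (fractional change, computed from
#'   `rs_end_MOhm / rs_MOhm - 1`).
#' @return The input with `qc_verdict` (`"accept"`, `"reject"`,
#'   `"unknown"`) and `qc_reasons` (comma-separated machine-readable
#'   reasons) columns added.
#' @export
reject_cell <- function(cells, qc = qc_defaults()) {
  cells <- tibble::as_tibble(cells)
  get0n <- function(nm) if (nm %in% names(cells)) cells[[nm]] else
    rep(NA_real_, nrow(cells))
  ihold <- get0n("i_hold_pA"); vm <- get0n("vm_mV")
  rs0 <- get0n("rs_MOhm"); rs1 <- get0n("rs_end_MOhm")
  drift <- abs(rs1 / rs0 - 1)
  verdict <- character(nrow(cells)); reasons <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- character()
    unknown <- FALSE
    chk <- function(x, lim, test, reason) {
      if (is.na(x)) { unknown <<- TRUE } else if (test(x, lim)) r <<- c(r, reason)
    }
    chk(ihold[i], qc$i_hold_max, function(x, l) abs(x) > l, "holding_current")
    chk(vm[i],    qc$vm_max,     function(x, l) x > l,      "membrane_potential")
    chk(rs0[i],   qc$rs_max,     function(x, l) x > l,      "series_resistance")
    chk(drift[i], qc$rs_drift_max, function(x, l) x > l,    "series_drift")
    if (length(r)) {
      verdict[i] <- "reject"; reasons[i] <- paste(r, collapse = ",")
    } else if (unknown) {
      verdict[i] <- "unknown"; reasons[i] <- "missing_measurement"
    } else {
      verdict[i] <- "accept"; reasons[i] <- ""
    }
  }
  cells$qc_verdict <- verdict
  cells$qc_reasons <- reasons
  cells
}

#' Default whole-cell QC limits
#' @return Named list of limits used by [reject_cell()].
#' @export
qc_defaults <- function() {
  list(i_hold_max = 150, vm_max = -50, rs_max = 30, rs_drift_max = 0.20)
}
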