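#' Write a cohort to a plain-text directory
#'
#' The canonical on-disk dialect is a directory of CSV files plus a JSON
#' provenance sidecar: `cells.csv` (per-cell metadata), `sweeps.csv` (sweep
#' index with dt/mode/holding), `markers.csv`, one trace CSV per sweep
#' under `traces/`, and optional `params.json` with simulator ground truth.
#' All floating-point values are written with 17 significant digits, so a
#' write/read round trip reproduces every double bit-exactly.
#'
#' @param cohort A cohort tibble from [new_cohort()] or [generate_cohort()].
#' @param path Directory to create (must not exist or be empty).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (dir.exists(path) && length(list.files(path)))
    stop("refusing to write into non-empty directory: ", path, call. = FALSE)
  dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.17g", x)

  utils::write.csv(cohort_cells(cohort), file.path(path, "cells.csv"),
                   row.names = FALSE)

  idx <- list(); mk <- list()
  for (i in seq_len(nrow(cohort))) {
    sl <- cohort$sweeps[[i]]
    for (k in seq_along(sl)) {
      sw <- sl[[k]]
      f <- sprintf("%s__%s__%03d.csv", cohort$cell_id[i], cohort$protocol[i], k)
      df <- data.frame(value = fmt(sw$samples), stimulus = fmt(sw$stimulus))
      utils::write.csv(df, file.path(path, "traces", f), row.names = FALSE,
                       quote = FALSE)
      idx[[length(idx) + 1L]] <- data.frame(
        cell_id = cohort$cell_id[i], protocol = cohort$protocol[i],
        sweep_index = k, file = f, dt = fmt(sw$dt), mode = sw$mode,
        holding = fmt(sw$holding), n = length(sw$samples))
      if (nrow(sw$markers))
        mk[[length(mk) + 1L]] <- data.frame(
          cell_id = cohort$cell_id[i], protocol = cohort$protocol[i],
          sweep_index = k, label = sw$markers$label,
          time = fmt(sw$markers$time))
    }
  }
  utils::write.csv(do.call(rbind, idx), file.path(path, "sweeps.csv"),
                   row.names = FALSE, quote = FALSE)
  mk <- if (length(mk)) do.call(rbind, mk) else
    data.frame(cell_id = character(), protocol = character(),
               sweep_index = integer(), label = character(), time = character())
  utils::write.csv(mk, file.path(path, "markers.csv"), row.names = FALSE,
                   quote = FALSE)

  if ("params" %in% names(cohort)) {
    pc <- cohort[!duplicated(cohort$cell_id), ]
    pl <- stats::setNames(pc$params, pc$cell_id)
    jsonlite::write_json(pl, file.path(path, "params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  prov <- list(format = "spinephys_csv_dir_v1",
               seed = attr(cohort, "seed"), preset = attr(cohort, "preset"))
  jsonlite::write_json(prov, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a cohort from disk
#'
#' Reads the CSV directory dialect written by [write_cohort()]. A sweep
#' whose trace file is malformed (unequal or unparseable columns) is
#' rejected with a message while the rest of the cohort loads. The `nwb`
#' and `hdf5_sweeptable` dialects are recognised names but not provided by
#' this build; requesting them raises an informative error.
#'
#' @param path Directory written by [write_cohort()].
#' @param format Dialect; only `"csv_dir"` is available.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, format = c("csv_dir", "nwb", "hdf5_sweeptable")) {
  format <- match.arg(format)
  if (format != "csv_dir")
    stop("dialect '", format, "' requires an HDF5 reader, which this build ",
         "does not include; use format = 'csv_dir'", call. = FALSE)
  if (!dir.exists(path)) stop("no such cohort directory: ", path, call. = FALSE)
  for (f in c("cells.csv", "sweeps.csv", "markers.csv"))
    if (!file.exists(file.path(path, f)))
      stop("cohort is missing required file: ", f, call. = FALSE)

  cells <- utils::read.csv(file.path(path, "cells.csv"),
                           colClasses = "character")
  need <- c("cell_id", "genotype", "animal_id", "litter_id", "slice_id")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells.csv is missing metadata field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  idx <- utils::read.csv(file.path(path, "sweeps.csv"),
                         colClasses = c(dt = "character",
                                        holding = "character"))
  mk <- utils::read.csv(file.path(path, "markers.csv"),
                        colClasses = c(time = "character"))

  params <- NULL
  pf <- file.path(path, "params.json")
  if (file.exists(pf))
    params <- jsonlite::read_json(pf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)

  rows <- list()
  key <- interaction(idx$cell_id, idx$protocol, drop = TRUE)
  for (g in levels(key)) {
    sub <- idx[key == g, , drop = FALSE]
    sub <- sub[order(sub$sweep_index), , drop = FALSE]
    sweeps <- list()
    for (k in seq_len(nrow(sub))) {
      tr <- tryCatch(
        utils::read.csv(file.path(path, "traces", sub$file[k]),
                        colClasses = "numeric"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(tr) || !all(c("value", "stimulus") %in% names(tr)) ||
          anyNA(tr$value) || anyNA(tr$stimulus) ||
          nrow(tr) != sub$n[k]) {
        message("rejecting malformed sweep trace: ", sub$file[k])
        next
      }
      mrows <- mk[mk$cell_id == sub$cell_id[k] &
                  mk$protocol == sub$protocol[k] &
                  mk$sweep_index == sub$sweep_index[k], , drop = FALSE]
      sweeps[[length(sweeps) + 1L]] <- new_sweep(
        tr$value, tr$stimulus, as.numeric(sub$dt[k]), sub$mode[k],
        markers = tibble::tibble(label = as.character(mrows$label),
                                 time = as.numeric(mrows$time)),
        holding = as.numeric(sub$holding[k]))
    }
    meta <- cells[cells$cell_id == sub$cell_id[1], , drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = meta$cell_id, genotype = meta$genotype,
      animal_id = meta$animal_id, litter_id = meta$litter_id,
      slice_id = meta$slice_id, protocol = sub$protocol[1],
      sweeps = list(sweeps))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$cell_id, out$protocol), ]
  if (!is.null(params))
    out$params <- params[out$cell_id]
  prov <- jsonlite::read_json(file.path(path, "cohort.json"),
                              simplifyVector = TRUE)
  new_cohort(out, seed = prov$seed, preset = prov$preset)
}
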