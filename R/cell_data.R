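## Readers and writers for the delimited cell and patient tables emitted by
## phenotyping software (and by the package's own simulator). Field
## separator (comma or tab) is auto-detected from the header line.

.CELL_COLUMNS <- c("cell_id", "x_um", "y_um", "region", "core_id",
                   "patient_id", "panel")
.PATIENT_COLUMNS <- c("patient_id", "rfs_months", "event", "age_group",
                      "gender", "histology", "smoking_index_group",
                      "stage_group")

.COVARIATE_LEVELS <- list(
  age_group = c("<=65", ">65"),
  gender = c("Male", "Female"),
  histology = c("LUAD", "LUSC"),
  smoking_index_group = c("<400", ">=400"),
  stage_group = c("I-II", "III"))

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.readDelim <- function(path) {
  sep <- .sniffSep(path)
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a per-cell table into CellCore objects
#'
#' Reads a delimited text table (comma or tab, auto-detected) of segmented
#' cells with columns `cell_id, x_um, y_um, region, core_id, patient_id,
#' panel` plus the panel's marker columns coded 0/1, and groups the cells
#' into one [CellCore] per `core_id`. Unknown extra columns are preserved
#' in the cell data. Malformed rows are reported with their file line
#' numbers.
#'
#' @param path File path.
#' @param panel Expected panel (`"panel1"`/`"panel2"`); `NULL` takes the
#'   table's `panel` column.
#' @param window Core window as `c(width, height)` um (origin 0) or a named
#'   `xmin/xmax/ymin/ymax` vector; the window fixes the area used for
#'   densities. Defaults to the 1 mm-square TMA frame.
#' @return Named list of [CellCore] objects (one per core).
#' @export
readCellTable <- function(path, panel = NULL, window = c(1000, 1000)) {
  df <- .readDelim(path)
  missing <- setdiff(.CELL_COLUMNS, colnames(df))
  if (length(missing))
    stop("cell table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(panel)) {
    panel <- unique(df$panel)
    if (length(panel) != 1L)
      stop("table mixes panels (", paste(panel, collapse = ", "),
           "); read panels separately or pass `panel`")
  }
  if (!panel %in% c("panel1", "panel2"))
    stop("unknown panel '", panel, "'")
  markers <- panelMarkers(panel)
  missing <- setdiff(markers, colnames(df))
  if (length(missing))
    stop("cell table lacks marker column(s) for ", panel, ": ",
         paste(missing, collapse = ", "))

  ## row-level validation, reporting file line numbers (header is line 1)
  lineno <- seq_len(nrow(df)) + 1L
  bad <- function(cond, what) {
    if (any(cond))
      stop("malformed cell table rows (", what, ") at line(s) ",
           paste(head(lineno[cond], 10L), collapse = ", "),
           if (sum(cond) > 10L) " ..." else "", call. = FALSE)
  }
  badRegion <- !df$region %in% c("IM", "TC")
  if (any(badRegion))
    stop("unknown region label(s) ",
         paste(unique(df$region[badRegion]), collapse = ", "),
         " at line(s) ", paste(head(lineno[badRegion], 10L), collapse = ", "),
         "; region must be IM or TC", call. = FALSE)
  bad(!is.finite(suppressWarnings(as.numeric(df$x_um))) |
      !is.finite(suppressWarnings(as.numeric(df$y_um))),
      "non-finite coordinates")
  for (mk in markers)
    bad(!df[[mk]] %in% c(0, 1), paste0("marker ", mk, " not 0/1"))

  cores <- split(df, df$core_id)
  out <- lapply(cores, function(cd) {
    if (length(unique(cd$region)) != 1L)
      stop("core ", cd$core_id[1], " spans multiple regions")
    if (length(unique(cd$patient_id)) != 1L)
      stop("core ", cd$core_id[1], " spans multiple patients")
    cells <- data.frame(cell_id = as.character(cd$cell_id),
                        x = as.numeric(cd$x_um), y = as.numeric(cd$y_um),
                        stringsAsFactors = FALSE)
    for (mk in markers) cells[[mk]] <- cd[[mk]] == 1
    extra <- setdiff(colnames(cd), c(.CELL_COLUMNS, markers))
    for (col in extra) cells[[col]] <- cd[[col]]
    CellCore(cells, coreId = cd$core_id[1], patientId = cd$patient_id[1],
             region = cd$region[1], panel = panel, bounds = window)
  })
  out[order(names(out))]
}

#' Write CellCore objects to a delimited cell table
#'
#' Inverse of [readCellTable()]; `readCellTable(writeCellTable(...))` is
#' the identity on the cell set up to row order.
#'
#' @param cores A [CellCore] or list of them.
#' @param path Output file.
#' @param sep Field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cores, path, sep = ",") {
  if (is(cores, "CellCore")) cores <- list(cores)
  rows <- lapply(cores, function(core) {
    cl <- cells(core)
    markers <- panelMarkers(panel(core))
    out <- data.frame(cell_id = cl$cell_id, x_um = cl$x, y_um = cl$y,
                      region = region(core), core_id = coreId(core),
                      patient_id = patientId(core), panel = panel(core),
                      stringsAsFactors = FALSE)
    for (mk in markers) out[[mk]] <- as.integer(cl[[mk]])
    extra <- setdiff(colnames(cl), c("cell_id", "x", "y", markers))
    for (col in extra) out[[col]] <- cl[[col]]
    out
  })
  write.csv2_ <- function(d) write.table(
    d, path, sep = sep, row.names = FALSE, quote = FALSE)
  write.csv2_(do.call(rbind, rows))
  invisible(path)
}

#' Read a per-patient clinical table
#'
#' Columns: `patient_id, rfs_months, event, age_group, gender, histology,
#' smoking_index_group, stage_group`. Times are months since diagnosis;
#' `event` is 1 for observed recurrence, 0 for censoring. Covariate
#' categories are validated against fixed vocabularies; duplicate patient
#' ids and negative times are rejected.
#'
#' @param path File path.
#' @return data.frame, one row per patient, with a `split` column
#'   initialized to `"unassigned"` if absent.
#' @export
readPatientTable <- function(path) {
  df <- .readDelim(path)
  missing <- setdiff(.PATIENT_COLUMNS, colnames(df))
  if (length(missing))
    stop("patient table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  df$rfs_months <- as.numeric(df$rfs_months)
  if (any(!is.finite(df$rfs_months) | df$rfs_months < 0))
    stop("rfs_months must be finite and >= 0")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0/1")
  for (cov in names(.COVARIATE_LEVELS)) {
    badv <- setdiff(unique(df[[cov]]), .COVARIATE_LEVELS[[cov]])
    if (length(badv))
      stop("covariate ", cov, " has value(s) outside its vocabulary: ",
           paste(badv, collapse = ", "), " (allowed: ",
           paste(.COVARIATE_LEVELS[[cov]], collapse = ", "), ")")
  }
  if (!"split" %in% colnames(df)) df$split <- "unassigned"
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write a per-patient clinical table
#'
#' @param patients data.frame as returned by [readPatientTable()].
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
writePatientTable <- function(patients, path, sep = ",") {
  write.table(patients, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
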