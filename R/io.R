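#' Read a nuclear point table
#'
#' Point tables are plain CSV/TSV files with one row per nucleus and a header
#' containing at least `x_um`, `y_um` and `dot_count`; an `embryo_id` column
#' is carried through when present and a `type` column, if any, is ignored and
#' recomputed as `min(dot_count, 2)`. An empty file (or a header with no data
#' rows) yields an empty field.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (comma separated) or `"tsv"` (tab separated).
#' @param bounds Optional rectangle `c(x_min, x_max, y_min, y_max)`; defaults
#'   to the bounding box of the data.
#' @return A [nuclear_field()].
#' @export
read_point_table <- function(path, dialect = c("csv", "tsv"), bounds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(nuclear_field(bounds = bounds, embryo_id = basename(path)))
  }
  reader <- if (dialect == "csv") read.csv else read.delim
  tab <- reader(path, stringsAsFactors = FALSE)
  required <- c("x_um", "y_um", "dot_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("point table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    return(nuclear_field(bounds = bounds, embryo_id = basename(path)))
  }
  for (col in required) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(vals) & !is.na(tab[[col]]))) {
      stop("non-numeric values in column '", col, "'", call. = FALSE)
    }
    tab[[col]] <- vals
  }
  dup <- duplicated(tab[, c("x_um", "y_um")])
  if (any(dup)) {
    stop("duplicate nuclear coordinates at rows: ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  embryo_id <- if ("embryo_id" %in% names(tab)) {
    as.character(tab$embryo_id[1])
  } else {
    basename(path)
  }
  nuclear_field(x = tab$x_um, y = tab$y_um, dot_count = tab$dot_count,
                bounds = bounds, embryo_id = embryo_id)
}

#' Write a nuclear point table
#'
#' Writes the field as a delimited text file with header
#' `embryo_id,x_um,y_um,dot_count,type`. Coordinates are written at full
#' double precision, so a read/write round trip reproduces positions to
#' better than 1e-9 micrometres and types exactly.
#'
#' @param field A [nuclear_field()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_point_table <- function(field, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_field(field)
  nuc <- field$nuclei
  out <- data.frame(
    embryo_id = rep(field$embryo_id, nrow(nuc)),
    x_um = format(nuc$x, digits = 17, scientific = FALSE, trim = TRUE),
    y_um = format(nuc$y, digits = 17, scientific = FALSE, trim = TRUE),
    dot_count = nuc$dot_count,
    type = nuc$type,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write point table to ", path, call. = FALSE)
  invisible(path)
}

#' Crop a field to a rectangular window
#'
#' Retains nuclei whose centres fall inside the window under a half-open
#' convention: `x_min <= x < x_max` and `y_min <= y < y_max`. Half-open
#' membership means adjacent windows that tile a field never count a nucleus
#' twice. The returned field's bounds are set to the window. An empty result
#' is a warning, not an error. The convention mirrors the standardized
#' 100 x 100 um experimental field cropped from each embryo image (130-230 um
#' along the anteroposterior axis, -50 to 50 um across it).
#'
#' @param field A [nuclear_field()].
#' @param window Rectangle `c(x_min, x_max, y_min, y_max)` in micrometres;
#'   must overlap the field bounds.
#' @return A [nuclear_field()] restricted to the window.
#' @examples
#' f <- nuclear_field(x = c(100, 150, 250), y = c(0, 0, 0),
#'                    bounds = c(0, 300, -60, 60))
#' n_nuclei(crop_field(f, c(130, 230, -50, 50)))  # 1
#' @export
crop_field <- function(field, window) {
  validate_field(field)
  window <- as.numeric(window)
  if (length(window) != 4 || window[2] <= window[1] || window[4] <= window[3]) {
    stop("window must be c(x_min, x_max, y_min, y_max) with positive area",
         call. = FALSE)
  }
  b <- field$bounds
  if (window[1] >= b[2] || window[2] <= b[1] ||
      window[3] >= b[4] || window[4] <= b[3]) {
    stop("crop window does not overlap the field bounds", call. = FALSE)
  }
  nuc <- field$nuclei
  keep <- nuc$x >= window[1] & nuc$x < window[2] &
          nuc$y >= window[3] & nuc$y < window[4]
  if (!any(keep)) {
    warning("crop window contains no nuclei", call. = FALSE)
  }
  nuclear_field(x = nuc$x[keep], y = nuc$y[keep],
                dot_count = nuc$dot_count[keep],
                bounds = window, embryo_id = field$embryo_id)
}
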