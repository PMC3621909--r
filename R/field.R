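#' Construct a nuclear field
#'
#' A nuclear field is the basic container of the package: an ordered set of
#' nuclear centres in a rectangular window, each carrying a raw intron-dot
#' count and the transcriptional type derived from it. The type is always
#' `min(dot_count, 2)`: nuclei with two or more actively transcribing copies
#' are Type-2, one copy is Type-1, none is Type-0. The raw count is retained
#' for audit but every statistic in the package works on the clamped type.
#'
#' @param x,y Numeric vectors of nuclear centre coordinates in micrometres.
#' @param dot_count Non-negative integer vector of intron-dot counts per
#'   nucleus (recycled if scalar). Defaults to 0.
#' @param bounds Rectangle `c(x_min, x_max, y_min, y_max)` in micrometres.
#'   Defaults to the bounding box of the data (or the unit square for an
#'   empty field).
#' @param embryo_id Character label for the source embryo or simulation.
#' @return An object of class `nuclear_field`: a list with elements `nuclei`
#'   (data frame with columns `x`, `y`, `dot_count`, `type`), `bounds` and
#'   `embryo_id`.
#' @examples
#' f <- nuclear_field(x = c(1, 4), y = c(1, 5), dot_count = c(0, 3),
#'                    bounds = c(0, 10, 0, 10))
#' f$nuclei$type  # 0 and 2: counts above 2 are clamped
#' @export
nuclear_field <- function(x = numeric(), y = numeric(), dot_count = 0L,
                          bounds = NULL, embryo_id = "field") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  n <- length(x)
  dot_count <- as.integer(rep_len(dot_count, n))
  if (is.null(bounds)) {
    bounds <- if (n > 0) c(range(x), range(y)) else c(0, 1, 0, 1)
  }
  bounds <- as.numeric(bounds)
  field <- structure(
    list(
      nuclei = data.frame(x = x, y = y, dot_count = dot_count,
                          type = classify_type(dot_count)),
      bounds = bounds,
      embryo_id = as.character(embryo_id)
    ),
    class = "nuclear_field"
  )
  validate_field(field)
  field
}

#' Map intron-dot counts to transcriptional types
#'
#' Types are the dot count clamped at two: rare nuclei in which more than two
#' dots are detected are treated as Type-2. The mapping is total and
#' idempotent.
#'
#' @param dot_count Non-negative integer vector.
#' @return Integer vector of types in `{0, 1, 2}`.
#' @export
classify_type <- function(dot_count) {
  dot_count <- as.integer(dot_count)
  if (any(is.na(dot_count)) || any(dot_count < 0)) {
    stop("dot counts must be non-negative integers", call. = FALSE)
  }
  pmin(dot_count, 2L)
}

validate_field <- function(field) {
  nuc <- field$nuclei
  b <- field$bounds
  if (length(b) != 4 || any(!is.finite(b)) || b[2] <= b[1] || b[4] <= b[3]) {
    stop("bounds must be a finite rectangle c(x_min, x_max, y_min, y_max) ",
         "with positive area", call. = FALSE)
  }
  if (nrow(nuc) == 0) return(invisible(field))
  if (any(!is.finite(nuc$x)) || any(!is.finite(nuc$y))) {
    stop("nuclear coordinates must be finite", call. = FALSE)
  }
  dup <- duplicated(nuc[, c("x", "y")])
  if (any(dup)) {
    stop("duplicate nuclear coordinates at rows: ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  inside <- nuc$x >= b[1] & nuc$x <= b[2] & nuc$y >= b[3] & nuc$y <= b[4]
  if (!all(inside)) {
    stop("all nuclei must lie inside the field bounds; offending rows: ",
         paste(utils::head(which(!inside), 5), collapse = ", "), call. = FALSE)
  }
  if (!all(nuc$type == pmin(nuc$dot_count, 2L))) {
    stop("type column inconsistent with dot counts", call. = FALSE)
  }
  invisible(field)
}

#' @export
print.nuclear_field <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("<nuclear_field '%s': %d nuclei in [%g, %g] x [%g, %g] um>\n",
              x$embryo_id, nrow(x$nuclei), b[1], b[2], b[3], b[4]))
  tc <- type_counts(x)
  cat(sprintf("  types 0/1/2: %d/%d/%d; density %.4f nuclei/um^2\n",
              tc[1], tc[2], tc[3],
              if (field_area(x) > 0) nrow(x$nuclei) / field_area(x) else NA))
  invisible(x)
}

#' Number of nuclei in a field
#' @param field A `nuclear_field`.
#' @return Integer count.
#' @export
n_nuclei <- function(field) nrow(field$nuclei)

#' Area of a field in square micrometres
#' @param field A `nuclear_field`.
#' @return Numeric area.
#' @export
field_area <- function(field) {
  b <- field$bounds
  (b[2] - b[1]) * (b[4] - b[3])
}

#' Per-type nuclear counts and proportions
#'
#' @param field A `nuclear_field`.
#' @return `type_counts` returns an integer vector of length 3 named
#'   `"0" "1" "2"`; `type_proportions` the same normalised to sum to 1.
#' @export
type_counts <- function(field) {
  out <- integer(3)
  names(out) <- as.character(0:2)
  tab <- table(factor(field$nuclei$type, levels = 0:2))
  out[] <- as.integer(tab)
  out
}

#' @rdname type_counts
#' @export
type_proportions <- function(field) {
  tc <- type_counts(field)
  if (sum(tc) == 0) stop("empty field has no type proportions", call. = FALSE)
  tc / sum(tc)
}

# Replace the labels of a field, keeping positions; dot_count follows type.
set_types <- function(field, types) {
  types <- as.integer(types)
  stopifnot(length(types) == n_nuclei(field), all(types %in% 0:2))
  field$nuclei$type <- types
  field$nuclei$dot_count <- types
  field
}

# Row indices of nuclei of a type (NULL = all types combined).
type_index <- function(field, type = NULL) {
  if (is.null(type)) return(seq_len(n_nuclei(field)))
  which(field$nuclei$type == as.integer(type))
}
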