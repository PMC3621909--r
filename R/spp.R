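#' Radial bin grid for K- and H-functions
#'
#' Distances are binned into annuli of width `delta_r` (2 um by default) up
#' to `r_max` (100 um, the field size). K and H are cumulative statistics:
#' each profile value refers to the circle of radius equal to the upper edge
#' of its bin, so the evaluation radii are `delta_r, 2 delta_r, ..., r_max`.
#'
#' @param r_max Largest evaluation radius, um; must be a multiple of
#'   `delta_r`.
#' @param delta_r Annulus width, um.
#' @return A list of class `radial_grid` with elements `edges`, `delta_r`,
#'   `r_max`.
#' @export
radial_grid <- function(r_max = 100, delta_r = 2) {
  if (delta_r <= 0) stop("delta_r must be positive", call. = FALSE)
  k <- r_max / delta_r
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("r_max must be a positive multiple of delta_r", call. = FALSE)
  }
  structure(list(edges = seq_len(round(k)) * delta_r,
                 delta_r = delta_r, r_max = r_max),
            class = "radial_grid")
}

#' Overall nuclear density
#'
#' The overall density is the exact ratio `d = N / A` of the number of
#' nuclei of the requested type (all types when `type = NULL`) to the field
#' area.
#'
#' @param field A [nuclear_field()].
#' @param type Optional type in `{0, 1, 2}`; `NULL` for all nuclei.
#' @return Density in nuclei/um^2.
#' @export
overall_density <- function(field, type = NULL) {
  A <- field_area(field)
  if (A <= 0) stop("field has zero area", call. = FALSE)
  length(type_index(field, type)) / A
}

#' Local nuclear density around every nucleus
#'
#' For each nucleus i the local density is `d_i = n_i / (pi R^2)` where
#' `n_i` counts the nuclei of the requested type within distance `R` of
#' nucleus i, excluding nucleus i itself. Distances near the field edge are
#' taken on the periodic 3x3 tiling of the field, the same edge compensation
#' used by the K-functions.
#'
#' @param field A [nuclear_field()].
#' @param type Optional type counted in the neighbourhood; `NULL` for all.
#' @param R Neighbourhood radius in um (default 8, a little over the
#'   nuclear diameter).
#' @return Numeric vector of local densities, one per nucleus of the field.
#' @export
local_density <- function(field, type = NULL, R = 8) {
  if (R <= 0) stop("R must be positive", call. = FALSE)
  validate_field(field)
  nuc <- field$nuclei
  ti <- type_index(field, type)
  b <- field$bounds
  same <- is.null(type)  # reference list identical to target list
  counts <- cpp_counts_within(nuc$x, nuc$y, nuc$x[ti], nuc$y[ti],
                              R, b[2] - b[1], b[4] - b[3],
                              TRUE, FALSE)
  if (!same) {
    # subtract the self-count for reference nuclei that are of the type
    counts[seq_len(nrow(nuc)) %in% ti] <-
      counts[seq_len(nrow(nuc)) %in% ti] - 1L
  } else {
    counts <- counts - 1L
  }
  counts / (pi * R^2)
}

#' Pairwise centre-to-centre distances
#'
#' Euclidean distances between nuclear centres, with self-pairs excluded.
#' When the reference and target sets coincide (same type, or both `NULL`)
#' the `n (n - 1) / 2` unordered distances are returned; otherwise every
#' ordered reference-to-target distance is returned (references that also
#' belong to the target set are never paired with themselves).
#'
#' @param field A [nuclear_field()].
#' @param reference_type,target_type Optional types in `{0, 1, 2}`; `NULL`
#'   means all nuclei.
#' @return Numeric vector of distances in um.
#' @export
pairwise_distances <- function(field, reference_type = NULL,
                               target_type = NULL) {
  validate_field(field)
  ri <- type_index(field, reference_type)
  ti <- type_index(field, target_type)
  if (length(ri) < 1 || length(ti) < 1) {
    stop("need at least one reference and one target nucleus", call. = FALSE)
  }
  nuc <- field$nuclei
  if (identical(ri, ti)) {
    if (length(ri) < 2) stop("need at least two nuclei for pairwise distances",
                             call. = FALSE)
    return(as.numeric(stats::dist(cbind(nuc$x[ri], nuc$y[ri]))))
  }
  dx <- outer(nuc$x[ri], nuc$x[ti], "-")
  dy <- outer(nuc$y[ri], nuc$y[ti], "-")
  d <- sqrt(dx^2 + dy^2)
  self <- outer(ri, ti, "==")
  as.numeric(d[!self])
}

#' Nearest-neighbour distances
#'
#' For each nucleus of the requested type, the minimum distance to any other
#' nucleus of that type. By default distances are measured on the periodic
#' tiling of the field (minimum-image torus metric), the same edge
#' compensation used by every other statistic in the package: without it,
#' nuclei near the window edge report inflated NNDs and the regularity
#' index of a random pattern is biased below its theoretical value in small
#' fields. `periodic = FALSE` gives the uncorrected within-window metric.
#'
#' @param field A [nuclear_field()].
#' @param type Optional type; `NULL` for all nuclei.
#' @param periodic Use the torus metric of the field rectangle?
#' @return Numeric vector of NNDs, one per nucleus of the type.
#' @export
nnd <- function(field, type = NULL, periodic = TRUE) {
  validate_field(field)
  ti <- type_index(field, type)
  if (length(ti) < 2) {
    stop("nearest-neighbour distances need at least two nuclei",
         call. = FALSE)
  }
  nuc <- field$nuclei
  b <- field$bounds
  cpp_nnd(nuc$x[ti], nuc$y[ti], b[2] - b[1], b[4] - b[3], periodic)
}

#' Clark-Evans regularity index
#'
#' The regularity index is the mean nearest-neighbour distance divided by
#' its sample standard deviation (n - 1 denominator). For points placed
#' completely at random in the plane the index approaches
#' `sqrt(pi / (4 - pi)) ~ 1.91`; regularly spaced patterns give larger
#' values. A perfectly regular lattice has zero NND spread, which is
#' rejected as degenerate.
#'
#' @param nnd_values Numeric vector of at least 3 nearest-neighbour
#'   distances.
#' @return Dimensionless ratio.
#' @examples
#' regularity_index(c(1, 1, 2))  # 2.309
#' @export
regularity_index <- function(nnd_values) {
  nnd_values <- as.numeric(nnd_values)
  if (length(nnd_values) < 3) {
    stop("regularity index needs at least 3 NND values", call. = FALSE)
  }
  s <- sd(nnd_values)
  if (s <= 1e-9 * abs(mean(nnd_values))) {  # relative zero: perfect lattice
    stop("degenerate regularity: NND standard deviation is zero",
         call. = FALSE)
  }
  mean(nnd_values) / s
}

#' Surround a field with 8 periodic copies
#'
#' Builds the 3x3 periodic tiling used as the edge correction throughout the
#' package: the field is surrounded with 8 identical translated copies so
#' that every centre-tile nucleus has a complete neighbourhood. For radii up
#' to half the field size the minimum tiled distance between two nuclei
#' equals the torus metric.
#'
#' @param field A [nuclear_field()].
#' @return A [nuclear_field()] with `9 N` nuclei and 3x-expanded bounds; its
#'   `nuclei` data frame gains columns `parent` (row index in the original
#'   field) and `center` (logical, untranslated copy).
#' @export
tile_field <- function(field) {
  validate_field(field)
  nuc <- field$nuclei
  b <- field$bounds
  W <- b[2] - b[1]; H <- b[4] - b[3]
  off <- expand.grid(dx = c(0, -1, 1), dy = c(0, -1, 1))  # center tile first
  n <- nrow(nuc)
  tiled <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
    data.frame(x = nuc$x + off$dx[k] * W, y = nuc$y + off$dy[k] * H,
               dot_count = nuc$dot_count, type = nuc$type,
               parent = seq_len(n),
               center = off$dx[k] == 0 & off$dy[k] == 0)
  }))
  out <- structure(
    list(nuclei = tiled,
         bounds = c(b[1] - W, b[2] + W, b[3] - H, b[4] + H),
         embryo_id = field$embryo_id),
    class = "nuclear_field"
  )
  out
}

new_radial_profile <- function(grid, values, statistic, types,
                               per_field = NULL) {
  structure(list(grid = grid, r = grid$edges, values = values,
                 statistic = statistic, types = types,
                 per_field = per_field),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile %s%s: %d bins, r in (0, %g] um>\n",
              x$statistic,
              if (length(x$types)) paste0("_", paste(x$types, collapse = "")) else "",
              length(x$r), max(x$r)))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  out <- data.frame(r_um = x$r, value = x$values)
  names(out)[2] <- x$statistic
  out
}

#' Univariate Ripley K-function with periodic-tiling edge correction
#'
#' For the nuclei of one type (or all nuclei), `K(r)` is the average number
#' of further nuclei of that type within distance r of a typical nucleus,
#' scaled by the type's density:
#' `K(r) = (1 / (d N)) * sum_i #\{j != i : ||x_i - x_j|| <= r\}`,
#' where references i run over the centre tile and neighbours j are counted
#' across the 3x3 periodic tiling of the field. Under complete spatial
#' randomness `K(r) = pi r^2`; the statistic is density-normalised so fields
#' of different density are comparable. Values are evaluated at the upper
#' edges of the 2 um annulus grid and are nondecreasing in r.
#'
#' @param field A [nuclear_field()].
#' @param type Type in `{0, 1, 2}` or `NULL` for all nuclei combined.
#' @param grid A [radial_grid()].
#' @return A `radial_profile` with statistic `"K"`.
#' @examples
#' f <- nuclear_field(x = c(2, 5), y = c(5, 5), bounds = c(0, 10, 0, 10))
#' ripley_k(f, grid = radial_grid(10, 2))$values[2]  # K(4) = 50
#' @export
ripley_k <- function(field, type = NULL, grid = radial_grid()) {
  validate_field(field)
  ti <- type_index(field, type)
  n_i <- length(ti)
  if (n_i < 2) {
    stop("K-function needs at least two nuclei of the requested type",
         call. = FALSE)
  }
  nuc <- field$nuclei
  b <- field$bounds
  d_i <- n_i / field_area(field)
  counts <- cpp_cum_counts(nuc$x[ti], nuc$y[ti], nuc$x[ti], nuc$y[ti],
                           grid$edges, b[2] - b[1], b[4] - b[3],
                           TRUE, TRUE)
  new_radial_profile(grid, counts / (d_i * n_i), "K",
                     if (is.null(type)) integer() else as.integer(type))
}

#' Bivariate (cross-type) Ripley K-function
#'
#' `K_ij(r)` counts, around a typical Type-i nucleus, the Type-j nuclei
#' within distance r, scaled by the Type-j density:
#' `K_ij(r) = (1 / (d_j N_i)) * sum_{i-refs} #\{type-j within r\}`,
#' with the same periodic-tiling counting as [ripley_k()]. If the two types
#' are placed independently of one another, `K_ij(r) = pi r^2` whatever the
#' individual patterns look like. The estimator satisfies the exchange
#' identity `d_i N_i K_ij = d_j N_j K_ji`.
#'
#' @param field A [nuclear_field()].
#' @param type_i Reference type.
#' @param type_j Target type (`type_i != type_j`).
#' @param grid A [radial_grid()].
#' @return A `radial_profile` with statistic `"K_ij"` and `types`
#'   `c(type_i, type_j)`.
#' @export
ripley_k_bivariate <- function(field, type_i, type_j, grid = radial_grid()) {
  validate_field(field)
  if (identical(as.integer(type_i), as.integer(type_j))) {
    stop("bivariate K needs two distinct types", call. = FALSE)
  }
  ri <- type_index(field, type_i)
  ti <- type_index(field, type_j)
  if (length(ri) < 1 || length(ti) < 1) {
    stop("both types must be non-empty", call. = FALSE)
  }
  nuc <- field$nuclei
  b <- field$bounds
  d_j <- length(ti) / field_area(field)
  counts <- cpp_cum_counts(nuc$x[ri], nuc$y[ri], nuc$x[ti], nuc$y[ti],
                           grid$edges, b[2] - b[1], b[4] - b[3],
                           TRUE, FALSE)
  new_radial_profile(grid, counts / (d_j * length(ri)), "K_ij",
                     c(as.integer(type_i), as.integer(type_j)))
}

#' H-transform of a K-profile
#'
#' `H(r) = sqrt(K(r) / pi) - r`, applied per bin. Subtracting r turns the
#' parabolic CSR benchmark into the zero line, so departures read directly
#' as signs: `H > 0` means spatial clustering (more like-typed or
#' cross-typed neighbours than random), `H < 0` repulsion. Since `K >= 0`,
#' `H(r) >= -r` always.
#'
#' @param profile A K-type `radial_profile` from [ripley_k()] or
#'   [ripley_k_bivariate()].
#' @return A `radial_profile` with statistic `"H"` (or `"H_ij"`).
#' @export
h_transform <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!profile$statistic %in% c("K", "K_ij")) {
    stop("h_transform expects a K-type profile", call. = FALSE)
  }
  if (any(profile$values < 0)) {
    stop("negative K values: upstream invariant violated", call. = FALSE)
  }
  new_radial_profile(profile$grid,
                     sqrt(profile$values / pi) - profile$r,
                     if (profile$statistic == "K") "H" else "H_ij",
                     profile$types)
}

#' Univariate or bivariate H-function in one step
#'
#' Convenience wrappers composing [ripley_k()] / [ripley_k_bivariate()] with
#' [h_transform()].
#'
#' @inheritParams ripley_k
#' @inheritParams ripley_k_bivariate
#' @return A `radial_profile` with statistic `"H"` or `"H_ij"`.
#' @export
h_function <- function(field, type = NULL, grid = radial_grid()) {
  h_transform(ripley_k(field, type, grid))
}

#' @rdname h_function
#' @export
h_function_bivariate <- function(field, type_i, type_j,
                                 grid = radial_grid()) {
  h_transform(ripley_k_bivariate(field, type_i, type_j, grid))
}
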