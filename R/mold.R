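#' Configuration for a synthetic blastoderm mold
#'
#' A "mold" is a fixed set of nuclear positions onto which transcriptional
#' labels are placed by permutation or simulation. Synthetic molds emulate
#' the early cycle-14 nuclear monolayer: a 100 x 100 um field at about
#' 0.024 nuclei/um^2 with regular spacing on the order of the nuclear
#' diameter (~6 um).
#'
#' Two generative processes are available. The default, `"packing"`, draws
#' uniform random positions and relaxes hard-core overlaps on the torus of
#' the field until all pairwise distances reach `min_spacing`, then applies
#' a small uniform positional jitter: a disordered dense packing whose
#' pair correlations, like those of a real monolayer, decay after the first
#' coordination shell. `"lattice"` instead jitters a triangular lattice
#' whose constant is set from the target density; it is simpler but retains
#' crystalline long-range order, which imprints persistent oscillations on
#' second-order statistics at all radii. Both land the regularity index of
#' the monolayer well above the random-point value of about 1.91, in the
#' regime observed for real blastoderm fields.
#'
#' @param width,height Field dimensions in micrometres.
#' @param target_density Target nuclear density in nuclei/um^2.
#' @param min_spacing Nominal nuclear diameter in micrometres; the packing
#'   must be feasible, i.e. `target_density <= (2/sqrt(3))/min_spacing^2`
#'   (the hexagonal bound).
#' @param jitter Half-width of the uniform positional jitter per axis, um.
#'   The default 0.5 um models the residual positional disorder of nuclear
#'   centres after packing.
#' @param spacing_tol Fraction of `min_spacing` the realized minimum pair
#'   distance may fall short by (after jitter) before generation is treated
#'   as infeasible.
#' @param process `"packing"` (default) or `"lattice"`.
#' @return A list of class `mold_config`.
#' @export
mold_config <- function(width = 100, height = 100, target_density = 0.024,
                        min_spacing = 6, jitter = 0.5, spacing_tol = 0.35,
                        process = c("packing", "lattice")) {
  process <- match.arg(process)
  cfg <- list(width = width, height = height,
              target_density = target_density, min_spacing = min_spacing,
              jitter = jitter, spacing_tol = spacing_tol, process = process)
  if (width <= 0 || height <= 0 || target_density <= 0) {
    stop("width, height and target_density must be positive", call. = FALSE)
  }
  if (target_density * width * height < 1) {
    stop("configuration yields fewer than one nucleus", call. = FALSE)
  }
  if (min_spacing < 0 || jitter < 0) {
    stop("min_spacing and jitter must be non-negative", call. = FALSE)
  }
  if (min_spacing > 0 &&
      target_density > (2 / sqrt(3)) / min_spacing^2 + 1e-12) {
    stop("infeasible packing: target_density exceeds the hexagonal bound ",
         "(2/sqrt(3))/min_spacing^2", call. = FALSE)
  }
  structure(cfg, class = "mold_config")
}

#' Generate a blastoderm-like nuclear mold
#'
#' Realizes the configured point process (see [mold_config()]) on the torus
#' of the field rectangle. The realized density is within 10% of the target
#' (exact for the packing process, which places `round(density * area)`
#' nuclei) and the realized minimum pairwise distance must reach
#' `min_spacing * (1 - spacing_tol)`; violations are errors, not warnings.
#' Deterministic given `seed`. With `process = "lattice"` and `jitter = 0`
#' the lattice is perfect; such a degenerate field has zero
#' nearest-neighbour-distance spread, so the regularity index is undefined
#' on it.
#'
#' @param config A [mold_config()].
#' @param seed Optional integer seed.
#' @return A [nuclear_field()] with all nuclei Type-0 (unlabelled).
#' @examples
#' m <- generate_mold(seed = 1)
#' n_nuclei(m)  # 240 at the default 100 x 100 um, 0.024 nuclei/um^2
#' @export
generate_mold <- function(config = mold_config(), seed = NULL) {
  if (!inherits(config, "mold_config")) config <- do.call(mold_config, config)
  if (!is.null(seed)) set.seed(seed)
  W <- config$width; H <- config$height; d <- config$target_density
  if (config$process == "packing") {
    n <- as.integer(round(d * W * H))
    relaxed <- cpp_relax_packing(runif(n, 0, W), runif(n, 0, H),
                                 W, H, config$min_spacing, 5000L, 1e-3)
    if (!relaxed$converged) {
      stop("hard-core relaxation did not converge; the configuration is ",
           "too dense for min_spacing", call. = FALSE)
    }
    x <- relaxed$x; y <- relaxed$y
  } else {
    a <- sqrt(2 / (sqrt(3) * d))        # triangular lattice constant
    n_col <- max(1L, as.integer(round(W / a)))
    n_row <- max(2L, 2L * as.integer(round(H / (a * sqrt(3)))))
    ax <- W / n_col                      # realized column spacing
    rh <- H / n_row                      # realized row height
    row <- rep(seq_len(n_row) - 1L, each = n_col)
    col <- rep(seq_len(n_col) - 1L, times = n_row)
    x <- (col + 0.5 * (row %% 2L)) * ax
    y <- (row + 0.5) * rh
    n <- length(x)
  }
  realized <- n / (W * H)
  if (abs(realized - d) > 0.1 * d) {
    stop(sprintf(paste0("cannot realize target density %.4g within 10%% ",
                        "(process gives %.4g)"), d, realized), call. = FALSE)
  }
  if (config$jitter > 0) {
    x <- (x + runif(n, -config$jitter, config$jitter)) %% W
    y <- (y + runif(n, -config$jitter, config$jitter)) %% H
  }
  field <- nuclear_field(x = x, y = y, dot_count = 0L,
                         bounds = c(0, W, 0, H), embryo_id = "mold")
  if (config$min_spacing > 0 && n >= 2) {
    min_d <- min(cpp_nnd(x, y, W, H, TRUE))
    if (min_d < config$min_spacing * (1 - config$spacing_tol)) {
      stop(sprintf(paste0("realized minimum spacing %.3g um violates ",
                          "min_spacing %.3g um (tolerance %.0f%%); ",
                          "reduce jitter or density"),
                   min_d, config$min_spacing, 100 * config$spacing_tol),
           call. = FALSE)
    }
  }
  field
}

#' Generate a completely spatially random field
#'
#' Places `n` nuclei independently and uniformly over the bounds, with no
#' spacing constraint: the binomial-process analogue of complete spatial
#' randomness used as the reference for the regularity index and K-function
#' benchmarks.
#'
#' @param n Number of nuclei (>= 1).
#' @param bounds Rectangle `c(x_min, x_max, y_min, y_max)` in micrometres.
#' @param seed Optional integer seed.
#' @return A [nuclear_field()] with all nuclei Type-0.
#' @export
generate_random_field <- function(n, bounds = c(0, 100, 0, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  bounds <- as.numeric(bounds)
  x <- runif(n, bounds[1], bounds[2])
  y <- runif(n, bounds[3], bounds[4])
  nuclear_field(x = x, y = y, dot_count = 0L, bounds = bounds,
                embryo_id = "csr")
}

#' Randomly assign transcriptional types at fixed proportions
#'
#' Assigns types 0/1/2 to the nuclei of a field by exact-count apportionment:
#' per-type counts are `proportions * N` rounded by the largest-remainder
#' rule, and the resulting multiset of labels is randomly permuted over the
#' nuclear positions. Positions are untouched. This is the label-permutation
#' null of the package: it maintains the overall proportions of the three
#' types exactly, as when experimental labels are reshuffled on their mold.
#'
#' @param field A [nuclear_field()].
#' @param proportions Numeric vector of length 3 over types (0, 1, 2),
#'   summing to 1 within 1e-9.
#' @param seed Optional integer seed.
#' @return The field with new types (dot counts set equal to types).
#' @examples
#' f <- generate_random_field(4, seed = 1)
#' table(assign_labels_random(f, c(0.25, 0.5, 0.25), seed = 2)$nuclei$type)
#' @export
assign_labels_random <- function(field, proportions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_field(field)
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3 || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  n <- n_nuclei(field)
  counts <- apportion_counts(proportions, n)
  labels <- rep(0:2, times = counts)
  set_types(field, sample(labels, n))
}

# Largest-remainder apportionment of n among the given proportions.
apportion_counts <- function(proportions, n) {
  quota <- proportions * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (sum(base) != n) stop("apportionment infeasible", call. = FALSE)
  as.integer(base)
}
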