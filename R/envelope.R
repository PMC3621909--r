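#' Label-permutation Monte Carlo envelope
#'
#' The null model of the package: nuclear positions are a fixed "mold" and
#' only the transcriptional labels are random. Each simulation reshuffles
#' the labels of every field (positions fixed, per-field type counts fixed),
#' evaluates the statistic per field and averages across fields; repeating
#' this `n_sims` times (199 by default) yields a pointwise null
#' distribution. The 95% confidence band is read off as rank order
#' statistics: with the default `rank = 5`, the 5th smallest and 5th
#' largest of the 199 null values per bin, i.e. the top/bottom-5 envelope.
#' Bins where the observed across-field mean escapes the band are merged
#' into contiguous significant r ranges.
#'
#' @param fields A [nuclear_field()] or list of them (e.g. 14 experimental
#'   fields).
#' @param statistic Function mapping a field to a `radial_profile` (or a
#'   plain numeric vector of fixed length), e.g.
#'   `function(f) h_function(f, type = 2)`.
#' @param n_sims Number of label permutations (must be at least `2 * rank`).
#' @param rank Order statistic used for the bounds (5 of 199 gives a
#'   pointwise ~95% two-sided band, about 2.5% per tail).
#' @param seed Optional integer seed.
#' @return An object of class `envelope_result`: list with `r`, `observed`,
#'   `null_profiles` (`n_sims` x bins), `lower`, `upper`, `outside`
#'   (logical per bin), `significant_ranges` (data frame `r_lo`, `r_hi`),
#'   `n_sims`, `rank`.
#' @export
permutation_null <- function(fields, statistic, n_sims = 199, rank = 5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fields, "nuclear_field")) fields <- list(fields)
  stopifnot(length(fields) >= 1)
  if (n_sims < 2 * rank) {
    stop("n_sims must be at least 2 * rank", call. = FALSE)
  }
  first <- statistic(fields[[1]])
  r <- if (inherits(first, "radial_profile")) first$r else
    seq_along(profile_values(first))
  eval_all <- function(flds) {
    rowMeans(vapply(flds, function(f) profile_values(statistic(f)),
                    numeric(length(r))))
  }
  observed <- eval_all(fields)
  ref_counts <- lapply(fields, type_counts)
  null_profiles <- matrix(NA_real_, n_sims, length(r))
  for (s in seq_len(n_sims)) {
    permuted <- lapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      g <- set_types(f, sample(f$nuclei$type))
      # permutation must conserve positions and per-type counts
      stopifnot(identical(type_counts(g), ref_counts[[k]]),
                identical(g$nuclei$x, f$nuclei$x))
      g
    })
    null_profiles[s, ] <- eval_all(permuted)
  }
  bounds <- rank_bounds(null_profiles, rank)
  outside <- observed < bounds$lower | observed > bounds$upper
  structure(
    list(r = r, observed = observed, null_profiles = null_profiles,
         lower = bounds$lower, upper = bounds$upper, outside = outside,
         significant_ranges = contiguous_ranges(outside, r),
         n_sims = n_sims, rank = rank),
    class = "envelope_result"
  )
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("<envelope_result: %d sims, rank-%d bounds, %d bins>\n",
              x$n_sims, x$rank, length(x$r)))
  if (nrow(x$significant_ranges) > 0) {
    cat("  observed outside the envelope for r in:\n")
    apply(x$significant_ranges, 1, function(rr)
      cat(sprintf("    %g - %g um\n", rr[1], rr[2])))
  } else {
    cat("  observed inside the envelope at every r\n")
  }
  invisible(x)
}

profile_values <- function(p) {
  if (inherits(p, "radial_profile")) p$values else as.numeric(p)
}

# Pointwise rank-based bounds of a null matrix (sims x bins).
rank_bounds <- function(null_profiles, rank) {
  if (rank < 1 || 2 * rank > nrow(null_profiles)) {
    stop("rank out of range for the number of simulations", call. = FALSE)
  }
  lower <- apply(null_profiles, 2, function(v) sort(v)[rank])
  upper <- apply(null_profiles, 2, function(v)
    sort(v, decreasing = TRUE)[rank])
  list(lower = lower, upper = upper)
}

# Merge a logical flag vector into contiguous (r_lo, r_hi) runs.
contiguous_ranges <- function(flags, r) {
  if (!any(flags)) {
    return(data.frame(r_lo = numeric(), r_hi = numeric(),
                      bin_lo = integer(), bin_hi = integer()))
  }
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  data.frame(r_lo = r[starts[keep]], r_hi = r[ends[keep]],
             bin_lo = starts[keep], bin_hi = ends[keep])
}

#' Kolmogorov-Smirnov detection of significant r ranges
#'
#' Compares two sets of per-field radial profiles (e.g. the H-functions of
#' 14 experimental fields against 14 label-permuted fields) bin by bin: at
#' each radius a two-sample KS test is applied to the across-field values,
#' and maximal contiguous runs of bins with `p < alpha` are reported as
#' significant r ranges.
#'
#' @param experimental,simulated Numeric matrices, fields x bins, sharing
#'   one radial grid; at least 3 rows each.
#' @param r Evaluation radii (um), one per column; defaults to the column
#'   index.
#' @param alpha Significance level per bin (no multiplicity correction
#'   across bins).
#' @return A list of class `ks_range_result` with `p_values`, `significant`
#'   (logical per bin) and `ranges` (data frame `r_lo`, `r_hi`, `bin_lo`,
#'   `bin_hi`).
#' @export
ks_range_test <- function(experimental, simulated, r = NULL, alpha = 0.05) {
  experimental <- as.matrix(experimental)
  simulated <- as.matrix(simulated)
  if (ncol(experimental) != ncol(simulated)) {
    stop("profile sets are on different radial grids", call. = FALSE)
  }
  if (nrow(experimental) < 3 || nrow(simulated) < 3) {
    stop("need at least 3 profiles per side", call. = FALSE)
  }
  if (is.null(r)) r <- seq_len(ncol(experimental))
  if (length(r) != ncol(experimental)) {
    stop("r must have one value per bin", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(experimental)), function(b) {
    suppressWarnings(
      ks.test(experimental[, b], simulated[, b])$p.value
    )
  }, numeric(1))
  sig <- p < alpha
  structure(list(p_values = p, significant = sig,
                 ranges = contiguous_ranges(sig, r), alpha = alpha, r = r),
            class = "ks_range_result")
}

#' Normal-approximation binomial confidence interval
#'
#' If the count of a given nuclear type among `N` nuclei follows a binomial
#' distribution `B(N, P)`, the proportion's 95% confidence interval is
#' `P +/- z sqrt(P (1 - P) / N)` with `z = 1.96`, clipped to `[0, 1]`.
#' Used as the theoretical counterpart of the Monte Carlo envelopes for
#' neighbour-type proportions.
#'
#' @param p Type probability in `[0, 1]`.
#' @param n Number of draws (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' binomial_ci(0.5, 100)  # (0.402, 0.598)
#' @export
binomial_ci <- function(p, n, level = 0.95) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}
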