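#' Voronoi immediate neighbours on the periodic tiling
#'
#' Two nuclei are immediate neighbours when their Voronoi cells share an
#' edge of positive length; contact through a single degenerate vertex (as
#' between the diagonals of four co-circular points) does not count. The
#' tessellation is computed on the 3x3 periodic tiling of the field so that
#' every centre-tile nucleus has a bounded cell, and neighbours reached
#' through an image are reported as their centre-tile identities (periodic
#' wrap). The resulting relation is symmetric and free of self-neighbours.
#'
#' @param field A [nuclear_field()] with at least 4 non-collinear nuclei.
#' @param eps Minimum Voronoi edge length (um) to count as a shared edge;
#'   defaults to `1e-8 * max(field width, height)`.
#' @return An object of class `neighbor_table`: list with `neighbors` (list
#'   of integer vectors, per nucleus), `types` (integer vector) and
#'   `n_nuclei`.
#' @export
voronoi_neighbors <- function(field, eps = NULL) {
  validate_field(field)
  n <- n_nuclei(field)
  if (n < 4) stop("Voronoi analysis needs at least 4 nuclei", call. = FALSE)
  nuc <- field$nuclei
  if (all(abs((nuc$x - nuc$x[1]) * (nuc$y[2] - nuc$y[1]) -
              (nuc$y - nuc$y[1]) * (nuc$x[2] - nuc$x[1])) < 1e-12)) {
    stop("degenerate geometry: all nuclei are collinear", call. = FALSE)
  }
  b <- field$bounds
  if (is.null(eps)) eps <- 1e-8 * max(b[2] - b[1], b[4] - b[3])
  tf <- tile_field(field)
  tn <- tf$nuclei
  dd <- deldir::deldir(tn$x, tn$y, rw = tf$bounds)
  seg <- dd$dirsgs
  len2 <- (seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2
  seg <- seg[len2 > eps^2, , drop = FALSE]
  touches_center <- tn$center[seg$ind1] | tn$center[seg$ind2]
  seg <- seg[touches_center, , drop = FALSE]
  a <- tn$parent[seg$ind1]
  bb <- tn$parent[seg$ind2]
  keep <- a != bb  # a nucleus is never its own neighbour, even via an image
  seg <- seg[keep, , drop = FALSE]
  a <- a[keep]; bb <- bb[keep]
  # every adjacency on the torus lifts to exactly one tiled edge per
  # centre-tile endpoint, so appending from the centre side(s) of each
  # positive-length segment counts each shared edge once per endpoint —
  # keeping multiplicity when two cells meet along more than one edge
  # (possible only through the periodic wrap of very small fields)
  neighbors <- rep(list(integer()), n)
  c1 <- tn$center[seg$ind1]
  c2 <- tn$center[seg$ind2]
  for (k in seq_len(nrow(seg))) {
    if (c1[k]) neighbors[[a[k]]] <- c(neighbors[[a[k]]], bb[k])
    if (c2[k]) neighbors[[bb[k]]] <- c(neighbors[[bb[k]]], a[k])
  }
  neighbors <- lapply(neighbors, sort)
  structure(list(neighbors = neighbors, types = nuc$type, n_nuclei = n),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<neighbor_table: %d nuclei, mean degree %.2f>\n",
              x$n_nuclei, mean(deg)))
  invisible(x)
}

#' Type composition of the immediate neighbourhood of a focal type
#'
#' Pools, over every nucleus of the focal type (and over fields when
#' several are supplied), the counts of immediate Voronoi neighbours of
#' each type, and compares the resulting proportions against two nulls:
#' (a) the theoretical binomial confidence interval with the global type
#' proportions as the success probabilities and the total neighbour count
#' as N ([binomial_ci()]); and (b), when `n_sims > 0`, a label-permutation
#' Monte Carlo envelope (the tessellation is computed once per field; only
#' the labels are reshuffled).
#'
#' @param fields A [nuclear_field()] or list of them.
#' @param focal_type Type whose neighbourhood is examined.
#' @param n_sims Number of label permutations for the Monte Carlo envelope
#'   (0 to skip; 199 in the standard analysis).
#' @param rank Order statistic for the envelope bounds (default 5).
#' @param seed Optional integer seed.
#' @param tables Optional precomputed list of [voronoi_neighbors()] tables
#'   matching `fields`.
#' @return An object of class `neighbor_proportions`: list with `counts`,
#'   `proportions` (length-3, over neighbour types), `global_proportions`,
#'   `binomial_bounds` (3 x 2 matrix), `outside_binomial`, and when
#'   `n_sims > 0` also `mc_lower`, `mc_upper`, `outside_mc`.
#' @export
neighbor_type_proportions <- function(fields, focal_type, n_sims = 0,
                                      rank = 5, seed = NULL, tables = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fields, "nuclear_field")) fields <- list(fields)
  if (is.null(tables)) tables <- lapply(fields, voronoi_neighbors)
  focal_type <- as.integer(focal_type)

  pooled_counts <- function(type_lists) {
    counts <- c(`0` = 0, `1` = 0, `2` = 0)
    for (k in seq_along(tables)) {
      types <- type_lists[[k]]
      focal <- which(types == focal_type)
      if (length(focal) == 0) next
      nb_types <- types[unlist(tables[[k]]$neighbors[focal])]
      tab <- table(factor(nb_types, levels = 0:2))
      counts <- counts + as.integer(tab)
    }
    counts
  }

  obs_types <- lapply(fields, function(f) f$nuclei$type)
  counts <- pooled_counts(obs_types)
  n_total <- sum(counts)
  if (n_total == 0) {
    stop("no neighbours found around the focal type", call. = FALSE)
  }
  props <- counts / n_total
  all_types <- unlist(obs_types)
  global <- as.integer(table(factor(all_types, levels = 0:2))) /
    length(all_types)
  names(global) <- as.character(0:2)
  bounds <- t(vapply(global, function(p) binomial_ci(p, n_total),
                     numeric(2)))
  out <- list(counts = counts, proportions = props,
              global_proportions = global,
              binomial_bounds = bounds,
              outside_binomial = props < bounds[, 1] | props > bounds[, 2],
              focal_type = focal_type, n_neighbors = n_total)
  if (n_sims > 0) {
    null_props <- matrix(NA_real_, n_sims, 3)
    for (s in seq_len(n_sims)) {
      perm_types <- lapply(obs_types, sample)
      pc <- pooled_counts(perm_types)
      null_props[s, ] <- pc / sum(pc)
    }
    mc <- rank_bounds(null_props, rank)
    out$mc_lower <- mc$lower
    out$mc_upper <- mc$upper
    out$outside_mc <- props < mc$lower | props > mc$upper
    out$n_sims <- n_sims
  }
  structure(out, class = "neighbor_proportions")
}

#' @export
print.neighbor_proportions <- function(x, ...) {
  cat(sprintf("<neighbor_proportions around Type-%d (%d neighbours)>\n",
              x$focal_type, x$n_neighbors))
  for (k in 1:3) {
    flag <- if (isTRUE(x$outside_binomial[k])) " *outside binomial CI*" else ""
    cat(sprintf("  Type-%d: %.3f (CI %.3f-%.3f)%s\n", k - 1,
                x$proportions[k], x$binomial_bounds[k, 1],
                x$binomial_bounds[k, 2], flag))
  }
  invisible(x)
}

#' Cumulative distribution of reference-to-target distances
#'
#' Pools, across fields, the centre-to-centre distances from every nucleus
#' of the reference type to every nucleus of each target type, and returns
#' the empirical cumulative distribution functions together with pairwise
#' two-sample KS comparisons between the target-type distributions. The
#' left-most ECDF (stochastically smallest distances, summarised by the
#' smallest mean) indicates which type is reached soonest from a reference
#' nucleus.
#'
#' @param fields A [nuclear_field()] or list of them.
#' @param reference_type Reference type (e.g. 2).
#' @param target_type Optional single target type; `NULL` compares all
#'   types present.
#' @return An object of class `type_distance_ecdf`: list with `distances`
#'   (named list per target type), `ecdf` (list of ECDF functions), `ks`
#'   (data frame `pair`, `statistic`, `p_value`) and `leftmost` (target
#'   type with the smallest mean distance).
#' @export
type_distance_ecdf <- function(fields, reference_type, target_type = NULL) {
  if (inherits(fields, "nuclear_field")) fields <- list(fields)
  targets <- if (is.null(target_type)) 0:2 else as.integer(target_type)
  dists <- lapply(targets, function(tt) {
    unlist(lapply(fields, function(f) {
      ri <- type_index(f, reference_type)
      ti <- type_index(f, tt)
      if (length(ri) == 0 || length(ti) == 0) return(numeric())
      if (identical(ri, ti) && length(ri) < 2) return(numeric())
      pairwise_distances(f, reference_type, tt)
    }))
  })
  names(dists) <- as.character(targets)
  dists <- dists[lengths(dists) > 0]
  if (length(dists) == 0) {
    stop("no reference-to-target distances in the pooled data",
         call. = FALSE)
  }
  ecdfs <- lapply(dists, ecdf)
  ks <- NULL
  tt <- names(dists)
  if (length(tt) >= 2) {
    pairs <- utils::combn(tt, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      res <- suppressWarnings(ks.test(dists[[a]], dists[[b]]))
      data.frame(pair = paste0(a, "-", b),
                 statistic = unname(res$statistic),
                 p_value = res$p.value)
    }))
  }
  structure(list(distances = dists, ecdf = ecdfs, ks = ks,
                 leftmost = names(which.min(vapply(dists, mean, numeric(1)))),
                 reference_type = as.integer(reference_type)),
            class = "type_distance_ecdf")
}

#' @export
print.type_distance_ecdf <- function(x, ...) {
  cat(sprintf("<type_distance_ecdf from Type-%d: targets %s>\n",
              x$reference_type, paste(names(x$distances), collapse = ", ")))
  cat(sprintf("  left-most (closest) target type: %s\n", x$leftmost))
  if (!is.null(x$ks)) print(x$ks, row.names = FALSE)
  invisible(x)
}
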