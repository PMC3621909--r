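#' Build nested nuclear lineage clones on a mold
#'
#' Reconstructs plausible cycle-11 to cycle-14 lineages on a fixed set of
#' cycle-14 nuclear positions, without modelling the earlier positions or
#' movements. Every 8 neighbouring nuclei are grouped into one clone (the
#' descendants of a single cycle-11 nucleus after three divisions) by greedy
#' spatial aggregation: a random unassigned nucleus is drawn and grouped
#' with its 7 nearest unassigned neighbours, repeatedly; fewer than 8
#' leftover nuclei form one final undersized clone. Each 8-clone is then
#' split uniformly at random into two 4-clones (cycle-12 ancestors) and
#' each 4-clone into two 2-clones (cycle-13 ancestors).
#'
#' @param mold A [nuclear_field()] with at least 8 nuclei.
#' @param seed Optional integer seed.
#' @return An object of class `lineage_forest`: list with `mold` and
#'   integer clone-id vectors `clone8`, `clone4`, `clone2` (one id per
#'   nucleus; `clone2` refines `clone4` refines `clone8`).
#' @export
build_clones <- function(mold, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_field(mold)
  n <- n_nuclei(mold)
  if (n < 8) stop("clone construction needs at least 8 nuclei", call. = FALSE)
  x <- mold$nuclei$x; y <- mold$nuclei$y
  clone8 <- integer(n)
  unassigned <- seq_len(n)
  cid <- 0L
  while (length(unassigned) >= 8) {
    cid <- cid + 1L
    s <- if (length(unassigned) == 1) unassigned else sample(unassigned, 1)
    d2 <- (x[unassigned] - x[s])^2 + (y[unassigned] - y[s])^2
    grp <- unassigned[order(d2)[1:8]]  # s itself is at distance 0
    clone8[grp] <- cid
    unassigned <- setdiff(unassigned, grp)
  }
  if (length(unassigned) > 0) {
    cid <- cid + 1L
    clone8[unassigned] <- cid
  }
  clone4 <- split_clones(clone8, 4L)
  clone2 <- split_clones(clone4, 2L)
  forest <- structure(list(mold = mold, clone8 = clone8, clone4 = clone4,
                           clone2 = clone2),
                      class = "lineage_forest")
  validate_forest(forest)
  forest
}

# Refine each parent clone into random child groups of the given size
# (the last child group of a parent may be smaller when sizes do not divide).
split_clones <- function(parent_ids, size) {
  child <- integer(length(parent_ids))
  next_id <- 0L
  for (pid in unique(parent_ids)) {
    members <- which(parent_ids == pid)
    perm <- if (length(members) == 1) members else sample(members)
    chunk <- ceiling(seq_along(perm) / size)
    for (ch in unique(chunk)) {
      next_id <- next_id + 1L
      child[perm[chunk == ch]] <- next_id
    }
  }
  child
}

validate_forest <- function(forest) {
  with(forest, {
    stopifnot(length(clone8) == n_nuclei(mold),
              all(clone8 > 0), all(clone4 > 0), all(clone2 > 0))
    # strict nesting: each child clone maps into exactly one parent clone
    stopifnot(!anyDuplicated(unique(cbind(clone4, clone8))[, "clone4"]),
              !anyDuplicated(unique(cbind(clone2, clone4))[, "clone2"]))
  })
  invisible(forest)
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest: %d nuclei in %d/%d/%d clones of 8/4/2>\n",
              n_nuclei(x$mold), length(unique(x$clone8)),
              length(unique(x$clone4)), length(unique(x$clone2))))
  invisible(x)
}

#' Anteroposterior clone widths in percent egg length
#'
#' The width of a clone is its extent along the x (anteroposterior) axis,
#' `max(x) - min(x)` within the clone, divided by the embryo length and
#' expressed in percent EL. The default embryo length of 590 um is the
#' flattened egg length. Undersized remainder clones (arising when the
#' nuclear count does not divide by the clone size) are excluded by
#' default; with `full_only = FALSE` they are reported too (a singleton
#' clone has width 0).
#'
#' @param forest A [build_clones()] result.
#' @param level Clone level: 8, 4 or 2.
#' @param embryo_length Egg length in um (default 590).
#' @param full_only Drop clones smaller than `level`?
#' @return Numeric vector of per-clone widths in % EL.
#' @export
clone_width_el <- function(forest, level = 8, embryo_length = 590,
                           full_only = TRUE) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (embryo_length <= 0) stop("embryo_length must be positive",
                               call. = FALSE)
  level <- match.arg(as.character(level), c("8", "4", "2"))
  ids <- forest[[paste0("clone", level)]]
  x <- forest$mold$nuclei$x
  widths <- vapply(split(x, ids), function(xs) diff(range(xs)), numeric(1))
  if (full_only) {
    widths <- widths[tabulate(ids)[as.integer(names(widths))] ==
                       as.integer(level)]
  }
  unname(widths) / embryo_length * 100
}

#' Transcribing-probability schedule across nuclear cycles
#'
#' The per-gene-copy probability of being caught actively transcribing in a
#' snapshot at cycles 11-14. The default schedule (90%, 90%, 50%, 50%)
#' reflects the experimentally observed drop between cycles 12 and 13.
#' Probabilities may only stay level or decrease (states can be switched
#' off between cycles but never on), and the cycle-14 probability must
#' equal the cycle-13 one: no further state change is modelled after the
#' last division.
#'
#' @param p11,p12,p13,p14 Probabilities in `[0, 1]`.
#' @return A named numeric vector of class `transcription_schedule`.
#' @export
transcription_schedule <- function(p11 = 0.9, p12 = 0.9, p13 = 0.5,
                                   p14 = 0.5) {
  p <- c(`11` = p11, `12` = p12, `13` = p13, `14` = p14)
  if (any(p < 0 | p > 1)) {
    stop("transcribing probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p12 > p11 + 1e-12 || p13 > p12 + 1e-12) {
    stop("transcribing probabilities cannot increase between cycles: ",
         "no switch-on mechanism is modelled", call. = FALSE)
  }
  if (abs(p14 - p13) > 1e-12) {
    stop("cycle-14 probability must equal the cycle-13 probability",
         call. = FALSE)
  }
  structure(p, class = "transcription_schedule")
}

#' Expected type fractions at a transcribing probability
#'
#' With two gene copies per nucleus transcribing independently with
#' probability `p`, the nuclear types follow `Binomial(2, p)`: fractions
#' `(1 - p)^2`, `2 p (1 - p)`, `p^2` of Types 0, 1 and 2. At `p = 0.9`
#' this is (1%, 18%, 81%); at `p = 0.5`, (25%, 50%, 25%).
#'
#' @param p Per-copy transcribing probability.
#' @return Named numeric vector of fractions over types 0, 1, 2.
#' @export
type_fractions <- function(p) {
  stopifnot(p >= 0, p <= 1)
  c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
}

#' Simulate transcriptional states on a lineage forest
#'
#' With inheritance, each cycle-11 ancestor (one per 8-clone) draws its
#' number of active copies from `Binomial(2, p11)` and daughters adopt the
#' parental state at every division; whenever the schedule steps down, each
#' active copy is independently retained with probability
#' `p_next / p_prev` (switched off otherwise), applied at the matching
#' lineage level: entering cycle 12 per 4-clone, entering cycle 13 per
#' 2-clone. At the default 90/90/50/50 schedule the only switch-off happens
#' entering cycle 13, with per-copy off-probability 4/9, and the cycle-14
#' marginal is exactly `Binomial(2, 0.5)` — the same marginal as the
#' no-inheritance scenario, so the two scenarios differ only in spatial
#' arrangement. Without inheritance, every cycle-14 nucleus independently
#' draws its type from `Binomial(2, p14)`.
#'
#' @param forest A [build_clones()] result.
#' @param schedule A [transcription_schedule()].
#' @param inheritance Logical: propagate states through the lineage?
#' @param seed Optional integer seed.
#' @return The mold as a typed [nuclear_field()]; positions are untouched,
#'   only types (and dot counts, set equal to types) change.
#' @export
simulate_states <- function(forest, schedule = transcription_schedule(),
                            inheritance = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(forest, "lineage_forest"))
  if (!inherits(schedule, "transcription_schedule")) {
    schedule <- do.call(transcription_schedule, as.list(schedule))
  }
  n <- n_nuclei(forest$mold)
  if (!inheritance) {
    return(set_types(forest$mold, rbinom(n, 2, schedule[["14"]])))
  }
  keep12 <- if (schedule[["11"]] > 0) schedule[["12"]] / schedule[["11"]] else 0
  keep13 <- if (schedule[["12"]] > 0) schedule[["13"]] / schedule[["12"]] else 0
  ids8 <- unique(forest$clone8)
  a8 <- rbinom(length(ids8), 2, schedule[["11"]])
  names(a8) <- as.character(ids8)
  map48 <- unique(cbind(c4 = forest$clone4, c8 = forest$clone8))
  a4 <- rbinom(nrow(map48), a8[as.character(map48[, "c8"])], keep12)
  names(a4) <- as.character(map48[, "c4"])
  map24 <- unique(cbind(c2 = forest$clone2, c4 = forest$clone4))
  a2 <- rbinom(nrow(map24), a4[as.character(map24[, "c4"])], keep13)
  names(a2) <- as.character(map24[, "c2"])
  set_types(forest$mold, as.integer(a2[as.character(forest$clone2)]))
}

#' Run a replicated lineage-inheritance experiment
#'
#' The end-to-end contrast of the package: on one fixed mold, repeat
#' `n_replicates` times (99 in the standard analysis) a fresh clone
#' assignment and state simulation, with or without inheritance, and
#' compute the Type-0, Type-1, Type-2 H-functions and the Type-0/Type-2
#' bivariate H-function of each replicate. With inheritance, the Type-0 and
#' Type-2 mean H rise above zero over a contiguous range of radii starting
#' near the nuclear diameter — dispersed clustering — while the bivariate
#' profile turns negative (mutual repulsion); without inheritance all
#' profiles hover around the CSR line.
#'
#' @param mold A [nuclear_field()] used as the fixed mold, or a
#'   [mold_config()] from which one is generated.
#' @param schedule A [transcription_schedule()].
#' @param inheritance Logical scenario switch.
#' @param n_replicates Number of replicate simulations.
#' @param seed Optional integer seed.
#' @param grid A [radial_grid()].
#' @return An object of class `lineage_experiment`: list with `r`,
#'   `profiles` (named list of replicate x bin matrices `H0`, `H1`, `H2`,
#'   `H02`), `mean`, `sd` (named lists of per-bin vectors),
#'   `positive_ranges` (named list of data frames of contiguous r ranges
#'   where the mean profile is positive), `inheritance`, `mold`.
#' @export
run_experiment <- function(mold, schedule = transcription_schedule(),
                           inheritance = TRUE, n_replicates = 99,
                           seed = NULL, grid = radial_grid()) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(mold, "mold_config")) mold <- generate_mold(mold)
  validate_field(mold)
  stats_names <- c("H0", "H1", "H2", "H02")
  profiles <- lapply(stats_names, function(s)
    matrix(NA_real_, n_replicates, length(grid$edges)))
  names(profiles) <- stats_names
  for (rep in seq_len(n_replicates)) {
    forest <- build_clones(mold)
    field <- simulate_states(forest, schedule, inheritance)
    tc <- type_counts(field)
    if (any(tc[c("0", "2")] < 2)) {
      stop("replicate produced fewer than two Type-0 or Type-2 nuclei; ",
           "this schedule is too extreme for the field size", call. = FALSE)
    }
    profiles$H0[rep, ] <- h_function(field, 0, grid)$values
    profiles$H1[rep, ] <- h_function(field, 1, grid)$values
    profiles$H2[rep, ] <- h_function(field, 2, grid)$values
    profiles$H02[rep, ] <- h_function_bivariate(field, 0, 2, grid)$values
  }
  means <- lapply(profiles, colMeans)
  sds <- lapply(profiles, function(m) apply(m, 2, sd))
  pos <- lapply(means, function(m) contiguous_ranges(m > 0, grid$edges))
  structure(list(r = grid$edges, profiles = profiles, mean = means,
                 sd = sds, positive_ranges = pos,
                 inheritance = inheritance, n_replicates = n_replicates,
                 mold = mold),
            class = "lineage_experiment")
}

#' @export
print.lineage_experiment <- function(x, ...) {
  cat(sprintf("<lineage_experiment: %d replicates, inheritance %s>\n",
              x$n_replicates, if (x$inheritance) "ON" else "OFF"))
  for (s in names(x$positive_ranges)) {
    pr <- x$positive_ranges[[s]]
    msg <- if (nrow(pr) == 0) "never positive" else
      paste(sprintf("%g-%g um", pr$r_lo, pr$r_hi), collapse = ", ")
    cat(sprintf("  mean %s > 0 for r in: %s\n", s, msg))
  }
  invisible(x)
}
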