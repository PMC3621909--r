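test_that("clone construction partitions nuclei into nested 8/4/2 groups", {
  f <- generate_random_field(16, c(0, 40, 0, 40), seed = 90)
  fst <- build_clones(f, seed = 91)
  expect_length(unique(fst$clone8), 2L)
  expect_length(unique(fst$clone4), 4L)
  expect_length(unique(fst$clone2), 8L)
  expect_true(all(table(fst$clone8) == 8))
  expect_true(all(table(fst$clone4) == 4))
  expect_true(all(table(fst$clone2) == 2))
  # strict nesting: each child clone lies inside one parent clone
  expect_true(all(tapply(fst$clone8, fst$clone4,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(fst$clone4, fst$clone2,
                         function(v) length(unique(v))) == 1))
  # deterministic given seed
  expect_identical(build_clones(f, seed = 91)$clone2, fst$clone2)
  expect_error(build_clones(generate_random_field(5, seed = 92)),
               "at least 8")
})

test_that("a non-multiple-of-8 field leaves one undersized remainder clone", {
  f <- generate_random_field(21, c(0, 50, 0, 50), seed = 93)
  fst <- build_clones(f, seed = 94)
  sizes <- table(fst$clone8)
  expect_identical(sum(sizes == 8), 2L)
  expect_identical(sum(sizes == 5), 1L)
})

test_that("most clones are spatially compact under greedy aggregation", {
  m <- generate_mold(seed = 95)
  threshold <- 4 * mean(nnd(m))
  set.seed(96)
  mx <- unlist(replicate(10, {
    fst <- build_clones(m)
    vapply(split(seq_len(n_nuclei(m)), fst$clone8),
           function(ix) max(stats::dist(m$nuclei[ix, c("x", "y")])),
           numeric(1))
  }, simplify = FALSE))
  # the clones built late from scattered remnants are stringier, so only
  # the bulk of the clones stays within a few NND of one another
  expect_lt(median(mx), threshold)
  expect_gt(mean(mx < threshold), 0.5)
})

test_that("clone widths convert to percent egg length", {
  f <- make_field(c(100, 110, seq(10, 80, 10)), rep(c(10, 20), 5),
                  bounds = c(0, 200, 0, 30))
  fst <- build_clones(f, seed = 97)
  # direct arithmetic on a hand-built clone
  expect_equal(diff(range(c(100, 110))) / 590 * 100, 1.695, tolerance = 1e-3)
  w_all <- clone_width_el(fst, full_only = FALSE)
  expect_true(all(w_all >= 0))
  # a singleton remainder clone has zero width
  g <- generate_random_field(9, c(0, 50, 0, 50), seed = 98)
  gf <- build_clones(g, seed = 99)
  expect_identical(min(clone_width_el(gf, full_only = FALSE)), 0)
  expect_length(clone_width_el(gf), 1L)  # remainder excluded by default
})

test_that("schedules validate monotonicity and the cycle-14 freeze", {
  expect_error(transcription_schedule(p12 = 0.95), "cannot increase")
  expect_error(transcription_schedule(p13 = 0.95), "cannot increase")
  expect_error(transcription_schedule(p14 = 0.6), "cycle-14")
  expect_error(transcription_schedule(p11 = 1.2), "\\[0, 1\\]")
  s <- transcription_schedule(0.6, 0.6, 0.4, 0.4)
  expect_equal(unname(s[["13"]]), 0.4)
})

test_that("state simulation conserves the mold and honours degenerate cases", {
  m <- generate_mold(seed = 100)
  fst <- build_clones(m, seed = 101)
  f <- simulate_states(fst, seed = 102)
  expect_equal(f$nuclei$x, m$nuclei$x)
  expect_equal(f$nuclei$y, m$nuclei$y)
  all_on <- simulate_states(fst, transcription_schedule(1, 1, 1, 1),
                            inheritance = TRUE, seed = 103)
  expect_true(all(all_on$nuclei$type == 2L))
  # deterministic given seed
  expect_identical(simulate_states(fst, seed = 102)$nuclei$type,
                   f$nuclei$type)
})

test_that("with inheritance, whole 2-clones share one state", {
  m <- generate_mold(seed = 104)
  fst <- build_clones(m, seed = 105)
  f <- simulate_states(fst, inheritance = TRUE, seed = 106)
  per_clone <- tapply(f$nuclei$type, fst$clone2,
                      function(v) length(unique(v)))
  expect_true(all(per_clone == 1))
})

test_that("cycle-14 marginals are binomial in both scenarios", {
  m <- generate_mold(seed = 107)
  # defaults: both scenarios must land on Binomial(2, 0.5) = (25, 50, 25)%
  set.seed(108)
  frac <- function(inherit) {
    counts <- rowSums(vapply(1:99, function(k)
      type_counts(simulate_states(build_clones(m), inheritance = inherit)),
      integer(3)))
    counts / sum(counts)
  }
  expect_lt(max(abs(frac(FALSE) - c(0.25, 0.5, 0.25))), 0.02)
  expect_lt(max(abs(frac(TRUE) - c(0.25, 0.5, 0.25))), 0.02)
  # a flat 90% schedule gives the (1, 18, 81)% snapshot fractions
  set.seed(109)
  sch <- transcription_schedule(0.9, 0.9, 0.9, 0.9)
  counts <- rowSums(vapply(1:99, function(k)
    type_counts(simulate_states(build_clones(m), sch, inheritance = TRUE)),
    integer(3)))
  expect_lt(max(abs(counts / sum(counts) - c(0.01, 0.18, 0.81))), 0.03)
  expect_equal(unname(type_fractions(0.9)), c(0.01, 0.18, 0.81))
  expect_equal(unname(type_fractions(0.5)), c(0.25, 0.5, 0.25))
})

test_that("the inheritance contrast is robust to the transcribing schedule", {
  m <- generate_mold(seed = 110)
  for (p_late in c(0.4, 0.6)) {
    sch <- transcription_schedule(0.6, 0.6, p_late, p_late)
    on <- run_experiment(m, sch, TRUE, n_replicates = 15, seed = 111)
    off <- run_experiment(m, sch, FALSE, n_replicates = 15, seed = 112)
    mid <- on$r >= 8 & on$r <= 44
    expect_gt(mean(on$mean$H2[mid]), 0)
    expect_gt(mean(on$mean$H0[mid]), 0)
    expect_gt(mean(on$mean$H2[mid]), 2 * abs(mean(off$mean$H2[mid])))
  }
})
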