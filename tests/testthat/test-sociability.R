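topo4 <- ring_topology(4)

test_that("time together counts only shared compartment time", {
  w <- c(0, 1000)
  a <- make_track("C1", c(0, 1000))
  b <- make_track("C1", c(0, 1000))
  tt <- time_together(a, b, w, topo4)
  expect_equal(tt$together_s, 1000)
  expect_equal(tt$analyzable_s, 1000)

  c2 <- make_track("C2", c(0, 1000))
  expect_equal(time_together(a, c2, w, topo4)$together_s, 0)

  corr <- make_track("CORRIDOR", c(0, 1000))
  tt3 <- time_together(a, corr, w, topo4)
  expect_equal(tt3$analyzable_s, 0)
  expect_false(tt3$defined)
})

test_that("expected time together is the preference dot product", {
  u <- setNames(rep(0.25, 4), paste0("C", 1:4))
  expect_equal(expected_time_together(u, u, 1000), 250)

  p1 <- setNames(c(1, 0, 0, 0), paste0("C", 1:4))
  p2 <- setNames(c(0, 1, 0, 0), paste0("C", 1:4))
  expect_equal(expected_time_together(p1, p2, 1000), 0)

  set.seed(5)
  for (i in 1:20) {
    x <- runif(4); x <- setNames(x / sum(x), paste0("C", 1:4))
    y <- runif(4); y <- setNames(y / sum(y), paste0("C", 1:4))
    t_ij <- runif(1, 100, 10000)
    expect_equal(expected_time_together(x, y, t_ij), t_ij * sum(x * y))
  }
  expect_error(expected_time_together(u * 2, u, 100), "sum to 1")
})

test_that("always-together mice with uniform preferences score 0.75", {
  # both mice cycle through all four compartments in lockstep
  locs <- rep(paste0("C", 1:4), 10)
  brk <- seq(0, 4000, by = 100)
  a <- make_track(locs, brk)
  m <- incohort_sociability(list(x = a, y = a), c(0, 4000), topo4, "p")
  expect_equal(m$s["x", "y"], 0.75)
  expect_equal(m$t_base["x", "y"], 4000)
})

test_that("sociability matrices are symmetric, bounded and zero-diagonal", {
  sc <- sim_config(n_mice = 5, schedule = dark_only_schedule(43200),
                   affinity = block_affinity(c(1, 1, 1, 2, 2), 1), seed = 19)
  res <- simulate_cohort(sc)
  m <- incohort_sociability(res$truth$tracks, c(0, 43200), res$topology, "dark1")
  expect_identical(m$s, t(m$s))
  expect_equal(unname(diag(m$s)), rep(0, 5))
  off <- m$s[upper.tri(m$s)]
  expect_true(all(off >= -1 & off <= 1, na.rm = TRUE))
})

test_that("relabeling tags permutes the matrix and nothing else", {
  sc <- sim_config(n_mice = 4, schedule = dark_only_schedule(43200), seed = 29)
  res <- simulate_cohort(sc)
  tr <- res$truth$tracks
  m1 <- incohort_sociability(tr, c(0, 43200), res$topology)
  perm <- c(3, 1, 4, 2)
  m2 <- incohort_sociability(tr[perm], c(0, 43200), res$topology)
  expect_equal(m2$s, m1$s[perm, perm])
})

test_that("pair statistics match the 1-s grid brute force", {
  sc <- sim_config(n_mice = 3, schedule = dark_only_schedule(43200), seed = 37,
                   affinity = block_affinity(c(1, 1, 2), 1))
  res <- simulate_cohort(sc)
  tr <- lapply(res$truth$tracks, round_track)
  w <- c(0, 43200)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    tt <- time_together(tr[[pair[1]]], tr[[pair[2]]], w, res$topology)
    gr <- grid_pair(tr[[pair[1]]], tr[[pair[2]]], w, res$topology)
    expect_equal(tt$together_s, gr$together_s, tolerance = 1e-6)
    expect_equal(tt$analyzable_s, gr$analyzable_s, tolerance = 1e-6)
  }
  m <- incohort_sociability(tr, w, res$topology)
  g12 <- grid_pair(tr[[1]], tr[[2]], w, res$topology)
  expect_equal(m$s[1, 2], g12$s, tolerance = 1e-6)
})

test_that("per-mouse summary is the two-stage partner/phase mean", {
  tags <- c("a", "b", "c")
  mk <- function(vals, phase) {
    s <- matrix(0, 3, 3, dimnames = list(tags, tags))
    s[upper.tri(s)] <- vals
    s <- s + t(s)
    structure(list(phase = phase, s = s, t_base = s * 0 + 100),
              class = "sociability_matrix")
  }
  m1 <- mk(c(0.1, 0.2, 0.3), "p1")  # pairs (a,b), (a,c), (b,c)
  # identical matrices: the summary equals the single-phase partner mean
  expect_equal(per_mouse_sociability(list(m1, m1, m1)),
               per_mouse_sociability(list(m1)))
  expect_equal(per_mouse_sociability(list(m1))[["a"]], mean(c(0.1, 0.2)))

  # a mouse undefined in one phase is averaged over the remaining phases
  m2 <- mk(c(0.4, 0.5, 0.6), "p2")
  m2$s["a", ] <- m2$s[, "a"] <- NA
  diag(m2$s) <- 0
  out <- per_mouse_sociability(list(m1, m2))
  expect_equal(out[["a"]], mean(c(0.1, 0.2)))
  expect_equal(out[["b"]], mean(c(mean(c(0.1, 0.3)), 0.6)))

  # random matrices: matches a hand-computed two-stage mean
  set.seed(41)
  ms <- lapply(1:3, function(i) mk(runif(3, -0.2, 0.2), paste0("r", i)))
  hand <- rowMeans(vapply(ms, function(m) {
    s <- m$s; diag(s) <- NA; rowMeans(s, na.rm = TRUE)
  }, numeric(3)))
  expect_equal(unname(per_mouse_sociability(ms)), unname(hand))
})

test_that("odor approach is 1 under identical behavior and tracks doubling", {
  tr <- make_track(rep(c("C3", "C1"), 4), seq(0, 800, by = 100))
  # identical test and baseline windows within a periodic track
  out <- approach_to_social_odor(list(m = tr), "C3", "C1",
                                 c(0, 400), c(400, 800), topo4)
  expect_equal(out$ratio, 1)

  # doubling stimulus time in the test phase doubles the ratio as eps -> 0
  base <- make_track(c("C3", "C1"), c(0, 100, 400))
  test <- make_track(c("C3", "C1"), c(400, 600, 800))
  both <- make_track(c("C3", "C1", "C3", "C1"), c(0, 100, 400, 600, 800))
  out2 <- approach_to_social_odor(list(m = both), "C3", "C1",
                                  c(400, 800), c(0, 400), topo4,
                                  epsilon_s = 1e-9)
  expect_equal(out2$ratio, (200 / 200) / (100 / 300), tolerance = 1e-6)
  expect_error(approach_to_social_odor(list(m = both), "C3", "C3",
                                       c(400, 800), c(0, 400), topo4),
               "must differ")
})

test_that("undefined pairs propagate as missing, never zero", {
  a <- make_track("C1", c(0, 100))
  b <- make_track("UNKNOWN", c(0, 100))
  m <- incohort_sociability(list(a = a, b = b), c(0, 100), topo4)
  expect_true(is.na(m$s["a", "b"]))
  expect_equal(m$t_base["a", "b"], 0)
})
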