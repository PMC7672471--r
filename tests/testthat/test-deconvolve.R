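test_that("tag likelihood is modal, symmetric, and strand-mirrored", {
  Lc <- 200; mu <- 100
  # + strand mode at mu - 6
  p_mode <- tag_likelihood(mu - 6, "+", mu, Lc)
  for (d in c(1, 3, 10))
    expect_gt(p_mode, tag_likelihood(mu - 6 + d, "+", mu, Lc))
  # symmetry about the strand mode
  for (d in c(1, 4, 9))
    expect_equal(tag_likelihood(mu - 6 + d, "+", mu, Lc),
                 tag_likelihood(mu - 6 - d, "+", mu, Lc), tolerance = 1e-12)
  # strand mirror: Pr(col, + | mu) = Pr(2 mu - col, - | mu)
  for (col in c(80, 94, 100, 110))
    expect_equal(tag_likelihood(col, "+", mu, Lc),
                 tag_likelihood(2 * mu - col, "-", mu, Lc), tolerance = 1e-12)
  # matches the precomputed matrices used inside EM
  LM <- exoalign:::likelihood_matrices(tag_distribution_model(), Lc)
  expect_equal(LM$plus[mu, 87], tag_likelihood(87, "+", mu, Lc),
               tolerance = 1e-12)
  expect_equal(sum(LM$plus[mu, ]), 1, tolerance = 1e-9)
})

test_that("EM recovers a single planted crosslink", {
  set.seed(21)
  proj <- list(e1 = sim_window_tags(100, 1000, 200))
  fit <- em_fit(proj, 200, em_config(alpha = 20))
  expect_equal(length(fit$mu), 1L)
  expect_lte(abs(fit$mu - 100), 2)
  expect_true(fit$converged)
  q <- quantify(fit, proj)
  expect_equal(unname(q$normalized[1, 1]), 1)
})

test_that("EM separates two crosslinks 30 bp apart with equal weights", {
  set.seed(22)
  proj <- list(e1 = sim_window_tags(c(80, 110), c(500, 500), 200))
  fit <- em_fit(proj, 200, em_config(alpha = 20))
  expect_equal(length(fit$mu), 2L)
  expect_true(all(abs(sort(fit$mu) - c(80, 110)) <= 2))
  expect_true(all(fit$pi >= 0.4 & fit$pi <= 0.6))
})

test_that("alpha = 0 reduces the MAP update to maximum likelihood", {
  set.seed(23)
  proj <- list(e1 = sim_window_tags(c(90, 120), c(400, 200), 200))
  fit <- em_fit(proj, 200, em_config(alpha = 0, max_iterations = 50))
  # with alpha = 0 no component is eliminated and pi_j = N_j / N exactly
  expect_equal(unname(fit$pi[1, ]),
               unname(fit$N[1, ] / sum(fit$N[1, ])), tolerance = 1e-9)
  expect_gt(length(fit$mu), 2)  # grid components survive (no sparsity)
})

test_that("EM invariants: pi sums, responsibility mass, posterior ascent", {
  set.seed(24)
  proj <- list(a = sim_window_tags(c(70, 100, 130), c(600, 900, 300), 220),
               b = sim_window_tags(c(70, 100, 130), c(300, 300, 900), 220))
  fit <- em_fit(proj, 220, em_config(alpha = 20))
  # pi rows sum to 1 after every iteration
  expect_lt(max(fit$trace$max_pi_dev), 1e-9)
  # responsibility conservation: recovered mass equals total tag weight
  expect_equal(unname(rowSums(fit$N)),
               unname(vapply(proj, function(p) sum(p$w), numeric(1))),
               tolerance = 1e-6)
  # log posterior non-decreasing while the active set is unchanged
  tr <- fit$trace
  same <- tr$active_sig[-1] == tr$active_sig[-nrow(tr)]
  dlp <- diff(tr$log_posterior)
  expect_true(all(dlp[same] >= -1e-6))
})

test_that("number of surviving components is non-increasing in alpha", {
  set.seed(25)
  proj <- list(e1 = sim_window_tags(c(60, 100, 140), c(800, 500, 300), 200))
  sizes <- vapply(c(0, 5, 20, 80, 250), function(a) suppressWarnings(
    length(em_fit(proj, 200, em_config(alpha = a))$mu)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("all components below alpha retains the strongest, with warning", {
  set.seed(26)
  proj <- list(e1 = sim_window_tags(100, 30, 200))
  expect_warning(fit <- em_fit(proj, 200, em_config(alpha = 500)),
                 "strongest")
  expect_equal(length(fit$mu), 1L)
  expect_equal(unname(fit$pi[1, 1]), 1)
})

test_that("quantification recovers planted per-protein strength rows", {
  set.seed(27)
  # protein A: 80% site 1 / 20% site 2; B opposite; C only site 3
  mus <- c(80, 120, 160)
  proj <- list(A = sim_window_tags(mus, c(800, 200, 0), 240),
               B = sim_window_tags(mus, c(200, 800, 0), 240),
               C = sim_window_tags(mus, c(0, 0, 1000), 240))
  fit <- em_fit(proj, 240, em_config(alpha = 20))
  q <- quantify(fit, proj)
  # map recovered components to nearest truth site
  stopifnot(length(q$mu) >= 3)
  site_of <- vapply(q$mu, function(m) which.min(abs(mus - m)), integer(1))
  agg <- t(vapply(1:3, function(j)
    rowSums(q$normalized[, site_of == j, drop = FALSE]), numeric(3)))
  truth <- rbind(c(.8, .2, 0), c(.2, .8, 0), c(0, 0, 1))
  expect_lt(max(abs(t(agg) - truth)), 0.05)
  # tags far from a component contribute ~nothing to it
  far <- which(site_of == 3)
  expect_lt(sum(q$normalized["A", far]), 0.01)
})

test_that("condition comparison recovers a planted occupancy shift", {
  set.seed(28)
  mus <- c(90, 140)
  p1 <- list(A = sim_window_tags(mus, c(800, 200), 220),
             B = sim_window_tags(mus, c(500, 500), 220))
  p2 <- list(A = sim_window_tags(mus, c(400, 600), 220),  # 50% mass moved
             B = sim_window_tags(mus, c(500, 500), 220))
  fit <- em_fit(c(p1, p2), 220, em_config(alpha = 20))
  q1 <- quantify(fit, p1); q2 <- quantify(fit, p2)
  fd <- compare_conditions(q1, q2)
  site_of <- vapply(q1$mu, function(m) which.min(abs(mus - m)), integer(1))
  expect_lt(max(fd["A", site_of == 1]), 0)  # lost mass at site 1
  expect_gt(max(fd["A", site_of == 2]), 0)  # gained at site 2
  expect_lt(max(abs(fd["B", ])), 0.25)      # unshifted protein ~flat

  # identical matrices give identically zero fold differences
  expect_true(all(compare_conditions(q1, q1) == 0))
  # mismatched positions are fatal
  qx <- q1; qx$mu <- qx$mu + 1
  expect_error(compare_conditions(qx, q2), "mismatched")
})
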