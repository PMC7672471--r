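# Shared fixtures, built in code.

# The "variably spaced complex" world used by the alignment tests: 6
# experiments over two dense blocks of 4 crosslink sites each (12 bp pitch),
# region-specific spacer between the blocks, tRNA-like spacer range.
# Strength matrix drawn once from a fixed seed and frozen here.
dense_world_truth <- function(n_regions, tags_per_region = 5000,
                              jitter_halfwidth = 30, spacers = NULL,
                              reverse_fraction = 0,
                              spacer_range = c(5, 60), K = 6) {
  set.seed(9901)
  so <- c(-66, -54, -42, -30, 18, 30, 42, 54)
  bl <- c(1, 1, 1, 1, 2, 2, 2, 2)
  st <- matrix(rgamma(K * 8, 1.5), K, 8)
  st <- st / rowSums(st)
  synthetic_truth(n_regions = n_regions, window = 400,
                  experiments = sprintf("e%02d", seq_len(K)),
                  site_offsets = so, site_blocks = bl, strengths = st,
                  tags_per_region = tags_per_region,
                  spacer_range = spacer_range, spacers = spacers,
                  reverse_fraction = reverse_fraction,
                  jitter_halfwidth = jitter_halfwidth)
}

dense_gap_cfg <- function() gap_config(5, 0.5)

region_profiles <- function(sim) {
  lapply(seq_len(nrow(sim$regions)), function(r)
    build_profile(sim$libraries, sim$regions[r, ], sim$window))
}

# alignment-space column of each planted site, per region (R x J)
planted_site_columns <- function(ma, sim) {
  offs <- sim$truth$site_window_offsets
  sapply(seq_len(ncol(offs)), function(j)
    sapply(seq_len(nrow(sim$regions)), function(r) {
      id <- sim$regions$id[r]
      o <- offs[r, j]
      if (ma$orientations[[id]] == "-") o <- sim$window + 1L - o
      ma$region_maps[[id]][o]
    }))
}

# per-region total gap length inserted inside the region's aligned span
region_gap_lengths <- function(ma, sim) {
  vapply(sim$regions$id, function(id) {
    map <- ma$region_maps[[id]]
    diff(range(map)) + 1L - length(map)
  }, integer(1))
}

# noise-free two-block profile built from expected tag densities; per-site
# weights differ per experiment (site j weighted j^k) so the layout is not
# palindromic and orientation is identifiable
expected_profile <- function(spacer, L = 200, K = 3,
                             sites1 = c(50, 65), sites2 = c(110, 125),
                             scale = 500, shift = 0) {
  v <- matrix(0, 2 * K, L)
  sites <- c(sites1, sites2 + spacer)
  for (j in seq_along(sites)) {
    s <- sites[j]
    w <- scale * dnorm(seq_len(L), s + shift - 6, 6)
    cc <- scale * dnorm(seq_len(L), s + shift + 6, 6)
    for (k in seq_len(K)) {
      wt <- j^((k - 1) / 2)
      v[2 * k - 1, ] <- v[2 * k - 1, ] + round(w * wt)
      v[2 * k, ] <- v[2 * k, ] + round(cc * wt)
    }
  }
  profile_matrix(v, paste0("e", seq_len(K)), "r")
}

# direct one-line transcription of the printed column similarity -- the
# independent oracle for column_similarity()
similarity_oracle <- function(x, y) {
  K <- length(x) / 2
  qb <- mean(x); pb <- mean(y)
  a <- (x[seq(1, 2 * K, 2)] - qb) * (x[seq(2, 2 * K, 2)] - qb)
  b <- (y[seq(1, 2 * K, 2)] - pb) * (y[seq(2, 2 * K, 2)] - pb)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# weighted tag list drawn from the paired-Gaussian model at given sites
sim_window_tags <- function(mus, n_per_site, Lc,
                            model = tag_distribution_model()) {
  half <- model$offset / 2
  recs <- lapply(seq_along(mus), function(j) {
    n <- n_per_site[j]
    if (n == 0) return(NULL)
    st <- sample(c("+", "-"), n, replace = TRUE)
    pos <- round(rnorm(n, mus[j] + ifelse(st == "+", -half, half),
                       model$sigma))
    data.frame(col = pmin(pmax(pos, 1), Lc), strand = st, w = 1)
  })
  df <- do.call(rbind, recs)
  stats::aggregate(w ~ col + strand, df, sum)
}
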