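#' ChIP-exo tag distribution model
#'
#' The expected tag density around a single protein-DNA crosslinking point:
#' a pair of Gaussians with standard deviation `sigma` (6 bp), the + strand
#' one centered `offset/2` bp to the left of the crosslink and the - strand
#' one `offset/2` bp to the right (12 bp strand offset). This reflects
#' lambda exonuclease stopping on average ~6 bp before the crosslink on each
#' strand.
#'
#' @param sigma Gaussian sd in bp.
#' @param offset distance between the + and - strand modes in bp.
#' @return list with `sigma` and `offset`.
#' @export
tag_distribution_model <- function(sigma = 6, offset = 12) {
  stopifnot(sigma > 0, offset >= 0)
  list(sigma = sigma, offset = offset)
}

#' EM configuration
#'
#' @param alpha sparseness prior in tag-count units -- the minimum number of
#'   tags required to support a crosslinking event. If `NULL`, set per
#'   experiment as `max(1, alpha_frac * total tag weight)`.
#' @param alpha_frac fraction of each experiment's tag total used when
#'   `alpha` is `NULL` (default 1%).
#' @param init_spacing initial component spacing in bp (default 5).
#' @param search_halfwidth half-width of the outward position search in the
#'   M-step, in bp (default 50).
#' @param max_iterations,convergence_tol stopping rule: total absolute
#'   change in mixing weights across experiments below the tolerance, or the
#'   iteration cap.
#' @return list of class `EMConfig`.
#' @export
em_config <- function(alpha = NULL, alpha_frac = 0.01, init_spacing = 5,
                      search_halfwidth = 50, max_iterations = 500,
                      convergence_tol = 1e-6) {
  stopifnot(is.null(alpha) || alpha >= 0, init_spacing >= 1,
            search_halfwidth >= 1)
  structure(list(alpha = alpha, alpha_frac = alpha_frac,
                 init_spacing = init_spacing,
                 search_halfwidth = search_halfwidth,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "EMConfig")
}

# Discretized, window-renormalized per-strand densities for every integer
# crosslink position mu in 1..Lc. Rows are mu, columns are tag positions;
# each row sums to 1. A tiny floor keeps logs finite.
likelihood_matrices <- function(model, Lc) {
  pos <- seq_len(Lc)
  half <- model$offset / 2
  Pp <- outer(pos, pos, function(mu, x) dnorm(x, mu - half, model$sigma))
  Pm <- outer(pos, pos, function(mu, x) dnorm(x, mu + half, model$sigma))
  Pp <- pmax(Pp / rowSums(Pp), 1e-300)
  Pm <- pmax(Pm / rowSums(Pm), 1e-300)
  list(plus = Pp, minus = Pm, lplus = log(Pp), lminus = log(Pm))
}

#' Probability of a tag given a crosslink position
#'
#' Discretized Gaussian density of observing a tag 5' end at `column` on
#' `strand`, given a crosslinking event at `mu`, renormalized so each
#' strand's density sums to 1 over the window `1..Lc`.
#'
#' @param column tag 5' position (alignment column).
#' @param strand `"+"` or `"-"`.
#' @param mu crosslink position.
#' @param Lc window length.
#' @param model a [tag_distribution_model()].
#' @return probability.
#' @export
tag_likelihood <- function(column, strand, mu, Lc,
                           model = tag_distribution_model()) {
  stopifnot(strand %in% c("+", "-"))
  half <- model$offset / 2
  center <- if (strand == "+") mu - half else mu + half
  d <- dnorm(seq_len(Lc), center, model$sigma)
  d[column] / sum(d)
}

#' Tag projections from a composite profile
#'
#' Collapses a (background-corrected) composite ProfileMatrix into the
#' weighted tag list the EM consumes: per experiment, one record per nonzero
#' cell with its alignment column, strand, and (possibly fractional) weight.
#'
#' @param P a composite [profile_matrix()] of raw or background-corrected
#'   counts.
#' @return named list (one per experiment) of data.frames with columns
#'   `col`, `strand`, `w`.
#' @export
composite_projections <- function(P) {
  stopifnot(inherits(P, "ProfileMatrix"))
  out <- lapply(seq_len(P$K), function(k) {
    W <- P$values[2L * k - 1L, ]; C <- P$values[2L * k, ]
    iw <- which(W > 0); ic <- which(C > 0)
    data.frame(col = c(iw, ic),
               strand = rep(c("+", "-"), c(length(iw), length(ic))),
               w = c(W[iw], C[ic]))
  })
  names(out) <- P$experiments
  out
}

# per-experiment likelihood matrix (tags x components) for positions mus
lik_for <- function(pr, mus, LM) {
  out <- matrix(0, nrow = nrow(pr), ncol = length(mus))
  pl <- pr$strand == "+"
  if (any(pl)) out[pl, ] <- t(LM$plus[mus, pr$col[pl], drop = FALSE])
  if (any(!pl)) out[!pl, ] <- t(LM$minus[mus, pr$col[!pl], drop = FALSE])
  out
}

log_posterior <- function(proj, mus, pi_mat, alpha, LM) {
  lp <- 0
  for (k in seq_along(proj)) {
    pr <- proj[[k]]
    if (nrow(pr) == 0) next
    lik <- lik_for(pr, mus, LM)
    mix <- as.vector(lik %*% pi_mat[k, ])
    lp <- lp + sum(pr$w * log(pmax(mix, 1e-300)))
    act <- pi_mat[k, ] > 0
    lp <- lp - alpha[k] * sum(log(pi_mat[k, act]))
  }
  lp
}

#' Fit the crosslink mixture model by EM
#'
#' Components are initialized on a regular grid along the window (one every
#' `init_spacing` bp) with uniform weights per experiment. Each iteration
#' runs, per experiment, the responsibility E-step and the MAP weight update
#' under a negative Dirichlet prior,
#' `pi_j = max(0, N_j - alpha) / sum_j' max(0, N_j' - alpha)`,
#' followed by a single position update shared across experiments: each
#' component's position moves to the integer column within
#' `search_halfwidth` of its previous value that maximizes the
#' responsibility-weighted log-likelihood summed over all experiments (the
#' cross-experiment positional coupling). Components that land on the same
#' position are combined; components with zero weight in every experiment
#' are pruned. Iteration stops when the total absolute change in weights
#' falls below `convergence_tol`.
#'
#' @param proj tag projections, as from [composite_projections()].
#' @param Lc window (alignment span) length in columns.
#' @param cfg an [em_config()].
#' @param model a [tag_distribution_model()].
#' @return An object of class `CrosslinkComponents`: `mu` (positions),
#'   `pi` (K x J weights, rows sum to 1 per experiment), `N` (responsibility
#'   mass), `alpha` (per experiment), `trace` (per iteration: log posterior,
#'   number of components, active-set signature), `converged`, `n_iter`.
#' @export
em_fit <- function(proj, Lc, cfg = em_config(),
                   model = tag_distribution_model()) {
  K <- length(proj)
  totals <- vapply(proj, function(p) sum(p$w), numeric(1))
  if (all(totals == 0)) stop("no tags in any experiment")
  alpha <- if (is.null(cfg$alpha)) pmax(1, cfg$alpha_frac * totals)
           else rep(cfg$alpha, K)
  LM <- likelihood_matrices(model, Lc)

  mus <- seq.int(max(1L, cfg$init_spacing %/% 2L), Lc, by = cfg$init_spacing)
  J <- length(mus)
  pi_mat <- matrix(1 / J, nrow = K, ncol = J)
  N_mat <- matrix(0, nrow = K, ncol = J)
  trace <- NULL
  converged <- FALSE
  warned <- FALSE
  it <- 0

  while (it < cfg$max_iterations) {
    it <- it + 1
    gam <- vector("list", K)

    # E-step + MAP pi update, per experiment
    pi_old <- pi_mat
    for (k in seq_len(K)) {
      pr <- proj[[k]]
      if (nrow(pr) == 0) { gam[[k]] <- matrix(0, 0, J); next }
      lik <- lik_for(pr, mus, LM)
      num <- sweep(lik, 2, pi_mat[k, ], `*`)
      den <- rowSums(num)
      g <- num / pmax(den, 1e-300)
      gam[[k]] <- g
      N <- colSums(pr$w * g)
      N_mat[k, ] <- N
      act <- pmax(0, N - alpha[k])
      if (sum(act) == 0) {
        if (!warned) {
          warning("all components fell below alpha in experiment '",
                  names(proj)[k], "'; retaining the strongest component")
          warned <- TRUE
        }
        pi_new <- numeric(J); pi_new[which.max(N)] <- 1
      } else pi_new <- act / sum(act)
      pi_mat[k, ] <- pi_new
    }

    # shared position update: argmax over +/- search_halfwidth, summed
    # responsibilities across experiments; ties resolve toward previous mu
    mus_new <- mus
    for (j in seq_len(J)) {
      if (all(pi_mat[, j] == 0)) next
      cand <- seq.int(max(1L, mus[j] - cfg$search_halfwidth),
                      min(Lc, mus[j] + cfg$search_halfwidth))
      sc <- numeric(length(cand))
      for (k in seq_len(K)) {
        pr <- proj[[k]]
        if (nrow(pr) == 0) next
        wg <- pr$w * gam[[k]][, j]
        pl <- pr$strand == "+"
        if (any(pl))
          sc <- sc + as.vector(LM$lplus[cand, pr$col[pl], drop = FALSE] %*%
                                 wg[pl])
        if (any(!pl))
          sc <- sc + as.vector(LM$lminus[cand, pr$col[!pl], drop = FALSE] %*%
                                  wg[!pl])
      }
      best <- which(sc == max(sc))
      if (length(best) > 1)
        best <- best[order(abs(cand[best] - mus[j]), cand[best])[1]]
      mus_new[j] <- cand[best]
    }
    mus <- mus_new

    # combine components sharing a position
    merged <- anyDuplicated(mus) > 0
    if (merged) {
      keep <- !duplicated(mus)
      for (mval in unique(mus[duplicated(mus)])) {
        grp <- which(mus == mval)
        pi_mat[, grp[1]] <- rowSums(pi_mat[, grp, drop = FALSE])
        N_mat[, grp[1]] <- rowSums(N_mat[, grp, drop = FALSE])
      }
      mus <- mus[keep]
      pi_mat <- pi_mat[, keep, drop = FALSE]
      N_mat <- N_mat[, keep, drop = FALSE]
      pi_old <- pi_old[, keep, drop = FALSE]  # dimensions for delta only
      J <- length(mus)
    }

    # prune components dead in every experiment
    alive <- colSums(pi_mat) > 0
    pruned <- !all(alive)
    if (pruned) {
      mus <- mus[alive]
      pi_mat <- pi_mat[, alive, drop = FALSE]
      N_mat <- N_mat[, alive, drop = FALSE]
      pi_old <- pi_old[, alive, drop = FALSE]
      J <- length(mus)
    }

    sig <- paste0(J, "|", paste(mus, collapse = ","), "|",
                  paste(which(pi_mat > 0), collapse = ","))
    lp <- log_posterior(proj, mus, pi_mat, alpha, LM)
    trace <- rbind(trace, data.frame(iter = it, log_posterior = lp,
                                     n_components = J, active_sig = sig,
                                     max_pi_dev = max(abs(rowSums(pi_mat) - 1))))

    delta <- sum(abs(pi_mat - pi_old))
    if (!pruned && !merged && delta < cfg$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  o <- order(mus)
  structure(list(mu = mus[o],
                 pi = matrix(pi_mat[, o], nrow = K,
                             dimnames = list(names(proj), NULL)),
                 N = matrix(N_mat[, o], nrow = K,
                            dimnames = list(names(proj), NULL)),
                 alpha = alpha, trace = trace,
                 converged = converged, n_iter = it,
                 experiments = names(proj), Lc = Lc, model = model),
            class = "CrosslinkComponents")
}

#' @export
print.CrosslinkComponents <- function(x, ...) {
  cat(sprintf("CrosslinkComponents: %d component(s) at [%s], %d experiment(s), %s after %d iteration(s)\n",
              length(x$mu), paste(x$mu, collapse = ", "),
              length(x$experiments),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Quantify crosslinking strengths per experiment
#'
#' With component positions fixed, assigns each experiment's tags to
#' components by maximum-likelihood mixture weights (EM on the weights only,
#' no sparseness prior), yielding the expected tag count per (experiment,
#' component) and the row-normalized relative strengths.
#'
#' @param components a [em_fit()] result (positions are taken from it).
#' @param proj tag projections (possibly a different condition's than the
#'   ones the components were fit on).
#' @param tol,max_iter weight-update convergence controls.
#' @return An object of class `CrosslinkMatrix`: `mu`, `raw` (K x J expected
#'   tag counts), `normalized` (rows sum to 1), `experiments`, `zero_rows`.
#' @export
quantify <- function(components, proj, tol = 1e-10, max_iter = 1000) {
  mus <- components$mu
  J <- length(mus)
  Lc <- components$Lc
  LM <- likelihood_matrices(components$model, Lc)
  K <- length(proj)
  raw <- matrix(0, nrow = K, ncol = J,
                dimnames = list(names(proj), NULL))
  for (k in seq_len(K)) {
    pr <- proj[[k]]
    if (nrow(pr) == 0) next
    lik <- lik_for(pr, mus, LM)
    p <- rep(1 / J, J)
    tot <- sum(pr$w)
    for (i in seq_len(max_iter)) {
      num <- sweep(lik, 2, p, `*`)
      g <- num / pmax(rowSums(num), 1e-300)
      N <- colSums(pr$w * g)
      p_new <- N / tot
      if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
      p <- p_new
    }
    raw[k, ] <- p * tot
  }
  rs <- rowSums(raw)
  zero <- rs == 0
  if (any(zero))
    warning("experiment(s) with zero tags: ",
            paste(names(proj)[zero], collapse = ", "))
  norm <- raw
  norm[!zero, ] <- raw[!zero, , drop = FALSE] / rs[!zero]
  structure(list(mu = mus, raw = raw, normalized = norm,
                 experiments = names(proj), zero_rows = zero),
            class = "CrosslinkMatrix")
}

#' @export
print.CrosslinkMatrix <- function(x, ...) {
  cat(sprintf("CrosslinkMatrix: %d experiment(s) x %d crosslink position(s)\n",
              nrow(x$raw), ncol(x$raw)))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Fold differences in crosslinking strength between conditions
#'
#' Per (experiment, position): `log2((s2 + eps) / (s1 + eps))` on the
#' row-normalized strengths, where `eps` is a small pseudo-weight guarding
#' against empty components. Both matrices must be quantifications against
#' the same fitted component positions.
#'
#' @param m1,m2 [quantify()] results for condition 1 and 2.
#' @param eps pseudo-weight (default 1e-3).
#' @return matrix of log2 fold differences (experiments x positions).
#' @export
compare_conditions <- function(m1, m2, eps = 1e-3) {
  if (!identical(m1$mu, m2$mu))
    stop("crosslink matrices have mismatched component positions; ",
         "fit components jointly across conditions")
  if (!identical(dim(m1$normalized), dim(m2$normalized)))
    stop("crosslink matrices have mismatched dimensions")
  log2((m2$normalized + eps) / (m1$normalized + eps))
}

#' Write a crosslink components/strengths table
#'
#' One row per (experiment, crosslink position), with positions optionally
#' reported relative to a reference alignment column.
#'
#' @param m a `CrosslinkMatrix`.
#' @param path output TSV.
#' @param ref_column reference column subtracted from positions (default 0).
#' @export
write_crosslink_tsv <- function(m, path, ref_column = 0) {
  out <- do.call(rbind, lapply(seq_along(m$experiments), function(k) {
    data.frame(experiment = m$experiments[k],
               position = m$mu - ref_column,
               raw_strength = m$raw[k, ],
               normalized_strength = m$normalized[k, ])
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
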