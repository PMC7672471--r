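#' PCA of crosslinking preferences
#'
#' Standard PCA on the row-normalized crosslinking-strength matrix
#' (experiments x positions): rows are mean-centered but not variance-scaled
#' (row normalization to sum 1 is the only preprocessing), and the
#' experiments are projected onto the leading principal components to
#' visualize which proteins share crosslinking preferences. Each component
#' is sign-oriented so the first experiment with a nonzero coordinate has a
#' positive one, making reruns deterministic.
#'
#' @param m a [quantify()] result (or any matrix whose rows sum to 1).
#' @param n_components number of components to retain (clipped to what the
#'   matrix supports, with a warning).
#' @return An object of class `PcaResult`: `coordinates` (experiments x
#'   components), `explained_variance_ratio`, `loadings`, `sdev`.
#' @export
pca_crosslinks <- function(m, n_components = 2) {
  X <- if (inherits(m, "CrosslinkMatrix")) m$normalized else as.matrix(m)
  if (nrow(X) < 2) stop("PCA needs at least 2 experiments")
  max_nc <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_nc) {
    warning("n_components clipped from ", n_components, " to ", max_nc)
    n_components <- max_nc
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, length(pr$sdev))
  var_tot <- sum(pr$sdev^2)
  ratio <- if (var_tot > 0) pr$sdev^2 / var_tot else rep(0, length(pr$sdev))
  coords <- pr$x[, seq_len(nc), drop = FALSE]
  loads <- pr$rotation[, seq_len(nc), drop = FALSE]
  for (p in seq_len(nc)) {
    nz <- which(abs(coords[, p]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], p] < 0) {
      coords[, p] <- -coords[, p]
      loads[, p] <- -loads[, p]
    }
  }
  rownames(coords) <- rownames(X)
  structure(list(coordinates = coords,
                 explained_variance_ratio = ratio[seq_len(nc)],
                 loadings = loads,
                 sdev = pr$sdev),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult: explained variance ratio",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "), "\n")
  print(round(x$coordinates, 4))
  invisible(x)
}

#' Write PCA outputs as TSV
#'
#' @param p a [pca_crosslinks()] result.
#' @param coords_path,variance_path output files.
#' @export
write_pca_tsv <- function(p, coords_path, variance_path) {
  co <- data.frame(experiment = rownames(p$coordinates), p$coordinates,
                   check.names = FALSE)
  write.table(co, coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(component = seq_along(p$explained_variance_ratio),
                         explained_variance_ratio = p$explained_variance_ratio),
              variance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coords_path)
}
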