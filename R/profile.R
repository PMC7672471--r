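#' Construct a profile matrix
#'
#' A ProfileMatrix is the 2K x L per-base, strand-separated tag-count matrix
#' for one region (or for a composite of several merged regions). Rows are
#' experiment-major, Watson then Crick: rows 2k-1 and 2k belong to experiment
#' k. `gap_counts[l]` records how many contributing regions are gapped at
#' column l (0 for a single un-merged region).
#'
#' @param values 2K x L non-negative numeric matrix.
#' @param experiments character vector of K experiment names.
#' @param region_ids ids of the contributing regions.
#' @param gap_counts integer vector of length L (default all 0).
#' @param is_normalized has per-region max normalization been applied?
#' @return An object of class `ProfileMatrix`.
#' @export
profile_matrix <- function(values, experiments, region_ids,
                           gap_counts = NULL, is_normalized = FALSE) {
  values <- as.matrix(values)
  experiments <- unname(experiments)
  K <- length(experiments)
  if (nrow(values) != 2L * K)
    stop("values must have 2K rows (K = ", K, ", got ", nrow(values), ")")
  if (any(values < 0)) stop("profile values must be non-negative")
  L <- ncol(values)
  if (is.null(gap_counts)) gap_counts <- integer(L)
  stopifnot(length(gap_counts) == L)
  rownames(values) <- paste0(rep(experiments, each = 2), c(":W", ":C"))
  structure(list(values = values, K = K, L = L,
                 experiments = experiments,
                 region_ids = region_ids,
                 gap_counts = as.integer(gap_counts),
                 n_regions = length(region_ids),
                 is_normalized = is_normalized),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix: %d experiment(s) x %d columns, %d region(s)%s\n",
              x$K, x$L, x$n_regions,
              if (x$is_normalized) " (normalized)" else ""))
  invisible(x)
}

#' Build the multi-experiment profile matrix for one region
#'
#' Stacks [extract_window()] rows for each experiment, in the order the
#' libraries are given, producing the raw (unnormalized) 2K x L matrix.
#'
#' @param libraries list of [tag_library()] objects, one per experiment.
#' @param region one row of a `RegionSet`.
#' @param L window length in bp.
#' @return A [profile_matrix()] of raw counts.
#' @export
build_profile <- function(libraries, region, L) {
  stopifnot(length(libraries) >= 1)
  rows <- lapply(libraries, extract_window, region = region, L = L)
  experiments <- vapply(libraries, function(x) x$name, character(1))
  profile_matrix(do.call(rbind, rows), experiments = experiments,
                 region_ids = region$id)
}

#' Per-region max normalization
#'
#' Divides each experiment's two strand rows by the maximum tag count that
#' experiment attains anywhere in the region (both strands jointly), so every
#' experiment's profile peaks at 1 within the region. All-zero experiments
#' are left untouched. Normalized values feed the alignment stage only; the
#' EM stage always consumes raw counts.
#'
#' @param P a [profile_matrix()].
#' @return The normalized ProfileMatrix.
#' @export
normalize_per_region <- function(P) {
  stopifnot(inherits(P, "ProfileMatrix"))
  v <- P$values
  for (k in seq_len(P$K)) {
    r <- c(2L * k - 1L, 2L * k)
    mx <- max(v[r, ])
    if (mx > 0) v[r, ] <- v[r, ] / mx
  }
  P$values <- v
  P$is_normalized <- TRUE
  P
}

#' Dump a ProfileMatrix as long-format TSV
#'
#' Columns: region_id (comma-joined for composites), offset, experiment,
#' watson, crick, gap_count.
#'
#' @param P a [profile_matrix()].
#' @param path output file.
#' @export
write_profile_tsv <- function(P, path) {
  rid <- paste(P$region_ids, collapse = ",")
  out <- do.call(rbind, lapply(seq_len(P$K), function(k) {
    data.frame(region_id = rid, offset = seq_len(P$L),
               experiment = P$experiments[k],
               watson = P$values[2L * k - 1L, ],
               crick = P$values[2L * k, ],
               gap_count = P$gap_counts)
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
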