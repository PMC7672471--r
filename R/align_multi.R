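#' Merge two aligned profiles into a composite
#'
#' Builds the composite profile of a computed pairwise alignment: matched
#' columns are summed cell-wise in raw counts; columns where one node is
#' gapped (including unaligned overhangs, which overlap alignment keeps)
#' take the present node's counts, and the gap-count array is incremented by
#' the number of regions in the absent node. If the alignment used the
#' reversed orientation of `B`, `B` is reversed before merging and the
#' returned `b_cols` map refers to the original (forward) B columns.
#'
#' @param A,B raw-count [profile_matrix()] objects.
#' @param aln a `PairwiseAlignment` of (normalized) A vs B.
#' @return list with `profile` (merged raw ProfileMatrix), `a_cols`,
#'   `b_cols` (integer maps: column of A/B -> merged column) and `reversed`.
#' @export
merge_pair <- function(A, B, aln) {
  reversed <- aln$orientation == "reversed"
  if (reversed) B <- reverse_profile(B)
  n <- A$L; m <- B$L
  stopifnot(aln$n == n, aln$m == m)
  path <- aln$path
  i0 <- aln$start[1]; j0 <- aln$start[2]
  bi <- aln$end[1]; bj <- aln$end[2]

  # merged column sequence: (ai, bj) pairs with 0 = absent
  pre_a <- if (i0 > 0) cbind(seq_len(i0), 0L) else NULL
  pre_b <- if (j0 > 0) cbind(0L, seq_len(j0)) else NULL
  suf_a <- if (bi < n) cbind(seq.int(bi + 1L, n), 0L) else NULL
  suf_b <- if (bj < m) cbind(0L, seq.int(bj + 1L, m)) else NULL
  cols <- rbind(pre_a, pre_b, path, suf_a, suf_b)
  Lm <- nrow(cols)

  vals <- matrix(0, nrow = 2L * A$K, ncol = Lm)
  gc <- integer(Lm)
  ia <- cols[, 1]; ib <- cols[, 2]
  ha <- ia > 0; hb <- ib > 0
  vals[, ha] <- vals[, ha, drop = FALSE] + A$values[, ia[ha], drop = FALSE]
  vals[, hb] <- vals[, hb, drop = FALSE] + B$values[, ib[hb], drop = FALSE]
  gc[ha] <- gc[ha] + A$gap_counts[ia[ha]]
  gc[hb] <- gc[hb] + B$gap_counts[ib[hb]]
  gc[!ha] <- gc[!ha] + A$n_regions
  gc[!hb] <- gc[!hb] + B$n_regions

  a_cols <- integer(n); a_cols[ia[ha]] <- which(ha)
  b_cols_or <- integer(m); b_cols_or[ib[hb]] <- which(hb)
  b_cols <- if (reversed) b_cols_or[m + 1L - seq_len(m)] else b_cols_or

  prof <- profile_matrix(vals, experiments = A$experiments,
                         region_ids = c(A$region_ids, B$region_ids),
                         gap_counts = gc)
  list(profile = prof, a_cols = a_cols, b_cols = b_cols, reversed = reversed)
}

new_leaf_node <- function(P, idx) {
  maps <- list(seq_len(P$L))
  names(maps) <- P$region_ids
  ors <- stats::setNames("+", P$region_ids)
  list(profile = P, region_maps = maps, orientations = ors,
       min_idx = idx, leaves = P$region_ids, tree = P$region_ids[1])
}

#' Progressive multiple alignment of region profiles
#'
#' Greedy agglomeration: score all node pairs by affine-gap overlap
#' alignment of their per-experiment max-normalized composites, repeatedly
#' merge the most similar pair into a composite (raw counts summed,
#' gap-count array carried along), re-score the new node against all
#' remaining nodes, and stop when a single node is left. Ties in "most
#' similar pair" break lexicographically by the lowest contributing region
#' index, making reruns deterministic.
#'
#' @param profiles list of single-region raw [profile_matrix()] objects
#'   (same experiments, same L).
#' @param cfg a [gap_config()].
#' @param verbose print merge progress.
#' @return An object of class `MultipleAlignment`: `composite` (raw
#'   ProfileMatrix with gap counts over alignment columns), `region_maps`
#'   (per region: window offset -> alignment column), `orientations`
#'   (per region "+"/"-" relative to the composite), `region_order` (leaf
#'   order of the merge tree), `merge_tree` (Newick string), `merges`
#'   (data.frame of merge scores), and `K`/`experiments`/`L_alignment`.
#' @export
progressive_align <- function(profiles, cfg = gap_config(), verbose = FALSE) {
  stopifnot(length(profiles) >= 2)
  K <- profiles[[1]]$K
  for (p in profiles)
    if (p$K != K || !identical(p$experiments, profiles[[1]]$experiments))
      stop("all profiles must share the same experiments")

  nodes <- lapply(seq_along(profiles), function(i)
    new_leaf_node(profiles[[i]], i))
  norm_of <- function(nd) normalize_per_region(nd$profile)
  norms <- lapply(nodes, norm_of)

  pair_aln <- function(u, v) align_overlap(norms[[u]], norms[[v]], cfg)
  nn <- length(nodes)
  alns <- vector("list", nn * nn)
  dim(alns) <- c(nn, nn)
  S <- matrix(-Inf, nn, nn)
  for (u in seq_len(nn - 1)) for (v in seq.int(u + 1, nn)) {
    alns[[u, v]] <- pair_aln(u, v)
    S[u, v] <- alns[[u, v]]$score
  }
  merges <- NULL

  while (length(nodes) > 1) {
    best <- max(S, na.rm = TRUE)
    cand <- which(S == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key1 <- vapply(cand[, 1], function(u) nodes[[u]]$min_idx, numeric(1))
      key2 <- vapply(cand[, 2], function(v) nodes[[v]]$min_idx, numeric(1))
      lo <- pmin(key1, key2); hi <- pmax(key1, key2)
      cand <- cand[order(lo, hi)[1], , drop = FALSE]
    }
    u <- cand[1, 1]; v <- cand[1, 2]
    aln <- alns[[u, v]]
    mp <- merge_pair(nodes[[u]]$profile, nodes[[v]]$profile, aln)
    if (verbose)
      message(sprintf("merge %s + %s (score %.2f, %s)",
                      nodes[[u]]$tree, nodes[[v]]$tree, aln$score,
                      aln$orientation))
    merges <- rbind(merges, data.frame(score = aln$score,
                                       orientation = aln$orientation,
                                       size = mp$profile$n_regions))

    maps_u <- lapply(nodes[[u]]$region_maps, function(mm) mp$a_cols[mm])
    m_v <- nodes[[v]]$profile$L
    maps_v <- lapply(nodes[[v]]$region_maps, function(mm) mp$b_cols[mm])
    ors_v <- nodes[[v]]$orientations
    if (mp$reversed) ors_v <- stats::setNames(ifelse(ors_v == "+", "-", "+"),
                                              names(ors_v))
    newnode <- list(profile = mp$profile,
                    region_maps = c(maps_u, maps_v),
                    orientations = c(nodes[[u]]$orientations, ors_v),
                    min_idx = min(nodes[[u]]$min_idx, nodes[[v]]$min_idx),
                    leaves = c(nodes[[u]]$leaves, nodes[[v]]$leaves),
                    tree = paste0("(", nodes[[u]]$tree, ",",
                                  nodes[[v]]$tree, ")"))

    keep <- setdiff(seq_along(nodes), c(u, v))
    nodes <- nodes[keep]; norms <- norms[keep]
    S <- S[keep, keep, drop = FALSE]
    alns <- alns[keep, keep, drop = FALSE]
    nodes[[length(nodes) + 1L]] <- newnode
    norms[[length(norms) + 1L]] <- norm_of(newnode)
    nn <- length(nodes)
    S2 <- matrix(-Inf, nn, nn)
    if (nn > 1) S2[seq_len(nn - 1), seq_len(nn - 1)] <- S
    S <- S2
    alns2 <- vector("list", nn * nn); dim(alns2) <- c(nn, nn)
    if (nn > 1) alns2[seq_len(nn - 1), seq_len(nn - 1)] <- alns
    alns <- alns2
    for (u2 in seq_len(nn - 1)) {
      alns[[u2, nn]] <- pair_aln(u2, nn)
      S[u2, nn] <- alns[[u2, nn]]$score
    }
  }

  final <- nodes[[1]]
  structure(list(composite = final$profile,
                 region_maps = final$region_maps,
                 orientations = final$orientations,
                 region_order = final$leaves,
                 merge_tree = paste0(final$tree, ";"),
                 merges = merges,
                 K = K, experiments = profiles[[1]]$experiments,
                 L_alignment = final$profile$L),
            class = "MultipleAlignment")
}

#' @export
print.MultipleAlignment <- function(x, ...) {
  cat(sprintf("MultipleAlignment: %d region(s), %d experiment(s), %d alignment column(s)\n",
              length(x$region_maps), x$K, x$L_alignment))
  invisible(x)
}

#' Estimate a control-to-signal scaling factor
#'
#' Simplified stand-in for NCIS-style scaling: the genome is cut into bins,
#' and the scaling factor is the median of (signal count / control count)
#' over "low-total" bins -- bins whose combined signal+control total is
#' below the genome-wide median, where the background component dominates.
#' Falls back to the total-count ratio when no usable bin exists (e.g. all
#' bins equal).
#'
#' @param signal,control [tag_library()] objects.
#' @param bin_size bin width in bp (default 10 kb).
#' @return list with `scale_factor` (> 0) and `method`.
#' @export
estimate_control_scale <- function(signal, control, bin_size = 10000) {
  if (control$total_tag_count == 0)
    stop("control library is empty; skip background subtraction instead")
  bin_key <- function(lib) paste0(lib$tags$chrom, ":",
                                  (lib$tags$pos - 1L) %/% bin_size)
  ts <- table(bin_key(signal))
  tc <- table(bin_key(control))
  keys <- union(names(ts), names(tc))
  s <- as.numeric(ts[keys]); s[is.na(s)] <- 0
  cc <- as.numeric(tc[keys]); cc[is.na(cc)] <- 0
  tot <- s + cc
  low <- tot < median(tot) & cc > 0
  if (any(low)) {
    list(scale_factor = median(s[low] / cc[low]), method = "low_bin_median")
  } else {
    list(scale_factor = signal$total_tag_count / control$total_tag_count,
         method = "total_ratio")
  }
}

# Project a control library into alignment-column space through the
# multiple alignment's per-region maps and orientations.
project_control_composite <- function(ma, control, regions, L) {
  ctrl <- matrix(0, nrow = 2, ncol = ma$L_alignment)
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    if (!reg$id %in% names(ma$region_maps)) next
    w <- extract_window(control, reg, L)
    if (ma$orientations[[reg$id]] == "-")
      w <- rbind(rev(w[2, ]), rev(w[1, ]))
    map <- ma$region_maps[[reg$id]]
    ok <- !is.na(map)
    ctrl[1, map[ok]] <- ctrl[1, map[ok]] + w[1, ok]
    ctrl[2, map[ok]] <- ctrl[2, map[ok]] + w[2, ok]
  }
  ctrl
}

#' Subtract scaled control signal from the final composite
#'
#' Applied only after the full multiple alignment is built: control tags are
#' projected through the same per-region coordinate maps (and orientation
#' flips) as the signal, scaled per signal experiment, and subtracted
#' per base and per strand with a floor at 0.
#'
#' @param ma a [progressive_align()] result.
#' @param control control [tag_library()].
#' @param regions the `RegionSet` the alignment was built from.
#' @param L window length used for the profiles.
#' @param scaling single scale factor, or named vector/list with one scale
#'   per experiment (e.g. from [estimate_control_scale()]).
#' @return `ma` with a background-corrected composite; the projected control
#'   composite and the scales used are attached as `control_composite` and
#'   `scales`.
#' @export
subtract_background <- function(ma, control, regions, L, scaling) {
  if (is.list(scaling) && !is.null(scaling$scale_factor))
    scaling <- scaling$scale_factor
  scales <- if (length(scaling) == 1 && is.null(names(scaling)))
    stats::setNames(rep(as.numeric(scaling), ma$K), ma$experiments)
  else unlist(scaling)[ma$experiments]
  if (any(is.na(scales) | scales <= 0))
    stop("need a positive control scale for every experiment")

  ctrl <- project_control_composite(ma, control, regions, L)
  v <- ma$composite$values
  for (k in seq_len(ma$K)) {
    r <- c(2L * k - 1L, 2L * k)
    v[r, ] <- pmax(0, v[r, ] - scales[[k]] * ctrl)
  }
  ma$composite$values <- v
  ma$control_composite <- ctrl
  ma$scales <- scales
  ma
}

#' Write multiple-alignment artifacts as TSV
#'
#' `write_alignment_tsv` emits one row per (region, window offset) with the
#' alignment column and orientation; `write_gap_tsv` emits per-column gap
#' counts; the merge tree is available as `ma$merge_tree` (Newick).
#'
#' @param ma a `MultipleAlignment`.
#' @param path output file.
#' @export
write_alignment_tsv <- function(ma, path) {
  out <- do.call(rbind, lapply(names(ma$region_maps), function(id) {
    map <- ma$region_maps[[id]]
    data.frame(region_id = id, window_offset = seq_along(map),
               alignment_column = ifelse(is.na(map), "GAP", map),
               orientation = ma$orientations[[id]])
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
write_gap_tsv <- function(ma, path) {
  write.table(data.frame(alignment_column = seq_len(ma$L_alignment),
                         gap_count = ma$composite$gap_counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
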