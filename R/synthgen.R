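#' Describe a synthetic multi-experiment ChIP-exo world
#'
#' The generator emulates a variably spaced regulatory complex bound at many
#' regions (the tRNA-gene setting): every region carries the same J
#' crosslink sites arranged in two blocks, with a region-specific spacer
#' inserted between the blocks (mimicking intragenic promoter length
#' variation), optional region reversal, and optional anchor jitter
#' (mimicking randomized alignment starting points). Tags are drawn from the
#' paired-Gaussian tag model (sigma = 6 bp, strands offset 12 bp) plus a
#' uniform background; all planted truth is recorded.
#'
#' @param n_regions number of regions R.
#' @param window window length L in bp.
#' @param experiments experiment names (K).
#' @param site_offsets layout-space site positions (bp relative to the true
#'   region center, before the spacer is applied).
#' @param site_blocks block membership (1 or 2) per site; block-2 sites are
#'   shifted right by each region's spacer.
#' @param strengths K x J matrix of per-experiment site strengths, rows
#'   summing to 1.
#' @param tags_per_region total signal tags per experiment per region.
#' @param background_rate uniform background, tags/bp per experiment/region.
#' @param spacer_range inclusive range spacers are drawn from when
#'   `spacers` is NULL.
#' @param spacers,orientations,jitters optional pre-realized per-region
#'   values (length R; orientations +1/-1). When NULL they are drawn at
#'   generation time: spacers uniform over `spacer_range`, orientations all
#'   +1 unless `reverse_fraction` > 0, jitters uniform in
#'   `[-jitter_halfwidth, jitter_halfwidth]`.
#' @param reverse_fraction fraction of regions planted in reverse
#'   orientation.
#' @param jitter_halfwidth anchor jitter half-range in bp (0 = none).
#' @param model a [tag_distribution_model()].
#' @return list of class `SyntheticTruth`.
#' @export
synthetic_truth <- function(n_regions = 30, window = 400,
                            experiments = c("exptA", "exptB", "exptC"),
                            site_offsets = c(-70, -55, -40, 20, 35, 50),
                            site_blocks = c(1, 1, 1, 2, 2, 2),
                            strengths = NULL,
                            tags_per_region = 3000,
                            background_rate = 0,
                            spacer_range = c(5, 60),
                            spacers = NULL, orientations = NULL,
                            jitters = NULL,
                            reverse_fraction = 0, jitter_halfwidth = 0,
                            model = tag_distribution_model()) {
  J <- length(site_offsets)
  stopifnot(length(site_blocks) == J, all(site_blocks %in% c(1, 2)))
  K <- length(experiments)
  if (is.null(strengths)) {
    strengths <- rbind(c(0.35, 0.25, 0.20, 0.10, 0.06, 0.04),
                       c(0.05, 0.10, 0.15, 0.20, 0.25, 0.25),
                       c(0.04, 0.06, 0.10, 0.20, 0.25, 0.35))[seq_len(K), seq_len(J), drop = FALSE]
    strengths <- strengths / rowSums(strengths)
  }
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) == K, ncol(strengths) == J)
  if (any(abs(rowSums(strengths) - 1) > 1e-8))
    stop("strength rows must sum to 1")
  if (!is.null(spacers)) stopifnot(length(spacers) == n_regions,
                                   all(spacers >= spacer_range[1]),
                                   all(spacers <= spacer_range[2]))
  if (length(tags_per_region) == 1)
    tags_per_region <- rep(tags_per_region, K)
  structure(list(n_regions = n_regions, window = as.integer(window),
                 experiments = experiments,
                 site_offsets = site_offsets, site_blocks = site_blocks,
                 strengths = strengths,
                 tags_per_region = tags_per_region,
                 background_rate = background_rate,
                 spacer_range = spacer_range,
                 spacers = spacers, orientations = orientations,
                 jitters = jitters,
                 reverse_fraction = reverse_fraction,
                 jitter_halfwidth = jitter_halfwidth,
                 model = model),
            class = "SyntheticTruth")
}

#' Generate a synthetic dataset with known truth
#'
#' Regions are placed without overlap on a toy chromosome `chrS`.
#' Deterministic given `seed` and the truth; per-region spacers,
#' orientations and jitters are drawn here unless already fixed in `truth`,
#' and the realized values are returned so a second condition can be
#' generated over the identical regions (pass the returned `$truth` with
#' modified `strengths` and a new seed).
#'
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed.
#' @return list with `libraries` (named [tag_library()] per experiment),
#'   `regions` (`RegionSet`, all reported on the + strand -- planted
#'   reversals are for the aligner to discover), `window`, and `truth` (the
#'   input truth augmented with realized `spacers`, `orientations`,
#'   `jitters`, `anchors0`, per-region true `site_positions` (genomic) and
#'   `site_window_offsets` (R x J, in extraction-window coordinates)).
#' @export
generate_synthetic <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(seed)
  R <- truth$n_regions; L <- truth$window
  K <- length(truth$experiments); J <- length(truth$site_offsets)
  half <- truth$model$offset / 2; sigma <- truth$model$sigma

  pitch <- 2L * L
  anchors0 <- pitch * seq_len(R)
  spacers <- truth$spacers
  if (is.null(spacers))
    spacers <- sample(seq(truth$spacer_range[1], truth$spacer_range[2]),
                      R, replace = TRUE)
  orientations <- truth$orientations
  if (is.null(orientations)) {
    orientations <- rep(1L, R)
    if (truth$reverse_fraction > 0) {
      nrev <- round(truth$reverse_fraction * R)
      orientations[sample(R, nrev)] <- -1L
    }
  }
  jitters <- truth$jitters
  if (is.null(jitters)) {
    jitters <- if (truth$jitter_halfwidth > 0)
      sample(seq(-truth$jitter_halfwidth, truth$jitter_halfwidth), R,
             replace = TRUE)
    else rep(0L, R)
  }

  site_positions <- matrix(0L, R, J)
  tag_frames <- lapply(seq_len(K), function(k) vector("list", R))
  for (r in seq_len(R)) {
    lay_mu <- truth$site_offsets + spacers[r] * (truth$site_blocks == 2)
    site_positions[r, ] <- anchors0[r] + orientations[r] * lay_mu
    wstart <- anchors0[r] + jitters[r] - L %/% 2L
    for (k in seq_len(K)) {
      counts <- as.vector(rmultinom(1, truth$tags_per_region[k],
                                    truth$strengths[k, ]))
      site_of <- rep(seq_len(J), counts)
      n <- length(site_of)
      strand_lay <- sample(c("+", "-"), n, replace = TRUE)
      p_lay <- round(rnorm(n, lay_mu[site_of] +
                             ifelse(strand_lay == "+", -half, half), sigma))
      if (orientations[r] == 1L) {
        pos <- anchors0[r] + p_lay; strand <- strand_lay
      } else {
        pos <- anchors0[r] - p_lay
        strand <- ifelse(strand_lay == "+", "-", "+")
      }
      tag_frames[[k]][[r]] <- data.frame(chrom = "chrS",
                                         pos = as.integer(pos),
                                         strand = strand)
    }
  }
  # background drawn in a second pass so that, for a fixed seed, the signal
  # tags are identical whether or not background is requested
  if (truth$background_rate > 0) {
    for (r in seq_len(R)) {
      wstart <- anchors0[r] + jitters[r] - L %/% 2L
      for (k in seq_len(K)) {
        nb <- rpois(1, truth$background_rate * L)
        if (nb == 0) next
        bg <- data.frame(chrom = "chrS",
                         pos = as.integer(wstart +
                                            sample.int(L, nb, replace = TRUE) - 1L),
                         strand = sample(c("+", "-"), nb, replace = TRUE))
        tag_frames[[k]][[r]] <- rbind(tag_frames[[k]][[r]], bg)
      }
    }
  }

  libraries <- lapply(seq_len(K), function(k)
    tag_library(do.call(rbind, tag_frames[[k]]), name = truth$experiments[k]))
  names(libraries) <- truth$experiments

  regions <- region_set(data.frame(chrom = "chrS",
                                   anchor = anchors0 + jitters,
                                   strand = "+",
                                   id = sprintf("region%02d", seq_len(R))))
  # true site offsets inside each extraction window (1-based)
  wstarts <- anchors0 + jitters - L %/% 2L
  site_window_offsets <- site_positions - wstarts + 1L

  truth$spacers <- spacers
  truth$orientations <- orientations
  truth$jitters <- jitters
  truth$anchors0 <- anchors0
  truth$site_positions <- site_positions
  truth$site_window_offsets <- site_window_offsets
  list(libraries = libraries, regions = regions, window = L, truth = truth)
}

#' Generate a matched synthetic control experiment
#'
#' Pure uniform background over every region window of a generated dataset,
#' at `rate` tags/bp -- the signal-free input the background-subtraction
#' stage is supposed to remove.
#'
#' @param sim a [generate_synthetic()] result.
#' @param rate control tags per bp per region.
#' @param seed RNG seed.
#' @param name library name.
#' @return A [tag_library()].
#' @export
generate_synthetic_control <- function(sim, rate, seed = 1,
                                       name = "control") {
  set.seed(seed)
  L <- sim$window
  frames <- lapply(seq_len(nrow(sim$regions)), function(r) {
    wstart <- sim$regions$anchor[r] - L %/% 2L
    n <- rpois(1, rate * L)
    if (n == 0) return(NULL)
    data.frame(chrom = sim$regions$chrom[r],
               pos = as.integer(wstart + sample.int(L, n, replace = TRUE) - 1L),
               strand = sample(c("+", "-"), n, replace = TRUE))
  })
  frames <- frames[!vapply(frames, is.null, logical(1))]
  tag_library(if (length(frames)) do.call(rbind, frames)
              else data.frame(chrom = character(), pos = integer(),
                              strand = character()),
              name = name)
}

#' Write a tag library as TSV / SAM; write regions as BED
#'
#' `write_tags_tsv` writes the 3-column format [read_tags()] accepts.
#' `write_tags_sam` writes a minimal valid SAM file (fixed-length reads;
#' - strand tags become reverse-strand reads whose rightmost base is the
#' tag position). `write_regions_bed` writes 6-column BED whose midpoint
#' reproduces each region's anchor.
#'
#' @param lib a [tag_library()].
#' @param path output file.
#' @param chrom_len chromosome length for the SAM header.
#' @param read_len read length used for SAM records.
#' @export
write_tags_tsv <- function(lib, path) {
  write.table(lib$tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags_tsv
#' @export
write_tags_sam <- function(lib, path, chrom_len = NULL, read_len = 20) {
  tt <- lib$tags
  if (is.null(chrom_len))
    chrom_len <- max(tt$pos) + read_len
  chroms <- unique(tt$chrom)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_len)))
  rev <- tt$strand == "-"
  pos <- ifelse(rev, tt$pos - read_len + 1L, tt$pos)
  flag <- ifelse(rev, 16L, 0L)
  ord <- order(tt$chrom, pos)
  rec <- sprintf("tag%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 seq_len(nrow(tt)), flag[ord], tt$chrom[ord], pos[ord],
                 read_len, strrep("A", read_len))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_tags_tsv
#' @param regions a `RegionSet`.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     regions$chrom, regions$anchor - 1L, regions$anchor,
                     regions$id, regions$strand), path)
  invisible(path)
}

#' @rdname write_tags_tsv
#' @param truth realized truth (from [generate_synthetic()]`$truth`).
#' @export
write_truth_json <- function(truth, path) {
  keep <- truth[c("n_regions", "window", "experiments", "site_offsets",
                  "site_blocks", "strengths", "tags_per_region",
                  "background_rate", "spacers", "orientations", "jitters",
                  "anchors0", "site_positions", "site_window_offsets")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
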