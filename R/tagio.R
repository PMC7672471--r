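#' Construct a tag library
#'
#' A TagLibrary holds the stranded 5' positions of mapped sequencing tags for
#' one experiment, grouped by chromosome. Only the 5'-most genomic base of
#' each read matters downstream; everything else about the read is discarded.
#'
#' @param tags data.frame with columns `chrom` (character), `pos` (1-based
#'   integer 5' position) and `strand` (`"+"` or `"-"`).
#' @param name experiment label.
#' @return An object of class `TagLibrary`.
#' @export
tag_library <- function(tags, name = "expt") {
  stopifnot(is.data.frame(tags), all(c("chrom", "pos", "strand") %in% names(tags)))
  if (nrow(tags) > 0) {
    if (!all(tags$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(tags$pos < 1)) stop("tag positions must be >= 1")
  }
  tags <- tags[order(tags$chrom, tags$pos, tags$strand), , drop = FALSE]
  rownames(tags) <- NULL
  structure(list(name = name,
                 tags = tags,
                 total_tag_count = nrow(tags)),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s': %d tags on %d chromosome(s)\n",
              x$name, x$total_tag_count, length(unique(x$tags$chrom))))
  invisible(x)
}

cigar_ref_width <- function(cigar) {
  # reference-consuming ops: M, D, N, =, X
  widths <- vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    tok <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", tok))
    op <- substring(tok, nchar(tok))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  widths
}

read_tags_sam_text <- function(path, min_mapq, include_r2) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(data.frame(chrom = character(), pos = integer(),
                                            strand = character()))
  f <- strsplit(lines, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  chrom <- vapply(f, function(x) x[3], character(1))
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  cigar <- vapply(f, function(x) x[6], character(1))
  keep <- bitwAnd(flag, 0x4L) == 0 &                      # mapped
    bitwAnd(flag, 0x100L) == 0 & bitwAnd(flag, 0x800L) == 0 &  # primary
    mapq >= min_mapq & chrom != "*"
  if (!include_r2) keep <- keep & bitwAnd(flag, 0x80L) == 0
  flag <- flag[keep]; chrom <- chrom[keep]; pos <- pos[keep]; cigar <- cigar[keep]
  rev <- bitwAnd(flag, 0x10L) != 0
  p5 <- ifelse(rev, pos + cigar_ref_width(cigar) - 1L, pos)
  data.frame(chrom = chrom, pos = as.integer(p5),
             strand = ifelse(rev, "-", "+"))
}

read_tags_bam <- function(path, min_mapq, include_r2) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package")
  res <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "strand", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      mapqFilter = min_mapq))[[1]]
  keep <- !is.na(res$pos)
  if (!include_r2) keep <- keep & bitwAnd(res$flag, 0x80L) == 0
  chrom <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  strand <- as.character(res$strand)[keep]
  cigar <- res$cigar[keep]
  rev <- strand == "-"
  p5 <- ifelse(rev, pos + cigar_ref_width(cigar) - 1L, pos)
  data.frame(chrom = chrom, pos = as.integer(p5), strand = strand)
}

#' Read mapped tags from a BAM/SAM/TSV file
#'
#' Extracts one stranded tag per retained read, located at the read's 5'-most
#' genomic base (leftmost base for + strand reads, rightmost for - strand).
#' Reads failing the mapping-quality cutoff, unmapped reads, and
#' secondary/supplementary alignments are dropped. By default only R1 of a
#' pair contributes a tag.
#'
#' Accepted formats, by extension: `.bam` (indexed or not, via Rsamtools),
#' `.sam` (plain text), anything else is read as a 3-column TSV
#' (`chrom`, `pos`, `strand`; a header line is detected and skipped).
#'
#' @param path input file.
#' @param min_mapq minimum MAPQ to retain a read (default 5).
#' @param name experiment label (defaults to file base name).
#' @param dedup drop duplicate (chrom, 5' position, strand) tags. Default
#'   `FALSE`: duplicate marking is assumed to have happened upstream.
#' @param include_r2 also take tags from second-of-pair reads.
#' @return A [tag_library()].
#' @export
read_tags <- function(path, min_mapq = 5, name = NULL, dedup = FALSE,
                      include_r2 = FALSE) {
  if (!file.exists(path)) stop("tag file not readable: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  tags <- switch(ext,
    bam = read_tags_bam(path, min_mapq, include_r2),
    sam = read_tags_sam_text(path, min_mapq, include_r2),
    {
      first <- readLines(path, n = 1)
      has_header <- length(first) == 1 && grepl("^chrom", first)
      df <- if (has_header)
        read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "character"))
      else
        read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "strand"),
                   colClasses = c("character", "integer", "character"))
      names(df) <- c("chrom", "pos", "strand")
      df
    })
  if (dedup) tags <- unique(tags)
  if (nrow(tags) == 0) stop("no tags retained from ", path)
  tag_library(tags, name = name)
}

#' Read a region list
#'
#' Accepts either 6-column BED (0-based half-open; the anchor is the interval
#' midpoint) or a plain text list of `chrom:position:strand` records
#' (1-based). All regions are later expanded to windows of a common length.
#'
#' @param path regions file.
#' @return data.frame of class `RegionSet` with columns `chrom`, `anchor`
#'   (1-based bp), `strand`, `id`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("regions file not readable: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no regions in ", path)
  if (grepl(":", lines[1])) {
    f <- strsplit(lines, ":")
    df <- data.frame(chrom = vapply(f, `[`, "", 1),
                     anchor = as.integer(vapply(f, `[`, "", 2)),
                     strand = vapply(f, `[`, "", 3))
    df$id <- paste0("region", seq_len(nrow(df)))
  } else {
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 6)) stop("BED input must have 6 columns")
    start0 <- as.integer(vapply(f, `[`, "", 2))
    end0 <- as.integer(vapply(f, `[`, "", 3))
    df <- data.frame(chrom = vapply(f, `[`, "", 1),
                     anchor = as.integer(floor((start0 + end0) / 2)) + 1L,
                     strand = vapply(f, `[`, "", 6),
                     id = vapply(f, `[`, "", 4))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("region strand must be '+' or '-'")
  region_set(df)
}

#' @rdname read_regions
#' @param df data.frame with columns chrom, anchor, strand, id.
#' @export
region_set <- function(df) {
  stopifnot(all(c("chrom", "anchor", "strand", "id") %in% names(df)))
  if (anyDuplicated(df$id)) stop("region ids must be unique")
  rownames(df) <- NULL
  class(df) <- c("RegionSet", "data.frame")
  df
}

window_bounds <- function(anchor, L) {
  start <- anchor - L %/% 2
  c(start, start + L - 1L)
}

#' Extract a strand-separated tag-count window
#'
#' Counts tag 5' ends per base over the window `[anchor - L/2, anchor + L/2 - 1]`
#' in two rows: W (+ strand) and C (- strand). For a - strand region the
#' window is reversed and the strand rows swapped, so that all regions share
#' a common orientation.
#'
#' @param tags a [tag_library()].
#' @param region one row of a `RegionSet` (or any list with chrom, anchor,
#'   strand, id).
#' @param L window length in bp.
#' @param chrom_len optional chromosome length for bounds checking.
#' @return 2 x L integer matrix with rows `W`, `C`.
#' @export
extract_window <- function(tags, region, L, chrom_len = NULL) {
  b <- window_bounds(region$anchor, as.integer(L))
  if (b[1] < 1 || (!is.null(chrom_len) && b[2] > chrom_len))
    stop("window off chromosome for region ", region$id)
  tt <- tags$tags
  tt <- tt[tt$chrom == region$chrom & tt$pos >= b[1] & tt$pos <= b[2], , drop = FALSE]
  off <- tt$pos - b[1] + 1L
  W <- tabulate(off[tt$strand == "+"], nbins = L)
  C <- tabulate(off[tt$strand == "-"], nbins = L)
  m <- rbind(W = W, C = C)
  if (region$strand == "-") m <- rbind(W = rev(m["C", ]), C = rev(m["W", ]))
  m
}
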