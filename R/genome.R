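# genome coordinate model: layouts, cytobands, bin grids.
# All coordinates are 0-based half-open (BED convention); 1-based only at
# I/O boundaries that demand it (e.g. SEG import).

#' Construct a genome layout
#'
#' A `genome_layout` fixes the coordinate system every other cnscope object
#' lives in: chromosome names (canonical, "chr"-stripped), lengths, display
#' order, cumulative offsets for a linear genome-wide x-axis, and optional
#' cytobands for the ideogram.
#'
#' Alt/patch/unlocalised contigs are dropped with a warning; duplicated or
#' non-positive-length chromosomes are an error.
#'
#' @param chroms data.frame with columns `name` and `length`; row order is
#'   the display order
#' @param cytobands optional data.frame with columns `chrom`, `start`, `end`,
#'   `band`, `stain` (0-based half-open); see [read_cytobands()]
#' @return an object of class `genome_layout` with elements `chroms`
#'   (name, length, display_order, offset) and `cytobands`
#' @export
genome_layout <- function(chroms, cytobands = NULL) {
  stopifnot(is.data.frame(chroms), all(c("name", "length") %in% names(chroms)))
  chroms$name <- normalize_chrom(chroms$name)
  drop <- is_alt_contig(chroms$name)
  if (any(drop)) {
    warn2("dropping %d alt/patch contig(s): %s", sum(drop),
          paste(head(chroms$name[drop], 5), collapse = ", "))
    chroms <- chroms[!drop, , drop = FALSE]
  }
  if (!nrow(chroms)) stop2("no chromosomes")
  if (anyDuplicated(chroms$name))
    stop2("duplicated chromosome names: %s",
          paste(unique(chroms$name[duplicated(chroms$name)]), collapse = ", "))
  chroms$length <- as.numeric(chroms$length)
  if (any(is.na(chroms$length) | chroms$length <= 0))
    stop2("chromosome lengths must be positive")
  chroms <- data.frame(name = chroms$name, length = chroms$length,
                       display_order = seq_len(nrow(chroms)),
                       offset = cumsum(c(0, chroms$length[-nrow(chroms)])),
                       stringsAsFactors = FALSE)
  obj <- structure(list(chroms = chroms, cytobands = NULL),
                   class = "genome_layout")
  if (!is.null(cytobands)) obj <- set_cytobands(obj, cytobands)
  obj
}

set_cytobands <- function(layout, bands) {
  stopifnot(is.data.frame(bands),
            all(c("chrom", "start", "end") %in% names(bands)))
  bands$chrom <- normalize_chrom(bands$chrom)
  bands <- bands[bands$chrom %in% layout$chroms$name, , drop = FALSE]
  bands <- bands[genome_order(bands, layout), , drop = FALSE]
  # bands on a chromosome must be sorted and non-overlapping
  for (ch in unique(bands$chrom)) {
    b <- bands[bands$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop2("overlapping cytobands on chromosome %s", ch)
  }
  rownames(bands) <- NULL
  layout$cytobands <- bands
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes, %.1f Mb total, %s cytobands\n",
              nrow(x$chroms), sum(x$chroms$length) / 1e6,
              if (is.null(x$cytobands)) "no" else nrow(x$cytobands)))
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chroms$name)
  if (anyNA(i)) stop2("unknown chromosome: %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$chroms$length[i]
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp (the UCSC
#' chrom.sizes dialect, no header).
#'
#' @param path file path or connection
#' @param cytobands optional cytoband table to attach (see [read_cytobands()])
#' @return a [genome_layout()]
#' @export
read_chrom_sizes <- function(path, cytobands = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("chrom.sizes needs 2 columns, found %d", ncol(df))
  genome_layout(data.frame(name = df[[1]], length = df[[2]]), cytobands)
}

#' Read a UCSC cytoBand.txt table
#'
#' Five tab-separated columns, no header: chrom, start (0-based), end,
#' band name, Giemsa stain code.
#'
#' @param path file path or connection
#' @return data.frame with columns chrom, start, end, band, stain
#' @export
read_cytobands <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "band", "stain"))
  df$chrom <- normalize_chrom(df$chrom)
  df
}

# ---- bin grids ----------------------------------------------------------

new_bin_grid <- function(bins, label, bin_size) {
  rownames(bins) <- NULL
  structure(list(resolution_label = label, bin_size = bin_size,
                 bins = bins[, c("chrom", "start", "end"), drop = FALSE]),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> '%s': %d bins%s\n", x$resolution_label,
              nrow(x$bins),
              if (x$bin_size > 0) sprintf(" of %g bp", x$bin_size) else
                " (irregular)"))
  invisible(x)
}

n_bins <- function(grid) nrow(grid$bins)

#' Tile a genome into fixed-width bins
#'
#' Covers every base of every chromosome exactly once; the last bin of each
#' chromosome is truncated at the chromosome length.
#'
#' @param layout a [genome_layout()]
#' @param bin_size bin width in bp (> 0)
#' @param label resolution label; defaults to the conventional name for the
#'   display scale ("genome" for 1 Mb, "arm" for 50 kb, "region" for 5 kb)
#'   or `"<bin_size>bp"` otherwise
#' @return a `bin_grid`
#' @export
tile_genome <- function(layout, bin_size, label = NULL) {
  if (!nrow(layout$chroms)) stop2("no chromosomes")
  if (!is.numeric(bin_size) || bin_size <= 0) stop2("bin_size must be > 0")
  if (is.null(label)) label <- default_scale_label(bin_size)
  pieces <- lapply(seq_len(nrow(layout$chroms)), function(i) {
    len <- layout$chroms$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = layout$chroms$name[i], start = starts,
               end = pmin(starts + bin_size, len), stringsAsFactors = FALSE)
  })
  new_bin_grid(do.call(rbind, pieces), label, bin_size)
}

default_scale_label <- function(bin_size) {
  switch(as.character(bin_size),
         "1e+06" = , "1000000" = "genome",
         "50000" = "arm",
         "5000" = "region",
         sprintf("%gbp", bin_size))
}

#' Build an irregular bin grid from bait/target intervals
#'
#' Overlapping or bookended input targets are merged; output is sorted in
#' genome order. This is the finest display resolution ("target").
#'
#' @param targets data.frame with chrom/start/end (0-based half-open)
#' @param layout a [genome_layout()]; targets beyond a chromosome end are an
#'   error naming the offending interval
#' @return a `bin_grid` with `resolution_label = "target"`, `bin_size = 0`
#' @export
bait_grid <- function(targets, layout) {
  stopifnot(is.data.frame(targets),
            all(c("chrom", "start", "end") %in% names(targets)))
  if (!nrow(targets)) stop2("no target intervals")
  targets$chrom <- normalize_chrom(targets$chrom)
  bad <- !(targets$chrom %in% layout$chroms$name)
  if (any(bad)) stop2("target on unknown chromosome: %s:%d-%d",
                      targets$chrom[bad][1], targets$start[bad][1],
                      targets$end[bad][1])
  over <- targets$end > chrom_length(layout, targets$chrom) | targets$start < 0
  if (any(over)) stop2("target beyond chromosome end: %s:%d-%d",
                       targets$chrom[over][1], targets$start[over][1],
                       targets$end[over][1])
  if (any(targets$start >= targets$end)) stop2("target with start >= end")
  pieces <- lapply(intersect(layout$chroms$name, unique(targets$chrom)),
    function(ch) {
      t <- targets[targets$chrom == ch, ]
      r <- IRanges::reduce(IRanges::IRanges(t$start + 1L, t$end))
      data.frame(chrom = ch, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    })
  new_bin_grid(do.call(rbind, pieces), "target", 0)
}

#' Map a chromosome position to the linear genome-wide coordinate
#'
#' @param layout a [genome_layout()]
#' @param chrom chromosome name(s)
#' @param pos position(s) in bp, `0 <= pos <= length`
#' @return numeric genome-linear coordinate(s): chromosome offset + pos
#' @export
locate <- function(layout, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  i <- match(chrom, layout$chroms$name)
  if (anyNA(i)) stop2("unknown chromosome: %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", "))
  if (any(pos < 0 | pos > layout$chroms$length[i]))
    stop2("position outside chromosome")
  layout$chroms$offset[i] + pos
}

# grid equality check used by operations that require matching grids
same_grid <- function(a, b) {
  identical(dim(a$bins), dim(b$bins)) &&
    all(a$bins$chrom == b$bins$chrom) &&
    all(a$bins$start == b$bins$start) &&
    all(a$bins$end == b$bins$end)
}
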