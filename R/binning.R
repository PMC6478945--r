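# aggregation of per-interval values onto bin grids and re-binning between
# resolutions. Apportionment is linear in overlap width throughout, so every
# operation is checkable against a per-base accumulation oracle and read
# counts are conserved for intervals that lie inside the grid.

#' Construct a binned-counts object
#' @param grid a `bin_grid`
#' @param counts per-bin non-negative values (NA = no data)
#' @param gc optional per-bin GC fraction in \[0,1\]
#' @param sample_id sample identifier
#' @param provenance free-text processing history
#' @return an object of class `binned_counts`
#' @export
binned_counts <- function(grid, counts, gc = NULL, sample_id = NA_character_,
                          provenance = "") {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != n_bins(grid))
    stop2("counts length %d != bin count %d", length(counts), n_bins(grid))
  if (any(!is.na(counts) & counts < 0)) stop2("negative counts")
  if (!is.null(gc)) {
    gc <- as.numeric(gc)
    if (length(gc) != n_bins(grid)) stop2("gc length mismatch")
    if (any(!is.na(gc) & (gc < 0 | gc > 1))) stop2("gc outside [0,1]")
  }
  structure(list(grid = grid, counts = counts, gc = gc,
                 sample_id = sample_id, provenance = provenance),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %s, %d bins, total %.4g, sample=%s\n",
              x$grid$resolution_label, n_bins(x$grid),
              sum(x$counts, na.rm = TRUE), x$sample_id))
  invisible(x)
}

#' Aggregate per-interval counts onto a bin grid
#'
#' Each input count is apportioned to overlapping bins proportionally to
#' overlap width, so the total count is conserved for intervals fully inside
#' the grid. Per-bin GC is the overlap-width-weighted mean of the
#' contributing intervals' gc values (NA where no contributing interval
#' carries gc).
#'
#' @param intervals a [track_table()] of kind counts (or any value track)
#' @param grid target `bin_grid`
#' @return a [binned_counts()] on `grid`
#' @export
aggregate_counts <- function(intervals, grid) {
  stopifnot(inherits(intervals, "track_table"), inherits(grid, "bin_grid"))
  rec <- intervals$records
  nb <- n_bins(grid)
  counts <- numeric(nb)
  gc_num <- numeric(nb); gc_den <- numeric(nb)
  if (nrow(rec)) {
    h <- overlap_hits(rec, grid$bins)
    if (nrow(h)) {
      frac <- h$width / (rec$end[h$q] - rec$start[h$q])
      contrib <- rec$N[h$q] * frac
      counts <- as.numeric(tapply_sum(contrib, h$s, nb))
      has_gc <- !is.na(rec$gc[h$q])
      if (any(has_gc)) {
        gc_num <- tapply_sum(ifelse(has_gc, rec$gc[h$q] * h$width, 0), h$s, nb)
        gc_den <- tapply_sum(ifelse(has_gc, h$width, 0), h$s, nb)
      }
    }
  }
  gc <- ifelse(gc_den > 0, gc_num / gc_den, NA_real_)
  binned_counts(grid, counts, gc = if (any(gc_den > 0)) gc else NULL,
                sample_id = intervals$sample_id,
                provenance = sprintf("aggregate_counts(%s -> %s)",
                                     intervals$grid_label,
                                     grid$resolution_label))
}

# fast grouped sum into a fixed-length vector
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, group = idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Re-bin a value track onto a coarser (or any) grid
#'
#' Each output bin takes the overlap-width-weighted mean of the fine values
#' covering it; bins with no coverage get NA (an explicit gap, never 0 and
#' never interpolated). When the fine track carries per-record sd, the
#' re-binned sd follows the variance-of-weighted-mean convention
#' `sd^2 = sum(w_i * sd_i^2) / (sum w_i)^2` with `w_i` the overlap widths,
#' treating fine bins as independent estimates.
#'
#' @param fine a [track_table()] (kind cn_bins or cn_segments)
#' @param coarse target `bin_grid`
#' @return a [track_table()] of kind cn_bins on the coarse grid
#' @export
rebin_values <- function(fine, coarse) {
  stopifnot(inherits(fine, "track_table"), inherits(coarse, "bin_grid"))
  rec <- fine$records
  nb <- n_bins(coarse)
  num <- numeric(nb); den <- numeric(nb)
  var_num <- numeric(nb); any_sd <- FALSE
  if (nrow(rec)) {
    h <- overlap_hits(rec, coarse$bins)
    if (nrow(h)) {
      ok <- !is.na(rec$N[h$q])
      h <- h[ok, , drop = FALSE]
      num <- tapply_sum(rec$N[h$q] * h$width, h$s, nb)
      den <- tapply_sum(h$width, h$s, nb)
      sds <- rec$sd[h$q]
      if (any(!is.na(sds))) {
        any_sd <- TRUE
        var_num <- tapply_sum(ifelse(is.na(sds), 0, sds^2) * h$width, h$s, nb)
      }
    }
  }
  value <- ifelse(den > 0, num / den, NA_real_)
  sd <- if (any_sd) ifelse(den > 0, sqrt(var_num) / den, NA_real_) else NA_real_
  out <- data.frame(chrom = coarse$bins$chrom, start = coarse$bins$start,
                    end = coarse$bins$end, N = value, sd = sd)
  track_table(out, kind = "cn_bins", grid_label = coarse$resolution_label,
              sample_id = fine$sample_id,
              provenance = sprintf("rebin(%s -> %s)", fine$grid_label,
                                   coarse$resolution_label))
}

#' Default display scales
#'
#' The four display resolutions: 1 Mb for the genome-wide panel, 50 kb for
#' the arm panel, 5 kb for the region panel, plus the irregular bait grid.
#' All four are configurable wherever they are consumed.
#' @return named numeric vector of bin sizes in bp
#' @export
default_scales <- function() c(genome = 1e6, arm = 5e4, region = 5e3)

#' Aggregate a counts track at every display scale
#'
#' Produces one [binned_counts()] per fixed-width scale plus one at bait
#' resolution when targets are supplied. Deterministic given its inputs.
#'
#' @param counts a [track_table()] of kind counts
#' @param layout a [genome_layout()]
#' @param bait_targets optional data.frame of target intervals (chrom,
#'   start, end); adds a "target" resolution
#' @param scales named numeric vector of bin sizes; default
#'   [default_scales()]
#' @return named list of [binned_counts()], one per resolution
#' @export
build_all_scales <- function(counts, layout, bait_targets = NULL,
                             scales = default_scales()) {
  if (!length(scales)) stop2("scales must be non-empty")
  if (is.null(names(scales)) || any(!nzchar(names(scales))))
    names(scales) <- vapply(scales, default_scale_label, "")
  out <- lapply(seq_along(scales), function(i)
    aggregate_counts(counts, tile_genome(layout, scales[[i]],
                                         label = names(scales)[i])))
  names(out) <- names(scales)
  if (!is.null(bait_targets))
    out$target <- aggregate_counts(counts, bait_grid(bait_targets, layout))
  out
}

# binned_counts -> track_table (kind counts or cn_bins)
binned_to_track <- function(bc, kind = "counts", sd = NULL) {
  df <- data.frame(chrom = bc$grid$bins$chrom, start = bc$grid$bins$start,
                   end = bc$grid$bins$end, N = bc$counts)
  if (!is.null(bc$gc)) df$gc <- bc$gc
  if (!is.null(sd)) df$sd <- sd
  track_table(df, kind = kind, grid_label = bc$grid$resolution_label,
              sample_id = bc$sample_id, provenance = bc$provenance)
}

# track_table on a known grid -> binned_counts (records must tile the grid)
track_to_binned <- function(track, grid) {
  stopifnot(inherits(track, "track_table"), inherits(grid, "bin_grid"))
  rec <- track$records
  if (nrow(rec) != n_bins(grid) ||
      !all(rec$chrom == grid$bins$chrom & rec$start == grid$bins$start &
             rec$end == grid$bins$end))
    stop2("track records do not match the grid bins")
  binned_counts(grid, rec$N, gc = if (all(is.na(rec$gc))) NULL else rec$gc,
                sample_id = track$sample_id, provenance = track$provenance)
}
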