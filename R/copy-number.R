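# the numerical core: library-size scaling, GC correction, robust
# median/MAD reference model, CN estimation with error bars, ratio mode,
# and QC statistics.
#
# Order of operations: aggregate -> scale -> GC-correct -> CN. GC factors
# are estimated per resolution independently, because bait-level GC differs
# from 1 Mb-bin GC and each display scale must be self-consistent.

#' Scale a sample's counts to a reference
#'
#' The scale factor is the median, over bins where both the reference median
#' and the sample count are positive, of `ref_median_i / counts_i`. The
#' factor is recorded in the provenance and as attribute `scale_factor`.
#'
#' @param counts a [binned_counts()]
#' @param reference a [reference_model()] on the same grid, or a numeric
#'   vector of per-bin reference medians
#' @return the scaled [binned_counts()]
#' @export
scale_library <- function(counts, reference) {
  stopifnot(inherits(counts, "binned_counts"))
  ref_med <- if (inherits(reference, "reference_model")) {
    if (!same_grid(counts$grid, reference$grid)) stop2("grid mismatch")
    reference$ref_median
  } else as.numeric(reference)
  if (length(ref_med) != n_bins(counts$grid)) stop2("reference length mismatch")
  usable <- !is.na(ref_med) & ref_med > 0 & !is.na(counts$counts) &
    counts$counts > 0
  if (!any(usable)) stop2("cannot scale: no usable bins")
  s <- median(ref_med[usable] / counts$counts[usable])
  out <- counts
  out$counts <- counts$counts * s
  out$provenance <- paste0(counts$provenance,
                           sprintf("; scale_library(s=%.6g)", s))
  attr(out, "scale_factor") <- s
  out
}

#' GC-correct binned counts
#'
#' Stratified running-median correction: bins are grouped into GC strata of
#' width `strata_width` (default 2%), the median count per stratum is
#' smoothed by a running median across strata, and each count is multiplied
#' by `global_median / f(gc_bin)`. Bins without a gc value pass through
#' unchanged and are reported in attribute `uncorrected_bins`.
#'
#' @param counts a [binned_counts()] with gc present for at least
#'   `min_gc_frac` of the nonzero bins
#' @param strata_width GC stratum width (fraction, default 0.02)
#' @param min_gc_frac minimum fraction of nonzero bins that must carry gc
#' @return the corrected [binned_counts()]
#' @export
gc_correct <- function(counts, strata_width = 0.02, min_gc_frac = 0.9) {
  stopifnot(inherits(counts, "binned_counts"))
  x <- counts$counts
  nz <- which(!is.na(x) & x > 0)
  if (!length(nz)) stop2("all-zero counts: nothing to correct")
  gc <- counts$gc
  if (is.null(gc)) stop2("no gc values on this track")
  have_gc <- !is.na(gc)
  if (mean(have_gc[nz]) < min_gc_frac)
    stop2("gc present for only %.0f%% of nonzero bins (need >= %.0f%%)",
          100 * mean(have_gc[nz]), 100 * min_gc_frac)
  use <- nz[have_gc[nz]]
  stratum <- floor(gc[use] / strata_width)
  med_by_stratum <- tapply(x[use], stratum, median)
  lev <- as.numeric(names(med_by_stratum))
  o <- order(lev)
  lev <- lev[o]; f <- as.numeric(med_by_stratum)[o]
  k <- min(5L, if (length(f) %% 2 == 0) length(f) - 1L else length(f))
  if (k >= 3) f <- runmed(f, k = k, endrule = "median")
  global_med <- median(x[use])
  fac <- f[match(floor(gc / strata_width), lev)]
  corrected <- ifelse(have_gc & !is.na(fac) & fac > 0,
                      x * (global_med / fac), x)
  out <- counts
  out$counts <- corrected
  out$provenance <- paste0(counts$provenance,
                           sprintf("; gc_correct(width=%g)", strata_width))
  attr(out, "uncorrected_bins") <- which(!have_gc | is.na(fac) | fac <= 0)
  attr(out, "gc_factor") <- data.frame(gc = lev * strata_width, factor = f)
  out
}

#' Build a robust reference model from a cohort
#'
#' Each sample is first normalised to the cohort (one pass: scaled by the
#' median ratio to the per-bin cross-sample median). Per bin, the reference
#' location is the median of the normalised counts across samples and the
#' reference SD is 1.4826 times the median absolute deviation — robust
#' estimators, so tumour samples can sit in the reference set without
#' biasing it. With a single sample the reference SD is undefined (NA) but
#' CN is still computable, enabling two-sample ratio workflows.
#'
#' @param samples list of [binned_counts()] on a common grid
#' @param grid the common `bin_grid` (defaults to the first sample's grid)
#' @return an object of class `reference_model` with per-bin `ref_median`
#'   and `ref_sd`, `n_samples` and `member_ids`
#' @export
build_reference <- function(samples, grid = NULL) {
  if (!length(samples)) stop2("need at least one sample")
  stopifnot(all(vapply(samples, inherits, TRUE, "binned_counts")))
  if (is.null(grid)) grid <- samples[[1]]$grid
  for (s in samples) if (!same_grid(s$grid, grid)) stop2("grid mismatch")
  m <- vapply(samples, function(s) s$counts, numeric(n_bins(grid)))
  m <- matrix(m, nrow = n_bins(grid))
  # one-pass cohort normalisation: scale each sample to the per-bin median
  pseudo <- apply(m, 1, median, na.rm = TRUE)
  if (ncol(m) > 1) {
    for (j in seq_len(ncol(m))) {
      usable <- !is.na(pseudo) & pseudo > 0 & !is.na(m[, j]) & m[, j] > 0
      if (!any(usable)) stop2("cannot scale sample %d to cohort", j)
      m[, j] <- m[, j] * median(pseudo[usable] / m[usable, j])
    }
  }
  ref_median <- apply(m, 1, median, na.rm = TRUE)
  ref_sd <- if (ncol(m) > 1) {
    1.4826 * apply(abs(m - ref_median), 1, median, na.rm = TRUE)
  } else rep(NA_real_, n_bins(grid))
  ids <- vapply(samples, function(s) as.character(s$sample_id), "")
  structure(list(grid = grid, ref_median = ref_median, ref_sd = ref_sd,
                 n_samples = length(samples), member_ids = ids),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %d samples, %d bins (%s)\n", x$n_samples,
              n_bins(x$grid), x$grid$resolution_label))
  invisible(x)
}

# per-bin low-coverage floor: max(min_reads, floor_frac of the chromosome's
# median reference level). Avoids exploding ratios in dead bins.
low_ref_floor <- function(reference, min_reads = 10, floor_frac = 0.01) {
  med_by_chr <- tapply(reference$ref_median, reference$grid$bins$chrom,
                       median, na.rm = TRUE)
  pmax(min_reads,
       floor_frac * as.numeric(med_by_chr[reference$grid$bins$chrom]))
}

#' Estimate copy number against a reference model
#'
#' `cn_i = ploidy * x_i / ref_median_i` and
#' `sd_i = ploidy * ref_sd_i / ref_median_i`. The reported sd carries only
#' the sample-side contribution, not the uncertainty of the reference
#' itself, so it underestimates the true SD of the CN estimate; with enough
#' reference samples it is a good lower bound. Bins whose reference median
#' falls below the low-coverage floor (`max(min_reads, floor_frac *
#' chromosome median)`) are flagged `low_ref` with missing CN.
#'
#' @param sample a [binned_counts()], already library-scaled and
#'   GC-corrected
#' @param reference a [reference_model()] on the same grid
#' @param ploidy baseline copy number (default 2); a named vector gives a
#'   per-chromosome override (e.g. `c(2, X = 1, Y = 1)` with the unnamed
#'   element as the default)
#' @param min_reads,floor_frac low-coverage floor parameters
#' @return an object of class `cn_estimate`: per-bin `cn`, `sd` and a
#'   logical flag data.frame (`low_ref`, `masked`, `missing`)
#' @export
estimate_cn <- function(sample, reference, ploidy = 2, min_reads = 10,
                        floor_frac = 0.01) {
  stopifnot(inherits(sample, "binned_counts"),
            inherits(reference, "reference_model"))
  if (!same_grid(sample$grid, reference$grid)) stop2("grid mismatch")
  nb <- n_bins(sample$grid)
  pl_default <- if (is.null(names(ploidy))) ploidy[[1]] else {
    d <- unname(ploidy[names(ploidy) == ""])
    if (length(d)) d[1] else 2
  }
  pl <- rep(pl_default, nb)
  if (!is.null(names(ploidy))) {
    for (ch in setdiff(names(ploidy), ""))
      pl[sample$grid$bins$chrom == ch] <- ploidy[[ch]]
  }
  floor_i <- low_ref_floor(reference, min_reads, floor_frac)
  low <- is.na(reference$ref_median) | reference$ref_median < floor_i
  miss <- is.na(sample$counts)
  cn <- ifelse(low | miss, NA_real_,
               pl * sample$counts / reference$ref_median)
  sd <- ifelse(low | miss, NA_real_,
               pl * reference$ref_sd / reference$ref_median)
  structure(list(grid = sample$grid, cn = cn, sd = sd,
                 flags = data.frame(low_ref = low, masked = logical(nb),
                                    missing = miss | low),
                 sample_id = sample$sample_id,
                 provenance = paste0(sample$provenance, "; estimate_cn")),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf(
    "<cn_estimate> %d bins (%s), median CN %.3g, %d low_ref, %d masked\n",
    n_bins(x$grid), x$grid$resolution_label, median(x$cn, na.rm = TRUE),
    sum(x$flags$low_ref), sum(x$flags$masked)))
  invisible(x)
}

# cn_estimate -> track_table for writing/rendering
cn_to_track <- function(cn, kind = "cn_bins") {
  df <- data.frame(chrom = cn$grid$bins$chrom, start = cn$grid$bins$start,
                   end = cn$grid$bins$end, N = cn$cn, sd = cn$sd)
  track_table(df, kind = kind, grid_label = cn$grid$resolution_label,
              sample_id = cn$sample_id, provenance = cn$provenance)
}

#' Ratio of two samples (multi-sample ratio mode)
#'
#' One sample is chosen as the denominator and the per-bin ratio is
#' returned: for two [cn_estimate()]s the CN ratio, for two
#' [binned_counts()] the count ratio after scaling the denominator to the
#' numerator (so any counts-based data works, e.g. RNA-seq abundance for a
#' differential-expression view). Bins where the denominator falls below
#' `denom_floor` are missing.
#'
#' @param sample_a numerator ([cn_estimate()] or [binned_counts()])
#' @param sample_b denominator, same class and grid
#' @param denom_floor minimum denominator value; defaults to 0.25 for CN
#'   tracks and the low-coverage floor's `min_reads = 10` for count tracks
#' @return an object of class `ratio_track`: per-bin `ratio` plus `missing`
#' @export
ratio_mode <- function(sample_a, sample_b, denom_floor = NULL) {
  if (inherits(sample_a, "cn_estimate") && inherits(sample_b, "cn_estimate")) {
    if (!same_grid(sample_a$grid, sample_b$grid)) stop2("grid mismatch")
    a <- sample_a$cn; b <- sample_b$cn
    if (is.null(denom_floor)) denom_floor <- 0.25
  } else if (inherits(sample_a, "binned_counts") &&
             inherits(sample_b, "binned_counts")) {
    if (!same_grid(sample_a$grid, sample_b$grid)) stop2("grid mismatch")
    sample_b <- scale_library(sample_b, sample_a$counts)
    a <- sample_a$counts; b <- sample_b$counts
    if (is.null(denom_floor)) denom_floor <- 10
  } else stop2("ratio_mode needs two cn_estimate or two binned_counts")
  bad <- is.na(a) | is.na(b) | b < denom_floor
  structure(list(grid = sample_a$grid,
                 ratio = ifelse(bad, NA_real_, a / b),
                 missing = bad,
                 sample_id = paste0(sample_a$sample_id, "/",
                                    sample_b$sample_id)),
            class = "ratio_track")
}

#' QC summary statistics
#'
#' Robust coefficient of variation (`1.4826 * MAD / median`, over nonzero
#' non-missing bins) for the raw counts, the GC-corrected counts and the
#' estimated CN — the three numbers read off before interpreting a sample.
#' When targets are given, each statistic is also split into targeted vs
#' untargeted bins.
#'
#' @param raw a [binned_counts()] before correction
#' @param corrected the same sample after [gc_correct()]
#' @param cn the sample's [cn_estimate()]
#' @param targets optional data.frame of target intervals for the
#'   targeted/untargeted split
#' @return a data.frame of class `qc_summary` with columns metric, subset,
#'   cv, n_bins; CV is NA with a warning where the median is zero
#' @export
qc_summary <- function(raw, corrected, cn, targets = NULL) {
  stopifnot(inherits(raw, "binned_counts"),
            inherits(corrected, "binned_counts"),
            inherits(cn, "cn_estimate"))
  if (!same_grid(raw$grid, corrected$grid) || !same_grid(raw$grid, cn$grid))
    stop2("grids not aligned")
  vecs <- list(cv_raw = raw$counts, cv_gc = corrected$counts, cv_cn = cn$cn)
  subsets <- list(all = rep(TRUE, n_bins(raw$grid)))
  if (!is.null(targets)) {
    hit <- rep(FALSE, n_bins(raw$grid))
    h <- overlap_hits(raw$grid$bins, targets)
    hit[unique(h$q)] <- TRUE
    subsets$target <- hit
    subsets$offtarget <- !hit
  }
  rows <- list()
  for (mname in names(vecs)) for (sname in names(subsets)) {
    v <- vecs[[mname]][subsets[[sname]]]
    v <- v[!is.na(v) & v > 0]
    cv <- robust_cv(v)
    if (length(v) && is.na(cv)) warn2("median zero for %s/%s", mname, sname)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mname, subset = sname, cv = cv, n_bins = length(v))
  }
  out <- do.call(rbind, rows)
  out$resolution <- raw$grid$resolution_label
  structure(out, class = c("qc_summary", "data.frame"))
}
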