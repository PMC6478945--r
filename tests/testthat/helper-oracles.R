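# shared fixtures and independent oracles. Oracles are deliberately written
# the dumb way (per-base arrays, explicit sorting) and never call the code
# paths they check.

tiny_layout <- function(lens = c(A = 2500000, B = 1800000, C = 900000)) {
  genome_layout(data.frame(name = names(lens), length = unname(lens)))
}

# random counts-like track on one or more chromosomes
random_track <- function(layout, n, seed, kind = "counts", max_width = 5000,
                         with_optional = TRUE) {
  set.seed(seed)
  chroms <- layout$chroms$name
  ch <- sample(chroms, n, replace = TRUE)
  len <- layout$chroms$length[match(ch, chroms)]
  start <- floor(runif(n, 0, len - max_width))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  df <- data.frame(chrom = ch, start = start, end = start + width,
                   N = if (kind == "baf") round(runif(n), 4) else
                     round(runif(n, 0, 1000), 3))
  if (with_optional) {
    df$sd <- round(runif(n, 0, 10), 3)
    df$gc <- round(runif(n, 0.2, 0.8), 4)
    df$label <- sprintf("feat%05d", seq_len(n))
  }
  track_table(df, kind = kind, layout = layout)
}

# per-base accumulation oracle for aggregate_counts, one chromosome at a time
oracle_aggregate <- function(rec, grid) {
  out <- numeric(nrow(grid$bins))
  for (ch in unique(grid$bins$chrom)) {
    L <- max(grid$bins$end[grid$bins$chrom == ch])
    base <- numeric(L)
    r <- rec[rec$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      s <- max(0, r$start[i]); e <- min(L, r$end[i])
      if (e > s) base[(s + 1):e] <- base[(s + 1):e] +
          r$N[i] / (r$end[i] - r$start[i])
    }
    bi <- which(grid$bins$chrom == ch)
    for (k in bi)
      out[k] <- sum(base[(grid$bins$start[k] + 1):grid$bins$end[k]])
  }
  out
}

# per-base expansion oracle for rebin_values (weighted mean over covered bp)
oracle_rebin <- function(rec, grid) {
  out <- rep(NA_real_, nrow(grid$bins))
  for (ch in unique(grid$bins$chrom)) {
    L <- max(grid$bins$end[grid$bins$chrom == ch])
    base <- rep(NA_real_, L)
    r <- rec[rec$chrom == ch & !is.na(rec$N), , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      s <- max(0, r$start[i]); e <- min(L, r$end[i])
      if (e > s) base[(s + 1):e] <- r$N[i]
    }
    bi <- which(grid$bins$chrom == ch)
    for (k in bi) {
      v <- base[(grid$bins$start[k] + 1):grid$bins$end[k]]
      if (any(!is.na(v))) out[k] <- mean(v, na.rm = TRUE)
    }
  }
  out
}

# per-base boolean-occupancy oracle for bait merging
oracle_merge <- function(targets, layout) {
  out <- list()
  for (ch in layout$chroms$name) {
    t <- targets[targets$chrom == ch, , drop = FALSE]
    if (!nrow(t)) next
    L <- layout$chroms$length[layout$chroms$name == ch]
    occ <- logical(L)
    for (i in seq_len(nrow(t))) occ[(t$start[i] + 1):t$end[i]] <- TRUE
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# explicit sort-based median and MAD, independent of stats::median
sort_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (!n) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
sort_mad_sd <- function(x) 1.4826 * sort_median(abs(x - sort_median(x)))

# brute-force reference oracle replicating the one-pass cohort
# normalisation + per-bin median/MAD, all through sort_median
oracle_reference <- function(mat) {
  pseudo <- apply(mat, 1, sort_median)
  if (ncol(mat) > 1) {
    for (j in seq_len(ncol(mat))) {
      use <- pseudo > 0 & mat[, j] > 0
      mat[, j] <- mat[, j] * sort_median(pseudo[use] / mat[use, j])
    }
  }
  med <- apply(mat, 1, sort_median)
  sd <- 1.4826 * apply(abs(mat - med), 1, sort_median)
  list(median = med, sd = sd)
}

# simulated diploid Poisson counts on a grid with a gc field
poisson_sample <- function(grid, gc, depth, bias_strength = 1, id = "s") {
  mu <- depth * exp(bias_strength * (gc - 0.5))
  binned_counts(grid, rpois(length(mu), mu), gc = gc, sample_id = id)
}
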