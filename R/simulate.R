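# synthetic-cohort simulator: reference cohorts plus test samples with
# planted CNV segments of known integer copy number, a smooth GC-bias
# field and Poisson (optionally overdispersed) counting noise. Stands in
# for patient data, which is not publicly available, and drives the
# parameter-recovery test suite.
#
# Per bin, the expected count is
#   mean_depth * (CN_eff / 2) * exp(gc_bias_strength * (gc - 0.5))
# with CN_eff = 2 * (1 - f) + CN * f for a planted segment of copy number
# CN at cellular fraction f, and counts drawn Poisson around it.

#' An hg19-like genome layout
#'
#' 24 chromosomes with the standard hg19 lengths and synthetic cytobands
#' derived from approximate centromere positions (bands are evenly spaced
#' with alternating stains — good enough for the ideogram, not a copy of
#' any real cytoband table).
#'
#' @param cytobands attach synthetic cytobands?
#' @return a [genome_layout()]
#' @export
hg19_layout <- function(cytobands = TRUE) {
  layout <- genome_layout(data.frame(name = HG19_SIZES$name,
                                     length = HG19_SIZES$length))
  if (cytobands)
    layout <- set_cytobands(layout, synthetic_cytobands(layout,
                                                        HG19_CENTROMERES))
  layout
}

HG19_SIZES <- data.frame(
  name = c(1:22, "X", "Y"),
  length = c(249250621, 243199373, 198022430, 191154276, 180915260,
             171115067, 159138663, 146364022, 141213431, 135534747,
             135006516, 133851895, 115169878, 107349540, 102531392,
             90354753, 81195210, 78077248, 59128983, 63025520, 48129895,
             51304566, 155270560, 59373566),
  stringsAsFactors = FALSE)

HG19_CENTROMERES <- setNames(
  c(125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6, 49.0, 40.2, 53.7,
    35.8, 17.9, 17.6, 19.0, 36.6, 24.0, 17.2, 26.5, 27.5, 13.2, 14.7,
    60.6, 12.5) * 1e6,
  c(1:22, "X", "Y"))

#' Synthetic cytobands for any layout
#'
#' Splits each chromosome at its centromere (middle of the chromosome when
#' no centromere is given), emits short acen bands around the split and
#' evenly spaced p/q bands with alternating Giemsa stains. Synthetic:
#' intended for display structure, not biological band identity.
#'
#' @param layout a [genome_layout()]
#' @param centromeres named numeric vector chromosome -> centromere bp
#' @param bands_per_arm number of bands per arm
#' @return data.frame chrom/start/end/band/stain
#' @export
synthetic_cytobands <- function(layout, centromeres = NULL,
                                bands_per_arm = 5) {
  stains <- c("gneg", "gpos50", "gneg", "gpos75", "gneg", "gpos25")
  out <- list()
  for (i in seq_len(nrow(layout$chroms))) {
    ch <- layout$chroms$name[i]; len <- layout$chroms$length[i]
    cen <- if (!is.null(centromeres) && ch %in% names(centromeres))
      centromeres[[ch]] else len / 2
    cen <- round(min(max(cen, len * 0.05), len * 0.95))
    acen_w <- round(min(1.5e6, len * 0.02))
    arm <- function(a, b, prefix) {
      edges <- round(seq(a, b, length.out = bands_per_arm + 1))
      data.frame(chrom = ch, start = edges[-length(edges)], end = edges[-1],
                 band = paste0(prefix, seq_len(bands_per_arm)),
                 stain = stains[seq_len(bands_per_arm) %% length(stains) + 1])
    }
    p <- arm(0, cen - acen_w, "p")
    q <- arm(cen + acen_w, len, "q")
    acen <- data.frame(chrom = ch,
                       start = c(cen - acen_w, cen), end = c(cen, cen + acen_w),
                       band = c("p_cen", "q_cen"), stain = "acen")
    out[[i]] <- rbind(p, acen, q)
  }
  do.call(rbind, out)
}

#' A toy genome for fast tests
#'
#' Three 10 Mb chromosomes (configurable) with synthetic cytobands. Small
#' enough for per-base oracles.
#'
#' @param n_chrom number of chromosomes
#' @param chrom_len length of each chromosome in bp
#' @return a [genome_layout()]
#' @export
toy_layout <- function(n_chrom = 3, chrom_len = 1e7) {
  layout <- genome_layout(data.frame(name = paste0("T", seq_len(n_chrom)),
                                     length = rep(chrom_len, n_chrom)))
  set_cytobands(layout, synthetic_cytobands(layout, bands_per_arm = 3))
}

#' Approximate loci of genes used by the scenario presets
#'
#' hg19-like coordinates for a handful of clinically recurrent genes; used
#' only to place synthetic panel baits and planted CNVs.
#' @return data.frame gene/chrom/start/end
#' @export
gene_loci <- function() {
  data.frame(
    gene = c("TP53", "PTCH1", "KRAS", "RB1", "CDK4", "CCND1", "MYC",
             "ERBB2", "ATM", "BRCA1", "BRCA2", "PTEN", "CDKN2A", "EGFR",
             "MDM2", "CCL_CLUSTER"),
    chrom = c("17", "9", "12", "13", "12", "11", "8", "17", "11", "17",
              "13", "10", "9", "7", "12", "17"),
    start = c(7565097, 98205264, 25358180, 48877883, 58141510, 69455873,
              128748315, 37844393, 108093211, 41196312, 32889611,
              89623195, 21967751, 55086714, 69201956, 32400000),
    end = c(7590856, 98279247, 25403854, 49056122, 58146230, 69469242,
            128753680, 37884915, 108239829, 41277500, 32973805, 89728532,
            21995300, 55324313, 69239214, 32800000),
    stringsAsFactors = FALSE)
}

#' Synthesize a targeted panel over a gene set
#'
#' Places `exons_per_gene` evenly spaced baits of width `exon_width` across
#' each gene's span and builds the matching exon-level annotation track
#' (one transcript per gene, labelled `GENE|GENE-tx1|exonN`).
#'
#' @param layout a [genome_layout()]
#' @param genes data.frame like [gene_loci()]
#' @param exons_per_gene baits per gene
#' @param exon_width bait width in bp
#' @return list with elements `targets` (data.frame chrom/start/end/gene/
#'   exon) and `annotation` (a [track_table()])
#' @export
synthetic_panel <- function(layout, genes = gene_loci(),
                            exons_per_gene = 15, exon_width = 150) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    span <- genes$end[i] - genes$start[i]
    k <- if (span < exons_per_gene * exon_width * 2) {
      max(1L, floor(span / (2 * exon_width)))
    } else exons_per_gene
    starts <- round(seq(genes$start[i], genes$end[i] - exon_width,
                        length.out = k))
    rows[[i]] <- data.frame(chrom = genes$chrom[i], start = starts,
                            end = starts + exon_width,
                            gene = genes$gene[i], exon = seq_len(k))
  }
  targets <- do.call(rbind, rows)
  ann <- track_table(
    data.frame(chrom = targets$chrom, start = targets$start,
               end = targets$end, N = targets$exon,
               label = sprintf("%s|%s-tx1|exon%d", targets$gene,
                               targets$gene, targets$exon)),
    kind = "annotation", layout = layout)
  list(targets = targets, annotation = ann)
}

# deterministic smooth GC field: slow sinusoid along each chromosome plus a
# small seeded jitter, clipped to a realistic range
gc_field <- function(grid, layout, jitter_sd = 0.02) {
  mid <- (grid$bins$start + grid$bins$end) / 2
  ci <- match(grid$bins$chrom, layout$chroms$name)
  gc <- 0.45 + 0.1 * sin(2 * pi * mid / 2e7 + ci) +
    rnorm(nrow(grid$bins), 0, jitter_sd)
  pmin(pmax(gc, 0.2), 0.8)
}

#' Define a simulation scenario
#'
#' @param layout a [genome_layout()]
#' @param targets data.frame of bait intervals, or NULL for a whole-genome
#'   grid at `bin_size`
#' @param bin_size bin width for whole-genome scenarios (ignored when
#'   `targets` given)
#' @param mean_depth expected reads per bait/bin for a diploid bin at
#'   gc = 0.5
#' @param gc_bias_strength exponent slope of the GC bias field (0 = none)
#' @param cnv_segments data.frame chrom/start/end/cn/fraction of planted
#'   events for the test sample (fraction = cellular fraction in (0,1])
#' @param n_reference number of CNV-free reference samples
#' @param seed RNG seed: a fixed seed makes the whole cohort reproducible
#' @param overdispersion negative-binomial overdispersion (0 = Poisson);
#'   counts ~ NB with variance mu * (1 + overdispersion * mu)
#' @param name scenario name
#' @return an object of class `sim_scenario`
#' @export
sim_scenario <- function(layout, targets = NULL, bin_size = 5e4,
                         mean_depth = 500, gc_bias_strength = 1,
                         cnv_segments = NULL, n_reference = 20, seed = 1,
                         overdispersion = 0, name = "scenario") {
  if (mean_depth <= 0) stop2("mean_depth must be > 0")
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    if (!all(c("chrom", "start", "end", "cn", "fraction") %in%
             names(cnv_segments)))
      stop2("cnv_segments needs chrom/start/end/cn/fraction")
    if (any(cnv_segments$fraction <= 0 | cnv_segments$fraction > 1))
      stop2("cellular fraction must be in (0,1]")
    cnv_segments$chrom <- normalize_chrom(cnv_segments$chrom)
  }
  structure(list(layout = layout, targets = targets, bin_size = bin_size,
                 mean_depth = mean_depth,
                 gc_bias_strength = gc_bias_strength,
                 cnv_segments = cnv_segments, n_reference = n_reference,
                 seed = seed, overdispersion = overdispersion, name = name),
            class = "sim_scenario")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# expected diploid-relative copy number per bin given planted segments
effective_cn <- function(grid, cnv_segments) {
  cn_eff <- rep(2, n_bins(grid))
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    h <- overlap_hits(grid$bins, cnv_segments)
    if (nrow(h)) {
      f <- cnv_segments$fraction[h$s]
      cn <- cnv_segments$cn[h$s]
      # a bin partially covered by a segment mixes in proportion to overlap
      w <- h$width / (grid$bins$end[h$q] - grid$bins$start[h$q])
      delta <- (2 * (1 - f) + cn * f - 2) * w
      cn_eff <- cn_eff + tapply_sum(delta, h$q, n_bins(grid))
    }
  }
  cn_eff
}

draw_counts <- function(mu, overdispersion) {
  if (overdispersion > 0) {
    size <- 1 / overdispersion
    rpois(length(mu), mu * stats::rgamma(length(mu), shape = size,
                                         rate = size))
  } else rpois(length(mu), mu)
}

#' Simulate a reference cohort plus a test sample
#'
#' Draws `n_reference` CNV-free samples and one test sample carrying the
#' scenario's planted segments, all on the scenario's grid, with a shared
#' smooth GC-bias field and per-sample depth wobble (log-normal, 10%).
#' Fully reproducible for a fixed seed.
#'
#' @param scn a [sim_scenario()]
#' @return list with elements `grid`, `gc` (per-bin GC), `reference` (list
#'   of counts [track_table()]s), `test` (counts track), `truth`
#'   (data.frame chrom/start/end/true_cn/fraction) and `layout`
#' @export
simulate_cohort <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  grid <- if (!is.null(scn$targets)) bait_grid(scn$targets, scn$layout)
    else tile_genome(scn$layout, scn$bin_size)
  with_seed(scn$seed, {
    gc <- gc_field(grid, scn$layout)
    bias <- exp(scn$gc_bias_strength * (gc - 0.5))
    make_sample <- function(id, cn_eff) {
      depth <- scn$mean_depth * exp(rnorm(1, 0, 0.1))
      mu <- depth * (cn_eff / 2) * bias
      binned_to_track(
        binned_counts(grid, draw_counts(mu, scn$overdispersion), gc = gc,
                      sample_id = id,
                      provenance = sprintf("simulated (%s)", scn$name)),
        kind = "counts")
    }
    reference <- lapply(seq_len(scn$n_reference), function(j)
      make_sample(sprintf("ref%02d", j), rep(2, n_bins(grid))))
    test <- make_sample("test", effective_cn(grid, scn$cnv_segments))
    truth <- if (!is.null(scn$cnv_segments) && nrow(scn$cnv_segments)) {
      data.frame(chrom = scn$cnv_segments$chrom,
                 start = scn$cnv_segments$start,
                 end = scn$cnv_segments$end,
                 true_cn = scn$cnv_segments$cn,
                 fraction = scn$cnv_segments$fraction)
    } else data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), true_cn = numeric(0),
                      fraction = numeric(0))
    list(grid = grid, gc = gc, reference = reference, test = test,
         truth = truth, layout = scn$layout)
  })
}

#' Write a truth table
#' @param truth data.frame chrom/start/end/true_cn/fraction
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_truth <- function(truth, path) {
  lines <- c("chrom\tstart\tend\ttrue_cn\tfraction",
             if (nrow(truth)) paste(truth$chrom, fmt_num(truth$start),
                                    fmt_num(truth$end),
                                    fmt_num(truth$true_cn),
                                    fmt_num(truth$fraction), sep = "\t"))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' The four scenario presets
#'
#' Fully specified scenarios emulating the clinical regimes the tool is
#' used in:
#' * `germline_exon_del` — targeted gene panel at 500x mean bait depth,
#'   20 reference samples, one clonal single-exon heterozygous deletion
#'   (exon 15 of the PTCH1-like panel gene).
#' * `hyperdiploid` — genome-wide 50 kb bins, whole-chromosome gains on
#'   chromosomes 3, 5, 7, 9, 11, 15, 19 and 21, monosomy 13 and a focal
#'   deletion at the TP53 locus, at 90% cellular fraction (10 truth
#'   segments).
#' * `ctdna_focal_amp` — targeted panel from plasma ctDNA at 60% tumour
#'   fraction: two high-level focal amplifications (20 and 15 copies) plus
#'   a focal TP53 deletion.
#' * `lowpass_wgs` — ~2x whole-genome coverage in 50 kb bins (about 667
#'   150 bp reads per bin), one whole-chromosome gain and one focal
#'   amplification on 17q.
#'
#' Seeds are fixed per preset so every run of a preset is byte-identical.
#'
#' @param layout genome layout for the presets; default [hg19_layout()]
#' @return named list of [sim_scenario()]s
#' @export
scenario_presets <- function(layout = hg19_layout()) {
  loci <- gene_loci()
  locus <- function(g) loci[loci$gene == g, c("chrom", "start", "end")]
  panel <- synthetic_panel(layout)
  ptch1_ex15 <- panel$targets[panel$targets$gene == "PTCH1" &
                                panel$targets$exon == 15, ]
  seg <- function(df, cn, fraction) {
    data.frame(chrom = df$chrom, start = df$start, end = df$end, cn = cn,
               fraction = fraction)
  }
  whole_chrom <- function(ch) {
    data.frame(chrom = ch, start = 0, end = chrom_length(layout, ch))
  }
  hyper <- do.call(rbind, c(
    lapply(c("3", "5", "7", "9", "11", "15", "19", "21"), function(ch)
      seg(whole_chrom(ch), 3, 0.9)),
    list(seg(whole_chrom("13"), 1, 0.9),
         seg(data.frame(chrom = "17", start = 7.4e6, end = 7.7e6), 1, 0.9))))
  list(
    germline_exon_del = sim_scenario(
      layout, targets = panel$targets, mean_depth = 500,
      gc_bias_strength = 1, cnv_segments = seg(ptch1_ex15, 1, 1),
      n_reference = 20, seed = 101, name = "germline_exon_del"),
    hyperdiploid = sim_scenario(
      layout, bin_size = 5e4, mean_depth = 100, gc_bias_strength = 0.5,
      cnv_segments = hyper, n_reference = 12, seed = 102,
      name = "hyperdiploid"),
    ctdna_focal_amp = sim_scenario(
      layout, targets = panel$targets, mean_depth = 800,
      gc_bias_strength = 1,
      cnv_segments = rbind(seg(locus("KRAS"), 20, 0.6),
                           seg(locus("CCND1"), 15, 0.6),
                           seg(locus("TP53"), 1, 0.6)),
      n_reference = 15, seed = 103, name = "ctdna_focal_amp"),
    lowpass_wgs = sim_scenario(
      layout, bin_size = 5e4, mean_depth = 667, gc_bias_strength = 0.5,
      cnv_segments = rbind(seg(whole_chrom("9"), 3, 0.8),
                           seg(locus("CCL_CLUSTER"), 8, 0.8)),
      n_reference = 10, seed = 104, name = "lowpass_wgs"))
}

#' Run the estimation pipeline on a simulated cohort
#'
#' Convenience wrapper used by tests and the CLI: builds the reference from
#' the cohort, scales + GC-corrects the test sample and estimates CN on the
#' simulation's native grid.
#'
#' @param sim output of [simulate_cohort()]
#' @return list with `reference` ([build_reference()] model), `cn`
#'   ([estimate_cn()] result), `corrected` and `raw` [binned_counts()]
#' @export
run_pipeline <- function(sim) {
  ref_counts <- lapply(sim$reference, track_to_binned, grid = sim$grid)
  ref_corr <- lapply(ref_counts, gc_correct)
  ref <- build_reference(ref_corr, sim$grid)
  raw <- track_to_binned(sim$test, sim$grid)
  corrected <- gc_correct(scale_library(raw, ref))
  corrected <- scale_library(corrected, ref)
  list(reference = ref, cn = estimate_cn(corrected, ref),
       corrected = corrected, raw = raw)
}

#' Compare a CN estimate with a truth table
#'
#' For each truth segment: the median estimated CN over bins overlapping
#' the segment, the expected mixture CN `2(1-f) + cn*f`, and the detection
#' verdict — the segment's median deviates from 2 in the true direction by
#' at least half the true deviation.
#'
#' @param cn a [estimate_cn()] result
#' @param truth data.frame chrom/start/end/true_cn/fraction
#' @return the truth data.frame plus columns `seg_median`, `expected_cn`,
#'   `n_bins`, `detected`
#' @export
recover_truth <- function(cn, truth) {
  if (!nrow(truth)) {
    truth$seg_median <- numeric(0); truth$expected_cn <- numeric(0)
    truth$n_bins <- integer(0); truth$detected <- logical(0)
    return(truth)
  }
  h <- overlap_hits(cn$grid$bins, truth)
  truth$seg_median <- NA_real_; truth$n_bins <- 0L
  for (s in unique(h$s)) {
    bins <- h$q[h$s == s]
    truth$seg_median[s] <- median(cn$cn[bins], na.rm = TRUE)
    truth$n_bins[s] <- length(bins)
  }
  truth$expected_cn <- 2 * (1 - truth$fraction) +
    truth$true_cn * truth$fraction
  dev_true <- truth$expected_cn - 2
  dev_obs <- truth$seg_median - 2
  truth$detected <- !is.na(truth$seg_median) &
    sign(dev_obs) == sign(dev_true) & abs(dev_obs) >= abs(dev_true) / 2
  truth
}
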