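# shared internal helpers: chromosome-name handling, genome ordering,
# interval overlap (backed by IRanges), numeric formatting

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip a leading "chr" prefix from chromosome names
#'
#' Inputs mix UCSC-style names ("chr17") with bare names ("17"); the
#' canonical internal form is the bare name. The prefix is re-added at
#' output boundaries when a dialect asks for it.
#'
#' @param x character vector of chromosome names
#' @return character vector without the "chr" prefix
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# rank for chromosome names when no layout dictates an order:
# numeric first, then X, Y, MT, then everything else alphabetically
chrom_rank <- function(x) {
  x <- normalize_chrom(x)
  n <- suppressWarnings(as.integer(x))
  r <- ifelse(!is.na(n), n,
    ifelse(x == "X", 1e6, ifelse(x == "Y", 1e6 + 1,
      ifelse(x %in% c("M", "MT"), 1e6 + 2, NA_real_))))
  other <- is.na(r)
  if (any(other)) r[other] <- 2e6 + match(x[other], sort(unique(x[other])))
  r
}

# contigs we drop on input: alt/patch/random/unlocalised
is_alt_contig <- function(x) {
  grepl("_", x, fixed = TRUE) | grepl("alt$|random$|^Un|^GL|^KI|hap", x)
}

# order for interval data.frames (chrom/start columns); layout order when given
genome_order <- function(df, layout = NULL) {
  if (!is.null(layout)) {
    order(match(df$chrom, layout$chroms$name), df$start, df$end)
  } else {
    order(chrom_rank(df$chrom), df$start, df$end)
  }
}

# all pairwise overlaps between two interval data.frames (0-based half-open).
# Returns data.frame(q, s, width) with row indices into q/s and overlap widths.
overlap_hits <- function(q, s) {
  stopifnot(all(c("chrom", "start", "end") %in% names(q)),
            all(c("chrom", "start", "end") %in% names(s)))
  out_q <- integer(0); out_s <- integer(0); out_w <- numeric(0)
  for (ch in intersect(unique(q$chrom), unique(s$chrom))) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    qr <- IRanges::IRanges(start = q$start[qi] + 1L, end = q$end[qi])
    sr <- IRanges::IRanges(start = s$start[si] + 1L, end = s$end[si])
    h <- IRanges::findOverlaps(qr, sr)
    if (length(h)) {
      qh <- qi[S4Vectors::queryHits(h)]
      sh <- si[S4Vectors::subjectHits(h)]
      out_q <- c(out_q, qh)
      out_s <- c(out_s, sh)
      out_w <- c(out_w, pmin(q$end[qh], s$end[sh]) - pmax(q$start[qh], s$start[sh]))
    }
  }
  data.frame(q = out_q, s = out_s, width = out_w)
}

# fixed float formatting for deterministic writers: 6 significant digits,
# NA as ".", integers without trailing zeros
fmt_num <- function(x) {
  ifelse(is.na(x), ".", formatC(x, digits = 6, format = "g"))
}

# genomic coordinates are whole numbers; never use scientific notation
fmt_coord <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.0f", x))
}

fmt_chr <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))

parse_num <- function(x) {
  x[x == "."] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# robust location/scale used throughout: median and 1.4826 * median |x - med|
robust_median <- function(x) median(x, na.rm = TRUE)

robust_sd <- function(x, center = NULL) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (is.null(center)) center <- median(x)
  1.4826 * median(abs(x - center))
}

# robust coefficient of variation; NA (with a warning upstream) if median == 0
robust_cv <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  m <- median(x)
  if (m == 0) return(NA_real_)
  robust_sd(x) / m
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)
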