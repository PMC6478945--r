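# contextual filtering for clinical display: per-assay blacklists that mask
# recurrent false positives (flag, never delete — curators must still be
# able to inspect masked bins), per-disease whitelists that limit displayed
# annotations to clinically relevant genes, canonical-transcript selection,
# and overflow flagging against the display ceiling.

#' Construct a region list (blacklist or whitelist)
#'
#' @param name list name (e.g. the assay or disease it belongs to)
#' @param mode "blacklist" or "whitelist"
#' @param regions data.frame with chrom/start/end, or NULL
#' @param genes character vector of gene symbols, or NULL (at least one of
#'   `regions`/`genes` must be non-empty)
#' @return an object of class `region_list`
#' @export
region_list <- function(name, mode = c("blacklist", "whitelist"),
                        regions = NULL, genes = NULL) {
  mode <- match.arg(mode)
  if ((is.null(regions) || !nrow(regions)) && !length(genes))
    stop2("region list '%s' is empty", name)
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    regions$chrom <- normalize_chrom(regions$chrom)
    if (any(regions$start >= regions$end)) stop2("region with start >= end")
  }
  structure(list(name = name, mode = mode, regions = regions,
                 genes = genes), class = "region_list")
}

#' Read a region list from a BED (intervals) or TSV (gene symbols) file
#'
#' BED3+: chrom, start, end per line, no header. Gene lists: one symbol per
#' line (first column of a TSV).
#'
#' @param path input file
#' @param mode "blacklist" or "whitelist"
#' @param type "bed" for intervals, "genes" for symbols
#' @param name list name; defaults to the file name
#' @return a [region_list()]
#' @export
read_region_list <- function(path, mode, type = c("bed", "genes"),
                             name = basename(path)) {
  type <- match.arg(type)
  if (type == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    region_list(name, mode,
                regions = data.frame(chrom = df[[1]],
                                     start = as.numeric(df[[2]]),
                                     end = as.numeric(df[[3]])))
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    region_list(name, mode, genes = unique(as.character(df[[1]])))
  }
}

#' Mask blacklisted bins in a CN estimate
#'
#' Bins overlapping any blacklist region get the `masked` flag; CN and sd
#' values are retained (the mask is a display decision, not a deletion).
#'
#' @param cn a [estimate_cn()] result
#' @param bl a [region_list()] with mode "blacklist"
#' @return the `cn_estimate` with updated `masked` flags
#' @export
apply_blacklist <- function(cn, bl) {
  stopifnot(inherits(cn, "cn_estimate"), inherits(bl, "region_list"))
  if (bl$mode != "blacklist") stop2("apply_blacklist needs a blacklist")
  if (!is.null(bl$regions) && nrow(bl$regions)) {
    h <- overlap_hits(cn$grid$bins, bl$regions)
    cn$flags$masked[unique(h$q)] <- TRUE
  }
  cn
}

#' Filter an annotation track by a whitelist
#'
#' Annotation records whose gene matches a whitelisted symbol, or whose
#' interval overlaps a whitelisted region, are kept; everything else is
#' removed. CN tracks are never whitelisted — the whitelist limits display
#' annotations, not data.
#'
#' @param annotation a [track_table()] of kind annotation
#' @param wl a [region_list()] with mode "whitelist"
#' @return the filtered annotation track
#' @export
apply_whitelist <- function(annotation, wl) {
  stopifnot(inherits(annotation, "track_table"),
            inherits(wl, "region_list"))
  if (wl$mode != "whitelist") stop2("apply_whitelist needs a whitelist")
  if (annotation$kind != "annotation")
    stop2("whitelists apply to annotation tracks only")
  keep <- rep(FALSE, nrow(annotation$records))
  if (length(wl$genes))
    keep <- keep | annotation_genes(annotation) %in% wl$genes
  if (!is.null(wl$regions) && nrow(wl$regions)) {
    h <- overlap_hits(annotation$records, wl$regions)
    keep[unique(h$q)] <- TRUE
  }
  annotation$records <- annotation$records[keep, , drop = FALSE]
  rownames(annotation$records) <- NULL
  annotation
}

#' Keep one clinically relevant transcript per gene
#'
#' Genes named in the canonical map keep the mapped transcript; genes absent
#' from the map keep their longest transcript (genomic span; ties broken by
#' the lexicographically smallest transcript id).
#'
#' @param annotation a [track_table()] of kind annotation with labels
#'   `GENE|transcript|exonN`
#' @param canonical named character vector or two-column data.frame / TSV
#'   path mapping gene symbol to transcript id
#' @return the filtered annotation track (one transcript per gene)
#' @export
filter_transcripts <- function(annotation, canonical = NULL) {
  stopifnot(inherits(annotation, "track_table"),
            annotation$kind == "annotation")
  if (is.character(canonical) && length(canonical) == 1 &&
      file.exists(canonical)) {
    df <- read.delim(canonical, header = FALSE, stringsAsFactors = FALSE)
    canonical <- setNames(as.character(df[[2]]), df[[1]])
  } else if (is.data.frame(canonical)) {
    canonical <- setNames(as.character(canonical[[2]]), canonical[[1]])
  }
  genes <- annotation_genes(annotation)
  txs <- annotation_tx(annotation)
  rec <- annotation$records
  keep_tx <- vapply(unique(genes), function(g) {
    i <- which(genes == g)
    if (!is.null(canonical) && g %in% names(canonical) &&
        canonical[[g]] %in% txs[i]) return(canonical[[g]])
    # longest transcript by genomic span, tie -> smallest id
    spans <- vapply(unique(txs[i]), function(tx) {
      j <- i[txs[i] == tx]
      max(rec$end[j]) - min(rec$start[j])
    }, numeric(1))
    cand <- sort(names(spans)[spans == max(spans)])
    cand[1]
  }, character(1))
  keep <- txs == keep_tx[genes]
  annotation$records <- rec[keep, , drop = FALSE]
  rownames(annotation$records) <- NULL
  annotation
}

#' Flag values exceeding the display ceiling
#'
#' Strictly greater than `ymax`: a value exactly at the ceiling displays at
#' the ceiling, values above it are drawn as overflow markers prompting the
#' user to rescale.
#'
#' @param values numeric vector (NA never overflows)
#' @param ymax display ceiling (> 0)
#' @return logical vector, TRUE exactly where `value > ymax`
#' @export
flag_overflow <- function(values, ymax) {
  if (!is.numeric(ymax) || length(ymax) != 1 || ymax <= 0)
    stop2("ymax must be a single positive number")
  !is.na(values) & values > ymax
}
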