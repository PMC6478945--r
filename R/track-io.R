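# track and index table I/O.
#
# Every displayable quantity travels as a tab-separated "track table" with a
# minimal fixed set of columns: chrom, start, end, N (the value: copy
# number, read count, ratio or B-allele frequency depending on the track
# kind) plus optional sd, gc and label. A single index table catalogues all
# track tables for one or more samples. Coordinates in files are 0-based
# half-open; missing values are written as ".".

TRACK_KINDS <- c("counts", "cn_bins", "cn_segments", "breakpoints", "baf",
                 "annotation", "cytoband", "chromosomes")

TRACK_COLUMNS <- c("chrom", "start", "end", "N", "sd", "gc", "label")

#' Construct a track table
#'
#' The canonical in-memory form always carries all seven columns (missing
#' optional columns are filled with NA) and is sorted in genome order.
#'
#' @param records data.frame with at least chrom, start, end, N
#' @param kind one of `r paste(TRACK_KINDS, collapse = ", ")`
#' @param layout optional [genome_layout()] used for ordering and validation;
#'   records on chromosomes absent from the layout are dropped with a warning
#' @param grid_label resolution tag ("genome", "arm", "region", "target") or
#'   "irregular"
#' @param sample_id sample identifier
#' @param provenance free-text metadata recorded with the table
#' @return an object of class `track_table`
#' @export
track_table <- function(records, kind, layout = NULL,
                        grid_label = "irregular", sample_id = NA_character_,
                        provenance = "") {
  kind <- match.arg(kind, TRACK_KINDS)
  stopifnot(is.data.frame(records))
  need <- c("chrom", "start", "end", "N")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop2("track records missing column(s): %s",
                          paste(miss, collapse = ", "))
  rec <- records
  rec$chrom <- normalize_chrom(rec$chrom)
  for (col in c("sd", "gc", "label"))
    if (!col %in% names(rec))
      rec[[col]] <- rep(if (col == "label") NA_character_ else NA_real_,
                        nrow(rec))
  rec <- rec[, TRACK_COLUMNS, drop = FALSE]
  rec$start <- as.numeric(rec$start); rec$end <- as.numeric(rec$end)
  rec$N <- as.numeric(rec$N); rec$sd <- as.numeric(rec$sd)
  rec$gc <- as.numeric(rec$gc); rec$label <- as.character(rec$label)
  if (nrow(rec)) {
    if (any(rec$start >= rec$end)) stop2("record with start >= end")
    if (any(rec$start < 0)) stop2("record with negative start")
    if (any(!is.na(rec$sd) & rec$sd < 0)) stop2("negative sd")
    if (any(!is.na(rec$gc) & (rec$gc < 0 | rec$gc > 1)))
      stop2("gc outside [0,1]")
    if (kind == "baf" && any(!is.na(rec$N) & (rec$N < 0 | rec$N > 1)))
      stop2("baf track with N outside [0,1]")
    dropped <- 0L
    if (!is.null(layout)) {
      keep <- rec$chrom %in% layout$chroms$name
      dropped <- sum(!keep)
      if (dropped) {
        warn2("dropped %d record(s) on unknown chromosome(s): %s", dropped,
              paste(head(unique(rec$chrom[!keep]), 5), collapse = ", "))
        rec <- rec[keep, , drop = FALSE]
      }
      over <- rec$end > chrom_length(layout, rec$chrom)
      if (any(over)) stop2("record beyond chromosome end: %s:%g-%g",
                           rec$chrom[over][1], rec$start[over][1],
                           rec$end[over][1])
    }
    rec <- rec[genome_order(rec, layout), , drop = FALSE]
  }
  rownames(rec) <- NULL
  structure(list(kind = kind, grid_label = grid_label,
                 sample_id = sample_id, provenance = provenance,
                 records = rec),
            class = "track_table")
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> kind=%s grid=%s sample=%s: %d records\n",
              x$kind, x$grid_label, x$sample_id, nrow(x$records)))
  invisible(x)
}

#' Read a track table
#'
#' Tab-separated with header; mandatory columns chrom, start, end, N for
#' value tracks. Rows on chromosomes unknown to the layout are dropped with
#' a counted warning. Accepts LF and CRLF line endings.
#'
#' @param path file path or connection
#' @inheritParams track_table
#' @param kind expected track kind
#' @return a [track_table()]
#' @export
read_track <- function(path, kind, layout = NULL, grid_label = "irregular",
                       sample_id = NA_character_) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = character(0))
  need <- c("chrom", "start", "end", "N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("track file %s missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  for (col in c("start", "end")) {
    v <- parse_num(df[[col]])
    bad <- which(is.na(v) & df[[col]] != ".")
    if (length(bad)) stop2("non-numeric %s at line %d of %s", col,
                           bad[1] + 1L, path)
    df[[col]] <- v
  }
  nv <- parse_num(df$N)
  bad <- which(is.na(nv) & df$N != ".")
  if (length(bad)) stop2("non-numeric N at line %d of %s", bad[1] + 1L, path)
  df$N <- nv
  for (col in c("sd", "gc")) if (col %in% names(df)) df[[col]] <- parse_num(df[[col]])
  if ("label" %in% names(df)) df$label[df$label == "."] <- NA_character_
  if (nrow(df) && any(df$start >= df$end))
    stop2("start >= end at line %d of %s", which(df$start >= df$end)[1] + 1L, path)
  track_table(df, kind = kind, layout = layout, grid_label = grid_label,
              sample_id = sample_id)
}

#' Write a track table
#'
#' Deterministic TSV: fixed column order (chrom, start, end, N, sd, gc,
#' label), floats at 6 significant digits, NA written as ".", rows in genome
#' order, LF line endings. The same table always produces identical bytes.
#'
#' @param table a [track_table()]
#' @param path output file path
#' @param chr_prefix prepend "chr" to chromosome names on output
#' @return the path, invisibly
#' @export
write_track <- function(table, path, chr_prefix = FALSE) {
  stopifnot(inherits(table, "track_table"))
  rec <- table$records
  chrom <- if (chr_prefix) paste0("chr", rec$chrom) else rec$chrom
  lines <- c(paste(TRACK_COLUMNS, collapse = "\t"),
             if (nrow(rec)) paste(chrom,
                                  fmt_coord(rec$start), fmt_coord(rec$end),
                                  fmt_num(rec$N), fmt_num(rec$sd),
                                  fmt_num(rec$gc), fmt_chr(rec$label),
                                  sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# ---- index table --------------------------------------------------------

INDEX_COLUMNS <- c("sample_id", "kind", "resolution", "path", "name")

#' Read an index table
#'
#' The index is the catalogue: one row per displayable track table, with
#' columns sample_id, kind, resolution, path, name and an optional group tag
#' used for reference-set selection. Multi-sample mode is flagged on
#' automatically when more than one sample_id is present.
#'
#' @param path file path, URL or connection (anything [read.delim()] accepts)
#' @param base_dir directory against which relative paths in the index are
#'   resolved; defaults to the index file's directory
#' @return an object of class `index_table`: the row data.frame plus
#'   attributes `multi_sample` (logical) and `extra` (unknown columns)
#' @export
read_index <- function(path, base_dir = NULL) {
  df <- tryCatch(read.delim(path, header = TRUE, stringsAsFactors = FALSE),
                 error = function(e) stop2("cannot read index %s: %s", path,
                                           conditionMessage(e)))
  if (!nrow(df)) stop2("empty index table: %s", path)
  miss <- setdiff(INDEX_COLUMNS, names(df))
  if (length(miss)) stop2("index missing mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"group" %in% names(df)) df$group <- NA_character_
  key <- paste(df$sample_id, df$kind, df$resolution)
  if (anyDuplicated(key))
    stop2("duplicate index rows for: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  extra <- setdiff(names(df), c(INDEX_COLUMNS, "group"))
  if (is.null(base_dir) && is.character(path)) base_dir <- dirname(path)
  idx <- df[, c(INDEX_COLUMNS, "group")]
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]+://)", idx$path)
    idx$path[rel] <- file.path(base_dir, idx$path[rel])
  }
  missing_files <- !grepl("://", idx$path) & !file.exists(idx$path)
  structure(idx, class = c("index_table", "data.frame"),
            multi_sample = length(unique(idx$sample_id)) > 1L,
            extra = df[, extra, drop = FALSE],
            missing_paths = idx$path[missing_files])
}

#' Write an index table
#' @param index an `index_table` or data.frame with the index columns
#' @param path output file path
#' @return the path, invisibly
#' @export
write_index <- function(index, path) {
  df <- as.data.frame(index)[, c(INDEX_COLUMNS, "group")]
  df$group[is.na(df$group)] <- "."
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Is multi-sample mode on for this index?
#' @param index an `index_table`
#' @return logical
#' @export
multi_sample_mode <- function(index) isTRUE(attr(index, "multi_sample"))

# ---- caller-output ingestion -------------------------------------------

#' Import third-party copy-number caller output
#'
#' Converts caller output into a track table suitable for re-binning and
#' display. Supported dialects:
#' * `seg`: DNAcopy-style SEG (ID, chrom, loc.start, loc.end, num.mark,
#'   seg.mean), 1-based inclusive coordinates, seg.mean on the log2-ratio
#'   scale; converted to linear CN via `CN = 2 * 2^log2ratio`. Kind
#'   `cn_segments`.
#' * `bedgraph`: chrom/start/end/value, 0-based half-open, no header; values
#'   taken as linear CN unless `log2 = TRUE`. Kind `cn_bins`.
#' * `ratio_table`: TSV with header chrom/start/end/ratio, 0-based; linear
#'   depth ratio relative to diploid, `CN = 2 * ratio`. Kind `cn_bins`.
#'
#' @param path input file
#' @param dialect one of "seg", "bedgraph", "ratio_table"
#' @param layout a [genome_layout()]
#' @param log2 for `bedgraph`: are the values log2 ratios?
#' @param sample_id sample identifier for the resulting table
#' @return a [track_table()] of kind cn_segments or cn_bins
#' @export
import_caller_output <- function(path, dialect, layout, log2 = FALSE,
                                 sample_id = NA_character_) {
  dialects <- c("seg", "bedgraph", "ratio_table")
  if (!dialect %in% dialects)
    stop2("unrecognized dialect '%s'; supported: %s", dialect,
          paste(dialects, collapse = ", "))
  if (dialect == "seg") {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop2("SEG file needs 6 columns, found %d", ncol(df))
    names(df)[1:6] <- c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                        "seg.mean")
    rec <- data.frame(chrom = df$chrom, start = df$loc.start - 1,
                      end = df$loc.end, N = 2 * 2^df$seg.mean)
    kind <- "cn_segments"
    if (is.na(sample_id) && length(unique(df$ID)) == 1L) sample_id <- df$ID[1]
  } else if (dialect == "bedgraph") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     comment.char = "#")
    df <- df[!grepl("^track", df[[1]]), , drop = FALSE]
    if (ncol(df) < 4) stop2("bedGraph needs 4 columns")
    v <- as.numeric(df[[4]])
    rec <- data.frame(chrom = df[[1]], start = as.numeric(df[[2]]),
                      end = as.numeric(df[[3]]),
                      N = if (log2) 2 * 2^v else v)
    kind <- "cn_bins"
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "ratio")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop2("ratio_table missing column(s): %s",
                            paste(miss, collapse = ", "))
    rec <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      N = 2 * df$ratio)
    kind <- "cn_bins"
  }
  track_table(rec, kind = kind, layout = layout, sample_id = sample_id,
              provenance = sprintf("imported dialect=%s from %s", dialect,
                                   basename(path)))
}

# ---- annotations --------------------------------------------------------

#' Read a transcript annotation into an exon-level track
#'
#' One record per exon, labelled `GENE|transcript|exonN` with exon numbers
#' in transcription order (exon 1 is the 3'-most genomic exon on the minus
#' strand). N carries the exon number so the track fits the common schema.
#'
#' @param path input file
#' @param dialect "refFlat" (UCSC refFlat.txt, no header, 11 columns) or
#'   "gtf" (exon features with gene_name/gene_id and transcript_id
#'   attributes)
#' @param layout a [genome_layout()]
#' @return a [track_table()] of kind annotation
#' @export
read_annotation <- function(path, dialect = c("refFlat", "gtf"), layout) {
  dialect <- match.arg(dialect)
  if (dialect == "refFlat") rec <- parse_refflat(path) else rec <- parse_gtf(path)
  track_table(rec, kind = "annotation", layout = layout,
              provenance = sprintf("annotation dialect=%s", dialect))
}

parse_refflat <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11) stop2("refFlat needs 11 columns, found %d", ncol(df))
  names(df)[1:11] <- c("geneName", "name", "chrom", "strand", "txStart",
                       "txEnd", "cdsStart", "cdsEnd", "exonCount",
                       "exonStarts", "exonEnds")
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    starts <- as.numeric(strsplit(df$exonStarts[i], ",")[[1]])
    ends <- as.numeric(strsplit(df$exonEnds[i], ",")[[1]])
    if (length(starts) != df$exonCount[i] || length(ends) != df$exonCount[i])
      stop2("malformed refFlat row at line %d: exon list length != exonCount", i)
    k <- length(starts)
    exon_no <- if (df$strand[i] == "-") rev(seq_len(k)) else seq_len(k)
    out[[i]] <- data.frame(chrom = df$chrom[i], start = starts, end = ends,
                           N = exon_no,
                           label = sprintf("%s|%s|exon%d", df$geneName[i],
                                           df$name[i], exon_no))
  }
  do.call(rbind, out)
}

parse_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9)
  if (length(bad)) stop2("malformed GTF row at line %d", bad[1])
  keep <- vapply(f, function(x) x[3] == "exon", logical(1))
  f <- f[keep]
  if (!length(f)) stop2("no exon features in GTF")
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  rec <- do.call(rbind, lapply(f, function(x) {
    gene <- attr_get(x[9], "gene_name")
    if (is.na(gene)) gene <- attr_get(x[9], "gene_id")
    data.frame(chrom = x[1], start = as.numeric(x[4]) - 1,
               end = as.numeric(x[5]), strand = x[7], gene = gene,
               tx = attr_get(x[9], "transcript_id"))
  }))
  # exon numbering in transcription order within each transcript
  out <- lapply(split(rec, rec$tx), function(t) {
    t <- t[order(t$start), ]
    k <- nrow(t)
    exon_no <- if (t$strand[1] == "-") rev(seq_len(k)) else seq_len(k)
    data.frame(chrom = t$chrom, start = t$start, end = t$end, N = exon_no,
               label = sprintf("%s|%s|exon%d", t$gene, t$tx, exon_no))
  })
  do.call(rbind, out)
}

# gene / transcript accessors for annotation tracks (label "GENE|tx|exonN")
annotation_genes <- function(track) {
  vapply(strsplit(track$records$label, "|", fixed = TRUE), `[`, "", 1)
}
annotation_tx <- function(track) {
  vapply(strsplit(track$records$label, "|", fixed = TRUE), `[`, "", 2)
}

# ---- breakpoints --------------------------------------------------------

#' Read a breakpoint table (BEDPE-like)
#'
#' Eight tab-separated columns with header: chrom1, start1, end1, chrom2,
#' start2, end2, type, support. Each end is a (typically 1 bp) interval.
#'
#' @param path input file
#' @param layout optional [genome_layout()]; rows with both ends on unknown
#'   chromosomes are dropped with a warning
#' @return a data.frame of class `breakpoint_table`
#' @export
read_breakpoints <- function(path, layout = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "type",
            "support")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("breakpoint file missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$chrom1 <- normalize_chrom(df$chrom1)
  df$chrom2 <- normalize_chrom(df$chrom2)
  if (any(df$support < 0)) stop2("negative breakpoint support")
  if (!is.null(layout)) {
    keep <- df$chrom1 %in% layout$chroms$name |
      df$chrom2 %in% layout$chroms$name
    if (any(!keep)) {
      warn2("dropped %d breakpoint(s) on unknown chromosomes", sum(!keep))
      df <- df[keep, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("breakpoint_table", "data.frame"))
}

#' Write a breakpoint table
#' @param bp a `breakpoint_table` or compatible data.frame
#' @param path output file path
#' @return the path, invisibly
#' @export
write_breakpoints <- function(bp, path) {
  df <- as.data.frame(bp)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "type",
            "support")
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df[, cols])),
                                            sep = "\t")))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
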