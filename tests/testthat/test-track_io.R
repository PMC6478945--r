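test_that("write_track is deterministic and round-trips bitwise", {
  lay <- tiny_layout()
  tr <- random_track(lay, 10000, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, f1)
  write_track(tr, f2)
  expect_identical(readBin(f1, "raw", 1e8), readBin(f2, "raw", 1e8))

  back <- read_track(f1, "counts", lay)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_track(back, f3)
  expect_identical(readBin(f1, "raw", 1e8), readBin(f3, "raw", 1e8))
  # read-back equals the original up to float formatting
  expect_equal(back$records$N, tr$records$N, tolerance = 1e-5)
  expect_equal(back$records$label, tr$records$label)
})

test_that("round-trip holds for every track kind", {
  lay <- tiny_layout()
  for (kind in c("counts", "cn_bins", "cn_segments", "baf", "annotation",
                 "cytoband", "chromosomes")) {
    tr <- random_track(lay, 50, seed = 7, kind = kind)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_track(tr, f)
    back <- read_track(f, kind, lay)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_track(back, f2)
    expect_identical(readLines(f), readLines(f2), label = kind)
  }
})

test_that("read_track validates, drops unknown contigs, reads CRLF", {
  lay <- tiny_layout()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tN", "A\t0\t100\t5", "B\t50\t70\t2",
               "A\t200\t300\t1"), f)
  tr <- read_track(f, "counts", lay)
  expect_equal(nrow(tr$records), 3)
  expect_equal(tr$records$chrom, c("A", "A", "B"))  # genome-sorted

  writeLines(c("chrom\tstart\tend\tN", "A\t0\t100\t5",
               "UNKNOWN\t0\t10\t1", "B\t0\t10\t2"), f)
  expect_warning(tr2 <- read_track(f, "counts", lay), "dropped 1 record")
  expect_equal(nrow(tr2$records), 2)

  writeLines(c("chrom\tstart\tend\tN", "A\t0\t100\tfive"), f)
  expect_error(read_track(f, "counts", lay), "non-numeric N at line 2")
  writeLines(c("chrom\tstart\tend\tN", "A\t100\t100\t5"), f)
  expect_error(read_track(f, "counts", lay), "start >= end")
  writeLines(c("chrom\tstart\tend\tN", "A\t0\t99000000\t5"), f)
  expect_error(read_track(f, "counts", lay), "beyond chromosome end")

  # CRLF input accepted; writer emits LF only
  con <- file(f, "wb")
  writeLines(c("chrom\tstart\tend\tN", "A\t0\t100\t5"), con, sep = "\r\n")
  close(con)
  tr3 <- read_track(f, "counts", lay)
  expect_equal(tr3$records$N, 5)
  fo <- withr::local_tempfile()
  write_track(tr3, fo)
  expect_false(any(grepl("\r", readLines(fo))))

  # empty table -> header-only file
  empty <- track_table(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), N = numeric(0)),
                       "counts")
  write_track(empty, fo)
  expect_equal(readLines(fo), "chrom\tstart\tend\tN\tsd\tgc\tlabel")
})

test_that("index table parsing, multi-sample flag and validation", {
  d <- withr::local_tempdir()
  rows <- data.frame(
    sample_id = "S1",
    kind = c("annotation", "annotation", "cytoband", "chromosomes",
             "cn_bins", "cn_bins", "cn_bins", "cn_bins", "cn_segments",
             "breakpoints"),
    resolution = c("all", "target", "irregular", "irregular", "genome",
                   "arm", "region", "target", "irregular", "irregular"),
    path = sprintf("t%02d.tsv", 1:10),
    name = sprintf("table %d", 1:10), group = ".")
  f <- file.path(d, "index.tsv")
  write_index(rows, f)
  idx <- read_index(f)
  expect_equal(nrow(idx), 10)
  expect_false(multi_sample_mode(idx))
  expect_equal(sum(idx$kind == "cn_bins"), 4)  # four CN resolutions

  rows2 <- rows
  rows2$sample_id[6:10] <- "S2"
  write_index(rows2, f)
  expect_true(multi_sample_mode(read_index(f)))

  # empty file is an error, not an empty index
  writeLines(character(0), f)
  expect_error(read_index(f), "cannot read|empty")
  writeLines("sample_id\tkind\tresolution\tpath\tname", f)
  expect_error(read_index(f), "empty index")

  writeLines(c("sample_id\tkind\tpath", "a\tb\tc"), f)
  expect_error(read_index(f), "missing mandatory column.*resolution")

  rows3 <- rbind(rows, rows[1, ])
  write_index(rows3, f)
  expect_error(read_index(f), "duplicate")
})

test_that("import_caller_output converts SEG/bedGraph/ratio dialects", {
  lay <- tiny_layout()
  d <- withr::local_tempdir()
  seg <- file.path(d, "calls.seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "S\tA\t1\t1000000\t50\t0",
               "S\tA\t1000001\t2000000\t50\t-1",
               "S\tB\t1\t500000\t10\t1"), seg)
  tr <- import_caller_output(seg, "seg", lay)
  expect_equal(tr$kind, "cn_segments")
  expect_equal(tr$records$N, c(2, 1, 4))          # 2*2^{0,-1,1}
  expect_equal(tr$records$start[1], 0)            # 1-based -> 0-based
  expect_equal(tr$sample_id, "S")

  bg <- file.path(d, "calls.bedgraph")
  writeLines(c("track type=bedGraph", "A\t0\t100\t3.5", "B\t0\t50\t1"), bg)
  tr2 <- import_caller_output(bg, "bedgraph", lay)
  expect_equal(tr2$records$N, c(3.5, 1))
  tr2l <- import_caller_output(bg, "bedgraph", lay, log2 = TRUE)
  expect_equal(tr2l$records$N, 2 * 2^c(3.5, 1))

  rt <- file.path(d, "ratios.tsv")
  writeLines(c("chrom\tstart\tend\tratio", "A\t0\t100\t0.5"), rt)
  expect_equal(import_caller_output(rt, "ratio_table", lay)$records$N, 1)

  expect_error(import_caller_output(seg, "vcfish", lay),
               "unrecognized dialect.*seg, bedgraph, ratio_table")
})

test_that("imported caller output re-exported is accepted back (closure)", {
  lay <- tiny_layout()
  d <- withr::local_tempdir()
  seg <- file.path(d, "calls.seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "S\tA\t1\t1200000\t10\t0.585"), seg)
  tr <- import_caller_output(seg, "seg", lay)
  f <- file.path(d, "out.tsv")
  write_track(tr, f)
  back <- read_track(f, "cn_segments", lay)
  expect_equal(back$records$N, tr$records$N, tolerance = 1e-5)
})

test_that("read_annotation parses refFlat with strand-aware exon numbers", {
  lay <- tiny_layout()
  d <- withr::local_tempdir()
  rf <- file.path(d, "ann.refFlat")
  mk_row <- function(gene, tx, chrom, strand, starts, ends)
    paste(gene, tx, chrom, strand, min(starts), max(ends), min(starts),
          max(ends), length(starts), paste0(paste(starts, collapse = ","), ","),
          paste0(paste(ends, collapse = ","), ","), sep = "\t")
  writeLines(c(
    mk_row("G1", "tx1", "A", "+", c(1000, 2000, 3000), c(1100, 2100, 3100)),
    mk_row("G2", "tx2", "A", "-", c(5000, 6000, 7000), c(5100, 6100, 7100)),
    mk_row("G3", "tx3", "B", "+", c(100, 300), c(200, 400)),
    mk_row("G4", "tx4", "B", "+", 1000, 1200),
    mk_row("G5", "tx5", "C", "+", c(10, 40, 70, 100), c(20, 50, 80, 110))),
    rf)
  ann <- read_annotation(rf, "refFlat", lay)
  expect_equal(nrow(ann$records), 3 + 3 + 2 + 1 + 4)  # sum of exonCount
  g1 <- ann$records[grepl("^G1", ann$records$label), ]
  expect_equal(g1$label, sprintf("G1|tx1|exon%d", 1:3))
  # minus strand: exon 1 is the 3'-most genomic exon
  g2 <- ann$records[grepl("^G2", ann$records$label), ]
  expect_equal(g2$label[g2$start == 7000], "G2|tx2|exon1")
  expect_equal(g2$label[g2$start == 5000], "G2|tx2|exon3")
})

test_that("read_annotation parses GTF", {
  lay <- tiny_layout()
  d <- withr::local_tempdir()
  gtf <- file.path(d, "ann.gtf")
  attr1 <- 'gene_id "g1"; gene_name "GENEA"; transcript_id "txA";'
  writeLines(c("#comment",
               paste("A", "src", "exon", "1001", "1100", ".", "+", ".",
                     attr1, sep = "\t"),
               paste("A", "src", "exon", "2001", "2100", ".", "+", ".",
                     attr1, sep = "\t"),
               paste("A", "src", "CDS", "1001", "1100", ".", "+", ".",
                     attr1, sep = "\t")), gtf)
  ann <- read_annotation(gtf, "gtf", lay)
  expect_equal(nrow(ann$records), 2)
  expect_equal(ann$records$label, c("GENEA|txA|exon1", "GENEA|txA|exon2"))
  expect_equal(ann$records$start, c(1000, 2000))  # 1-based -> 0-based
})

test_that("breakpoint tables round-trip and validate", {
  lay <- tiny_layout()
  d <- withr::local_tempdir()
  f <- file.path(d, "bp.tsv")
  bp <- data.frame(chrom1 = c("A", "B"), start1 = c(100, 5000),
                   end1 = c(101, 5001), chrom2 = c("A", "C"),
                   start2 = c(9000, 100), end2 = c(9001, 101),
                   type = c("DEL", "TRA"), support = c(12L, 3L))
  write_breakpoints(bp, f)
  back <- read_breakpoints(f, lay)
  expect_equal(as.data.frame(back), bp)
  writeLines(c("chrom1\tstart1\tend1", "A\t1\t2"), f)
  expect_error(read_breakpoints(f), "missing column")
})
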