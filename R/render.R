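# deterministic static rendering of the three-panel multi-scale view:
# genome-wide (1 Mb) with a cytoband ideogram, a region panel (50 kb) and a
# detail panel (5 kb and/or bait bins) with exon annotations, plus optional
# overlays (error bars, segments, breakpoints, BAF, overflow triangles).
#
# The figure is first composed as a scene — a list of drawing primitives in
# absolute pixel coordinates — then serialised. The SVG writer formats
# every coordinate with fixed precision, so identical inputs always give
# byte-identical SVG. A grDevices backend handles PNG/PDF from the same
# scene.

PALETTE <- c(point = "#2166ac", low = "#b2182b", high = "#1a9850",
             overflow = "#d73027", segment = "#4d4d4d", band_ink = "#333333",
             breakpoint = "#762a83", baf = "#fdae61", error = "#9ecae1",
             target = "#08519c", axis = "#000000", grid = "#dddddd",
             exon = "#5e3c99")

#' Declarative view specification
#'
#' Replaces the interactive browser's clicks with a declarative
#' description: which panels to draw, the region/detail selections, an
#' optional gene zoom, the display ceiling and the overlay set.
#'
#' @param panels ordered subset of c("genome", "region", "detail")
#' @param region_selection data.frame/list with chrom, start, end for the
#'   region panel (default: the whole first chromosome)
#' @param detail_selection same for the detail panel (default: the region
#'   selection)
#' @param gene_zoom gene symbol; overrides `detail_selection` using the
#'   annotation track
#' @param ymax display ceiling in copies (values above it become overflow
#'   triangles; rescale to reveal focal amplifications)
#' @param overlays subset of c("error_bars", "targeted_track", "segments",
#'   "breakpoints", "baf")
#' @param output output file path
#' @param format "svg" (deterministic), "png" or "pdf"
#' @return an object of class `view_spec`
#' @export
view_spec <- function(panels = c("genome", "region", "detail"),
                      region_selection = NULL, detail_selection = NULL,
                      gene_zoom = NULL, ymax = 6,
                      overlays = c("error_bars", "targeted_track"),
                      output = "view.svg", format = "svg") {
  panels <- match.arg(panels, c("genome", "region", "detail"),
                      several.ok = TRUE)
  if (!length(panels)) stop2("panels must be non-empty")
  if (ymax <= 0) stop2("ymax must be > 0")
  overlays <- intersect(overlays, c("error_bars", "targeted_track",
                                    "segments", "breakpoints", "baf"))
  format <- match.arg(format, c("svg", "png", "pdf"))
  structure(list(panels = panels, region_selection = region_selection,
                 detail_selection = detail_selection, gene_zoom = gene_zoom,
                 ymax = ymax, overlays = overlays, output = output,
                 format = format),
            class = "view_spec")
}

#' Zoom interval for a gene
#'
#' The interval spanning all of the gene's exon records, padded by 5% of
#' the span on each side (clamped to the chromosome when a layout is
#' given).
#'
#' @param annotation a [track_table()] of kind annotation
#' @param gene gene symbol
#' @param layout optional [genome_layout()] for clamping
#' @return list(chrom, start, end)
#' @export
gene_zoom <- function(annotation, gene, layout = NULL) {
  stopifnot(inherits(annotation, "track_table"))
  genes <- annotation_genes(annotation)
  i <- which(genes == gene)
  if (!length(i)) {
    near <- unique(genes[agrepl(gene, genes, max.distance = 0.3)])
    stop2("unknown gene '%s'%s", gene,
          if (length(near)) paste0("; near matches: ",
                                   paste(head(near, 5), collapse = ", "))
          else "")
  }
  rec <- annotation$records[i, ]
  if (length(unique(rec$chrom)) > 1)
    stop2("gene '%s' maps to multiple chromosomes", gene)
  span <- max(rec$end) - min(rec$start)
  pad <- 0.05 * span
  start <- min(rec$start) - pad
  end <- max(rec$end) + pad
  if (!is.null(layout)) {
    start <- max(0, start)
    end <- min(chrom_length(layout, rec$chrom[1]), end)
  }
  list(chrom = rec$chrom[1], start = start, end = end)
}

#' Tabulate the records under a selection
#'
#' All records of the given track(s) overlapping the selection, with their
#' value, sd, gc, label and genomic position, plus a summary attribute
#' (median N over the selection) — the per-feature detail table of the
#' review workflow.
#'
#' @param tracks a [track_table()] or named list of them (all are
#'   reported, with a `track` column)
#' @param selection list/data.frame with chrom, start, end
#' @return data.frame of overlapping records; attribute `summary_median`
#'   holds the median N (NA when empty)
#' @export
feature_report <- function(tracks, selection) {
  if (inherits(tracks, "track_table")) tracks <- list(track = tracks)
  sel <- data.frame(chrom = normalize_chrom(selection$chrom),
                    start = selection$start, end = selection$end)
  out <- list()
  for (nm in names(tracks)) {
    rec <- tracks[[nm]]$records
    h <- overlap_hits(rec, sel)
    if (nrow(h)) {
      r <- rec[sort(unique(h$q)), , drop = FALSE]
      r$track <- nm
      out[[nm]] <- r
    }
  }
  rep_df <- if (length(out)) do.call(rbind, out) else
    cbind(data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), N = numeric(0), sd = numeric(0),
                     gc = numeric(0), label = character(0)),
          track = character(0))
  rownames(rep_df) <- NULL
  attr(rep_df, "summary_median") <-
    if (nrow(rep_df)) median(rep_df$N, na.rm = TRUE) else NA_real_
  rep_df
}

# ---- scene construction -------------------------------------------------

scene_new <- function(width, height) {
  env <- new.env(parent = emptyenv())
  env$width <- width; env$height <- height; env$items <- list()
  env
}
scene_add <- function(sc, item) sc$items[[length(sc$items) + 1L]] <- item
sc_rect <- function(sc, x0, y0, x1, y1, fill = "none", stroke = "none",
                    lw = 1)
  scene_add(sc, list(t = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                     fill = fill, stroke = stroke, lw = lw))
sc_line <- function(sc, x0, y0, x1, y1, col, lw = 1)
  scene_add(sc, list(t = "line", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                     col = col, lw = lw))
sc_point <- function(sc, x, y, col, r = 1.6)
  scene_add(sc, list(t = "point", x = x, y = y, col = col, r = r))
sc_tri <- function(sc, x, y, col, r = 4)
  scene_add(sc, list(t = "tri", x = x, y = y, col = col, r = r))
sc_text <- function(sc, x, y, s, size = 10, col = PALETTE[["axis"]],
                    anchor = "middle")
  scene_add(sc, list(t = "text", x = x, y = y, s = s, size = size,
                     col = col, anchor = anchor))
sc_arc <- function(sc, x0, x1, y, h, col, lw = 1)
  scene_add(sc, list(t = "arc", x0 = x0, x1 = x1, y = y, h = h, col = col,
                     lw = lw))

stain_fill <- function(stain) {
  switch(stain,
         gneg = "#ffffff", gpos25 = "#c8c8c8", gpos50 = "#969696",
         gpos75 = "#646464", gpos100 = "#323232", acen = "#cc4444",
         gvar = "#e0e0e0", stalk = "#8888aa", "#ffffff")
}

# one CN panel: frame, y axis at integer copies, points, error bars,
# overflow triangles, optional overlays. xmap maps bp -> pixel.
draw_cn_panel <- function(sc, px, track, xmap, xlim, ymax, overlays,
                          segments_track = NULL, breakpoints = NULL,
                          baf = NULL, annotation = NULL, title = "",
                          target_track = NULL) {
  y_of <- function(v) px$y1 - (pmin(v, ymax) / ymax) * (px$y1 - px$y0)
  sc_rect(sc, px$x0, px$y0, px$x1, px$y1, fill = "#ffffff",
          stroke = PALETTE[["axis"]], lw = 0.8)
  for (cpy in 0:floor(ymax)) {
    yy <- y_of(cpy)
    sc_line(sc, px$x0, yy, px$x1, yy,
            col = if (cpy == 2) "#bbbbbb" else PALETTE[["grid"]],
            lw = if (cpy == 2) 1 else 0.5)
    sc_text(sc, px$x0 - 6, yy + 3, sprintf("%d", cpy), size = 8,
            anchor = "end")
  }
  sc_text(sc, px$x0 - 28, (px$y0 + px$y1) / 2, "CN", size = 9,
          anchor = "middle")
  sc_text(sc, (px$x0 + px$x1) / 2, px$y0 - 4, title, size = 10)
  plot_points <- function(rec, col, r = 1.6) {
    if (is.null(rec) || !nrow(rec)) return(0)
    # overlap semantics (matches feature_report); midpoints clamped to panel
    keep <- rec$end > xlim[1] & rec$start < xlim[2] & !is.na(rec$N)
    df <- data.frame(x = pmin(pmax((rec$start + rec$end) / 2, xlim[1]),
                              xlim[2]),
                     N = rec$N, sd = rec$sd)[keep, , drop = FALSE]
    if (!nrow(df)) return(0)
    xp <- xmap(df$x)
    over <- flag_overflow(df$N, ymax)
    if ("error_bars" %in% overlays && any(!is.na(df$sd))) {
      ok <- which(!is.na(df$sd) & !over)
      for (k in ok)
        sc_line(sc, xp[k], y_of(pmax(df$N[k] - df$sd[k], 0)),
                xp[k], y_of(df$N[k] + df$sd[k]),
                col = PALETTE[["error"]], lw = 0.8)
    }
    if (any(!over)) sc_point(sc, xp[!over], y_of(df$N[!over]), col = col, r = r)
    if (any(over)) sc_tri(sc, xp[over], px$y0 + 5, col = PALETTE[["overflow"]])
    sum(over)
  }
  n_over <- 0
  if (!is.null(track)) {
    rec <- track$records[track$records$chrom == attr(xlim, "chrom"), ,
                         drop = FALSE]
    n_over <- n_over + plot_points(rec, PALETTE[["point"]])
  }
  if ("targeted_track" %in% overlays && !is.null(target_track)) {
    rec <- target_track$records[
      target_track$records$chrom == attr(xlim, "chrom"), , drop = FALSE]
    n_over <- n_over + plot_points(rec, PALETTE[["target"]], r = 1.2)
  }
  if ("segments" %in% overlays && !is.null(segments_track)) {
    rec <- segments_track$records
    rec <- rec[rec$chrom == attr(xlim, "chrom") & rec$end > xlim[1] &
                 rec$start < xlim[2], , drop = FALSE]
    for (k in seq_len(nrow(rec)))
      sc_line(sc, xmap(max(rec$start[k], xlim[1])),
              y_of(rec$N[k]), xmap(min(rec$end[k], xlim[2])),
              y_of(rec$N[k]), col = PALETTE[["segment"]], lw = 2)
  }
  if ("breakpoints" %in% overlays && !is.null(breakpoints)) {
    bp <- as.data.frame(breakpoints)
    ch <- attr(xlim, "chrom")
    in1 <- bp$chrom1 == ch & bp$start1 >= xlim[1] & bp$start1 <= xlim[2]
    in2 <- bp$chrom2 == ch & bp$start2 >= xlim[1] & bp$start2 <= xlim[2]
    for (k in which(in1 | in2)) {
      if (in1[k] && in2[k] && bp$chrom1[k] == bp$chrom2[k]) {
        sc_arc(sc, xmap(bp$start1[k]), xmap(bp$start2[k]), px$y0 + 12, 10,
               col = PALETTE[["breakpoint"]], lw = 1)
      }
      for (endk in c(1, 2)[c(in1[k], in2[k])]) {
        xpos <- xmap(bp[[paste0("start", endk)]][k])
        sc_line(sc, xpos, px$y0 + 2, xpos, px$y0 + 12,
                col = PALETTE[["breakpoint"]], lw = 1.2)
        partner <- if (endk == 1) bp$chrom2[k] else bp$chrom1[k]
        if (partner != ch)
          sc_text(sc, xpos, px$y0 + 20, paste0("->", partner), size = 7,
                  col = PALETTE[["breakpoint"]])
      }
    }
  }
  if ("baf" %in% overlays && !is.null(baf)) {
    rec <- baf$records[baf$records$chrom == attr(xlim, "chrom"), ,
                       drop = FALSE]
    rec <- rec[!is.na(rec$N) & rec$start >= xlim[1] & rec$end <= xlim[2], ,
               drop = FALSE]
    if (nrow(rec))
      sc_point(sc, xmap((rec$start + rec$end) / 2),
               px$y1 - rec$N * (px$y1 - px$y0), col = PALETTE[["baf"]],
               r = 1)
  }
  if (!is.null(annotation)) {
    rec <- annotation$records
    rec <- rec[rec$chrom == attr(xlim, "chrom") & rec$end > xlim[1] &
                 rec$start < xlim[2], , drop = FALSE]
    ya <- px$y1 + 6
    for (k in seq_len(nrow(rec)))
      sc_rect(sc, xmap(max(rec$start[k], xlim[1])), ya,
              xmap(min(rec$end[k], xlim[2])), ya + 6,
              fill = PALETTE[["exon"]])
    if (nrow(rec)) {
      genes <- vapply(strsplit(rec$label, "|", fixed = TRUE), `[`, "", 1)
      for (g in unique(genes)) {
        i <- genes == g
        sc_text(sc, xmap(pmin(pmax((min(rec$start[i]) + max(rec$end[i])) / 2,
                                   xlim[1]), xlim[2])),
                ya + 16, g, size = 8, col = PALETTE[["exon"]])
      }
    }
  }
  n_over
}

#' Render the multi-scale view
#'
#' Draws up to three stacked panels — genome-wide with a cytoband ideogram,
#' a region panel and a detail panel with exon annotations — with linked
#' selections, overflow triangles where values exceed `spec$ymax`, and the
#' configured overlays. SVG output is byte-stable: identical inputs give
#' identical files. Returns the per-feature report for the detail
#' selection.
#'
#' @param tracks named list of CN [track_table()]s keyed by resolution
#'   ("genome", "arm", "region", "target"); each panel needs its
#'   resolution present
#' @param layout a [genome_layout()]
#' @param spec a [view_spec()]
#' @param annotation optional annotation [track_table()] (needed for
#'   `gene_zoom`)
#' @param segments,baf optional overlay [track_table()]s
#' @param breakpoints optional `breakpoint_table`
#' @return list with `file` (the written image), `report` (the
#'   [feature_report()] for the detail selection) and `n_overflow`
#'   (overflow triangles drawn, by panel)
#' @export
render_view <- function(tracks, layout, spec, annotation = NULL,
                        segments = NULL, breakpoints = NULL, baf = NULL) {
  stopifnot(inherits(spec, "view_spec"))
  need <- c(genome = "genome", region = "arm", detail = "region")
  for (p in spec$panels) {
    if (p == "detail" &&
        ("region" %in% names(tracks) || "target" %in% names(tracks))) next
    if (!need[[p]] %in% names(tracks))
      stop2("panel '%s' needs resolution '%s' which is missing from tracks",
            p, need[[p]])
  }
  region_sel <- spec$region_selection %||%
    list(chrom = layout$chroms$name[1], start = 0,
         end = layout$chroms$length[1])
  region_sel$chrom <- normalize_chrom(region_sel$chrom)
  detail_sel <- if (!is.null(spec$gene_zoom)) {
    if (is.null(annotation)) stop2("gene_zoom needs an annotation track")
    gene_zoom(annotation, spec$gene_zoom, layout)
  } else spec$detail_selection %||% region_sel
  detail_sel$chrom <- normalize_chrom(detail_sel$chrom)

  width <- 1000; panel_h <- 170; ideo_h <- 26; margin <- 46; gap <- 46
  n_p <- length(spec$panels)
  height <- margin + n_p * (panel_h + gap) +
    ("genome" %in% spec$panels) * ideo_h + 10
  sc <- scene_new(width, height)
  sc_rect(sc, 0, 0, width, height, fill = "#ffffff")
  x0 <- 60; x1 <- width - 20
  y <- margin
  n_overflow <- c()

  for (p in spec$panels) {
    px <- list(x0 = x0, y0 = y, x1 = x1, y1 = y + panel_h)
    if (p == "genome") {
      glen <- sum(layout$chroms$length)
      gmap <- function(bp_chrom, bp_pos)
        x0 + locate(layout, bp_chrom, bp_pos) / glen * (x1 - x0)
      # frame + axis
      y_of <- function(v) px$y1 - (pmin(v, spec$ymax) / spec$ymax) *
        (px$y1 - px$y0)
      sc_rect(sc, px$x0, px$y0, px$x1, px$y1, fill = "#ffffff",
              stroke = PALETTE[["axis"]], lw = 0.8)
      for (cpy in 0:floor(spec$ymax)) {
        sc_line(sc, px$x0, y_of(cpy), px$x1, y_of(cpy),
                col = if (cpy == 2) "#bbbbbb" else PALETTE[["grid"]],
                lw = if (cpy == 2) 1 else 0.5)
        sc_text(sc, px$x0 - 6, y_of(cpy) + 3, sprintf("%d", cpy), size = 8,
                anchor = "end")
      }
      sc_text(sc, (px$x0 + px$x1) / 2, px$y0 - 4,
              sprintf("genome-wide (%s)", tracks$genome$sample_id %||% ""),
              size = 10)
      # chromosome separators + labels
      for (i in seq_len(nrow(layout$chroms))) {
        ch <- layout$chroms$name[i]
        xs <- gmap(ch, 0); xe <- gmap(ch, layout$chroms$length[i])
        if (i > 1) sc_line(sc, xs, px$y0, xs, px$y1, col = PALETTE[["grid"]],
                           lw = 0.5)
        sc_text(sc, (xs + xe) / 2, px$y1 + 12, ch, size = 7)
      }
      rec <- tracks$genome$records
      rec <- rec[!is.na(rec$N), , drop = FALSE]
      if (nrow(rec)) {
        xp <- gmap(rec$chrom, (rec$start + rec$end) / 2)
        over <- flag_overflow(rec$N, spec$ymax)
        if (any(!over))
          sc_point(sc, xp[!over], y_of(rec$N[!over]),
                   col = PALETTE[["point"]], r = 1.2)
        if (any(over))
          sc_tri(sc, xp[over], px$y0 + 5, col = PALETTE[["overflow"]])
        n_overflow["genome"] <- sum(over)
      } else n_overflow["genome"] <- 0
      # highlight the region selection
      sc_rect(sc, gmap(region_sel$chrom, region_sel$start), px$y0,
              gmap(region_sel$chrom, region_sel$end), px$y1,
              fill = "none", stroke = PALETTE[["overflow"]], lw = 1)
      y <- px$y1 + 16
      # ideogram strip
      if (!is.null(layout$cytobands)) {
        for (k in seq_len(nrow(layout$cytobands))) {
          b <- layout$cytobands[k, ]
          sc_rect(sc, gmap(b$chrom, b$start), y,
                  gmap(b$chrom, b$end), y + ideo_h - 8,
                  fill = stain_fill(b$stain), stroke = PALETTE[["band_ink"]],
                  lw = 0.3)
        }
      }
      y <- y + ideo_h + gap - 16
    } else {
      sel <- if (p == "region") region_sel else detail_sel
      xlim <- c(sel$start, sel$end)
      attr(xlim, "chrom") <- sel$chrom
      xmap <- function(bp) px$x0 + (bp - xlim[1]) / diff(xlim) *
        (px$x1 - px$x0)
      track <- if (p == "region") tracks$arm else tracks$region
      n_overflow[p] <- draw_cn_panel(
        sc, px, track, xmap, xlim, spec$ymax, spec$overlays,
        segments_track = if (p != "region") segments else segments,
        breakpoints = breakpoints, baf = baf,
        annotation = if (p == "detail") annotation else NULL,
        title = sprintf("%s %s:%s-%s", p, sel$chrom,
                        format(sel$start, big.mark = ",", scientific = FALSE,
                               trim = TRUE),
                        format(sel$end, big.mark = ",", scientific = FALSE,
                               trim = TRUE)),
        target_track = if (p == "detail") tracks$target else NULL)
      y <- px$y1 + gap + ("detail" == p) * 0
    }
  }

  write_scene(sc, spec$output, spec$format)
  detail_tracks <- tracks[intersect(c("target", "region"), names(tracks))]
  if (!"targeted_track" %in% spec$overlays) detail_tracks$target <- NULL
  rep_df <- feature_report(detail_tracks, detail_sel)
  list(file = spec$output, report = rep_df, n_overflow = n_overflow)
}

# ---- serialisation ------------------------------------------------------

f2 <- function(x) sprintf("%.2f", x)

svg_item <- function(it) {
  switch(it$t,
    rect = sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      f2(it$x0), f2(it$y0), f2(it$x1 - it$x0), f2(it$y1 - it$y0), it$fill,
      it$stroke, f2(it$lw)),
    line = sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      f2(it$x0), f2(it$y0), f2(it$x1), f2(it$y1), it$col, f2(it$lw)),
    point = paste(sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                          f2(it$x), f2(it$y), f2(it$r), it$col),
                  collapse = "\n"),
    tri = paste(sprintf(
      '<path d="M %s %s L %s %s L %s %s Z" fill="%s"/>',
      f2(it$x - it$r), f2(it$y + it$r), f2(it$x + it$r), f2(it$y + it$r),
      f2(it$x), f2(it$y - it$r), it$col), collapse = "\n"),
    text = sprintf(
      '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="%s" text-anchor="%s">%s</text>',
      f2(it$x), f2(it$y), f2(it$size), it$col, it$anchor,
      xml_escape(it$s)),
    arc = sprintf(
      '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s"/>',
      f2(it$x0), f2(it$y), f2((it$x0 + it$x1) / 2), f2(it$y - it$h),
      f2(it$x1), f2(it$y), it$col, f2(it$lw)),
    stop2("unknown scene item '%s'", it$t))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

write_scene <- function(sc, path, format = "svg") {
  if (format == "svg") {
    lines <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      sc$width, sc$height, sc$width, sc$height),
      unlist(lapply(sc$items, svg_item)), "</svg>")
    con <- file(path, open = "wb"); on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    if (format == "png") png(path, width = sc$width, height = sc$height)
    else pdf(path, width = sc$width / 96, height = sc$height / 96)
    on.exit(dev.off())
    op <- par(mar = c(0, 0, 0, 0))
    plot(NA, xlim = c(0, sc$width), ylim = c(sc$height, 0), axes = FALSE,
         xlab = "", ylab = "", xaxs = "i", yaxs = "i")
    for (it in sc$items) draw_item_device(it)
    par(op)
  }
  invisible(path)
}

draw_item_device <- function(it) {
  na_col <- function(x) if (identical(x, "none")) NA else x
  switch(it$t,
    rect = rect(it$x0, it$y1, it$x1, it$y0, col = na_col(it$fill),
                border = na_col(it$stroke), lwd = it$lw),
    line = segments(it$x0, it$y0, it$x1, it$y1, col = it$col, lwd = it$lw),
    point = points(it$x, it$y, pch = 16, col = it$col,
                   cex = it$r / 2),
    tri = points(it$x, it$y, pch = 17, col = it$col, cex = it$r / 3),
    text = text(it$x, it$y, it$s, cex = it$size / 12,
                adj = switch(it$anchor, middle = 0.5, end = 1, 0),
                col = it$col),
    arc = lines(seq(it$x0, it$x1, length.out = 20),
                it$y - it$h * sin(seq(0, pi, length.out = 20)) / 2,
                col = it$col, lwd = it$lw))
  invisible()
}

#' Thin HTML export embedding the rendered view
#'
#' Writes a single self-contained HTML page with the SVG inline and
#' client-side pan/zoom via scroll — no server required.
#'
#' @param svg_path path to an SVG written by [render_view()]
#' @param out output HTML path
#' @return the path, invisibly
#' @export
write_html_view <- function(svg_path, out) {
  svg <- readLines(svg_path)
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             "<title>CN view</title>",
             "<style>body{margin:0;overflow:auto}svg{display:block}</style>",
             "</head><body>", svg, "</body></html>")
  con <- file(out, open = "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(out)
}
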