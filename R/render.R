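#' Default colour per allele-origin status
#'
#' A fixed, documented palette; every canonical case code plus the two
#' non-case statuses gets one colour. Override entries by name to
#' customise (`case_palette(c("1_1" = "navy"))`).
#'
#' @param overrides Named character vector of colour overrides.
#' @return Named character vector mapping status codes to hex colours.
#' @export
case_palette <- function(overrides = NULL) {
  pal <- c("1_1"  = "#1f77b4", "1_2"  = "#d62728", "1_3"  = "#7f7f7f",
           "1_4"  = "#9467bd", "1_5"  = "#aec7e8", "2_6"  = "#ff9896",
           "3_7"  = "#2ca02c", "3_8"  = "#98df8a", "3_9"  = "#ff7f0e",
           "3_10" = "#8c564b", "4_11" = "#e377c2",
           "MONOMORPHIC" = "#c7c7c7", "UNCLASSIFIED" = "#17becf")
  if (!is.null(overrides)) pal[names(overrides)] <- overrides
  pal
}

#' Colour marker intervals or marker positions by allele-origin case
#'
#' In `"marker"` mode every assignment yields one tick at its
#' coordinate. In `"interval"` mode, maximal runs of adjacent
#' assignments sharing the same case code are merged into one coloured
#' segment spanning them; an interval flanked by markers with different
#' codes is left uncoloured, because the exact recombination position
#' between the two markers is unknown. If two assignments share an
#' identical coordinate but disagree on the code (as can happen with
#' consensus map positions), no interval is emitted through that
#' coordinate and a collision is recorded in the `"collisions"`
#' attribute (with a warning).
#'
#' @param assignments Tibble with at least `coordinate` and `status`,
#'   sorted by coordinate, with filtered statuses already removed.
#' @param mode `"interval"` or `"marker"`.
#' @return Tibble of class `coloured_segments` with columns `start`,
#'   `end`, `status`, `kind` (`"INTERVAL"` or `"MARKER_TICK"`);
#'   attribute `"collisions"` holds the collision coordinates.
#' @examples
#' a <- tibble::tibble(coordinate = c(0, 10, 20),
#'                     status = c("1_1", "1_1", "1_2"))
#' colour_intervals(a, mode = "interval")
#' @export
colour_intervals <- function(assignments, mode = c("interval", "marker")) {
  mode <- match.arg(tolower(mode), c("interval", "marker"))
  coord <- assignments$coordinate
  status <- assignments$status
  if (is.unsorted(coord)) {
    stop("assignments must be sorted by coordinate", call. = FALSE)
  }
  collisions <- if (length(coord)) {
    unique(coord[stats::ave(as.integer(factor(status)), coord,
      FUN = function(s) length(unique(s))) > 1L])
  } else numeric()
  if (length(collisions)) {
    warning(length(collisions), " coordinate(s) carry conflicting case ",
            "codes; no interval is drawn through them", call. = FALSE)
  }
  if (mode == "marker") {
    out <- tibble::tibble(start = coord, end = coord, status = status,
                          kind = "MARKER_TICK")
  } else {
    n <- length(coord)
    if (n == 0L) {
      out <- tibble::tibble(start = numeric(), end = numeric(),
                            status = character(), kind = character())
    } else {
      is_coll <- coord %in% collisions
      # a run breaks on a case change or at any collision coordinate
      brk <- c(TRUE, status[-1L] != status[-n] |
                 is_coll[-1L] | is_coll[-n])
      grp <- cumsum(brk)
      start <- tapply(coord, grp, min)
      end <- tapply(coord, grp, max)
      st <- tapply(status, grp, function(s) s[1L])
      keep <- end > start
      out <- tibble::tibble(start = as.numeric(start[keep]),
                            end = as.numeric(end[keep]),
                            status = as.character(st[keep]),
                            kind = "INTERVAL")
    }
  }
  attr(out, "collisions") <- collisions
  class(out) <- c("coloured_segments", class(out))
  out
}

# ---- vector scene -----------------------------------------------------

scene_rect <- function(x, y, w, h, fill, stroke = "none") {
  tibble::tibble(type = "rect", x1 = x, y1 = y, x2 = x + w, y2 = y + h,
                 fill = fill, stroke = stroke, text = NA_character_,
                 size = NA_real_, anchor = NA_character_)
}
scene_line <- function(x1, y1, x2, y2, stroke, size = 1) {
  tibble::tibble(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 fill = NA_character_, stroke = stroke,
                 text = NA_character_, size = size, anchor = NA_character_)
}
scene_text <- function(x, y, text, size = 10, anchor = "start") {
  tibble::tibble(type = "text", x1 = x, y1 = y, x2 = NA_real_,
                 y2 = NA_real_, fill = "#000000", stroke = NA_character_,
                 text = text, size = size, anchor = anchor)
}

fmt2 <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_scene_svg <- function(scene, width, height, path) {
  out <- c(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
    'viewBox="0 0 %s %s">'),
    fmt2(width), fmt2(height), fmt2(width), fmt2(height)),
    '<rect x="0" y="0" width="100%" height="100%" fill="#ffffff"/>')
  for (i in seq_len(nrow(scene))) {
    r <- scene[i, ]
    out <- c(out, switch(r$type,
      rect = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
        fmt2(r$x1), fmt2(r$y1), fmt2(r$x2 - r$x1), fmt2(r$y2 - r$y1),
        r$fill, r$stroke),
      line = sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        fmt2(r$x1), fmt2(r$y1), fmt2(r$x2), fmt2(r$y2), r$stroke,
        fmt2(r$size)),
      text = sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="%s">%s</text>',
        fmt2(r$x1), fmt2(r$y1), fmt2(r$size),
        c(start = "start", middle = "middle", end = "end")[[r$anchor]],
        xml_escape(r$text))))
  }
  out <- c(out, "</svg>")
  # fixed separator and encoding keep re-renders byte-identical
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_scene_png <- function(scene, width, height, path) {
  grDevices::png(path, width = ceiling(width), height = ceiling(height),
                 res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(0, width), ylim = c(height, 0),
                 axes = FALSE, xlab = "", ylab = "")
  for (i in seq_len(nrow(scene))) {
    r <- scene[i, ]
    if (r$type == "rect") {
      graphics::rect(r$x1, r$y2, r$x2, r$y1, col = r$fill,
                     border = if (identical(r$stroke, "none")) NA
                              else r$stroke)
    } else if (r$type == "line") {
      graphics::segments(r$x1, r$y1, r$x2, r$y2, col = r$stroke,
                         lwd = r$size)
    } else {
      adj <- c(start = 0, middle = 0.5, end = 1)[[r$anchor]]
      graphics::text(r$x1, r$y1, r$text, adj = c(adj, 0),
                     cex = r$size / 12)
    }
  }
  invisible(path)
}

# ---- figure composition ----------------------------------------------

track_width <- 12
panel_gap <- 36
margin_left <- 30
margin_top <- 56
legend_row <- 16

compose_panel <- function(table, assignment, chromosome, config,
                          colouring, palette, x0, lengths = NULL) {
  tr <- build_tracks(table, chromosome, lengths = lengths)
  scene <- list()
  xs <- x0
  track_x <- c()
  for (side in c("genetic", "physical")) {
    track <- tr[[side]]
    if (is.null(track)) next
    ext <- canvas_extent(track, config)
    scene <- c(scene, list(scene_rect(xs, margin_top, track_width, ext,
                                      fill = "#f2f2f2",
                                      stroke = "#000000")))
    pos_col <- if (side == "genetic") "genetic_pos" else "physical_pos"
    a <- assignment[!assignment$filtered &
                      !is.na(assignment[[pos_col]]), , drop = FALSE]
    a <- a[order(a[[pos_col]]), , drop = FALSE]
    cc <- to_canvas(track, config)
    canvas_of <- stats::setNames(cc$canvas, cc$marker)
    a <- a[a$marker %in% names(canvas_of), , drop = FALSE]
    coords <- tibble::tibble(coordinate = unname(canvas_of[a$marker]),
                             status = a$status, marker = a$marker)
    coords <- coords[order(coords$coordinate), , drop = FALSE]
    segs <- suppressWarnings(colour_intervals(coords, mode = colouring))
    for (j in seq_len(nrow(segs))) {
      s <- segs[j, ]
      col <- pal_col(palette, s$status)
      if (s$kind == "INTERVAL") {
        scene <- c(scene, list(scene_rect(
          xs + 0.5, margin_top + s$start, track_width - 1,
          s$end - s$start, fill = col)))
      } else {
        scene <- c(scene, list(scene_line(
          xs, margin_top + s$start, xs + track_width,
          margin_top + s$end, stroke = col, size = 1.5)))
      }
    }
    if (config$mode == "chromosome" && config$show_marker_names &&
        side == "physical") {
      for (j in seq_len(nrow(coords))) {
        scene <- c(scene, list(scene_text(
          xs + track_width + 4, margin_top + coords$coordinate[j] + 3,
          coords$marker[j], size = 7)))
      }
    }
    track_x[side] <- xs
    xs <- xs + track_width + config$spacing
  }
  if (!is.null(tr$genetic) && !is.null(tr$physical)) {
    conn <- pair_connectors(tr$genetic, tr$physical, config)
    for (j in seq_len(nrow(conn))) {
      scene <- c(scene, list(scene_line(
        track_x[["genetic"]] + track_width,
        margin_top + conn$genetic_coord[j],
        track_x[["physical"]],
        margin_top + conn$physical_coord[j],
        stroke = "#bbbbbb", size = 0.5)))
    }
  }
  used <- sum(!vapply(tr, is.null, logical(1)))
  width <- if (used) used * track_width + (used - 1) * config$spacing
           else track_width
  scene <- c(list(scene_text(x0 + width / 2, margin_top - 8, chromosome,
                             size = 10, anchor = "middle")), scene)
  heights <- vapply(tr[!vapply(tr, is.null, logical(1))],
                    canvas_extent, numeric(1), config = config)
  list(scene = dplyr::bind_rows(scene), width = width,
       height = if (length(heights)) max(heights) else 0)
}

#' Render a graphical-genotyping figure
#'
#' Classifies the requested individuals of interest, lays each selected
#' chromosome out as a paired genetic/physical track column, colours
#' intervals or marker positions by allele-origin case, draws cross-map
#' connectors and a legend, and writes the figure as SVG or PNG. In the
#' default mode up to ten IOIs and any number of chromosomes can be
#' drawn; the single-chromosome mode takes exactly one IOI and one
#' chromosome and additionally draws marker names. SVG output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param table A `genotype_table`.
#' @param iois Character vector of IOI sample names (max 10 in default
#'   mode; exactly 1 in chromosome mode).
#' @param path Output file path.
#' @param chromosomes Chromosomes to draw (default: all in the table;
#'   chromosome mode requires exactly one).
#' @param n_parents Parents used for classification (see
#'   [discriminate()]).
#' @param config A [layout_config()]; its mode governs the caps.
#' @param colouring `"interval"` or `"marker"` (see
#'   [colour_intervals()]).
#' @param palette Status colours, see [case_palette()].
#' @param format `"svg"` or `"png"`.
#' @param strict Passed to [discriminate()].
#' @param lengths Optional chromosome lengths (bp) for track extents.
#' @return `path`, invisibly.
#' @export
render_figure <- function(table, iois, path, chromosomes = NULL,
                          n_parents = NULL, config = layout_config(),
                          colouring = c("interval", "marker"),
                          palette = case_palette(),
                          format = c("svg", "png"), strict = TRUE,
                          lengths = NULL) {
  colouring <- match.arg(colouring)
  format <- match.arg(format)
  stopifnot(inherits(table, "genotype_table"),
            inherits(config, "layout_config"))
  if (is.null(chromosomes)) chromosomes <- unique(table$chromosome)
  if (config$mode == "default") {
    if (length(iois) > 10L) {
      stop("at most ten individuals can be displayed in default mode, ",
           "got ", length(iois), call. = FALSE)
    }
  } else {
    if (length(iois) != 1L || length(chromosomes) != 1L) {
      stop("chromosome mode displays exactly one individual and one ",
           "chromosome", call. = FALSE)
    }
  }
  assignments <- discriminate(table, iois, n_parents = n_parents,
                              strict = strict)
  scenes <- list()
  x <- margin_left
  max_h <- 0
  statuses_seen <- character()
  for (s in iois) {
    a_ioi <- assignments[assignments$ioi == s, , drop = FALSE]
    x_start <- x
    for (chr in chromosomes) {
      a <- a_ioi[a_ioi$chromosome == chr, , drop = FALSE]
      panel <- compose_panel(table, a, chr, config, colouring, palette, x,
                             lengths = lengths)
      scenes <- c(scenes, list(panel$scene))
      statuses_seen <- union(statuses_seen,
                             a$status[!a$filtered])
      max_h <- max(max_h, panel$height)
      x <- x + panel$width + panel_gap
    }
    scenes <- c(scenes, list(scene_text((x_start + x - panel_gap) / 2,
                                        margin_top - 28, s, size = 12,
                                        anchor = "middle")))
  }
  # legend in canonical order, only for statuses present
  ordered <- intersect(names(case_descriptions()), statuses_seen)
  leg_y <- margin_top + max_h + 24
  leg <- list()
  for (i in seq_along(ordered)) {
    st <- ordered[i]
    y <- leg_y + (i - 1) * legend_row
    leg <- c(leg, list(
      scene_rect(margin_left, y - 9, 12, 10,
                 fill = pal_col(palette, st),
                 stroke = "#000000"),
      scene_text(margin_left + 18, y,
                 paste0(st, ": ", case_descriptions()[[st]]), size = 9)))
  }
  scene <- dplyr::bind_rows(c(scenes, leg))
  width <- x - panel_gap + margin_left + 260
  height <- leg_y + length(ordered) * legend_row + 20
  if (format == "svg") write_scene_svg(scene, width, height, path)
  else write_scene_png(scene, width, height, path)
  invisible(path)
}

# colour lookup with a black fallback for statuses missing from the palette
pal_col <- function(palette, status) {
  v <- unname(palette[status])
  if (is.na(v)) "#000000" else v
}

#' Plot case assignments with ggplot2
#'
#' A quick exploratory view of [discriminate()] output: one horizontal
#' band per chromosome with markers coloured by allele-origin status on
#' the chosen positional scale.
#'
#' @param object A `case_assignments` tibble.
#' @param scale `"physical"` (bp) or `"genetic"` (cM) x-axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_assignments <- function(object, scale = c("physical",
                                                        "genetic"), ...) {
  scale <- match.arg(scale)
  pos <- if (scale == "physical") "physical_pos" else "genetic_pos"
  df <- object[!object$filtered & !is.na(object[[pos]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[pos]], y = .data$chromosome, colour = .data$status)) +
    ggplot2::geom_point(shape = 124, size = 5) +
    ggplot2::scale_colour_manual(values = case_palette()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ioi), ncol = 1L) +
    ggplot2::labs(
      x = if (scale == "physical") "physical position (bp)"
          else "genetic position (cM)",
      y = "chromosome", colour = "case") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.case_assignments
#' @param assignments A `case_assignments` tibble.
#' @export
plot_assignments <- function(assignments, scale = c("physical",
                                                    "genetic")) {
  autoplot.case_assignments(assignments, scale = scale)
}
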