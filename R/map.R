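new_map_track <- function(marker, position, chromosome, scale,
                          extent = NULL) {
  ord <- order(position)  # stable: ties keep input order
  out <- tibble::tibble(marker = marker[ord], position = position[ord])
  attr(out, "chromosome") <- chromosome
  attr(out, "scale") <- scale
  attr(out, "extent") <- if (is.null(extent)) {
    if (nrow(out)) max(out$position) else 0
  } else extent
  class(out) <- c("map_track", class(out))
  out
}

#' @export
print.map_track <- function(x, ...) {
  cat("# Map track: chromosome ", attr(x, "chromosome"), ", ",
      attr(x, "scale"), " scale, extent ", format(attr(x, "extent")),
      "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Build genetic and physical marker tracks for one chromosome
#'
#' Splits the markers of one chromosome into a genetic (cM) track
#' containing exactly the markers with a genetic position, and a physical
#' (bp) track containing exactly those with a physical position. Either
#' track is absent (`NULL`) when no marker carries that position type.
#' Markers on a track are ordered by ascending coordinate; ties keep the
#' input order. The track extent is the maximum observed position unless
#' a chromosome length is supplied.
#'
#' When the table's fourth column holds a second genetic map (see
#' [read_genotype_table()]), the second track is genetic-scaled as well.
#'
#' @param table A `genotype_table`.
#' @param chromosome Chromosome label occurring in the table.
#' @param lengths Optional named vector of chromosome lengths (bp) to
#'   override physical track extents (see [read_chrom_lengths()]).
#' @return List with elements `genetic` and `physical`, each a
#'   `map_track` tibble (`marker`, `position`) or `NULL`.
#' @export
build_tracks <- function(table, chromosome, lengths = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (!chromosome %in% table$chromosome) {
    stop("chromosome not present in table: ", chromosome, call. = FALSE)
  }
  rows <- table$chromosome == chromosome
  g_ok <- rows & !is.na(table$genetic_pos)
  p_ok <- rows & !is.na(table$physical_pos)
  second_scale <- if (identical(attr(table, "col4"), "genetic"))
    "GENETIC" else "PHYSICAL"
  genetic <- if (any(g_ok)) {
    new_map_track(table$marker[g_ok], table$genetic_pos[g_ok],
                  chromosome, "GENETIC")
  }
  physical <- if (any(p_ok)) {
    ext <- if (!is.null(lengths) && chromosome %in% names(lengths))
      unname(lengths[chromosome]) else NULL
    new_map_track(table$marker[p_ok], table$physical_pos[p_ok],
                  chromosome, second_scale, extent = ext)
  }
  list(genetic = genetic, physical = physical)
}

#' Layout configuration for track rendering
#'
#' Collects the display parameters: the zoom factor (capped at 10 in
#' default mode and 30 in single-chromosome mode), the canvas spacing
#' between the genetic and physical track of a chromosome, the divisor
#' applied to physical (bp) coordinates so that both maps fit one canvas,
#' the orientation, and whether marker and locus names are drawn
#' (possible only in chromosome mode).
#'
#' @param mode `"default"` (several chromosomes, up to ten individuals)
#'   or `"chromosome"` (one chromosome of one individual, with names).
#' @param zoom Positive zoom factor; at most 10 (`default`) or 30
#'   (`chromosome`).
#' @param spacing Canvas distance between the paired tracks.
#' @param physical_divisor Positive number dividing bp coordinates for
#'   display (default 1e6, i.e. 1 canvas unit per Mb at zoom 1).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param show_marker_names,show_locus_names Draw names next to markers
#'   (chromosome mode only).
#' @return A `layout_config` list.
#' @export
layout_config <- function(mode = c("default", "chromosome"), zoom = 1,
                          spacing = 60, physical_divisor = 1e6,
                          orientation = c("vertical", "horizontal"),
                          show_marker_names = (mode == "chromosome"),
                          show_locus_names = FALSE) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  cap <- if (mode == "default") 10 else 30
  if (!is.numeric(zoom) || length(zoom) != 1L || is.na(zoom) ||
      zoom <= 0) {
    stop("`zoom` must be a positive number", call. = FALSE)
  }
  if (zoom > cap) {
    stop("zoom ", zoom, " exceeds the ", mode, "-mode cap of ", cap,
         call. = FALSE)
  }
  if (!is.numeric(physical_divisor) || physical_divisor <= 0) {
    stop("`physical_divisor` must be positive", call. = FALSE)
  }
  force(show_marker_names)
  structure(list(mode = mode, zoom = zoom, spacing = spacing,
                 physical_divisor = physical_divisor,
                 orientation = orientation,
                 show_marker_names = isTRUE(show_marker_names),
                 show_locus_names = isTRUE(show_locus_names)),
            class = "layout_config")
}

#' Project track positions onto the canvas
#'
#' A strictly increasing linear map: genetic coordinates are multiplied
#' by the zoom factor; physical coordinates are divided by the physical
#' divisor first, so both tracks share a canvas scale.
#'
#' @param track A `map_track` from [build_tracks()].
#' @param config A [layout_config()].
#' @return Tibble with columns `marker`, `position`, `canvas`.
#' @export
to_canvas <- function(track, config = layout_config()) {
  stopifnot(inherits(track, "map_track"), inherits(config, "layout_config"))
  divisor <- if (attr(track, "scale") == "PHYSICAL")
    config$physical_divisor else 1
  tibble::tibble(marker = track$marker, position = track$position,
                 canvas = track$position / divisor * config$zoom)
}

canvas_extent <- function(track, config) {
  divisor <- if (attr(track, "scale") == "PHYSICAL")
    config$physical_divisor else 1
  attr(track, "extent") / divisor * config$zoom
}

#' Connectors between the genetic and physical track of a chromosome
#'
#' One connector per marker present on both tracks; markers present on
#' only one track get none.
#'
#' @param genetic,physical `map_track`s for the same chromosome.
#' @param config A [layout_config()] used to express the endpoints in
#'   canvas coordinates.
#' @return Tibble with columns `marker`, `genetic_coord`,
#'   `physical_coord` (canvas units), in genetic-track order.
#' @export
pair_connectors <- function(genetic, physical,
                            config = layout_config()) {
  stopifnot(inherits(genetic, "map_track"),
            inherits(physical, "map_track"))
  if (!identical(attr(genetic, "chromosome"),
                 attr(physical, "chromosome"))) {
    stop("tracks belong to different chromosomes: ",
         attr(genetic, "chromosome"), " vs ",
         attr(physical, "chromosome"), call. = FALSE)
  }
  g <- to_canvas(genetic, config)
  p <- to_canvas(physical, config)
  shared <- dplyr::inner_join(
    dplyr::select(g, "marker", genetic_coord = "canvas"),
    dplyr::select(p, "marker", physical_coord = "canvas"),
    by = "marker")
  shared
}
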