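#' @importFrom rlang .data
NULL

gt_max_samples <- 500L
gt_max_markers <- 50000L

new_genotype_table <- function(df, roles, col4 = "physical") {
  stopifnot(all(c("chromosome", "marker", "genetic_pos", "physical_pos",
                  "lod") %in% names(df)))
  samples <- setdiff(names(df), c("chromosome", "marker", "genetic_pos",
                                  "physical_pos", "lod"))
  out <- tibble::as_tibble(df)
  attr(out, "samples") <- samples
  attr(out, "roles") <- roles
  attr(out, "col4") <- col4
  class(out) <- c("genotype_table", class(out))
  out
}

#' Sample names of a genotype table
#'
#' @param table A `genotype_table`.
#' @return Character vector of sample (genotype) column names, in file
#'   order: the four parent columns first, then any further accessions.
#' @export
sample_names <- function(table) attr(table, "samples")

#' Parent role bindings of a genotype table
#'
#' Roles are positional: columns 6 and 7 of the input file are the
#' parents P1 and P2 of a biparental scheme, columns 8 and 9 the
#' recurrent parent P3 and parent P4 used when establishing near-isogenic
#' lines. A role whose genotype column is entirely missing is recorded as
#' an absent parent (`NA`).
#'
#' @param table A `genotype_table`.
#' @return Named character vector `c(P1 = ..., P2 = ..., P3 = ..., P4 = ...)`
#'   mapping each role to a sample name, `NA` for absent parents.
#' @export
parent_roles <- function(table) attr(table, "roles")

# Row-subset a genotype_table without losing its attributes.
subset_markers <- function(table, keep) {
  out <- table
  cls <- class(out)
  class(out) <- setdiff(cls, "genotype_table")
  out <- out[keep, , drop = FALSE]
  attr(out, "samples") <- attr(table, "samples")
  attr(out, "roles") <- attr(table, "roles")
  attr(out, "col4") <- attr(table, "col4")
  class(out) <- cls
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  roles <- parent_roles(x)
  cat("# Genotype table: ", nrow(x), " markers x ",
      length(sample_names(x)), " samples, ",
      length(unique(x$chromosome)), " chromosomes\n", sep = "")
  cat("# Parents: ",
      paste(names(roles), ifelse(is.na(roles), "<absent>", roles),
            sep = "=", collapse = " "), "\n", sep = "")
  NextMethod()
  invisible(x)
}

parse_position <- function(x, marker, what) {
  x <- gsub(",", "", trimws(x), fixed = TRUE)
  x[x %in% c("NA", "")] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) & !is.na(x)
  if (any(bad)) {
    stop("non-numeric ", what, " for marker(s): ",
         paste(utils::head(marker[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  val
}

#' Read a nine-column genotype table
#'
#' Reads the tab-delimited genotype table format: a header row followed
#' by one row per marker with at least nine columns. Column 1 is the
#' chromosome, column 2 the marker name, column 3 the genetic position
#' (cM), column 4 the physical position (bp) or alternatively a second
#' genetic position, column 5 a LOD value, columns 6-9 the genotypes of
#' parents P1-P4, and columns 10 onwards further accessions. Missing
#' information is given as `"NA"`; thousands separators in positions
#' (`12,000`) are accepted. At most 500 samples and 50,000 markers can
#' be loaded.
#'
#' @param path Path to a tab-delimited text file.
#' @param col4 Semantics of column 4: `"physical"` (bp, default) or
#'   `"genetic"` when the file carries a second genetic map.
#' @return A `genotype_table`: a tibble with columns `chromosome`,
#'   `marker`, `genetic_pos`, `physical_pos`, `lod` and one column of
#'   canonical call symbols per sample, plus role bindings (see
#'   [parent_roles()]).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("chr\tmarker\tcM\tbp\tlod\tP1\tP2\tP3\tP4",
#'              "1A\tSNP_1\t0.00\t12,000\t3.0\tA\tT\tA\tA"), f)
#' read_genotype_table(f)
#' @export
read_genotype_table <- function(path, col4 = c("physical", "genetic")) {
  col4 <- match.arg(col4)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  if (ncol(raw) < 9L) {
    stop("genotype table requires at least nine columns, found ",
         ncol(raw), call. = FALSE)
  }
  n_samples <- ncol(raw) - 5L
  if (n_samples > gt_max_samples) {
    stop("capacity exceeded: ", n_samples, " samples (maximum ",
         gt_max_samples, ")", call. = FALSE)
  }
  if (nrow(raw) > gt_max_markers) {
    stop("capacity exceeded: ", nrow(raw), " markers (maximum ",
         gt_max_markers, ")", call. = FALSE)
  }
  marker <- raw[[2L]]
  dup <- duplicated(marker)
  if (any(dup)) {
    stop("duplicate marker name(s): ",
         paste(utils::head(unique(marker[dup]), 5L), collapse = ", "),
         call. = FALSE)
  }
  genetic_pos <- parse_position(raw[[3L]], marker, "genetic position")
  physical_pos <- parse_position(raw[[4L]], marker,
                                 if (col4 == "physical") "physical position"
                                 else "second genetic position")
  if (col4 == "physical" && any(physical_pos < 0, na.rm = TRUE)) {
    stop("negative physical position for marker(s): ",
         paste(marker[which(physical_pos < 0)], collapse = ", "),
         call. = FALSE)
  }
  lod <- parse_position(raw[[5L]], marker, "LOD value")
  if (any(is.na(genetic_pos) & is.na(physical_pos))) {
    warning("marker(s) without any genetic or physical position: ",
            paste(utils::head(
              marker[is.na(genetic_pos) & is.na(physical_pos)], 5L),
              collapse = ", "), call. = FALSE)
  }
  sample_cols <- names(raw)[6:ncol(raw)]
  calls <- lapply(raw[sample_cols], normalize_call)
  df <- tibble::tibble(chromosome = raw[[1L]], marker = marker,
                       genetic_pos = genetic_pos,
                       physical_pos = physical_pos, lod = lod)
  df <- dplyr::bind_cols(df, tibble::as_tibble(calls))
  role_names <- sample_cols[1:4]
  all_na <- vapply(df[role_names], function(x) all(is.na(x)), logical(1))
  # header-only files cannot bind roles either
  if (nrow(df) == 0L) all_na[] <- TRUE
  roles <- stats::setNames(ifelse(all_na, NA_character_, role_names),
                           c("P1", "P2", "P3", "P4"))
  new_genotype_table(df, roles, col4)
}

#' Write a genotype table back to its tab-delimited format
#'
#' Inverse of [read_genotype_table()]: absent values are written as the
#' literal token `"NA"`, failed calls as `"NA"`, and positions without
#' thousands separators. Reading the written file reproduces all calls,
#' positions and role bindings.
#'
#' @param table A `genotype_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  samples <- sample_names(table)
  fmt_num <- function(x) {
    out <- ifelse(is.na(x), "NA",
                  format(x, scientific = FALSE, trim = TRUE, digits = 15))
    out
  }
  header <- c("chromosome", "marker", "genetic_pos", "physical_pos",
              "lod", samples)
  body <- cbind(table$chromosome, table$marker, fmt_num(table$genetic_pos),
                fmt_num(table$physical_pos), fmt_num(table$lod))
  for (s in samples) {
    v <- table[[s]]
    body <- cbind(body, ifelse(is.na(v), "NA", v))
  }
  lines <- c(paste(header, collapse = "\t"),
             if (nrow(table)) apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a consensus genetic map
#'
#' Reads a tab-delimited file with a header row and columns marker,
#' chromosome, and optionally a genetic position in cM. Duplicate marker
#' rows that agree on the chromosome are collapsed to the first
#' occurrence; duplicates with conflicting chromosomes are dropped
#' entirely and reported via a warning and the `"conflicts"` attribute.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `marker`, `chromosome`, `genetic_pos`
#'   (`NA` when the file has no cM column), one row per marker.
#' @export
read_consensus_map <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    warning("consensus map is empty: ", path, call. = FALSE)
    out <- tibble::tibble(marker = character(), chromosome = character(),
                          genetic_pos = numeric())
    attr(out, "conflicts") <- character()
    return(out)
  }
  cm <- if (ncol(raw) >= 3L) parse_position(raw[[3L]], raw[[1L]],
                                            "genetic position")
        else rep(NA_real_, nrow(raw))
  map <- tibble::tibble(marker = raw[[1L]], chromosome = raw[[2L]],
                        genetic_pos = cm)
  conf <- map |>
    dplyr::distinct(.data$marker, .data$chromosome) |>
    dplyr::count(.data$marker) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull(.data$marker)
  if (length(conf)) {
    warning(length(conf), " marker(s) dropped from consensus map for ",
            "conflicting chromosome assignments: ",
            paste(utils::head(conf, 5L), collapse = ", "), call. = FALSE)
  }
  out <- map |>
    dplyr::filter(!(.data$marker %in% conf)) |>
    dplyr::distinct(.data$marker, .keep_all = TRUE)
  attr(out, "conflicts") <- conf
  out
}

#' Export case assignments as a tab-delimited marker table
#'
#' Writes one row per (marker, IOI) assignment with columns
#' `chromosome`, `marker`, `genetic_pos`, `physical_pos`, `ioi`,
#' `status`. Re-reading with [read_marker_table()] yields the same
#' records.
#'
#' @param assignments A `case_assignments` tibble (see [discriminate()]),
#'   or any tibble with the columns above. May be empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(assignments, path) {
  cols <- c("chromosome", "marker", "genetic_pos", "physical_pos",
            "ioi", "status")
  missing_cols <- setdiff(cols, names(assignments))
  if (length(missing_cols)) {
    stop("assignments lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fmt <- function(x) {
    if (!length(x)) return(character())
    if (is.numeric(x)) as.character(ifelse(is.na(x), "NA",
                              format(x, scientific = FALSE, trim = TRUE,
                                     digits = 15)))
    else as.character(ifelse(is.na(x), "NA", as.character(x)))
  }
  body <- vapply(cols, function(cn) fmt(assignments[[cn]]),
                 character(nrow(assignments)))
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(assignments))
               apply(matrix(body, nrow = nrow(assignments)), 1L,
                     paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#'
#' @param path Path to the exported table.
#' @return Tibble with columns `chromosome`, `marker`, `genetic_pos`,
#'   `physical_pos`, `ioi`, `status`.
#' @export
read_marker_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  tibble::tibble(
    chromosome = raw$chromosome,
    marker = raw$marker,
    genetic_pos = parse_position(raw$genetic_pos, raw$marker,
                                 "genetic position"),
    physical_pos = parse_position(raw$physical_pos, raw$marker,
                                  "physical position"),
    ioi = raw$ioi,
    status = raw$status)
}

#' Read tabular BLAST hits (outfmt 6)
#'
#' Reads the standard 12-column tabular BLAST output (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`, no header). Reverse-strand hits (subject start greater
#' than subject end) are normalised so that `sstart <= send`, with the
#' original orientation kept in a `strand` column.
#'
#' @param path Path to the hit file.
#' @return A tibble with the 12 standard columns plus `strand`
#'   (`"+"`/`"-"`).
#' @export
read_blast_tab <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(
      qseqid = character(), sseqid = character(), pident = numeric(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = numeric(),
      send = numeric(), evalue = numeric(), bitscore = numeric(),
      strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("expected 12 tab-separated columns but found ", nf[bad],
         " at line ", bad, call. = FALSE)
  }
  m <- do.call(rbind, fields)
  raw_start <- as.numeric(m[, 9L])
  raw_end <- as.numeric(m[, 10L])
  tibble::tibble(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = pmin(raw_start, raw_end), send = pmax(raw_start, raw_end),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    strand = ifelse(raw_start <= raw_end, "+", "-"))
}

#' Read a chromosome-lengths table
#'
#' Optional override for track extents: tab-delimited with a header row
#' and columns chromosome, length (bp).
#'
#' @param path Path to the lengths file.
#' @return Named numeric vector of lengths, names are chromosome labels.
#' @export
read_chrom_lengths <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE, na = character())
  stats::setNames(as.numeric(gsub(",", "", raw[[2L]], fixed = TRUE)),
                  raw[[1L]])
}
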