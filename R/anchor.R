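anchor_statuses <- c("ANCHORED_SINGLE_CHR", "ANCHORED_CONSENSUS",
                     "NO_HIT", "DISCARDED_NO_CONSENSUS", "DISCARDED_SPAN")

#' Assign physical positions to markers from BLAST hits
#'
#' Applies the hit-filter cascade to per-marker BLAST hits: (1) markers
#' without hits are `NO_HIT`; (2) markers whose hits fall on exactly one
#' chromosome keep that chromosome as the candidate; (3) markers hitting
#' several chromosomes are resolved through the consensus genetic map --
#' if the map places the marker on one of the hit chromosomes the hits
#' are restricted to it, otherwise the marker is
#' `DISCARDED_NO_CONSENSUS`; (4) if any two hits on the candidate
#' chromosome lie more than `max_span` bp apart the marker is
#' `DISCARDED_SPAN`; otherwise it is anchored
#' (`ANCHORED_SINGLE_CHR`/`ANCHORED_CONSENSUS`) at the subject start of
#' the best remaining hit (highest bitscore, then lowest e-value, then
#' lowest subject start).
#'
#' @param hits Tibble of BLAST hits as from [read_blast_tab()]; only
#'   `qseqid`, `sseqid`, `sstart`, `evalue`, `bitscore` are used.
#' @param consensus Consensus map tibble from [read_consensus_map()]
#'   (columns `marker`, `chromosome`), or `NULL` for no resolution step.
#' @param markers Optional character vector of all query markers, so
#'   that markers without a single hit are reported as `NO_HIT`;
#'   defaults to the markers present in `hits`.
#' @param max_span Maximum distance (bp) between two hits on the
#'   candidate chromosome, default 1,000,000.
#' @return A tibble of class `anchor_results` with columns `marker`,
#'   `status`, `chromosome`, `physical_pos`; chromosome and position are
#'   `NA` unless the marker was anchored.
#' @examples
#' hits <- tibble::tibble(qseqid = "M1", sseqid = "1A", sstart = 100,
#'                        evalue = 1e-30, bitscore = 180)
#' assign_physical_positions(hits)
#' @export
assign_physical_positions <- function(hits, consensus = NULL,
                                      markers = NULL,
                                      max_span = 1e6) {
  if (!is.numeric(max_span) || length(max_span) != 1L ||
      is.na(max_span) || max_span <= 0) {
    stop("`max_span` must be a positive number of base pairs",
         call. = FALSE)
  }
  cons_chr <- if (!is.null(consensus) && nrow(consensus)) {
    stats::setNames(consensus$chromosome, consensus$marker)
  } else character()
  if (is.null(markers)) markers <- unique(hits$qseqid)
  one <- function(mk) {
    h <- hits[hits$qseqid == mk, , drop = FALSE]
    if (!nrow(h)) {
      return(tibble::tibble(marker = mk, status = "NO_HIT",
                            chromosome = NA_character_,
                            physical_pos = NA_real_))
    }
    chrs <- unique(h$sseqid)
    if (length(chrs) == 1L) {
      cand <- chrs
      anchored_as <- "ANCHORED_SINGLE_CHR"
    } else {
      cand <- unname(cons_chr[mk])
      if (is.na(cand) || !cand %in% chrs) {
        return(tibble::tibble(marker = mk,
                              status = "DISCARDED_NO_CONSENSUS",
                              chromosome = NA_character_,
                              physical_pos = NA_real_))
      }
      anchored_as <- "ANCHORED_CONSENSUS"
    }
    h <- h[h$sseqid == cand, , drop = FALSE]
    if (max(h$sstart) - min(h$sstart) > max_span) {
      return(tibble::tibble(marker = mk, status = "DISCARDED_SPAN",
                            chromosome = NA_character_,
                            physical_pos = NA_real_))
    }
    best <- h[order(-h$bitscore, h$evalue, h$sstart), , drop = FALSE][1L, ]
    tibble::tibble(marker = mk, status = anchored_as,
                   chromosome = cand, physical_pos = best$sstart)
  }
  out <- dplyr::bind_rows(lapply(markers, one))
  class(out) <- c("anchor_results", class(out))
  out
}

#' Tally anchoring dispositions
#'
#' @param results An `anchor_results` tibble from
#'   [assign_physical_positions()].
#' @return Named integer vector over the five disposition statuses; the
#'   counts sum to the number of markers.
#' @export
summarize_anchoring <- function(results) {
  counts <- table(factor(results$status, levels = anchor_statuses))
  stats::setNames(as.integer(counts), anchor_statuses)
}

#' Write anchoring results as a tab-delimited table
#'
#' @param results An `anchor_results` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(results, path) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            format(x, scientific = FALSE, trim = TRUE,
                                   digits = 15))
  lines <- c("marker\tstatus\tchromosome\tphysical_pos",
             if (nrow(results))
               paste(results$marker, results$status,
                     fmt(results$chromosome), fmt(results$physical_pos),
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
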