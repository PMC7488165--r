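# Build a genotype-table file from call rows, then read it back.
# Each row: chromosome, marker, genetic, physical, lod, then calls.
write_gt_file <- function(rows, samples = c("P1", "P2", "P3", "P4"),
                          path = tempfile(fileext = ".txt")) {
  header <- paste(c("chr", "marker", "cM", "bp", "lod", samples),
                  collapse = "\t")
  writeLines(c(header, vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}

example_row <- c("1A", "SNP_1", "0.00", "12,000", "3.0", "A", "T", "A", "A")

# Independent brute-force re-implementation of the anchoring flow chart:
# plain loops, no shared code with assign_physical_positions().
oracle_anchor <- function(hits, consensus, markers, max_span = 1e6) {
  out <- list()
  for (mk in markers) {
    rows <- which(hits$qseqid == mk)
    if (length(rows) == 0L) {
      out[[mk]] <- list(status = "NO_HIT", chromosome = NA, pos = NA)
      next
    }
    chrs <- unique(hits$sseqid[rows])
    if (length(chrs) == 1L) {
      cand <- chrs
      status <- "ANCHORED_SINGLE_CHR"
    } else {
      cand <- NA
      if (!is.null(consensus)) {
        hit_cons <- consensus$chromosome[consensus$marker == mk]
        if (length(hit_cons) == 1L && hit_cons %in% chrs) cand <- hit_cons
      }
      if (is.na(cand)) {
        out[[mk]] <- list(status = "DISCARDED_NO_CONSENSUS",
                          chromosome = NA, pos = NA)
        next
      }
      status <- "ANCHORED_CONSENSUS"
    }
    rows <- rows[hits$sseqid[rows] == cand]
    starts <- hits$sstart[rows]
    wide <- FALSE
    for (i in seq_along(starts)) {
      for (j in seq_along(starts)) {
        if (abs(starts[i] - starts[j]) > max_span) wide <- TRUE
      }
    }
    if (wide) {
      out[[mk]] <- list(status = "DISCARDED_SPAN", chromosome = NA,
                        pos = NA)
      next
    }
    best <- rows[1L]
    for (r in rows) {
      if (hits$bitscore[r] > hits$bitscore[best] ||
          (hits$bitscore[r] == hits$bitscore[best] &&
             hits$evalue[r] < hits$evalue[best]) ||
          (hits$bitscore[r] == hits$bitscore[best] &&
             hits$evalue[r] == hits$evalue[best] &&
             hits$sstart[r] < hits$sstart[best])) best <- r
    }
    out[[mk]] <- list(status = status, chromosome = cand,
                      pos = hits$sstart[best])
  }
  out
}

# random hit table for oracle comparisons
random_hit_table <- function(n_markers = 50, seed = 1) {
  set.seed(seed)
  chroms <- paste0("chr", 1:5)
  hits <- list()
  cons <- list()
  markers <- sprintf("M%03d", seq_len(n_markers))
  for (mk in markers) {
    n_hits <- sample(0:10, 1L)
    if (n_hits == 0L) next
    chr <- sample(chroms, n_hits, replace = TRUE)
    hits[[mk]] <- tibble::tibble(
      qseqid = mk, sseqid = chr,
      pident = round(runif(n_hits, 80, 100), 1),
      length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L,
      qend = 100L,
      sstart = sample(1:5e6, n_hits),
      send = sample(1:5e6, n_hits),
      evalue = signif(10^runif(n_hits, -50, 0), 3),
      bitscore = sample(50:200, n_hits, replace = TRUE),
      strand = "+")
    if (runif(1) < 0.5) {
      cons[[mk]] <- tibble::tibble(marker = mk,
                                   chromosome = sample(chroms, 1L),
                                   genetic_pos = NA_real_)
    }
  }
  list(hits = dplyr::bind_rows(hits),
       consensus = dplyr::bind_rows(cons),
       markers = markers)
}
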