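hit <- function(mk, chr, sstart, bitscore = 180, evalue = 1e-30) {
  tibble::tibble(qseqid = mk, sseqid = chr, pident = 99, length = 100L,
                 mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
                 sstart = sstart, send = sstart + 99, evalue = evalue,
                 bitscore = bitscore, strand = "+")
}

test_that("the four cascade dispositions resolve as documented", {
  hits <- dplyr::bind_rows(
    hit("M1", "1A", 100),
    hit("M2", "1A", 1000), hit("M2", "1A", 2500000),
    hit("M3", "1A", 500), hit("M3", "2B", 700, bitscore = 200),
    hit("M4", "1A", 500), hit("M4", "2B", 700))
  cons <- tibble::tibble(marker = "M3", chromosome = "2B",
                         genetic_pos = NA_real_)
  res <- assign_physical_positions(hits, consensus = cons,
                                   markers = c("M1", "M2", "M3", "M4",
                                               "M5"))
  get <- function(mk) res[res$marker == mk, ]
  expect_identical(get("M1")$status, "ANCHORED_SINGLE_CHR")
  expect_identical(get("M1")$chromosome, "1A")
  expect_identical(get("M1")$physical_pos, 100)
  expect_identical(get("M2")$status, "DISCARDED_SPAN")
  expect_identical(get("M3")$status, "ANCHORED_CONSENSUS")
  expect_identical(get("M3")$chromosome, "2B")
  expect_identical(get("M3")$physical_pos, 700)
  expect_identical(get("M4")$status, "DISCARDED_NO_CONSENSUS")
  expect_identical(get("M5")$status, "NO_HIT")
  # chromosome/position present exactly for anchored statuses
  anchored <- grepl("^ANCHORED", res$status)
  expect_identical(!is.na(res$chromosome), anchored)
  expect_identical(!is.na(res$physical_pos), anchored)
})

test_that("the best hit is chosen by bitscore, then e-value, then position", {
  hits <- dplyr::bind_rows(
    hit("M1", "1A", 5000, bitscore = 150),
    hit("M1", "1A", 100, bitscore = 180),
    hit("M2", "1A", 900, bitscore = 180, evalue = 1e-40),
    hit("M2", "1A", 400, bitscore = 180, evalue = 1e-30),
    hit("M3", "1A", 800), hit("M3", "1A", 300))
  res <- assign_physical_positions(hits)
  expect_identical(res$physical_pos,
                   c(100, 900, 300))
})

test_that("span filtering applies to consensus-resolved markers too", {
  hits <- dplyr::bind_rows(
    hit("M1", "1A", 100), hit("M1", "1A", 1500000),
    hit("M1", "2B", 100))
  cons <- tibble::tibble(marker = "M1", chromosome = "1A",
                         genetic_pos = NA_real_)
  res <- assign_physical_positions(hits, consensus = cons)
  expect_identical(res$status, "DISCARDED_SPAN")
  # span exactly at the threshold passes (the rule is "more than")
  hits2 <- dplyr::bind_rows(hit("M2", "1A", 100),
                            hit("M2", "1A", 100 + 1e6))
  expect_identical(assign_physical_positions(hits2)$status,
                   "ANCHORED_SINGLE_CHR")
  expect_error(assign_physical_positions(hits2, max_span = -5),
               "positive")
})

test_that("raising max_span never turns an anchored marker into a discard", {
  rt <- random_hit_table(30, seed = 99)
  res1 <- assign_physical_positions(rt$hits, consensus = rt$consensus,
                                    markers = rt$markers, max_span = 1e6)
  res2 <- assign_physical_positions(rt$hits, consensus = rt$consensus,
                                    markers = rt$markers, max_span = 5e6)
  was_anchored <- grepl("^ANCHORED", res1$status)
  expect_false(any(res2$status[was_anchored] == "DISCARDED_SPAN"))
})

test_that("the cascade matches an independent brute-force oracle", {
  for (seed in 1:5) {
    rt <- random_hit_table(50, seed = seed)
    res <- assign_physical_positions(rt$hits, consensus = rt$consensus,
                                     markers = rt$markers)
    oracle <- oracle_anchor(rt$hits, rt$consensus, rt$markers)
    for (mk in rt$markers) {
      o <- oracle[[mk]]
      r <- res[res$marker == mk, ]
      expect_identical(r$status, o$status, label = paste(seed, mk))
      if (grepl("^ANCHORED", o$status)) {
        expect_identical(r$physical_pos, as.numeric(o$pos))
        expect_identical(r$chromosome, o$chromosome)
      }
    }
  }
})

test_that("summaries conserve every marker in exactly one status", {
  rt <- random_hit_table(40, seed = 7)
  res <- assign_physical_positions(rt$hits, consensus = rt$consensus,
                                   markers = rt$markers)
  counts <- summarize_anchoring(res)
  expect_identical(sum(counts), length(rt$markers))
  expect_identical(sum(summarize_anchoring(res[0, ])), 0L)
  g <- glance(res)
  expect_identical(sum(unlist(g)), length(rt$markers))
})

test_that("anchor tables write and reflect the results", {
  res <- assign_physical_positions(hit("M1", "1A", 100))
  f <- tempfile()
  write_anchor_table(res, f)
  lines <- readLines(f)
  expect_identical(length(lines), 2L)
  expect_match(lines[2], "M1\tANCHORED_SINGLE_CHR\t1A\t100")
})
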