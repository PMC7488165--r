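iupac_het <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  c("A C" = "M", "A G" = "R", "A T" = "W", "C G" = "S",
    "C T" = "Y", "G T" = "K")[key]
}

# run `code` under an isolated RNG stream; the global seed is untouched
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the crossing-scheme simulator
#'
#' Defines a synthetic study: the crossing scheme, genome dimensions,
#' planted donor introgression blocks, and per-call noise rates. The
#' same seed always yields the same tables.
#'
#' Schemes: `"DH"` and `"F2"` are biparental (parents P1/P2); `"BCFx"`
#' is a backcross with donor P1 and recurrent parent P2; `"NIL"` is a
#' near-isogenic line with donor P1, second cross parent P2 and
#' recurrent parent P3. The individual of interest carries the donor
#' (P1) allele inside the planted blocks and the recurrent/background
#' allele outside them.
#'
#' @param scheme One of `"NIL"`, `"DH"`, `"F2"`, `"BCFx"`.
#' @param n_chromosomes Number of chromosomes (default 14, a tetraploid
#'   wheat complement).
#' @param markers_per_chromosome Markers simulated per chromosome.
#' @param genetic_length Genetic length of each chromosome in cM.
#' @param physical_length Physical length of each chromosome in bp.
#' @param blocks Planted donor introgression blocks: tibble/data frame
#'   with columns `chromosome` (1-based index or label `chr<i>`),
#'   `start`, `end` (bp). Default: a large target introgression on
#'   chromosome 1 and a smaller linkage-drag fragment on chromosome 3.
#' @param polymorphic_fraction Fraction of markers polymorphic between
#'   donor and recurrent background.
#' @param het_rate Probability that an IOI call is replaced by the
#'   IUPAC heterozygote of the two parental alleles.
#' @param failure_rate Probability that an IOI call fails (`NA`);
#'   applied after `het_rate` and taking precedence.
#' @param n_iois Number of individuals of interest to simulate.
#' @param seed Integer seed for the simulator's private random stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(scheme = c("NIL", "DH", "F2", "BCFx"),
                       n_chromosomes = 14L,
                       markers_per_chromosome = 200L,
                       genetic_length = 150,
                       physical_length = 6e8,
                       blocks = NULL,
                       polymorphic_fraction = 0.9,
                       het_rate = 0, failure_rate = 0,
                       n_iois = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  rates <- c(polymorphic_fraction, het_rate, failure_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(blocks)) {
    blocks <- tibble::tibble(
      chromosome = c("chr1", "chr3"),
      start = c(0.25, 0.70) * physical_length,
      end = c(0.45, 0.80) * physical_length)
  } else {
    blocks <- tibble::as_tibble(blocks)
    if (is.numeric(blocks$chromosome)) {
      blocks$chromosome <- paste0("chr", blocks$chromosome)
    }
  }
  if (any(blocks$start < 0 | blocks$end > physical_length |
          blocks$start >= blocks$end)) {
    stop("introgression blocks must lie within the chromosome extent",
         call. = FALSE)
  }
  structure(list(scheme = scheme, n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 genetic_length = genetic_length,
                 physical_length = physical_length, blocks = blocks,
                 polymorphic_fraction = polymorphic_fraction,
                 het_rate = het_rate, failure_rate = failure_rate,
                 n_iois = as.integer(n_iois), seed = as.integer(seed)),
            class = "sim_config")
}

# monotone piecewise-linear cM ~ bp map, flattened around the centromere
genetic_from_physical <- function(bp, physical_length, genetic_length) {
  x <- bp / physical_length
  breaks <- c(0, 0.3, 0.7, 1)
  rates <- c(2, 0.2, 2)           # telomeres recombine, centromere barely
  seg_len <- diff(breaks) * rates
  total <- sum(seg_len)
  cum <- c(0, cumsum(seg_len))
  seg <- findInterval(x, breaks, rightmost.closed = TRUE)
  g <- cum[seg] + (x - breaks[seg]) * rates[seg]
  g / total * genetic_length
}

#' Simulate a crossing-scheme genotype table with known truth
#'
#' Generates a genotype table for the configured scheme: biallelic
#' homozygous parents (polymorphic at the configured fraction of
#' markers), an IOI that carries the donor (P1) allele inside the
#' planted introgression blocks and the recurrent/background allele
#' outside, and heterozygous/failed IOI calls injected at the configured
#' rates. Genetic positions follow a monotone centromere-flattened map
#' of the physical positions. The truth table records, for every
#' (marker, IOI), the status that [classify_marker()] must return.
#'
#' For the NIL scheme, the second cross parent P2 is simulated with the
#' recurrent-type allele at polymorphic markers, so donor segments are
#' unambiguously attributable to P1 (truth `1_1` inside blocks, `3_9`
#' outside).
#'
#' @param config A [sim_config()].
#' @return List with elements `table` (a `genotype_table`) and `truth`
#'   (tibble `marker`, `chromosome`, `genetic_pos`, `physical_pos`,
#'   `ioi`, `status`, `in_block`).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    n_chr <- config$n_chromosomes
    m_per <- config$markers_per_chromosome
    chroms <- paste0("chr", seq_len(n_chr))
    rows <- list()
    for (ci in seq_len(n_chr)) {
      bp <- sort(round(stats::runif(m_per, 1, config$physical_length)))
      bp <- bp + seq_len(m_per) - 1L  # break exact ties, keep order
      rows[[ci]] <- tibble::tibble(
        chromosome = chroms[ci],
        marker = sprintf("%s_M%03d", chroms[ci], seq_len(m_per)),
        physical_pos = pmin(bp, config$physical_length),
        genetic_pos = round(genetic_from_physical(
          pmin(bp, config$physical_length), config$physical_length,
          config$genetic_length), 2),
        lod = round(stats::runif(m_per, 2, 20), 1))
    }
    mk <- dplyr::bind_rows(rows)
    n <- nrow(mk)

    alleles <- t(vapply(seq_len(n), function(i)
      sample(c("A", "C", "G", "T"), 2L), character(2)))
    donor <- alleles[, 1L]
    background <- alleles[, 2L]
    poly <- stats::runif(n) < config$polymorphic_fraction
    donor[!poly] <- background[!poly]

    in_block <- rep(FALSE, n)
    for (bi in seq_len(nrow(config$blocks))) {
      b <- config$blocks[bi, ]
      in_block <- in_block | (mk$chromosome == b$chromosome &
                                mk$physical_pos >= b$start &
                                mk$physical_pos <= b$end)
    }

    scheme <- config$scheme
    n_parents <- if (scheme == "NIL") 3L else 2L
    parents <- matrix(NA_character_, n, 4L)
    parents[, 1L] <- donor
    parents[, 2L] <- background
    if (n_parents >= 3L) parents[, 3L] <- background
    parent_names <- c("DonorParent", "CrossParent", "RecurrentParent",
                      "Parent4")

    base_call <- ifelse(in_block, donor, background)
    base_status <- rep(NA_character_, n)
    donor_case <- "1_1"
    other_case <- if (scheme == "NIL") "3_9" else "1_2"
    base_status[poly & in_block] <- donor_case
    base_status[poly & !in_block] <- other_case
    base_status[!poly] <- "MONOMORPHIC"

    ioi_names <- sprintf("IOI_%d", seq_len(config$n_iois))
    calls <- list()
    truth <- list()
    for (s in ioi_names) {
      call_s <- base_call
      status_s <- base_status
      het <- stats::runif(n) < config$het_rate
      if (any(het)) {
        # at monomorphic markers pair the shared allele with another base
        second <- ifelse(donor == background,
                         ifelse(background == "A", "T", "A"), donor)
        call_s[het] <- iupac_het(second[het], background[het])
        status_s[het] <- "1_4"
      }
      fail <- stats::runif(n) < config$failure_rate
      call_s[fail] <- NA_character_
      status_s[fail] <- "1_3"
      calls[[s]] <- call_s
      truth[[s]] <- tibble::tibble(
        marker = mk$marker, chromosome = mk$chromosome,
        genetic_pos = mk$genetic_pos, physical_pos = mk$physical_pos,
        ioi = s, status = status_s, in_block = in_block)
    }

    df <- mk[, c("chromosome", "marker", "genetic_pos", "physical_pos",
                 "lod")]
    for (j in 1:4) df[[parent_names[j]]] <- parents[, j]
    for (s in ioi_names) df[[s]] <- calls[[s]]
    roles <- stats::setNames(
      ifelse(seq_len(4L) <= n_parents, parent_names, NA_character_),
      paste0("P", 1:4))
    list(table = new_genotype_table(df, roles),
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate BLAST hit tables with known anchoring truth
#'
#' Produces a tabular hit set for a collection of markers with true
#' physical anchors, planting the hit patterns the anchoring cascade
#' must distinguish: clean single-chromosome hits, multi-chromosome hits
#' resolvable through the consensus map, multi-chromosome hits without a
#' consensus entry, same-chromosome hits spread wider than the span
#' threshold, and markers without any hit. The truth table records the
#' status [assign_physical_positions()] must return for each marker.
#'
#' @param anchors Tibble with columns `marker`, `chromosome`,
#'   `physical_pos`: the true anchor of every marker.
#' @param p_multi_consensus,p_no_consensus,p_wide_span,p_no_hit
#'   Probabilities of each planted hit pattern (remainder: clean single
#'   hits). Must sum to at most 1.
#' @param span Distance (bp) between the two same-chromosome hits of a
#'   wide-span marker; must exceed the cascade's `max_span` for the
#'   pattern to be discarded (default 2,000,000).
#' @param seed Integer seed.
#' @return List with `hits` (a BLAST-hit tibble as from
#'   [read_blast_tab()]), `truth` (tibble `marker`, `status`,
#'   `chromosome`, `physical_pos` expected from the cascade) and
#'   `consensus` (consensus-map tibble covering the resolvable markers).
#' @export
simulate_blast_hits <- function(anchors, p_multi_consensus = 0,
                                p_no_consensus = 0, p_wide_span = 0,
                                p_no_hit = 0, span = 2e6, seed = 1L) {
  anchors <- tibble::as_tibble(anchors)
  probs <- c(p_multi_consensus, p_no_consensus, p_wide_span, p_no_hit)
  if (any(probs < 0) || sum(probs) > 1) {
    stop("pattern probabilities must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  with_sim_seed(seed, {
    n <- nrow(anchors)
    pool <- unique(anchors$chromosome)
    if (length(pool) < 2L) pool <- c(pool, "chrUn")
    cat_lab <- c("multi_consensus", "no_consensus", "wide_span",
                 "no_hit", "single")
    cats <- apply(stats::rmultinom(n, 1L, c(probs, 1 - sum(probs))),
                  2L, which.max)
    hit_row <- function(mk, chr, sstart, bitscore, len = 100L) {
      evalue <- signif(2^(-bitscore / 3), 3)
      tibble::tibble(qseqid = mk, sseqid = chr, pident = 99.0,
                     length = len, mismatch = 1L, gapopen = 0L,
                     qstart = 1L, qend = len, sstart = sstart,
                     send = sstart + len - 1, evalue = evalue,
                     bitscore = bitscore, strand = "+")
    }
    hits <- list()
    truth <- list()
    consensus <- list()
    for (i in seq_len(n)) {
      mk <- anchors$marker[i]
      chr <- anchors$chromosome[i]
      bp <- anchors$physical_pos[i]
      other <- sample(setdiff(pool, chr), 1L)
      kind <- cat_lab[cats[i]]
      if (kind == "no_hit") {
        truth[[i]] <- tibble::tibble(marker = mk, status = "NO_HIT",
                                     chromosome = NA_character_,
                                     physical_pos = NA_real_)
        next
      }
      if (kind == "single") {
        extra <- sample(0:2, 1L)
        h <- hit_row(mk, chr, bp, 180)
        if (extra > 0) {
          h <- dplyr::bind_rows(h, hit_row(
            mk, chr, bp + sample(1000:50000, extra), 180 - seq_len(extra)))
        }
        hits[[i]] <- h
        truth[[i]] <- tibble::tibble(marker = mk,
                                     status = "ANCHORED_SINGLE_CHR",
                                     chromosome = chr, physical_pos = bp)
      } else if (kind == "multi_consensus") {
        hits[[i]] <- dplyr::bind_rows(
          hit_row(mk, chr, bp, 180),
          hit_row(mk, other, sample(1:1e6, 1L), 150))
        consensus[[i]] <- tibble::tibble(marker = mk, chromosome = chr,
                                         genetic_pos = NA_real_)
        truth[[i]] <- tibble::tibble(marker = mk,
                                     status = "ANCHORED_CONSENSUS",
                                     chromosome = chr, physical_pos = bp)
      } else if (kind == "no_consensus") {
        hits[[i]] <- dplyr::bind_rows(
          hit_row(mk, chr, bp, 180),
          hit_row(mk, other, sample(1:1e6, 1L), 179))
        truth[[i]] <- tibble::tibble(marker = mk,
                                     status = "DISCARDED_NO_CONSENSUS",
                                     chromosome = NA_character_,
                                     physical_pos = NA_real_)
      } else {  # wide_span
        hits[[i]] <- dplyr::bind_rows(
          hit_row(mk, chr, bp, 180),
          hit_row(mk, chr, bp + span, 170))
        truth[[i]] <- tibble::tibble(marker = mk,
                                     status = "DISCARDED_SPAN",
                                     chromosome = NA_character_,
                                     physical_pos = NA_real_)
      }
    }
    list(hits = dplyr::bind_rows(hits),
         truth = dplyr::bind_rows(truth),
         consensus = dplyr::bind_rows(consensus))
  })
}

#' Write simulated fixtures to disk
#'
#' Convenience wrapper: writes the simulated genotype table, its truth
#' table, and (optionally) a matching BLAST hit file + consensus map
#' into a directory.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param blast Logical; also simulate and write BLAST fixtures for the
#'   markers of the first chromosome.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_fixtures <- function(config, dir, blast = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cross(config)
  files <- c(genotypes = file.path(dir, "genotypes.txt"),
             truth = file.path(dir, "truth.txt"))
  write_genotype_table(sim$table, files[["genotypes"]])
  readr::write_tsv(sim$truth, files[["truth"]])
  if (blast) {
    anchors <- sim$truth |>
      dplyr::distinct(.data$marker, .keep_all = TRUE) |>
      dplyr::select("marker", "chromosome", "physical_pos")
    bl <- simulate_blast_hits(anchors, p_multi_consensus = 0.2,
                              p_no_consensus = 0.1, p_wide_span = 0.1,
                              p_no_hit = 0.05, seed = config$seed)
    files <- c(files, hits = file.path(dir, "hits.tsv"),
               consensus = file.path(dir, "consensus_map.txt"),
               anchor_truth = file.path(dir, "anchor_truth.txt"))
    readr::write_tsv(bl$hits[, setdiff(names(bl$hits), "strand")],
                     files[["hits"]], col_names = FALSE)
    readr::write_tsv(bl$consensus, files[["consensus"]])
    readr::write_tsv(bl$truth, files[["anchor_truth"]])
  }
  invisible(files)
}
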