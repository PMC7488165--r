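test_that("the same seed reproduces tables exactly; seeds differ otherwise", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 30,
                    het_rate = 0.1, failure_rate = 0.1, seed = 4)
  s1 <- simulate_cross(cfg)
  s2 <- simulate_cross(cfg)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cross(sim_config(n_chromosomes = 2,
                                  markers_per_chromosome = 30,
                                  het_rate = 0.1, failure_rate = 0.1,
                                  seed = 5))
  expect_false(identical(as.data.frame(s1$table),
                         as.data.frame(s3$table)))
})

test_that("the simulator does not disturb the global random stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cross(sim_config(n_chromosomes = 1,
                                      markers_per_chromosome = 10,
                                      seed = 99)))
  expect_identical(runif(1), before)
})

test_that("zero-noise truth marks exactly the planted donor-block markers", {
  blocks <- tibble::tibble(chromosome = "chr1", start = 2e8, end = 3e8)
  sim <- simulate_cross(sim_config("NIL", n_chromosomes = 2,
                                   markers_per_chromosome = 100,
                                   blocks = blocks,
                                   polymorphic_fraction = 1, seed = 10))
  inside <- sim$truth$chromosome == "chr1" &
    sim$truth$physical_pos >= 2e8 & sim$truth$physical_pos <= 3e8
  expect_true(all(sim$truth$status[inside] == "1_1"))
  expect_true(all(sim$truth$status[!inside] == "3_9"))
  expect_identical(sim$truth$in_block, inside)
  # and classification recovers the truth exactly
  a <- discriminate(sim$table, "IOI_1", n_parents = 3)
  expect_identical(a$status, sim$truth$status)
})

test_that("biparental schemes use two bound parents and 1_1/1_2 truth", {
  sim <- simulate_cross(sim_config("DH", n_chromosomes = 1,
                                   markers_per_chromosome = 50,
                                   polymorphic_fraction = 1, seed = 2))
  roles <- parent_roles(sim$table)
  expect_identical(unname(is.na(roles)), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(sim$truth$status %in% c("1_1", "1_2")))
  a <- discriminate(sim$table, "IOI_1", n_parents = 2)
  expect_identical(a$status, sim$truth$status)
})

test_that("full failure rate forces every truth status to 1_3", {
  sim <- simulate_cross(sim_config(n_chromosomes = 1,
                                   markers_per_chromosome = 20,
                                   failure_rate = 1, seed = 6))
  expect_true(all(sim$truth$status == "1_3"))
  a <- discriminate(sim$table, "IOI_1", n_parents = 3)
  expect_true(all(a$status == "1_3"))
  expect_true(all(a$filtered))
})

test_that("noisy calls deviate only to the heterozygous or failed cases", {
  sim <- simulate_cross(sim_config(n_chromosomes = 2,
                                   markers_per_chromosome = 100,
                                   het_rate = 0.2, failure_rate = 0.1,
                                   seed = 12))
  a <- discriminate(sim$table, "IOI_1", n_parents = 3)
  expect_identical(a$status, sim$truth$status)
  noisy <- sim$truth$status %in% c("1_4", "1_3")
  clean <- simulate_cross(sim_config(n_chromosomes = 2,
                                     markers_per_chromosome = 100,
                                     seed = 12))
  expect_identical(a$status[!noisy], clean$truth$status[!noisy])
})

test_that("genetic positions are a monotone compressed map of physical ones", {
  sim <- simulate_cross(sim_config(n_chromosomes = 1,
                                   markers_per_chromosome = 200,
                                   seed = 3))
  tab <- sim$table
  ord <- order(tab$physical_pos)
  expect_true(all(diff(tab$genetic_pos[ord]) >= 0))
  # centromeric compression: mid-chromosome cM/bp slope below telomeric
  L <- 6e8
  mid <- tab$physical_pos > 0.4 * L & tab$physical_pos < 0.6 * L
  tel <- tab$physical_pos < 0.2 * L
  slope <- function(sel) {
    p <- tab$physical_pos[sel]; g <- tab$genetic_pos[sel]
    (max(g) - min(g)) / (max(p) - min(p))
  }
  expect_lt(slope(mid), slope(tel))
})

test_that("blocks outside the chromosome extent are rejected", {
  expect_error(sim_config(blocks = tibble::tibble(
    chromosome = "chr1", start = -5, end = 100)), "within the chromosome")
  expect_error(sim_config(blocks = tibble::tibble(
    chromosome = "chr1", start = 10, end = 7e8)), "within the chromosome")
  expect_error(sim_config(het_rate = 1.2), "rates")
})

test_that("simulated BLAST hits reproduce their truth through the cascade", {
  anchors <- tibble::tibble(marker = sprintf("M%02d", 1:60),
                            chromosome = rep(paste0("chr", 1:3), 20),
                            physical_pos = seq(1e5, 6e6, length.out = 60))
  bl <- simulate_blast_hits(anchors, p_multi_consensus = 0.25,
                            p_no_consensus = 0.15, p_wide_span = 0.15,
                            p_no_hit = 0.1, seed = 17)
  res <- assign_physical_positions(bl$hits, consensus = bl$consensus,
                                   markers = anchors$marker)
  joined <- dplyr::left_join(bl$truth, res, by = "marker",
                             suffix = c("_truth", "_got"))
  expect_identical(joined$status_got, joined$status_truth)
  expect_identical(joined$physical_pos_got, joined$physical_pos_truth)
  # determinism
  bl2 <- simulate_blast_hits(anchors, p_multi_consensus = 0.25,
                             p_no_consensus = 0.15, p_wide_span = 0.15,
                             p_no_hit = 0.1, seed = 17)
  expect_identical(bl$hits, bl2$hits)
})

test_that("extreme hit-noise settings force their planted status", {
  anchors <- tibble::tibble(marker = paste0("M", 1:10),
                            chromosome = "chr1",
                            physical_pos = seq(1e5, 1e6, length.out = 10))
  clean <- simulate_blast_hits(anchors, seed = 1)
  expect_true(all(clean$truth$status == "ANCHORED_SINGLE_CHR"))
  expect_identical(clean$truth$physical_pos, anchors$physical_pos)
  wide <- simulate_blast_hits(anchors, p_wide_span = 1, span = 2e6,
                              seed = 1)
  res <- assign_physical_positions(wide$hits, markers = anchors$marker,
                                   max_span = 1e6)
  expect_true(all(res$status == "DISCARDED_SPAN"))
})

test_that("fixture writing produces consumable files", {
  dir <- tempfile()
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 20,
                    seed = 9)
  files <- write_sim_fixtures(cfg, dir, blast = TRUE)
  expect_true(all(file.exists(files)))
  tab <- read_genotype_table(files[["genotypes"]])
  expect_identical(nrow(tab), 40L)
  hits <- read_blast_tab(files[["hits"]])
  expect_true(nrow(hits) > 0)
})
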