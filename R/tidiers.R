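#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genotype table into long form
#'
#' One row per (marker, sample) call, with the call symbol and its
#' zygosity class.
#'
#' @param x A `genotype_table`.
#' @param ... Unused.
#' @return Tibble with columns `marker`, `chromosome`, `genetic_pos`,
#'   `physical_pos`, `sample`, `role`, `call`, `zygosity`.
#' @export
tidy.genotype_table <- function(x, ...) {
  samples <- sample_names(x)
  roles <- parent_roles(x)
  role_of <- stats::setNames(rep(NA_character_, length(samples)), samples)
  role_of[stats::na.omit(roles)] <- names(roles)[!is.na(roles)]
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("marker", "chromosome", "genetic_pos",
                             "physical_pos", samples)],
    cols = dplyr::all_of(samples), names_to = "sample",
    values_to = "call")
  long$role <- unname(role_of[long$sample])
  long$zygosity <- classify_call(long$call)
  long
}

#' One-row summary of a genotype table
#'
#' @param x A `genotype_table`.
#' @param ... Unused.
#' @return One-row tibble: marker, sample, chromosome and bound-parent
#'   counts, plus how many markers carry each position type.
#' @export
glance.genotype_table <- function(x, ...) {
  roles <- parent_roles(x)
  tibble::tibble(
    n_markers = nrow(x),
    n_samples = length(sample_names(x)),
    n_chromosomes = length(unique(x$chromosome)),
    n_parents_bound = sum(!is.na(roles)),
    n_genetic_pos = sum(!is.na(x$genetic_pos)),
    n_physical_pos = sum(!is.na(x$physical_pos)))
}

#' Tally case assignments per IOI and status
#'
#' @param x A `case_assignments` tibble from [discriminate()].
#' @param ... Unused.
#' @return Tibble with columns `ioi`, `status`, `n`, `filtered`.
#' @export
tidy.case_assignments <- function(x, ...) {
  dplyr::count(tibble::as_tibble(x), .data$ioi, .data$status,
               .data$filtered)
}

#' One-row summary of a discrimination run
#'
#' @param x A `case_assignments` tibble.
#' @param ... Unused.
#' @return One-row tibble with assignment, IOI, filtered and
#'   distinct-case counts.
#' @export
glance.case_assignments <- function(x, ...) {
  tibble::tibble(
    n_assignments = nrow(x),
    n_iois = length(unique(x$ioi)),
    n_filtered = sum(x$filtered),
    n_cases = length(intersect(unique(x$status), canonical_cases())))
}

#' One-row summary of an anchoring run
#'
#' @param x An `anchor_results` tibble.
#' @param ... Unused.
#' @return One-row tibble with the count of each disposition status.
#' @export
glance.anchor_results <- function(x, ...) {
  counts <- summarize_anchoring(x)
  tibble::as_tibble(as.list(counts))
}
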