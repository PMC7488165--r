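#' The eleven canonical allele-origin cases
#'
#' Case codes are written `x_y`, where `x` is the number of genotyped
#' parents at which the case first becomes detectable and `y` is the case
#' index. Cases detectable with fewer parents remain detectable with more.
#'
#' @return Character vector of the eleven canonical case codes.
#' @examples
#' canonical_cases()
#' @export
canonical_cases <- function() {
  c("1_1", "1_2", "1_3", "1_4", "1_5", "2_6",
    "3_7", "3_8", "3_9", "3_10", "4_11")
}

#' Human-readable description of each canonical case
#'
#' @return Named character vector, one description per canonical case code
#'   (plus the two non-case statuses).
#' @export
case_descriptions <- function() {
  c("1_1"  = "IOI-allele was derived from parent P1",
    "1_2"  = "IOI-allele was derived from parent P2",
    "1_3"  = "Analysis failed because of failed genotypic data",
    "1_4"  = "Allele in IOI is heterozygous",
    "1_5"  = "Allele in parent P1 is heterozygous",
    "2_6"  = "Allele in parent P2 is heterozygous",
    "3_7"  = "IOI-allele was derived from parent P3",
    "3_8"  = "Allele in recurrent parent P3 is heterozygous",
    "3_9"  = "IOI-allele was derived from parent P2 or P3",
    "3_10" = "IOI-allele was derived from parent P1 or P3",
    "4_11" = "Allele in parent P4 is heterozygous",
    "MONOMORPHIC"  = "Marker is monomorphic across IOI and parents",
    "UNCLASSIFIED" = "Allele pattern not covered by the canonical cases")
}

# Vectorised classifier core. `parents` is an n x k character matrix of
# canonical symbols (NA = failed), `ioi` a length-n vector. Returns a
# length-n status vector. The precedence is: failed > heterozygous parent
# (lowest index first) > heterozygous IOI > homozygous allele matching.
classify_rows <- function(parents, ioi, strict = TRUE) {
  k <- ncol(parents)
  n <- length(ioi)
  stopifnot(nrow(parents) == n, k >= 1L, k <= 4L)
  status <- rep(NA_character_, n)

  # (1) any failed call involved
  failed <- is.na(ioi) | rowSums(is.na(parents)) > 0L
  status[failed] <- "1_3"

  # (2) lowest-index heterozygous parent
  het_case <- c("1_5", "2_6", "3_8", "4_11")
  for (j in seq_len(k)) {
    sel <- is.na(status) & parents[, j] %in% het_symbols
    status[sel] <- het_case[j]
  }

  # (3) heterozygous IOI
  status[is.na(status) & ioi %in% het_symbols] <- "1_4"

  # (4) all calls homozygous: match set S of parents sharing the IOI allele
  rem <- which(is.na(status))
  if (length(rem)) {
    m <- parents[rem, , drop = FALSE] == ioi[rem]
    mask <- as.integer(m %*% 2^(seq_len(k) - 1L))
    full <- 2L^k - 1L
    s <- rep(NA_character_, length(rem))
    if (k == 1L) {
      # a lone match is attributed to P1; a mismatch to the ungenotyped P2
      s[mask == 1L] <- "1_1"
      s[mask == 0L] <- "1_2"
    } else {
      s[mask == full] <- "MONOMORPHIC"
      s[is.na(s) & mask == 1L] <- "1_1"                  # S = {P1}
      s[is.na(s) & mask == 2L] <- "1_2"                  # S = {P2}
      if (k >= 3L) {
        s[is.na(s) & mask == 4L] <- "3_7"                # S = {P3}
        s[is.na(s) & mask == 6L] <- "3_9"                # S = {P2,P3}
        s[is.na(s) & mask == 5L] <- "3_10"               # S = {P1,P3}
      }
      other <- is.na(s)
      if (any(other)) {
        if (strict) {
          s[other] <- "UNCLASSIFIED"
        } else {
          s[other] <- vapply(mask[other], function(b) {
            idx <- which(bitwAnd(b, 2^(seq_len(k) - 1L)) > 0L)
            if (!length(idx)) "ext_none"
            else paste0("ext_", paste0("P", idx, collapse = ""))
          }, character(1))
        }
      }
    }
    status[rem] <- s
  }
  status
}

#' Classify the origin of one marker allele in an individual of interest
#'
#' Compares the genotype of the individual of interest (IOI) with the
#' genotypes of its one to four parents and returns the allele-origin
#' status: a canonical case code (see [canonical_cases()]),
#' `"MONOMORPHIC"`, or `"UNCLASSIFIED"`. The decision is total and
#' deterministic, with precedence failed call > heterozygous parent
#' (lowest parent index first) > heterozygous IOI > homozygous allele
#' matching.
#'
#' With a single genotyped parent, an IOI allele that differs from P1 is
#' attributed to the ungenotyped second parent (case `1_2`), and a match
#' is case `1_1`; monomorphism cannot be established with one parent.
#' With two or more parents, an allele shared by every parent is
#' `"MONOMORPHIC"`. In strict mode (default) parent match sets outside
#' the canonical taxonomy return `"UNCLASSIFIED"`; with `strict = FALSE`
#' they return extension labels such as `"ext_P1P2"`.
#'
#' @param parent_calls Character vector of 1 to 4 parent call symbols
#'   (P1 first).
#' @param ioi_call Single call symbol for the individual of interest.
#' @param strict Logical; restrict output to the canonical taxonomy
#'   (default `TRUE`).
#' @return A single status string.
#' @examples
#' classify_marker(c("A"), "A")            # "1_1"
#' classify_marker(c("T", "T", "A"), "A")  # "3_7"
#' classify_marker(c("A", "A"), "A")       # "MONOMORPHIC"
#' @export
classify_marker <- function(parent_calls, ioi_call, strict = TRUE) {
  if (length(parent_calls) < 1L || length(parent_calls) > 4L) {
    stop("between 1 and 4 parent calls are required, got ",
         length(parent_calls), call. = FALSE)
  }
  if (length(ioi_call) != 1L) {
    stop("`ioi_call` must be a single call symbol", call. = FALSE)
  }
  p <- matrix(normalize_call(parent_calls), nrow = 1L)
  classify_rows(p, normalize_call(ioi_call), strict = strict)
}

#' Enumerate the canonical cases reachable with a given number of parents
#'
#' Exhaustively classifies every combination of call symbols (four
#' homozygote bases, six IUPAC heterozygote codes, and the failed state)
#' across `n_parents` parents and the IOI, and returns the set of
#' canonical case codes that occur. The sizes are 5, 6, 10 and 11 for
#' one to four parents.
#'
#' @param n_parents Integer between 1 and 4.
#' @param strict Logical; see [classify_marker()].
#' @return Character vector of reachable canonical case codes, in
#'   canonical order.
#' @examples
#' enumerate_cases(1)
#' length(enumerate_cases(4))  # 11
#' @export
enumerate_cases <- function(n_parents, strict = TRUE) {
  if (length(n_parents) != 1L || is.na(n_parents) ||
      n_parents < 1 || n_parents > 4) {
    stop("`n_parents` must be between 1 and 4", call. = FALSE)
  }
  n_parents <- as.integer(n_parents)
  alphabet <- c(hom_symbols, het_symbols, NA_character_)
  grid <- expand.grid(rep(list(alphabet), n_parents + 1L),
                      stringsAsFactors = FALSE)
  parents <- as.matrix(grid[, seq_len(n_parents), drop = FALSE])
  ioi <- grid[[n_parents + 1L]]
  status <- classify_rows(parents, ioi, strict = strict)
  canon <- canonical_cases()
  canon[canon %in% unique(status)]
}

#' Classify every marker of a genotype table for one or more IOIs
#'
#' Runs the allele-origin classification of [classify_marker()] across
#' all markers of a genotype table for each named individual of interest
#' (IOI), against the first `n_parents` bound parent roles. Results for
#' distinct IOIs are independent: a multi-IOI run equals the
#' concatenation of the single-IOI runs.
#'
#' By default, failed (`1_3`) and monomorphic markers are flagged as
#' filtered (column `filtered`), mirroring the default exclusion of
#' uninformative data; they remain in the output so nothing is silently
#' dropped. Use `drop_filtered = TRUE` to remove them.
#'
#' @param table A `genotype_table` (see [read_genotype_table()]).
#' @param ioi Character vector of sample names to classify (each treated
#'   independently).
#' @param n_parents Number of parents to use (1-4); defaults to the
#'   number of bound parent roles.
#' @param strict Logical; see [classify_marker()].
#' @param filter_failed,filter_monomorphic Logical; mark `1_3` /
#'   monomorphic assignments as filtered (default `TRUE`).
#' @param drop_filtered Logical; drop filtered assignments from the
#'   result instead of flagging them (default `FALSE`).
#' @return A tibble of class `case_assignments` with columns
#'   `marker`, `chromosome`, `genetic_pos`, `physical_pos`, `ioi`,
#'   `status`, `filtered`.
#' @examples
#' tab <- simulate_cross(sim_config(seed = 1))$table
#' discriminate(tab, ioi = sample_names(tab)[5], n_parents = 3)
#' @export
discriminate <- function(table, ioi, n_parents = NULL, strict = TRUE,
                         filter_failed = TRUE, filter_monomorphic = TRUE,
                         drop_filtered = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  samples <- sample_names(table)
  unknown <- setdiff(ioi, samples)
  if (length(unknown)) {
    stop("unknown IOI sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  roles <- parent_roles(table)
  bound <- names(roles)[!is.na(roles)]
  if (is.null(n_parents)) n_parents <- length(bound)
  if (n_parents < 1 || n_parents > 4) {
    stop("`n_parents` must be between 1 and 4", call. = FALSE)
  }
  need <- paste0("P", seq_len(n_parents))
  if (!all(need %in% bound)) {
    stop("parent role(s) not bound in the table: ",
         paste(setdiff(need, bound), collapse = ", "), call. = FALSE)
  }
  pmat <- as.matrix(as.data.frame(table)[, roles[need], drop = FALSE])
  out <- purrr::map(ioi, function(s) {
    status <- classify_rows(pmat, table[[s]], strict = strict)
    tibble::tibble(
      marker = table$marker,
      chromosome = table$chromosome,
      genetic_pos = table$genetic_pos,
      physical_pos = table$physical_pos,
      ioi = s,
      status = status,
      filtered = (filter_failed & status == "1_3") |
        (filter_monomorphic & status == "MONOMORPHIC")
    )
  })
  out <- dplyr::bind_rows(out)
  if (drop_filtered) out <- dplyr::filter(out, !.data$filtered)
  class(out) <- c("case_assignments", class(out))
  out
}

#' Keep only assignments with a wanted case code
#'
#' @param assignments A `case_assignments` tibble from [discriminate()].
#' @param wanted Character vector of status codes to keep (canonical case
#'   codes, `"MONOMORPHIC"` or `"UNCLASSIFIED"`).
#' @return The subset of `assignments` whose status is in `wanted`,
#'   original order preserved.
#' @examples
#' tab <- simulate_cross(sim_config(seed = 1))$table
#' a <- discriminate(tab, ioi = sample_names(tab)[5], n_parents = 3)
#' filter_by_case(a, "1_1")
#' @export
filter_by_case <- function(assignments, wanted) {
  known <- c(canonical_cases(), "MONOMORPHIC", "UNCLASSIFIED")
  bad <- setdiff(wanted, known)
  if (length(bad)) {
    stop("unknown case code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- assignments[assignments$status %in% wanted, , drop = FALSE]
  out
}

#' Keep putatively informative markers
#'
#' A marker is putatively informative for a set of samples if (a) none of
#' the listed samples has a failed call at it, (b) it is not monomorphic
#' across them, and (c) it carries at least one genetic or physical
#' position.
#'
#' @param table A `genotype_table`.
#' @param samples Character vector of sample names to assess.
#' @return The `genotype_table` restricted to informative markers.
#' @export
filter_informative <- function(table, samples) {
  stopifnot(inherits(table, "genotype_table"))
  unknown <- setdiff(samples, sample_names(table))
  if (length(unknown)) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  calls <- as.matrix(as.data.frame(table)[, samples, drop = FALSE])
  no_fail <- rowSums(is.na(calls)) == 0L
  n_distinct <- apply(calls, 1L, function(r) length(unique(r[!is.na(r)])))
  polymorphic <- n_distinct > 1L
  positioned <- !is.na(table$genetic_pos) | !is.na(table$physical_pos)
  keep <- no_fail & polymorphic & positioned
  subset_markers(table, keep)
}
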