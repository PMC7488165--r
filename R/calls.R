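#' Genotype call symbols
#'
#' Genotype calls are single-character symbols: `A`, `C`, `G`, `T` for a
#' homozygote, the six IUPAC two-base ambiguity codes `M`, `R`, `W`, `S`,
#' `Y`, `K` for a heterozygote, and a missing/failed token for calls that
#' produced no usable signal. Several missing spellings are accepted on
#' input (`"NA"`, `"-"`, `"f"`, `"N"`, and the empty string); they are all
#' normalised to one failed state, represented internally as `NA` and
#' written back out as the literal token `"NA"`.
#'
#' @name genotype-calls
#' @keywords internal
NULL

hom_symbols <- c("A", "C", "G", "T")
het_symbols <- c("M", "R", "W", "S", "Y", "K")
missing_tokens <- c("NA", "-", "F", "N", "")

#' Normalise genotype call symbols
#'
#' Upper-cases symbols, maps every accepted missing/failed spelling
#' (`"NA"`, `"-"`, `"f"`, `"N"`, `""`) to `NA`, and rejects anything that
#' is neither a homozygote base, an IUPAC heterozygote code, nor a missing
#' token.
#'
#' @param x Character vector of raw call symbols.
#' @return Character vector of canonical upper-case symbols with `NA` for
#'   failed/missing calls.
#' @examples
#' normalize_call(c("a", "t", "m", "na", "-", "f"))
#' @export
normalize_call <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% missing_tokens] <- NA_character_
  bad <- !is.na(x) & !(x %in% c(hom_symbols, het_symbols))
  if (any(bad)) {
    stop("unknown genotype symbol(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Classify a call symbol as homozygous, heterozygous or failed
#'
#' @param x Character vector of call symbols (raw or canonical).
#' @return Character vector with values `"HOM"`, `"HET"` or `"FAILED"`.
#' @examples
#' classify_call(c("A", "W", "NA"))
#' @export
classify_call <- function(x) {
  x <- normalize_call(x)
  out <- rep("FAILED", length(x))
  out[x %in% hom_symbols] <- "HOM"
  out[x %in% het_symbols] <- "HET"
  out
}
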