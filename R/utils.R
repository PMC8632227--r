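#' @importFrom methods is
#' @importFrom stats rbinom rpois runif setNames median complete.cases
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a package error
#'
#' User-facing errors (bad inputs, infeasible configuration) carry class
#' `imr_user_error`; internal invariant violations carry `imr_internal_error`.
#' @noRd
imr_stop <- function(msg, class = "imr_user_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "imr_error", "error", "condition")))
}

#' Reverse complement of character DNA sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement (no reversal) of single bases given as characters
#' @noRd
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Numeric part of a chromosome name ("Chr5" -> 5)
#' @noRd
chrom_number <- function(chrom) {
  n <- suppressWarnings(as.integer(gsub("\\D", "", chrom)))
  ifelse(is.na(n), match(chrom, unique(chrom)), n)
}

#' Random DNA string(s) at a target GC content
#' @noRd
random_dna <- function(n, gc = 0.46) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' GC fraction of character sequences
#' @noRd
gc_fraction <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Percentage of a part in a whole
#'
#' Convenience for the proportion statistics reported throughout
#' (heterozygosity, genic/intronic/splice fractions, homozygous-InDel
#' share): `100 * n_part / n_total`.
#'
#' @param n_part count in the category of interest
#' @param n_total total count
#' @return percentage in `[0, 100]`
#' @examples
#' count_percent(97833, 865781) # genic share of homozygous SNPs
#' @export
count_percent <- function(n_part, n_total) {
  stopifnot(n_total > 0, n_part >= 0, n_part <= n_total)
  100 * n_part / n_total
}
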