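#' @import data.table
#' @importFrom stats cor rnorm runif sd setNames
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "band", "chrom", "pos", "strand", "fragment", "weight",
  "raw", "per_kb", "start", "end", "seq_", "n_src", "J", "state", "NO",
  "k", "strain", "rS", "p_value", "mode"
))

#' Reverse complement of nucleotide strings
#'
#' Vectorized reverse complement over the alphabet `{A,C,G,T,N}`.
#'
#' @param x character vector of uppercase nucleotide strings.
#' @return character vector of the same length.
#' @examples
#' revcomp("GAATTC")  # "GAATTC" (palindrome)
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all k-length windows of a single sequence string, as a character vector;
# 0-based window starts are seq_along(result) - 1
sliding_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fread wrapper skipping leading '#' comment lines (e.g. the provenance
# header the CLI prepends to its outputs)
fread_skip_comments <- function(path, ...) {
  first <- readLines(path, n = 50L, warn = FALSE)
  n_skip <- match(FALSE, startsWith(first, "#"), nomatch = length(first) + 1L) - 1L
  data.table::fread(path, skip = n_skip, ...)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
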