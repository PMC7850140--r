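#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head tail
NULL

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred vector from a SAM/FASTQ quality string (offset 33).
phred_vector <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

# SAM flag bit helper (vectorized).
flag_bit <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

# Substring k-mers of a single sequence.
kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Canonical SV call table schema. All calls flowing through the package use
# these columns; constructors fill what they know and as_calls() pads the rest.
call_schema <- function() {
  list(chrom = NA_character_, pos = NA_integer_, svtype = NA_character_,
       size = NA_integer_, end = NA_integer_, support = NA_integer_,
       evidence = NA_character_, imprecise = NA,
       partner_chrom = NA_character_, partner_pos = NA_integer_,
       id = NA_character_, mate_id = NA_character_,
       inserted_seq = NA_character_)
}

#' Canonical SV call tables
#'
#' Every call set flowing through the package is a plain data.frame with a
#' fixed column set: chrom, pos, svtype (DEL/INS/INV/TRA), size (NA when
#' unresolved), end, support, evidence, imprecise, partner_chrom,
#' partner_pos, id, mate_id, inserted_seq. \code{as_calls} pads a partial
#' frame onto that schema; \code{empty_calls} returns the zero-row table.
#'
#' @return A canonical call data.frame.
#' @export
empty_calls <- function() {
  s <- call_schema()
  as.data.frame(lapply(s, function(x) x[0]), stringsAsFactors = FALSE)
}

#' @rdname empty_calls
#' @param df data.frame holding any subset of the canonical columns.
#' @export
as_calls <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(empty_calls())
  s <- call_schema()
  for (col in names(s)) {
    if (!col %in% names(df)) df[[col]] <- rep(s[[col]], nrow(df))
  }
  df <- df[, names(s)]
  for (col in c("pos", "size", "end", "support", "partner_pos")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$imprecise <- as.logical(df$imprecise) & !is.na(df$imprecise)
  rownames(df) <- NULL
  df
}

sort_calls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  calls <- calls[order(calls$chrom, calls$pos, calls$svtype,
                       ifelse(is.na(calls$size), 0L, calls$size)), ]
  rownames(calls) <- NULL
  calls
}
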