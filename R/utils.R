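#' @useDynLib bsmapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide sequences
#'
#' Standard Watson-Crick complement (with `N` mapped to `N`), reversed.
#' The operation is an involution: `reverse_complement(reverse_complement(x))`
#' returns `x`.
#'
#' @param x character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## CIGAR helpers -------------------------------------------------------------

parse_cigar <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDS]", cigar)[[1]]
  if (ops[1] == -1) stop("malformed CIGAR string '", cigar, "'")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string '", cigar, "'")
  data.frame(
    len = as.integer(sub("[MIDS]$", "", toks)),
    op = sub("^[0-9]+", "", toks),
    stringsAsFactors = FALSE
  )
}

cigar_query_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I", "S")])
}

cigar_ref_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "D")])
}

## Recompute an alignment score from its edit script under a scoring scheme.
## Soft-clipped bases are free; each gap run costs open + (k - 1) * extend.
score_from_cigar <- function(read, ref_seq, start, cigar, params) {
  p <- parse_cigar(cigar)
  qp <- 1L
  rp <- start + 1L
  score <- 0L
  for (k in seq_len(nrow(p))) {
    n <- p$len[k]
    op <- p$op[k]
    if (op == "M") {
      a <- substring(read, qp, qp + n - 1L)
      b <- substring(ref_seq, rp, rp + n - 1L)
      av <- strsplit(a, "", fixed = TRUE)[[1]]
      bv <- strsplit(b, "", fixed = TRUE)[[1]]
      match <- av == bv & av != "N"
      score <- score + sum(match) * params$match + sum(!match) * params$mismatch
      qp <- qp + n
      rp <- rp + n
    } else if (op == "I") {
      score <- score + params$gap_open + (n - 1L) * params$gap_extend
      qp <- qp + n
    } else if (op == "D") {
      score <- score + params$gap_open + (n - 1L) * params$gap_extend
      rp <- rp + n
    } else if (op == "S") {
      qp <- qp + n
    }
  }
  score
}

log_msg <- function(..., verbose = TRUE) {
  if (verbose) message("[bsmapr] ", ...)
}
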