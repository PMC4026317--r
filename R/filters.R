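# Post-processing of 3-letter hits: recount differences in the original
# 4-letter alphabet with asymmetric bisulfite matching, drop false positives
# (diff4 > max_diff), and resolve per-read ambiguity.

#' Asymmetric 4-letter difference count
#'
#' Walks the edit script over the original (unconverted) read and genome.
#' An aligned column is a match when the bases are equal, or when the read
#' has `T` over a genome `C` (C2T space), or the read has `A` over a genome
#' `G` (G2A space) -- the bisulfite-induced asymmetry. Every other aligned
#' pair is a substitution; each inserted or deleted base counts 1;
#' soft-clipped bases count 0; `N` never matches. For hits from
#' reverse-complemented query sets the read must be supplied as aligned
#' (reverse-complemented) against the Watson-forward genome.
#'
#' @param read character vector: the query exactly as aligned, 4-letter.
#' @param genome a [bs_genome] (unconverted).
#' @param name,start,cigar per-hit reference sequence, 0-based start and
#'   CIGAR (`M/I/D/S`).
#' @param space `"C2T"` or `"G2A"` (the pass's conversion space); recycled.
#' @return integer vector of difference counts.
#' @examples
#' g <- bs_genome(c(chr = "CTGT"))
#' count_differences_4letter("TTGT", g, "chr", 0L, "4M", "C2T")  # 0
#' @export
count_differences_4letter <- function(read, genome, name, start, cigar, space) {
  stopifnot(inherits(genome, "bs_genome"))
  n <- max(length(read), length(name), length(start), length(cigar))
  read <- rep_len(read, n); name <- rep_len(name, n)
  start <- rep_len(as.integer(start), n); cigar <- rep_len(cigar, n)
  space <- rep_len(space, n)
  if (!all(space %in% c("C2T", "G2A"))) stop("space must be 'C2T' or 'G2A'")
  ridx <- match(name, names(genome$sequences))
  if (anyNA(ridx)) stop("unknown reference sequence: ", name[is.na(ridx)][1])
  cpp_count_diff4(read, unname(genome$sequences), ridx, start, cigar,
                  space == "C2T")
}

#' Validate hits in 4-letter space
#'
#' Adds the asymmetric 4-letter difference count (`diff4`) and the validity
#' flag `valid = (diff4 <= max_diff)` to a hit table. Invalid hits are the
#' false positives of the 3-letter strategy and are excluded from read
#' resolution.
#'
#' @param hits hit table from [align_pass()] / [run_mapping()] with a `pass`
#'   column.
#' @param reads_aligned character vector of 4-letter queries as aligned,
#'   parallel to `hits` rows.
#' @param genome unconverted [bs_genome].
#' @param space per-hit conversion space (`"C2T"`/`"G2A"`).
#' @param max_diff validity threshold (inclusive).
#' @return `hits` with added `diff4` and `valid` columns.
#' @export
validate_hits <- function(hits, reads_aligned, genome, space, max_diff) {
  if (nrow(hits) == 0) {
    hits$diff4 <- integer(0); hits$valid <- logical(0)
    return(hits)
  }
  hits$diff4 <- count_differences_4letter(reads_aligned, genome, hits$name,
                                          hits$start, hits$cigar, space)
  hits$valid <- hits$diff4 <= max_diff
  hits
}

#' Resolve one read from its validated hits
#'
#' The best score `b` is the maximum over all valid hits. A read is
#' *ambiguous* iff (i) hits achieving `b` exist in at least two distinct
#' passes, or (ii) at least two hits achieve `b` within a single pass.
#' Otherwise the single best hit (ties in score broken by fewer `diff4`,
#' then sequence name, start, pass -- deterministic) makes the read
#' unique-best. Ambiguous reads are dropped unless `keep_ambiguous`.
#'
#' @param hits validated hits of one read across passes (rows with
#'   `valid == FALSE` are ignored); must carry `pass`, `score`, `diff4`.
#' @param report_policy `"unique-best"`, `"all-best"` or `"all-valid"`.
#' @param keep_ambiguous keep the best hit of ambiguous reads (reported with
#'   their ambiguity rule) instead of dropping them.
#' @return list with `status` (`unique-best`, `ambiguous`, `filtered`,
#'   `unmapped`), `rule` (`NA`, `"i"` or `"ii"`), `chosen` (one-row hit or
#'   `NULL`), `n_best`, and `retained` (hit table per the report policy).
#' @export
resolve_read <- function(hits, report_policy = "unique-best",
                         keep_ambiguous = FALSE) {
  had_any <- nrow(hits) > 0
  if (had_any && !is.null(hits$valid)) hits <- hits[hits$valid, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(status = if (had_any) "filtered" else "unmapped",
                rule = NA_character_, chosen = NULL, n_best = 0L,
                retained = hits))
  }
  ord <- order(-hits$score, hits$diff4, hits$name, hits$start, hits$pass)
  hits <- hits[ord, , drop = FALSE]
  b <- hits$score[1]
  best <- hits[hits$score == b, , drop = FALSE]
  n_best <- nrow(best)
  rule <- NA_character_
  if (length(unique(best$pass)) >= 2) rule <- "i"
  else if (n_best >= 2) rule <- "ii"
  retained <- switch(report_policy,
                     "unique-best" = hits[1, , drop = FALSE],
                     "all-best" = best,
                     "all-valid" = hits)
  if (!is.na(rule)) {
    list(status = "ambiguous", rule = rule,
         chosen = if (keep_ambiguous) hits[1, , drop = FALSE] else NULL,
         n_best = n_best, retained = retained)
  } else {
    list(status = "unique-best", rule = rule, chosen = hits[1, , drop = FALSE],
         n_best = n_best, retained = retained)
  }
}
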