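# 3-letter-space alignment engine: exhaustive ungapped search, two-step
# gapped end-to-end alignment, and seeded local alignment. The search is
# complete: ungapped mode scans every window (no heuristic misses), and the
# gapped modes seed with max_diff + 1 non-overlapping exact pieces, which by
# the pigeonhole principle guarantees an intact seed for any alignment with
# at most max_diff differences; every seed hit is verified by banded dynamic
# programming.

#' Alignment parameters
#'
#' @param max_diff maximum number of differences (substitutions plus inserted
#'   and deleted bases) allowed after validation in the original 4-letter
#'   alphabet (the CLI's `-m` flag). Boundary inclusive: `diff4 <= max_diff`
#'   is valid.
#' @param mode `"ungapped"` (complete Hamming scan), `"e2e"` (two-step gapped
#'   end-to-end: ungapped first step, banded dynamic programming for reads
#'   unresolved there) or `"local"` (seeded Smith-Waterman with soft-clipped
#'   ends). Default `"local"`.
#' @param step1_mm 3-letter mismatches allowed in the ungapped step.
#'   Defaults: `min(max_diff, 4)` for ungapped mode (at most four mismatches
#'   are searched in 3-letter space), `0` for the first step of the gapped
#'   modes.
#' @param max_hits hit cap per read (applied per pass after best-score
#'   sorting, then re-applied after merging passes); `Inf` disables the cap.
#'   The CLI's `-l` flag; default 2.
#' @param report_policy which hits to retain alongside the per-read status:
#'   `"unique-best"`, `"all-best"` or `"all-valid"`.
#' @param match,mismatch,gap_open,gap_extend integer alignment scores;
#'   `match > 0 > mismatch` and `gap_open <= gap_extend < 0`. A gap of length
#'   k costs `gap_open + (k - 1) * gap_extend`.
#' @param dp_trigger fraction of the perfect score (`length * match`) a
#'   dynamic-programming alignment must reach to be reported; default 0.3.
#' @param band_width half-width of the reference window around a seed anchor
#'   diagonal; default `2 * max_diff + 1`.
#' @param max_clip_frac local mode only: maximum fraction of the read that
#'   may be soft-clipped (default 0.5).
#' @param min_seed minimum seed length in bp for the gapped modes.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(max_diff = 5L,
                             mode = c("local", "ungapped", "e2e"),
                             step1_mm = NULL,
                             max_hits = 2L,
                             report_policy = c("unique-best", "all-best",
                                               "all-valid"),
                             match = 1L, mismatch = -2L,
                             gap_open = -3L, gap_extend = -1L,
                             dp_trigger = 0.3,
                             band_width = NULL,
                             max_clip_frac = 0.5,
                             min_seed = 8L) {
  mode <- match.arg(mode)
  report_policy <- match.arg(report_policy)
  max_diff <- as.integer(max_diff)
  if (is.na(max_diff) || max_diff < 0) stop("max_diff must be >= 0")
  if (is.null(step1_mm))
    step1_mm <- if (mode == "ungapped") min(max_diff, 4L) else 0L
  step1_mm <- as.integer(step1_mm)
  if (step1_mm < 0 || step1_mm > 4)
    stop("step1_mm must be in 0..4 (at most four 3-letter mismatches are searched)")
  if (!(match > 0 && mismatch < 0)) stop("scores must satisfy match > 0 > mismatch")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("scores must satisfy gap_open <= gap_extend < 0")
  if (!is.infinite(max_hits)) {
    max_hits <- as.integer(max_hits)
    if (is.na(max_hits) || max_hits < 1) stop("max_hits must be >= 1 or Inf")
  }
  band_width <- as.integer(band_width %||% (2L * max_diff + 1L))
  structure(
    list(max_diff = max_diff, mode = mode, step1_mm = step1_mm,
         max_hits = max_hits, report_policy = report_policy,
         match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         dp_trigger = dp_trigger, band_width = band_width,
         max_clip_frac = max_clip_frac, min_seed = as.integer(min_seed)),
    class = "alignment_params"
  )
}

ref_sequences <- function(ref3) {
  if (inherits(ref3, "bs_converted_genome")) ref3$sequences
  else if (is.character(ref3)) {
    if (is.null(names(ref3))) names(ref3) <- paste0("seq", seq_along(ref3))
    ref3
  } else stop("ref3 must be a bs_converted_genome or a named character vector")
}

empty_hits <- function() {
  data.frame(qidx = integer(0), name = character(0), start = integer(0),
             cigar = character(0), mm3 = integer(0), gaps = integer(0),
             score = integer(0), stringsAsFactors = FALSE)
}

#' Complete ungapped search
#'
#' Returns every position where the Hamming distance (with `N` never
#' matching) between the query and a reference window is at most `max_mm`.
#' The scan is exhaustive; there are provably no heuristic misses.
#'
#' @param query3 a single converted read.
#' @param ref3 a converted genome ([convert_genome()]) or named character
#'   vector of converted sequences.
#' @param max_mm maximum 3-letter mismatches, at most 4.
#' @return data.frame with columns `name`, `start` (0-based), `mm3`.
#' @export
find_ungapped <- function(query3, ref3, max_mm) {
  stopifnot(length(query3) == 1, max_mm >= 0)
  if (max_mm > 4) stop("max_mm must be <= 4")
  seqs <- ref_sequences(ref3)
  res <- cpp_align_batch(query3, unname(seqs), 0L, as.integer(max_mm), 0L,
                         1L, -2L, -3L, -1L, 0, 0L, 0L, 1L, 8L, 0.5)
  data.frame(name = names(seqs)[res$ref], start = res$start, mm3 = res$mm3,
             stringsAsFactors = FALSE)
}

#' Banded end-to-end alignment at an anchor
#'
#' Optimal semi-global alignment of the full query within a reference window
#' of `band_width` margin around the anchor diagonal, under the affine-gap
#' scoring in `params`. Indels are left-aligned. Returned only if the score
#' reaches the dynamic-programming trigger.
#'
#' @param query3 converted read.
#' @param ref3 converted genome or named character vector.
#' @param name,anchor reference sequence name and anchored 0-based start.
#' @param params [alignment_params()].
#' @return one-row hit data.frame (`name`, `start`, `cigar`, `mm3`, `gaps`,
#'   `score`), or `NULL` when no alignment reaches the trigger.
#' @export
align_global_banded <- function(query3, ref3, name, anchor, params) {
  seqs <- ref_sequences(ref3)
  if (!name %in% names(seqs)) stop("unknown reference sequence: ", name)
  G <- nchar(seqs[[name]])
  L <- nchar(query3)
  ws <- max(0L, anchor - params$band_width)
  we <- min(G, anchor + L + params$band_width)
  if (we - ws < 1) return(NULL)
  d <- cpp_dp_window(query3, substring(seqs[[name]], ws + 1L, we),
                     params$match, params$mismatch, params$gap_open,
                     params$gap_extend, FALSE)
  if (!isTRUE(d$found) || d$score < params$dp_trigger * L * params$match)
    return(NULL)
  data.frame(name = name, start = ws + d$ref_start, cigar = d$cigar,
             mm3 = d$mm3, gaps = d$gaps, score = d$score,
             stringsAsFactors = FALSE)
}

#' Seeded local alignment
#'
#' Best local (soft-clipped) alignments of the query in 3-letter space.
#' Soft-clipped bases are excluded from the mismatch count and from the
#' score; hits clipping more than `max_clip_frac` of the read, or scoring
#' below the trigger, are discarded.
#'
#' @inheritParams align_global_banded
#' @return hit data.frame (possibly empty).
#' @export
align_local <- function(query3, ref3, params) {
  seqs <- ref_sequences(ref3)
  p <- params
  res <- cpp_align_batch(query3, unname(seqs), 2L, p$max_diff, p$step1_mm,
                         p$match, p$mismatch, p$gap_open, p$gap_extend,
                         p$dp_trigger, p$band_width,
                         if (is.infinite(p$max_hits)) 0L else p$max_hits,
                         p$max_diff + 1L, p$min_seed, p$max_clip_frac)
  data.frame(name = names(seqs)[res$ref], start = res$start,
             cigar = res$cigar, mm3 = res$mm3, gaps = res$gaps,
             score = res$score, stringsAsFactors = FALSE)
}

#' Align a set of converted queries against a converted genome
#'
#' Dispatches on `params$mode`: `ungapped` runs the complete Hamming scan at
#' `step1_mm` mismatches; `e2e` runs the ungapped step first and banded
#' end-to-end dynamic programming for reads without any step-1 hit; `local`
#' runs seeded local alignment. Hits are sorted best-score-first (ties by
#' fewer mismatches, then sequence, start, edit script) and truncated to
#' `max_hits`; truncated query indices are recorded in the `"truncated"`
#' attribute. Queries are aligned in forward orientation only: the mapping
#' orchestrator supplies reverse-complemented query sets.
#'
#' @param queries3 character vector of converted reads.
#' @param ref3 a [convert_genome()] result.
#' @param params [alignment_params()].
#' @return data.frame with columns `qidx`, `name`, `start`, `cigar`, `mm3`,
#'   `gaps`, `score` and attribute `truncated`.
#' @export
align_pass <- function(queries3, ref3, params) {
  stopifnot(inherits(params, "alignment_params"))
  if (inherits(ref3, "bs_converted_genome")) {
    banned <- if (ref3$mode == "C2T") "C" else "G"
    if (any(grepl(banned, queries3, fixed = TRUE)))
      stop("conversion-mode mismatch: queries contain '", banned,
           "' but reference is ", ref3$mode, "-converted")
  }
  seqs <- ref_sequences(ref3)
  mode_code <- c(ungapped = 0L, e2e = 1L, local = 2L)[[params$mode]]
  p <- params
  res <- cpp_align_batch(queries3, unname(seqs), mode_code,
                         p$step1_mm, p$step1_mm,
                         p$match, p$mismatch, p$gap_open, p$gap_extend,
                         if (mode_code == 0L) 0 else p$dp_trigger,
                         p$band_width,
                         if (is.infinite(p$max_hits)) 0L else p$max_hits,
                         p$max_diff + 1L, p$min_seed, p$max_clip_frac)
  out <- data.frame(qidx = res$qidx, name = names(seqs)[res$ref],
                    start = res$start, cigar = res$cigar, mm3 = res$mm3,
                    gaps = res$gaps, score = res$score,
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- res$truncated
  out
}
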