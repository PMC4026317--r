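# End-to-end mapping pipeline: conversion, two/four passes, 4-letter
# validation, ambiguity resolution, per-read outcomes and filter statistics.

#' Map bisulfite-treated reads against a reference genome
#'
#' Runs the full pipeline: builds the C->T and G->A converted genomes
#' (RRBS-masked when a digestion spec is given), aligns the converted reads
#' in two (directional) or four (non-directional) passes in 3-letter space,
#' recounts differences in the original 4-letter alphabet with the
#' asymmetric bisulfite rule, removes false positives (`diff4 > max_diff`)
#' and resolves each read to unique-best / ambiguous / filtered / unmapped.
#'
#' @param reads data.frame with columns `id`, `seq` (optionally `qual`), a
#'   named character vector, or a [read_fastq()] result.
#' @param genome a [bs_genome].
#' @param params [alignment_params()].
#' @param library_type `"directional"` (passes 1-2, classes `+FW`/`-FW`) or
#'   `"non-directional"` (passes 1-4, all four classes).
#' @param digestion optional [parse_digestion_site()] spec; when given, the
#'   genome is digested in silico and fragments outside the size-selection
#'   window are masked before alignment (RRBS mode).
#' @param keep_ambiguous keep the best hit of ambiguous reads (reported with
#'   mapping quality 0 in SAM) instead of dropping them.
#' @param verbose log filter statistics to standard error.
#' @return an object of class `bs_mapping`: list with elements
#'   \describe{
#'     \item{reads}{per-read outcome table: `id`, `status`, `class`, `chrom`,
#'       `start` (0-based), `cigar`, `mm3`, `diff4`, `gaps`, `score`, `pass`,
#'       `rule`, `n_best`, `reason`.}
#'     \item{hits}{retained hits per the report policy (with `qid` column),
#'       re-capped at `max_hits` after merging passes.}
#'     \item{stats}{filter statistics (input, rejected, too_many_n, unmapped,
#'       filtered, ambiguous_rule_i, ambiguous_rule_ii, unique_best,
#'       hits_raw, hits_invalid).}
#'     \item{params, plan, input, genome_lengths, mask}{run metadata.}
#'   }
#' @export
map_reads <- function(reads, genome, params = alignment_params(),
                      library_type = c("directional", "non-directional"),
                      digestion = NULL, keep_ambiguous = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(genome, "bs_genome"), inherits(params, "alignment_params"))
  library_type <- match.arg(library_type)
  reads <- as_read_table(reads)
  n <- nrow(reads)
  if (anyDuplicated(reads$id)) stop("duplicate read ids")

  status <- rep("unmapped", n)
  reason <- rep(NA_character_, n)
  rejected <- nchar(reads$qual) != nchar(reads$seq)
  if (any(rejected)) {
    reason[rejected] <- "quality-length-mismatch"
    log_msg("rejected ", sum(rejected),
            " read(s) with read/quality length mismatch", verbose = verbose)
  }
  n_count <- nchar(gsub("[^N]", "", reads$seq))
  too_many_n <- !rejected & n_count > params$max_diff
  reason[too_many_n] <- "too-many-N"

  plan <- plan_passes(library_type)
  converted <- list()
  mask <- NULL
  fragments <- NULL
  for (mode in unique(plan$conversion)) {
    cg <- convert_genome(genome, mode)
    if (!is.null(digestion)) {
      if (is.null(fragments)) fragments <- digest_genome(genome, digestion)
      cg <- mask_for_rrbs(cg, fragments)
      mask <- cg$mask
    }
    converted[[mode]] <- cg
  }

  alignable <- which(!rejected & !too_many_n)
  sub <- reads[alignable, , drop = FALSE]
  pass_hits <- run_mapping(sub, genome, params, plan, converted = converted)

  all_hits <- list()
  for (k in seq_len(nrow(plan))) {
    h <- pass_hits[[as.character(plan$pass[k])]]
    if (nrow(h) == 0) next
    treads <- transform_reads(sub$seq, plan$transform[k])
    h <- validate_hits(h, treads[h$qidx], genome, plan$conversion[k],
                       params$max_diff)
    all_hits[[length(all_hits) + 1]] <- h
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else {
    h <- empty_hits(); h$pass <- integer(0); h$diff4 <- integer(0)
    h$valid <- logical(0); h
  }
  hits_raw <- nrow(hits)
  hits_invalid <- sum(!hits$valid)

  class_v <- rep(NA_character_, n)
  chrom <- rep(NA_character_, n); startv <- rep(NA_integer_, n)
  cigar <- rep(NA_character_, n); mm3 <- rep(NA_integer_, n)
  diff4 <- rep(NA_integer_, n); gaps <- rep(NA_integer_, n)
  score <- rep(NA_integer_, n); passv <- rep(NA_integer_, n)
  rule <- rep(NA_character_, n); n_best <- rep(0L, n)
  retained_all <- list()

  # vectorised resolution: identical semantics to resolve_read() per read
  # (the per-read function remains the reference implementation and is
  # exercised against this path in the tests)
  with_hits <- unique(hits$qidx)
  status[alignable[with_hits]] <- "filtered"      # overwritten when valid
  vh <- hits[hits$valid, , drop = FALSE]
  if (nrow(vh) > 0) {
    ord <- order(vh$qidx, -vh$score, vh$diff4, vh$name, vh$start, vh$pass)
    vh <- vh[ord, , drop = FALSE]
    first <- !duplicated(vh$qidx)
    qlev <- vh$qidx[first]
    best_score <- vh$score[first][match(vh$qidx, qlev)]
    is_best <- vh$score == best_score
    bb_q <- vh$qidx[is_best]
    nb <- tabulate(match(bb_q, qlev), nbins = length(qlev))
    pass_dedup <- !duplicated(paste(bb_q, vh$pass[is_best]))
    np <- tabulate(match(bb_q[pass_dedup], qlev), nbins = length(qlev))
    rule_g <- ifelse(np >= 2, "i", ifelse(nb >= 2, "ii", NA_character_))
    amb <- !is.na(rule_g)
    gidx <- alignable[qlev]
    status[gidx] <- ifelse(amb, "ambiguous", "unique-best")
    rule[gidx] <- rule_g
    n_best[gidx] <- nb
    take <- !amb | keep_ambiguous
    ch <- vh[first, , drop = FALSE][take, , drop = FALSE]
    tg <- gidx[take]
    class_v[tg] <- assign_origin_class(ch$pass, plan)
    chrom[tg] <- ch$name; startv[tg] <- ch$start; cigar[tg] <- ch$cigar
    mm3[tg] <- ch$mm3; diff4[tg] <- ch$diff4; gaps[tg] <- ch$gaps
    score[tg] <- ch$score; passv[tg] <- ch$pass

    if (params$report_policy != "unique-best") {
      keep_rows <- if (params$report_policy == "all-best") is_best
                   else rep(TRUE, nrow(vh))
      ret <- vh[keep_rows, , drop = FALSE]
      if (!is.infinite(params$max_hits)) {   # re-cap after merging passes
        rank_in_read <- stats::ave(seq_len(nrow(ret)), ret$qidx,
                                   FUN = seq_along)
        ret <- ret[rank_in_read <= params$max_hits, , drop = FALSE]
      }
      ret$qid <- reads$id[alignable[ret$qidx]]
      retained_all[[1]] <- ret
    }
  }
  status[rejected | too_many_n] <- "unmapped"

  out_reads <- data.frame(
    id = reads$id, status = status, class = class_v, chrom = chrom,
    start = startv, cigar = cigar, mm3 = mm3, diff4 = diff4, gaps = gaps,
    score = score, pass = passv, rule = rule, n_best = n_best,
    reason = reason, stringsAsFactors = FALSE
  )

  stats <- list(
    input = n,
    rejected = sum(rejected),
    too_many_n = sum(too_many_n),
    hits_raw = hits_raw,
    hits_invalid = hits_invalid,
    unmapped = sum(out_reads$status == "unmapped"),
    filtered = sum(out_reads$status == "filtered"),
    ambiguous_rule_i = sum(out_reads$status == "ambiguous" &
                             out_reads$rule == "i", na.rm = TRUE),
    ambiguous_rule_ii = sum(out_reads$status == "ambiguous" &
                              out_reads$rule == "ii", na.rm = TRUE),
    unique_best = sum(out_reads$status == "unique-best")
  )
  if (verbose)
    log_msg(paste(names(stats), unlist(stats), sep = "=", collapse = " "))

  structure(
    list(reads = out_reads,
         hits = if (length(retained_all)) do.call(rbind, retained_all) else NULL,
         stats = stats, params = params, plan = plan, input = reads,
         genome_lengths = genome$lengths, mask = mask,
         keep_ambiguous = keep_ambiguous, digestion = digestion),
    class = "bs_mapping"
  )
}

#' @export
print.bs_mapping <- function(x, ...) {
  s <- x$stats
  cat("bs_mapping:", s$input, "reads,",
      attr(x$plan, "library_type"), "library, mode", x$params$mode, "\n")
  cat(sprintf("  unique-best %d (%.1f%%), ambiguous %d (rule i %d / ii %d),\n",
              s$unique_best, 100 * s$unique_best / max(1, s$input),
              s$ambiguous_rule_i + s$ambiguous_rule_ii,
              s$ambiguous_rule_i, s$ambiguous_rule_ii))
  cat(sprintf("  filtered %d, unmapped %d (of which %d rejected, %d too many N)\n",
              s$filtered, s$unmapped, s$rejected, s$too_many_n))
  invisible(x)
}

#' @export
summary.bs_mapping <- function(object, ...) {
  print(object)
  tab <- table(object$reads$class[object$reads$status == "unique-best"])
  if (length(tab)) {
    cat("  unique-best by origin class:\n")
    for (nm in names(tab)) cat("    ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  invisible(object$stats)
}

#' Write the machine-readable filter-statistics summary
#'
#' One `key<TAB>value` line per statistic.
#'
#' @param mapping a [map_reads()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(mapping, path) {
  stopifnot(inherits(mapping, "bs_mapping"))
  s <- mapping$stats
  lines <- c(
    paste0("version\t", as.character(utils::packageVersion("bsmapr"))),
    paste0("mode\t", mapping$params$mode),
    paste0("max_diff\t", mapping$params$max_diff),
    paste0("library_type\t", attr(mapping$plan, "library_type")),
    paste(names(s), unlist(s), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
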