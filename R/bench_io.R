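# Evaluation metrics against simulated truth, SAM emission, and metric
# tables.

#' Score mapped reads against a truth ledger
#'
#' A unique-best read is *correct* iff its sequence name matches the truth,
#' its reported start is within `tolerance` bp of the true start, and its
#' origin class matches. Precision is `n_correct / n_unique_best` (0 when no
#' read is unique-best), recall is `n_correct / n_reads`, and F1 their
#' harmonic mean (0 when `p + r = 0`).
#'
#' @param mapping a [map_reads()] result (or its `reads` data.frame).
#' @param truth a truth ledger ([read_truth()] / `bs_simulation$truth`).
#' @param tolerance allowed start deviation in bp. The default 0 suits the
#'   ungapped and end-to-end modes; local mode conventionally uses 5 bp
#'   because soft-clipping shifts starts.
#' @return a list of class `eval_metrics`: `n_reads`, `n_unique_best`,
#'   `n_correct`, `precision`, `recall`, `f1`, `tolerance`.
#' @export
score_mappings <- function(mapping, truth, tolerance = 0) {
  reads <- if (inherits(mapping, "bs_mapping")) mapping$reads else mapping
  miss <- setdiff(reads$id, truth$id)
  if (length(miss))
    stop("read id(s) missing from truth: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  t_idx <- match(reads$id, truth$id)
  ub <- reads$status == "unique-best"
  correct <- ub &
    reads$chrom == truth$chrom[t_idx] &
    abs(reads$start - truth$start[t_idx]) <= tolerance &
    reads$class == truth$class[t_idx]
  correct[is.na(correct)] <- FALSE
  n_reads <- nrow(reads)
  n_ub <- sum(ub)
  n_ok <- sum(correct)
  p <- if (n_ub > 0) n_ok / n_ub else 0
  r <- if (n_reads > 0) n_ok / n_reads else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(
    list(n_reads = n_reads, n_unique_best = n_ub, n_correct = n_ok,
         precision = p, recall = r, f1 = f1, tolerance = tolerance),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "eval_metrics: %d reads, %d unique-best, %d correct (tolerance %d bp)\n",
    x$n_reads, x$n_unique_best, x$n_correct, x$tolerance))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Cumulative unique-best fraction by difference count
#'
#' For each `k` in `0..k_max`, the fraction of all reads that are
#' unique-best with at most `k` 4-letter differences. Nondecreasing in `k`.
#'
#' @param mapping a [map_reads()] result (or its `reads` data.frame).
#' @param k_max largest difference count tabulated.
#' @return data.frame with columns `k`, `fraction`.
#' @export
cumulative_by_differences <- function(mapping, k_max) {
  reads <- if (inherits(mapping, "bs_mapping")) mapping$reads else mapping
  n <- nrow(reads)
  ub <- reads$status == "unique-best"
  ks <- 0:k_max
  frac <- vapply(ks, function(k)
    if (n > 0) sum(ub & !is.na(reads$diff4) & reads$diff4 <= k) / n else 0,
    numeric(1))
  data.frame(k = ks, fraction = frac)
}

#' Write mapped reads as SAM
#'
#' Emits a valid SAM file with `@HD`/`@SQ`/`@PG` header and one record per
#' read. POS is 1-based; hits obtained from reverse-complemented query sets
#' carry the reverse flag with SEQ stored reverse-complemented (i.e. exactly
#' as aligned to the Watson-forward genome). Custom tags: `ZC:Z` origin
#' class, `ZP:i` pass id, `ZM:i` 4-letter difference count, `ZA:Z` ambiguity
#' rule (for ambiguous reads kept with `keep_ambiguous`, written with
#' mapping quality 0), `ZF:Z` reason for unmapped/filtered reads (emitted
#' with the unmapped flag).
#'
#' @param mapping a [map_reads()] result.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapping, path) {
  stopifnot(inherits(mapping, "bs_mapping"))
  rd <- mapping$reads
  input <- mapping$input[match(rd$id, mapping$input$id), , drop = FALSE]
  lens <- mapping$genome_lengths
  plan <- mapping$plan

  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(lens), "\tLN:", unname(lens)),
    paste0("@PG\tID:bsmapr\tPN:bsmapr\tVN:",
           as.character(utils::packageVersion("bsmapr")))
  )

  mapped <- !is.na(rd$chrom)
  lines <- character(nrow(rd))
  for (k in seq_len(nrow(rd))) {
    if (mapped[k]) {
      if (rd$start[k] < 0 ||
          rd$start[k] + cigar_ref_len(rd$cigar[k]) > lens[[rd$chrom[k]]])
        stop("alignment outside reference bounds for read ", rd$id[k])
      tf <- plan$transform[match(rd$pass[k], plan$pass)]
      seq <- transform_reads(input$seq[k], tf)
      qual <- input$qual[k]
      if (tf == "revcomp")
        qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
      flag <- if (tf == "revcomp") 16L else 0L
      mapq <- if (rd$status[k] == "ambiguous") 0L else 255L
      tags <- c(paste0("ZC:Z:", rd$class[k]),
                paste0("ZP:i:", rd$pass[k]),
                paste0("ZM:i:", rd$diff4[k]))
      if (!is.na(rd$rule[k])) tags <- c(tags, paste0("ZA:Z:", rd$rule[k]))
      lines[k] <- paste(c(rd$id[k], flag, rd$chrom[k], rd$start[k] + 1L,
                          mapq, rd$cigar[k], "*", 0L, 0L, seq, qual, tags),
                        collapse = "\t")
    } else {
      reason <- if (!is.na(rd$reason[k])) rd$reason[k] else rd$status[k]
      if (rd$status[k] == "ambiguous") reason <- paste0("ambiguous-rule-",
                                                        rd$rule[k])
      lines[k] <- paste(c(rd$id[k], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                          input$seq[k], input$qual[k],
                          paste0("ZF:Z:", reason)),
                        collapse = "\t")
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write evaluation metrics as TSV
#'
#' @param metrics an `eval_metrics` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  df <- data.frame(metric = c("n_reads", "n_unique_best", "n_correct",
                              "precision", "recall", "f1", "tolerance"),
                   value = c(metrics$n_reads, metrics$n_unique_best,
                             metrics$n_correct, metrics$precision,
                             metrics$recall, metrics$f1, metrics$tolerance))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
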