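# Pass orchestration: read conversion, the two/four alignment passes, and the
# pass -> bisulfite origin class bijection.
#
# Each pass aligns queries in forward orientation against the converted
# forward genome; reverse-complemented query sets are materialised here. The
# class algebra: the reverse complement of a C->T-converted fragment equals
# the G->A conversion of its reverse complement, so
#   pass 1 (identity,  C2T vs C2T genome) -> +FW
#   pass 2 (revcomp,   G2A vs G2A genome) -> -FW
#   pass 3 (identity,  G2A vs G2A genome) -> -RC
#   pass 4 (revcomp,   C2T vs C2T genome) -> +RC

#' Plan the alignment passes for a library type
#'
#' Directional libraries need two passes, non-directional four.
#'
#' @param library_type `"directional"` or `"non-directional"`.
#' @return data.frame with columns `pass`, `transform` (`identity` /
#'   `revcomp`), `conversion` (query and reference conversion, always equal),
#'   `class` (bisulfite origin class).
#' @export
plan_passes <- function(library_type = c("directional", "non-directional")) {
  library_type <- match.arg(library_type)
  plan <- data.frame(
    pass = 1:4,
    transform = c("identity", "revcomp", "identity", "revcomp"),
    conversion = c("C2T", "G2A", "G2A", "C2T"),
    class = c("+FW", "-FW", "-RC", "+RC"),
    stringsAsFactors = FALSE
  )
  plan <- plan[if (library_type == "directional") 1:2 else 1:4, ]
  attr(plan, "library_type") <- library_type
  plan
}

#' Origin class of a pass
#'
#' @param pass pass id.
#' @param plan a [plan_passes()] result.
#' @return the origin class label (`+FW`, `-FW`, `+RC`, `-RC`).
#' @export
assign_origin_class <- function(pass, plan) {
  i <- match(pass, plan$pass)
  if (anyNA(i)) stop("pass id outside plan: ", paste(pass[is.na(i)], collapse = ","))
  plan$class[i]
}

## Apply a pass's query transform to 4-letter reads.
transform_reads <- function(seqs, transform) {
  if (transform == "revcomp") reverse_complement(seqs) else seqs
}

#' Run the alignment passes
#'
#' For each pass in the plan, reads are transformed (identity or reverse
#' complement), converted to the pass's 3-letter alphabet and aligned against
#' the matching converted genome. Passes are independent; the result is
#' invariant to pass and read order.
#'
#' @param reads data.frame with columns `id`, `seq` (and optionally `qual`),
#'   or a named character vector of read sequences.
#' @param genome a [bs_genome].
#' @param params [alignment_params()].
#' @param plan a [plan_passes()] result.
#' @param converted optional named list of pre-built converted genomes
#'   (`C2T`, `G2A`), e.g. RRBS-masked ones; built on the fly when missing.
#' @return list with one element per pass: the [align_pass()] hit table with
#'   an added `pass` column.
#' @export
run_mapping <- function(reads, genome, params, plan, converted = NULL) {
  reads <- as_read_table(reads)
  if (is.null(converted)) {
    converted <- list()
    for (mode in unique(plan$conversion))
      converted[[mode]] <- convert_genome(genome, mode)
  }
  out <- list()
  for (k in seq_len(nrow(plan))) {
    tseq <- transform_reads(reads$seq, plan$transform[k])
    q3 <- convert_sequence(tseq, plan$conversion[k])
    hits <- align_pass(q3, converted[[plan$conversion[k]]], params)
    hits$pass <- rep(plan$pass[k], nrow(hits))
    out[[as.character(plan$pass[k])]] <- hits
  }
  out
}

## Normalise read input to a data.frame(id, seq, qual).
as_read_table <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "seq") %in% names(reads)))
    reads$seq <- toupper(reads$seq)
    if (is.null(reads$qual))
      reads$qual <- strrep("I", nchar(reads$seq))
    return(reads)
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("read", seq_along(reads))
    return(data.frame(id = ids, seq = toupper(unname(reads)),
                      qual = strrep("I", nchar(reads)),
                      stringsAsFactors = FALSE))
  }
  stop("reads must be a data.frame(id, seq[, qual]) or a named character vector")
}
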