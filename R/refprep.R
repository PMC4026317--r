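# Reference preparation: loading, 3-letter conversion, RRBS in-silico
# digestion and fragment masking. Coordinates are 0-based half-open
# throughout; conversion to 1-based happens only at SAM/TSV emission.

#' Construct a genome object
#'
#' A genome is an ordered set of named uppercase nucleotide sequences over
#' `A/C/G/T/N`.
#'
#' @param sequences named character vector of sequences.
#' @return an object of class `bs_genome` with elements `sequences` and
#'   `lengths`.
#' @export
bs_genome <- function(sequences) {
  stopifnot(is.character(sequences))
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all sequences must have non-empty names")
  if (anyDuplicated(nm))
    stop("duplicate sequence name: ", nm[duplicated(nm)][1])
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    rec <- nm[bad][1]
    ch <- regmatches(sequences[bad][1], regexpr("[^ACGTN]", sequences[bad][1]))
    stop("record '", rec, "' contains non-nucleotide residue '", ch, "'")
  }
  structure(
    list(sequences = sequences, lengths = setNames(nchar(sequences), nm)),
    class = "bs_genome"
  )
}

#' @export
print.bs_genome <- function(x, ...) {
  cat("bs_genome with", length(x$sequences), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  n <- min(6L, length(x$lengths))
  for (i in seq_len(n))
    cat("  ", names(x$lengths)[i], ": ", x$lengths[i], " bp\n", sep = "")
  if (length(x$lengths) > n) cat("  ...\n")
  invisible(x)
}

#' Load a reference genome from a FASTA file
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than `N`
#' (`R Y S W K M B D H V`) are collapsed to `N`; `U` is read as `T`.
#' Any other residue is a hard error naming the offending record.
#'
#' @param path path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return a [bs_genome] object; record order is preserved.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- chartr("RYSWKMBDHV", strrep("N", 10L), seqs)
  bs_genome(seqs)
}

#' Generate a random reference genome
#'
#' Uniform i.i.d. `A/C/G/T` sequences; handy for simulation studies and for
#' property tests against brute-force oracles.
#'
#' @param lengths named integer vector of sequence lengths (names become
#'   sequence names; unnamed input gets `chr1`, `chr2`, ...).
#' @param seed optional RNG seed; the caller's RNG state is restored.
#' @return a [bs_genome].
#' @export
random_genome <- function(lengths, seed = NULL) {
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  with_seed(seed, {
    seqs <- vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
    bs_genome(seqs)
  })
}

#' Convert a nucleotide sequence to the 3-letter alphabet
#'
#' `C2T` replaces every cytosine with thymine; `G2A` replaces every guanine
#' with adenine. All other characters (including `N`) are unchanged; length is
#' preserved and the operation is idempotent.
#'
#' @param seq character vector of sequences over `A/C/G/T/N`.
#' @param mode `"C2T"` or `"G2A"`.
#' @return converted character vector.
#' @examples
#' convert_sequence("ACGTN", "C2T")
#' convert_sequence("ACGTN", "G2A")
#' @export
convert_sequence <- function(seq, mode) {
  if (length(mode) != 1 || !mode %in% c("C2T", "G2A"))
    stop("unknown conversion mode: ", paste(mode, collapse = ","))
  if (mode == "C2T") chartr("C", "T", seq) else chartr("G", "A", seq)
}

#' Build a 3-letter converted genome
#'
#' @param genome a [bs_genome].
#' @param mode `"C2T"` or `"G2A"`.
#' @return an object of class `bs_converted_genome` holding the base genome,
#'   the conversion mode, the converted sequences and an (initially `NULL`)
#'   RRBS mask.
#' @seealso [mask_for_rrbs()]
#' @export
convert_genome <- function(genome, mode) {
  stopifnot(inherits(genome, "bs_genome"))
  structure(
    list(base = genome, mode = mode,
         sequences = convert_sequence(genome$sequences, mode),
         mask = NULL),
    class = "bs_converted_genome"
  )
}

#' @export
print.bs_converted_genome <- function(x, ...) {
  cat("bs_converted_genome (", x$mode, ") over ",
      length(x$sequences), " sequence(s)",
      if (!is.null(x$mask)) ", RRBS-masked" else "", "\n", sep = "")
  invisible(x)
}

#' Parse a restriction-site specification
#'
#' The site is written with a dash at the cut position, e.g. `"C-CGG"` for
#' MspI. Fragment bounds give the size-selection window in bp.
#'
#' @param text site specification with exactly one dash.
#' @param low,high minimum and maximum retained fragment length (bp),
#'   `0 < low <= high`.
#' @return an object of class `bs_digestion_spec` with fields `recognition`,
#'   `cut_offset`, `low`, `high`.
#' @examples
#' parse_digestion_site("C-CGG", 40, 500)
#' @export
parse_digestion_site <- function(text, low, high) {
  stopifnot(is.character(text), length(text) == 1)
  ndash <- lengths(regmatches(text, gregexpr("-", text, fixed = TRUE)))
  if (ndash != 1)
    stop("site specification must contain exactly one '-': ", text)
  recognition <- gsub("-", "", text, fixed = TRUE)
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition))
    stop("recognition site may contain only A/C/G/T: ", text)
  cut_offset <- regexpr("-", text, fixed = TRUE)[1] - 1L
  low <- as.integer(low); high <- as.integer(high)
  if (is.na(low) || is.na(high) || low <= 0 || low > high)
    stop("fragment bounds must satisfy 0 < low <= high")
  structure(
    list(recognition = recognition, cut_offset = cut_offset,
         low = low, high = high),
    class = "bs_digestion_spec"
  )
}

#' @export
print.bs_digestion_spec <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "-",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat("in-silico digestion: site ", site, ", retained fragments ",
      x$low, "-", x$high, " bp\n", sep = "")
  invisible(x)
}

#' In-silico restriction digestion
#'
#' Cuts the forward strand of every sequence at `occurrence_start +
#' cut_offset` for each exact occurrence of the recognition site (overlapping
#' occurrences included; `N` never matches). Fragments are the half-open
#' intervals between consecutive cuts plus the leading and trailing
#' intervals. A fragment is retained iff its length lies in `low..high`
#' *and* it is flanked by a cut on both sides: a genuine restriction
#' fragment carries enzyme-cut ends, so chromosome-terminal pieces do not
#' occur in an RRBS library. A sequence without any site degenerates to a
#' single spanning fragment, retained by the length rule alone.
#'
#' Only the forward strand is searched; for palindromic sites such as MspI's
#' `CCGG` this is equivalent to digesting both strands. Non-palindromic
#' enzymes are a documented limitation.
#'
#' @param genome a [bs_genome].
#' @param spec a [parse_digestion_site()] result.
#' @return data.frame with columns `name`, `start` (0-based), `end`
#'   (exclusive), `length`, `retained`; fragments of one sequence tile it
#'   without overlap.
#' @export
digest_genome <- function(genome, spec) {
  stopifnot(inherits(genome, "bs_genome"), inherits(spec, "bs_digestion_spec"))
  out <- lapply(names(genome$sequences), function(nm) {
    seq <- genome$sequences[[nm]]
    len <- nchar(seq)
    occ <- gregexpr(paste0("(?=", spec$recognition, ")"), seq, perl = TRUE)[[1]]
    raw_cuts <- if (occ[1] == -1) integer(0)
                else sort(unique(as.integer(occ) - 1L + spec$cut_offset))
    cuts <- raw_cuts[raw_cuts > 0 & raw_cuts < len]
    bounds <- c(0L, cuts, len)
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    flanked <- if (length(raw_cuts) == 0) rep(TRUE, length(start))
               else start %in% raw_cuts & end %in% raw_cuts
    data.frame(
      name = nm, start = start, end = end, flanked = flanked,
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, out)
  frags$length <- frags$end - frags$start
  frags$retained <- frags$flanked &
    frags$length >= spec$low & frags$length <= spec$high
  frags$flanked <- NULL
  frags
}

#' Mask non-retained RRBS territory
#'
#' Positions of the converted genome falling in non-retained fragments are
#' replaced by `N`; retained fragments are untouched. The retained intervals
#' are recorded in the `mask` field so downstream stages can report retained
#' territory. Idempotent.
#'
#' @param converted a [convert_genome()] result.
#' @param fragments a [digest_genome()] result; must tile `converted$base`.
#' @return the masked `bs_converted_genome`.
#' @export
mask_for_rrbs <- function(converted, fragments) {
  stopifnot(inherits(converted, "bs_converted_genome"), is.data.frame(fragments))
  lens <- converted$base$lengths
  mask <- list()
  for (nm in names(converted$sequences)) {
    fr <- fragments[fragments$name == nm, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    if (nrow(fr) == 0 || fr$start[1] != 0 || fr$end[nrow(fr)] != lens[[nm]] ||
        (nrow(fr) > 1 && any(fr$start[-1] != fr$end[-nrow(fr)])))
      stop("fragments do not tile sequence '", nm, "'")
    seq <- converted$sequences[[nm]]
    drop <- fr[!fr$retained, , drop = FALSE]
    if (nrow(drop) > 0) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (k in seq_len(nrow(drop)))
        chars[(drop$start[k] + 1L):drop$end[k]] <- "N"
      seq <- paste(chars, collapse = "")
    }
    converted$sequences[[nm]] <- seq
    keep <- fr[fr$retained, c("start", "end"), drop = FALSE]
    rownames(keep) <- NULL
    mask[[nm]] <- keep
  }
  converted$mask <- mask
  converted
}

#' Export digestion fragments as BED-like text
#'
#' Six tab-separated columns: name, start, end, id, length, retained.
#'
#' @param fragments a [digest_genome()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  df <- data.frame(
    name = fragments$name,
    start = fragments$start,
    end = fragments$end,
    id = paste0("frag", seq_len(nrow(fragments))),
    length = fragments$length,
    retained = as.integer(fragments$retained)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
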