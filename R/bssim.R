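# Synthetic bisulfite read simulator (WGBS and RRBS) with ground truth.
#
# Class algebra used to build a read from a Watson window w:
#   +FW : w        with converted eligible C -> T
#   -FW : rc(w)    with converted eligible C -> T   (Crick source strand)
#   +RC : rc(w)    with converted eligible G -> A   (rc of the +FW fragment)
#   -RC : w        with converted eligible G -> A   (rc of the -FW fragment)
# Eligible sites are the cytosines of the fragment's bisulfite source strand,
# which appear as C (+FW, -FW) or G (+RC, -RC) in the read's own orientation.
# Sequencing errors are substitutions injected after conversion, with a
# positional probability profile that decays exponentially toward the 5' end
# (errors concentrate at the 3' end, mimicking real base callers).

#' Simulation specification
#'
#' @param n_reads number of reads (>= 1).
#' @param read_length read length L in bp (>= 20).
#' @param conversion `"uniform-rate"`: every eligible cytosine converts
#'   independently with `conversion_rate`; `"per-cytosine"`: each read draws
#'   a methylation state per eligible site (probability `meth_prob` of being
#'   methylated) and unmethylated sites always convert.
#' @param conversion_rate uniform-rate mode conversion fraction in `[0, 1]`.
#' @param meth_prob per-cytosine mode: global methylation probability, or a
#'   named list of per-sequence numeric vectors (one probability per Watson
#'   position) for a position-wise map.
#' @param error_rate mean sequencing error rate E in `[0, 1)`.
#' @param decay exponential shape lambda (> 0, or 0 for a flat profile) of
#'   the positional error curve; default 3.
#' @param library_type `"directional"` (classes `+FW`, `-FW`) or
#'   `"non-directional"` (all four classes, uniformly).
#' @param seed RNG seed; identical spec and seed give byte-identical output.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_reads, read_length,
                            conversion = c("uniform-rate", "per-cytosine"),
                            conversion_rate = 0.5, meth_prob = 0.5,
                            error_rate = 0, decay = 3,
                            library_type = c("directional", "non-directional"),
                            seed = 1L) {
  conversion <- match.arg(conversion)
  library_type <- match.arg(library_type)
  n_reads <- as.integer(n_reads); read_length <- as.integer(read_length)
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (read_length < 20) stop("read_length must be >= 20")
  if (conversion_rate < 0 || conversion_rate > 1)
    stop("conversion_rate must be in [0, 1]")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (decay < 0) stop("decay must be >= 0")
  structure(
    list(n_reads = n_reads, read_length = read_length, conversion = conversion,
         conversion_rate = conversion_rate, meth_prob = meth_prob,
         error_rate = error_rate, decay = decay, library_type = library_type,
         seed = seed),
    class = "simulation_spec"
  )
}

#' Positional sequencing-error probabilities
#'
#' `e_k = c * exp(lambda * (k - 1) / (L - 1))` with `c` chosen so that
#' `mean(e_k) = E`; the profile is nondecreasing toward the 3' end.
#' Probabilities that would reach 1 are clipped (with a warning) and the
#' remainder re-normalised to preserve the mean; if the mean is unreachable
#' even with all positions clipped, an error is raised.
#'
#' @param L read length.
#' @param E mean error rate, `0 <= E < 1`.
#' @param lambda decay shape (>= 0; 0 gives the uniform profile `e_k = E`).
#' @return numeric vector of length `L`.
#' @export
positional_error_rates <- function(L, E, lambda = 3) {
  stopifnot(L >= 1, E >= 0, E < 1, lambda >= 0)
  if (E == 0) return(numeric(L))
  if (lambda == 0 || L == 1) return(rep(E, L))
  shape <- exp(lambda * (seq_len(L) - 1) / (L - 1))
  e <- E * L * shape / sum(shape)
  cap <- 1 - 1e-12
  if (any(e >= cap)) {
    warning("positional error profile clipped at 1; re-normalising")
    for (it in seq_len(L)) {
      clip <- e >= cap
      if (!any(clip) || all(clip)) break
      deficit <- E * L - sum(pmin(e, cap))
      free <- !clip
      e[clip] <- cap
      e[free] <- e[free] + deficit * e[free] / sum(e[free])
    }
    e <- pmin(e, cap)
    if (abs(mean(e) - E) > 1e-6)
      stop("error rate E and decay lambda are jointly infeasible after clipping")
  }
  e
}

## sample genome windows of length `len` free of N; bounded retries
sample_windows <- function(genome, len, n, max_tries = 1000L) {
  lens <- genome$lengths
  ok <- lens >= len
  if (!any(ok)) stop("genome shorter than the read length")
  lens <- lens[ok]
  weights <- lens - len + 1
  chrom <- character(n); start <- integer(n); win <- character(n)
  todo <- seq_len(n)
  for (try in seq_len(max_tries)) {
    if (!length(todo)) break
    ci <- sample.int(length(lens), length(todo), replace = TRUE,
                     prob = weights)
    st <- as.integer(floor(stats::runif(length(todo)) * weights[ci]))
    sq <- substring(genome$sequences[names(lens)[ci]], st + 1L, st + len)
    good <- !grepl("N", sq, fixed = TRUE)
    idx <- todo[good]
    chrom[idx] <- names(lens)[ci[good]]
    start[idx] <- st[good]
    win[idx] <- sq[good]
    todo <- todo[!good]
  }
  if (length(todo))
    stop("could not sample N-free windows after ", max_tries, " tries")
  list(chrom = chrom, start = start, window = win)
}

## comma-joined per-row TRUE column indices of a logical matrix
pos_strings <- function(mat) {
  out <- rep("", nrow(mat))
  idx <- which(mat, arr.ind = TRUE)
  if (nrow(idx)) {
    o <- order(idx[, 1], idx[, 2])
    sp <- split(idx[o, 2], idx[o, 1])
    out[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = ",")
  }
  out
}

## per-row states (0/1) at the TRUE cells of `elig`, column order
state_strings <- function(elig, meth) {
  out <- rep("", nrow(elig))
  idx <- which(elig, arr.ind = TRUE)
  if (nrow(idx)) {
    o <- order(idx[, 1], idx[, 2])
    st <- as.integer(meth[idx[o, , drop = FALSE]])
    sp <- split(st, idx[o, 1])
    out[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = ",")
  }
  out
}

## per-site methylation probability matrix (reads x positions) for one
## (class, length) group
meth_prob_matrix <- function(spec, chrom, start, len, cls) {
  ngr <- length(start)
  if (!is.list(spec$meth_prob))
    return(matrix(spec$meth_prob, ngr, len))
  offs <- if (cls %in% c("+FW", "-RC")) 0:(len - 1L) else (len:1L) - 1L
  gpos <- outer(start, offs, "+")   # 0-based Watson position per cell
  p <- matrix(NA_real_, ngr, len)
  for (nm in unique(chrom)) {
    v <- spec$meth_prob[[nm]]
    if (is.null(v)) stop("no methylation probability map for ", nm)
    rows <- chrom == nm
    p[rows, ] <- v[gpos[rows, , drop = FALSE] + 1L]
  }
  p
}

## core generator shared by WGBS and RRBS: builds reads + truth from sampled
## (chrom, start, window, class) tuples, vectorised over reads per
## (class, length) group. Positions in the truth ledger are 1-based read
## coordinates.
build_reads <- function(spec, chrom, start, window, class, prefix) {
  n <- length(window)
  seqs <- character(n); conv_list <- rep("", n); err_list <- rep("", n)
  meth_pos_list <- rep("", n); meth_state_list <- rep("", n)
  len_all <- nchar(window)
  bases <- c("A", "C", "G", "T")

  for (gi in split(seq_len(n), paste(class, len_all))) {
    cls <- class[gi[1]]
    len <- len_all[gi[1]]
    m <- length(gi)
    oriented <- if (cls %in% c("+FW", "-RC")) window[gi]
                else reverse_complement(window[gi])
    chars <- matrix(unlist(strsplit(oriented, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = m, ncol = len, byrow = TRUE)
    eligible_char <- if (cls %in% c("+FW", "-FW")) "C" else "G"
    to <- if (eligible_char == "C") "T" else "A"
    elig <- chars == eligible_char

    if (spec$conversion == "uniform-rate") {
      conv <- elig & matrix(stats::runif(m * len) < spec$conversion_rate,
                            m, len)
      meth <- NULL
    } else {
      p <- meth_prob_matrix(spec, chrom[gi], start[gi], len, cls)
      meth <- elig & matrix(stats::runif(m * len), m, len) < p
      conv <- elig & !meth           # unmethylated sites always convert
    }
    chars[conv] <- to

    eprof <- positional_error_rates(len, spec$error_rate, spec$decay)
    err <- matrix(stats::runif(m * len), m, len) <
           matrix(eprof, m, len, byrow = TRUE)
    if (any(err)) {
      cur <- chars[err]
      shift <- sample.int(3L, length(cur), replace = TRUE)
      chars[err] <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    }

    seqs[gi] <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    conv_list[gi] <- pos_strings(conv)
    err_list[gi] <- pos_strings(err)
    if (!is.null(meth)) {
      meth_pos_list[gi] <- pos_strings(elig)
      meth_state_list[gi] <- state_strings(elig, meth)
    }
  }

  ids <- sprintf("%s%06d", prefix, seq_len(n))
  list(
    reads = data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                       stringsAsFactors = FALSE),
    truth = data.frame(id = ids, chrom = chrom, start = start, class = class,
                       conv_pos = conv_list, err_pos = err_list,
                       meth_pos = meth_pos_list, meth_state = meth_state_list,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a whole-genome bisulfite library
#'
#' Samples origin classes uniformly over the classes allowed by the library
#' type and loci uniformly over N-free windows, applies bisulfite conversion
#' on the fragment's source strand, builds the read for its class, injects
#' substitution errors per the positional profile and emits constant `I`
#' (Q40) qualities.
#'
#' @param genome a [bs_genome].
#' @param spec a [simulation_spec()].
#' @return an object of class `bs_simulation`: list with `reads` (data.frame
#'   `id`, `seq`, `qual`), `truth` (ground-truth ledger: `id`, `chrom`,
#'   `start` 0-based Watson window start, `class`, `conv_pos`, `err_pos`,
#'   `meth_pos`, `meth_state`; positions are 1-based read coordinates) and
#'   `spec`.
#' @export
simulate_wgbs <- function(genome, spec) {
  stopifnot(inherits(genome, "bs_genome"), inherits(spec, "simulation_spec"))
  if (max(genome$lengths) < spec$read_length)
    stop("genome shorter than the read length")
  with_seed(spec$seed, {
    classes <- if (spec$library_type == "directional") c("+FW", "-FW")
               else c("+FW", "-FW", "+RC", "-RC")
    cls <- sample(classes, spec$n_reads, replace = TRUE)
    sw <- sample_windows(genome, spec$read_length, spec$n_reads)
    out <- build_reads(spec, sw$chrom, sw$start, sw$window, cls, "wgbs_")
    structure(c(out, list(spec = spec, protocol = "WGBS")),
              class = "bs_simulation")
  })
}

#' Simulate a reduced-representation (RRBS) bisulfite library
#'
#' Digests the genome in silico, samples retained fragments uniformly, and
#' sequences each sampled fragment from its 5' end on the sampled strand:
#' Watson-source classes (`+FW`, `+RC`) start at the fragment start,
#' Crick-source classes (`-FW`, `-RC`) end at the fragment end. Reads are
#' truncated to the fragment length when the fragment is shorter than the
#' read length. Conversion and errors as in [simulate_wgbs()].
#'
#' @param genome a [bs_genome].
#' @param spec a [simulation_spec()].
#' @param digestion a [parse_digestion_site()] spec.
#' @return a `bs_simulation`; the truth ledger records the Watson start of
#'   each read's window.
#' @export
simulate_rrbs <- function(genome, spec, digestion) {
  stopifnot(inherits(genome, "bs_genome"), inherits(spec, "simulation_spec"),
            inherits(digestion, "bs_digestion_spec"))
  frags <- digest_genome(genome, digestion)
  ret <- frags[frags$retained, , drop = FALSE]
  if (nrow(ret) == 0) stop("no retained fragments after digestion")
  with_seed(spec$seed, {
    classes <- if (spec$library_type == "directional") c("+FW", "-FW")
               else c("+FW", "-FW", "+RC", "-RC")
    n <- spec$n_reads
    cls <- character(n); chrom <- character(n)
    start <- integer(n); win <- character(n)
    todo <- seq_len(n)
    for (try in seq_len(1000L)) {
      if (!length(todo)) break
      fi <- sample.int(nrow(ret), length(todo), replace = TRUE)
      cl <- sample(classes, length(todo), replace = TRUE)
      len <- pmin(spec$read_length, ret$length[fi])
      st <- ifelse(cl %in% c("+FW", "+RC"), ret$start[fi], ret$end[fi] - len)
      sq <- substring(genome$sequences[ret$name[fi]], st + 1L, st + len)
      good <- !grepl("N", sq, fixed = TRUE)
      idx <- todo[good]
      cls[idx] <- cl[good]; chrom[idx] <- ret$name[fi[good]]
      start[idx] <- st[good]; win[idx] <- sq[good]
      todo <- todo[!good]
    }
    if (length(todo))
      stop("could not sample N-free RRBS fragments")
    out <- build_reads(spec, chrom, start, win, cls, "rrbs_")
    structure(c(out, list(spec = spec, protocol = "RRBS",
                          fragments = frags)),
              class = "bs_simulation")
  })
}

#' @export
print.bs_simulation <- function(x, ...) {
  cat("bs_simulation:", nrow(x$reads), x$protocol, "reads of",
      x$spec$read_length, "bp,", x$spec$library_type, "library\n")
  cat("  conversion:", x$spec$conversion,
      if (x$spec$conversion == "uniform-rate")
        paste0("(rate ", x$spec$conversion_rate, ")")
      else paste0("(methylation probability ",
                  if (is.list(x$spec$meth_prob)) "map" else x$spec$meth_prob,
                  ")"),
      "; mean error rate", x$spec$error_rate, "\n")
  invisible(x)
}

#' Reconstruct a simulated read from genome and truth
#'
#' Deterministically re-derives the emitted sequence from the reference and a
#' truth-ledger row (origin window, class, converted positions); error
#' positions are excluded from the comparison by the caller, or must be
#' empty. Used to verify the simulator's bookkeeping.
#'
#' @param genome a [bs_genome].
#' @param truth one row of a `bs_simulation` truth ledger.
#' @param read_length the simulated read length.
#' @return the reconstructed read sequence (errors not re-applied).
#' @export
rebuild_read <- function(genome, truth, read_length) {
  stopifnot(nrow(truth) == 1)
  gseq <- genome$sequences[[truth$chrom]]
  len <- min(read_length, nchar(gseq) - truth$start)
  w <- substring(gseq, truth$start + 1L, truth$start + len)
  cls <- truth$class
  oriented <- if (cls %in% c("+FW", "-RC")) w else reverse_complement(w)
  chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
  conv <- if (nzchar(truth$conv_pos))
    as.integer(strsplit(truth$conv_pos, ",", fixed = TRUE)[[1]]) else integer(0)
  to <- if (cls %in% c("+FW", "-FW")) "T" else "A"
  chars[conv] <- to
  paste(chars, collapse = "")
}

#' Write simulated reads as FASTQ
#'
#' @param sim a `bs_simulation` or a data.frame with `id`, `seq`, `qual`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "bs_simulation")) sim$reads else sim
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (Sanger / Phred+33 qualities).
#' @return data.frame with columns `id` (up to the first whitespace), `seq`,
#'   `qual`.
#' @export
read_fastq <- function(path) {
  # the reader attaches its qualities as metadata columns and warns when the
  # quality container drops them again; the drop is intentional here
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    seq = as.character(set),
    qual = as.character(Biostrings::quality(set)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a ground-truth ledger
#'
#' Tab-separated, format version 1: `id`, `chrom`, `start` (0-based Watson),
#' `class`, `conv_pos`, `err_pos`, `meth_pos`, `meth_state` (1-based read
#' coordinates, comma-separated).
#'
#' @param sim a `bs_simulation` (or its `truth` data.frame).
#' @param path file path.
#' @return `path` (write) or the truth data.frame (read).
#' @export
write_truth <- function(sim, path) {
  truth <- if (inherits(sim, "bs_simulation")) sim$truth else sim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#bsmapr-truth-v1", con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                    colClasses = c(conv_pos = "character",
                                   err_pos = "character",
                                   meth_pos = "character",
                                   meth_state = "character"),
                    stringsAsFactors = FALSE)
}
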