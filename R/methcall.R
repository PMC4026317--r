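# Per-cytosine methylation-level estimation from unique-best alignments.
#
# Reads of the C2T-space classes (+FW, +RC) report Watson cytosines: at an
# aligned column over a genome C, a read C is a methylated call and a read T
# an unmethylated one. Reads of the G2A-space classes (-FW, -RC) report Crick
# cytosines, which appear as G on the Watson strand: read G is methylated,
# read A unmethylated. Any other read base at a cytosine column is ignored
# (sequencing error or SNP, indistinguishable here).

#' Sequence context of a cytosine
#'
#' Reads the two downstream bases on the cytosine's own strand: `CG...` is
#' CpG, `C[ACT]G` is CHG, `C[ACT][ACT]` is CHH. When a base needed for the
#' decision is `N` or beyond the sequence end, the context is `unknown`.
#' For `-` strand sites (a Watson `G`), downstream means leftwards on the
#' complement.
#'
#' @param genome a [bs_genome] or a single nucleotide string.
#' @param position 0-based position(s) on the Watson strand.
#' @param strand `"+"` (genome base must be `C`) or `"-"` (genome base must
#'   be `G`); recycled.
#' @param name sequence name (defaults to the first sequence).
#' @return character vector: `"CpG"`, `"CHG"`, `"CHH"` or `"unknown"`.
#' @examples
#' cytosine_context("ACGT", 1, "+")   # CpG
#' cytosine_context("TTCG", 3, "-")   # CpG on the Crick strand
#' @export
cytosine_context <- function(genome, position, strand, name = NULL) {
  seq <- if (inherits(genome, "bs_genome")) {
    name <- name %||% names(genome$sequences)[1]
    genome$sequences[[name]]
  } else {
    stopifnot(is.character(genome), length(genome) == 1)
    toupper(genome)
  }
  n <- max(length(position), length(strand))
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)
  len <- nchar(seq)
  base <- substring(seq, position + 1L, position + 1L)
  bad <- (strand == "+" & base != "C") | (strand == "-" & base != "G")
  if (any(bad))
    stop("no cytosine on strand ", strand[bad][1], " at 0-based position ",
         position[bad][1])
  b1 <- character(n); b2 <- character(n)
  p <- strand == "+"
  if (any(p)) {
    b1[p] <- substring(seq, position[p] + 2L, position[p] + 2L)
    b2[p] <- substring(seq, position[p] + 3L, position[p] + 3L)
  }
  if (any(!p)) {
    # Crick: downstream = leftwards, complemented (clamped at the start)
    i1 <- pmax(position[!p], 0L)
    i2 <- pmax(position[!p] - 1L, 0L)
    b1[!p] <- chartr("ACGTN", "TGCAN", substring(seq, i1, i1))
    b2[!p] <- chartr("ACGTN", "TGCAN", substring(seq, i2, i2))
  }
  ctx <- rep("unknown", n)
  known1 <- b1 %in% c("A", "C", "G", "T")
  known2 <- b2 %in% c("A", "C", "G", "T")
  ctx[known1 & b1 == "G"] <- "CpG"
  ctx[known1 & b1 != "G" & known2 & b2 == "G"] <- "CHG"
  ctx[known1 & b1 != "G" & known2 & b2 != "G"] <- "CHH"
  ctx
}

#' Accumulate per-cytosine methylation calls
#'
#' Walks every aligned column (indel and soft-clip columns are skipped) of
#' the contributing alignments and tallies methylated/unmethylated calls per
#' reference cytosine and strand, then computes the level
#' `n_meth / (n_meth + n_unmeth)`. Records are emitted only for covered
#' sites.
#'
#' @param mapping a [map_reads()] result.
#' @param genome the unconverted [bs_genome] used for mapping.
#' @param use `"unique-best"` (default analysis mode) or `"all-best"`
#'   (admits the best hits of ambiguous reads kept with `keep_ambiguous`,
#'   at the user's risk).
#' @param min_base_quality optional minimum Phred base quality for a column
#'   to be counted (default off).
#' @return data.frame of methylation records: `name`, `pos` (0-based,
#'   Watson), `strand`, `context`, `n_meth`, `n_unmeth`, `level`.
#' @export
accumulate_calls <- function(mapping, genome, use = c("unique-best", "all-best"),
                             min_base_quality = NULL) {
  stopifnot(inherits(mapping, "bs_mapping"), inherits(genome, "bs_genome"))
  use <- match.arg(use)
  rd <- mapping$reads
  keep <- rd$status == "unique-best"
  if (use == "all-best") keep <- keep | rd$status == "ambiguous"
  keep <- keep & !is.na(rd$chrom)
  rd <- rd[keep, , drop = FALSE]
  input <- mapping$input[match(rd$id, mapping$input$id), , drop = FALSE]

  counts <- new.env(parent = emptyenv())
  for (nm in names(genome$lengths)) {
    assign(nm, list(mp = integer(genome$lengths[[nm]]),
                    up = integer(genome$lengths[[nm]]),
                    mm = integer(genome$lengths[[nm]]),
                    um = integer(genome$lengths[[nm]])), envir = counts)
  }

  plan <- mapping$plan

  # fast path: ungapped alignments without quality filtering, tallied in
  # bulk per (space, chromosome, read length) group
  simple <- grepl("^[0-9]+M$", rd$cigar) & is.null(min_base_quality)
  if (any(simple)) {
    sr <- rd[simple, , drop = FALSE]
    si <- input[simple, , drop = FALSE]
    tf <- plan$transform[match(sr$pass, plan$pass)]
    aligned <- ifelse(tf == "revcomp", reverse_complement(si$seq), si$seq)
    space_c2t <- sr$class %in% c("+FW", "+RC")
    len <- nchar(aligned)
    for (gi in split(seq_along(aligned),
                     paste(space_c2t, sr$chrom, len))) {
      ch <- sr$chrom[gi[1]]
      L <- len[gi[1]]
      c2t <- space_c2t[gi[1]]
      gv <- strsplit(genome$sequences[[ch]], "", fixed = TRUE)[[1]]
      rm_ <- matrix(unlist(strsplit(aligned[gi], "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(gi), ncol = L, byrow = TRUE)
      pos <- outer(sr$start[gi], seq_len(L), "+")   # 1-based genome position
      gm <- matrix(gv[pos], nrow = length(gi))
      cnt <- get(ch, envir = counts)
      nb <- genome$lengths[[ch]]
      if (c2t) {
        sel <- gm == "C"
        cnt$mp <- cnt$mp + tabulate(pos[sel & rm_ == "C"], nbins = nb)
        cnt$up <- cnt$up + tabulate(pos[sel & rm_ == "T"], nbins = nb)
      } else {
        sel <- gm == "G"
        cnt$mm <- cnt$mm + tabulate(pos[sel & rm_ == "G"], nbins = nb)
        cnt$um <- cnt$um + tabulate(pos[sel & rm_ == "A"], nbins = nb)
      }
      assign(ch, cnt, envir = counts)
    }
    rd <- rd[!simple, , drop = FALSE]
    input <- input[!simple, , drop = FALSE]
  }

  for (k in seq_len(nrow(rd))) {
    tf <- plan$transform[match(rd$pass[k], plan$pass)]
    aligned <- transform_reads(input$seq[k], tf)
    qual <- input$qual[k]
    if (tf == "revcomp") qual <- paste(rev(strsplit(qual, "")[[1]]),
                                       collapse = "")
    space_c2t <- rd$class[k] %in% c("+FW", "+RC")
    gseq <- genome$sequences[[rd$chrom[k]]]
    cig <- parse_cigar(rd$cigar[k])
    qp <- 1L; rp <- rd$start[k] + 1L
    cnt <- get(rd$chrom[k], envir = counts)
    for (j in seq_len(nrow(cig))) {
      nlen <- cig$len[j]; op <- cig$op[j]
      if (op == "M") {
        rv <- strsplit(substring(aligned, qp, qp + nlen - 1L), "")[[1]]
        gv <- strsplit(substring(gseq, rp, rp + nlen - 1L), "")[[1]]
        ok <- rep(TRUE, nlen)
        if (!is.null(min_base_quality)) {
          qv <- utf8ToInt(substring(qual, qp, qp + nlen - 1L)) - 33L
          ok <- qv >= min_base_quality
        }
        pos <- rp:(rp + nlen - 1L)
        if (space_c2t) {
          sel <- gv == "C" & ok
          cnt$mp[pos[sel & rv == "C"]] <- cnt$mp[pos[sel & rv == "C"]] + 1L
          cnt$up[pos[sel & rv == "T"]] <- cnt$up[pos[sel & rv == "T"]] + 1L
        } else {
          sel <- gv == "G" & ok
          cnt$mm[pos[sel & rv == "G"]] <- cnt$mm[pos[sel & rv == "G"]] + 1L
          cnt$um[pos[sel & rv == "A"]] <- cnt$um[pos[sel & rv == "A"]] + 1L
        }
        qp <- qp + nlen; rp <- rp + nlen
      } else if (op == "I" || op == "S") {
        qp <- qp + nlen
      } else if (op == "D") {
        rp <- rp + nlen
      }
    }
    assign(rd$chrom[k], cnt, envir = counts)
  }

  recs <- list()
  for (nm in names(genome$lengths)) {
    cnt <- get(nm, envir = counts)
    for (str in c("+", "-")) {
      if (str == "+") { m <- cnt$mp; u <- cnt$up } else { m <- cnt$mm; u <- cnt$um }
      cov <- which(m + u > 0L)
      if (!length(cov)) next
      recs[[length(recs) + 1]] <- data.frame(
        name = nm, pos = cov - 1L, strand = str,
        context = cytosine_context(genome, cov - 1L, str, name = nm),
        n_meth = m[cov], n_unmeth = u[cov],
        level = m[cov] / (m[cov] + u[cov]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(name = character(0), pos = integer(0), strand = character(0),
               context = character(0), n_meth = integer(0),
               n_unmeth = integer(0), level = numeric(0))
  out <- out[order(out$name, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation level from counts
#'
#' @param n_meth,n_unmeth methylated / unmethylated call counts; every pair
#'   must have positive coverage (zero-coverage sites yield no record, never
#'   0/0).
#' @return `n_meth / (n_meth + n_unmeth)`.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  tot <- n_meth + n_unmeth
  if (any(tot <= 0)) stop("zero coverage: no methylation level is defined")
  n_meth / tot
}

#' Write per-cytosine methylation calls as TSV
#'
#' Columns: name, 1-based position, strand, context, level, n_meth,
#' coverage.
#'
#' @param records an [accumulate_calls()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_methylation_tsv <- function(records, path) {
  df <- data.frame(name = records$name, position = records$pos + 1L,
                   strand = records$strand, context = records$context,
                   level = records$level, n_meth = records$n_meth,
                   coverage = records$n_meth + records$n_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write methylation levels as bedGraph
#'
#' 0-based half-open intervals with `level * 100` as the score.
#'
#' @inheritParams write_methylation_tsv
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(records, path) {
  df <- data.frame(records$name, records$pos, records$pos + 1L,
                   round(100 * records$level, 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
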