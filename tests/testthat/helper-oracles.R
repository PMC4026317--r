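# Independent brute-force oracles used by the property tests. These
# deliberately re-derive every quantity from first principles (sliding
# windows, full dynamic-programming matrices, per-column walks) and share no
# code with the package implementation paths they check.

## every locus with Hamming distance <= max_mm (N never matches)
oracle_ungapped <- function(query, refs, max_mm) {
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  L <- length(qv)
  out <- list()
  for (nm in names(refs)) {
    rv <- strsplit(refs[[nm]], "", fixed = TRUE)[[1]]
    G <- length(rv)
    if (L > G) next
    n0 <- G - L + 1L
    mm <- integer(n0)
    for (j in seq_len(L)) {
      rs <- rv[j:(j + n0 - 1L)]
      mm <- mm + (rs != qv[j] | rs == "N" | qv[j] == "N")
    }
    keep <- which(mm <= max_mm)
    if (length(keep))
      out[[length(out) + 1]] <- data.frame(name = nm, start = keep - 1L,
                                           mm3 = mm[keep],
                                           stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(name = character(0), start = integer(0), mm3 = integer(0))
}

## full-matrix affine-gap (Gotoh) optimal score; semi-global (query
## end-to-end, free reference ends) or local
oracle_gotoh <- function(q, w, match = 1, mismatch = -2, open = -3,
                         ext = -1, local = FALSE) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  wv <- strsplit(w, "", fixed = TRUE)[[1]]
  L <- length(qv); W <- length(wv)
  NEG <- -1e9
  H <- matrix(NEG, L + 1, W + 1)
  I <- matrix(NEG, L + 1, W + 1)
  D <- matrix(NEG, L + 1, W + 1)
  H[1, ] <- 0
  if (!local) {
    I[2:(L + 1), 1] <- open + (0:(L - 1)) * ext
    H[2:(L + 1), 1] <- I[2:(L + 1), 1]
  } else {
    H[, 1] <- 0
  }
  for (i in 1:L) {
    sc <- ifelse(wv == qv[i] & qv[i] != "N", match, mismatch)
    I[i + 1, 2:(W + 1)] <- pmax(H[i, 2:(W + 1)] + open,
                                I[i, 2:(W + 1)] + ext)
    m_row <- H[i, 1:W] + sc
    for (j in 1:W) {
      D[i + 1, j + 1] <- max(H[i + 1, j] + open, D[i + 1, j] + ext)
      h <- max(m_row[j], I[i + 1, j + 1], D[i + 1, j + 1])
      if (local && h < 0) h <- 0
      H[i + 1, j + 1] <- h
    }
  }
  if (local) max(H) else max(H[L + 1, ])
}

## per-column asymmetric 4-letter recount
oracle_diff4 <- function(read, refseq, start, cigar, space) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  gv <- strsplit(refseq, "", fixed = TRUE)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  qp <- 1L; rp <- start + 1L; diff <- 0L
  for (tok in toks) {
    n <- as.integer(sub("[MIDS]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    if (op == "M") {
      for (t in seq_len(n)) {
        a <- rv[qp + t - 1L]; b <- gv[rp + t - 1L]
        ok <- (a == b && a != "N") ||
          (space == "C2T" && a == "T" && b == "C") ||
          (space == "G2A" && a == "A" && b == "G")
        if (!ok) diff <- diff + 1L
      }
      qp <- qp + n; rp <- rp + n
    } else if (op == "I") { diff <- diff + n; qp <- qp + n
    } else if (op == "D") { diff <- diff + n; rp <- rp + n
    } else { qp <- qp + n }
  }
  diff
}

## independent context labelling via direct string inspection
oracle_context <- function(seq, pos, strand) {
  n <- nchar(seq)
  at <- function(i) if (i < 0 || i >= n) "" else substring(seq, i + 1, i + 1)
  comp <- function(b) chartr("ACGTN", "TGCAN", b)
  if (strand == "+") { b1 <- at(pos + 1); b2 <- at(pos + 2) }
  else { b1 <- comp(at(pos - 1)); b2 <- comp(at(pos - 2)) }
  if (!b1 %in% c("A", "C", "G", "T")) return("unknown")
  if (b1 == "G") return("CpG")
  if (!b2 %in% c("A", "C", "G", "T")) return("unknown")
  if (b2 == "G") "CHG" else "CHH"
}

## random nucleotide string
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## mutate a sequence with k substitutions drawn from `alphabet` (use the
## reduced alphabet for 3-letter-space queries so converted-space invariants
## hold)
mutate_subs <- function(seq, k, alphabet = c("A", "C", "G", "T")) {
  if (k == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(alphabet, v[p]), 1)
  paste(v, collapse = "")
}

A3_C2T <- c("A", "G", "T")   # the C2T 3-letter alphabet

## small temporary FASTA writer
write_tmp_fasta <- function(seqs, width = 0) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else writeLines(s, con)
  }
  path
}
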