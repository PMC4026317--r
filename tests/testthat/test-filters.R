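# 4-letter asymmetric recount, false-positive removal and ambiguity
# resolution.

test_that("asymmetric matching follows the bisulfite chemistry", {
  # read T over genome C is a match in C2T space
  g <- bs_genome(c(chr = "CTGT"))
  expect_equal(count_differences_4letter("TTGT", g, "chr", 0L, "4M", "C2T"), 0L)
  # the reverse direction (read C over genome T) is a mismatch even though
  # the 3-letter encodings are identical
  g2 <- bs_genome(c(chr = "TACG"))
  expect_equal(count_differences_4letter("CACG", g2, "chr", 0L, "4M", "C2T"), 1L)
  # read A over genome G matches in G2A space
  g3 <- bs_genome(c(chr = "GAGA"))
  expect_equal(count_differences_4letter("AAAA", g3, "chr", 0L, "4M", "G2A"), 0L)
  # but not in C2T space
  expect_equal(count_differences_4letter("AAAA", g3, "chr", 0L, "4M", "C2T"), 2L)
})

test_that("indels and soft clips are counted as specified", {
  g <- bs_genome(c(chr = "AACCGGTTAA"))
  # 2 inserted bases count 2; soft-clipped bases count 0
  expect_equal(count_differences_4letter("AACCGG", g, "chr", 0L, "4M2I",
                                         "C2T"), 2L)
  expect_equal(count_differences_4letter("GGAACC", g, "chr", 0L, "2S4M",
                                         "C2T"), 0L)
  # a deletion consumes reference and counts its length
  expect_equal(count_differences_4letter("AAGGTTAA", g, "chr", 0L, "2M2D6M",
                                         "C2T"), 2L)
  # inconsistent edit scripts are a hard error
  expect_error(count_differences_4letter("AACC", g, "chr", 0L, "6M", "C2T"),
               "edit script|inconsistent")
  expect_error(count_differences_4letter("AACC", g, "chr", 8L, "4M", "C2T"),
               "inconsistent")
})

test_that("recount equals an independent per-column oracle", {
  set.seed(99)
  gseq <- rand_seq(3000)
  g <- bs_genome(c(chr = gseq))
  n_checked <- 0L
  for (i in 1:300) {
    start <- sample(2800, 1)
    space <- sample(c("C2T", "G2A"), 1)
    # build a random edit script and a read consistent with it
    ops <- c("M", sample(c("M", "M", "M", "I", "D"), sample(1:3, 1),
                         replace = TRUE), "M")
    lens <- pmax(1L, stats::rpois(length(ops), 8))
    read_parts <- character(0)
    rp <- start
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        seg <- substring(gseq, rp + 1, rp + lens[k])
        segv <- strsplit(seg, "", fixed = TRUE)[[1]]
        for (t in seq_along(segv)) {
          r <- runif(1)
          if (r < 0.25 && space == "C2T" && segv[t] == "C") segv[t] <- "T"
          else if (r < 0.25 && space == "G2A" && segv[t] == "G") segv[t] <- "A"
          else if (r < 0.35) segv[t] <- sample(c("A", "C", "G", "T"), 1)
        }
        read_parts <- c(read_parts, paste(segv, collapse = ""))
        rp <- rp + lens[k]
      } else if (ops[k] == "I") {
        read_parts <- c(read_parts, rand_seq(lens[k]))
      } else {
        rp <- rp + lens[k]
      }
    }
    read <- paste(read_parts, collapse = "")
    cigar <- paste0(lens, ops, collapse = "")
    mine <- count_differences_4letter(read, g, "chr", start, cigar, space)
    expect_equal(mine, oracle_diff4(read, gseq, start, cigar, space))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 300L)
})

test_that("validation threshold is inclusive and monotone in max_diff", {
  hits <- data.frame(qidx = 1L, name = "chr", start = 0L, cigar = "4M",
                     mm3 = 0L, gaps = 0L, score = 4L, pass = 1L)
  g <- bs_genome(c(chr = "TACG"))
  v2 <- validate_hits(hits, "CACG", g, "C2T", max_diff = 2)
  expect_true(v2$valid)         # diff4 = 1 <= 2
  v1 <- validate_hits(hits, "CACG", g, "C2T", max_diff = 1)
  expect_true(v1$valid)         # boundary inclusive: diff4 = 1 <= 1
  v0 <- validate_hits(hits, "CACG", g, "C2T", max_diff = 0)
  expect_false(v0$valid)        # false positive removed
  # increasing max_diff never invalidates a hit
  for (m in 0:5) {
    vm <- validate_hits(hits, "CACG", g, "C2T", max_diff = m)
    if (m >= 1) expect_true(vm$valid)
  }
})

make_hit <- function(pass, score, diff4 = 0L, name = "chr", start = 0L) {
  data.frame(qidx = 1L, name = name, start = start, cigar = "10M", mm3 = 0L,
             gaps = 0L, score = score, pass = pass, diff4 = diff4,
             valid = TRUE)
}

test_that("resolve_read implements both ambiguity rules", {
  # one valid hit in one pass: unique-best
  r1 <- resolve_read(make_hit(1, 10))
  expect_equal(r1$status, "unique-best")
  expect_true(is.na(r1$rule))

  # equal-best hits in two passes: rule (i)
  r2 <- resolve_read(rbind(make_hit(1, 10), make_hit(2, 10, start = 50L)))
  expect_equal(r2$status, "ambiguous")
  expect_equal(r2$rule, "i")
  expect_null(r2$chosen)

  # two equal-best hits within one pass: rule (ii)
  r3 <- resolve_read(rbind(make_hit(1, 10), make_hit(1, 10, start = 50L)))
  expect_equal(r3$status, "ambiguous")
  expect_equal(r3$rule, "ii")

  # a strictly better hit in one pass wins despite worse hits elsewhere
  r4 <- resolve_read(rbind(make_hit(1, 10), make_hit(2, 8, start = 50L)))
  expect_equal(r4$status, "unique-best")
  expect_equal(r4$chosen$pass, 1L)

  # keep_ambiguous retains the deterministic best hit
  r5 <- resolve_read(rbind(make_hit(1, 10, start = 70L),
                           make_hit(2, 10, start = 50L)),
                     keep_ambiguous = TRUE)
  expect_equal(r5$status, "ambiguous")
  expect_equal(r5$chosen$start, 50L)   # (chrom, start, pass) order

  # all hits invalid: filtered; no hits: unmapped
  inv <- make_hit(1, 10); inv$valid <- FALSE
  expect_equal(resolve_read(inv)$status, "filtered")
  expect_equal(resolve_read(inv[0, ])$status, "unmapped")
})

test_that("report policies retain the documented hit sets", {
  hits <- rbind(make_hit(1, 10), make_hit(1, 8, start = 30L),
                make_hit(2, 10, start = 50L), make_hit(2, 6, start = 70L))
  expect_equal(nrow(resolve_read(hits, "unique-best")$retained), 1L)
  expect_equal(nrow(resolve_read(hits, "all-best")$retained), 2L)
  expect_equal(nrow(resolve_read(hits, "all-valid")$retained), 4L)
})

test_that("hits are validated before resolution (filter-order regression)", {
  # the higher-scoring hit is a 4-letter false positive; the read must
  # resolve to the valid lower-scoring hit instead of being dropped
  a <- make_hit(1, 10, diff4 = 7L); a$valid <- FALSE
  b <- make_hit(2, 8, diff4 = 1L, start = 50L)
  r <- resolve_read(rbind(a, b))
  expect_equal(r$status, "unique-best")
  expect_equal(r$chosen$pass, 2L)
  expect_equal(r$chosen$start, 50L)
})

test_that("score ties break by diff4 before coordinates", {
  a <- make_hit(1, 10, diff4 = 2L, start = 10L)
  b <- make_hit(1, 9, diff4 = 0L, start = 90L)
  r <- resolve_read(rbind(a, b))
  expect_equal(r$chosen$start, 10L)  # higher score wins outright
  c1 <- make_hit(1, 10, diff4 = 2L, start = 10L)
  c2 <- make_hit(1, 10, diff4 = 0L, start = 90L)
  r2 <- resolve_read(rbind(c1, c2))
  # equal best scores in one pass: ambiguous, but the retained order puts
  # the smaller diff4 first
  expect_equal(r2$status, "ambiguous")
  expect_equal(r2$retained$start[1], 90L)
})

test_that("disabling the ambiguity filter never loses unique-best reads", {
  g <- random_genome(c(chr1 = 4000L), seed = 61)
  # duplicate a block to create genuine ambiguity
  s <- g$sequences[["chr1"]]
  dup <- paste0(substring(s, 1, 3000), substring(s, 1001, 1500),
                substring(s, 3001, 4000))
  gd <- bs_genome(c(chr1 = dup))
  spec <- simulation_spec(n_reads = 300, read_length = 60, error_rate = 0,
                          seed = 62)
  sim <- simulate_wgbs(gd, spec)
  params <- alignment_params(mode = "ungapped")
  m_drop <- map_reads(sim$reads, gd, params, keep_ambiguous = FALSE)
  m_keep <- map_reads(sim$reads, gd, params, keep_ambiguous = TRUE)
  # same reads flagged ambiguous; with keep_ambiguous they carry a hit
  amb <- m_drop$reads$status == "ambiguous"
  expect_equal(m_keep$reads$status == "ambiguous", amb)
  expect_true(all(!is.na(m_keep$reads$chrom[amb])))
  expect_true(all(is.na(m_drop$reads$chrom[amb])))
  # mapped-read count never decreases when the filter is disabled
  expect_gte(sum(!is.na(m_keep$reads$chrom)), sum(!is.na(m_drop$reads$chrom)))
  # reads that stay unique-best report identical hits either way
  ub <- m_drop$reads$status == "unique-best"
  expect_equal(m_drop$reads[ub, c("chrom", "start", "cigar")],
               m_keep$reads[ub, c("chrom", "start", "cigar")])
})

test_that("pipeline resolution agrees with per-read resolve_read", {
  g <- random_genome(c(chr1 = 3000L, chr2 = 2000L), seed = 63)
  # duplicated block across chromosomes provokes rule-i style ties too
  s1 <- g$sequences[["chr1"]]
  g <- bs_genome(c(chr1 = s1,
                   chr2 = paste0(substring(s1, 1, 500),
                                 g$sequences[["chr2"]])))
  spec <- simulation_spec(n_reads = 400, read_length = 60, error_rate = 0.04,
                          library_type = "non-directional", seed = 64)
  sim <- simulate_wgbs(g, spec)
  params <- alignment_params(mode = "ungapped", report_policy = "all-valid",
                             max_hits = Inf)
  m <- map_reads(sim$reads, g, params, library_type = "non-directional")
  # re-resolve every read from its retained all-valid hits with the
  # single-read reference implementation
  hits <- m$hits
  for (id in unique(m$reads$id)) {
    h <- hits[!is.na(hits$qid) & hits$qid == id, , drop = FALSE]
    if (nrow(h) == 0) next
    h$valid <- TRUE
    ref <- resolve_read(h)
    row <- m$reads[m$reads$id == id, ]
    expect_equal(row$status, ref$status)
    if (!is.na(ref$rule)) expect_equal(row$rule, ref$rule)
    if (row$status == "unique-best") {
      expect_equal(row$chrom, ref$chosen$name)
      expect_equal(row$start, ref$chosen$start)
    }
  }
})
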