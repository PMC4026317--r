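# Evaluation metrics, SAM emission and the command-line interface.

fake_reads <- function(n, n_ub, n_ok) {
  # synthetic outcome table: first n_ok unique-best+correct, then wrong ones
  truth <- data.frame(id = paste0("r", 1:n), chrom = "chr1",
                      start = 10L * (1:n), class = "+FW",
                      stringsAsFactors = FALSE)
  rd <- data.frame(id = truth$id, status = "unmapped", class = NA_character_,
                   chrom = NA_character_, start = NA_integer_,
                   diff4 = NA_integer_, stringsAsFactors = FALSE)
  if (n_ub > 0) {
    rd$status[1:n_ub] <- "unique-best"
    rd$chrom[1:n_ub] <- "chr1"
    rd$class[1:n_ub] <- "+FW"
    rd$start[1:n_ub] <- truth$start[1:n_ub]
    rd$diff4[1:n_ub] <- 0L
    if (n_ub > n_ok) rd$start[(n_ok + 1):n_ub] <- 1L  # wrong locus
  }
  list(reads = rd, truth = truth)
}

test_that("precision, recall and F1 follow their definitions", {
  x <- fake_reads(100, 80, 60)
  m <- score_mappings(x$reads, x$truth)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.60)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round(m$f1, 4), 0.6667)

  all_ok <- fake_reads(50, 50, 50)
  m2 <- score_mappings(all_ok$reads, all_ok$truth)
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(1, 1, 1))

  none <- fake_reads(50, 0, 0)
  m3 <- score_mappings(none$reads, none$truth)
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))  # no 0/0 error
  # F1 never exceeds the arithmetic mean
  expect_lte(m$f1, (m$precision + m$recall) / 2)
})

test_that("start tolerance and class mismatches are enforced", {
  x <- fake_reads(10, 10, 10)
  x$reads$start[1] <- x$truth$start[1] + 3L
  x$reads$class[2] <- "-FW"
  m0 <- score_mappings(x$reads, x$truth, tolerance = 0)
  expect_equal(m0$n_correct, 8L)
  m5 <- score_mappings(x$reads, x$truth, tolerance = 5)
  expect_equal(m5$n_correct, 9L)   # the shifted start is forgiven, not the class
  # unknown ids are a hard error
  bad <- x$reads; bad$id[1] <- "stranger"
  expect_error(score_mappings(bad, x$truth), "missing from truth")
})

test_that("cumulative_by_differences is a nondecreasing step table", {
  rd <- data.frame(id = paste0("r", 1:4),
                   status = c("unique-best", "unique-best", "unique-best",
                              "unique-best"),
                   diff4 = c(0L, 1L, 1L, 3L))
  tab <- cumulative_by_differences(rd, 3)
  expect_equal(tab$fraction, c(0.25, 0.75, 0.75, 1.0))
  expect_true(all(diff(tab$fraction) >= 0))
  # unmapped reads dilute the fractions
  rd2 <- rbind(rd, data.frame(id = "r5", status = "unmapped",
                              diff4 = NA_integer_))
  tab2 <- cumulative_by_differences(rd2, 3)
  expect_equal(tab2$fraction[4], 0.8)
})

test_that("SAM records follow the coordinate and flag conventions", {
  g <- random_genome(c(chr1 = 2000L), seed = 201)
  s <- g$sequences[["chr1"]]
  reads <- data.frame(
    id = c("fw", "crick", "lost"),
    seq = c(substring(s, 100, 149),                       # +FW at 0-based 99
            reverse_complement(substring(s, 300, 349)),   # -FW at 0-based 299
            strrep("N", 50)),                             # unmappable
    stringsAsFactors = FALSE)
  m <- map_reads(reads, g, alignment_params(mode = "ungapped"))
  path <- tempfile(fileext = ".sam")
  write_sam(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@HD\tVN:", lines)))
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:2000$", lines)))
  body <- lines[!grepl("^@", lines)]
  f <- strsplit(body[grepl("^fw\t", body)], "\t")[[1]]
  expect_equal(as.integer(f[2]), 0L)
  expect_equal(as.integer(f[4]), 100L)        # 1-based POS
  expect_equal(f[6], "50M")
  expect_true("ZC:Z:+FW" %in% f)
  cr <- strsplit(body[grepl("^crick\t", body)], "\t")[[1]]
  expect_equal(as.integer(cr[2]), 16L)        # reverse flag
  expect_equal(as.integer(cr[4]), 300L)
  expect_true("ZC:Z:-FW" %in% cr)
  expect_equal(cr[10], substring(s, 300, 349))  # SEQ stored as aligned
  lost <- strsplit(body[grepl("^lost\t", body)], "\t")[[1]]
  expect_equal(as.integer(lost[2]), 4L)       # unmapped flag
  expect_true(any(grepl("^ZF:Z:", lost)))
})

test_that("SAM round-trips through an external parser with tags intact", {
  skip_if_not_installed("Rsamtools")
  g <- random_genome(c(chr1 = 10000L), seed = 211)
  spec <- simulation_spec(n_reads = 200, read_length = 60, error_rate = 0.02,
                          seed = 212)
  sim <- simulate_wgbs(g, spec)
  m <- map_reads(sim$reads, g, alignment_params(mode = "ungapped"))
  path <- tempfile(fileext = ".sam")
  write_sam(m, path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)  # validates
  p <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "strand", "seq"),
    tag = c("ZC", "ZP", "ZM")))[[1]]
  expect_equal(length(p$qname), nrow(m$reads))
  mapped <- !is.na(p$pos)
  # recomputing diff4 from the parsed records reproduces the ZM tag
  spaces <- ifelse(p$tag$ZC[mapped] %in% c("+FW", "+RC"), "C2T", "G2A")
  diff4 <- count_differences_4letter(
    as.character(p$seq[mapped]), g, as.character(p$rname[mapped]),
    p$pos[mapped] - 1L, p$cigar[mapped], spaces)
  expect_equal(diff4, p$tag$ZM[mapped])
})

test_that("run summaries and metric files are machine readable", {
  g <- random_genome(c(chr1 = 3000L), seed = 221)
  spec <- simulation_spec(n_reads = 50, read_length = 50, seed = 222)
  sim <- simulate_wgbs(g, spec)
  m <- map_reads(sim$reads, g, alignment_params(mode = "ungapped"))
  f <- tempfile()
  write_run_summary(m, f)
  tab <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_true(all(c("version", "mode", "unique_best") %in% tab$V1))
  mt <- tempfile()
  write_metrics_tsv(score_mappings(m, sim$truth), mt)
  mtab <- read.table(mt, sep = "\t", header = TRUE)
  expect_equal(mtab$value[mtab$metric == "precision"], 1)
})

test_that("the command line maps, simulates and evaluates end to end", {
  dir <- tempfile(); dir.create(dir)
  g <- random_genome(c(chr1 = 5000L), seed = 231)
  ref <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$sequences), ref)

  fq <- file.path(dir, "reads.fq")
  tr <- file.path(dir, "truth.tsv")
  st <- suppressMessages(bsmapr_cli(c(
    "simulate", "--ref", ref, "--out", fq, "--truth", tr,
    "--n-reads", "80", "--read-length", "50", "--error-rate", "0.02",
    "--seed", "7")))
  expect_equal(st, 0L)
  expect_true(file.exists(fq) && file.exists(tr))

  # seeded simulation is reproducible through the CLI
  fq2 <- file.path(dir, "reads2.fq")
  suppressMessages(bsmapr_cli(c(
    "simulate", "--ref", ref, "--out", fq2, "--truth",
    file.path(dir, "t2.tsv"), "--n-reads", "80", "--read-length", "50",
    "--error-rate", "0.02", "--seed", "7")))
  expect_identical(readLines(fq), readLines(fq2))

  sam <- file.path(dir, "out.sam")
  st2 <- suppressMessages(bsmapr_cli(c(
    "map", "--ref", ref, "--reads", fq, "--out", sam,
    "-m", "5", "--ungapped", "-l", "2",
    "--summary", file.path(dir, "run.tsv"))))
  expect_equal(st2, 0L)
  expect_true(file.exists(sam))
  expect_true(file.exists(file.path(dir, "run.tsv")))

  st3 <- suppressMessages(bsmapr_cli(c(
    "evaluate", "--ref", ref, "--reads", fq, "--truth", tr,
    "--ungapped", "--out", file.path(dir, "metrics.tsv"))))
  expect_equal(st3, 0L)
  met <- read.table(file.path(dir, "metrics.tsv"), sep = "\t", header = TRUE)
  expect_gte(met$value[met$metric == "precision"], 0.95)

  meth <- file.path(dir, "meth.tsv")
  st4 <- suppressMessages(bsmapr_cli(c(
    "call", "--ref", ref, "--reads", fq, "--out", meth, "--ungapped")))
  expect_equal(st4, 0L)
  expect_gt(nrow(read.table(meth, header = TRUE, sep = "\t")), 0L)

  # digestion subcommand and the converted-reference index
  g2 <- bs_genome(c(chr = "TTCCGGAAACCGGTT"))
  ref2 <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g2$sequences), ref2)
  bed <- file.path(dir, "frags.bed")
  st5 <- suppressMessages(bsmapr_cli(c(
    "digest", "--ref", ref2, "-d", "C-CGG", "--low", "4", "--high", "8",
    "--out", bed)))
  expect_equal(st5, 0L)
  frags <- read.table(bed, sep = "\t")
  expect_equal(frags$V2, c(0L, 3L, 10L))
  idx <- file.path(dir, "idx")
  st6 <- suppressMessages(bsmapr_cli(c("index", "--ref", ref2, "--out-dir",
                                       idx)))
  expect_equal(st6, 0L)
  c2t <- Biostrings::readDNAStringSet(file.path(idx, "C2T.fa"))
  expect_equal(as.character(c2t[[1]]), "TTTTGGAAATTGGTT")
})

test_that("conflicting and malformed CLI flags fail cleanly", {
  expect_equal(suppressMessages(bsmapr_cli(c("map", "--ungapped", "--e2e",
                                             "--ref", "x", "--reads", "y",
                                             "--out", "z"))), 1L)
  expect_equal(suppressMessages(bsmapr_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(bsmapr_cli(c("map", "--no-such-flag"))), 1L)
  expect_output(bsmapr_cli("help"), "usage: bsmapr")
})
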