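params <- scoring_params()

test_that("six_frame_translate produces six frames matching translate", {
  fr <- six_frame_translate("ATGAAA", "c")
  expect_equal(nrow(fr), 6)
  expect_equal(fr$prot[fr$strand == "+" & fr$offset == 0], "MK")
  expect_equal(fr$prot[fr$strand == "-" & fr$offset == 0],
               translate(reverse_complement("ATGAAA"), 0))
  # oracle: per-frame translate calls on a random 300-mer
  set.seed(21)
  s <- rand_nuc(300)
  fr2 <- six_frame_translate(s, "r")
  rc <- reverse_complement(s)
  for (i in seq_len(nrow(fr2))) {
    src <- if (fr2$strand[i] == "+") s else rc
    expect_equal(fr2$prot[i], translate(src, fr2$offset[i]))
  }
  expect_warning(short <- six_frame_translate("AT", "tiny"), "shorter")
  expect_equal(nrow(short), 0)
})

test_that("local_align matches scoring contract and the DP oracle", {
  a <- local_align("MKT", "MKT", params)
  expect_equal(a$raw_score, 15L)  # BLOSUM62 diagonal M=K=T=5
  expect_equal(a$q_aln, "MKT")
  b <- local_align("AAAA", "CCCC", params)
  expect_equal(b$raw_score, 0L)
  expect_equal(b$q_aln, "")
  set.seed(22)
  for (i in 1:40) {
    q <- rand_prot(sample(3:12, 1))
    s <- rand_prot(sample(3:12, 1))
    expect_equal(local_align(q, s, params)$raw_score,
                 as.integer(oracle_align_score(q, s, type = "local")),
                 info = paste(q, s))
  }
})

test_that("bitscore and evalue follow the Karlin-Altschul forms", {
  # frozen hand evaluations of (lambda*S - ln K)/ln 2
  expect_equal(bitscore(0, params), 4.60825, tolerance = 1e-5)
  expect_equal(bitscore(100, params), 43.12833, tolerance = 1e-5)
  raws <- seq(0, 500, by = 25)
  expect_true(all(diff(bitscore(raws, params)) > 0))

  expect_equal(evalue(0, 100, 1e6), 1e8)  # 2^0 = 1
  expect_equal(evalue(43.12833, 100, 1e6), 1.043e-5, tolerance = 1e-3)
  # halves per extra bit
  expect_equal(evalue(11, 50, 1e5), evalue(10, 50, 1e5) / 2)
})

test_that("search recovers planted contigs and respects strand", {
  set.seed(23)
  contig <- rand_nuc(120)
  decoys <- vapply(1:4, function(i) rand_nuc(120), character(1))
  contigs <- seq_records(c("t", paste0("d", 1:4)), c(contig, decoys),
                         "nucleotide")
  q <- list(id = "q", seq = translate(contig, 0))
  hits <- search(q, contigs, params)
  expect_equal(hits$sseqid[1], "t")
  expect_equal(hits$pident[1], 100)
  expect_equal(hits$strand[1], "+")

  # strand symmetry: reverse-complementing the database preserves
  # bitscores and flips strands
  rc_contigs <- contigs
  rc_contigs$seq <- vapply(contigs$seq, reverse_complement, character(1))
  hits_rc <- search(q, rc_contigs, params)
  expect_equal(hits_rc$sseqid[1], "t")
  expect_equal(hits_rc$bitscore[1], hits$bitscore[1])
  expect_equal(hits_rc$strand[1], "-")
  expect_true(hits_rc$sstart[1] > hits_rc$send[1])
})

test_that("search ranking matches the all-pairs DP oracle", {
  set.seed(24)
  # one orthologue planted at high identity, one at moderate, decoys
  base <- rand_nuc(90)
  mutate_nt <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(NTS, ch[p]), 1)
    paste(ch, collapse = "")
  }
  contigs <- seq_records(
    c("hi", "lo", paste0("d", 1:8)),
    c(mutate_nt(base, 8), mutate_nt(base, 30),
      vapply(1:8, function(i) rand_nuc(90), character(1))),
    "nucleotide")
  q <- list(id = "q", seq = translate(base, 0))
  hits <- search(q, contigs, params, evalue_cutoff = Inf)
  oracle <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    oracle_frame_scores(q$seq, contigs$seq[i], contigs$id[i])
  }))
  oracle <- oracle[oracle$score > 0, ]
  # every reported HSP's raw score equals the oracle's for that frame
  for (i in seq_len(nrow(hits))) {
    o <- oracle[oracle$contig_id == hits$sseqid[i] &
                oracle$strand == hits$strand[i] &
                oracle$offset == hits$frame_offset[i], ]
    expect_equal(hits$raw_score[i], as.integer(o$score))
  }
  expect_equal(nrow(hits), nrow(oracle))
  # contig ranking by best score agrees
  oracle_best <- tapply(oracle$score, oracle$contig_id, max)
  oracle_rank <- names(sort(oracle_best, decreasing = TRUE))
  expect_equal(unique(hits$sseqid)[1:2], oracle_rank[1:2])
  expect_equal(unique(hits$sseqid)[1:2], c("hi", "lo"))
})

test_that("E-value filtering is honoured and monotone in the cutoff", {
  set.seed(25)
  contigs <- seq_records(paste0("c", 1:5),
                         vapply(1:5, function(i) rand_nuc(150),
                                character(1)), "nucleotide")
  q <- list(id = "q", seq = translate(contigs$seq[1], 0))
  cutoffs <- c(1e-10, 1e-4, 1, 1e4, Inf)
  counts <- vapply(cutoffs, function(ct) {
    h <- search(q, contigs, params, evalue_cutoff = ct)
    expect_true(all(h$evalue <= ct))
    nrow(h)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reverse_search reports the planted protein on top", {
  set.seed(26)
  cds <- paste0("ATG", rand_nuc_codons(49))
  p <- translate(cds, 0)
  q30 <- strsplit(p, "")[[1]]
  idx <- sample(seq_along(q30), round(0.3 * length(q30)))
  for (i in idx) q30[i] <- sample(setdiff(AAS, q30[i]), 1)
  prots <- seq_records(c("P", "Q"), c(p, paste(q30, collapse = "")),
                       "protein")
  contig <- list(id = "c1", seq = cds)
  hits <- reverse_search(contig, prots, params)
  expect_equal(hits$sseqid[1], "P")
  expect_equal(hits$pident[1], 100)
  # all-N contig: no positive-scoring alignment
  expect_equal(nrow(reverse_search(list(id = "n", seq = strrep("N", 60)),
                                   prots, params)), 0)
})

test_that("outfmt-6 writer/reader round-trips bit-exactly", {
  set.seed(27)
  contigs <- seq_records(paste0("c", 1:3),
                         vapply(1:3, function(i) rand_nuc(200),
                                character(1)), "nucleotide")
  q <- list(id = "q", seq = translate(contigs$seq[2], 0))
  hits <- search(q, contigs, params, evalue_cutoff = Inf)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_outfmt6(hits, f1)
  back <- read_outfmt6(f1)
  write_outfmt6(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # reader tolerates extra trailing columns
  f3 <- withr::local_tempfile(
    lines = paste(readLines(f1), "extra1", "extra2", sep = "\t"))
  expect_equal(read_outfmt6(f3), back)
})
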