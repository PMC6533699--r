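params <- scoring_params()

# Small planted world shared by several blocks: three genes with exact
# CDS contigs plus decoys.
make_planted <- function(seed = 41, n_genes = 3, len_aa = 60) {
  set.seed(seed)
  cds <- vapply(seq_len(n_genes), function(i)
    paste0("ATG", rand_nuc_codons(len_aa - 1), "TAA"), character(1))
  prots <- vapply(cds, function(s) sub("\\*$", "", translate(s, 0)),
                  character(1))
  ids <- sprintf("g%02d", seq_len(n_genes))
  contigs <- seq_records(c(paste0(ids, "_c1"), "decoy1", "decoy2"),
                         c(cds, rand_nuc(180), rand_nuc(180)),
                         "nucleotide")
  list(baits = seq_records(ids, unname(prots), "protein"),
       contigs = contigs)
}

test_that("best_contigs orders by bitscore, evalue, then contig id", {
  h <- data.frame(sseqid = c("c2", "c1", "c3"),
                  bitscore = c(150, 200, 200),
                  evalue = c(1e-20, 1e-50, 1e-40))
  expect_equal(best_contigs(h, 1), "c1")
  expect_equal(best_contigs(h, 2), c("c1", "c3"))
  expect_equal(best_contigs(h, 5), c("c1", "c3", "c2"))
  expect_equal(best_contigs(h[0, ], 1), character(0))
})

test_that("reciprocal_best_hit validates planted baits", {
  w <- make_planted()
  r <- reciprocal_best_hit(w$baits[1, ], w$contigs, w$baits, params)
  expect_true(r$is_rbh)
  expect_equal(r$best_contig_ids[1], "g01_c1")
  expect_equal(unname(r$reverse_top[1]), "g01")
  expect_equal(r$reverse_mode, "whole_contig")

  # longest-ORF reverse mode agrees on this clean fixture
  r2 <- reciprocal_best_hit(w$baits[1, ], w$contigs, w$baits, params,
                            reverse_mode = "longest_orf", min_aa = 30)
  expect_true(r2$is_rbh)
  expect_equal(r2$reverse_mode, "longest_orf")

  # bait missing from the reference set
  expect_error(
    reciprocal_best_hit(list(id = "zz", seq = w$baits$seq[1]),
                        w$contigs, w$baits, params),
    "absent")
})

test_that("a paralog-only database breaks reciprocity", {
  set.seed(42)
  cds <- paste0("ATG", rand_nuc_codons(79), "TAA")
  p <- sub("\\*$", "", translate(cds, 0))
  # paralog Q: 30% of residues changed at codon level
  ch <- strsplit(cds, "")[[1]]
  q_cds <- cds
  pos <- sample(2:79, 24)
  for (cp in pos) {
    codon_start <- 3 * (cp - 1) + 1
    repeat {
      new <- rand_nuc_codons(1)
      if (translate(new, 0) != translate(substr(q_cds, codon_start,
                                                codon_start + 2), 0) &&
          translate(new, 0) != "*") break
    }
    substr(q_cds, codon_start, codon_start + 2) <- new
  }
  q <- sub("\\*$", "", translate(q_cds, 0))
  reference <- seq_records(c("B", "Q"), c(p, q), "protein")
  contigs <- seq_records("q_c1", q_cds, "nucleotide")
  r <- reciprocal_best_hit(reference[1, ], contigs, reference, params)
  expect_equal(r$best_contig_ids, "q_c1")  # forward still finds it
  expect_equal(unname(r$reverse_top[1]), "Q")
  expect_false(r$is_rbh)

  # empty forward result
  r2 <- reciprocal_best_hit(reference[1, ],
                            seq_records("x", strrep("N", 90),
                                        "nucleotide"),
                            reference, params)
  expect_false(r2$is_rbh)
  expect_equal(length(r2$best_contig_ids), 0)
})

test_that("removing a bait's contig flips only that bait (locality)", {
  w <- make_planted(seed = 43)
  all_r <- lapply(seq_len(nrow(w$baits)), function(i)
    reciprocal_best_hit(w$baits[i, ], w$contigs, w$baits, params))
  expect_true(all(vapply(all_r, `[[`, logical(1), "is_rbh")))
  pruned <- w$contigs[w$contigs$id != "g02_c1", ]
  pruned_r <- lapply(seq_len(nrow(w$baits)), function(i)
    reciprocal_best_hit(w$baits[i, ], pruned, w$baits, params))
  expect_equal(vapply(pruned_r, `[[`, logical(1), "is_rbh"),
               c(TRUE, FALSE, TRUE))
})

test_that("detection_rate divides RBH count by total baits", {
  mk <- function(flag) structure(list(is_rbh = flag),
                                 class = "rbh_result")
  expect_equal(detection_rate(list(mk(TRUE), mk(TRUE), mk(FALSE),
                                   mk(FALSE)), 4), 50)
  expect_equal(detection_rate(replicate(10, mk(FALSE),
                                        simplify = FALSE), 10), 0)
  expect_error(detection_rate(list(), 0), "positive")
  expect_error(detection_rate(list(mk(TRUE), mk(TRUE)), 1), "smaller")
})

test_that("rbh_set_summary computes exclusive regions partitioning the union", {
  s <- rbh_set_summary(list(A = c("1", "2"), B = c("2", "3")))
  reg <- setNames(s$regions$count, s$regions$region)
  expect_equal(unname(reg[c("A", "B", "A&B")]), c(1, 1, 1))
  expect_equal(s$union_size, 3)

  ident <- rbh_set_summary(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$regions$count[ident$regions$region == "A&B"], 2)
  expect_equal(sum(ident$regions$count), ident$union_size)

  # partition property on random sets
  set.seed(44)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j)
      as.character(sample(1:200, 100, replace = FALSE)))
    names(sets) <- c("brain", "kidney", "liver")
    sm <- rbh_set_summary(sets)
    expect_equal(sum(sm$regions$count), sm$union_size)
    expect_equal(sm$union_size, length(unique(unlist(sets))))
  }
  expect_error(rbh_set_summary(list(A = "1")))
})
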