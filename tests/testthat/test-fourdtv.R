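test_that("fourfold-site classification follows the standard code", {
  expect_true(is_fourfold_site("GGT", "GGA"))   # Gly family
  expect_false(is_fourfold_site("AGA", "AGG"))  # AG* splits Arg/Ser
  expect_false(is_fourfold_site("GGT", "GCT"))  # prefix differs
  expect_false(is_fourfold_site("GG-", "GGA"))  # gap excluded
  expect_false(is_fourfold_site("GGN", "GGA"))  # N excluded
  expect_error(is_fourfold_site("GGTT", "GGA"), "3 characters")

  # every prefix the implementation accepts is fourfold by the 64-entry table
  prefixes <- unique(substr(names(oracle_code), 1, 2))
  for (pre in prefixes) {
    codon <- paste0(pre, "A")
    expect_identical(is_fourfold_site(codon, codon),
                     oracle_is_fourfold_codon(codon),
                     info = pre)
  }
})

test_that("fourdtv matches hand-enumerated examples", {
  res <- fourdtv(tibble::tibble(pair_id = "p1",
                                seq_a = "GGTCCTATG", seq_b = "GGACCCATG"))
  expect_equal(res$n_4d_sites, 2L)       # GG* and CC* columns; ATG not 4D
  expect_equal(res$n_transversions, 1L)  # T<->A transversion; T<->C transition
  expect_equal(res$fourdtv, 0.5)

  res2 <- fourdtv(tibble::tibble(pair_id = "p2", seq_a = "CCT", seq_b = "CCC"))
  expect_equal(res2$n_4d_sites, 1L)
  expect_equal(res2$n_transversions, 0L)
  expect_equal(res2$fourdtv, 0)

  # identical sequences always give zero transversions
  s <- paste(rep("GGA", 20), collapse = "")
  res3 <- fourdtv(tibble::tibble(pair_id = "p3", seq_a = s, seq_b = s))
  expect_equal(res3$n_transversions, 0L)
  expect_equal(res3$fourdtv, 0)

  # zero scorable sites is not an error
  res4 <- fourdtv(tibble::tibble(pair_id = "p4", seq_a = "ATG", seq_b = "ATG"))
  expect_false(res4$defined)
  expect_true(is.na(res4$fourdtv))
})

test_that("fourdtv equals the brute-force oracle and is symmetric", {
  set.seed(101)
  for (i in 1:50) {
    pr <- random_codon_pair(sample(10:80, 1))
    res <- fourdtv(tibble::tibble(pair_id = "x", seq_a = pr$seq_a,
                                  seq_b = pr$seq_b))
    orc <- oracle_4dtv(pr$seq_a, pr$seq_b)
    expect_identical(res$n_4d_sites, orc$n_4d)
    expect_identical(res$n_transversions, orc$n_tv)
    rev <- fourdtv(tibble::tibble(pair_id = "x", seq_a = pr$seq_b,
                                  seq_b = pr$seq_a))
    expect_identical(res$n_4d_sites, rev$n_4d_sites)
    expect_identical(res$n_transversions, rev$n_transversions)
  }
})

test_that("replacing a non-fourfold column leaves the result unchanged", {
  set.seed(11)
  base_a <- "GGTATGCCC"
  base_b <- "GGAATGCCT"
  res0 <- fourdtv(tibble::tibble(pair_id = "m", seq_a = base_a, seq_b = base_b))
  # swap the ATG/ATG column for other non-fourfold columns
  for (repl in c("TGG", "AAA", "ATT")) {
    a2 <- paste0("GGT", repl, "CCC")
    b2 <- paste0("GGA", repl, "CCT")
    res1 <- fourdtv(tibble::tibble(pair_id = "m", seq_a = a2, seq_b = b2))
    expect_identical(res1$n_4d_sites, res0$n_4d_sites)
    expect_identical(res1$n_transversions, res0$n_transversions)
  }
})

test_that("alignment contract violations are rejected at load", {
  expect_error(as_codon_pairs(tibble::tibble(pair_id = "a", seq_a = "GGTA",
                                             seq_b = "GGTA")), "codon")
  expect_error(as_codon_pairs(tibble::tibble(pair_id = "a", seq_a = "GGT",
                                             seq_b = "GGTGGT")), "length")
  expect_error(as_codon_pairs(tibble::tibble(pair_id = "a", seq_a = "G-T",
                                             seq_b = "GGT")), "gap")
  expect_error(as_codon_pairs(tibble::tibble(pair_id = "a", seq_a = "GXT",
                                             seq_b = "GGT")), "invalid")
})

test_that("corrected 4DTv inverts the two-state saturation curve", {
  res <- fourdtv(tibble::tibble(pair_id = "p", seq_a = "GGTGGT", seq_b = "GGAGGT"),
                 corrected = TRUE)
  expect_equal(res$fourdtv, 0.5 * 0 + 0.5) # 1 tv of 2 sites
  expect_equal(res$fourdtv_corrected, Inf) # saturated at 0.5
  res2 <- fourdtv(tibble::tibble(pair_id = "p", seq_a = strrep("GGT", 10),
                                 seq_b = paste0("GGA", strrep("GGT", 9))),
                  corrected = TRUE)
  expect_equal(res2$fourdtv_corrected, -log(1 - 2 * 0.1) / 2)
})

test_that("anchor extraction enforces the five-anchor block rule", {
  seqs <- setNames(rep("GGTCCT", 14), paste0("g", 1:14))
  small_block <- tibble::tibble(block_id = "b0", gene_a = paste0("g", 1:4),
                                gene_b = paste0("g", 11:14))
  expect_error(extract_anchor_pairs(small_block, seqs), "no scorable pairs")

  ok_block <- tibble::tibble(block_id = "b1", gene_a = paste0("g", 1:5),
                             gene_b = paste0("g", c(6:10)))
  out <- extract_anchor_pairs(ok_block, seqs)
  expect_equal(nrow(out), 5L)

  # 5-anchor + 7-anchor blocks, one gene unresolvable -> 11 pairs + a log
  seqs2 <- setNames(rep("GGTCCT", 30), paste0("h", 1:30))
  anchors <- dplyr::bind_rows(
    tibble::tibble(block_id = "b1", gene_a = paste0("h", 1:5),
                   gene_b = paste0("h", 11:15)),
    tibble::tibble(block_id = "b2", gene_a = paste0("h", 16:22),
                   gene_b = paste0("h", 23:29)))
  seqs2 <- seqs2[names(seqs2) != "h20"]
  expect_message(out2 <- extract_anchor_pairs(anchors, seqs2), "skipped 1")
  expect_equal(nrow(out2), 11L)
})

test_that("tandem duplicates against a common homeolog are counted once", {
  positions <- tibble::tibble(
    gene = c("t1", "t2", "t3", "far", "X", "Y", "Z"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    rank = c(10, 11, 12, 18, 1, 2, 3))
  res <- tibble::tibble(
    pair_id = c("p1", "p2", "p3"),
    gene_a = c("t1", "t2", "t3"), gene_b = "X",
    n_4d_sites = c(5L, 9L, 7L))
  kept <- dedup_tandem(res, positions, window = 5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$gene_a, "t2")  # highest n_4d_sites wins

  # same genes against three DIFFERENT homeologs: all retained
  res2 <- dplyr::mutate(res, gene_b = c("X", "Y", "Z"))
  expect_equal(nrow(dedup_tandem(res2, positions, window = 5)), 3L)

  # outside the window: both retained (ranks 10 and 10 + window + 1 = 18, window 7)
  res3 <- tibble::tibble(pair_id = c("p1", "p4"), gene_a = c("t1", "far"),
                         gene_b = "X", n_4d_sites = c(5L, 5L))
  expect_equal(nrow(dedup_tandem(res3, positions, window = 7)), 2L)
  # tie on n_4d_sites: lexicographically smallest tandem gene id kept
  res4 <- dplyr::mutate(res, n_4d_sites = 5L)
  expect_equal(dedup_tandem(res4, positions, window = 5)$gene_a, "t1")

  expect_error(dedup_tandem(res, positions[-1, ], window = 5), "t1")
})
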