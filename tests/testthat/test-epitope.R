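test_that("15-mer enumeration yields L - 14 windows in order", {
  s20 <- paste(rep("ACDEF", 4), collapse = "")
  out <- enumerate_candidates(sequence = s20)
  expect_equal(nrow(out), 6)
  expect_equal(out$start, 1:6)
  expect_true(all(nchar(out$peptide) == 15))
  expect_equal(out$peptide[1], substr(s20, 1, 15))
  expect_equal(nrow(enumerate_candidates(sequence = strrep("A", 15))), 1)
  expect_equal(nrow(enumerate_candidates(sequence = strrep("A", 14))), 0)
})

test_that("invalid residues are reported with their position", {
  expect_error(enumerate_candidates(sequence = "ACDEFGHIKLMNPQRSTVWYX"),
               "position 21")
  expect_error(enumerate_candidates(sequence = "ACB"), "'B' at position 3")
})

test_that("short eluted peptides are skipped with a warning", {
  expect_warning(out <- enumerate_candidates(
    peptides = c(strrep("A", 14), paste0(strrep("C", 15), "D"))), "skipped")
  expect_equal(nrow(out), 2)           # two distinct windows from the 16-mer
  expect_true(all(out$start == 0))
  # identical windows from an eluted list collapse to one candidate
  expect_equal(nrow(enumerate_candidates(peptides = strrep("C", 16))), 1)
})

test_that("self-filter removes exact within-record matches only", {
  cand <- enumerate_candidates(sequence = paste0(strrep("A", 15),
                                                 strrep("C", 15)))
  prot <- c(rec1 = paste0("GGG", strrep("a", 15), "GGG"))  # lower case
  kept <- filter_self(cand, prot)
  expect_false(strrep("A", 15) %in% kept$peptide)
  expect_true(strrep("C", 15) %in% kept$peptide)
  # empty proteome retains everything
  expect_equal(filter_self(cand, character(0)), cand)
  # match split across two records is NOT a self hit
  pep <- "ACDEFGHIKLMNPQR"
  prot2 <- c(a = paste0("WWWWW", substr(pep, 1, 8)),
             b = paste0(substr(pep, 9, 15), "WWWWW"))
  cand2 <- data.frame(peptide = pep, start = 1L)
  expect_equal(nrow(filter_self(cand2, prot2)), 1)
  # idempotent and order preserving
  once <- filter_self(cand, prot)
  expect_identical(filter_self(once, prot), once)
})

test_that("greedy selection keeps the five best non-overlapping peptides", {
  # 10 mutually disjoint candidates with distinct ranks
  pep <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "D", "E"), 15, replace = TRUE), collapse = ""),
    "")
  set.seed(1)
  cand <- data.frame(peptide = pep, start = seq(1, by = 20, length.out = 10))
  ranks <- data.frame(peptide = pep, allele = "DRB1*01:01",
                      el_rank = c(5, 3, 8, 1, 9, 2, 7, 4, 10, 6))
  sel <- select_epitopes(cand, ranks, max_n = 5)
  expect_length(sel, 5)
  expect_equal(sort(vapply(sel, `[[`, 0, "best_rank")), 1:5)
  # under quota: both selected
  sel2 <- select_epitopes(cand[1:2, ], ranks, max_n = 5)
  expect_length(sel2, 2)
})

test_that("overlapping candidates are skipped per the greedy trace", {
  pep <- c(strrep("A", 15), strrep("C", 15), strrep("D", 15))
  cand <- data.frame(peptide = pep, start = c(1L, 8L, 30L))
  ranks <- data.frame(peptide = pep, allele = "X", el_rank = c(0.5, 0.7, 1.0))
  sel <- select_epitopes(cand, ranks)
  expect_equal(vapply(sel, `[[`, 0L, "start"), c(1L, 30L))
})

test_that("selection is invariant to candidate order and breaks ties deterministically", {
  pep <- c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC", "DDDDDDDDDDDDDDD")
  cand <- data.frame(peptide = pep, start = c(1L, 40L, 20L))
  ranks <- data.frame(peptide = pep, allele = "X", el_rank = c(1, 1, 1))
  sel1 <- select_epitopes(cand, ranks, max_n = 2)
  sel2 <- select_epitopes(cand[c(3, 1, 2), ], ranks, max_n = 2)
  expect_identical(sel1, sel2)
  # equal rank: smaller start wins
  expect_equal(vapply(sel1, `[[`, 0L, "start"), c(1L, 20L))
  # candidates from eluted lists (start 0) never overlap
  cand0 <- data.frame(peptide = pep, start = 0L)
  expect_length(select_epitopes(cand0, ranks, max_n = 3), 3)
})

test_that("selection rejects bad configurations and unranked candidates", {
  cand <- data.frame(peptide = "AAAAAAAAAAAAAAA", start = 1L)
  ranks <- data.frame(peptide = "CCCCCCCCCCCCCCC", allele = "X",
                      el_rank = 1)
  expect_error(select_epitopes(cand, ranks, max_n = 0),
               "configuration error")
  expect_error(select_epitopes(cand, ranks), "without any reference-set")
})

test_that("elution-rank tables are read, deduplicated and validated", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tel_rank",
               "AAAAAAAAAAAAAAA\tDRB1*01:01\t0.7"), tf)
  tab <- read_elution_ranks(tf)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$el_rank, 0.7)

  writeLines(c("peptide\tallele\tel_rank",
               "AAAAAAAAAAAAAAA\tDRB1*01:01\t2.0",
               "AAAAAAAAAAAAAAA\tDRB1*01:01\t1.0"), tf)
  expect_warning(tab2 <- read_elution_ranks(tf), "minimum")
  expect_equal(tab2$el_rank, 1.0)

  writeLines(c("peptide\tallele\tel_rank",
               "AAAAAAAAAAAAAAA\tDRB1*01:01\t150"), tf)
  expect_error(read_elution_ranks(tf), "0, 100")

  writeLines(c("peptide\tallele", "AAAAAAAAAAAAAAA\tDRB1*01:01"), tf)
  expect_error(read_elution_ranks(tf), "missing column")
})

test_that("selected epitopes round-trip through the TSV writer", {
  sc <- hi_scenario()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_epitopes(sc$drug$epitopes, tf)
  tab <- utils::read.delim(tf, check.names = FALSE)
  expect_equal(nrow(tab), length(sc$drug$epitopes))
  expect_equal(tab$peptide, vapply(sc$drug$epitopes, `[[`, "", "peptide"))
  expect_equal(tab$best_rank,
               vapply(sc$drug$epitopes, `[[`, 0, "best_rank"),
               tolerance = 1e-9)
})
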