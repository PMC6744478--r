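write_xl_csv <- function(rows) {
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(rows, tf, row.names = FALSE, quote = FALSE)
  tf
}

xl_row <- function(pa = "P1", pos_a = 5, pb = "P1", pos_b = 12, charge = 3,
                   id = "psm1") {
  data.frame(protein_a = pa, peptide_a = "KAAAK", link_pos_a = pos_a,
             protein_b = pb, peptide_b = "KCCCK", link_pos_b = pos_b,
             charge = charge, psm_id = id, score = 30, qvalue = 0.001)
}

test_that("crosslink tables read with schema validation and row filtering", {
  tab <- rbind(xl_row(id = "a"), xl_row(pos_a = 8, id = "b"),
               xl_row(pos_b = 20, id = "c"))
  rec <- read_crosslink_table(write_xl_csv(tab))
  expect_equal(nrow(rec), 3)
  # missing required column is named in the error
  expect_error(read_crosslink_table(write_xl_csv(tab[, -5])), "peptide_b")
  # 1-based positions: a 0 position rejects that row only
  tab$link_pos_a[2] <- 0
  expect_message(rec <- read_crosslink_table(write_xl_csv(tab)), "dropped")
  expect_equal(nrow(rec), 2)
  expect_equal(nrow(attr(rec, "rejected")), 1)
})

test_that("dialect column maps adapt third-party exports", {
  tab <- xl_row()
  names(tab)[names(tab) == "protein_a"] <- "Protein1"
  rec <- read_crosslink_table(write_xl_csv(tab),
                              dialect = c(protein_a = "Protein1"))
  expect_equal(rec$protein_a, "P1")
  expect_error(
    read_crosslink_table(write_xl_csv(tab), dialect = c(protein_a = "nope")),
    "nope")
})

test_that("q-value threshold drops rows when requested", {
  tab <- rbind(xl_row(id = "a"), xl_row(id = "b"))
  tab$qvalue <- c(0.001, 0.2)
  expect_message(rec <- read_crosslink_table(write_xl_csv(tab),
                                             qvalue_max = 0.01), "q-value")
  expect_equal(rec$psm_id, "a")
})

test_that("peptides map to all (overlapping) start offsets", {
  expect_equal(map_peptide_to_sequence("AAA", "AAAA"), c(1L, 2L))
  expect_equal(map_peptide_to_sequence("QQQ", "AAAA"), integer(0))
  expect_error(map_peptide_to_sequence("", "AAAA"), "non-empty")
  # synthetic full-protein sequence with a peptide planted uniquely at 218,
  # emulating locating a peptide by its leading residues
  set.seed(7)
  backbone <- paste(sample(c("A", "G", "S", "L", "V"), 400, TRUE),
                    collapse = "")
  seq <- paste0(substr(backbone, 1, 217), "ETMWKDY",
                substr(backbone, 225, 400))
  expect_equal(map_peptide_to_sequence("ETMWKDY", seq), 218L)
})

test_that("PSM records dedupe to canonical residue pairs", {
  tab <- rbind(xl_row(charge = 3, id = "a"), xl_row(charge = 3, id = "b"),
               xl_row(charge = 4, id = "c"))
  pairs <- dedupe_to_residue_pairs(read_crosslink_table(write_xl_csv(tab)))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$psm_count, 3)
  expect_equal(pairs$charges_seen, "3,4")
  expect_equal(pairs$kind, "intra")
})

test_that("both reported orientations collapse to one canonical pair", {
  tab <- rbind(xl_row(pa = "P2", pos_a = 9, pb = "P1", pos_b = 5, id = "a"),
               xl_row(pa = "P1", pos_a = 5, pb = "P2", pos_b = 9, id = "b"))
  pairs <- dedupe_to_residue_pairs(read_crosslink_table(write_xl_csv(tab)))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$protein_a, "P1")
  expect_equal(pairs$pos_a, 5)
  expect_equal(pairs$kind, "inter")
})

test_that("dedupe accounting and idempotence invariants hold", {
  set.seed(11)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    xl_row(pa = sample(c("P1", "P2"), 1), pos_a = sample(5:8, 1),
           pb = sample(c("P1", "P2"), 1), pos_b = sample(9:12, 1),
           charge = sample(3:5, 1), id = paste0("p", i))
  }))
  rec <- read_crosslink_table(write_xl_csv(rows))
  pairs <- dedupe_to_residue_pairs(rec)
  expect_lte(nrow(pairs), nrow(rec))
  expect_equal(sum(pairs$psm_count), nrow(rec))
  # feeding the unique pairs back through as one-PSM records is a fixpoint
  rec2 <- data.frame(protein_a = pairs$protein_a, peptide_a = "K",
                     link_pos_a = pairs$pos_a, protein_b = pairs$protein_b,
                     peptide_b = "K", link_pos_b = pairs$pos_b,
                     charge = NA, psm_id = seq_len(nrow(pairs)),
                     score = NA, qvalue = NA)
  pairs2 <- dedupe_to_residue_pairs(rec2)
  expect_equal(pairs2[, c("protein_a", "pos_a", "protein_b", "pos_b", "kind")],
               pairs[, c("protein_a", "pos_a", "protein_b", "pos_b", "kind")])
})

test_that("sequence validation excludes out-of-range and non-K links", {
  seqs <- c(P1 = "AAKAAKAA")   # lysines at 3 and 6
  tab <- rbind(xl_row(pos_a = 3, pos_b = 6, id = "good"),
               xl_row(pos_a = 3, pos_b = 99, id = "range"))
  rec <- read_crosslink_table(write_xl_csv(tab))
  expect_message(pairs <- dedupe_to_residue_pairs(rec, sequences = seqs),
                 "excluded")
  expect_equal(nrow(pairs), 1)
  # strict mode also rejects links on non-lysine residues
  tab2 <- rbind(xl_row(pos_a = 3, pos_b = 6, id = "good"),
                xl_row(pos_a = 2, pos_b = 6, id = "nonK"))
  rec2 <- read_crosslink_table(write_xl_csv(tab2))
  expect_equal(nrow(dedupe_to_residue_pairs(rec2, sequences = seqs)), 2)
  expect_message(
    strict <- dedupe_to_residue_pairs(rec2, sequences = seqs,
                                      strict_lysine = TRUE), "excluded")
  expect_equal(nrow(strict), 1)
})

test_that("residue pairs survive a CSV round trip", {
  pairs <- dedupe_to_residue_pairs(
    make_crosslink_table(make_bundle_fixture(), n_pairs = 6, seed = 5))
  tf <- tempfile(fileext = ".csv")
  write_residue_pairs(pairs, tf)
  back <- read_residue_pairs(tf)
  expect_equal(as.data.frame(back), as.data.frame(pairs),
               ignore_attr = TRUE)
})

test_that("FASTA reading normalizes case and validates content", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1 desc", "acdef", ">seq2", "GHIKL"), tf)
  seqs <- read_fasta(tf)
  expect_equal(seqs, c(seq1 = "ACDEF", seq2 = "GHIKL"))
  writeLines(c(">a", "ACDEF", ">a", "GHIKL"), tf)
  expect_error(read_fasta(tf), "duplicate")
  writeLines(c(">a", "AC1EF"), tf)
  expect_error(read_fasta(tf), "1")
})
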