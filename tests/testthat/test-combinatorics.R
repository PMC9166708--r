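# The independent oracle used throughout this file: writing the branch-point
# pair of arm i as base b_i on the arm's reference strand, a one-step
# migration along the (1,3) axis re-pairs the freed bases as b1:comp(b3) and
# b3:comp(b1), both of which are Watson-Crick exactly when b1 == b3 (and
# likewise b2 == b4 for the (2,4) axis).  So immobility reduces to
# b1 != b3 AND b2 != b4.  The package must reach the same answers through
# its explicit re-pairing model.
closed_form_migrates <- function(q, axis) {
  v <- strsplit(q, "")[[1]]
  if (axis == "1-3") v[1] == v[3] else v[2] == v[4]
}

test_that("complement is an involution and maps Watson-Crick partners", {
  b <- c("A", "C", "G", "T")
  expect_identical(unname(wc_complement(wc_complement(b))), b)
  expect_identical(unname(wc_complement(b)), c("T", "G", "C", "A"))
  expect_error(wc_complement("N"), "not a DNA base")
})

test_that("re-pairing model agrees with the closed-form identity condition on all 256 x 2 cases", {
  for (q in all_assignments()) {
    for (axis in c("1-3", "2-4")) {
      expect_identical(migrates_one_step(q, axis), closed_form_migrates(q, axis),
                       info = paste(q, axis))
    }
  }
  expect_error(migrates_one_step("ACGT", "1-2"), "invalid axis")
})

test_that("homogeneous quartets migrate on both axes; fully asymmetric ones on neither", {
  expect_true(migrates_one_step("AAAA", "1-3"))
  expect_true(migrates_one_step("AAAA", "2-4"))
  expect_false(is_immobile("GGGG"))
  # different junction-proximal bases on both axes
  expect_false(migrates_one_step("ACGT", "1-3"))
  expect_false(migrates_one_step("ACGT", "2-4"))
  expect_true(is_immobile("ACGT"))
})

test_that("migration is invariant under rotating the assignment by two positions", {
  rot2 <- function(q) { v <- strsplit(q, "")[[1]]; paste(v[c(3, 4, 1, 2)], collapse = "") }
  for (q in all_assignments()) {
    expect_identical(migrates_one_step(q, "1-3"), migrates_one_step(rot2(q), "1-3"))
    expect_identical(migrates_one_step(q, "2-4"), migrates_one_step(rot2(q), "2-4"))
  }
})

test_that("immobility commutes with cyclic rotation of the quartet", {
  rot <- function(q, b) { v <- strsplit(q, "")[[1]]; paste(v[((seq_len(4) - 1 + b) %% 4) + 1], collapse = "") }
  for (q in all_assignments()) {
    base <- is_immobile(q)
    for (b in 1:3) expect_identical(is_immobile(rot(q, b)), base, info = q)
  }
})

test_that("enumeration finds 144 immobile assignments in 36 rotational classes partitioning them", {
  all <- all_assignments()
  expect_length(all, 256)
  n_imm <- sum(vapply(all, is_immobile, logical(1)))
  # cross-check by inclusion-exclusion on the two independent axis conditions:
  # 256 - 64 - 64 + 16
  expect_identical(n_imm, 144L)
  cls <- enumerate_immobile_classes()
  expect_identical(nrow(cls), 36L)
  members <- unlist(cls$members)
  expect_identical(sum(cls$orbit_size), 144L)
  expect_identical(length(members), 144L)
  expect_identical(anyDuplicated(members), 0L)   # each in exactly one class
  expect_true(all(vapply(members, is_immobile, logical(1))))
  expect_true(all(cls$orbit_size >= 1 & cls$orbit_size <= 4))
  # canonical member is the lexicographic minimum of its orbit
  expect_true(all(mapply(function(can, mem) can == min(mem),
                         cls$canonical, cls$members)))
  # determinism: re-running yields an identical ordered table
  cls2 <- enumerate_immobile_classes()
  expect_identical(cls, cls2)
})

test_that("class labels can be remapped by a user table", {
  labs <- sprintf("J%d", 1:36)
  cls <- enumerate_immobile_classes(labels = labs)
  expect_identical(cls$label, labs)
  expect_error(enumerate_immobile_classes(labels = c("a", "b")), "one entry per class")
})

test_that("realized sequences round-trip the branch point and respect seeds", {
  cls <- enumerate_immobile_classes()
  ss <- realize_sequences(cls$canonical[5], arm_length = 8, stem_seed = 3)
  expect_identical(unname(nchar(ss$strands)), rep(16L, 4))
  expect_identical(unclass(branch_quartet(ss)),
                   strsplit(cls$canonical[5], "")[[1]])
  # reproducible under the same seed
  ss2 <- realize_sequences(cls$canonical[5], arm_length = 8, stem_seed = 3)
  expect_identical(ss$strands, ss2$strands)
  # different seed: same branch point, different stems
  ss3 <- realize_sequences(cls$canonical[5], arm_length = 8, stem_seed = 4)
  expect_identical(branch_quartet(ss3), branch_quartet(ss))
  expect_false(identical(ss$strands, ss3$strands))
})

test_that("explicit stems are validated against the branch point", {
  expect_error(realize_sequences("ACGT", arm_length = 4,
                                 stems = c("AAAA", "AAAA", "AAAA", "AAAA")),
               "inconsistent")
  ss <- realize_sequences("ACGT", arm_length = 4,
                          stems = c("AAA", "CCC", "GGG", "TTT"))
  expect_identical(unclass(branch_quartet(ss)), c("A", "C", "G", "T"))
  expect_error(realize_sequences("ACGT", arm_length = 1), "arm_length")
})

test_that("FASTA and TSV exports are readable and complete", {
  cls <- enumerate_immobile_classes()
  ss <- realize_sequences(cls$canonical[1], arm_length = 6, stem_seed = 1)
  fa <- tempfile(fileext = ".fasta")
  export_fasta(ss, fa)
  lines <- readLines(fa)
  expect_identical(sum(grepl("^>", lines)), 4L)
  expect_true(any(grepl("arm_length=6", lines)))
  tsv <- tempfile(fileext = ".tsv")
  write_class_table(cls, tsv)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 36L)
  expect_identical(tab$canonical, cls$canonical)
})
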