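test_that("two clean subfamilies are recovered exactly", {
  spec <- toy_family_spec(n_subgroups = 2, seqs_per_subgroup = 10,
                          n_columns = 30, epsilon = 0)
  fam <- generate_family(spec)
  part <- assign_subgroups(fam$tree, fam$alignment, c(5, 12))
  expect_setequal(unique(part$subgroup_id), c("1", "2"))
  # membership agrees with the planted truth up to label naming
  truth <- setNames(fam$partition$subgroup_id, fam$partition$id)
  got <- setNames(part$subgroup_id, part$id)
  tab <- table(truth[names(got)], got)
  expect_equal(sort(as.vector(tab)), c(0, 0, 10, 10))
  # a partition is a function: each leaf appears once
  expect_equal(anyDuplicated(part$id), 0)
})

test_that("the full analog subfamily count is recovered at low noise", {
  spec <- family_spec(n_subgroups = 22, seqs_per_subgroup = 50, n_columns = 60,
                      planted = list(list(role = "strong",
                                          positions = c(8, 21, 34, 47, 60, 13),
                                          partition = "pairs", coupling = 1)),
                      epsilon = 0.02, seed = 13, reference_id = "ref1")
  fam <- generate_family(spec)
  # at noise 0.02 a six-position signature stays identical in ~89% of a
  # subgroup's members, so a 0.75 homogeneity floor captures each clade whole
  part <- assign_subgroups(fam$tree, fam$alignment,
                           c(8, 21, 34, 47, 60, 13), homogeneity = 0.75)
  n_sub <- length(setdiff(unique(part$subgroup_id), "0"))
  expect_equal(n_sub, 22)
})

test_that("full homogeneity admits only perfectly conserved clades", {
  # on a clean family the strictest and the default floor agree exactly
  clean <- generate_family(toy_family_spec(n_subgroups = 3,
                                           seqs_per_subgroup = 12,
                                           n_columns = 30, epsilon = 0,
                                           seed = 31))
  p09 <- assign_subgroups(clean$tree, clean$alignment, c(5, 12), homogeneity = 0.9)
  p10 <- assign_subgroups(clean$tree, clean$alignment, c(5, 12), homogeneity = 1.0)
  n <- function(p) length(setdiff(unique(p$subgroup_id), "0"))
  expect_equal(n(p09), 3)
  expect_equal(n(p10), 3)

  # on a noisy family, every clade admitted at homogeneity 1 is invariant
  noisy <- generate_family(toy_family_spec(n_subgroups = 3,
                                           seqs_per_subgroup = 12,
                                           n_columns = 30, epsilon = 0.3,
                                           seed = 31))
  pt <- assign_subgroups(noisy$tree, noisy$alignment, c(5, 12), homogeneity = 1.0)
  sig <- apply(noisy$alignment$mat[, c(5, 12)], 1, paste, collapse = "")
  for (g in setdiff(unique(pt$subgroup_id), "0")) {
    expect_equal(length(unique(sig[pt$id[pt$subgroup_id == g]])), 1)
  }

  missing <- ape::read.tree(text = "(ghost:1,ref1:1);")
  expect_error(assign_subgroups(missing, noisy$alignment, c(5, 12)),
               class = "coevomotif_lookup_error")
})

test_that("ring export writes one labelled COLORSTRIP per position", {
  spec <- toy_family_spec(n_subgroups = 2, seqs_per_subgroup = 5,
                          n_columns = 30, epsilon = 0, seed = 17)
  fam <- generate_family(spec)
  sel <- tibble::tibble(position = c(5L, 8L, 12L, 15L, 20L, 25L),
                        column = c(5L, 8L, 12L, 15L, 20L, 25L))
  out <- withr::local_tempdir()
  files <- export_itol_rings(fam$tree, fam$alignment, sel, out)
  expect_length(files, 6)
  expect_equal(basename(files),
               sprintf("ring_position_%d.txt", c(5, 8, 12, 15, 20, 25)))
  first <- readLines(files[1])
  expect_equal(first[1], "DATASET_COLORSTRIP")
  expect_true("DATASET_LABEL,5" %in% first)

  # acid residues carry the shared D/E color from the packaged scheme
  aln <- msa(c("t1", "t2", "t3"), c("E", "D", "-"))
  tree <- ape::read.tree(text = "(t1:1,(t2:1,t3:1):1);")
  f <- export_itol_rings(tree, aln, 1L, out)
  ring <- read_itol_ring(f[1])
  expect_equal(ring$color[ring$id == "t1"], "#E60A0A")
  expect_equal(ring$color[ring$id == "t2"], "#E60A0A")
  expect_equal(ring$color[ring$id == "t3"], "#FFFFFF")

  # round trip recovers the residue per leaf, and re-export is byte-stable
  expect_equal(setNames(ring$residue, ring$id),
               c(t1 = "E", t2 = "D", t3 = "-"))
  bytes1 <- readBin(f[1], "raw", file.size(f[1]))
  f2 <- export_itol_rings(tree, aln, 1L, out)
  bytes2 <- readBin(f2[1], "raw", file.size(f2[1]))
  expect_identical(bytes1, bytes2)
})

test_that("partition tables round-trip through TSV", {
  part <- tibble::tibble(id = c("a", "b"), subgroup_id = c("10.1", "3"),
                         specificity_label = c("KP", "unknown"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, tmp)
  back <- read_partition(tmp)
  expect_equal(back$subgroup_id, c("10.1", "3"))
  expect_equal(back$specificity_label, c("KP", "unknown"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tsubgroup_id", "a\t1", "a\t2"), dup)
  expect_error(read_partition(dup), class = "coevomotif_validation_error")
})
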