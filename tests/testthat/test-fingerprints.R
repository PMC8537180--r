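test_that("consensus tokens follow the threshold rules", {
  expect_equal(consensus_token(c(E = 1)), "E")
  expect_equal(consensus_token(c(M = 0.5, F = 0.5)), "[MF]")
  expect_equal(consensus_token(c(F = 0.6, M = 0.3, A = 0.1)), "F")
  expect_equal(consensus_token(setNames(rep(0.2, 5), c("A", "C", "D", "E", "F"))), "x")
  # frequency ties break in substitution-matrix residue order (R before K)
  expect_equal(consensus_token(c(K = 0.45, R = 0.45, A = 0.1)), "[RK]")
  expect_error(consensus_token(c(A = 0.4)), class = "coevomotif_value_error")
})

test_that("motif parsing handles brackets and wildcards", {
  expect_equal(parse_motif("KV[MF]NES"), c("K", "V", "[MF]", "N", "E", "S"))
  expect_equal(parse_motif("EEAPxx"), c("E", "E", "A", "P", "x", "x"))
  expect_error(parse_motif("A[MF"), class = "coevomotif_format_error")
})

test_that("motif extraction reproduces planted consensus and hand counts", {
  # invariant position: single-letter token at the maximal information content
  ids <- sprintf("s%02d", 1:10)
  aln <- msa(ids, rep("KE", 10))
  part <- tibble::tibble(id = ids, subgroup_id = "1")
  fps <- extract_motifs(aln, part, c(1, 2))
  expect_equal(fps$token, c("K", "E"))
  expect_equal(fps$info_bits, rep(log2(20), 2), tolerance = 1e-12)

  # planted MP-like subgroup: K/V/(M|F at 50:50)/N/E/S
  mf <- rep(c("M", "F"), 5)
  rows <- paste0("KV", mf, "NES")
  aln2 <- msa(ids, rows)
  fps2 <- extract_motifs(aln2, part, 1:6)
  expect_equal(motif_consensus(fps2)$motif_string, "KV[MF]NES")

  # frequencies against hand counts (uniform weights): 7 E, 2 D, 1 gap
  col <- c(rep("E", 7), rep("D", 2), "-")
  aln3 <- msa(ids, col)
  fps3 <- extract_motifs(aln3, part, 1)
  f <- fps3$freqs[[1]]
  expect_equal(unname(f["E"]), 7 / 9, tolerance = 1e-12)
  expect_equal(unname(f["D"]), 2 / 9, tolerance = 1e-12)

  # zero coverage at a position: wildcard with a warning, not an error
  aln4 <- msa(ids, rep("-A", 10))
  expect_warning(fps4 <- extract_motifs(aln4, part, c(1, 2)),
                 "no residue coverage")
  expect_equal(fps4$token[fps4$column == 1], "x")
})

test_that("logo matrix heights are frequency times information content", {
  ids <- sprintf("s%02d", 1:8)
  aln <- msa(ids, c(rep("K", 4), rep("R", 4)))
  part <- tibble::tibble(id = ids, subgroup_id = "g")
  fps <- extract_motifs(aln, part, 1)
  m <- logo_matrix(fps, "g")
  expect_equal(unname(m[1, "K"]), 0.5 * (log2(20) - 1), tolerance = 1e-12)
  expect_equal(unname(m[1, "R"]), 0.5 * (log2(20) - 1), tolerance = 1e-12)
  expect_error(logo_matrix(fps, "missing"), class = "coevomotif_lookup_error")
})

test_that("classification matches the worked fingerprint examples", {
  ref <- gh65_fingerprints()
  got <- classify_sequence(c(TbGP = "TRIGPP", ChGP = "FAITQA",
                             HoGP = "EEAPWS", CaGP = "DQGQDE"), ref)
  expect_equal(got$label, c("TP", "oligoNP", "KP", "T6PP"))
  expect_equal(got$match_score, rep(1, 4))

  # bracket token accepts either residue; matching is case-insensitive
  expect_equal(classify_sequence(c(q = "KVFNES"), ref)$label, "MP")
  expect_equal(classify_sequence(c(q = "kvmnes"), ref)$label, "MP")

  expect_error(classify_sequence(c(q = "EEAP"), ref),
               class = "coevomotif_dimension_error")
})

test_that("wildcard-only motifs are masked and ties collapse to unknown", {
  ref <- tibble::tibble(specificity_label = c("A1", "A2", "ALLX"),
                        motif_string = c("KKKKKK", "EEEEEE", "xxxxxx"))
  # all-x motif never wins, even though it "matches" everything
  got <- classify_sequence(c(q = "KKKKKK"), ref)
  expect_equal(got$label, "A1")
  d <- got$detail[[1]]
  expect_true(is.na(d$match_score[d$label == "ALLX"]))

  # a perfect tie between two labels is reported as unknown
  tie <- tibble::tibble(specificity_label = c("A1", "A2"),
                        motif_string = c("KKKxxx", "xxxKKK"))
  expect_equal(classify_sequence(c(q = "KKKKKK"), tie)$label, "unknown")

  # sub-threshold best match (4/6 = 0.67) is unknown at the 0.8 default
  expect_equal(classify_sequence(c(q = "KKEEEE"), ref)$label, "unknown")
  expect_equal(classify_sequence(c(q = "KKEEEE"), ref, accept_threshold = 0.5)$label,
               "A2")
})

test_that("mechanism verdicts follow the phosphate-site rule", {
  sets <- list(c("R", "K"), "Y")
  expect_equal(mechanism_call("ARCYD", c(2, 4), sets), "phosphorylase")
  expect_equal(mechanism_call("AACYD", c(2, 4), sets), "hydrolase")
  expect_equal(mechanism_call("A-CYD", c(2, 4), sets), "undetermined")
  expect_equal(mechanism_call("AXCYD", c(2, 4), sets), "undetermined")
  expect_error(mechanism_call("ARCYD"), class = "coevomotif_config_error")
  expect_error(mechanism_call("ARCYD", c(2, 4), list("R")),
               class = "coevomotif_dimension_error")
  expect_error(mechanism_call("ARC", c(2, 9), sets), class = "coevomotif_index_error")
})

test_that("noise-free planted subgroups classify back to themselves", {
  spec <- toy_family_spec(n_subgroups = 5, seqs_per_subgroup = 12,
                          n_columns = 40, epsilon = 0,
                          positions = c(4, 11, 23, 31))
  fam <- generate_family(spec)
  sel <- tibble::tibble(position = c(4, 11, 23, 31), column = c(4, 11, 23, 31))
  fps <- extract_motifs(fam$alignment, fam$partition, sel)
  cons <- motif_consensus(fps)
  # single planted residue per subgroup and position: 4 single-letter tokens
  expect_true(all(nchar(cons$motif_string) == 4))
  ref <- tibble::tibble(specificity_label = cons$subgroup_id,
                        motif_string = cons$motif_string)
  queries <- apply(fam$alignment$mat[, sel$column], 1, paste, collapse = "")
  got <- classify_sequence(setNames(queries, fam$alignment$ids), ref)
  truth <- setNames(fam$partition$subgroup_id, fam$partition$id)
  expect_equal(mean(got$label == truth[got$query_id]), 1.0)

  # negative control: shuffling subgroup labels destroys self-consistency
  set.seed(99)
  shuffled <- fam$partition
  shuffled$subgroup_id <- sample(shuffled$subgroup_id)
  fps_s <- extract_motifs(fam$alignment, shuffled, sel)
  cons_s <- motif_consensus(fps_s)
  ref_s <- tibble::tibble(specificity_label = cons_s$subgroup_id,
                          motif_string = cons_s$motif_string)
  got_s <- classify_sequence(setNames(queries, fam$alignment$ids), ref_s,
                             accept_threshold = 0)
  truth_s <- setNames(shuffled$subgroup_id, shuffled$id)
  expect_lt(mean(got_s$label == truth_s[got_s$query_id]), 0.5)
})

test_that("the packaged specificity vocabulary is intact", {
  tab <- gh65_specificities()
  expect_equal(nrow(tab), 10)
  expect_setequal(tab$abbreviation,
                  c("MP", "TP", "T6PP", "KP", "NP", "GRP", "GGP",
                    "oligoNP", "TH", "PGGHG"))
  expect_true(all(grepl("^[23]\\.[24]\\.1\\.", tab$ec)))
})
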