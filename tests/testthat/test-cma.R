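test_that("position-based weights match the direct per-column formula", {
  # identical rows share the weight
  aln <- msa(c("a", "b", "c"), rep("ACDEF", 3))
  w <- henikoff_weights(aln)
  expect_equal(w$weight, rep(1, 3))

  # duplicated sequence is down-weighted relative to a distinct one
  aln2 <- msa(c("a1", "a2", "b"), c("ACDEF", "ACDEF", "WYHKR"))
  w2 <- henikoff_weights(aln2)
  expect_gt(w2$weight[w2$id == "b"], w2$weight[w2$id == "a1"])
  expect_equal(w2$weight[w2$id == "a1"], w2$weight[w2$id == "a2"])
  expect_equal(sum(w2$weight), 3)

  # random alignments against the textbook summation oracle
  for (s in 1:5) {
    a <- random_msa(10, 12, alphabet = c(AA20[1:6], "-", "X"), seed = s)
    expect_equal(henikoff_weights(a)$weight, oracle_henikoff(a), tolerance = 1e-12)
  }

  expect_error(henikoff_weights(msa(c("a", "b"), c("--", "--"))),
               class = "coevomotif_degenerate_error")
})

test_that("column pair score equals the brute-force counting oracle", {
  # perfect two-state bijection scores exactly 1
  aln <- msa(sprintf("s%d", 1:8),
             paste0(rep(c("A", "C"), 4), rep(c("W", "Y"), 4)))
  expect_equal(column_pair_score(aln, 1, 2, min_pairs = 2), 1.0)

  # 8-row toys with gaps, X and non-uniform weights, vs the oracle
  for (s in 1:10) {
    a <- random_msa(8, 5, alphabet = c(AA20[1:4], "-", "X"), seed = 100 + s)
    w <- tibble::tibble(id = a$ids, weight = seq(0.5, 4, length.out = 8))
    w$weight <- w$weight / sum(w$weight) * 8
    for (j in 2:5) {
      got <- column_pair_score(a, 1, j, weights = w, min_pairs = 2, h_min = 1e-9)
      want <- oracle_pair_score(a, 1, j, w = setNames(w$weight, w$id)[a$ids])
      if (is.na(want)) expect_true(is.na(got)) else {
        expect_equal(got, min(max(want, 0), 1), tolerance = 1e-12)
      }
    }
  }
})

test_that("masking triggers on constant columns and sparse overlap", {
  aln <- msa(sprintf("s%d", 1:30),
             paste0(rep("A", 30), sample(c("C", "W"), 30, replace = TRUE)))
  expect_true(is.na(column_pair_score(aln, 1, 2)))       # zero-entropy column
  small <- random_msa(10, 3, seed = 1)
  expect_true(is.na(column_pair_score(small, 1, 2, min_pairs = 20)))
  expect_error(column_pair_score(small, 1, 99), class = "coevomotif_index_error")
  expect_error(column_pair_score(small, 2, 2), class = "coevomotif_index_error")
})

test_that("independent columns score near zero at large n", {
  set.seed(42)
  n <- 2000
  a <- msa(sprintf("s%04d", 1:n),
           paste0(sample(AA20, n, TRUE), sample(AA20, n, TRUE)))
  expect_lt(column_pair_score(a, 1, 2), 0.05)
})

test_that("score matrix is symmetric, bounded and row-permutation invariant", {
  a <- random_msa(25, 5, alphabet = AA20[1:6], seed = 5)
  cr <- cma_matrix(a, min_pairs = 5)
  expect_equal(cr$scores, t(cr$scores))
  expect_true(all(is.na(diag(cr$scores))))
  vals <- cr$scores[!is.na(cr$scores)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(nrow(tidy(cr)) + sum(is.na(cr$scores[upper.tri(cr$scores)])), 10)

  perm <- sample(length(a$ids))
  ap <- msa(a$ids[perm], apply(a$mat[perm, , drop = FALSE], 1, paste, collapse = ""))
  crp <- cma_matrix(ap, min_pairs = 5)
  expect_equal(crp$scores, cr$scores, tolerance = 1e-12)
})

test_that("pair scores are invariant under residue relabeling of one column", {
  # bijective relabeling of a single column preserves mutual information
  for (s in 1:100) {
    set.seed(200 + s)
    a <- random_msa(15, 4, alphabet = AA20[1:5])
    cr <- cma_matrix(a, min_pairs = 5, h_min = 1e-9)
    relab <- setNames(sample(AA20[6:10]), AA20[1:5])
    m <- a$mat
    m[, 2] <- relab[m[, 2]]
    ar <- msa(a$ids, apply(m, 1, paste, collapse = ""))
    crr <- cma_matrix(ar, min_pairs = 5, h_min = 1e-9)
    expect_equal(crr$scores, cr$scores, tolerance = 1e-12)
  }
})

test_that("network construction counts degrees and nests with the threshold", {
  scores <- matrix(NA_real_, 4, 4)
  scores[1, 2] <- scores[2, 1] <- 0.95
  scores[1, 3] <- scores[3, 1] <- 0.85
  scores[2, 3] <- scores[3, 2] <- 0.70
  scores[1, 4] <- scores[4, 1] <- 0.82
  cr <- structure(list(scores = scores, positions = c(10L, 20L, 30L, 40L),
                       numbering = NULL), class = "cma_result")
  net <- build_network(cr, 0.8)
  expect_equal(nrow(net$edges), 3)
  deg <- setNames(net$nodes$degree, net$nodes$position)
  expect_equal(deg[["10"]], 3)
  expect_equal(deg[["20"]], 1)
  expect_equal(deg[["40"]], 1)

  # monotone nesting: edges at a higher threshold are a subset
  net9 <- build_network(cr, 0.9)
  key <- function(e) paste(e$column_i, e$column_j)
  expect_true(all(key(net9$edges) %in% key(net$edges)))

  empty <- build_network(structure(list(scores = scores * 0.5,
                                        positions = 1:4, numbering = NULL),
                                   class = "cma_result"), 0.8)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(select_positions(empty)), 0)
})

test_that("two-stage selection rule matches a brute-force predicate filter", {
  # constructed matrix where exactly the six reference positions qualify
  pos <- c(64L, 392L, 394L, 402L, 416L, 585L, 100L, 200L, 300L)
  L <- length(pos)
  scores <- matrix(NA_real_, L, L)
  put <- function(i, j, v) scores[i, j] <<- scores[j, i] <<- v
  for (i in 1:5) put(i, i + 1, 0.95)      # chain through the six
  put(1, 6, 0.93)
  put(7, 8, 0.85)                          # strong pair but never above 0.9
  put(2, 9, 0.82)                          # position 300: one partner only
  cr <- structure(list(scores = scores, positions = pos, numbering = NULL),
                  class = "cma_result")
  net <- build_network(cr, 0.8)
  sel <- select_positions(net, cr, strong_threshold = 0.9, min_partners = 2)
  expect_equal(sel$position, c(64L, 392L, 394L, 402L, 416L, 585L))

  expect_error(select_positions(net, cr, strong_threshold = 0.5),
               class = "coevomotif_value_error")

  # random matrices against an independent predicate filter
  for (s in 1:20) {
    set.seed(300 + s)
    L <- 12
    m <- matrix(NA_real_, L, L)
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      m[i, j] <- m[j, i] <- round(runif(1), 2)
    }
    crr <- structure(list(scores = m, positions = seq_len(L) * 10L,
                          numbering = NULL), class = "cma_result")
    got <- select_positions(build_network(crr, 0.8), crr)$position
    want <- sort((seq_len(L) * 10L)[vapply(seq_len(L), function(i) {
      v <- m[i, -i]
      max(v) > 0.9 && sum(v >= 0.8) >= 2
    }, logical(1))])
    expect_equal(got, want)
  }
})

test_that("planted couplings at full strength score exactly 1 and are selected", {
  spec <- toy_family_spec(n_subgroups = 4, seqs_per_subgroup = 30,
                          n_columns = 20, epsilon = 0,
                          positions = c(3, 9, 15))
  fam <- generate_family(spec)
  cr <- cma_matrix(fam$alignment, min_pairs = 5, reference_id = "ref1")
  expect_equal(cr$scores[3, 9], 1.0)
  expect_equal(cr$scores[3, 15], 1.0)
  expect_equal(cr$scores[9, 15], 1.0)
  # every planted pair beats every background pair
  planted <- c(3, 9, 15)
  bg <- setdiff(seq_len(20), planted)
  bg_scores <- cr$scores[bg, bg]
  expect_lt(max(bg_scores, na.rm = TRUE), 1.0)
  sel <- select_positions(build_network(cr, 0.8), cr)
  expect_equal(sel$position, planted)
})
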