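#' Position-based (Henikoff) sequence weights
#'
#' Down-weights redundant sequences before residue counting. For every
#' column c with k distinct residue types, a row showing residue a (present
#' in n_a rows) receives 1 / (k * n_a); gaps and `X` contribute nothing.
#' Raw weights are summed over columns and normalised so that they sum to
#' the number of sequences.
#'
#' @param aln An [msa] object.
#' @return A tibble with columns `id` and `weight` (sum equals the number of
#'   sequences).
#' @export
henikoff_weights <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  n <- length(aln$ids)
  if (n == 0) abort("Empty alignment.", class = "coevomotif_degenerate_error")
  raw <- numeric(n)
  informative <- 0L
  for (c in seq_len(n_columns(aln))) {
    col <- aln$mat[, c]
    res <- col %in% AA_ORDER
    if (!any(res)) next
    informative <- informative + 1L
    counts <- table(col[res])
    k <- length(counts)
    raw[res] <- raw[res] + 1 / (k * as.numeric(counts[col[res]]))
  }
  if (informative == 0L) {
    abort("Alignment has no columns with residues; cannot weight.",
          class = "coevomotif_degenerate_error")
  }
  if (any(raw == 0)) {
    warn("Some sequences are gap/X-only; assigning them the mean raw weight.")
    raw[raw == 0] <- mean(raw[raw > 0])
  }
  tibble(id = aln$ids, weight = raw / sum(raw) * n)
}

# Integer-code an alignment: residues 1..20 in AA_ORDER, 0 for gap or X.
encode_alignment <- function(aln) {
  codes <- match(aln$mat, AA_ORDER, nomatch = 0L)
  matrix(as.integer(codes), nrow = nrow(aln$mat), ncol = ncol(aln$mat))
}

weights_vector <- function(aln, weights) {
  if (is.null(weights)) return(rep(1, length(aln$ids)))
  w <- setNames(weights$weight, weights$id)[aln$ids]
  if (anyNA(w)) abort("`weights` must cover every sequence id.",
                      class = "coevomotif_lookup_error")
  unname(w)
}

#' Correlation score between two alignment columns
#'
#' The package's correlated-mutation statistic: weighted mutual information
#' of the residues at columns i and j, normalised by the smaller of the two
#' weighted column entropies, so scores lie in `[0, 1]`. Rows carrying a gap
#' or `X` at either column are excluded (pairwise-complete). The score is
#' masked (`NA`) when fewer than `min_pairs` rows remain or when either
#' column entropy falls below `h_min` bits: normalised mutual information is
#' unstable on sparse or near-invariant columns.
#'
#' @param aln An [msa] object.
#' @param i,j Distinct 1-based column indices.
#' @param weights Optional tibble from [henikoff_weights()]; defaults to
#'   uniform weights.
#' @param min_pairs Minimum pairwise-complete rows (default 20).
#' @param h_min Minimum column entropy in bits (default 0.1).
#' @return A score in `[0, 1]`, or `NA` when masked.
#' @export
column_pair_score <- function(aln, i, j, weights = NULL,
                              min_pairs = 20, h_min = 0.1) {
  stopifnot(inherits(aln, "msa"))
  L <- n_columns(aln)
  for (x in c(i, j)) {
    if (x < 1 || x > L) {
      abort(paste0("Column index ", x, " out of range 1..", L, "."),
            class = "coevomotif_index_error")
    }
  }
  if (i == j) abort("Columns i and j must differ.", class = "coevomotif_index_error")
  nmi_pair_cpp(encode_alignment(aln), weights_vector(aln, weights),
               as.integer(i), as.integer(j), length(AA_ORDER),
               as.integer(min_pairs), h_min)
}

#' Full correlated-mutation score matrix
#'
#' Scores every unordered pair of alignment columns with
#' [column_pair_score()]. When a `reference_id` is given, columns are
#' annotated with reference residue numbers (see [build_numbering_map()]);
#' all downstream reporting then speaks in reference numbering.
#'
#' @inheritParams column_pair_score
#' @param reference_id Optional id of the numbering reference sequence.
#' @return A `cma_result` object: list with `scores` (symmetric L x L matrix,
#'   `NA`-masked diagonal and masked pairs), `positions` (per-column reference
#'   residue number, `NA` where unmapped or no reference), and `numbering`
#'   (the numbering-map tibble or `NULL`).
#' @export
cma_matrix <- function(aln, weights = NULL, reference_id = NULL,
                       min_pairs = 20, h_min = 0.1) {
  stopifnot(inherits(aln, "msa"))
  scores <- nmi_matrix_cpp(encode_alignment(aln), weights_vector(aln, weights),
                           length(AA_ORDER), as.integer(min_pairs), h_min)
  positions <- rep(NA_integer_, n_columns(aln))
  numbering <- NULL
  if (!is.null(reference_id)) {
    numbering <- build_numbering_map(aln, reference_id)
    positions[numbering$column] <- numbering$residue_no
  }
  structure(list(scores = scores, positions = positions, numbering = numbering),
            class = "cma_result")
}

#' @export
print.cma_result <- function(x, ...) {
  L <- ncol(x$scores)
  defined <- sum(!is.na(x$scores[upper.tri(x$scores)]))
  cat("<cma_result> ", L, " columns, ", defined, " scored pairs (of ",
      choose(L, 2), ")\n", sep = "")
  if (defined > 0) {
    cat("  max score:", round(max(x$scores, na.rm = TRUE), 4), "\n")
  }
  invisible(x)
}

#' Tidy a correlation matrix into a pair table
#'
#' @param x A `cma_result`.
#' @param ... Unused.
#' @return A tibble with one row per scored (unmasked) unordered column pair:
#'   `column_i`, `column_j`, `position_i`, `position_j`, `score`.
#' @export
tidy.cma_result <- function(x, ...) {
  ut <- which(upper.tri(x$scores) & !is.na(x$scores), arr.ind = TRUE)
  tibble(column_i = ut[, 1], column_j = ut[, 2],
         position_i = x$positions[ut[, 1]],
         position_j = x$positions[ut[, 2]],
         score = x$scores[ut])
}

position_label <- function(cr, cols) {
  ifelse(is.na(cr$positions[cols]), cols, cr$positions[cols])
}

#' Build the co-evolution network
#'
#' Nodes are alignment columns incident to at least one pair scoring at or
#' above `edge_threshold`; edges are those pairs. Node labels use reference
#' numbering where available (falling back to the column index).
#'
#' @param cr A `cma_result` from [cma_matrix()].
#' @param edge_threshold Minimum score for an edge (default 0.8).
#' @return A `coevolution_network` object: list with `edges` (tibble
#'   `column_i`, `column_j`, `position_i`, `position_j`, `score`) and `nodes`
#'   (tibble `column`, `position`, `degree`, `max_score`).
#' @export
build_network <- function(cr, edge_threshold = 0.8) {
  stopifnot(inherits(cr, "cma_result"))
  if (!(edge_threshold > 0 && edge_threshold <= 1)) {
    abort("`edge_threshold` must be in (0, 1].", class = "coevomotif_value_error")
  }
  pairs <- tidy(cr)
  edges <- pairs[pairs$score >= edge_threshold, , drop = FALSE]
  cols <- sort(unique(c(edges$column_i, edges$column_j)))
  nodes <- purrr::map_dfr(cols, function(c) {
    inc <- edges[edges$column_i == c | edges$column_j == c, ]
    tibble(column = c,
           position = ifelse(is.na(cr$positions[c]), c, cr$positions[c]),
           degree = nrow(inc),
           max_score = max(inc$score))
  })
  if (length(cols) == 0) {
    nodes <- tibble(column = integer(0), position = integer(0),
                    degree = integer(0), max_score = numeric(0))
  }
  structure(list(edges = edges, nodes = nodes, edge_threshold = edge_threshold),
            class = "coevolution_network")
}

#' @export
print.coevolution_network <- function(x, ...) {
  cat("<coevolution_network> ", nrow(x$nodes), " positions, ", nrow(x$edges),
      " edges (score >= ", x$edge_threshold, ")\n", sep = "")
  invisible(x)
}

#' Select specificity-determining positions
#'
#' Two-stage rule: a position qualifies iff its best score over all pairs is
#' strictly greater than `strong_threshold` and it has at least
#' `min_partners` correlation partners at the network's edge threshold.
#' Output rows are sorted by ascending reference number.
#'
#' @param net A `coevolution_network` from [build_network()].
#' @param cr Optional `cma_result`; when supplied, the per-position maximum
#'   score is taken over all pairs rather than only over qualifying edges
#'   (equivalent whenever `strong_threshold >=` the edge threshold).
#' @param strong_threshold Score a position must exceed at least once
#'   (default 0.9). Must be at least the network's edge threshold.
#' @param min_partners Minimum number of partners (default 2).
#' @return A tibble with columns `position`, `column`, `max_score`,
#'   `n_partners`, sorted by `position`.
#' @export
select_positions <- function(net, cr = NULL, strong_threshold = 0.9,
                             min_partners = 2) {
  stopifnot(inherits(net, "coevolution_network"))
  if (strong_threshold < net$edge_threshold) {
    abort("`strong_threshold` must be >= the network's edge threshold.",
          class = "coevomotif_value_error")
  }
  nodes <- net$nodes
  if (nrow(nodes) == 0) {
    return(tibble(position = integer(0), column = integer(0),
                  max_score = numeric(0), n_partners = integer(0)))
  }
  mx <- nodes$max_score
  if (!is.null(cr)) {
    mx <- vapply(nodes$column, function(c) {
      v <- cr$scores[c, ]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
  }
  sel <- nodes[!is.na(mx) & mx > strong_threshold & nodes$degree >= min_partners, ]
  mx <- mx[!is.na(mx) & mx > strong_threshold & nodes$degree >= min_partners]
  out <- tibble(position = sel$position, column = sel$column,
                max_score = mx, n_partners = sel$degree)
  dplyr::arrange(out, .data$position)
}
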