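#' Pairwise sequence identity
#'
#' Identity between two unaligned sequences, defined as the number of
#' identical aligned positions in a global alignment divided by the length of
#' the shorter sequence. The alignment uses match = 1, mismatch = 0 and a
#' linear gap penalty of -1, a fixed cheap scoring that keeps results
#' bit-stable. This mirrors the short-sequence identity convention of common
#' redundancy-reduction tools.
#'
#' @param a,b Unaligned amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  alpha <- c(AA_ORDER, "X")
  sub <- matrix(0, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(sub) <- 1
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                      substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Longest-first greedy clustering: sequences are sorted by decreasing length
#' (ties by id, lexicographic); each sequence joins the first existing
#' representative with pairwise identity above the threshold, otherwise it
#' founds a new cluster. Cluster representatives are returned. Sequences in
#' `keep_list` (e.g. experimentally characterised family members) are always
#' present in the output even when redundant, mirroring the manual
#' re-addition of annotated representatives after clustering.
#'
#' All pairs are compared exactly; there is no k-mer prefilter. This is
#' intended for desk-scale datasets of at most a few thousand sequences.
#'
#' @param seqs A tibble/data.frame with columns `id` and `seq` (unaligned),
#'   or a named character vector.
#' @param identity_threshold Identity above which a sequence is redundant.
#'   Default 0.9 (sequences with more than 90 percent identity collapse).
#' @param keep_list Character vector of ids to retain unconditionally.
#' @return A list with `seqs` (tibble of representatives, in input order),
#'   `clusters` (tibble `id`, `representative`) and `report` (a one-row
#'   curation tibble: `n_input`, `n_after_redundancy`, `n_kept_back`).
#' @export
greedy_redundancy_filter <- function(seqs, identity_threshold = 0.9,
                                     keep_list = character(0)) {
  seqs <- as_seq_tbl(seqs)
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    abort("`identity_threshold` must be in (0, 1].", class = "coevomotif_value_error")
  }
  if (nrow(seqs) == 0) {
    return(list(seqs = seqs,
                clusters = tibble(id = character(0), representative = character(0)),
                report = tibble(n_input = 0L, n_after_redundancy = 0L, n_kept_back = 0L)))
  }
  ord <- order(-nchar(seqs$seq), seqs$id, method = "radix")
  reps <- integer(0)                     # indices into seqs, in founding order
  assignment <- character(nrow(seqs))
  for (k in ord) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs$seq[k], seqs$seq[r]) > identity_threshold) {
        assignment[k] <- seqs$id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      assignment[k] <- seqs$id[k]
    }
  }
  rep_ids <- seqs$id[sort(reps)]
  kept_back <- setdiff(intersect(keep_list, seqs$id), rep_ids)
  out_ids <- seqs$id[seqs$id %in% c(rep_ids, kept_back)]
  list(seqs = seqs[seqs$id %in% out_ids, , drop = FALSE],
       clusters = tibble(id = seqs$id, representative = assignment),
       report = tibble(n_input = nrow(seqs),
                       n_after_redundancy = length(out_ids),
                       n_kept_back = length(kept_back)))
}

as_seq_tbl <- function(seqs) {
  if (is.character(seqs) && !is.null(names(seqs))) {
    seqs <- tibble(id = names(seqs), seq = unname(seqs))
  }
  seqs <- as_tibble(seqs)
  if (!all(c("id", "seq") %in% names(seqs))) {
    abort("`seqs` needs columns `id` and `seq`.", class = "coevomotif_value_error")
  }
  if (anyDuplicated(seqs$id)) {
    abort("Sequence ids must be unique.", class = "coevomotif_validation_error")
  }
  seqs$seq <- toupper(seqs$seq)
  seqs
}

#' Remove columns with high gap content
#'
#' A column is removed iff its gap fraction is greater than or equal to
#' `max_gap_frac` (so the default 0.95 removes columns whose gap content is
#' 95 percent or higher). `X` counts as a residue of unknown type, not as a
#' gap. The operation is idempotent.
#'
#' @param aln An [msa] object.
#' @param max_gap_frac Gap fraction at or above which a column is dropped.
#' @return A list with `alignment` (trimmed [msa]) and `removed_columns`
#'   (integer vector of removed 1-based column indices).
#' @export
trim_gap_columns <- function(aln, max_gap_frac = 0.95) {
  stopifnot(inherits(aln, "msa"))
  if (!(max_gap_frac > 0 && max_gap_frac <= 1)) {
    abort("`max_gap_frac` must be in (0, 1].", class = "coevomotif_value_error")
  }
  if (length(aln$ids) == 0 || n_columns(aln) == 0) {
    return(list(alignment = aln, removed_columns = integer(0)))
  }
  gap_frac <- colMeans(aln$mat == "-")
  drop <- which(gap_frac >= max_gap_frac)
  keep <- setdiff(seq_len(n_columns(aln)), drop)
  mat <- aln$mat[, keep, drop = FALSE]
  rows <- if (length(aln$ids)) apply(mat, 1, paste, collapse = "") else character(0)
  list(alignment = msa(aln$ids, rows, descriptions = aln$descriptions),
       removed_columns = as.integer(drop))
}

#' Remove sequences lacking the catalytic acid
#'
#' Drops every row whose character at the catalytic column is not in
#' `allowed_residues`. The default `{D, E}` treats any non-acidic residue
#' (including gaps and `X`) as "lacking the catalytic acid"; pass
#' `allowed_residues = setdiff(c(AA, "X"), "-")`-style sets for the laxer
#' reading in which only a gap disqualifies.
#'
#' @param aln An [msa] object.
#' @param catalytic_column 1-based alignment column of the catalytic acid.
#' @param allowed_residues Residues accepted at that column.
#' @return A list with `alignment` (filtered [msa]) and `report` (tibble with
#'   `n_input`, `n_removed_catalytic`, `n_kept`, and list-columns `kept_ids`,
#'   `removed_ids`).
#' @export
filter_missing_catalytic <- function(aln, catalytic_column,
                                     allowed_residues = c("D", "E")) {
  stopifnot(inherits(aln, "msa"))
  if (catalytic_column < 1 || catalytic_column > n_columns(aln)) {
    abort(paste0("`catalytic_column` ", catalytic_column, " out of range 1..",
                 n_columns(aln), "."), class = "coevomotif_index_error")
  }
  ok <- aln$mat[, catalytic_column] %in% toupper(allowed_residues)
  kept <- aln$ids[ok]
  removed <- aln$ids[!ok]
  rows <- apply(aln$mat[ok, , drop = FALSE], 1, paste, collapse = "")
  list(alignment = msa(kept, rows, descriptions = aln$descriptions[kept]),
       report = tibble(n_input = length(aln$ids),
                       n_removed_catalytic = length(removed),
                       n_kept = length(kept),
                       kept_ids = list(kept),
                       removed_ids = list(removed)))
}
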