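AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Random alignment fixture built in code.
random_msa <- function(n, L, alphabet = AA20, gap_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (gap_rate > 0) m[matrix(runif(n * L) < gap_rate, n, L)] <- "-"
  msa(sprintf("s%03d", seq_len(n)), apply(m, 1, paste, collapse = ""))
}

# Independent brute-force oracle for the column-correlation statistic:
# direct weighted count-and-sum on the residue tables, no shared code with
# the package kernel.
oracle_pair_score <- function(aln, i, j, w = NULL) {
  x <- aln$mat[, i]; y <- aln$mat[, j]
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !(x %in% c("-", "X")) & !(y %in% c("-", "X"))
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) == 0) return(NA_real_)
  joint <- tapply(w, list(x, y), sum, default = 0)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  (H(px) + H(py) - H(as.vector(p))) / min(H(px), H(py))
}

# Textbook position-based weighting, computed directly per column.
oracle_henikoff <- function(aln) {
  n <- length(aln$ids)
  raw <- numeric(n)
  for (c in seq_len(n_columns(aln))) {
    col <- aln$mat[, c]
    keep <- !(col %in% c("-", "X"))
    if (!any(keep)) next
    tab <- table(col[keep])
    raw[keep] <- raw[keep] + 1 / (length(tab) * as.numeric(tab[col[keep]]))
  }
  raw / sum(raw) * n
}

# Exhaustive greedy clustering oracle over a precomputed identity matrix.
oracle_greedy <- function(ids, seqs, idmat, threshold) {
  ord <- order(-nchar(seqs), ids, method = "radix")
  reps <- integer(0)
  for (k in ord) {
    hit <- FALSE
    for (r in reps) {
      if (idmat[k, r] > threshold) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, k)
  }
  sort(ids[reps])
}

# Dense 2-D grid-search oracle for the Michaelis-Menten least-squares fit.
oracle_mm_grid <- function(S, v, km_range, vmax_range, n_grid = 200) {
  kms <- seq(km_range[1], km_range[2], length.out = n_grid)
  vms <- seq(vmax_range[1], vmax_range[2], length.out = n_grid)
  best <- c(NA, NA); best_ss <- Inf
  for (km in kms) {
    pred_base <- S / (km + S)
    for (vm in vms) {
      ss <- sum((v - vm * pred_base)^2)
      if (ss < best_ss) { best_ss <- ss; best <- c(km, vm) }
    }
  }
  list(KM = best[1], Vmax = best[2], ss = best_ss)
}

# Tiny two-subfamily spec used across tests.
toy_family_spec <- function(n_subgroups = 2, seqs_per_subgroup = 10,
                            n_columns = 30, epsilon = 0, seed = 7,
                            positions = c(5, 12), coupling = 1.0) {
  family_spec(n_subgroups = n_subgroups, seqs_per_subgroup = seqs_per_subgroup,
              n_columns = n_columns,
              planted = list(list(role = "strong", positions = positions,
                                  partition = seq_len(n_subgroups),
                                  coupling = coupling)),
              epsilon = epsilon, seed = seed, reference_id = "ref1",
              hub = positions[1], strong = positions)
}
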