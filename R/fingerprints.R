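#' Packaged table of characterised GH65 specificities
#'
#' The ten substrate specificities currently described for glycoside
#' hydrolase family 65, with EC numbers, enzyme names, abbreviations,
#' substrates and products.
#'
#' @return A tibble with columns `ec`, `enzyme`, `abbreviation`, `substrate`,
#'   `product`.
#' @export
gh65_specificities <- function() {
  path <- system.file("extdata", "gh65_specificities.tsv", package = "coevomotif")
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       colClasses = "character"))
}

#' Packaged GH65 fingerprint motifs
#'
#' Consensus fingerprint motifs over the six specificity-determining
#' positions for the specificities whose motifs are established in the
#' literature, plus the single-sequence motif of the uncharacterised
#' subgroup 7. Tokens are single residues, bracketed alternatives like
#' `[MF]`, or the wildcard `x`.
#'
#' @return A tibble with columns `specificity_label`, `motif_string`, `note`.
#' @export
gh65_fingerprints <- function() {
  read_fingerprint_table(system.file("extdata", "gh65_fingerprints.tsv",
                                     package = "coevomotif"))
}

#' Read a fingerprint reference table
#'
#' @param path TSV with header columns `specificity_label` and `motif_string`
#'   (additional columns are carried along).
#' @return A tibble.
#' @export
read_fingerprint_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Fingerprint table not found: ", path), class = "coevomotif_io_error")
  }
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = "character"))
  if (!all(c("specificity_label", "motif_string") %in% names(tab))) {
    abort("Fingerprint table needs columns `specificity_label` and `motif_string`.",
          class = "coevomotif_format_error")
  }
  tab
}

#' Parse a motif string into tokens
#'
#' `"KV[MF]NES"` becomes the token list `K, V, [MF], N, E, S`; `x` is the
#' wildcard token.
#'
#' @param motif A motif string.
#' @return Character vector of tokens.
#' @export
parse_motif <- function(motif) {
  out <- character(0)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars)) {
        abort(paste0("Unbalanced bracket in motif '", motif, "'."),
              class = "coevomotif_format_error")
      }
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else {
      out <- c(out, chars[i])
      i <- i + 1
    }
  }
  out
}

token_set <- function(token) {
  if (token == "x" || token == "X") return(NULL)   # wildcard
  gsub("\\[|\\]", "", token) |> strsplit("", fixed = TRUE) |> unlist()
}

#' Consensus token from a residue-frequency vector
#'
#' Rules (defaults chosen to reproduce the printed family motifs on fixture
#' data; all thresholds are arguments):
#' a single residue when the top frequency is at least `single_min` and leads
#' the runner-up by at least `lead_min`; a bracketed pair `[AB]` when the top
#' two each reach `pair_each` and jointly `pair_joint`; otherwise the
#' wildcard `x`. Bracket members are ordered by decreasing frequency, ties
#' broken by the conventional substitution-matrix residue order.
#'
#' @param freqs Named numeric vector of residue frequencies summing to 1
#'   (tolerance 1e-6).
#' @param single_min,lead_min,pair_each,pair_joint Consensus thresholds.
#' @return A token string.
#' @export
#' @examples
#' consensus_token(c(E = 1))
#' consensus_token(c(M = 0.5, F = 0.5))
consensus_token <- function(freqs, single_min = 0.5, lead_min = 0.2,
                            pair_each = 0.2, pair_joint = 0.7) {
  if (length(freqs) == 0 || abs(sum(freqs) - 1) > 1e-6) {
    abort("`freqs` must be a normalized frequency vector.",
          class = "coevomotif_value_error")
  }
  full <- setNames(rep(0, length(AA_ORDER)), AA_ORDER)
  full[names(freqs)] <- freqs
  ord <- order(-full, match(names(full), AA_ORDER))
  top <- full[ord[1]]; second <- full[ord[2]]
  if (top >= single_min && (top - second) >= lead_min) {
    return(names(full)[ord[1]])
  }
  if (top >= pair_each && second >= pair_each && (top + second) >= pair_joint) {
    return(paste0("[", names(full)[ord[1]], names(full)[ord[2]], "]"))
  }
  "x"
}

#' Extract per-subgroup fingerprint motifs at selected positions
#'
#' For every subgroup and selected position, computes weighted residue
#' frequencies (gaps and `X` excluded from the normalisation), the
#' Schneider-Stephens information content `log2(20) - H` in bits (no
#' small-sample correction), and a consensus token. A subgroup with zero
#' residue coverage at a position gets the wildcard token with a warning.
#'
#' @param aln An [msa] object.
#' @param partition A tibble with columns `id` and `subgroup_id` (see
#'   [assign_subgroups()] or [read_partition()]); every subgroup used must be
#'   non-empty.
#' @param positions Selection tibble from [select_positions()] (columns
#'   `position`, `column`), or an integer vector of alignment columns.
#' @param weights Optional [henikoff_weights()] tibble.
#' @param ... Consensus thresholds passed to [consensus_token()].
#' @return A `fingerprint_set` tibble with columns `subgroup_id`, `position`,
#'   `column`, `token`, `info_bits` and list-column `freqs`, plus the
#'   per-subgroup consensus strings available via [motif_consensus()].
#' @export
extract_motifs <- function(aln, partition, positions, weights = NULL, ...) {
  stopifnot(inherits(aln, "msa"))
  partition <- as_tibble(partition)
  sel <- as_selection(positions)
  w <- setNames(weights_vector(aln, weights), aln$ids)
  missing_ids <- setdiff(partition$id, aln$ids)
  if (length(missing_ids) > 0) {
    abort(paste0("Partition ids absent from alignment: ",
                 paste(head(missing_ids, 3), collapse = ", ")),
          class = "coevomotif_lookup_error")
  }
  groups <- split(partition$id, partition$subgroup_id)
  out <- purrr::map_dfr(names(groups), function(g) {
    ids <- groups[[g]]
    purrr::map_dfr(seq_len(nrow(sel)), function(k) {
      col <- aln$mat[ids, sel$column[k]]
      keep <- col %in% AA_ORDER
      if (!any(keep)) {
        warn(paste0("Subgroup ", g, " has no residue coverage at position ",
                    sel$position[k], "; token set to 'x'."))
        return(tibble(subgroup_id = g, position = sel$position[k],
                      column = sel$column[k], token = "x",
                      info_bits = NA_real_, freqs = list(numeric(0))))
      }
      ws <- w[ids][keep]
      fr <- tapply(ws, factor(col[keep], levels = AA_ORDER), sum, default = 0)
      fr <- fr / sum(fr)
      fr <- fr[fr > 0]
      h <- -sum(fr * log2(fr))
      tibble(subgroup_id = g, position = sel$position[k], column = sel$column[k],
             token = consensus_token(fr, ...),
             info_bits = log2(20) - h,
             freqs = list(setNames(as.numeric(fr), names(fr))))
    })
  })
  class(out) <- c("fingerprint_set", class(out))
  out
}

as_selection <- function(positions) {
  if (is.numeric(positions)) {
    return(tibble(position = as.integer(positions), column = as.integer(positions)))
  }
  positions <- as_tibble(positions)
  if (!all(c("position", "column") %in% names(positions))) {
    abort("`positions` needs columns `position` and `column` (or be an integer vector).",
          class = "coevomotif_value_error")
  }
  positions
}

#' Per-subgroup consensus motif strings
#'
#' @param fps A `fingerprint_set` from [extract_motifs()].
#' @return A tibble with columns `subgroup_id`, `motif_string` (tokens
#'   concatenated in ascending position order).
#' @export
motif_consensus <- function(fps) {
  fps |>
    dplyr::arrange(.data$subgroup_id, .data$position) |>
    dplyr::group_by(.data$subgroup_id) |>
    dplyr::summarise(motif_string = paste(.data$token, collapse = ""),
                     .groups = "drop")
}

#' Sequence-logo matrix for one subgroup
#'
#' @param fps A `fingerprint_set`.
#' @param subgroup Subgroup id.
#' @return A position x residue matrix of letter heights in bits
#'   (frequency times information content), suitable for logo rendering.
#' @export
logo_matrix <- function(fps, subgroup) {
  sub <- fps[fps$subgroup_id == subgroup, ]
  if (nrow(sub) == 0) {
    abort(paste0("No fingerprints for subgroup '", subgroup, "'."),
          class = "coevomotif_lookup_error")
  }
  sub <- dplyr::arrange(sub, .data$position)
  m <- matrix(0, nrow(sub), length(AA_ORDER),
              dimnames = list(sub$position, AA_ORDER))
  for (k in seq_len(nrow(sub))) {
    f <- sub$freqs[[k]]
    if (length(f) > 0 && !is.na(sub$info_bits[k])) {
      m[k, names(f)] <- f * sub$info_bits[k]
    }
  }
  m
}

#' Predict specificity from fingerprint residues
#'
#' Matches each query's residues at the selected positions against a
#' fingerprint reference table. Per label, the match fraction is the number
#' of matched positions divided by the number of non-wildcard positions
#' (a single letter matches itself; `[MF]` matches M or F; `x` matches
#' anything but is excluded from the denominator, so `EEAPxx` is a
#' four-position constraint). The best label is the argmax; ties or a best
#' score below `accept_threshold` yield `unknown`. All-wildcard motifs are
#' masked and never win. Matching is case-insensitive and deterministic.
#'
#' @param queries Named character vector of residue strings (one character
#'   per selected position), or a tibble with columns `query_id`, `residues`.
#' @param reference Fingerprint table (see [gh65_fingerprints()] or
#'   [read_fingerprint_table()]).
#' @param accept_threshold Minimum best match fraction (default 0.8).
#' @return A tibble with one row per query: `query_id`, `label`,
#'   `match_score`, and list-column `detail` (per-label scores).
#' @export
#' @examples
#' classify_sequence(c(q1 = "EEAPWS"), gh65_fingerprints())
classify_sequence <- function(queries, reference, accept_threshold = 0.8) {
  if (is.character(queries)) {
    if (is.null(names(queries))) {
      names(queries) <- paste0("query", seq_along(queries))
    }
    queries <- tibble(query_id = names(queries), residues = unname(queries))
  }
  queries <- as_tibble(queries)
  reference <- as_tibble(reference)
  tokens <- lapply(reference$motif_string, parse_motif)
  n_pos <- unique(lengths(tokens))
  if (length(n_pos) != 1) {
    abort("All reference motifs must have the same number of positions.",
          class = "coevomotif_dimension_error")
  }
  purrr::map_dfr(seq_len(nrow(queries)), function(q) {
    res <- strsplit(toupper(queries$residues[q]), "", fixed = TRUE)[[1]]
    if (length(res) != n_pos) {
      abort(paste0("Query '", queries$query_id[q], "' has ", length(res),
                   " residues; reference motifs have ", n_pos, " positions."),
            class = "coevomotif_dimension_error")
    }
    detail <- purrr::map_dfr(seq_along(tokens), function(t) {
      tk <- tokens[[t]]
      informative <- !vapply(tk, function(x) is.null(token_set(x)), logical(1))
      denom <- sum(informative)
      if (denom == 0) {
        return(tibble(label = reference$specificity_label[t],
                      match_score = NA_real_, n_informative = 0L))
      }
      hits <- vapply(which(informative), function(k) res[k] %in% token_set(tk[k]),
                     logical(1))
      tibble(label = reference$specificity_label[t],
             match_score = sum(hits) / denom, n_informative = denom)
    })
    scored <- detail[!is.na(detail$match_score), ]
    if (nrow(scored) == 0) {
      best <- "unknown"; best_score <- NA_real_
    } else {
      best_score <- max(scored$match_score)
      winners <- scored$label[scored$match_score == best_score]
      best <- if (length(winners) == 1 && best_score >= accept_threshold &&
                  winners != "unknown") winners else "unknown"
    }
    tibble(query_id = queries$query_id[q], label = best,
           match_score = best_score, detail = list(detail))
  })
}

#' Predict reaction mechanism from phosphate-binding positions
#'
#' Inspects the residues a sequence carries at alignment columns known to be
#' involved in phosphate binding. Verdicts: `phosphorylase` when every
#' configured position carries a residue from its configured set;
#' `hydrolase` when at least one position deviates; `undetermined` when any
#' configured position is gapped (or `X`). The package ships no default
#' positions: the relevant sites are structure- and family-specific, so they
#' must be supplied (an editable example configuration is installed at
#' `extdata/phosphate_sites_example.yaml`).
#'
#' @param row Aligned sequence: a single string or character vector of
#'   residues.
#' @param phosphate_columns Integer vector of 1-based alignment columns.
#' @param phosphorylase_residues List (same length) of residue sets expected
#'   in phosphorylases at each column.
#' @return One of `"phosphorylase"`, `"hydrolase"`, `"undetermined"`.
#' @export
mechanism_call <- function(row, phosphate_columns, phosphorylase_residues) {
  if (missing(phosphate_columns) || length(phosphate_columns) == 0 ||
      missing(phosphorylase_residues) || length(phosphorylase_residues) == 0) {
    abort(paste0("No phosphate-binding positions configured. Supply ",
                 "`phosphate_columns` and `phosphorylase_residues`; see the ",
                 "editable example in extdata/phosphate_sites_example.yaml."),
          class = "coevomotif_config_error")
  }
  if (length(phosphate_columns) != length(phosphorylase_residues)) {
    abort("`phosphate_columns` and `phosphorylase_residues` lengths differ.",
          class = "coevomotif_dimension_error")
  }
  if (length(row) == 1 && nchar(row) > 1) {
    row <- strsplit(toupper(row), "", fixed = TRUE)[[1]]
  } else {
    row <- toupper(row)
  }
  if (any(phosphate_columns < 1 | phosphate_columns > length(row))) {
    abort("Configured phosphate column out of range.", class = "coevomotif_index_error")
  }
  res <- row[phosphate_columns]
  if (any(res %in% c("-", "X"))) return("undetermined")
  ok <- vapply(seq_along(res),
               function(k) res[k] %in% toupper(phosphorylase_residues[[k]]),
               logical(1))
  if (all(ok)) "phosphorylase" else "hydrolase"
}
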