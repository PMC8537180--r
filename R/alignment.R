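#' Construct a validated multiple sequence alignment
#'
#' The alignment is the central container of the package: a rectangular block
#' of aligned protein sequences over the 20 standard amino acids plus `X`
#' (unknown residue, treated as missing data downstream) and `-` (gap).
#' Lowercase input is normalised to uppercase; `.` gaps are normalised to `-`.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned rows (same length as `ids`), all of
#'   equal width.
#' @param descriptions Optional character vector of description lines. They are
#'   carried along verbatim and never parsed for metadata.
#'
#' @return An object of class `msa`: a list with elements `ids`, `mat` (an
#'   `n x L` character matrix of single residues, rownames = ids) and
#'   `descriptions`.
#' @export
#' @examples
#' aln <- msa(c("s1", "s2"), c("AC-D", "ACED"))
#' n_columns(aln)
msa <- function(ids, seqs, descriptions = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs)) {
    abort("`ids` and `seqs` must have the same length.", class = "coevomotif_dimension_error")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "coevomotif_validation_error")
  }
  widths <- nchar(seqs)
  if (length(seqs) > 0 && length(unique(widths)) > 1) {
    bad <- ids[widths != widths[1]][1]
    abort(paste0("Alignment rows have unequal lengths (first offender: '", bad, "')."),
          class = "coevomotif_dimension_error")
  }
  ncol <- if (length(seqs) > 0) widths[1] else 0L
  mat <- matrix(character(0), nrow = 0, ncol = ncol)
  if (length(seqs) > 0) {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  }
  ok <- c(AA_ORDER, "X", "-")
  bad <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad) > 0) {
    abort(paste0("Invalid residue character(s) in alignment: ",
                 paste(shQuote(bad), collapse = ", ")),
          class = "coevomotif_validation_error")
  }
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat,
                 descriptions = descriptions %||% setNames(rep("", length(ids)), ids)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " sequences x ", n_columns(x), " columns\n", sep = "")
  show <- head(x$ids, 5)
  for (id in show) {
    row <- paste(x$mat[id, seq_len(min(50, n_columns(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, row, if (n_columns(x) > 50) "..." else ""))
  }
  if (length(x$ids) > 5) cat("  ... and", length(x$ids) - 5, "more\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An [msa] object.
#' @return Integer column count.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  ncol(aln$mat)
}

#' Turn an alignment into a tidy tibble
#'
#' @param x An [msa] object.
#' @param ... Unused.
#' @return A tibble with columns `id` and `seq` (the aligned row as a string).
#' @export
as_tibble.msa <- function(x, ...) {
  tibble(id = x$ids,
         seq = unname(apply(x$mat, 1, paste, collapse = "")))
}

#' Read a protein multiple sequence alignment
#'
#' FASTA parsing is delegated to Biostrings; Stockholm files (single- or
#' multi-block, `#=GF`/`#=GC` annotation lines skipped) are parsed directly.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return A validated [msa] object.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Alignment file not found: ", path), class = "coevomotif_io_error")
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) abort(paste0("FASTA parse failure in '", path, "': ",
                                                     conditionMessage(e)),
                                              class = "coevomotif_format_error"))
    nm <- names(set)
    ids <- sub("\\s.*$", "", nm)
    desc <- sub("^\\S+\\s*", "", nm)
    msa(ids, as.character(set), descriptions = setNames(desc, ids))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
      abort(paste0("Not a Stockholm file (missing '# STOCKHOLM' header): ", path),
            class = "coevomotif_format_error")
    }
    seqs <- list()
    order_seen <- character(0)
    for (ln in lines[-1]) {
      if (grepl("^//", ln)) break
      if (ln == "" || grepl("^#", ln)) next
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2) {
        abort(paste0("Malformed Stockholm sequence line: '", ln, "'"),
              class = "coevomotif_format_error")
      }
      id <- parts[1]
      if (!id %in% order_seen) order_seen <- c(order_seen, id)
      seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2])
    }
    msa(order_seen, unlist(seqs[order_seen], use.names = FALSE))
  }
}

#' Write an alignment to FASTA or Stockholm
#'
#' Writing then reading back yields an identical alignment (round-trip
#' identity), which the test-suite asserts for both formats.
#'
#' @param aln An [msa] object.
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  stopifnot(inherits(aln, "msa"))
  format <- match.arg(format)
  rows <- apply(aln$mat, 1, paste, collapse = "")
  if (length(aln$ids) == 0) rows <- character(0)
  out <- tryCatch({
    if (format == "fasta") {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      for (i in seq_along(aln$ids)) {
        desc <- aln$descriptions[[aln$ids[i]]]
        hdr <- if (!is.null(desc) && nzchar(desc)) paste(aln$ids[i], desc) else aln$ids[i]
        writeLines(c(paste0(">", hdr), rows[i]), con)
      }
      if (length(aln$ids) == 0) invisible(NULL)
    } else {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      writeLines("# STOCKHOLM 1.0", con)
      if (length(aln$ids) > 0) {
        pad <- max(nchar(aln$ids))
        writeLines(sprintf(paste0("%-", pad, "s %s"), aln$ids, rows), con)
      }
      writeLines("//", con)
    }
  }, error = function(e) {
    abort(paste0("Cannot write alignment to '", path, "': ", conditionMessage(e)),
          class = "coevomotif_io_error")
  })
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' All user-facing position labels in the package follow the numbering of a
#' designated reference sequence (for glycoside hydrolase family 65 the
#' kojibiose phosphorylase of *Caldicellulosiruptor saccharolyticus* is the
#' conventional anchor). The k-th non-gap character of the reference row maps
#' its column to residue number k; columns where the reference is gapped stay
#' unmapped.
#'
#' @param aln An [msa] object.
#' @param reference_id Id of the reference sequence, present in `aln`.
#' @return A tibble with columns `column` (1-based alignment column),
#'   `residue_no` (1-based reference numbering) and `residue` (the reference
#'   residue at that column). Unmapped columns are absent.
#' @export
#' @examples
#' aln <- msa(c("ref", "s2"), c("A-CD", "AGCD"))
#' build_numbering_map(aln, "ref")
build_numbering_map <- function(aln, reference_id) {
  stopifnot(inherits(aln, "msa"))
  if (!reference_id %in% aln$ids) {
    abort(paste0("Reference id '", reference_id, "' not found in the alignment."),
          class = "coevomotif_lookup_error")
  }
  row <- aln$mat[reference_id, ]
  nongap <- which(row != "-")
  tibble(column = nongap,
         residue_no = seq_along(nongap),
         residue = unname(row[nongap]))
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with validation that leaf names are
#' unique. Branch lengths and support values are retained.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Tree file not found: ", path), class = "coevomotif_io_error")
  }
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste0("Newick parse failure in '", path, "': ",
                                                  conditionMessage(e)),
                                           class = "coevomotif_format_error"))
  if (is.null(tr)) {
    abort(paste0("Newick parse failure in '", path, "'."), class = "coevomotif_format_error")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort("Tree has duplicated leaf names.", class = "coevomotif_validation_error")
  }
  tr
}
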