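#' RasMol amino-acid colors
#'
#' The conventional fixed amino-acid color scheme (acidic D/E share one
#' color, basic K/R another, and so on), packaged as a hex table. Gaps map
#' to neutral white `#FFFFFF` and `X` to grey.
#'
#' @return A tibble with columns `residue`, `color`.
#' @export
rasmol_colors <- function() {
  path <- system.file("extdata", "rasmol_colors.tsv", package = "coevomotif")
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       colClasses = "character"))
}

#' Read or write a subgroup partition table
#'
#' @param path TSV with header `sequence_id`, `subgroup_id` and optional
#'   `specificity_label`.
#' @return A tibble with columns `id`, `subgroup_id` (and
#'   `specificity_label` if present). Dotted subgroup labels such as
#'   `"10.1"` are passed through verbatim.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Partition file not found: ", path), class = "coevomotif_io_error")
  }
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = "character"))
  if (!all(c("sequence_id", "subgroup_id") %in% names(tab))) {
    abort("Partition table needs columns `sequence_id` and `subgroup_id`.",
          class = "coevomotif_format_error")
  }
  names(tab)[names(tab) == "sequence_id"] <- "id"
  if (anyDuplicated(tab$id)) {
    abort("A sequence may belong to at most one subgroup.",
          class = "coevomotif_validation_error")
  }
  tab
}

#' @rdname read_partition
#' @param partition Tibble with columns `id`, `subgroup_id` (and optionally
#'   `specificity_label`).
#' @export
write_partition <- function(partition, path) {
  out <- as_tibble(partition)
  names(out)[names(out) == "id"] <- "sequence_id"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Residue string of each leaf over the selected columns.
leaf_signatures <- function(aln, sel) {
  apply(aln$mat[, sel$column, drop = FALSE], 1, paste, collapse = "")
}

#' Assign subgroups from tree clades and fingerprint homogeneity
#'
#' A reconstruction aid for the expert subdivision of a family tree into
#' specificity subgroups: the tree is traversed from the root down, and the
#' largest clades in which at least `homogeneity` of the leaves share an
#' identical residue string over the selected positions (and which hold at
#' least `min_clade_size` leaves) become subgroups, numbered in traversal
#' order. Leaves not captured by any such clade fall into subgroup `"0"`
#' (unassigned). A user-supplied partition table (see [read_partition()])
#' always takes precedence over this heuristic in the pipeline.
#'
#' @param tree An `ape::phylo` tree whose tips are alignment sequence ids.
#' @param aln An [msa] object.
#' @param positions Selection tibble or integer column vector (see
#'   [extract_motifs()]).
#' @param min_clade_size Minimum leaves for a subgroup (default 5).
#' @param homogeneity Minimum fraction of leaves sharing the modal residue
#'   string (default 0.9). Raising it towards 1 refines the partition into
#'   more, smaller subgroups.
#' @return A tibble with columns `id`, `subgroup_id`.
#' @export
assign_subgroups <- function(tree, aln, positions, min_clade_size = 5,
                             homogeneity = 0.9) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "msa"))
  missing_ids <- setdiff(tree$tip.label, aln$ids)
  if (length(missing_ids) > 0) {
    abort(paste0("Tree leaves absent from alignment: ",
                 paste(head(missing_ids, 3), collapse = ", ")),
          class = "coevomotif_lookup_error")
  }
  sel <- as_selection(positions)
  sig <- leaf_signatures(aln, sel)
  ntip <- length(tree$tip.label)
  assignment <- setNames(rep(NA_character_, ntip), tree$tip.label)
  counter <- 0L

  # descendant tips per node via single post-order pass
  tips_of <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_of[[i]] <- tree$tip.label[i]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    tips_of[[par]] <- c(tips_of[[par]], tips_of[[child]])
  }

  visit <- function(node) {
    tips <- tips_of[[node]]
    if (length(tips) >= min_clade_size) {
      frac <- max(table(sig[tips])) / length(tips)
      if (frac >= homogeneity) {
        counter <<- counter + 1L
        assignment[tips] <<- as.character(counter)
        return(invisible(NULL))
      }
    }
    if (node > ntip) {
      children <- tree$edge[tree$edge[, 1] == node, 2]
      for (ch in sort(children)) visit(ch)
    }
    invisible(NULL)
  }
  root <- ntip + 1L
  visit(root)
  assignment[is.na(assignment)] <- "0"
  tibble(id = tree$tip.label, subgroup_id = unname(assignment[tree$tip.label]))
}

#' Export iTOL COLORSTRIP ring datasets
#'
#' Writes one iTOL COLORSTRIP dataset file per selected position, so the
#' residues at the specificity-determining positions can be viewed as
#' colored rings around the family tree (RasMol color scheme; gap leaves
#' white). Ring files are named and labelled by reference position number in
#' ascending order (inner to outer ring when loaded in order), and each file
#' carries a legend enumerating the color mapping. Output is byte-stable for
#' identical inputs.
#'
#' @param tree An `ape::phylo` tree whose tips are alignment sequence ids.
#' @param aln An [msa] object.
#' @param positions Selection tibble or integer column vector.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths (ascending position order).
#' @export
export_itol_rings <- function(tree, aln, positions, out_dir) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "msa"))
  sel <- dplyr::arrange(as_selection(positions), .data$position)
  missing_ids <- setdiff(tree$tip.label, aln$ids)
  if (length(missing_ids) > 0) {
    abort(paste0("Tree leaves absent from alignment: ",
                 paste(head(missing_ids, 3), collapse = ", ")),
          class = "coevomotif_lookup_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory '", out_dir, "'."),
                   class = "coevomotif_io_error")
  }
  cols <- rasmol_colors()
  colmap <- setNames(cols$color, cols$residue)
  res_color <- function(r) {
    if (r == "-") "#FFFFFF" else unname(colmap[r]) %||% "#BEBEBE"
  }
  paths <- character(nrow(sel))
  legend_res <- names(colmap)
  for (k in seq_len(nrow(sel))) {
    pos <- sel$position[k]
    path <- file.path(out_dir, sprintf("ring_position_%s.txt", pos))
    residues <- aln$mat[tree$tip.label, sel$column[k]]
    hex <- vapply(residues, res_color, character(1))
    lines <- c(
      "DATASET_COLORSTRIP",
      "SEPARATOR COMMA",
      sprintf("DATASET_LABEL,%s", pos),
      "COLOR,#888888",
      "COLOR_BRANCHES,0",
      sprintf("LEGEND_TITLE,Residue (RasMol scheme), position %s", pos),
      sprintf("LEGEND_SHAPES,%s", paste(rep(1, length(legend_res)), collapse = ",")),
      sprintf("LEGEND_COLORS,%s", paste(unname(colmap), collapse = ",")),
      sprintf("LEGEND_LABELS,%s", paste(legend_res, collapse = ",")),
      "DATA",
      sprintf("%s,%s,%s", tree$tip.label, hex, residues)
    )
    writeLines(lines, path)
    paths[k] <- path
  }
  paths
}

#' Re-parse an exported ring dataset
#'
#' Reads back a COLORSTRIP file written by [export_itol_rings()], recovering
#' the residue-per-leaf mapping (round trip).
#'
#' @param path Path to a ring dataset file.
#' @return A tibble with columns `id`, `color`, `residue`.
#' @export
read_itol_ring <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- match("DATA", lines)
  if (is.na(start)) {
    abort(paste0("No DATA section in '", path, "'."), class = "coevomotif_format_error")
  }
  dat <- strsplit(lines[(start + 1):length(lines)], ",", fixed = TRUE)
  tibble(id = vapply(dat, `[`, "", 1),
         color = vapply(dat, `[`, "", 2),
         residue = vapply(dat, `[`, "", 3))
}
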