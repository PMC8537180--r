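pipeline_defaults <- function() {
  list(
    alignment = NULL,          # path to the family MSA (required)
    format = "fasta",
    tree = NULL,               # optional Newick path
    reference_id = NULL,       # numbering reference sequence id
    partition = NULL,          # optional partition TSV (overrides the heuristic)
    queries = NULL,            # optional TSV query_id, residues
    fingerprint_table = NULL,  # optional TSV; defaults to the packaged table
    out_dir = NULL,            # required
    redundancy = FALSE,        # all-pairs greedy clustering is quadratic;
                               # enable only for curated, desk-scale sets
    identity_threshold = 0.90,
    keep_list = character(0),
    catalytic_column = NULL,   # reference-numbered; NULL skips the filter
    allowed_residues = c("D", "E"),
    max_gap_frac = 0.95,
    min_pairs = 20,
    h_min = 0.1,
    edge_threshold = 0.8,
    strong_threshold = 0.9,
    min_partners = 2,
    min_clade_size = 5,
    homogeneity = 0.9,
    accept_threshold = 0.8,
    write_matrix = FALSE,
    seed = 1L,
    log_level = "info"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "coevomotif_pipeline_error")
  })
}

#' Run the full specificity-mapping pipeline
#'
#' Chains preprocessing (optional redundancy reduction, catalytic-acid
#' filter, gap-column trimming), correlated-mutation analysis, position
#' selection, subgroup fingerprint extraction, optional query
#' classification, and iTOL ring export, then writes a reproducible run
#' manifest (package version, config hash, input checksums, per-stage
#' counts). Any stage error aborts with the stage name; outputs written by
#' earlier stages are preserved.
#'
#' @param config A named list of settings, or a path to a YAML file. Unknown
#'   keys are rejected; see the package vignette for the full key list.
#'   Threshold defaults are 0.90 identity, 0.95 gap fraction, 0.8 edge
#'   score, 0.9 strong score and 2 partners.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "coevomotif_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  for (key in c("alignment", "out_dir")) {
    if (is.null(cfg[[key]])) {
      abort(paste0("Config key '", key, "' is required."),
            class = "coevomotif_config_error")
    }
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  inputs <- purrr::compact(cfg[c("alignment", "tree", "partition", "queries",
                                 "fingerprint_table")])
  checksums <- as.list(tools::md5sum(unlist(inputs)))

  aln <- stage("read", read_alignment(cfg$alignment, cfg$format))
  counts <- list(n_input = length(aln$ids))

  if (isTRUE(cfg$redundancy)) {
    stage("redundancy", {
      degapped <- as_tibble(aln) |>
        dplyr::mutate(seq = gsub("-", "", .data$seq, fixed = TRUE))
      red <- greedy_redundancy_filter(degapped, cfg$identity_threshold,
                                      cfg$keep_list)
      keep <- aln$ids %in% red$seqs$id
      aln <- msa(aln$ids[keep],
                  apply(aln$mat[keep, , drop = FALSE], 1, paste, collapse = ""),
                  descriptions = aln$descriptions[aln$ids[keep]])
      counts$n_after_redundancy <- length(aln$ids)
    })
  }

  if (!is.null(cfg$catalytic_column)) {
    stage("catalytic_filter", {
      col <- cfg$catalytic_column
      if (!is.null(cfg$reference_id)) {
        nm <- build_numbering_map(aln, cfg$reference_id)
        hit <- nm$column[nm$residue_no == col]
        if (length(hit) != 1) {
          abort(paste0("Catalytic residue ", col, " is not mapped in the reference."))
        }
        col <- hit
      }
      fc <- filter_missing_catalytic(aln, col, cfg$allowed_residues)
      aln <- fc$alignment
      counts$n_removed_catalytic <- fc$report$n_removed_catalytic
    })
  }

  trimmed <- stage("trim", trim_gap_columns(aln, cfg$max_gap_frac))
  aln <- trimmed$alignment
  counts$n_columns_removed <- length(trimmed$removed_columns)
  counts$n_columns <- n_columns(aln)
  write_alignment(aln, file.path(cfg$out_dir, "curated_alignment.fasta"), "fasta")

  w <- stage("weights", henikoff_weights(aln))
  cr <- stage("cma", cma_matrix(aln, w, reference_id = cfg$reference_id,
                                min_pairs = cfg$min_pairs, h_min = cfg$h_min))
  net <- stage("network", build_network(cr, cfg$edge_threshold))
  sel <- stage("select", select_positions(net, cr, cfg$strong_threshold,
                                          cfg$min_partners))
  counts$n_network_positions <- nrow(net$nodes)
  counts$n_selected <- nrow(sel)
  write.table(net$edges, file.path(cfg$out_dir, "coevolution_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sel, file.path(cfg$out_dir, "selected_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$write_matrix)) {
    pairs <- tidy(cr)
    write.table(pairs, file.path(cfg$out_dir, "cma_matrix_upper.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tree <- if (!is.null(cfg$tree)) stage("read_tree", read_tree(cfg$tree)) else NULL
  partition <- NULL
  if (!is.null(cfg$partition)) {
    partition <- stage("partition", read_partition(cfg$partition))
  } else if (!is.null(tree) && nrow(sel) > 0) {
    partition <- stage("partition",
                       assign_subgroups(tree, aln, sel, cfg$min_clade_size,
                                        cfg$homogeneity))
  }

  motifs <- NULL
  if (!is.null(partition) && nrow(sel) > 0) {
    motifs <- stage("motifs", {
      fps <- extract_motifs(aln, partition[partition$subgroup_id != "0", ],
                            sel, w)
      cons <- motif_consensus(fps)
      write.table(cons, file.path(cfg$out_dir, "subgroup_motifs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fps
    })
    counts$n_subgroups <- length(unique(partition$subgroup_id[partition$subgroup_id != "0"]))
  }

  if (!is.null(cfg$queries)) {
    stage("classify", {
      q <- read.delim(cfg$queries, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
      ref <- if (!is.null(cfg$fingerprint_table)) {
        read_fingerprint_table(cfg$fingerprint_table)
      } else gh65_fingerprints()
      pred <- classify_sequence(q, ref, cfg$accept_threshold)
      write.table(pred[, c("query_id", "label", "match_score")],
                  file.path(cfg$out_dir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$n_predictions <- nrow(pred)
    })
  }

  if (!is.null(tree) && nrow(sel) > 0) {
    stage("annotate",
          export_itol_rings(tree, aln, sel, file.path(cfg$out_dir, "rings")))
  }

  cfg_serial <- cfg
  cfg_serial$keep_list <- as.list(cfg$keep_list)
  manifest <- list(
    tool = "coevomotif",
    version = as.character(utils::packageVersion("coevomotif")),
    config = cfg_serial,
    config_md5 = digest_json(cfg_serial),
    input_md5 = checksums,
    counts = counts,
    selected_positions = sel$position
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

digest_json <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}
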