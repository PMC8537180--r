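# Background residue profiles for unplanted columns.
BACKGROUND_PROFILES <- list(
  uniform = setNames(rep(1 / 20, 20), AA_ORDER),
  # Average amino-acid composition of well-curated protein databases
  # (Robinson-Robinson style frequencies), renormalised.
  swissprot = local({
    f <- c(A = 8.3, R = 5.7, N = 4.4, D = 5.3, C = 1.7, Q = 4.0, E = 6.2,
           G = 7.2, H = 2.2, I = 5.2, L = 9.0, K = 5.7, M = 2.4, F = 4.0,
           P = 5.1, S = 6.9, T = 5.8, W = 1.3, Y = 3.2, V = 6.6)
    f[AA_ORDER] / sum(f)
  })
)

subgroup_classes <- function(partition, n_subgroups) {
  if (is.numeric(partition)) {
    if (length(partition) != n_subgroups) {
      abort("Explicit partition must have one class per subgroup.",
            class = "coevomotif_value_error")
    }
    return(as.integer(partition))
  }
  s <- seq_len(n_subgroups)
  switch(partition,
         pairs = as.integer(ceiling(s / 2)),
         pairs_shifted = as.integer(ceiling(((s %% n_subgroups) + 1) / 2)),
         abort(paste0("Unknown partition '", partition, "'."),
               class = "coevomotif_value_error"))
}

#' Specify a synthetic protein family with planted co-evolution
#'
#' The generator emulates the statistical structure that specificity-
#' determining positions are assumed to have: residues conserved within each
#' subfamily but switching together across subfamily boundaries. Each
#' planted group of columns shares a partition of the subgroups into residue
#' classes; a column shows its subgroup's class residue with probability
#' `coupling` (else a uniform random residue), after which each residue is
#' flipped to a random other residue with probability `epsilon`. Unplanted
#' columns are drawn i.i.d. from a shared background profile, independently
#' of subgroup, so they carry no phylogenetic signal by construction.
#'
#' @param n_subgroups Number of subfamilies.
#' @param seqs_per_subgroup Sequences per subfamily.
#' @param n_columns Alignment width.
#' @param planted List of planted groups; each a list with `positions`
#'   (1-based columns; the synthetic reference row is gap-free so columns
#'   and reference residue numbers coincide), `partition` (`"pairs"`,
#'   `"pairs_shifted"`, or an explicit integer class per subgroup) and
#'   `coupling` in `[0, 1]`, plus a free-text `role`.
#' @param epsilon Per-site substitution probability at planted columns, in
#'   `[0, 0.5)`.
#' @param gap_rate Per-cell gap probability (reference row exempt).
#' @param background `"swissprot"`, `"uniform"`, or a named frequency vector.
#' @param reference_id Id given to the gap-free numbering reference row
#'   (the first sequence of subgroup 1).
#' @param hub Reference position designated as the network hub.
#' @param strong Reference positions planted as the strongly-correlated set.
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @return A `family_spec` object (validated list).
#' @export
family_spec <- function(n_subgroups, seqs_per_subgroup, n_columns, planted,
                        epsilon = 0.02, gap_rate = 0, background = "swissprot",
                        reference_id = "reference", hub = NULL, strong = NULL,
                        seed = 1L) {
  if (!(epsilon >= 0 && epsilon < 0.5)) {
    abort("`epsilon` must be in [0, 0.5).", class = "coevomotif_value_error")
  }
  if (gap_rate < 0 || gap_rate >= 1) {
    abort("`gap_rate` must be in [0, 1).", class = "coevomotif_value_error")
  }
  if (is.character(background)) {
    if (!background %in% names(BACKGROUND_PROFILES)) {
      abort(paste0("Unknown background profile '", background, "'."),
            class = "coevomotif_value_error")
    }
    background <- BACKGROUND_PROFILES[[background]]
  }
  background <- background[AA_ORDER]
  if (anyNA(background)) {
    abort("`background` must name all 20 residues.", class = "coevomotif_value_error")
  }
  all_pos <- unlist(lapply(planted, `[[`, "positions"))
  if (anyDuplicated(all_pos)) {
    abort("Planted positions must be disjoint across groups.",
          class = "coevomotif_value_error")
  }
  if (length(all_pos) >= n_columns || any(all_pos < 1) || any(all_pos > n_columns)) {
    abort("Planted positions must fit strictly inside 1..n_columns.",
          class = "coevomotif_value_error")
  }
  for (g in planted) {
    if (!(g$coupling >= 0 && g$coupling <= 1)) {
      abort("`coupling` must be in [0, 1].", class = "coevomotif_value_error")
    }
    cls <- subgroup_classes(g$partition, n_subgroups)
    if (max(cls) > 20) {
      abort("A partition may have at most 20 classes (one residue each).",
            class = "coevomotif_value_error")
    }
  }
  structure(list(n_subgroups = as.integer(n_subgroups),
                 seqs_per_subgroup = as.integer(seqs_per_subgroup),
                 n_columns = as.integer(n_columns),
                 planted = planted, epsilon = epsilon, gap_rate = gap_rate,
                 background = background, reference_id = reference_id,
                 hub = hub, strong = strong, seed = as.integer(seed)),
            class = "family_spec")
}

#' Load a family specification from YAML
#'
#' @param path YAML file with the fields of [family_spec()]. Unknown keys
#'   are rejected.
#' @param seed Optional seed overriding the file's.
#' @return A `family_spec`.
#' @export
family_spec_from_yaml <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Spec file not found: ", path), class = "coevomotif_io_error")
  }
  y <- yaml::read_yaml(path)
  allowed <- c("n_subgroups", "seqs_per_subgroup", "n_columns", "planted",
               "epsilon", "gap_rate", "background", "reference_id", "hub",
               "strong", "seed")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown key(s) in family spec: ", paste(unknown, collapse = ", ")),
          class = "coevomotif_config_error")
  }
  if (!is.null(seed)) y$seed <- seed
  do.call(family_spec, y)
}

#' The shipped GH65-analog family specification
#'
#' The default synthetic stand-in for the glycoside hydrolase family 65
#' dataset: 22 subgroups of 50 sequences over 600 columns with 24 planted
#' co-evolving positions (a strongly coupled six labelled 64, 392, 394, 402,
#' 416 and 585 via the gap-free reference row, with 392 the network hub; 15
#' weakly coupled catalytic-domain positions; and the loop trio 56/62/63 on
#' a partition of its own) at substitution noise 0.02. See
#' `extdata/gh65_analog.yaml` for the editable file.
#'
#' @param seed Optional seed overriding the shipped one (65).
#' @return A `family_spec`.
#' @export
gh65_analog_spec <- function(seed = NULL) {
  family_spec_from_yaml(system.file("extdata", "gh65_analog.yaml",
                                    package = "coevomotif"),
                        seed = seed)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic family with known ground truth
#'
#' Draws the alignment described by a [family_spec()], a star-of-ladders
#' phylogeny consistent with the subgroups, and the true partition. Output
#' is deterministic per seed.
#'
#' @param spec A `family_spec`.
#' @return A list with `alignment` ([msa]), `tree` (`ape::phylo`),
#'   `partition` (tibble `id`, `subgroup_id`) and `ground_truth` (list with
#'   the planted column table, hub and strong set; serialise with
#'   [write_family()]).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  K <- spec$n_subgroups
  n <- K * spec$seqs_per_subgroup
  L <- spec$n_columns
  subgroup <- rep(seq_len(K), each = spec$seqs_per_subgroup)
  ids <- sprintf("sg%02d_seq%03d", subgroup,
                 sequence(rep(spec$seqs_per_subgroup, K)))
  ids[1] <- spec$reference_id

  mat <- with_local_seed(spec$seed, {
    m <- matrix(sample(AA_ORDER, n * L, replace = TRUE, prob = spec$background),
                nrow = n, ncol = L)
    for (g in spec$planted) {
      cls <- subgroup_classes(g$partition, K)
      for (pos in g$positions) {
        resmap <- sample(AA_ORDER, max(cls))
        col <- resmap[cls[subgroup]]
        if (g$coupling < 1) {
          mix <- runif(n) > g$coupling
          col[mix] <- sample(AA_ORDER, sum(mix), replace = TRUE)
        }
        if (spec$epsilon > 0) {
          flip <- runif(n) < spec$epsilon
          if (any(flip)) {
            col[flip] <- vapply(col[flip],
                                function(a) sample(setdiff(AA_ORDER, a), 1), "")
          }
        }
        m[, pos] <- col
      }
    }
    if (spec$gap_rate > 0) {
      gap <- matrix(runif(n * L) < spec$gap_rate, n, L)
      gap[1, ] <- FALSE                      # reference row stays gap-free
      m[gap] <- "-"
    }
    m
  })
  rows <- apply(mat, 1, paste, collapse = "")
  aln <- msa(ids, rows)
  tree <- family_tree(ids, subgroup)
  partition <- tibble(id = ids, subgroup_id = as.character(subgroup))
  planted_tbl <- purrr::map_dfr(spec$planted, function(g) {
    tibble(position = as.integer(g$positions), role = g$role %||% "planted",
           coupling = g$coupling)
  })
  list(alignment = aln, tree = tree, partition = partition,
       ground_truth = list(planted = planted_tbl,
                           hub = spec$hub, strong = spec$strong,
                           epsilon = spec$epsilon, seed = spec$seed,
                           n_subgroups = K,
                           seqs_per_subgroup = spec$seqs_per_subgroup))
}

# Star of ladders: one rooted ladder (caterpillar) per subgroup.
family_tree <- function(ids, subgroup) {
  ladder <- function(tips) {
    if (length(tips) == 1) return(sprintf("%s:0.02", tips))
    node <- sprintf("%s:0.02", tips[1])
    for (t in tips[-1]) {
      node <- sprintf("(%s,%s:0.02):0.01", node, t)
    }
    node
  }
  subtrees <- vapply(split(ids, subgroup),
                     function(tips) sprintf("(%s):0.3", ladder(tips)), "")
  ape::read.tree(text = paste0("(", paste(subtrees, collapse = ","), ");"))
}

#' Serialise a generated family to disk
#'
#' Writes the alignment (FASTA), tree (Newick), partition (TSV) and the
#' ground truth as a JSON sidecar, so tests and downstream runs never
#' re-derive what was planted.
#'
#' @param fam Output of [generate_family()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths.
#' @export
write_family <- function(fam, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "family.fasta"),
             tree = file.path(dir, "family.nwk"),
             partition = file.path(dir, "partition.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_alignment(fam$alignment, paths[["alignment"]], "fasta")
  ape::write.tree(fam$tree, paths[["tree"]])
  write_partition(fam$partition, paths[["partition"]])
  jsonlite::write_json(fam$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  paths
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' Mean rates follow `v = Vmax * S / (KM + S)` with
#' `Vmax = kcat * 60 / MW` (U/mg); observed rates are the mean times a
#' lognormal multiplicative noise term with unit mean and coefficient of
#' variation `noise_cv`.
#'
#' @param K_M Michaelis constant (mM).
#' @param k_cat Turnover number (s^-1).
#' @param E0 Enzyme concentration (mg/mL), metadata only.
#' @param MW Molecular weight (kDa).
#' @param concentrations Substrate concentrations (mM).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per concentration.
#' @param seed Optional integer seed.
#' @return A [rate_data] tibble with columns `conc_mM`, `rate_U_mg`,
#'   `replicate`.
#' @export
generate_mm_data <- function(K_M, k_cat, E0 = 0.005, MW = 73.7,
                             concentrations = c(0.25, 0.5, 1, 1.5, 2, 3, 5, 7.5, 10),
                             noise_cv = 0, replicates = 1, seed = NULL) {
  if (K_M <= 0 || k_cat <= 0 || E0 <= 0 || MW <= 0 || noise_cv < 0 ||
      any(concentrations <= 0)) {
    abort("All kinetic parameters must be positive.", class = "coevomotif_value_error")
  }
  vmax <- k_cat * 60 / MW
  S <- rep(concentrations, each = replicates)
  mean_rate <- vmax * S / (K_M + S)
  noise <- if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    draw <- function() rlnorm(length(S), meanlog = -sdl^2 / 2, sdlog = sdl)
    if (is.null(seed)) draw() else with_local_seed(seed, draw())
  } else rep(1, length(S))
  out <- rate_data(S, mean_rate * noise, enzyme_mg_ml = E0, mw_kda = MW)
  out$replicate <- rep(seq_len(replicates), times = length(concentrations))
  out
}
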