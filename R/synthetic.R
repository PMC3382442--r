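#' Generate a synthetic protein structure
#'
#' Places `n_residues` alpha-carbons as a self-avoiding random walk with
#' 3.8 A steps (the canonical consecutive CA-CA spacing) and a minimum
#' separation of 3.5 A between non-consecutive residues. Residue types are
#' drawn from a uniform background over the 20 amino acids. For the
#' `"binding"` class a cluster sphere is centred on a randomly chosen
#' residue and the types of all residues inside it are resampled with the
#' planted property's types up-weighted by the enrichment factor, emulating
#' the locally concentrated patches of (typically positively charged)
#' residues that distinguish DNA-binding proteins. With enrichment 1 the
#' two classes are distributionally identical.
#'
#' @param n_residues Number of residues (default 150).
#' @param label `"binding"` or `"nonbinding"`.
#' @param planted_property Property whose residues are enriched inside the
#'   cluster (default `"Positive"`).
#' @param cluster_radius Cluster sphere radius in Angstroms (default 10).
#' @param enrichment Multiplicative weight (>= 1) given to planted-property
#'   types when resampling inside the cluster (default 5).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param id Structure identifier.
#' @param table Property table defining the planted property.
#' @return A [protein_structure()].
#' @export
#' @examples
#' s <- generate_structure(30, label = "binding", seed = 1)
#' s
generate_structure <- function(n_residues = 150L,
                               label = c("nonbinding", "binding"),
                               planted_property = "Positive",
                               cluster_radius = 10, enrichment = 5,
                               seed = 1L, id = NULL,
                               table = default_property_table()) {
  label <- match.arg(label)
  if (n_residues < 1L) {
    abort("n_residues must be >= 1", class = "bh_error_config")
  }
  if (enrichment < 1) {
    abort("enrichment factor must be >= 1", class = "bh_error_config")
  }
  if (cluster_radius <= 0) {
    abort("cluster_radius must be > 0", class = "bh_error_config")
  }
  if (!planted_property %in% names(table)) {
    abort(paste0("unknown planted property: ", planted_property),
          class = "bh_error_config")
  }
  if (is.null(id)) id <- paste0("syn", seed)
  with_seed(seed, {
    coords <- saw_walk(n_residues, step = 3.8, min_sep = 3.5)
    types <- sample(amino_acids(), n_residues, replace = TRUE)
    center <- NULL
    if (label == "binding") {
      center <- coords[sample.int(n_residues, 1L), ]
      inside <- rowSums(sweep(coords, 2, center)^2) <= cluster_radius^2
      # enrichment = fold change of the planted property's frequency inside
      # the cluster (capped at 1); the remaining mass is shared by the other
      # types in their background proportions
      planted <- amino_acids() %in% table[[planted_property]]
      p_bg <- rep(1 / 20, 20)
      p_in <- min(1, enrichment * sum(p_bg[planted]))
      w <- ifelse(planted, p_bg * p_in / sum(p_bg[planted]),
                  p_bg * (1 - p_in) / sum(p_bg[!planted]))
      types[inside] <- sample(amino_acids(), sum(inside), replace = TRUE,
                              prob = w)
    }
    out <- protein_structure(
      tibble(chain = "A", seq_index = seq_len(n_residues), icode = "",
             res_type = types,
             x = coords[, 1], y = coords[, 2], z = coords[, 3]),
      id = id
    )
    # where the property was planted, for diagnostics and generator tests
    attr(out, "cluster_center") <- center
    out
  })
}

# Self-avoiding walk: fixed step length, minimum separation between
# non-consecutive points; bounded per-step retries with whole-chain restarts.
saw_walk <- function(n, step = 3.8, min_sep = 3.5, max_retries = 100L,
                     max_restarts = 50L) {
  for (attempt in seq_len(max_restarts)) {
    coords <- matrix(0, nrow = n, ncol = 3)
    ok <- TRUE
    i <- 2L
    while (i <= n) {
      placed <- FALSE
      for (r in seq_len(max_retries)) {
        g <- stats::rnorm(3)
        dir <- g / sqrt(sum(g^2))
        cand <- coords[i - 1L, ] + step * dir
        if (i > 2L) {
          d2 <- rowSums(sweep(coords[seq_len(i - 2L), , drop = FALSE], 2,
                              cand)^2)
          if (min(d2) < min_sep^2) next
        }
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
      i <- i + 1L
    }
    if (ok) return(coords)
  }
  abort("self-avoiding walk failed after bounded restarts",
        class = "bh_error_degenerate")
}

#' Generate a labeled synthetic dataset
#'
#' Generates `n_pos` binding and `n_neg` non-binding structures with
#' [generate_structure()], optionally writing each as a minimal PDB file
#' together with a manifest CSV (`id`, `path`, `label`) consumable by
#' [read_dataset()]. Per-structure seeds are derived from `seed`, so the
#' dataset is reproducible and written files are byte-identical across runs.
#'
#' @param n_pos,n_neg Number of binding / non-binding structures.
#' @param dir Output directory for PDB files and `manifest.csv`; `NULL`
#'   (default) keeps the dataset in memory only.
#' @param seed Integer master seed.
#' @inheritParams generate_structure
#' @return A [as_bh_dataset()] tibble; when `dir` is given it has a
#'   `"manifest"` attribute with the manifest path.
#' @export
generate_dataset <- function(n_pos, n_neg, n_residues = 150L,
                             planted_property = "Positive",
                             cluster_radius = 10, enrichment = 5,
                             seed = 1L, dir = NULL,
                             table = default_property_table()) {
  if (n_pos < 1L || n_neg < 1L) {
    abort("n_pos and n_neg must be >= 1", class = "bh_error_config")
  }
  ids <- c(sprintf("pos%03d", seq_len(n_pos)),
           sprintf("neg%03d", seq_len(n_neg)))
  labels <- c(rep("binding", n_pos), rep("nonbinding", n_neg))
  structures <- purrr::map2(ids, labels, function(i, lab) {
    generate_structure(n_residues = n_residues, label = lab,
                       planted_property = planted_property,
                       cluster_radius = cluster_radius,
                       enrichment = enrichment,
                       seed = derive_seed(seed, i), id = i, table = table)
  })
  ds <- as_bh_dataset(tibble(id = ids, label = labels,
                             structure = structures))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(ids, ".pdb"))
    purrr::walk2(structures, paths, write_pdb)
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(
      data.frame(id = ids, path = paste0(ids, ".pdb"), label = labels),
      manifest, row.names = FALSE, quote = FALSE
    )
    attr(ds, "manifest") <- manifest
  }
  ds
}
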