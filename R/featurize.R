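template_key <- function(template, radius) {
  paste0("R", format(radius), "|", paste(template, collapse = ","))
}

attr_id_of <- function(template, radius, counts) {
  paste0(template_key(template, radius), "|", paste(counts, collapse = ","))
}

# Vectorized attribute ids for a whole matrix of count vectors.
attr_ids_of <- function(template, radius, counts_matrix) {
  paste0(template_key(template, radius), "|",
         do.call(paste, c(as.data.frame(counts_matrix), sep = ",")))
}

#' Collect the attribute space from training histograms
#'
#' Propositionalization step one: scans all histograms generated from the
#' training proteins and creates one numerical attribute per (template,
#' sampling radius, count vector) whose bin weight is non-zero in at least
#' one training histogram. Evaluation proteins must not be passed here: the
#' attribute space is fixed at training time.
#'
#' @param hist_tbl A tibble with columns `id` (protein) and `histogram`
#'   (list of `ball_histogram`s); one row per protein and template.
#' @return A tibble of class `bh_attribute_space` with columns `attr_id`,
#'   `template` (list), `radius` and `counts` (list of integer vectors), in
#'   deterministic order: templates in first-appearance order, count vectors
#'   lexicographically.
#' @export
collect_attributes <- function(hist_tbl) {
  if (!nrow(hist_tbl)) {
    abort("empty training histogram set", class = "bh_error_config")
  }
  keys <- vapply(hist_tbl$histogram, function(h) {
    template_key(hist_template(h), hist_radius(h))
  }, character(1))
  groups <- split(hist_tbl$histogram, factor(keys, levels = unique(keys)))
  rows <- purrr::map_dfr(groups, function(hists) {
    template <- hist_template(hists[[1]])
    radius <- hist_radius(hists[[1]])
    bins <- dplyr::distinct(
      dplyr::filter(dplyr::bind_rows(lapply(hists, as_tibble)),
                    .data$weight > 0)[, template, drop = FALSE]
    )
    bins <- bins[do.call(order, unname(as.list(bins))), , drop = FALSE]
    mat <- as.matrix(bins)
    counts <- lapply(seq_len(nrow(mat)), function(i) as.integer(mat[i, ]))
    tibble(
      attr_id = attr_ids_of(template, radius, mat),
      template = rep(list(template), length(counts)),
      radius = radius,
      counts = counts
    )
  })
  if (anyDuplicated(rows$attr_id)) {
    abort("duplicated (template, radius) groups in training histograms",
          class = "bh_error_config")
  }
  structure(rows, class = c("bh_attribute_space", class(rows)))
}

#' Vectorize one protein's histograms against an attribute space
#'
#' Propositionalization step two: the feature value of each attribute is the
#' corresponding bin weight of the protein's histogram, or 0 when the bin is
#' absent. Bins observed for the protein but missing from the space (novel
#' at evaluation time) are dropped.
#'
#' @param histograms A list of `ball_histogram`s for one protein, covering
#'   every (template, radius) group of the space.
#' @param space A `bh_attribute_space` from [collect_attributes()].
#' @return A named numeric vector aligned with `space$attr_id`, values in
#'   `[0, 1]`.
#' @export
vectorize <- function(histograms, space) {
  have <- vapply(histograms, function(h) {
    template_key(hist_template(h), hist_radius(h))
  }, character(1))
  need <- unique(vapply(seq_len(nrow(space)), function(i) {
    template_key(space$template[[i]], space$radius[[i]])
  }, character(1)))
  if (!all(need %in% have)) {
    abort(paste0("missing histograms for groups: ",
                 paste(setdiff(need, have), collapse = "; ")),
          class = "bh_error_config")
  }
  weights <- stats::setNames(numeric(nrow(space)), space$attr_id)
  for (h in histograms) {
    template <- hist_template(h)
    radius <- hist_radius(h)
    counts <- as.matrix(as_tibble(h)[template])
    ids <- attr_ids_of(template, radius, counts)
    pos <- match(ids, space$attr_id)
    keep <- !is.na(pos)
    weights[pos[keep]] <- h$weight[keep]
  }
  weights
}

#' Build a feature matrix for a set of proteins
#'
#' Applies [vectorize()] to each protein's histograms and assembles a tibble
#' with one row per protein.
#'
#' @param hist_tbl A tibble with columns `id`, optionally `label`, and
#'   `histogram` (list of `ball_histogram`s), one row per (protein,
#'   template).
#' @param space A `bh_attribute_space`.
#' @return A tibble with columns `id`, `label` (if present) and one numeric
#'   column per attribute.
#' @export
featurize_dataset <- function(hist_tbl, space) {
  ids <- unique(hist_tbl$id)
  vecs <- lapply(ids, function(i) {
    vectorize(hist_tbl$histogram[hist_tbl$id == i], space)
  })
  mat <- do.call(rbind, vecs)
  out <- tibble(id = ids)
  if (!is.null(hist_tbl[["label"]])) {
    out$label <- hist_tbl$label[match(ids, hist_tbl$id)]
  }
  dplyr::bind_cols(out, as_tibble(as.data.frame(mat, check.names = FALSE)))
}

chi2_stat <- function(x, label) {
  bin <- cut(x, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  tab <- table(droplevels(bin), label)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  out <- tryCatch(
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic)),
    error = function(e) 0
  )
  if (!is.finite(out)) 0 else out
}

#' Rank attributes by chi-squared association with the class
#'
#' Each feature (a bin-weight fraction in `[0, 1]`) is discretized into 10
#' equal-width bins (empty bins dropped) and scored with the chi-squared
#' statistic of the bin-by-class contingency table. Higher scores mean
#' stronger association with the binding label.
#'
#' @param features A feature tibble from [featurize_dataset()] including a
#'   `label` column with both classes present.
#' @param space Optional `bh_attribute_space` restricting and ordering the
#'   attributes; defaults to all non-`id`/`label` columns.
#' @return A tibble with columns `attr_id`, `statistic` and `rank`, in
#'   descending score order (ties keep attribute order).
#' @export
rank_features <- function(features, space = NULL) {
  if (is.null(features[["label"]])) {
    abort("features must carry a 'label' column", class = "bh_error_config")
  }
  label <- factor(features$label)
  if (nlevels(label) < 2L) {
    abort("both classes must be present to rank features",
          class = "bh_error_config")
  }
  attrs <- if (is.null(space)) {
    setdiff(names(features), c("id", "label"))
  } else {
    space$attr_id
  }
  stat <- vapply(attrs, function(a) chi2_stat(features[[a]], label), numeric(1))
  ord <- order(-stat, seq_along(stat))
  tibble(attr_id = attrs[ord], statistic = unname(stat[ord]),
         rank = seq_along(ord))
}

#' Read and write feature matrices as TSV
#'
#' One row per protein, a header of attribute ids, and a final `label`
#' column when labels are present.
#'
#' @param features A feature tibble from [featurize_dataset()].
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the tibble.
#' @export
write_features <- function(features, path) {
  cols <- c(setdiff(names(features), "label"),
            intersect("label", names(features)))
  utils::write.table(features[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}
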