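#' Average histogram of a protein class
#'
#' The unweighted arithmetic mean of bin weights across proteins: each
#' protein contributes equally regardless of size. Inputs must share the
#' same template and sampling radius; the mean of normalized histograms is
#' itself normalized.
#'
#' @param histograms A list of `ball_histogram`s with identical template and
#'   radius.
#' @return A `ball_histogram`.
#' @export
class_average <- function(histograms) {
  if (!length(histograms)) {
    abort("need at least one histogram", class = "bh_error_config")
  }
  template <- hist_template(histograms[[1]])
  radius <- hist_radius(histograms[[1]])
  for (h in histograms) {
    if (!identical(hist_template(h), template) ||
        !isTRUE(all.equal(hist_radius(h), radius))) {
      abort("histograms mix templates or sampling radii",
            class = "bh_error_config")
    }
  }
  all_bins <- dplyr::bind_rows(lapply(histograms, as_tibble))
  bins <- dplyr::summarise(
    dplyr::group_by(all_bins, dplyr::across(dplyr::all_of(template))),
    weight = sum(.data$weight) / length(histograms), .groups = "drop"
  )
  new_ball_histogram(bins, template, radius, 0L)
}

#' Bhattacharyya distance between two ball histograms
#'
#' \eqn{D_B(h_a, h_b) = -\ln \sum_x \sqrt{h_a(x) \, h_b(x)}}, summed over
#' the joint support. Zero for identical histograms, infinite when the
#' supports are disjoint.
#'
#' @param ha,hb `ball_histogram`s over the same template and radius.
#' @return A non-negative number, possibly `Inf`.
#' @export
#' @examples
#' a <- ball_histogram(data.frame(Gly = c(1, 0), weight = c(0.6, 0.4)))
#' b <- ball_histogram(data.frame(Gly = c(1, 0), weight = c(0.4, 0.6)))
#' bhattacharyya(a, b)
bhattacharyya <- function(ha, hb) {
  template <- hist_template(ha)
  if (!identical(template, hist_template(hb))) {
    abort("histograms have different templates", class = "bh_error_config")
  }
  ra <- hist_radius(ha); rb <- hist_radius(hb)
  if (!(is.na(ra) && is.na(rb)) && !isTRUE(all.equal(ra, rb))) {
    abort("histograms have different sampling radii", class = "bh_error_config")
  }
  joined <- dplyr::full_join(
    as_tibble(ha), as_tibble(hb),
    by = template, suffix = c("_a", "_b")
  )
  wa <- tidyr::replace_na(joined$weight_a, 0)
  wb <- tidyr::replace_na(joined$weight_b, 0)
  bc <- sum(sqrt(wa * wb))
  if (bc <= 0) return(Inf)
  max(0, -log(bc))
}

#' Class-average histograms for template search
#'
#' Bundles the mean full-pool histograms of the binding (positive) and
#' non-binding (negative) classes, the objects whose Bhattacharyya distance
#' the template search maximizes.
#'
#' @param positives,negatives Lists of full-pool `ball_histogram`s, one per
#'   protein of the class.
#' @return A list with elements `positive` and `negative` (class
#'   `bh_class_averages`).
#' @export
class_averages <- function(positives, negatives) {
  if (!length(positives) || !length(negatives)) {
    abort("both classes must be non-empty", class = "bh_error_config")
  }
  out <- list(positive = class_average(positives),
              negative = class_average(negatives))
  structure(out, class = "bh_class_averages")
}

#' Template-search configuration
#'
#' @param pool Ordered candidate property names; default [default_pool()].
#' @param max_length Maximum template length L (default 3; the number of
#'   histogram bins grows exponentially in L, and the sample size needed for
#'   learning grows exponentially in that, so L is kept small).
#' @param lambda Penalty multiplier in `[0, 1]` applied to the score of
#'   candidates that are subsets of an already discovered template; 1
#'   disables the penalty, 0 suppresses redundant subsets entirely.
#'   Default 0.5.
#' @param n_templates Number of templates to discover.
#' @param distance_cap Finite surrogate used in scores when the Bhattacharyya
#'   distance is infinite (disjoint supports), so the subset penalty remains
#'   meaningful; default `-log(1e-12)`. Uncapped distances are reported.
#' @param table Property table the pool refers to.
#' @return A list of class `bh_search_config`.
#' @export
search_config <- function(pool = default_pool(table), max_length = 3L,
                          lambda = 0.5, n_templates = 1L,
                          distance_cap = -log(1e-12),
                          table = default_property_table()) {
  if (lambda < 0 || lambda > 1) {
    abort("lambda must be in [0, 1]", class = "bh_error_config")
  }
  if (max_length < 1L) abort("max_length must be >= 1", class = "bh_error_config")
  if (distance_cap <= 0) abort("distance_cap must be > 0", class = "bh_error_config")
  if (n_templates < 1L) abort("n_templates must be >= 1", class = "bh_error_config")
  pool <- validate_template(pool, table)
  structure(list(pool = pool, max_length = as.integer(max_length),
                 lambda = lambda, n_templates = as.integer(n_templates),
                 distance_cap = distance_cap),
            class = "bh_search_config")
}

# A memoised Bhattacharyya scorer over sub-templates of the averages'
# template. Stacks both classes' bins into one integer matrix; projections
# are pooled in C++. Returns function(idx) -> BC coefficient, idx being
# sorted column indices into the full template.
make_scorer <- function(averages) {
  template <- hist_template(averages$positive)
  if (!identical(template, hist_template(averages$negative))) {
    abort("class averages have different templates", class = "bh_error_config")
  }
  pa <- as_tibble(averages$positive)
  pb <- as_tibble(averages$negative)
  counts <- rbind(as.matrix(pa[template]), as.matrix(pb[template]))
  storage.mode(counts) <- "integer"
  wa <- c(pa$weight, numeric(nrow(pb)))
  wb <- c(numeric(nrow(pa)), pb$weight)
  # pool identical full-pool rows once so every score call touches fewer rows
  grp <- row_group_cpp(counts)
  keep <- !duplicated(grp)
  if (!all(keep)) {
    wa <- as.numeric(rowsum(wa, grp)[, 1])
    wb <- as.numeric(rowsum(wb, grp)[, 1])
    counts <- counts[keep, , drop = FALSE]
  }
  cache <- new.env(parent = emptyenv())
  function(idx) {
    key <- paste0("t", paste(idx, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    bc <- bc_coef_cpp(counts, wa, wb, as.integer(idx))
    cache[[key]] <- bc
    bc
  }
}

bc_to_distance <- function(bc) {
  if (bc <= 0) Inf else max(0, -log(bc))
}

#' Heuristic score of a candidate template
#'
#' The Bhattacharyya distance between the two class-average histograms
#' marginalized to the template, with infinite distances replaced by the
#' configured cap, multiplied by `lambda` if the template is a subset of an
#' already discovered template.
#'
#' @param template Character vector of property names within the pool.
#' @param averages A [class_averages()] object over the full pool.
#' @param discovered List of previously discovered templates (character
#'   vectors).
#' @param config A [search_config()].
#' @return A single non-negative number.
#' @export
heuristic_score <- function(template, averages, discovered = list(),
                            config = search_config()) {
  full <- hist_template(averages$positive)
  idx <- sort(match(template, full))
  if (anyNA(idx)) {
    abort("template not within the averages' property pool",
          class = "bh_error_config")
  }
  scorer <- make_scorer(averages)
  d <- min(bc_to_distance(scorer(idx)), config$distance_cap)
  if (is_subset_of_any(template, discovered)) d <- config$lambda * d
  d
}

is_subset_of_any <- function(template, discovered) {
  any(vapply(discovered, function(t) all(template %in% t), logical(1)))
}

# Core best-first search over the template lattice, on column indices of the
# averages' full template. Pops the best-scoring open node (ties: shorter
# template, then earlier pool order), tracks the best template by uncapped
# distance among non-discovered candidates, and expands every popped node by
# one property until Open is exhausted.
bfs_core <- function(scorer, pool_idx, discovered_idx, config) {
  lambda <- config$lambda
  cap <- config$distance_cap
  L <- config$max_length
  keyof <- function(idx) paste0("t", paste(idx, collapse = ","))
  disc_keys <- vapply(discovered_idx, keyof, character(1))
  subset_of_discovered <- function(idx) {
    any(vapply(discovered_idx, function(d) all(idx %in% d), logical(1)))
  }
  score_of <- function(idx) {
    d <- min(bc_to_distance(scorer(idx)), cap)
    if (length(idx) && subset_of_discovered(idx)) d <- lambda * d
    d
  }
  # Open as parallel vectors; nodes stored as index vectors
  open_nodes <- list(integer(0))
  open_scores <- score_of(integer(0))
  closed <- new.env(parent = emptyenv())
  closed[[keyof(integer(0))]] <- TRUE
  if (length(discovered_idx) >= 2L) {
    for (i in seq_along(discovered_idx)[-length(discovered_idx)]) {
      for (j in (i + 1L):length(discovered_idx)) {
        inter <- sort(intersect(discovered_idx[[i]], discovered_idx[[j]]))
        k <- keyof(inter)
        if (length(inter) && is.null(closed[[k]])) {
          closed[[k]] <- TRUE
          open_nodes[[length(open_nodes) + 1L]] <- inter
          open_scores <- c(open_scores, score_of(inter))
        }
      }
    }
  }
  best <- NULL
  best_dist <- -Inf
  fallback <- NULL
  fallback_score <- -Inf
  lex_lt <- function(a, b) {
    # earlier pool order wins at equal length
    cmp <- a - b[seq_along(a)]
    nz <- which(cmp != 0)
    if (!length(nz)) FALSE else cmp[nz[1]] < 0
  }
  while (length(open_nodes)) {
    top <- which(open_scores == max(open_scores))
    if (length(top) > 1L) {
      lens <- lengths(open_nodes[top])
      top <- top[lens == min(lens)]
      if (length(top) > 1L) {
        pick <- top[1]
        for (cand in top[-1]) {
          if (lex_lt(open_nodes[[cand]], open_nodes[[pick]])) pick <- cand
        }
        top <- pick
      }
    }
    top <- top[1]
    node <- open_nodes[[top]]
    node_score <- open_scores[top]
    open_nodes <- open_nodes[-top]
    open_scores <- open_scores[-top]
    if (length(node)) {
      not_discovered <- !(keyof(node) %in% disc_keys)
      if (not_discovered) {
        d <- bc_to_distance(scorer(node))
        if (d > best_dist) {
          best <- node
          best_dist <- d
        }
        if (node_score > fallback_score) {
          fallback <- node
          fallback_score <- node_score
        }
      }
    }
    if (length(node) < L) {
      for (p in setdiff(pool_idx, node)) {
        child <- sort(c(node, p))
        k <- keyof(child)
        if (is.null(closed[[k]])) {
          closed[[k]] <- TRUE
          open_nodes[[length(open_nodes) + 1L]] <- child
          open_scores <- c(open_scores, score_of(child))
        }
      }
    }
  }
  if (is.null(best)) best <- fallback
  if (is.null(best)) {
    abort("template lattice exhausted: no non-discovered template left",
          class = "bh_error_exhausted")
  }
  best
}

#' Best-first search for a single informative template
#'
#' Searches the lattice of templates (ordered property subsets of the pool,
#' up to the configured maximum length) for the template maximizing the
#' Bhattacharyya distance between the class-average histograms marginalized
#' to it. The open set is seeded with the empty template and all non-empty
#' pairwise intersections of already discovered templates; candidates that
#' are subsets of discovered templates have their scores multiplied by
#' `lambda`. The returned template is the best-scoring candidate not yet
#' discovered; ties are broken toward shorter templates, then earlier pool
#' order, making the search deterministic.
#'
#' @inheritParams heuristic_score
#' @return A character vector of property names (pool order).
#' @export
best_first_search <- function(averages, discovered = list(),
                              config = search_config()) {
  full <- hist_template(averages$positive)
  pool_idx <- match(config$pool, full)
  if (anyNA(pool_idx)) {
    abort("search pool is not contained in the averages' template",
          class = "bh_error_config")
  }
  discovered_idx <- lapply(discovered, function(t) sort(match(t, full)))
  scorer <- make_scorer(averages)
  idx <- bfs_core(scorer, pool_idx, discovered_idx, config)
  full[idx]
}

#' Discover a diverse set of informative templates
#'
#' Runs [best_first_search()] repeatedly, accumulating discovered templates;
#' later runs penalize subsets of earlier discoveries (factor `lambda`) and
#' seed their open set with pairwise intersections of the discoveries, which
#' steers the search toward diverse templates sharing an informative core.
#'
#' @param positives,negatives Lists of full-pool `ball_histogram`s (one per
#'   protein) for the binding and non-binding classes.
#' @param config A [search_config()]; `config$n_templates` searches are run.
#' @return A tibble with columns `template` (list of character vectors),
#'   `n_properties`, `distance` (uncapped Bhattacharyya distance of the
#'   class averages marginalized to the template) and `distance_capped`, in
#'   discovery order. If the lattice holds fewer distinct templates than
#'   requested, fewer rows are returned with a warning.
#' @export
discover_templates <- function(positives, negatives, config = search_config()) {
  averages <- class_averages(positives, negatives)
  full <- hist_template(averages$positive)
  pool_idx <- match(config$pool, full)
  if (anyNA(pool_idx)) {
    abort("search pool is not contained in the histograms' template",
          class = "bh_error_config")
  }
  scorer <- make_scorer(averages)
  discovered_idx <- list()
  rows <- list()
  for (i in seq_len(config$n_templates)) {
    idx <- tryCatch(
      bfs_core(scorer, pool_idx, discovered_idx, config),
      bh_error_exhausted = function(e) NULL
    )
    if (is.null(idx)) {
      warn(sprintf("template lattice exhausted after %d of %d templates",
                   length(discovered_idx), config$n_templates))
      break
    }
    discovered_idx[[length(discovered_idx) + 1L]] <- idx
    d <- bc_to_distance(scorer(idx))
    rows[[i]] <- tibble(
      template = list(full[idx]),
      n_properties = length(idx),
      distance = d,
      distance_capped = min(d, config$distance_cap)
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a template-discovery report as JSON
#'
#' @param templates A tibble from [discover_templates()].
#' @param path Output path.
#' @param config Optional [search_config()] echoed into the report.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path, config = NULL) {
  report <- list(
    templates = lapply(seq_len(nrow(templates)), function(i) {
      list(properties = templates$template[[i]],
           distance = templates$distance[[i]],
           distance_capped = templates$distance_capped[[i]])
    })
  )
  if (!is.null(config)) report$config <- unclass(config)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
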