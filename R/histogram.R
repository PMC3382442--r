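#' Bounding sphere of a protein structure
#'
#' The sampling domain for ball-histogram construction: a sphere centred at
#' the structure's geometric center whose radius is the distance to the
#' farthest residue plus the sampling-ball radius `R`, so that every ball
#' that can contain a residue is reachable.
#'
#' @param structure A [protein_structure()].
#' @param R Sampling-ball radius in Angstroms, > 0.
#' @return A list with elements `center` (length-3 numeric) and `radius`.
#' @export
#' @examples
#' s <- protein_structure(
#'   data.frame(res_type = c("Arg", "Gly"), x = c(0, 10), y = 0, z = 0)
#' )
#' bounding_sphere(s, R = 12)
bounding_sphere <- function(structure, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    abort("sampling-ball radius R must be a single positive number",
          class = "bh_error_config")
  }
  center <- geometric_center(structure)
  d <- sqrt(rowSums(sweep(ca_coords(structure), 2, center)^2))
  list(center = center, radius = max(d) + R)
}

# Deterministic per-structure stream: fold the structure id into the global
# seed so dataset-level runs are reproducible and order-independent.
derive_seed <- function(seed, id) {
  h <- 0
  for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% 2147483629
  as.integer((h + (as.numeric(seed) %% 2147483629) * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# n points uniform in the ball (center, radius): isotropic Gaussian direction
# scaled by radius * U^(1/3).
sample_ball_centers <- function(n, center, radius) {
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  norms <- sqrt(rowSums(g^2))
  norms[norms == 0] <- 1
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(g / norms * r, 2, center, `+`)
}

#' Count residues satisfying template properties inside a sampling ball
#'
#' Returns, for a ball of radius `R` at `center`, the vector whose i-th entry
#' is the number of residues whose alpha-carbon lies within the ball
#' (Euclidean distance <= R, boundary inclusive) and whose type satisfies the
#' template's i-th property. A residue contributes to several entries when
#' properties overlap. A ball containing no residue at all is distinguished
#' from one whose residues match no property: the former returns `NULL` (the
#' "empty ball" marker), the latter the all-zero vector.
#'
#' @param structure A [protein_structure()].
#' @param template Character vector of distinct property names.
#' @param center Length-3 numeric, ball center in Angstroms.
#' @param R Ball radius in Angstroms.
#' @param table A [property_table()].
#' @return A named integer vector aligned with `template`, or `NULL` for an
#'   empty ball.
#' @export
count_in_ball <- function(structure, template, center, R,
                          table = default_property_table()) {
  template <- validate_template(template, table)
  if (!is.numeric(R) || R <= 0) {
    abort("R must be positive", class = "bh_error_config")
  }
  d2 <- rowSums(sweep(ca_coords(structure), 2, center)^2)
  inside <- d2 <= R^2
  if (!any(inside)) return(NULL)
  types <- structure$res_type[inside]
  stats::setNames(
    vapply(template, function(p) sum(types %in% table[[p]]), integer(1)),
    template
  )
}

new_ball_histogram <- function(bins, template, radius, n_samples,
                               n_kept = NULL) {
  bins <- as_tibble(bins)
  for (p in template) bins[[p]] <- as.integer(bins[[p]])
  ord <- do.call(order, unname(as.list(bins[template])))
  bins <- bins[ord, c(template, "weight")]
  structure(bins,
            template = template, radius = as.numeric(radius),
            n_samples = as.integer(n_samples),
            n_kept = if (!is.null(n_kept)) as.integer(n_kept),
            class = c("ball_histogram", class(bins)))
}

#' Construct a ball histogram explicitly from its bins
#'
#' Builds a [ball histogram][build_histogram] object from a table of count
#' vectors and weights, e.g. to encode an analytically known distribution.
#'
#' @param bins A data frame with one integer column per template property
#'   (named after it) and a `weight` column of non-negative weights summing
#'   to 1 within 1e-9.
#' @param template Character vector of property names; defaults to the bin
#'   columns other than `weight`, in order.
#' @param radius Sampling-ball radius the histogram refers to.
#' @param n_samples Number of Monte-Carlo samples behind the weights (0 for
#'   analytic histograms).
#' @return A tibble of class `ball_histogram` with attributes `template`,
#'   `radius` and `n_samples`.
#' @export
#' @examples
#' ball_histogram(
#'   data.frame(Arg = c(1, 0), Lys = c(1, 0), weight = c(0.5, 0.5)),
#'   radius = 8
#' )
ball_histogram <- function(bins, template = NULL, radius = NA_real_,
                           n_samples = 0L) {
  bins <- as_tibble(bins)
  if (is.null(template)) template <- setdiff(names(bins), "weight")
  if (!"weight" %in% names(bins) || !all(template %in% names(bins))) {
    abort("bins need one column per template property plus 'weight'",
          class = "bh_error_config")
  }
  if (any(bins$weight < 0)) {
    abort("bin weights must be non-negative", class = "bh_error_config")
  }
  if (nrow(bins) && abs(sum(bins$weight) - 1) > 1e-9) {
    abort("bin weights must sum to 1", class = "bh_error_config")
  }
  for (p in template) bins[[p]] <- as.integer(bins[[p]])
  new_ball_histogram(bins, template, radius, n_samples)
}

#' @export
print.ball_histogram <- function(x, ...) {
  cat("# ball_histogram: template (", paste(attr(x, "template"), collapse = ", "),
      "), R = ", attr(x, "radius"), " A, ", nrow(x), " bins, n_samples = ",
      attr(x, "n_samples"), "\n", sep = "")
  NextMethod()
}

#' Histogram accessors
#'
#' @param hist A `ball_histogram`.
#' @return The template (character vector), sampling radius, or sample count
#'   stored with the histogram.
#' @export
hist_template <- function(hist) attr(hist, "template")

#' @rdname hist_template
#' @export
hist_radius <- function(hist) attr(hist, "radius")

#' @rdname hist_template
#' @export
hist_n_samples <- function(hist) attr(hist, "n_samples")

# Aggregate a matrix of count vectors (rows = samples) into normalized bins.
aggregate_counts <- function(counts, template) {
  df <- as_tibble(as.data.frame(counts))
  names(df) <- template
  bins <- dplyr::count(df, dplyr::across(dplyr::all_of(template)),
                       name = "weight")
  bins$weight <- bins$weight / sum(bins$weight)
  bins
}

#' Build a ball histogram by Monte-Carlo sampling
#'
#' Draws `n_samples` ball centers uniformly from the structure's bounding
#' sphere, counts for each ball the residues satisfying every template
#' property, discards balls containing no residue at all, and normalizes the
#' resulting bin counts so weights sum to 1. The histogram estimates the
#' joint probability that a random sampling ball containing at least one
#' residue contains exactly `t_i` residues satisfying property `f_i`.
#'
#' The sampling stream depends only on (`structure` id, `R`, `seed`,
#' `n_samples`), not on the template, so histograms for different templates
#' built with the same seed share the same sample set and
#' [marginalize()] of a larger-template histogram reproduces the direct
#' histogram exactly.
#'
#' @inheritParams count_in_ball
#' @param n_samples Number of Monte-Carlo samples (> 0). Default 10000.
#' @param seed Integer seed; combined with the structure id to form the
#'   per-structure stream.
#' @param bounding_margin Extra Angstroms added to the bounding-sphere
#'   radius (default 0). The histogram is insensitive to this because empty
#'   balls are discarded; the argument exists to demonstrate that
#'   insensitivity.
#' @return A [ball_histogram()] object.
#' @export
#' @examples
#' s <- protein_structure(data.frame(res_type = "Arg", x = 0, y = 0, z = 0))
#' build_histogram(s, "Arg", R = 4, n_samples = 100, seed = 1)
build_histogram <- function(structure, template, R, n_samples = 10000L,
                            seed = 1L, table = default_property_table(),
                            bounding_margin = 0) {
  template <- validate_template(template, table)
  if (!is.numeric(n_samples) || n_samples < 1) {
    abort("n_samples must be a positive integer", class = "bh_error_config")
  }
  sph <- bounding_sphere(structure, R)
  centers <- with_seed(derive_seed(seed, structure_id(structure)),
                       sample_ball_centers(n_samples, sph$center,
                                           sph$radius + bounding_margin))
  coords <- ca_coords(structure)
  M <- property_matrix(structure$res_type, template, table)
  rn2 <- rowSums(coords^2)
  n_res <- nrow(coords)
  chunk <- max(1L, floor(4e6 / n_res))
  counts_list <- list()
  kept <- 0L
  for (start in seq(1L, n_samples, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_samples)
    cc <- centers[idx, , drop = FALSE]
    d2 <- matrix(rn2, n_res, length(idx)) - 2 * coords %*% t(cc) +
      matrix(rowSums(cc^2), n_res, length(idx), byrow = TRUE)
    inside <- d2 <= R^2
    nonempty <- colSums(inside) > 0L
    if (any(nonempty)) {
      counts_list[[length(counts_list) + 1L]] <-
        crossprod(inside[, nonempty, drop = FALSE] * 1L, M)
      kept <- kept + sum(nonempty)
    }
  }
  if (kept == 0L) {
    abort("degenerate sampling: every sampled ball was empty",
          class = "bh_error_degenerate")
  }
  counts <- do.call(rbind, counts_list)
  bins <- aggregate_counts(counts, template)
  new_ball_histogram(bins, template, R, n_samples, n_kept = kept)
}

#' Full-pool master histogram
#'
#' Builds the histogram of count vectors over an entire property pool (the
#' largest possible template). Histograms for any sub-template can then be
#' obtained exactly by [marginalize()], avoiding repeated sampling during
#' template search.
#'
#' @inheritParams build_histogram
#' @param pool Ordered character vector of property names; defaults to
#'   [default_pool()].
#' @return A [ball_histogram()] whose template is the full pool.
#' @export
master_histogram <- function(structure, pool = default_pool(table), R,
                             n_samples = 10000L, seed = 1L,
                             table = default_property_table()) {
  build_histogram(structure, pool, R, n_samples, seed, table)
}

#' Marginalize a ball histogram onto a sub-template
#'
#' Projects each bin's count vector onto the positions of `sub` and sums the
#' weights of bins that collide, yielding the histogram that direct
#' construction with template `sub` (and the same sample set) would produce.
#' Total mass is preserved.
#'
#' @param hist A `ball_histogram`.
#' @param sub Character vector of property names, a subset of the
#'   histogram's template.
#' @return A `ball_histogram` with template `sub`.
#' @export
#' @examples
#' h <- ball_histogram(
#'   data.frame(Arg = c(1, 0), Lys = c(1, 0), weight = c(0.5, 0.5))
#' )
#' marginalize(h, "Arg")
marginalize <- function(hist, sub) {
  stopifnot(inherits(hist, "ball_histogram"))
  sub <- as.character(sub)
  if (!all(sub %in% hist_template(hist))) {
    abort("sub-template must be a subset of the histogram's template",
          class = "bh_error_config")
  }
  if (anyDuplicated(sub)) {
    abort("sub-template properties must be distinct", class = "bh_error_config")
  }
  tab <- as_tibble(hist)[, c(sub, "weight")]
  nk <- attr(hist, "n_kept")
  if (!is.null(nk)) {
    # Monte-Carlo weights are k / n_kept; pooling the integer numerators and
    # dividing once reproduces direct construction bit-for-bit
    tab$weight <- round(tab$weight * nk)
  }
  bins <- dplyr::summarise(
    dplyr::group_by(tab, dplyr::across(dplyr::all_of(sub))),
    weight = sum(.data$weight), .groups = "drop"
  )
  if (!is.null(nk)) bins$weight <- bins$weight / nk
  new_ball_histogram(bins, sub, hist_radius(hist), hist_n_samples(hist),
                     n_kept = nk)
}

#' Read and write ball histograms as TSV with a JSON header
#'
#' The file starts with a single comment line `# {json}` recording the
#' template, sampling radius and sample count, followed by a tab-separated
#' table of count vectors and weights. Weights are written with 17
#' significant digits so that reading the file back reproduces the histogram
#' exactly.
#'
#' @param hist A `ball_histogram`.
#' @param path File path.
#' @return `write_histogram()` returns `path` invisibly; `read_histogram()`
#'   returns a `ball_histogram`.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "ball_histogram"))
  template <- hist_template(hist)
  meta <- jsonlite::toJSON(
    list(template = template, radius = hist_radius(hist),
         n_samples = hist_n_samples(hist),
         n_kept = attr(hist, "n_kept")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  header <- paste(c(template, "weight"), collapse = "\t")
  counts <- as.matrix(as_tibble(hist)[template])
  rows <- paste(apply(counts, 1L, paste, collapse = "\t"),
                sprintf("%.17g", hist$weight), sep = "\t")
  writeLines(c(paste0("# ", meta), header, rows), path)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("histogram file not found: ", path), class = "bh_error_parse")
  }
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "# ")) {
    abort("missing JSON header line", class = "bh_error_parse")
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[[1]]))
  tab <- utils::read.delim(text = lines[-1], check.names = FALSE)
  out <- ball_histogram(tab, template = as.character(meta$template),
                        radius = as.numeric(meta$radius),
                        n_samples = meta$n_samples)
  if (!is.null(meta$n_kept)) attr(out, "n_kept") <- as.integer(meta$n_kept)
  out
}

#' Plot a ball histogram
#'
#' One-property histograms are drawn as bar charts, two-property histograms
#' as weight-shaded tile plots; for longer templates each property's marginal
#' is shown as a facetted bar chart.
#'
#' @param object A `ball_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ball_histogram <- function(object, ...) {
  template <- hist_template(object)
  df <- as_tibble(object)
  if (length(template) == 1L) {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = factor(.data[[template]]), y = .data$weight)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = paste0("# ", template), y = "probability")
  } else if (length(template) == 2L) {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = factor(.data[[template[1]]]), y = factor(.data[[template[2]]]),
      fill = .data$weight)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = paste0("# ", template[1]),
                    y = paste0("# ", template[2]), fill = "probability")
  } else {
    marg <- purrr::map_dfr(template, function(p) {
      m <- as_tibble(marginalize(object, p))
      tibble(property = p, count = m[[p]], weight = m$weight)
    })
    p <- ggplot2::ggplot(marg, ggplot2::aes(
      x = factor(.data$count), y = .data$weight)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~property, scales = "free_x") +
      ggplot2::labs(x = "count", y = "marginal probability")
  }
  p + ggplot2::ggtitle(sprintf("Ball histogram (R = %s A)",
                               format(hist_radius(object))))
}
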