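# Independent oracles, deliberately implemented without reusing the package
# internals they check.

# Dense-grid integration of the ball-count distribution: enumerates a cubic
# lattice over the bounding sphere, keeps lattice points inside it, counts
# residues per property in the ball at each point, drops empty balls and
# normalizes. Deterministic; feasible only for tiny structures.
grid_histogram <- function(structure, template, R, step = 0.25,
                           table = default_property_table()) {
  coords <- as.matrix(structure[, c("x", "y", "z")])
  center <- colMeans(coords)
  rs <- max(sqrt(rowSums(sweep(coords, 2, center)^2))) + R
  ax <- seq(-rs, rs, by = step)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- pts[rowSums(pts^2) <= rs^2, , drop = FALSE]
  pts <- sweep(pts, 2, center, `+`)
  counts <- matrix(0L, nrow(pts), length(template))
  inside_any <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums(sweep(pts, 2, coords[i, ])^2)
    inb <- d2 <= R^2
    inside_any <- inside_any | inb
    for (j in seq_along(template)) {
      if (structure$res_type[i] %in% table[[template[j]]]) {
        counts[, j] <- counts[, j] + as.integer(inb)
      }
    }
  }
  counts <- counts[inside_any, , drop = FALSE]
  df <- as.data.frame(counts)
  names(df) <- template
  agg <- stats::aggregate(list(weight = rep(1, nrow(df))), df, sum)
  agg$weight <- agg$weight / sum(agg$weight)
  ball_histogram(agg, template = template, radius = R)
}

# Greedy template construction: start from the empty template, repeatedly
# add the single property that maximizes the (capped) class distance, no
# backtracking. The known-suboptimal baseline the best-first search must
# beat.
greedy_search <- function(averages, config) {
  full <- hist_template(averages$positive)
  current <- character(0)
  repeat {
    if (length(current) >= config$max_length) break
    cand <- setdiff(config$pool, current)
    scores <- vapply(cand, function(p) {
      heuristic_score(c(current, p), averages, list(), config)
    }, numeric(1))
    current <- c(current, cand[[which.max(scores)]])
  }
  full[sort(match(current, full))]
}

# All templates of length 1..L over the pool (as character vectors).
enumerate_templates <- function(pool, max_length) {
  out <- list()
  for (k in seq_len(max_length)) {
    if (k > length(pool)) break
    combs <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

# Maximum capped class distance over all enumerable non-discovered
# templates; the exhaustive reference for the best-first search.
exhaustive_best_distance <- function(averages, discovered, config) {
  all_t <- enumerate_templates(config$pool, config$max_length)
  keyof <- function(t) paste(sort(t), collapse = ",")
  disc <- vapply(discovered, keyof, character(1))
  best <- -Inf
  for (t in all_t) {
    if (keyof(t) %in% disc) next
    d <- min(bhattacharyya(marginalize(averages$positive, t),
                           marginalize(averages$negative, t)),
             config$distance_cap)
    if (d > best) best <- d
  }
  best
}

# Random sparse class-average pair over a small pool, for search-vs-
# enumeration property tests.
random_averages <- function(pool, seed, n_bins = 6) {
  set.seed(seed)
  mk <- function() {
    bins <- as.data.frame(matrix(sample(0:2, n_bins * length(pool),
                                        replace = TRUE),
                                 ncol = length(pool)))
    names(bins) <- pool
    bins <- unique(bins)
    w <- stats::runif(nrow(bins))
    bins$weight <- w / sum(w)
    ball_histogram(bins, radius = 8)
  }
  class_averages(list(mk()), list(mk()))
}

# Trapezoidal ROC integration from first principles.
trapezoid_auc <- function(score, label) {
  pos <- as.character(label) == "binding"
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(score[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(score[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
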