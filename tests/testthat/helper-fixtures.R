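# Small structure and histogram builders used across the suite.

make_structure <- function(coords, types, id = "fix") {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  protein_structure(
    tibble::tibble(res_type = types,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    id = id
  )
}

# A minimal PDB exercising altLoc, HETATM solvent, a mappable modified
# residue (MSE) and a second model that must be ignored.
write_fixture_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ARG A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AARG A   1       1.000   2.000   3.000  0.50  0.00           C",
    "ATOM      3  CA BARG A   1       1.100   2.100   3.100  0.50  0.00           C",
    "ATOM      4  CA  LYS A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      5  CA  GLY B   1       7.000   8.000   9.000  1.00  0.00           C",
    "HETATM    6  CA  MSE A   3      10.000  11.000  12.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      8  CA  TRP A   1      50.000  50.000  50.000  1.00  0.00           C",
    "ENDMDL",
    "END"
  ), path)
  path
}

# The worked pairwise class histograms of the two-class template example:
# binding proteins have perfectly correlated Arg/Lys ball counts, non-binding
# perfectly anti-correlated, and a mildly informative Gly margin.
ex2_pair <- function(which = c("arg_lys", "arg_gly", "lys_gly"),
                     class = c("binding", "nonbinding")) {
  which <- match.arg(which)
  class <- match.arg(class)
  nm <- switch(which, arg_lys = c("Arg", "Lys"), arg_gly = c("Arg", "Gly"),
               lys_gly = c("Lys", "Gly"))
  w <- if (which == "arg_lys") {
    if (class == "binding") c(0.5, 0, 0, 0.5) else c(0, 0.5, 0.5, 0)
  } else {
    if (class == "binding") c(0.4, 0.1, 0.2, 0.3) else c(0.1, 0.4, 0.3, 0.2)
  }
  bins <- data.frame(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), weight = w)
  names(bins)[1:2] <- nm
  ball_histogram(bins[bins$weight > 0, ], radius = 8)
}

# A three-property joint consistent with the example's headline facts:
# identical (Arg) and (Lys) marginals across classes, disjoint (Arg, Lys)
# joint supports, and a 0.6/0.4 vs 0.4/0.6 Gly margin that lures greedy
# search to Gly first.
ex2_joint3 <- function(class = c("binding", "nonbinding")) {
  class <- match.arg(class)
  if (class == "binding") {
    ball_histogram(data.frame(Arg = c(1, 1, 0, 0), Lys = c(1, 1, 0, 0),
                              Gly = c(1, 0, 1, 0),
                              weight = c(0.3, 0.2, 0.3, 0.2)), radius = 8)
  } else {
    ball_histogram(data.frame(Arg = c(1, 1, 0, 0), Lys = c(0, 0, 1, 1),
                              Gly = c(1, 0, 1, 0),
                              weight = c(0.2, 0.3, 0.2, 0.3)), radius = 8)
  }
}

l1_dist <- function(ha, hb) {
  template <- hist_template(ha)
  joined <- dplyr::full_join(tibble::as_tibble(ha), tibble::as_tibble(hb),
                             by = template, suffix = c("_a", "_b"))
  wa <- tidyr::replace_na(joined$weight_a, 0)
  wb <- tidyr::replace_na(joined$weight_b, 0)
  sum(abs(wa - wb))
}

random_rigid_transform <- function(structure, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 30)
  coords <- as.matrix(structure[, c("x", "y", "z")]) %*% q
  coords <- sweep(coords, 2, shift, `+`)
  out <- structure
  out$x <- coords[, 1]; out$y <- coords[, 2]; out$z <- coords[, 3]
  out
}
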