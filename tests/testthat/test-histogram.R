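test_that("bounding sphere radius is farthest residue distance plus R", {
  s1 <- make_structure(c(0, 0, 0), "Arg")
  b1 <- bounding_sphere(s1, R = 4)
  expect_equal(b1$center, c(x = 0, y = 0, z = 0))
  expect_equal(b1$radius, 4)

  s2 <- make_structure(c(0, 0, 0, 10, 0, 0), c("Arg", "Gly"))
  b2 <- bounding_sphere(s2, R = 12)
  expect_equal(b2$center, c(x = 5, y = 0, z = 0))
  expect_equal(b2$radius, 17)

  s3 <- generate_structure(40, seed = 2)
  expect_gte(bounding_sphere(s3, R = 8)$radius, 8)
  expect_error(bounding_sphere(s3, R = 0), class = "bh_error_config")
})

test_that("count_in_ball counts per property and flags empty balls", {
  # 2 Arg + 1 Leu in the ball -> (2, 0) for template (Arg, Lys)
  s <- make_structure(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 30, 0, 0),
                      c("Arg", "Arg", "Leu", "Lys"))
  expect_equal(count_in_ball(s, c("Arg", "Lys"), c(0, 0, 0), R = 4),
               c(Arg = 2L, Lys = 0L))
  # 1 His + 1 Asp -> (0, 0): not empty, just no matching residues
  s2 <- make_structure(c(0, 0, 0, 1, 0, 0), c("His", "Asp"))
  expect_equal(count_in_ball(s2, c("Arg", "Lys"), c(0, 0, 0), R = 4),
               c(Arg = 0L, Lys = 0L))
  # no residue at all -> EMPTY marker, distinguished from the zero vector
  expect_null(count_in_ball(s2, c("Arg", "Lys"), c(100, 0, 0), R = 4))
  # overlapping properties both count the same residue
  s3 <- make_structure(c(0, 0, 0), "Arg")
  expect_equal(count_in_ball(s3, c("Arg", "Positive"), c(0, 0, 0), R = 4),
               c(Arg = 1L, Positive = 1L))
  # ball membership is boundary-inclusive
  s4 <- make_structure(c(4, 0, 0), "Arg")
  expect_equal(count_in_ball(s4, "Arg", c(0, 0, 0), R = 4), c(Arg = 1L))
})

test_that("single-residue structures give a point-mass histogram", {
  s <- make_structure(c(2, -1, 5), "Arg")
  h <- build_histogram(s, "Arg", R = 6, n_samples = 500, seed = 9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$Arg, 1L)
  expect_equal(h$weight, 1)
})

test_that("histograms are normalized and deterministic given the seed", {
  for (seed in 1:3) {
    s <- generate_structure(60, label = "binding", seed = seed)
    for (R in c(4, 8)) {
      h <- build_histogram(s, c("Positive", "Gly"), R = R,
                           n_samples = 2000, seed = seed)
      expect_equal(sum(h$weight), 1, tolerance = 1e-9)
      expect_true(all(h$weight >= 0))
    }
  }
  s <- generate_structure(50, seed = 4)
  h1 <- build_histogram(s, c("Arg", "Lys"), R = 8, n_samples = 3000, seed = 11)
  h2 <- build_histogram(s, c("Arg", "Lys"), R = 8, n_samples = 3000, seed = 11)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  h3 <- build_histogram(s, c("Arg", "Lys"), R = 8, n_samples = 3000, seed = 12)
  expect_false(isTRUE(all.equal(as.data.frame(h1), as.data.frame(h3))))
})

test_that("two residues farther apart than 2R split mass evenly", {
  # the non-empty region is two disjoint, equal-volume balls: one around the
  # Arg (count 1), one around the Gly (count 0)
  s <- make_structure(c(0, 0, 0, 20, 0, 0), c("Arg", "Gly"))
  h <- build_histogram(s, "Arg", R = 6, n_samples = 200000, seed = 5)
  expect_equal(sort(h$Arg), c(0L, 1L))
  expect_equal(h$weight[h$Arg == 1], 0.5, tolerance = 0.01)
  expect_equal(h$weight[h$Arg == 0], 0.5, tolerance = 0.01)
})

test_that("degenerate sampling is reported when every ball is empty", {
  # a single residue with tiny R relative to the bounding sphere can in
  # principle yield all-empty draws only with pathological luck; force the
  # condition instead with an impossible sample budget by mocking is not
  # needed: two residues 1000 A apart with R = 1 make non-empty draws rare
  s <- make_structure(c(0, 0, 0, 1000, 0, 0), c("Arg", "Gly"))
  expect_error(build_histogram(s, "Arg", R = 0.5, n_samples = 3, seed = 1),
               class = "bh_error_degenerate")
})

test_that("marginalization matches the worked two-property tables", {
  pos <- ex2_pair("arg_lys", "binding")
  m_arg <- marginalize(pos, "Arg")
  expect_equal(m_arg$weight[m_arg$Arg == 1], 0.5)
  expect_equal(m_arg$weight[m_arg$Arg == 0], 0.5)

  pos_ag <- ex2_pair("arg_gly", "binding")
  m_gly <- marginalize(pos_ag, "Gly")
  expect_equal(m_gly$weight[m_gly$Gly == 1], 0.6)
  expect_equal(m_gly$weight[m_gly$Gly == 0], 0.4)

  # identity projection leaves the histogram unchanged
  same <- marginalize(pos_ag, c("Arg", "Gly"))
  expect_equal(as.data.frame(same), as.data.frame(pos_ag))
  expect_error(marginalize(pos_ag, "Lys"), class = "bh_error_config")
})

test_that("marginalizing the master reproduces direct histograms exactly", {
  pool <- default_pool()
  for (seed in c(3, 8)) {
    s <- generate_structure(60, label = "binding", seed = seed)
    m <- master_histogram(s, pool, R = 8, n_samples = 2000, seed = 21)
    expect_equal(ncol(m) - 1L, length(pool))  # full-pool shape
    for (tpl in list("Arg", c("Arg", "Lys"), c("Positive", "Gly", "Cys"))) {
      direct <- build_histogram(s, tpl, R = 8, n_samples = 2000, seed = 21)
      expect_identical(as.data.frame(marginalize(m, tpl)),
                       as.data.frame(direct))
    }
  }
})

test_that("histogram files round-trip exactly", {
  s <- generate_structure(40, seed = 6)
  h <- build_histogram(s, c("Arg", "Positive"), R = 8, n_samples = 1000,
                       seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(h, path)
  h2 <- read_histogram(path)
  expect_identical(as.data.frame(h2), as.data.frame(h))
  expect_identical(hist_template(h2), hist_template(h))
  expect_identical(hist_radius(h2), hist_radius(h))
  expect_identical(hist_n_samples(h2), hist_n_samples(h))
})

test_that("explicit histogram construction validates its contract", {
  expect_error(
    ball_histogram(data.frame(Arg = 1, weight = 0.9)),
    class = "bh_error_config"
  )
  expect_error(
    ball_histogram(data.frame(Arg = c(1, 0), weight = c(1.5, -0.5))),
    class = "bh_error_config"
  )
})
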