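test_that("name-distribution tables reproduce the counts worked example", {
  inventory <- c("fles", "flacon", "pot", sprintf("w%02d", 1:39))  # 42 names
  resp <- data.frame(object = "obj1", group = "monolingual_A",
                     name = c("fles", "flacon", "pot"), count = c(11, 10, 4))
  tab <- name_distribution(resp, "monolingual_A", inventory = inventory,
                           objects = c("obj1", "obj2"))
  expect_equal(ncol(tab), 42)
  expect_equal(unname(tab["obj1", c("fles", "flacon", "pot")]), c(11, 10, 4))
  expect_equal(sum(tab["obj1", ] != 0), 3)
  expect_equal(sum(tab["obj1", ]), 25)            # responding participants
  ## objects without responses give flagged all-zero rows
  expect_equal(unname(tab["obj2", ]), rep(0, 42))
  expect_identical(attr(tab, "empty_objects"), "obj2")
  expect_error(name_distribution(resp, "monolingual_A", inventory = c("fles")),
               class = "bilexnet_inconsistent_data")
})

test_that("similarity profiles enumerate all pairs in canonical order", {
  set.seed(2)
  tab <- matrix(rpois(73 * 8, 3), 73)
  expect_length(similarity_profile(tab), 73 * 72 / 2)  # 2628 for 73 objects
  ## brute-force all-pairs oracle, row-major pair order
  tab4 <- matrix(runif(20), 4)
  prof <- similarity_profile(tab4)
  oracle <- c(cor(tab4[1, ], tab4[2, ]), cor(tab4[1, ], tab4[3, ]),
              cor(tab4[1, ], tab4[4, ]), cor(tab4[2, ], tab4[3, ]),
              cor(tab4[2, ], tab4[4, ]), cor(tab4[3, ], tab4[4, ]))
  expect_equal(as.numeric(prof), oracle)
  ## identical rows correlate perfectly
  tab4[2, ] <- tab4[1, ]
  expect_equal(as.numeric(similarity_profile(tab4))[1], 1)
  ## constant rows are recorded as excluded, not dropped silently
  tab4[3, ] <- 5
  prof <- similarity_profile(tab4)
  expect_equal(attr(prof, "n_excluded"), 3)
  expect_length(prof, 6)
})

test_that("the Fisher transform matches its closed form and inverts", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(fisher_z(-r), -fisher_z(r))                 # odd
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(r), atanh(r))                      # closed form
})

test_that("the two-correlation Z statistic is zero for equal correlations", {
  set.seed(4)
  p1 <- runif(50); p2 <- p1 + rnorm(50, sd = 0.3)
  ct <- compare_correlations(p1, p2, p1, p2)
  expect_equal(unname(ct$statistic), 0)
  expect_equal(ct$p.value, 1)
  ## direction: a higher first correlation gives Z > 0
  p3 <- runif(50)
  p4 <- p3 + rnorm(50, sd = 3)
  if (cor(p1, p2) > cor(p3, p4)) {
    ct <- compare_correlations(p1, p2, p3, p4)
    expect_gt(unname(ct$statistic), 0)
  }
  expect_error(compare_correlations(p1, p1, p1, p2),
               class = "bilexnet_degenerate")
})

test_that("typicality activations follow the reverse pathway by hand", {
  m <- toy_model()
  ## bump at w1's BMU (node 2, radius 0) through t(sp_A): activation at
  ## object BMUs 1..3 is column 2 of sp_A
  t1 <- typicality_activation(m, "w1")
  expect_equal(unname(t1), c(0.9, 0.6, 0.3))
  t2 <- typicality_activation(m, "w2")
  expect_equal(unname(t2), c(0.1, 0.5, 0.8))
  ## hand-computed Pearson correlation across objects
  tc <- typicality_correlation(m, "w1", "w2")
  expect_equal(tc$r, cor(c(0.9, 0.6, 0.3), c(0.1, 0.5, 0.8)))
  expect_equal(tc$z, atanh(tc$r))
  expect_equal(tc$n, 3)
  expect_error(typicality_activation(m, "nope"), class = "bilexnet_unknown_word")
})

test_that("weighted category centers and outliers match hand geometry", {
  m <- toy_model()
  ## objects sit at nodes 1..3 of a 1 x 4 grid: coords (1,1), (1,2), (1,3)
  g <- category_geometry(m, "A", names = c("w1", "w2"))
  ## w1 weights (0.9, 0.6, 0.3): mean col = (0.9 + 1.2 + 0.9) / 1.8
  expect_equal(unname(g$categories$w1$center_mean),
               c(1, (0.9 * 1 + 0.6 * 2 + 0.3 * 3) / 1.8))
  ## weighted median column for w1: cumulative shares 0.5, 0.83, 1 -> the
  ## lower weighted median is column 1
  expect_equal(unname(g$categories$w1$center_median), c(1, 1))
  ## membership by highest naming activation
  expect_true("o1" %in% g$categories$w1$members)
  expect_true("o3" %in% g$categories$w2$members)
  ## single object with weight 1: both centers equal its BMU coordinate
  sp <- matrix(0, 4, 4); sp[1, 2] <- 1; sp[2, 4] <- 1e-6; sp[3, 4] <- 1
  g1 <- category_geometry(toy_model(sp), "A", names = c("w1", "w2"))
  expect_equal(unname(g1$categories$w1$center_mean), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(g1$categories$w1$center_median), c(1, 1))
})

test_that("outlier flags follow nearest-center comparison by hand", {
  ## two equal-weight objects: the mean center is their midpoint
  sp <- matrix(0, 4, 4)
  sp[1, 2] <- 0.8; sp[2, 2] <- 0.8    # w1 weights objects 1, 2
  sp[3, 4] <- 0.9                      # w2 weights object 3
  m <- toy_model(sp)
  g <- category_geometry(m, "A", names = c("w1", "w2"))
  expect_equal(unname(g$categories$w1$center_mean), c(1, 1.5))
  ## o2 (col 2) is 0.5 from w1's center and 1.43 from w2's: no outlier
  expect_length(g$categories$w1$outliers, 0)
  props <- outlier_proportions(g)
  expect_equal(unname(props["w1"]), 0)
  ## force an outlier: o1 is a (weak) member of w1 at column 1, but w1's
  ## center sits at column 2.36 while w2's activation mass lies at column 1
  sp2 <- matrix(0, 4, 4)
  sp2[1, 2] <- 0.2; sp2[2, 2] <- 1; sp2[3, 2] <- 1   # w1 weights (.2, 1, 1)
  sp2[1, 4] <- 0.1                                   # w2 weight at o1 only
  m2 <- toy_model(sp2)
  g2 <- category_geometry(m2, "A", names = c("w1", "w2"))
  expect_equal(unname(g2$categories$w1$center_mean[2]), 5.2 / 2.2)
  expect_equal(unname(g2$categories$w2$center_mean), c(1, 1))
  expect_setequal(g2$categories$w1$members, c("o1", "o2", "o3"))
  expect_identical(g2$categories$w1$outliers, "o1")
  props <- outlier_proportions(g2)
  expect_equal(unname(props["w1"]), 1 / 3)
  expect_true(is.na(props["w2"]))                    # empty category
})

test_that("indirect-to-direct distance ratios respect the triangle inequality", {
  ## coincident bilingual and monolingual prototypes: ratio exactly 1
  expect_equal(indirect_direct_ratio(c(0, 0), c(3, 4), c(0, 0), c(3, 4)), 1)
  ## hand-placed coordinates
  r <- indirect_direct_ratio(c(0, 0), c(10, 0), c(1, 1), c(9, 1))
  expect_equal(r, (sqrt(2) + sqrt(2) + 8) / 10)
  set.seed(6)
  for (k in 1:100) {
    pts <- matrix(runif(8, 0, 10), 4, 2)
    r <- indirect_direct_ratio(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_gte(r, 1 - 1e-12)
  }
  expect_error(indirect_direct_ratio(c(1, 1), c(1, 1), c(0, 0), c(2, 2)),
               class = "bilexnet_degenerate")
})

test_that("stepwise discriminant analysis isolates the informative feature", {
  set.seed(9)
  n <- 40
  grp <- rep(c("p", "q"), each = n / 2)
  x <- matrix(rnorm(n * 6), n)
  x[grp == "q", 1] <- x[grp == "q", 1] + 6   # one separating feature
  fit <- stepwise_dfa(x, grp)
  expect_identical(fit$selected, 1L)
  expect_equal(fit$n_dims, 1)
  expect_lt(fit$p.value, 0.05)
  expect_true(fit$separable)
  ## canonical correlation cross-checked against MASS::lda scores
  ld <- MASS::lda(x[, fit$selected, drop = FALSE], grouping = grp)
  sc <- as.numeric(predict(ld)$x)
  expect_equal(fit$canonical_correlation,
               abs(cor(sc, as.numeric(factor(grp)))), tolerance = 1e-6)
})

test_that("identical class distributions are flagged non-separable", {
  set.seed(10)
  x <- matrix(rnorm(60 * 4), 60)
  fit <- stepwise_dfa(x, rep(c("p", "q"), 30))
  expect_equal(fit$n_dims, 0)
  expect_false(fit$separable)
  expect_error(stepwise_dfa(x, rep("p", 60)), class = "bilexnet_bad_grouping")
  expect_error(stepwise_dfa(x[1:3, ], c("p", "p", "q")),
               class = "bilexnet_bad_grouping")
})
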