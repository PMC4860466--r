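test_that("the default configuration matches the emulated study scale", {
  d <- memo("default_data", synth_dataset(synth_config(seed = 2)))
  expect_equal(dim(d$features), c(73, 68))
  expect_equal(sum(d$lexicon$language == "A"), 42)
  expect_equal(sum(d$lexicon$language == "B"), 39)
  ## every object receives between 1 and 9 distinct names in every group
  for (g in unique(d$responses$group)) {
    sub <- d$responses[d$responses$group == g, ]
    n_names <- table(sub$object)
    expect_true(all(n_names >= 1 & n_names <= 9))
    expect_length(n_names, 73)
    ## agreement proportions sum to one (counts sum to participants)
    expect_true(all(tapply(sub$count, sub$object, sum) == 25))
  }
})

test_that("generation is fully reproducible from the configuration", {
  cfg <- tiny_config(seed = 31)
  d1 <- synth_dataset(cfg)
  d2 <- synth_dataset(cfg)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$lexicon, d2$lexicon)
  expect_identical(d1$responses, d2$responses)
})

test_that("flip noise controls the departure from the prototypes", {
  cfg0 <- synth_config(n_objects = 6, n_features = 10, n_names = c(4, 4),
                       flip_noise = 0, seed = 5)
  obj <- synth_objects(cfg0)
  for (i in seq_len(6))
    expect_equal(unname(obj$features[i, ]),
                 obj$prototypes_a[obj$category[i], ])
  ## with noise <= 0.2, objects still cluster by category
  cfg <- synth_config(flip_noise = 0.2, seed = 5)
  obj <- synth_objects(cfg)
  d <- as.matrix(dist(obj$features))
  same <- outer(obj$category, obj$category, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))
})

test_that("cognate fraction controls shared spellings across languages", {
  cfg0 <- synth_config(n_names = c(10, 8), cognate_fraction = 0, seed = 9)
  lex <- synth_lexicons(cfg0)
  expect_length(intersect(lex$spelling[lex$language == "A"],
                          lex$spelling[lex$language == "B"]), 0)
  cfg1 <- synth_config(n_names = c(10, 8), cognate_fraction = 1, seed = 9)
  lex <- synth_lexicons(cfg1)
  a <- lex[lex$language == "A", ]; b <- lex[lex$language == "B", ]
  expect_identical(a$spelling[1:8], b$spelling)
  expect_identical(a$ipa[1:8], b$ipa)
})

test_that("every generated word fits both templates", {
  d <- memo("default_data", synth_dataset(synth_config(seed = 2)))
  for (i in seq_len(nrow(d$lexicon))) {
    expect_length(encode_phonology(d$lexicon$ipa[i]), 81)
    expect_length(encode_orthography(d$lexicon$spelling[i]), 297)
  }
})

test_that("cross-language alignment decays with the divergence parameter", {
  mean_r <- function(delta) {
    rs <- vapply(1:3, function(s) {
      d <- synth_dataset(synth_config(divergence = delta, seed = 100 + s))
      inv_a <- d$lexicon$word[d$lexicon$language == "A"]
      inv_b <- d$lexicon$word[d$lexicon$language == "B"]
      pa <- similarity_profile(name_distribution(d$responses, "monolingual_A", inv_a))
      pb <- similarity_profile(name_distribution(d$responses, "monolingual_B", inv_b))
      cor(as.numeric(pa), as.numeric(pb), use = "pairwise.complete.obs")
    }, numeric(1))
    mean(rs)
  }
  r0 <- mean_r(0); r25 <- mean_r(0.25); r50 <- mean_r(0.5)
  expect_gt(r0, r25)
  expect_gt(r25, r50)
  expect_gt(r0, 0.9)   # aligned categories sit near the ceiling
})

test_that("the bilingual mixture sits between the two monolingual patterns", {
  d <- memo("default_data", synth_dataset(synth_config(seed = 2)))
  inv_a <- d$lexicon$word[d$lexicon$language == "A"]
  inv_b <- d$lexicon$word[d$lexicon$language == "B"]
  r_of <- function(g1, g2, i1, i2) {
    p1 <- similarity_profile(name_distribution(d$responses, g1, i1))
    p2 <- similarity_profile(name_distribution(d$responses, g2, i2))
    cor(as.numeric(p1), as.numeric(p2), use = "pairwise.complete.obs")
  }
  r_bi <- r_of("bilingual_A", "bilingual_B", inv_a, inv_b)
  r_mono <- r_of("monolingual_A", "monolingual_B", inv_a, inv_b)
  expect_gt(r_bi, r_mono)
})

test_that("datasets round-trip through the delimited-file interface", {
  d <- synth_dataset(tiny_config(seed = 12))
  dir <- tempfile("bilexdata")
  write_bilex_data(d, dir)
  expect_true(all(file.exists(file.path(dir,
    c("stimuli.csv", "lexicon.csv", "responses.csv", "manifest.json")))))
  d2 <- read_bilex_data(dir)
  expect_equal(d2$features, d$features)
  expect_equal(d2$lexicon, d$lexicon)
  expect_equal(d2$responses, d$responses)
  expect_equal(d2$config$seed, d$config$seed)
  unlink(dir, recursive = TRUE)
})

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(kappa = 0))
  expect_error(synth_config(divergence = 1.5))
  expect_error(synth_config(n_features = 1, n_categories = 3),
               class = "bilexnet_bad_config")
})
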