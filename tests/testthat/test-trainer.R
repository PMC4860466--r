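test_that("training is bit-identical under a fixed seed", {
  d <- tiny_data()
  m1 <- bilexnet(d, epochs = 10, seed = 3, control = tiny_control())
  m2 <- bilexnet(d, epochs = 10, seed = 3, control = tiny_control())
  expect_equal(m1$maps$semantic$weights, m2$maps$semantic$weights)
  expect_equal(m1$assoc, m2$assoc)
  expect_equal(m1$lateral, m2$lateral)
  expect_equal(m1$registry, m2$registry)
})

test_that("zero-epoch training returns an untouched random initial state", {
  m <- bilexnet(tiny_data(), epochs = 0, seed = 3, control = tiny_control())
  expect_equal(nrow(m$log), 0)
  expect_true(all(m$assoc$sp_A == 0))
  set.seed(bilexnet:::.derive_seed(3, "som_s"))
  W0 <- matrix(runif(10 * 12 * ncol(tiny_data()$features)), 10 * 12)
  expect_equal(m$maps$semantic$weights, W0)
})

test_that("phase gating: no Hebbian before its phase, no reading pathways before theirs", {
  m <- tiny_model()
  log <- m$log
  hs <- m$control$hebbian_start; rs <- m$control$reading_start
  expect_true(all(log$n_sp[log$epoch <= hs] == 0))
  expect_true(all(log$n_lateral[log$epoch <= hs] == 0))
  expect_true(all(log$n_sp[log$epoch > hs] > 0))
  expect_true(all(log$n_so[log$epoch <= rs] == 0))
  expect_true(all(log$n_po[log$epoch <= rs] == 0))
  expect_true(all(log$n_po[log$epoch > rs] > 0))
})

test_that("ablations remove exactly the named component", {
  m_nl <- tiny_model("bilingual", "no_lateral")
  expect_null(m_nl$lateral)
  expect_true(all(m_nl$log$n_lateral == 0))
  expect_false(is.null(m_nl$maps$orthographic))
  m_no <- tiny_model("bilingual", "no_orthography")
  expect_null(m_no$maps$orthographic)
  expect_false(any(grepl("^so_|^po$|^op$", names(m_no$assoc))))
  expect_true(all(m_no$log$n_so == 0) && all(m_no$log$n_po == 0))
  expect_true(all(is.na(m_no$log$qe_o)))
})

test_that("monolingual conditions never touch the other language", {
  m_a <- tiny_model("monolingual_A")
  expect_identical(m_a$languages, "A")
  expect_true(all(m_a$registry$language == "A"))
  expect_null(m_a$lateral)
  expect_null(m_a$agreement$B)
  expect_false("sp_B" %in% names(m_a$assoc))
})

test_that("the semantic map is shared across conditions under one seed", {
  ## all groups receive identical feature vectors, so with a common seed the
  ## semantic map (its own RNG stream) is the same in every condition
  m_bi <- tiny_model("bilingual")
  m_a <- tiny_model("monolingual_A")
  m_b <- tiny_model("monolingual_B")
  expect_equal(m_bi$maps$semantic$weights, m_a$maps$semantic$weights)
  expect_equal(m_a$maps$semantic$weights, m_b$maps$semantic$weights)
})

test_that("quantization error falls and the radius never rises", {
  m <- tiny_model()
  log <- m$log
  expect_lte(log$qe_s[nrow(log)], log$qe_s[m$control$hebbian_start])
  expect_lte(log$qe_p[nrow(log)], log$qe_p[m$control$hebbian_start])
  expect_true(all(diff(log$radius_s) <= 0))
  expect_true(all(diff(log$radius_p) <= 0))
  expect_true(all(diff(log$radius_o[!is.na(log$radius_o)]) <= 0))
  expect_true(all(log$radius_s >= m$control$radius_floor))
})

test_that("replicate ensembles differ in initial weights but reproduce exactly", {
  d <- tiny_data()
  e1 <- bilexnet_ensemble(d, n = 2, base_seed = 5, epochs = 3,
                          control = tiny_control())
  e2 <- bilexnet_ensemble(d, n = 2, base_seed = 5, epochs = 3,
                          control = tiny_control())
  expect_equal(e1[[1]]$maps$semantic$weights, e2[[1]]$maps$semantic$weights)
  expect_equal(e1[[2]]$assoc, e2[[2]]$assoc)
  expect_false(isTRUE(all.equal(e1[[1]]$maps$semantic$weights,
                                e1[[2]]$maps$semantic$weights)))
  ## a singleton ensemble equals a direct fit with the base seed
  s1 <- bilexnet_ensemble(d, n = 1, base_seed = 5, epochs = 3,
                          control = tiny_control())
  m <- bilexnet(d, epochs = 3, seed = 5, control = tiny_control())
  expect_equal(s1[[1]]$maps$phonological$weights, m$maps$phonological$weights)
})

test_that("datasets with orphan response names are rejected", {
  d <- tiny_data()
  bad <- d$responses
  bad$name[1] <- "no_such_word"
  expect_error(bilex_data(d$features, d$lexicon, bad),
               class = "bilexnet_inconsistent_data")
})
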