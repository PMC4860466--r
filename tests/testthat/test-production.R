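test_that("the three naming routes sum exactly to the total activation", {
  nm <- predict(tiny_model(), language = "A")
  expect_equal(nm$actp, nm$sem + nm$lateral + nm$ortho)
  expect_true(all(nm$sem >= 0 & nm$lateral >= 0 & nm$ortho >= 0))
  nm_b <- predict(tiny_model(), language = "B")
  expect_equal(nm_b$actp, nm_b$sem + nm_b$lateral + nm_b$ortho)
})

test_that("ablated pathways contribute exactly zero to their route", {
  nm <- predict(tiny_model("bilingual", "no_lateral"), language = "A")
  expect_true(all(nm$lateral == 0))
  nm <- predict(tiny_model("bilingual", "no_orthography"), language = "A")
  expect_true(all(nm$ortho == 0))
  ## monolingual models have no non-target language to feed the lateral route
  nm <- predict(tiny_model("monolingual_A"), language = "A")
  expect_true(all(nm$lateral == 0))
})

test_that("zeroing the lateral matrix on a frozen state changes only the lateral term", {
  m <- tiny_model()
  m0 <- m
  m0$lateral[] <- 0
  nm <- predict(m, "A")
  nm0 <- predict(m0, "A")
  expect_equal(nm0$sem, nm$sem)
  expect_equal(nm0$ortho, nm$ortho)
  expect_true(all(nm0$lateral == 0))
  expect_true(any(nm$lateral > 0))
})

test_that("an untrained model produces no positive candidates", {
  m <- bilexnet(tiny_data(), epochs = 2, seed = 1, control = tiny_control())
  nm <- predict(m, "A")
  expect_true(all(nm$actp == 0))
  expect_false(any(nm$dominant))
  expect_setequal(attr(nm, "no_response"), m$objects$object)
  expect_error(predict(tiny_model(), objects = "nonexistent"),
               class = "bilexnet_unknown_object")
})

test_that("the 80% rule declares co-dominant names under strict inequality", {
  expect_setequal(dominant_names(c(a = 0.55, b = 0.45, c = 0.10)), c("a", "b"))
  expect_identical(dominant_names(c(a = 0.9, b = 0.1)), "a")
  ## 0.4 / 0.5 is exactly 80%, not more: a single dominant
  expect_identical(dominant_names(c(a = 0.5, b = 0.4)), "a")
  expect_error(dominant_names(c(a = 0, b = 0)), class = "bilexnet_no_response")
})

test_that("naming accuracy counts intersections of dominant-name sets", {
  ## hand-scored fixture: 3 of 5 objects share a dominant name with the norms
  model <- list(agreement = list(A = list(
    o1 = c(x = 1), o2 = c(x = 0.5, y = 0.45), o3 = c(y = 1),
    o4 = c(z = 1), o5 = c(z = 0.8, x = 0.2))))
  naming <- data.frame(
    object = rep(c("o1", "o2", "o3", "o4", "o5"), each = 2),
    word = rep(c("x", "y"), 5),
    dominant = c(TRUE, FALSE,   # o1 -> x: hit
                 FALSE, TRUE,   # o2 -> y: hit (y co-dominant empirically)
                 TRUE, FALSE,   # o3 -> x: miss
                 TRUE, TRUE,    # o4 -> x,y: miss (empirical z)
                 FALSE, TRUE),  # o5 -> y: miss
    stringsAsFactors = FALSE)
  expect_equal(naming_accuracy(model, "A", naming = naming), 40)
})

test_that("words sharing a phonological BMU are reported and tie-broken", {
  m <- toy_model()
  m$registry <- rbind(m$registry,
                      data.frame(word = "w3", language = "A", ipa = "ka",
                                 spelling = "ka", bmu_p = 2L,
                                 bmu_o = NA_integer_,
                                 stringsAsFactors = FALSE))
  nm <- predict(m, "A")
  expect_setequal(attr(nm, "bmu_collisions"), c("w1", "w3"))
  ## w1 and w3 read the same node, so their activations tie exactly;
  ## only one of them may be dominant for o1
  sub <- nm[nm$object == "o1", ]
  expect_equal(sub$actp[sub$word == "w1"], sub$actp[sub$word == "w3"])
  expect_equal(sum(sub$dominant[sub$word %in% c("w1", "w3")]), 1)
})

test_that("simulated distributions and response draws are consistent", {
  m <- tiny_model()
  tab <- simulated_distribution(m, "A")
  expect_identical(rownames(tab), m$objects$object)
  expect_identical(colnames(tab), m$registry$word[m$registry$language == "A"])
  nm <- predict(m, "A")
  expect_equal(unname(tab["obj01", nm$word[nm$object == "obj01"]]),
               nm$actp[nm$object == "obj01"])
  sims <- simulate(m, nsim = 2, seed = 1, language = "A", participants = 10)
  expect_length(sims, 2)
  agg <- tapply(sims[[1]]$count, sims[[1]]$object, sum)
  expect_true(all(agg == 10))
})
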