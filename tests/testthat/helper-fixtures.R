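## Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## a small but complete synthetic dataset
tiny_config <- function(seed = 7) {
  synth_config(n_objects = 9L, n_features = 12L, n_categories = 3L,
               n_names = c(5L, 5L), participants = 15L, seed = seed)
}

tiny_data <- function() memo("tiny_data", synth_dataset(tiny_config()))

tiny_control <- function() {
  bilex_control(rows = 10L, cols = 12L, radius_init = 5L,
                hebbian_start = 4L, reading_start = 8L)
}

## small trained models shared across test files
tiny_model <- function(condition = "bilingual", ablation = "none") {
  key <- paste("tiny_model", condition, ablation)
  memo(key, bilexnet(tiny_data(), condition, ablation, epochs = 16L,
                     seed = 42L, control = tiny_control()))
}

## a hand-specified minimal model for geometry/typicality hand checks:
## 1 x 4 semantic and phonological grids, 3 objects at nodes 1..3,
## two language-A words at phonological nodes 2 and 4
toy_model <- function(sp = NULL) {
  grid4 <- function(dim) {
    g <- list(rows = 1L, cols = 4L, dim = dim,
              weights = matrix(0, 4, dim), coords = grid_coords(1L, 4L))
    class(g) <- "som_grid"
    g
  }
  if (is.null(sp)) {
    sp <- matrix(0, 4, 4)
    sp[1, 2] <- 0.9; sp[2, 2] <- 0.6; sp[3, 2] <- 0.3  # word w1 at node 2
    sp[1, 4] <- 0.1; sp[2, 4] <- 0.5; sp[3, 4] <- 0.8  # word w2 at node 4
  }
  structure(list(
    maps = list(semantic = grid4(5L), phonological = grid4(81L),
                orthographic = NULL),
    assoc = list(sp_A = sp),
    lateral = NULL,
    registry = data.frame(word = c("w1", "w2"), language = "A",
                          ipa = c("pa", "ta"), spelling = c("pa", "ta"),
                          bmu_p = c(2L, 4L), bmu_o = NA_integer_,
                          stringsAsFactors = FALSE),
    objects = data.frame(object = c("o1", "o2", "o3"), bmu_s = 1:3,
                         stringsAsFactors = FALSE),
    agreement = list(A = list(o1 = c(w1 = 1), o2 = c(w1 = 0.6, w2 = 0.4),
                              o3 = c(w2 = 1))),
    features = matrix(0, 3, 5, dimnames = list(c("o1", "o2", "o3"), NULL)),
    languages = "A",
    radius = list(s = 0L, p = 0L, o = NA),
    log = data.frame(),
    condition = "monolingual_A", ablation = "no_orthography",
    epochs = 16L, seed = 1L,
    control = bilex_control(rows = 1L, cols = 4L, hebbian_start = 4L,
                            reading_start = 8L)),
    class = "bilexnet")
}
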