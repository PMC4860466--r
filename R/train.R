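#' Control parameters for training a bilingual lexical network
#'
#' Defaults are the standard model's: 30 x 40 maps, SOM learning rate
#' annealed linearly from 0.2 to 0.1 over the first 100 epochs, constant
#' Hebbian rate 0.2, initial neighbourhood radius 15 shrunk by the
#' 25%-quantization-error rule every 5 epochs (floor 1), associative
#' learning switched on after epoch `hebbian_start` and the
#' orthographic pathways after epoch `reading_start`, and a minimum
#' orthographic spreading radius of 3 at test.
#'
#' @param rows,cols Map size.
#' @param lr_start,lr_end,lr_anneal SOM learning-rate schedule (see
#'   [learning_rate()]).
#' @param beta Hebbian learning rate.
#' @param radius_init,radius_floor,check_interval Neighbourhood radius
#'   schedule (see [adapt_radius()]).
#' @param hebbian_start Epoch after which Hebbian learning (semantic to
#'   phonological, lateral) and orthographic map training begin.
#' @param reading_start Epoch after which the semantic-orthographic and
#'   phonological-orthographic pathways begin.
#' @param ortho_min_radius Minimum orthographic activation-spreading radius
#'   at test.
#' @return A list of class `bilex_control`.
#' @export
bilex_control <- function(rows = 30L, cols = 40L, lr_start = 0.2, lr_end = 0.1,
                          lr_anneal = 100L, beta = 0.2, radius_init = 15L,
                          radius_floor = 1L, check_interval = 5L,
                          hebbian_start = 50L, reading_start = 100L,
                          ortho_min_radius = 3L) {
  if (!(hebbian_start > 0 && reading_start > hebbian_start))
    stop(errorCondition("phase boundaries must satisfy 0 < hebbian_start < reading_start",
                        class = c("bilexnet_bad_phase", "bilexnet_error", "error")))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 lr_start = lr_start, lr_end = lr_end,
                 lr_anneal = as.integer(lr_anneal), beta = beta,
                 radius_init = as.integer(radius_init),
                 radius_floor = as.integer(radius_floor),
                 check_interval = as.integer(check_interval),
                 hebbian_start = as.integer(hebbian_start),
                 reading_start = as.integer(reading_start),
                 ortho_min_radius = as.integer(ortho_min_radius)),
            class = "bilex_control")
}

## associative matrix store: raw weights + lazy row scale + row max tracker
.assoc_new <- function(n_src, n_tgt) {
  e <- new.env(parent = emptyenv())
  e$W <- matrix(0, n_src, n_tgt)
  e$scale <- rep(1, n_src)
  e$rowmax <- rep(0, n_src)
  e
}

.assoc_eff <- function(a) cpp_effective(a$W, a$scale)

## nonzero support of an activation field, 0-based for the C++ side
.fieldify <- function(vec) {
  idx <- which(vec > 0)
  list(idx = idx - 1L, val = vec[idx])
}

## neighbourhood of a node on a rows x cols grid given coords matrix
.nb_raw <- function(coords, node, radius) {
  d2 <- (coords[, 1L] - coords[node, 1L])^2 + (coords[, 2L] - coords[node, 2L])^2
  nodes <- which(d2 <= radius^2 + 1e-9)
  sigma <- max(radius, 1)
  list(nodes = nodes, g = exp(-d2[nodes] / (2 * sigma^2)))
}

## BLAS-based BMU search against fixed weights (w2 = per-node squared norms):
## identical to the exhaustive search, via |w - x|^2 = |w|^2 - 2 w.x + |x|^2
.bmus_blas <- function(W, X, w2 = rowSums(W * W)) {
  d2 <- w2 - 2 * (W %*% t(X))
  idx <- max.col(-t(d2), ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(idx, seq_len(nrow(X)))] + rowSums(X * X), 0))
  list(index = idx, dist = dist)
}

## empirical name agreement per object for one language's monolingual group:
## named list object -> named numeric vector of proportions
.agreement_list <- function(responses, lang) {
  grp <- responses[responses$group == paste0("monolingual_", lang), , drop = FALSE]
  out <- list()
  for (ob in unique(grp$object)) {
    rows <- grp[grp$object == ob, , drop = FALSE]
    out[[ob]] <- stats::setNames(rows$count / sum(rows$count), rows$name)
  }
  out
}

#' Fit the multi-layer SOM model of bilingual object naming
#'
#' Trains the semantic, phonological and (unless ablated) orthographic
#' 30 x 40 self-organizing maps on a bilingual naming dataset under the
#' three-phase protocol: (1) the semantic and phonological maps train
#' independently; (2) after `hebbian_start` epochs the orthographic map
#' starts training and name-agreement-scaled Hebbian learning links the
#' semantic and phonological maps per language, together with
#' cross-language lateral connections between co-activated names; (3)
#' after `reading_start` epochs the semantic-orthographic and
#' phonological-orthographic (one-to-one) pathways join.  Stimulus order
#' is re-randomised every epoch from the seed; the same seed always
#' produces a bit-identical model.
#'
#' @param data A [bilex_data()] dataset.
#' @param condition `"bilingual"` trains on both languages' lexicons and
#'   monolingual naming norms; `"monolingual_A"`/`"monolingual_B"` train a
#'   single-language model (no lateral connections).
#' @param ablation `"no_orthography"` removes the orthographic map and its
#'   pathways; `"no_lateral"` removes the cross-language lateral
#'   connections.
#' @param epochs Training epochs (the standard model uses 500).
#' @param seed Integer seed for weight initialisation and stimulus order.
#' @param control A [bilex_control()] list.
#' @return An object of class `bilexnet`; see [predict.bilexnet()] for
#'   simulated naming.
#' @export
bilexnet <- function(data, condition = c("bilingual", "monolingual_A", "monolingual_B"),
                     ablation = c("none", "no_orthography", "no_lateral"),
                     epochs = 500L, seed = 1L, control = bilex_control()) {
  condition <- match.arg(condition)
  ablation <- match.arg(ablation)
  stopifnot(inherits(data, "bilex_data"), epochs >= 0)
  ctl <- control
  langs <- switch(condition, bilingual = c("A", "B"),
                  monolingual_A = "A", monolingual_B = "B")
  use_ortho <- ablation != "no_orthography"
  use_lateral <- ablation != "no_lateral" && condition == "bilingual"

  lex <- data$lexicon[data$lexicon$language %in% langs, , drop = FALSE]
  lex <- lex[order(match(lex$language, c("A", "B"))), , drop = FALSE]
  rownames(lex) <- NULL
  n_words <- nrow(lex)
  sem_X <- data$features
  n_obj <- nrow(sem_X)
  phon_X <- t(vapply(lex$ipa, encode_phonology, numeric(81)))
  orth_X <- if (use_ortho) t(vapply(lex$spelling, encode_orthography, numeric(297))) else NULL
  agree <- lapply(stats::setNames(langs, langs),
                  function(l) .agreement_list(data$responses, l))
  for (l in langs) {
    nm <- unique(unlist(lapply(agree[[l]], names)))
    if (!all(nm %in% lex$word[lex$language == l]))
      stop(errorCondition("response names missing from the lexicon",
                          class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  }

  n_nodes <- ctl$rows * ctl$cols
  coords <- grid_coords(ctl$rows, ctl$cols)

  ## per-map RNG streams: the semantic stream depends only on the objects,
  ## so the semantic map is identical across conditions for a given seed
  set.seed(.derive_seed(seed, "som_s"))
  W_s <- matrix(stats::runif(n_nodes * ncol(sem_X)), n_nodes)
  ord_s <- if (epochs > 0) replicate(epochs, sample.int(n_obj)) else NULL
  set.seed(.derive_seed(seed, "som_p"))
  W_p <- matrix(stats::runif(n_nodes * 81L), n_nodes)
  ord_p <- if (epochs > 0) replicate(epochs, sample.int(n_words)) else NULL
  W_o <- ord_o <- NULL
  if (use_ortho) {
    set.seed(.derive_seed(seed, "som_o"))
    W_o <- matrix(stats::runif(n_nodes * 297L), n_nodes)
    ord_o <- if (epochs > 0) replicate(epochs, sample.int(n_words)) else NULL
  }
  w2_s <- rowSums(W_s * W_s)
  w2_p <- rowSums(W_p * W_p)
  w2_o <- if (use_ortho) rowSums(W_o * W_o) else NULL

  assoc <- list()
  for (l in langs) assoc[[paste0("sp_", l)]] <- .assoc_new(n_nodes, n_nodes)
  if (use_ortho) {
    for (l in langs) assoc[[paste0("so_", l)]] <- .assoc_new(n_nodes, n_nodes)
    assoc$po <- .assoc_new(n_nodes, n_nodes)
    assoc$op <- .assoc_new(n_nodes, n_nodes)
  }
  lateral <- if (use_lateral) matrix(0, n_words, n_words,
                                     dimnames = list(lex$word, lex$word)) else NULL

  rad <- list(s = ctl$radius_init, p = ctl$radius_init, o = ctl$radius_init)
  qe_hist <- list(s = numeric(0), p = numeric(0), o = numeric(0))
  log_rows <- vector("list", epochs)
  word_lang <- lex$language
  words_by_lang <- lapply(stats::setNames(langs, langs), function(l) which(word_lang == l))
  word_index <- stats::setNames(seq_len(n_words), lex$word)

  train_pass <- function(W, w2, X, order_col, lr, radius) {
    for (i in order_col) {
      b <- which.min(w2 - 2 * as.numeric(W %*% X[i, ]))
      nb <- .nb_raw(coords, b, radius)
      cpp_som_update_tracked(W, w2, X[i, ], nb$nodes - 1L, nb$g, lr)
    }
  }
  step_radius <- function(map, epoch_in_map) {
    ci <- ctl$check_interval
    h <- qe_hist[[map]]
    if (epoch_in_map %% ci == 0L && length(h) >= 2L * ci) {
      st <- adapt_radius(list(radius = rad[[map]], qe_history = h,
                              check_interval = ci, floor = ctl$radius_floor))
      rad[[map]] <<- st$radius
    }
  }

  for (epoch in seq_len(epochs)) {
    lr <- learning_rate(epoch - 1L, ctl$lr_start, ctl$lr_end, ctl$lr_anneal)
    hebb_on <- epoch > ctl$hebbian_start
    read_on <- epoch > ctl$reading_start
    n_up <- c(sp = 0L, so = 0L, po = 0L, lateral = 0L)

    train_pass(W_s, w2_s, sem_X, ord_s[, epoch], lr, rad$s)
    train_pass(W_p, w2_p, phon_X, ord_p[, epoch], lr, rad$p)
    if (use_ortho && hebb_on) train_pass(W_o, w2_o, orth_X, ord_o[, epoch], lr, rad$o)

    bm_s <- .bmus_blas(W_s, sem_X, w2_s)
    bm_p <- .bmus_blas(W_p, phon_X, w2_p)
    qe_hist$s <- c(qe_hist$s, mean(bm_s$dist))
    qe_hist$p <- c(qe_hist$p, mean(bm_p$dist))
    step_radius("s", epoch); step_radius("p", epoch)
    bm_o <- NULL
    if (use_ortho && hebb_on) {
      bm_o <- .bmus_blas(W_o, orth_X, w2_o)
      qe_hist$o <- c(qe_hist$o, mean(bm_o$dist))
      step_radius("o", length(qe_hist$o))
    }

    if (hebb_on) {
      ## per-word target bumps on the phonological (and orthographic) map
      nb_p <- lapply(bm_p$index, .nb_raw, coords = coords, radius = rad$p)
      nb_o <- if (!is.null(bm_o)) lapply(bm_o$index, .nb_raw, coords = coords,
                                         radius = rad$o) else NULL
      for (oi in ord_s[, epoch]) {
        ob <- rownames(sem_X)[oi]
        src_nb <- .nb_raw(coords, bm_s$index[oi], rad$s)
        src_idx <- src_nb$nodes - 1L
        src_val <- src_nb$g
        for (l in langs) {
          nn <- agree[[l]][[ob]]
          if (is.null(nn)) next
          widx <- word_index[names(nn)]
          tgt <- numeric(n_nodes)
          for (k in seq_along(widx)) {
            nb <- nb_p[[widx[k]]]
            tgt[nb$nodes] <- tgt[nb$nodes] + nn[k] * nb$g
          }
          f <- .fieldify(tgt)
          cpp_hebb(assoc[[paste0("sp_", l)]]$W, assoc[[paste0("sp_", l)]]$scale,
                   assoc[[paste0("sp_", l)]]$rowmax, src_idx, src_val,
                   f$idx, f$val, ctl$beta)
          n_up["sp"] <- n_up["sp"] + length(widx)
          if (read_on && use_ortho) {
            tgt_o <- numeric(n_nodes)
            for (k in seq_along(widx)) {
              nb <- nb_o[[widx[k]]]
              tgt_o[nb$nodes] <- tgt_o[nb$nodes] + nn[k] * nb$g
            }
            fo <- .fieldify(tgt_o)
            cpp_hebb(assoc[[paste0("so_", l)]]$W, assoc[[paste0("so_", l)]]$scale,
                     assoc[[paste0("so_", l)]]$rowmax, src_idx, src_val,
                     fo$idx, fo$val, ctl$beta)
            n_up["so"] <- n_up["so"] + length(widx)
          }
        }
        if (use_lateral) {
          na <- agree[["A"]][[ob]]; nb_ <- agree[["B"]][[ob]]
          if (!is.null(na) && !is.null(nb_)) {
            ia <- word_index[names(na)]; ib <- word_index[names(nb_)]
            inc <- ctl$beta * outer(as.numeric(na), as.numeric(nb_))
            lateral[ia, ib] <- lateral[ia, ib] + inc
            lateral[ib, ia] <- lateral[ib, ia] + t(inc)
            mx <- apply(lateral, 1L, max)
            over <- which(mx > 1)
            if (length(over)) lateral[over, ] <- lateral[over, , drop = FALSE] / mx[over]
            n_up["lateral"] <- n_up["lateral"] + length(ia) * length(ib)
          }
        }
      }
      if (read_on && use_ortho) {
        ## one-to-one phonological <-> orthographic mapping per word form
        for (wi in ord_p[, epoch]) {
          np <- nb_p[[wi]]; no <- nb_o[[wi]]
          cpp_hebb(assoc$po$W, assoc$po$scale, assoc$po$rowmax,
                   np$nodes - 1L, np$g, no$nodes - 1L, no$g, ctl$beta)
          cpp_hebb(assoc$op$W, assoc$op$scale, assoc$op$rowmax,
                   no$nodes - 1L, no$g, np$nodes - 1L, np$g, ctl$beta)
          n_up["po"] <- n_up["po"] + 2L
        }
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, qe_s = qe_hist$s[epoch], qe_p = qe_hist$p[epoch],
      qe_o = if (use_ortho && hebb_on) qe_hist$o[length(qe_hist$o)] else NA_real_,
      radius_s = rad$s, radius_p = rad$p,
      radius_o = if (use_ortho && hebb_on) rad$o else NA_integer_,
      n_sp = n_up[["sp"]], n_so = n_up[["so"]], n_po = n_up[["po"]],
      n_lateral = n_up[["lateral"]])
  }

  grid_of <- function(W) {
    g <- list(rows = ctl$rows, cols = ctl$cols, dim = ncol(W), weights = W,
              coords = coords)
    class(g) <- "som_grid"
    g
  }
  registry <- data.frame(lex,
                         bmu_p = .bmus_blas(W_p, phon_X, w2_p)$index,
                         bmu_o = if (use_ortho) .bmus_blas(W_o, orth_X, w2_o)$index
                                 else NA_integer_,
                         stringsAsFactors = FALSE)
  objects <- data.frame(object = rownames(sem_X),
                        bmu_s = .bmus_blas(W_s, sem_X, w2_s)$index,
                        stringsAsFactors = FALSE)
  model <- structure(list(
    maps = list(semantic = grid_of(W_s), phonological = grid_of(W_p),
                orthographic = if (use_ortho) grid_of(W_o) else NULL),
    assoc = lapply(assoc, .assoc_eff),
    lateral = lateral,
    registry = registry, objects = objects, agreement = agree,
    features = sem_X, languages = langs,
    radius = list(s = rad$s, p = rad$p, o = if (use_ortho) rad$o else NA),
    log = if (epochs > 0) do.call(rbind, log_rows) else data.frame(),
    condition = condition, ablation = ablation, epochs = as.integer(epochs),
    seed = as.integer(seed), control = ctl, call = match.call()),
    class = "bilexnet")
  model
}

#' Train an ensemble of replicate models
#'
#' Trains `n` replicates of the same model with different random initial
#' weights and stimulus orders (replicate i uses seed `base_seed + i - 1`),
#' mirroring the practice of averaging reported statistics over an
#' ensemble of simulations.
#'
#' @param data A [bilex_data()] dataset.
#' @param n Number of replicates (the standard protocol uses 20).
#' @param base_seed Seed of the first replicate.
#' @param ... Passed on to [bilexnet()].
#' @return A list of `bilexnet` models, class `bilexnet_ensemble`.
#' @export
bilexnet_ensemble <- function(data, n = 20L, base_seed = 1L, ...) {
  stopifnot(n >= 1)
  out <- lapply(seq_len(n), function(i) bilexnet(data, seed = base_seed + i - 1L, ...))
  class(out) <- "bilexnet_ensemble"
  out
}
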