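## Simulated object naming ---------------------------------------------------
##
## A stimulus activates the semantic map (Gaussian bump at its BMU) and the
## resulting activation reaches each candidate name's phonological BMU along
## three additive routes:
##   semantic:  S -> P through the target language's Hebbian pathway,
##   lateral:   S -> P through the non-target language, then across the
##              cross-language lateral connections,
##   ortho:     S -> O, item-level spreading among orthographically close
##              word forms (grid distance <= max(3, final O radius)), fed
##              back through O -> P.
## The activation read at a word's phonological BMU is the simulated name
## agreement; the three terms sum exactly to the total (ACTp decomposition).

.clip01 <- function(x) pmin(pmax(x, 0), 1)

## semantic input fields for the listed objects: one Gaussian bump per row,
## normalised to unit mass so propagated activations live on the
## name-agreement scale (an activation of 0.8 reads as agreement 0.8)
.semantic_fields <- function(model, object_ids) {
  g <- model$maps$semantic
  idx <- match(object_ids, model$objects$object)
  t(vapply(model$objects$bmu_s[idx],
           function(b) {
             bump <- gaussian_bump(g, b, model$radius$s)
             bump / sum(bump)
           },
           numeric(g$rows * g$cols)))
}

## the three route matrices (objects x target-language words)
.naming_routes <- function(model, target, object_ids) {
  reg <- model$registry
  tgt_rows <- which(reg$language == target)
  if (!length(tgt_rows))
    stop(errorCondition(sprintf("model has no language '%s'", target),
                        class = c("bilexnet_unknown_language", "bilexnet_error", "error")))
  A_s <- .semantic_fields(model, object_ids)
  n_obj <- nrow(A_s)
  tgt_words <- reg$word[tgt_rows]

  sem_field <- .clip01(A_s %*% model$assoc[[paste0("sp_", target)]])
  sem <- sem_field[, reg$bmu_p[tgt_rows], drop = FALSE]

  lat <- matrix(0, n_obj, length(tgt_rows))
  non <- setdiff(model$languages, target)
  if (length(non) && !is.null(model$lateral)) {
    non_rows <- which(reg$language == non)
    p_non <- .clip01(A_s %*% model$assoc[[paste0("sp_", non)]])
    act_non <- p_non[, reg$bmu_p[non_rows], drop = FALSE]
    L <- model$lateral[reg$word[non_rows], tgt_words, drop = FALSE]
    lat <- .clip01(act_non %*% L)
  }

  orth <- matrix(0, n_obj, length(tgt_rows))
  if (!is.null(model$maps$orthographic)) {
    o_field <- matrix(0, n_obj, ncol(A_s))
    for (l in model$languages)
      o_field <- o_field + A_s %*% model$assoc[[paste0("so_", l)]]
    o_field <- .clip01(o_field)
    ## item-level spreading among orthographic word BMUs
    act_items <- o_field[, reg$bmu_o, drop = FALSE]     # objects x all words
    co <- model$maps$orthographic$coords[reg$bmu_o, , drop = FALSE]
    r_spread <- max(model$control$ortho_min_radius, model$radius$o, na.rm = TRUE)
    d2 <- outer(co[, 1L], co[, 1L], "-")^2 + outer(co[, 2L], co[, 2L], "-")^2
    nbr <- (d2 <= r_spread^2 + 1e-9)
    diag(nbr) <- FALSE                                  # similar *other* items
    spread <- act_items %*% nbr                          # sum of activated neighbours
    ## feed back to the phonological map through O -> P
    o2 <- matrix(0, n_obj, ncol(A_s))
    for (k in seq_len(nrow(reg)))
      o2[, reg$bmu_o[k]] <- o2[, reg$bmu_o[k]] + spread[, k]
    p_from_o <- .clip01(.clip01(o2) %*% model$assoc$op)
    orth <- p_from_o[, reg$bmu_p[tgt_rows], drop = FALSE]
  }
  dimnames(sem) <- dimnames(lat) <- dimnames(orth) <- list(object_ids, tgt_words)
  list(sem = sem, lateral = lat, ortho = orth)
}

#' Simulate object naming in one language
#'
#' Presents each object to the semantic map and reads the activation
#' propagated to the phonological best-matching unit of every candidate
#' name of the target language, decomposed into the semantic, lateral and
#' orthographic routes (which sum exactly to the total activation `actp`,
#' the simulated name agreement).  A candidate is dominant if it has the
#' highest activation, or an activation strictly greater than 80% of the
#' highest (see [dominant_names()]).
#'
#' @param object A fitted [bilexnet()] model.
#' @param language Target language ("A" or "B").
#' @param objects Object ids to name (default: all objects in the training
#'   data).
#' @param ... Unused.
#' @return A data frame of class `bilex_naming` with columns `object`,
#'   `language`, `word`, `sem`, `lateral`, `ortho`, `actp`, `dominant`.
#'   Objects with no positively activated candidate are listed in
#'   `attr(, "no_response")`; words sharing a phonological BMU (whose
#'   activations are read at the same node, with exact ties resolved by
#'   the higher summed associative in-weight) in `attr(, "bmu_collisions")`.
#' @export
predict.bilexnet <- function(object, language = "A", objects = NULL, ...) {
  model <- object
  if (is.null(objects)) objects <- model$objects$object
  unknown <- setdiff(objects, model$objects$object)
  if (length(unknown))
    stop(errorCondition(sprintf("unknown object(s): %s",
                                paste(utils::head(unknown, 3L), collapse = ", ")),
                        class = c("bilexnet_unknown_object", "bilexnet_error", "error")))
  r <- .naming_routes(model, language, objects)
  actp <- r$sem + r$lateral + r$ortho
  ## words sharing a phonological BMU are reported; if such words tie on
  ## activation, dominance goes to the higher summed associative in-weight
  reg_t <- model$registry[model$registry$language == language, , drop = FALSE]
  shared <- reg_t$bmu_p %in% reg_t$bmu_p[duplicated(reg_t$bmu_p)]
  collisions <- reg_t$word[shared]
  inw <- colSums(model$assoc[[paste0("sp_", language)]])[reg_t$bmu_p]
  if (!is.null(model$lateral))
    inw <- inw + colSums(model$lateral)[reg_t$word]
  no_resp <- character(0)
  rows <- lapply(seq_along(objects), function(i) {
    sc <- actp[i, ]
    dom <- rep(FALSE, length(sc))
    if (any(sc > 0)) {
      dom <- sc >= max(sc) | sc > 0.8 * max(sc)
      if (length(collisions) && sum(dom) > 1L) {
        for (node in unique(reg_t$bmu_p[shared])) {
          grp <- which(reg_t$bmu_p == node & dom & sc == max(sc[reg_t$bmu_p == node]))
          if (length(grp) > 1L) dom[grp[-which.max(inw[grp])]] <- FALSE
        }
      }
    } else no_resp <- c(no_resp, objects[i])
    no_resp <<- no_resp
    data.frame(object = objects[i], language = language, word = colnames(actp),
               sem = r$sem[i, ], lateral = r$lateral[i, ], ortho = r$ortho[i, ],
               actp = sc, dominant = dom, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bilex_naming", "data.frame")
  attr(out, "no_response") <- no_resp
  attr(out, "bmu_collisions") <- collisions
  out
}

#' Dominant names under the 80% co-dominance rule
#'
#' The highest-scoring name is always dominant; any further name whose
#' score is strictly greater than 80% of the highest score is co-dominant
#' (e.g. scores 0.55 and 0.45 give two dominant names, since 0.45/0.55 >
#' 0.8, while 0.5 and 0.4 give one).
#'
#' @param scores Named numeric vector of name-agreement scores or candidate
#'   activations; at least one must be positive.
#' @param threshold Co-dominance threshold (0.8).
#' @return Character vector of dominant names.
#' @export
dominant_names <- function(scores, threshold = 0.8) {
  if (!any(scores > 0))
    stop(errorCondition("no candidate with positive activation",
                        class = c("bilexnet_no_response", "bilexnet_error", "error")))
  mx <- max(scores)
  names(scores)[scores >= mx | scores > threshold * mx]
}

## empirical dominant-name sets per object for one language (80% rule on
## the monolingual group's agreement proportions)
.empirical_dominants <- function(model, language) {
  lapply(model$agreement[[language]], dominant_names)
}

#' Simulated naming accuracy against the empirical dominant names
#'
#' Applies the 80% dominance rule to both the model's simulated agreements
#' and the dataset's empirical agreement proportions, and scores an object
#' as correct when the two dominant-name sets intersect.
#'
#' @param model A fitted [bilexnet()] model.
#' @param language Target language.
#' @param naming Optional precomputed result of [predict.bilexnet()].
#' @return Percentage of correctly named objects (0 to 100).
#' @export
naming_accuracy <- function(model, language = "A", naming = NULL) {
  emp <- .empirical_dominants(model, language)
  if (!length(emp))
    stop(errorCondition("no empirical responses for this language",
                        class = c("bilexnet_empty_input", "bilexnet_error", "error")))
  if (is.null(naming)) naming <- predict(model, language = language)
  obs <- names(emp)
  hit <- vapply(obs, function(ob) {
    sub <- naming[naming$object == ob & naming$dominant, , drop = FALSE]
    length(intersect(sub$word, emp[[ob]])) > 0
  }, logical(1))
  100 * mean(hit)
}

#' Model-simulated name-distribution table for one language
#'
#' Rows are objects, columns the language's name inventory, entries the
#' simulated name agreements (total phonological activation per candidate).
#'
#' @param model A fitted [bilexnet()] model.
#' @param language Target language.
#' @return Numeric matrix objects x names.
#' @export
simulated_distribution <- function(model, language = "A") {
  nm <- predict(model, language = language)
  words <- unique(nm$word)
  objs <- unique(nm$object)
  matrix(nm$actp, nrow = length(objs), ncol = length(words), byrow = TRUE,
         dimnames = list(objs, words))
}
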