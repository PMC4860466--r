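#' @export
print.bilexnet <- function(x, ...) {
  cat("Multi-layer SOM model of bilingual object naming\n")
  cat(sprintf("  condition: %s%s\n", x$condition,
              if (x$ablation != "none") paste0(" (", x$ablation, ")") else ""))
  cat(sprintf("  maps: %d x %d nodes; %d objects, %d word forms (%s)\n",
              x$control$rows, x$control$cols, nrow(x$objects),
              nrow(x$registry), paste(x$languages, collapse = "+")))
  cat(sprintf("  trained %d epochs, seed %d\n", x$epochs, x$seed))
  invisible(x)
}

#' Summarise a fitted bilingual naming model
#'
#' Reports final quantization errors and radii per map and, for each
#' in-condition language, the simulated naming accuracy against the
#' empirical dominant names.
#'
#' @param object A fitted [bilexnet()] model.
#' @param ... Unused.
#' @return An object of class `summary.bilexnet`.
#' @export
summary.bilexnet <- function(object, ...) {
  log <- object$log
  acc <- if (object$epochs > object$control$hebbian_start)
    vapply(object$languages, function(l) naming_accuracy(object, l), numeric(1))
  else stats::setNames(rep(NA_real_, length(object$languages)), object$languages)
  out <- list(condition = object$condition, ablation = object$ablation,
              epochs = object$epochs,
              final_qe = if (nrow(log)) log[nrow(log), c("qe_s", "qe_p", "qe_o")] else NULL,
              final_radius = object$radius, accuracy = acc)
  class(out) <- "summary.bilexnet"
  out
}

#' @export
print.summary.bilexnet <- function(x, ...) {
  cat(sprintf("bilexnet model (%s, ablation %s), %d epochs\n",
              x$condition, x$ablation, x$epochs))
  if (!is.null(x$final_qe))
    cat(sprintf("  final quantization error: semantic %.4f, phonological %.4f%s\n",
                x$final_qe$qe_s, x$final_qe$qe_p,
                if (is.na(x$final_qe$qe_o)) "" else
                  sprintf(", orthographic %.4f", x$final_qe$qe_o)))
  cat(sprintf("  final radius: semantic %s, phonological %s, orthographic %s\n",
              x$final_radius$s, x$final_radius$p, x$final_radius$o))
  for (l in names(x$accuracy))
    if (!is.na(x$accuracy[[l]]))
      cat(sprintf("  naming accuracy, language %s: %.1f%%\n", l, x$accuracy[[l]]))
  invisible(x)
}

#' Extract associative pathway weights
#'
#' @param object A fitted [bilexnet()] model.
#' @param pathway Which pathway matrix to return, e.g. `"sp_A"` (semantic
#'   to phonological, language A), `"so_B"`, `"po"`, `"op"`, or
#'   `"lateral"` for the cross-language word-level lateral matrix.
#' @param ... Unused.
#' @return A numeric weight matrix.
#' @export
coef.bilexnet <- function(object, pathway = "sp_A", ...) {
  if (pathway == "lateral") return(object$lateral)
  if (!pathway %in% names(object$assoc))
    stop(sprintf("unknown pathway '%s'; available: %s, lateral", pathway,
                 paste(names(object$assoc), collapse = ", ")))
  object$assoc[[pathway]]
}

#' Plot training trajectories or the semantic map
#'
#' `which = "training"` draws the per-epoch quantization error and
#' neighbourhood radius of each map; `which = "map"` draws the objects at
#' their semantic best-matching units, coloured by their empirical dominant
#' name in `language`.
#'
#' @param x A fitted [bilexnet()] model.
#' @param which `"training"` or `"map"`.
#' @param language Language used to colour the map plot.
#' @param ... Further graphical parameters (unused).
#' @export
plot.bilexnet <- function(x, which = c("training", "map"), language = NULL, ...) {
  which <- match.arg(which)
  if (which == "training") {
    log <- x$log
    if (!nrow(log)) stop("model was trained for 0 epochs")
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    graphics::matplot(log$epoch, cbind(log$qe_s, log$qe_p, log$qe_o),
                      type = "l", lty = 1, col = c("black", "steelblue", "tomato"),
                      xlab = "epoch", ylab = "quantization error")
    graphics::legend("topright", c("semantic", "phonological", "orthographic"),
                     col = c("black", "steelblue", "tomato"), lty = 1, bty = "n")
    graphics::matplot(log$epoch, cbind(log$radius_s, log$radius_p, log$radius_o),
                      type = "s", lty = 1, col = c("black", "steelblue", "tomato"),
                      xlab = "epoch", ylab = "neighbourhood radius")
  } else {
    if (is.null(language)) language <- x$languages[1L]
    co <- x$maps$semantic$coords[x$objects$bmu_s, , drop = FALSE]
    dom <- vapply(x$objects$object, function(ob) {
      d <- x$agreement[[language]][[ob]]
      if (is.null(d)) NA_character_ else dominant_names(d)[1L]
    }, character(1))
    cols <- as.integer(factor(dom))
    graphics::plot(co[, 2L], co[, 1L], col = cols, pch = 19,
                   xlab = "map column", ylab = "map row",
                   xlim = c(1, x$maps$semantic$cols),
                   ylim = c(1, x$maps$semantic$rows))
    graphics::legend("topright", legend = levels(factor(dom)),
                     col = seq_along(levels(factor(dom))), pch = 19, bty = "n")
  }
  invisible(x)
}

#' Simulate naming-response tables from a fitted model
#'
#' Draws multinomial participant responses per object from the model's
#' simulated name agreements (normalised to probabilities), producing
#' response tables in the same format the trainer consumes.
#'
#' @param object A fitted [bilexnet()] model.
#' @param nsim Number of simulated response tables.
#' @param seed Optional seed.
#' @param language Target language.
#' @param participants Participants per simulated group.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `object`, `group`,
#'   `name`, `count`.
#' @export
simulate.bilexnet <- function(object, nsim = 1, seed = NULL, language = "A",
                              participants = 25L, ...) {
  if (!is.null(seed)) set.seed(seed)
  dist <- simulated_distribution(object, language)
  lapply(seq_len(nsim), function(s) {
    rows <- lapply(rownames(dist), function(ob) {
      p <- dist[ob, ]
      if (sum(p) <= 0) return(NULL)
      cnt <- as.vector(stats::rmultinom(1L, participants, p / sum(p)))
      keep <- cnt > 0
      data.frame(object = ob, group = paste0("simulated_", language),
                 name = colnames(dist)[keep], count = cnt[keep],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' @export
print.bilexnet_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d replicate bilexnet models (%s%s)\n", length(x),
              x[[1]]$condition,
              if (x[[1]]$ablation != "none") paste0(", ", x[[1]]$ablation) else ""))
  invisible(x)
}
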