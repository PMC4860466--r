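## Convergence analysis battery ---------------------------------------------

#' Build a name-distribution table for one response group
#'
#' One row per object, one column per name of the group's inventory,
#' entries the response counts.  For example, an object named fles by 11
#' participants, flacon by 10 and pot by 4 yields a row with 11, 10 and 4
#' in those columns and zeros elsewhere.
#'
#' @param responses Response data frame (`object`, `group`, `name`,
#'   `count`).
#' @param group Group tag to tabulate.
#' @param inventory Column (name) set; defaults to all names the group
#'   produced.
#' @param objects Row (object) set; defaults to all objects in `responses`.
#' @return Numeric matrix objects x names; objects with no responses give
#'   all-zero rows and are listed in `attr(, "empty_objects")`.
#' @export
name_distribution <- function(responses, group, inventory = NULL, objects = NULL) {
  sub <- responses[responses$group == group, , drop = FALSE]
  if (is.null(objects)) objects <- sort(unique(responses$object))
  if (is.null(inventory)) inventory <- sort(unique(sub$name))
  if (!all(sub$name %in% inventory))
    stop(errorCondition("response name outside the given inventory",
                        class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  if (!all(sub$object %in% objects))
    stop(errorCondition("response object outside the given object set",
                        class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  tab <- matrix(0, length(objects), length(inventory),
                dimnames = list(objects, inventory))
  tab[cbind(match(sub$object, objects), match(sub$name, inventory))] <- sub$count
  attr(tab, "empty_objects") <- setdiff(objects, unique(sub$object))
  tab
}

#' Pairwise name-distribution similarity profile
#'
#' The Pearson correlation between every unordered pair of objects' name
#' distributions, in canonical row-major upper-triangle order, giving a
#' vector of length n(n-1)/2 (2628 for 73 objects).  Pairs involving a
#' constant distribution have an undefined correlation; they are recorded
#' as `NA` and counted in `attr(, "n_excluded")`, and are excluded
#' pairwise by downstream correlation comparisons.
#'
#' @param tab Objects x names matrix of counts or simulated agreements.
#' @return Numeric vector of class `similarity_profile`.
#' @export
similarity_profile <- function(tab) {
  n <- nrow(tab)
  if (n < 2L)
    stop(errorCondition("need at least two objects",
                        class = c("bilexnet_empty_input", "bilexnet_error", "error")))
  C <- suppressWarnings(stats::cor(t(tab)))
  ut <- upper.tri(C)
  idx <- which(ut, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  prof <- C[ut][ord]
  structure(prof, n_objects = n, n_excluded = sum(is.na(prof)),
            class = "similarity_profile")
}

#' Fisher r-to-z transformation and its inverse
#'
#' `fisher_z(r) = 0.5 * log((1 + r) / (1 - r))`; odd in `r` and exactly
#' inverted by `fisher_z_inv`.
#'
#' @param r Correlation(s) in (-1, 1).
#' @param z z-value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)

#' Compare two between-group profile correlations
#'
#' Computes `r1 = cor(profile1, profile2)` and `r2 = cor(profile3,
#' profile4)` (pairwise-complete), Fisher-transforms both, and tests their
#' difference with `Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, where `n1`
#' and `n2` are the numbers of complete profile pairs.
#'
#' @param profile1,profile2 Similarity profiles whose correlation forms
#'   `r1`.
#' @param profile3,profile4 Profiles forming `r2`.
#' @return An object of class `htest` with the Z statistic, two-sided
#'   p-value, and estimates `r1`, `r2`.
#' @export
compare_correlations <- function(profile1, profile2, profile3, profile4) {
  stopifnot(length(profile1) == length(profile2),
            length(profile3) == length(profile4))
  ok1 <- stats::complete.cases(cbind(as.numeric(profile1), as.numeric(profile2)))
  ok2 <- stats::complete.cases(cbind(as.numeric(profile3), as.numeric(profile4)))
  r1 <- stats::cor(as.numeric(profile1)[ok1], as.numeric(profile2)[ok1])
  r2 <- stats::cor(as.numeric(profile3)[ok2], as.numeric(profile4)[ok2])
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop(errorCondition("perfect correlation: Fisher z is infinite",
                        class = c("bilexnet_degenerate", "bilexnet_error", "error")))
  n1 <- sum(ok1); n2 <- sum(ok2)
  Z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(statistic = c(Z = Z),
                 p.value = 2 * stats::pnorm(-abs(Z)),
                 estimate = c(r1 = r1, r2 = r2),
                 parameter = c(n1 = n1, n2 = n2),
                 method = "Fisher r-to-z comparison of two correlations",
                 data.name = "similarity profiles"),
            class = "htest")
}

#' Simulated typicality of each object for a category name
#'
#' Presents the name to the phonological map (a Gaussian bump at its BMU)
#' and propagates the activation back to the semantic map through the
#' transpose of the language's semantic-phonological pathway (Hebbian
#' links are learned bidirectionally).  In a bilingual model the presented
#' name also activates the other language's word forms through the lateral
#' connections, and their activation flows back through that language's
#' transposed pathway as well.  The activation read at each object's
#' semantic BMU is that object's typicality for the category.
#'
#' @param model A fitted [bilexnet()] model.
#' @param word A registered word (category name).
#' @return Named numeric vector of activations over objects.
#' @export
typicality_activation <- function(model, word) {
  reg <- model$registry
  k <- match(word, reg$word)
  if (is.na(k))
    stop(errorCondition(sprintf("word '%s' is not registered", word),
                        class = c("bilexnet_unknown_word", "bilexnet_error", "error")))
  bump <- gaussian_bump(model$maps$phonological, reg$bmu_p[k], model$radius$p)
  bump <- bump / sum(bump)   # unit mass: activations on the agreement scale
  W <- model$assoc[[paste0("sp_", reg$language[k])]]
  sem <- as.numeric(bump %*% t(W))
  non <- setdiff(model$languages, reg$language[k])
  if (length(non) && !is.null(model$lateral)) {
    non_rows <- which(reg$language == non)
    lw <- model$lateral[reg$word[k], reg$word[non_rows]]
    if (any(lw > 0)) {
      Wn <- model$assoc[[paste0("sp_", non)]]
      sem <- sem + as.numeric(Wn[, reg$bmu_p[non_rows], drop = FALSE] %*% lw)
    }
  }
  sem <- .clip01(sem)
  stats::setNames(sem[model$objects$bmu_s], model$objects$object)
}

#' Correlation of typicality profiles for a translation pair
#'
#' Correlates, across objects, the typicality activations elicited by two
#' category names — either both from one bilingual model, or one from each
#' of a pair of monolingual models.
#'
#' @param model_1 Model providing `word_1`.
#' @param word_1,word_2 The two category names.
#' @param model_2 Model providing `word_2` (defaults to `model_1`).
#' @return A list with the Pearson `r`, Fisher `z` and `n` (objects).
#' @export
typicality_correlation <- function(model_1, word_1, word_2, model_2 = model_1) {
  t1 <- typicality_activation(model_1, word_1)
  t2 <- typicality_activation(model_2, word_2)
  if (stats::sd(t1) == 0 || stats::sd(t2) == 0)
    stop(errorCondition("zero-variance typicality vector",
                        class = c("bilexnet_degenerate", "bilexnet_error", "error")))
  r <- stats::cor(t1, t2)
  list(r = r, z = fisher_z(r), n = length(t1))
}

.weighted_mean_coord <- function(coords, w) colSums(coords * w) / sum(w)

.weighted_median_coord <- function(coords, w) {
  apply(coords, 2L, function(v) {
    o <- order(v)
    cw <- cumsum(w[o]) / sum(w)
    v[o][which(cw >= 0.5)[1L]]
  })
}

#' Weighted category centers, membership and outliers on the semantic map
#'
#' For each category name, the boundary-dependent center is the
#' activation-weighted mean of the objects' semantic BMU coordinates and
#' the boundary-independent center the activation-weighted per-coordinate
#' median, with weights the objects' typicality activations for that name
#' (computed over all objects).  An object is a member of the category
#' whose name receives its highest naming activation; a member is an
#' outlier when it lies closer (Euclidean, map coordinates) to another
#' category's boundary-dependent center than to its own.
#'
#' @param model A fitted [bilexnet()] model.
#' @param language Language of the category names.
#' @param names Category names; defaults to the language's dominant names
#'   observed in the training norms.
#' @return An object of class `category_geometry`: per name, the two
#'   centers, member objects and outlier flags.
#' @export
category_geometry <- function(model, language = "A", names = NULL) {
  reg <- model$registry
  if (is.null(names)) {
    doms <- unlist(lapply(.empirical_dominants(model, language), `[`, 1L))
    names <- unique(doms)
  }
  stopifnot(all(names %in% reg$word[reg$language == language]))
  coords <- model$maps$semantic$coords[model$objects$bmu_s, , drop = FALSE]
  rownames(coords) <- model$objects$object
  typ <- sapply(names, function(w) typicality_activation(model, w))
  ## membership from the naming direction: highest-activation name wins
  nm <- predict(model, language = language)
  member_of <- vapply(model$objects$object, function(ob) {
    sub <- nm[nm$object == ob, , drop = FALSE]
    sub <- sub[sub$word %in% names, , drop = FALSE]
    if (!nrow(sub) || max(sub$actp) <= 0) return(NA_character_)
    sub$word[which.max(sub$actp)]
  }, character(1))
  cats <- lapply(stats::setNames(names, names), function(w) {
    wts <- typ[, w]
    if (sum(wts) <= 0)
      stop(errorCondition(sprintf("category '%s' has zero total activation", w),
                          class = c("bilexnet_empty_category", "bilexnet_error", "error")))
    list(center_mean = .weighted_mean_coord(coords, wts),
         center_median = .weighted_median_coord(coords, wts),
         members = model$objects$object[!is.na(member_of) & member_of == w])
  })
  centers <- t(sapply(cats, `[[`, "center_mean"))
  for (w in names) {
    mem <- cats[[w]]$members
    if (length(mem)) {
      d_own <- sqrt(rowSums((coords[mem, , drop = FALSE] -
                               matrix(centers[w, ], length(mem), 2, byrow = TRUE))^2))
      d_oth <- rep(Inf, length(mem))
      for (w2 in setdiff(names, w)) {
        d2 <- sqrt(rowSums((coords[mem, , drop = FALSE] -
                              matrix(centers[w2, ], length(mem), 2, byrow = TRUE))^2))
        d_oth <- pmin(d_oth, d2)
      }
      cats[[w]]$outliers <- mem[d_oth < d_own]
    } else cats[[w]]$outliers <- character(0)
  }
  structure(list(language = language, categories = cats, coords = coords),
            class = "category_geometry")
}

#' @export
print.category_geometry <- function(x, ...) {
  cat(sprintf("Category geometry (language %s)\n", x$language))
  for (w in names(x$categories)) {
    c_ <- x$categories[[w]]
    cat(sprintf("  %s: center (%.2f, %.2f), %d members, %d outliers\n", w,
                c_$center_mean[1], c_$center_mean[2],
                length(c_$members), length(c_$outliers)))
  }
  invisible(x)
}

#' Distance between two category centers
#'
#' @param geom_1,geom_2 [category_geometry()] objects (may be the same).
#' @param name_1,name_2 Category names within each geometry.
#' @param type `"mean"` (boundary-dependent) or `"median"`
#'   (boundary-independent) centers.
#' @return Euclidean distance in map coordinates.
#' @export
center_distance <- function(geom_1, geom_2, name_1, name_2,
                            type = c("mean", "median")) {
  type <- match.arg(type)
  f <- paste0("center_", type)
  sqrt(sum((geom_1$categories[[name_1]][[f]] -
              geom_2$categories[[name_2]][[f]])^2))
}

#' Indirect-to-direct distance ratio of bilingual vs monolingual prototypes
#'
#' With `a` the distance between the two monolingual prototypes, `b` and
#' `c` the distances from each monolingual prototype to the corresponding
#' bilingual one, and `d` the distance between the bilingual prototypes,
#' returns `(b + c + d) / a`.  The ratio equals 1 exactly when the
#' bilingual prototypes lie on the segment between the monolingual ones,
#' and is always at least 1 by the triangle inequality.
#'
#' @param mono_a,mono_b,bi_a,bi_b Length-2 coordinate vectors of the four
#'   prototypes (monolingual A/B, bilingual A/B).
#' @return The distance ratio.
#' @export
indirect_direct_ratio <- function(mono_a, mono_b, bi_a, bi_b) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  a <- d(mono_a, mono_b)
  if (a == 0)
    stop(errorCondition("monolingual prototypes coincide (direct distance 0)",
                        class = c("bilexnet_degenerate", "bilexnet_error", "error")))
  (d(mono_a, bi_a) + d(mono_b, bi_b) + d(bi_a, bi_b)) / a
}

## Wilks lambda of a feature subset for a two-group discriminant problem
.wilks <- function(x, g1, g2, cols, ridge = 0) {
  xs <- x[, cols, drop = FALSE]
  m <- colMeans(xs)
  Tm <- crossprod(sweep(xs, 2L, m))
  W1 <- crossprod(sweep(xs[g1, , drop = FALSE], 2L, colMeans(xs[g1, , drop = FALSE])))
  W2 <- crossprod(sweep(xs[g2, , drop = FALSE], 2L, colMeans(xs[g2, , drop = FALSE])))
  Wm <- W1 + W2
  if (ridge > 0) {
    lam <- ridge * mean(diag(Tm))
    Tm <- Tm + diag(lam, ncol(Tm))
    Wm <- Wm + diag(lam, ncol(Wm))
  }
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  det(Wm) / dT
}

#' Stepwise discriminant analysis of category boundary complexity
#'
#' Forward-stepwise two-group linear discriminant feature selection with
#' Wilks-lambda partial-F entry and removal tests.  Features enter while
#' their F-to-enter p-value is at most `p_enter`, leave when their
#' F-to-remove p-value is at least `p_remove`, and selection also stops
#' when the canonical correlation changes by less than `cc_tol` between
#' steps.  The number of selected features (`n_dims`) indexes the
#' complexity of the boundary between the two categories.
#'
#' @param x Objects x features numeric matrix.
#' @param grouping Two-level factor (or vector) of category labels.
#' @param p_enter,p_remove Entry and removal significance thresholds.
#' @param cc_tol Canonical-correlation stability tolerance.
#' @param ridge Ridge factor applied to near-singular scatter matrices
#'   (recorded in the result when used).
#' @return An object of class `stepwise_dfa`: selected feature indices,
#'   `n_dims`, canonical correlation, Wilks lambda with its exact-F test,
#'   and a `separable` flag.
#' @export
stepwise_dfa <- function(x, grouping, p_enter = 0.05, p_remove = 0.10,
                         cc_tol = 0.01, ridge = 1e-8) {
  x <- as.matrix(x)
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2L)
    stop(errorCondition("exactly two categories are required",
                        class = c("bilexnet_bad_grouping", "bilexnet_error", "error")))
  if (any(table(grouping) < 2L))
    stop(errorCondition("each category needs at least 2 members",
                        class = c("bilexnet_bad_grouping", "bilexnet_error", "error")))
  g1 <- which(grouping == levels(grouping)[1L])
  g2 <- which(grouping == levels(grouping)[2L])
  n <- nrow(x); g <- 2L
  wilks <- function(cols) {
    l <- .wilks(x, g1, g2, cols)
    used_ridge <<- used_ridge || is.na(l)
    if (is.na(l)) l <- .wilks(x, g1, g2, cols, ridge = ridge)
    l
  }
  used_ridge <- FALSE
  sel <- integer(0)
  lambda <- 1
  cc <- 0
  repeat {
    if (length(sel) >= min(ncol(x), n - g - 1L)) break
    cand <- setdiff(seq_len(ncol(x)), sel)
    p <- length(sel)
    df2 <- n - g - p
    if (df2 <= 0) break
    lams <- vapply(cand, function(v) wilks(c(sel, v)), numeric(1))
    partial <- lams / lambda
    Fs <- df2 / (g - 1) * (1 - partial) / pmax(partial, .Machine$double.eps)
    pv <- stats::pf(Fs, g - 1, df2, lower.tail = FALSE)
    best <- which.min(pv)
    if (!is.finite(pv[best]) || pv[best] > p_enter) break
    sel <- c(sel, cand[best])
    entered <- cand[best]
    lambda <- lams[best]
    new_cc <- sqrt(max(0, 1 - lambda))
    ## backward pass: drop any feature that no longer earns its place
    repeat {
      if (length(sel) < 2L) break
      drop_cand <- setdiff(sel, entered)
      if (!length(drop_cand)) break
      p_full <- length(sel)
      df2r <- n - g - (p_full - 1L)
      lam_wo <- vapply(drop_cand, function(v) wilks(setdiff(sel, v)), numeric(1))
      partial_r <- lambda / lam_wo
      Fr <- df2r / (g - 1) * (1 - partial_r) / pmax(partial_r, .Machine$double.eps)
      pvr <- stats::pf(Fr, g - 1, df2r, lower.tail = FALSE)
      worst <- which.max(pvr)
      if (pvr[worst] < p_remove) break
      lambda <- lam_wo[worst]
      sel <- setdiff(sel, drop_cand[worst])
    }
    if (abs(new_cc - cc) < cc_tol) { cc <- new_cc; break }
    cc <- new_cc
  }
  p <- length(sel)
  if (p > 0) {
    Fstat <- (1 - lambda) / lambda * (n - p - 1) / p
    pval <- stats::pf(Fstat, p, n - p - 1, lower.tail = FALSE)
  } else { Fstat <- NA_real_; pval <- NA_real_ }
  structure(list(selected = sel, n_dims = p,
                 canonical_correlation = sqrt(max(0, 1 - lambda)),
                 wilks_lambda = lambda, statistic = Fstat, p.value = pval,
                 separable = p > 0, ridge_used = used_ridge,
                 groups = levels(grouping), n = n),
            class = "stepwise_dfa")
}

#' @export
print.stepwise_dfa <- function(x, ...) {
  cat(sprintf("Stepwise discriminant analysis: %s vs %s (n = %d)\n",
              x$groups[1], x$groups[2], x$n))
  if (x$separable)
    cat(sprintf("  %d feature(s) selected: %s\n  canonical correlation %.3f; Wilks lambda %.4f, F = %.2f, p = %.3g\n",
                x$n_dims, paste(x$selected, collapse = ", "),
                x$canonical_correlation, x$wilks_lambda, x$statistic, x$p.value))
  else cat("  no feature passed the entry test (non-separable)\n")
  invisible(x)
}

#' Proportion of boundary outliers per category
#'
#' The number of category members closer to another category's center than
#' to their own, divided by the number of members.  Categories with no
#' members give `NA`.
#'
#' @param geometry A [category_geometry()] result.
#' @return Named numeric vector of proportions.
#' @export
outlier_proportions <- function(geometry) {
  vapply(geometry$categories, function(c_) {
    if (!length(c_$members)) return(NA_real_)
    length(c_$outliers) / length(c_$members)
  }, numeric(1))
}
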