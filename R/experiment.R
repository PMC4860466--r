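#' Run the bilingual convergence experiment end to end
#'
#' For each replicate seed, trains four models on the same dataset — the
#' standard bilingual model, the two monolingual models, and a bilingual
#' model without lateral connections — and computes the convergence
#' statistics compared across the literature's conditions: the
#' Fisher-transformed cross-language correlation of name-distribution
#' similarity profiles (bilingual languages vs the paired monolingual
#' models, with the two-correlation Z statistic), the same correlation for
#' the no-lateral ablation, simulated naming accuracies, and the distances
#' between translation-pair category centers (boundary-dependent mean and
#' boundary-independent median centers) in the bilingual vs the
#' monolingual models.
#'
#' Translation pairs default to the dominant category names: the first
#' word of each language per category when the lexicon carries a
#' `category` column, otherwise the most frequent empirical names.
#'
#' @param data A [bilex_data()] dataset.
#' @param n_replicates Replicates (seeds `base_seed + 0:(n-1)`).
#' @param epochs Training epochs per model.
#' @param base_seed First replicate seed.
#' @param control A [bilex_control()]; scale `hebbian_start` /
#'   `reading_start` with `epochs`.
#' @param verbose Print per-replicate progress.
#' @return An object of class `bilex_experiment`: a list with
#'   `replicates` (one row of statistics per replicate), `summary`
#'   (ensemble means), and `logs` (per-replicate bilingual training logs).
#' @export
convergence_experiment <- function(data, n_replicates = 5L, epochs = 200L,
                                   base_seed = 1L,
                                   control = bilex_control(hebbian_start = 20L,
                                                           reading_start = 40L),
                                   verbose = FALSE) {
  lex <- data$lexicon
  if ("category" %in% names(lex)) {
    cats <- sort(unique(lex$category))
    pairs <- data.frame(
      a = vapply(cats, function(k) lex$word[lex$language == "A" & lex$category == k][1L],
                 character(1)),
      b = vapply(cats, function(k) lex$word[lex$language == "B" & lex$category == k][1L],
                 character(1)))
  } else {
    top <- function(l) {
      resp <- data$responses[data$responses$group == paste0("monolingual_", l), ]
      tot <- sort(tapply(resp$count, resp$name, sum), decreasing = TRUE)
      names(tot)[seq_len(min(3L, length(tot)))]
    }
    ta <- top("A"); tb <- top("B")
    n <- min(length(ta), length(tb))
    pairs <- data.frame(a = ta[seq_len(n)], b = tb[seq_len(n)])
  }

  prof <- function(model, lang)
    similarity_profile(simulated_distribution(model, lang))
  rows <- vector("list", n_replicates)
  logs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    seed <- base_seed + i - 1L
    if (verbose) message("replicate ", i, " (seed ", seed, ")")
    m_bi <- bilexnet(data, "bilingual", "none", epochs, seed, control)
    m_nl <- bilexnet(data, "bilingual", "no_lateral", epochs, seed, control)
    m_a <- bilexnet(data, "monolingual_A", "none", epochs, seed, control)
    m_b <- bilexnet(data, "monolingual_B", "none", epochs, seed, control)

    p_bi_a <- prof(m_bi, "A"); p_bi_b <- prof(m_bi, "B")
    p_nl_a <- prof(m_nl, "A"); p_nl_b <- prof(m_nl, "B")
    p_mo_a <- prof(m_a, "A");  p_mo_b <- prof(m_b, "B")
    ct_mono <- compare_correlations(p_bi_a, p_bi_b, p_mo_a, p_mo_b)
    ct_nolat <- compare_correlations(p_bi_a, p_bi_b, p_nl_a, p_nl_b)

    g_bi_a <- category_geometry(m_bi, "A", pairs$a)
    g_bi_b <- category_geometry(m_bi, "B", pairs$b)
    g_mo_a <- category_geometry(m_a, "A", pairs$a)
    g_mo_b <- category_geometry(m_b, "B", pairs$b)
    cd <- function(g1, g2, type) mean(vapply(seq_len(nrow(pairs)), function(k)
      center_distance(g1, g2, pairs$a[k], pairs$b[k], type), numeric(1)))
    ratio <- mean(vapply(seq_len(nrow(pairs)), function(k)
      indirect_direct_ratio(
        g_mo_a$categories[[pairs$a[k]]]$center_mean,
        g_mo_b$categories[[pairs$b[k]]]$center_mean,
        g_bi_a$categories[[pairs$a[k]]]$center_mean,
        g_bi_b$categories[[pairs$b[k]]]$center_mean), numeric(1)))

    rows[[i]] <- data.frame(
      seed = seed,
      r_bilingual = unname(ct_mono$estimate["r1"]),
      r_monolingual = unname(ct_mono$estimate["r2"]),
      r_no_lateral = unname(ct_nolat$estimate["r2"]),
      z_bilingual = fisher_z(unname(ct_mono$estimate["r1"])),
      z_monolingual = fisher_z(unname(ct_mono$estimate["r2"])),
      z_no_lateral = fisher_z(unname(ct_nolat$estimate["r2"])),
      Z_bi_vs_mono = unname(ct_mono$statistic),
      Z_bi_vs_nolat = unname(ct_nolat$statistic),
      accuracy_bi_A = naming_accuracy(m_bi, "A"),
      accuracy_bi_B = naming_accuracy(m_bi, "B"),
      center_mean_bi = cd(g_bi_a, g_bi_b, "mean"),
      center_mean_mono = cd(g_mo_a, g_mo_b, "mean"),
      center_median_bi = cd(g_bi_a, g_bi_b, "median"),
      center_median_mono = cd(g_mo_a, g_mo_b, "median"),
      distance_ratio = ratio)
    logs[[i]] <- m_bi$log
  }
  reps <- do.call(rbind, rows)
  out <- list(replicates = reps,
              summary = as.list(colMeans(reps[, -1, drop = FALSE])),
              pairs = pairs, logs = logs,
              epochs = epochs, n_replicates = n_replicates,
              base_seed = base_seed)
  class(out) <- "bilex_experiment"
  out
}

#' @export
print.bilex_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Bilingual convergence experiment: %d replicates x 4 conditions, %d epochs\n",
              x$n_replicates, x$epochs))
  cat(sprintf("  cross-language profile correlation: bilingual %.3f, monolingual %.3f, no-lateral %.3f\n",
              s$r_bilingual, s$r_monolingual, s$r_no_lateral))
  cat(sprintf("  Z (bilingual vs monolingual) %.2f; Z (bilingual vs no-lateral) %.2f\n",
              s$Z_bi_vs_mono, s$Z_bi_vs_nolat))
  cat(sprintf("  naming accuracy (bilingual): A %.1f%%, B %.1f%%\n",
              s$accuracy_bi_A, s$accuracy_bi_B))
  cat(sprintf("  translation-pair center distance (mean centers): bilingual %.2f vs monolingual %.2f\n",
              s$center_mean_bi, s$center_mean_mono))
  cat(sprintf("  translation-pair center distance (median centers): bilingual %.2f vs monolingual %.2f\n",
              s$center_median_bi, s$center_median_mono))
  cat(sprintf("  indirect/direct prototype distance ratio: %.2f\n", s$distance_ratio))
  invisible(x)
}
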