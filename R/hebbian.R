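#' Name-agreement-scaled Hebbian update of an associative matrix
#'
#' Increments every directed weight `w[k, l]` by `beta * source[k] *
#' target[l] * agreement`, then applies multiplicative normalisation per
#' outgoing weight vector: any row whose maximum exceeds 1 is rescaled so
#' its maximum is exactly 1.  This keeps every associative weight in
#' \[0, 1\] while preserving the relative strengths of a node's outgoing
#' connections.
#'
#' @param W Associative weight matrix (source nodes x target nodes),
#'   non-negative.
#' @param source,target Activation fields on the source and target maps,
#'   values in \[0, 1\] (see [gaussian_bump()]).
#' @param agreement Name agreement N in \[0, 1\] scaling the update; e.g.
#'   0.8125 for a name produced by 81.25% of a group's speakers.
#' @param beta Hebbian learning rate (constant 0.2 in the standard model).
#' @return The updated matrix.
#' @export
#' @examples
#' W <- matrix(0, 1, 1)
#' hebbian_update(W, 1, 1, agreement = 0.8125)  # 0.2 * 1 * 1 * 0.8125
hebbian_update <- function(W, source, target, agreement, beta = 0.2) {
  if (agreement < 0)
    stop(errorCondition("name agreement must be non-negative",
                        class = c("bilexnet_bad_agreement", "bilexnet_error", "error")))
  stopifnot(beta > 0, agreement <= 1)
  if (length(source) != nrow(W) || length(target) != ncol(W))
    stop(errorCondition("activation field lengths do not match matrix shape",
                        class = c("bilexnet_dim_mismatch", "bilexnet_error", "error")))
  W <- W + beta * agreement * outer(as.numeric(source), as.numeric(target))
  .cap_rows(W)
}

## multiplicative normalisation: rescale any outgoing vector whose max > 1
.cap_rows <- function(W) {
  mx <- apply(W, 1L, max)
  over <- which(mx > 1)
  if (length(over)) W[over, ] <- W[over, , drop = FALSE] / mx[over]
  W
}

#' Propagate an activation field through an associative matrix
#'
#' Target activation is the weighted sum `sum_k alpha_k w[k, l]`, clipped to
#' \[0, 1\].
#'
#' @param field Activation vector on the source map.
#' @param W Associative matrix (source nodes x target nodes).
#' @return Activation vector on the target map.
#' @export
propagate <- function(field, W) {
  if (length(field) != nrow(W))
    stop(errorCondition("activation field length does not match matrix",
                        class = c("bilexnet_dim_mismatch", "bilexnet_error", "error")))
  out <- as.numeric(as.numeric(field) %*% W)
  pmin(pmax(out, 0), 1)
}

#' Cross-language lateral connection matrix
#'
#' Directed Hebbian weights between phonological-map nodes belonging to
#' different languages.  Connections are stored sparsely between registered
#' word BMU nodes only; self-connections and within-language pairs stay
#' zero.
#'
#' @param nodes Integer node indices on the phonological map (word BMUs).
#' @param language Language tag ("A"/"B") per node.
#' @param n_map Number of nodes on the phonological map.
#' @return An object of class `lateral_matrix`.
#' @export
lateral_matrix <- function(nodes, language, n_map) {
  stopifnot(length(nodes) == length(language))
  language <- as.character(language)
  if (anyDuplicated(nodes))
    stop(errorCondition("a node cannot belong to both language node sets",
                        class = c("bilexnet_overlapping_nodes", "bilexnet_error", "error")))
  structure(list(nodes = as.integer(nodes), language = language,
                 n_map = as.integer(n_map),
                 weights = matrix(0, length(nodes), length(nodes))),
            class = "lateral_matrix")
}

#' Hebbian update of lateral connections from co-activated names
#'
#' For every cross-language node pair, both directed weights are
#' incremented by `beta * alpha_a * alpha_b` and then normalised as in
#' [hebbian_update()] (outgoing vectors capped at 1).  Within-language
#' pairs and self-connections are untouched.
#'
#' @param lateral A [lateral_matrix()].
#' @param field_a,field_b Activation vectors over the full phonological map;
#'   `field_a` must be zero off language A's node set and `field_b` zero off
#'   language B's.
#' @param beta Hebbian learning rate.
#' @return The updated `lateral_matrix`.
#' @export
lateral_update <- function(lateral, field_a, field_b, beta = 0.2) {
  a_idx <- which(lateral$language == "A")
  b_idx <- which(lateral$language == "B")
  if (any(field_a[lateral$nodes[b_idx]] != 0) ||
      any(field_b[lateral$nodes[a_idx]] != 0))
    stop(errorCondition("language fields overlap the other language's node set",
                        class = c("bilexnet_overlapping_nodes", "bilexnet_error", "error")))
  aa <- field_a[lateral$nodes[a_idx]]
  bb <- field_b[lateral$nodes[b_idx]]
  if (length(a_idx) && length(b_idx) && any(aa != 0) && any(bb != 0)) {
    inc <- beta * outer(aa, bb)
    lateral$weights[a_idx, b_idx] <- lateral$weights[a_idx, b_idx] + inc
    lateral$weights[b_idx, a_idx] <- lateral$weights[b_idx, a_idx] + t(inc)
    lateral$weights <- .cap_rows(lateral$weights)
  }
  lateral
}

#' Propagate activation across languages through lateral connections
#'
#' Reads the field at the source language's registered nodes, sends it
#' through the directed lateral weights, and returns the induced activation
#' (clipped to \[0, 1\]) on the full phonological map, supported on the
#' other language's registered nodes.
#'
#' @param lateral A [lateral_matrix()].
#' @param field Activation vector over the full phonological map.
#' @param from Source language tag ("A" or "B").
#' @return Activation vector of length `lateral$n_map`.
#' @export
lateral_propagate <- function(lateral, field, from = "A") {
  from_idx <- which(lateral$language == from)
  to_idx <- which(lateral$language != from)
  out <- numeric(lateral$n_map)
  if (length(from_idx) && length(to_idx)) {
    v <- as.numeric(field[lateral$nodes[from_idx]] %*%
                      lateral$weights[from_idx, to_idx, drop = FALSE])
    out[lateral$nodes[to_idx]] <- pmin(pmax(v, 0), 1)
  }
  out
}
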