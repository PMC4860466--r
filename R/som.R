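#' Create a self-organizing map grid
#'
#' A rectangular (non-wrapping) grid of `rows` x `cols` nodes, each holding a
#' weight vector of length `dim` initialised uniformly at random in \[0, 1\].
#' Node indices are row-major; grid distance between nodes is Euclidean on
#' their (row, col) coordinates.
#'
#' @param dim Input dimensionality (68, 81 and 297 for the semantic,
#'   phonological and orthographic maps at their defaults).
#' @param rows,cols Grid size; the model default is 30 x 40.
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class `som_grid`: a list with `rows`, `cols`, `dim`,
#'   `weights` (nodes x dim matrix) and `coords` (nodes x 2 matrix).
#' @export
som_grid <- function(dim, rows = 30L, cols = 40L, seed = NULL) {
  stopifnot(rows >= 1, cols >= 1, dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rows * cols
  g <- list(rows = as.integer(rows), cols = as.integer(cols),
            dim = as.integer(dim),
            weights = matrix(stats::runif(n * dim), nrow = n, ncol = dim),
            coords = grid_coords(rows, cols))
  class(g) <- "som_grid"
  g
}

#' Row-major (row, col) coordinates of every node of a grid
#' @param rows,cols Grid size.
#' @return A (rows*cols) x 2 integer matrix.
#' @export
grid_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("SOM grid: %d x %d nodes, input dimension %d\n",
              x$rows, x$cols, x$dim))
  invisible(x)
}

#' Best-matching unit of an input vector
#'
#' Returns the index (row-major, 1-based) of the node whose weight vector is
#' closest to `x` in Euclidean distance; ties go to the lowest index.
#'
#' @param grid A [som_grid()].
#' @param x Input vector of length `grid$dim`.
#' @return Integer node index.
#' @export
find_bmu <- function(grid, x) {
  if (length(x) != grid$dim)
    stop(errorCondition(sprintf("input length %d does not match map dimension %d",
                                length(x), grid$dim),
                        class = c("bilexnet_dim_mismatch", "bilexnet_error", "error")))
  cpp_bmu(grid$weights, as.numeric(x)) + 1L
}

## squared grid distance from node `node` to all nodes
.grid_dist2 <- function(grid, node) {
  (grid$coords[, 1L] - grid$coords[node, 1L])^2 +
    (grid$coords[, 2L] - grid$coords[node, 2L])^2
}

## nodes within `radius` of `node` and their truncated-Gaussian kernel values
.neighbourhood <- function(grid, node, radius) {
  d2 <- .grid_dist2(grid, node)
  nodes <- which(d2 <= radius^2 + 1e-9)
  sigma <- max(radius, 1)
  list(nodes = nodes, g = exp(-d2[nodes] / (2 * sigma^2)))
}

#' One neighbourhood update of a map toward an input
#'
#' Every node within grid distance `radius` of the best-matching unit moves
#' toward `x` by `lr * exp(-d^2 / (2 sigma^2))` with `sigma = radius`
#' (`sigma = 1` when `radius = 0`); nodes beyond the radius are unchanged.
#'
#' @param grid A [som_grid()].
#' @param x Input vector.
#' @param bmu Node index of the best-matching unit (see [find_bmu()]).
#' @param lr Learning rate in (0, 1\].
#' @param radius Neighbourhood radius (non-negative).
#' @return The updated grid.
#' @export
som_update <- function(grid, x, bmu = find_bmu(grid, x), lr, radius) {
  stopifnot(lr >= 0, lr <= 1, radius >= 0)
  if (length(x) != grid$dim)
    stop(errorCondition("input length does not match map dimension",
                        class = c("bilexnet_dim_mismatch", "bilexnet_error", "error")))
  nb <- .neighbourhood(grid, bmu, radius)
  grid$weights <- grid$weights + 0  # copy: leave the caller's grid untouched
  cpp_som_update(grid$weights, as.numeric(x), nb$nodes - 1L, nb$g, lr)
  grid
}

#' Mean quantization error of a map over a stimulus set
#'
#' The quantization error is the mean, over stimuli, of the Euclidean
#' distance in input space between a stimulus and the weight vector of its
#' best-matching unit.
#'
#' @param grid A [som_grid()].
#' @param X A stimulus matrix (rows = stimuli) or a single vector.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(grid, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L)
    stop(errorCondition("empty stimulus set",
                        class = c("bilexnet_empty_input", "bilexnet_error", "error")))
  if (ncol(X) != grid$dim)
    stop(errorCondition("stimulus dimension does not match map dimension",
                        class = c("bilexnet_dim_mismatch", "bilexnet_error", "error")))
  mean(cpp_bmus(grid$weights, as.matrix(X))$dist)
}

#' Linearly annealed SOM learning rate
#'
#' The learning rate decreases linearly from `start` to `end` over the first
#' `anneal` epochs and stays at `end` afterwards (defaults: 0.2 to 0.1 over
#' 100 epochs).
#'
#' @param epoch Epoch number (0-based; `learning_rate(0)` is `start`).
#' @param start,end,anneal Schedule parameters.
#' @return Learning rate.
#' @export
learning_rate <- function(epoch, start = 0.2, end = 0.1, anneal = 100) {
  start - (start - end) * pmin(epoch, anneal) / anneal
}

#' Self-adjusting neighbourhood radius rule
#'
#' Every `check_interval` epochs the mean quantization error of the last
#' `check_interval` epochs is compared to the mean of the preceding
#' `check_interval`: if it remains within 25% of the previous mean, the
#' radius decreases by 1 (never below `floor`).
#'
#' @param state A list with elements `radius`, `qe_history` (per-epoch mean
#'   quantization errors, most recent last), and optionally `check_interval`
#'   (default 5) and `floor` (default 1).
#' @param band Relative band within which errors count as "similar" (0.25).
#' @return The state with `radius` possibly decremented.
#' @export
adapt_radius <- function(state, band = 0.25) {
  ci <- state$check_interval %||% 5L
  floor_ <- state$floor %||% 1L
  h <- state$qe_history
  if (length(h) < 2L * ci || length(h) %% ci != 0L)
    stop(errorCondition(
      sprintf("radius rule needs a multiple of %d epochs and at least %d of history", ci, 2L * ci),
      class = c("bilexnet_insufficient_history", "bilexnet_error", "error")))
  cur <- mean(h[(length(h) - ci + 1L):length(h)])
  prev <- mean(h[(length(h) - 2L * ci + 1L):(length(h) - ci)])
  if (state$radius > floor_ && abs(cur - prev) <= band * prev)
    state$radius <- state$radius - 1L
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian activation bump centred on a node
#'
#' Activation field used for Hebbian training and testing: nodes within
#' `radius` of `center` carry `exp(-d^2 / (2 sigma^2))` with `sigma =
#' max(radius, 1)`; all other nodes are zero, and the centre is 1.
#'
#' @param grid A [som_grid()].
#' @param center Node index.
#' @param radius Bump radius.
#' @return Numeric activation vector over all nodes, values in \[0, 1\].
#' @export
gaussian_bump <- function(grid, center, radius) {
  act <- numeric(grid$rows * grid$cols)
  nb <- .neighbourhood(grid, center, radius)
  act[nb$nodes] <- nb$g
  act
}
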