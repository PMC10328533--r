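# Mass-univariate channel statistics: paired t maps, threshold-free
# cluster enhancement (TFCE), sign-flip max-statistic permutation
# correction, Gaussian channel-map smoothing, and TRF weight power.

#' Grid adjacency for synthetic channel layouts
#'
#' Builds the 4-neighbour adjacency of an `nx` by `ny` channel grid
#' with unit spacing, the stand-in for anatomical source adjacency in
#' simulations.
#'
#' @param nx,ny Grid dimensions.
#' @return List with `adjacency` (symmetric logical matrix, no
#'   self-loops) and `coords` (channels x 2 matrix).
#' @export
grid_adjacency <- function(nx, ny) {
  stopifnot(nx >= 1L, ny >= 1L)
  coords <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  adj <- d > 0 & d < 1.5
  dimnames(adj) <- NULL
  list(adjacency = adj, coords = coords)
}

adjacency_edges <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!isSymmetric(adjacency * 1))
    stop_speechTRF("adjacency must be symmetric", "bad_adjacency")
  if (any(diag(adjacency) != 0))
    stop_speechTRF("adjacency must have no self-loops", "bad_adjacency")
  idx <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
  list(from = idx[, 1L] - 1L, to = idx[, 2L] - 1L)
}

# Edges over a channels x time lattice: spatial edges within each time
# point plus temporal edges between consecutive time points.
spacetime_edges <- function(adjacency, n_ch, n_time) {
  sp <- adjacency_edges(adjacency)
  from <- to <- integer(0)
  for (t in seq_len(n_time) - 1L) {
    from <- c(from, sp$from + t * n_ch)
    to <- c(to, sp$to + t * n_ch)
  }
  if (n_time > 1L) {
    node <- seq_len(n_ch * (n_time - 1L)) - 1L
    from <- c(from, node)
    to <- c(to, node + n_ch)
  }
  list(from = from, to = to)
}

#' Mass-univariate paired t map
#'
#' Per-channel paired (related-samples) t statistic between two matched
#' sets of channel maps, with `n - 1` degrees of freedom. A channel
#' whose paired differences are constant and nonzero has no finite t
#' and is an error; all-zero differences give t = 0.
#'
#' @param a,b Subjects x channels matrices (or subjects x channels x
#'   time arrays) with matched rows.
#' @return Vector (or channels x time matrix) of t statistics.
#' @export
paired_t_map <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  d <- a - b
  if (length(dim(d)) == 3L) {
    dims <- dim(d)
    dm <- matrix(d, nrow = dims[1L])
    t_flat <- paired_t_map(dm, matrix(0, dims[1L], ncol(dm)))
    return(matrix(t_flat, dims[2L], dims[3L]))
  }
  n <- nrow(d)
  if (n < 2L)
    stop_speechTRF("need at least 2 matched replicates", "too_few")
  m <- colMeans(d)
  s <- apply(d, 2L, sd)
  t_stat <- numeric(length(m))
  zero_var <- s == 0
  if (any(zero_var & m != 0))
    stop_speechTRF("constant nonzero paired difference (infinite t)",
                   "degenerate_t")
  ok <- !zero_var
  t_stat[ok] <- m[ok] / (s[ok] / sqrt(n))
  t_stat
}

#' Threshold-free cluster enhancement
#'
#' Integrates, over thresholds `h` in steps of `dh`, the quantity
#' `extent(h)^E * h^H * dh` for every channel, where `extent(h)` is the
#' size of the connected suprathreshold component containing the
#' channel. Negative map values are processed symmetrically on the
#' negated map and subtracted, so the output is signed. `values` may be
#' a vector (space-only) or a channels x time matrix, in which case
#' clusters extend over space and time.
#'
#' @param values Finite statistic map: vector of channel values or a
#'   channels x time matrix.
#' @param adjacency Symmetric channel adjacency matrix without
#'   self-loops.
#' @param E Extent exponent (default 0.5).
#' @param H Height exponent (default 2).
#' @param dh Threshold step; default `max(abs(values)) / n_steps`.
#' @param n_steps Number of integration steps when `dh` is `NULL`
#'   (default 100).
#' @return Enhanced map with the shape of `values`.
#' @export
tfce <- function(values, adjacency, E = 0.5, H = 2, dh = NULL,
                 n_steps = 100L) {
  if (any(!is.finite(values)))
    stop_speechTRF("statistic map must be finite", "nonfinite_input")
  is_mat <- is.matrix(values)
  if (is_mat) {
    edges <- spacetime_edges(adjacency, nrow(values), ncol(values))
  } else {
    if (length(values) != nrow(adjacency))
      stop_speechTRF("map length does not match adjacency",
                     "bad_adjacency")
    edges <- adjacency_edges(adjacency)
  }
  v <- as.vector(values)
  vmax <- max(abs(v))
  if (vmax == 0) return(values * 0)
  dh <- dh %||% (vmax / n_steps)
  pos <- tfce_pos_cpp(pmax(v, 0), edges$from, edges$to, E, H, dh)
  neg <- tfce_pos_cpp(pmax(-v, 0), edges$from, edges$to, E, H, dh)
  out <- pos - neg
  if (is_mat) matrix(out, nrow(values), ncol(values)) else out
}

#' Sign-flip cluster permutation test with TFCE correction
#'
#' Tests a paired contrast across channels (and optionally time) by
#' building the null from random sign flips of each subject's
#' difference map. The observed paired t map is TFCE-enhanced; each
#' permutation's maximum absolute TFCE value forms the max-statistic
#' null distribution, and every channel's two-tailed corrected p-value
#' is the fraction of permutations (plus the observed map) whose
#' maximum reaches its absolute TFCE score.
#'
#' @param a,b Subjects x channels matrices (or subjects x channels x
#'   time arrays), matched by row.
#' @param adjacency Channel adjacency matrix.
#' @param n_perm Number of sign-flip permutations (default 1000; the
#'   reference analysis scale is 8000).
#' @param seed Integer seed making the permutation draw reproducible.
#' @param E,H,n_steps TFCE parameters (see [tfce()]).
#' @return List with `t_map`, `tfce_map`, `p` (corrected p-values,
#'   shape of the map), `perm_max` (null distribution), `n_perm`.
#' @export
cluster_permutation <- function(a, b, adjacency, n_perm = 1000L,
                                seed = 1L, E = 0.5, H = 2,
                                n_steps = 100L) {
  stopifnot(identical(dim(a), dim(b)))
  n_sub <- dim(a)[1L]
  if (n_sub < 2L)
    stop_speechTRF("need at least 2 subjects", "too_few")
  d <- a - b
  t_obs <- paired_t_map(a, b)
  dh <- max(abs(t_obs)) / n_steps
  if (dh == 0) dh <- NULL
  tfce_obs <- tfce(t_obs, adjacency, E = E, H = H, dh = dh,
                   n_steps = n_steps)
  flat_dim <- if (is.matrix(t_obs)) dim(t_obs) else length(t_obs)
  zeros_like <- if (is.matrix(t_obs))
    array(0, c(n_sub, dim(t_obs))) else matrix(0, n_sub, length(t_obs))
  set.seed(seed)
  perm_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n_sub, replace = TRUE)
    dp <- d * signs  # recycles over the subject (first) dimension
    t_p <- paired_t_map(dp, zeros_like)
    tf <- tfce(t_p, adjacency, E = E, H = H, dh = dh,
               n_steps = n_steps)
    perm_max[p] <- max(abs(tf))
  }
  obs_abs <- abs(as.vector(tfce_obs))
  p_val <- vapply(obs_abs, function(x)
    (1 + sum(perm_max >= x)) / (n_perm + 1), numeric(1))
  p_out <- if (is.matrix(t_obs)) matrix(p_val, flat_dim[1L], flat_dim[2L])
  else p_val
  list(t_map = t_obs, tfce_map = tfce_obs, p = p_out,
       perm_max = perm_max, n_perm = n_perm)
}

#' Gaussian smoothing of a channel map
#'
#' Replaces each channel's value by a Gaussian-weighted average of all
#' channels, with weights `exp(-dist^2 / (2 sd^2))` normalized to sum
#' to one per channel. `sd = 0` returns the map unchanged; a constant
#' map is always unchanged.
#'
#' @param values Channel vector or channels x time matrix.
#' @param coords Channels x k coordinate matrix.
#' @param sd Gaussian standard deviation in coordinate units.
#' @return Smoothed map, same shape.
#' @export
smooth_map <- function(values, coords, sd) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(v) != nrow(coords))
    stop_speechTRF("coordinates do not match channels", "bad_coords")
  stopifnot(sd >= 0)
  if (sd == 0) return(values)
  w <- exp(-as.matrix(dist(coords))^2 / (2 * sd^2))
  w <- w / rowSums(w)
  out <- w %*% v
  if (is.matrix(values)) out else as.vector(out)
}

#' Power of TRF weights
#'
#' Element-wise squared kernel coefficients, the nonnegative summary
#' used for condition contrasts of TRF time courses; invariant to sign
#' flips of the kernel.
#'
#' @param kernel A [trf_kernel()] or a numeric matrix/array of
#'   coefficients.
#' @return Object of the same shape with squared values.
#' @export
weight_power <- function(kernel) {
  if (inherits(kernel, "trf_kernel")) return(kernel$beta^2)
  kernel^2
}
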