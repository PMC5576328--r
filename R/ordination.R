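#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: double-centre -0.5 * D^2, eigendecompose, and
#' scale eigenvectors by the square roots of the positive eigenvalues. All
#' eigenvalues (including negative ones) are reported; coordinates are built
#' from positive axes only, and no negative-eigenvalue correction is applied.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @return list of class `mb_pcoa` with `sample_ids`, `coordinates`
#'   (samples x positive axes, decreasing eigenvalue order), `eigenvalues`,
#'   and `proportion_explained` (per positive axis, relative to the positive
#'   eigenvalue mass).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 samples for ordination")
  ids <- rownames(dm) %||% paste0("s", seq_len(n))
  # double-centring: B = (I - 11'/n) (-D^2/2) (I - 11'/n)
  a <- -0.5 * dm^2
  b <- sweep(a, 1L, rowMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  rownames(coords) <- ids
  if (ncol(coords)) colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(sample_ids = ids,
                 coordinates = coords,
                 eigenvalues = eig$values,
                 proportion_explained = if (any(pos))
                   eig$values[pos] / sum(eig$values[pos]) else numeric(0)),
            class = "mb_pcoa")
}

# Take the first `axes` columns of an ordination, zero-padding when fewer
# positive axes exist.
ordination_axes <- function(ord, axes = 3L) {
  co <- ord$coordinates
  n <- length(ord$sample_ids)
  out <- matrix(0, n, axes, dimnames = list(ord$sample_ids, paste0("PC", seq_len(axes))))
  k <- min(axes, ncol(co))
  if (k > 0) out[, seq_len(k)] <- co[, seq_len(k)]
  out
}

#' Procrustes M-squared between two configurations
#'
#' Centres both configurations, scales each to unit sum of squares, and
#' applies the optimal rotation/reflection and dilation of the second onto
#' the first; the returned M^2 is the minimised residual sum of squares,
#' 0 for identical shapes and at most 1 under the unit-norm convention.
#'
#' @param config_a,config_b numeric matrices with matching rows (same
#'   samples), e.g. principal coordinates 1-3.
#' @param axes number of columns used (configurations are trimmed or
#'   zero-padded to this width).
#' @return M^2 in `[0, 1]`.
#' @export
procrustes_m2 <- function(config_a, config_b, axes = ncol(config_a)) {
  pad <- function(m) {
    m <- as.matrix(m)
    out <- matrix(0, nrow(m), axes)
    k <- min(axes, ncol(m))
    out[, seq_len(k)] <- m[, seq_len(k)]
    out
  }
  x <- pad(config_a); y <- pad(config_b)
  if (nrow(x) != nrow(y)) stop("configurations must have the same rows")
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  ssx <- sum(x^2); ssy <- sum(y^2)
  if (ssx == 0 || ssy == 0) stop("degenerate configuration: all points coincide")
  x <- x / sqrt(ssx); y <- y / sqrt(ssy)
  sv <- svd(crossprod(x, y))
  m2 <- 1 - sum(sv$d)^2
  min(max(m2, 0), 1)
}

#' Monte-Carlo Procrustes comparison of two paired ordinations
#'
#' Ordinates each distance matrix (rows matched by pair: one matrix per
#' sampling method), computes M^2 on the leading axes, and assesses it
#' against a null in which the pair correspondence of the second
#' configuration is shuffled; p = (1 + #\{M^2_perm <= M^2_obs\}) / (1 + n_perm).
#'
#' @param dm_a,dm_b distance matrices over the same pairs, rows matched.
#' @param axes number of principal coordinates used (default 3).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `m_squared`, `p_monte_carlo`, `n_perm`, `axes_used`.
#' @export
procrustes_monte_carlo <- function(dm_a, dm_b, axes = 3L, n_perm = 1000,
                                   seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (nrow(as.matrix(dm_a)) != nrow(as.matrix(dm_b)))
    stop("distance matrices must cover the same paired sample set")
  xa <- ordination_axes(pcoa(dm_a), axes)
  xb <- ordination_axes(pcoa(dm_b), axes)
  obs <- procrustes_m2(xa, xb, axes = axes)
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (procrustes_m2(xa, xb[sample.int(nrow(xb)), , drop = FALSE],
                        axes = axes) <= obs + 1e-12)
        hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(m_squared = obs, p_monte_carlo = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, axes_used = axes)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all n(n-1)/2 distances (average ranks for ties) and computes
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2; the p-value permutes group labels, using the add-one
#' estimator.
#'
#' @param dm symmetric distance matrix.
#' @param groups group labels, named by sample id or aligned with the
#'   matrix rows; every group needs >= 2 samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = NULL) {
  dm <- as.matrix(dm)
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  if (length(groups) != nrow(dm) || anyNA(groups))
    stop("every sample needs a group label")
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  n <- nrow(dm)
  lower <- which(lower.tri(dm))
  r <- rank(dm[lower])
  m <- length(lower)
  row_i <- row(dm)[lower]; col_j <- col(dm)[lower]
  stat <- function(g) {
    between <- g[row_i] != g[col_j]
    (mean(r[between]) - mean(r[!between])) / (m / 2)
  }
  r_obs <- stat(groups)
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (stat(groups[sample.int(n)]) >= r_obs - 1e-12) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(R = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
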