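#' Principal-coordinates starting configuration
#'
#' Classical multidimensional scaling of a distance matrix: double-centre
#' `-D^2/2` and scale the two leading eigenvectors by the square roots of
#' their eigenvalues (via [stats::cmdscale()]).  Axis signs are fixed so
#' that the coordinate with the largest absolute value on each axis is
#' positive, making the result fully deterministic.
#'
#' @param m symmetric distance matrix with zero diagonal and finite
#'   entries.
#' @return an n x 2 coordinate matrix, rownames from `m`.
#' @export
pcoa_start <- function(m) {
  if (!isSymmetric(unname(as.matrix(m)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(m))) stop("distance matrix must be finite")
  xy <- stats::cmdscale(stats::as.dist(m), k = min(2, nrow(m) - 1))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)[, 1:2, drop = FALSE]  # degenerate 1D
  for (k in 1:2) {
    j <- which.max(abs(xy[, k]))
    if (length(j) && xy[j, k] < 0) xy[, k] <- -xy[, k]
  }
  rownames(xy) <- rownames(m)
  xy
}

# correlation from precomputed sums over np pairs
.cor_from_sums <- function(np, sx, sxx, sy, syy, sxy) {
  num <- np * sxy - sx * sy
  den <- sqrt(np * sxx - sx^2) * sqrt(np * syy - sy^2)
  if (den <= 0) return(NA_real_)
  num / den
}

#' Great-deluge refinement of a 2D configuration
#'
#' Maximizes the Pearson correlation between the condensed input distances
#' and the condensed Euclidean distances of a 2D configuration.  One
#' uniformly chosen individual is perturbed per iteration by centred
#' Gaussian noise; a move is accepted iff the new objective is at least
#' the current water level, which starts at the initial objective and
#' rises by `rain_speed * (best - level)` after every acceptance.  The
#' step size is halved after `patience` consecutive rejections.  Stops at
#' `max_iter` iterations or when the level is within `1e-9` of the best
#' objective; the best-ever configuration is returned.
#'
#' @param m symmetric distance matrix.
#' @param start starting coordinates (default [pcoa_start()]).
#' @param step_sigma proposal s.d.; default 10% of the coordinate spread.
#' @param rain_speed water-level rise factor per acceptance.
#' @param max_iter iteration budget.
#' @param patience consecutive rejections before the step is halved.
#' @param seed RNG seed (local to this call).
#' @return list of class `embedding2d`: `coords`, `start_cor`,
#'   `final_cor`, `iterations`, `seed`.
#' @export
great_deluge <- function(m, start = pcoa_start(m), step_sigma = NULL,
                         rain_speed = 0.02, max_iter = 2e5, patience = 500,
                         seed = 1L) {
  if (max_iter < 1) stop("max_iter must be at least 1")
  n <- nrow(m)
  if (n < 3) stop("at least three individuals required")
  x <- as.vector(stats::as.dist(m))   # same pair order as dist(coords)
  if (stats::sd(x) == 0) stop("input distances are constant; objective undefined")
  coords <- as.matrix(start)
  if (is.null(step_sigma))
    step_sigma <- 0.1 * max(apply(coords, 2, function(v) diff(range(v))), 1e-8)

  # condensed-vector index map matching dist() ordering (lower triangle,
  # column-major)
  pair_index <- matrix(0L, n, n)
  pair_index[lower.tri(pair_index)] <- seq_len(n * (n - 1) / 2)
  pair_index <- pair_index + t(pair_index)
  idx_of <- lapply(seq_len(n), function(i) pair_index[i, -i])
  others <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))

  y <- as.vector(stats::dist(coords))
  np <- length(x)
  sx <- sum(x); sxx <- sum(x^2)
  sy <- sum(y); syy <- sum(y^2); sxy <- sum(x * y)
  obj <- .cor_from_sums(np, sx, sxx, sy, syy, sxy)
  start_cor <- obj
  best <- obj
  best_coords <- coords
  level <- obj
  rejections <- 0L
  accepted <- 0L
  iter <- 0L

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  while (iter < max_iter) {
    if (accepted > 0L && level >= best - 1e-9) break
    if (step_sigma < 1e-14) break                 # proposals have collapsed
    iter <- iter + 1L
    i <- sample.int(n, 1)
    prop <- coords[i, ] + stats::rnorm(2, sd = step_sigma)
    oth <- others[[i]]
    d_new <- sqrt((coords[oth, 1] - prop[1])^2 + (coords[oth, 2] - prop[2])^2)
    pos <- idx_of[[i]]
    d_old <- y[pos]
    sy2 <- sy + sum(d_new) - sum(d_old)
    syy2 <- syy + sum(d_new^2) - sum(d_old^2)
    sxy2 <- sxy + sum(x[pos] * (d_new - d_old))
    obj_new <- .cor_from_sums(np, sx, sxx, sy2, syy2, sxy2)
    if (!is.na(obj_new) && obj_new >= level) {
      coords[i, ] <- prop
      y[pos] <- d_new
      sy <- sy2; syy <- syy2; sxy <- sxy2
      obj <- obj_new
      if (obj > best) {
        best <- obj
        best_coords <- coords
      }
      level <- level + rain_speed * (best - level)
      rejections <- 0L
      accepted <- accepted + 1L
    } else {
      rejections <- rejections + 1L
      if (rejections >= patience) {
        step_sigma <- step_sigma / 2
        rejections <- 0L
      }
    }
  }
  structure(list(coords = best_coords, start_cor = start_cor,
                 final_cor = best, iterations = iter, seed = seed),
            class = "embedding2d")
}
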