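# Circular pseudo-time reconstruction from snapshot tables: feature
# transform, Gaussian-mixture clustering, exact shortest circular tour
# through the cluster means, within-cluster ordering by chord
# projection, rank-to-time conversion via the asynchronous age density,
# and local-level Kalman smoothing of the resulting pseudo-time courses.

#' Variance-stabilising feature transform
#'
#' Each feature is rescaled to a mean of 1e4 and then transformed as
#' `log2(value + 1)`: \eqn{\tilde v = \log_2(10^4\, v / \bar v + 1)}.
#' The mean-rescaling makes the transform invariant to the (arbitrary)
#' scale of fluorescence units.
#'
#' @param table snapshot data frame (see [make_snapshot()]) or a plain
#'   cells x features data frame / matrix
#' @return the table with feature columns transformed
#' @export
transform_features <- function(table) {
  feats <- if (is.data.frame(table)) snapshot_features(table) else colnames(table)
  for (f in feats) {
    v <- table[, f]
    if (any(!is.finite(v)) || any(v < 0))
      stop("feature '", f, "' must be finite and non-negative")
    m <- mean(v)
    if (m == 0) stop("feature '", f, "' is identically zero")
    table[, f] <- log2(1e4 * v / m + 1)
  }
  table
}

# Exact shortest circular tour through k points: enumerate the (k-1)!/2
# distinct tours (first point fixed, orientation identified).
shortest_circular_tour <- function(centers) {
  k <- nrow(centers)
  if (k > 10) stop("exact tour enumeration supported for k <= 10")
  D <- as.matrix(stats::dist(centers))
  if (k <= 3) return(list(tour = seq_len(k), length = sum(D[cbind(seq_len(k), c(2:k, 1))])))
  perms <- permutations_of(2:k)
  best <- NULL; best_len <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    if (p[1] > p[length(p)]) next   # orientation dedup
    tour <- c(1L, p)
    len <- sum(D[cbind(tour, c(tour[-1], tour[1]))])
    if (len < best_len) { best_len <- len; best <- tour }
  }
  list(tour = best, length = best_len)
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out[[i]] <- cbind(x[i], rest)
  }
  do.call(rbind, out)
}

tour_length <- function(centers, tour) {
  D <- as.matrix(stats::dist(centers))
  sum(D[cbind(tour, c(tour[-1], tour[1]))])
}

#' Reconstruct the circular cell-cycle ordering of a snapshot
#'
#' The transformed features are clustered with a `k`-component Gaussian
#' mixture ([mclust::Mclust]); the shortest circular tour through the
#' cluster means is found exactly by enumeration; cells are ordered
#' within each cluster by their distance difference to the flanking
#' cluster means along the tour (ties broken by cell index), then the
#' whole order is polished by projecting onto a smoothed closed
#' reference curve.  The resulting order is circular: orientation and
#' start are resolved separately by [orient_cycle()].
#'
#' @param table snapshot data frame
#' @param k_clusters number of mixture components (<= 10; default 8)
#' @param seed RNG seed for the mixture fit
#' @param features optional subset of feature columns to use
#' @param transform apply [transform_features()] first (default TRUE)
#' @param n_pcs project the transformed features onto this many
#'   principal components before clustering and curve fitting (NULL
#'   disables); averages feature noise out of the curve geometry
#' @param restarts number of independent mixture fits ordered and
#'   compared (shortest closed path through all cells wins)
#' @param refine iterations of principal-closed-curve refinement: cells
#'   are positioned by arc-length projection onto the tour polyline and
#'   the reference cycle is re-estimated by circular moving averages
#'   (0 keeps the raw cluster/chord order)
#' @return a `ccOrder` object: `order` (row indices of `table` in
#'   circular order), `clusters`, `tour`, plus the inputs needed for
#'   orientation
#' @export
reconstruct_order <- function(table, k_clusters = 8, seed = 1,
                              features = NULL, transform = TRUE,
                              refine = 3, n_pcs = 8, restarts = 5) {
  feats <- snapshot_features(table)
  if (!is.null(features)) {
    missing <- setdiff(features, feats)
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
    feats <- features
  }
  if (nrow(table) < k_clusters) stop("need at least k_clusters cells")
  if (length(feats) < 2) stop("need at least 2 features")
  tab <- table
  if (transform) tab <- transform_features(tab)
  X <- as.matrix(tab[, feats, drop = FALSE])
  if (!is.null(n_pcs) && ncol(X) > n_pcs) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_pcs, ncol(pc$x)))
    X <- pc$x[, keep, drop = FALSE]
  }

  # Mclust() resolves mclustBIC in the calling frame; alias it locally
  mclustBIC <- mclust::mclustBIC
  # mixture fits on a closed 1-D curve are seed-sensitive (a component
  # can straddle disjoint arcs, which no tour can repair), so several
  # restarts are ordered independently and the candidate whose final
  # ordering has the shortest closed path through all cells wins
  best <- NULL
  best_len <- Inf
  n_valid <- 0
  for (attempt in seq_len(10)) {
    fit <- withCallingHandlers(
      tryCatch(withr_seed(seed + attempt - 1, {
        # the default hierarchical initialisation is deterministic, so
        # restarts are made distinct through random-subset initialisation
        init <- if (attempt == 1) NULL else
          list(subset = sample(nrow(X), max(k_clusters * 10,
                                            round(nrow(X) / 2))))
        mclust::Mclust(X, G = k_clusters,
                       modelNames = c("EII", "VII", "EEI", "VVI", "VVV"),
                       initialization = init, verbose = FALSE)
      }),
      error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit) || length(unique(fit$classification)) < k_clusters)
      next
    n_valid <- n_valid + 1
    cand <- order_cells(X, fit$classification, k_clusters, refine)
    Xo <- X[cand$order, , drop = FALSE]
    len <- sum(sqrt(rowSums((Xo - Xo[c(2:nrow(Xo), 1), ])^2)))
    if (len < best_len) {
      best_len <- len
      best <- c(cand, list(clusters = fit$classification))
    }
    if (n_valid >= restarts) break
  }
  if (is.null(best))
    stop("Gaussian mixture fit degenerate after 10 attempts")
  structure(list(order = best$order, clusters = best$clusters,
                 tour = best$tour, centers = best$centers,
                 features = feats, path_length = best_len,
                 n = nrow(table)),
            class = "ccOrder")
}

# Complete circular ordering for one clustering: exact tour through the
# cluster means, within-cluster ordering by the distance difference to
# the flanking means (monotone along the local arc even where it bends
# sharply, e.g. across division), then coarse-to-fine refinement by
# projection onto a smoothed closed reference curve.
order_cells <- function(X, cl, k, refine) {
  centers <- t(vapply(seq_len(k),
                      function(g) colMeans(X[cl == g, , drop = FALSE]),
                      numeric(ncol(X))))
  tour <- shortest_circular_tour(centers)$tour
  order_idx <- integer(0)
  for (pos in seq_len(k)) {
    g <- tour[pos]
    prev <- centers[tour[if (pos == 1) k else pos - 1], ]
    nxt <- centers[tour[if (pos == k) 1 else pos + 1], ]
    idx <- which(cl == g)
    Xi <- X[idx, , drop = FALSE]
    d_prev <- sqrt(rowSums(sweep(Xi, 2, prev)^2))
    d_next <- sqrt(rowSums(sweep(Xi, 2, nxt)^2))
    order_idx <- c(order_idx, idx[order(d_prev - d_next, idx)])
  }
  if (refine > 0) {
    schedule <- c(2L, 4L, rep(6L, max(0L, refine - 2L)))[seq_len(refine)]
    for (per_cluster in schedule) {
      nodes <- smoothed_cycle_nodes(X[order_idx, , drop = FALSE],
                                    m = per_cluster * k)
      pos <- polyline_positions(X, nodes)
      order_idx <- order(pos, seq_len(nrow(X)))
    }
  }
  list(order = order_idx, tour = tour, centers = centers)
}

# Arc-length position of each row of X on the closed polyline through
# `nodes` (rows).  Returns a numeric position in [0, total length).
polyline_positions <- function(X, nodes) {
  m <- nrow(nodes)
  nxt <- rbind(nodes[-1, , drop = FALSE], nodes[1, , drop = FALSE])
  seg <- nxt - nodes
  seg_len <- sqrt(rowSums(seg^2))
  arc0 <- cumsum(c(0, seg_len[-m]))
  n <- nrow(X)
  best_d <- rep(Inf, n); best_pos <- numeric(n)
  for (s in seq_len(m)) {
    if (seg_len[s] < 1e-12) next
    a <- nodes[s, ]; v <- seg[s, ]
    t <- (X %*% v - sum(a * v)) / sum(v * v)
    t <- pmin(pmax(as.vector(t), 0), 1)
    proj <- outer(t, v) + rep(a, each = n)
    d2 <- rowSums((X - proj)^2)
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]
    best_pos[upd] <- arc0[s] + t[upd] * seg_len[s]
  }
  best_pos
}

# Reference cycle from an ordered data matrix: circular moving average
# evaluated at `m` equally spaced anchor cells.
smoothed_cycle_nodes <- function(Xo, m = 50, span = NULL) {
  n <- nrow(Xo)
  m <- min(m, max(8, n %/% 4))
  if (is.null(span)) span <- max(2, round(n / m))
  anchors <- round(seq(1, n, length.out = m + 1))[-(m + 1)]
  idx_mat <- outer(anchors, -span:span, `+`)
  idx_mat <- ((idx_mat - 1) %% n) + 1
  t(apply(idx_mat, 1, function(ii) colMeans(Xo[ii, , drop = FALSE])))
}

withr_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  expr
}

#' @export
print.ccOrder <- function(x, ...) {
  cat("<ccOrder> ", x$n, " cells, ", length(x$tour), " clusters",
      if (!is.null(x$orientation))
        paste0(", oriented (start ", x$start, ", direction ", x$orientation, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Resolve orientation and start of a circular order
#'
#' The direction is chosen so that the CycA-like hint feature increases
#' over most of the cycle (largest circular-rank correlation); the start
#' is placed at the largest drop of the CycB-like hint (division).  Both
#' can be overridden.
#'
#' @param ord a `ccOrder` from [reconstruct_order()]
#' @param table the snapshot table the order refers to
#' @param hints named character vector with entries `rising` (CycA-like)
#'   and `division` (CycB-like); defaults look for CycA/CCNA and
#'   Cb/CCNB-type columns
#' @param start,direction explicit overrides (1-based position in the
#'   current order; direction +1/-1)
#' @return the `ccOrder` with `orientation`, `start` and `ranks` fields
#'   set (`ranks[i]` is the circular rank, 0-based, of table row `i`)
#' @export
orient_cycle <- function(ord, table, hints = NULL, start = NULL,
                         direction = NULL) {
  n <- ord$n
  idx <- ord$order
  if (is.null(direction) || is.null(start)) {
    feats <- snapshot_features(table)
    pick <- function(cands) {
      for (cc in cands) {
        hit <- grep(cc, feats, value = TRUE)
        if (length(hit)) return(hit[1])
      }
      NULL
    }
    rising <- if (!is.null(hints) && "rising" %in% names(hints)) hints[["rising"]]
              else pick(c("^CycA", "^CCNA", "CycA", "CCNA"))
    division <- if (!is.null(hints) && "division" %in% names(hints)) hints[["division"]]
                else pick(c("^tCycB$", "^pCb", "^Cb$", "^CCNB", "CycB", "CCNB"))
    if (is.null(rising) || is.null(division))
      stop("orientation hints not found; supply `hints` or explicit start/direction")
    win <- max(3, round(n / 30))
    smooth_circ <- function(v) {
      vv <- c(tail(v, win), v, head(v, win))
      stats::filter(vv, rep(1 / (2 * win + 1), 2 * win + 1))[win + seq_len(n)]
    }
    ca <- as.numeric(table[idx, rising])
    cb <- as.numeric(table[idx, division])
    if (is.null(direction)) {
      # direction in which the CycA-like signal has the larger circular
      # linear-trend correlation after aligning to its own minimum
      score <- function(v) {
        s <- smooth_circ(v)
        st <- which.min(s)
        max(stats::cor(seq_len(n), s[((seq_len(n) + st - 2) %% n) + 1]))
      }
      direction <- if (score(ca) >= score(rev(ca))) 1L else -1L
    }
    if (direction == -1L) { idx <- rev(idx); ca <- rev(ca); cb <- rev(cb) }
    if (is.null(start)) {
      s <- smooth_circ(cb)
      drops <- s - s[c(2:n, 1)]     # drop from position i to i+1
      start <- (which.max(drops) %% n) + 1
    }
  } else {
    if (direction == -1L) idx <- rev(idx)
  }
  idx <- c(idx[start:n], idx[seq_len(start - 1)])
  ranks <- integer(n)
  ranks[idx] <- seq_len(n) - 1L
  ord$order <- idx
  ord$orientation <- as.integer(direction)
  ord$start <- start
  ord$ranks <- ranks
  ord
}

#' Convert a circular rank to cell-cycle time
#'
#' Inverts the rank function of the asynchronous age density,
#' \eqn{r(t) = 2N(1 - (1/2)^{t/T})}, giving
#' \eqn{t = -T \log_2(1 - r/(2N))}.  Rank 0 maps to age 0 and rank `N`
#' to exactly one doubling time.
#'
#' @param r rank(s), `0 <= r <= N`
#' @param N population size
#' @param T doubling time (min)
#' @return pseudo-time(s) in minutes, strictly increasing in `r`
#' @export
rank_to_time <- function(r, N, T) {
  if (any(r < 0) || any(r > N)) stop("ranks must lie in [0, N]")
  -T * log2(1 - r / (2 * N))
}

#' Pseudo-times of an oriented order
#'
#' @param ord an oriented `ccOrder` (after [orient_cycle()])
#' @param T doubling time (min)
#' @return numeric vector aligned with the original table rows
#' @export
order_pseudotimes <- function(ord, T) {
  if (is.null(ord$ranks)) stop("order is not oriented; run orient_cycle() first")
  rank_to_time(ord$ranks, ord$n, T)
}

#' Local-level Kalman smoothing of a pseudo-time course
#'
#' Fits the local-level state-space model
#' \eqn{x_{t+1} = x_t + \epsilon_x}, \eqn{y_t = x_t + \epsilon_y}
#' by maximum likelihood ([stats::StructTS] with `type = "level"`) and
#' returns the fixed-interval smoothed level ([stats::tsSmooth]).  The
#' series is padded circularly with the last `pad` fraction at the
#' beginning and the first `pad` fraction at the end, so the smoothing
#' respects the periodicity of the cell cycle; the padding is removed
#' again before returning.
#'
#' @param series ordered numeric values (one variable along pseudo-time)
#' @param pad circular padding fraction (default 0.1)
#' @return list with `smoothed` (same length as input) and `variances`
#'   (`sigma_x2`, `sigma_y2` maximum-likelihood estimates)
#' @export
kalman_smooth <- function(series, pad = 0.1) {
  if (length(series) < 10) stop("series too short")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  if (stats::sd(series) < 1e-12) {
    # a constant series has a degenerate likelihood; it is its own smooth
    return(list(smoothed = series,
                variances = c(sigma_x2 = 0, sigma_y2 = 0)))
  }
  npad <- floor(pad * n)
  padded <- c(tail(series, npad), series, head(series, npad))
  fit <- stats::StructTS(padded, type = "level")
  sm <- as.numeric(stats::tsSmooth(fit))
  list(smoothed = sm[npad + seq_len(n)],
       variances = c(sigma_x2 = unname(fit$coef["level"]),
                     sigma_y2 = unname(fit$coef["epsilon"])))
}

#' Correlation between true and reconstructed cell-cycle times
#'
#' Pseudo-time is defined modulo the period with unknown direction, so
#' the Pearson correlation is maximised over all `N` circular start
#' offsets and both orientations ("circular alignment").  The plain
#' Pearson correlation of the supplied assignment is also reported.
#'
#' @param ord an oriented `ccOrder`, or an integer vector of circular
#'   ranks (0-based, aligned with `true_ages`)
#' @param true_ages true cell ages (min)
#' @param T doubling time used for the rank-to-time conversion
#'   (defaults to `max(true_ages)` padded by the mean gap)
#' @return list with `R` (best circularly-aligned Pearson), `R_raw`
#'   (no re-alignment), `offset` and `orientation` at the optimum
#' @export
correlation_with_truth <- function(ord, true_ages, T = NULL) {
  ranks <- if (inherits(ord, "ccOrder")) {
    if (is.null(ord$ranks)) stop("order is not oriented")
    ord$ranks
  } else as.integer(ord)
  n <- length(true_ages)
  stopifnot(length(ranks) == n)
  if (is.null(T)) T <- max(true_ages) * (n + 1) / n
  t_of_rank <- rank_to_time(0:(n - 1), n, T)
  best <- -Inf; best_off <- 0L; best_dir <- 1L
  raw <- stats::cor(t_of_rank[ranks + 1], true_ages)
  for (dir in c(1L, -1L)) {
    rk <- if (dir == 1L) ranks else (n - 1L) - ranks
    for (off in 0:(n - 1)) {
      t_assigned <- t_of_rank[((rk + off) %% n) + 1]
      r <- stats::cor(t_assigned, true_ages)
      if (r > best) { best <- r; best_off <- off; best_dir <- dir }
    }
  }
  list(R = best, R_raw = raw, offset = best_off, orientation = best_dir)
}
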