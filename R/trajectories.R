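## Temporal trajectory clustering.
##
## Per gene, the 4-point temporal profile is the z-scored vector of age-group
## means of log2 CPM (population sd over the 4 points). Profiles are grouped
## with a one-dimensional circular self-organizing map (SOM) whose distance
## is 1 minus a co-expression similarity: the Pearson correlation of the two
## profiles after linear interpolation onto a uniform grid over real age.
## The cluster count is chosen by BIC on the SOM quantization error.

#' Z-scored temporal profiles per gene
#'
#' @param log2cpm gene x sample matrix.
#' @param age_months per-sample age group.
#' @return list with `means` (gene x age group means), `z` (z-scored
#'   profiles, population sd; constant genes dropped), and `constant`
#'   (logical flag per gene).
#' @export
temporal_profiles <- function(log2cpm, age_months) {
  ages <- sort(unique(age_months))
  means <- vapply(ages, function(a) {
    rowMeans(log2cpm[, age_months == a, drop = FALSE])
  }, numeric(nrow(log2cpm)))
  colnames(means) <- as.character(ages)
  ctr <- means - rowMeans(means)
  sd_pop <- sqrt(rowMeans(ctr^2))
  constant <- sd_pop < 1e-12
  z <- ctr[!constant, , drop = FALSE] / sd_pop[!constant]
  list(means = means, z = z, constant = constant, ages = ages)
}

# Interpolation weight matrix: grid_points x length(ages), rows = linear
# interpolation weights of each uniform-grid age onto the observed ages.
interp_weights <- function(ages, grid_points = 101) {
  grid <- seq(min(ages), max(ages), length.out = grid_points)
  W <- matrix(0, nrow = grid_points, ncol = length(ages))
  for (gi in seq_along(grid)) {
    x <- grid[gi]
    j <- findInterval(x, ages, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(ages) - 1)
    w <- (x - ages[j]) / (ages[j + 1] - ages[j])
    W[gi, j] <- 1 - w
    W[gi, j + 1] <- w
  }
  W
}

# Trapezoid quadrature weights for an endpoint-inclusive uniform grid.
trap_weights <- function(n) c(0.5, rep(1, n - 2), 0.5)

# 4x4 covariance kernel of the interpolated series under trapezoid
# quadrature: cov(Wa, Wb) = a' C b. Lets the SOM evaluate interpolated
# correlations without forming the grid series; trapezoid weighting makes
# the grid correlation converge O(h^2) to the continuous-interpolant value.
interp_kernel <- function(ages, grid_points = 101) {
  W <- interp_weights(ages, grid_points)
  w <- trap_weights(nrow(W))
  S <- sum(w)
  M <- diag(w) / S - tcrossprod(w) / S^2
  crossprod(W, M %*% W)
}

#' Co-expression similarity of two temporal profiles
#'
#' Both profiles are linearly interpolated onto a uniform `grid_points` grid
#' over the real age axis; the similarity is the Pearson correlation of the
#' interpolated series under trapezoid quadrature weights, in [-1, 1].
#' Interpolating over real age (not rank) weights long age intervals
#' accordingly; the trapezoid weighting makes the value converge O(h^2) to
#' the correlation of the continuous interpolants, so the 101-point default
#' already agrees with a dense grid to ~1e-3.
#'
#' @param profile_a,profile_b numeric profiles on the same age axis.
#' @param ages age axis (default `c(3, 6, 12, 20)` months).
#' @param grid_points interpolation grid size (default 101).
#' @return similarity in [-1, 1].
#' @export
coexpression_similarity <- function(profile_a, profile_b,
                                    ages = c(3, 6, 12, 20),
                                    grid_points = 101) {
  stopifnot(length(profile_a) == length(ages),
            length(profile_b) == length(ages))
  C <- interp_kernel(ages, grid_points)
  va <- drop(t(profile_a) %*% C %*% profile_a)
  vb <- drop(t(profile_b) %*% C %*% profile_b)
  if (va <= 1e-12 * (sum(profile_a^2) + 1) ||
      vb <= 1e-12 * (sum(profile_b^2) + 1)) {
    stop("constant interpolated series: similarity undefined")
  }
  drop(t(profile_a) %*% C %*% profile_b) / sqrt(va * vb)
}

# Kernel-based similarity of one profile against the rows of a matrix.
kernel_similarity <- function(x, nodes, C) {
  cx <- drop(C %*% x)
  num <- drop(nodes %*% cx)
  den <- sqrt(sum(x * cx) * rowSums((nodes %*% C) * nodes))
  num / den
}

#' Circular SOM clustering of temporal profiles
#'
#' One-dimensional SOM with `k` nodes arranged on a ring, trained with
#' distance `1 - coexpression_similarity` and a Gaussian ring-distance
#' neighborhood whose width decays exponentially from `k/2` to 0.5 over the
#' epochs; the learning rate decays from 0.5 to 0.01. Nodes are initialized
#' by sampling profiles. Deterministic given `seed`.
#'
#' @param z gene x age matrix of z-scored profiles ([temporal_profiles()]).
#' @param k number of nodes (>= 2, <= number of profiles).
#' @param epochs training epochs (default 200).
#' @param ages age axis matching the profile columns.
#' @param grid_points interpolation grid for the similarity (default 101).
#' @param seed integer seed.
#' @return list of class `som_model`: `k`, `nodes` (k x ages node profiles,
#'   circular order), `assignment` (named node index per gene),
#'   `similarity` (gene's similarity to its node), `rss`, `bic`.
#' @export
som_cluster <- function(z, k, epochs = 200, ages = c(3, 6, 12, 20),
                        grid_points = 101, seed = 1) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of profiles")
  C <- interp_kernel(ages, grid_points)
  ring_dist <- outer(seq_len(k), seq_len(k), function(i, j) {
    d <- abs(i - j); pmin(d, k - d)
  })
  lr0 <- 0.5; lr1 <- 0.01
  sg0 <- k / 2; sg1 <- 0.5
  with_seed(seed, {
    nodes <- z[sample.int(n, k), , drop = FALSE]
    for (ep in seq_len(epochs)) {
      frac <- if (epochs == 1) 1 else (ep - 1) / (epochs - 1)
      lr <- lr0 * (lr1 / lr0)^frac
      sg <- sg0 * (sg1 / sg0)^frac
      for (i in sample.int(n)) {
        x <- z[i, ]
        bmu <- which.max(kernel_similarity(x, nodes, C))
        h <- exp(-ring_dist[bmu, ]^2 / (2 * sg^2))
        nodes <- nodes + (lr * h) * (matrix(x, nrow = k, ncol = ncol(z),
                                            byrow = TRUE) - nodes)
      }
    }
    # batch convergence step: with the neighborhood frozen out, each node
    # settles at the mean of its members (empty nodes keep their trained
    # profile); assignments are then recomputed once.
    for (it in 1:2) {
      sim <- t(apply(z, 1, kernel_similarity, nodes = nodes, C = C))
      assignment <- max.col(sim, ties.method = "first")
      if (it == 2) break
      for (j in seq_len(k)) {
        idx <- which(assignment == j)
        if (length(idx)) nodes[j, ] <- colMeans(z[idx, , drop = FALSE])
      }
    }
    names(assignment) <- rownames(z)
    rss <- max(sum((z - nodes[assignment, , drop = FALSE])^2), 1e-12)
    d <- ncol(z)
    # BIC of the spherical-Gaussian classification likelihood at the SOM
    # partition: quantization error + mixing-proportion entropy, penalized
    # by k means, k-1 proportions and one shared variance. The proportion
    # term is what keeps a well-populated cluster from being split merely
    # because a split always reduces in-sample RSS.
    nc <- tabulate(assignment, nbins = k)
    nc <- nc[nc > 0]
    bic <- n * d * log(rss / (n * d)) + 2 * sum(nc * log(n / nc)) +
      k * (d + 1) * log(n)
    structure(
      list(k = k, nodes = nodes, assignment = assignment,
           similarity = sim[cbind(seq_len(n), assignment)],
           rss = rss, bic = bic),
      class = "som_model"
    )
  })
}

#' Select the cluster count by BIC
#'
#' Fits [som_cluster()] for each candidate `k` and picks the minimizer of
#' the spherical-Gaussian classification-likelihood BIC,
#' `n*d*ln(RSS/(n*d)) + 2*sum_c n_c*ln(n/n_c) + k*(d+1)*ln(n)`
#' (d = number of ages, n_c = cluster sizes).
#'
#' @param z z-scored profile matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed (child seeds per k keep fits independent).
#' @param ... passed to [som_cluster()].
#' @return list with `k_star`, `bic` (data frame k/bic/rss) and `model`
#'   (the fit at `k_star`).
#' @export
select_k_bic <- function(z, k_range = 2:10, seed = 1, ...) {
  k_range <- k_range[k_range <= nrow(z)]
  fits <- lapply(k_range, function(k) {
    som_cluster(z, k, seed = child_seed(seed, k), ...)
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- which.min(bic)
  list(
    k_star = k_range[best],
    bic = data.frame(k = k_range, bic = bic,
                     rss = vapply(fits, `[[`, numeric(1), "rss")),
    model = fits[[best]]
  )
}

#' Mean member profile per cluster
#'
#' @param model a `som_model`.
#' @param z the profile matrix the model was fit on.
#' @return cluster x age matrix of mean member z-profiles (NA rows for
#'   empty nodes).
#' @export
cluster_mean_profiles <- function(model, z) {
  out <- matrix(NA_real_, nrow = model$k, ncol = ncol(z),
                dimnames = list(paste0("node", seq_len(model$k)), colnames(z)))
  for (j in seq_len(model$k)) {
    idx <- which(model$assignment == j)
    if (length(idx)) out[j, ] <- colMeans(z[idx, , drop = FALSE])
  }
  out
}
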