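# Signed-rank machinery shared by the observed test and the sign-flip
# permutation null. Effects enter as D = AUC - 0.5 (subjects x cells).
# Per cell: r_ij = rank of |d_ij| among the non-zero |d| of cell j
# (zeros contribute nothing), S = sum_i sign(d_ij) r_ij,
# Var(S) = sum_i r_ij^2 under random sign flips, z = S / sqrt(Var).
signed_rank_prep <- function(D) {
  n_cell <- ncol(D)
  R <- matrix(0, nrow(D), n_cell)
  clean <- logical(n_cell)
  for (j in seq_len(n_cell)) {
    d <- D[, j]
    nz <- d != 0
    r <- numeric(length(d))
    r[nz] <- rank(abs(d[nz]))
    R[, j] <- sign(d) * r
    clean[j] <- all(nz) && !any(duplicated(abs(d[nz])))
  }
  sigma <- sqrt(colSums(R^2))
  list(SR = R, sigma = sigma, Tsum = colSums(abs(R)), clean = clean,
       n_nonzero = colSums(D != 0))
}

# Two-sided p for signed-rank sums S (vector), given per-cell totals.
# Exact via psignrank for clean cells (no zeros, no tied |d|, n <= 50);
# normal approximation with continuity correction otherwise.
signed_rank_p <- function(S, Tsum, sigma, n, clean) {
  p <- numeric(length(S))
  nrm <- !clean | n > 50
  if (any(nrm)) {
    z_abs <- ifelse(sigma[nrm] > 0, (abs(S[nrm]) - 1) / sigma[nrm], 0)
    p[nrm] <- 2 * stats::pnorm(-pmax(z_abs, 0))
  }
  if (any(!nrm)) {
    V <- (S[!nrm] + Tsum[!nrm]) / 2
    nn <- n[!nrm]
    lo <- stats::psignrank(V, nn)
    hi <- 1 - stats::psignrank(V - 1, nn)
    p[!nrm] <- pmin(2 * pmin(lo, hi), 1)
  }
  p[sigma == 0] <- 1
  p
}

#' Group-level signed-rank test of AUC against chance
#'
#' Wilcoxon signed-rank test of the per-subject AUC against 0.5 at every
#' sample, across subjects. Returns the standardized statistic
#' \code{z = S / sqrt(Var(S))} (S the signed-rank sum of AUC - 0.5) and a
#' two-sided sample-level p value (exact for clean cells with n <= 50,
#' normal approximation with continuity correction otherwise). A sample
#' where every subject is exactly at chance yields z = 0, p = 1.
#'
#' @param auc subjects x samples matrix of AUC values.
#' @param chance chance level, default 0.5.
#' @return data.frame with columns \code{z} and \code{p}, one row per
#'   sample.
#' @export
test_vs_chance <- function(auc, chance = 0.5) {
  if (nrow(auc) < 5L)
    stop("test_vs_chance: need at least 5 subjects")
  pr <- signed_rank_prep(auc - chance)
  S <- colSums(pr$SR)
  z <- ifelse(pr$sigma > 0, S / pr$sigma, 0)
  p <- signed_rank_p(S, pr$Tsum, pr$sigma, pr$n_nonzero, pr$clean)
  data.frame(z = z, p = p)
}

# Per-cell critical |S| such that the two-sided p falls below alpha,
# consistent with signed_rank_p.
signed_rank_crit <- function(Tsum, sigma, n, clean, alpha) {
  crit <- rep(Inf, length(sigma))
  ok <- sigma > 0
  nrm <- ok & (!clean | n > 50)
  crit[nrm] <- 1 + sigma[nrm] * stats::qnorm(1 - alpha / 2) + 1e-9
  ex <- ok & !nrm
  if (any(ex)) {
    for (key in unique(n[ex])) {
      idx <- ex & n == key
      Tn <- key * (key + 1) / 2
      V <- 0:Tn
      p <- pmin(2 * pmin(stats::psignrank(V, key),
                         1 - stats::psignrank(V - 1, key)), 1)
      sig_V <- V[p < alpha & V > Tn / 2]
      crit[idx] <- if (length(sig_V)) 2 * min(sig_V) - Tn else Inf
    }
  }
  crit
}

# Connected supra-threshold clusters of the standardized statistic.
# `shape` NULL -> 1-D adjacency; c(nr, nc) -> 4-connectivity on a grid.
# Positive and negative excursions form separate clusters; mass is the
# signed sum of z. Returns list of list(cells, mass).
find_clusters <- function(z, supra_pos, supra_neg, shape = NULL) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) supra_pos else supra_neg
    if (!any(supra)) next
    if (is.null(shape)) {
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        cells <- starts[i]:ends[i]
        out[[length(out) + 1L]] <- list(cells = cells,
                                        mass = sum(z[cells]))
      }
    } else {
      for (comp in grid_components(which(supra), shape)) {
        out[[length(out) + 1L]] <- list(cells = comp, mass = sum(z[comp]))
      }
    }
  }
  out
}

# 4-connected components of a set of linear grid indices (column-major).
grid_components <- function(cells, shape) {
  if (!length(cells)) return(list())
  nr <- shape[1]
  row <- (cells - 1L) %% nr + 1L
  inset <- logical(shape[1] * shape[2])
  inset[cells] <- TRUE
  edges <- NULL
  down <- cells[row < nr & inset[pmin(cells + 1L, length(inset))]]
  if (length(down)) edges <- rbind(edges, cbind(down, down + 1L))
  right <- cells[cells + nr <= length(inset)]
  right <- right[inset[right + nr]]
  if (length(right)) edges <- rbind(edges, cbind(right, right + nr))
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  idx <- integer(length(inset))
  idx[cells] <- seq_along(cells)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(cbind(idx[edges[, 1]], idx[edges[, 2]])))
  comp <- igraph::components(g)$membership
  split(cells, comp)
}

#' Cluster-based permutation test of decoding against chance
#'
#' Forms clusters where the sample-level signed-rank p (see
#' \code{\link{test_vs_chance}}) falls below \code{alpha_cluster}
#' (positive and negative excursions separately; adjacency in 1-D,
#' 4-connectivity for the temporal-generalization matrix) and scores each
#' cluster by the sum of standardized signed-rank z values. The null
#' distribution is the maximal absolute cluster mass under random
#' per-subject sign flips of (AUC - 0.5); cluster p values carry the
#' (1 + count) / (1 + n_perm) correction, so the attainable floor is
#' 1 / (n_perm + 1).
#'
#' @param auc subjects x samples matrix, or subjects x samples x samples
#'   array for the generalization matrix.
#' @param alpha_cluster two-sided cluster-forming threshold on the
#'   sample-level p.
#' @param n_perm number of sign-flip permutations.
#' @param seed permutation seed.
#' @param chance chance level.
#' @return a \code{cluster_result}: list with \code{clusters} (each with
#'   \code{cells} — sample indices, or linear indices into the matrix —,
#'   \code{mass}, \code{p}), sorted by descending absolute mass, plus
#'   \code{z} and \code{p_sample} reshaped to the input geometry,
#'   \code{alpha}, \code{n_perm}, \code{null_max_mass}.
#' @export
cluster_permutation <- function(auc, alpha_cluster = 0.05, n_perm = 1000L,
                                seed = 1L, chance = 0.5) {
  if (n_perm < 100L)
    warning("cluster_permutation: n_perm < 100 gives an unstable p floor")
  dims <- dim(auc)
  shape <- if (length(dims) == 3L) dims[2:3] else NULL
  n_sub <- dims[1]
  if (n_sub < 5L) stop("cluster_permutation: need at least 5 subjects")
  D <- matrix(auc - chance, nrow = n_sub)
  pr <- signed_rank_prep(D)

  S_obs <- colSums(pr$SR)
  z_obs <- ifelse(pr$sigma > 0, S_obs / pr$sigma, 0)
  p_obs <- signed_rank_p(S_obs, pr$Tsum, pr$sigma, pr$n_nonzero, pr$clean)
  crit <- signed_rank_crit(pr$Tsum, pr$sigma, pr$n_nonzero, pr$clean,
                           alpha_cluster)

  obs_clusters <- find_clusters(z_obs, p_obs < alpha_cluster & z_obs > 0,
                                p_obs < alpha_cluster & z_obs < 0, shape)

  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                  n_perm, n_sub)
  null_max <- numeric(n_perm)
  chunk <- max(1L, floor(2e7 / length(S_obs)))
  for (start in seq(1L, n_perm, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_perm)
    Sp <- flips[rows, , drop = FALSE] %*% pr$SR
    for (r in seq_along(rows)) {
      S <- Sp[r, ]
      z <- ifelse(pr$sigma > 0, S / pr$sigma, 0)
      cl <- find_clusters(z, S >= crit, S <= -crit, shape)
      null_max[rows[r]] <- if (length(cl))
        max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
    }
  }

  clusters <- lapply(obs_clusters, function(cl) {
    cl$p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    cl
  })
  if (length(clusters)) {
    ord <- order(-vapply(clusters, function(cl) abs(cl$mass), numeric(1)))
    clusters <- clusters[ord]
  }
  geom <- function(x) if (is.null(shape)) x else matrix(x, shape[1], shape[2])
  structure(list(clusters = clusters, alpha = alpha_cluster,
                 n_perm = n_perm, z = geom(z_obs), p_sample = geom(p_obs),
                 null_max_mass = null_max, seed = seed),
            class = "cluster_result")
}
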