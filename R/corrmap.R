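#' Match independent components across conditions by topography correlation
#'
#' Clusters the components of two decompositions (congruent and
#' incongruent) on the Pearson correlation of their topographies
#' ("inverse weights"). Clusters are grown greedily from template
#' components: a template's cluster collects, per condition, the up-to-
#' \code{max_per_group} unconsumed components whose absolute correlation
#' with the template reaches \code{threshold} (best first); consumed
#' components are unavailable to later clusters. Each cluster with
#' members from both conditions emits the cross-condition pair with the
#' highest absolute correlation. The greedy pass is repeated for
#' \code{n_init} seeded template orderings and the most recurrent pairing
#' is retained (ties broken by larger total absolute correlation, then by
#' lower component indices). Absolute correlation is used throughout
#' because ICA component sign is arbitrary; \code{sign_flip} records
#' pairs whose signed correlation is negative.
#'
#' @param decomp_a,decomp_b \code{group_decomposition} objects sharing
#'   the channel space (conventionally a = congruent, b = incongruent).
#' @param threshold minimum absolute Pearson correlation for cluster
#'   membership.
#' @param max_per_group maximum members per condition per cluster.
#' @param n_init number of template orderings.
#' @param seed seed for the orderings.
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{idx_congruent}, \code{idx_incongruent}, \code{correlation}
#'   (signed), \code{sign_flip}; sorted by descending absolute
#'   correlation. Zero rows (with a warning) when nothing matches.
#' @export
match_components <- function(decomp_a, decomp_b, threshold = 0.85,
                             max_per_group = 3L, n_init = 40L, seed = 1L) {
  if (!identical(decomp_a$channels, decomp_b$channels))
    stop("match_components: decompositions must share the channel space")
  ka <- ncol(decomp_a$A)
  kb <- ncol(decomp_b$A)
  topos <- cbind(decomp_a$A, decomp_b$A)
  group <- rep(c("a", "b"), c(ka, kb))
  R <- suppressWarnings(stats::cor(topos))   # correlations between all topos
  R[is.na(R)] <- 0

  set.seed(seed)
  orders <- lapply(seq_len(n_init), function(i) sample(ka + kb))
  pairings <- lapply(orders, function(ord)
    greedy_pairing(ord, R, group, ka, threshold, max_per_group))
  keys <- vapply(pairings, pairing_key, character(1))
  tab <- table(keys)
  best_keys <- names(tab)[tab == max(tab)]
  cand <- pairings[match(best_keys, keys)]
  if (length(cand) > 1L) {
    tot <- vapply(cand, function(p) sum(abs(p$correlation)), numeric(1))
    cand <- cand[tot == max(tot)]
    if (length(cand) > 1L)
      cand <- cand[order(vapply(cand, pairing_key, character(1)))][1]
  }
  pairs <- cand[[1]]
  if (nrow(pairs) == 0L) {
    warning("match_components: no component pair above threshold ",
            threshold)
    return(pairs)
  }
  pairs <- pairs[order(-abs(pairs$correlation),
                       pairs$idx_congruent), , drop = FALSE]
  pairs$pair_id <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs[c("pair_id", "idx_congruent", "idx_incongruent", "correlation",
          "sign_flip")]
}

# One greedy clustering pass over a template ordering.
greedy_pairing <- function(ord, R, group, ka, threshold, max_per_group) {
  consumed <- rep(FALSE, length(group))
  out <- list()
  for (tmpl in ord) {
    if (consumed[tmpl]) next
    members <- integer(0)
    for (g in c("a", "b")) {
      idx <- which(group == g & !consumed & abs(R[tmpl, ]) >= threshold)
      idx <- setdiff(idx, tmpl)
      if (group[tmpl] == g) idx <- c(tmpl, idx)
      if (length(idx) > 1L)
        idx <- idx[order(-abs(R[tmpl, idx]))]
      members <- c(members, utils::head(idx, max_per_group))
    }
    ma <- members[group[members] == "a"]
    mb <- members[group[members] == "b"]
    if (length(ma) && length(mb)) {
      sub <- abs(R[ma, mb, drop = FALSE])
      bi <- arrayInd(which.max(sub), dim(sub))
      ia <- ma[bi[1]]
      ib <- mb[bi[2]]
      out[[length(out) + 1L]] <- data.frame(
        idx_congruent = ia, idx_incongruent = ib - ka,
        correlation = R[ia, ib], sign_flip = R[ia, ib] < 0)
      consumed[members] <- TRUE
    } else {
      consumed[tmpl] <- TRUE
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(idx_congruent = integer(0), idx_incongruent = integer(0),
                  correlation = numeric(0), sign_flip = logical(0))
}

pairing_key <- function(p) {
  if (nrow(p) == 0L) return("")
  o <- order(p$idx_congruent, p$idx_incongruent)
  paste(p$idx_congruent[o], p$idx_incongruent[o], sep = ":", collapse = ";")
}

#' Exhaustive best assignment between two topography sets
#'
#' Enumerates all injective assignments of the rows of the (small) score
#' matrix to columns and returns the one maximizing the total score.
#' Serves as the independent oracle for pairing/recovery checks.
#'
#' @param score matrix (k x m, k <= m) of assignment scores, e.g.
#'   absolute correlations.
#' @return list with \code{assignment} (column index per row) and
#'   \code{total}.
#' @export
best_assignment <- function(score) {
  k <- nrow(score)
  m <- ncol(score)
  if (k > m) stop("best_assignment: need nrow <= ncol")
  best <- list(assignment = NULL, total = -Inf)
  recurse <- function(row, used, acc, cur) {
    if (row > k) {
      if (acc > best$total) best <<- list(assignment = cur, total = acc)
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(row + 1L, used, acc + score[row, j], c(cur, j))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0, integer(0))
  best
}
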