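#' Shannon entropy of a binary label vector
#'
#' Plug-in (maximum-likelihood) entropy of the empirical label distribution,
#' in bits: \eqn{-\sum_y p(y) \log_2 p(y)} with the convention
#' \eqn{0 \log_2 0 = 0}. For binary labels the result lies in \[0, 1\]: 0 for
#' a constant vector, 1 for a balanced one.
#'
#' @param labels Vector of 0/1 values (integer, numeric or logical).
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' shannon_entropy(c(0, 0, 0, 0, 1, 1, 1, 1)) # 1
#' shannon_entropy(c(1, 1, 1, 1))             # 0
#' @export
shannon_entropy <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("no observations", call. = FALSE)
  if (anyNA(labels) || any(labels != 0L & labels != 1L)) {
    stop("labels must be binary", call. = FALSE)
  }
  p <- tabulate(labels + 1L, nbins = 2L) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Collapse the selected columns of a 0/1 matrix into one integer pattern id
# per row. Ids are compressed after every column so they never exceed the
# number of rows (2^m raw patterns cannot be enumerated for large m; only
# observed patterns are tracked).
pattern_ids <- function(values) {
  id <- values[, 1L] + 1L
  if (ncol(values) > 1L) {
    for (j in 2L:ncol(values)) {
      id <- (id - 1L) * 2L + values[, j] + 1L
      id <- match(id, sort(unique(id)))
    }
  }
  id
}

# Plug-in mutual information (bits) between integer group ids (1..G) and
# binary labels. Negative values from floating-point cancellation are
# clamped to 0.
mi_plugin <- function(gid, labels) {
  n <- length(labels)
  g <- max(gid)
  nxy <- tabulate((gid - 1L) * 2L + labels + 1L, nbins = 2L * g)
  nx <- nxy[seq(1L, 2L * g, by = 2L)] + nxy[seq(2L, 2L * g, by = 2L)]
  ny <- tabulate(labels + 1L, nbins = 2L)
  nyv <- rep(ny, times = g)
  nxv <- rep(nx, each = 2L)
  keep <- nxy > 0L
  mi <- sum(nxy[keep] / n * log2(as.numeric(nxy[keep]) * n /
                                  (as.numeric(nxv[keep]) * nyv[keep])))
  max(mi, 0)
}

check_feature_subset <- function(fids, universe) {
  if (length(fids) == 0L) stop("empty feature set", call. = FALSE)
  missing <- setdiff(fids, universe)
  if (length(missing) > 0L) {
    stop("unknown feature_id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(fids)
}

#' Joint mutual information between a feature set and activity labels
#'
#' Treats the selected fingerprint bits jointly as a single discrete variable
#' over the bit patterns actually observed among the compounds, and returns
#' the plug-in mutual information (base-2 logs) between that joint pattern and
#' the binary activity labels. Unobserved patterns have zero empirical
#' probability and contribute nothing, so patterns are never enumerated
#' exhaustively.
#'
#' @param activity An [activity_set()].
#' @param feats Character vector of feature identifiers, a non-empty subset of
#'   `feature_ids(activity)`.
#' @return Mutual information in bits; non-negative, bounded by the entropy of
#'   both the joint pattern and the labels.
#' @examples
#' a <- table2_fixture()$activity_sets[[1]]
#' joint_mutual_information(a, "X1")
#' @export
joint_mutual_information <- function(activity, feats) {
  stopifnot(inherits(activity, "activity_set"))
  check_feature_subset(feats, feature_ids(activity))
  gid <- pattern_ids(activity$matrix$values[, feats, drop = FALSE])
  mi_plugin(gid, activity$labels)
}

#' Entropy-normalized mutual information for one target
#'
#' Mutual information between a feature set and a target's activity labels,
#' divided by the Shannon entropy of the labels, giving the fraction of the
#' target's activity information captured by those bits (0 = independent,
#' 1 = fully determining).
#'
#' @inheritParams joint_mutual_information
#' @return A fraction in \[0, 1\].
#' @export
normalized_mi <- function(activity, feats) {
  stopifnot(inherits(activity, "activity_set"))
  se <- shannon_entropy(activity$labels)
  if (se == 0) {
    stop("degenerate target: entropy of activity labels is zero (target ",
         activity$target_id, ")", call. = FALSE)
  }
  min(joint_mutual_information(activity, feats) / se, 1)
}

#' Average Information Content of a feature set over a target collection
#'
#' The multi-target selection score: entropy-normalized mutual information
#' between the feature set and each target's activity labels, averaged over
#' the K targets,
#' \deqn{AIC_Y(X) = \frac{1}{K}\sum_{i=1}^{K} \frac{MI(X; Y_i)}{SE(Y_i)}.}
#' Each per-target factor is estimated on that target's own compound set, so
#' targets with disjoint compound sets are handled naturally. The score lies
#' in \[0, 1\]; it is 1 when the bits fully determine activity for every
#' target and 0 when they are independent of all of them. A feature set fully
#' informative for l of k targets and uninformative for the rest scores l/k.
#'
#' @param collection A [target_collection()].
#' @param feats Character vector of feature identifiers within the
#'   collection's feature universe.
#' @return The AIC score, a fraction in \[0, 1\].
#' @examples
#' average_information_content(table1_fixture(), c("X1", "X2")) # 2/3
#' @export
average_information_content <- function(collection, feats) {
  mean(per_target_nmi(collection, feats))
}

# Named vector of per-target normalized MI for a feature subset.
per_target_nmi <- function(collection, feats) {
  stopifnot(inherits(collection, "target_collection"))
  check_feature_subset(feats, collection$feature_universe)
  vapply(collection$activity_sets, normalized_mi, numeric(1L), feats = feats)
}
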