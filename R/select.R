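#' Greedy AIC-Max selection of informative fingerprint bits
#'
#' Builds an N-bit reduced representation by greedy forward selection: at each
#' step every remaining candidate bit is scored by the Average Information
#' Content of the already-selected bits plus the candidate, and the best
#' candidate joins the selection (ties broken to the lowest index in feature
#' universe order). Because AIC scores whole groups of bits jointly, a bit
#' duplicating (or negating) information already selected gains nothing and is
#' passed over in favour of complementary bits.
#'
#' Scoring a candidate jointly with all s selected bits costs grows with the
#' number of observed patterns, so for long selections the conditioning
#' context may be restricted to a random subsample of the selected bits:
#' with `subsample_size = n`, each iteration draws one uniform random subset
#' of `min(n, s)` selected bits, shared by all candidates of that iteration,
#' and the candidate is scored jointly with that subset. The recorded trace is
#' always the exact AIC of the full selected set, so traces are comparable
#' across configurations. With `subsample_size = NULL` the conditioning is
#' exact and the trace is non-decreasing.
#'
#' @param collection A [target_collection()].
#' @param n_select Number of bits to select (N >= 1, at most the universe
#'   size).
#' @param subsample_size Either `NULL` for exact conditioning on all selected
#'   bits, or a positive integer n giving the size of the per-iteration random
#'   conditioning subsample (the value used in large-scale fingerprint runs is
#'   10).
#' @param seed Integer seed for the subsample draws; the call owns its RNG
#'   stream and leaves the global RNG state untouched.
#' @return An `aic_selection` object: `selected` (ordered feature ids),
#'   `aic_trace` (exact AIC of the selection after each step),
#'   `per_target_trace` (tibble of per-target normalized MI after each step),
#'   and `config`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' res <- aic_max_select(table2_fixture(), n_select = 2)
#' res$selected   # "X1" "X2"
#' res$aic_trace  # 0.384, 1
#' @export
aic_max_select <- function(collection, n_select, subsample_size = NULL,
                           seed = 1L) {
  stopifnot(inherits(collection, "target_collection"))
  universe <- collection$feature_universe
  n_select <- as.integer(n_select)
  if (n_select < 1L) stop("n_select must be >= 1", call. = FALSE)
  if (n_select > length(universe)) {
    stop("n_select (", n_select, ") exceeds feature universe size (",
         length(universe), ")", call. = FALSE)
  }
  if (!is.null(subsample_size)) {
    subsample_size <- as.integer(subsample_size)
    if (subsample_size < 1L) stop("subsample_size must be >= 1", call. = FALSE)
  }
  sets <- collection$activity_sets
  se <- vapply(sets, function(a) shannon_entropy(a$labels), numeric(1L))
  degenerate <- names(se)[se == 0]
  if (length(degenerate) > 0L) {
    stop("degenerate target: entropy of activity labels is zero (target ",
         paste(degenerate, collapse = ", "), ")", call. = FALSE)
  }
  vals <- lapply(sets, function(a) a$matrix$values)
  labs <- lapply(sets, function(a) a$labels)
  k <- length(sets)

  selected_idx <- integer(0L)
  aic_trace <- numeric(0L)
  exact_gids <- vector("list", k)   # pattern ids of the full selection
  trace_rows <- list()

  withr::with_seed(seed, {
    for (step in seq_len(n_select)) {
      remaining <- setdiff(seq_along(universe), selected_idx)
      # conditioning context for this iteration's candidate scores
      if (is.null(subsample_size) || length(selected_idx) == 0L) {
        ctx_gids <- exact_gids
      } else {
        sub <- sample(selected_idx, min(subsample_size, length(selected_idx)))
        ctx_gids <- lapply(seq_len(k), function(t) {
          pattern_ids(vals[[t]][, sub, drop = FALSE])
        })
      }
      scores <- vapply(remaining, function(j) {
        s <- 0
        for (t in seq_len(k)) {
          col <- vals[[t]][, j]
          gid <- if (is.null(ctx_gids[[t]])) col + 1L
                 else (ctx_gids[[t]] - 1L) * 2L + col + 1L
          s <- s + min(mi_plugin(gid, labs[[t]]) / se[[t]], 1)
        }
        s / k
      }, numeric(1L))
      best <- remaining[which(scores >= max(scores) - 1e-12)[1L]]
      selected_idx <- c(selected_idx, best)
      for (t in seq_len(k)) {
        col <- vals[[t]][, best]
        gid <- if (is.null(exact_gids[[t]])) col + 1L
               else (exact_gids[[t]] - 1L) * 2L + col + 1L
        exact_gids[[t]] <- match(gid, sort(unique(gid)))
      }
      nmi <- vapply(seq_len(k), function(t) {
        min(mi_plugin(exact_gids[[t]], labs[[t]]) / se[[t]], 1)
      }, numeric(1L))
      aic_trace <- c(aic_trace, mean(nmi))
      trace_rows[[step]] <- tibble::tibble(
        step = step, target_id = names(sets), norm_mi = nmi
      )
    }
  })

  structure(
    list(
      selected = universe[selected_idx],
      aic_trace = aic_trace,
      per_target_trace = dplyr::bind_rows(trace_rows),
      config = list(n_select = n_select, subsample_size = subsample_size,
                    seed = as.integer(seed), tie_break = "lowest_index",
                    method = "greedy")
    ),
    class = "aic_selection"
  )
}

#' Exhaustive best subset by Average Information Content
#'
#' Evaluates AIC on every feature subset of the given size and returns the
#' maximizer (ties broken to the lexicographically smallest index tuple).
#' Feasible only for small universes -- the number of subsets explodes
#' combinatorially (a 10-of-1000 search has on the order of 2e23 subsets) --
#' so a guard refuses instances above `guard` subsets; this function serves
#' as an exact oracle against which the greedy selector is checked.
#'
#' @inheritParams aic_max_select
#' @param size Subset size to search.
#' @param guard Maximum number of subsets to enumerate (default 1e6).
#' @return An `aic_selection` object with `selected` in universe order and
#'   `aic_trace` holding the exact AIC of each prefix of the winning subset.
#' @examples
#' exhaustive_best_subset(table2_fixture(), size = 2)$selected # "X1" "X2"
#' @export
exhaustive_best_subset <- function(collection, size, guard = 1e6) {
  stopifnot(inherits(collection, "target_collection"))
  universe <- collection$feature_universe
  size <- as.integer(size)
  if (size < 1L || size > length(universe)) {
    stop("size must be between 1 and the universe size", call. = FALSE)
  }
  n_subsets <- choose(length(universe), size)
  if (n_subsets > guard) {
    stop("subset count ", format(n_subsets), " exceeds guard (", guard,
         "); use aic_max_select for instances this large", call. = FALSE)
  }
  combos <- utils::combn(seq_along(universe), size)
  scores <- apply(combos, 2L, function(idx) {
    average_information_content(collection, universe[idx])
  })
  best <- combos[, which(scores >= max(scores) - 1e-12)[1L]]
  sel <- universe[best]
  trace <- vapply(seq_along(sel), function(s) {
    average_information_content(collection, sel[seq_len(s)])
  }, numeric(1L))
  pt <- information_curve(collection, sel, sizes = length(sel))
  structure(
    list(
      selected = sel,
      aic_trace = trace,
      per_target_trace = tibble::tibble(step = length(sel),
                                        target_id = pt$target_id,
                                        norm_mi = pt$norm_mi),
      config = list(n_select = size, subsample_size = NULL, seed = NA_integer_,
                    tie_break = "lowest_index", method = "exhaustive")
    ),
    class = "aic_selection"
  )
}

#' Information growth curve of a selection
#'
#' Recomputes, for each requested prefix size s, the exact per-target
#' normalized mutual information of the first s selected bits, together with
#' their mean (the AIC). This is the curve relating representation length to
#' captured activity information.
#'
#' @param collection A [target_collection()].
#' @param result An `aic_selection` or a character vector of feature ids in
#'   selection order.
#' @param sizes Integer vector of prefix sizes (0 allowed: an empty set
#'   carries no information). Defaults to every prefix.
#' @return A tibble with columns `n_bits`, `target_id`, `norm_mi`, `aic`
#'   (the mean over targets, repeated within each `n_bits` group).
#' @export
information_curve <- function(collection, result, sizes = NULL) {
  stopifnot(inherits(collection, "target_collection"))
  sel <- if (inherits(result, "aic_selection")) result$selected
         else as.character(result)
  check_feature_subset(sel, collection$feature_universe)
  if (is.null(sizes)) sizes <- seq_along(sel)
  sizes <- as.integer(sizes)
  if (any(sizes < 0L) || any(sizes > length(sel))) {
    stop("prefix sizes must lie in [0, ", length(sel), "]", call. = FALSE)
  }
  tids <- target_ids(collection)
  rows <- lapply(sizes, function(s) {
    nmi <- if (s == 0L) stats::setNames(rep(0, length(tids)), tids)
           else per_target_nmi(collection, sel[seq_len(s)])
    tibble::tibble(n_bits = s, target_id = tids, norm_mi = unname(nmi),
                   aic = mean(nmi))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.aic_selection <- function(x, ...) {
  cat(sprintf("<aic_selection (%s): %d bits, final AIC = %.4f>\n",
              x$config$method, length(x$selected),
              x$aic_trace[length(x$aic_trace)]))
  cat("selected:", paste(utils::head(x$selected, 10L), collapse = ", "),
      if (length(x$selected) > 10L) "..." else "", "\n")
  invisible(x)
}
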