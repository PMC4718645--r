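#' Specification of a synthetic multi-target dataset
#'
#' Describes a multi-target binary dataset with planted ground truth,
#' emulating the structure of real screening data: per-target compound sets of
#' actives plus putative inactives at a fixed ratio, a handful of
#' activity-determining ("informative") bits, redundant bits that exactly copy
#' or negate informative ones, and independent noise bits.
#'
#' Each target's activity rule is an AND over a pair of informative bits by
#' default (pairs cycle through the informative pool so every planted bit
#' matters for some target); `rules` can override this with one integer vector
#' of informative-bit indices per target (activity = AND over those bits) or a
#' function of the informative-bit matrix returning a logical vector.
#'
#' Actives have their informative bits drawn at `bit_prevalence` conditioned
#' on the rule holding; putative inactives are drawn at half that prevalence
#' conditioned on the rule failing, mimicking decoys sampled from a vendor
#' library being structurally distinct from actives. Noise and redundant bits
#' are unaffected by the labels.
#'
#' @param n_targets Number of targets K (default 3).
#' @param n_actives Actives per target (default 200).
#' @param inactive_ratio Putative inactives per active (default 9, the
#'   standard decoy ratio).
#' @param n_informative Number of activity-determining bits (default 5).
#' @param n_redundant Number of exact copies/negations of informative bits
#'   (default 10; copy and negation alternate by index).
#' @param n_noise Number of independent noise bits (default 85).
#' @param bit_prevalence Probability a bit is set (default 0.5).
#' @param label_noise Probability of flipping each label (default 0; must be
#'   < 0.5).
#' @param rules Optional per-target activity rules (see Details).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_targets = 3, n_actives = 200, inactive_ratio = 9,
                           n_informative = 5, n_redundant = 10, n_noise = 85,
                           bit_prevalence = 0.5, label_noise = 0,
                           rules = NULL, seed = 1L) {
  stopifnot(n_targets >= 1, n_actives >= 1, inactive_ratio >= 0,
            n_informative >= 1, n_redundant >= 0, n_noise >= 0,
            bit_prevalence > 0, bit_prevalence < 1,
            label_noise >= 0, label_noise < 0.5)
  if (is.null(rules)) {
    rules <- lapply(seq_len(n_targets), function(i) {
      b <- c(2L * i - 1L, 2L * i)
      (b - 1L) %% n_informative + 1L
    })
  }
  if (length(rules) != n_targets) {
    stop("need one activity rule per target", call. = FALSE)
  }
  for (r in rules) {
    if (!is.function(r)) {
      r <- as.integer(r)
      if (length(r) == 0L || any(r < 1L) || any(r > n_informative)) {
        stop("activity rule references informative bits outside 1..",
             n_informative, call. = FALSE)
      }
    }
  }
  structure(
    list(n_targets = as.integer(n_targets), n_actives = as.integer(n_actives),
         inactive_ratio = inactive_ratio,
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant), n_noise = as.integer(n_noise),
         bit_prevalence = bit_prevalence, label_noise = label_noise,
         rules = rules, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

apply_rule <- function(rule, inf_bits) {
  if (is.function(rule)) as.logical(rule(inf_bits))
  else rowSums(inf_bits[, as.integer(rule), drop = FALSE] == 1L) == length(rule)
}

# Draw `n` rows of informative bits iid Bernoulli(prev), conditioned on the
# activity rule evaluating to `want`. Rejection sampling in batches.
draw_conditioned <- function(n, n_informative, prev, rule, want) {
  out <- matrix(0L, nrow = 0L, ncol = n_informative)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) {
      stop("activity rule outcome has negligible probability at ",
           "bit_prevalence = ", prev, call. = FALSE)
    }
    batch <- matrix(
      as.integer(stats::runif(4L * n * n_informative) < prev),
      ncol = n_informative
    )
    keep <- apply_rule(rule, batch) == want
    out <- rbind(out, batch[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic multi-target collection with known ground truth
#'
#' Realizes a [synthetic_spec()]: each target gets an independent compound
#' set of `n_actives` actives and `round(n_actives * inactive_ratio)` putative
#' inactives, labels determined by the target's rule over the planted
#' informative bits (then flipped with probability `label_noise`), redundant
#' bits that are exact copies or negations of informative bits, and
#' independent noise bits. Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements
#'   * `collection`: the [target_collection()];
#'   * `truth`: tibble with one row per feature (`feature_id`, `role` in
#'     informative/redundant/noise, `source_feature`, `transform`);
#'   * `rules`: tibble describing each target's activity rule.
#' @examples
#' sim <- generate_multitarget_data(synthetic_spec(n_actives = 50, seed = 7))
#' sim$truth
#' @export
generate_multitarget_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_inact <- as.integer(round(spec$n_actives * spec$inactive_ratio))
  n_total <- spec$n_actives + n_inact
  inf_ids <- sprintf("informative:%d", seq_len(spec$n_informative))
  red_ids <- sprintf("redundant:%d", seq_len(spec$n_redundant))
  noise_ids <- sprintf("noise:%d", seq_len(spec$n_noise))
  universe <- c(inf_ids, red_ids, noise_ids)
  red_source <- if (spec$n_redundant > 0L) {
    (seq_len(spec$n_redundant) - 1L) %% spec$n_informative + 1L
  } else integer(0L)
  red_negate <- seq_len(spec$n_redundant) %% 2L == 0L  # odd copy, even negate

  sets <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_targets), function(i) {
      rule <- spec$rules[[i]]
      inf_act <- draw_conditioned(spec$n_actives, spec$n_informative,
                                  spec$bit_prevalence, rule, TRUE)
      inf_inact <- if (n_inact > 0L) {
        draw_conditioned(n_inact, spec$n_informative,
                         spec$bit_prevalence / 2, rule, FALSE)
      } else matrix(0L, 0L, spec$n_informative)
      inf <- rbind(inf_act, inf_inact)
      red <- matrix(0L, n_total, spec$n_redundant)
      for (r in seq_len(spec$n_redundant)) {
        src <- inf[, red_source[r]]
        red[, r] <- if (red_negate[r]) 1L - src else src
      }
      noise <- matrix(as.integer(stats::runif(n_total * spec$n_noise) <
                                   spec$bit_prevalence),
                      n_total, spec$n_noise)
      labels <- c(rep(1L, spec$n_actives), rep(0L, n_inact))
      if (spec$label_noise > 0) {
        flip <- stats::runif(n_total) < spec$label_noise
        labels[flip] <- 1L - labels[flip]
      }
      values <- cbind(inf, red, noise)
      dimnames(values) <- list(sprintf("t%d_c%d", i, seq_len(n_total)),
                               universe)
      activity_set(bit_matrix(values), labels, sprintf("target_%d", i))
    })
  })

  truth <- tibble::tibble(
    feature_id = universe,
    role = c(rep("informative", spec$n_informative),
             rep("redundant", spec$n_redundant),
             rep("noise", spec$n_noise)),
    source_feature = c(rep(NA_character_, spec$n_informative),
                       inf_ids[red_source],
                       rep(NA_character_, spec$n_noise)),
    transform = c(rep(NA_character_, spec$n_informative),
                  ifelse(red_negate, "negation", "copy"),
                  rep(NA_character_, spec$n_noise))
  )
  rules <- tibble::tibble(
    target_id = sprintf("target_%d", seq_len(spec$n_targets)),
    rule = vapply(spec$rules, function(r) {
      if (is.function(r)) "custom function"
      else paste0("AND(", paste(inf_ids[as.integer(r)], collapse = ", "), ")")
    }, character(1L))
  )
  list(collection = target_collection(sets), truth = truth, rules = rules)
}

#' Toy collection: three targets each determined by its own bit
#'
#' An 8-compound, 3-bit matrix enumerating all bit patterns, shared by three
#' targets whose activity labels equal X1, X2 and X3 respectively. The classic
#' illustration of the AIC extremes: each bit scores 1 against its own target,
#' 0 against any other, and the pair \{X1, X2\} scores 2/3 over all three
#' targets (full information for two targets out of three).
#'
#' @return A [target_collection()] with K = 3.
#' @examples
#' average_information_content(table1_fixture(), "X1") # vs all 3 targets: 1/3
#' @export
table1_fixture <- function() {
  values <- as.matrix(expand.grid(X3 = 0:1, X2 = 0:1, X1 = 0:1))[, 3:1]
  storage.mode(values) <- "integer"
  rownames(values) <- as.character(1:8)
  bm <- bit_matrix(values)
  target_collection(lapply(1:3, function(i) {
    activity_set(bm, values[, i], sprintf("Y%d", i))
  }))
}

#' Toy collection: redundant and irrelevant bits
#'
#' One target, 8 compounds, 4 bits: activity Y = X1 AND X2; X3 is independent
#' of Y; X4 = NOT(X1) is perfectly anti-correlated with X1. Illustrates that
#' adding an irrelevant bit (X3) or a fully correlated one (X4) leaves the
#' score unchanged: AIC(X1) = AIC(X1, X3) = AIC(X1, X4) = 0.38, while
#' \{X1, X2\} reaches 1.
#'
#' @return A [target_collection()] with K = 1.
#' @export
table2_fixture <- function() {
  x1 <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  x2 <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  x3 <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  values <- cbind(X1 = x1, X2 = x2, X3 = x3, X4 = 1L - x1)
  rownames(values) <- as.character(1:8)
  target_collection(list(
    activity_set(bit_matrix(values), as.integer(x1 & x2), "Y")
  ))
}
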