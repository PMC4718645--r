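#' Binary fingerprint matrix
#'
#' A `bit_matrix` holds a compounds-by-features binary (0/1) matrix with
#' stable string identifiers for both axes. Feature identifiers conventionally
#' carry fingerprint provenance as `"<fingerprint>:<bit-index>"` (e.g.
#' `"pubchem:647"`), but any unique strings are accepted.
#'
#' @param x A data frame whose first column holds compound identifiers and
#'   whose remaining columns are 0/1 bits (column names become feature
#'   identifiers), or a numeric/integer/logical matrix of 0s and 1s.
#' @param compound_ids Optional character vector of compound identifiers;
#'   required when `x` is a matrix without rownames.
#' @param feature_ids Optional character vector of feature identifiers;
#'   required when `x` is a matrix without colnames.
#' @param pattern_descriptions Optional named character vector mapping
#'   feature identifiers to free-text substructure descriptions.
#'
#' @return A `bit_matrix` object.
#' @examples
#' df <- tibble::tibble(compound_id = c("c1", "c2"),
#'                      `maccs:1` = c(0, 1), `maccs:2` = c(1, 1))
#' bm <- bit_matrix(df)
#' dim(bm)
#' @export
bit_matrix <- function(x, compound_ids = NULL, feature_ids = NULL,
                       pattern_descriptions = NULL) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      stop("data frame input needs a compound-id column plus >= 1 bit column",
           call. = FALSE)
    }
    compound_ids <- as.character(x[[1L]])
    feature_ids <- colnames(x)[-1L]
    values <- as.matrix(x[, -1L, drop = FALSE])
  } else if (is.matrix(x)) {
    values <- x
    if (is.null(compound_ids)) compound_ids <- rownames(x)
    if (is.null(feature_ids)) feature_ids <- colnames(x)
  } else {
    stop("`x` must be a data frame or a matrix", call. = FALSE)
  }
  if (is.null(compound_ids) || is.null(feature_ids)) {
    stop("compound and feature identifiers are required", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  compound_ids <- as.character(compound_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(compound_ids)) {
    stop("duplicate compound_ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature_ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(compound_ids) == nrow(values),
            length(feature_ids) == ncol(values))
  dimnames(values) <- list(compound_ids, feature_ids)
  validate_bits(values)
  structure(
    list(values = values, pattern_descriptions = pattern_descriptions),
    class = "bit_matrix"
  )
}

validate_bits <- function(values) {
  if (anyNA(values)) stop("bit matrix contains missing values", call. = FALSE)
  bad <- which(values != 0L & values != 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rn <- rownames(values)
    cn <- colnames(values)
    r <- bad[1L, 1L]; c <- bad[1L, 2L]
    stop(sprintf(
      "non-binary cell value %s at compound %s, feature %s",
      values[r, c],
      if (is.null(rn)) r else rn[r],
      if (is.null(cn)) c else cn[c]
    ), call. = FALSE)
  }
  invisible(values)
}

#' @export
dim.bit_matrix <- function(x) dim(x$values)

#' @export
as.matrix.bit_matrix <- function(x, ...) x$values

#' Convert a bit matrix to a tibble
#'
#' @param x A `bit_matrix`.
#' @param ... Unused.
#' @return A tibble whose first column `compound_id` holds compound
#'   identifiers, followed by one 0/1 column per feature.
#' @export
as_tibble.bit_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(compound_id = rownames(x$values)),
    tibble::as_tibble(x$values)
  )
}

#' Identifiers of a bit matrix or collection
#'
#' @param x A `bit_matrix`, `activity_set` or `target_collection`.
#' @return Character vector of feature (or compound) identifiers.
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.bit_matrix <- function(x) colnames(x$values)

#' @export
feature_ids.activity_set <- function(x) colnames(x$matrix$values)

#' @export
feature_ids.target_collection <- function(x) x$feature_universe

#' @rdname feature_ids
#' @export
compound_ids <- function(x) UseMethod("compound_ids")

#' @export
compound_ids.bit_matrix <- function(x) rownames(x$values)

#' @export
compound_ids.activity_set <- function(x) rownames(x$matrix$values)

#' @export
print.bit_matrix <- function(x, ...) {
  cat(sprintf("<bit_matrix: %d compounds x %d features>\n",
              nrow(x$values), ncol(x$values)))
  print(utils::head(as_tibble.bit_matrix(x)), ...)
  invisible(x)
}

#' One target's labeled compound set
#'
#' Couples a [bit_matrix()] with a binary activity label per compound
#' (1 = active, 0 = inactive or putative inactive) for a single biological
#' target. This is the unit on which empirical probabilities -- the label
#' distribution, the joint bit-pattern distribution, and their joint -- are
#' estimated.
#'
#' @param matrix A `bit_matrix`.
#' @param labels Integer/numeric/logical vector of 0/1 activity labels, one
#'   per compound.
#' @param target_id Single string naming the target.
#' @return An `activity_set` object.
#' @export
activity_set <- function(matrix, labels, target_id) {
  stopifnot(inherits(matrix, "bit_matrix"),
            is.character(target_id), length(target_id) == 1L)
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix$values)) {
    stop("labels length (", length(labels), ") does not match compound count (",
         nrow(matrix$values), ") for target ", target_id, call. = FALSE)
  }
  if (anyNA(labels) || any(labels != 0L & labels != 1L)) {
    stop("labels must be binary", call. = FALSE)
  }
  structure(list(matrix = matrix, labels = labels, target_id = target_id),
            class = "activity_set")
}

#' @export
print.activity_set <- function(x, ...) {
  cat(sprintf("<activity_set '%s': %d compounds (%d active), %d features>\n",
              x$target_id, nrow(x$matrix$values), sum(x$labels),
              ncol(x$matrix$values)))
  invisible(x)
}

#' A multi-target collection over a shared feature universe
#'
#' Bundles K [activity_set()]s whose matrices share an identical, identically
#' ordered feature universe. Compound sets may (and typically do) differ
#' between targets: each target's dataset is assembled independently, so a
#' compound needs an activity label for only one target.
#'
#' @param activity_sets A list of `activity_set` objects (K >= 1).
#' @return A `target_collection` object with elements `activity_sets` and
#'   `feature_universe`.
#' @examples
#' coll <- table2_fixture()
#' feature_ids(coll)
#' @export
target_collection <- function(activity_sets) {
  if (inherits(activity_sets, "activity_set")) {
    activity_sets <- list(activity_sets)
  }
  stopifnot(is.list(activity_sets), length(activity_sets) >= 1L)
  ok <- vapply(activity_sets, inherits, logical(1L), what = "activity_set")
  if (!all(ok)) stop("all elements must be activity_set objects", call. = FALSE)
  universe <- feature_ids(activity_sets[[1L]])
  for (a in activity_sets[-1L]) {
    if (!identical(feature_ids(a), universe)) {
      stop("feature universe mismatch for target ", a$target_id, call. = FALSE)
    }
  }
  ids <- vapply(activity_sets, `[[`, character(1L), "target_id")
  if (anyDuplicated(ids)) stop("duplicate target_ids", call. = FALSE)
  names(activity_sets) <- ids
  structure(list(activity_sets = activity_sets, feature_universe = universe),
            class = "target_collection")
}

#' @export
print.target_collection <- function(x, ...) {
  cat(sprintf("<target_collection: %d targets, %d shared features>\n",
              length(x$activity_sets), length(x$feature_universe)))
  for (a in x$activity_sets) print(a)
  invisible(x)
}

#' @rdname feature_ids
#' @export
target_ids <- function(x) {
  stopifnot(inherits(x, "target_collection"))
  names(x$activity_sets)
}
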