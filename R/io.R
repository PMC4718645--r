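#' Read a bit matrix from CSV
#'
#' Two dialects are accepted. `"dense"`: a header row of feature ids, a first
#' column of compound ids, and 0/1 cells. `"sparse"`: a triplet file with
#' columns `compound_id`, `feature_id`, `value` listing only set bits (absent
#' pairs are 0); identifier order follows first appearance unless explicit
#' `compound_ids`/`feature_ids` are supplied (needed to preserve all-zero rows
#' or columns, which a triplet file cannot represent).
#'
#' @param path Path to a CSV file.
#' @param dialect `"dense"` (default) or `"sparse"`.
#' @param compound_ids,feature_ids Optional explicit identifier order for the
#'   sparse dialect.
#' @return A [bit_matrix()].
#' @export
read_bit_matrix <- function(path, dialect = c("dense", "sparse"),
                            compound_ids = NULL, feature_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "dense") {
    df[[1L]] <- as.character(df[[1L]])
    return(bit_matrix(df))
  }
  need <- c("compound_id", "feature_id", "value")
  if (!all(need %in% names(df))) {
    stop("sparse dialect needs columns compound_id, feature_id, value",
         call. = FALSE)
  }
  bad <- which(df$value != 1)
  if (length(bad) > 0L) {
    stop(sprintf("non-binary cell value %s at compound %s, feature %s",
                 df$value[bad[1L]], df$compound_id[bad[1L]],
                 df$feature_id[bad[1L]]), call. = FALSE)
  }
  cids <- if (is.null(compound_ids)) unique(as.character(df$compound_id))
          else as.character(compound_ids)
  fids <- if (is.null(feature_ids)) unique(as.character(df$feature_id))
          else as.character(feature_ids)
  unknown_c <- setdiff(df$compound_id, cids)
  unknown_f <- setdiff(df$feature_id, fids)
  if (length(unknown_c) || length(unknown_f)) {
    stop("triplet refers to undeclared ids: ",
         paste(c(unknown_c, unknown_f), collapse = ", "), call. = FALSE)
  }
  values <- matrix(0L, length(cids), length(fids),
                   dimnames = list(cids, fids))
  values[cbind(match(df$compound_id, cids), match(df$feature_id, fids))] <- 1L
  bit_matrix(values)
}

#' Write a bit matrix to CSV
#'
#' @param x A [bit_matrix()].
#' @param path Output CSV path.
#' @param dialect `"dense"` (default) or `"sparse"` triplets of set bits.
#' @return `path`, invisibly.
#' @export
write_bit_matrix <- function(x, path, dialect = c("dense", "sparse")) {
  stopifnot(inherits(x, "bit_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    readr::write_csv(as_tibble.bit_matrix(x), path, progress = FALSE)
  } else {
    set <- which(x$values == 1L, arr.ind = TRUE)
    readr::write_csv(
      tibble::tibble(
        compound_id = rownames(x$values)[set[, 1L]],
        feature_id = colnames(x$values)[set[, 2L]],
        value = 1L
      )[order(set[, 1L], set[, 2L]), ],
      path, progress = FALSE
    )
  }
  invisible(path)
}

#' Load a multi-target collection from a manifest
#'
#' The manifest is a JSON file binding K targets to one shared feature
#' universe:
#' ```
#' {
#'   "feature_universe": ["maccs:1", ...]  (or omitted: inferred from the
#'                                          first target's matrix),
#'   "targets": [
#'     {"target_id": "5HT2A",
#'      "matrix_path": "5ht2a_bits.csv",
#'      "dialect": "dense",                 (optional, default dense)
#'      "labels_path": "5ht2a_labels.csv"   (CSV compound_id,label)
#'       or "labels_column": "active"       (a column of the dense matrix)
#'     }, ...
#'   ]
#' }
#' ```
#' Relative paths resolve against the manifest's directory. Every target's
#' matrix must carry exactly the universe's features, in any order (columns
#' are reordered to the universe).
#'
#' @param manifest_path Path to the manifest JSON.
#' @return A [target_collection()].
#' @export
load_collection <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$targets) || length(man$targets) == 0L) {
    stop("manifest declares no targets", call. = FALSE)
  }
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  universe <- if (!is.null(man$feature_universe)) {
    unlist(man$feature_universe, use.names = FALSE)
  } else NULL
  sets <- lapply(man$targets, function(tg) {
    dialect <- tg$dialect %||% "dense"
    path <- resolve(tg$matrix_path)
    if (!is.null(tg$labels_column) && dialect == "dense") {
      df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      if (!tg$labels_column %in% names(df)) {
        stop("labels_column '", tg$labels_column, "' absent from ", path,
             call. = FALSE)
      }
      labels <- df[[tg$labels_column]]
      df[[tg$labels_column]] <- NULL
      df[[1L]] <- as.character(df[[1L]])
      bm <- bit_matrix(df)
    } else {
      bm <- read_bit_matrix(path, dialect = dialect,
                            feature_ids = universe)
      lab_df <- readr::read_csv(resolve(tg$labels_path),
                                show_col_types = FALSE, progress = FALSE)
      labels <- lab_df$label[match(compound_ids(bm),
                                   as.character(lab_df$compound_id))]
      if (anyNA(labels)) {
        stop("labels file for target ", tg$target_id,
             " misses some compounds", call. = FALSE)
      }
    }
    activity_set(bm, labels, tg$target_id)
  })
  if (is.null(universe)) universe <- feature_ids(sets[[1L]])
  sets <- lapply(sets, function(a) {
    have <- feature_ids(a)
    missing <- setdiff(universe, have)
    extra <- setdiff(have, universe)
    if (length(missing) || length(extra)) {
      stop("feature universe mismatch for target ", a$target_id,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    if (identical(have, universe)) a
    else activity_set(bit_matrix(a$matrix$values[, universe, drop = FALSE]),
                      a$labels, a$target_id)
  })
  target_collection(sets)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a collection (with labels and manifest) to a directory
#'
#' Emits one dense matrix CSV and one labels CSV per target plus a
#' `manifest.json`, in the exact formats [load_collection()] reads back.
#'
#' @param collection A [target_collection()].
#' @param dir Output directory (created if absent).
#' @param dialect Matrix dialect, `"dense"` (default) or `"sparse"`.
#' @return The manifest path, invisibly.
#' @export
write_collection <- function(collection, dir, dialect = c("dense", "sparse")) {
  stopifnot(inherits(collection, "target_collection"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  targets <- lapply(collection$activity_sets, function(a) {
    stem <- gsub("[^A-Za-z0-9_.-]", "_", a$target_id)
    mpath <- paste0(stem, "_bits.csv")
    lpath <- paste0(stem, "_labels.csv")
    write_bit_matrix(a$matrix, file.path(dir, mpath), dialect = dialect)
    readr::write_csv(
      tibble::tibble(compound_id = compound_ids(a), label = a$labels),
      file.path(dir, lpath), progress = FALSE
    )
    list(target_id = a$target_id, matrix_path = mpath, labels_path = lpath,
         dialect = dialect)
  })
  manifest <- list(feature_universe = collection$feature_universe,
                   targets = unname(targets))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

# md5 of an R object via serialization to a temp file (provenance digests).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

#' Write a selection report
#'
#' One CSV row per selected bit with its rank, provenance (fingerprint name
#' and bit index parsed from the `"<fingerprint>:<bit>"` id when present),
#' optional pattern description, the exact AIC after the step and the
#' per-target normalized MI after the step; plus a JSON sidecar
#' (`<path>.json`) carrying the selection config, seed and input digests so a
#' run can be reproduced exactly.
#'
#' @param result An `aic_selection` from [aic_max_select()].
#' @param collection The [target_collection()] the selection was run on.
#' @param path Output CSV path.
#' @return A tibble of the report rows, invisibly.
#' @export
write_selection_report <- function(result, collection, path) {
  stopifnot(inherits(result, "aic_selection"),
            inherits(collection, "target_collection"))
  has_colon <- grepl(":", result$selected, fixed = TRUE)
  fp <- ifelse(has_colon, sub(":.*$", "", result$selected), NA_character_)
  bit <- ifelse(has_colon, sub("^[^:]*:", "", result$selected), NA_character_)
  pd <- collection$activity_sets[[1L]]$matrix$pattern_descriptions
  report <- tibble::tibble(
    rank = seq_along(result$selected),
    feature_id = result$selected,
    fingerprint = fp,
    bit_index = bit,
    pattern_description = if (is.null(pd)) NA_character_
                          else unname(pd[result$selected]),
    aic_after_step = result$aic_trace
  )
  wide <- tidyr::pivot_wider(result$per_target_trace,
                             names_from = "target_id",
                             values_from = "norm_mi",
                             names_prefix = "nmi_")
  report <- dplyr::bind_cols(report, wide[, -1L, drop = FALSE])
  readr::write_csv(report, path, progress = FALSE)
  sidecar <- list(
    config = result$config,
    selected = result$selected,
    input_digests = lapply(collection$activity_sets, function(a) {
      list(matrix = object_digest(a$matrix$values),
           labels = object_digest(a$labels))
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
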