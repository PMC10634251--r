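# Pose-table data model and the ".types" table dialect.
#
# A pose table is a data.frame with one row per docked pose:
#   pose_id, pocket_id, complex_id, rmsd, is_good, affinity,
#   affinity_source, rec_path, lig_path
# Missing affinity is NA_real_ in memory and the sentinel 0.000 on disk:
# pK 0 is outside the meaningful assay range, but conflating it with a
# real value in memory invites silent bugs, so the sentinel only exists
# in the file dialect.

POSE_TABLE_COLS <- c(
  "pose_id", "pocket_id", "complex_id", "rmsd", "is_good",
  "affinity", "affinity_source", "rec_path", "lig_path"
)

#' Construct a pose table from per-pose vectors
#'
#' Low-level constructor; most users obtain pose tables from
#' [read_types_table()] or [generate_corpus()]. `is_good` is always
#' recomputed from `rmsd` (strictly below 2 Angstrom is a good pose) and
#' `affinity_source` from `affinity` missingness, so the invariants hold
#' by construction.
#'
#' @param pocket_id,complex_id,rmsd,affinity,rec_path,lig_path per-pose vectors.
#' @param pose_id optional pose identifiers; derived from `complex_id`
#'   plus a per-complex counter when `NULL`.
#' @param affinity_source optional; entries must be `"experimental"`,
#'   `"imputed"` or `"missing"` and consistent with `affinity`.
#' @return a `pose_table` data.frame.
#' @export
pose_table <- function(pocket_id, complex_id, rmsd, affinity,
                       rec_path = NA_character_, lig_path = NA_character_,
                       pose_id = NULL, affinity_source = NULL) {
  n <- length(complex_id)
  rmsd <- as.numeric(rmsd)
  if (any(!is.finite(rmsd)) || any(rmsd < 0)) {
    abort_fmt("rmsd must be finite and non-negative")
  }
  affinity <- as.numeric(affinity)
  if (any(affinity < 0, na.rm = TRUE)) {
    abort_fmt("negative affinities are not supported (pK scale)")
  }
  if (is.null(pose_id)) {
    idx <- stats::ave(seq_len(n), complex_id, FUN = seq_along)
    pose_id <- sprintf("%s#%03d", complex_id, idx)
  }
  if (anyDuplicated(pose_id)) abort_fmt("pose_ids must be unique")
  src <- ifelse(is.na(affinity), "missing", "experimental")
  if (!is.null(affinity_source)) {
    bad <- xor(affinity_source == "missing", is.na(affinity))
    if (any(bad)) abort_fmt("affinity_source inconsistent with affinity missingness")
    src <- affinity_source
  }
  tbl <- data.frame(
    pose_id = as.character(pose_id),
    pocket_id = as.character(pocket_id),
    complex_id = as.character(complex_id),
    rmsd = rmsd,
    is_good = rmsd < 2.0,
    affinity = affinity,
    affinity_source = src,
    rec_path = rep_len(as.character(rec_path), n),
    lig_path = rep_len(as.character(lig_path), n),
    stringsAsFactors = FALSE
  )
  class(tbl) <- c("pose_table", "data.frame")
  validate_pose_table(tbl)
  tbl
}

#' Validate a pose table's invariants
#'
#' Checks pose-id uniqueness, the 2 Angstrom good/bad rule, consistency of
#' `affinity_source` with missingness, and that every complex carries a
#' single affinity value (complexes inherit one label; poses never carry
#' conflicting experimental labels).
#'
#' @param table a `pose_table`.
#' @return the table, invisibly; errors on violation.
#' @export
validate_pose_table <- function(table) {
  if (!is.data.frame(table) || !all(POSE_TABLE_COLS %in% names(table))) {
    abort_fmt("not a pose_table: missing columns")
  }
  if (anyDuplicated(table$pose_id)) abort_fmt("pose_ids must be unique")
  if (any(!is.finite(table$rmsd)) || any(table$rmsd < 0)) {
    abort_fmt("rmsd must be finite and non-negative")
  }
  if (!identical(table$is_good, table$rmsd < 2.0)) {
    abort_fmt("is_good inconsistent with rmsd (< 2 Angstrom rule)")
  }
  if (any(xor(table$affinity_source == "missing", is.na(table$affinity)))) {
    abort_fmt("affinity_source == 'missing' must coincide with NA affinity")
  }
  if (any(table$affinity < 0, na.rm = TRUE)) abort_fmt("negative affinity")
  # one experimental label per complex (imputed labels may be pose-specific)
  exp_rows <- table$affinity_source == "experimental"
  per_cx <- split(table$affinity[exp_rows], table$complex_id[exp_rows])
  bad <- vapply(per_cx, function(a) length(unique(a)) > 1, logical(1))
  if (any(bad)) {
    abort_fmt(
      "complex(es) with inconsistent affinity labels: %s",
      paste(head(names(per_cx)[bad], 5), collapse = ", ")
    )
  }
  invisible(table)
}

#' Read a ".types" pose table
#'
#' Parses the whitespace-separated dialect
#' `pose_label affinity rmsd rec_path lig_path` (one docked pose per
#' line, `#` starts a comment, UTF-8). The rmsd column is authoritative
#' for the good/bad pose flag: lines whose `pose_label` disagrees with
#' the strict `rmsd < 2` rule produce a warning, not an error. An
#' affinity of exactly 0 is the missing-label sentinel and becomes `NA`.
#' `pocket_id` is the first path component of `rec_path`; `complex_id`
#' is the pocket plus the ligand file stem.
#'
#' @param path file to read.
#' @return a `pose_table`.
#' @export
read_types_table <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lineno <- seq_along(lines)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0) {
    return(pose_table(character(), character(), numeric(), numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 5)) {
    abort_fmt("parse error at line %d: expected >= 5 fields, got %d",
              lineno[which(nf < 5)[1]], nf[which(nf < 5)[1]])
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:5]))
  pose_label <- suppressWarnings(as.numeric(m[, 1]))
  affinity <- suppressWarnings(as.numeric(m[, 2]))
  rmsd <- suppressWarnings(as.numeric(m[, 3]))
  bad_num <- which(is.na(pose_label) | is.na(affinity) | is.na(rmsd))
  if (length(bad_num)) {
    abort_fmt("parse error at line %d: non-numeric field", lineno[bad_num[1]])
  }
  if (any(affinity < 0)) {
    abort_fmt(
      "negative affinity at line %d: sign-encoded dialects are not supported; pose quality is carried by the rmsd column",
      lineno[which(affinity < 0)[1]]
    )
  }
  if (any(rmsd < 0)) {
    abort_fmt("negative rmsd at line %d", lineno[which(rmsd < 0)[1]])
  }
  rec_path <- m[, 4]
  lig_path <- m[, 5]
  pocket_id <- vapply(strsplit(rec_path, "/", fixed = TRUE), `[[`, "", 1)
  stem <- sub("\\.[^.]*$", "", basename(lig_path))
  complex_id <- paste0(pocket_id, ":", stem)
  is_good <- rmsd < 2.0
  conflict <- which((pose_label != 0) != is_good)
  if (length(conflict)) {
    warning(sprintf(
      "%d pose label(s) conflict with the rmsd < 2 Angstrom rule (e.g. line %d); rmsd is authoritative",
      length(conflict), lineno[conflict[1]]
    ), call. = FALSE)
  }
  affinity[affinity == 0] <- NA_real_
  pose_table(pocket_id, complex_id, rmsd, affinity,
             rec_path = rec_path, lig_path = lig_path)
}

#' Write a pose table in the ".types" dialect
#'
#' Inverse of [read_types_table()]: affinity to three decimals with
#' missing labels serialised as `0.000`, rmsd to three decimals, stable
#' record order, so reading the written file reproduces the table.
#'
#' @param table a `pose_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_types_table <- function(table, path) {
  validate_pose_table(table)
  aff <- ifelse(is.na(table$affinity), 0, table$affinity)
  lines <- sprintf("%d %.3f %.3f %s %s",
                   as.integer(table$is_good), aff, table$rmsd,
                   table$rec_path, table$lig_path)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Assign pocket clusters to cross-validation folds
#'
#' Clustered cross-validation: each pocket-similarity cluster is
#' independently assigned a uniformly random fold, so similar pockets
#' never straddle the train/test boundary.
#'
#' @param cluster_map named list: cluster id -> character vector of
#'   pocket ids. Every pocket must appear in exactly one cluster.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed; assignment is deterministic given it.
#' @return a `fold_assignment`: list with `n_folds`, `folds` (named
#'   integer vector pocket -> fold in `1:n_folds`) and `cluster_map`.
#' @export
assign_clustered_folds <- function(cluster_map, n_folds = 3, seed) {
  if (!is.list(cluster_map) || length(cluster_map) == 0) {
    abort_fmt("cluster_map must be a non-empty named list")
  }
  if (!is_number(n_folds) || n_folds < 2) abort_fmt("n_folds must be >= 2")
  pockets <- unlist(cluster_map, use.names = FALSE)
  if (anyDuplicated(pockets)) {
    abort_fmt("pocket(s) in more than one cluster: %s",
              paste(head(unique(pockets[duplicated(pockets)]), 5), collapse = ", "))
  }
  cluster_fold <- withr::with_seed(
    as.integer(seed),
    sample.int(n_folds, length(cluster_map), replace = TRUE)
  )
  folds <- rep(cluster_fold, lengths(cluster_map))
  names(folds) <- pockets
  structure(
    list(n_folds = as.integer(n_folds), folds = folds, cluster_map = cluster_map),
    class = "fold_assignment"
  )
}

#' Write / read a fold assignment as two-column delimited text
#'
#' Serialised as tab-separated `pocket_id<TAB>fold`, one pocket per line.
#'
#' @param fa a `fold_assignment`.
#' @param path file path.
#' @return `path` (write) / a named integer vector pocket -> fold (read).
#' @export
write_fold_assignment <- function(fa, path) {
  stopifnot(inherits(fa, "fold_assignment"))
  writeLines(sprintf("%s\t%d", names(fa$folds), fa$folds), path)
  invisible(path)
}

#' @rdname write_fold_assignment
#' @export
read_fold_assignment <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("pocket_id", "fold"),
                  stringsAsFactors = FALSE)
  structure(as.integer(d$fold), names = d$pocket_id)
}

#' Percentage of unlabeled poses, to one decimal
#'
#' The percentage formula used by [compute_dataset_stats()], exposed so
#' that externally reported pose counts can be fed through it directly.
#'
#' @param n_unlabeled,n_poses pose counts.
#' @return `100 * n_unlabeled / n_poses`, rounded to one decimal.
#' @export
percent_unlabeled <- function(n_unlabeled, n_poses) {
  if (n_poses <= 0) abort_fmt("n_poses must be positive")
  round(100 * n_unlabeled / n_poses, 1)
}

#' Summary statistics of a pose table
#'
#' Counts pockets, complexes and poses, the unlabeled poses and their
#' percentage, and the good/bad pose split. Percentages are reported to
#' one decimal.
#'
#' @param table a `pose_table` with at least one pose.
#' @return a `dataset_stats` list: `n_pockets`, `n_complexes`, `n_poses`,
#'   `n_unlabeled_poses`, `pct_unlabeled`, `n_good`, `n_bad`, `pct_bad`.
#' @export
compute_dataset_stats <- function(table) {
  validate_pose_table(table)
  if (nrow(table) == 0) abort_fmt("empty table has no statistics")
  n_poses <- nrow(table)
  n_unl <- sum(is.na(table$affinity))
  n_good <- sum(table$is_good)
  structure(list(
    n_pockets = length(unique(table$pocket_id)),
    n_complexes = length(unique(table$complex_id)),
    n_poses = n_poses,
    n_unlabeled_poses = n_unl,
    pct_unlabeled = percent_unlabeled(n_unl, n_poses),
    n_good = n_good,
    n_bad = n_poses - n_good,
    pct_bad = round(100 * (n_poses - n_good) / n_poses, 1)
  ), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(
    "pose-table stats: %d pockets, %d complexes, %d poses\n  unlabeled poses: %d (%.1f%%)\n  bad poses: %d (%.1f%%)\n",
    x$n_pockets, x$n_complexes, x$n_poses,
    x$n_unlabeled_poses, x$pct_unlabeled, x$n_bad, x$pct_bad
  ))
  invisible(x)
}

#' Write dataset statistics as flat key-value JSON
#'
#' @param stats a `dataset_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset_stats <- function(stats, path) {
  stopifnot(inherits(stats, "dataset_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply imputed affinity labels to a pose table
#'
#' Writes model-imputed labels into currently unlabeled records, marking
#' them `affinity_source == "imputed"`. Experimental labels are never
#' overwritten: a key targeting an experimentally labeled complex is an
#' error, as is a key unknown to the table or a target that already
#' carries a label.
#'
#' @param table a `pose_table`.
#' @param labels named numeric vector. Names are pose ids
#'   (`mode = "per_pose"`) or complex ids (`mode = "per_complex"`).
#' @param mode `"per_pose"` writes each value to one pose;
#'   `"per_complex"` writes one value to every pose of the complex (the
#'   same single value for every pose, as with experimental labels).
#' @return a new `pose_table`; the input is not modified.
#' @export
apply_imputed_labels <- function(table, labels, mode = c("per_complex", "per_pose")) {
  mode <- match.arg(mode)
  validate_pose_table(table)
  if (length(labels) == 0) return(table)
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    abort_fmt("labels must be a named numeric vector")
  }
  if (any(!is.finite(labels))) abort_fmt("imputed labels must be finite")
  key_col <- if (mode == "per_pose") table$pose_id else table$complex_id
  unknown <- setdiff(names(labels), key_col)
  if (length(unknown)) {
    abort_fmt("unknown %s key(s): %s", mode,
              paste(head(unknown, 5), collapse = ", "))
  }
  rows <- key_col %in% names(labels)
  src <- table$affinity_source[rows]
  if (any(src == "experimental")) {
    abort_fmt("refusing to overwrite experimental label(s) (e.g. %s)",
              table$complex_id[rows][src == "experimental"][1])
  }
  if (any(src == "imputed")) {
    abort_fmt("target(s) already carry an imputed label; re-impute from the pristine table")
  }
  out <- table
  out$affinity[rows] <- unname(labels[key_col[rows]])
  out$affinity_source[rows] <- "imputed"
  validate_pose_table(out)
  out
}
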