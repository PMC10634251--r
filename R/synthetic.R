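# Seeded synthetic pose corpora with the statistical structure the
# self-training framework assumes: many poses per pocket-ligand pair, a
# small good-pose fraction, affinity signal attenuated by pose quality,
# and a configurable missing-label mechanism.

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate a large cross-docking corpus at desk scale: 20 poses
#' per complex, a ~5% good-pose rate among non-cognate poses (the real
#' corpora are ~96% high-rmsd), and 59% of complexes missing their
#' affinity label. The affinity signal in the features is attenuated by
#' pose quality `q = exp(-rmsd/2)`, so high-rmsd poses carry weak
#' affinity information — the property that makes good-only aggregation
#' meaningfully different from all-pose aggregation.
#'
#' @param n_pockets number of binding pockets.
#' @param ligands_per_pocket ligands docked per pocket (one complex each).
#' @param poses_per_complex docked poses retained per complex.
#' @param good_pose_rate probability that a non-cognate pose is < 2 A rmsd.
#' @param cognate_good_prob probability that the designated cognate pose
#'   (first pose of each complex) is good.
#' @param pk_mean,pk_sd Normal parameters of the per-complex true pK,
#'   truncated to the plausible assay range 2-12.
#' @param feature_dim length of the per-pose feature vector.
#' @param signal_weight weight of the affinity-bearing feature term
#'   `pK * q * u`.
#' @param quality_weight weight of the pose-quality term `q * v`.
#' @param noise_sd standard deviation of the i.i.d. Gaussian feature noise.
#' @param missing_fraction fraction of complexes whose label is hidden by
#'   [hide_labels()].
#' @param missing_mechanism `"by_complex"` (missing-at-random over
#'   complexes, the default) or `"by_pocket"` (whole pockets masked).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_pockets = 40, ligands_per_pocket = 5,
                             poses_per_complex = 20,
                             good_pose_rate = 0.05, cognate_good_prob = 0.8,
                             pk_mean = 6.0, pk_sd = 1.5,
                             feature_dim = 16,
                             signal_weight = 1.0, quality_weight = 1.0,
                             noise_sd = 0.1,
                             missing_fraction = 0.59,
                             missing_mechanism = c("by_complex", "by_pocket")) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_pockets = as.integer(n_pockets),
    ligands_per_pocket = as.integer(ligands_per_pocket),
    poses_per_complex = as.integer(poses_per_complex),
    good_pose_rate = good_pose_rate, cognate_good_prob = cognate_good_prob,
    pk_mean = pk_mean, pk_sd = pk_sd,
    feature_dim = as.integer(feature_dim),
    signal_weight = signal_weight, quality_weight = quality_weight,
    noise_sd = noise_sd,
    missing_fraction = missing_fraction, missing_mechanism = missing_mechanism
  )
  probs <- c(cfg$good_pose_rate, cfg$cognate_good_prob, cfg$missing_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_fmt("probabilities must lie in [0, 1]")
  }
  counts <- c(cfg$n_pockets, cfg$ligands_per_pocket, cfg$poses_per_complex,
              cfg$feature_dim)
  if (any(counts < 1)) abort_fmt("counts must be positive")
  if (!is_number(cfg$pk_sd) || cfg$pk_sd <= 0) abort_fmt("pk_sd must be > 0")
  if (!is_number(cfg$noise_sd) || cfg$noise_sd < 0) abort_fmt("noise_sd must be >= 0")
  structure(cfg, class = "synthetic_config")
}

# truncated-normal draws via inverse-CDF so the draw count is fixed
rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a fully labeled synthetic pose corpus
#'
#' Draws `n_pockets * ligands_per_pocket` complexes with
#' `poses_per_complex` poses each. Per complex, a true pK is drawn from
#' Normal(`pk_mean`, `pk_sd`) truncated to 2-12; the first pose of each
#' complex plays the cognate pose and is good with probability
#' `cognate_good_prob`, the rest with probability `good_pose_rate`. Good
#' poses get rmsd ~ Uniform(0.2, 1.8) A and bad poses
#' Uniform(2.5, 10) A (only the 2 A dichotomy matters downstream);
#' rmsd is recorded to three decimals, matching the file dialect. Pose
#' quality is `q = exp(-rmsd/2)` and the feature vector is
#' `signal_weight * pK * q * u + quality_weight * q * v + noise`, with
#' `u`, `v` fixed unit directions drawn once per corpus. Every complex is
#' labeled; hiding labels is a separate step ([hide_labels()]). Fully
#' deterministic given `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return a list with `table` (a fully labeled `pose_table`), `truth`
#'   (list: `complex_pk` named numeric, `pose_quality` named numeric) and
#'   `features` (numeric matrix, rownames = pose ids, colnames `f0...`).
#' @export
generate_corpus <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n_cx <- config$n_pockets * config$ligands_per_pocket
  n_poses <- n_cx * config$poses_per_complex
  pocket <- sprintf("P%03d", seq_len(config$n_pockets))
  out <- withr::with_seed(as.integer(seed), {
    pocket_of_cx <- rep(pocket, each = config$ligands_per_pocket)
    stem <- sprintf("lig%02d", rep(seq_len(config$ligands_per_pocket),
                                   times = config$n_pockets))
    complex_id <- paste0(pocket_of_cx, ":", stem)
    # recorded at the file dialect's 3-decimal precision so that the
    # written corpus round-trips exactly
    true_pk <- round(rtruncnorm(n_cx, config$pk_mean, config$pk_sd, 2, 12), 3)
    names(true_pk) <- complex_id

    cx_of_pose <- rep(seq_len(n_cx), each = config$poses_per_complex)
    is_cognate <- rep(c(TRUE, rep(FALSE, config$poses_per_complex - 1)), n_cx)
    p_good <- ifelse(is_cognate, config$cognate_good_prob, config$good_pose_rate)
    good <- runif(n_poses) < p_good
    rmsd <- numeric(n_poses)
    rmsd[good] <- runif(sum(good), 0.2, 1.8)
    rmsd[!good] <- runif(sum(!good), 2.5, 10)
    rmsd <- round(rmsd, 3)

    u <- rnorm(config$feature_dim); u <- u / sqrt(sum(u^2))
    v <- rnorm(config$feature_dim); v <- v / sqrt(sum(v^2))
    q <- exp(-rmsd / 2)
    pk_pose <- true_pk[cx_of_pose]
    feats <- config$signal_weight * (pk_pose * q) %o% u +
      config$quality_weight * q %o% v +
      matrix(rnorm(n_poses * config$feature_dim, 0, config$noise_sd),
             n_poses, config$feature_dim)

    tbl <- pose_table(
      pocket_id = pocket_of_cx[cx_of_pose],
      complex_id = complex_id[cx_of_pose],
      rmsd = rmsd,
      affinity = pk_pose,
      rec_path = sprintf("%s/%s_rec.pdb", pocket_of_cx[cx_of_pose],
                         pocket_of_cx[cx_of_pose]),
      lig_path = sprintf("%s/%s.sdf", pocket_of_cx[cx_of_pose],
                         stem[cx_of_pose])
    )
    rownames(feats) <- tbl$pose_id
    colnames(feats) <- sprintf("f%d", seq_len(config$feature_dim) - 1)
    quality <- q
    names(quality) <- tbl$pose_id
    list(table = tbl,
         truth = list(complex_pk = true_pk, pose_quality = quality),
         features = feats)
  })
  structure(c(out, list(config = config, seed = as.integer(seed))),
            class = "affinity_corpus")
}

#' Hide affinity labels to emulate unlabeled complexes
#'
#' `by_complex` hides exactly `round(missing_fraction * n_complexes)`
#' complexes chosen uniformly without replacement (missing at random).
#' `by_pocket` masks whole pockets in a random order until the fraction
#' of unlabeled complexes first reaches `missing_fraction`, probing
#' pocket-level missingness bias. Deterministic given `seed`.
#'
#' @param table a fully labeled `pose_table`.
#' @param missing_fraction fraction of complexes to unlabel, in \[0, 1\].
#' @param mechanism `"by_complex"` or `"by_pocket"`.
#' @param seed integer seed.
#' @return a new `pose_table` with hidden labels set to missing.
#' @export
hide_labels <- function(table, missing_fraction,
                        mechanism = c("by_complex", "by_pocket"), seed) {
  mechanism <- match.arg(mechanism)
  validate_pose_table(table)
  if (!is_number(missing_fraction) || missing_fraction < 0 || missing_fraction > 1) {
    abort_fmt("missing_fraction must lie in [0, 1]")
  }
  if (any(is.na(table$affinity))) abort_fmt("table must be fully labeled")
  complexes <- unique(table$complex_id)
  hide_cx <- withr::with_seed(as.integer(seed), {
    if (mechanism == "by_complex") {
      sample(complexes, round(missing_fraction * length(complexes)))
    } else {
      pockets <- sample(unique(table$pocket_id))
      cx_per_pocket <- split(unique(table[, c("pocket_id", "complex_id")])$complex_id,
                             unique(table[, c("pocket_id", "complex_id")])$pocket_id)
      hidden <- character(0)
      for (p in pockets) {
        if (length(hidden) >= missing_fraction * length(complexes)) break
        hidden <- c(hidden, cx_per_pocket[[p]])
      }
      hidden
    }
  })
  out <- table
  rows <- out$complex_id %in% hide_cx
  out$affinity[rows] <- NA_real_
  out$affinity_source[rows] <- "missing"
  out
}

#' Summarise a corpus against its generating truth
#'
#' Reports the realized good-pose fraction, realized missing-complex
#' fraction and the true-pK range, recomputed directly from the table.
#'
#' @param table a `pose_table`.
#' @param truth the `truth` component of [generate_corpus()] output.
#' @return a list: `n_poses`, `n_complexes`, `good_fraction`,
#'   `missing_fraction`, `pk_range`.
#' @export
corpus_summary <- function(table, truth) {
  validate_pose_table(table)
  cx <- unique(table$complex_id)
  if (!all(cx %in% names(truth$complex_pk)) ||
      !all(table$pose_id %in% names(truth$pose_quality))) {
    abort_fmt("truth table does not cover this corpus")
  }
  missing_cx <- vapply(split(is.na(table$affinity), table$complex_id),
                       all, logical(1))
  list(
    n_poses = nrow(table),
    n_complexes = length(cx),
    good_fraction = mean(table$is_good),
    missing_fraction = mean(missing_cx),
    pk_range = range(truth$complex_pk[cx])
  )
}

#' Write / read a per-pose feature matrix as delimited text
#'
#' Format: CSV with header `pose_id,f0,...`, one row per pose.
#'
#' @param features numeric matrix with pose-id rownames.
#' @param path file path.
#' @return `path` (write) / the matrix (read).
#' @export
write_features <- function(features, path) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  df <- data.frame(pose_id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pose_id
  m
}

#' Read a synthetic-corpus configuration from a flat key-value file
#'
#' Accepts YAML-style `key: value` lines (comments with `#`); keys match
#' the arguments of [synthetic_config()].
#'
#' @param path configuration file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(args) <- keys
  known <- names(formals(synthetic_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) abort_fmt("unknown config key(s): %s",
                                 paste(unknown, collapse = ", "))
  do.call(synthetic_config, args)
}
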