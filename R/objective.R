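# Dual-task training objective: logistic pose-classification loss plus a
# pseudo-Huber affinity loss that is hinged on high-rmsd poses, and the
# balanced, pocket-stratified minibatch sampler with upsampling.

#' Loss configuration
#'
#' @param delta pseudo-Huber transition scale in pK units. The loss is
#'   quadratic for errors well below `delta` and linear above; 4.0 keeps
#'   it quadratic over typical pK errors.
#' @param pose_weight,affinity_weight non-negative weights of the two
#'   loss terms in the combined objective.
#' @param prob_floor clipping bound applied inside the logistic loss so
#'   that degenerate probabilities stay finite.
#' @return a `loss_config` list.
#' @export
loss_config <- function(delta = 4.0, pose_weight = 1.0, affinity_weight = 1.0,
                        prob_floor = 1e-6) {
  if (!is_number(delta) || delta <= 0) abort_fmt("delta must be > 0")
  if (pose_weight < 0 || affinity_weight < 0) abort_fmt("loss weights must be >= 0")
  if (!is_number(prob_floor) || prob_floor <= 0 || prob_floor >= 0.5) {
    abort_fmt("prob_floor must lie in (0, 0.5)")
  }
  structure(list(delta = delta, pose_weight = pose_weight,
                 affinity_weight = affinity_weight, prob_floor = prob_floor),
            class = "loss_config")
}

#' Pseudo-Huber loss
#'
#' `delta^2 * (sqrt(1 + (d/delta)^2) - 1)`: quadratic (`d^2/2`) for small
#' `|d|`, linear (`delta * |d|`) asymptotically; even and strictly
#' increasing in `|d|`.
#'
#' @param d residual(s); must be finite.
#' @param delta transition scale, > 0.
#' @return non-negative loss, vectorized over `d`.
#' @export
pseudo_huber <- function(d, delta = 4.0) {
  if (!is_number(delta) || delta <= 0) abort_fmt("delta must be > 0")
  if (any(!is.finite(d))) abort_fmt("residuals must be finite")
  delta^2 * (sqrt(1 + (d / delta)^2) - 1)
}

#' Hinged pseudo-Huber affinity loss
#'
#' For a good (< 2 A rmsd) pose the loss penalises both over- and
#' under-prediction: `pseudo_huber(pred - label)`. For a bad pose the
#' loss is hinged: exactly 0 whenever the model under-predicts
#' (`pred <= label`), since a low-quality pose should not score a high
#' affinity, and `pseudo_huber(pred - label)` when it over-predicts.
#' A missing label contributes 0 (and is excluded from the affinity-term
#' normalisation in [combined_batch_loss()]). The rule is applied
#' identically to experimental and imputed labels.
#'
#' @param pred predicted affinity (pK), finite.
#' @param label affinity label (pK) or `NA` for missing.
#' @param is_good logical good-pose flag.
#' @param config a [loss_config()].
#' @return non-negative loss, vectorized.
#' @export
affinity_loss <- function(pred, label, is_good, config = loss_config()) {
  if (any(!is.finite(pred))) abort_fmt("predictions must be finite")
  n <- max(length(pred), length(label), length(is_good))
  pred <- rep_len(pred, n); label <- rep_len(label, n)
  is_good <- rep_len(is_good, n)
  d <- pred - label
  d[!is_good] <- pmax(0, d[!is_good])
  out <- numeric(n)
  ok <- !is.na(label)
  out[ok] <- pseudo_huber(d[ok], config$delta)
  out
}

#' Logistic pose-classification loss
#'
#' `-log(p)` for a good pose and `-log(1 - p)` for a bad one, with the
#' probability clipped to `[prob_floor, 1 - prob_floor]` so degenerate
#' predictions stay finite.
#'
#' @param prob_good predicted probability of the good class, in \[0, 1\].
#' @param is_good logical good-pose flag.
#' @param config a [loss_config()].
#' @return non-negative loss, vectorized.
#' @export
pose_loss <- function(prob_good, is_good, config = loss_config()) {
  if (any(is.na(prob_good)) || any(prob_good < 0 | prob_good > 1)) {
    abort_fmt("prob_good must lie in [0, 1]")
  }
  n <- max(length(prob_good), length(is_good))
  p <- rep_len(prob_good, n); g <- rep_len(is_good, n)
  p <- ifelse(g, p, 1 - p)
  -log(pmin(pmax(p, config$prob_floor), 1 - config$prob_floor))
}

#' Combined batch loss
#'
#' `pose_weight * mean(pose losses) + affinity_weight * mean(affinity
#' losses over poses with a label)`. Unlabeled poses are masked out of
#' the affinity mean (not averaged in as zeros); with no labeled pose in
#' the batch the affinity term is 0.
#'
#' @param predictions data.frame/list with `pose_score` and
#'   `affinity_pred` aligned to `batch$pose_ids` (checked).
#' @param batch a batch from [make_balanced_batches()], or any list with
#'   `pose_ids`, `is_good`, `affinity`.
#' @param config a [loss_config()].
#' @return list: `total`, `pose_term`, `affinity_term`, `n_labeled`.
#' @export
combined_batch_loss <- function(predictions, batch, config = loss_config()) {
  n <- length(batch$pose_ids)
  if (length(predictions$pose_score) != n ||
      length(predictions$affinity_pred) != n) {
    abort_fmt("predictions are not aligned to the batch")
  }
  if (!is.null(predictions$pose_id) &&
      !identical(as.character(predictions$pose_id), as.character(batch$pose_ids))) {
    abort_fmt("prediction pose_ids do not match the batch")
  }
  pl <- pose_loss(predictions$pose_score, batch$is_good, config)
  al <- affinity_loss(predictions$affinity_pred, batch$affinity,
                      batch$is_good, config)
  labeled <- !is.na(batch$affinity)
  aff_term <- if (any(labeled)) mean(al[labeled]) else 0
  pose_term <- mean(pl)
  list(total = config$pose_weight * pose_term + config$affinity_weight * aff_term,
       pose_term = pose_term, affinity_term = aff_term,
       n_labeled = sum(labeled))
}

#' Balanced, pocket-stratified minibatch iterator
#'
#' Returns an infinite iterator over batches that are exactly balanced
#' with respect to the pose class: each batch holds `batch_size/2` good
#' and `batch_size/2` bad poses. Each slot is filled by drawing a pocket
#' uniformly at random (among pockets containing the required class) and
#' then a pose of that class within the pocket uniformly with
#' replacement — so the minority class is upsampled and every pocket is
#' sampled evenly regardless of its pose count. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param table a `pose_table` with at least one good and one bad pose.
#' @param features numeric matrix with pose-id rownames covering the table.
#' @param batch_size even batch size (default 50).
#' @param seed integer seed of the private sampling stream.
#' @return a function `next_batch()` returning a `pose_batch` list:
#'   `pose_ids`, `features`, `is_good`, `affinity`, `complex_id`,
#'   `pocket_id`.
#' @export
make_balanced_batches <- function(table, features, batch_size = 50, seed) {
  validate_pose_table(table)
  if (batch_size %% 2 != 0 || batch_size < 2) {
    abort_fmt("batch_size must be a positive even number")
  }
  missing_feat <- setdiff(table$pose_id, rownames(features))
  if (length(missing_feat)) {
    abort_fmt("features missing for %d pose(s)", length(missing_feat))
  }
  idx_by <- function(flag) {
    rows <- which(table$is_good == flag)
    if (length(rows) == 0) {
      abort_fmt("no %s pose in any pocket", if (flag) "good" else "bad")
    }
    sp <- split(rows, table$pocket_id[rows])
    list(flat = unlist(sp, use.names = FALSE),
         start = cumsum(c(1, head(lengths(sp), -1))),
         len = lengths(sp))
  }
  good <- idx_by(TRUE)
  bad <- idx_by(FALSE)
  feat <- features[table$pose_id, , drop = FALSE]
  k <- batch_size / 2
  stream <- rng_stream(seed)

  draw <- function(pool) {
    p <- sample.int(length(pool$len), k, replace = TRUE)
    off <- pmin(pool$len[p], ceiling(runif(k) * pool$len[p]))
    off[off < 1] <- 1
    pool$flat[pool$start[p] + off - 1]
  }

  function() {
    rows <- stream(function() c(draw(good), draw(bad)))
    structure(list(
      pose_ids = table$pose_id[rows],
      features = feat[rows, , drop = FALSE],
      is_good = table$is_good[rows],
      affinity = table$affinity[rows],
      complex_id = table$complex_id[rows],
      pocket_id = table$pocket_id[rows]
    ), class = "pose_batch")
  }
}
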