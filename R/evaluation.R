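# Pose selection, affinity and pose metrics, and the significance
# machinery: bootstrap CI of the mean, two-sample t-test between rounds,
# and the 10,000-rep bootstrap RMSE comparison.

#' Select each complex's top-scored pose
#'
#' Per complex, the pose with the highest predicted pose score becomes
#' the candidate whose predicted affinity is evaluated. Exact score ties
#' are broken by the lexicographically lowest pose id (deterministic).
#'
#' @param predictions a `prediction_table` covering the table.
#' @param table a `pose_table`.
#' @return a `candidate_set` data.frame: `complex_id`, `pose_id`,
#'   `pose_score`, `affinity_pred`, `rmsd`, `affinity` (`NA` when the
#'   complex has no experimental label).
#' @export
select_top_pose <- function(predictions, table) {
  validate_pose_table(table)
  miss <- setdiff(table$pose_id, predictions$pose_id)
  if (length(miss)) {
    abort_fmt("complex(es) without predictions (e.g. pose %s)", miss[1])
  }
  p <- structure(predictions$pose_score, names = predictions$pose_id)
  a <- structure(predictions$affinity_pred, names = predictions$pose_id)
  score <- unname(p[table$pose_id])
  # order by complex, then score descending, then pose_id ascending:
  # the first row per complex is the winner
  ord <- order(table$complex_id, -score, table$pose_id)
  first <- ord[!duplicated(table$complex_id[ord])]
  exp_aff <- table$affinity
  exp_aff[table$affinity_source != "experimental"] <- NA_real_
  out <- data.frame(
    complex_id = table$complex_id[first],
    pose_id = table$pose_id[first],
    pose_score = score[first],
    affinity_pred = unname(a[table$pose_id[first]]),
    rmsd = table$rmsd[first],
    affinity = exp_aff[first],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Affinity regression metrics over labeled complexes
#'
#' RMSE, Pearson R and the coefficient of determination
#' `1 - SS_res/SS_tot` (with the squared Pearson correlation reported
#' secondarily as `pearson_r2`), computed over the candidates whose
#' complex has an experimental label; unlabeled complexes are excluded.
#'
#' @param candidates a `candidate_set` from [select_top_pose()].
#' @return list: `rmse`, `pearson_r`, `r_squared`, `pearson_r2`, `n`.
#' @export
affinity_metrics <- function(candidates) {
  ok <- !is.na(candidates$affinity)
  y <- candidates$affinity[ok]
  yhat <- candidates$affinity_pred[ok]
  if (length(y) < 2 || length(unique(y)) < 2) {
    abort_fmt("affinity metrics need >= 2 labeled complexes with non-constant labels")
  }
  res <- yhat - y
  r <- stats::cor(yhat, y)
  list(
    rmse = sqrt(mean(res^2)),
    pearson_r = r,
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    pearson_r2 = r^2,
    n = length(y)
  )
}

#' Pose classification metrics
#'
#' AUC is the rank-based probability that a randomly chosen good pose
#' outscores a randomly chosen bad one (ties count one half), computed
#' over all poses of the table. Top1 is the fraction of complexes whose
#' selected candidate pose is below 2 A rmsd; the denominator is all
#' complexes.
#'
#' @param predictions a `prediction_table` covering the table.
#' @param table a `pose_table` containing both pose classes.
#' @param candidates a `candidate_set` from [select_top_pose()].
#' @return list: `auc`, `top1`.
#' @export
pose_metrics <- function(predictions, table, candidates) {
  s <- structure(predictions$pose_score, names = predictions$pose_id)
  score <- unname(s[table$pose_id])
  if (any(is.na(score))) abort_fmt("predictions do not cover the table")
  g <- table$is_good
  n_pos <- sum(g); n_neg <- sum(!g)
  if (n_pos == 0 || n_neg == 0) {
    abort_fmt("AUC undefined: only one pose class present")
  }
  r <- rank(score)          # midranks handle ties as 1/2
  auc <- (sum(r[g]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auc = auc, top1 = mean(candidates$rmsd < 2.0))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values numeric vector, length >= 2.
#' @param n_boot bootstrap replicates (default 10,000).
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @param seed integer seed.
#' @return list: `mean`, `lower`, `upper`.
#' @export
bootstrap_ci_mean <- function(values, n_boot = 10000, alpha = 0.05, seed) {
  n <- length(values)
  if (n < 2) abort_fmt("need at least two values")
  boots <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    rowMeans(matrix(values[idx], n_boot, n))
  })
  qs <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  list(mean = mean(values), lower = qs[1], upper = qs[2])
}

#' Two-sample t-test between per-model metric populations
#'
#' Unpaired Student's t-test with pooled variance, comparing e.g. the
#' five per-seed RMSE values of round 0 against those of round 1. With
#' zero pooled variance and equal means the p-value is 1 by convention.
#'
#' @param metrics_a,metrics_b numeric vectors, each of length >= 2.
#' @return list: `t`, `df`, `p_value` (two-sided).
#' @export
compare_rounds_ttest <- function(metrics_a, metrics_b) {
  if (length(metrics_a) < 2 || length(metrics_b) < 2) {
    abort_fmt("each group needs >= 2 values")
  }
  if (stats::var(metrics_a) == 0 && stats::var(metrics_b) == 0) {
    if (mean(metrics_a) == mean(metrics_b)) {
      return(list(t = 0, df = length(metrics_a) + length(metrics_b) - 2,
                  p_value = 1))
    }
    return(list(t = Inf, df = length(metrics_a) + length(metrics_b) - 2,
                p_value = 0))
  }
  tt <- t.test(metrics_a, metrics_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Bootstrap RMSE comparison between two residual vectors
#'
#' Bootstraps the RMSE of each per-complex residual vector (resampling
#' complexes with replacement, default 10,000 replicates), reports the
#' two 95% percentile intervals, flags significance when the intervals
#' do not overlap, and reports the one-tailed bootstrap p-value for the
#' hypothesis that `errors_b` has lower RMSE than `errors_a` (the
#' fraction of replicate pairs in which b's RMSE is at least a's).
#'
#' @param errors_a,errors_b non-empty residual vectors (prediction minus
#'   label per complex).
#' @param n_boot replicates (default 10,000).
#' @param alpha two-sided level of each interval.
#' @param seed integer seed.
#' @return list: `rmse_a`, `ci_a`, `rmse_b`, `ci_b`, `significant`,
#'   `one_tailed_p`, `n_boot`.
#' @export
bootstrap_rmse_compare <- function(errors_a, errors_b, n_boot = 10000,
                                   alpha = 0.05, seed) {
  if (length(errors_a) == 0 || length(errors_b) == 0) {
    abort_fmt("residual vectors must be non-empty")
  }
  boot_rmse <- function(e) {
    n <- length(e)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    sqrt(rowMeans(matrix(e[idx]^2, n_boot, n)))
  }
  res <- withr::with_seed(as.integer(seed), {
    list(a = boot_rmse(errors_a), b = boot_rmse(errors_b))
  })
  ci <- function(x) unname(quantile(x, c(alpha / 2, 1 - alpha / 2)))
  ci_a <- ci(res$a); ci_b <- ci(res$b)
  list(
    rmse_a = sqrt(mean(errors_a^2)), ci_a = ci_a,
    rmse_b = sqrt(mean(errors_b^2)), ci_b = ci_b,
    significant = ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1],
    one_tailed_p = mean(res$b >= res$a),
    n_boot = n_boot
  )
}

#' Full metrics report for one model's test-fold predictions
#'
#' Convenience wrapper combining [select_top_pose()],
#' [affinity_metrics()] and [pose_metrics()], optionally with
#' complex-level bootstrap 95% intervals for each metric.
#'
#' @param predictions a `prediction_table`.
#' @param table the test `pose_table`.
#' @param n_boot bootstrap replicates for the intervals; 0 skips them.
#' @param seed integer seed (required when `n_boot > 0`).
#' @return a `metrics_report` list: `rmse`, `pearson_r`, `r_squared`,
#'   `pearson_r2`, `auc`, `top1`, `n_complexes_evaluated`, and a `ci`
#'   element (per-metric `lower`/`upper`) when `n_boot > 0`.
#' @export
evaluate_predictions <- function(predictions, table, n_boot = 0, seed = NULL) {
  cand <- select_top_pose(predictions, table)
  am <- affinity_metrics(cand)
  pm <- pose_metrics(predictions, table, cand)
  rep <- list(rmse = am$rmse, pearson_r = am$pearson_r,
              r_squared = am$r_squared, pearson_r2 = am$pearson_r2,
              auc = pm$auc, top1 = pm$top1, n_complexes_evaluated = am$n)
  if (n_boot > 0) {
    if (is.null(seed)) abort_fmt("bootstrap intervals need a seed")
    ok <- !is.na(cand$affinity)
    y <- cand$affinity[ok]; yhat <- cand$affinity_pred[ok]
    n <- length(y)
    stat <- function(idx) {
      res <- yhat[idx] - y[idx]
      c(rmse = sqrt(mean(res^2)),
        pearson_r = if (length(unique(y[idx])) > 1) stats::cor(yhat[idx], y[idx]) else NA,
        top1 = mean(cand$rmsd[idx] < 2.0))
    }
    boots <- withr::with_seed(as.integer(seed), {
      t(vapply(seq_len(n_boot),
               function(i) stat(sample.int(n, n, replace = TRUE)),
               numeric(3)))
    })
    rep$ci <- apply(boots, 2, function(x) {
      unname(quantile(x, c(0.025, 0.975), na.rm = TRUE))
    })
    rep$n_boot <- n_boot
  }
  structure(rep, class = "metrics_report")
}

#' Write a metrics report as JSON or append it as a flat CSV row
#'
#' @param report a `metrics_report`.
#' @param path output file (`.json` or `.csv` by extension).
#' @param experiment,round,seed optional identifiers for the CSV row.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, experiment = NA, round = NA,
                                 seed = NA) {
  stopifnot(inherits(report, "metrics_report"))
  if (grepl("\\.csv$", path)) {
    row <- data.frame(experiment = experiment, round = round, seed = seed,
                      rmse = report$rmse, pearson_r = report$pearson_r,
                      r_squared = report$r_squared, auc = report$auc,
                      top1 = report$top1, n = report$n_complexes_evaluated)
    write.table(row, path, sep = ",", row.names = FALSE,
                col.names = !file.exists(path), append = file.exists(path))
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
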