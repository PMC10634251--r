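# Imputation schemes for missing affinity labels, per-complex
# aggregation, fractional inclusion of imputed labels, and the iterative
# train -> impute -> retrain loop.

SCHEME_NAMES <- c(
  "individual", "individual_ensemble",
  "median_ensemble", "median_good_only_ensemble",
  "max_ensemble", "max_good_only_ensemble",
  "min_ensemble", "min_good_only_ensemble"
)

#' The eight imputation schemes
#'
#' `individual` uses each seed model's raw per-pose predictions as that
#' seed's own training labels (per-seed training sets differ);
#' `individual_ensemble` averages the per-pose predictions over seeds
#' into one shared per-pose label. The remaining schemes operate per
#' complex: for each seed the median / max / min of that seed's pose
#' predictions within the complex (over all poses, or only the good
#' ones for `*_good_only_*`) is taken, and the per-seed values are then
#' averaged, yielding a single value used for every pose of the complex
#' — just as with experimental labels.
#'
#' @param name one of `imputation_scheme_names()`.
#' @return an `imputation_scheme`: list `name`, `granularity`
#'   (`"per_pose"` / `"per_complex"`), `statistic` (`"none"`,
#'   `"median"`, `"max"`, `"min"`), `good_only`.
#' @export
imputation_scheme <- function(name) {
  name <- match.arg(name, SCHEME_NAMES)
  per_pose <- name %in% c("individual", "individual_ensemble")
  structure(list(
    name = name,
    granularity = if (per_pose) "per_pose" else "per_complex",
    statistic = if (per_pose) "none" else sub("_.*$", "", name),
    good_only = grepl("good_only", name, fixed = TRUE)
  ), class = "imputation_scheme")
}

#' @rdname imputation_scheme
#' @export
imputation_scheme_names <- function() SCHEME_NAMES

#' Aggregate one complex's pose predictions into a single label
#'
#' Applies `statistic` over the selected poses: all of them, or only the
#' good (< 2 A rmsd) ones when `good_only`. A complex with no good pose
#' falls back to the all-pose statistic with `fallback_used = TRUE`
#' rather than being silently dropped from imputation. The median of an
#' even count is the midpoint of the two central values.
#'
#' @param values per-pose predicted affinities, non-empty.
#' @param is_good logical flags aligned to `values`.
#' @param statistic `"median"`, `"max"` or `"min"`.
#' @param good_only restrict to good poses?
#' @return list: `value`, `fallback_used`.
#' @export
aggregate_complex <- function(values, is_good, statistic = c("median", "max", "min"),
                              good_only = FALSE) {
  statistic <- match.arg(statistic)
  if (length(values) == 0) abort_fmt("no poses to aggregate")
  if (length(is_good) != length(values)) abort_fmt("flags not aligned to values")
  fallback <- FALSE
  sel <- values
  if (good_only) {
    if (any(is_good)) sel <- values[is_good] else fallback <- TRUE
  }
  f <- switch(statistic, median = median, max = max, min = min)
  list(value = f(sel), fallback_used = fallback)
}

#' Impute missing affinity labels from seed-model predictions
#'
#' Computes the imputed labels for every unlabeled complex of `table`
#' under `scheme` (see [imputation_scheme()]), clamping values to
#' `clamp_range` so model extrapolations cannot inject physically
#' implausible pK labels. Only unlabeled complexes receive labels.
#'
#' For the good-only schemes, a complex with no pose below 2 Angstrom
#' has no trustworthy prediction to aggregate: hinge-trained models
#' systematically under-predict high-rmsd poses, so an all-pose
#' statistic there is exactly the artifact good-only aggregation exists
#' to remove. By default such complexes are left unimputed
#' (`fallback = "skip"`, recorded in the provenance); `"all_pose"`
#' restores the all-pose statistic with `fallback_used` flagged.
#'
#' @param per_seed_predictions list of `prediction_table`s, one per seed
#'   model, each covering every pose of every unlabeled complex.
#' @param table the `pose_table` being imputed.
#' @param scheme an [imputation_scheme()] or its name.
#' @param clamp_range numeric length-2 pK interval (default `c(2, 12)`).
#' @param fallback good-only handling of zero-good-pose complexes:
#'   `"skip"` (default) or `"all_pose"`.
#' @return an `imputation_result` list:
#'   * `scheme`, `granularity`;
#'   * `labels` — for `individual`, a list of per-seed named per-pose
#'     mappings; for `individual_ensemble`, one named per-pose mapping;
#'     for per-complex schemes, one named per-complex mapping;
#'   * `provenance` — data.frame (`complex_id`, `affinity`, `scheme`,
#'     `imputed`, `fallback_used`) covering every unlabeled complex, for
#'     per-complex schemes.
#' @export
impute_labels <- function(per_seed_predictions, table, scheme,
                          clamp_range = c(2, 12),
                          fallback = c("skip", "all_pose")) {
  fallback <- match.arg(fallback)
  if (is.character(scheme)) scheme <- imputation_scheme(scheme)
  stopifnot(inherits(scheme, "imputation_scheme"))
  validate_pose_table(table)
  if (!is.list(per_seed_predictions) || length(per_seed_predictions) == 0) {
    abort_fmt("need at least one prediction table")
  }
  unlabeled <- is.na(table$affinity)
  target <- table[unlabeled, c("pose_id", "complex_id", "is_good")]
  if (nrow(target) == 0) {
    abort_fmt("table has no unlabeled complex to impute")
  }
  pred_for <- function(pt) {
    miss <- setdiff(target$pose_id, pt$pose_id)
    if (length(miss)) {
      abort_fmt("prediction table does not cover %d unlabeled pose(s) (e.g. %s)",
                length(miss), miss[1])
    }
    structure(pt$affinity_pred, names = pt$pose_id)[target$pose_id]
  }
  clamp <- function(x) pmin(pmax(x, clamp_range[1]), clamp_range[2])

  if (scheme$name == "individual") {
    labels <- lapply(per_seed_predictions, function(pt) clamp(pred_for(pt)))
    return(structure(list(scheme = scheme$name, granularity = "per_pose",
                          labels = labels, provenance = NULL),
                     class = "imputation_result"))
  }
  if (scheme$name == "individual_ensemble") {
    mat <- vapply(per_seed_predictions, pred_for, numeric(nrow(target)))
    lab <- clamp(rowMeans(as.matrix(mat)))
    names(lab) <- target$pose_id
    return(structure(list(scheme = scheme$name, granularity = "per_pose",
                          labels = lab, provenance = NULL),
                     class = "imputation_result"))
  }
  # per-complex schemes: aggregate within complex per seed, then average
  cx_rows <- split(seq_len(nrow(target)), target$complex_id)
  per_seed <- lapply(per_seed_predictions, pred_for)
  agg <- t(vapply(cx_rows, function(rows) {
    flags <- target$is_good[rows]
    no_good <- scheme$good_only && !any(flags)
    if (no_good && fallback == "skip") {
      return(c(NA_real_, 1))
    }
    per_seed_vals <- vapply(per_seed, function(pv) {
      aggregate_complex(pv[rows], flags, scheme$statistic, scheme$good_only)$value
    }, numeric(1))
    c(mean(per_seed_vals), as.numeric(no_good))
  }, numeric(2)))
  lab_all <- clamp(agg[, 1])
  names(lab_all) <- names(cx_rows)
  keep <- !is.na(lab_all)
  prov <- data.frame(complex_id = names(cx_rows),
                     affinity = unname(lab_all),
                     scheme = scheme$name,
                     imputed = unname(keep),
                     fallback_used = unname(agg[, 2] > 0 & keep),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scheme = scheme$name, granularity = "per_complex",
                 labels = lab_all[keep], provenance = prov),
            class = "imputation_result")
}

#' Select a nested random fraction of imputed labels
#'
#' Draws a uniformly random subset of exactly `round(fraction * n)` keys.
#' Subsets are nested under a fixed seed: the 20% subset is contained in
#' the 40% subset, and so on — the design used when characterising how
#' much imputed data is needed (successively adding increments of 20%).
#'
#' @param imputed named numeric mapping (complex -> label).
#' @param fraction in \[0, 1\].
#' @param seed integer seed of the selection order.
#' @return the sub-mapping.
#' @export
select_fraction <- function(imputed, fraction, seed) {
  if (!is_number(fraction) || fraction < 0 || fraction > 1) {
    abort_fmt("fraction must lie in [0, 1]")
  }
  n <- length(imputed)
  perm <- withr::with_seed(as.integer(seed), sample(names(imputed)))
  imputed[perm[seq_len(round(fraction * n))]]
}

#' Experiment plan for the iterative imputation loop
#'
#' @param scheme an [imputation_scheme()] or its name.
#' @param n_seeds number of seed models per round (default 5).
#' @param max_rounds imputation rounds after the baseline (>= 0).
#' @param fraction fraction of imputed labels added each round.
#' @param fraction_seed seed of the nested fraction selection.
#' @param stop_metric early-termination metric; only `"test_rmse"`.
#' @param clamp_range pK clamp interval for imputed labels.
#' @param fallback good-only handling of zero-good-pose complexes; see
#'   [impute_labels()].
#' @return an `imputation_plan` list.
#' @export
imputation_plan <- function(scheme, n_seeds = 5, max_rounds = 1,
                            fraction = 1.0, fraction_seed = 1,
                            stop_metric = "test_rmse",
                            clamp_range = c(2, 12),
                            fallback = c("skip", "all_pose")) {
  if (is.character(scheme)) scheme <- imputation_scheme(scheme)
  stop_metric <- match.arg(stop_metric, "test_rmse")
  fallback <- match.arg(fallback)
  if (max_rounds < 0) abort_fmt("max_rounds must be >= 0")
  if (fraction < 0 || fraction > 1) abort_fmt("fraction must lie in [0, 1]")
  structure(list(scheme = scheme, n_seeds = as.integer(n_seeds),
                 max_rounds = as.integer(max_rounds), fraction = fraction,
                 fraction_seed = as.integer(fraction_seed),
                 stop_metric = stop_metric, clamp_range = clamp_range,
                 fallback = fallback),
            class = "imputation_plan")
}

#' Run the iterative train / impute / retrain loop
#'
#' Round 0 trains the seed ensemble on the original labels (missing
#' labels ignored) and records test-fold metrics. Each subsequent round
#' predicts every pose of every unlabeled training complex with the
#' previous round's models, imputes labels under the plan's scheme,
#' optionally keeps only a nested random fraction, rebuilds the training
#' table from the pristine one via [apply_imputed_labels()], retrains
#' all seed models from fresh initialisation, and records metrics. The
#' loop stops early when mean test RMSE fails to improve on the previous
#' round (the worsened round is kept in the history), or at
#' `max_rounds`. For the `individual` scheme each seed model trains on
#' its own seed's imputed labels; all other schemes share one imputed
#' table across seeds.
#'
#' @param train_table,test_table disjoint `pose_table`s (no shared
#'   pocket; checked).
#' @param features feature matrix covering both tables.
#' @param plan an [imputation_plan()].
#' @param train_cfg a [train_config()]; its seed is replaced per model.
#' @param seeds integer seeds, length `plan$n_seeds`.
#' @param loss_cfg a [loss_config()].
#' @param trainer,predictor injectable learner functions with the
#'   signatures of [train_model()] and [predict_poses()].
#' @param out_dir optional directory; per-round imputed labels (CSV) and
#'   metrics (JSON) are persisted there.
#' @return a `round_history`: list with `rounds` (each: `round`,
#'   `metrics` data.frame per seed, `mean_rmse`, `mean_pearson_r`,
#'   `mean_auc`, `mean_top1`, `imputation` result or NULL) and
#'   `stop_reason`.
#' @export
run_rounds <- function(train_table, test_table, features, plan,
                       train_cfg = desk_train_config(),
                       seeds = seq_len(plan$n_seeds),
                       loss_cfg = loss_config(),
                       trainer = train_model, predictor = predict_poses,
                       out_dir = NULL) {
  stopifnot(inherits(plan, "imputation_plan"))
  validate_pose_table(train_table)
  validate_pose_table(test_table)
  leak <- intersect(unique(train_table$pocket_id), unique(test_table$pocket_id))
  if (length(leak)) {
    abort_fmt("cluster leakage: pocket(s) in both train and test (e.g. %s)",
              leak[1])
  }
  if (length(seeds) != plan$n_seeds) {
    abort_fmt("need exactly %d seeds", plan$n_seeds)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fit_seed <- function(tbl, s) {
    cfg <- train_cfg
    cfg$seed <- as.integer(s)
    trainer(tbl, features, cfg, loss_cfg)
  }
  eval_models <- function(models) {
    rows <- lapply(seq_along(models), function(k) {
      pred <- predictor(models[[k]], test_table, features)
      cand <- select_top_pose(pred, test_table)
      am <- affinity_metrics(cand)
      pm <- pose_metrics(pred, test_table, cand)
      data.frame(seed = seeds[k], rmse = am$rmse, pearson_r = am$pearson_r,
                 r_squared = am$r_squared, auc = pm$auc, top1 = pm$top1)
    })
    do.call(rbind, rows)
  }

  persist <- function(round_rec) {
    if (is.null(out_dir)) return(invisible())
    base <- file.path(out_dir, sprintf("round%d", round_rec$round))
    m <- round_rec$metrics
    jsonlite::write_json(
      list(round = round_rec$round, per_seed = m,
           mean_rmse = round_rec$mean_rmse,
           mean_pearson_r = round_rec$mean_pearson_r,
           mean_auc = round_rec$mean_auc, mean_top1 = round_rec$mean_top1),
      paste0(base, "_metrics.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    imp <- round_rec$imputation
    if (!is.null(imp)) {
      if (!is.null(imp$provenance)) {
        write.csv(imp$provenance, paste0(base, "_labels.csv"), row.names = FALSE)
      } else {
        lab <- imp$labels
        if (is.list(lab)) lab <- lab[[1]]
        write.csv(data.frame(pose_id = names(lab), affinity = unname(lab),
                             scheme = imp$scheme),
                  paste0(base, "_labels.csv"), row.names = FALSE)
      }
    }
    invisible()
  }

  make_round <- function(r, models, imputation) {
    m <- eval_models(models)
    rec <- list(round = r, metrics = m, mean_rmse = mean(m$rmse),
                mean_pearson_r = mean(m$pearson_r), mean_auc = mean(m$auc),
                mean_top1 = mean(m$top1), imputation = imputation)
    persist(rec)
    rec
  }

  models <- lapply(seeds, fit_seed, tbl = train_table)
  rounds <- list(make_round(0L, models, NULL))
  stop_reason <- "max_rounds"

  has_missing <- any(is.na(train_table$affinity))
  r <- 1L
  while (r <= plan$max_rounds) {
    if (!has_missing) { stop_reason <- "nothing to impute"; break }
    preds <- lapply(models, predictor, table = train_table, features = features)
    imp <- impute_labels(preds, train_table, plan$scheme, plan$clamp_range,
                         fallback = plan$fallback)

    keep_cx <- function(mapping_names) {
      cx <- if (plan$scheme$granularity == "per_complex") mapping_names else {
        unique(train_table$complex_id[match(mapping_names, train_table$pose_id)])
      }
      sel <- select_fraction(structure(rep(0, length(cx)), names = cx),
                             plan$fraction, plan$fraction_seed)
      names(sel)
    }
    if (plan$scheme$name == "individual") {
      tables <- lapply(imp$labels, function(lab) {
        cx_keep <- keep_cx(names(lab))
        pose_keep <- names(lab)[train_table$complex_id[
          match(names(lab), train_table$pose_id)] %in% cx_keep]
        apply_imputed_labels(train_table, lab[pose_keep], "per_pose")
      })
      models <- mapply(function(tbl, s) fit_seed(tbl, s), tables, seeds,
                       SIMPLIFY = FALSE)
    } else {
      lab <- imp$labels
      if (plan$scheme$granularity == "per_complex") {
        lab <- lab[keep_cx(names(lab))]
        tbl <- apply_imputed_labels(train_table, lab, "per_complex")
      } else {
        cx_keep <- keep_cx(names(lab))
        pose_keep <- names(lab)[train_table$complex_id[
          match(names(lab), train_table$pose_id)] %in% cx_keep]
        tbl <- apply_imputed_labels(train_table, lab[pose_keep], "per_pose")
      }
      models <- lapply(seeds, fit_seed, tbl = tbl)
    }

    rounds[[r + 1L]] <- make_round(r, models, imp)
    if (rounds[[r + 1L]]$mean_rmse >= rounds[[r]]$mean_rmse) {
      stop_reason <- "no improvement"
      break
    }
    r <- r + 1L
  }

  out <- structure(list(rounds = rounds, stop_reason = stop_reason,
                        plan = plan), class = "round_history")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(stop_reason = stop_reason, scheme = plan$scheme$name,
           n_rounds = length(rounds) - 1L,
           mean_rmse = vapply(rounds, `[[`, numeric(1), "mean_rmse")),
      file.path(out_dir, "history.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.round_history <- function(x, ...) {
  cat(sprintf("imputation rounds (%s), stop: %s\n",
              x$plan$scheme$name, x$stop_reason))
  for (r in x$rounds) {
    cat(sprintf("  round %d: mean RMSE %.3f, R %.3f, AUC %.3f, Top1 %.3f\n",
                r$round, r$mean_rmse, r$mean_pearson_r, r$mean_auc, r$mean_top1))
  }
  invisible(x)
}
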