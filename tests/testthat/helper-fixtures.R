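# Fixture builders shared across the suite. Everything is generated in
# code under explicit seeds; no data files.

# tiny pose table: k complexes spread over ceiling(k/2) pockets,
# poses_per complex poses each, labels optionally hidden per complex
tiny_table <- function(k = 4, poses_per = 5, labeled = rep(TRUE, k),
                       pk = seq(4, by = 0.5, length.out = k),
                       rmsd_fun = function(n) c(1.0, runif(n - 1, 2.5, 9))) {
  if (k == 0) {
    return(pose_table(character(0), character(0), numeric(0), numeric(0)))
  }
  pocket <- sprintf("PK%02d", ceiling(seq_len(k) / 2))
  cx <- sprintf("%s:lig%02d", pocket, seq_len(k))
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(pocket_id = pocket[i], complex_id = cx[i],
               stem = sprintf("lig%02d", i),
               rmsd = round(rmsd_fun(poses_per), 3),
               affinity = if (labeled[i]) pk[i] else NA_real_)
  }))
  pose_table(rows$pocket_id, rows$complex_id, rows$rmsd, rows$affinity,
             rec_path = sprintf("%s/%s_rec.pdb", rows$pocket_id, rows$pocket_id),
             lig_path = sprintf("%s/%s.sdf", rows$pocket_id, rows$stem))
}

# constant-output model: zeroed network, affinity head bias = aff,
# pose head bias chosen so the pose score is sigmoid(logit)
stub_model <- function(feature_dim = 16, aff = 5, pose_logit = 0) {
  p <- list(
    W1 = matrix(0, feature_dim, 4), b1 = numeric(4),
    W2 = matrix(0, 4, 4), b2 = numeric(4),
    w_pose = matrix(0, 4, 1), b_pose = pose_logit,
    w_aff = matrix(0, 4, 1), b_aff = aff
  )
  structure(list(params = p, arch = list(feature_dim = feature_dim, hidden = c(4, 4)),
                 seed = 0L, history = data.frame()),
            class = "affinity_model")
}

# prediction table with given per-pose values
stub_predictions <- function(pose_ids, affinity_pred, pose_score = 0.5) {
  out <- data.frame(pose_id = pose_ids,
                    pose_score = rep_len(pose_score, length(pose_ids)),
                    affinity_pred = rep_len(affinity_pred, length(pose_ids)),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}

# brute-force reference for impute_labels: explicit loops over poses,
# complexes and seeds, independent of the package's vectorised path
brute_force_impute <- function(per_seed_predictions, table, scheme_name,
                               clamp_range = c(2, 12), fallback = "skip") {
  sc <- imputation_scheme(scheme_name)
  clamp <- function(x) min(max(x, clamp_range[1]), clamp_range[2])
  unlab <- table[is.na(table$affinity), ]
  get_pred <- function(pt, id) pt$affinity_pred[match(id, pt$pose_id)]
  if (sc$granularity == "per_pose") {
    per_seed <- lapply(per_seed_predictions, function(pt) {
      v <- vapply(unlab$pose_id, function(id) get_pred(pt, id), numeric(1))
      vapply(v, clamp, numeric(1))
    })
    if (sc$name == "individual") return(per_seed)
    out <- numeric(nrow(unlab))
    for (i in seq_len(nrow(unlab))) {
      vals <- numeric(0)
      for (pt in per_seed_predictions) {
        vals <- c(vals, get_pred(pt, unlab$pose_id[i]))
      }
      out[i] <- clamp(mean(vals))
    }
    names(out) <- unlab$pose_id
    return(out)
  }
  cxs <- unique(unlab$complex_id)
  out <- numeric(0)
  for (cx in cxs) {
    rows <- unlab[unlab$complex_id == cx, ]
    if (sc$good_only && !any(rows$is_good) && fallback == "skip") next
    seed_vals <- numeric(0)
    for (pt in per_seed_predictions) {
      v <- vapply(rows$pose_id, function(id) get_pred(pt, id), numeric(1))
      sel <- if (sc$good_only && any(rows$is_good)) v[rows$is_good] else v
      seed_vals <- c(seed_vals, switch(sc$statistic,
                                       median = median(sel),
                                       max = max(sel), min = min(sel)))
    }
    out[cx] <- clamp(mean(seed_vals))
  }
  out
}

# random fixture for the aggregation-oracle checks
random_impute_fixture <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(2:5, 1)
    poses_per <- sample(2:6, 1)
    labeled <- runif(k) < 0.4
    if (all(labeled)) labeled[1] <- FALSE
    tbl <- tiny_table(k, poses_per, labeled,
                      pk = round(runif(k, 3, 9), 3),
                      rmsd_fun = function(n) {
                        g <- runif(n) < 0.3
                        ifelse(g, runif(n, 0.2, 1.8), runif(n, 2.5, 10))
                      })
    preds <- lapply(1:5, function(s) {
      stub_predictions(tbl$pose_id, runif(nrow(tbl), 0, 14),
                       pose_score = runif(nrow(tbl)))
    })
    list(table = tbl, preds = preds)
  })
}
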