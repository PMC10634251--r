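# Reference learner: a small dual-head feed-forward network on
# precomputed per-pose features. Two shared hidden layers of 64
# rectified units feed two output heads — a logistic pose score and a
# linear affinity — so the two tasks are coupled through shared weights.
# Trained by SGD with momentum and weight decay on balanced batches
# under the combined objective, with patience-based learning-rate drops.

#' Training configuration
#'
#' Production-scale defaults: learning rate 0.01, momentum 0.9, weight
#' decay 0.001, batch size 50, evaluation of a fixed reduced subset of
#' the training complexes (fraction `percent_reduced` = 0.132) every
#' 1000 iterations, learning rate divided by 10 after 200 evaluations
#' without improvement, at most 3 drops after which training ends.
#' [desk_train_config()] shrinks the schedule (eval every 100
#' iterations, patience 10, cap 20,000 iterations) so experiments run in
#' minutes on one CPU.
#'
#' @param learning_rate initial SGD learning rate.
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 weight decay added to weight gradients.
#' @param batch_size even minibatch size.
#' @param eval_interval iterations between reduced-set evaluations.
#' @param patience_evals evaluations without improvement before a
#'   learning-rate drop.
#' @param lr_drop_factor divisor applied to the learning rate at a drop.
#' @param max_lr_drops number of drops allowed; training ends at the last.
#' @param percent_reduced fraction of training complexes held in the
#'   fixed reduced evaluation subset.
#' @param max_iterations safety cap on SGD iterations.
#' @param hidden sizes of the shared hidden layers.
#' @param seed integer seed controlling initialisation, the reduced-set
#'   draw and the batch stream.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         weight_decay = 0.001, batch_size = 50,
                         eval_interval = 1000, patience_evals = 200,
                         lr_drop_factor = 10, max_lr_drops = 3,
                         percent_reduced = 0.132, max_iterations = 250000,
                         hidden = c(64, 64), seed = 1) {
  vals <- c(learning_rate, momentum, weight_decay, batch_size, eval_interval,
            patience_evals, lr_drop_factor, max_lr_drops, percent_reduced,
            max_iterations)
  if (any(!is.finite(vals)) || any(vals[-2] <= 0) || momentum < 0) {
    abort_fmt("train_config values must be positive (momentum >= 0)")
  }
  if (percent_reduced > 1) abort_fmt("percent_reduced must lie in (0, 1]")
  structure(list(
    learning_rate = learning_rate, momentum = momentum,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    eval_interval = as.integer(eval_interval),
    patience_evals = as.integer(patience_evals),
    lr_drop_factor = lr_drop_factor, max_lr_drops = as.integer(max_lr_drops),
    percent_reduced = percent_reduced,
    max_iterations = as.integer(max_iterations),
    hidden = as.integer(hidden), seed = as.integer(seed)
  ), class = "train_config")
}

#' @rdname train_config
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(..., seed = 1) {
  train_config(eval_interval = 100, patience_evals = 10,
               max_iterations = 20000, ..., seed = seed)
}

#' Patience-based learning-rate schedule
#'
#' Stateful closure implementing the early-stopping rule: feed it one
#' monitored loss per evaluation; after `patience_evals` consecutive
#' evaluations without improvement over the best seen, the learning rate
#' divides by `lr_drop_factor`; at the `max_lr_drops`-th drop training
#' ends. Exposed separately so the schedule can be driven by any loss
#' stream.
#'
#' @param initial_lr starting learning rate.
#' @param patience_evals,lr_drop_factor,max_lr_drops see [train_config()].
#' @return a function `step(loss)` returning a list `lr`, `n_drops`,
#'   `stop`.
#' @export
make_lr_schedule <- function(initial_lr, patience_evals, lr_drop_factor,
                             max_lr_drops) {
  lr <- initial_lr
  best <- Inf
  since_best <- 0L
  n_drops <- 0L
  function(loss) {
    if (loss < best) {
      best <<- loss
      since_best <<- 0L
    } else {
      since_best <<- since_best + 1L
      if (since_best >= patience_evals) {
        lr <<- lr / lr_drop_factor
        n_drops <<- n_drops + 1L
        since_best <<- 0L
      }
    }
    list(lr = lr, n_drops = n_drops, stop = n_drops >= max_lr_drops)
  }
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))
add_bias <- function(m, b) m + rep(b, each = nrow(m))

init_params <- function(feature_dim, hidden) {
  sizes <- c(feature_dim, hidden)
  p <- list()
  for (i in seq_along(hidden)) {
    p[[paste0("W", i)]] <- matrix(
      rnorm(sizes[i] * sizes[i + 1], 0, sqrt(2 / sizes[i])),
      sizes[i], sizes[i + 1]
    )
    p[[paste0("b", i)]] <- numeric(sizes[i + 1])
  }
  h <- hidden[length(hidden)]
  p$w_pose <- matrix(rnorm(h, 0, 0.01), h, 1)
  p$b_pose <- 0
  p$w_aff <- matrix(rnorm(h, 0, 0.01), h, 1)
  p$b_aff <- 0
  p
}

forward_net <- function(p, X) {
  H1 <- relu(add_bias(X %*% p$W1, p$b1))
  H2 <- relu(add_bias(H1 %*% p$W2, p$b2))
  list(H1 = H1, H2 = H2,
       pose_score = as.vector(sigmoid(H2 %*% p$w_pose + p$b_pose)),
       affinity_pred = as.vector(H2 %*% p$w_aff + p$b_aff))
}

# gradient of the combined batch loss w.r.t. all parameters
backward_net <- function(p, X, fw, is_good, affinity, loss_cfg) {
  n <- nrow(X)
  # pose head: d/dz of -log sigmoid terms is (p - y)
  dz_pose <- loss_cfg$pose_weight * (fw$pose_score - as.numeric(is_good)) / n
  # affinity head: hinged pseudo-Huber derivative d / sqrt(1 + (d/delta)^2)
  labeled <- !is.na(affinity)
  m <- sum(labeled)
  d <- fw$affinity_pred - affinity
  d[!is_good] <- pmax(0, d[!is_good])
  d[!labeled] <- 0
  g_aff <- d / sqrt(1 + (d / loss_cfg$delta)^2)
  dz_aff <- if (m > 0) loss_cfg$affinity_weight * g_aff / m else numeric(n)

  G2 <- dz_pose %o% as.vector(p$w_pose) + dz_aff %o% as.vector(p$w_aff)
  G2[fw$H2 <= 0] <- 0
  G1 <- G2 %*% t(p$W2)
  G1[fw$H1 <= 0] <- 0
  list(
    W1 = crossprod(X, G1), b1 = colSums(G1),
    W2 = crossprod(fw$H1, G2), b2 = colSums(G2),
    w_pose = crossprod(fw$H2, dz_pose), b_pose = sum(dz_pose),
    w_aff = crossprod(fw$H2, dz_aff), b_aff = sum(dz_aff)
  )
}

WEIGHT_NAMES <- c("W1", "W2", "w_pose", "w_aff")

#' Train the reference learner
#'
#' Fits the dual-head feed-forward network by SGD with momentum and
#' weight decay on balanced, pocket-stratified batches under the
#' combined loss. A reduced evaluation subset of `percent_reduced` of
#' the training complexes is fixed at start; every `eval_interval`
#' iterations its combined loss is recorded and drives the
#' patience-based learning-rate schedule ([make_lr_schedule()]).
#' Training ends at the `max_lr_drops`-th drop or at `max_iterations`.
#' Fully deterministic given `config$seed`.
#'
#' @param train_table a `pose_table` containing both pose classes.
#' @param features numeric matrix, pose-id rownames covering the table.
#' @param config a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @return an `affinity_model`: list with `params`, `arch`, `seed` and
#'   `history` (data.frame iteration / loss / lr).
#' @export
train_model <- function(train_table, features, config = desk_train_config(),
                        loss_cfg = loss_config()) {
  validate_pose_table(train_table)
  if (all(train_table$is_good) || !any(train_table$is_good)) {
    abort_fmt("training table must contain both good and bad poses")
  }
  complexes <- unique(train_table$complex_id)

  state <- withr::with_seed(config$seed, {
    params <- init_params(ncol(features), config$hidden)
    n_red <- max(1L, round(config$percent_reduced * length(complexes)))
    reduced_cx <- sample(complexes, n_red)
    list(params = params, reduced_cx = reduced_cx)
  })
  params <- state$params
  red_rows <- train_table$complex_id %in% state$reduced_cx
  red_X <- features[train_table$pose_id[red_rows], , drop = FALSE]
  red_batch <- list(pose_ids = train_table$pose_id[red_rows],
                    is_good = train_table$is_good[red_rows],
                    affinity = train_table$affinity[red_rows])

  reduced_loss <- function(p) {
    fw <- forward_net(p, red_X)
    combined_batch_loss(
      list(pose_score = fw$pose_score, affinity_pred = fw$affinity_pred),
      red_batch, loss_cfg
    )$total
  }

  next_batch <- make_balanced_batches(train_table, features,
                                      config$batch_size, seed = config$seed)
  schedule <- make_lr_schedule(config$learning_rate, config$patience_evals,
                               config$lr_drop_factor, config$max_lr_drops)
  vel <- lapply(params, function(x) x * 0)
  lr <- config$learning_rate
  history <- list(data.frame(iteration = 0L, loss = reduced_loss(params),
                             lr = lr))

  for (it in seq_len(config$max_iterations)) {
    b <- next_batch()
    fw <- forward_net(params, b$features)
    gr <- backward_net(params, b$features, fw, b$is_good, b$affinity, loss_cfg)
    for (nm in names(params)) {
      g <- gr[[nm]]
      if (nm %in% WEIGHT_NAMES) g <- g + config$weight_decay * params[[nm]]
      vel[[nm]] <- config$momentum * vel[[nm]] - lr * g
      params[[nm]] <- params[[nm]] + vel[[nm]]
    }
    if (it %% config$eval_interval == 0) {
      loss <- reduced_loss(params)
      if (!is.finite(loss)) {
        abort_fmt("training diverged: non-finite reduced-set loss at iteration %d", it)
      }
      st <- schedule(loss)
      lr <- st$lr
      history[[length(history) + 1L]] <-
        data.frame(iteration = it, loss = loss, lr = lr)
      if (st$stop) break
    }
  }

  # canonical parameter form: no dimnames inherited from the features
  params <- lapply(params, function(x) {
    if (is.matrix(x)) dimnames(x) <- NULL
    x
  })
  structure(list(
    params = params,
    arch = list(feature_dim = ncol(features), hidden = config$hidden),
    seed = config$seed,
    history = do.call(rbind, history)
  ), class = "affinity_model")
}

#' Predict pose scores and affinities
#'
#' @param model an `affinity_model`.
#' @param table a `pose_table`.
#' @param features numeric matrix covering the table's poses.
#' @return a `prediction_table` data.frame: `pose_id`, `pose_score` in
#'   \[0, 1\], `affinity_pred` in pK units.
#' @export
predict_poses <- function(model, table, features) {
  stopifnot(inherits(model, "affinity_model"))
  missing_feat <- setdiff(table$pose_id, rownames(features))
  if (length(missing_feat)) {
    abort_fmt("features missing for %d pose(s) (e.g. %s)",
              length(missing_feat), missing_feat[1])
  }
  X <- features[table$pose_id, , drop = FALSE]
  fw <- forward_net(model$params, X)
  out <- data.frame(pose_id = table$pose_id, pose_score = fw$pose_score,
                    affinity_pred = fw$affinity_pred,
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Train an ensemble of independently seeded models
#'
#' One model per seed, independently trained on the same table; order of
#' `seeds` is preserved.
#'
#' @param train_table,features,base_config as in [train_model()].
#' @param seeds distinct integer seeds (default `1:5`).
#' @param loss_cfg a [loss_config()].
#' @return a list of `affinity_model`s.
#' @export
train_seed_ensemble <- function(train_table, features,
                                base_config = desk_train_config(),
                                seeds = 1:5, loss_cfg = loss_config()) {
  if (anyDuplicated(seeds)) abort_fmt("seeds must be distinct")
  lapply(seeds, function(s) {
    cfg <- base_config
    cfg$seed <- as.integer(s)
    train_model(train_table, features, cfg, loss_cfg)
  })
}

#' Ensemble prediction by per-pose averaging
#'
#' Arithmetic mean of `pose_score` and `affinity_pred` across models;
#' with one model this is [predict_poses()].
#'
#' @param models non-empty list of `affinity_model`s.
#' @param table,features as in [predict_poses()].
#' @param reduce aggregation; only `"mean"` is defined.
#' @return a `prediction_table`.
#' @export
ensemble_predict <- function(models, table, features, reduce = "mean") {
  reduce <- match.arg(reduce, "mean")
  if (length(models) == 0) abort_fmt("empty model list")
  preds <- lapply(models, predict_poses, table = table, features = features)
  out <- preds[[1]]
  out$pose_score <- rowMeans(vapply(preds, `[[`, numeric(nrow(out)), "pose_score"))
  out$affinity_pred <- rowMeans(vapply(preds, `[[`, numeric(nrow(out)), "affinity_pred"))
  out
}

#' Serialise / load a model as JSON-of-arrays
#'
#' Self-describing: architecture descriptor, train seed, parameters and
#' training history travel together in one JSON document.
#'
#' @param model an `affinity_model`.
#' @param path file path.
#' @return `path` (write) / an `affinity_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "affinity_model"))
  doc <- list(
    arch = model$arch, seed = model$seed,
    params = lapply(model$params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
      else list(dim = NULL, data = as.vector(x))
    }),
    history = model$history
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(doc$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else if (length(p$data) == 1) p$data else as.numeric(p$data)
  })
  structure(list(
    params = params,
    arch = list(feature_dim = doc$arch$feature_dim,
                hidden = as.integer(doc$arch$hidden)),
    seed = doc$seed,
    history = as.data.frame(doc$history)
  ), class = "affinity_model")
}
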