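test_that("scheme names derive granularity, statistic and good-only flags", {
  for (nm in imputation_scheme_names()) {
    sc <- imputation_scheme(nm)
    expect_equal(sc$granularity == "per_pose",
                 nm %in% c("individual", "individual_ensemble"))
    expect_equal(sc$good_only, grepl("good_only", nm))
    if (sc$granularity == "per_complex") {
      expect_true(sc$statistic %in% c("median", "max", "min"))
      expect_true(startsWith(nm, sc$statistic))
    } else {
      expect_equal(sc$statistic, "none")
    }
  }
  expect_error(imputation_scheme("mean_ensemble"), "arg")
})

test_that("per-complex aggregation selects, falls back and takes midpoints", {
  got <- aggregate_complex(c(5, 6, 9), c(TRUE, TRUE, FALSE), "median",
                           good_only = TRUE)
  expect_equal(got$value, 5.5)  # median of the two good poses
  expect_false(got$fallback_used)

  expect_equal(aggregate_complex(c(5, 6, 9), c(TRUE, TRUE, FALSE), "max",
                                 good_only = FALSE)$value, 9)

  # no good pose: all-pose statistic with the fallback flagged
  fb <- aggregate_complex(c(5, 6, 9), c(FALSE, FALSE, FALSE), "median",
                          good_only = TRUE)
  expect_equal(fb$value, 6)
  expect_true(fb$fallback_used)

  expect_error(aggregate_complex(numeric(0), logical(0), "median"), "no poses")
  expect_error(aggregate_complex(1, c(TRUE, FALSE), "median"), "aligned")
})

test_that("imputation reproduces the hand-enumerated two-stage aggregates", {
  # one unlabeled 3-pose complex, good flags T,T,F
  tbl <- tiny_table(2, 3, labeled = c(TRUE, FALSE),
                    rmsd_fun = function(n) c(1, 1.5, 5))
  ids <- tbl$pose_id[tbl$complex_id == "PK01:lig02"]

  # individual ensemble: per-pose mean over seeds
  pa <- stub_predictions(tbl$pose_id, 5.0)
  pb <- stub_predictions(tbl$pose_id, 6.0)
  ie <- impute_labels(list(pa, pb), tbl, "individual_ensemble")
  expect_equal(unname(ie$labels[ids]), rep(5.5, 3))
  expect_setequal(names(ie$labels), ids)

  # median good only: seed A good poses {5, 6} -> 5.5, seed B {7, 7} -> 7,
  # then mean(5.5, 7) = 6.25 for the complex
  pa2 <- stub_predictions(tbl$pose_id, 0)
  pa2$affinity_pred[match(ids, pa2$pose_id)] <- c(5, 6, 9)
  pb2 <- stub_predictions(tbl$pose_id, 0)
  pb2$affinity_pred[match(ids, pb2$pose_id)] <- c(7, 7, 11)
  mg <- impute_labels(list(pa2, pb2), tbl, "median_good_only_ensemble")
  expect_equal(unname(mg$labels[["PK01:lig02"]]), 6.25)
  expect_false(mg$provenance$fallback_used)
  expect_equal(mg$provenance$complex_id, "PK01:lig02")

  # individual: one mapping per seed, differing when the models differ
  ind <- impute_labels(list(pa, pb), tbl, "individual")
  expect_length(ind$labels, 2)
  expect_false(identical(ind$labels[[1]], ind$labels[[2]]))

  # labels are clamped into the plausible pK range
  hot <- impute_labels(list(stub_predictions(tbl$pose_id, 25)), tbl,
                       "max_ensemble")
  expect_equal(unname(hot$labels[["PK01:lig02"]]), 12)

  # coverage gaps are an error
  short <- stub_predictions(tbl$pose_id[-match(ids[1], tbl$pose_id)], 5)
  expect_error(impute_labels(list(short), tbl, "median_ensemble"), "cover")
  lab_only <- tiny_table(2, 3)
  expect_error(impute_labels(list(pa), lab_only, "median_ensemble"),
               "no unlabeled")
})

test_that("all eight schemes match brute-force enumeration exactly", {
  for (i in 1:150) {
    fx <- random_impute_fixture(1000 + i)
    for (nm in imputation_scheme_names()) {
      for (fb in c("skip", "all_pose")) {
        got <- impute_labels(fx$preds, fx$table, nm, fallback = fb)
        want <- brute_force_impute(fx$preds, fx$table, nm, fallback = fb)
        if (nm == "individual") {
          for (k in seq_along(want)) {
            expect_equal(got$labels[[k]], want[[k]], tolerance = 1e-12)
          }
        } else if (length(want) == 0) {
          expect_length(got$labels, 0)
        } else {
          expect_equal(got$labels[names(want)], want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("aggregate ordering min <= median <= max holds on any fixture", {
  withr::with_seed(55, {
    for (i in 1:200) {
      v <- runif(sample(1:9, 1), 0, 12)
      g <- runif(length(v)) < 0.4
      for (go in c(FALSE, TRUE)) {
        lo <- aggregate_complex(v, g, "min", go)$value
        md <- aggregate_complex(v, g, "median", go)$value
        hi <- aggregate_complex(v, g, "max", go)$value
        expect_true(lo <= md && md <= hi)
        # good-only aggregates never use bad-pose values unless fallback
        agg <- aggregate_complex(v, g, "max", TRUE)
        if (!agg$fallback_used && any(g)) {
          expect_true(agg$value %in% v[g])
        }
      }
    }
  })
})

test_that("fractional label subsets are exact, nested and seeded", {
  lab <- structure(runif(100, 2, 12), names = sprintf("C%03d", 1:100))
  expect_identical(select_fraction(lab, 1.0, 5), lab[names(select_fraction(lab, 1.0, 5))])
  expect_length(select_fraction(lab, 1.0, 5), 100)
  expect_length(select_fraction(lab, 0.0, 5), 0)
  expect_length(select_fraction(lab, 0.2, 5), 20)

  for (s in c(1, 9, 42)) {
    prev <- character(0)
    for (f in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
      cur <- names(select_fraction(lab, f, s))
      expect_length(cur, round(f * 100))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
  expect_error(select_fraction(lab, 1.2, 1), "\\[0, 1\\]")
})

test_that("a perfect predictor makes good-only median imputation exact", {
  co <- generate_corpus(synthetic_config(), 7)
  tbl <- hide_labels(co$table, 0.59, "by_complex", 11)
  truth <- co$truth$complex_pk
  # stub that predicts the true pK for every pose
  perfect <- stub_predictions(tbl$pose_id, unname(truth[tbl$complex_id]))
  imp <- impute_labels(rep(list(perfect), 5), tbl, "median_good_only_ensemble")
  expect_equal(imp$labels[names(imp$labels)],
               truth[names(imp$labels)], tolerance = 1e-12)
  # complexes with no good pose are left unimputed by default, flagged
  prov <- imp$provenance
  expect_false(any(prov$fallback_used))
  expect_setequal(prov$complex_id[prov$imputed], names(imp$labels))
  expect_setequal(prov$complex_id,
                  unique(tbl$complex_id[is.na(tbl$affinity)]))
  # under the all-pose fallback a perfect predictor labels every complex,
  # and round-1 training data equals the fully labeled corpus
  imp_fb <- impute_labels(rep(list(perfect), 5), tbl,
                          "median_good_only_ensemble", fallback = "all_pose")
  back <- apply_imputed_labels(tbl, imp_fb$labels, "per_complex")
  expect_equal(back$affinity, co$table$affinity)
})

test_that("the round loop stops, persists and guards leakage", {
  co <- generate_corpus(synthetic_config(n_pockets = 6, ligands_per_pocket = 2,
                                         poses_per_complex = 6), 3)
  tbl <- hide_labels(co$table, 0.5, "by_complex", 4)
  tr <- tbl[tbl$pocket_id %in% sprintf("P%03d", 1:4), ]
  te <- co$table[co$table$pocket_id %in% sprintf("P%03d", 5:6), ]

  # stub learner: each training round's models predict with a fixed noise
  # level; the level worsens at round 2
  noise_for_round <- c(0.2, 0.1, 0.9, 0.9, 0.9, 0.9)
  calls <- new.env(); calls$n <- 0
  stub_trainer <- function(tbl, features, cfg, ...) {
    calls$n <- calls$n + 1
    m <- stub_model(ncol(features), aff = 6)
    m$round <- ceiling(calls$n / 2)  # 2 seeds per round
    m
  }
  stub_predictor <- function(model, table, features) {
    truth <- co$truth$complex_pk[table$complex_id]
    withr::with_seed(model$round, stub_predictions(
      table$pose_id,
      unname(truth) + rnorm(nrow(table), 0, noise_for_round[model$round]),
      pose_score = exp(-table$rmsd)
    ))
  }

  plan <- imputation_plan("median_ensemble", n_seeds = 2, max_rounds = 5)
  out_dir <- withr::local_tempdir()
  hist <- run_rounds(tr, te, co$features, plan, desk_train_config(),
                     seeds = 1:2, trainer = stub_trainer,
                     predictor = stub_predictor, out_dir = out_dir)
  expect_equal(hist$stop_reason, "no improvement")
  # baseline + improving round 1 + worsened round 2, kept in history
  expect_length(hist$rounds, 3)
  rmses <- vapply(hist$rounds, `[[`, numeric(1), "mean_rmse")
  expect_lt(rmses[2], rmses[1])
  expect_gte(rmses[3], rmses[2])
  expect_true(file.exists(file.path(out_dir, "round1_labels.csv")))
  expect_true(file.exists(file.path(out_dir, "history.json")))

  # baseline only when no rounds are requested
  h0 <- run_rounds(tr, te, co$features,
                   imputation_plan("median_ensemble", n_seeds = 2,
                                   max_rounds = 0),
                   seeds = 1:2, trainer = stub_trainer,
                   predictor = function(m, table, features)
                     stub_predictions(table$pose_id,
                                      unname(co$truth$complex_pk[table$complex_id]),
                                      pose_score = exp(-table$rmsd)))
  expect_length(h0$rounds, 1)
  expect_equal(h0$rounds[[1]]$round, 0)

  # shared pockets across the split are cluster leakage
  expect_error(run_rounds(tr, co$table[co$table$pocket_id == "P001", ],
                          co$features, plan, seeds = 1:2,
                          trainer = stub_trainer,
                          predictor = function(...) NULL),
               "leakage")
})

test_that("experimental labels survive every round untouched", {
  co <- generate_corpus(synthetic_config(n_pockets = 6, ligands_per_pocket = 2,
                                         poses_per_complex = 5), 8)
  tbl <- hide_labels(co$table, 0.5, "by_complex", 9)
  tr <- tbl[tbl$pocket_id %in% sprintf("P%03d", 1:4), ]
  te <- co$table[co$table$pocket_id %in% sprintf("P%03d", 5:6), ]
  seen <- list()
  spy_trainer <- function(tbl, features, cfg, ...) {
    seen[[length(seen) + 1]] <<- tbl
    stub_model(ncol(features), aff = 6)
  }
  spy_predictor <- function(model, table, features) {
    withr::with_seed(1, stub_predictions(table$pose_id,
                                         runif(nrow(table), 4, 8),
                                         pose_score = exp(-table$rmsd)))
  }
  invisible(run_rounds(tr, te, co$features,
                       imputation_plan("min_good_only_ensemble", n_seeds = 2,
                                       max_rounds = 2),
                       seeds = 1:2, trainer = spy_trainer,
                       predictor = spy_predictor))
  exp_rows <- tr$affinity_source == "experimental"
  for (tbl_seen in seen) {
    expect_identical(tbl_seen$affinity[exp_rows], tr$affinity[exp_rows])
    expect_identical(tbl_seen$affinity_source[exp_rows],
                     tr$affinity_source[exp_rows])
  }
})
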