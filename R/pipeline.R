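CLINICAL_FEATURES <- c("T_stage", "N_stage", "grade", "CEA",
                       "distance_anal_margin", "tumor_size")

MODEL_KINDS <- c("Clinical", "Radiomic", "Combined",
                 "ComBat_Radiomic", "ComBat_Combined")

.model_columns <- function(kind, radiomic_names) {
  switch(kind,
         Clinical = list(clinical = TRUE, radiomic = character(0), combat = FALSE),
         Radiomic = list(clinical = FALSE, radiomic = radiomic_names, combat = FALSE),
         Combined = list(clinical = TRUE, radiomic = radiomic_names, combat = FALSE),
         ComBat_Radiomic = list(clinical = FALSE, radiomic = radiomic_names, combat = TRUE),
         ComBat_Combined = list(clinical = TRUE, radiomic = radiomic_names, combat = TRUE),
         stop("unknown model kind: ", kind))
}

#' Run the five-model pCR prediction experiment end to end
#'
#' Orchestrates the full workflow on a cohort: radiomic feature extraction,
#' ComBat harmonization (fitted on the pooled feature table, labels never
#' used), training-set-only feature selection, SMOTE balancing, network
#' fitting with training-set Youden cutoff locking, and frozen-cutoff
#' evaluation on the testing institution — once for each of the five model
#' kinds (Clinical, Radiomic, Combined, ComBat_Radiomic, ComBat_Combined).
#' Testing-cohort labels enter evaluation only; no fitting or
#' cutoff-selection code path sees them.
#'
#' @param cohort a [generate_cohort()] result (or an equivalent list with
#'   `patients` and `clinical`).
#' @param seed master seed; every stage derives its randomness from it.
#' @param models subset of the five model kinds to run.
#' @param auc_min,rho_max selection thresholds (reference values 0.60 and
#'   0.7).
#' @param n_boot bootstrap replicates for internal validation (reference
#'   value 1000); 0 skips the bootstrap summary.
#' @param combat_pooled fit ComBat on the pooled (train + test) table
#'   (default, mirroring harmonization before feature-set reduction) or on
#'   the training institution only.
#' @param features optional precomputed feature table from
#'   [extract_cohort()] to skip extraction.
#' @param verbose print stage progress.
#' @return An object of class `pcr_experiment`: list with `report_train`
#'   and `report_test` data.frames (one row per model), `models`,
#'   `selection`, `decision_curves` (testing cohort), `features`,
#'   `features_combat`, and `timings`.
#' @export
run_experiment <- function(cohort, seed = 1L, models = MODEL_KINDS,
                           auc_min = 0.60, rho_max = 0.7, n_boot = 0L,
                           combat_pooled = TRUE, features = NULL,
                           verbose = FALSE) {
  models <- match.arg(models, MODEL_KINDS, several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  clin <- cohort$clinical
  train_idx <- which(clin$site == 1L)
  test_idx <- which(clin$site == 2L)
  y <- clin$pCR

  say("extracting radiomic features (%d patients)...", nrow(clin))
  if (is.null(features)) features <- extract_cohort(cohort$patients)
  stopifnot(identical(features$patient_id, clin$patient_id))
  rad <- features[, setdiff(names(features), "patient_id")]
  t_extract <- proc.time()[["elapsed"]] - t0

  say("fitting ComBat on %s...", if (combat_pooled) "pooled cohort" else "training set")
  keep <- vapply(rad, function(x) var(x) > 0, TRUE)
  rad_v <- rad[, keep, drop = FALSE]
  cb_fit_rows <- if (combat_pooled) seq_len(nrow(rad_v)) else train_idx
  cb <- fit_combat(rad_v[cb_fit_rows, , drop = FALSE], clin$site[cb_fit_rows])
  rad_cb <- apply_combat(cb, rad_v, clin$site)
  clin_feats <- clin[, CLINICAL_FEATURES]

  experiment_models <- list(); selections <- list()
  report_train <- report_test <- NULL
  curves <- list()
  for (i in seq_along(models)) {
    kind <- models[i]
    say("model %s: selection + fit...", kind)
    spec <- .model_columns(kind, colnames(rad_v))
    radtab <- if (spec$combat) rad_cb else rad_v
    tab <- radtab[, spec$radiomic, drop = FALSE]
    if (spec$clinical) tab <- if (ncol(tab)) cbind(clin_feats, tab) else clin_feats
    set.seed(seed * 1000L + i)
    sel <- select_features(tab[train_idx, , drop = FALSE], y[train_idx],
                           auc_min = auc_min, rho_max = rho_max)
    kept <- attr(sel, "retained")
    if (length(kept) == 0L) {
      # no feature survives: fall back to the single best-AUC feature so the
      # model stays defined
      kept <- sel$feature[which.max(sel$auc)]
    }
    fit <- pcr_model(tab[train_idx, kept, drop = FALSE], y[train_idx],
                     kind = kind, n_boot = n_boot, seed = seed * 1000L + i)
    ev_tr <- evaluate_model(fit, tab[train_idx, , drop = FALSE], y[train_idx])
    ev_te <- evaluate_model(fit, tab[test_idx, , drop = FALSE], y[test_idx])
    report_train <- rbind(report_train, report_row(fit, ev_tr))
    report_test <- rbind(report_test, report_row(fit, ev_te))
    curves[[kind]] <- decision_curve(ev_te$scores, y[test_idx])
    experiment_models[[kind]] <- fit
    selections[[kind]] <- sel
  }
  structure(list(report_train = report_train, report_test = report_test,
                 models = experiment_models, selection = selections,
                 decision_curves = curves,
                 features = features, features_combat = rad_cb,
                 combat = cb, seed = seed,
                 timings = c(extract_s = t_extract,
                             total_s = proc.time()[["elapsed"]] - t0)),
            class = "pcr_experiment")
}

#' @export
print.pcr_experiment <- function(x, ...) {
  cat("pCR prediction experiment (seed ", x$seed, ")\n\n", sep = "")
  cat("Training cohort:\n")
  print(x$report_train[, c("Model", "AUC", "p", "Cutoff_pct",
                           "Se_pct", "Sp_pct", "Bacc_pct")], row.names = FALSE)
  cat("\nTesting cohort (frozen cutoffs):\n")
  print(x$report_test[, c("Model", "AUC", "p", "Cutoff_pct",
                          "Se_pct", "Sp_pct", "Bacc_pct")], row.names = FALSE)
  invisible(x)
}

#' Write experiment artifacts to a directory
#'
#' Emits `features.csv`, `features_combat.csv`, `selection.csv`,
#' `report_train.csv`, `report_test.csv`, `dca.csv`, one JSON per fitted
#' model, the fitted ComBat model (`combat_model.json`) and the feature
#' provenance catalog (`feature_catalog.json`).
#'
#' @param x a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(cbind(patient_id = x$features$patient_id, x$features_combat),
            file.path(dir, "features_combat.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(x$selection), function(k)
    cbind(model = k, as.data.frame(x$selection[[k]]))))
  write.csv(sel, file.path(dir, "selection.csv"), row.names = FALSE)
  write.csv(x$report_train, file.path(dir, "report_train.csv"), row.names = FALSE)
  write.csv(x$report_test, file.path(dir, "report_test.csv"), row.names = FALSE)
  dca <- do.call(rbind, lapply(names(x$decision_curves), function(k)
    cbind(model = k, x$decision_curves[[k]])))
  write.csv(dca, file.path(dir, "dca.csv"), row.names = FALSE)
  models_dir <- file.path(dir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  for (k in names(x$models))
    write_model_json(x$models[[k]], file.path(models_dir, paste0(k, ".json")))
  write_combat_json(x$combat, file.path(dir, "combat_model.json"))
  jsonlite::write_json(
    feature_catalog(setdiff(names(x$features), "patient_id")),
    file.path(dir, "feature_catalog.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Segmentation-robustness replay
#'
#' Re-evaluates every pre-trained model on a testing subset whose masks were
#' re-delineated (here: simulated second-observer masks from
#' [perturb_mask()]): features are re-extracted from the new masks,
#' harmonized with the already-fitted ComBat model, and scored at the locked
#' cutoffs.
#'
#' @param experiment a [run_experiment()] result.
#' @param cohort the cohort the experiment ran on.
#' @param n_subset number of testing patients to replay (reference: 25).
#' @param seed seed for subset choice, Dice targets and perturbations.
#' @return list with `report` (per-model Se/Sp/Bacc on the replayed subset
#'   next to the primary-mask values), `dice` (achieved per-patient Dice)
#'   and `subset_ids`.
#' @export
evaluate_robustness <- function(experiment, cohort, n_subset = 25L, seed = 99L) {
  set.seed(seed)
  clin <- cohort$clinical
  test_idx <- which(clin$site == 2L)
  pick <- sort(sample(test_idx, min(n_subset, length(test_idx))))
  targets <- 0.41 + 0.58 * rbeta(length(pick), 2, 1.5)
  dice <- numeric(length(pick))
  patients2 <- list()
  for (j in seq_along(pick)) {
    p <- cohort$patients[[pick[j]]]
    for (mod in names(p$images)) {
      m2 <- perturb_mask(p$images[[mod]]$mask, targets[j])
      if (mod == "T2") dice[j] <- dice_coefficient(p$images[[mod]]$mask, m2)
      p$images[[mod]]$mask <- m2
    }
    patients2[[j]] <- p
  }
  feats2 <- extract_cohort(patients2)
  rad2 <- feats2[, setdiff(names(feats2), "patient_id")]
  rad2 <- rad2[, experiment$combat$features, drop = FALSE]
  rad2_cb <- apply_combat(experiment$combat, rad2, clin$site[pick])
  y2 <- clin$pCR[pick]
  clin2 <- clin[pick, CLINICAL_FEATURES]
  rows <- NULL
  for (k in names(experiment$models)) {
    fit <- experiment$models[[k]]
    spec <- .model_columns(k, experiment$combat$features)
    radtab <- if (spec$combat) rad2_cb else rad2
    tab <- if (spec$clinical) cbind(clin2, radtab) else radtab
    ev <- tryCatch(evaluate_model(fit, tab, y2), error = function(e) NULL)
    if (is.null(ev)) next  # subset may miss a class entirely
    primary <- experiment$report_test[experiment$report_test$Model == k, ]
    rows <- rbind(rows, data.frame(
      Model = k, AUC = round(ev$auc, 2),
      Se_pct = ev$metrics$se_pct, Sp_pct = ev$metrics$sp_pct,
      Bacc_pct = ev$metrics$bacc_pct,
      Bacc_primary_pct = primary$Bacc_pct, stringsAsFactors = FALSE))
  }
  list(report = rows, dice = dice, subset_ids = clin$patient_id[pick])
}
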