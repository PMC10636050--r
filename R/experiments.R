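#' Leave-one-center-out federated benchmark
#'
#' Rotates the role of evaluation center: each center in turn acts as the
#' Central Server's held-out set while the remaining centers train a
#' federated model under each aggregation strategy. For comparison, a
#' "NoFed" baseline trains the identical architecture on each single
#' training center alone for `n_rounds * local_epochs` epochs and evaluates
#' it on the same held-out center. The best FL model per rotation (highest
#' AUC) is compared to each NoFed baseline with the Hanley-McNeil test.
#'
#' @param centers List of >= 3 [cohort_dataset()] objects sharing a panel.
#' @param strategies Character vector of strategy names (see
#'   [strategy_config()]).
#' @param n_rounds,local_epochs Federated round budget (defaults 5 x 100).
#' @param model_config Optional [model_config()] template; defaults to the
#'   standard recipe sized to the panel.
#' @param seed Master seed.
#' @param use_best Evaluate the best round's model instead of the final
#'   round's (default `FALSE`: final round).
#' @return A `data.frame` with one row per (held-out center, method) and
#'   columns `held_out`, `method`, `Sen`, `Spe`, `Pre`, `MCC`, `AUC`,
#'   `AUPRC` (all on the 0-1 scale; `MCC` in [-1, 1]), plus an attribute
#'   `hanley_mcneil`: per rotation, best-FL vs each NoFed AUC comparison.
#' @export
run_exp1 <- function(centers,
                     strategies = c("fedavg", "fedavgm", "fedadam",
                                    "fedyogi", "fedadagrad"),
                     n_rounds = 5L, local_epochs = 100L,
                     model_config = NULL, seed = 1L, use_best = FALSE) {
  stop_if_not(length(centers) >= 3,
              "need >= 3 centers (>= 2 training centers per rotation)")
  G <- dim(centers[[1]]$tensor)[3]
  if (is.null(model_config)) model_config <- fedgi::model_config(n_genes = G)
  rows <- list()
  hm_rows <- list()
  for (h in seq_along(centers)) {
    held <- centers[[h]]
    train_centers <- centers[-h]
    clients <- lapply(train_centers, function(co) client_node(co$center_id, co))
    fl_scores <- list()
    for (strat in strategies) {
      rc <- fl_run_config(n_rounds, local_epochs, strategy_config(strat),
                          seed = derive_seed(seed, "exp1", held$center_id, strat))
      fit <- run_federated_training(clients, rc, eval_cohort = held,
                                    model_config = model_config)
      model <- if (use_best) fit$best_model else fit$model
      scores <- predict_proba(model, held)
      fl_scores[[strat]] <- scores
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(held_out = held$center_id, method = strat),
              as.data.frame(metrics_report(held$labels, scores)))
    }
    nofed_scores <- list()
    for (co in train_centers) {
      cfg <- model_config
      cfg$epochs <- as.integer(n_rounds * local_epochs)
      cfg$seed <- derive_seed(seed, "exp1-nofed", held$center_id, co$center_id)
      fit <- train_local(init_model(cfg), co, cfg)
      scores <- predict_proba(fit$model, held)
      nofed_scores[[co$center_id]] <- scores
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(held_out = held$center_id,
                         method = paste0("NoFed (", co$center_id, ")")),
              as.data.frame(metrics_report(held$labels, scores)))
    }
    fl_auc <- vapply(fl_scores, function(s) auc(held$labels, s), 0)
    best <- names(fl_auc)[which.max(fl_auc)]
    for (id in names(nofed_scores)) {
      hm <- hanley_mcneil_test(held$labels, fl_scores[[best]],
                               nofed_scores[[id]])
      hm_rows[[length(hm_rows) + 1L]] <-
        data.frame(held_out = held$center_id, best_fl = best,
                   nofed_center = id, auc_fl = hm$auc_a,
                   auc_nofed = hm$auc_b, z = hm$z, p = hm$p)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "hanley_mcneil") <- do.call(rbind, hm_rows)
  out
}

#' Federated n-fold cross-validation vs the centralized model
#'
#' Pools a cohort, splits it into `n` folds (random or
#' class-ratio-preserving stratified splits), and for every rotation holds
#' one fold out as the Central Server's evaluation set while the remaining
#' `n - 1` folds become `n - 1` federated clients. The centralized arm
#' trains the identical architecture on the union of the training folds for
#' `n_rounds * local_epochs` epochs and is evaluated on the same fold.
#'
#' @param pooled A pooled [cohort_dataset()] (see [merge_cohorts()]).
#' @param n_folds_list Integer vector of fold counts (default the full
#'   benchmark grid 3..31).
#' @param split_modes Subset of `c("random", "stratified")`.
#' @param strategy A [strategy_config()] for the FL arm (default FedAvg).
#' @param n_rounds,local_epochs Federated round budget (defaults 5 x 100).
#' @param model_config Optional [model_config()] template.
#' @param seed Master seed.
#' @return A `data.frame` with one row per (n_folds, split_mode, arm) and
#'   columns `mean_auc`, `sd_auc`, `mean_auprc`, `sd_auprc`, `n_rotations`;
#'   attribute `per_rotation` holds the fold-level reports.
#' @export
run_exp2 <- function(pooled,
                     n_folds_list = c(3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L,
                                      21L, 31L),
                     split_modes = c("random", "stratified"),
                     strategy = strategy_config("fedavg"),
                     n_rounds = 5L, local_epochs = 100L,
                     model_config = NULL, seed = 1L) {
  split_modes <- match.arg(split_modes, several.ok = TRUE)
  G <- dim(pooled$tensor)[3]
  if (is.null(model_config)) model_config <- fedgi::model_config(n_genes = G)
  rows <- list()
  detail <- list()
  for (mode in split_modes) {
    splitter <- if (mode == "random") split_random else split_stratified
    for (n in n_folds_list) {
      folds <- splitter(pooled, n, seed = derive_seed(seed, "split", mode, n))
      fl_reports <- list()
      cen_reports <- list()
      for (r in seq_len(n)) {
        held <- folds[[r]]
        train_folds <- folds[-r]
        held_ids <- held$sample_ids
        for (f in train_folds)
          stop_if_not(!any(f$sample_ids %in% held_ids),
                      "evaluation fold leaked into training folds")
        clients <- lapply(seq_along(train_folds), function(j)
          client_node(sprintf("fold%02d", which(seq_len(n) != r)[j]),
                      train_folds[[j]]))
        rc <- fl_run_config(n_rounds, local_epochs, strategy,
                            seed = derive_seed(seed, "exp2", mode, n, r))
        fit <- run_federated_training(clients, rc,
                                      model_config = model_config)
        fl_reports[[r]] <- metrics_report(held$labels,
                                          predict_proba(fit$model, held))
        cfg <- model_config
        cfg$epochs <- as.integer(n_rounds * local_epochs)
        cfg$seed <- derive_seed(seed, "exp2-central", mode, n, r)
        merged <- merge_cohorts(train_folds, center_id = "central")
        cen_fit <- train_local(init_model(cfg), merged, cfg)
        cen_reports[[r]] <- metrics_report(held$labels,
                                           predict_proba(cen_fit$model, held))
      }
      for (arm in c("fl", "centralized")) {
        reports <- if (arm == "fl") fl_reports else cen_reports
        avg <- cv_average(reports)
        rows[[length(rows) + 1L]] <-
          data.frame(n_folds = n, split_mode = mode, arm = arm,
                     mean_auc = avg$mean[["auc"]], sd_auc = avg$sd[["auc"]],
                     mean_auprc = avg$mean[["auprc"]],
                     sd_auprc = avg$sd[["auprc"]], n_rotations = n)
        detail[[paste(mode, n, arm, sep = "_")]] <- reports
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_rotation") <- detail
  out
}
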