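#' A client node in the simulated federation
#'
#' Wraps one center's local cohort and training configuration. The round
#' protocol interacts with clients only through [client_train()], which
#' receives a parameter vector and returns a [client_update()] — parameters
#' and a sample count, never data — which is what keeps raw data local.
#'
#' @param id Client identifier string (stable across runs; used to derive
#'   per-round training seeds, so results do not depend on client order).
#' @param cohort The client's local [cohort_dataset()].
#' @param config Optional [model_config()] override for local training;
#'   defaults to the global model's configuration at run time.
#' @return A list of class `client_node`.
#' @export
client_node <- function(id, cohort, config = NULL) {
  stop_if_not(inherits(cohort, "cohort_dataset"), "cohort must be a cohort_dataset")
  stop_if_not(n_samples(cohort) >= 1, "client cohort must be non-empty")
  structure(list(id = as.character(id), cohort = cohort, config = config),
            class = "client_node")
}

#' Local training as seen by the server
#'
#' Broadcast interface of the round protocol: the client receives the global
#' parameter vector, trains `epochs` local epochs from it with a fresh
#' optimizer state, and returns only its trained parameters and sample
#' count.
#'
#' @param client A [client_node()].
#' @param global_model The broadcast `model_params` (parameters are copied;
#'   the client starts from them).
#' @param epochs Number of local epochs for this round.
#' @param seed Seed for this client-round (shuffles, dropout).
#' @return A [client_update()].
#' @export
client_train <- function(client, global_model, epochs, seed) {
  config <- client$config %||% global_model$config
  config$epochs <- as.integer(epochs)
  config$seed <- as.integer(seed)
  fit <- train_local(global_model, client$cohort, config)
  client_update(flatten_params(fit$model), n_samples(client$cohort))
}

#' Federated run configuration
#'
#' Defaults follow the round budget used for small exome cohorts: 5 rounds
#' of 100 local epochs each.
#'
#' @param n_rounds Number of FL rounds R (default 5).
#' @param local_epochs Local epochs per round E (default 100).
#' @param strategy A [strategy_config()] (default FedAvg).
#' @param seed Master seed; client-round seeds and the initialization seed
#'   are derived from it deterministically.
#' @return A list of class `fl_run_config`.
#' @export
fl_run_config <- function(n_rounds = 5L, local_epochs = 100L,
                          strategy = strategy_config("fedavg"), seed = 1L) {
  stop_if_not(n_rounds >= 1, "n_rounds must be >= 1")
  stop_if_not(local_epochs >= 1, "local_epochs must be >= 1")
  stop_if_not(inherits(strategy, "strategy_config"),
              "strategy must be a strategy_config")
  structure(list(n_rounds = as.integer(n_rounds),
                 local_epochs = as.integer(local_epochs),
                 strategy = strategy, seed = as.integer(seed)),
            class = "fl_run_config")
}

#' Execute one round of the centralized synchronous protocol
#'
#' (1) broadcast the global parameters to every client, (2) each client
#' trains `epochs` local epochs from them with a fresh local optimizer
#' state, (3) collect the client updates, (4) apply the aggregation
#' strategy. Clients are aggregated in lexicographic id order so the result
#' is independent of list order.
#'
#' @param global_model The current global `model_params`.
#' @param clients List of [client_node()] objects.
#' @param strategy A [strategy_config()].
#' @param state An [aggregation_state()].
#' @param epochs Local epochs for this round.
#' @param master_seed Seed from which per-client seeds are derived.
#' @param round_index 1-based round number (enters seed derivation).
#' @return List with `model`, `state` and `log` (round index, per-client
#'   sample counts and weights, global-parameter checksum).
#' @export
run_round <- function(global_model, clients, strategy, state,
                      epochs = 100L, master_seed = 1L, round_index = 1L) {
  stop_if_not(length(clients) >= 1, "need at least one client")
  ids <- vapply(clients, `[[`, "", "id")
  stop_if_not(!anyDuplicated(ids), "client ids must be unique")
  ord <- order(ids)
  updates <- vector("list", length(clients))
  for (i in ord) {
    seed_i <- derive_seed(master_seed, "round", round_index, "client", ids[i])
    up <- tryCatch(
      client_train(clients[[i]], global_model, epochs, seed_i),
      error = function(e) stop(sprintf(
        "client '%s' failed in round %d: %s; round aborted",
        ids[i], round_index, conditionMessage(e)), call. = FALSE))
    updates[[i]] <- up
  }
  step <- aggregate_step(strategy, state, flatten_params(global_model),
                         updates[ord])
  n_k <- vapply(updates, `[[`, 0L, "n_samples")
  log <- list(round = as.integer(round_index),
              client_ids = ids,
              n_samples = n_k,
              weights = n_k / sum(n_k),
              checksum = sum(step$global))
  list(model = set_theta(global_model, step$global),
       state = step$state, log = log)
}

#' Run the full federated training loop
#'
#' Initializes the global model (seed derived from the run seed), then
#' executes `n_rounds` sequential rounds. If an evaluation cohort is given
#' (the Central Server's own data), per-round held-out metrics are logged
#' and the best round's model is retained alongside the final one.
#'
#' @param clients List of [client_node()] objects sharing a panel.
#' @param run_config An [fl_run_config()].
#' @param eval_cohort Optional [cohort_dataset()] held by the server.
#' @param model_config Optional [model_config()]; defaults to the
#'   standard recipe sized to the clients' panel.
#' @return List of class `fl_fit` with `model` (final round),
#'   `best_model`, `best_round`, `logs` (one entry per round) and `state`.
#' @export
run_federated_training <- function(clients, run_config = fl_run_config(),
                                   eval_cohort = NULL, model_config = NULL) {
  stop_if_not(length(clients) >= 1, "need at least one client")
  G <- dim(clients[[1]]$cohort$tensor)[3]
  for (cl in clients)
    stop_if_not(dim(cl$cohort$tensor)[3] == G,
                "all clients must share the panel width")
  if (is.null(model_config))
    model_config <- fedgi::model_config(n_genes = G)
  model_config$seed <- derive_seed(run_config$seed, "global-init")
  model <- init_model(model_config)
  state <- aggregation_state(length(model$theta))
  logs <- vector("list", run_config$n_rounds)
  best_auc <- -Inf
  best_model <- model
  best_round <- NA_integer_
  for (r in seq_len(run_config$n_rounds)) {
    out <- run_round(model, clients, run_config$strategy, state,
                     epochs = run_config$local_epochs,
                     master_seed = run_config$seed, round_index = r)
    model <- out$model
    state <- out$state
    log <- out$log
    if (!is.null(eval_cohort)) {
      scores <- predict_proba(model, eval_cohort)
      rep <- metrics_report(eval_cohort$labels, scores)
      log$eval <- rep
      if (!is.na(rep$auc) && rep$auc > best_auc) {
        best_auc <- rep$auc
        best_model <- model
        best_round <- r
      }
    }
    logs[[r]] <- log
  }
  structure(list(model = model, best_model = best_model,
                 best_round = best_round, logs = logs, state = state),
            class = "fl_fit")
}

#' @export
print.fl_fit <- function(x, ...) {
  last <- x$logs[[length(x$logs)]]
  cat(sprintf("<fl_fit> %d rounds, %d clients (n = %s)\n",
              length(x$logs), length(last$n_samples),
              paste(last$n_samples, collapse = "/")))
  if (!is.null(last$eval))
    cat(sprintf("  final-round held-out AUC %.3f (best round %s)\n",
                last$eval$auc, x$best_round))
  invisible(x)
}
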