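#' Server-side aggregation strategy configuration
#'
#' Five strategies are supported. FedAvg is the sample-weighted average of
#' client parameters. FedAvgM applies server momentum to the pseudo-gradient
#' (aggregate minus previous global). FedAdam, FedYogi and FedAdagrad treat
#' the pseudo-gradient with the corresponding adaptive per-coordinate
#' optimizer on the server. Defaults mirror common choices in the federated
#' optimization literature: `server_lr` 1 for FedAvg/FedAvgM and 0.1 for the
#' adaptive strategies, momentum 0.9, beta1 0.9, beta2 0.99, tau 1e-3.
#'
#' @param name One of "fedavg", "fedavgm", "fedadam", "fedyogi",
#'   "fedadagrad".
#' @param server_lr Server learning rate eta (> 0).
#' @param beta Server momentum for FedAvgM (0 <= beta < 1).
#' @param beta1,beta2 First/second-moment decay rates for the adaptive
#'   strategies.
#' @param tau Adaptivity floor added to the root second moment (> 0).
#' @return A list of class `strategy_config`.
#' @export
strategy_config <- function(name = c("fedavg", "fedavgm", "fedadam",
                                     "fedyogi", "fedadagrad"),
                            server_lr = NULL, beta = 0.9,
                            beta1 = 0.9, beta2 = 0.99, tau = 1e-3) {
  name <- match.arg(name)
  if (is.null(server_lr))
    server_lr <- if (name %in% c("fedavg", "fedavgm")) 1.0 else 0.1
  stop_if_not(server_lr > 0, "server_lr must be > 0")
  stop_if_not(beta >= 0 && beta < 1, "beta must be in [0, 1)")
  stop_if_not(beta1 >= 0 && beta1 < 1 && beta2 >= 0 && beta2 < 1,
              "beta1 and beta2 must be in [0, 1)")
  stop_if_not(tau > 0, "tau must be > 0")
  structure(list(name = name, server_lr = server_lr, beta = beta,
                 beta1 = beta1, beta2 = beta2, tau = tau),
            class = "strategy_config")
}

#' One client's contribution to a round
#' @param parameters Flat numeric parameter vector (the client's model after
#'   local training).
#' @param n_samples The client's local sample count (aggregation weight).
#' @return A list of class `client_update`.
#' @export
client_update <- function(parameters, n_samples) {
  stop_if_not(n_samples >= 1, "n_samples must be >= 1")
  structure(list(parameters = as.numeric(parameters),
                 n_samples = as.integer(n_samples)),
            class = "client_update")
}

#' Server-side optimizer state
#'
#' Holds the first moment, second moment and momentum buffers (all zero at
#' round 0) plus a round counter. FedAvg ignores it; FedAvgM uses `buffer`;
#' the adaptive strategies use `m` and `v`.
#'
#' @param n_params Model parameter-vector length.
#' @return A list of class `aggregation_state`.
#' @export
aggregation_state <- function(n_params) {
  structure(list(m = numeric(n_params), v = numeric(n_params),
                 buffer = numeric(n_params), round = 0L),
            class = "aggregation_state")
}

check_updates <- function(updates, n_params = NULL) {
  stop_if_not(length(updates) >= 1, "need at least one client update")
  lens <- vapply(updates, function(u) length(u$parameters), 0L)
  stop_if_not(length(unique(lens)) == 1,
              "client parameter vectors must have equal lengths")
  if (!is.null(n_params))
    stop_if_not(lens[1] == n_params,
                "client update length does not match the global model")
  invisible(updates)
}

#' Sample-weighted mean of client parameter vectors
#'
#' Elementwise `sum_k (n_k / sum_j n_j) theta_k`: the FedAvg consensus.
#'
#' @param updates List of [client_update()] objects.
#' @return Flat numeric vector.
#' @export
weighted_mean <- function(updates) {
  check_updates(updates)
  w <- vapply(updates, `[[`, 0L, "n_samples")
  w <- w / sum(w)
  mat <- vapply(updates, `[[`, numeric(length(updates[[1]]$parameters)),
                "parameters")
  drop(mat %*% w)
}

#' FedAvg aggregation step
#'
#' Returns the sample-weighted mean of the client updates; `prev_global` is
#' used only for shape validation.
#'
#' @param prev_global Flat global parameter vector from the previous round.
#' @param updates List of [client_update()] objects.
#' @return New global parameter vector.
#' @export
fedavg_step <- function(prev_global, updates) {
  check_updates(updates, length(prev_global))
  weighted_mean(updates)
}

#' FedAvgM aggregation step (server momentum)
#'
#' The pseudo-update is `delta = weighted_mean(updates) - prev_global`; the
#' momentum buffer is updated as `buffer <- beta * buffer + delta` and the
#' new global is `prev_global + eta * buffer`. With `beta = 0, eta = 1` this
#' reduces exactly to FedAvg.
#'
#' @param state An [aggregation_state()].
#' @param prev_global Flat global parameter vector.
#' @param updates List of [client_update()] objects.
#' @param beta Momentum coefficient.
#' @param eta Server learning rate.
#' @return List with `global` (new parameter vector) and `state`.
#' @export
fedavgm_step <- function(state, prev_global, updates, beta = 0.9, eta = 1.0) {
  check_updates(updates, length(prev_global))
  delta <- weighted_mean(updates) - prev_global
  state$buffer <- beta * state$buffer + delta
  state$round <- state$round + 1L
  list(global = prev_global + eta * state$buffer, state = state)
}

#' Adaptive server aggregation step (FedAdam / FedYogi / FedAdagrad)
#'
#' Treats the pseudo-gradient `delta = weighted_mean(updates) - prev_global`
#' with an adaptive per-coordinate optimizer on the server:
#' `m <- beta1 m + (1 - beta1) delta`; the second moment is
#' `v <- v + delta^2` (adagrad), `v <- beta2 v + (1 - beta2) delta^2`
#' (adam), or `v <- v - (1 - beta2) delta^2 sign(v - delta^2)` (yogi);
#' then `global <- prev_global + eta * m / (sqrt(v) + tau)`.
#'
#' @param state An [aggregation_state()].
#' @param prev_global Flat global parameter vector.
#' @param updates List of [client_update()] objects.
#' @param variant One of "adam", "yogi", "adagrad".
#' @param beta1,beta2 Moment decay rates.
#' @param eta Server learning rate.
#' @param tau Adaptivity floor.
#' @return List with `global` and `state`.
#' @export
fedopt_step <- function(state, prev_global, updates,
                        variant = c("adam", "yogi", "adagrad"),
                        beta1 = 0.9, beta2 = 0.99, eta = 0.1, tau = 1e-3) {
  variant <- match.arg(variant)
  check_updates(updates, length(prev_global))
  delta <- weighted_mean(updates) - prev_global
  state$m <- beta1 * state$m + (1 - beta1) * delta
  d2 <- delta^2
  state$v <- switch(variant,
    adagrad = state$v + d2,
    adam = beta2 * state$v + (1 - beta2) * d2,
    yogi = state$v - (1 - beta2) * d2 * sign(state$v - d2))
  state$round <- state$round + 1L
  list(global = prev_global + eta * state$m / (sqrt(state$v) + tau),
       state = state)
}

#' Apply one aggregation step under a named strategy
#'
#' Dispatcher used by the round protocol: routes to [fedavg_step()],
#' [fedavgm_step()] or [fedopt_step()] according to the strategy name.
#'
#' @param strategy A [strategy_config()].
#' @param state An [aggregation_state()].
#' @param prev_global Flat global parameter vector.
#' @param updates List of [client_update()] objects.
#' @return List with `global` and `state`.
#' @export
aggregate_step <- function(strategy, state, prev_global, updates) {
  switch(strategy$name,
    fedavg = {
      g <- fedavg_step(prev_global, updates)
      state$round <- state$round + 1L
      list(global = g, state = state)
    },
    fedavgm = fedavgm_step(state, prev_global, updates,
                           beta = strategy$beta, eta = strategy$server_lr),
    fedadam = fedopt_step(state, prev_global, updates, "adam",
                          strategy$beta1, strategy$beta2,
                          strategy$server_lr, strategy$tau),
    fedyogi = fedopt_step(state, prev_global, updates, "yogi",
                          strategy$beta1, strategy$beta2,
                          strategy$server_lr, strategy$tau),
    fedadagrad = fedopt_step(state, prev_global, updates, "adagrad",
                             strategy$beta1, strategy$beta2,
                             strategy$server_lr, strategy$tau),
    stop("unknown aggregation strategy: ", strategy$name))
}
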