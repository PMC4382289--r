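#' CMA-ES optimizer settings
#'
#' @param lambda population size (at least 4).
#' @param sigma0 initial step size as a fraction of the normalized bound
#'   range.
#' @param max_iter iteration budget.
#' @param stall_iter stop after this many consecutive iterations without
#'   best-ever improvement.
#' @param seed random seed (recorded in all outputs).
#' @param workers parallel evaluation processes (forked; 1 = serial).
#' @return an `optimizer_settings` list.
#' @export
optimizer_settings <- function(lambda = 16, sigma0 = 0.15, max_iter = 300,
                               stall_iter = 300, seed = 1, workers = 1) {
  if (lambda < 4) stop("lambda must be at least 4")
  structure(list(lambda = lambda, sigma0 = sigma0, max_iter = max_iter,
                 stall_iter = stall_iter, seed = seed, workers = workers),
            class = "optimizer_settings")
}

#' Covariance matrix adaptation evolution strategy
#'
#' Gradient-free stochastic optimizer: a multivariate Gaussian search
#' distribution (mean, step size, covariance) is adapted toward low-objective
#' regions from ranked candidate samples (the standard (mu/mu_w, lambda)
#' formulation with cumulative step-size adaptation and rank-one/rank-mu
#' covariance updates). Candidates are clipped to the box bounds before
#' evaluation. The starting point is evaluated once up front, so the returned
#' best never regresses below the warm start. Non-finite objective values are
#' treated as +Inf (candidate rejected by ranking). Deterministic given the
#' seed; candidate evaluations within a generation are independent and may be
#' evaluated in parallel without changing the result (results are ordered by
#' candidate index).
#'
#' @param objective_fn function mapping a numeric vector to a scalar cost.
#' @param x0 starting point (normalized design vector).
#' @param settings an [optimizer_settings()].
#' @param lower,upper box bounds (scalars or vectors).
#' @param callback optional function called after each iteration with
#'   `(iteration, best_value, best)`; useful for logging or checkpointing.
#' @return list with `best` (vector), `best_value`, `history` (data.frame:
#'   iteration, best and mean generation cost, best-so-far, step size), and
#'   `settings`.
#' @export
cma_optimize <- function(objective_fn, x0, settings = optimizer_settings(),
                         lower = 0, upper = 1, callback = NULL) {
  n <- length(x0)
  lambda <- settings$lambda
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  set.seed(settings$seed)

  evaluate <- function(cands) {
    vals <- if (settings$workers > 1 &&
                requireNamespace("parallel", quietly = TRUE)) {
      unlist(parallel::mclapply(cands, objective_fn,
                                mc.cores = settings$workers))
    } else {
      vapply(cands, objective_fn, numeric(1))
    }
    vals[!is.finite(vals)] <- Inf
    vals
  }

  # strategy parameters (Hansen's defaults)
  mu <- floor(lambda / 2)
  weights <- log(mu + 0.5) - log(seq_len(mu))
  weights <- weights / sum(weights)
  mueff <- 1 / sum(weights^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- settings$sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); invsqrtC <- diag(n)
  counteval <- 0

  best_x <- xmean
  best_val <- objective_fn(xmean)
  if (!is.finite(best_val)) best_val <- Inf
  counteval <- counteval + 1

  hist <- vector("list", settings$max_iter)
  stall <- 0
  for (it in seq_len(settings$max_iter)) {
    arz <- matrix(rnorm(n * lambda), n, lambda)
    ed <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(ed$values, 1e-20))
    B <- ed$vectors
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arx <- pmin(pmax(arx, lower), upper)
    cands <- lapply(seq_len(lambda), function(k) arx[, k])
    vals <- evaluate(cands)
    counteval <- counteval + lambda
    idx <- order(vals)
    improved <- vals[idx[1]] < best_val
    if (improved) { best_val <- vals[idx[1]]; best_x <- arx[, idx[1]] }
    stall <- if (improved) 0 else stall + 1

    xold <- xmean
    sel <- arx[, idx[seq_len(mu)], drop = FALSE]
    xmean <- drop(sel %*% weights)
    y <- (xmean - xold) / sigma
    invsqrtC <- B %*% ((1 / D) * t(B))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% y)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * counteval / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y
    artmp <- (sel - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (weights * t(artmp))
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    hist[[it]] <- data.frame(iteration = it, best = vals[idx[1]],
                             mean = mean(vals[is.finite(vals)]),
                             best_so_far = best_val, sigma = sigma)
    if (!is.null(callback)) callback(it, best_val, best_x)
    if (stall >= settings$stall_iter) break
    if (sigma < 1e-12) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  list(best = best_x, best_value = best_val, history = history,
       evaluations = counteval, settings = settings)
}

#' Gait objective closure for the optimizer
#'
#' Wraps [simulate_walker()] + [total_objective()] into a scalar function of
#' the normalized design vector, for one scenario. Guards are added on top of
#' the plain objective so that forward progression at the target speed is
#' enforced over the whole rollout, not only between heel-strikes: a rollout
#' with no steps at all is charged the velocity penalty of its whole-rollout
#' mean forward COM speed, and strike-free stretches before the first or
#' after the last heel-strike longer than `guard_gap` seconds (clearly longer
#' than any step) are charged as additional pseudo-steps. Without these
#' guards, quiet standing -- possibly after a few valid steps -- is cheaper
#' than walking and becomes the optimizer's attractor.
#'
#' @param scenario a [walking_scenario()].
#' @param weights an [objective_weights()]; the scenario's target speed
#'   overrides the weight default.
#' @inheritParams simulate_walker
#' @param guard_gap maximal tolerated strike-free stretch (s) at either end
#'   of the rollout before the velocity guard engages.
#' @return function mapping a design vector to the scalar cost `R`.
#' @export
make_gait_objective <- function(scenario = walking_scenario(),
                                weights = objective_weights(),
                                model = walker_model(),
                                contact = contact_params(),
                                muscles = mtu_table(),
                                wiring = default_wiring(),
                                dt = 5e-4, record_hz = 100,
                                guard_gap = 0.8) {
  weights$target_speed <- scenario$target_speed
  force(model); force(contact); force(muscles); force(wiring)
  function(z) {
    tr <- simulate_walker(z, scenario, model = model, contact = contact,
                          muscles = muscles, wiring = wiring, dt = dt,
                          record_hz = record_hz)
    R <- suppressWarnings(total_objective(tr, weights)$R)
    pen_v <- function(x0, x1, t0, t1)
      weights$w_vel * q_penalty((x1 - x0) / max(t1 - t0, 1e-6) -
                                  weights$target_speed, weights$vel_epsilon)
    s <- tr$samples
    if (nrow(tr$events) < 2) {
      R <- R + pen_v(s$com_x[1], tail(s$com_x, 1), 0, tr$t_end)
    } else {
      ev <- tr$events[order(tr$events$time), ]
      if (ev$time[1] > guard_gap)
        R <- R + pen_v(s$com_x[1], ev$com_x[1], 0, ev$time[1])
      n <- nrow(ev)
      if (tr$t_end - ev$time[n] > guard_gap)
        R <- R + pen_v(ev$com_x[n], tail(s$com_x, 1), ev$time[n], tr$t_end)
    }
    R
  }
}

#' Scenario continuation
#'
#' Optimizes an ordered schedule of scenarios (increasing load or incline),
#' initializing each optimization from the best solution of the previous one.
#' A scenario whose best solution still falls is flagged, and later scenarios
#' continue from the last non-falling solution.
#'
#' @param scenarios list of [walking_scenario()] in schedule order.
#' @param x0 starting design vector for the first scenario.
#' @param settings an [optimizer_settings()]; the seed is advanced by one per
#'   scenario so stages draw independent samples.
#' @param ... passed to [make_gait_objective()] (model, contact, muscles,
#'   wiring, weights, dt, record_hz).
#' @return list of per-scenario results: `scenario`, `solution`, `value`,
#'   `fell`, `seed`, `history`.
#' @export
continuation <- function(scenarios, x0, settings = optimizer_settings(), ...) {
  out <- vector("list", length(scenarios))
  warm <- x0
  extra <- list(...)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    st <- settings; st$seed <- settings$seed + i - 1
    obj <- do.call(make_gait_objective, c(list(scenario = sc), extra))
    res <- cma_optimize(obj, warm, st)
    tr <- do.call(simulate_walker,
                  c(list(design = res$best, scenario = sc),
                    extra[intersect(names(extra),
                                    c("model", "contact", "muscles", "wiring",
                                      "dt", "record_hz"))]))
    out[[i]] <- list(scenario = sc, solution = res$best,
                     value = res$best_value, fell = tr$fell,
                     seed = st$seed, history = res$history)
    if (!tr$fell) warm <- res$best
  }
  out
}
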