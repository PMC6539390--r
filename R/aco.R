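# Ant-colony-optimization wrapper feature selection over the 36 color
# components.  Each component is a node with two states (include / exclude);
# an ant's path through the nodes is a candidate subset, scored by the
# weighted mean absolute deviation (BestCost) of a BPNN fitted on the subset.
# Pheromone is kept per (component, state), evaporated each iteration and
# reinforced by every ant in proportion to 1 / cost (ant-cycle model).

#' Control parameters for the ACO feature selector
#'
#' Defaults are the study settings: 20 ants, 100 iterations, initial
#' pheromone 1, pheromone and visibility exponents `alpha = beta = 1`, and
#' evaporation coefficient `rho = 0.05`.
#'
#' @param n_ants colony size.
#' @param max_iterations number of colony iterations.
#' @param initial_pheromone starting pheromone on every (component, state).
#' @param alpha pheromone-concentration exponent.
#' @param beta visibility exponent.
#' @param evaporation evaporation coefficient `rho` in (0, 1).
#' @param deposit_total pheromone `Q` released per ant, spread as `Q / cost`.
#' @param evaporation_mode `"conventional"` keeps a `(1 - rho)` fraction per
#'   iteration; `"literal"` keeps a `rho` fraction (the update rule read
#'   exactly as printed, where `rho` multiplies the old pheromone).
#' @param visibility_mode `"abs_correlation"` (default: include-state
#'   visibility is the absolute Pearson correlation between component and
#'   response on the calibration set, the usual wrapper-selection heuristic
#'   and the only reading under which the stated visibility exponent
#'   `beta = 1` has any effect) or `"uniform"` (no heuristic preference;
#'   `beta` is then inert).
#' @param min_subset_size smallest admissible subset; constructions below it
#'   are topped up with the highest include-probability components.
#' @param train_weight,test_weight BestCost weights for the calibration and
#'   validation deviations (must sum to 1).
#' @return a list of class `aco_control`.
#' @export
aco_control <- function(n_ants = 20, max_iterations = 100,
                        initial_pheromone = 1, alpha = 1, beta = 1,
                        evaporation = 0.05, deposit_total = 1,
                        evaporation_mode = c("conventional", "literal"),
                        visibility_mode = c("abs_correlation", "uniform"),
                        min_subset_size = 1,
                        train_weight = 0.75, test_weight = 0.25) {
  if (n_ants < 1) stop("'n_ants' must be >= 1")
  if (evaporation <= 0 || evaporation >= 1) stop("'evaporation' must be in (0, 1)")
  if (abs(train_weight + test_weight - 1) > 1e-12)
    stop("'train_weight' + 'test_weight' must equal 1")
  if (initial_pheromone <= 0) stop("'initial_pheromone' must be > 0")
  structure(list(n_ants = as.integer(n_ants),
                 max_iterations = as.integer(max_iterations),
                 initial_pheromone = initial_pheromone,
                 alpha = alpha, beta = beta, evaporation = evaporation,
                 deposit_total = deposit_total,
                 evaporation_mode = match.arg(evaporation_mode),
                 visibility_mode = match.arg(visibility_mode),
                 min_subset_size = as.integer(min_subset_size),
                 train_weight = train_weight, test_weight = test_weight),
            class = "aco_control")
}

#' State-selection probabilities from pheromone and visibility
#'
#' For each component the probability of choosing state `j` (include or
#' exclude) is `tau_j^alpha * eta_j^beta / sum_j tau_j^alpha * eta_j^beta`.
#'
#' @param tau pheromone: a length-2 vector `(include, exclude)` or an
#'   n x 2 matrix.
#' @param eta visibility, same shape as `tau`.
#' @param alpha,beta exponents.
#' @return probabilities with the shape of `tau`; each pair sums to 1.
#' @export
#' @examples
#' selection_probabilities(c(2, 1), c(1, 1))
selection_probabilities <- function(tau, eta, alpha = 1, beta = 1) {
  vec <- is.null(dim(tau))
  tau <- rbind(tau)[, , drop = FALSE]
  eta <- rbind(eta)[, , drop = FALSE]
  if (any(tau <= 0) || any(eta <= 0)) stop("'tau' and 'eta' must be positive")
  w <- tau^alpha * eta^beta
  p <- w / rowSums(w)
  if (vec) drop(p) else p
}

#' Construct a candidate subset from the pheromone table
#'
#' Every component's state is sampled independently from
#' [selection_probabilities()]; if fewer than `min_subset_size` components
#' end up included, those with the highest include-probability are forced in.
#' Uses the current RNG stream.
#'
#' @param tau,eta 36 x 2 (or n x 2) pheromone and visibility tables, columns
#'   `(include, exclude)`.
#' @param control an [aco_control()].
#' @return logical inclusion mask of length n.
#' @export
construct_subset <- function(tau, eta, control = aco_control()) {
  p <- selection_probabilities(tau, eta, control$alpha, control$beta)
  p_inc <- p[, 1L]
  mask <- runif(length(p_inc)) < p_inc
  short <- control$min_subset_size - sum(mask)
  if (short > 0L) {
    force_in <- order(p_inc, decreasing = TRUE)
    force_in <- force_in[!mask[force_in]][seq_len(short)]
    mask[force_in] <- TRUE
  }
  mask
}

#' Weighted mean-absolute-deviation objective (BestCost)
#'
#' `BestCost = w_train * mean(|e_train|) + w_test * mean(|e_test|)`, with
#' deviations `e = measured - predicted` on the calibration and validation
#' sets and default weights 0.75 / 0.25.
#'
#' @param deviations_train,deviations_test absolute deviation vectors.
#' @param train_weight,test_weight convex weights.
#' @return scalar cost.
#' @export
#' @examples
#' best_cost(c(1, 1), 2)
best_cost <- function(deviations_train, deviations_test,
                      train_weight = 0.75, test_weight = 0.25) {
  if (length(deviations_train) == 0L || length(deviations_test) == 0L)
    stop("deviation vectors must be non-empty")
  train_weight * mean(abs(deviations_train)) +
    test_weight * mean(abs(deviations_test))
}

#' Pheromone released by one ant (ant-cycle model)
#'
#' `delta_tau = Q / L` with `L` the ant's cost; smaller cost, larger deposit.
#' Costs below `eps` are clamped so the deposit is capped at `Q / eps`.
#'
#' @param cost the ant's BestCost.
#' @param Q total pheromone released per ant.
#' @param eps lower clamp for the cost.
#' @return scalar deposit.
#' @export
deposit_amount <- function(cost, Q = 1, eps = 1e-12) {
  Q / max(cost, eps)
}

#' Evaporate and reinforce the pheromone table
#'
#' Conventional mode keeps `(1 - rho)` of the old pheromone; literal mode
#' keeps `rho` (the printed form of the update, in which `rho` multiplies the
#' old value).  Every ant deposits `Q / cost` on the state it chose for each
#' component.  Pheromone is floored at `1e-6`.
#'
#' @param tau n x 2 pheromone table, columns `(include, exclude)`.
#' @param masks list of logical inclusion masks, one per ant.
#' @param costs numeric costs, one per ant.
#' @param control an [aco_control()].
#' @return updated pheromone table.
#' @export
update_pheromone <- function(tau, masks, costs, control = aco_control()) {
  keep <- if (control$evaporation_mode == "conventional")
    1 - control$evaporation else control$evaporation
  out <- tau * keep
  for (k in seq_along(masks)) {
    d <- deposit_amount(costs[[k]], control$deposit_total)
    inc <- masks[[k]]
    out[cbind(seq_len(nrow(tau)), ifelse(inc, 1L, 2L))] <-
      out[cbind(seq_len(nrow(tau)), ifelse(inc, 1L, 2L))] + d
  }
  pmax(out, 1e-6)
}

#' Evaluate one feature subset with a BPNN fit
#'
#' Trains a network on the calibration samples restricted to the masked
#' components, computes absolute deviations on calibration and validation
#' sets, and returns the BestCost together with Rc2/RMSECV/Rp2/RMSEP.
#' A diverging fit is recorded as infinite cost so the solution never wins.
#'
#' @param mask logical inclusion mask over the feature columns.
#' @param split a [split_by_batch()] result.
#' @param control an [aco_control()] (for the BestCost weights).
#' @param train_control a [bpnn_control()].
#' @param seed seed for the network initialization.
#' @param feature_cols feature column names (default the 36 components).
#' @param response response column (default `"od_measured"`).
#' @return list with `mask`, `cost`, `metrics`.
#' @export
evaluate_subset <- function(mask, split, control = aco_control(),
                            train_control = bpnn_control(), seed = NULL,
                            feature_cols = feature_names(),
                            response = "od_measured") {
  if (sum(mask) < 1L) stop("'mask' must include at least one component")
  cols <- feature_cols[mask]
  Xc <- as.matrix(split$calibration[, cols, drop = FALSE])
  Xv <- as.matrix(split$validation[, cols, drop = FALSE])
  yc <- split$calibration[[response]]
  yv <- split$validation[[response]]
  fit <- tryCatch(bpnn(Xc, yc, control = train_control, seed = seed),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(mask = mask, cost = Inf,
                metrics = c(Rc2 = NA, RMSECV = NA, Rp2 = NA, RMSEP = NA)))
  pc <- predict(fit, Xc)
  pv <- predict(fit, Xv)
  cost <- best_cost(abs(yc - pc), abs(yv - pv),
                    control$train_weight, control$test_weight)
  list(mask = mask, cost = cost,
       metrics = c(Rc2 = r2(yc, pc), RMSECV = rmse(yc, pc),
                   Rp2 = r2(yv, pv), RMSEP = rmse(yv, pv)))
}

# Memoizing cost function over masks for one run: identical masks are
# evaluated once (the fit is deterministic given the run's training seed).
make_subset_cost_fn <- function(split, control, train_control, train_seed,
                                feature_cols = feature_names(),
                                response = "od_measured") {
  cache <- new.env(parent = emptyenv())
  function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sol <- evaluate_subset(mask, split, control, train_control,
                           seed = train_seed, feature_cols = feature_cols,
                           response = response)
    cache[[key]] <- sol
    sol
  }
}

#' Run the ACO search once
#'
#' Generic engine: any cost function over inclusion masks can be optimized.
#' Each iteration, `n_ants` subsets are constructed from the pheromone table,
#' evaluated, and all ants reinforce their chosen states; the best-so-far
#' solution is tracked elitistically.
#'
#' @param cost_fn function taking a logical mask and returning either a
#'   numeric cost or a list with elements `cost` (and optionally `metrics`).
#' @param n_components number of selectable components.
#' @param control an [aco_control()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @param visibility optional n x 2 visibility table (default uniform).
#' @return object of class `aco_run`: `best_mask`, `best_cost`,
#'   `best_metrics`, `convergence_curve` (best-so-far cost per iteration),
#'   `convergence_iteration` (last iteration improving by more than 1e-6),
#'   `pheromone` (final table), `seed`.
#' @export
aco_run <- function(cost_fn, n_components, control = aco_control(),
                    seed = NULL, visibility = NULL) {
  if (is.null(visibility))
    visibility <- matrix(1, n_components, 2L)
  tau <- matrix(control$initial_pheromone, n_components, 2L,
                dimnames = list(NULL, c("include", "exclude")))
  with_seed(seed, {
    best <- list(cost = Inf, mask = NULL, metrics = NULL)
    curve <- numeric(control$max_iterations)
    conv_iter <- 0L
    for (it in seq_len(control$max_iterations)) {
      masks <- replicate(control$n_ants,
                         construct_subset(tau, visibility, control),
                         simplify = FALSE)
      sols <- lapply(masks, function(m) {
        s <- cost_fn(m)
        if (is.numeric(s)) s <- list(cost = s)
        s
      })
      costs <- vapply(sols, `[[`, numeric(1L), "cost")
      k <- which.min(costs)
      if (costs[k] < best$cost - 1e-6) conv_iter <- it
      if (costs[k] < best$cost)
        best <- list(cost = costs[k], mask = masks[[k]],
                     metrics = sols[[k]]$metrics)
      curve[it] <- best$cost
      tau <- update_pheromone(tau, masks, costs, control)
    }
    structure(list(best_mask = best$mask, best_cost = best$cost,
                   best_metrics = best$metrics, convergence_curve = curve,
                   convergence_iteration = conv_iter, pheromone = tau,
                   seed = seed),
              class = "aco_run")
  })
}

#' @export
print.aco_run <- function(x, ...) {
  cat(sprintf("ACO run: best cost %.4f with %d component(s), converged at iteration %d\n",
              x$best_cost, sum(x$best_mask), x$convergence_iteration))
  if (!is.null(names(x$best_mask)))
    cat("selected:", paste(names(x$best_mask)[x$best_mask], collapse = ", "), "\n")
  invisible(x)
}

#' Plot the convergence curve of an ACO run
#'
#' @param x an [aco_run()] result.
#' @param ... passed to [plot()].
#' @export
plot.aco_run <- function(x, ...) {
  plot(seq_along(x$convergence_curve), x$convergence_curve, type = "s",
       xlab = "iteration", ylab = "best-so-far BestCost", ...)
  abline(v = x$convergence_iteration, lty = 2)
  invisible(x)
}

# Visibility table for a data split under the configured mode.
visibility_for_split <- function(split, control,
                                 feature_cols = feature_names(),
                                 response = "od_measured") {
  n <- length(feature_cols)
  if (control$visibility_mode == "uniform") return(matrix(1, n, 2L))
  X <- as.matrix(split$calibration[, feature_cols, drop = FALSE])
  y <- split$calibration[[response]]
  r <- abs(apply(X, 2L, function(col)
    if (sd(col) == 0) 0 else cor(col, y)))
  cbind(include = pmax(r, 1e-3), exclude = 1 - pmin(r, 1 - 1e-3))
}

#' ACO feature selection on a calibration/validation split
#'
#' One seeded search over the 36 color components, scored by the BestCost of
#' a BPNN fitted per candidate subset.  The network-initialization seed is
#' derived from the run seed, and identical subsets within a run are
#' evaluated once.
#'
#' @param split a [split_by_batch()] result.
#' @param control an [aco_control()].
#' @param train_control a [bpnn_control()] for the per-subset fits.
#' @param seed integer run seed.
#' @param feature_cols,response data columns (defaults: the 36 components,
#'   `od_measured`).
#' @return an `aco_run` whose `best_mask` is named by component.
#' @export
aco_select <- function(split, control = aco_control(),
                       train_control = bpnn_control(), seed = NULL,
                       feature_cols = feature_names(),
                       response = "od_measured") {
  train_seed <- with_seed(seed, draw_seeds(1L))
  cost_fn <- make_subset_cost_fn(split, control, train_control, train_seed,
                                 feature_cols, response)
  vis <- visibility_for_split(split, control, feature_cols, response)
  run <- aco_run(cost_fn, length(feature_cols), control, seed = seed,
                 visibility = vis)
  names(run$best_mask) <- feature_cols
  run
}

#' Repeated ACO runs with component-selection frequencies
#'
#' The search is stochastic, so it is repeated (50 times in the study) under
#' the same settings with seeds `base_seed + 1, ..., base_seed + n_runs`, and
#' each component's selection count over the per-run best subsets is
#' tallied.
#'
#' @inheritParams aco_select
#' @param n_runs number of independent runs (default 50).
#' @param base_seed integer; run `i` uses seed `base_seed + i`.
#' @return object of class `aco_runs`: `runs` (list of `aco_run`),
#'   `frequency` (data.frame `component`, `dye`, `channel`, `count`),
#'   `n_runs`.
#' @export
aco_repeat <- function(split, control = aco_control(),
                       train_control = bpnn_control(), n_runs = 50,
                       base_seed = 0, feature_cols = feature_names(),
                       response = "od_measured") {
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  runs <- lapply(seq_len(n_runs), function(i)
    aco_select(split, control, train_control, seed = base_seed + i,
               feature_cols = feature_cols, response = response))
  counts <- Reduce(`+`, lapply(runs, function(r) as.integer(r$best_mask)))
  parts <- strsplit(feature_cols, ":", fixed = TRUE)
  freq <- data.frame(component = feature_cols,
                     dye = vapply(parts, `[`, "", 1L),
                     channel = vapply(parts, function(p) p[length(p)], ""),
                     count = counts)
  structure(list(runs = runs, frequency = freq, n_runs = n_runs,
                 base_seed = base_seed),
            class = "aco_runs")
}

#' @export
print.aco_runs <- function(x, ...) {
  cat(sprintf("%d ACO runs; best cost %.4f\n", x$n_runs,
              min(vapply(x$runs, `[[`, numeric(1L), "best_cost"))))
  top <- x$frequency[order(-x$frequency$count), ]
  cat("top components by selection frequency:\n")
  print(head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' Plot selection frequencies over repeated ACO runs
#'
#' @param x an [aco_repeat()] result.
#' @param ... passed to [barplot()].
#' @export
plot.aco_runs <- function(x, ...) {
  barplot(x$frequency$count, names.arg = x$frequency$component, las = 2,
          cex.names = 0.6, ylab = sprintf("selections in %d runs", x$n_runs),
          ...)
  invisible(x)
}

#' Select components by cross-run frequency threshold
#'
#' Components chosen in at least `threshold` of the runs, ordered by count
#' (descending) with ties broken by component index.
#'
#' @param freq an `aco_runs` object or its `frequency` data.frame.
#' @param threshold minimum selection count.
#' @return character vector of component names (possibly empty).
#' @export
select_by_frequency <- function(freq, threshold) {
  if (inherits(freq, "aco_runs")) freq <- freq$frequency
  if (threshold < 0) stop("'threshold' must be >= 0")
  hit <- freq[freq$count >= threshold, , drop = FALSE]
  hit <- hit[order(-hit$count, seq_len(nrow(hit))), , drop = FALSE]
  hit$component
}
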