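test_that("state-selection probabilities follow the pheromone/visibility rule", {
  expect_equal(selection_probabilities(c(2, 1), c(1, 1)), c(2 / 3, 1 / 3))
  expect_equal(selection_probabilities(c(5, 5), c(2, 2)), c(0.5, 0.5))
  # beta = 0 removes the visibility influence
  expect_equal(selection_probabilities(c(1, 1), c(9, 1), beta = 0), c(0.5, 0.5))
  # matrix form: every row sums to 1, general exponents honoured
  set.seed(1)
  tau <- matrix(runif(72, 0.1, 5), 36, 2)
  eta <- matrix(runif(72, 0.1, 5), 36, 2)
  p <- selection_probabilities(tau, eta, alpha = 2, beta = 0.5)
  expect_equal(rowSums(p), rep(1, 36))
  expect_equal(p[3, 1],
               (tau[3, 1]^2 * sqrt(eta[3, 1])) /
                 (tau[3, 1]^2 * sqrt(eta[3, 1]) + tau[3, 2]^2 * sqrt(eta[3, 2])))
  expect_error(selection_probabilities(c(0, 1), c(1, 1)), "positive")
})

test_that("subset construction samples the rule and enforces the size floor", {
  ctrl <- aco_control()
  eta <- matrix(1, 36, 2)
  # overwhelming include pheromone: all components included
  tau_inc <- cbind(rep(1e6, 36), rep(1, 36))
  set.seed(2)
  for (i in 1:100) expect_true(all(construct_subset(tau_inc, eta, ctrl)))
  # overwhelming exclude pheromone: the forcing rule keeps one component
  tau_exc <- cbind(rep(1e-6, 36), rep(1, 36))
  set.seed(3)
  m <- construct_subset(tau_exc, eta, ctrl)
  expect_equal(sum(m), 1L)
  # empirical inclusion frequency tracks the analytic probability
  tau <- cbind(rep(3, 36), rep(1, 36))   # p_include = 0.75
  set.seed(4)
  freq <- rowMeans(replicate(4000, construct_subset(tau, eta, ctrl)))
  expect_lt(max(abs(freq - 0.75)), 0.03)
})

test_that("BestCost is the stated weighted mean absolute deviation", {
  expect_equal(best_cost(c(0, 0), c(0, 0)), 0)
  expect_equal(best_cost(c(1, 1), 2), 0.75 * 1 + 0.25 * 2)
  # equal deviation sets: the convex weights cancel
  expect_equal(best_cost(c(2, 4), c(2, 4)), 3)
  expect_equal(best_cost(c(2, 4), c(2, 4), 0.9, 0.1), 3)
  expect_error(best_cost(numeric(0), 1), "non-empty")
})

test_that("pheromone deposits and updates follow the ant-cycle model", {
  expect_equal(deposit_amount(2, Q = 1), 0.5)
  expect_equal(deposit_amount(1, Q = 1) / deposit_amount(2, Q = 1), 2)
  expect_equal(deposit_amount(0, Q = 1), 1e12)  # epsilon guard

  ctrl <- aco_control()
  tau <- matrix(1, 1, 2)
  # conventional: tau <- 0.95 * 1 + 0.5 on the chosen (include) state
  up <- update_pheromone(tau, list(TRUE), 2, ctrl)
  expect_equal(up[1, 1], 1.45)
  expect_equal(up[1, 2], 0.95)
  # literal printed form: tau <- rho * tau
  ctrl_lit <- aco_control(evaporation_mode = "literal")
  up2 <- update_pheromone(tau, list(), numeric(0), ctrl_lit)
  expect_equal(up2[1, ], c(0.05, 0.05), ignore_attr = TRUE)
  # with no deposits the table decays monotonically to the floor
  t3 <- matrix(1, 4, 2)
  for (i in 1:400) t3 <- update_pheromone(t3, list(), numeric(0), ctrl)
  expect_true(all(t3 >= 1e-6))
  expect_lt(max(t3), 1e-6 + 1e-8)
})

test_that("subset evaluation separates informative from noise components", {
  d <- generate_dataset(seed = 5)
  s <- split_by_batch(d)
  mk <- function(idx) { m <- rep(FALSE, 36); m[idx] <- TRUE; m }
  true_mask <- mk(c(9, 24))
  noise_mask <- mk(c(15, 20))
  wins <- 0
  for (i in 1:20) {
    ct <- evaluate_subset(true_mask, s, train_control = quick_train(),
                          seed = i)$cost
    cn <- evaluate_subset(noise_mask, s, train_control = quick_train(),
                          seed = i)$cost
    wins <- wins + (ct < cn)
  }
  expect_gte(wins, 19)
  # determinism of a repeated evaluation
  e1 <- evaluate_subset(true_mask, s, train_control = quick_train(), seed = 1)
  e2 <- evaluate_subset(true_mask, s, train_control = quick_train(), seed = 1)
  expect_identical(e1, e2)
  expect_error(evaluate_subset(rep(FALSE, 36), s), "at least one")
})

test_that("the search matches exhaustive enumeration on a tiny cost table", {
  # deterministic cost over all 15 non-empty masks of 4 components;
  # optimum at {1, 3}
  cost_table <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    costs <- c("1010" = 0.10, "1000" = 0.40, "0010" = 0.45, "1110" = 0.22,
               "1011" = 0.25, "1100" = 0.55, "0110" = 0.60, "0011" = 0.58,
               "0100" = 0.90, "0001" = 0.95, "1001" = 0.50, "0101" = 0.85,
               "0111" = 0.35, "1101" = 0.30, "1111" = 0.28)
    unname(costs[key])
  }
  # exhaustive oracle
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  masks <- masks[rowSums(masks) > 0, ]
  all_costs <- apply(masks, 1, function(m) cost_table(as.logical(m)))
  best <- as.logical(masks[which.min(all_costs), ])
  expect_equal(best, c(TRUE, FALSE, TRUE, FALSE))

  ctrl <- aco_control(n_ants = 20, max_iterations = 50)
  hits <- 0
  for (i in 1:100) {
    run <- aco_run(cost_table, 4, ctrl, seed = i)
    hits <- hits + identical(run$best_mask, best)
  }
  expect_gte(hits, 95)
})

test_that("runs are elitist, convergent and seed-deterministic", {
  noisy_cost <- function(mask) sum(mask) + runif(1)  # favours tiny subsets
  ctrl <- aco_control(n_ants = 5, max_iterations = 20)
  r1 <- aco_run(noisy_cost, 8, ctrl, seed = 4)
  r2 <- aco_run(noisy_cost, 8, ctrl, seed = 4)
  expect_identical(r1[names(r1) != "pheromone"], r2[names(r2) != "pheromone"])
  expect_identical(r1$pheromone, r2$pheromone)
  expect_length(r1$convergence_curve, 20L)
  expect_true(all(diff(r1$convergence_curve) <= 0))
  expect_gte(r1$convergence_iteration, 1L)
  expect_equal(r1$convergence_curve[r1$convergence_iteration], r1$best_cost)
})

test_that("repeated runs tally frequencies over per-run best subsets", {
  fixed_cost <- function(mask)
    sum(mask != c(TRUE, TRUE, rep(FALSE, 4))) / 6 + 0.01
  ctrl <- aco_control(n_ants = 8, max_iterations = 15)
  split_stub <- NULL
  runs <- lapply(1:3, function(i)
    aco_run(fixed_cost, 6, ctrl, seed = 100 + i))
  counts <- Reduce(`+`, lapply(runs, function(r) as.integer(r$best_mask)))
  expect_true(all(counts <= 3))
  expect_equal(counts[1:2], c(3, 3))  # the planted optimum is always found

  # select_by_frequency semantics on a constructed table
  freq <- data.frame(component = paste0("c", 1:5),
                     dye = "d", channel = "R",
                     count = c(30, 26, 5, 2, 26))
  expect_equal(select_by_frequency(freq, 25), c("c1", "c2", "c5"))
  expect_equal(select_by_frequency(freq, 27), "c1")
  expect_equal(length(select_by_frequency(freq, 0)), 5L)
  expect_equal(select_by_frequency(freq, 31), character(0))
})
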