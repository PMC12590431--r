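# The loop tests run with reduced budgets (small n_init / n_iter / pool);
# the full-budget behaviour is exercised in test-acceptance.R.

make_small_state <- function(seed = 1, n_iter = 6) {
  run_al(design_space(),
         al_config(n_init = 10, n_iter = n_iter, pool_size = 256,
                   n_val = 40, tune_budget = 8, seed = seed),
         oracle_params())
}

test_that("validation sets are labelled, constrained and reproducible", {
  sp <- design_space()
  v <- make_validation(sp, 100, seed = 2)
  expect_equal(nrow(v), 100)
  expect_true(all(v$pre_MPa <= v$main_MPa))
  expect_true(all(v$survival_frac > 0 & v$survival_frac <= 1))
  expect_identical(v, make_validation(sp, 100, seed = 2))
})

test_that("max-std acquisition equals the brute-force argmax", {
  sp <- design_space()
  set.seed(6)
  tr <- sobol_design(sp, 12, 1)
  tr$y <- evaluate_oracle(tr)$survival_frac
  m <- gp_fit(normalize_points(tr, sp), tr$y, gp_hyperparams(0.3, 0.3))
  pool <- random_design(sp, 200, seed = 4)
  acq <- acquire_max_std(m, pool, sp)
  sds <- vapply(seq_len(200), function(i)
    gp_predict(m, normalize_points(pool[i, , drop = FALSE], sp))$sd,
    numeric(1))
  expect_equal(acq$index, which.max(sds))
  expect_equal(acq$std, max(sds))
  # singleton pool returns its only point
  one <- acquire_max_std(m, pool[7, , drop = FALSE], sp)
  expect_equal(one$index, 1)
  expect_error(acquire_max_std(m, pool[0, ], sp), "empty")
})

test_that("a model trained on the centre ranks corners above the centre", {
  sp <- design_space()
  centre <- process_points(2500, 100, 225)
  m <- gp_fit(normalize_points(centre, sp), 0.5, gp_hyperparams(0.3, 1))
  corners <- process_points(c(0, 5000, 0, 5000), c(0, 0, 350, 350),
                            c(400, 400, 400, 400))
  pool <- rbind(corners, centre)
  acq <- acquire_max_std(m, pool, sp)
  expect_lt(acq$index, 5)                 # never the centre point
})

test_that("metrics match hand-computed values", {
  sp <- design_space()
  # build a validation frame directly and a fake-perfect model via the
  # oracle labels themselves
  v <- sobol_design(sp, 10, 3)
  v$survival_frac <- evaluate_oracle(v)$survival_frac
  X <- normalize_points(v, sp)
  m <- gp_fit(X, v$survival_frac, gp_hyperparams(0.3, 0.5, 1e-8))
  met <- compute_metrics(m, v, sp)        # interpolation: near-perfect
  expect_gt(met$r2, 0.999)
  expect_lt(met$rmse, 1e-3)
  # hand example: y = (1,2,3), yhat = (1,2,4) -> R2 = 0.5, RMSE = sqrt(1/3)
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  expect_equal(1 - sum((y - yhat)^2) / sum((y - mean(y))^2), 0.5)
  expect_equal(sqrt(mean((y - yhat)^2)), sqrt(1 / 3))
  v0 <- v; v0$survival_frac <- rep(0.5, 10)
  expect_error(compute_metrics(m, v0, sp), "variance")
})

test_that("the loop bookkeeping and reproducibility contracts hold", {
  st <- make_small_state(seed = 11, n_iter = 5)
  expect_equal(nrow(st$train), 15)
  expect_equal(nrow(st$history), 6)       # initial entry + 5 iterations
  expect_equal(st$history$iteration, 0:5)
  st2 <- make_small_state(seed = 11, n_iter = 5)
  expect_identical(st$train, st2$train)
  expect_identical(st$history, st2$history)
  # n_iter = 0: metrics of the initial model only
  st0 <- run_al(design_space(),
                al_config(n_init = 10, n_iter = 0, pool_size = 64,
                          n_val = 20, tune_budget = 5, seed = 2))
  expect_equal(nrow(st0$train), 10)
  expect_equal(nrow(st0$history), 1)
})

test_that("acquisitions favour the boundary more than random points do", {
  near_face <- function(pts, sp) {
    u <- normalize_points(pts, sp)
    apply(u, 1, function(r) any(r < 0.1 | r > 0.9))
  }
  sp <- design_space()
  frac_acq <- frac_rand <- numeric(5)
  for (s in 1:5) {
    st <- make_small_state(seed = s, n_iter = 6)
    acq <- st$train[-(1:10), ]
    frac_acq[s] <- mean(near_face(acq, sp))
    frac_rand[s] <- mean(near_face(random_design(sp, 64, seed = 100 + s),
                                   sp))
  }
  expect_gt(mean(frac_acq), mean(frac_rand))
})

test_that("labelling a point suppresses its posterior uncertainty", {
  sp <- design_space()
  tr <- sobol_design(sp, 15, 1)
  tr$y <- evaluate_oracle(tr)$survival_frac
  h <- gp_hyperparams(0.3, 0.4, 1e-6)
  m <- gp_fit(normalize_points(tr, sp), tr$y, h)
  pool <- random_design(sp, 512, seed = 9)
  acq <- acquire_max_std(m, pool, sp)
  x_star <- acq$point
  x_star$y <- evaluate_oracle(x_star)$survival_frac
  tr2 <- rbind(tr, x_star)
  m2 <- gp_fit(normalize_points(tr2, sp), tr2$y, h)
  sd_after <- gp_predict(m2, normalize_points(acq$point, sp))$sd
  expect_lt(sd_after, 0.1 * acq$std)
})

test_that("the error metric improves over the loop", {
  st <- make_small_state(seed = 21, n_iter = 12)
  h <- st$history
  expect_lt(h$rmse[nrow(h)], h$rmse[h$iteration == 1])
})
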