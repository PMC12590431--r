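# Active-learning loop: Sobol initial design -> oracle labels -> GP fit
# -> maximum-posterior-std acquisition -> oracle query -> retrain, with
# validation metrics tracked per iteration.

#' Active-learning configuration
#'
#' @param n_init initial Sobol design size (default 30).
#' @param n_iter number of acquisition iterations (default 78).
#' @param pool_size random candidate pool scored per iteration.
#' @param n_val Sobol validation-set size.
#' @param retune_every hyperparameter retuning period in iterations
#'   (1 = retune at every iteration).
#' @param tune_budget EI+ acquisitions per hyperparameter tuning run.
#' @param seed global seed; per-component seeds are derived from it by a
#'   fixed splitting rule (init design `seed`, validation `seed + 10000`,
#'   tuner `seed + 20000`, iteration-`i` pool `seed + 30000 + i`).
#' @return object of class `al_config`.
#' @export
al_config <- function(n_init = 30, n_iter = 78, pool_size = 4096,
                      n_val = 100, retune_every = 1, tune_budget = 30,
                      seed = 1L) {
  stopifnot(n_init >= 3, n_iter >= 0, pool_size >= 1, n_val >= 2,
            retune_every >= 1, tune_budget >= 1)
  structure(list(n_init = n_init, n_iter = n_iter, pool_size = pool_size,
                 n_val = n_val, retune_every = retune_every,
                 tune_budget = tune_budget, seed = as.integer(seed)),
            class = "al_config")
}

#' Oracle-labelled Sobol validation set
#'
#' Generates `n_val` Sobol points with a scrambling seed distinct from the
#' training design and labels them with the oracle.
#'
#' @param space a [design_space()].
#' @param n_val number of validation points.
#' @param seed scrambling seed (must differ from the training-design
#'   seed).
#' @param params oracle parameters used for labelling.
#' @return data.frame of process points with a `survival_frac` column.
#' @export
make_validation <- function(space, n_val = 100, seed = 2L,
                            params = oracle_params()) {
  pts <- sobol_design(space, n_val, seed)
  pts$survival_frac <- evaluate_oracle(pts, params)$survival_frac
  pts
}

#' Maximum-standard-deviation acquisition
#'
#' Returns the candidate-pool point at which the GP posterior standard
#' deviation is largest (ties broken by lowest index).
#'
#' @param model a fitted [gp_model][gp_fit()].
#' @param pool data.frame of candidate process points.
#' @param space the [design_space()] used for normalisation.
#' @return list with `point` (one-row data.frame), `std` and `index`.
#' @export
acquire_max_std <- function(model, pool, space) {
  if (nrow(pool) < 1) stop("candidate pool is empty")
  pr <- gp_predict(model, normalize_points(pool, space))
  i <- which(pr$sd == max(pr$sd))[1]
  list(point = pool[i, , drop = FALSE], std = pr$sd[i], index = i)
}

#' Validation metrics of a surrogate
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot` and root mean
#' square error of the posterior mean against oracle labels.
#'
#' @param model a fitted [gp_model][gp_fit()].
#' @param validation labelled validation set (from [make_validation()]).
#' @param space the [design_space()] used for normalisation.
#' @return list with `r2` and `rmse` (survival-fraction scale).
#' @export
compute_metrics <- function(model, validation, space) {
  stopifnot(nrow(validation) >= 2)
  y <- validation$survival_frac
  if (stats::var(y) == 0)
    stop("validation targets have zero variance; R^2 undefined")
  yhat <- gp_predict(model, normalize_points(validation, space))$mean
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean((y - yhat)^2)))
}

#' Run the active-learning loop
#'
#' Executes the full loop: label an initial Sobol design with the oracle,
#' tune and fit the GP surrogate, then repeatedly (i) draw a fresh
#' constraint-respecting random pool, (ii) query the oracle at the pool
#' point of maximum posterior standard deviation, (iii) append it to the
#' training set, retune the hyperparameters on schedule and refit, and
#' (iv) record validation metrics. Fully reproducible from the config
#' seed.
#'
#' @param space a [design_space()].
#' @param config an [al_config()].
#' @param params oracle parameters used for labelling.
#' @param verbose if `TRUE`, print one structured line per iteration.
#' @return object of class `al_state`: `train` (labelled points),
#'   `model`, `hyperparams`, `validation`, and `history` (one row per
#'   completed model: iteration, r2, rmse, acquired point, pool max-std).
#' @export
run_al <- function(space, config = al_config(), params = oracle_params(),
                   verbose = FALSE) {
  stopifnot(inherits(config, "al_config"))
  seed <- config$seed
  train <- sobol_design(space, config$n_init, seed)
  train$survival_frac <- evaluate_oracle(train, params)$survival_frac
  val <- make_validation(space, config$n_val, seed + 10000L, params)

  refit <- function(train, retune, h) {
    Xn <- normalize_points(train, space)
    if (retune)
      h <- tune_hyperparams(Xn, train$survival_frac,
                            budget = config$tune_budget,
                            seed = seed + 20000L, warm_start = h)
    list(model = gp_fit(Xn, train$survival_frac, h), h = h)
  }
  f <- refit(train, retune = TRUE, h = NULL)
  met <- compute_metrics(f$model, val, space)
  history <- data.frame(iteration = 0L, r2 = met$r2, rmse = met$rmse,
                        speed_mm_min = NA_real_, pre_MPa = NA_real_,
                        main_MPa = NA_real_, max_std = NA_real_)
  if (verbose)
    message(sprintf("iter %3d | n=%3d | R2=%.4f RMSE=%.4f", 0L,
                    nrow(train), met$r2, met$rmse))

  it <- 0L
  attempt <- 0L
  while (it < config$n_iter) {
    attempt <- attempt + 1L
    if (attempt > 2L * config$n_iter + 10L)
      stop("too many failed oracle queries; aborting the loop")
    pool <- random_design(space, config$pool_size, seed + 30000L + attempt)
    acq <- acquire_max_std(f$model, pool, space)
    lab <- tryCatch(evaluate_oracle(acq$point, params),
                    error = function(e) {
                      warning(sprintf(
                        "oracle failed at acquired point (attempt %d): %s",
                        attempt, conditionMessage(e)))
                      NULL
                    })
    if (is.null(lab)) next   # failed query: iteration not counted
    it <- it + 1L
    new_row <- acq$point
    new_row$survival_frac <- lab$survival_frac
    train <- rbind(train, new_row)
    f <- refit(train, retune = (it %% config$retune_every == 0L), h = f$h)
    met <- compute_metrics(f$model, val, space)
    history <- rbind(history, data.frame(
      iteration = it, r2 = met$r2, rmse = met$rmse,
      speed_mm_min = acq$point$speed_mm_min, pre_MPa = acq$point$pre_MPa,
      main_MPa = acq$point$main_MPa, max_std = acq$std))
    if (verbose)
      message(sprintf(
        "iter %3d | n=%3d | R2=%.4f RMSE=%.4f | acq=(%.0f, %.1f, %.1f) std=%.4f",
        it, nrow(train), met$r2, met$rmse, acq$point$speed_mm_min,
        acq$point$pre_MPa, acq$point$main_MPa, acq$std))
  }
  rownames(train) <- NULL
  structure(list(train = train, model = f$model, hyperparams = f$h,
                 validation = val, history = history, space = space,
                 config = config), class = "al_state")
}

#' @export
print.al_state <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "Active-learning state: %d training points, final R2 = %.4f, RMSE = %.4f\n",
    nrow(x$train), last$r2, last$rmse))
  invisible(x)
}
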