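# Epsilon-SVR (RBF kernel) over windowed features, with chain-level
# cross-validation, grid search, and persistence.

#' SVR hyperparameter settings
#'
#' @param C Regularization (cost), > 0.
#' @param gamma RBF kernel width, > 0. `NULL` means 1/ncol(features) at fit
#'   time (the libsvm default).
#' @param epsilon Tube width of the epsilon-insensitive loss, > 0.
#' @param w Encoder half-window recorded with the model.
#' @param mode Encoder mode, `"seq"` or `"prof"`.
#' @return List of class `svr_config`.
#' @export
svr_config <- function(C = 1, gamma = NULL, epsilon = 0.1, w = 40,
                       mode = c("seq", "prof")) {
  mode <- match.arg(mode)
  if (C <= 0 || epsilon <= 0 || (!is.null(gamma) && gamma <= 0)) {
    stop("C, gamma and epsilon must be positive", call. = FALSE)
  }
  structure(list(C = C, gamma = gamma, epsilon = epsilon, w = w, mode = mode),
            class = "svr_config")
}

#' Chain-level k-fold assignment
#'
#' Randomly partitions chain identifiers into k folds of sizes differing by
#' at most one. All positions of a chain share its fold, so no chain leaks
#' between training and test. Deterministic given the seed.
#'
#' @param chain_ids Character vector of distinct chain identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return Tibble `chain`, `fold` (fold in 1..k).
#' @export
chain_kfold_split <- function(chain_ids, k = 5, seed = 1) {
  stopifnot(!anyDuplicated(chain_ids))
  n <- length(chain_ids)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop("`k` (", k, ") exceeds the number of chains (", n, ")",
                  call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(chain_ids))
  tibble::tibble(
    chain = shuffled,
    fold = rep_len(seq_len(k), n)
  ) |> dplyr::arrange(.data$chain)
}

#' Fit the epsilon-SVR
#'
#' Radial-basis epsilon-SVR mapping windowed feature rows to normalized ASA
#' targets. Features are used as-is (they are already in \[-1, 1\] by
#' construction); no internal rescaling.
#'
#' @param features Numeric matrix, rows aligned with `targets`. Only rows
#'   whose residue passed the completeness filter should be included.
#' @param targets Numeric vector of normalized ASA values.
#' @param cfg An [svr_config()].
#' @param bounds Optional profile normalization bounds persisted with the
#'   model (prof mode).
#' @param chains Optional character vector of training chain ids, recorded
#'   as metadata.
#' @return An object of class `rnasa_svr`.
#' @export
svr_train <- function(features, targets, cfg = svr_config(), bounds = NULL,
                      chains = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(targets))
  if (nrow(features) < 10) {
    stop("refusing to train on fewer than 10 rows (got ", nrow(features), ")",
         call. = FALSE)
  }
  if (!all(is.finite(features)) || !all(is.finite(targets))) {
    stop("non-finite feature or target", call. = FALSE)
  }
  gamma <- cfg$gamma %||% (1 / ncol(features))
  fit <- e1071::svm(
    x = features, y = targets,
    type = "eps-regression", kernel = "radial",
    cost = cfg$C, gamma = gamma, epsilon = cfg$epsilon,
    scale = FALSE, fitted = FALSE
  )
  structure(
    list(
      fit = fit,
      config = cfg,
      gamma = gamma,
      n_features = ncol(features),
      bounds = bounds,
      chains = chains,
      version = as.character(utils::packageVersion("rnasa"))
    ),
    class = "rnasa_svr"
  )
}

#' Predict normalized and absolute ASA
#'
#' Raw regressor outputs are clipped to \[0, 1.25\] on the normalized scale
#' (the small overshoot allowance avoids censoring genuinely large areas)
#' and multiplied by the normalization constant to report Angstrom^2.
#'
#' @param object An `rnasa_svr` model.
#' @param features Feature matrix with the model's column dimension.
#' @param cfg An [asa_config()] supplying the normalization constant.
#' @param ... Unused.
#' @return Tibble `asa_norm`, `asa_A2`.
#' @export
predict.rnasa_svr <- function(object, features, cfg = asa_config(), ...) {
  stopifnot(is.matrix(features))
  if (ncol(features) != object$n_features) {
    stop("feature dimension ", ncol(features),
         " does not match the model's ", object$n_features, call. = FALSE)
  }
  raw <- if (object$fit$tot.nSV == 0) {
    # every training point inside the epsilon tube: the decision function
    # is the constant intercept
    rep(-object$fit$rho, nrow(features))
  } else {
    as.numeric(stats::predict(object$fit, features))
  }
  norm <- pmin(1.25, pmax(0, raw))
  tibble::tibble(asa_norm = norm, asa_A2 = norm * cfg$norm_constant)
}

#' Persist / restore a trained model
#'
#' The archive holds the fitted regressor, configuration, encoder mode,
#' profile bounds, and metadata, version-stamped. Reloading reproduces
#' predictions bit-identically.
#'
#' @param model An `rnasa_svr`.
#' @param path File path for the archive.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rnasa_svr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "rnasa_svr")) stop("not an rnasa model archive", call. = FALSE)
  m
}

#' Chain-level cross-validation
#'
#' Each fold's chains are predicted by a model trained on the remaining
#' folds, so every position is predicted exactly once by a model that never
#' saw its chain. The pooled Pearson r over all held-out predictions is the
#' headline metric; per-chain correlations are also returned.
#'
#' @param features Feature matrix.
#' @param targets Normalized ASA vector aligned with `features`.
#' @param chain Character vector of chain ids per row.
#' @param k Folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @param cfg An [svr_config()].
#' @return An object of class `rnasa_cv`: tibble `predictions` (`chain`,
#'   `row`, `fold`, `actual`, `predicted`), `folds`, pooled `r`, `per_chain`.
#' @export
cross_validate <- function(features, targets, chain, k = 5, seed = 1,
                           cfg = svr_config()) {
  stopifnot(nrow(features) == length(targets), length(chain) == length(targets))
  folds <- chain_kfold_split(unique(chain), k = k, seed = seed)
  fold_of <- folds$fold[match(chain, folds$chain)]

  preds <- purrr::map(seq_len(k), function(f) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    model <- svr_train(features[train, , drop = FALSE], targets[train], cfg)
    p <- predict(model, features[test, , drop = FALSE])
    tibble::tibble(
      chain = chain[test], row = test, fold = f,
      actual = targets[test], predicted = p$asa_norm
    )
  }) |> purrr::list_rbind() |> dplyr::arrange(.data$row)

  per_chain <- preds |>
    dplyr::group_by(chain = .data$chain) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (stats::sd(.data$actual) > 0 && stats::sd(.data$predicted) > 0) {
        stats::cor(.data$actual, .data$predicted)
      } else NA_real_,
      .groups = "drop"
    )

  structure(
    list(
      predictions = preds,
      folds = folds,
      r = pearson_r(preds$predicted, preds$actual),
      per_chain = per_chain,
      k = k, seed = seed, config = cfg
    ),
    class = "rnasa_cv"
  )
}

#' Grid search over (C, gamma) by pooled cross-validated correlation
#'
#' Evaluates every grid pair with [cross_validate()] and returns the pair
#' maximizing pooled held-out Pearson r, ties broken toward smaller C then
#' smaller gamma. The full grid table is returned for audit.
#'
#' @inheritParams cross_validate
#' @param C_grid,gamma_grid Numeric grids; defaults are log-2 spaced,
#'   C in 2^(-3..7), gamma in 2^(-9..1).
#' @param epsilon Tube width passed through.
#' @return List: `best` ([svr_config()]), `table` (tibble `C`, `gamma`, `r`).
#' @export
grid_search <- function(features, targets, chain, k = 5, seed = 1,
                        C_grid = 2^seq(-3, 7, by = 2),
                        gamma_grid = 2^seq(-9, 1, by = 2),
                        epsilon = 0.1) {
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1)
  grid <- tidyr::expand_grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$r <- purrr::map2_dbl(grid$C, grid$gamma, function(C, g) {
    cv <- cross_validate(features, targets, chain, k = k, seed = seed,
                         cfg = svr_config(C = C, gamma = g, epsilon = epsilon))
    cv$r
  })
  best <- grid |>
    dplyr::arrange(dplyr::desc(.data$r), .data$C, .data$gamma) |>
    dplyr::slice(1)
  list(
    best = svr_config(C = best$C, gamma = best$gamma, epsilon = epsilon),
    table = grid
  )
}

#' Window-size sweep under chain-level cross-validation
#'
#' Evaluates the pooled held-out correlation for each candidate half-window:
#' the curve typically rises while the window grows toward the span of the
#' true sequence dependency, then flattens or falls as added features only
#' increase overfitting risk.
#'
#' @param set Tibble with `chain`, `position`, `base`, `target` columns (as
#'   from [make_asa_regression_set()]).
#' @param w_grid Integer vector of half-windows to evaluate.
#' @inheritParams cross_validate
#' @return Tibble `w`, `n_features`, `r`.
#' @export
window_sweep <- function(set, w_grid, k = 5, seed = 1, cfg = svr_config()) {
  purrr::map(w_grid, function(w) {
    rf <- regression_features(set, w = w)
    cvw <- cross_validate(rf$features, rf$targets, rf$chain, k = k,
                          seed = seed,
                          cfg = svr_config(C = cfg$C, gamma = cfg$gamma,
                                           epsilon = cfg$epsilon, w = w,
                                           mode = cfg$mode))
    tibble::tibble(w = w, n_features = ncol(rf$features), r = cvw$r)
  }) |> purrr::list_rbind()
}

#' @export
print.rnasa_svr <- function(x, ...) {
  cat("<rnasa_svr> epsilon-SVR, RBF kernel\n")
  cat("  mode:", x$config$mode, " window:", x$config$w,
      " features:", x$n_features, "\n")
  cat("  C:", x$config$C, " gamma:", signif(x$gamma, 4),
      " epsilon:", x$config$epsilon, "\n")
  cat("  support vectors:", x$fit$tot.nSV, " version:", x$version, "\n")
  invisible(x)
}

#' @export
print.rnasa_cv <- function(x, ...) {
  cat("<rnasa_cv> ", x$k, "-fold chain-level cross-validation (seed ",
      x$seed, ")\n", sep = "")
  cat("  positions:", nrow(x$predictions),
      " chains:", nrow(x$folds), "\n")
  cat("  pooled Pearson r:", round(x$r, 3), "\n")
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x An `rnasa_cv` object.
#' @param ... Unused.
#' @return One row per chain: `chain`, `fold`, `n`, `r`.
#' @export
tidy.rnasa_cv <- function(x, ...) {
  dplyr::left_join(x$per_chain, x$folds, by = "chain") |>
    dplyr::select("chain", "fold", "n", "r")
}

#' @rdname tidy.rnasa_cv
#' @return `glance`: one row with `k`, `n_chains`, `n_positions`, pooled
#'   `r`, `mean_chain_r`.
#' @export
glance.rnasa_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_chains = nrow(x$folds),
    n_positions = nrow(x$predictions),
    r = x$r,
    mean_chain_r = mean(x$per_chain$r, na.rm = TRUE)
  )
}

#' @export
glance.rnasa_svr <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode, w = x$config$w, n_features = x$n_features,
    C = x$config$C, gamma = x$gamma, epsilon = x$config$epsilon,
    n_support_vectors = x$fit$tot.nSV
  )
}
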