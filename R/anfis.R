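# First-order Takagi-Sugeno ANFIS, written from scratch.
#
# Five-layer network over a grid-partitioned rule base:
#   L1 fuzzification: triangular memberships mu_j,k(x_j) per input j, MF k
#   L2 firing strengths: w_r = prod_j mu_{j, rule_r[j]}(x_j)
#   L3 normalization: wbar_r = w_r / sum(w)
#   L4 weighted consequents: wbar_r * f_r, f_r linear (order 1) or constant
#   L5 sum: output = sum_r wbar_r f_r
# Hybrid learning: consequents by (ridge-regularized) global least squares
# on the layer-4 design matrix; premise MF parameters by gradient descent.

#' ANFIS configuration
#'
#' @param n_inputs Number of input variables (4 for the safety-risk model).
#' @param mfs_per_input Membership functions per input; 3 by default
#'   (81 rules for four inputs), 5 mirrors the five-level linguistic
#'   ladder exactly.
#' @param consequent_order 1 (linear rule outputs, the default) or 0
#'   (constant).
#' @param epochs Maximum training passes.
#' @param premise_step Gradient step size for premise parameters; 0 freezes
#'   the premises (pure least-squares training).
#' @param ridge Ridge weight for the consequent solve; guards
#'   underdetermined rule bases.
#' @param tol Early-stop tolerance on the training-RMSE improvement.
#' @param seed Optional seed; controls premise jitter (if `init_jitter > 0`)
#'   only — the default initialization is deterministic.
#' @param init_jitter Standard deviation of optional jitter on the initial
#'   MF modes; 0 (default) keeps the even spacing.
#' @return An `anfis_config` list.
#' @export
anfis_config <- function(n_inputs = 4, mfs_per_input = 3,
                         consequent_order = 1, epochs = 30,
                         premise_step = 0.01, ridge = 1e-6,
                         tol = 1e-6, seed = NULL, init_jitter = 0) {
  stopifnot(n_inputs >= 1, mfs_per_input >= 2,
            consequent_order %in% c(0, 1),
            epochs >= 1, premise_step >= 0, ridge >= 0, tol >= 0,
            init_jitter >= 0)
  structure(list(
    n_inputs = as.integer(n_inputs),
    mfs_per_input = as.integer(mfs_per_input),
    consequent_order = as.integer(consequent_order),
    epochs = as.integer(epochs),
    premise_step = premise_step,
    ridge = ridge,
    tol = tol,
    seed = seed,
    init_jitter = init_jitter
  ), class = "anfis_config")
}

# evenly spaced triangular MFs spanning [0,1]; first/last are shoulders.
# For m = 5 these coincide with the linguistic-ladder TFNs.
.init_premise <- function(m, jitter = 0) {
  modes <- seq(0, 1, length.out = m)
  if (jitter > 0) {
    modes <- modes + stats::rnorm(m, 0, jitter)
    modes <- sort(pmin(pmax(modes, 0), 1))
  }
  step <- 1 / (m - 1)
  lapply(seq_len(m), function(k) {
    tri_mf(max(modes[k] - step, if (k == 1) modes[k] else -0.25),
           modes[k],
           min(modes[k] + step, if (k == m) modes[k] else 1.25))
  })
}

#' Build an untrained ANFIS model
#'
#' Premise MFs are initialized as evenly spaced triangles spanning `[0, 1]`
#' with mode spacing `1/(mfs_per_input - 1)`; the first and last are
#' shoulders, so the grid covers the whole input cube and every point fires
#' at least one rule. The rule base is the full grid partition (one MF per
#' input in every combination); consequent coefficients start at zero.
#'
#' @param config An [anfis_config()].
#' @return An `anfis` object (untrained).
#' @export
build_anfis <- function(config = anfis_config()) {
  stopifnot(inherits(config, "anfis_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  premise <- lapply(seq_len(config$n_inputs), function(j) {
    .init_premise(config$mfs_per_input, config$init_jitter)
  })
  rules <- as.matrix(expand.grid(rep(list(seq_len(config$mfs_per_input)),
                                     config$n_inputs)))
  dimnames(rules) <- list(NULL, paste0("x", seq_len(config$n_inputs)))
  n_coef <- if (config$consequent_order == 1) config$n_inputs + 1L else 1L
  structure(list(
    config = config,
    premise = premise,
    rules = rules,
    consequents = matrix(0, nrow(rules), n_coef),
    trained = FALSE
  ), class = "anfis")
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf(
    "Takagi-Sugeno ANFIS: %d inputs, %d MFs/input, %d rules, order-%d consequents (%s)\n",
    x$config$n_inputs, x$config$mfs_per_input, nrow(x$rules),
    x$config$consequent_order, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.as_input_matrix <- function(x, n_inputs) {
  if (is.null(dim(x))) x <- matrix(x, ncol = n_inputs)
  x <- as.matrix(x)
  if (ncol(x) != n_inputs) {
    stop("expected ", n_inputs, " input columns, got ", ncol(x))
  }
  storage.mode(x) <- "double"
  x
}

# layer 1-3: normalized firing strengths, n x n_rules
.normalized_weights <- function(model, X) {
  n <- nrow(X)
  mu <- lapply(seq_len(model$config$n_inputs), function(j) {
    vapply(seq_along(model$premise[[j]]),
           function(k) triangular_membership(X[, j], model$premise[[j]][[k]]),
           numeric(n))
  })
  W <- matrix(1, n, nrow(model$rules))
  for (j in seq_len(model$config$n_inputs)) {
    muj <- matrix(mu[[j]], nrow = n)
    W <- W * muj[, model$rules[, j], drop = FALSE]
  }
  s <- rowSums(W)
  if (any(s <= 0)) {
    stop("degenerate rule coverage: no rule fires for ",
         sum(s <= 0), " input point(s)")
  }
  W / s
}

# rule outputs f_r(x), n x n_rules
.rule_outputs <- function(model, X) {
  if (model$config$consequent_order == 1) {
    d <- model$config$n_inputs
    X %*% t(model$consequents[, seq_len(d), drop = FALSE]) +
      matrix(model$consequents[, d + 1], nrow(X), nrow(model$consequents),
             byrow = TRUE)
  } else {
    matrix(model$consequents[, 1], nrow(X), nrow(model$consequents),
           byrow = TRUE)
  }
}

#' Forward pass through the five layers
#'
#' Evaluates the network: memberships, product firing strengths, normalized
#' weights, weighted rule consequents, and their sum.
#'
#' @param model An `anfis` object.
#' @param x An input vector (length `n_inputs`) or matrix with one row per
#'   record; components must lie in `[0, 1]`.
#' @return Numeric vector of outputs, one per record.
#' @export
anfis_forward <- function(model, x) {
  stopifnot(inherits(model, "anfis"))
  X <- .as_input_matrix(x, model$config$n_inputs)
  if (any(X < 0 | X > 1)) stop("inputs must lie in [0, 1]")
  Wn <- .normalized_weights(model, X)
  rowSums(Wn * .rule_outputs(model, X))
}

# layer-4 design matrix: columns grouped by rule, [wbar*x1..wbar*xd, wbar]
.design_matrix <- function(model, Wn, X) {
  if (model$config$consequent_order == 0) return(Wn)
  d <- model$config$n_inputs
  R <- ncol(Wn)
  A <- matrix(0, nrow(X), R * (d + 1))
  for (r in seq_len(R)) {
    cols <- (r - 1) * (d + 1) + seq_len(d + 1)
    A[, cols] <- cbind(Wn[, r] * X, Wn[, r])
  }
  A
}

.solve_consequents <- function(A, y, ridge) {
  p <- ncol(A)
  M <- crossprod(A) + ridge * diag(p)
  beta <- tryCatch(solve(M, crossprod(A, y)), error = function(e) NULL)
  if (is.null(beta)) {
    warning("singular consequent system; adding minimal ridge")
    ridge2 <- max(1e-8, 1e-10 * mean(diag(crossprod(A))))
    beta <- solve(crossprod(A) + ridge2 * diag(p), crossprod(A, y))
  }
  drop(beta)
}

.set_consequents <- function(model, beta) {
  n_coef <- ncol(model$consequents)
  model$consequents <- matrix(beta, nrow(model$rules), n_coef, byrow = TRUE)
  model
}

# flatten premise MFs to a parameter vector and back (for the gradient step)
.premise_to_vec <- function(premise) {
  unlist(lapply(premise, function(mfs) {
    unlist(lapply(mfs, function(mf) c(mf$a, mf$b, mf$c)))
  }))
}

.vec_to_premise <- function(theta, n_inputs, m) {
  i <- 0
  lapply(seq_len(n_inputs), function(j) {
    lapply(seq_len(m), function(k) {
      v <- theta[(j - 1) * m * 3 + (k - 1) * 3 + 1:3]
      # clamp: keep a <= b <= c and the support inside [-0.25, 1.25]
      b <- min(max(v[2], -0.25), 1.25)
      a <- min(max(min(v[1], b), -0.25), b)
      cc <- max(min(max(v[3], b), 1.25), b)
      tri_mf(a, b, cc)
    })
  })
}

.training_mse <- function(model, X, y, theta = NULL) {
  if (!is.null(theta)) {
    model$premise <- .vec_to_premise(theta, model$config$n_inputs,
                                     model$config$mfs_per_input)
  }
  pred <- tryCatch(anfis_forward(model, X), error = function(e) NULL)
  if (is.null(pred)) return(Inf)  # coverage hole under perturbed premises
  mean((pred - y)^2)
}

#' Train an ANFIS by hybrid learning
#'
#' Each epoch (i) runs the forward pass to obtain normalized firing
#' strengths for every training record, (ii) solves the consequent
#' coefficients globally by ridge-regularized linear least squares on the
#' layer-4 design matrix, and (iii) takes one gradient-descent step on the
#' premise MF parameters (squared-error loss, consequents held fixed;
#' central finite differences), clamping each MF to `a <= b <= c` with
#' support inside `[-0.25, 1.25]`. Training stops at `epochs` or when the
#' training-RMSE improvement falls below `tol`.
#'
#' @param model An `anfis` from [build_anfis()].
#' @param x Training inputs (matrix, rows = records, columns in `[0, 1]`).
#' @param y Training targets in `[0, 1]`.
#' @return The trained `anfis`, with a `train_report` attribute: list of
#'   per-epoch training `rmse`, `stop_epoch`, and final parameters.
#' @export
anfis_fit <- function(model, x, y) {
  stopifnot(inherits(model, "anfis"), is.numeric(y))
  cfg <- model$config
  X <- .as_input_matrix(x, cfg$n_inputs)
  if (nrow(X) < 1) stop("need at least one training pair")
  if (length(y) != nrow(X)) stop("x and y sizes differ")
  if (any(y < 0 | y > 1)) stop("targets must lie in [0, 1]")

  rmse_hist <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    Wn <- .normalized_weights(model, X)
    A <- .design_matrix(model, Wn, X)
    beta <- .solve_consequents(A, y, cfg$ridge)
    model <- .set_consequents(model, beta)
    resid <- drop(A %*% beta) - y
    rmse_hist[epoch] <- sqrt(mean(resid^2))

    if (epoch > 1 &&
        abs(rmse_hist[epoch - 1] - rmse_hist[epoch]) < cfg$tol) break

    if (cfg$premise_step > 0 && epoch < cfg$epochs) {
      theta <- .premise_to_vec(model$premise)
      h <- 1e-5
      grad <- vapply(seq_along(theta), function(i) {
        tp <- theta; tp[i] <- tp[i] + h
        tm <- theta; tm[i] <- tm[i] - h
        (.training_mse(model, X, y, tp) - .training_mse(model, X, y, tm)) /
          (2 * h)
      }, numeric(1))
      grad[!is.finite(grad)] <- 0
      if (any(is.nan(grad))) stop("NaN gradient in premise update")
      theta <- theta - cfg$premise_step * grad
      new_premise <- .vec_to_premise(theta, cfg$n_inputs, cfg$mfs_per_input)
      # reject updates that open a coverage hole
      old_premise <- model$premise
      model$premise <- new_premise
      if (!is.finite(.training_mse(model, X, y))) model$premise <- old_premise
    }
  }

  model$trained <- TRUE
  attr(model, "train_report") <- list(
    rmse = rmse_hist,
    stop_epoch = length(rmse_hist),
    premise = model$premise,
    consequents = model$consequents
  )
  model
}

#' Predict normalized risk magnitudes
#'
#' Applies the forward pass to each record and clips the output to
#' `[0, 1]` for downstream band classification; the number of clipped
#' predictions is attached as attribute `n_clipped`.
#'
#' @param model A trained `anfis`.
#' @param x Input matrix or vector, values in `[0, 1]`.
#' @return Numeric vector of predictions in `[0, 1]` (empty input gives an
#'   empty vector).
#' @export
anfis_predict <- function(model, x) {
  stopifnot(inherits(model, "anfis"))
  if (!model$trained) stop("model is untrained; call anfis_fit() first")
  X <- .as_input_matrix(x, model$config$n_inputs)
  if (nrow(X) == 0) {
    out <- numeric(0)
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  raw <- anfis_forward(model, X)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "n_clipped") <- sum(raw < 0 | raw > 1)
  out
}

#' Site-level train/test split
#'
#' Splits assessment records by site, so that whole sites land on one side
#' — the generalization test mimics predicting risks on construction sites
#' the model never saw. By default 7 of 10 sites train (a 7:3 ratio);
#' explicit site lists override the fraction.
#'
#' @param records Data frame with a `site_id` column.
#' @param train_sites,test_sites Optional explicit site identifier vectors.
#' @param train_fraction Fraction of sites assigned to training when no
#'   explicit lists are given (default 0.7).
#' @param seed Optional seed for the site sampling (reproducible splits).
#' @return A list with data frames `train` and `test` (a partition of
#'   `records`).
#' @export
split_by_site <- function(records, train_sites = NULL, test_sites = NULL,
                          train_fraction = 0.7, seed = NULL) {
  stopifnot(is.data.frame(records), "site_id" %in% names(records))
  sites <- unique(records$site_id)
  if (length(sites) < 2) stop("need at least 2 sites to split")
  if (is.null(train_sites) && !is.null(test_sites)) {
    train_sites <- setdiff(sites, test_sites)
  }
  if (is.null(train_sites)) {
    n_train <- round(train_fraction * length(sites))
    if (n_train < 1 || n_train >= length(sites)) {
      stop("train_fraction leaves no sites on one side")
    }
    if (!is.null(seed)) set.seed(seed)
    train_sites <- sample(sites, n_train)
  }
  if (!all(train_sites %in% sites)) stop("unknown training site(s)")
  if (length(setdiff(sites, train_sites)) < 1) {
    stop("no sites left for testing")
  }
  list(
    train = records[records$site_id %in% train_sites, , drop = FALSE],
    test = records[!records$site_id %in% train_sites, , drop = FALSE]
  )
}

#' Serialize an ANFIS model to JSON
#'
#' @param model An `anfis` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anfis <- function(model, path) {
  stopifnot(inherits(model, "anfis"))
  doc <- list(
    format = "anfisrisk-model",
    version = 1L,
    config = model$config[setdiff(names(model$config), "seed")],
    premise = lapply(model$premise, function(mfs) {
      lapply(mfs, function(mf) c(mf$a, mf$b, mf$c))
    }),
    rules = unclass(model$rules),
    consequents = model$consequents,
    trained = model$trained
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ANFIS model from JSON
#'
#' @param path File written by [write_anfis()].
#' @return An `anfis` object.
#' @export
read_anfis <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "anfisrisk-model")) {
    stop("not an anfisrisk model file: ", path)
  }
  cfg <- do.call(anfis_config, lapply(doc$config[c(
    "n_inputs", "mfs_per_input", "consequent_order", "epochs",
    "premise_step", "ridge", "tol", "init_jitter")], as.numeric))
  model <- build_anfis(cfg)
  model$premise <- lapply(doc$premise, function(mfs) {
    lapply(mfs, function(v) {
      v <- as.numeric(unlist(v))
      tri_mf(v[1], v[2], v[3])
    })
  })
  rules <- do.call(rbind, lapply(doc$rules, function(r) as.integer(unlist(r))))
  dimnames(rules) <- list(NULL, paste0("x", seq_len(cfg$n_inputs)))
  model$rules <- rules
  model$consequents <- do.call(rbind, lapply(doc$consequents,
                                             function(r) as.numeric(unlist(r))))
  model$trained <- isTRUE(doc$trained)
  model
}
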