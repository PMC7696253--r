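# Takagi-Sugeno ANFIS: structure, forward pass, hybrid training.

test_that("grid partition yields mfs_per_input^n_inputs rules", {
  expect_equal(nrow(build_anfis(anfis_config(4, 3))$rules), 81)
  expect_equal(nrow(build_anfis(anfis_config(2, 2))$rules), 4)
  expect_equal(nrow(build_anfis(anfis_config(4, 5))$rules), 625)
})

test_that("five MFs per input coincide with the linguistic-ladder TFNs", {
  m <- build_anfis(anfis_config(4, 5))
  sc <- rating_scales()
  tfn <- unique(sc[c("tfn_a", "tfn_b", "tfn_c")])
  for (j in 1:4) {
    got <- t(sapply(m$premise[[j]], function(mf) c(mf$a, mf$b, mf$c)))
    expect_equal(unname(got), unname(as.matrix(tfn)))
  }
})

test_that("default initialization covers [0,1] with shoulders", {
  m <- build_anfis(anfis_config(4, 3))
  for (j in 1:4) {
    mfs <- m$premise[[j]]
    expect_equal(c(mfs[[1]]$a, mfs[[1]]$b), c(0, 0))
    expect_equal(c(mfs[[3]]$b, mfs[[3]]$c), c(1, 1))
  }
  # every grid point fires at least one rule
  x <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25),
                             seq(0, 1, 0.25), seq(0, 1, 0.25)))
  expect_silent(anfis_forward(m, x))
})

test_that("normalized rule weights sum to one for every input point", {
  m <- build_anfis(anfis_config(4, 3))
  set.seed(11)
  X <- matrix(runif(200 * 4), 200, 4)
  Wn <- anfisrisk:::.normalized_weights(m, X)
  expect_true(all(abs(rowSums(Wn) - 1) < 1e-12))
})

test_that("hand-computed two-rule forward example is reproduced", {
  # MFs (0,0,1) and (0,1,1); order-0 consequents (0, 1); x = 0.25:
  # memberships (0.75, 0.25) are already normalized -> 0.75*0 + 0.25*1
  m <- hand_model(c(0, 1))
  expect_equal(anfis_forward(m, 0.25), 0.25)
  expect_equal(anfis_forward(m, c(0, 0.5, 1)), c(0, 0.5, 1))
})

test_that("a single-rule order-0 model returns its consequent everywhere", {
  m <- build_anfis(anfis_config(n_inputs = 1, mfs_per_input = 2,
                                consequent_order = 0))
  m$rules <- m$rules[1, , drop = FALSE]
  m$premise[[1]] <- list(tri_mf(-0.25, 0.5, 1.25))  # covers all of [0, 1]
  m$consequents <- matrix(0.37, 1, 1)
  expect_equal(anfis_forward(m, seq(0, 1, 0.1)), rep(0.37, 11))
})

test_that("at a grid vertex only the vertex rule fires", {
  m <- build_anfis(anfis_config(n_inputs = 2, mfs_per_input = 3,
                                consequent_order = 0))
  m$consequents <- matrix(seq_len(9) / 10, 9, 1)
  # modes at 0, 0.5, 1; vertex (0.5, 1) is rule with indices (2, 3)
  r <- which(m$rules[, 1] == 2 & m$rules[, 2] == 3)
  expect_equal(anfis_forward(m, c(0.5, 1)), m$consequents[r, 1])
})

test_that("order-0 output is a convex combination of consequents", {
  m <- build_anfis(anfis_config(n_inputs = 2, mfs_per_input = 3,
                                consequent_order = 0))
  set.seed(5)
  m$consequents <- matrix(runif(9), 9, 1)
  X <- matrix(runif(100), 50, 2)
  out <- anfis_forward(m, X)
  expect_true(all(out >= min(m$consequents) - 1e-12))
  expect_true(all(out <= max(m$consequents) + 1e-12))
})

test_that("training recovers an exactly representable target", {
  m <- build_anfis(anfis_config(n_inputs = 1, mfs_per_input = 2,
                                consequent_order = 0, epochs = 5,
                                premise_step = 0, ridge = 0))
  fit <- anfis_fit(m, matrix(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(as.numeric(fit$consequents), c(0, 1), tolerance = 1e-8)
  expect_lt(tail(attr(fit, "train_report")$rmse, 1), 1e-10)
  expect_lt(max(abs(anfis_predict(fit, matrix(c(0, 0.5, 1))) -
                    c(0, 0.5, 1))), 1e-6)
})

test_that("a constant target is fit exactly after one epoch", {
  m <- build_anfis(anfis_config(n_inputs = 2, mfs_per_input = 2,
                                consequent_order = 0, epochs = 3,
                                premise_step = 0, ridge = 0))
  set.seed(2)
  X <- matrix(runif(40), 20, 2)
  fit <- anfis_fit(m, X, rep(0.6, 20))
  expect_equal(as.numeric(fit$consequents), rep(0.6, 4), tolerance = 1e-8)
  expect_lt(attr(fit, "train_report")$rmse[1], 1e-10)
})

test_that("consequent solve equals the explicit normal-equations oracle", {
  # <= 8 rules, <= 30 samples, premises frozen; instances are kept
  # overdetermined so the solution is unique
  # the order-1 blended design is structurally collinear (the weighted
  # inputs sum to the plain input column), so the comparison is made at the
  # default ridge, where the regularized solution is unique and stable
  cases <- list(list(n_inputs = 3, order = 0, ridge = 1e-9),
                list(n_inputs = 2, order = 1, ridge = 1e-6))
  for (case in cases) {
    cfg <- anfis_config(n_inputs = case$n_inputs, mfs_per_input = 2,
                        consequent_order = case$order, epochs = 1,
                        premise_step = 0, ridge = case$ridge)
    m <- build_anfis(cfg)
    set.seed(case$order + 7)
    X <- matrix(runif(30 * case$n_inputs), 30, case$n_inputs)
    y <- runif(30)
    fit <- anfis_fit(m, X, y)
    oracle <- normal_equations_fit(m, X, y, ridge = case$ridge)
    got <- as.numeric(t(fit$consequents))
    expect_equal(got, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("training RMSE does not increase across epochs with frozen premises", {
  dat <- magnitude_surface_sample(150, seed = 9)
  m <- build_anfis(anfis_config(epochs = 6, premise_step = 0, tol = 0))
  fit <- anfis_fit(m, dat$X, dat$y)
  hist <- attr(fit, "train_report")$rmse
  expect_true(all(diff(hist) <= 1e-12))
})

test_that("the magnitude surface is learned to high held-out accuracy", {
  train <- magnitude_surface_sample(500, seed = 21)
  test <- magnitude_surface_sample(400, seed = 22)
  m <- anfis_fit(build_anfis(anfis_config(epochs = 15, premise_step = 0)),
                 train$X, train$y)
  pred <- anfis_predict(m, test$X)
  expect_lte(rmse(test$y, pred), 0.02)
})

test_that("hybrid premise updates keep MFs valid and do not break the fit", {
  dat <- magnitude_surface_sample(80, seed = 4)
  m <- anfis_fit(build_anfis(anfis_config(epochs = 4, premise_step = 0.01,
                                          tol = 0)),
                 dat$X, dat$y)
  for (j in 1:4) {
    for (mf in m$premise[[j]]) {
      expect_true(mf$a <= mf$b && mf$b <= mf$c)
      expect_gte(mf$a, -0.25)
      expect_lte(mf$c, 1.25)
    }
  }
  expect_lt(tail(attr(m, "train_report")$rmse, 1), 0.05)
})

test_that("prediction requires a trained model, clips, and is deterministic", {
  m <- build_anfis(anfis_config())
  expect_error(anfis_predict(m, matrix(0.5, 1, 4)), "untrained")
  dat <- magnitude_surface_sample(60, seed = 13)
  fit <- anfis_fit(m, dat$X, dat$y)
  p1 <- anfis_predict(fit, dat$X)
  p2 <- anfis_predict(fit, dat$X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  empty <- anfis_predict(fit, matrix(numeric(0), 0, 4))
  expect_length(empty, 0)
})

test_that("site-level split partitions records at the documented ratio", {
  cfg <- synthetic_config(n_risks = 29, n_sites = 10, seed = 3)
  dat <- generate_ratings(cfg)
  sp <- split_by_site(dat, train_fraction = 0.7, seed = 1)
  expect_equal(nrow(sp$train), 203)
  expect_equal(nrow(sp$test), 87)
  expect_equal(length(unique(sp$train$site_id)), 7)
  expect_equal(length(unique(sp$test$site_id)), 3)
  # partition
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(dat))
  expect_length(intersect(sp$train$site_id, sp$test$site_id), 0)
  # explicit test sites and reproducibility
  sp2 <- split_by_site(dat, test_sites = c("S01", "S02", "S03"))
  expect_equal(nrow(sp2$test), 87)
  sp3 <- split_by_site(dat, train_fraction = 0.7, seed = 1)
  expect_identical(sp$train$site_id, sp3$train$site_id)
  expect_error(split_by_site(dat[dat$site_id == "S01", ]), "at least 2 sites")
})

test_that("model JSON serialization round-trips", {
  dat <- magnitude_surface_sample(50, seed = 31)
  m <- anfis_fit(build_anfis(anfis_config(epochs = 3, premise_step = 0.01)),
                 dat$X, dat$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis(m, path)
  back <- read_anfis(path)
  expect_equal(back$consequents, m$consequents, tolerance = 1e-12)
  expect_equal(anfis_predict(back, dat$X), anfis_predict(m, dat$X),
               tolerance = 1e-12)
  expect_true(back$trained)
})
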