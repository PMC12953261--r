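# shared fixtures, built once per test run

profiles_fixture <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) prof <<- load_profiles()
    prof
  }
})

# the reference synthetic cohort (study-sized)
reference_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- sample_cohort(generator_spec(seed = 1))
    co
  }
})

# small cohort for cheap model tests
small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      co <<- sample_cohort(generator_spec(n_total = 220, n_depressed = 44, seed = 3))
    }
    co
  }
})

# cheap training controls for pipeline tests
fast_control <- function() {
  dep_control(xgb_nrounds = 60, boruta_max_iter = 25, boruta_trees = 120,
              greedy_nrounds = 40, greedy_folds = 3)
}

# two-group Gaussian design: `n_informative` mean-shifted features plus noise
make_two_group <- function(n = 400, n_informative = 5, n_noise = 20,
                           shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * (n_informative + n_noise)), n)
    colnames(X) <- c(sprintf("inf_%d", seq_len(n_informative)),
                     sprintf("noise_%d", seq_len(n_noise)))
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + shift * y
    list(X = X, y = y)
  })
}

# complementary-pair design: (x1, x2) carry a dominant interaction plus
# weak main effects, so the pair is far better than any single feature but
# each single feature still outranks pure noise. (A zero-main-effect XOR is
# unrecoverable for any forward-greedy search by construction: the first
# step would see no marginal signal at all.)
make_xor <- function(n = 500, n_noise = 6, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    x2 <- stats::rnorm(n)
    lp <- 4 * x1 * x2 + 1.5 * x1 + 1.5 * x2
    y <- stats::rbinom(n, 1, stats::plogis(lp))
    noise <- matrix(stats::rnorm(n * n_noise), n)
    X <- cbind(x1 = x1, x2 = x2, noise)
    colnames(X) <- c("x1", "x2", sprintf("noise_%d", seq_len(n_noise)))
    list(X = X, y = as.integer(y))
  })
}

# the discriminative biomarker panel used in subtype-recovery experiments
recovery_panel <- function() {
  c("bmi", "visceral_fat", "muscle_mass", "waist_circumference",
    "hip_circumference", "systolic_bp", "diastolic_bp", "hrv_sdnn",
    "hrv_rmssd", "hrv_baevskii", "igf1", "tsh", "triglycerides",
    "hdl_cholesterol", "leukocytes", "hemoglobin")
}

# brute-force nearest-neighbour oracle: plain double loop over rows
knn_oracle <- function(train, apply_to, k) {
  cols <- names(train)
  is_num <- vapply(train, is.numeric, logical(1))
  ctr <- vapply(train[cols[is_num]], function(x) mean(x, na.rm = TRUE), numeric(1))
  scl <- vapply(train[cols[is_num]], function(x) {
    s <- sd(x, na.rm = TRUE); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  p <- length(cols)
  out <- apply_to
  for (i in seq_len(nrow(apply_to))) {
    d <- numeric(nrow(train))
    for (t in seq_len(nrow(train))) {
      acc <- 0; m <- 0
      for (cn in cols) {
        xi <- apply_to[[cn]][i]; xt <- train[[cn]][t]
        if (is.na(xi) || is.na(xt)) next
        m <- m + 1
        acc <- acc + if (is.numeric(train[[cn]])) {
          ((xi - ctr[cn]) / scl[cn] - (xt - ctr[cn]) / scl[cn])^2
        } else as.numeric(as.character(xi) != as.character(xt))
      }
      d[t] <- if (m == 0) Inf else sqrt(p / m * acc)
    }
    for (cn in cols) {
      if (!is.na(out[[cn]][i])) next
      donors <- which(!is.na(train[[cn]]) & is.finite(d))
      nb <- donors[order(d[donors], donors)][seq_len(min(k, length(donors)))]
      if (is.numeric(train[[cn]])) {
        v <- mean(train[[cn]][nb])
        if (is.integer(out[[cn]])) v <- as.integer(round(v))
        out[[cn]][i] <- v
      } else {
        tab <- table(as.character(train[[cn]][nb]))
        out[[cn]][i] <- sort(names(tab)[tab == max(tab)])[1]
      }
    }
  }
  out
}

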