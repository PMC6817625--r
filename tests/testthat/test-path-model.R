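test_that("default spec has the published structural counts", {
  for (basis in c("F0", "VTL")) for (ratio in c("WSR", "WHR")) {
    spec <- build_path_spec(basis, ratio)
    expect_identical(nrow(spec$regressions), 38L)
    expect_identical(nrow(spec$covariances), 6L)
    expect_identical(sum(spec$roles == "exogenous"), 4L)
    expect_identical(sum(spec$roles == "mediator"), 4L)
    # construction guarantees a DAG
    expect_silent(voxpath:::assert_acyclic(spec))
  }
  spec <- build_path_spec("VTL", "WHR")
  expect_true(all(c("speech_vtl_cm", "whr") %in% spec$variables))
  expect_error(
    path_spec(c("a", "b"), c(a = "mediator", b = "mediator"),
              data.frame(response = c("a", "b"), predictor = c("b", "a"))),
    "cycle")
})

test_that("path coefficients equal the independent OLS oracle", {
  spec <- build_path_spec("F0", "WSR")
  set.seed(101)
  d <- simulate_path_data(spec, runif(38, -0.3, 0.3),
                          n = 400, covariances = rep(0.15, 6))
  fit <- fit_path_model(d, spec)
  Z <- as.data.frame(scale(d))
  for (resp in unique(spec$regressions$response)) {
    preds <- spec$regressions$predictor[spec$regressions$response == resp]
    oracle <- coef(lm(reformulate(preds, resp), data = Z))[preds]
    got <- fit$estimates$estimate[fit$estimates$type == "regression" &
                                    fit$estimates$lhs == resp]
    expect_equal(got, unname(oracle), tolerance = 1e-8)
  }
  # exogenous covariances are the sample correlations
  for (i in seq_len(6)) {
    v1 <- spec$covariances$var1[i]; v2 <- spec$covariances$var2[i]
    expect_equal(fit$estimates$estimate[fit$estimates$parameter ==
                                          paste0(v1, "~~", v2)],
                 cor(d[[v1]], d[[v2]]), tolerance = 1e-12)
  }
  expect_identical(fit$df, 11)
})

test_that("chain model recovers known standardized coefficients", {
  spec <- chain_spec()
  d <- simulate_path_data(spec, c(0.5, 0.5), n = 5000, seed = 7)
  fit <- fit_path_model(d, spec)
  expect_equal(fit$estimates$estimate, c(0.5, 0.5), tolerance = 0.05)
  # all variables were generated with unit variance
  expect_true(all(abs(apply(d, 2, sd) - 1) < 0.05))
  # determinism
  d2 <- simulate_path_data(spec, c(0.5, 0.5), n = 5000, seed = 7)
  expect_identical(d, d2)
})

test_that("null data yields small estimates and a just-identified chi-square of 0", {
  spec <- build_path_spec("F0", "WSR")
  set.seed(55)
  null_d <- as.data.frame(matrix(rnorm(1000 * 11), 1000,
                                 dimnames = list(NULL, spec$variables)))
  fit <- fit_path_model(null_d, spec)
  expect_lt(max(abs(fit$estimates$estimate)), 0.15)
  # saturated sub-model: every variable regressed on all predecessors
  vars <- c("a", "b", "c")
  sat <- path_spec(vars, c(a = "exogenous", b = "mediator", c = "outcome"),
                   data.frame(response = c("b", "c", "c"),
                              predictor = c("a", "a", "b")))
  ds <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  sfit <- fit_path_model(ds, sat)
  expect_identical(sfit$df, 0)
  expect_equal(sfit$chi_square, 0, tolerance = 1e-8)
  # implied covariance of a saturated fit reproduces the sample matrix
  expect_equal(sfit$implied_cov, sfit$sample_cov, tolerance = 1e-10)
})

test_that("fit rejects rank-deficient or undersized inputs", {
  spec <- chain_spec()
  d <- data.frame(x = rnorm(30), m = rnorm(30))
  d$y <- d$m  # duplicate column makes the design singular
  expect_error(fit_path_model(d, spec), "rank deficient")
  expect_error(fit_path_model(d[1:2, ], spec), "complete cases")
  expect_error(fit_path_model(d[c("x", "m")], spec), "lacks model variable")
})

test_that("implied covariance follows the RAM identity and path tracing", {
  spec <- chain_spec()
  # all coefficients zero, unit variances: identity
  p0 <- list(coefficients = c(0, 0), covariances = numeric(0),
             variances = c(x = 1, m = 1, y = 1))
  expect_equal(unname(implied_covariance(p0, spec)), diag(3))
  # single path x -> y with coefficient b: implied corr is b
  b <- 0.62
  xy <- path_spec(c("x", "y"), c(x = "exogenous", y = "outcome"),
                  data.frame(response = "y", predictor = "x"))
  Sig <- implied_covariance(list(coefficients = b, covariances = numeric(0),
                                 variances = c(x = 1, y = 1 - b^2)), xy)
  expect_equal(Sig["x", "y"], b)
  expect_equal(Sig["y", "y"], 1)
  # simulation oracle on a random acyclic spec
  spec4 <- path_spec(
    c("e1", "e2", "m1", "o1"),
    c(e1 = "exogenous", e2 = "exogenous", m1 = "mediator", o1 = "outcome"),
    data.frame(response = c("m1", "m1", "o1", "o1"),
               predictor = c("e1", "e2", "m1", "e1")),
    covariances = data.frame(var1 = "e1", var2 = "e2"))
  coefs <- c(0.4, -0.3, 0.5, 0.2)   # m1~e1, m1~e2, o1~m1, o1~e1
  rho <- 0.3
  # residual variances for unit total variance, derived by path tracing
  v_m1 <- 0.4^2 + 0.3^2 + 2 * 0.4 * (-0.3) * rho
  cov_m1_e1 <- 0.4 + (-0.3) * rho
  v_o1 <- 0.5^2 + 0.2^2 + 2 * 0.5 * 0.2 * cov_m1_e1
  Sig_model <- implied_covariance(
    list(coefficients = coefs, covariances = rho,
         variances = c(e1 = 1, e2 = 1, m1 = 1 - v_m1, o1 = 1 - v_o1)),
    spec4)
  expect_equal(unname(diag(Sig_model)), rep(1, 4), tolerance = 1e-12)
  d <- simulate_path_data(spec4, coefs, n = 2e5, covariances = rho, seed = 9)
  expect_equal(unname(cov(d)), unname(Sig_model), tolerance = 0.02)
})

test_that("ML chi-square matches its closed form and divergence properties", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(ml_chisquare(S, S, n = 101), 0)
  expect_equal(ml_chisquare(S, diag(2), n = 101), -100 * log(1 - 0.36),
               tolerance = 1e-10)
  set.seed(77)
  for (i in 1:8) {
    A <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(5) * 0.1
    B <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(5) * 0.1
    expect_gte(ml_chisquare(A, B, n = 50), 0)
  }
  expect_error(ml_chisquare(matrix(c(1, 2, 2, 1), 2), diag(2), 10),
               "positive definite")
})

test_that("permutation p-values honor the add-one bound and determinism", {
  spec <- chain_spec()
  set.seed(31)
  x <- rnorm(60); m <- 0.9 * x + rnorm(60, 0, sqrt(1 - 0.81))
  d <- data.frame(x = x, m = m, y = 0.9 * m + rnorm(60, 0, sqrt(1 - 0.81)))
  p <- permutation_pvalues(d, spec, B = 199, seed = 4)
  expect_true(all(p >= 1 / 200))
  # a strong effect beats every null replicate
  expect_equal(unname(p["m~x"]), 1 / 200)
  p2 <- permutation_pvalues(d, spec, B = 199, seed = 4)
  expect_identical(p, p2)
  # weak-signal data: p-values vary with the permutation stream
  set.seed(32)
  dw <- data.frame(x = rnorm(40), m = rnorm(40), y = rnorm(40))
  pw1 <- permutation_pvalues(dw, spec, B = 199, seed = 4)
  pw2 <- permutation_pvalues(dw, spec, B = 199, seed = 5)
  expect_false(identical(as.numeric(pw1), as.numeric(pw2)))
  # joint scheme also runs and respects the bound
  pj <- permutation_pvalues(d, spec, B = 99, seed = 4, scheme = "joint")
  expect_true(all(pj >= 1 / 100 & pj <= 1))
})

test_that("jackknife certifies strong signals and flags outlier-driven ones", {
  spec <- chain_spec()
  set.seed(91)
  n <- 200
  x <- rnorm(n); m <- 0.8 * x + rnorm(n, 0, 0.6)
  d <- data.frame(x = x, m = m, y = 0.8 * m + rnorm(n, 0, 0.6))
  jk <- jackknife_stability(d, spec)
  expect_true(all(jk$stable))
  # association manufactured by one influential point
  set.seed(92)
  n2 <- 40
  d2 <- data.frame(x = rnorm(n2), m = rnorm(n2), y = rnorm(n2))
  d2[n2, ] <- c(6, 6, 6)
  jk2 <- jackknife_stability(d2, spec)
  expect_lt(jk2$p_full[jk2$parameter == "m~x"], 0.05)  # looks significant
  expect_false(jk2$stable[jk2$parameter == "m~x"])     # but is not stable
  # non-significant in the full sample is unstable by definition
  set.seed(93)
  d3 <- data.frame(x = rnorm(50), m = rnorm(50), y = rnorm(50))
  jk3 <- jackknife_stability(d3, spec)
  expect_false(any(jk3$stable[jk3$p_full > 0.05]))
})
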