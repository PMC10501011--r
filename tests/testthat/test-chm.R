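## small fitting problems shared by several tests
make_h3_dataset <- function(n = 60, seed = 2, spread = 0.12) {
  set.seed(seed)
  pes <- surrogate_h3()
  configs <- lapply(seq_len(n), function(k) {
    cfg <- config_h3p(0.9)
    chm_config(cfg$elements, cfg$coords + spread * matrix(rnorm(9), 3))
  })
  energies <- vapply(configs, function(cf)
    surrogate_energy_gradient(pes, cf)$energy, 1)
  chm_dataset(configs, energies)
}

test_that("coefficient-space dimensions follow the class/constant rules", {
  t3 <- typing_h3p()
  b <- chm_basis_set(t3, 2)
  ## H3+: classes {H, HH}; L = 4 at M = 2 -> 2(L-1) + L
  expect_equal(b$L, 4)
  expect_equal(chm_coef_count(b), 2 * 3 + 4)
  ## per-class-L convention: 3 classes x L (the "3L" counting)
  bpc <- chm_basis_set(t3, 2, convention = "per_class")
  expect_equal(chm_coef_count(bpc), 3 * 4)
  ## HeH+ default column count 3 (L-1) + L
  b2 <- chm_basis_set(typing_hehp(), 1)
  expect_equal(chm_coef_count(b2), 3 * (b2$L - 1) + b2$L)
})

test_that("zero-coefficient model reduces to populations and core energy", {
  t3 <- typing_h3p()
  nl <- chm_nlparams(alpha = c(H = 1))
  model <- chm_model(chm_basis_set(t3, 2), nl)
  cfg <- config_h3p(0.92)
  ## P_aa = n_a = 2/3 ; P_ab = 0 ; n = 2
  for (a in 1:3) expect_equal(density_diagonal(cfg, model, a), 2 / 3)
  expect_equal(density_offdiagonal(cfg, model, 1, 2), 0)
  expect_equal(total_electron_count(cfg, model), 2, tolerance = 1e-12)
  cm <- core_matrices(cfg, model$typing)
  expect_equal(chm_energy(cfg, model),
               cm$Enuc + sum(2 / 3 * diag(cm$Hcore)), tolerance = 1e-12)
  ## HeH+ populations
  mh <- chm_model(chm_basis_set(typing_hehp(), 1),
                  chm_nlparams(alpha = c(He = 1.2, H = 0.8)))
  heh <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 0.8)))
  expect_equal(density_diagonal(heh, mh, 1), 2)
  expect_equal(density_diagonal(heh, mh, 2), 0)
  ## CH5+ electron count 6 + 5 * 4/5 = 10
  m5 <- chm_model(chm_basis_set(typing_ch5p(), 1),
                  chm_nlparams(alpha = c(C = 1, H = 1)))
  expect_equal(total_electron_count(config_ch5p(), m5), 10,
               tolerance = 1e-12)
})

test_that("density covariance and energy invariance under permutations", {
  t3 <- typing_h3p()
  model <- random_chm_model(t3, 2, seed = 5, scale = 0.01)
  g <- build_perm_group(t3)
  for (seed in 1:5) {
    cfg <- random_config(c("H", "H", "H"), seed = seed, min_sep = 0.6)
    e0 <- chm_energy(cfg, model)
    P0 <- vapply(1:3, function(a) density_diagonal(cfg, model, a), 1)
    for (gi in seq_len(g$order)) {
      perm <- g$elements[gi, ]
      pc <- apply_permutation(cfg, perm, t3)
      ## P_{g(a)g(a)}(g R) = P_aa(R); swap of atoms 1,2 exchanges P_11/P_22
      for (a in 1:3)
        expect_equal(density_diagonal(pc, model, perm[a]), P0[a],
                     tolerance = 1e-12)
      ## off-diagonal relabeling P_1c <-> P_2c
      expect_equal(density_offdiagonal(pc, model, perm[1], perm[3]),
                   density_offdiagonal(cfg, model, 1, 3), tolerance = 1e-12)
      expect_equal(chm_energy(pc, model), e0, tolerance = 1e-10)
    }
  }
})

test_that("electron count matches explicit P.S matrix contraction", {
  t3 <- typing_h3p()
  model <- random_chm_model(t3, 2, seed = 9, scale = 0.02)
  for (seed in 1:4) {
    cfg <- random_config(c("H", "H", "H"), seed = seed, min_sep = 0.6)
    cm <- core_matrices(cfg, model$typing)
    P <- matrix(0, 3, 3)
    for (a in 1:3) P[a, a] <- density_diagonal(cfg, model, a)
    for (a in 1:2) for (b in (a + 1):3)
      P[a, b] <- P[b, a] <- density_offdiagonal(cfg, model, a, b)
    expect_equal(total_electron_count(cfg, model), sum(P * cm$S),
                 tolerance = 1e-12)
    ## energy via explicit trace too
    e_explicit <- cm$Enuc + sum(P * cm$Hcore) +
      sum(model$coeffs$corr *
            evaluate_basis(model$bset$inv,
                           as.numeric(compute_distances(cfg)),
                           model$nlparams$d0))
    expect_equal(chm_energy(cfg, model), e_explicit, tolerance = 1e-12)
  }
})

test_that("off-diagonal density vanishes at large separation", {
  t2 <- typing_hehp()
  model <- random_chm_model(t2, 2, seed = 3, scale = 0.1)
  far <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 40)))
  expect_lt(abs(density_offdiagonal(far, model, 1, 2)), 1e-6)
})

test_that("energy decomposition components sum exactly", {
  t3 <- typing_h3p()
  model <- random_chm_model(t3, 2, seed = 13, scale = 0.05)
  cfg <- random_config(c("H", "H", "H"), seed = 21, min_sep = 0.7)
  dec <- energy_decomposition(cfg, model)
  expect_equal(dec$hf_like + dec$correction,
               hartree2cm(chm_energy(cfg, model)), tolerance = 1e-9)
  m0 <- model
  m0$coeffs$corr[] <- 0
  expect_equal(energy_decomposition(cfg, m0)$correction, 0)
})

test_that("fit_linear recovers synthetic targets and honors weights", {
  set.seed(4)
  X <- matrix(rnorm(200 * 12), 200)
  beta <- rnorm(12)
  y <- drop(X %*% beta)
  fl <- fit_linear(X, y)
  expect_false(fl$rank_deficient)
  expect_equal(drop(X %*% fl$coef), y, tolerance = 1e-9)
  ## duplicated rows leave the solution unchanged
  fl2 <- fit_linear(rbind(X, X[1:30, ]), c(y, y[1:30]))
  expect_equal(fl2$coef, fl$coef, tolerance = 1e-8)
  ## zero weight removes a contaminated row
  ybad <- y; ybad[7] <- ybad[7] + 100
  w <- rep(1, 200); w[7] <- 0
  fl3 <- fit_linear(X, ybad, w)
  expect_equal(fl3$coef, fl$coef, tolerance = 1e-8)
  ## rank-deficient: minimum-norm flagged, not fatal
  Xr <- cbind(X, X[, 1] + X[, 2])
  expect_warning(fl4 <- fit_linear(Xr, y), "minimum-norm")
  expect_true(fl4$rank_deficient)
  expect_equal(drop(Xr %*% fl4$coef), y, tolerance = 1e-8)
  expect_error(fit_linear(X, y, rep(0, 200)), "all-zero")
})

test_that("synthetic CHM data is recovered to near machine precision", {
  t3 <- typing_h3p()
  truth <- random_chm_model(t3, 2, seed = 17, scale = 0.02)
  set.seed(23)
  configs <- lapply(1:50, function(k)
    random_config(c("H", "H", "H"), seed = 100 + k, min_sep = 0.6))
  energies <- chm_energy(configs, truth)
  ds <- chm_dataset(configs, energies)
  fit <- fit_chm(ds, t3, 2, truth$nlparams, charge_weight = 0)
  pred <- chm_energy(ds, fit$model)
  expect_lt(max(abs(pred - energies)) / max(abs(energies)), 1e-8)
  ## design dimensions as documented
  des <- assemble_design(ds, fit$model$bset, truth$nlparams,
                         charge_weight = 0.01)
  expect_equal(ncol(des$X), chm_coef_count(fit$model$bset))
  expect_equal(nrow(des$X), 2 * length(ds))
})

test_that("PIP baseline fits an exact degree-M invariant polynomial", {
  t3 <- typing_h3p()
  basis <- enumerate_invariant_basis(t3, 2)
  set.seed(31)
  coef_true <- rnorm(basis_size(basis), sd = 0.01)
  configs <- lapply(1:40, function(k)
    random_config(c("H", "H", "H"), seed = 300 + k, min_sep = 0.6))
  Dm <- vapply(configs, function(cf) as.numeric(compute_distances(cf)),
               numeric(3))
  energies <- drop(crossprod(evaluate_basis(basis, Dm, 2.0), coef_true))
  ds <- chm_dataset(configs, energies)
  fit <- fit_pip_baseline(ds, t3, 2, d0 = 2.0)
  expect_lt(fit$rmse_train, 1e-6)
  ## predictions round-trip
  rep <- evaluate_report(fit, ds)
  expect_equal(rep$rmse, fit$rmse_train, tolerance = 1e-8)
})

test_that("nested bases: RMSE non-increasing in M; CHM(M) <= PIP(M)", {
  ds <- make_h3_dataset(n = 80, seed = 6)
  t3 <- typing_h3p()
  nl <- chm_nlparams(d0 = 2, t0 = 2, alpha = c(H = 1))
  rmse_pip <- vapply(1:3, function(M)
    fit_pip_baseline(ds, t3, M, d0 = 2)$rmse_train, 1)
  rmse_chm <- vapply(1:3, function(M)
    fit_chm(ds, t3, M, nl, charge_weight = 0)$rmse_train, 1)
  expect_true(all(diff(rmse_pip) <= 1e-8))
  expect_true(all(diff(rmse_chm) <= 1e-8))
  ## the CHM span contains the full correction-energy PIP space
  expect_true(all(rmse_chm <= rmse_pip + 1e-8))
})

test_that("evaluate_report invariants", {
  ds <- make_h3_dataset(n = 40, seed = 8)
  fit <- fit_pip_baseline(ds, typing_h3p(), 2)
  rep <- evaluate_report(fit$model, ds)
  expect_equal(rep$rmse, sqrt(mean(rep$residuals^2)), tolerance = 1e-10)
  expect_gte(rep$max_error, rep$rmse)
  expect_equal(nrow(rep$table), length(ds))
})

test_that("optimize_nonlinear improves the fit and is deterministic", {
  ds <- make_h3_dataset(n = 60, seed = 10)
  t3 <- typing_h3p()
  space <- list(d0 = c(1.5, 2, 3), t0 = c(1.5, 2, 3),
                alpha.H = c(0.5, 1, 1.5))
  o1 <- optimize_nonlinear(ds, NULL, t3, 2, search_space = space, seed = 1,
                           charge_weight = 0, simplex_evals = 40)
  o2 <- optimize_nonlinear(ds, NULL, t3, 2, search_space = space, seed = 1,
                           charge_weight = 0, simplex_evals = 40)
  expect_identical(o1$nlparams, o2$nlparams)
  ## returned objective is no worse than the default-center fit
  center <- chm_nlparams(d0 = 2, t0 = 2, alpha = c(H = 1))
  f0 <- fit_chm(ds, t3, 2, center, charge_weight = 0)
  expect_lte(o1$objective, f0$rmse_train + 1e-9)
  expect_error(optimize_nonlinear(ds, NULL, t3, 2,
                                  search_space = list(d0 = Inf, t0 = 1,
                                                      alpha.H = 1)),
               "finite")
})

test_that("rotational/translational invariance of fitted predictions", {
  ds <- make_h3_dataset(n = 50, seed = 12)
  t3 <- typing_h3p()
  nl <- chm_nlparams(alpha = c(H = 1))
  fit <- fit_chm(ds, t3, 2, nl)
  cfg <- ds$configs[[5]]
  R <- random_rotation(9)
  moved <- chm_config(cfg$elements, sweep(cfg$coords %*% t(R), 2, -c(1, 2, 3)))
  expect_equal(chm_energy(moved, fit$model), chm_energy(cfg, fit$model),
               tolerance = 1e-10)
})
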