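test_that("invariant basis counts match brute-force orbit enumeration", {
  ## small systems, full-group brute force as an independent oracle
  cases <- list(list(typing_h3p(), 1), list(typing_h3p(), 2),
                list(typing_h3p(), 3), list(typing_hehp(), 3),
                list(chm_typing(list(A = 1:2, B = 3:4),
                                c(A = 1, B = 1), 0L), 3))
  for (cs in cases) {
    L <- basis_size(enumerate_invariant_basis(cs[[1]], cs[[2]]))
    expect_equal(L, oracle_orbit_count(cs[[1]], cs[[2]]),
                 info = sprintf("M=%d", cs[[2]]))
  }
  ## H3+ M=1: constant + symmetric sum of the three Morse variables
  b <- enumerate_invariant_basis(typing_h3p(), 1)
  expect_equal(basis_size(b), 2)
  expect_true(any(b$degree == 0))
})

test_that("enumeration is order-independent", {
  t3 <- typing_h3p()
  b <- enumerate_invariant_basis(t3, 3)
  ## shuffle raw monomial generation order by canonicalizing a permuted copy
  group <- build_perm_group(t3)
  E <- chmpes:::.enum_monomials(3, 3)
  set.seed(5)
  E2 <- E[sample(nrow(E)), , drop = FALSE]
  cn <- chmpes:::.canonicalize(E2, group)
  keep <- !duplicated(cn$key)
  terms <- cn$canon[keep, , drop = FALSE]
  ord <- chmpes:::.order_terms(terms, cn$key[keep])
  expect_equal(terms[ord, , drop = FALSE], b$terms)
})

test_that("evaluate_basis equals the full-group brute-force orbit sums", {
  t3 <- typing_h3p()
  b <- enumerate_invariant_basis(t3, 3)
  g <- b$group
  cfg <- random_config(c("H", "H", "H"), seed = 9)
  d <- as.numeric(compute_distances(cfg))
  vals <- evaluate_basis(b, d, 2.0)
  for (i in seq_len(basis_size(b)))
    expect_equal(vals[i], oracle_orbit_value(b$terms[i, ], g, d, 2.0),
                 tolerance = 1e-12)
})

test_that("invariant basis values are permutation invariant", {
  t5 <- typing_ch5p()
  b <- enumerate_invariant_basis(t5, 3)
  for (seed in 1:5) {
    cfg <- random_config(c("C", rep("H", 5)), seed = seed)
    v0 <- evaluate_basis(b, as.numeric(compute_distances(cfg)), 1.7)
    perm <- random_class_perm(t5, seed + 50)
    vp <- evaluate_basis(b,
                         as.numeric(compute_distances(
                           apply_permutation(cfg, perm, t5))), 1.7)
    expect_equal(vp, v0, tolerance = 1e-12)
  }
})

test_that("morse variables behave as documented", {
  expect_equal(morse_variables(0, 2), 1)
  expect_equal(morse_variables(2, 2), exp(-1))
  expect_error(morse_variables(1, 0), "> 0")
  set.seed(2)
  d <- runif(10, 0.3, 4)
  p <- sample(1:5, 10, replace = TRUE)
  expect_equal(morse_variables(d, 1.3)^p, exp(-p * d / 1.3),
               tolerance = 1e-14)
})

test_that("atom-covariant values relabel under like-atom permutations", {
  t3 <- typing_h3p()
  cfg <- random_config(c("H", "H", "H"), seed = 4)
  d <- as.numeric(compute_distances(cfg))
  bases <- lapply(1:3, function(a)
    enumerate_atom_covariant_basis(t3, 2, a))
  expect_equal(nrow(bases[[1]]$terms),
               basis_size(enumerate_invariant_basis(t3, 2)) - 1)
  vals <- lapply(bases, evaluate_basis, dist = d, scale = 1.9)
  ## full covariance over every group element: u_{g(a),i}(g R) = u_{a,i}(R)
  g <- build_perm_group(t3)
  for (gi in seq_len(g$order)) {
    perm <- g$elements[gi, ]
    dp <- as.numeric(compute_distances(apply_permutation(cfg, perm, t3)))
    for (a in 1:3) {
      vp <- evaluate_basis(bases[[perm[a]]], dp, 1.9)
      expect_equal(vp, vals[[a]], tolerance = 1e-12)
    }
  }
})

test_that("HeH+ atom covariant with M=1 is the bare Morse variable", {
  t2 <- typing_hehp()
  b <- enumerate_atom_covariant_basis(t2, 1, anchor = 1)
  cfg <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  expect_equal(nrow(b$terms), 1)
  expect_equal(evaluate_basis(b, as.numeric(compute_distances(cfg)), 2.2),
               exp(-1.1 / 2.2), tolerance = 1e-14)
})

test_that("pair-covariant values relabel correctly (P_1c <-> P_2c)", {
  t5 <- typing_ch5p()
  cfg <- random_config(c("C", rep("H", 5)), seed = 12)
  d <- as.numeric(compute_distances(cfg))
  ## swap H atoms 3 and 4 (indices of two like hydrogens)
  perm <- c(1, 2, 4, 3, 5, 6)
  dp <- as.numeric(compute_distances(apply_permutation(cfg, perm, t5)))
  b_12 <- enumerate_pair_covariant_basis(t5, 1, c(2, 3))
  b_13 <- enumerate_pair_covariant_basis(t5, 1, c(2, 4))
  ## permuting H3 <-> H4 maps the (H2,H3) value onto the (H2,H4) anchor
  expect_equal(evaluate_basis(b_13, dp, 2.1),
               evaluate_basis(b_12, d, 2.1), tolerance = 1e-12)
  ## symmetric in the two anchor atoms
  b_21 <- enumerate_pair_covariant_basis(t5, 1, c(3, 2))
  expect_equal(evaluate_basis(b_21, d, 2.1),
               evaluate_basis(b_12, d, 2.1), tolerance = 1e-14)
  expect_error(enumerate_pair_covariant_basis(t5, 1, c(2, 2)), "distinct")
})

test_that("formamide has the 7 pair classes and CH5+ the expected 2", {
  pc <- pair_classes(typing_formamide())
  expect_setequal(pc$names, c("HH", "CH", "HN", "HO", "CN", "CO", "NO"))
  expect_equal(length(pair_classes(typing_ch5p())$names), 2)
})

test_that("augment_basis adds exactly the expected one-body orbits", {
  t3 <- typing_h3p()
  b1 <- enumerate_invariant_basis(t3, 1)
  expect_equal(basis_size(b1), 2)
  aug <- augment_basis(b1, list(2, 3, 4))
  expect_equal(basis_size(aug), 5)   # one orbit per extra one-body power
  ## dedup: patterns not exceeding the base order warn and change nothing
  b2 <- enumerate_invariant_basis(t3, 2)
  expect_warning(aug2 <- augment_basis(b2, list(2)), "duplicates")
  expect_equal(basis_size(aug2), basis_size(b2))
  ## brute-force check of one added orbit: y^2 symmetric sum
  d <- c(0.8, 1.0, 1.2)
  vals <- evaluate_basis(aug, d, 2)
  expect_equal(vals[which(aug$degree == 2 &
                            apply(aug$terms, 1, max) == 2)],
               sum(exp(-2 * d / 2)), tolerance = 1e-13)
})

test_that("enumeration guard trips on absurd request", {
  expect_error(enumerate_invariant_basis(typing_ch5p(), 30), "cap")
  expect_error(enumerate_invariant_basis(typing_h3p(), -1), "M must be")
})
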