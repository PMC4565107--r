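# single-feature model builder for closed-form checks
one_feature_model <- function(marg_mean = 0, marg_sd = 1, mu = c(0, 0),
                              sigma = c(1, 1), rho = 0, kBT = 1, epsilon = 1e-12) {
  vb_model(list(hydrophobicity = list(
    marginal = list(mean = marg_mean, sd = marg_sd),
    joint = list(mu = mu, sigma = sigma, rho = rho))),
    kBT = kBT, epsilon = epsilon, weights = c(hydrophobicity = 1))
}

test_that("bivariate fitting recovers planted parameters", {
  planted_mu <- c(1.89, 2.21)
  ps <- sample_property_pairs(planted_mu, c(1, 1), 0.4, n = 1e4, seed = 42)
  fit <- fit_bivariate_normal(ps$pairs[, 1], ps$pairs[, 2], symmetrize = FALSE)
  expect_lt(abs(fit$mu[1] - 1.89), 0.05)
  expect_lt(abs(fit$mu[2] - 2.21), 0.05)
  expect_lt(abs(fit$rho - 0.4), 0.03)

  # symmetrized fit equals the closed-form moments of the two-order mixture
  sym <- fit_bivariate_normal(ps$pairs[, 1], ps$pairs[, 2], symmetrize = TRUE)
  m_bar <- mean(planted_mu)
  d <- (planted_mu[1] - planted_mu[2]) / 2
  var_mix <- 1 + d^2                 # sigma^2 + half-gap^2
  rho_mix <- (0.4 - d^2) / var_mix
  expect_equal(sym$mu, c(m_bar, m_bar), tolerance = 0.05)
  expect_equal(sym$sigma, rep(sqrt(var_mix), 2), tolerance = 0.05)
  expect_lt(abs(sym$rho - rho_mix), 0.03)

  # symmetrization makes the fit order-invariant
  swapped <- fit_bivariate_normal(ps$pairs[, 2], ps$pairs[, 1], symmetrize = TRUE)
  expect_equal(sym, swapped, tolerance = 1e-12)

  expect_error(fit_bivariate_normal(rep(1, 50), rep(1, 50)), "zero-variance")
})

test_that("pair energy vanishes under independence and matches the closed form", {
  ind <- one_feature_model(rho = 0)
  for (x in c(-2, -0.5, 0, 1, 3)) {
    expect_equal(pair_energy(c(hydrophobicity = x), c(hydrophobicity = -x), ind), 0,
                 tolerance = 1e-12)
  }

  # standard bivariate, rho = 0.5, at (0, 0):
  # joint 1/(2*pi*sqrt(0.75)) ~ 0.18378, marginals product ~ 0.15915,
  # S = -ln(1.15470) ~ -0.14384
  m <- one_feature_model(rho = 0.5)
  expect_equal(pair_energy(c(hydrophobicity = 0), c(hydrophobicity = 0), m),
               -0.143841036226, tolerance = 1e-6)

  # far tail: densities floored, energy finite
  far <- pair_energy(c(hydrophobicity = 50), c(hydrophobicity = 50), m)
  expect_true(is.finite(far))

  expect_error(pair_energy(c(hydrophobicity = 1), c(hydrophobicity = 1), list()),
               "not a fitted")
})

make_profile <- function(keys, vals) {
  df <- data.frame(reskey = keys, res_type = "ALA", surface_ratio = 0.5)
  for (f in c("hydrophobicity", "electrostatic", "hbonds")) {
    df[[paste0("pprime_", f)]] <- vals
    vals <- vals + 0.3  # decorrelate the three columns
  }
  class(df) <- c("vb_profile", "data.frame")
  df
}

test_that("score_all_pairs matches the elementwise loop and is order invariant", {
  model <- toy_trained_model()
  pa <- make_profile(paste0("A:", 1:3), c(-1.2, 0.4, 2.0))
  pb <- make_profile(paste0("B:", 1:4), c(0.1, -0.7, 1.5, 3.0))
  sc <- score_all_pairs(pa, pb, model)
  expect_equal(dim(sc$S), c(3, 4))
  fn <- names(model$features)
  for (i in 1:3) for (j in 1:4) {
    p1 <- sapply(fn, function(f) pa[[paste0("pprime_", f)]][i])
    p2 <- sapply(fn, function(f) pb[[paste0("pprime_", f)]][j])
    expect_equal(sc$S[i, j], pair_energy(p1, p2, model), tolerance = 1e-12)
  }
  # permuting input rows permutes, not changes, the scores
  perm <- sample(3)
  sc2 <- score_all_pairs(pa[perm, ], pb, model)
  expect_equal(sc2$S[match(pa$reskey, pa$reskey[perm]), ], sc$S,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(score_all_pairs(pa[0, ], pb, model), "empty")
})

test_that("neighborhood update adds distance-weighted neighbor energies", {
  # A has x1 at origin and r1 at 5.0 A; B has a single residue far in y
  sub_a <- mini_subunit("A", rbind(c(0, 0, 0), c(5, 0, 0)))
  sub_b <- mini_subunit("B", rbind(c(0, 50, 0)))
  S <- matrix(c(-1, -2), nrow = 2, dimnames = list(c("A:1", "A:2"), "B:1"))
  sc <- manual_scores(S)
  up <- neighborhood_update(sc, sub_a, sub_b, radius = 10)
  # S'(x1, B1) = -1 + (1/5) * (-2) = -1.4  (one neighbor, none on side B)
  expect_equal(up$S_prime["A:1", "B:1"], -1.4)
  expect_equal(up$S_prime["A:2", "B:1"], -2 + (1 / 5) * (-1))

  # no neighbor within the radius: S' = S
  lone <- neighborhood_update(sc, mini_subunit("A", rbind(c(0, 0, 0), c(30, 0, 0))),
                              sub_b, radius = 10)
  expect_equal(lone$S_prime, lone$S)

  # neighbor at exactly 10.0 A is included (inclusive bound)
  at10 <- neighborhood_update(sc, mini_subunit("A", rbind(c(0, 0, 0), c(10, 0, 0))),
                              sub_b, radius = 10)
  expect_equal(at10$S_prime["A:1", "B:1"], -1 + (1 / 10) * (-2))

  # shrinking radius toward zero reduces the update to the identity
  tiny <- neighborhood_update(sc, sub_a, sub_b, radius = 1e-6)
  expect_equal(tiny$S_prime, tiny$S)
  expect_error(neighborhood_update(sc, sub_a, sub_b, radius = 0), "radius")

  # residues lacking C-alpha are skipped with a warning
  no_ca <- mini_subunit("A", rbind(c(0, 0, 0), c(5, 0, 0)), elety = "CB")
  expect_warning(neighborhood_update(sc, no_ca, sub_b, radius = 10), "C-alpha")
})

test_that("model JSON round-trip reproduces scores bit-identically", {
  model <- toy_trained_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  pa <- make_profile(paste0("A:", 1:3), c(-1.2, 0.4, 2.0))
  pb <- make_profile(paste0("B:", 1:2), c(0.1, -0.7))
  expect_identical(score_all_pairs(pa, pb, model)$S,
                   score_all_pairs(pa, pb, back)$S)
})

test_that("positively-associated pairs are enriched in negative energies", {
  ps <- sample_property_pairs(c(1.89, 2.21), c(1, 1), 0.5, n = 4000, seed = 8)
  joint <- fit_bivariate_normal(ps$pairs[, 1], ps$pairs[, 2])
  marg <- list(mean = mean(ps$pairs), sd = sd(as.numeric(ps$pairs)))
  m <- vb_model(list(hydrophobicity = list(marginal = marg, joint = joint)),
                weights = c(hydrophobicity = 1))
  s_pairs <- mapply(function(a, b) pair_energy(c(hydrophobicity = a),
                                               c(hydrophobicity = b), m),
                    ps$pairs[, 1], ps$pairs[, 2])
  s_decoy <- mapply(function(a, b) pair_energy(c(hydrophobicity = a),
                                               c(hydrophobicity = b), m),
                    ps$decoys[, 1], ps$decoys[, 2])
  expect_lt(mean(s_pairs), mean(s_decoy))
})

test_that("fit_model is exchange-symmetric and validates its inputs", {
  train <- lapply(1:3, function(s) make_toy_complex(n_res_a = 10, n_res_b = 10,
                                                    n_contact_pairs = 4,
                                                    seed = 300 + s)$complex)
  m1 <- fit_model(train, min_pairs = 5)
  swapped <- lapply(train, function(cx) {
    structure(list(subunits = rev(cx$subunits)), class = "vb_structure")
  })
  m2 <- fit_model(swapped, min_pairs = 5)
  for (f in names(m1$features)) {
    expect_equal(m1$features[[f]]$joint, m2$features[[f]]$joint, tolerance = 1e-10)
    expect_equal(m1$features[[f]]$marginal, m2$features[[f]]$marginal, tolerance = 1e-10)
  }
  expect_error(fit_model(train[1]), "at least 2")
  expect_error(fit_model(train, min_pairs = 1e6), "insufficient")
})
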