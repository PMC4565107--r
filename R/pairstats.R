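#' Normal models of the structural neighboring property across interfaces
#'
#' For each feature, a univariate normal F(x) describes the property of
#' residues on one side of an interface, and a bivariate normal F(x1, x2)
#' describes property pairs across the interface. The effective free energy
#' of an interacting residue pair is the log-odds of the joint against the
#' product of marginals,
#' \deqn{s_f(x_1, x_2) = -k_BT \,\ln \frac{F(x_1, x_2)}{F(x_1)F(x_2)}}
#' combined over features with configurable weights. Negative values mark
#' pairs whose properties co-occur more often across interfaces than chance.
#'
#' @name pair_statistics
#' @keywords internal
NULL

.vb_sd_floor <- 1e-6

#' Construct a pair-statistics model
#'
#' Usually produced by [fit_model()]; the constructor is exported so
#' closed-form models can be built directly (e.g. in tests or from
#' published parameters).
#'
#' @param features Named list (one entry per feature in
#'   `c("hydrophobicity","electrostatic","hbonds")`, or a subset when
#'   matching `weights` are given) of lists with `marginal = list(mean, sd)`
#'   and `joint = list(mu = c(m1, m2), sigma = c(s1, s2), rho)`.
#' @param kBT Energy scale (dimensionless, default 1).
#' @param epsilon Density floor preventing infinite energies in the tails.
#' @param weights Named non-negative weights combining per-feature energies;
#'   default equal weights summing to 1 over the supplied features.
#' @return A `vb_model`.
#' @export
vb_model <- function(features, kBT = 1.0, epsilon = 1e-12, weights = NULL) {
  stopifnot(is.list(features), length(features) >= 1, !is.null(names(features)))
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(features), length(features)),
                               names(features))
  }
  weights <- weights[names(features)]
  if (any(is.na(weights)) || any(weights < 0) || sum(weights) == 0) {
    vb_stop("model", "weights must be non-negative, named per feature, not all zero")
  }
  if (epsilon <= 0) vb_stop("model", "epsilon must be > 0")
  for (f in names(features)) {
    p <- features[[f]]
    if (p$marginal$sd <= .vb_sd_floor) {
      vb_stop("model", "feature '%s': marginal sd below floor", f)
    }
    if (any(p$joint$sigma <= .vb_sd_floor) || abs(p$joint$rho) >= 1) {
      vb_stop("model", "feature '%s': joint covariance not positive definite", f)
    }
  }
  structure(list(features = features, kBT = kBT, epsilon = epsilon,
                 weights = weights, version = "1"),
            class = "vb_model")
}

#' @export
print.vb_model <- function(x, ...) {
  cat("vb_model (kBT =", x$kBT, ")\n")
  for (f in names(x$features)) {
    p <- x$features[[f]]
    cat(sprintf("  %-14s w=%.3f marginal N(%.3f, %.3f) joint mu=(%.3f, %.3f) sd=(%.3f, %.3f) rho=%.3f\n",
                f, x$weights[[f]], p$marginal$mean, p$marginal$sd,
                p$joint$mu[1], p$joint$mu[2], p$joint$sigma[1], p$joint$sigma[2],
                p$joint$rho))
  }
  invisible(x)
}

#' Maximum-likelihood bivariate-normal fit of property pairs
#'
#' Moment estimates (n in the denominator). With `symmetrize = TRUE` every
#' pair also enters in reversed order, reflecting that interfaces carry no
#' canonical side ordering; the fitted model then satisfies mu1 = mu2 and
#' sigma1 = sigma2 by construction.
#'
#' @param x1,x2 Numeric vectors of paired observations.
#' @param symmetrize Include both pair orders (default TRUE).
#' @return List `mu` (length 2), `sigma` (length 2), `rho`.
#' @export
fit_bivariate_normal <- function(x1, x2, symmetrize = TRUE) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  a <- if (symmetrize) c(x1, x2) else x1
  b <- if (symmetrize) c(x2, x1) else x2
  n <- length(a)
  mu <- c(mean(a), mean(b))
  sg <- c(sqrt(mean((a - mu[1])^2)), sqrt(mean((b - mu[2])^2)))
  if (any(sg <= .vb_sd_floor)) vb_stop("fit", "zero-variance pair sample")
  rho <- mean((a - mu[1]) * (b - mu[2])) / (sg[1] * sg[2])
  rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
  list(mu = mu, sigma = sg, rho = rho)
}

#' Fit the pair-statistics model from training complexes
#'
#' For each training complex (a two-subunit [vb_structure]): each subunit is
#' tessellated in isolation, property profiles computed, and interface
#' residue pairs collected at the heavy-atom contact cutoff. Marginals are
#' fitted per feature on the pooled p' of interface residues (each side
#' contributes); the joint is fitted on (p'(x1), p'(x2)) over interface
#' pairs, symmetrized by including both orderings.
#'
#' @param complexes List of two-subunit `vb_structure` objects (or lists
#'   `list(profile_a, profile_b, pairs)` with precomputed profiles and an
#'   interface pair data.frame `res_a`/`res_b`).
#' @param cutoff Heavy-atom contact cutoff (Angstroms, default 6).
#' @param kBT,epsilon,weights Passed to [vb_model()].
#' @param min_pairs Minimum pooled interface pairs (default 30).
#' @param symmetrize Symmetrize the joint fit (default TRUE).
#' @param padding Tessellation box padding.
#' @return A fitted `vb_model`.
#' @export
fit_model <- function(complexes, cutoff = 6.0, kBT = 1.0, epsilon = 1e-12,
                      weights = NULL, min_pairs = 30, symmetrize = TRUE,
                      padding = 5.0) {
  if (length(complexes) < 2) vb_stop("fit", "need at least 2 training complexes")
  feats <- vb_features()
  pooled_side <- stats::setNames(rep(list(numeric(0)), length(feats)), feats)
  pooled_p1 <- pooled_side
  pooled_p2 <- pooled_side

  for (cx in complexes) {
    if (inherits(cx, "vb_structure")) {
      if (length(cx$subunits) < 2) vb_stop("fit", "training complex has < 2 subunits")
      sub_a <- cx$subunits[[1]]
      sub_b <- cx$subunits[[2]]
      prof_a <- property_profile(sub_a, residue_areas(
        build_tessellation(structure_sites(sub_a), padding), sub_a))
      prof_b <- property_profile(sub_b, residue_areas(
        build_tessellation(structure_sites(sub_b), padding), sub_b))
      pairs <- heavy_atom_contacts(sub_a, sub_b, cutoff)
    } else {
      prof_a <- cx$profile_a
      prof_b <- cx$profile_b
      pairs <- cx$pairs
    }
    ia <- match(pairs$res_a, prof_a$reskey)
    ib <- match(pairs$res_b, prof_b$reskey)
    ok <- !is.na(ia) & !is.na(ib)  # both members must be surface residues
    ia <- ia[ok]; ib <- ib[ok]
    for (f in feats) {
      col <- paste0("pprime_", f)
      ra <- unique(ia); rb <- unique(ib)
      pooled_side[[f]] <- c(pooled_side[[f]], prof_a[[col]][ra], prof_b[[col]][rb])
      pooled_p1[[f]] <- c(pooled_p1[[f]], prof_a[[col]][ia])
      pooled_p2[[f]] <- c(pooled_p2[[f]], prof_b[[col]][ib])
    }
  }
  n_pairs <- length(pooled_p1[[1]])
  if (n_pairs < min_pairs) {
    vb_stop("fit", "insufficient interface pairs: %d (< %d)", n_pairs, min_pairs)
  }
  features <- list()
  for (f in feats) {
    v <- pooled_side[[f]]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s <= .vb_sd_floor) vb_stop("fit", "zero-variance feature '%s'", f)
    features[[f]] <- list(
      marginal = list(mean = m, sd = s),
      joint = fit_bivariate_normal(pooled_p1[[f]], pooled_p2[[f]], symmetrize)
    )
  }
  vb_model(features, kBT = kBT, epsilon = epsilon, weights = weights)
}

# log density helpers -------------------------------------------------------

log_dnorm1 <- function(x, mean, sd) dnorm(x, mean, sd, log = TRUE)

# log bivariate normal density, vectorized over x1/x2 of equal length
log_dbvnorm <- function(x1, x2, mu, sigma, rho) {
  z1 <- (x1 - mu[1]) / sigma[1]
  z2 <- (x2 - mu[2]) / sigma[2]
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  -log(2 * pi * sigma[1] * sigma[2] * sqrt(1 - rho^2)) - q / 2
}

# per-feature energy for vectors/matrices of evaluation points
feature_energy <- function(x1, x2, params, kBT, epsilon) {
  lj <- pmax(log_dbvnorm(x1, x2, params$joint$mu, params$joint$sigma, params$joint$rho),
             log(epsilon))
  lm1 <- pmax(log_dnorm1(x1, params$marginal$mean, params$marginal$sd), log(epsilon))
  lm2 <- pmax(log_dnorm1(x2, params$marginal$mean, params$marginal$sd), log(epsilon))
  -kBT * (lj - lm1 - lm2)
}

#' Effective free energy of an interacting residue pair
#'
#' @param p1,p2 Named numeric vectors of p' values for the model's features
#'   (one value per feature; names matching the model, or unnamed in model
#'   feature order).
#' @param model A fitted `vb_model`.
#' @param per_feature Return the per-feature energies instead of the
#'   weighted combination.
#' @return The energy S (scalar), or a named per-feature vector.
#' @export
pair_energy <- function(p1, p2, model, per_feature = FALSE) {
  if (!inherits(model, "vb_model")) vb_stop("energy", "model is not a fitted vb_model")
  fn <- names(model$features)
  if (is.null(names(p1))) names(p1) <- fn[seq_along(p1)]
  if (is.null(names(p2))) names(p2) <- fn[seq_along(p2)]
  if (any(!is.finite(p1[fn])) || any(!is.finite(p2[fn]))) {
    vb_stop("energy", "non-finite property values")
  }
  s <- vapply(fn, function(f) {
    feature_energy(p1[[f]], p2[[f]], model$features[[f]], model$kBT, model$epsilon)
  }, numeric(1))
  if (per_feature) return(s)
  sum(model$weights[fn] * s)
}

#' Score every surface-residue cross pair of two proteins
#'
#' @param profile_a,profile_b Property profiles ([property_profile()]) of
#'   the two proteins.
#' @param model A fitted `vb_model`.
#' @return A `vb_scores`: list with `S` (matrix, rows = A residues,
#'   columns = B residues, dimnames residue keys), `keys_a`, `keys_b`.
#'   Convert to a pair table with [as.data.frame()].
#' @export
score_all_pairs <- function(profile_a, profile_b, model) {
  if (nrow(profile_a) == 0 || nrow(profile_b) == 0) {
    vb_stop("score", "empty property profile")
  }
  fn <- names(model$features)
  nA <- nrow(profile_a)
  nB <- nrow(profile_b)
  S <- matrix(0, nA, nB, dimnames = list(profile_a$reskey, profile_b$reskey))
  for (f in fn) {
    col <- paste0("pprime_", f)
    X1 <- matrix(profile_a[[col]], nA, nB)
    X2 <- matrix(profile_b[[col]], nA, nB, byrow = TRUE)
    S <- S + model$weights[[f]] *
      feature_energy(X1, X2, model$features[[f]], model$kBT, model$epsilon)
  }
  structure(list(S = S, S_prime = NULL,
                 keys_a = profile_a$reskey, keys_b = profile_b$reskey),
            class = "vb_scores")
}

#' @export
as.data.frame.vb_scores <- function(x, ...) {
  df <- data.frame(
    res_a = rep(x$keys_a, times = length(x$keys_b)),
    res_b = rep(x$keys_b, each = length(x$keys_a)),
    S = as.numeric(x$S), stringsAsFactors = FALSE
  )
  if (!is.null(x$S_prime)) df$S_prime <- as.numeric(x$S_prime)
  df
}

#' Distance-weighted neighborhood update of pair energies
#'
#' Reinforces each pair's energy with the energies of spatial neighbors:
#' \deqn{S'(x_1,x_2) = S(x_1,x_2) + \sum_{dis(x_1,r_i)\le R} \frac{S(r_i,x_2)}{dis(x_1,r_i)}
#'   + \sum_{dis(x_2,r_j)\le R} \frac{S(x_1,r_j)}{dis(x_2,r_j)}}
#' where distances are between C-alpha atoms, r_i runs over residues of
#' protein A (excluding x1 itself), r_j over protein B (excluding x2), and
#' the radius bound is inclusive. Residues lacking a C-alpha atom are
#' skipped (with a warning): they neither receive nor contribute
#' neighborhood terms.
#'
#' @param scores A `vb_scores` from [score_all_pairs()].
#' @param sub_a,sub_b The subunits the profiles came from.
#' @param radius Neighborhood radius in Angstroms (default 10, inclusive).
#' @return The `vb_scores` with an `S_prime` matrix added.
#' @export
neighborhood_update <- function(scores, sub_a, sub_b, radius = 10.0) {
  if (radius <= 0) vb_stop("update", "radius must be > 0")
  sub_a <- as_subunit(sub_a, 1)
  sub_b <- as_subunit(sub_b, 2)
  ca_a <- ca_coords(sub_a, scores$keys_a)
  ca_b <- ca_coords(sub_b, scores$keys_b)
  for (nm in list(list(ca_a, "A"), list(ca_b, "B"))) {
    miss <- rownames(nm[[1]])[!stats::complete.cases(nm[[1]])]
    if (length(miss)) {
      warning(sprintf("side %s: residues lacking C-alpha skipped in update: %s",
                      nm[[2]], paste(miss, collapse = ", ")))
    }
  }
  wmat <- function(ca) {
    n <- nrow(ca)
    ok <- stats::complete.cases(ca)
    W <- matrix(0, n, n)
    if (sum(ok) >= 2) {
      d <- sqrt(pair_dist2(ca[ok, , drop = FALSE], ca[ok, , drop = FALSE]))
      diag(d) <- 0  # exact zero: self-distances can cancel to ~1e-6, not 0
      w <- ifelse(d <= radius & d > 1e-3, 1 / d, 0)
      W[ok, ok] <- w
    }
    W
  }
  WA <- wmat(ca_a)
  WB <- wmat(ca_b)
  scores$S_prime <- scores$S + WA %*% scores$S + scores$S %*% t(WB)
  scores
}

# JSON serialization ---------------------------------------------------------

#' Write a model to its JSON file format
#'
#' Schema: `{version, kBT, epsilon, weights, features: {<name>: {marginal:
#' {mean, sd}, joint: {mu: [2], sigma: [2], rho}}}}`. Full double precision
#' is written so that a round-trip reproduces scores bit-identically.
#'
#' @param model A `vb_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  obj <- list(version = model$version, kBT = model$kBT, epsilon = model$epsilon,
              weights = as.list(model$weights), features = model$features)
  # 17 significant digits: lossless decimal round-trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#' @param path Path to a model file written by [write_model()].
#' @return A `vb_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(obj$features, function(p) {
    list(marginal = list(mean = p$marginal$mean, sd = p$marginal$sd),
         joint = list(mu = as.numeric(p$joint$mu),
                      sigma = as.numeric(p$joint$sigma),
                      rho = p$joint$rho))
  })
  vb_model(feats, kBT = obj$kBT, epsilon = obj$epsilon,
           weights = unlist(obj$weights))
}

#' Write pair scores as TSV
#' @param scores A `vb_scores` (after [neighborhood_update()] if S' wanted).
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_scores_tsv <- function(scores, path, header = NULL) {
  df <- as.data.frame(scores)
  out <- data.frame(chain_a = sub(":.*$", "", df$res_a),
                    resid_a = sub("^[^:]*:", "", df$res_a),
                    chain_b = sub(":.*$", "", df$res_b),
                    resid_b = sub("^[^:]*:", "", df$res_b),
                    S = df$S)
  if (!is.null(df$S_prime)) out$S_prime <- df$S_prime
  vb_write_tsv(out, path, header)
  invisible(path)
}
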