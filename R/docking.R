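#' Docking-pose energy terms and linear re-scoring
#'
#' A pose (a candidate rigid arrangement of two subunits, as a two-subunit
#' [vb_structure]) is scored by a linear combination of energy terms. Two
#' terms are built in: the structural neighborhood energy (the pair
#' log-odds energy summed over all interface residue pairs) and an
#' amino-acid composition energy (negative log-probability of interface
#' residue types). Further terms (e.g. pi-pi stacking, dihedral-angle or
#' side-chain packing potentials) plug in as user functions with the same
#' `(pose, ...)` contract.
#'
#' @name docking_energy
#' @keywords internal
NULL

# interface residue pairs of a two-subunit pose (heavy-atom, strict <)
pose_interface_pairs <- function(pose, cutoff = 6.0) {
  if (!inherits(pose, "vb_structure") || length(pose$subunits) < 2) {
    vb_stop("docking", "pose must be a vb_structure with two subunits")
  }
  heavy_atom_contacts(pose$subunits[[1]], pose$subunits[[2]], cutoff)
}

#' Structural neighborhood energy of a pose
#'
#' Sum of the pair energy S over all interface residue pairs R of the pose:
#' each subunit is tessellated in isolation, property profiles computed,
#' and S(x1, x2) summed over heavy-atom contact pairs. Optionally the
#' neighborhood-updated S' is summed instead.
#'
#' @param pose Two-subunit `vb_structure`.
#' @param model Fitted `vb_model`.
#' @param cutoff Heavy-atom contact cutoff (default 6).
#' @param use_update Sum S' instead of S (default FALSE).
#' @param padding Tessellation padding.
#' @return Scalar energy.
#' @export
neighborhood_energy <- function(pose, model, cutoff = 6.0, use_update = FALSE,
                                padding = 5.0) {
  sub_a <- pose$subunits[[1]]
  sub_b <- pose$subunits[[2]]
  pairs <- pose_interface_pairs(pose, cutoff)
  if (nrow(pairs) == 0) vb_stop("docking", "pose has no interface contacts at %.1f A", cutoff)
  prof_a <- property_profile(sub_a, residue_areas(
    build_tessellation(structure_sites(sub_a), padding), sub_a))
  prof_b <- property_profile(sub_b, residue_areas(
    build_tessellation(structure_sites(sub_b), padding), sub_b))
  scores <- score_all_pairs(prof_a, prof_b, model)
  M <- scores$S
  if (use_update) {
    scores <- neighborhood_update(scores, sub_a, sub_b)
    M <- scores$S_prime
  }
  ia <- match(pairs$res_a, scores$keys_a)
  ib <- match(pairs$res_b, scores$keys_b)
  ok <- !is.na(ia) & !is.na(ib)
  if (!all(ok)) {
    warning(sprintf("%d interface pair(s) involve buried residues with no profile; skipped",
                    sum(!ok)))
  }
  if (!any(ok)) vb_stop("docking", "no scoreable interface pairs")
  sum(M[cbind(ia[ok], ib[ok])])
}

#' Amino-acid composition energy of a pose interface
#'
#' Negative summed log-probability of the interface residue types:
#' `-sum(log(aa_probs[type]))` over interface residues of both sides. With
#' uniform probabilities 1/20 and k interface residues this is k*log(20).
#'
#' @param pose Two-subunit `vb_structure`.
#' @param aa_probs Named probabilities per 3-letter residue type; strictly
#'   positive, summing to 1 (within 1e-6).
#' @param cutoff Heavy-atom contact cutoff.
#' @return Scalar energy (0 for an empty interface).
#' @export
amino_acid_energy <- function(pose, aa_probs, cutoff = 6.0) {
  if (any(aa_probs <= 0) || abs(sum(aa_probs) - 1) > 1e-6) {
    vb_stop("docking", "aa_probs must be strictly positive and sum to 1")
  }
  iface <- interface_residues(pose$subunits[[1]], pose$subunits[[2]], cutoff)
  keys <- c(iface$a, iface$b)
  if (length(keys) == 0) return(0)
  types <- c(residue_types(pose$subunits[[1]])[match(iface$a, residue_keys(pose$subunits[[1]]))],
             residue_types(pose$subunits[[2]])[match(iface$b, residue_keys(pose$subunits[[2]]))])
  p <- aa_probs[types]
  if (any(is.na(p))) {
    vb_stop("docking", "aa_probs missing residue type(s): %s",
            paste(unique(types[is.na(p)]), collapse = ", "))
  }
  -sum(log(p))
}

#' Interface amino-acid probabilities from training complexes
#'
#' Relative frequencies of interface residue types across training
#' complexes, with add-one (Laplace) smoothing so every standard type has
#' strictly positive probability.
#'
#' @param complexes List of two-subunit `vb_structure` objects.
#' @param cutoff Heavy-atom contact cutoff.
#' @return Named probability vector over the 20 standard residues.
#' @export
fit_aa_probs <- function(complexes, cutoff = 6.0) {
  counts <- stats::setNames(rep(1, length(.vb_standard_aa)), .vb_standard_aa)
  for (cx in complexes) {
    iface <- interface_residues(cx$subunits[[1]], cx$subunits[[2]], cutoff)
    types <- c(residue_types(cx$subunits[[1]])[match(iface$a, residue_keys(cx$subunits[[1]]))],
               residue_types(cx$subunits[[2]])[match(iface$b, residue_keys(cx$subunits[[2]]))])
    tb <- table(types)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts / sum(counts)
}

#' Linear combination of energy terms
#' @param values Numeric vector of term values.
#' @param coefficients Numeric vector of equal length.
#' @return The dot product.
#' @export
combine_energy <- function(values, coefficients) {
  if (length(values) != length(coefficients)) {
    vb_stop("combine", "length mismatch: %d values vs %d coefficients",
            length(values), length(coefficients))
  }
  sum(values * coefficients)
}

#' Fit term coefficients by least squares
#'
#' Regresses pose labels (e.g. interface RMSD, or a near-native indicator)
#' on the term design matrix; with noiseless linear labels the generating
#' coefficients are recovered exactly.
#'
#' @param terms Numeric matrix (poses x terms; column names kept).
#' @param labels Numeric vector, one label per pose.
#' @param intercept Include an intercept column (default FALSE).
#' @return List with `coefficients`, `fitted`, `residuals`, `sigma`.
#' @export
fit_coefficients <- function(terms, labels, intercept = FALSE) {
  X <- as.matrix(terms)
  if (nrow(X) < 2) vb_stop("fit_coefficients", "need at least 2 labeled poses")
  if (length(labels) != nrow(X)) vb_stop("fit_coefficients", "labels/poses length mismatch")
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    vb_stop("fit_coefficients", "rank-deficient design; dependent column(s): %s",
            paste(dep %||% "?", collapse = ", "))
  }
  beta <- qr.coef(qr_x, labels)
  fitted <- as.numeric(X %*% beta)
  res <- labels - fitted
  dof <- max(nrow(X) - ncol(X), 1)
  list(coefficients = beta, fitted = fitted, residuals = res,
       sigma = sqrt(sum(res^2) / dof))
}

#' Assemble an energy model
#'
#' @param terms Named list of term functions, each `function(pose)` (wrap
#'   any context such as a `vb_model` or `aa_probs` in a closure; see
#'   [term_neighborhood()] / [term_amino_acid()]).
#' @param coefficients Numeric vector, one per term (default all 1).
#' @return A `vb_energy_model`.
#' @export
energy_model <- function(terms, coefficients = rep(1, length(terms))) {
  stopifnot(is.list(terms), length(terms) >= 1, !is.null(names(terms)))
  if (length(coefficients) != length(terms)) {
    vb_stop("energy_model", "one coefficient per term required")
  }
  if (any(!is.finite(coefficients))) vb_stop("energy_model", "non-finite coefficients")
  structure(list(terms = terms, coefficients = coefficients),
            class = "vb_energy_model")
}

#' Built-in term: structural neighborhood energy
#' @param model Fitted `vb_model`.
#' @param ... Passed to [neighborhood_energy()].
#' @return A term function for [energy_model()].
#' @export
term_neighborhood <- function(model, ...) {
  force(model)
  function(pose) neighborhood_energy(pose, model, ...)
}

#' Built-in term: amino-acid composition energy
#' @param aa_probs Named interface probabilities (see [fit_aa_probs()]).
#' @param ... Passed to [amino_acid_energy()].
#' @return A term function for [energy_model()].
#' @export
term_amino_acid <- function(aa_probs, ...) {
  force(aa_probs)
  function(pose) amino_acid_energy(pose, aa_probs, ...)
}

#' Score one pose under an energy model
#' @param pose Two-subunit `vb_structure`.
#' @param emodel A `vb_energy_model`.
#' @return List with `terms` (named values) and `total`.
#' @export
score_pose <- function(pose, emodel) {
  vals <- vapply(emodel$terms, function(f) f(pose), numeric(1))
  list(terms = vals, total = combine_energy(vals, emodel$coefficients))
}

#' Rank poses by ascending total energy
#'
#' @param poses List of two-subunit `vb_structure` poses (named, or indexed
#'   by position).
#' @param emodel A `vb_energy_model`.
#' @param k Number of top poses to return (default all).
#' @return List with `ranking` (data.frame `pose_id`, term columns,
#'   `total`, sorted ascending, ties by input order) limited to `k` rows,
#'   and `failed` (data.frame `pose_id`, `error` for unscoreable poses).
#' @export
rank_poses <- function(poses, emodel, k = length(poses)) {
  ids <- names(poses) %||% as.character(seq_along(poses))
  if (is.null(names(poses))) names(poses) <- ids
  rows <- list()
  failed <- list()
  for (id in ids) {
    sc <- tryCatch(score_pose(poses[[id]], emodel), error = function(e) e)
    if (inherits(sc, "error")) {
      failed[[id]] <- conditionMessage(sc)
    } else {
      rows[[id]] <- c(sc$terms, total = sc$total)
    }
  }
  if (length(rows) == 0) vb_stop("rank_poses", "no scoreable poses")
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(pose_id = names(rows), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab <- tab[order(tab$total), , drop = FALSE]  # stable: ties keep input order
  if (k > nrow(tab)) {
    warning(sprintf("k = %d exceeds %d scoreable poses; returning all", k, nrow(tab)))
    k <- nrow(tab)
  }
  failed_df <- data.frame(pose_id = names(failed),
                          error = unlist(failed) %||% character(0),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(ranking = head(tab, k), failed = failed_df)
}
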