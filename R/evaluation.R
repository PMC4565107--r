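#' CAPRI-style evaluation of interface predictions and docked poses
#'
#' Residue-residue contacts for evaluation use the any-atom rule: two
#' residues across the interface are in contact when any of their atoms are
#' within 6 Angstroms (inclusive). Note the deliberate asymmetry with the
#' training-side definition, which uses heavy atoms and a strict
#' inequality; both knobs are exposed.
#'
#' @name evaluation
#' @keywords internal
NULL

#' Evaluation contacts between two subunits
#'
#' @param sub_a,sub_b Subunits (or structures; first two subunits used).
#' @param cutoff Distance cutoff in Angstroms (default 6, inclusive).
#' @param heavy_only Restrict to heavy atoms (default FALSE: any atom).
#' @param inclusive Use `<=` (default TRUE) rather than strict `<`.
#' @return Data frame `res_a`, `res_b`, `min_dist`.
#' @export
eval_contacts <- function(sub_a, sub_b, cutoff = 6.0, heavy_only = FALSE,
                          inclusive = TRUE) {
  sub_a <- as_subunit(sub_a, 1)
  sub_b <- as_subunit(sub_b, 2)
  a <- sub_coords(sub_a, heavy_only = heavy_only)
  b <- sub_coords(sub_b, heavy_only = heavy_only)
  d2 <- pair_dist2(a$xyz, b$xyz)
  hit <- if (inclusive) which(d2 <= cutoff^2, arr.ind = TRUE) else
    which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(res_a = character(), res_b = character(), min_dist = numeric()))
  }
  grp <- paste(a$reskey[hit[, 1]], b$reskey[hit[, 2]], sep = "\r")
  mind <- tapply(sqrt(d2[hit]), grp, min)
  parts <- do.call(rbind, strsplit(names(mind), "\r", fixed = TRUE))
  out <- data.frame(res_a = parts[, 1], res_b = parts[, 2],
                    min_dist = as.numeric(mind), stringsAsFactors = FALSE)
  out[order(out$res_a, out$res_b, method = "radix"), , drop = FALSE]
}

contact_key <- function(contacts) paste(contacts$res_a, contacts$res_b, sep = "|")

#' Fraction of native contacts recovered
#'
#' @param pred_contacts,native_contacts Contact sets: data frames with
#'   `res_a`/`res_b` (e.g. from [eval_contacts()]) or character vectors of
#'   pair keys.
#' @return `|pred intersect native| / |native|`.
#' @export
fnat <- function(pred_contacts, native_contacts) {
  p <- if (is.character(pred_contacts)) pred_contacts else contact_key(pred_contacts)
  n <- if (is.character(native_contacts)) native_contacts else contact_key(native_contacts)
  n <- unique(n); p <- unique(p)
  if (length(n) == 0) vb_stop("fnat", "native contact set is empty")
  length(intersect(p, n)) / length(n)
}

#' Fraction of non-native contacts among predictions
#'
#' @inheritParams fnat
#' @return `|pred \\ native| / |pred|`.
#' @export
fnonnat <- function(pred_contacts, native_contacts) {
  p <- if (is.character(pred_contacts)) pred_contacts else contact_key(pred_contacts)
  n <- if (is.character(native_contacts)) native_contacts else contact_key(native_contacts)
  n <- unique(n); p <- unique(p)
  if (length(p) == 0) vb_stop("fnonnat", "predicted contact set is empty")
  length(setdiff(p, n)) / length(p)
}

.vb_backbone <- c("N", "CA", "C", "O")

# backbone atoms of the given residue keys, in deterministic
# (reskey, backbone-order) order; returns coords + ids
backbone_atoms <- function(sub, keys) {
  s <- sub[sub$reskey %in% keys & sub$elety %in% .vb_backbone & sub$is_heavy, , drop = FALSE]
  s <- s[order(match(s$reskey, keys), match(s$elety, .vb_backbone)), , drop = FALSE]
  list(xyz = cbind(s$x, s$y, s$z), id = paste(s$reskey, s$elety))
}

#' Interface RMSD between a predicted and native complex
#'
#' Interface residues are defined on the native complex at the evaluation
#' contact cutoff; their backbone atoms (N, CA, C, O) are collected from
#' both structures, matched by residue key and atom name,
#' Kabsch-superposed, and the minimized RMSD returned. Residues missing a
#' backbone O are tolerated with a warning; a native interface residue
#' absent from the prediction is an error.
#'
#' @param pred,native Two-subunit `vb_structure`s with matching residue
#'   numbering.
#' @param cutoff Native interface contact cutoff (default 6, any-atom,
#'   inclusive).
#' @return Interface RMSD in Angstroms.
#' @export
irmsd <- function(pred, native, cutoff = 6.0) {
  if (length(native$subunits) < 2 || length(pred$subunits) < 2) {
    vb_stop("irmsd", "both complexes need two subunits")
  }
  iface <- eval_contacts(native$subunits[[1]], native$subunits[[2]], cutoff)
  keys_a <- unique(iface$res_a)
  keys_b <- unique(iface$res_b)
  if (length(keys_a) + length(keys_b) == 0) vb_stop("irmsd", "native has no interface")
  nat <- list(backbone_atoms(native$subunits[[1]], keys_a),
              backbone_atoms(native$subunits[[2]], keys_b))
  prd <- list(backbone_atoms(pred$subunits[[1]], keys_a),
              backbone_atoms(pred$subunits[[2]], keys_b))
  nat_id <- c(nat[[1]]$id, nat[[2]]$id)
  prd_id <- c(prd[[1]]$id, prd[[2]]$id)
  missing <- setdiff(nat_id, prd_id)
  miss_res <- unique(sub(" [A-Z]+$", "", missing))
  # a residue entirely absent is an error; a missing O alone is tolerated
  fully_missing <- miss_res[!vapply(miss_res, function(r) any(grepl(paste0("^", r, " CA$"), prd_id)), logical(1))]
  if (length(fully_missing)) {
    vb_stop("irmsd", "interface residue(s) missing from prediction: %s",
            paste(fully_missing, collapse = ", "))
  }
  if (length(missing)) {
    warning(sprintf("backbone atom(s) missing from prediction, skipped: %s",
                    paste(missing, collapse = ", ")))
  }
  common <- intersect(nat_id, prd_id)
  if (length(common) < 3) vb_stop("irmsd", "fewer than 3 matched backbone atoms")
  nat_xyz <- rbind(nat[[1]]$xyz, nat[[2]]$xyz)[match(common, nat_id), , drop = FALSE]
  prd_xyz <- rbind(prd[[1]]$xyz, prd[[2]]$xyz)[match(common, prd_id), , drop = FALSE]
  superpose(nat_xyz, prd_xyz)$rmsd
}

#' Binding-site prediction P-value
#'
#' Probability of obtaining at least `n` correctly predicted interface
#' residues when picking `N` surface residues at random, with per-trial
#' success probability q = m/M (m true interface residues among the M
#' surface residues): the binomial upper tail
#' \deqn{p = \sum_{i=n}^{N} \binom{N}{i} q^i (1-q)^{N-i}}
#' computed in log space for numerical stability.
#'
#' @param n Correctly predicted interface residues (0 <= n <= N, n <= m).
#' @param N Predicted interface residues.
#' @param m True interface residues among the surface residues.
#' @param M All surface residues (N <= M).
#' @return The P-value in (0, 1].
#' @export
binding_site_pvalue <- function(n, N, m, M) {
  if (n < 0 || N < 0 || m < 0 || M <= 0 || n > N || m > M || n > m || N > M) {
    vb_stop("pvalue", "invalid counts: need 0 <= n <= N <= M, n <= m <= M")
  }
  q <- m / M
  if (q < 0 || q > 1) vb_stop("pvalue", "q = m/M out of [0, 1]")
  if (n == 0) return(1)
  if (q == 1) return(1)
  i <- n:N
  lg <- lchoose(N, i) + i * log(q) + (N - i) * log1p(-q)
  mx <- max(lg)
  exp(mx + log(sum(exp(lg - mx))))
}

#' CAPRI metrics of a predicted complex against the native
#'
#' @param pred,native Two-subunit `vb_structure`s.
#' @param cutoff Evaluation contact cutoff (default 6).
#' @return List with `f_nat`, `f_nonnat`, `i_rmsd`.
#' @export
capri_metrics <- function(pred, native, cutoff = 6.0) {
  nat_ct <- eval_contacts(native$subunits[[1]], native$subunits[[2]], cutoff)
  prd_ct <- eval_contacts(pred$subunits[[1]], pred$subunits[[2]], cutoff)
  f_nat <- fnat(prd_ct, nat_ct)
  f_nonnat <- if (nrow(prd_ct)) fnonnat(prd_ct, nat_ct) else NA_real_
  list(f_nat = f_nat, f_nonnat = f_nonnat, i_rmsd = irmsd(pred, native, cutoff))
}
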