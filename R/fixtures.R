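#' Deterministic synthetic fixtures
#'
#' Generators for all test inputs: jittered lattices of weighted sites for
#' the tessellation, toy two-chain complexes with a planted interface,
#' property-pair samples from planted bivariate normals, and perturbed pose
#' sets. Every generator is a pure function of its parameters and seed.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

#' Jittered cubic-lattice weighted sites
#'
#' @param n_atoms Number of sites (>= 1).
#' @param spacing Lattice spacing in Angstroms (> 0, default 3).
#' @param jitter Uniform jitter half-width per coordinate (must stay below
#'   `spacing / 2` to rule out coincident centers).
#' @param seed Integer seed.
#' @param elements Element cycle assigning van der Waals weights.
#' @return Weighted-site data.frame (`x`, `y`, `z`, `weight`, `reskey`,
#'   `atom`) suitable for [build_tessellation()]. Each site is its own
#'   single-atom pseudo-residue.
#' @export
make_lattice_atoms <- function(n_atoms, spacing = 3.0, jitter = 0.0, seed = 1,
                               elements = c("C", "N", "O", "S")) {
  if (n_atoms < 1) vb_stop("fixtures", "n_atoms must be >= 1")
  if (spacing <= 0) vb_stop("fixtures", "spacing must be > 0")
  if (jitter >= spacing / 2) {
    vb_stop("fixtures", "jitter (%.3f) must be < spacing/2 (%.3f): collision risk",
            jitter, spacing / 2)
  }
  k <- ceiling(n_atoms^(1 / 3))
  grid <- expand.grid(ix = 0:(k - 1), iy = 0:(k - 1), iz = 0:(k - 1))
  grid <- grid[seq_len(n_atoms), , drop = FALSE]
  set.seed(seed)
  jit <- matrix(runif(3 * n_atoms, -jitter, jitter), ncol = 3)
  el <- rep_len(elements, n_atoms)
  r <- .vb_vdw_radii[el]
  r[is.na(r)] <- .vb_vdw_default
  data.frame(
    x = grid$ix * spacing + jit[, 1],
    y = grid$iy * spacing + jit[, 2],
    z = grid$iz * spacing + jit[, 3],
    weight = as.numeric(r)^2,
    reskey = paste0("X:", seq_len(n_atoms)),
    atom = el, stringsAsFactors = FALSE
  )
}

# idealized 5-atom pseudo-residue template (N, CA, C, O, CB), ~2 A radius
.vb_res_template <- data.frame(
  elety = c("N", "CA", "C", "O", "CB"),
  elesy = c("N", "C", "C", "O", "C"),
  x = c(-1.20, 0.00, 1.20, 1.30, 0.00),
  y = c(0.50, 0.00, 0.50, 1.70, -1.00),
  z = c(0.00, 0.00, 0.00, 0.20, 1.10)
)

# assemble a vb_subunit from per-residue placements
build_chain <- function(chain, origins, types, jitter_mat = NULL) {
  n <- nrow(origins)
  tpl <- .vb_res_template
  rows <- lapply(seq_len(n), function(i) {
    off <- if (is.null(jitter_mat)) c(0, 0, 0) else jitter_mat[i, ]
    data.frame(
      chain = chain, resno = i, insert = "", resid = types[i],
      elety = tpl$elety, elesy = tpl$elesy,
      x = tpl$x + origins[i, 1] + off[1],
      y = tpl$y + origins[i, 2] + off[2],
      z = tpl$z + origins[i, 3] + off[3],
      is_heavy = TRUE, stringsAsFactors = FALSE
    )
  })
  sub <- do.call(rbind, rows)
  sub$reskey <- vb_reskey(sub$chain, sub$resno, sub$insert)
  class(sub) <- c("vb_subunit", "data.frame")
  attr(sub, "id") <- chain
  sub
}

#' Toy two-chain complex with a planted interface
#'
#' Two pseudo-residue chains (5 heavy atoms per residue, idealized internal
#' geometry) are laid out on parallel lines with a 9.5 Angstrom residue
#' spacing -- close enough that consecutive C-alpha atoms fall inside the
#' default 10 A patch-graph radius -- with chain B a `gap` away in y.
#' A contiguous block of `n_contact_pairs` residue pairs is brought within
#' heavy-atom contact (< 6 A, matching realistic interfaces being spatially
#' contiguous patches) while every other cross pair stays beyond 8 A; the
#' construction is verified against [heavy_atom_contacts()] and errors if
#' the geometry is infeasible.
#'
#' By default residues of a planted pair share the same randomly drawn
#' residue type (from a hydrophobicity-spread set), which plants a positive
#' association between the two sides' properties; non-interface residues
#' draw independently from the background composition.
#'
#' @param n_res_a,n_res_b Residues per chain.
#' @param n_contact_pairs Planted contact pairs
#'   (<= min(n_res_a, n_res_b)).
#' @param gap Separation of the non-contacting parts in Angstroms
#'   (default 20; must be > 8 + contact offset).
#' @param seed Integer seed.
#' @param interface_types Types drawn for planted pairs.
#' @param background_types Types drawn for the remaining residues.
#' @param match_types Give both members of a planted pair the same type
#'   (default TRUE).
#' @param jitter Small positional jitter (Angstroms, default 0.2).
#' @return List with `complex` (two-subunit `vb_structure`, chains A and
#'   B), `planted` (data.frame `res_a`, `res_b` of planted contact pairs).
#' @export
make_toy_complex <- function(n_res_a = 20, n_res_b = 20, n_contact_pairs = 5,
                             gap = 20, seed = 1,
                             interface_types = c("ILE", "LEU", "VAL", "PHE",
                                                 "ALA", "ARG", "ASP", "TRP"),
                             background_types = rownames(.vb_feature_table),
                             match_types = TRUE, jitter = 0.2) {
  if (n_contact_pairs > min(n_res_a, n_res_b)) {
    vb_stop("fixtures", "n_contact_pairs exceeds min(n_res_a, n_res_b)")
  }
  if (gap < 14) vb_stop("fixtures", "gap must be >= 14 A to keep decoys beyond 8 A")
  set.seed(seed)
  spacing <- 9.5
  contact_dy <- 7.6

  # contiguous planted blocks (interfaces are contiguous patches)
  ia <- if (n_contact_pairs > 0)
    sample.int(n_res_a - n_contact_pairs + 1, 1) + seq_len(n_contact_pairs) - 1 else integer(0)
  ib <- if (n_contact_pairs > 0)
    sample.int(n_res_b - n_contact_pairs + 1, 1) + seq_len(n_contact_pairs) - 1 else integer(0)

  org_a <- cbind((seq_len(n_res_a) - 1) * spacing, 0, 0)
  org_b <- cbind((seq_len(n_res_b) - 1) * spacing + spacing / 2, gap, 0)
  # planted pairs: move the B partner directly opposite its A partner
  org_b[ib, 1] <- org_a[ia, 1]
  org_b[ib, 2] <- contact_dy

  types_a <- sample(background_types, n_res_a, replace = TRUE)
  types_b <- sample(background_types, n_res_b, replace = TRUE)
  iface_draw <- sample(interface_types, n_contact_pairs, replace = TRUE)
  types_a[ia] <- iface_draw
  types_b[ib] <- if (match_types) iface_draw else
    sample(interface_types, n_contact_pairs, replace = TRUE)

  jit <- function(n) matrix(runif(3 * n, -jitter, jitter), ncol = 3)
  sub_a <- build_chain("A", org_a, types_a, jit(n_res_a))
  sub_b <- build_chain("B", org_b, types_b, jit(n_res_b))
  cx <- structure(list(subunits = list(A = sub_a, B = sub_b)),
                  class = "vb_structure")

  planted <- if (n_contact_pairs > 0) {
    data.frame(res_a = paste0("A:", ia), res_b = paste0("B:", ib),
               stringsAsFactors = FALSE)
  } else {
    data.frame(res_a = character(0), res_b = character(0),
               stringsAsFactors = FALSE)
  }
  got <- heavy_atom_contacts(sub_a, sub_b, 6.0)
  if (!setequal(contact_key(got), contact_key(planted))) {
    vb_stop("fixtures", "infeasible geometry: realized contacts differ from planted set")
  }
  list(complex = cx, planted = planted)
}

#' Sample property pairs from a planted bivariate normal
#'
#' Draws `n` correlated pairs from N(mu, Sigma) plus `n` independent decoy
#' pairs from the product of the marginals.
#'
#' @param mu Length-2 mean.
#' @param sigma Length-2 standard deviations (> 0).
#' @param rho Correlation in (-1, 1).
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return List with matrices `pairs` and `decoys` (n x 2 each).
#' @export
sample_property_pairs <- function(mu, sigma, rho, n, seed = 1) {
  if (n < 1) vb_stop("fixtures", "n must be >= 1")
  if (any(sigma <= 0) || abs(rho) >= 1) {
    vb_stop("fixtures", "covariance not positive definite")
  }
  Sigma <- matrix(c(sigma[1]^2, rho * sigma[1] * sigma[2],
                    rho * sigma[1] * sigma[2], sigma[2]^2), 2, 2)
  set.seed(seed)
  pairs <- MASS::mvrnorm(n, mu, Sigma)
  decoys <- cbind(rnorm(n, mu[1], sigma[1]), rnorm(n, mu[2], sigma[2]))
  if (n == 1) pairs <- matrix(pairs, 1, 2)
  colnames(pairs) <- colnames(decoys) <- c("x1", "x2")
  list(pairs = pairs, decoys = decoys)
}

# rigid motion of a subunit: rotate by `angle` (radians) about random axis
# through its centroid, then translate
perturb_subunit <- function(sub, angle, translation) {
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  cen <- colMeans(xyz)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)  # Rodrigues
  new <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + translation, "+")
  sub$x <- new[, 1]; sub$y <- new[, 2]; sub$z <- new[, 3]
  sub
}

#' Synthetic pose set around a native toy complex
#'
#' Near-native poses apply small rigid perturbations to subunit B; far
#' poses apply large rotations and translations that break the interface.
#' Labels carry the true interface RMSD of each pose, computed with
#' [irmsd()] against the native.
#'
#' @param native Two-subunit `vb_structure`.
#' @param n_near,n_far Pose counts.
#' @param near_angle,near_trans Maximum near perturbation (radians,
#'   Angstroms); defaults 0.05 rad (~3 degrees) and 0.5 A.
#' @param far_angle,far_trans Far perturbation ranges; defaults up to pi
#'   and 25-40 A.
#' @param seed Integer seed.
#' @return List with `poses` (named list of `vb_structure`s) and `labels`
#'   (data.frame `pose_id`, `kind`, `i_rmsd`).
#' @export
make_pose_set <- function(native, n_near = 5, n_far = 5,
                          near_angle = 0.05, near_trans = 0.5,
                          far_angle = pi, far_trans = c(25, 40), seed = 1) {
  if (near_angle > far_angle || near_trans > max(far_trans)) {
    vb_stop("fixtures", "near perturbation scales must not exceed far scales")
  }
  set.seed(seed)
  poses <- list()
  labels <- list()
  mk <- function(kind, i, angle, trans) {
    sub_b <- perturb_subunit(native$subunits[[2]], angle, trans)
    pose <- native
    pose$subunits[[2]] <- sub_b
    id <- sprintf("%s_%02d", kind, i)
    poses[[id]] <<- pose
    labels[[id]] <<- data.frame(pose_id = id, kind = kind,
                                i_rmsd = irmsd(pose, native),
                                stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_near)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    mk("near", i, runif(1, 0, near_angle), runif(1, 0, near_trans) * dir)
  }
  for (i in seq_len(n_far)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    mk("far", i, runif(1, far_angle / 2, far_angle),
       runif(1, far_trans[1], far_trans[2]) * dir)
  }
  list(poses = poses, labels = do.call(rbind, c(labels, list(make.row.names = FALSE))))
}

#' Write a structure as PDB text
#'
#' @param x A `vb_structure` or `vb_subunit`.
#' @param path Output path; `NULL` returns the lines invisibly.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(x, path = NULL) {
  subs <- if (inherits(x, "vb_structure")) x$subunits else list(x)
  serial <- 0
  lines <- character(0)
  for (s in subs) {
    for (i in seq_len(nrow(s))) {
      serial <- serial + 1
      name <- s$elety[i]
      name4 <- if (nchar(name) <= 3) sprintf(" %-3s", name) else name
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name4, s$resid[i], s$chain[i], s$resno[i],
        ifelse(s$insert[i] == "", " ", s$insert[i]),
        s$x[i], s$y[i], s$z[i], 1.0, 0.0, s$elesy[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
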