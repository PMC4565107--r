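#' Weighted Voronoi (power/Laguerre) tessellation of heavy atoms
#'
#' Heavy atoms are treated as weighted sites of a power diagram: the cell of
#' site i is the set of points p with |p - c_i|^2 - w_i minimal, where the
#' weight w_i is the squared van der Waals radius. Cells are clipped to an
#' axis-aligned bounding box expanded by `padding`, so they tile the box
#' exactly; faces against the box count as solvent-exposed surface.
#'
#' @name tessellation
#' @keywords internal
NULL

# van der Waals radii (Angstroms) used as sqrt(weights); editable via the
# `radii` argument of structure_sites()
.vb_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vb_vdw_default <- 1.70

#' Weighted sites from a structure's heavy atoms
#'
#' @param x A `vb_structure` or `vb_subunit`.
#' @param radii Named vector of van der Waals radii per element (Angstroms);
#'   elements not listed fall back to the carbon-like default 1.70.
#' @return A data.frame of weighted sites: `x`, `y`, `z`, `weight`
#'   (squared radius, Angstrom^2), `reskey`, `atom`.
#' @export
structure_sites <- function(x, radii = .vb_vdw_radii) {
  subs <- if (inherits(x, "vb_structure")) x$subunits else list(as_subunit(x))
  at <- do.call(rbind, lapply(subs, function(s) {
    s[s$is_heavy, c("x", "y", "z", "elesy", "reskey", "elety"), drop = FALSE]
  }))
  r <- radii[at$elesy]
  r[is.na(r)] <- .vb_vdw_default
  data.frame(x = at$x, y = at$y, z = at$z, weight = as.numeric(r)^2,
             reskey = at$reskey, atom = at$elety,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the box-clipped power diagram of a set of weighted sites
#'
#' @param sites Data frame with columns `x`, `y`, `z`, `weight` (and
#'   optionally `reskey`, `atom` for downstream aggregation), e.g. from
#'   [structure_sites()] or [make_lattice_atoms()].
#' @param padding Bounding-box expansion beyond the extreme site
#'   coordinates, in Angstroms (default 5).
#' @param box Optional explicit box `c(xlo, xhi, ylo, yhi, zlo, zhi)`
#'   overriding the padded bounding box; must contain all sites.
#' @return A `vb_tessellation`: list with `sites`, `box`, `volumes`
#'   (per-cell, Angstrom^3) and `faces`, a data.frame with columns `site`
#'   (cell index), `neighbor` (site index, or `NA` for a box/boundary face)
#'   and `area` (Angstrom^2).
#' @export
build_tessellation <- function(sites, padding = 5.0, box = NULL) {
  sites <- as.data.frame(sites)
  if (nrow(sites) < 1) vb_stop("tessellation", "need at least one site")
  if (any(!is.finite(sites$weight)) || any(sites$weight <= 0)) {
    vb_stop("tessellation", "all site weights must be positive")
  }
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) vb_stop("tessellation", "non-finite site coordinates")
  dup <- duplicated(round(xyz, 9))
  if (any(dup)) {
    vb_stop("tessellation", "duplicate site centers (first at row %d)", which(dup)[1])
  }
  if (is.null(box)) {
    box <- as.numeric(rbind(apply(xyz, 2, min) - padding,
                            apply(xyz, 2, max) + padding))
  } else {
    box <- as.numeric(box)
    inside <- xyz[, 1] >= box[1] & xyz[, 1] <= box[2] &
      xyz[, 2] >= box[3] & xyz[, 2] <= box[4] &
      xyz[, 3] >= box[5] & xyz[, 3] <= box[6]
    if (!all(inside)) vb_stop("tessellation", "explicit box does not contain all sites")
  }
  cells <- power_cells_cpp(xyz, as.numeric(sites$weight), box)
  volumes <- vapply(cells, function(cl) cl$volume, numeric(1))
  faces <- do.call(rbind, lapply(seq_along(cells), function(i) {
    nb <- cells[[i]]$neighbor
    if (length(nb) == 0) return(NULL)
    data.frame(site = i, neighbor = ifelse(nb > 0, nb, NA_integer_),
               area = cells[[i]]$area)
  }))
  if (is.null(faces)) {
    faces <- data.frame(site = integer(), neighbor = integer(), area = numeric())
  }
  structure(list(sites = sites, box = box, volumes = volumes, faces = faces),
            class = "vb_tessellation")
}

#' @export
print.vb_tessellation <- function(x, ...) {
  cat(sprintf("vb_tessellation: %d sites, %d faces, box volume %.2f A^3\n",
              nrow(x$sites), nrow(x$faces), prod(x$box[c(2, 4, 6)] - x$box[c(1, 3, 5)])))
  invisible(x)
}

#' Aggregate a tessellation into per-residue areas
#'
#' For every residue: `total` is the summed area of its atoms' faces against
#' atoms of *other* residues plus the boundary (intra-residue faces are
#' internal bookkeeping and excluded); `surface` is the part facing the
#' box/solvent boundary; `contact` is split by partner residue. The identity
#' `surface + sum(contact) == total` holds by construction and is verified.
#'
#' @param tess A `vb_tessellation` whose sites carry a `reskey` column.
#' @param structure Optional `vb_structure`/`vb_subunit` used to attach
#'   residue types; every site owner must resolve to one of its residues.
#' @param area_tol Faces smaller than this (Angstrom^2) are treated as zero
#'   contact (default 1e-9).
#' @return A `vb_areas`: list with `residues` (data.frame `reskey`,
#'   `res_type`, `total`, `surface`, `ratio`) and `contacts` (data.frame
#'   `res_a`, `res_b`, `area`; both orders present, symmetric).
#' @export
residue_areas <- function(tess, structure = NULL, area_tol = 1e-9) {
  sites <- tess$sites
  if (is.null(sites$reskey)) vb_stop("residue_areas", "sites carry no residue keys")
  keys <- unique(sites$reskey)
  res_type <- rep(NA_character_, length(keys))
  if (!is.null(structure)) {
    subs <- if (inherits(structure, "vb_structure")) structure$subunits else list(structure)
    all_res <- do.call(rbind, lapply(subs, function(s) s[!duplicated(s$reskey), c("reskey", "resid")]))
    orphan <- setdiff(keys, all_res$reskey)
    if (length(orphan)) {
      vb_stop("residue_areas", "site owner(s) not in structure: %s",
              paste(orphan, collapse = ", "))
    }
    res_type <- all_res$resid[match(keys, all_res$reskey)]
  }

  f <- tess$faces
  owner <- sites$reskey[f$site]
  partner <- ifelse(is.na(f$neighbor), NA_character_, sites$reskey[f$neighbor])

  boundary <- is.na(partner)
  inter <- !boundary & owner != partner
  surface <- tapply(f$area[boundary], factor(owner[boundary], levels = keys), sum)
  surface[is.na(surface)] <- 0
  ct_area <- numeric(0)
  contacts <- data.frame(res_a = character(), res_b = character(), area = numeric())
  if (any(inter)) {
    grp <- paste(owner[inter], partner[inter], sep = "\r")
    ct <- tapply(f$area[inter], grp, sum)
    parts <- do.call(rbind, strsplit(names(ct), "\r", fixed = TRUE))
    contacts <- data.frame(res_a = parts[, 1], res_b = parts[, 2],
                           area = as.numeric(ct), stringsAsFactors = FALSE)
    contacts <- contacts[contacts$area > area_tol, , drop = FALSE]
    contacts <- contacts[order(match(contacts$res_a, keys), match(contacts$res_b, keys)), ]
    rownames(contacts) <- NULL
  }
  # total is summed directly over boundary + inter-residue faces (no contact
  # tolerance applied), so the surface + sum(contact) identity is a genuine
  # cross-check, not a tautology
  ext <- boundary | inter
  total <- tapply(f$area[ext], factor(owner[ext], levels = keys), sum)
  total[is.na(total)] <- 0
  total <- as.numeric(total)
  ratio <- ifelse(total > 0, as.numeric(surface) / total, 0)
  res <- data.frame(reskey = keys, res_type = res_type,
                    total = total, surface = as.numeric(surface), ratio = ratio,
                    stringsAsFactors = FALSE)
  structure(list(residues = res, contacts = contacts, area_tol = area_tol),
            class = "vb_areas")
}

#' Contact-area neighbors of a residue
#' @param areas A `vb_areas` object.
#' @param key Residue key.
#' @return Data frame of partners (`res_b`) and contact areas.
#' @export
area_neighbors <- function(areas, key) {
  areas$contacts[areas$contacts$res_a == key, c("res_b", "area"), drop = FALSE]
}

#' Write per-residue and contact areas as TSV
#' @param areas A `vb_areas` object.
#' @param residues_path,contacts_path Output paths (either may be `NULL`).
#' @param header Optional comment lines.
#' @export
write_areas_tsv <- function(areas, residues_path = NULL, contacts_path = NULL,
                            header = NULL) {
  if (!is.null(residues_path)) {
    r <- areas$residues
    out <- data.frame(chain = sub(":.*$", "", r$reskey),
                      resid = sub("^[^:]*:", "", r$reskey),
                      res_type = r$res_type,
                      total_A2 = round(r$total, 4),
                      surface_A2 = round(r$surface, 4))
    vb_write_tsv(out, residues_path, header)
  }
  if (!is.null(contacts_path)) {
    ct <- areas$contacts
    out <- data.frame(chain_a = sub(":.*$", "", ct$res_a),
                      resid_a = sub("^[^:]*:", "", ct$res_a),
                      chain_b = sub(":.*$", "", ct$res_b),
                      resid_b = sub("^[^:]*:", "", ct$res_b),
                      area_A2 = round(ct$area, 4))
    vb_write_tsv(out, contacts_path, header)
  }
  invisible(NULL)
}

#' Monte-Carlo oracle for power-diagram volumes and face areas
#'
#' Independent stochastic estimate used to validate the analytic
#' tessellation: cell volumes by uniform-point assignment to the site of
#' minimal power distance; face areas by counting samples within a thin slab
#' of half-width `delta` around the radical plane of the two nearest sites,
#' scaled by the slab thickness.
#'
#' @param sites Data frame with `x`, `y`, `z`, `weight`.
#' @param box Bounding box `c(xlo, xhi, ylo, yhi, zlo, zhi)`.
#' @param n_samples Number of uniform samples (>= 1e5).
#' @param seed Integer RNG seed.
#' @param delta Slab half-width in Angstroms (default 0.05).
#' @param chunk Samples per vectorized block.
#' @return List with `volumes`, `volume_se`, and `faces` (data.frame
#'   `site_i`, `site_j`, `area`, `se`; `site_i < site_j`).
#' @export
mc_area_oracle <- function(sites, box, n_samples = 1e6, seed = 1,
                           delta = 0.05, chunk = 2e5) {
  if (n_samples < 1e5) vb_stop("mc_oracle", "n_samples must be >= 1e5")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  w <- as.numeric(sites$weight)
  n <- nrow(xyz)
  vol_box <- prod(box[c(2, 4, 6)] - box[c(1, 3, 5)])
  counts <- numeric(n)
  slab_counts <- new.env(parent = emptyenv())
  done <- 0
  set.seed(seed)
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    p <- cbind(runif(m, box[1], box[2]), runif(m, box[3], box[4]),
               runif(m, box[5], box[6]))
    pw <- pair_dist2(p, xyz)
    pw <- sweep(pw, 2, w)  # power distances
    if (n == 1) {
      counts[1] <- counts[1] + m
    } else {
      ord1 <- max.col(-pw, ties.method = "first")
      counts <- counts + tabulate(ord1, nbins = n)
      # second-smallest power and its site
      pw2 <- pw
      pw2[cbind(seq_len(m), ord1)] <- Inf
      ord2 <- max.col(-pw2, ties.method = "first")
      gap <- pw2[cbind(seq_len(m), ord2)] - pw[cbind(seq_len(m), ord1)]
      # spatial distance from p to the radical plane of sites (ord1, ord2)
      cc <- sqrt(rowSums((xyz[ord1, , drop = FALSE] - xyz[ord2, , drop = FALSE])^2))
      dist_plane <- gap / (2 * cc)
      in_slab <- dist_plane <= delta
      if (any(in_slab)) {
        i <- pmin(ord1[in_slab], ord2[in_slab])
        j <- pmax(ord1[in_slab], ord2[in_slab])
        key <- paste(i, j, sep = "_")
        for (k in unique(key)) {
          cur <- get0(k, envir = slab_counts, ifnotfound = 0)
          assign(k, cur + sum(key == k), envir = slab_counts)
        }
      }
    }
    done <- done + m
  }
  frac <- counts / n_samples
  vol <- frac * vol_box
  vol_se <- sqrt(frac * (1 - frac) / n_samples) * vol_box
  keys <- ls(slab_counts)
  faces <- if (length(keys)) {
    cnt <- vapply(keys, function(k) get(k, envir = slab_counts), numeric(1))
    ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    fr <- cnt / n_samples
    data.frame(site_i = as.integer(ij[, 1]), site_j = as.integer(ij[, 2]),
               area = fr * vol_box / (2 * delta),
               se = sqrt(fr * (1 - fr) / n_samples) * vol_box / (2 * delta))
  } else {
    data.frame(site_i = integer(), site_j = integer(), area = numeric(), se = numeric())
  }
  list(volumes = vol, volume_se = vol_se, faces = faces)
}
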