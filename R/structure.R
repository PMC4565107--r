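#' Molecular structure model
#'
#' A `vb_structure` is a light hierarchical model of a (multi-chain) protein:
#' a named list of subunits, one per chain, each holding a flat atom table
#' (one row per atom) in the style of bio3d. Residues are addressed by a
#' *residue key* `"<chain>:<resno><insert>"` (e.g. `"A:52"` or `"A:52A"`),
#' which is unique within a structure and preserves author numbering and
#' insertion codes verbatim.
#'
#' @name vb_structure
#' @keywords internal
NULL

# Non-standard residues mapped to standard parents; unmapped non-standard
# residues are excluded with a warning.
.vb_nonstandard_map <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", CSO = "CYS", MLY = "LYS", M3L = "LYS"
)

.vb_standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.vb_water <- c("HOH", "DOD", "WAT")

vb_reskey <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

#' Read a protein structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only) into a [vb_structure]: one
#' subunit per selected chain. Waters and HETATM ligands are excluded;
#' a small table of common modified residues (MSE, SEP, ...) is mapped to
#' standard parents, and remaining non-standard residues are dropped with a
#' warning. Hydrogens are retained but flagged (`is_heavy = FALSE`); they
#' never enter contact or tessellation computations. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier, so 'A' wins).
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines
#'   (a single string with embedded newlines also works).
#' @param chains Optional character vector of chain identifiers to keep.
#'   Must be a subset of the chains present.
#' @return A `vb_structure`: named list of subunits. Each subunit is a
#'   data.frame with columns `chain`, `resno`, `insert`, `resid` (3-letter
#'   type), `elety` (atom name), `elesy` (element), `x`, `y`, `z`,
#'   `is_heavy`, `reskey`.
#' @export
read_structure <- function(pdb, chains = NULL) {
  lines <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  if (length(lines) == 0) vb_stop("read_structure", "empty PDB input")

  # first model only
  mdl <- grep("^MODEL", lines)
  if (length(mdl) >= 2) {
    endm <- grep("^ENDMDL", lines)
    stop_at <- if (length(endm)) endm[1] else mdl[2] - 1
    lines <- lines[seq_len(stop_at)]
  }

  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) vb_stop("read_structure", "no ATOM/HETATM records found")
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad)) {
    vb_stop("read_structure", "malformed (truncated) record at line %d: '%s'",
            bad[1], lines[bad[1]])
  }
  coords_txt <- substr(lines[rec], 31, 54)
  num_ok <- grepl("^[-+ .0-9]{24}$", coords_txt)
  if (!all(num_ok)) {
    ln <- which(rec)[which(!num_ok)[1]]
    vb_stop("read_structure", "non-numeric coordinates at line %d: '%s'",
            ln, lines[ln])
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  at <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)$atom

  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # drop waters; map or drop non-standard residues
  at <- at[!(at$resid %in% .vb_water), , drop = FALSE]
  is_het <- at$type == "HETATM"
  mapped <- at$resid %in% names(.vb_nonstandard_map)
  at$resid[mapped] <- .vb_nonstandard_map[at$resid[mapped]]
  keep <- at$resid %in% .vb_standard_aa
  if (any(!keep & !is_het)) {
    dropped <- unique(at$resid[!keep & !is_het])
    warning(sprintf("excluding unmapped non-standard residue type(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) vb_stop("read_structure", "no standard amino-acid atoms found")

  # altloc: keep highest occupancy per (chain, resno, insert, atom name);
  # ties resolved by altloc identifier so conformer 'A' wins
  atom_id <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(atom_id, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(atom_id[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$eleno), , drop = FALSE]  # restore file order

  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- substr(gsub("[0-9 ]", "", at$elety[miss]), 1, 1)
  elesy <- toupper(elesy)

  df <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, elesy = elesy,
    x = at$x, y = at$y, z = at$z,
    is_heavy = !(elesy %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  df$reskey <- vb_reskey(df$chain, df$resno, df$insert)
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    vb_stop("read_structure", "non-finite coordinates after parsing")
  }

  present <- unique(df$chain)
  if (!is.null(chains)) {
    if (length(chains) == 0) vb_stop("read_structure", "empty chain selection")
    missing <- setdiff(chains, present)
    if (length(missing)) {
      vb_stop("read_structure", "chain(s) not present: %s",
              paste(missing, collapse = ", "))
    }
    present <- chains
  }

  subunits <- lapply(present, function(ch) {
    sub <- df[df$chain == ch, , drop = FALSE]
    rownames(sub) <- NULL
    # a residue must retain at least one heavy atom
    nheavy <- tapply(sub$is_heavy, sub$reskey, sum)
    hollow <- names(nheavy)[nheavy == 0]
    if (length(hollow)) {
      warning(sprintf("dropping residue(s) with no heavy atoms: %s",
                      paste(hollow, collapse = ", ")))
      sub <- sub[!(sub$reskey %in% hollow), , drop = FALSE]
    }
    class(sub) <- c("vb_subunit", "data.frame")
    attr(sub, "id") <- ch
    sub
  })
  names(subunits) <- present
  structure(list(subunits = subunits), class = "vb_structure")
}

#' @export
print.vb_structure <- function(x, ...) {
  cat("vb_structure:", length(x$subunits), "subunit(s)\n")
  for (s in x$subunits) {
    cat(sprintf("  chain %s: %d residues, %d atoms (%d heavy)\n",
                attr(s, "id"), length(unique(s$reskey)), nrow(s), sum(s$is_heavy)))
  }
  invisible(x)
}

as_subunit <- function(x, which = 1) {
  if (inherits(x, "vb_subunit")) return(x)
  if (inherits(x, "vb_structure")) return(x$subunits[[which]])
  vb_stop("structure", "expected a vb_structure or vb_subunit")
}

residue_keys <- function(sub) unique(sub$reskey)

residue_types <- function(sub) {
  sub$resid[!duplicated(sub$reskey)]
}

# n x 3 coordinate matrix of (optionally heavy) atoms
sub_coords <- function(sub, heavy_only = TRUE) {
  s <- if (heavy_only) sub[sub$is_heavy, , drop = FALSE] else sub
  list(xyz = cbind(s$x, s$y, s$z), reskey = s$reskey)
}

# Calpha coordinates per residue key; rows NA when missing
ca_coords <- function(sub, keys = residue_keys(sub)) {
  ca <- sub[sub$elety == "CA" & sub$is_heavy, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(keys), ncol = 3,
              dimnames = list(keys, c("x", "y", "z")))
  idx <- match(keys, ca$reskey)
  ok <- !is.na(idx)
  m[ok, ] <- as.matrix(ca[idx[ok], c("x", "y", "z")])
  m
}

pair_dist2 <- function(a, b) {
  # squared cross-distance matrix, numerically clamped at zero
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Heavy-atom residue contacts between two subunits
#'
#' Two residues, one from each subunit, are in contact when some pair of
#' heavy atoms (one from each) lies strictly closer than `cutoff`.
#'
#' @param sub_a,sub_b Subunits (or `vb_structure`s, in which case the first
#'   and second subunit are used).
#' @param cutoff Contact distance in Angstroms (strict `<`); default 6.
#' @return A data.frame with columns `res_a`, `res_b` (residue keys) and
#'   `min_dist`, ordered by residue order in A then B.
#' @export
heavy_atom_contacts <- function(sub_a, sub_b, cutoff = 6.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    vb_stop("contacts", "cutoff must be a positive number")
  }
  sub_a <- as_subunit(sub_a, 1)
  sub_b <- as_subunit(sub_b, 2)
  if (nrow(sub_a) == 0 || nrow(sub_b) == 0) vb_stop("contacts", "empty subunit")
  a <- sub_coords(sub_a, heavy_only = TRUE)
  b <- sub_coords(sub_b, heavy_only = TRUE)
  d2 <- pair_dist2(a$xyz, b$xyz)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  keys_a <- residue_keys(sub_a)
  keys_b <- residue_keys(sub_b)
  if (nrow(hit) == 0) {
    return(data.frame(res_a = character(), res_b = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE))
  }
  ra <- a$reskey[hit[, 1]]
  rb <- b$reskey[hit[, 2]]
  grp <- paste(ra, rb, sep = "\r")
  mind <- tapply(sqrt(d2[hit]), grp, min)
  parts <- do.call(rbind, strsplit(names(mind), "\r", fixed = TRUE))
  out <- data.frame(res_a = parts[, 1], res_b = parts[, 2],
                    min_dist = as.numeric(mind), stringsAsFactors = FALSE)
  out <- out[order(match(out$res_a, keys_a), match(out$res_b, keys_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface residues of a subunit pair
#'
#' Residues participating in at least one heavy-atom contact (< `cutoff`)
#' across the interface; the two returned sets are exactly the projections
#' of the contact-pair set.
#'
#' @inheritParams heavy_atom_contacts
#' @return List with character vectors `a` and `b` of residue keys, in
#'   subunit residue order.
#' @export
interface_residues <- function(sub_a, sub_b, cutoff = 6.0) {
  sub_a <- as_subunit(sub_a, 1)
  sub_b <- as_subunit(sub_b, 2)
  ct <- heavy_atom_contacts(sub_a, sub_b, cutoff)
  list(
    a = intersect(residue_keys(sub_a), ct$res_a),
    b = intersect(residue_keys(sub_b), ct$res_b)
  )
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched coordinate sets, via SVD of the cross-covariance matrix with the
#' usual determinant sign correction.
#'
#' @param coords_ref,coords_mov N x 3 matrices (Angstroms) in matched order,
#'   N >= 3 and not collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd`, and `aligned` (the transformed moving coordinates,
#'   `mov %*% rotation + translation`).
#' @export
superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  if (ncol(coords_ref) != 3 || ncol(coords_mov) != 3 ||
      nrow(coords_ref) != nrow(coords_mov)) {
    vb_stop("superpose", "coordinate sets must be matched N x 3 matrices")
  }
  n <- nrow(coords_ref)
  if (n < 3) vb_stop("superpose", "need at least 3 matched points, got %d", n)
  cen_r <- colMeans(coords_ref)
  cen_m <- colMeans(coords_mov)
  r <- sweep(coords_ref, 2, cen_r)
  m <- sweep(coords_mov, 2, cen_m)
  sv_r <- svd(r)$d
  if (sv_r[2] < 1e-8 * max(sv_r[1], 1e-12)) {
    vb_stop("superpose", "degenerate (collinear) reference configuration")
  }
  s <- svd(crossprod(m, r))  # 3x3: t(m) %*% r
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  rot <- s$u %*% D %*% t(s$v)  # row-vector convention: m %*% rot ~ r
  aligned <- m %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - r)^2)))
  trans <- as.numeric(cen_r - cen_m %*% rot)
  list(rotation = rot, translation = trans, rmsd = rmsd,
       aligned = sweep(coords_mov %*% rot, 2, trans, "+"))
}

#' Write residue contacts to TSV
#'
#' @param contacts Data frame from [heavy_atom_contacts()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (prefixed `# `).
#' @export
write_contacts_tsv <- function(contacts, path, header = NULL) {
  split_key <- function(k) {
    chain <- sub(":.*$", "", k)
    resid <- sub("^[^:]*:", "", k)
    list(chain = chain, resid = resid)
  }
  ka <- split_key(contacts$res_a)
  kb <- split_key(contacts$res_b)
  out <- data.frame(chain_a = ka$chain, resid_a = ka$resid,
                    chain_b = kb$chain, resid_b = kb$resid,
                    min_dist = round(contacts$min_dist, 4))
  vb_write_tsv(out, path, header)
  invisible(path)
}

vb_write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
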