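#' Physicochemical site features of the 20 standard amino acids
#'
#' Three per-residue features drive the structural neighboring property:
#' hydrophobicity (Kyte-Doolittle scale), electrostatic potential (net
#' formal charge at physiological pH: +1 Arg/Lys, -1 Asp/Glu, 0 otherwise)
#' and the count of potential hydrogen bonds contributed by the residue's
#' atoms.
#'
#' @format Data frame with one row per amino acid (3-letter rownames) and
#'   columns `hydrophobicity`, `electrostatic`, `hbonds`.
#' @keywords internal
.vb_feature_table <- data.frame(
  hydrophobicity = c(
    ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
    GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
    LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
    SER = -0.8, THR = -0.7, TRP = 0.9, TYR = -1.3, VAL = 4.2
  ),
  electrostatic = c(
    ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0,
    GLN = 0, GLU = -1, GLY = 0, HIS = 0, ILE = 0,
    LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0,
    SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0
  ),
  hbonds = c(
    ALA = 2, ARG = 4, ASN = 4, ASP = 4, CYS = 2,
    GLN = 4, GLU = 4, GLY = 2, HIS = 4, ILE = 2,
    LEU = 2, LYS = 2, MET = 2, PHE = 2, PRO = 2,
    SER = 4, THR = 4, TRP = 3, TYR = 3, VAL = 2
  )
)

.vb_aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

#' Site features of an amino acid
#'
#' @param res_type Standard amino-acid code, 3-letter (any case) or
#'   1-letter.
#' @return Named numeric vector with `hydrophobicity`, `electrostatic` and
#'   `hbonds`.
#' @examples
#' site_features("Ile")  # hydrophobicity 4.5, charge 0, 2 hydrogen bonds
#' @export
site_features <- function(res_type) {
  code <- toupper(res_type)
  if (nchar(code) == 1) code <- unname(.vb_aa1to3[code])
  if (is.na(code) || !(code %in% rownames(.vb_feature_table))) {
    vb_stop("site_features", "unknown residue type '%s'; valid codes: %s",
            res_type, paste(rownames(.vb_feature_table), collapse = ", "))
  }
  unlist(.vb_feature_table[code, ])
}

#' The full site-feature table
#' @return Copy of the packaged 20-residue feature table.
#' @export
feature_table <- function() .vb_feature_table

# feature values for a vector of 3-letter codes, with a possibly rescaled
# table (used by property computations)
feature_values <- function(res_types, feature, table = .vb_feature_table) {
  stopifnot(feature %in% colnames(table))
  v <- table[res_types, feature]
  if (any(is.na(v))) {
    vb_stop("features", "unknown residue type(s): %s",
            paste(unique(res_types[is.na(v)]), collapse = ", "))
  }
  v
}

#' Structural neighboring property of one surface residue
#'
#' The property blends a residue's own feature with those of its Voronoi
#' contact neighbors, each weighted by solvent exposure:
#' \deqn{p'(x) = \frac{surface(x)}{total(x)} p(x) +
#'   \sum_{y:\,contact(x,y)>0} \frac{surface(y)}{total(y)} p(y)}
#' Neighbors with zero contact area contribute nothing. A fully exposed
#' isolated residue therefore has p' = p; a buried residue surrounded by
#' buried neighbors has p' = 0.
#'
#' @param x Residue key.
#' @param areas A `vb_areas` from [residue_areas()]; must cover `x` and all
#'   its contact partners, and carry residue types (or pass `res_types`).
#' @param feature One of `"hydrophobicity"`, `"electrostatic"`, `"hbonds"`.
#' @param table Feature table (default the packaged one).
#' @return The p' value (dimensionless).
#' @export
neighboring_property <- function(x, areas, feature = "hydrophobicity",
                                 table = .vb_feature_table) {
  r <- areas$residues
  i <- match(x, r$reskey)
  if (is.na(i)) vb_stop("property", "residue %s not in areas", x)
  if (r$total[i] <= 0) vb_stop("property", "residue %s has no tessellation cell (total area 0)", x)
  own <- r$ratio[i] * feature_values(r$res_type[i], feature, table)
  nb <- area_neighbors(areas, x)
  nb <- nb[nb$area > areas$area_tol, , drop = FALSE]
  if (nrow(nb) == 0) return(own)
  j <- match(nb$res_b, r$reskey)
  if (any(is.na(j))) {
    vb_stop("property", "areas missing contact partner(s) of %s", x)
  }
  own + sum(r$ratio[j] * feature_values(r$res_type[j], feature, table))
}

#' Property profile of all surface residues
#'
#' Computes the structural neighboring property p' for every surface
#' residue (tessellation surface area > 0) and each of the three features.
#'
#' @param x A `vb_structure` or `vb_subunit` (used for residue types if the
#'   areas lack them); may be `NULL` when `areas` carries types.
#' @param areas A `vb_areas` covering the structure.
#' @param table Feature table.
#' @return A `vb_profile` data.frame: `reskey`, `res_type`,
#'   `surface_ratio`, and one `pprime_<feature>` column per feature. Rows
#'   exist only for surface residues.
#' @export
property_profile <- function(x = NULL, areas, table = .vb_feature_table) {
  r <- areas$residues
  if (all(is.na(r$res_type))) {
    if (is.null(x)) vb_stop("profile", "areas carry no residue types and no structure given")
    subs <- if (inherits(x, "vb_structure")) x$subunits else list(x)
    all_res <- do.call(rbind, lapply(subs, function(s) s[!duplicated(s$reskey), c("reskey", "resid")]))
    r$res_type <- all_res$resid[match(r$reskey, all_res$reskey)]
  }
  surf <- r$surface > areas$area_tol
  prof <- data.frame(reskey = r$reskey[surf], res_type = r$res_type[surf],
                     surface_ratio = r$ratio[surf], stringsAsFactors = FALSE)
  if (nrow(prof) == 0) {
    for (f in vb_features()) prof[[paste0("pprime_", f)]] <- numeric(0)
    class(prof) <- c("vb_profile", "data.frame")
    return(prof)
  }
  # vectorized: p' = ratio*p + A %*% (ratio*p), A = contact-gated adjacency
  n <- nrow(r)
  A <- matrix(0, n, n, dimnames = list(r$reskey, r$reskey))
  ct <- areas$contacts[areas$contacts$area > areas$area_tol, , drop = FALSE]
  if (nrow(ct)) {
    A[cbind(match(ct$res_a, r$reskey), match(ct$res_b, r$reskey))] <- 1
  }
  for (f in vb_features()) {
    wp <- r$ratio * feature_values(r$res_type, f, table)
    pp <- wp + as.numeric(A %*% wp)
    prof[[paste0("pprime_", f)]] <- pp[surf]
  }
  rownames(prof) <- NULL
  class(prof) <- c("vb_profile", "data.frame")
  prof
}

#' Write a property profile as TSV
#' @param profile A `vb_profile`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_profile_tsv <- function(profile, path, header = NULL) {
  out <- data.frame(chain = sub(":.*$", "", profile$reskey),
                    resid = sub("^[^:]*:", "", profile$reskey),
                    res_type = profile$res_type,
                    surface_ratio = round(profile$surface_ratio, 6),
                    pprime_hydro = round(profile$pprime_hydrophobicity, 6),
                    pprime_elec = round(profile$pprime_electrostatic, 6),
                    pprime_hbond = round(profile$pprime_hbonds, 6))
  vb_write_tsv(out, path, header)
  invisible(path)
}
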