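#' Extraction configuration
#'
#' @param s_th Energy threshold: pairs with S <= `s_th` are harvested as
#'   interacting residues. Larger values are more permissive; the harvested
#'   set grows monotonically with `s_th`.
#' @param top_k Number of top-ranked interacting residues (across both
#'   sides) carried into clustering; `"all"` keeps every one. Default 100.
#' @param edge_radius C-alpha distance (Angstroms, inclusive) defining
#'   patch-graph edges within each protein; default 10.
#' @param min_patch_size Connected components smaller than this are
#'   discarded as weak signals; default 3.
#' @param update_radius Radius of the neighborhood update sphere
#'   (Angstroms, inclusive); default 10.
#' @param contact_cutoff Heavy-atom contact cutoff (Angstroms); default 6.
#' @param padding Tessellation box padding (Angstroms); default 5.
#' @return A validated `vb_config`.
#' @export
vb_config <- function(s_th = 0, top_k = 100, edge_radius = 10,
                      min_patch_size = 3, update_radius = 10,
                      contact_cutoff = 6, padding = 5) {
  if (!identical(top_k, "all")) {
    if (!is.numeric(top_k) || top_k < 1) vb_stop("config", "top_k must be >= 1 or \"all\"")
  }
  if (edge_radius <= 0) vb_stop("config", "edge_radius must be > 0")
  if (min_patch_size < 1) vb_stop("config", "min_patch_size must be >= 1")
  if (update_radius <= 0) vb_stop("config", "update_radius must be > 0")
  if (contact_cutoff <= 0) vb_stop("config", "contact_cutoff must be > 0")
  structure(list(s_th = s_th, top_k = top_k, edge_radius = edge_radius,
                 min_patch_size = min_patch_size, update_radius = update_radius,
                 contact_cutoff = contact_cutoff, padding = padding),
            class = "vb_config")
}

#' Harvest interacting residue pairs at a threshold
#'
#' @param scores A `vb_scores`.
#' @param s_th Threshold: pairs with S <= `s_th` are kept.
#' @return Data frame `res_a`, `res_b`, `S` (and `S_prime` when available),
#'   in deterministic A-major order.
#' @export
harvest_pairs <- function(scores, s_th) {
  df <- as.data.frame(scores)
  out <- df[df$S <= s_th, , drop = FALSE]
  out <- out[order(match(out$res_a, scores$keys_a),
                   match(out$res_b, scores$keys_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank interacting residues by updated pair energy
#'
#' Each residue appearing in a harvested pair is keyed by its best (lowest)
#' S' over its pairs; residues are sorted ascending, ties broken
#' lexicographically by (side, chain, residue id); the `top_k` prefix is
#' returned.
#'
#' @param pairs Harvested pairs carrying an `S_prime` column (run
#'   [neighborhood_update()] before [harvest_pairs()]).
#' @param top_k Count, or `"all"`.
#' @return Data frame `side` ("A"/"B"), `reskey`, `best_S_prime`, ranked.
#' @export
rank_residues <- function(pairs, top_k = "all") {
  score_col <- if (!is.null(pairs$S_prime)) "S_prime" else "S"
  if (nrow(pairs) == 0) {
    return(data.frame(side = character(), reskey = character(),
                      best_S_prime = numeric(), stringsAsFactors = FALSE))
  }
  long <- rbind(
    data.frame(side = "A", reskey = pairs$res_a, s = pairs[[score_col]],
               stringsAsFactors = FALSE),
    data.frame(side = "B", reskey = pairs$res_b, s = pairs[[score_col]],
               stringsAsFactors = FALSE)
  )
  if (nrow(long) == 0) {
    return(data.frame(side = character(), reskey = character(),
                      best_S_prime = numeric(), stringsAsFactors = FALSE))
  }
  grp <- paste(long$side, long$reskey, sep = "\r")
  best <- tapply(long$s, grp, min)
  parts <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  out <- data.frame(side = parts[, 1], reskey = parts[, 2],
                    best_S_prime = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$best_S_prime, out$side, out$reskey, method = "radix"), , drop = FALSE]
  if (!identical(top_k, "all")) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Cluster ranked residues into interface patches
#'
#' Within each protein separately, ranked residues become graph nodes with
#' undirected edges between C-alpha pairs within `edge_radius`; connected
#' components are the patches, and components smaller than
#' `min_patch_size` are discarded.
#'
#' @param residues Ranked residues from [rank_residues()].
#' @param sub_a,sub_b The two subunits (C-alpha coordinates needed).
#' @param config A `vb_config` (edge_radius, min_patch_size used).
#' @return A `vb_patchset`: list with `patches` (data.frame `side`,
#'   `patch_id`, `reskey`, `best_S_prime`) and `config`. Patch ids are
#'   `<side><rank>` ordered by best member energy.
#' @export
cluster_patches <- function(residues, sub_a, sub_b, config = vb_config()) {
  sub_a <- as_subunit(sub_a, 1)
  sub_b <- as_subunit(sub_b, 2)
  one_side <- function(side, sub) {
    rs <- residues[residues$side == side, , drop = FALSE]
    if (nrow(rs) == 0) return(NULL)
    ca <- ca_coords(sub, rs$reskey)
    ok <- stats::complete.cases(ca)
    rs <- rs[ok, , drop = FALSE]
    ca <- ca[ok, , drop = FALSE]
    if (nrow(rs) == 0) return(NULL)
    d <- sqrt(pair_dist2(ca, ca))
    adj <- d <= config$edge_radius
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    keep_comp <- as.integer(names(table(comp)))[table(comp) >= config$min_patch_size]
    rs$comp <- comp
    rs <- rs[rs$comp %in% keep_comp, , drop = FALSE]
    if (nrow(rs) == 0) return(NULL)
    # order patches by their best member energy, then lexicographic anchor
    stats_by <- vapply(split(rs$best_S_prime, rs$comp), min, numeric(1))
    anchor <- vapply(split(rs$reskey, rs$comp), min, character(1))
    ord <- order(stats_by, anchor)
    newid <- stats::setNames(seq_along(ord), names(stats_by)[ord])
    rs$patch_id <- paste0(side, newid[as.character(rs$comp)])
    rs$comp <- NULL
    rs
  }
  patches <- rbind(one_side("A", sub_a), one_side("B", sub_b))
  if (is.null(patches)) {
    patches <- data.frame(side = character(), patch_id = character(),
                          reskey = character(), best_S_prime = numeric(),
                          stringsAsFactors = FALSE)
  }
  patches <- patches[order(patches$patch_id, patches$best_S_prime, patches$reskey), ,
                     drop = FALSE]
  rownames(patches) <- NULL
  structure(list(patches = patches[, c("side", "patch_id", "reskey", "best_S_prime")],
                 config = config),
            class = "vb_patchset")
}

#' @export
print.vb_patchset <- function(x, ...) {
  p <- x$patches
  cat(sprintf("vb_patchset: %d residues in %d patch(es)\n",
              nrow(p), length(unique(p$patch_id))))
  if (nrow(p)) {
    for (id in unique(p$patch_id)) {
      cat(sprintf("  %s: %d residues, best S' %.3f\n", id,
                  sum(p$patch_id == id), min(p$best_S_prime[p$patch_id == id])))
    }
  }
  invisible(x)
}

#' Predict interface patches for a protein pair
#'
#' End-to-end pipeline: tessellate each protein, compute property profiles,
#' score all surface cross-pairs, apply the neighborhood update, harvest at
#' `s_th`, rank by S', and cluster into per-protein patches. Deterministic
#' for fixed inputs and configuration.
#'
#' @param protein_a,protein_b `vb_structure`/`vb_subunit` objects or PDB
#'   paths (first chain used if multi-chain).
#' @param model A fitted `vb_model`.
#' @param config A `vb_config`.
#' @return List with `patches` (a `vb_patchset`), `residues` (the ranked
#'   retained residues), `scores` (the `vb_scores`), `n_harvested`, and
#'   `config`.
#' @export
predict_interface <- function(protein_a, protein_b, model, config = vb_config()) {
  load_one <- function(p, lab) {
    if (is.character(p)) p <- read_structure(p)
    s <- as_subunit(p, 1)
    if (nrow(s) == 0) vb_stop(paste0("predict/", lab), "empty protein")
    s
  }
  sub_a <- load_one(protein_a, "input-A")
  sub_b <- load_one(protein_b, "input-B")

  profile_of <- function(sub, lab) {
    tess <- build_tessellation(structure_sites(sub), padding = config$padding)
    areas <- residue_areas(tess, sub)
    property_profile(sub, areas)
  }
  prof_a <- profile_of(sub_a, "tessellate-A")
  prof_b <- profile_of(sub_b, "tessellate-B")
  empty <- function() {
    structure(list(patches = data.frame(side = character(), patch_id = character(),
                                        reskey = character(), best_S_prime = numeric()),
                   config = config), class = "vb_patchset")
  }
  if (nrow(prof_a) == 0 || nrow(prof_b) == 0) {
    return(list(patches = empty(),
                residues = data.frame(side = character(), reskey = character(),
                                      best_S_prime = numeric()),
                scores = NULL, n_harvested = 0L, config = config))
  }
  scores <- score_all_pairs(prof_a, prof_b, model)
  scores <- neighborhood_update(scores, sub_a, sub_b, config$update_radius)
  harvested <- harvest_pairs(scores, config$s_th)
  ranked <- rank_residues(harvested, config$top_k)
  patches <- cluster_patches(ranked, sub_a, sub_b, config)
  list(patches = patches, residues = ranked, scores = scores,
       n_harvested = nrow(harvested), config = config)
}

#' Write predicted patches as TSV
#' @param patchset A `vb_patchset`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_patches_tsv <- function(patchset, path, header = NULL) {
  p <- patchset$patches
  out <- data.frame(side = p$side, patch_id = p$patch_id,
                    chain = sub(":.*$", "", p$reskey),
                    resid = sub("^[^:]*:", "", p$reskey),
                    best_S_prime = round(p$best_S_prime, 6))
  vb_write_tsv(out, path, header)
  invisible(path)
}
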