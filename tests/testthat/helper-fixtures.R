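# Shared test helpers: tiny hand-built structures, brute-force oracles, and
# a cached toy-trained model.

# a subunit with one atom per residue (default C-alpha), from an n x 3 matrix
mini_subunit <- function(chain, xyz, types = NULL, elety = "CA", elesy = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  df <- data.frame(
    chain = chain, resno = seq_len(n), insert = "",
    resid = if (is.null(types)) rep("ALA", n) else types,
    elety = rep_len(elety, n), elesy = rep_len(elesy, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_heavy = rep_len(elesy, n) != "H", stringsAsFactors = FALSE
  )
  df$reskey <- paste0(chain, ":", df$resno)
  class(df) <- c("vb_subunit", "data.frame")
  attr(df, "id") <- chain
  df
}

# subunit with explicit atoms: data.frame(resno, elety, elesy, x, y, z)
atoms_subunit <- function(chain, atoms, types = NULL) {
  n_res <- length(unique(atoms$resno))
  df <- data.frame(
    chain = chain, resno = atoms$resno, insert = "",
    resid = if (is.null(types)) rep("ALA", nrow(atoms)) else types[match(atoms$resno, sort(unique(atoms$resno)))],
    elety = atoms$elety, elesy = atoms$elesy,
    x = atoms$x, y = atoms$y, z = atoms$z,
    is_heavy = atoms$elesy != "H", stringsAsFactors = FALSE
  )
  df$reskey <- paste0(chain, ":", df$resno)
  class(df) <- c("vb_subunit", "data.frame")
  attr(df, "id") <- chain
  df
}

two_subunit_structure <- function(sub_a, sub_b) {
  structure(list(subunits = stats::setNames(list(sub_a, sub_b),
                                            c(attr(sub_a, "id"), attr(sub_b, "id")))),
            class = "vb_structure")
}

# brute-force residue contact oracle: double loop over all atom pairs
brute_contacts <- function(sub_a, sub_b, cutoff = 6, heavy_only = TRUE) {
  out <- list()
  for (ka in unique(sub_a$reskey)) {
    aa <- sub_a[sub_a$reskey == ka & (!heavy_only | sub_a$is_heavy), ]
    for (kb in unique(sub_b$reskey)) {
      bb <- sub_b[sub_b$reskey == kb & (!heavy_only | sub_b$is_heavy), ]
      dmin <- Inf
      for (i in seq_len(nrow(aa))) for (j in seq_len(nrow(bb))) {
        d <- sqrt(sum((c(aa$x[i], aa$y[i], aa$z[i]) - c(bb$x[j], bb$y[j], bb$z[j]))^2))
        dmin <- min(dmin, d)
      }
      if (dmin < cutoff) out[[length(out) + 1]] <- data.frame(res_a = ka, res_b = kb, min_dist = dmin)
    }
  }
  if (length(out) == 0) return(data.frame(res_a = character(), res_b = character(), min_dist = numeric()))
  do.call(rbind, out)
}

# numeric superposition oracle: minimize rmsd over 3 Euler angles + shift
numeric_superpose_rmsd <- function(ref, mov) {
  rotmat <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])), 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    R <- rotmat(p[1:3])
    sqrt(mean(rowSums((sweep(mov %*% t(R), 2, p[4:6], "+") - ref)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.8, 0, 0, 0), c(2, 1, -1, 1, -1, 1))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# uniform random rotation matrix (QR of Gaussian, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# model fitted once on toy complexes, cached across tests in this run
.toy_cache <- new.env(parent = emptyenv())
toy_trained_model <- function() {
  if (is.null(.toy_cache$model)) {
    train <- lapply(1:4, function(s) {
      make_toy_complex(n_res_a = 12, n_res_b = 12, n_contact_pairs = 5,
                       seed = 200 + s)$complex
    })
    .toy_cache$model <- fit_model(train, min_pairs = 10)
  }
  .toy_cache$model
}

# a hand-specifiable areas object (list layout matching residue_areas())
manual_areas <- function(residues, contacts = NULL, area_tol = 1e-9) {
  if (is.null(contacts)) {
    contacts <- data.frame(res_a = character(), res_b = character(), area = numeric())
  } else {
    # symmetrize to both orders, as residue_areas() stores them
    contacts <- rbind(contacts,
                      data.frame(res_a = contacts$res_b, res_b = contacts$res_a,
                                 area = contacts$area))
    contacts <- unique(contacts)
  }
  structure(list(residues = residues, contacts = contacts, area_tol = area_tol),
            class = "vb_areas")
}

# random hand-specified areas over n residues with sparse contacts
random_manual_areas <- function(seed, n = 8) {
  set.seed(seed)
  types <- sample(rownames(feature_table()), n, replace = TRUE)
  total <- runif(n, 5, 50)
  surface <- runif(n, 0, 1) * total
  res <- data.frame(reskey = paste0("A:", 1:n), res_type = types,
                    total = total, surface = surface, ratio = surface / total)
  pairs <- t(utils::combn(n, 2))
  on <- runif(nrow(pairs)) < 0.4
  ct <- data.frame(res_a = paste0("A:", pairs[on, 1]),
                   res_b = paste0("A:", pairs[on, 2]),
                   area = runif(sum(on), 0.5, 5))
  manual_areas(res, ct)
}

# scores object with an explicit S matrix
manual_scores <- function(S, keys_a = rownames(S), keys_b = colnames(S)) {
  dimnames(S) <- list(keys_a, keys_b)
  structure(list(S = S, S_prime = NULL, keys_a = keys_a, keys_b = keys_b),
            class = "vb_scores")
}

minimal_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.571   7.234  -4.880  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2      14.839   8.071  -2.147  1.00  0.00           C",
    "ATOM      5  C   GLY A   2      15.571   9.234  -1.880  1.00  0.00           C",
    "END")
}
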