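test_that("read_structure parses records, selects chains, and reports bad lines", {
  s <- read_structure(minimal_pdb_text())
  expect_length(s$subunits, 1)
  expect_equal(length(unique(s$subunits$A$reskey)), 2)
  expect_equal(nrow(s$subunits$A), 5)

  # two chains, select one
  bchain <- sub("A   1", "B   1", minimal_pdb_text()[1:3])
  substr(bchain, 7, 11) <- sprintf("%5d", 4:6)  # fresh serial numbers
  two <- c(minimal_pdb_text()[1:3], bchain, "END")
  sb <- read_structure(two, chains = "B")
  expect_length(sb$subunits, 1)
  expect_equal(unique(sb$subunits[[1]]$chain), "B")
  expect_error(read_structure(two, chains = "Z"), "not present")
  expect_error(read_structure(two, chains = character(0)), "empty chain selection")

  # truncated ATOM record -> error naming the line
  trunc <- minimal_pdb_text()
  trunc[2] <- substr(trunc[2], 1, 40)
  expect_error(read_structure(trunc), "line 2")
})

test_that("read_structure resolves altlocs, maps MSE, and flags hydrogens", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "HETATM    3  CA  MSE A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  H   MSE A   2       5.500   0.000   0.000  1.00  0.00           H",
    "HETATM    5  O   HOH A  99      20.000   0.000   0.000  1.00  0.00           O",
    "END")
  s <- read_structure(lines)
  sub <- s$subunits$A
  # highest occupancy altloc kept (B, occ 0.60)
  expect_equal(sub$x[sub$reskey == "A:1"], 1.0)
  # MSE mapped to MET
  expect_equal(unique(sub$resid[sub$reskey == "A:2"]), "MET")
  # hydrogen retained but not heavy; water excluded
  expect_true(any(!sub$is_heavy))
  expect_false(any(sub$reskey == "A:99"))
})

test_that("heavy-atom contacts honor the strict cutoff and match brute force", {
  a <- mini_subunit("A", c(0, 0, 0))
  b59 <- mini_subunit("B", c(5.9, 0, 0))
  b60 <- mini_subunit("B", c(6.0, 0, 0))
  expect_equal(nrow(heavy_atom_contacts(a, b59)), 1)
  expect_equal(heavy_atom_contacts(a, b59)$min_dist, 5.9)
  expect_equal(nrow(heavy_atom_contacts(a, b60)), 0)  # strictly less than
  expect_error(heavy_atom_contacts(a, b59, cutoff = 0), "positive")

  for (seed in 1:5) {
    set.seed(seed)
    sa <- atoms_subunit("A", data.frame(
      resno = rep(1:3, each = 2), elety = rep(c("CA", "CB"), 3),
      elesy = "C", x = runif(6, 0, 10), y = runif(6, 0, 10), z = runif(6, 0, 10)))
    sb <- atoms_subunit("B", data.frame(
      resno = rep(1:3, each = 2), elety = rep(c("CA", "CB"), 3),
      elesy = "C", x = runif(6, 0, 10), y = runif(6, 0, 10), z = runif(6, 0, 10)))
    got <- heavy_atom_contacts(sa, sb)
    want <- brute_contacts(sa, sb)
    expect_setequal(paste(got$res_a, got$res_b), paste(want$res_a, want$res_b))
    expect_equal(got$min_dist[order(got$res_a, got$res_b)],
                 want$min_dist[order(want$res_a, want$res_b)], tolerance = 1e-12)
    # symmetry: swapped arguments give the transposed pair set
    rev <- heavy_atom_contacts(sb, sa)
    expect_setequal(paste(rev$res_b, rev$res_a), paste(got$res_a, got$res_b))
  }
})

test_that("interface residues are exactly the projections of the contact set", {
  a <- mini_subunit("A", rbind(c(0, 0, 0), c(30, 0, 0)))
  b <- mini_subunit("B", rbind(c(3, 0, 0), c(0, 4, 0), c(60, 0, 0)))
  # a1 contacts b1 and b2; everything else is far
  ir <- interface_residues(a, b)
  expect_equal(ir$a, "A:1")
  expect_setequal(ir$b, c("B:1", "B:2"))

  far <- mini_subunit("B", c(100, 0, 0))
  ir0 <- interface_residues(a, far)
  expect_length(ir0$a, 0)
  expect_length(ir0$b, 0)

  set.seed(42)
  sa <- mini_subunit("A", matrix(runif(15, 0, 12), ncol = 3))
  sb <- mini_subunit("B", matrix(runif(15, 0, 12), ncol = 3))
  ct <- heavy_atom_contacts(sa, sb)
  ir <- interface_residues(sa, sb)
  expect_setequal(ir$a, unique(ct$res_a))
  expect_setequal(ir$b, unique(ct$res_b))
})

test_that("superpose recovers rigid motions and matches a numeric optimizer", {
  set.seed(7)
  ref <- matrix(rnorm(12, sd = 3), ncol = 3)

  same <- superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  # 90 degrees about z plus translation: recovered exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  mov <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- superpose(ref, mov)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$aligned, ref, tolerance = 1e-8)

  # perturbed copy: rmsd agrees with an independent numeric minimization
  mov2 <- ref + matrix(rnorm(12, sd = 0.3), ncol = 3)
  expect_equal(superpose(ref, mov2)$rmsd, numeric_superpose_rmsd(ref, mov2),
               tolerance = 1e-6)

  # and with bio3d's Kabsch fitting
  xyz_ref <- as.numeric(t(ref))
  xyz_mov <- as.numeric(t(mov2))
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz_ref, xyz_mov))
  expect_equal(superpose(ref, mov2)$rmsd,
               sqrt(mean(colSums(matrix((fitted - xyz_ref)^2, nrow = 3)))),
               tolerance = 1e-8)

  expect_error(superpose(ref[1:2, ], mov2[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superpose rmsd is invariant under proper rigid motions of the input", {
  set.seed(11)
  ref <- matrix(rnorm(18, sd = 2), ncol = 3)
  mov <- ref + matrix(rnorm(18, sd = 0.4), ncol = 3)
  base <- superpose(ref, mov)$rmsd
  for (i in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    moved <- sweep(mov %*% t(R), 2, t, "+")
    expect_equal(superpose(ref, moved)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("contacts TSV round-trips through the documented columns", {
  a <- mini_subunit("A", rbind(c(0, 0, 0), c(3, 0, 0)))
  b <- mini_subunit("B", rbind(c(0, 4, 0)))
  ct <- heavy_atom_contacts(a, b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contacts_tsv(ct, path, header = "test")
  got <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(got), nrow(ct))
  expect_named(got, c("chain_a", "resid_a", "chain_b", "resid_b", "min_dist"))
})
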