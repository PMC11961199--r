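test_that("reading a generated structure round-trips coordinates", {
  cfg <- tiny_synth_config()
  dir <- tempfile()
  emit_fixture_set(cfg, dir, n = 1)
  rec <- read_structure(file.path(dir, "structures", "enz001.pdb"), "A")
  gen <- small_dataset()  # different seed path; regenerate the emitted one
  ref <- synth_dataset(cfg, n = 1)[[1]]$record
  expect_equal(n_residues(rec), n_residues(ref))
  expect_equal(rec$ca_coords, ref$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(rec$sequence, ref$sequence)
  expect_equal(rec$residue_numbers, ref$residue_numbers)
})

test_that("residues without a Calpha are dropped with a warning", {
  lines <- c(
    pdb_lines(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_lines(2, "CA", "GLY", "A", 1, 1, 0, 0),
    pdb_lines(3, "C", "GLY", "A", 1, 2, 0, 0),
    pdb_lines(4, "N", "ALA", "A", 2, 4, 0, 0),  # no CA
    pdb_lines(5, "C", "ALA", "A", 2, 5, 0, 0),
    pdb_lines(6, "N", "SER", "A", 3, 7, 0, 0),
    pdb_lines(7, "CA", "SER", "A", 3, 8, 0, 0))
  path <- write_toy_pdb(lines)
  expect_warning(rec <- read_structure(path, "A"), "Calpha")
  expect_equal(n_residues(rec), 2)
  expect_equal(rec$sequence, "GS")
})

test_that("hydrogens, waters and hetero-compounds are excluded", {
  base <- c(
    pdb_lines(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_lines(2, "CA", "GLY", "A", 1, 1, 0, 0),
    pdb_lines(3, "CA", "ALA", "A", 2, 4, 0, 0),
    pdb_lines(4, "CB", "ALA", "A", 2, 5, 0, 0))
  extra <- c(
    pdb_lines(5, "H", "GLY", "A", 1, 0.5, 0, 0, element = "H"),
    pdb_lines(6, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
    pdb_lines(7, "FE", "HEM", "A", 91, 8, 8, 8, element = "FE",
              record = "HETATM"))
  clean <- read_structure(write_toy_pdb(base), "A")
  noisy <- read_structure(write_toy_pdb(c(base, extra)), "A")
  expect_equal(noisy$sequence, clean$sequence)
  expect_equal(noisy$atoms$element, clean$atoms$element)
  expect_equal(noisy$ca_coords, clean$ca_coords)
})

test_that("missing chains are reported with the available ones", {
  path <- write_toy_pdb(c(pdb_lines(1, "CA", "GLY", "A", 1, 0, 0, 0),
                          pdb_lines(2, "CA", "GLY", "B", 1, 3, 0, 0)))
  expect_error(read_structure(path, "C"), "available chains: A, B")
})

test_that("contact map matches hand distances and the pairwise oracle", {
  rec <- toy_record()  # Calphas at 0, 6, 12 A
  a <- contact_map(rec, cutoff = 10)
  expect_equal(a, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
               ignore_attr = TRUE)
  # empty-graph limit
  expect_true(all(contact_map(rec, cutoff = 0.1) == 0))
  # brute-force O(n^2) oracle on a 50-residue backbone
  set.seed(7)
  xyz <- generate_backbone(50)
  a <- contact_map(xyz, cutoff = 10)
  oracle <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 10)
      oracle[i, j] <- 1
  }
  expect_equal(a, oracle, ignore_attr = TRUE)
  expect_error(contact_map(rbind(c(0, 0, NA), c(1, 1, 1))), "finite")
  expect_error(contact_map(rec, cutoff = -1), "positive")
})

test_that("contact maps are symmetric and monotone in the cutoff", {
  set.seed(8)
  xyz <- generate_backbone(40)
  a6 <- contact_map(xyz, 6); a10 <- contact_map(xyz, 10)
  expect_identical(a6, t(a6))
  expect_true(all(diag(a10) == 0))
  expect_true(all(a6 <= a10))  # edge-set inclusion
})

test_that("atomic descriptor reproduces hand-countable averages", {
  rec <- toy_record(ca = matrix(c(0, 0, 0), 1))
  xa <- atomic_descriptor(rec, sasa = c(50))
  # glycine backbone N, CA, C, O: C twice, N once, O once
  expect_equal(unname(xa[1, 1:5]), c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(unname(xa[1, "sidechain"]), 0)
  expect_equal(unname(xa[1, "mass"]),
               mean(c(14.007, 12.011, 12.011, 15.999)))
  expect_equal(unname(xa[1, "b_factor"]), 30)
  expect_equal(unname(xa[1, "abs_sasa"]), 50)
  expect_equal(unname(xa[1, "rel_sasa"]), 50 / 104)  # glycine max ASA
  expect_equal(unname(xa[1, "reserved"]), 0)
  expect_equal(ncol(xa), 14)
})

test_that("an all-carbon residue averages to pure-carbon channels", {
  rec <- toy_record(ca = matrix(c(0, 0, 0), 1))
  rec$atoms$element <- rep("C", 4)
  xa <- atomic_descriptor(rec, sasa = c(10))
  expect_equal(unname(xa[1, 1:5]), c(1, 0, 0, 0, 0))
  expect_equal(unname(xa[1, "mass"]), 12.011)
  expect_equal(unname(xa[1, "vdw"]), 1.70)
})

test_that("atomic descriptor equals an independent re-averaging oracle", {
  b <- small_dataset()[[1]]
  rec <- b$record
  xa <- atomic_descriptor(rec, sasa = b$sasa)
  mass_tab <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  vdw_tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  for (i in c(1, 7, n_residues(rec))) {
    at <- rec$atoms[rec$atoms$res_index == i, ]
    expect_equal(unname(xa[i, 1]), mean(at$element == "C"))
    expect_equal(unname(xa[i, 4]), mean(at$element == "S"))
    expect_equal(unname(xa[i, "mass"]), mean(mass_tab[at$element]))
    expect_equal(unname(xa[i, "vdw"]), mean(vdw_tab[at$element]))
    expect_equal(unname(xa[i, "b_factor"]), mean(at$b))
    expect_equal(unname(xa[i, "sidechain"]), mean(at$is_sidechain))
  }
})

test_that("atomic descriptor is invariant to atom order within residues", {
  b <- small_dataset()[[2]]
  rec <- b$record
  xa1 <- atomic_descriptor(rec, sasa = b$sasa)
  set.seed(5)
  perm <- sample(nrow(rec$atoms))
  rec2 <- rec
  rec2$atoms <- rec$atoms[perm, ]
  expect_equal(atomic_descriptor(rec2, sasa = b$sasa), xa1)
})

test_that("sasa mismatches are rejected", {
  rec <- toy_record()
  expect_error(atomic_descriptor(rec, sasa = c(1, 2)), "does not match")
})

test_that("shrake-rupley accessibility behaves physically", {
  # a lone atom exposes its full solvent-extended sphere exactly
  rec1 <- toy_record(ca = matrix(c(0, 0, 0), 1))
  rec1$atoms <- rec1$atoms[2, ]  # keep only the CA carbon
  s1 <- compute_sasa(rec1)
  expect_equal(s1$abs_sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  # burying a residue between neighbors reduces its surface
  rec3 <- toy_record(ca = rbind(c(-4, 0, 0), c(0, 0, 0), c(4, 0, 0)))
  s3 <- compute_sasa(rec3)
  lone <- compute_sasa(toy_record(ca = matrix(c(0, 0, 0), 1)))
  expect_lt(s3$abs_sasa[2], lone$abs_sasa[1])
})

test_that("build_graph assembles a valid residue graph", {
  b <- small_dataset()[[1]]
  g <- build_graph(b$record, b$profiles, b$embedding, cutoff = 10,
                   sasa = b$sasa)
  expect_s3_class(g, "residue_graph")
  expect_equal(ncol(g$x_l) + ncol(g$x_a), 64)  # GCN input width theta
  expect_true(all(g$x_l >= 0 & g$x_l <= 1))
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(g$embedded)
})

test_that("build_graph zero-fills a missing embedding and flags it", {
  b <- small_dataset()[[1]]
  g <- build_graph(b$record, b$profiles, NULL, sasa = b$sasa)
  expect_false(g$embedded)
  expect_true(all(g$x_g == 0))
  # forward pass still defined
  model <- catsite_model(gcn_dims = c(4, 4, 4), branch_dim = 4,
                         fusion_dim = 4, seed = 1)
  expect_equal(dim(predict(model, g)), c(n_residues(b$record), 5))
})

test_that("build_graph rejects profile row mismatches naming the source", {
  b <- small_dataset()[[1]]
  bad <- toy_profiles(n_residues(b$record) + 1)
  expect_error(build_graph(b$record, bad, sasa = b$sasa), "PSSM")
})

test_that("contact maps write as dense matrix and edge list", {
  a <- contact_map(toy_record(), 10)
  f1 <- tempfile(); f2 <- tempfile()
  write_contact_map(a, f1, "dense")
  expect_equal(as.matrix(read.table(f1)), a, ignore_attr = TRUE)
  write_contact_map(a, f2, "edges")
  e <- read.table(f2, header = TRUE)
  expect_equal(nrow(e), sum(a) / 2)
  expect_true(all(e$i < e$j))
})
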