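test_that("molecular_graph validates its invariants", {
  expect_error(molecular_graph(data.frame(element = character(0))), "at least one atom")
  expect_error(molecular_graph(data.frame(element = c("C", "H"))), "hydrogens")
  atoms <- data.frame(element = c("C", "C"))
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 3, order = "single")),
               "out of range")
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 1, order = "single")),
               "self-bonds")
  expect_error(molecular_graph(atoms, data.frame(i = c(1, 2), j = c(2, 1),
                                                 order = "single")),
               "duplicate bond")
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 2, order = "ionic")),
               "bond order")
})

test_that("AP atom types classify element, heavy degree and pi electrons", {
  toys <- toy_molecules()
  expect_equal(format(ap_atom_type(toys$propane, 1)), "C(1,0)")
  expect_equal(format(ap_atom_type(toys$propane, 2)), "C(2,0)")
  expect_equal(format(ap_atom_type(toys$methane, 1)), "C(0,0)")
  # benzene carbon: two aromatic bonds -> degree 2, 2 pi electrons
  expect_equal(format(ap_atom_type(toys$benzene, 4)), "C(2,2)")
  # double and triple bond conventions
  co2ish <- molecular_graph(
    atoms = data.frame(element = c("O", "C", "O")),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "double")
  )
  expect_equal(format(ap_atom_type(co2ish, 2)), "C(2,2)")
  expect_equal(format(ap_atom_type(co2ish, 1)), "O(1,1)")
  nitrile <- molecular_graph(
    atoms = data.frame(element = c("C", "N")),
    bonds = data.frame(i = 1, j = 2, order = "triple")
  )
  expect_equal(format(ap_atom_type(nitrile, 2)), "N(1,2)")
  expect_error(ap_atom_type(toys$propane, 4), "out of range")
})

test_that("AP canonical text round-trips to fields", {
  toys <- toy_molecules()
  for (idx in 1:3) {
    t1 <- ap_atom_type(toys$ethanol, idx)
    t2 <- parse_ap_atom_type(format(t1))
    expect_equal(t2$element, t1$element)
    expect_equal(t2$heavy_degree, t1$heavy_degree)
    expect_equal(t2$pi_electrons, t1$pi_electrons)
  }
  expect_error(parse_ap_atom_type("C(1;0)"), "not a canonical")
})

test_that("BP atom types follow the rule table in precedence order", {
  toys <- toy_molecules()
  # sp3 carbon with no heteroatom neighbours -> hydrophobic
  expect_equal(bp_atom_type(toys$propane, 2), "hydrophobic")
  # hydroxyl oxygen (donor and acceptor) -> polar
  expect_equal(bp_atom_type(toys$ethanol, 3), "polar")
  # positively charged quaternary nitrogen -> cation, regardless of H
  nplus <- molecular_graph(
    atoms = data.frame(element = c("N", "C", "C", "C", "C"),
                       formal_charge = c(1L, 0L, 0L, 0L, 0L)),
    bonds = data.frame(i = 1, j = 2:5, order = "single")
  )
  expect_equal(bp_atom_type(nplus, 1), "cation")
  # carboxylate-like oxygen -> anion
  om <- molecular_graph(atoms = data.frame(element = "O", formal_charge = -1L))
  expect_equal(bp_atom_type(om, 1), "anion")
  # ether/carbonyl oxygen: acceptor without H
  ether <- molecular_graph(
    atoms = data.frame(element = c("C", "O", "C"),
                       attached_hydrogens = c(3L, 0L, 3L)),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "single")
  )
  expect_equal(bp_atom_type(ether, 2), "neutral_acceptor")
  # pyridine-like N without H: acceptor; sulfur and halogens
  s_atom <- molecular_graph(atoms = data.frame(element = "S"))
  expect_equal(bp_atom_type(s_atom, 1), "other")
  cl <- molecular_graph(atoms = data.frame(element = "Cl"))
  expect_equal(bp_atom_type(cl, 1), "hydrophobic")
  # every atom of every toy gets exactly one of the seven categories
  cats <- c("cation", "anion", "neutral_donor", "neutral_acceptor",
            "polar", "hydrophobic", "other")
  for (g in toys) {
    for (k in seq_len(nrow(g$atoms))) {
      expect_true(bp_atom_type(g, k) %in% cats)
    }
  }
})

test_that("topological distances are shortest bond paths", {
  toys <- toy_molecules()
  d <- topological_distances(toys$propane)
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 2)
  # 6-ring: opposite atoms at distance 3
  db <- topological_distances(toys$benzene)
  expect_equal(db[1, 4], 3)
  expect_equal(diag(db), rep(0, 6))
  expect_true(isSymmetric(db))
  # disconnected fragments are infinitely far apart
  dd <- topological_distances(toys$two_fragments)
  expect_equal(dd[1, 2], 1)
  expect_true(is.infinite(dd[1, 3]))
})

test_that("topological distances satisfy the triangle inequality", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_graph(sample(3:10, 1))
    d <- topological_distances(g)
    ok <- TRUE
    for (k in seq_len(nrow(d))) {
      relaxed <- outer(d[, k], d[k, ], `+`)  # path through k
      ok <- ok && all(d <= relaxed + 1e-9 | is.infinite(relaxed))
    }
    expect_true(ok)
  }
})

test_that("fingerprints match hand enumeration on the toy fixtures", {
  toys <- toy_molecules()
  fp <- generate_fingerprint(toys$propane, "AP", 7)
  expect_equal(as.integer(fp), c(2L, 1L))
  expect_equal(names(fp), c("AP|C(1,0)|1|C(2,0)", "AP|C(1,0)|2|C(1,0)"))
  # single heavy atom has no pairs
  expect_length(generate_fingerprint(toys$methane, "AP", 7), 0)
  # ethanol restricted to distance 1
  fp1 <- generate_fingerprint(toys$ethanol, "AP", 1)
  expect_equal(as.integer(fp1), c(1L, 1L))
  expect_equal(names(fp1), c("AP|C(1,0)|1|C(2,0)", "AP|C(2,0)|1|O(1,0)"))
  # the shipped expected-fingerprint fixture agrees for every toy molecule
  expected <- jsonlite::read_json(
    system.file("extdata", "toy_expected_ap.json", package = "qsardnn"),
    simplifyVector = TRUE)
  for (nm in names(toys)) {
    fp <- generate_fingerprint(toys[[nm]], "AP", 7)
    exp_counts <- unlist(expected[[nm]])
    if (is.null(exp_counts)) {
      expect_length(fp, 0)
    } else {
      expect_equal(as.integer(fp), unname(exp_counts[names(fp)]))
      expect_setequal(names(fp), names(exp_counts))
    }
  }
})

test_that("connected-graph fingerprint totals are n(n-1)/2 at full range", {
  set.seed(59)
  for (rep in 1:15) {
    g <- random_graph(sample(2:10, 1), connected = TRUE)
    n <- nrow(g$atoms)
    for (scheme in c("AP", "BP")) {
      fp <- generate_fingerprint(g, scheme, max_distance = n)
      expect_equal(sum(fp), n * (n - 1) / 2)
    }
  }
})

test_that("fingerprints are invariant under atom relabeling", {
  set.seed(101)
  for (rep in 1:15) {
    g <- random_graph(sample(3:10, 1))
    perm <- sample.int(nrow(g$atoms))
    inv <- order(perm)
    g2 <- molecular_graph(
      atoms = g$atoms[inv, c("element", "formal_charge", "attached_hydrogens"),
                      drop = FALSE],
      bonds = if (nrow(g$bonds) > 0) {
        data.frame(i = perm[g$bonds$i], j = perm[g$bonds$j], order = g$bonds$order)
      } else g$bonds
    )
    for (scheme in c("AP", "BP")) {
      f1 <- generate_fingerprint(g, scheme, 7)
      f2 <- generate_fingerprint(g2, scheme, 7)
      expect_equal(unclass(f1), unclass(f2), ignore_attr = TRUE)
      expect_equal(names(f1), names(f2))
    }
  }
})

test_that("merge_fingerprints forms a key-disjoint union with additive totals", {
  toys <- toy_molecules()
  ap <- generate_fingerprint(toys$propane, "AP", 7)
  bp <- generate_fingerprint(toys$propane, "BP", 7)
  merged <- merge_fingerprints(ap, bp)
  expect_equal(sum(merged), sum(ap) + sum(bp))
  expect_length(merged, length(ap) + length(bp))
  expect_setequal(names(merged), c(names(ap), names(bp)))
  # empty union empty
  m0 <- merge_fingerprints(generate_fingerprint(toys$methane, "AP"),
                           generate_fingerprint(toys$methane, "BP"))
  expect_length(m0, 0)
  # scheme mismatch is an error
  expect_error(merge_fingerprints(bp, ap), "scheme AP")
  expect_error(merge_fingerprints(ap, ap), "scheme BP")
})

test_that("SDF reading reproduces the hand-built graphs", {
  skip_if_not_installed("ChemmineR")
  sdf_path <- system.file("extdata", "toy_molecules.sdf", package = "qsardnn")
  mols <- suppressWarnings(read_sdf(sdf_path))
  expect_named(mols, c("ethanol", "benzene", "trimethylammonium"))
  toys <- toy_molecules()
  # ethanol: implicit hydrogens filled in by the valence model
  expect_equal(mols$ethanol$atoms$attached_hydrogens, c(3L, 2L, 1L))
  expect_equal(unclass(generate_fingerprint(mols$ethanol, "AP", 7)),
               unclass(generate_fingerprint(toys$ethanol, "AP", 7)),
               ignore_attr = TRUE)
  # benzene via aromatic bond orders
  expect_equal(unclass(generate_fingerprint(mols$benzene, "AP", 7)),
               unclass(generate_fingerprint(toys$benzene, "AP", 7)),
               ignore_attr = TRUE)
  # charged N with one explicit hydrogen folded in: N+ with 3 C and 1 H
  tma <- mols$trimethylammonium
  expect_equal(nrow(tma$atoms), 4L)
  expect_equal(tma$atoms$formal_charge[1], 1L)
  expect_equal(tma$atoms$attached_hydrogens[1], 1L)
  expect_equal(bp_atom_type(tma, 1), "cation")
  # whole-file fingerprint matrix covers the union vocabulary
  mat <- suppressWarnings(fingerprint_sdf(sdf_path, "merged", 7))
  expect_equal(nrow(mat), 3L)
  expect_true(all(mat >= 0))
  ap_eth <- generate_fingerprint(toys$ethanol, "AP", 7)
  expect_equal(unname(mat["ethanol", names(ap_eth)]), as.integer(ap_eth))
})
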