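test_that("load_structure parses records, MODEL blocks and model_policy", {
  f <- write_pdb_fixture(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0)
  ))
  tr <- load_structure(f)
  expect_length(tr$frames, 1L)
  expect_equal(nrow(tr$frames[[1]]$atoms), 2L)

  block <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0))
  f3 <- write_pdb_fixture(c("MODEL     1", block, "ENDMDL",
                            "MODEL     2", block, "ENDMDL",
                            "MODEL     3", block, "ENDMDL"))
  tr3 <- load_structure(f3, model_policy = "all")
  expect_length(tr3$frames, 3L)
  expect_identical(tr3$frames[[1]]$atoms$atom, tr3$frames[[3]]$atoms$atom)
  expect_length(load_structure(f3, model_policy = "first")$frames, 1L)
})

test_that("altloc policy keeps one copy chosen by occupancy, ties by letter", {
  f <- write_pdb_fixture(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(3, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.6, altloc = "B"),
    pdb_line(4, "C", "ALA", "A", 1, 3.0, 0, 0)
  ))
  m <- load_structure(f)$frames[[1]]
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)  # highest occupancy wins

  # tie: altloc letter order
  ft <- write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.5, altloc = "A"),
    pdb_line(3, "CB", "ALA", "A", 1, 9.0, 0, 0)
  ))
  mt <- load_structure(ft)$frames[[1]]
  expect_equal(mt$atoms$x[mt$atoms$atom == "CA"], 2.0)
})

test_that("waters and hydrogens are stripped; unknown elements error without default", {
  f <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_line(2, "O", "HOH", "A", 90, 9, 9, 9, element = "O")),
    pdb_line(3, "H1", "GLY", "A", 1, 1, 1, 1, element = "H")
  ))
  m <- load_structure(f)$frames[[1]]
  expect_equal(nrow(m$atoms), 1L)

  fz <- write_pdb_fixture(pdb_line(1, "FE", "HEM", "A", 1, 0, 0, 0, element = "FE"))
  expect_error(load_structure(fz, keep_hetatm = TRUE), "radius")
  expect_silent(load_structure(fz, keep_hetatm = TRUE, default_radius = 2.0))
  expect_error(load_structure(tempfile(), ), "not found")
  expect_error(load_structure(write_pdb_fixture("REMARK nothing")), "no ATOM")
})

test_that("select_chains subsets and errors on absent chains", {
  g <- cached_trimer(20, 8, 8, 8, 5)
  m <- g$model
  a <- select_chains(m, "A")
  expect_equal(unique(a$atoms$chain), "A")
  expect_equal(nrow(a$atoms), 20L)
  expect_identical(select_chains(m, c("A", "B", "C"))$atoms, m$atoms)
  expect_error(select_chains(m, "Z"), "not present")
})

test_that("calpha_coordinates returns residues in order and warns on missing CA", {
  f <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0)
  ))
  ca <- calpha_coordinates(load_structure(f)$frames[[1]])
  expect_equal(ca$resno, 1:3)
  expect_equal(ca$x, c(0, 3.8, 7.6))

  fm <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "N", "GLY", "A", 2, 3.8, 0, 0, element = "N"),
    pdb_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0)
  ))
  expect_warning(ca2 <- calpha_coordinates(load_structure(fm)$frames[[1]]),
                 "skipped")
  expect_equal(ca2$resno, c(1L, 3L))
  m_noca <- make_model(rbind(c(0, 0, 0)), atom = "CB")
  expect_error(calpha_coordinates(m_noca), "no CA")
})

test_that("sasa matches closed forms: isolated, additive, buried", {
  one <- make_model(rbind(c(0, 0, 0)), vdw = 1.7)
  expect_equal(as.numeric(sasa(one, 1.4, 960)), 4 * pi * 3.1^2, tolerance = 1e-12)

  two_far <- make_model(rbind(c(0, 0, 0), c(100, 0, 0)), vdw = 1.7)
  expect_equal(as.numeric(sasa(two_far, 1.4, 960)), 2 * 4 * pi * 3.1^2,
               tolerance = 1e-12)

  buried <- make_model(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  buried$atoms$vdw_radius <- c(3.0, 0.5)
  s <- sasa(buried, 1.0, 960)
  expect_equal(attr(s, "per_atom")$area[2], 0)
  expect_error(sasa(one, -1), "positive")
  expect_error(sasa(one, 1.4, 50), ">= 100")
})

test_that("sasa is monotone in probe radius and converges with lattice size", {
  one <- make_model(rbind(c(0, 0, 0)), vdw = 1.7)
  areas <- vapply(c(1.0, 1.4, 1.8), function(p) as.numeric(sasa(one, p, 200)),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_equal(areas, 4 * pi * (1.7 + c(1.0, 1.4, 1.8))^2, tolerance = 1e-12)

  cloud <- gen_ellipsoid_cloud(c(8, 10, 13), n = 50, mode = "filled", seed = 3)
  m <- make_model(cloud$points)
  s1 <- as.numeric(sasa(m, 1.4, 480))
  s2 <- sasa(m, 1.4, 960)
  expect_lt(abs(as.numeric(s2) - s1) / as.numeric(s2), 0.005)
  expect_equal(as.numeric(s2), sum(attr(s2, "per_atom")$area))
})

test_that("rmsd_series: identity, rigid translation, single displacement", {
  g <- cached_trimer(20, 8, 8, 8, 5)
  m <- g$model
  traj <- oligotopo:::new_trajectory(list(m, m, m), 0:2)
  expect_equal(rmsd_series(traj)$rmsd, rep(0, 3), tolerance = 1e-10)

  m_shift <- m
  m_shift$atoms$x <- m$atoms$x + 5
  tr2 <- oligotopo:::new_trajectory(list(m, m_shift), 0:1)
  expect_equal(rmsd_series(tr2, superpose = TRUE)$rmsd[2], 0, tolerance = 1e-8)
  expect_equal(rmsd_series(tr2, superpose = FALSE)$rmsd[2], 5, tolerance = 1e-10)

  # one atom displaced by 2 A among N atoms, no superposition: 2/sqrt(N)
  xyz <- gen_ellipsoid_cloud(c(20, 25, 30), n = 100, mode = "filled", seed = 8)$points
  m1 <- make_model(xyz)
  xyz2 <- xyz; xyz2[7, 3] <- xyz2[7, 3] + 2
  tr3 <- oligotopo:::new_trajectory(list(m1, make_model(xyz2)), 0:1)
  expect_equal(rmsd_series(tr3, selection = "all", superpose = FALSE)$rmsd[2],
               2 / sqrt(100), tolerance = 1e-10)
})

test_that("rmsd_series is invariant under rigid motion of all frames", {
  xyz <- gen_ellipsoid_cloud(c(10, 14, 19), n = 40, mode = "filled", seed = 2)$points
  xyz2 <- xyz + matrix(rnorm(120, sd = 0.5), 40, 3)
  tr <- oligotopo:::new_trajectory(list(make_model(xyz), make_model(xyz2)), 0:1)
  R <- oligotopo:::rotation_from_euler(c(0.3, 1.2, -0.8))
  move <- function(x) sweep(x %*% t(R), 2, c(7, -3, 11), "+")
  tr_m <- oligotopo:::new_trajectory(list(make_model(move(xyz)),
                                          make_model(move(xyz2))), 0:1)
  expect_equal(rmsd_series(tr, selection = "all")$rmsd,
               rmsd_series(tr_m, selection = "all")$rmsd, tolerance = 1e-8)
})

test_that("PDB write/load round trip preserves identity and coordinates", {
  g <- cached_trimer(20, 8, 8, 8, 5)
  f <- tempfile(fileext = ".pdb")
  write_pdb(g$model, f)
  back <- load_structure(f)$frames[[1]]
  expect_identical(back$atoms[, c("chain", "resno", "atom")],
                   g$model$atoms[, c("chain", "resno", "atom")])
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(g$model$atoms[, c("x", "y", "z")]))), 1e-3)
})
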