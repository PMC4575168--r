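test_that("the PDB reader parses ATOM records and handles edge cases", {
  tf <- tempfile(fileext = ".pdb")
  at <- rbind(pdb_atom("N", 1, 0, 0, 0, element = "N"),
              pdb_atom("CA", 1, 1.46, 0, 0),
              pdb_atom("C", 1, 2.0, 1.4, 0))
  write_pdb(tf, at)
  st <- parse_structure(tf)
  expect_equal(nrow(st), 3)
  expect_equal(st$x, c(0, 1.46, 2.0))
  expect_equal(st$radius, c(1.55, 1.7, 1.7))
  expect_equal(st$resname, rep("ALA", 3))
  # multi-model: first model only
  lines <- readLines(tf)
  body <- lines[1:3]
  writeLines(c("MODEL     1", body, "ENDMDL", "MODEL     2", body, body,
               "ENDMDL", "END"), tf)
  expect_equal(nrow(parse_structure(tf)), 3)
  # unknown element falls back to the default radius with a warning
  at2 <- pdb_atom("FE", 1, 0, 0, 0, resname = "HEM", element = "FE")
  write_pdb(tf, at2)
  expect_warning(st2 <- parse_structure(tf), "unknown element")
  expect_equal(st2$radius, 1.7)
  writeLines(c("REMARK nothing here", "END"), tf)
  expect_error(parse_structure(tf), "no ATOM")
})

test_that("Shrake-Rupley SASA matches analytic spheres", {
  tf <- tempfile(fileext = ".pdb")
  write_pdb(tf, pdb_atom("CA", 1, 0, 0, 0))
  s1 <- sasa(parse_structure(tf))
  expect_equal(s1$atom_area, 4 * pi * 3.1^2, tolerance = 0.01)
  # additivity for far-apart atoms
  write_pdb(tf, rbind(pdb_atom("CA", 1, 0, 0, 0),
                      pdb_atom("CA", 2, 100, 0, 0)))
  s2 <- sasa(parse_structure(tf))
  expect_equal(sum(s2$atom_area), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # an atom caged by a dense shell of neighbours is buried (< 1 A^2)
  shell <- expand.grid(x = c(-2.2, 0, 2.2), y = c(-2.2, 0, 2.2),
                       z = c(-2.2, 0, 2.2))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  cage <- rbind(pdb_atom("CA", 1, 0, 0, 0),
                pdb_atom("O", 2, shell$x, shell$y, shell$z, element = "O"))
  write_pdb(tf, cage)
  s3 <- sasa(parse_structure(tf))
  expect_lt(s3$atom_area[1], 1)
  expect_error(sasa(parse_structure(tf), n_points = 10))
})

test_that("SASA is invariant under rigid motions and point-density stable", {
  set.seed(14)
  base <- rbind(pdb_atom("CB", 1, 0, 0, 0),
                pdb_atom("CB", 2, 3, 1, 0),
                pdb_atom("O", 3, 1, 2.5, 1, element = "O"),
                pdb_atom("N", 4, -1, 1, 2, element = "N"))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(tf, base)
  st <- parse_structure(tf)
  a0 <- sum(sasa(st)$atom_area)
  for (i in 1:3) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                   0, 0, 1), 3, 3)
    xyz <- as.matrix(base[, c("x", "y", "z")]) %*% (Rx %*% Rz)
    rot <- base
    rot$x <- xyz[, 1] + runif(1, -5, 5)
    rot$y <- xyz[, 2] + runif(1, -5, 5)
    rot$z <- xyz[, 3] + runif(1, -5, 5)
    write_pdb(tf, rot)
    ar <- sum(sasa(parse_structure(tf))$atom_area)
    expect_lt(abs(ar - a0) / a0, 0.005)
  }
  # discretisation stability: 960 vs 4000 points within 2%
  a_fine <- sum(sasa(st, n_points = 4000)$atom_area)
  expect_lt(abs(a0 - a_fine) / a_fine, 0.02)
})

test_that("relative SASA classifies exposure at the 40% threshold", {
  tf <- tempfile(fileext = ".pdb")
  # a lone glycine backbone: area close to (and above) its reference
  write_pdb(tf, rbind(pdb_atom("N", 1, -1.46, 0, 0, resname = "GLY",
                               element = "N"),
                      pdb_atom("CA", 1, 0, 0, 0, resname = "GLY"),
                      pdb_atom("C", 1, 1.52, 0, 0, resname = "GLY"),
                      pdb_atom("O", 1, 2.2, 1.1, 0, resname = "GLY",
                               element = "O")))
  st <- parse_structure(tf)
  area <- sasa(st)$residue_area$area
  rs <- relative_sasa(area, "GLY")
  expect_gt(rs$rel_sasa, 0.85)
  expect_true(rs$exposed)
  expect_false(relative_sasa(30, "G")$exposed)   # buried
  expect_true(relative_sasa(0.40 * MAX_SASA[["G"]], "G")$exposed)  # boundary
  expect_error(relative_sasa(50, "XYZ"), "unknown residue")
})

test_that("alanine truncation removes side chains beyond the beta carbon", {
  tf <- tempfile(fileext = ".pdb")
  arg <- rbind(
    pdb_atom("N", 30, 0, 0, 0, resname = "ARG", element = "N"),
    pdb_atom("CA", 30, 1.5, 0, 0, resname = "ARG"),
    pdb_atom("C", 30, 2.2, 1.3, 0, resname = "ARG"),
    pdb_atom("O", 30, 3.2, 1.3, 0.5, resname = "ARG", element = "O"),
    pdb_atom("CB", 30, 1.9, -1.2, 0.8, resname = "ARG"),
    pdb_atom("CG", 30, 2.5, -2.4, 0.2, resname = "ARG"),
    pdb_atom("CD", 30, 3.0, -3.5, 1.1, resname = "ARG"),
    pdb_atom("NE", 30, 3.6, -4.6, 0.4, resname = "ARG", element = "N"),
    pdb_atom("CA", 31, 4.5, 0, 0, resname = "GLY"))
  write_pdb(tf, arg)
  st <- parse_structure(tf)
  tr <- ala_truncate(st, 30)
  expect_equal(sort(tr[tr$resno == 30]$atom), c("C", "CA", "CB", "N", "O"))
  expect_lt(nrow(tr), nrow(st))
  # glycine (no CB) is untouched
  tr2 <- ala_truncate(st, 31)
  expect_equal(nrow(tr2), nrow(st))
  expect_error(ala_truncate(st, 99))
})

test_that("orientation search sees an isolated sphere as a disc", {
  tf <- tempfile(fileext = ".pdb")
  write_pdb(tf, pdb_atom("CB", 1, 0, 0, 0))
  st <- parse_structure(tf)
  oa <- orientation_accessibility(st, 1)
  expect_equal(unname(oa), pi * 1.7^2, tolerance = 0.03)
  expect_error(orientation_accessibility(st, integer(0)), "no diversified")
})

test_that("occlusion: a caged sphere is visible only along the open axis", {
  # sphere at origin; occluding walls on five sides, open toward +z
  wall <- function(axis, sign) {
    g <- expand.grid(u = seq(-6, 6, 1.5), v = seq(-6, 6, 1.5))
    co <- switch(axis,
                 x = data.frame(x = sign * 5, y = g$u, z = g$v),
                 y = data.frame(x = g$u, y = sign * 5, z = g$v),
                 z = data.frame(x = g$u, y = g$v, z = sign * 5))
    pdb_atom("O", 2, co$x, co$y, co$z, resname = "HOH", element = "O")
  }
  atoms <- rbind(pdb_atom("CB", 1, 0, 0, 0),
                 wall("x", 1), wall("x", -1), wall("y", 1), wall("y", -1),
                 wall("z", -1))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(tf, atoms)
  st <- parse_structure(tf)
  oa <- orientation_accessibility(st, 1, coarse_step = 15)
  # the best orientation looks down the open +z axis and sees ~ pi r^2
  expect_equal(unname(oa), pi * 1.7^2, tolerance = 0.05 * pi * 1.7^2)
  # a fully caged target is essentially invisible from everywhere
  atoms2 <- rbind(atoms, wall("z", 1))
  write_pdb(tf, atoms2)
  oa2 <- orientation_accessibility(parse_structure(tf), 1,
                                   coarse_step = 15)
  expect_lt(unname(oa2), 0.2 * pi * 1.7^2)
})

test_that("orientation accessibility is rotation invariant (<= 3%)", {
  base <- rbind(pdb_atom("CB", 1, 0, 0, 0),
                pdb_atom("CB", 2, 4, 0.5, 0),
                pdb_atom("O", 3, 2, 2, 1, element = "O"))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(tf, base)
  oA <- orientation_accessibility(parse_structure(tf), 1:2,
                                  coarse_step = 15)
  th <- 0.6
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(base[, c("x", "y", "z")]) %*% Rz
  rot <- base; rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  write_pdb(tf, rot)
  oB <- orientation_accessibility(parse_structure(tf), 1:2,
                                  coarse_step = 15)
  expect_lt(max(abs(oA - oB) / oA), 0.03)
  # accessibility never exceeds the isolated-sphere cross-section
  expect_true(all(oA <= pi * 1.7^2 * 1.03))
})

test_that("exposure scores combine SASA and accessibility over structures", {
  tf1 <- tempfile(fileext = ".pdb"); tf2 <- tempfile(fileext = ".pdb")
  mk <- function(path, shift) {
    at <- rbind(
      pdb_atom("CA", 1, 0 + shift, 0, 0),
      pdb_atom("CB", 1, 1.2 + shift, 1.2, 0),
      pdb_atom("CA", 2, 4 + shift, 0, 0),
      pdb_atom("CB", 2, 5 + shift, -1, 0.5))
    write_pdb(path, at)
    parse_structure(path)
  }
  s1 <- mk(tf1, 0); s2 <- mk(tf2, 0.3)
  ep <- exposure_score(list(s1, s2), c(1, 2), site_labels = c("A1", "B2"))
  expect_equal(ep$site, c("A1", "B2"))
  expect_true(all(ep$eps >= 0 & ep$eps <= 1))
  expect_equal(max(ep$eps), 1)
  # single structure, single site normalises to exactly 1
  ep1 <- exposure_score(list(s1), 1)
  expect_equal(ep1$eps, 1)
  # hand-check the averaging against per-structure components
  comp <- lapply(list(s1, s2), function(st) {
    sa <- sasa(st)$residue_area
    tr <- ala_truncate(st, c(1, 2))
    oa <- orientation_accessibility(tr, c(1, 2))
    rel <- relative_sasa(sa$area, sa$resname)$rel_sasa
    list(rel = rel, acc = unname(oa))
  })
  rel_m <- colMeans(rbind(comp[[1]]$rel, comp[[2]]$rel))
  acc_m <- colMeans(rbind(comp[[1]]$acc, comp[[2]]$acc))
  eps_hand <- rel_m * acc_m
  eps_hand <- eps_hand / max(eps_hand)
  expect_equal(ep$eps, unname(eps_hand), tolerance = 1e-9)
  expect_error(exposure_score(list(s1), 9), "absent")
})
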