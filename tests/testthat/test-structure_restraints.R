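test_that("PDB parsing handles fixtures, altlocs and degenerate files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   LYS A 606      11.104  13.207  10.000  1.00 20.00",
    "ATOM      2  CA  LYS A 606      12.560  13.300  10.000  1.00 20.00",
    "ATOM      3  NZ  LYS A 606      15.000  16.000  12.000  1.00 20.00"),
    f)
  m <- read_pdb(f)
  expect_identical(nrow(m), 3L)
  expect_identical(unique(m$chain), "A")
  expect_identical(unique(m$resno), 606L)
  expect_setequal(m$atom, c("N", "CA", "NZ"))
  # no ATOM records
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(read_pdb(f2), "no ATOM records")
  expect_error(read_pdb(file.path(tempdir(), "absent.pdb")), "no such file")
  # malformed coordinates reported with a line number
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "ATOM      1  CA  LYS A 606      xx.xxx  13.300  10.000  1.00 20.00", f3)
  expect_error(read_pdb(f3), "line 1")
  # alternate locations resolve to the highest occupancy
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  NZ ALYS A 606       0.000   0.000   0.000  0.40 20.00",
    "ATOM      2  NZ BLYS A 606       9.000   0.000   0.000  0.60 20.00"),
    f4)
  m4 <- read_pdb(f4)
  expect_identical(nrow(m4), 1L)
  expect_equal(m4$x, 9.0)
})

test_that("PDB write/read round trip preserves coordinates to 0.001 A", {
  withr::with_seed(12, {
    atoms <- data.frame(
      chain = rep(c("A", "B"), each = 6),
      resno = rep(c(601L, 602L, 603L), each = 2, times = 2),
      resname = "LYS", atom = rep(c("CA", "NZ"), 6),
      x = runif(12, -50, 50), y = runif(12, -50, 50), z = runif(12, -50, 50),
      stringsAsFactors = FALSE)
  })
  m <- structure_model(atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  for (col in c("x", "y", "z"))
    expect_equal(m2[[col]], m[[col]], tolerance = 1e-3)
  expect_identical(m2$chain, m$chain)
  expect_identical(m2$resno, m$resno)
})

test_that("multi-copy chains keep only the first instance", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  LYS A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  LYS B   1       5.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  LYS A   1      99.000   0.000   0.000  1.00  0.00"),
    f)
  m <- read_pdb(f, first_chain_instance = TRUE)
  expect_identical(nrow(m), 2L)
  expect_equal(m$x[m$chain == "A"], 0)
})

test_that("anchor distances follow the Euclidean formula with NZ/CB/CA fallback", {
  atoms <- data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 1L, 2L), resname = "LYS",
    atom = c("CA", "NZ", "CA"),
    x = c(9, 0, 3), y = c(9, 0, 4), z = c(9, 0, 0),
    stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  # B/2 has no NZ or CB: falls back to CA; 3-4-5 triangle against A/1 NZ
  expect_equal(anchor_distance(m, anchor_spec("A", 1), anchor_spec("B", 2)), 5)
  expect_equal(anchor_distance(m, anchor_spec("A", 1), anchor_spec("A", 1)), 0)
  expect_error(anchor_distance(m, anchor_spec("A", 1), anchor_spec("C", 9)),
               "C/9")
  # random fixture against the hand formula; symmetry; triangle inequality
  withr::with_seed(21, {
    for (rep in 1:20) {
      p <- matrix(runif(9, -30, 30), 3)
      am <- structure_model(data.frame(
        chain = "A", resno = 1:3, resname = "LYS", atom = "NZ",
        x = p[, 1], y = p[, 2], z = p[, 3], stringsAsFactors = FALSE))
      a1 <- anchor_spec("A", 1); a2 <- anchor_spec("A", 2)
      a3 <- anchor_spec("A", 3)
      d12 <- anchor_distance(am, a1, a2)
      expect_equal(d12, sqrt(sum((p[1, ] - p[2, ])^2)), tolerance = 1e-6)
      expect_equal(d12, anchor_distance(am, a2, a1))
      expect_lte(anchor_distance(am, a1, a3),
                 d12 + anchor_distance(am, a2, a3) + 1e-9)
    }
  })
})

test_that("restraint evaluation applies the <= cap rule and flags unresolvables", {
  rec <- receptor_fixture()
  ctrl <- xl_restraint(anchor_spec("A", 606), anchor_spec("B", 559), cap = 15,
                       role = "control")
  tails <- xl_restraint(anchor_spec("A", 672), anchor_spec("B", 615), cap = 15)
  missing <- xl_restraint(anchor_spec("Z", 1), anchor_spec("A", 606))
  ev <- evaluate_restraints(rec, list(ctrl, tails, missing))
  expect_equal(ev$distance[1], 11.2, tolerance = 0.01)
  expect_true(ev$satisfied[1])                 # 11.2 <= 15
  expect_equal(ev$distance[2], 61.3, tolerance = 0.01)
  expect_false(ev$satisfied[2])                # 61.3 > 15
  expect_false(ev$evaluable[3])                # reported, not dropped
  # boundary: a distance exactly at the cap satisfies
  bm <- make_structure_fixture(data.frame(chain = c("A", "B"),
                                          resno = c(1L, 2L)),
                               matrix(c(0, 15, 15, 0), 2))
  evb <- evaluate_restraints(bm, list(xl_restraint(anchor_spec("A", 1),
                                                   anchor_spec("B", 2),
                                                   cap = 15)))
  expect_true(evb$satisfied[1])
  # verdicts invariant under rigid rotation + translation
  R <- random_rotation(3)
  rec2 <- transform_structure(rec, R, c(12, -7, 30))
  ev2 <- evaluate_restraints(rec2, list(ctrl, tails))
  expect_identical(ev2$satisfied, ev$satisfied[1:2])
  expect_equal(ev2$distance, ev$distance[1:2], tolerance = 1e-9)
})

test_that("bridging feasibility reproduces the mutual-exclusivity bounds", {
  # colocated-anchor bound: 2 x 15 = 30; 61.3 exceeds it
  r <- bridging_feasibility(61.3, cap = 15, mode = "paper")
  expect_identical(r$bound, 30)
  expect_false(r$feasible)
  expect_true(bridging_feasibility(0, cap = 15, mode = "paper")$feasible)
  expect_true(bridging_feasibility(0, 0, cap = 15, mode = "triangle")$feasible)
  expect_true(bridging_feasibility(29.9, cap = 15, mode = "paper")$feasible)
  # paper mode implies triangle mode whenever d_ligand <= 2 cap
  withr::with_seed(91, {
    for (rep in 1:50) {
      dr <- runif(1, 0, 80); dl <- runif(1, 0, 30); cap <- 15
      pm <- bridging_feasibility(dr, cap = cap, mode = "paper")$feasible
      tm <- bridging_feasibility(dr, dl, cap = cap, mode = "triangle")$feasible
      if (pm) expect_true(tm)
    }
  })
})

test_that("triangle mode agrees with a brute-force rigid placement search", {
  # oracle: place ligand anchor 1 in the cap-ball of receptor anchor 1 and
  # ligand anchor 2 anywhere on the d_ligand sphere around it, and ask
  # whether any placement also puts anchor 2 within cap of receptor anchor 2.
  # By rotational symmetry about the receptor axis the search reduces to a
  # dense 2-D grid (on-axis offset a, in-plane angle phi).  Geometries
  # within the grid resolution of the feasibility boundary are excluded.
  withr::with_seed(1234, {
    n_checked <- 0
    while (n_checked < 100) {
      dr <- runif(1, 5, 70); dl <- runif(1, 0, 50); cap <- runif(1, 5, 20)
      if (abs(abs(dr - dl) - 2 * cap) < 1) next   # boundary band
      a <- seq(-cap, cap, length.out = 301)
      phi <- seq(0, pi, length.out = 601)
      dx <- outer(a, dl * cos(phi), "+") - dr
      dy2 <- matrix(rep((dl * sin(phi))^2, each = length(a)),
                    nrow = length(a))
      grid_feasible <- min(sqrt(dx^2 + dy2)) <= cap
      tri <- bridging_feasibility(dr, dl, cap = cap, mode = "triangle")
      expect_identical(tri$feasible, grid_feasible)
      n_checked <- n_checked + 1
    }
  })
})

test_that("restraint tables round trip through TSV", {
  rs <- list(
    xl_restraint(anchor_spec("A", 672), anchor_spec("P", 409), cap = 15,
                 label = "a672-p409"),
    xl_restraint(anchor_spec("A", 606), anchor_spec("B", 559), cap = 15,
                 label = "ctrl", role = "control"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints_tsv(rs, f)
  back <- read_restraints_tsv(f)
  expect_identical(length(back), 2L)
  expect_identical(back[[2]]$role, "control")
  expect_identical(back[[1]]$anchor2$resno, 409L)
  expect_identical(back[[1]]$cap, 15)
})
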