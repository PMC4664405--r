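evidence_restraint <- function(cap = 15)
  xl_restraint(anchor_spec("B", 615), anchor_spec("L", 370), cap = cap,
               label = "b615-l370")

control_restraint <- function(cap = 15)
  xl_restraint(anchor_spec("A", 606), anchor_spec("B", 559), cap = cap,
               role = "control", label = "ctrl")

test_that("pose screening recovers exactly the planted satisfying poses", {
  rec <- receptor_fixture()
  pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 100,
                           f = 0.07, seed = 42)
  sc <- screen_poses(pe$pose_set,
                     list(evidence_restraint(), control_restraint()))
  expect_identical(unname(sc$summary["accepted"]), 7L)
  expect_setequal(sc$verdicts$pose_id[sc$verdicts$verdict == "accepted"],
                  pe$truth$pose_id[pe$truth$satisfying])
  # the control (11.2 A) passes in every pose; rejections come from evidence
  ctrl <- sc$evaluations[sc$evaluations$label == "ctrl", ]
  expect_true(all(ctrl$satisfied))
  expect_equal(unique(round(ctrl$distance, 1)), 11.2)
})

test_that("degenerate caps and duplicated poses behave as defined", {
  rec <- receptor_fixture()
  pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 20, f = 0.5,
                           seed = 7)
  # cap 0: only coincident anchors would pass; none do for generic poses
  sc0 <- screen_poses(pe$pose_set, list(evidence_restraint(cap = 0)))
  expect_identical(unname(sc0$summary["accepted"]), 0L)
  # duplicating a satisfying pose yields two accepted identical records
  sat_id <- pe$truth$pose_id[pe$truth$satisfying][1]
  dup <- pose_set(rec, list(p1 = pe$pose_set$poses[[sat_id]],
                            p2 = pe$pose_set$poses[[sat_id]]))
  scd <- screen_poses(dup, list(evidence_restraint()))
  expect_identical(unname(scd$summary["accepted"]), 2L)
  expect_equal(scd$evaluations$distance[1], scd$evaluations$distance[2])
})

test_that("accepted set is invariant to pose order and joint rigid transforms", {
  rec <- receptor_fixture()
  pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 30, f = 0.3,
                           seed = 9)
  rs <- list(evidence_restraint(), control_restraint())
  sc <- screen_poses(pe$pose_set, rs)
  shuffled <- pose_set(rec, rev(pe$pose_set$poses))
  sc2 <- screen_poses(shuffled, rs)
  expect_setequal(sc$verdicts$pose_id[sc$verdicts$verdict == "accepted"],
                  sc2$verdicts$pose_id[sc2$verdicts$verdict == "accepted"])
  # joint rigid transform of receptor + ligand
  R <- random_rotation(5); tr <- c(-20, 4, 33)
  rec_t <- transform_structure(rec, R, tr)
  poses_t <- lapply(pe$pose_set$poses, transform_structure, rotation = R,
                    translation = tr)
  sc3 <- screen_poses(pose_set(rec_t, poses_t), rs)
  expect_identical(sc3$verdicts$verdict, sc$verdicts$verdict)
  expect_equal(sc3$evaluations$distance, sc$evaluations$distance,
               tolerance = 1e-9)
})

test_that("poses with unresolvable anchors are counted, not accepted", {
  rec <- receptor_fixture()
  pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 5, f = 1,
                           seed = 3)
  broken <- pe$pose_set$poses
  broken[[2]] <- structure_model(data.frame(
    chain = "L", resno = 999L, resname = "LYS", atom = "NZ",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  sc <- screen_poses(pose_set(rec, broken), list(evidence_restraint()))
  expect_identical(unname(sc$summary["unevaluable"]), 1L)
  expect_identical(unname(sc$summary["accepted"]), 4L)
})

test_that("the acceptance-rate estimator hits the planted fraction", {
  rec <- receptor_fixture()
  rates <- vapply(1:20, function(seed) {
    pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 100,
                             f = 0.3, seed = seed)
    sc <- screen_poses(pe$pose_set, list(evidence_restraint()))
    unname(sc$summary["accepted"]) / 100
  }, 0)
  # the generator plants exactly floor(f n) satisfying poses and the screen
  # recovers them exactly, so every seed returns f
  expect_equal(mean(rates), 0.3, tolerance = 1e-12)
  expect_true(all(rates == 0.3))
})

test_that("the exclusivity report reproduces the two-site verdict logic", {
  rep1 <- exclusivity_report(d_receptor = 61.3, d_ligand = 25, cap = 15)
  expect_false(rep1$paper$feasible)
  expect_identical(rep1$paper$bound, 30)
  expect_match(rep1$verdict, "infeasible")
  expect_match(rep1$verdict, "30")
  rep2 <- exclusivity_report(d_receptor = 29.9, d_ligand = 25, cap = 15)
  expect_true(rep2$paper$feasible)
  expect_match(rep2$verdict, "feasible")
  # swapping which ligand anchor maps to which receptor anchor (equal caps)
  rep3 <- exclusivity_report(d_receptor = 61.3, d_ligand = 25, cap = 15)
  expect_identical(rep3$paper$feasible, rep1$paper$feasible)
  expect_identical(rep3$triangle$feasible, rep1$triangle$feasible)
  expect_output(print(rep1), "verdict")
})

test_that("screen results export to TSV and JSON", {
  rec <- receptor_fixture()
  pe <- make_pose_ensemble(rec, list(evidence_restraint()), n = 10, f = 0.5,
                           seed = 2)
  sc <- screen_poses(pe$pose_set, list(evidence_restraint()))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_screen_results(sc, tsv, js)
  back <- read.delim(tsv)
  expect_identical(nrow(back), 10L)
  summ <- jsonlite::read_json(js)
  expect_identical(summ$accepted, 5L)
})
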