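# Trajectory IO, Kabsch superposition, RMSD metrics, distance features.

test_that("feature CSV round-trips values and metadata", {
  v <- matrix(c(4.1, 4.3, 14.9, 1.0, 2.0, 3.0), ncol = 2,
              dimnames = list(NULL, c("d1", "d2")))
  ft <- featureTrajectory(v, frameInterval = 0.5, timeUnit = "ns",
                          source = "unit")
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(ft, path)
  back <- readFeatureCSV(path)
  expect_equal(featureValues(back), featureValues(ft), tolerance = 1e-9)
  expect_identical(frameInterval(back), 0.5)
  expect_identical(timeUnit(back), "ns")
  expect_identical(back@source, "unit")
})

test_that("feature CSV reader rejects malformed files with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  # frame index gap 0,1,3 -> row 3 is file line 4
  writeLines(c("frame,time,d1", "0,0,4.1", "1,1,4.2", "3,3,4.4"), path)
  expect_error(readFeatureCSV(path), "non-contiguous frames at line 4")
  writeLines(c("frame,time,d1", "0,0,4.1", "1,1"), path)
  expect_error(readFeatureCSV(path), "ragged row at line 3")
  writeLines(character(), path)
  expect_error(readFeatureCSV(path), "empty|header")
  writeLines(c("frame,time,d1"), path)
  expect_error(readFeatureCSV(path), "no data rows")
  expect_error(readFeatureCSV(file.path(tempdir(), "absent.csv")),
               "does not exist")
})

test_that("XYZ round-trips coordinates and labels", {
  toy <- makeToyStructures(3, 0.2, seed = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(toy$trajectory, path)
  back <- readXYZ(path, alignmentSubset = 1:8, metricSubset = 9:11)
  expect_equal(back@coords, toy$trajectory@coords, tolerance = 1e-9)
  expect_identical(back@atomLabels, toy$trajectory@atomLabels)
})

test_that("Kabsch superposition undoes rigid motions", {
  set.seed(5)
  ref <- matrix(rnorm(15), 5, 3)
  same <- kabschSuperpose(ref, ref)
  expect_lt(same$rmsd, 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- ref %*% t(Rz) + rep(c(5, 0, 0), each = 5)
  fit <- kabschSuperpose(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("reflections are disallowed: mirror image of a chiral frame keeps
           a positive residual equal to the rotation-only optimum", {
  set.seed(6)
  ref <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.2, 0, 0.3, 0.4, 1.1),
                4, 3, byrow = TRUE)
  mirror <- ref %*% diag(c(1, 1, -1))
  fit <- kabschSuperpose(mirror, ref)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  oracle <- bruteForceFitRMSD(mirror, ref, 1:4)
  expect_lt(abs(fit$rmsd - oracle), 1e-3)
  # and the Kabsch result is never beaten by any sampled rotation
  expect_lte(fit$rmsd, oracle + 1e-9)
})

test_that("degenerate alignment subsets are rejected", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabschSuperpose(line, line + 1), "collinear|degenerate")
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3), 1:2),
               "at least 3")
})

test_that("metric RMSD measures uniform metric-subset displacement exactly", {
  set.seed(7)
  a <- rbind(matrix(rnorm(24), 8, 3), matrix(rnorm(9), 3, 3))
  b <- a
  shift <- c(2, 0, 0)  # |shift| = 2 Angstrom on the metric atoms only
  b[9:11, ] <- b[9:11, ] + rep(shift, each = 3)
  expect_equal(metricRMSD(a, b, 1:8, 9:11), 2, tolerance = 1e-9)
  expect_equal(metricRMSD(a, a, 1:8, 9:11), 0, tolerance = 1e-12)
})

test_that("metric RMSD is a pseudo-metric on toy frames", {
  set.seed(8)
  toy <- makeToyStructures(9, 0.8, seed = 8)
  tr <- toy$trajectory
  al <- tr@alignmentSubset; me <- tr@metricSubset
  fr <- lapply(1:9, function(i) getFrame(tr, i))
  for (i in 1:6) {
    a <- fr[[i]]; b <- fr[[i + 1]]; c <- fr[[i + 2]]
    dab <- metricRMSD(a, b, al, me)
    dba <- metricRMSD(b, a, al, me)
    expect_lt(abs(dab - dba), 1e-9)                       # symmetry
    expect_gte(dab, 0)                                     # non-negativity
    dac <- metricRMSD(a, c, al, me)
    dbc <- metricRMSD(b, c, al, me)
    expect_lte(dac, dab + dbc + 1e-9)                      # triangle
  }
})

test_that("superposing on the metric subset itself minimizes its RMSD", {
  set.seed(9)
  for (rep in 1:5) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    fitted <- metricRMSD(a, b, 1:6, 1:6)
    expect_lte(fitted, rawRMSD(a, b) + 1e-9)
    # no random rigid motion of a does better
    toyR <- kabschSuperpose(matrix(rnorm(18), 6, 3),
                            matrix(rnorm(18), 6, 3))$rotation
    moved <- a %*% t(toyR) + rep(rnorm(3), each = 6)
    expect_lte(fitted, rawRMSD(moved, b) + 1e-9)
  }
})

test_that("distance features compute center-of-geometry separations", {
  coords <- array(0, dim = c(4, 3, 2))
  # frame 1: atoms at origin / (3,4,0); two-atom set {(0,0,0),(2,0,0)} vs (1,4,0)
  coords[1, , 1] <- c(0, 0, 0)
  coords[2, , 1] <- c(3, 4, 0)
  coords[3, , 1] <- c(2, 0, 0)
  coords[4, , 1] <- c(1, 4, 0)
  coords[, , 2] <- coords[, , 1]
  tr <- coordinateTrajectory(coords, atomLabels = c("A", "B", "C", "D"))
  ft <- distanceFeatures(tr, list(
    list(a = "A", b = "B"),          # 3-4-5 triangle
    list(a = c("A", "C"), b = "D"),  # center (1,0,0) to (1,4,0)
    list(a = "A", b = "A")),         # coincident
    names = c("d345", "dcog", "dzero"))
  v <- featureValues(ft)
  expect_equal(unname(v[1, ]), c(5, 4, 0), tolerance = 1e-12)
  expect_error(distanceFeatures(tr, list(list(a = "Z", b = "A"))),
               "unknown atom label")
})
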