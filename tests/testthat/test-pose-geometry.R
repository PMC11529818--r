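test_that("body vector is the abdomen-to-head principal axis", {
  expect_equal(bodyVector(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0)), c(1, 0, 0))
  expect_equal(bodyVector(c(-2, 0, 0), c(-1, 0, 0), c(0, 0, 0)), c(-1, 0, 0))
  expect_true(all(is.na(bodyVector(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))))

  # noisy near-collinear triple matches a direct total-least-squares fit
  set.seed(31)
  for (k in 1:20) {
    P <- rbind(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0)) + matrix(rnorm(9, 0, 0.05), 3)
    v <- bodyVector(P[1, ], P[2, ], P[3, ])
    sv <- svd(scale(P, scale = FALSE))$v[, 1]
    if (sum(sv * (P[1, ] - P[3, ])) < 0) sv <- -sv
    expect_equal(v, sv / sqrt(sum(sv^2)), tolerance = 1e-6)
  }
})

test_that("wing pitch is the angle to the negative body vector", {
  bv <- c(1, 0, 0)
  expect_equal(wingPitch(bv, c(0, 0, 0), c(-2, 0, 0)), 0)
  expect_equal(wingPitch(bv, c(0, 0, 0), c(0, 3, 0)), 90)
  u <- c(-cos(pi / 9), sin(pi / 9), 0)  # 20 degrees off the -x axis
  expect_equal(wingPitch(bv, c(0, 0, 0), u), 20, tolerance = 1e-9)
  expect_true(is.na(wingPitch(bv, c(1, 1, 1), c(1, 1, 1))))  # zero wing vec
})

test_that("wing offset angle measures deviation from the unity line", {
  expect_equal(wingOffsetAngle(50, 50), 0)
  expect_equal(wingOffsetAngle(50, 0), 45)
  expect_equal(wingOffsetAngle(0, 50), 45)
  expect_equal(wingOffsetAngle(50, 40), 45 - atan2(40, 50) * 180 / pi)
  expect_equal(wingOffsetAngle(50, 40), 6.34, tolerance = 1e-2)
  expect_equal(wingOffsetAngle(0, 0), 0)
  set.seed(32)
  L <- runif(100, 0, 180); R <- runif(100, 0, 180)
  off <- wingOffsetAngle(L, R)
  expect_true(all(off >= 0 & off <= 45 + 1e-9))
  expect_equal(wingOffsetAngle(L, R), wingOffsetAngle(R, L))  # symmetric
})

test_that("elevation angle uses the nearest wall with deterministic ties", {
  arena <- arenaBox(c(0, 20), c(0, 10), c(0, 10))
  # level fly on the floor
  expect_equal(elevationAngle(c(11, 5, 0.3), c(9, 5, 0.3), c(1, 0, 0), arena), 0)
  # pitched-up fly over the floor: asin of the z-component
  bv <- c(cos(pi / 6), 0, sin(pi / 6))
  h <- c(10, 5, 0.3) + bv
  a <- c(10, 5, 0.3) - bv
  expect_equal(elevationAngle(h, a, bv, arena), 30, tolerance = 1e-9)
  # equidistant floor / side wall: the first wall in config order (floor)
  # wins, so a horizontal fly reads 0, not 90
  expect_equal(elevationAngle(c(11, 0.5, 0.5), c(9, 0.5, 0.5), c(1, 0, 0),
                              arena), 0)
  # against wall_y0 (closer than floor): body vector lies in that wall too
  expect_equal(elevationAngle(c(11, 0.2, 5), c(9, 0.2, 5), c(1, 0, 0), arena), 0)
  # ... but a vertical body vector is in-plane for the side wall
  expect_equal(elevationAngle(c(10, 0.2, 6), c(10, 0.2, 4), c(0, 0, 1), arena), 0)
})

test_that("wall normals come from the third right singular vector", {
  w <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 3, 0), c(0, 3, 0))
  expect_equal(abs(wallNormal(w)), c(0, 0, 1))
  move <- randomRigid(33)
  n2 <- wallNormal(move(w))
  rot <- rigidRotation(move)
  expect_equal(abs(sum(n2 * rot(c(0, 0, 1)))), 1, tolerance = 1e-9)
})

test_that("wing plane angles behave on canonical and mirrored poses", {
  # canonical pose: fly along +x, thorax slightly raised
  h <- c(2, 0, 0); t <- c(1.2, 0, 0.15); a <- c(0, 0, 0)
  # wings splayed symmetrically in the horizontal plane
  l <- t + 2 * c(-cos(pi / 4), sin(pi / 4), 0)
  r <- t + 2 * c(-cos(pi / 4), -sin(pi / 4), 0)
  ang <- wingPlaneAngles(h, t, a, l, r)
  expect_equal(ang[["left_wing_azimuth"]], ang[["right_wing_azimuth"]],
               tolerance = 1e-9)
  expect_equal(ang[["left_wing_elevation"]], ang[["right_wing_elevation"]],
               tolerance = 1e-9)
  # wing vector parallel to the abdomen vector projects to 0
  l0 <- t + 1.5 * (a - t)
  ang0 <- wingPlaneAngles(h, t, a, l0, r)
  expect_equal(ang0[["left_wing_elevation"]], 0, tolerance = 1e-6)
  expect_equal(ang0[["left_wing_azimuth"]], 0, tolerance = 1e-6)
  # a wingtip constructed exactly inside the medial plane at a known planar
  # angle to the projected abdomen direction: azimuth recovers that angle
  unitize <- function(v) v / sqrt(sum(v^2))
  vcross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  aa <- a - t
  nf_o <- unitize(vcross(h - t, aa))
  P3 <- rbind(h, t, a)
  bv_o <- svd(scale(P3, scale = FALSE))$v[, 1]
  if (sum(bv_o * (h - a)) < 0) bv_o <- -bv_o
  nm_o <- unitize(vcross(bv_o, nf_o))
  aa_m <- unitize(aa - sum(aa * nm_o) * nm_o)  # abdomen dir in medial plane
  phi <- 25
  lw <- t + 2 * (cos(phi * pi / 180) * aa_m + sin(phi * pi / 180) * nf_o)
  angm <- wingPlaneAngles(h, t, a, lw, r)
  expect_equal(angm[["left_wing_azimuth"]], phi, tolerance = 1e-6)
  # collinear body points -> invalid frame
  expect_true(all(is.na(wingPlaneAngles(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                                        l, r))))
})

test_that("speed is displacement times frame rate with NA propagation", {
  still <- matrix(rep(c(1, 2, 3), each = 5), 5)
  expect_equal(flySpeed(still, 100), c(NA, 0, 0, 0, 0))
  walk <- cbind(seq(0, 0.08, by = 0.02), 0, 0)
  expect_equal(flySpeed(walk, 100)[-1], rep(2, 4))
  # sinusoidal trajectory matches the analytic speed within discretization
  fps <- 200; tt <- seq(0, 1, by = 1 / fps)
  traj <- cbind(sin(2 * pi * tt), 0, 0)
  sp <- flySpeed(traj, fps)
  analytic <- abs(2 * pi * cos(2 * pi * (tt - 0.5 / fps)))
  expect_lt(max(abs(sp[-1] - analytic[-1])), 0.05)
  # invalid frame invalidates the two adjacent speed samples
  walk[3, ] <- NA
  expect_equal(is.na(flySpeed(walk, 100)), c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("wingspan and per-bout baseline subtraction", {
  l <- matrix(c(1.5, 0, 0), 1); r <- matrix(c(-1.5, 0, 0), 1)
  expect_equal(wingspanSeries(l, r), 3.0)

  fps <- 10
  const <- rep(2, 400)
  expect_equal(baselineSubtract(const, fps, stimOnsetsS = 15), rep(0, 400))
  # step: 2.0 pre, 2.6 during the stimulus
  tr <- rep(2.0, 400); tr[151:300] <- 2.6
  out <- baselineSubtract(tr, fps, stimOnsetsS = 15)
  expect_equal(out[151:300], rep(0.6, 150))
  expect_equal(out[1:150], rep(0, 150))
  expect_error(baselineSubtract(c(NA, NA, 1, 1), 1, stimOnsetsS = 2,
                                preWindowS = 2), "no baseline")
})

test_that("gap interpolation fills only short interior gaps", {
  fps <- 100
  n <- 200
  coords <- array(rep(seq_len(n), 3), c(n, 3, 1),
                  dimnames = list(NULL, c("x", "y", "z"), "thorax"))
  valid <- matrix(TRUE, n, 1, dimnames = list(NULL, "thorax"))
  # 300 ms gap (30 frames): filled collinearly
  valid[51:80, 1] <- FALSE
  # 700 ms gap (70 frames): left invalid
  valid[101:170, 1] <- FALSE
  # trailing gap: left invalid
  valid[191:200, 1] <- FALSE
  coords[!valid[, 1], , 1] <- NA
  tr <- keypointTrack(coords, valid, fps)
  out <- interpolateGaps(tr, maxGapMs = 500)
  pv <- partValid(out)
  expect_true(all(pv[51:80, 1]))
  expect_true(all(!pv[101:170, 1]))
  expect_true(all(!pv[191:200, 1]))
  expect_equal(partCoords(out, "thorax")[51:80, 1], 51:80)

  # exact-boundary gap (50 frames = 500 ms) is NOT filled (strictly less)
  valid2 <- matrix(TRUE, n, 1, dimnames = list(NULL, "thorax"))
  valid2[51:100, 1] <- FALSE
  c2 <- coords; c2[, , 1] <- rep(seq_len(n), 3); c2[51:100, , 1] <- NA
  out2 <- interpolateGaps(keypointTrack(c2, valid2, fps), maxGapMs = 500)
  expect_true(all(!partValid(out2)[51:100, 1]))
})

test_that("random dropout interpolation is explained by a run-length oracle", {
  set.seed(34)
  fps <- 100; n <- 500
  coords <- array(rnorm(n * 3), c(n, 3, 1),
                  dimnames = list(NULL, c("x", "y", "z"), "p"))
  valid <- matrix(runif(n) > 0.25, n, 1, dimnames = list(NULL, "p"))
  coords[!valid[, 1], , 1] <- NA
  tr <- keypointTrack(coords, valid, fps)
  out <- interpolateGaps(tr, maxGapMs = 500)
  # oracle: re-scan the original validity runs
  r <- rle(!valid[, 1])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expected <- valid[, 1]
  for (k in which(r$values)) {
    interior <- starts[k] > 1L && ends[k] < n
    if (interior && r$lengths[k] < 50L) expected[starts[k]:ends[k]] <- TRUE
  }
  expect_equal(partValid(out)[, 1], expected, ignore_attr = TRUE)
  # every valid output frame is either original or linearly interpolated
  expect_true(all(is.finite(partCoords(out, "p")[expected, ])))
})

test_that("all observable angles are invariant under rigid motions", {
  set.seed(35)
  for (k in 1:15) {
    t0 <- c(0, 0, 0)
    h <- rnorm(3); a <- rnorm(3); lt <- rnorm(3); rt <- rnorm(3)
    bv <- bodyVector(h, t0, a)
    if (any(is.na(bv))) next
    move <- randomRigid(350 + k)
    rot <- rigidRotation(move)
    expect_equal(wingPitch(rot(bv), move(t0), move(lt)),
                 wingPitch(bv, t0, lt), tolerance = 1e-9)
    ang1 <- wingPlaneAngles(h, t0, a, lt, rt)
    ang2 <- wingPlaneAngles(move(h), move(t0), move(a), move(lt), move(rt))
    expect_equal(ang2, ang1, tolerance = 1e-9)
  }
})

test_that("observables propagate invalidity exactly from their dependencies", {
  set.seed(36)
  ps <- poseScript(nTrials = 1, trialS = 5, bouts = data.frame(),
                   dropoutRate = 0.2, seed = 36)
  ses <- generatePoseSession(ps)
  tr <- ses$tracks[[1]]
  obs <- computeObservables(tr, arena = ses$arena)
  v <- partValid(tr)
  deps <- list(
    left_pitch = c("head", "thorax", "abdomen_tip", "left_wingtip"),
    right_pitch = c("head", "thorax", "abdomen_tip", "right_wingtip"),
    offset_angle = c("head", "thorax", "abdomen_tip", "left_wingtip",
                     "right_wingtip"),
    elevation = c("head", "thorax", "abdomen_tip"),
    wingspan = c("left_wingtip", "right_wingtip"))
  for (s in names(deps)) {
    ok_deps <- rowSums(!v[, deps[[s]], drop = FALSE]) == 0L
    expect_equal(!is.na(getSignal(obs, s)), ok_deps, ignore_attr = TRUE,
                 label = s)
  }
  # speed depends on the thorax at the frame and its predecessor
  sp_ok <- v[, "thorax"] & c(FALSE, v[-nrow(v), "thorax"])
  expect_equal(!is.na(getSignal(obs, "speed")), sp_ok, ignore_attr = TRUE)
})

test_that("pose-estimation CSVs in the 3-row-header dialect are parsed", {
  path <- withr::local_tempfile(fileext = ".csv")
  lines <- c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,head,head,head,thorax,thorax,thorax",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,10.5,20.5,0.99,11,21,0.5",
    "1,10.6,20.4,0.95,11.2,20.9,0.96")
  writeLines(lines, path)
  v <- readDlcCsv(path)
  expect_named(v, c("head", "thorax"))
  expect_equal(v$head$xy[, 1], c(10.5, 10.6))
  expect_equal(v$thorax$likelihood, c(0.5, 0.96))
})
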