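test_that("waiting times are differences of event-averaged exit times", {
  ens <- make_ensemble(list(c(10, 13), c(12, 17)))
  wt <- waiting_times(ens)
  expect_identical(nrow(wt), 1L)
  expect_equal(wt$waiting_time, 15 - 11)  # <t(2)> - <t(1)>
  # single event: plain consecutive differences
  e1 <- make_ensemble(list(c(1, 4, 9, 16)))
  expect_equal(waiting_times(e1)$waiting_time, c(3, 5, 7))
  expect_error(waiting_times(make_ensemble(list())), "empty")
})

test_that("waiting times telescope back to the cumulative curve exactly", {
  set.seed(4)
  ets <- lapply(1:6, function(i) cumsum(runif(30, 0.1, 2)))
  ens <- make_ensemble(ets)
  curve <- exit_time_curves(ens)
  wt <- waiting_times(ens)
  expect_identical(curve$s, 1:30)
  expect_true(all(diff(curve$mean_exit_time) >= 0))
  expect_identical(sum(wt$waiting_time),
                   curve$mean_exit_time[30] - curve$mean_exit_time[1])
  expect_equal(curve$mean_exit_time[1] + cumsum(wt$waiting_time),
               curve$mean_exit_time[-1], tolerance = 1e-15)
})

test_that("crossing index finds the first sign change, with tie rule", {
  expect_identical(crossing_index(c(1, 2, 3, 4), c(2, 2.5, 2.8, 3.5)), 3L)
  expect_identical(crossing_index(c(1, 2), c(1, 2)), 1L)       # exact tie
  expect_identical(crossing_index(c(1, 2, 3), c(2, 3, 4)), NA_integer_)
  expect_identical(crossing_index(c(5, 4, 3), c(1, 2, 3)), 3L) # tie mid-way
})

test_that("centre of mass is the mean x, equivariant under translation", {
  pos <- cbind(c(39, 41), c(38, 38), c(40, 40))
  expect_equal(com_x(pos), 40)  # symmetric about the pore centre
  expect_equal(com_x(pos[1, , drop = FALSE]), 39)
  expect_equal(com_x(sweep(pos, 2, c(2.5, 0, 0), "+")), 42.5)
})

test_that("aspect ratio follows dx over twice the lateral extent", {
  g <- membrane_geometry(simulation_parameters())
  tp <- g$trans_plane_x
  cy <- g$pore_center[2]; cz <- g$pore_center[3]
  pos <- rbind(c(tp + 4, cy, cz),       # dx = 4
               c(tp + 1, cy + 3, cz),   # y_max = 3
               c(tp + 2, cy, cz + 4),   # z_max = 4
               c(tp - 5, cy + 9, cz))   # cis-side bead: ignored
  expect_equal(aspect_ratio_alpha(pos, g), 4 / (2 * 5))
  # rotation about the pore axis leaves alpha's building blocks invariant
  # when maxima sit on distinct beads only up to the max; use a single bead
  one <- rbind(c(tp + 2, cy + 1, cz + 1))
  th <- 0.7
  rot <- rbind(c(tp + 2, cy + cos(th) - sin(th), cz + sin(th) + cos(th)))
  a1 <- aspect_ratio_alpha(one, g)
  a2 <- aspect_ratio_alpha(rot, g)
  expect_equal(sqrt(sum((one[1, 2:3] - c(cy, cz))^2)),
               sqrt(sum((rot[1, 2:3] - c(cy, cz))^2)))
  # limits: axial rod -> large alpha; flat pancake -> small alpha
  rodp <- cbind(tp + (1:10), cy + 1e-3, cz)
  expect_gt(aspect_ratio_alpha(rodp, g), 100)
  flat <- cbind(tp + 0.01, cy + (1:10), cz)
  expect_lt(aspect_ratio_alpha(flat, g), 0.01)
  expect_warning(a <- aspect_ratio_alpha(rbind(c(tp - 1, cy, cz)), g),
                 "trans")
  expect_true(is.na(a))
})

test_that("shape factor matches closed forms and the double-loop oracle", {
  # two beads at distance d: R_g = d/2, Kirkwood R_h = 2d, delta = 1/4
  for (d in c(0.5, 1, 3)) {
    pos <- rbind(c(0, 0, 0), c(d, 0, 0))
    expect_equal(shape_factor_delta(pos), 0.25, tolerance = 1e-14)
  }
  # random configurations against the direct double loop
  set.seed(13)
  for (rep in 1:5) {
    pos <- matrix(rnorm(30), 10, 3)
    expect_equal(shape_factor_delta(pos), oracle_delta(pos),
                 tolerance = 1e-12)
  }
  # invariance under rigid motions
  pos <- matrix(rnorm(36), 12, 3)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pos %*% t(R) + matrix(c(5, -2, 7), 12, 3, byrow = TRUE)
  expect_equal(shape_factor_delta(moved), shape_factor_delta(pos),
               tolerance = 1e-12)
  # rod limit: delta grows with bead count toward the rod end of the scale
  d20 <- shape_factor_delta(rod_fixture(20))
  d100 <- shape_factor_delta(rod_fixture(100))
  expect_gt(d100, d20)
  expect_gt(d100, 2)
  # coincident beads are an error
  expect_error(shape_factor_delta(rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincident")
})

test_that("a dense uniform ball sits at the compact end of the delta scale", {
  d1 <- shape_factor_delta(ball_fixture(h = 0.2))
  d2 <- shape_factor_delta(ball_fixture(h = 0.13))
  expect_lt(abs(d1 - d2), 0.02)   # converging to a constant
  expect_lt(d2, 1)                # far from the rod end (4.0)
  expect_gt(d2, 0.77)             # Kirkwood estimate sits just above the
                                  # geometric sphere anchor sqrt(3/5)
  # and the closed-form sphere anchor itself
  expect_equal(delta_sphere_anchor(), sqrt(0.6))
  expect_equal(round(delta_sphere_anchor(), 2), 0.77)
})

test_that("translocation time summaries handle edge cases", {
  e1 <- make_ensemble(list(c(1, 2, 7)))
  s1 <- translocation_time_summary(e1)
  expect_equal(s1$mean_tau, 7)
  expect_true(is.na(s1$sd_tau))   # single event: sd undefined
  ens <- make_ensemble(list(c(1, 2, 5), c(2, 3, 9)))
  dup <- make_ensemble(list(c(1, 2, 5), c(2, 3, 9), c(1, 2, 5), c(2, 3, 9)))
  expect_equal(translocation_time_summary(dup)$mean_tau,
               translocation_time_summary(ens)$mean_tau)
  h <- translocation_time_histogram(ens, bins = 4)
  expect_equal(sum(h$count), 2)
})

test_that("per-s snapshot series average the tagged configurations", {
  # two fabricated events with known snapshot positions
  snap <- function(xshift) lapply(1:3, function(s)
    cbind(c(1, 2, 3) + xshift + s, c(0, 1, -1), c(0, 0, 0)))
  ens <- make_ensemble(list(c(1, 2, 3), c(1.5, 2.5, 3.5)),
                       snapshots = list(snap(0), snap(10)))
  cs <- com_vs_s(ens)
  expect_identical(cs$s, 1:3)
  expect_equal(cs$mean_com_x, c(2 + 1 + 5, 2 + 2 + 5, 2 + 3 + 5))
  expect_true(all(cs$n == 2))
  ds <- delta_vs_s(ens)
  expect_equal(ds$mean_delta,
               rep(shape_factor_delta(snap(0)[[1]]), 3), tolerance = 1e-12)
  # ensembles without snapshots are rejected with advice
  expect_error(com_vs_s(make_ensemble(list(c(1, 2, 3)))), "record_snapshots")
})

test_that("ensemble tidiers give long exit times and per-condition glances", {
  ens <- make_ensemble(list(c(1, 2), c(3, 4)))
  td <- tidy(ens)
  expect_identical(nrow(td), 4L)
  expect_identical(td$s, c(1L, 2L, 1L, 2L))
  expect_equal(td$exit_time, c(1, 2, 3, 4))
  gl <- glance(ens)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$mean_tau, 3)
  expect_identical(gl$n_events, 2L)
})

test_that("observable plots build without evaluation errors", {
  set.seed(2)
  ens <- make_ensemble(lapply(1:4, function(i) cumsum(runif(20, 0.2, 1))))
  expect_s3_class(plot_waiting_times(waiting_times(ens)), "ggplot")
  expect_s3_class(plot_exit_time_curves(exit_time_curves(ens)), "ggplot")
  expect_s3_class(plot_translocation_times(translocation_time_summary(ens)),
                  "ggplot")
  expect_s3_class(autoplot(ens), "ggplot")
})
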