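test_that("Pho4 transfer function has three levels with sharp transitions", {
  p <- regulon_params()
  expect_lt(pho4_nuclear(10 * p$phi_plateau, p), 0.01)
  expect_equal(pho4_nuclear(0, p), 1)
  mid <- sqrt(p$phi_full * p$phi_plateau)
  expect_lt(abs(pho4_nuclear(mid, p) - p$n_mid), 0.02)
  expect_error(pho4_nuclear(-1, p), "nonnegative")
  # monotone nonincreasing in s_in
  expect_true(all(diff(pho4_nuclear(seq(0, 50, by = 0.05), p)) <= 0))
})

test_that("quasi-steady internal phosphate reduces to the single-carrier solution", {
  p <- regulon_params()
  # high-affinity absent: low-affinity system alone (starvation -> 0)
  for (so in c(10, 100, 250, 400, 2000)) {
    ref <- solve_internal(p$params_L, p$J_demand, so)
    expect_equal(quasi_steady_internal(0, 1, so, p),
                 if (ref$starved) 0 else ref$s_in, tolerance = 1e-8)
  }
  # low-affinity fully inhibited at maximal e_H: high-affinity system alone
  eH_max <- p$alpha_H / p$delta
  pH <- transporter_params(p$params_H$k2, p$params_H$k4, p$params_H$Kd,
                           eH_max * p$params_H$et)
  for (so in c(2, 5, 20, 500)) {
    ref <- solve_internal(pH, p$J_demand, so)
    expect_equal(quasi_steady_internal(eH_max, 0, so, p),
                 if (ref$starved) 0 else ref$s_in, tolerance = 1e-8)
  }
  # no transport at all
  expect_equal(quasi_steady_internal(0, 0, 100, p), 0)
})

test_that("quasi-steady solution satisfies the two-carrier flux balance", {
  p <- regulon_params()
  set.seed(13)
  for (i in 1:50) {
    e_H <- runif(1, 0, 10); a_L <- runif(1); so <- runif(1, 0, 1500)
    s <- quasi_steady_internal(e_H, a_L, so, p)
    tot <- a_L * carrier_flux(p$params_L, so, s) +
      e_H * carrier_flux(p$params_H, so, s)
    if (s > 0) {
      expect_lt(abs(tot - p$J_demand), 1e-7 * p$J_demand)
    } else {
      expect_lte(tot, p$J_demand * (1 + 1e-9))
    }
  }
})

test_that("constant environments settle into the expected programs", {
  p <- regulon_params()
  rich <- simulate_regulon(p, data.frame(duration = 12, s_out = 1000))
  expect_identical(attr(rich, "state"), "OFF")
  expect_lt(rich$n[nrow(rich)], 0.01)
  starved <- simulate_regulon(p, data.frame(duration = 12, s_out = 0.5))
  expect_identical(attr(starved, "state"), "ON")
  expect_gt(starved$n[nrow(starved)], 0.96)
  expect_gt(starved$p_decoupled[nrow(starved)], 10)
  inter <- simulate_regulon(p, data.frame(duration = 12, s_out = 50))
  expect_identical(attr(inter, "state"), "PLATEAU")
  # all levels nonnegative and bounded by synthesis/dilution ratios
  for (tr in list(rich, starved, inter)) {
    expect_true(all(tr$e_H >= 0 & tr$spl2 >= 0 & tr$p_plateau >= 0))
    expect_true(all(tr$e_H <= p$alpha_H / p$delta * (1 + 1e-6)))
    expect_true(all(tr$p_plateau <=
                      (p$beta_P + p$alpha_P) / p$delta * (1 + 1e-6)))
    expect_true(all(tr$a_L >= 0 & tr$a_L <= 1))
    expect_true(all(diff(tr$time) > 0))
  }
  expect_error(simulate_regulon(p, data.frame(duration = 2, s_out = 50),
                                dt = 0.2), "dt")
})

test_that("return to rich phosphate leaves the cell committed to the plateau", {
  p <- regulon_params()
  traj <- simulate_regulon(p, data.frame(duration = c(6, 12, 12),
                                         s_out = c(1000, 50, 1000)))
  expect_identical(attr(traj, "state"), "PLATEAU")
  last <- traj[nrow(traj), ]
  expect_lt(last$a_L, 0.1)          # Spl2 keeps low-affinity carriers off
  expect_lt(abs(last$n - p$n_mid), 0.1 * p$n_mid)
})

test_that("state classification applies the label tolerances and detects drift", {
  p <- regulon_params()
  traj <- simulate_regulon(p, data.frame(duration = 12, s_out = 50))
  expect_identical(classify_state(traj, window = 1), "PLATEAU")
  # truncating to the transient makes the tail non-stationary
  early <- traj[traj$time <= 2, ]
  attr(early, "params") <- p
  expect_error(classify_state(early, window = 1),
               class = "phostat_not_converged")
  expect_error(classify_state(traj, window = 20), "shorter")
})

test_that("sweeps produce three contiguous programs with hysteresis", {
  p <- regulon_params()
  down <- regulon_sweep(p, direction = "down_from_rich")
  up <- regulon_sweep(p, direction = "up_from_starved")
  expect_setequal(unique(c(down$label, up$label)), c("OFF", "PLATEAU", "ON"))
  # blocks are contiguous along the down sweep (OFF..., PLATEAU..., ON...)
  expect_identical(rle(down$label)$values, c("OFF", "PLATEAU", "ON"))
  # up and down sweeps disagree on a non-empty set of concentrations
  m <- merge(as.data.frame(down), as.data.frame(up), by = "s_out")
  hyst <- m$s_out[m$label.x != m$label.y]
  expect_gt(length(hyst), 0)
  # the plateau persists at rich concentrations on the up sweep
  expect_identical(up$label[up$s_out == max(up$s_out)], "PLATEAU")
  # grid entirely below the high-affinity critical point: all ON
  lo_grid <- c(0.5, 1, 2)
  expect_true(all(regulon_sweep(p, lo_grid, "down_from_rich")$label == "ON"))
  expect_true(all(regulon_sweep(p, lo_grid, "up_from_starved")$label == "ON"))
})

test_that("plateau states share the robust high-affinity set point", {
  p <- regulon_params()
  down <- regulon_sweep(p, direction = "down_from_rich")
  up <- regulon_sweep(p, direction = "up_from_starved")
  plateau <- rbind(as.data.frame(down), as.data.frame(up))
  plateau <- plateau[plateau$label == "PLATEAU", ]
  expect_true(all(plateau$s_in > p$phi_full & plateau$s_in < p$phi_plateau))
  # low-affinity carriers essentially inactive; s_in near the pure
  # high-affinity set point
  eH_max <- p$alpha_H / p$delta
  pH <- transporter_params(p$params_H$k2, p$params_H$k4, p$params_H$Kd,
                           eH_max * p$params_H$et)
  for (i in seq_len(nrow(plateau))) {
    ref <- solve_internal(pH, p$J_demand, plateau$s_out[i])$s_in
    expect_lt(abs(plateau$s_in[i] - ref) / ref, 0.05)
  }
  # perfect adaptation: < 1.5-fold variation of s_in and reporter output
  expect_lt(max(plateau$s_in) / min(plateau$s_in), 1.5)
  expect_lt(max(plateau$p_plateau) / min(plateau$p_plateau), 1.5)
  # decoupled reporter stays near basal in every plateau state
  basal <- p$beta_P / p$delta
  expect_true(all(plateau$p_decoupled < 2 * basal))
})

test_that("bistable window exists and vanishes without Spl2 inhibition", {
  p <- regulon_params()
  bw <- bistable_window(p)
  expect_false(bw$empty)
  # lower edge above the low-affinity-only activation point (s_out = 300)
  expect_gt(bw$lower, critical_external(p$params_L, p$J_demand))
  no_spl2 <- bistable_window(regulon_params(K_S = Inf))
  expect_true(no_spl2$empty)
  # grid below the high-affinity critical point: single ON attractor
  expect_true(bistable_window(p, c(0.5, 1, 2))$empty)
})

test_that("hysteresis disappears when Spl2 cannot inhibit the low-affinity system", {
  p <- regulon_params(K_S = Inf)
  down <- regulon_sweep(p, direction = "down_from_rich")
  up <- regulon_sweep(p, direction = "up_from_starved")
  m <- merge(as.data.frame(down), as.data.frame(up), by = "s_out")
  expect_identical(m$label.x, m$label.y)
})

test_that("population sweep fractions are seeded, monotone and mixed", {
  p <- regulon_params()
  det <- population_sweep(p, cv_etL = 0, n_cells = 5, seed = 1)
  expect_true(all(det$fraction_activated %in% c(0, 1)))
  expect_equal(rle(det$fraction_activated)$values, c(0, 1))  # one step
  ps <- population_sweep(p, cv_etL = 0.3, n_cells = 200, seed = 1)
  # down sweep reported at decreasing s_out: fraction nondecreasing
  expect_true(all(diff(ps$fraction_activated) >= 0))
  expect_equal(ps$fraction_activated[which.min(ps$s_out)], 1)
  expect_true(any(ps$fraction_activated > 0 & ps$fraction_activated < 1))
  expect_identical(ps, population_sweep(p, cv_etL = 0.3, n_cells = 200,
                                        seed = 1))
})
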