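test_that("ligand-free steady state solves the resting balance", {
  # hand-solved 2x2 balance: vs - ke0*Rs + kr*Ri = 0, ke0*Rs = (kr+kdeg)*Ri
  p <- receptor_params(vs = 0.01, ke0 = 0.02, kr = 0, kdeg = 0.05)
  s <- initial_steady_state(p)
  expect_equal(unname(s[["Rs"]]), 0.5)
  expect_equal(unname(s[["Ri"]]), 0.2)
  expect_equal(unname(s[["Cs"]]) + unname(s[["Ps"]]) + unname(s[["Pi"]]), 0)

  # pools scale linearly with r_scale
  p10 <- receptor_params(vs = 0.01, ke0 = 0.02, kr = 0, kdeg = 0.05,
                         r_scale = 10)
  s10 <- initial_steady_state(p10)
  expect_equal(unname(s10[["Rs"]]), 5)
  expect_equal(unname(s10[["Ri"]]), 2)

  # closed surface pool: unit convention Rs = r_scale * 1
  pc <- receptor_params(vs = 0, ke0 = 0, ke1 = 0.2, kdeg = 0.05, kr = 0,
                        r_scale = 3)
  sc <- initial_steady_state(pc)
  expect_equal(unname(sc[["Rs"]]), 3)
  expect_equal(unname(sc[["Ri"]]), 0)

  # synthesis without a degradation route has no finite equilibrium
  expect_error(
    initial_steady_state(receptor_params(vs = 0.01, kdeg = 0)),
    class = "non_convergent_equilibrium")
})

test_that("default parameters put the resting E-cell surface pool at 1", {
  s <- initial_steady_state(receptor_params())
  expect_equal(unname(s[["Rs"]]), 1, tolerance = 1e-12)
})

test_that("parameter validation rejects invalid rate sets", {
  expect_error(receptor_params(kon = -1), "kon")
  expect_error(receptor_params(ke0 = 0.3, ke1 = 0.1), "ke1")
  expect_error(ligand_spec("EGF", kd = 0), "kd")
  expect_error(ligand_spec("EGF", concentration = -1), "concentration")
})

test_that("without ligand the resting state is a fixed point", {
  p <- receptor_params()
  traj <- simulate_receptor(p, ligand_spec("EGF", concentration = 0),
                            times = seq(0, 300, 10))
  for (sp in colnames(traj$states)) {
    expect_equal(unname(traj$states[, sp]),
                 rep(unname(traj$states[1L, sp]), length(traj$times)),
                 tolerance = 1e-7)
  }
  expect_true(all(traj$states[, c("Ps", "Pi")] == 0))
})

test_that("binding-only submodel matches the closed-form exponential", {
  # trafficking and catalysis off: two-species reversible binding
  kon <- 0.1; kd <- 2; L <- 1
  p <- receptor_params(kon = kon, kp = 0, kdp = 0, ke0 = 0, ke1 = 0,
                       kdpi = 0, kr = 0, kdeg = 0, kdegP = 0, vs = 0)
  lig <- ligand_spec("EGF", concentration = L, kd = kd)
  krel <- kon * L + kon * kd          # relaxation rate
  t_half <- log(2) / krel
  # run to 30 half-lives so the residual transient (2^-30) is below the
  # 1e-6 comparison tolerance at the terminal point
  times <- seq(0, 30 * t_half, length.out = 121)
  traj <- simulate_receptor(p, lig, times, init = model_state(Rs = 1))
  feq <- L / (L + kd)
  closed_form <- feq * (1 - exp(-krel * times))
  expect_equal(unname(traj$states[, "Cs"]), closed_form, tolerance = 1e-6)
  expect_equal(unname(traj$states[nrow(traj$states), "Cs"]), feq,
               tolerance = 1e-6)
  # no phosphorylation means no phospho signal
  expect_equal(readout(traj, "pEGFR_total"), rep(0, length(times)))
})

test_that("total receptor is conserved in the closed system", {
  p <- receptor_params(vs = 0, kdeg = 0, kdegP = 0)
  traj <- simulate_receptor(p, ligand_spec("EGF", 1.8),
                            times = seq(0, 310, 1),
                            init = model_state(Rs = 1, Ri = 0.4))
  total <- rowSums(traj$states)
  expect_lt(max(abs(total - total[1L])) / total[1L], 1e-6)
})

test_that("species stay non-negative under stimulation", {
  for (lig in list(ligand_spec("EGF", 1.8), ligand_spec("AREG", 1.8))) {
    traj <- simulate_receptor(receptor_params(), lig, seq(0, 310, 5))
    expect_true(all(traj$states >= 0))
  }
})

test_that("readouts are the stated pool sums", {
  traj <- structure(list(
    times = c(0, 1),
    states = matrix(c(1, 0.2, 0.1, 0.05, 0.3,
                      1, 0.2, 0.1, 0.05, 0.3),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(NULL, c("Rs", "Cs", "Ps", "Pi", "Ri"))),
    ligand = ligand_spec("EGF"), params = receptor_params()),
    class = "egfr_trajectory")
  expect_equal(readout(traj, "pEGFR_total"), c(0.15, 0.15))
  expect_equal(readout(traj, "surface_EGFR"), c(1.3, 1.3))
  expect_equal(readout(traj, "total_EGFR"), c(1.65, 1.65))
  expect_error(readout(traj, "pAKT"), class = "invalid_readout")
})

test_that("higher-affinity ligand gives strictly more integrated signal", {
  p <- receptor_params()
  a_egf <- integrated_pEGFR(p, ligand_spec("X", 1.8, kd = 20))
  a_low <- integrated_pEGFR(p, ligand_spec("Y", 1.8, kd = 200))
  expect_gt(a_egf, a_low)
})

test_that("chronic AREG leaves more receptor on the surface than EGF", {
  p <- receptor_params()
  times <- seq(0, 2880, 30)   # 48 h
  s_end <- function(lig) {
    traj <- simulate_receptor(p, lig, times)
    tail(readout(traj, "surface_EGFR"), 1L)
  }
  expect_gt(s_end(ligand_spec("AREG", 1.8)), s_end(ligand_spec("EGF", 1.8)))
})

test_that("trajectories export with the documented CSV header", {
  traj <- simulate_receptor(receptor_params(), ligand_spec("EGF"),
                            times = seq(0, 10, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time_min", "Rs", "Cs", "Ps", "Pi", "Ri"))
  expect_equal(df$Rs, unname(traj$states[, "Rs"]))
})
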