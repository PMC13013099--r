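test_that("parameter constructors enforce their invariants", {
  p <- lif_params()
  expect_equal(p$v_th_base, 1.0)
  expect_equal(p$v_leak, 0)
  expect_equal(p$v_reset, 0)
  expect_error(lif_params(tau_m_base = 0), "tau_m_base")
  expect_error(lif_params(dt = -1), "dt")
  expect_error(lif_params(tau_min = 0), "tau_min")
  expect_error(context_mod("threshold", p = numeric(0)), "projection")
  expect_error(context_mod("threshold", p = 1, c = -0.5), "c must")
})

test_that("effective threshold is the base plus the context-scaled projection", {
  prm <- lif_params()
  # context off: identity for any p
  m0 <- context_mod("threshold", p = c(2, -3, 0.5), c = 0)
  expect_equal(effective_threshold(m0, prm), c(1, 1, 1))
  # signed shifts, no clamping
  m1 <- context_mod("threshold", p = c(0.5, -0.2), c = 1)
  expect_equal(effective_threshold(m1, prm), c(1.5, 0.8))
  m2 <- context_mod("threshold", p = c(-5), c = 1)
  expect_equal(effective_threshold(m2, prm), -4)
  # wrong mode is a contract violation
  expect_error(effective_threshold(context_mod("tau", p = 1, c = 1), prm),
               "mode")
})

test_that("effective tau is additive with a positive clamp", {
  prm <- lif_params(tau_m_base = 16)
  expect_equal(effective_tau(context_mod("tau", p = c(7, -2), c = 0), prm),
               c(16, 16))
  expect_equal(effective_tau(context_mod("tau", p = 0.4, c = 1), prm), 16.4)
  # clamp guards against sign flips
  expect_equal(effective_tau(context_mod("tau", p = -100, c = 1), prm),
               prm$tau_min)
  expect_error(effective_tau(context_mod("threshold", p = 1, c = 1), prm),
               "mode")
  # inverse parameterization shifts the leak rate instead
  prmi <- lif_params(tau_m_base = 16, tau_param = "inverse")
  expect_equal(effective_tau(context_mod("tau", p = 1 / 16, c = 1), prmi),
               1 / (2 / 16))
})

test_that("lif_step follows the Euler update, jump condition and reset", {
  prm <- lif_params(tau_m_base = 4, dt = 1)
  st <- lif_init_state(1)
  # fixed point at rest
  s1 <- lif_step(st, 0, prm)
  expect_equal(s1$v, 0)
  expect_equal(s1$z, 0)
  # hand-applied forward-Euler update: v' = 0 + (1/4)(0 - 0 + 1) = 0.25
  s2 <- lif_step(st, 1, prm)
  expect_equal(s2$v, 0.25)
  expect_equal(s2$z, 0)
  # crossing the threshold spikes and resets to v_reset
  s3 <- lif_step(list(v = 1.1, z = 0), 1, lif_params(tau_m_base = 10))
  expect_equal(s3$z, 1)
  expect_equal(s3$v, 0)
  expect_error(lif_step(st, NaN, prm), "finite")
})

test_that("spike/reset conservation holds along random trajectories", {
  prm <- lif_params(tau_m_base = 4)
  st <- lif_init_state(20)
  set.seed(1)
  for (t in 1:200) {
    st2 <- lif_step(st, rnorm(20, mean = 0.8, sd = 1.5), prm)
    expect_true(all(st2$z %in% c(0, 1)))
    expect_true(all(st2$v[st2$z == 1] == prm$v_reset))
    st <- st2
  }
})

test_that("leaky-integrator readout integrates but never spikes or resets", {
  prm <- lif_params(tau_m_base = 8)
  st <- lif_init_state(1)
  for (i in 1:10) st <- li_step(st, 0, prm)
  expect_equal(st$v, 0)
  # constant current: exponential relaxation toward I with rate dt/tau;
  # closed form of the Euler recursion v_t = I (1 - (1 - dt/tau)^t)
  st <- lif_init_state(1)
  I <- 3
  vs <- numeric(40)
  for (t in 1:40) { st <- li_step(st, I, prm); vs[t] <- st$v }
  expect_equal(vs, I * (1 - (1 - 1 / 8)^(1:40)), tolerance = 1e-12)
  expect_true(all(diff(vs) > 0) && all(vs < I))
  # pure accumulator mode (tau -> Inf): k unit impulses sum to k
  st <- lif_init_state(1)
  for (k in 1:7) st <- li_step(st, 1, prm, tau = Inf)
  expect_equal(st$v, 7)
})

test_that("fi_curve matches the closed-form LIF rate at fine dt", {
  prm <- lif_params(tau_m_base = 4, dt = 0.01)
  I <- c(1.5, 2, 4)
  rates <- fi_curve(prm, current_levels = I, duration = 20000)
  expect_true(all(abs(rates / closed_form_rate(I, 4) - 1) < 0.05))
})

test_that("fi_curve is zero at or below threshold and monotone in I and v_th", {
  prm <- lif_params(tau_m_base = 4)
  lv <- seq(0.2, 1, by = 0.2)
  expect_equal(fi_curve(prm, current_levels = lv, duration = 500),
               rep(0, length(lv)))
  grid <- seq(0.5, 5, by = 0.25)
  r <- fi_curve(prm, current_levels = grid, duration = 1000)
  expect_true(all(diff(r) >= 0))
  # higher threshold, same currents: rates cannot increase
  r_hi <- fi_curve(prm, context_mod("threshold", p = 0.5, c = 1),
                   current_levels = grid, duration = 1000)
  expect_true(all(r_hi <= r))
  expect_error(fi_curve(prm, current_levels = numeric(0)), "non-empty")
  expect_error(fi_curve(prm, current_levels = 1, duration = 10), "100")
})

test_that("threshold modulation shifts the FI curve; tau modulation reshapes it", {
  prm <- lif_params(tau_m_base = 4, dt = 0.05)
  grid <- seq(1.05, 5, by = 0.05)
  base <- fi_curve(prm, current_levels = grid, duration = 4000)
  shift <- fi_curve(prm, context_mod("threshold", p = 0.5, c = 1),
                    current_levels = grid, duration = 4000)
  slow <- fi_curve(prm, context_mod("tau", p = 4, c = 1),
                   current_levels = grid, duration = 4000)
  # threshold shift: the shifted curve tracks base(I - handled via closed
  # form) -- verify against the closed form with v_th = 1.5
  expect_true(max(abs(shift - closed_form_rate(grid, 4, v_th = 1.5))) < 0.02)
  # tau change is multiplicative (rate scales by tau ratio), not a shift:
  # the ratio to base is near-constant while a pure shift would not be
  sup <- grid > 1.6
  ratio <- slow[sup] / base[sup]
  expect_true(max(abs(ratio - 0.5)) < 0.05)
  shifted_ratio <- shift[sup] / base[sup]
  expect_true(diff(range(shifted_ratio)) > 0.2)
})

test_that("context-off layers are bit-identical to unmodulated layers", {
  # the acceptance-level check lives in test-acceptance.R; this covers the
  # scalar API
  prm <- lif_params(tau_m_base = 4)
  set.seed(7)
  p <- rnorm(10)
  st_a <- lif_init_state(10); st_b <- lif_init_state(10); st_c <- lif_init_state(10)
  for (t in 1:100) {
    I <- rnorm(10, 0.9, 0.5)
    st_a <- lif_step(st_a, I, prm)
    st_b <- lif_step(st_b, I, prm, context_mod("threshold", p = p, c = 0))
    st_c <- lif_step(st_c, I, prm, context_mod("tau", p = p, c = 0))
    expect_identical(st_a, st_b)
    expect_identical(st_a, st_c)
  }
})

test_that("surrogate derivative has SuperSpike form", {
  expect_equal(surrogate_grad(1, 1, beta = 100), 1)
  expect_equal(surrogate_grad(1.1, 1, beta = 100),
               1 / (100 * 0.1 + 1)^2)
  expect_equal(surrogate_grad(0.9, 1, beta = 100),
               surrogate_grad(1.1, 1, beta = 100))
})
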