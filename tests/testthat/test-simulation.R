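test_that("zero drive keeps the membrane at rest", {
  d <- neuron_dynamics(i_ext = 0)
  out <- simulate_lif(d, duration = 50, dt = 0.1)
  expect_equal(out$series$values, rep(-65, 501))
  expect_length(out$spikes, 0)
})

test_that("subthreshold traces match the closed-form solution", {
  d <- neuron_dynamics(v_rest = -65, v_thr = -50, r_m = 10, tau_m = 10, i_ext = 1)
  out <- simulate_lif(d, duration = 100, dt = 0.01)
  expect_length(out$spikes, 0)
  expect_length(out$series$values, 10001)
  v_end <- out$series$values[length(out$series$values)]
  expect_equal(v_end, -55, tolerance = 1e-3 / 55)
  # pointwise agreement with v(t) = v_rest + r_m i_ext (1 - exp(-t/tau))
  err <- max(abs(out$series$values - lif_closed_form(d, out$series$times)))
  expect_lt(err, 1e-6)
})

test_that("the integrator converges at fourth order in the subthreshold regime", {
  d <- neuron_dynamics(i_ext = 1)
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    out <- simulate_lif(d, duration = 100, dt = dt)
    max(abs(out$series$values - lif_closed_form(d, out$series$times)))
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("suprathreshold spike counts match the closed-form interspike interval", {
  d <- neuron_dynamics(v_rest = -65, v_thr = -50, v_reset = -65,
                       r_m = 10, tau_m = 10, i_ext = 2, t_ref = 0)
  out <- simulate_lif(d, duration = 1000, dt = 0.01)
  predicted <- floor(1000 / lif_isi(d))        # = floor(1000 / (10 ln 4)) = 72
  expect_equal(predicted, 72)
  expect_equal(length(out$spikes), 72)
  # spike times sit on the closed-form lattice up to the O(dt) detection bias
  expect_equal(diff(out$spikes),
               rep(diff(out$spikes)[1], length(out$spikes) - 1),
               tolerance = 1e-8)
  expect_lt(abs(diff(out$spikes)[1] - lif_isi(d)), 0.011)
})

test_that("a refractory period lengthens the interspike interval accordingly", {
  d0 <- neuron_dynamics(i_ext = 2, t_ref = 0)
  d5 <- neuron_dynamics(i_ext = 2, t_ref = 5)
  out0 <- simulate_lif(d0, 500, 0.01)
  out5 <- simulate_lif(d5, 500, 0.01)
  expect_lt(length(out5$spikes), length(out0$spikes))
  expect_lte(abs(floor(500 / lif_isi(d5)) - length(out5$spikes)), 1)
  # clamped at reset during the refractory window
  i_spike <- which(out5$series$times == out5$spikes[1])
  clamped <- out5$series$values[i_spike + seq_len(400)]  # 4 ms at dt = 0.01
  expect_equal(clamped, rep(-65, 400))
})

test_that("spike count is non-decreasing in the drive current", {
  counts <- vapply(seq(1.6, 3.0, by = 0.2), function(i_ext) {
    length(simulate_lif(neuron_dynamics(i_ext = i_ext), 500, 0.025)$spikes)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])
})

test_that("series length always equals floor(duration/dt) + 1", {
  d <- neuron_dynamics(i_ext = 2)
  for (case in list(c(10, 0.1), c(100, 0.025), c(7, 0.3), c(0, 0.1))) {
    out <- simulate_lif(d, case[1], case[2])
    expect_length(out$series$values, floor(case[1] / case[2]) + 1)
    expect_equal(out$series$times[1], 0)
  }
  expect_error(simulate_lif(d, 10, 0), class = "nsc_invalid_argument")
  expect_error(simulate_lif(d, -1, 0.1), class = "nsc_invalid_argument")
  expect_error(neuron_dynamics(tau_m = -1), class = "nsc_invalid_argument")
  expect_error(neuron_dynamics(v_thr = -70), class = "nsc_invalid_argument")
})

test_that("experiments complete with one series per watched path", {
  withr::with_tempdir({
    p <- tiny_project(".", seed = 12, sizes = c(2), n_connections = 0)
    proj <- read_project_file(p$project_path)
    e <- proj$experiments[[1]]
    e$duration <- 10; e$dt <- 0.1
    proj <- set_experiment(proj, e)

    done <- run_experiment(proj, "exp1")
    expect_identical(done$state, "COMPLETED")
    expect_length(done$results, 2)
    for (ts in done$results) expect_length(ts$values, 101)

    # parameter overrides flow into the simulated cell only
    e2 <- new_experiment("quiet", duration = 10, dt = 0.1,
                         watched = c("net.pop1[0].v", "net.pop1[1].v"),
                         parameter_overrides = list("net.pop1[0].i_ext" = 0))
    proj$experiments <- c(proj$experiments, list(e2))
    done2 <- run_experiment(proj, "quiet")
    expect_identical(done2$state, "COMPLETED")
    expect_equal(done2$results[["net.pop1[0].v"]]$values, rep(-65, 101))
    expect_gt(max(done2$results[["net.pop1[1].v"]]$values), -65)
  })
})

test_that("experiments with nothing watched or bad configuration settle correctly", {
  withr::with_tempdir({
    p <- tiny_project(".", seed = 13, sizes = c(1), n_connections = 0)
    proj <- read_project_file(p$project_path)
    e0 <- new_experiment("nothing", duration = 5, dt = 0.1)
    bad_dt <- new_experiment("bad_dt", duration = 5, dt = 0,
                             watched = "net.pop1[0].v")
    bad_path <- new_experiment("bad_path", duration = 5, dt = 0.1,
                               watched = "net.pop1[0].nope")
    bad_override <- new_experiment("bad_override", duration = 5, dt = 0.1,
                                   watched = "net.pop1[0].v",
                                   parameter_overrides = list("net.pop1[0].i_ext" = 99))
    proj$experiments <- c(proj$experiments, list(e0, bad_dt, bad_path, bad_override))

    done0 <- run_experiment(proj, "nothing")
    expect_identical(done0$state, "COMPLETED")
    expect_length(done0$results, 0)

    for (id in c("bad_dt", "bad_path", "bad_override")) {
      failed <- run_experiment(proj, id)
      expect_identical(failed$state, "ERROR")
      expect_length(failed$results, 0)
      expect_true(nzchar(failed$error_message))
    }
    failed <- run_experiment(proj, "bad_dt")
    expect_match(failed$error_message, "dt")
  })
})

test_that("the lifecycle state machine admits only legal transitions", {
  legal <- list(DESIGN = "QUEUED", QUEUED = "RUNNING",
                RUNNING = c("COMPLETED", "ERROR"),
                COMPLETED = character(0), ERROR = character(0))
  states <- names(legal)
  withr::with_seed(101, {
    for (rep in 1:300) {
      e <- new_experiment("e")
      for (step in 1:6) {
        target <- sample(states, 1)
        before <- e$state
        res <- tryCatch(experiment_transition(e, target), nsc_error = function(err) err)
        if (inherits(res, "nsc_error")) {
          expect_false(target %in% legal[[before]])
          expect_identical(e$state, before)   # rejected attempts change nothing
        } else {
          e <- res
          expect_true(e$state %in% legal[[before]])
        }
      }
    }
  })
})

test_that("parameter sweeps are atomic and deterministic", {
  withr::with_tempdir({
    p <- tiny_project(".", seed = 14, sizes = c(1), n_connections = 0)
    proj <- read_project_file(p$project_path)

    exps <- sweep_experiments(proj, "exp1", "net.pop1[0].i_ext", c(0, 1, 2))
    expect_length(exps, 3)
    expect_identical(vapply(exps, `[[`, "", "state"), rep("DESIGN", 3))
    expect_identical(vapply(exps, `[[`, "", "id"),
                     c("exp1_sweep1", "exp1_sweep2", "exp1_sweep3"))
    expect_equal(exps[[2]]$parameter_overrides[["net.pop1[0].i_ext"]], 1)

    expect_length(sweep_experiments(proj, "exp1", "net.pop1[0].i_ext", numeric(0)), 0)

    # i_ext bounds are [0, 10]: one offending value voids the whole sweep
    expect_error(sweep_experiments(proj, "exp1", "net.pop1[0].i_ext", c(1, 99, 2)),
                 class = "nsc_bounds_error")
    expect_error(sweep_experiments(proj, "exp1", "net.pop1[0].v", c(1)),
                 class = "nsc_capability_not_supported")
  })
})

test_that("watch_all records every membrane potential exactly once", {
  withr::with_tempdir({
    p <- tiny_project(".", seed = 15, sizes = c(2, 3), n_connections = 0)
    proj <- read_project_file(p$project_path)
    e <- new_experiment("fresh", duration = 5, dt = 0.1,
                        watched = "net.pop1[0].v")     # pre-watched path
    proj$experiments <- c(proj$experiments, list(e))
    watched <- watch_all(proj, "fresh")$watched
    expect_length(watched, 5)
    expect_false(anyDuplicated(watched) > 0)

    # empty model: empty watched set
    p0 <- tiny_project("empty", seed = 16, sizes = c(0), n_connections = 0)
    proj0 <- read_project_file(p0$project_path)
    expect_length(watch_all(proj0, "exp1")$watched, 0)

    # watch_all outside DESIGN is illegal
    done <- run_experiment(proj, "fresh")
    proj <- set_experiment(proj, done)
    expect_error(watch_all(proj, "fresh"), class = "nsc_illegal_state")
  })
})
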