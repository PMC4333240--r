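test_that("arrest probability has the linear-decay closed form", {
  expect_equal(adhesion_arrest_probability(0, 10, 50), 0)
  expect_equal(adhesion_arrest_probability(1, 0, 50), 1)
  expect_equal(adhesion_arrest_probability(0.5, 25, 50), 0.25)
  expect_equal(adhesion_arrest_probability(0.7, 50, 50), 0)
  expect_equal(adhesion_arrest_probability(0.7, 80, 50), 0)
  expect_error(adhesion_arrest_probability(-0.1, 10, 50), "domain error")
  expect_error(adhesion_arrest_probability(1.2, 10, 50), "domain error")
})

test_that("arrest probability is monotone in expression", {
  e <- seq(0, 1, by = 0.05)
  for (d in c(0, 10, 30, 49)) {
    p <- adhesion_arrest_probability(e, d, 50)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("contact rules: LTin initiate, LTi mature, cap at 1", {
  lto <- list(differentiated = FALSE, expression = 0, lti_contacts = 0L)

  # (undiff, LTin) -> differentiated at l0
  a <- handle_contact(lto, "LTin", l0 = 0.2, dl = 0.05)
  expect_true(a$differentiated)
  expect_equal(a$expression, 0.2)

  # (undiff, LTi) -> unchanged: only LTin initiate
  b <- handle_contact(lto, "LTi", l0 = 0.2, dl = 0.05)
  expect_identical(b, lto)

  # (diff, LTi) -> matured by dl, contact counted
  c1 <- handle_contact(a, "LTi", l0 = 0.2, dl = 0.05)
  expect_equal(c1$expression, 0.25)
  expect_equal(c1$lti_contacts, 1L)

  # (diff, LTin) -> no further effect
  d1 <- handle_contact(a, "LTin", l0 = 0.2, dl = 0.05)
  expect_identical(d1, a)

  # expression is capped at 1
  hot <- list(differentiated = TRUE, expression = 0.98, lti_contacts = 40L)
  e1 <- handle_contact(hot, "LTi", dl = 0.05)
  expect_equal(e1$expression, 1)
})

test_that("arrested cells are absorbing for both kinds", {
  set.seed(5)
  env <- create_environment(test_cfg())
  for (kind in c("LTin", "LTi")) {
    cell <- motile_cell(kind, c(100, 100), state = "arrested")
    stepper <- if (kind == "LTin") step_ltin else step_lti
    out <- stepper(cell, env)
    expect_identical(out$cell, cell)
    expect_equal(nrow(out$events), 0)
  }
})

test_that("a free LTin walk moves exactly speed*dt and stays migrating", {
  cfg <- test_cfg(environment = list(lto_count = 0L))
  set.seed(9)
  env <- create_environment(cfg)
  step_len <- cfg$cells$speed_um_per_min * cfg$dt_min
  cell <- motile_cell("LTin", c(500, 200))
  for (i in 1:20) {
    out <- step_ltin(cell, env)
    d <- wrapped_distance(out$cell$position, cell$position, env)
    expect_equal(d, step_len, tolerance = 1e-9)
    expect_equal(out$cell$state, "migrating")
    expect_equal(nrow(out$events), 0)
    cell <- out$cell
  }
})

test_that("an LTi step in a flat field is an unbiased step of speed*dt", {
  cfg <- test_cfg(environment = list(lto_count = 0L))
  set.seed(10)
  env <- create_environment(cfg)
  cell <- motile_cell("LTi", c(500, 200))
  out <- step_lti(cell, env)
  expect_equal(wrapped_distance(out$cell$position, cell$position, env),
               cfg$cells$speed_um_per_min * cfg$dt_min, tolerance = 1e-9)
})

test_that("a fully biased LTi steps along the chemokine gradient", {
  cfg <- sim_config("full")
  env <- create_environment_stub <- list(
    width = cfg$environment$width_um, height = cfg$environment$height_um,
    lto = data.frame(x = 2500, y = 500, radius = 10, differentiated = TRUE,
                     expression = 1, lti_contacts = 0L),
    config = cfg)
  class(env) <- "pp_environment"
  # at 40 um from a saturated source the level is ~0.87 < 1, so bias < 1;
  # put the cell close enough that level >= 1 cannot occur with one source:
  # instead verify the b=1 limit with two stacked sources
  env$lto <- rbind(env$lto, env$lto)
  start <- c(2500, 450)  # 50 um south of the sources, level = 2*(1-50/rc) > 1
  set.seed(2)
  out <- step_lti(motile_cell("LTi", start), env)
  moved <- out$cell$position - start
  # gradient points north; the step must be exactly along it
  expect_equal(moved[1], 0, tolerance = 1e-6)
  expect_equal(moved[2], cfg$cells$speed_um_per_min * cfg$dt_min,
               tolerance = 1e-6)
})

test_that("LTin contact with an undifferentiated LTo differentiates it", {
  cfg <- test_cfg()
  set.seed(21)
  env <- create_environment(cfg)
  # place an LTin right on top of LTo 1: every move keeps it within contact
  target <- c(env$lto$x[1], env$lto$y[1])
  cell <- motile_cell("LTin", target)
  out <- step_ltin(cell, env)
  expect_true(1 %in% out$events$lto)
  lto1 <- as.list(env$lto[1, ])
  upd <- handle_contact(lto1, "LTin", l0 = cfg$adhesion$l0,
                        dl = cfg$adhesion$dl)
  expect_true(upd$differentiated)
  expect_equal(upd$expression, cfg$adhesion$l0)
})

test_that("free random walks have near-zero mean displacement and linear MSD", {
  # with no LTo in the domain, nothing can ever arrest
  cfg <- test_cfg(environment = list(lto_count = 0L))
  r <- run_simulation(cfg, seed = 123, record = TRUE)
  expect_equal(r$n_arrested, 0)
  expect_equal(r$patch_count, 0)
  # displacement statistics over repeated single-cell walks (unwrapped x)
  cfg2 <- cfg
  set.seed(77)
  env <- create_environment(cfg2)
  n_cells <- 80
  n_steps <- 100
  disp <- matrix(0, n_cells, 2)
  for (i in seq_len(n_cells)) {
    cell <- motile_cell("LTin", c(500, 200))
    for (s in seq_len(n_steps)) cell <- step_ltin(cell, env)$cell
    # unwrap x displacement through the seam
    dx <- cell$position[1] - 500
    if (dx > env$width / 2) dx <- dx - env$width
    if (dx < -env$width / 2) dx <- dx + env$width
    disp[i, ] <- c(dx, cell$position[2] - 200)
  }
  step_len <- cfg2$cells$speed_um_per_min * cfg2$dt_min
  msd_expected <- n_steps * step_len^2   # sum of unit-variance steps
  msd_observed <- mean(rowSums(disp^2))
  expect_lt(abs(mean(disp)), 3 * step_len * sqrt(n_steps / n_cells))
  expect_gt(msd_observed / msd_expected, 0.6)
  expect_lt(msd_observed / msd_expected, 1.5)
})
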