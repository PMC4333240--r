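test_that("LTo placement honours count, spacing and bounds", {
  set.seed(42)
  cfg <- sim_config("full", environment = list(lto_count = 50L,
                                               lto_radius_um = 10))
  env <- create_environment(cfg)
  expect_equal(nrow(env$lto), 50)
  expect_equal(nrow(env$motile), 0)
  expect_false(any(env$lto$differentiated))
  expect_true(all(env$lto$x >= 0 & env$lto$x < env$width))
  expect_true(all(env$lto$y >= 0 & env$lto$y <= env$height))
  d <- as.matrix(dist(cbind(env$lto$x, env$lto$y)))
  # pairwise wrapped distances all exceed one LTo diameter
  for (i in 1:49) for (j in (i + 1):50) {
    wd <- wdist_oracle(c(env$lto$x[i], env$lto$y[i]),
                       c(env$lto$x[j], env$lto$y[j]), env$width)
    expect_gt(wd, 20)
  }
})

test_that("empty and infeasible LTo requests behave as specified", {
  set.seed(1)
  env0 <- create_environment(sim_config("test",
                                        environment = list(lto_count = 0L)))
  expect_equal(nrow(env0$lto), 0)
  expect_equal(nrow(env0$motile), 0)

  expect_error(
    create_environment(sim_config("test",
                                  environment = list(lto_count = 2000L,
                                                     lto_radius_um = 10))),
    "placement error")
})

test_that("placement is reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config("test")
  set.seed(7)
  a <- create_environment(cfg)
  set.seed(7)
  b <- create_environment(cfg)
  expect_identical(a, b)
})

test_that("positions wrap periodically in x and reflect in y", {
  env <- bare_env(5000, 1000)
  expect_equal(wrap_position(c(5010, 500), env), c(10, 500))
  expect_equal(wrap_position(c(-5, 500), env), c(4995, 500))
  expect_equal(wrap_position(c(2500, 1010), env), c(2500, 990))
  expect_equal(wrap_position(c(2500, -10), env), c(2500, 10))
  p <- wrap_position(c(12345.6, -2345.6), env)
  expect_true(p[1] >= 0 && p[1] < 5000)
  expect_true(p[2] >= 0 && p[2] <= 1000)
})

test_that("wrapped distance respects the periodic seam", {
  env <- bare_env(5000, 1000)
  expect_equal(wrapped_distance(c(1, 500), c(4999, 500), env), 2)
  expect_equal(wrapped_distance(c(0, 0), c(0, 300), env), 300)
  # random pairs agree with the R oracle
  set.seed(11)
  for (i in 1:25) {
    p <- c(runif(1, 0, 5000), runif(1, 0, 1000))
    q <- c(runif(1, 0, 5000), runif(1, 0, 1000))
    expect_equal(wrapped_distance(p, q, env), wdist_oracle(p, q, 5000))
  }
})

make_chem_env <- function(lto_df, cfg = sim_config("full")) {
  env <- list(width = cfg$environment$width_um,
              height = cfg$environment$height_um,
              lto = lto_df, config = cfg)
  class(env) <- "pp_environment"
  env
}

test_that("chemokine field follows the additive linear-decay kernel", {
  cfg <- sim_config("full")
  rc <- cfg$chemokine$r_chem_um
  no_src <- make_chem_env(data.frame(
    x = 2500, y = 500, radius = 10, differentiated = FALSE,
    expression = 0, lti_contacts = 0L), cfg)
  expect_equal(chemokine_level(no_src, c(2500, 500)), 0)
  expect_equal(chemokine_gradient(no_src, c(1000, 200)), c(0, 0))

  one <- make_chem_env(data.frame(
    x = 2500, y = 500, radius = 10, differentiated = TRUE,
    expression = 1, lti_contacts = 0L), cfg)
  expect_equal(chemokine_level(one, c(2500, 500)), 1)
  expect_equal(chemokine_level(one, c(2500 + rc / 2, 500)), 0.5)
  expect_equal(chemokine_level(one, c(2500 + rc, 500)), 0)
  expect_equal(chemokine_level(one, c(2500 + 2 * rc, 500)), 0)

  half <- make_chem_env(data.frame(
    x = 2500, y = 500, radius = 10, differentiated = TRUE,
    expression = 0.5, lti_contacts = 0L), cfg)
  expect_equal(chemokine_level(half, c(2500 + rc / 2, 500)), 0.25)

  two <- make_chem_env(data.frame(
    x = c(2500, 2500), y = c(500, 500), radius = 10,
    differentiated = TRUE, expression = 0.5, lti_contacts = 0L), cfg)
  expect_equal(chemokine_level(two, c(2500 + rc / 2, 500)), 0.5)
})

test_that("sub-threshold sources do not contribute chemokine", {
  cfg <- sim_config("full")
  dim_src <- make_chem_env(data.frame(
    x = 2500, y = 500, radius = 10, differentiated = TRUE,
    expression = cfg$chemokine$threshold / 2, lti_contacts = 0L), cfg)
  expect_equal(chemokine_level(dim_src, c(2500, 500)), 0)
})

test_that("chemokine gradient points up the field and vanishes at a source", {
  cfg <- sim_config("full")
  src <- make_chem_env(data.frame(
    x = 2500, y = 700, radius = 10, differentiated = TRUE,
    expression = 1, lti_contacts = 0L), cfg)
  g <- chemokine_gradient(src, c(2500, 550))  # source due north
  expect_equal(g[1], 0, tolerance = 1e-8)
  expect_gt(g[2], 0)
  expect_equal(chemokine_gradient(src, c(2500, 700)), c(0, 0))
})

test_that("chemokine level is bounded by the summed source expressions", {
  cfg <- sim_config("full")
  set.seed(3)
  n <- 12
  lto <- data.frame(x = runif(n, 0, 5000), y = runif(n, 0, 1000),
                    radius = 10, differentiated = TRUE,
                    expression = runif(n, 0.3, 1), lti_contacts = 0L)
  env <- make_chem_env(lto, cfg)
  for (i in 1:30) {
    p <- c(runif(1, 0, 5000), runif(1, 0, 1000))
    lev <- chemokine_level(env, p)
    expect_gte(lev, 0)
    expect_lte(lev, sum(lto$expression))
  }
})
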