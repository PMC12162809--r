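## Study configuration, fixtures, provenance and the batch runner.

test_that("fixtures are deterministic and well-formed", {
  p1 <- make_fixtures("patch")
  p2 <- make_fixtures("patch")
  expect_identical(p1$nodes, p2$nodes)
  expect_identical(p1$elems, p2$elems)
  expect_silent(validate_mesh(p1))
  ## cyclic point history has the exact loading period available
  h <- make_fixtures("point_histories", mode = "cyclic", n_steps = 5L)
  expect_length(h, 5L)
  expect_equal(h[[2]]$time - h[[1]]$time, 1800)
  expect_equal(h[[1]]$F_unloaded, diag(3))
  expect_error(make_fixtures("nonsense"))
})

test_that("study configuration validates parameter names and variations", {
  expect_error(study_config(material_overrides = list(bogus = 1)),
               "unknown material parameter")
  expect_error(study_config(variation = "nonsense"))
  cfg <- study_config(variation = "stiffness+10")
  v <- tehvsim:::apply_variation(cfg$variation, design1_params(),
                                 material_params())
  expect_equal(v$mat$k1_cf, 36.31)
  expect_equal(v$mat$k2_cf, 12.91)
  v2 <- tehvsim:::apply_variation("contractility-", design1_params(),
                                  material_params())
  expect_equal(v2$mat$sigma_max, 20)
  v3 <- tehvsim:::apply_variation("coaptation+", design2_params(),
                                  material_params())
  expect_equal(v3$geo$H, 16.31)
  v4 <- tehvsim:::apply_variation("coaptation+", design1_params(),
                                  material_params())
  expect_equal(v4$geo$tip_extension, 2.01)
  v5 <- tehvsim:::apply_variation("thin", design1_params(), material_params())
  expect_equal(v5$geo$thickness, 0.4)
})

test_that("YAML configuration round-trips", {
  cfg <- study_config(designs = 1L, codes = c("Ns", "Wc"),
                      conditions = "pulmonary", variation = "thin",
                      n_profile = 8L, remodel_step = 2,
                      material_overrides = list(sigma_max = 25))
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_study_config(cfg, f)
  cfg2 <- read_study_config(f)
  expect_equal(cfg2$codes, c("Ns", "Wc"))
  expect_equal(cfg2$variation, "thin")
  expect_equal(cfg2$material_overrides$sigma_max, 25)
  expect_equal(cfg2$remodel_step, 2)
})

test_that("a single-cell study produces one fully populated result row", {
  cfg <- study_config(designs = 1L, codes = "Mm", conditions = "pulmonary",
                      n_profile = 6L, n_span = 6L, n_layers = 1L,
                      order = 1L, remodel_step = 8, max_duration = 1)
  res <- run_study(cfg)
  r <- res$results
  expect_identical(nrow(r), 1L)
  expect_true(r$converged)
  expect_true(is.finite(r$roa))
  expect_true(is.finite(r$belly_length_unloaded))
  expect_true(is.finite(r$peak_stress))
  expect_true(is.finite(r$S_cf))
  expect_match(r$config_hash, "^[0-9a-f]{32}$")
  ## re-running the cell reproduces the row bit-identically
  res2 <- run_study(cfg)
  expect_identical(res$results[setdiff(names(r), "C_tot")],
                   res2$results[setdiff(names(r), "C_tot")])
})
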