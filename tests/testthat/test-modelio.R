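test_that("the packaged model declares the full roster", {
  m <- ec_model()
  expect_length(m$species, 21)
  expect_length(m$params, 43)
  expect_length(m$initial, 17)
  expect_length(m$env_species, 4)
})

test_that("the shipped model description loads and equals the constructor", {
  f <- system.file("extdata", "ec_model.yaml", package = "angiosprout")
  expect_true(nzchar(f))
  m <- load_model(f)
  ref <- ec_model()
  expect_equal(m$species, ref$species)
  expect_equal(m$params, ref$params)
  expect_equal(m$initial, ref$initial)
  expect_equal(length(m$reactions), length(ref$reactions))
})

test_that("native round-trip write -> read is the identity", {
  m <- ec_model(params = c(kt = 123.456, hill_h = 2))
  tf <- tempfile(fileext = ".yaml")
  write_model(m, tf)
  m2 <- load_model(tf)
  tf2 <- tempfile(fileext = ".yaml")
  write_model(m2, tf2)
  expect_equal(load_model(tf2), m2)
  expect_equal(m2$params, m$params)
  expect_equal(m2$species, m$species)
  # loaded model drives identical dynamics
  r1 <- reaction_rates(m, dll4_nb = 7, vegf_local = 50)
  r2 <- reaction_rates(m2, dll4_nb = 7, vegf_local = 50)
  expect_equal(r2, r1)
})

test_that("SBML round-trip preserves roster, parameters and kinetics", {
  m <- ec_model()
  tf <- tempfile(fileext = ".xml")
  write_model(m, tf)
  m2 <- load_model(tf)
  expect_equal(m2$species, m$species)
  expect_equal(m2$params, m$params)
  expect_equal(m2$initial[names(m$initial)], m$initial)
  r1 <- reaction_rates(m, dll4_nb = 3, vegf_local = 100)
  r2 <- reaction_rates(m2, dll4_nb = 3, vegf_local = 100)
  expect_equal(r2[names(r1)], r1)
  # the SBML is well-formed XML with one reaction element per reaction
  doc <- xml2::read_xml(tf)
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  expect_length(rx, length(m$reactions))
})

test_that("unknown rate laws and empty rosters are rejected loudly", {
  m <- ec_model()
  tf <- tempfile(fileext = ".xml")
  write_model(m, tf)
  txt <- readLines(tf)
  txt <- sub('law="mass_action"', 'law="michaelis_menten"', txt)
  tf_bad <- tempfile(fileext = ".xml")
  writeLines(txt, tf_bad)
  expect_error(load_model(tf_bad), "unknown rate law")

  tf_y <- tempfile(fileext = ".yaml")
  write_model(m, tf_y)
  y <- yaml::read_yaml(tf_y)
  y$species <- list()
  tf_y2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(y, tf_y2)
  expect_error(load_model(tf_y2), "no species")
})

test_that("model validation catches structural defects", {
  m <- ec_model()
  m$reactions[[1]]$law <- "bogus"
  expect_error(validate_model(m), "unknown rate law")
  m <- ec_model()
  m$reactions[[2]]$params[["vmax"]] <- "missing_param"
  expect_error(validate_model(m), "unknown parameter")
  m <- ec_model()
  m$species <- c(m$species[-1], m$species[2])
  expect_error(validate_model(m), "duplicate")
  expect_error(ec_model(params = c(nonexistent = 1)), "unknown parameter")
  expect_error(ec_model(params = c(kt = -1)), ">= 0")
})

test_that("field and mask writers round-trip through disk", {
  f <- field(matrix(runif(30), 5, 6), name = "vegf")
  tf <- tempfile(fileext = ".csv")
  write_field_csv(f, tf)
  expect_equal(unname(read_field_csv(tf)), unname(f$grid), tolerance = 1e-12)
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  tp <- tempfile(fileext = ".png")
  write_mask_png(mask, tp)
  expect_equal(read_mask_png(tp), mask)
})
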