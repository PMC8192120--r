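test_that("scheme construction enforces basic structural invariants", {
  expect_error(kinetic_scheme(
    tibble::tibble(name = c("A", "A"), conformation = "outward"),
    tibble::tibble(from = "A", to = "A", kf0 = 1, kr0 = 1, zQ = 0)),
    "unique")
  expect_error(kinetic_scheme(
    tibble::tibble(name = "A", conformation = "outward"),
    tibble::tibble(from = "A", to = "Z", kf0 = 1, kr0 = 1, zQ = 0)),
    "unknown states")
  expect_error(two_state_scheme(-1, 1), "non-negative")
  expect_error(two_state_scheme(1, 1, zQ = Inf), "finite")
})

test_that("validate_scheme reports diagnostics instead of raising", {
  expect_length(validate_scheme(build_dat_model()$scheme), 0)
  expect_length(validate_scheme(build_net_model()$scheme), 0)
  expect_length(validate_scheme(build_sert_model(with_li_deadend = TRUE)$scheme), 0)

  # duplicate edge between the same unordered pair
  dup <- kinetic_scheme(
    tibble::tibble(name = c("A", "B"), conformation = c("outward", "inward")),
    tibble::tibble(from = c("A", "B"), to = c("B", "A"),
                   kf0 = 1, kr0 = 1, zQ = 0))
  expect_match(validate_scheme(dup), "duplicate", all = FALSE)

  # destination gains a ligand with no coupling declared
  bad <- binding_scheme()
  bad$transitions$lig_f <- NA_character_
  expect_match(validate_scheme(bad), "ligand-count mismatch", all = FALSE)

  # unreachable states
  disc <- kinetic_scheme(
    tibble::tibble(name = c("A", "B", "C"), conformation = "outward"),
    tibble::tibble(from = "A", to = "B", kf0 = 1, kr0 = 1, zQ = 0))
  expect_match(validate_scheme(disc), "disconnected", all = FALSE)
})

test_that("schemes round-trip losslessly through the text serialization", {
  for (m in list(build_dat_model(), build_sert_model(with_li_deadend = TRUE))) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scheme(m$scheme, path)
    back <- read_scheme(path)
    expect_equal(back$states$name, m$scheme$states$name)
    expect_equal(back$transitions$kf0, m$scheme$transitions$kf0,
                 tolerance = 1e-12)
    expect_equal(back$transitions$kr0, m$scheme$transitions$kr0,
                 tolerance = 1e-12)
    expect_equal(back$transitions$zQ, m$scheme$transitions$zQ)
    expect_identical(back$transitions$lig_f, m$scheme$transitions$lig_f)
    expect_identical(back$meta$substrate_bound_in,
                     m$scheme$meta$substrate_bound_in)
    # behavioural equality: identical generator
    cond <- get_condition_preset("physiological")
    expect_equal(build_generator(back, cond, -0.06),
                 build_generator(m$scheme, cond, -0.06), tolerance = 1e-12)
  }
})

test_that("condition presets encode the recording solutions", {
  phys <- get_condition_preset("physiological")
  expect_equal(unname(phys$inside["K"]), 0.163)
  expect_equal(unname(phys$inside["Na"]), 0.006)
  expect_equal(unname(phys$outside["Na"]), 0.163)
  expect_equal(unname(phys$inside["H"]), 10^-7.2)

  nmdg <- get_condition_preset("NMDG_in")
  expect_equal(unname(nmdg$inside[c("Na", "K", "Li")]), c(0, 0, 0))

  expect_equal(unname(get_condition_preset("high_Na_in")$inside["Na"]), 0.163)
  expect_equal(unname(get_condition_preset("high_Li_in")$inside["Li"]), 0.163)
  expect_equal(unname(get_condition_preset("pH5.6_in")$inside["H"]), 10^-5.6)
  # external Na+ is 163 mM in every preset
  for (nm in condition_preset_names()) {
    expect_equal(unname(get_condition_preset(nm)$outside["Na"]), 0.163)
  }
  expect_error(get_condition_preset("outer_space"), "unknown")
})

test_that("shipped fixture files match the builders", {
  for (id in c("DAT", "NET", "SERT")) {
    path <- system.file("extdata", "models", paste0(id, "_APP.yaml"),
                        package = "slc6sim")
    skip_if(path == "", "fixture files not installed")
    fixture <- read_scheme(path)
    built <- if (id == "SERT") build_sert_model(with_li_deadend = TRUE) else
      build_transporter_model(id)
    cond <- get_condition_preset("physiological")
    expect_equal(build_generator(fixture, cond, -0.06),
                 build_generator(built$scheme, cond, -0.06),
                 tolerance = 1e-10)
  }
})
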