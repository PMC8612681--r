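test_that("presets regenerate the printed concentration vectors exactly", {
  cfg <- preset("freestrand-160")
  expect_identical(
    cfg$condition[c("activator/c1", "c1s", "c2/inhibitor", "c2s", "input")],
    c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
      "c2s" = 160, "input" = 160)
  )
  # 10 nM origami with 16 connectors -> 160 nM connector pools, input 1 eq
  og <- preset("origami-basic-10")
  expect_identical(unname(og$condition[["input"]]), 160)
  expect_identical(unname(og$condition[["activator/c1"]]), 160)
  expect_identical(og$monomer_concentrations,
                   c(cylinder = 10, cuboid = 10))
  # fuel A preset: 15 nM cuboids 16c, 10 nM cylinders 16c, input + fuel A 160
  fa <- preset("origami-fuelA")
  expect_identical(unname(fa$condition[["c2/inhibitor"]]), 240)
  expect_identical(unname(fa$condition[["fuelA"]]), 160)
  # the three printed fuel A concentrations each have their own preset
  expect_identical(unname(preset("origami-fuelA-240")$condition[["fuelA"]]), 240)
  expect_identical(unname(preset("origami-fuelA-80")$condition[["fuelA"]]), 80)
  expect_identical(unname(preset("origami-fuelB-480")$condition[["fuelB"]]), 480)
  # threshold presets at 160 nM gate (and optional 160 nM fuel B)
  th <- preset("origami-threshold-fuelB")
  expect_identical(unname(th$condition[["threshold"]]), 160)
  expect_identical(unname(th$condition[["fuelB"]]), 160)
})

test_that("fuel A presets encode the 1.5:1 cuboid:cylinder stoichiometry", {
  for (nm in c("freestrand-fuelA-240", "origami-fuelA")) {
    cfg <- preset(nm)
    expect_equal(unname(cfg$condition[["c2/inhibitor"]] /
                          cfg$condition[["activator/c1"]]), 1.5)
  }
})

test_that("origami configurations validate the connector arithmetic", {
  # connector totals must equal monomer concentration x connectors per face
  expect_error(
    circuit_config("basic",
                   c("activator/c1" = 100, "c1s" = 100, "c2/inhibitor" = 160,
                     "c2s" = 160, "input" = 160),
                   origami_mode = TRUE,
                   connectors_per_face = c(cylinder = 16L, cuboid = 16L),
                   monomer_concentrations = c(cylinder = 10, cuboid = 10)),
    "inconsistent"
  )
  # 8-connector cuboids at 20 nM keep the 160 nM pool
  c8 <- preset("origami-cuboid8c-20")
  expect_identical(unname(c8$condition[["c2/inhibitor"]]), 160)
  expect_identical(unname(c8$connectors_per_face[["cuboid"]]), 8L)
})

test_that("configuration errors are rejected before computation", {
  expect_error(preset("no-such-preset"), "unknown preset")
  expect_error(circuit_config("amplifier", c(input = 1)), "unknown circuit modules")
  expect_error(circuit_config("basic", c(widget = 1)), "unknown species")
  expect_error(preset("freestrand-160", widget = 5), "unknown species")
  # species outside the configured modules are rejected
  expect_error(
    build_circuit(circuit_config("basic", c("input" = 160, "fuelA" = 100))),
    "not part of the configured modules"
  )
})

test_that("origami mode toggles tethering; free strands leave it empty", {
  expect_setequal(build_circuit("origami-basic-10")$tethered_strands,
                  c("c1", "c1s", "c2", "c2s"))
  expect_length(build_circuit("freestrand-160")$tethered_strands, 0L)
})
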