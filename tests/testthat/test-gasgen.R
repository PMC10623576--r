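test_that("dilution factor follows the flow ratio convention", {
  expect_identical(dilution_factor(flow_config()), 1600)
  expect_identical(dilution_factor(flow_config(chamber_flow = 1,
                                               dilution_flow = 1)), 1)
  expect_identical(dilution_factor(flow_config(chamber_flow = 0.005,
                                               dilution_flow = 0.1)), 20)
  expect_equal(dilution_factor(flow_config(), convention = "total"), 1601)
  expect_error(flow_config(chamber_flow = 0), "chamber_flow")
  expect_error(flow_config(dilution_flow = -1), "dilution_flow")
})

test_that("headspace molarity follows Henry's law with the 1e3 scale", {
  acetone <- get_compound("acetone")
  pyridine <- get_compound("pyridine")
  expect_identical(headspace_gas_molarity(0, acetone), 0)
  expect_equal(headspace_gas_molarity(0.67, acetone), 1e-3)
  expect_equal(headspace_gas_molarity(1.0, pyridine), 1 / 2730)
  # unit-scale convention available
  expect_equal(headspace_gas_molarity(0.67, acetone, henry_scale = 1), 1)
  expect_error(headspace_gas_molarity(-1, acetone), "stock_molarity")
})

test_that("molar-to-ppm conversion matches the ideal-gas oracle", {
  vm <- ideal_gas_molar_volume(298.15, 101325) # 24.4655 L/mol
  expect_identical(molar_to_ppm(0), 0)
  expect_equal(molar_to_ppm(4.0874e-8, 298.15, 101325),
               4.0874e-8 * vm * 1e6, tolerance = 1e-9)
  expect_equal(molar_to_ppm(4.0874e-8, 298.15, 101325), 1.0,
               tolerance = 1e-3)
  # pure-gas limit: 1/Vm mol/L is the whole gas
  expect_equal(molar_to_ppm(1 / vm, 298.15, 101325), 1e6,
               tolerance = 1e-12)
  # oracle agreement across a range of conditions
  for (Tk in c(273.15, 298.15, 333.15)) {
    for (P in c(9e4, 101325)) {
      x <- 3.7e-9
      expect_equal(molar_to_ppm(x, Tk, P),
                   x * ideal_gas_molar_volume(Tk, P) * 1e6,
                   tolerance = 1e-9)
    }
  }
  expect_error(molar_to_ppm(1, temperature = 0), "temperature")
  expect_error(molar_to_ppm(1, pressure = -1), "pressure")
})

test_that("outlet concentration chains Henry, ideal gas and dilution", {
  acetone <- get_compound("acetone")
  flows <- flow_config()
  expect_identical(outlet_ppm(0, acetone, flows), 0)
  # 1 M acetone stock: 1/670 mol/L headspace, x24.4655e6, /1600
  vm <- ideal_gas_molar_volume(298.15, 101325)
  expect_equal(outlet_ppm(1, acetone, flows), vm * 1e6 / 670 / 1600,
               tolerance = 1e-12)
  expect_equal(outlet_ppm(1, acetone, flows), 22.82, tolerance = 1e-3)
  # headspace at 1 ppm diluted by 1600
  stock_1ppm_headspace <- 1e-6 / vm * 670
  expect_equal(outlet_ppm(stock_1ppm_headspace, acetone, flows), 1 / 1600,
               tolerance = 1e-12)
  # linearity in the stock and inverse proportionality to the Henry constant
  s <- c(1e-4, 2e-4, 8e-4)
  expect_equal(outlet_ppm(s, acetone, flows), s * outlet_ppm(1, acetone,
                                                             flows))
  h2 <- compound("x", 58, 2 * 0.67, 782.1)
  expect_equal(outlet_ppm(1, h2, flows), outlet_ppm(1, acetone, flows) / 2)
})

test_that("required stock inverts the outlet concentration", {
  acetone <- get_compound("acetone")
  flows <- flow_config()
  expect_identical(required_stock(0, acetone, flows), 0)
  # round trip at 1e-12 relative over random stocks
  withr::with_seed(42, {
    for (stock in 10^stats::runif(10, -7, 0)) {
      expect_equal(required_stock(outlet_ppm(stock, acetone, flows),
                                  acetone, flows),
                   stock, tolerance = 1e-12)
    }
  })
  # hand-computed target for the lowest crossover set point:
  # 1.1e-8 mole fraction -> /Vm -> x1600 -> x670
  vm <- ideal_gas_molar_volume(298.15, 101325)
  expect_equal(required_stock(1.1e-2, acetone, flows),
               1.1e-8 / vm * 1600 * 670, tolerance = 1e-12)
  expect_equal(required_stock(1.1e-2, acetone, flows), 4.82e-4,
               tolerance = 1e-3)
})

test_that("concentration ladders are half-logarithmic with both endpoints", {
  l <- concentration_ladder(1, 3, 0.5)
  expect_length(l, 7)
  expect_equal(as.numeric(l), c(1, 3.1623, 10, 31.623, 100, 316.23, 1000),
               tolerance = 1e-4)
  expect_equal(as.numeric(concentration_ladder(1, 1, 1)), c(1, 10))
  l2 <- concentration_ladder(1.1e-2, 3, 0.5)
  expect_equal(l2[1], 1.1e-2)
  expect_equal(l2[length(l2)], 11, tolerance = 1e-12)
  # length and span invariants
  for (d in c(1, 2, 3)) {
    lad <- concentration_ladder(0.27, d, 0.5)
    expect_length(lad, d / 0.5 + 1)
    expect_equal(lad[length(lad)] / lad[1], 10^d, tolerance = 1e-12)
    expect_true(all(diff(log10(lad)) > 0))
    expect_equal(diff(log10(lad)), rep(0.5, d / 0.5), tolerance = 1e-12)
  }
  expect_error(concentration_ladder(1, 1.3, 0.5), "multiple")
  expect_error(concentration_ladder(0, 3), "base_ppm")
})

test_that("compound records validate their physical parameters", {
  expect_error(compound("x", -1, 1, 700), "monoisotopic_mass")
  expect_error(compound("x", 58, 0, 700), "henry_constant")
  expect_error(compound("x", 58, 1, -5), "gas_phase_basicity")
  tab <- compounds()
  expect_setequal(tab$name, c("acetone", "d6-acetone", "d3-acoh",
                              "pyridine", "ammonia"))
  # deuterated compounds share the parent Henry constant; isotopologues
  # share gas-phase basicity
  expect_equal(tab$henry_constant[tab$name == "d6-acetone"],
               tab$henry_constant[tab$name == "acetone"])
  expect_equal(tab$gas_phase_basicity[tab$name == "d6-acetone"],
               tab$gas_phase_basicity[tab$name == "acetone"])
  expect_equal(mz_protonated(get_compound("pyridine")), 80.0495,
               tolerance = 1e-5)
})
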