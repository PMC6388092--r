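# Unit conversion, the complexation-energy difference, and conformer
# aggregation.

RT298 <- 1.98720425864083e-3 * 298.15

test_that("energy conversion applies the declared factors and round-trips", {
  expect_identical(convertEnergy(5.0, "kcal_per_mol"), 5.0)
  expect_identical(convertEnergy(1.0, "hartree"), 627.5095)
  expect_equal(convertEnergy(-0.01, "hartree"), -6.275095)
  # round trip to 1e-9 relative
  for (v in c(-123.456, 1e-6, 8.31)) {
    back <- convertEnergy(v, "hartree") / energyUnit("hartree")$to_kcal_factor
    expect_equal(back, v, tolerance = 1e-9)
  }
  expect_error(convertEnergy(1, "eV"), "eV", class = "theoceptor_schema_error")
  expect_error(convertEnergy(NaN, "hartree"), class = "theoceptor_schema_error")
})

test_that("complexation energy is complex minus ligand minus receptor", {
  expect_identical(deltaEnergy(-10, -4, -6), 0)
  # components constructed to sum to the compound-1 value; sign convention:
  # negative favours binding
  expect_equal(deltaEnergy(-120.3, -60.0, -42.6), -17.7)
  expect_identical(deltaEnergy(0, 0, 0), 0)
  expect_error(deltaEnergy(-10, NA_real_, -6), "e_ligand",
               class = "theoceptor_schema_error")
  expect_error(deltaEnergy(-10, -4, Inf), "e_receptor",
               class = "theoceptor_schema_error")
})

test_that("Boltzmann ensemble energy matches closed forms", {
  expect_identical(boltzmannEnergy(-17.7), -17.7)
  # m degenerate states: E - RT log m
  expect_equal(boltzmannEnergy(c(0, 0)), -RT298 * log(2), tolerance = 1e-12)
  expect_equal(boltzmannEnergy(rep(-5, 4)), -5 - RT298 * log(4), tolerance = 1e-12)
  # large-gap limit collapses to the minimum
  expect_equal(boltzmannEnergy(c(0, 50)), 0, tolerance = 1e-10)
  expect_error(boltzmannEnergy(numeric(0)), class = "theoceptor_schema_error")
  expect_error(boltzmannEnergy(c(0, 1), temperature = 0),
               class = "theoceptor_schema_error")
  expect_error(boltzmannEnergy(c(0, 1), temperature = -10),
               class = "theoceptor_schema_error")
})

test_that("Boltzmann energy never exceeds the minimum and is order-invariant", {
  set.seed(11)
  for (i in 1:25) {
    e <- rnorm(sample(2:8, 1), mean = -15, sd = 10)
    b <- boltzmannEnergy(e)
    expect_lte(b, min(e))
    expect_equal(boltzmannEnergy(sample(e)), b, tolerance = 1e-12)
  }
  # huge spreads must not overflow thanks to the min-shift
  expect_equal(boltzmannEnergy(c(-1e6, 0, 1e6)), -1e6)
})

test_that("Boltzmann energy decreases monotonically as conformers are appended", {
  set.seed(12)
  e <- rnorm(6, -10, 5)
  vals <- vapply(seq_along(e), function(k) boltzmannEnergy(e[1:k]), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("Boltzmann energy tends to the minimum as T tends to zero", {
  e <- c(-17.7, -17.2, -12.0)
  expect_equal(boltzmannEnergy(e, temperature = 1e-6), min(e), tolerance = 1e-6)
})

test_that("assembleDeltaE reduces conformer ensembles to a complexation energy", {
  recs <- data.frame(
    species_id = c("lig1", "lig1", "receptor"),
    state = c("complex", "free_ligand", "receptor"),
    hypothesis = "default", conformer_id = c("c1", "f1", "r1"),
    energy = c(-120.3, -60.0, -42.6), stringsAsFactors = FALSE
  )
  expect_equal(assembleDeltaE(recs, "lig1"), -17.7)

  # a duplicate-energy complex conformer leaves the minimum unchanged but
  # lowers the Boltzmann ensemble by RT log 2
  recs2 <- rbind(recs, data.frame(species_id = "lig1", state = "complex",
                                  hypothesis = "default", conformer_id = "c2",
                                  energy = -120.3, stringsAsFactors = FALSE))
  expect_equal(assembleDeltaE(recs2, "lig1"), -17.7)
  expect_equal(assembleDeltaE(recs2, "lig1", aggregate = "boltzmann"),
               -17.7 - RT298 * log(2), tolerance = 1e-12)
  # with one conformer per state both aggregations agree
  expect_equal(assembleDeltaE(recs, "lig1", aggregate = "boltzmann"),
               assembleDeltaE(recs, "lig1", aggregate = "minimum"))
})

test_that("assembleDeltaE rejects missing states, ambiguous receptors and mixed hypotheses", {
  recs <- data.frame(
    species_id = c("lig1", "lig1", "receptor"),
    state = c("complex", "free_ligand", "receptor"),
    hypothesis = "default", conformer_id = c("c1", "f1", "r1"),
    energy = c(-120.3, -60.0, -42.6), stringsAsFactors = FALSE
  )
  expect_error(assembleDeltaE(recs[-2, ], "lig1"), "free_ligand",
               class = "theoceptor_schema_error")
  expect_error(assembleDeltaE(recs[-3, ], "lig1"), "receptor",
               class = "theoceptor_schema_error")
  two_rec <- rbind(recs, within(recs[3, ], conformer_id <- "r2"))
  expect_error(assembleDeltaE(two_rec, "lig1"), "ambiguous",
               class = "theoceptor_schema_error")
  # hypotheses are never mixed during aggregation
  mixed <- rbind(recs, data.frame(species_id = "lig1", state = "complex",
                                  hypothesis = "boat", conformer_id = "c9",
                                  energy = -110, stringsAsFactors = FALSE))
  expect_error(assembleDeltaE(mixed, "lig1"), "hypothes",
               class = "theoceptor_schema_error")
  expect_equal(assembleDeltaE(mixed, "lig1", hypothesis = "default"), -17.7)
})

test_that("energy tables read with unit conversion and key validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species_id,state,hypothesis,conformer_id,energy,unit,comment",
    "lig1,complex,default,c1,-0.2,hartree,opt",
    "lig1,free_ligand,default,f1,-60.0,kcal_per_mol,opt",
    "rec,receptor,default,r1,-42.6,kcal_per_mol,opt"
  ), path)
  expect_warning(tab <- readEnergyTable(path), "comment")
  expect_equal(tab$energy[1], -0.2 * 627.5095)
  expect_equal(assembleDeltaE(tab, "lig1"),
               deltaEnergy(-0.2 * 627.5095, -60, -42.6))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species_id,state,hypothesis,conformer_id,energy",
    "lig1,complex,default,c1,-1",
    "lig1,complex,default,c1,-2"
  ), dup)
  expect_error(readEnergyTable(dup), "duplicate", class = "theoceptor_schema_error")
  expect_error(readEnergyTable(file.path(tempdir(), "nope.csv")),
               class = "theoceptor_io_error")
})
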