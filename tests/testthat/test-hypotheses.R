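# Ranking of competing structural interpretations and the
# conformer-focusing penalty.

test_that("the lowest bound-state energy wins with margins in both states", {
  h <- hypothesisSet("ring-pucker", c("chair", "boat"), c(0, 10), c(0, 9))
  rep <- rankHypotheses(h, threshold = 1.0)
  expect_identical(rep$preferred, "chair")
  expect_equal(rep$bound_margin, 10)
  expect_equal(rep$free_margin, 9)
  expect_identical(rep$verdict, "decisive")
})

test_that("sub-threshold gaps are declared indistinguishable", {
  h <- hypothesisSet("oxygen-placement", c("posA", "posB"), c(0, 0.2))
  rep <- rankHypotheses(h, threshold = 1.0)
  expect_identical(rep$verdict, "indistinguishable")
  expect_equal(rep$bound_margin, 0.2)
  expect_true(is.na(rep$free_margin)) # bound-state-only comparison
  # exact ties break lexicographically and cannot be decisive
  tie <- rankHypotheses(hypothesisSet("x", c("zeta", "alpha"), c(1, 1)))
  expect_identical(tie$preferred, "alpha")
  expect_identical(tie$verdict, "indistinguishable")
})

test_that("free-state and bound-state preferences can disagree", {
  h <- hypothesisSet("ring-sub", c("axial", "equatorial"), c(0, 5), c(0, 0.4))
  rep <- rankHypotheses(h)
  expect_identical(rep$preferred, "axial")
  expect_equal(rep$bound_margin, 5)
  expect_equal(rep$free_margin, 0.4)
})

test_that("margins are invariant to energy zero shifts and entry order", {
  set.seed(55)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    labels <- paste0("h", seq_len(m))
    bound <- rnorm(m, 0, 6)
    free <- rnorm(m, 0, 3)
    base <- rankHypotheses(hypothesisSet("lig", labels, bound, free))
    shifted <- rankHypotheses(
      hypothesisSet("lig", labels, bound + 137.2, free - 55.5))
    expect_identical(shifted$preferred, base$preferred)
    expect_equal(shifted$bound_margin, base$bound_margin, tolerance = 1e-10)
    expect_equal(shifted$free_margin, base$free_margin, tolerance = 1e-10)
    perm <- sample(m)
    permuted <- rankHypotheses(
      hypothesisSet("lig", labels[perm], bound[perm], free[perm]))
    expect_identical(permuted$preferred, base$preferred)
    expect_equal(permuted$bound_margin, base$bound_margin)
    expect_equal(permuted$free_margin, base$free_margin)
  }
})

test_that("the conformer-focusing penalty is the free-state cost of the bioactive form", {
  h3 <- hypothesisSet("c3", c("axial", "equatorial"), c(0, 4), c(0.6, 0))
  expect_equal(conformerFocusing(h3), 0.6)
  # zero when bound and free minima coincide
  agree <- hypothesisSet("c1", c("chair", "boat"), c(0, 10), c(0, 9))
  expect_equal(conformerFocusing(agree), 0)
  set.seed(56)
  for (i in 1:30) {
    m <- sample(2:6, 1)
    h <- hypothesisSet("r", paste0("h", seq_len(m)), rnorm(m, 0, 5), rnorm(m, 0, 5))
    cf <- conformerFocusing(h)
    expect_gte(cf, 0)
    expect_lte(cf, max(h$entries$free_energy) - min(h$entries$free_energy))
  }
})

test_that("hypothesis sets validate their inputs", {
  expect_error(hypothesisSet("x", "only-one", 0), class = "theoceptor_schema_error")
  expect_error(hypothesisSet("x", c("a", "a"), c(0, 1)),
               class = "theoceptor_schema_error")
  expect_error(rankHypotheses(hypothesisSet("x", c("a", "b"), c(0, 1)),
                              threshold = -1),
               class = "theoceptor_schema_error")
  expect_error(conformerFocusing(hypothesisSet("x", c("a", "b"), c(0, 1))),
               "free-state", class = "theoceptor_schema_error")
  # bound-preferred entry lacking a free energy is rejected
  h <- hypothesisSet("x", c("a", "b", "c"), c(0, 1, 2), c(NA, 0.5, 0.1))
  expect_error(conformerFocusing(h), class = "theoceptor_schema_error")
})

test_that("hypothesis CSVs parse into per-ligand sets with unit conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ligand_id,hypothesis,state,energy,unit",
    "ligA,chair,bound,0,kcal_per_mol",
    "ligA,boat,bound,10,kcal_per_mol",
    "ligA,chair,free,0,kcal_per_mol",
    "ligA,boat,free,9,kcal_per_mol",
    "ligB,tautomer1,bound,0,kcal_per_mol",
    "ligB,tautomer2,bound,0.01,hartree"
  ), path)
  sets <- readHypothesisTable(path)
  expect_named(sets, c("ligA", "ligB"))
  expect_equal(rankHypotheses(sets$ligA)$bound_margin, 10)
  expect_equal(sets$ligB$entries$bound_energy[2], 6.275095)

  nobound <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ligand_id,hypothesis,state,energy",
               "ligA,chair,free,0", "ligA,boat,bound,1"), nobound)
  expect_error(readHypothesisTable(nobound), "bound",
               class = "theoceptor_schema_error")
})
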