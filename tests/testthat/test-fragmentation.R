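test_that("the nine hydrogen-rearrangement rules carry the exact deltas", {
  tbl <- hr_rules()
  expected <- c(P1 = -1L, P2 = 1L, P3 = 0L, P4 = -2L,
                N1 = -1L, N2 = -3L, N3 = -2L, N4 = 0L, N5 = -2L)
  expect_equal(stats::setNames(tbl$hydrogen_delta, tbl$id), expected)
  expect_equal(tbl$polarity, c(rep("positive", 4), rep("negative", 5)))
  expect_equal(tbl$precursor_form[tbl$id %in% c("P3", "P4", "N4", "N5")],
               rep("ionized", 4))
})

test_that("applying rules delegates to the ion m/z arithmetic", {
  expect_equal(apply_hr_rule("C16H32O3", "N1"), 271.2279, tolerance = 1e-4)
  expect_equal(apply_hr_rule("C16H32O3", "N2"),
               apply_hr_rule("C16H32O3", "N1") - 2 * 1.0078250,
               tolerance = 1e-6)
  # N4 is the identity rule on the ionized form: delta 0
  expect_equal(apply_hr_rule("C16H32O3", "N4"),
               formula_mass("C16H32O3") + 0.00054858, tolerance = 1e-6)
  # combinations sum their deltas (two-cleavage assignments)
  expect_equal(apply_hr_rule("C18H34O2", c("N2", "N5")),
               ion_mz("C18H34O2", -5, -1))
  expect_error(apply_hr_rule("C16H32O3", "N9"), "unknown HR rule")
  expect_error(apply_hr_rule("C16H32O3", c("N1", "P1")), "polarity")
})

test_that("Cer[NS] yields 10 diagnostic ions and Cer[AS] yields 14", {
  ns <- generate_spectrum("Cer[NS] d18:1/26:0", "[M+CH3COO]-")
  expect_equal(ns$n_peaks, 10L)
  pk <- ns$peaks[[1]]
  expect_equal(sum(pk$origin == "fatty-acid"), 6L)   # b, c, d + satellites
  expect_equal(sum(pk$origin == "sphingoid"), 4L)    # e, f + satellites

  as_ <- generate_spectrum("Cer[AS] d18:1/16:0", "[M+CH3COO]-")
  expect_equal(as_$n_peaks, 14L)
  hit <- as_$peaks[[1]] |>
    dplyr::filter(abs(.data$mz - 271.2279) < 0.002)
  expect_equal(nrow(hit), 1)
  expect_match(hit$label, "nucleophilic substitution")
  expect_equal(hit$formula, "C16H32O3")
  expect_equal(hit$rule, "N1")
})

test_that("unsupported adducts and missing templates raise named errors", {
  expect_error(generate_spectrum("Cer[NS] d18:1/16:0", "[M+K]+"),
               "unsupported adduct")
  expect_error(generate_spectrum("SM d18:1/16:0", "[M+H]+"),
               "no fragment template.*SM")
})

test_that("generated spectra satisfy the structural invariants", {
  lib <- small_library()
  for (i in seq_len(nrow(lib))) {
    rec <- lib[i, ]
    pk <- rec$peaks[[1]]
    expect_true(all(diff(pk$mz) > 0))                   # sorted, merged
    expect_true(all(pk$mz < rec$precursor_mz + 0.5))
    expect_equal(max(pk$intensity), 999)
    expect_true(all(pk$intensity >= 0 & pk$intensity <= 999))
    # fragment formulas are sub-formulas of species + adduct atoms
    species_plus <- chem_formula(rec$formula) + "C2H4O2"  # acetate headroom
    for (f in pk$formula) {
      expect_true(formula_contains(species_plus, f), info = rec$name)
    }
  }
})

test_that("one extra fatty-acid carbon shifts only fatty-acid ions by CH2", {
  a <- generate_spectrum("Cer[NS] d18:1/16:0", "[M+CH3COO]-")$peaks[[1]]
  b <- generate_spectrum("Cer[NS] d18:1/17:0", "[M+CH3COO]-")$peaks[[1]]
  a <- dplyr::arrange(a, .data$label)
  b <- dplyr::arrange(b, .data$label)
  expect_equal(a$label, b$label)
  fa <- a$origin == "fatty-acid"
  expect_equal(b$mz[fa] - a$mz[fa], rep(14.01565, sum(fa)),
               tolerance = 1e-5)
  expect_equal(b$mz[!fa], a$mz[!fa], tolerance = 1e-9)
})

test_that("positive-mode templates give the dehydration series", {
  rec <- generate_spectrum("Cer[BS] d18:1/26:0", "[M+H]+")
  pk <- rec$peaks[[1]]
  expect_equal(rec$polarity, "positive")
  expect_equal(nrow(pk), 4)
  mh <- adduct_mz(chem_formula(rec$formula), "[M+H]+")
  expect_equal(sort(pk$mz, decreasing = TRUE)[1:2],
               c(mh - 18.010565, mh - 2 * 18.010565), tolerance = 1e-4)
  # the d18:1 sphingosine dehydration fragment
  expect_true(any(abs(pk$mz - 264.2686) < 0.001))
})

test_that("build_library enumerates species x adducts and empty configs", {
  cfg <- enumeration_config(classes = "Cer[NS]", fa_c = c(16, 18), fa_db = 0,
                            base_c = 18, base_db = 1)
  lib <- build_library(cfg)
  expect_equal(nrow(lib), 2 * 3)
  expect_equal(nrow(build_library(list())), 0)
})

test_that("observed peaks annotate to the nearest template ion", {
  ann <- annotate_peaks(data.frame(mz = c(271.227, 400.000)),
                        "Cer[AS] d18:1/16:0", "[M+CH3COO]-",
                        tolerance_mda = 10)
  expect_true(ann$matched[1])
  expect_lt(abs(ann$delta_mda[1]), 1)
  expect_match(ann$label[1], "nucleophilic")
  expect_false(ann$matched[2])
})

test_that("annotation ties go to the lower template m/z", {
  rec <- generate_spectrum("Cer[AS] d18:1/16:0", "[M+CH3COO]-")
  theo <- sort(rec$peaks[[1]]$mz)
  mid <- (theo[1] + theo[2]) / 2
  ann <- annotate_peaks(data.frame(mz = mid), "Cer[AS] d18:1/16:0",
                        "[M+CH3COO]-",
                        tolerance_mda = (theo[2] - theo[1]) * 1000)
  expect_equal(ann$theo_mz, theo[1])
})

test_that("result objects plot as ggplot stick/trace displays", {
  rec <- generate_spectrum("Cer[NS] d18:1/16:0", "[M-H]-")
  p <- plot_spectrum(rec)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(rec), "ggplot")
  ds <- synth_rt_dataset(30, 3, c(x01 = 2), seed = 6)
  expect_s3_class(autoplot(fit_stepwise(ds$descriptors, ds$rt)), "ggplot")
})
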