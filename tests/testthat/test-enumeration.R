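test_that("shorthand names parse into the expected compositions", {
  sp <- parse_lipid_names("Cer[AS] d18:1/16:0")
  expect_equal(sp$class, "Cer[AS]")
  expect_equal(sp$base_kind, "S")
  expect_equal(c(sp$base_c, sp$base_db, sp$base_oh), c(18L, 1L, 2L))
  expect_equal(c(sp$fa_c, sp$fa_db), c(16L, 0L))
  expect_equal(sp$fa_type, "A")

  sp2 <- parse_lipid_names("Cer[AP] t18:0/24:0")
  expect_equal(sp2$base_kind, "P")
  expect_equal(sp2$base_oh, 3L)

  # parenthesized and spaced variants are the same name
  sp3 <- parse_lipid_names("Cer[AP](t18:0/24:0)")
  expect_equal(sp3$formula, sp2$formula)

  expect_error(parse_lipid_names("Cer[XX] d18:1/16:0"), "parse|unknown")
  expect_error(parse_lipid_names("Cer[NS] t18:1/16:0"), "inconsistent")
  expect_error(parse_lipid_names("Cer[NS] d18:1/16:0/18:0"), "not allowed")
  expect_error(parse_lipid_names("Cer[EOS] d18:1/30:0"), "required")
  expect_error(parse_lipid_names("gibberish"), "cannot parse")
})

test_that("block condensation gives the documented formulas", {
  cases <- tibble::tribble(
    ~name,                       ~formula,
    "Cer[NS] d18:1/26:0",        "C44H87NO3",
    "Cer[AS] d18:1/16:0",        "C34H67NO4",
    "HexCer[NS] d18:1/24:0",     "C48H93NO8",
    "Cer[AP] t18:0/24:0",        "C42H85NO5",
    "SM d18:1/16:0",             "C39H79N2O6P"
  )
  got <- parse_lipid_names(cases$name)
  expect_equal(got$formula, cases$formula)
})

test_that("parse . format is the identity over a mixed enumeration", {
  cfg <- enumeration_config(
    classes = c("Cer[NS]", "Cer[AP]", "HexCer[BS]", "Cer[EOS]", "SM"),
    fa_c = c(16, 18), fa_db = 0:1, base_c = 18, base_db = 0:1,
    est_c = 18, est_db = 1)
  sp <- enumerate_species(cfg)
  expect_gt(nrow(sp), 0)
  back <- parse_lipid_names(sp$name)
  cols <- c("class", "base_c", "base_db", "base_oh", "fa_c", "fa_db",
            "est_c", "est_db")
  expect_equal(as.data.frame(back[cols]), as.data.frame(sp[cols]))
})

test_that("enumeration is the cartesian product in lexicographic order", {
  cfg <- enumeration_config(classes = "Cer[NS]", fa_c = c(16, 18),
                            fa_db = 0, base_c = 18, base_db = 1)
  sp <- enumerate_class("Cer[NS]", cfg)
  expect_equal(nrow(sp), 2)

  cfg2 <- enumeration_config(classes = "Cer[NS]", fa_c = 16:18, fa_db = 0:2,
                             base_c = 18:19, base_db = 0:1)
  sp2 <- enumerate_class("Cer[NS]", cfg2)
  # brute-force oracle: nested loops
  oracle <- list()
  for (fc in 16:18) for (fd in 0:2) for (bc in 18:19) for (bd in 0:1) {
    oracle[[length(oracle) + 1]] <- c(fc, fd, bc, bd)
  }
  expect_equal(nrow(sp2), length(oracle))
  got <- unname(as.matrix(sp2[, c("fa_c", "fa_db", "base_c", "base_db")]))
  expect_equal(got, do.call(rbind, oracle))
  expect_false(any(duplicated(sp2$name)))
})

test_that("the published default ranges give the raw combination count", {
  cfg <- enumeration_config(classes = "Cer[NS]")
  sp <- enumerate_class("Cer[NS]", cfg)
  expect_equal(nrow(sp), 25 * 4 * 17 * 8)  # 13,600 before class filters
  expect_false(any(duplicated(sp$name)))
})

test_that("configuration validation happens at load time", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- class: \"Cer[NS]\"",
    "  fa_c: {min: 18, max: 16}",
    "  base_c: {min: 18, max: 18}"), path)
  expect_error(load_enumeration_config(path), "min 18 > max 16")

  ok <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- class: \"Cer[NS]\"",
    "  fa_c: {min: 16, max: 18}",
    "  base_c: {min: 18, max: 18}",
    "  base_db: [1]",
    "  parity: even"), ok)
  cfg <- load_enumeration_config(ok)
  expect_equal(nrow(enumerate_class("Cer[NS]", cfg)), 2 * 4)
})

test_that("empty ranges enumerate nothing rather than failing", {
  cfg <- enumeration_config(classes = "Cer[NS]", fa_c = integer(0),
                            base_c = 18)
  expect_equal(nrow(enumerate_class("Cer[NS]", cfg)), 0)
})

test_that("manifest arithmetic matches the published per-class counts", {
  man <- reference_manifest()
  expect_equal(nrow(man), 21)
  expect_equal(man$spectra[man$class == "Cer[NS]"], 3360L * 3L)   # 10,080
  expect_equal(man$spectra[man$class == "SM"], 3384L * 2L)        # 6,768
  expect_equal(man$spectra[man$class == "Cer[EOS]"], 25536L * 3L) # 76,608
  expect_equal(sum(man$structures), 109448L)
  expect_equal(man$spectra, man$structures * man$adducts)
})

test_that("build_manifest counts structures times adducts for every class", {
  lib <- small_library()
  man <- build_manifest(lib)
  expect_equal(man$spectra, man$structures * man$adducts)
  expect_equal(sum(man$spectra), nrow(lib))
})
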