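test_that("MSP round-trips every emitted field", {
  lib <- small_library()[1:12, ]
  desc <- tibble::tibble(name = lib$name, XLogP = 20, SssCH2 = 0, C2SP3 = 0,
                         BIC0 = 0, ATSC2m = 0, ATSC2v = 0,
                         LipoaffinityIndex = 3, SpMAD_Dzi = 0)
  lib <- attach_predicted_rt(lib, dplyr::distinct(desc))
  lib$smiles <- assemble_smiles(parse_lipid_names(lib$name))
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  back <- read_msp(path)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(back$name, lib$name)
  expect_equal(back$class, lib$class)
  expect_equal(back$adduct, lib$adduct)
  expect_equal(back$polarity, lib$polarity)
  expect_equal(back$formula, lib$formula)
  expect_equal(back$smiles, lib$smiles)
  expect_equal(back$precursor_mz, lib$precursor_mz, tolerance = 1e-4)
  expect_equal(back$rt_pred, lib$rt_pred, tolerance = 0.005 + 1e-9)
  for (i in seq_len(nrow(lib))) {
    expect_equal(back$peaks[[i]]$mz, lib$peaks[[i]]$mz, tolerance = 1e-4)
    expect_equal(back$peaks[[i]]$intensity, round(lib$peaks[[i]]$intensity))
    expect_equal(back$peaks[[i]]$label, lib$peaks[[i]]$label)
  }
  # identical inputs give byte-identical files (no timestamps in body)
  path2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("RETENTIONTIME is emitted as 2-decimal minutes when present", {
  lib <- small_library()[1, ]
  lib$rt_pred <- 12.3456
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  expect_true(any(grepl("^RETENTIONTIME: 12.35$", readLines(path))))
})

test_that("CRLF line endings parse identically", {
  lib <- small_library()[1:3, ]
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  crlf <- withr::local_tempfile(fileext = ".msp")
  writeLines(paste0(readLines(path), "\r"), crlf, sep = "\n")
  expect_equal(read_msp(crlf), read_msp(path))
})

test_that("peak-count mismatches and truncation are parse errors", {
  lib <- small_library()[1:2, ]
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  lines <- readLines(path)
  np <- grep("^Num Peaks:", lines)[1]
  lines[np] <- "Num Peaks: 99"
  bad <- withr::local_tempfile(fileext = ".msp")
  writeLines(lines, bad)
  expect_error(read_msp(bad), "record 1.*Num Peaks")

  truncated <- withr::local_tempfile(fileext = ".msp")
  writeLines(utils::head(readLines(path), -2), truncated)
  expect_error(read_msp(truncated), "record 2")
})

test_that("an empty record set writes an empty file", {
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(small_library()[0, ], path)
  expect_equal(length(readLines(path)), 0)
  expect_equal(nrow(read_msp(path)), 0)
})

test_that("unknown MSP headers are preserved in the comment map", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "NAME: test",
    "PRECURSORMZ: 500.0000",
    "PRECURSORTYPE: [M-H]-",
    "IONMODE: negative",
    "FORMULA: C10H20O2",
    "INSTRUMENT: QTOF",
    "Num Peaks: 1",
    "100.0000 999"), path)
  rec <- read_msp(path)
  expect_match(rec$comment, "instrument=QTOF")
})

test_that("template TSV carries the diagnostic fragments per row", {
  rec <- generate_spectrum("Cer[NS] d18:1/26:0", "[M+CH3COO]-")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_template_tsv(rec, path)
  tbl <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(tbl), 1)
  expect_equal(length(strsplit(tbl$fragments, ";")[[1]]), 10)  # 10 ions
  expect_true(is.na(tbl$rt))  # empty RT cell without prediction
})

test_that("manifest TSV totals equal the per-class sums", {
  man <- reference_manifest()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest_tsv(man, path)
  tbl <- utils::read.delim(path)
  tot <- tbl[tbl$class == "total", ]
  expect_equal(tot$structures, sum(man$structures))
  expect_equal(tot$spectra, sum(man$spectra))
})

test_that("MGF queries parse with RT in minutes and polarity from charge", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=q1",
    "PEPMASS=712.6345",
    "RTINSECONDS=738",
    "CHARGE=1-",
    "536.5047 999",
    "271.2279 400",
    "END IONS",
    "",
    "BEGIN IONS",
    "TITLE=q2",
    "PEPMASS=500.1",
    "CHARGE=1+",
    "100.1 10",
    "END IONS"), path)
  q <- read_mgf(path)
  expect_equal(nrow(q), 2)
  expect_equal(q$query_id, c("q1", "q2"))
  expect_equal(q$rt[1], 12.3)
  expect_equal(q$polarity, c("negative", "positive"))
  expect_equal(nrow(q$peaks[[1]]), 2)
})
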