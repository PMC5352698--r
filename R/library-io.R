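# Readers/writers: NIST-dialect MSP spectra, MGF query peak lists,
# LipidBlast-style TSV templates and manifests. All numeric formatting is
# locale-independent: m/z with 4 decimals, intensities as integers 0-999,
# retention times with 2 decimals.

fmt_mz <- function(x) sprintf("%.4f", x)

#' Write a spectral library as MSP
#'
#' NIST text dialect: one header block per record, `Num Peaks:` followed by
#' one `mz intensity "annotation"` line per peak, one blank line between
#' records, stable field order, no timestamps. An empty record tibble
#' yields an empty file.
#'
#' @param records A record tibble (from [build_library()], optionally with
#'   `rt_pred` and `smiles` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  has <- function(r, col) col %in% names(r) && !is.na(r[[col]])
  blocks <- purrr::map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    lines <- c(
      paste0("NAME: ", r$name),
      paste0("PRECURSORMZ: ", fmt_mz(r$precursor_mz)),
      paste0("PRECURSORTYPE: ", r$adduct),
      paste0("IONMODE: ", r$polarity))
    if (has(r, "rt_pred")) {
      lines <- c(lines, paste0("RETENTIONTIME: ", sprintf("%.2f", r$rt_pred)))
    }
    lines <- c(lines, paste0("FORMULA: ", r$formula))
    if (has(r, "smiles")) {
      lines <- c(lines, paste0("SMILES: ", r$smiles))
    }
    comment <- if (has(r, "comment")) r$comment
               else paste0("class=", r$class)
    lines <- c(lines, paste0("COMMENT: ", comment))
    pk <- r$peaks[[1]]
    ann <- if ("label" %in% names(pk)) pk$label else rep("", nrow(pk))
    peak_lines <- paste0(fmt_mz(pk$mz), " ", round(pk$intensity),
                         ifelse(nzchar(ann), paste0(" \"", ann, "\""), ""))
    paste(c(lines, paste0("Num Peaks: ", nrow(pk)), peak_lines),
          collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses the dialect written by [write_msp()]; tolerates CRLF endings,
#' case-insensitive header keys and `NumPeaks`/`Num Peaks` variants.
#' Headers the reader does not model are preserved in the `comment` field
#' as `key=value` pairs. A record whose peak count disagrees with its
#' `Num Peaks` header is a parse error naming the record.
#'
#' @param path Input file path.
#' @return A record tibble: `name`, `class`, `adduct`, `polarity`,
#'   `precursor_mz`, `formula`, `rt_pred`, `smiles`, `comment`, `n_peaks`,
#'   `peaks` (list of tibbles `mz`, `intensity`, `label`).
#' @export
read_msp <- function(path) {
  raw <- gsub("\r$", "", readLines(path, warn = FALSE))
  blocks <- split(raw, cumsum(!nzchar(raw)))
  blocks <- purrr::map(blocks, ~.x[nzchar(.x)])
  blocks <- unname(blocks[purrr::map_int(blocks, length) > 0])
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    out[[bi]] <- parse_msp_block(blocks[[bi]], bi)
  }
  if (length(out) == 0) return(empty_msp_records())
  dplyr::bind_rows(out)
}

empty_msp_records <- function() {
  tibble::tibble(name = character(0), class = character(0),
                 adduct = character(0), polarity = character(0),
                 precursor_mz = numeric(0), formula = character(0),
                 rt_pred = numeric(0), smiles = character(0),
                 comment = character(0), n_peaks = integer(0), peaks = list())
}

parse_msp_block <- function(lines, bi) {
  {
    # peaks start after the Num Peaks header
    np_idx <- grep("^num ?peaks:", tolower(lines))
    if (length(np_idx) != 1) {
      stop("MSP record ", bi, ": missing Num Peaks header", call. = FALSE)
    }
    headers <- lines[seq_len(np_idx)]
    peak_lines <- if (np_idx < length(lines)) lines[(np_idx + 1):length(lines)]
                  else character(0)
    keys <- tolower(gsub(" ", "", sub(":.*$", "", headers)))
    vals <- trimws(sub("^[^:]*:", "", headers))
    h <- stats::setNames(vals, keys)
    hget <- function(k) if (k %in% names(h)) unname(h[[k]]) else NA_character_
    n_declared <- as.integer(hget("numpeaks"))
    if (length(peak_lines) != n_declared) {
      stop("MSP record ", bi, " ('", h["name"], "'): Num Peaks says ",
           n_declared, " but ", length(peak_lines), " peak line(s) found",
           call. = FALSE)
    }
    pk <- parse_peak_lines(peak_lines, bi)
    known <- c("name", "precursormz", "precursortype", "ionmode",
               "retentiontime", "formula", "smiles", "comment", "numpeaks")
    extra <- h[!names(h) %in% known]
    comment <- hget("comment")
    if (length(extra) > 0) {
      extra_str <- paste(names(extra), unname(extra), sep = "=",
                         collapse = "; ")
      comment <- if (is.na(comment)) extra_str
                 else paste(comment, extra_str, sep = "; ")
    }
    cls <- if (!is.na(comment) && grepl("class=", comment)) {
      sub(".*class=([^;]+).*", "\\1", comment)
    } else NA_character_
    tibble::tibble(
      name = hget("name"),
      class = cls,
      adduct = hget("precursortype"),
      polarity = tolower(hget("ionmode")),
      precursor_mz = suppressWarnings(as.numeric(hget("precursormz"))),
      formula = hget("formula"),
      rt_pred = suppressWarnings(as.numeric(hget("retentiontime"))),
      smiles = hget("smiles"),
      comment = comment,
      n_peaks = nrow(pk),
      peaks = list(pk))
  }
}

parse_peak_lines <- function(lines, record_index) {
  if (length(lines) == 0) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0),
                          label = character(0)))
  }
  m <- regmatches(lines,
                  regexec("^\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s*(\"(.*)\")?\\s*$",
                          lines, perl = TRUE))
  bad <- purrr::map_int(m, length) == 0
  if (any(bad)) {
    stop("MSP record ", record_index, ": unparseable peak line '",
         lines[which(bad)[1]], "'", call. = FALSE)
  }
  tibble::tibble(
    mz = purrr::map_dbl(m, ~as.numeric(.x[2])),
    intensity = purrr::map_dbl(m, ~as.numeric(.x[3])),
    label = purrr::map_chr(m, ~if (nzchar(.x[4])) .x[5] else NA_character_))
}

#' Read MGF query peak lists
#'
#' Mascot generic format, read-only: `BEGIN IONS`/`END IONS` blocks with
#' `TITLE`, `PEPMASS`, optional `RTINSECONDS` and `CHARGE`.
#'
#' @param path Input file path.
#' @return A query tibble: `query_id`, `precursor_mz`, `rt` (minutes, NA if
#'   absent), `polarity`, `peaks`.
#' @export
read_mgf <- function(path) {
  raw <- gsub("\r$", "", readLines(path, warn = FALSE))
  starts <- grep("^BEGIN IONS$", raw)
  ends <- grep("^END IONS$", raw)
  if (length(starts) != length(ends)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  }
  purrr::map2_dfr(starts, ends, function(s, e) {
    lines <- raw[(s + 1):(e - 1)]
    kv <- grepl("=", lines, fixed = TRUE)
    h <- stats::setNames(sub("^[^=]*=", "", lines[kv]),
                         toupper(sub("=.*$", "", lines[kv])))
    pk_lines <- lines[!kv & nzchar(trimws(lines))]
    parts <- strsplit(trimws(pk_lines), "\\s+", perl = TRUE)
    pk <- tibble::tibble(
      mz = purrr::map_dbl(parts, ~as.numeric(.x[1])),
      intensity = purrr::map_dbl(parts, ~as.numeric(.x[2])))
    charge <- h["CHARGE"]
    polarity <- if (!is.na(charge) && grepl("-", charge)) "negative"
                else "positive"
    rt_s <- suppressWarnings(as.numeric(h["RTINSECONDS"]))
    tibble::tibble(
      query_id = unname(h["TITLE"] %|na|% paste0("query_", s)),
      precursor_mz = as.numeric(strsplit(unname(h["PEPMASS"]), " ")[[1]][1]),
      rt = if (is.na(rt_s)) NA_real_ else rt_s / 60,
      polarity = polarity,
      peaks = list(pk))
  })
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Write a LipidBlast-style template TSV
#'
#' One row per record: name, class, adduct, precursor m/z, formula, SMILES,
#' predicted RT (2 decimals; empty when absent) and the fragment list as
#' semicolon-joined `mz:intensity:label` triplets.
#'
#' @param records A record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template_tsv <- function(records, path) {
  rows <- purrr::map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    pk <- r$peaks[[1]]
    frags <- paste(fmt_mz(pk$mz), round(pk$intensity),
                   if ("label" %in% names(pk)) pk$label else "",
                   sep = ":", collapse = ";")
    rt <- if ("rt_pred" %in% names(r) && !is.na(r$rt_pred))
      sprintf("%.2f", r$rt_pred) else ""
    smiles <- if ("smiles" %in% names(r) && !is.na(r$smiles)) r$smiles else ""
    paste(r$name, r$class, r$adduct, fmt_mz(r$precursor_mz), r$formula,
          smiles, rt, frags, sep = "\t")
  })
  writeLines(c(paste("name", "class", "adduct", "precursor_mz", "formula",
                     "smiles", "rt", "fragments", sep = "\t"), rows), path)
  invisible(path)
}

#' Write a per-class manifest TSV with a totals row
#'
#' @param manifest A manifest tibble ([build_manifest()] or
#'   [reference_manifest()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_tsv <- function(manifest, path) {
  lines <- c(
    paste("class", "structures", "adducts", "spectra", sep = "\t"),
    purrr::pmap_chr(manifest[c("class", "structures", "adducts", "spectra")],
                    function(class, structures, adducts, spectra) {
                      paste(class, structures, adducts, spectra, sep = "\t")
                    }),
    paste("total", sum(manifest$structures), "",
          sum(manifest$spectra), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert MSP records to query features
#'
#' @param records A record tibble from [read_msp()] or [build_library()].
#' @return A query tibble for [identify_features()].
#' @export
as_query_features <- function(records) {
  tibble::tibble(
    query_id = records$name,
    precursor_mz = records$precursor_mz,
    rt = if ("rt_pred" %in% names(records)) records$rt_pred
         else NA_real_,
    polarity = records$polarity,
    peaks = purrr::map(records$peaks,
                       ~tibble::as_tibble(.x)[, c("mz", "intensity")]))
}
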