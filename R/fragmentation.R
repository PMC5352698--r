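# Hydrogen-rearrangement rule engine and template-driven spectrum generation.

#' Hydrogen-rearrangement rules for low-energy CID
#'
#' The nine allowed hydrogen gains/losses accompanying bond cleavage:
#' P1-P4 in positive mode, N1-N5 in negative mode. `precursor_form` records
#' whether the rule is formulated from the neutralized (`"neutral"`) or the
#' already ionized (`"ionized"`) precursor; the hydrogen delta is applied to
#' the neutralized fragment formula either way.
#'
#' @return A tibble with `id`, `polarity`, `precursor_form`,
#'   `hydrogen_delta`, `equation`.
#' @export
hr_rules <- function() {
  tibble::tribble(
    ~id,  ~polarity,  ~precursor_form, ~hydrogen_delta, ~equation,
    "P1", "positive", "neutral",  -1L, "M -> [M' - H]+",
    "P2", "positive", "neutral",  +1L, "M -> [M' + H]+",
    "P3", "positive", "ionized",   0L, "M+ -> M'+",
    "P4", "positive", "ionized",  -2L, "M+ -> [M' - 2H]+",
    "N1", "negative", "neutral",  -1L, "M -> [M' - H]-",
    "N2", "negative", "neutral",  -3L, "M -> [M' - 3H]-",
    "N3", "negative", "neutral",  -2L, "M -> [M' - 2H]-",
    "N4", "negative", "ionized",   0L, "M- -> M'-",
    "N5", "negative", "ionized",  -2L, "M- -> [M' - 2H]-"
  )
}

rule_delta <- function(ids) {
  tbl <- hr_rules()
  idx <- match(ids, tbl$id)
  if (anyNA(idx)) {
    stop("unknown HR rule id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  list(delta = sum(tbl$hydrogen_delta[idx]),
       polarity = unique(tbl$polarity[idx]))
}

#' Apply a hydrogen-rearrangement rule to a neutral fragment
#'
#' @param fragment_neutral Neutral fragment formula (string or
#'   `chem_formula`).
#' @param rule A rule id (`"N1"`, ...) or vector of ids for two-cleavage
#'   combinations (deltas are summed).
#' @param include_electron Include the electron mass?
#' @return The fragment ion m/z.
#' @examples
#' apply_hr_rule("C16H32O3", "N1") # 271.2279
#' @export
apply_hr_rule <- function(fragment_neutral, rule, include_electron = TRUE) {
  rd <- rule_delta(rule)
  if (length(rd$polarity) != 1) {
    stop("cannot combine rules of opposite polarity", call. = FALSE)
  }
  charge <- if (rd$polarity == "positive") 1L else -1L
  ion_mz(fragment_neutral, rd$delta, charge, include_electron)
}

# ---- template registry -----------------------------------------------------

parse_fragment_expr <- function(expr) {
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) %% 2 != 1) {
    stop("malformed fragment expression '", expr, "'", call. = FALSE)
  }
  ops <- c("+", toks[seq_along(toks) %% 2 == 0])
  terms <- toks[seq_along(toks) %% 2 == 1]
  if (!all(ops %in% c("+", "-"))) {
    stop("malformed fragment expression '", expr, "'", call. = FALSE)
  }
  purrr::map2(ops, terms, function(op, term) {
    lit <- if (term %in% c("M", "fa", "base", "ester")) term
           else chem_formula(term)
    list(op = op, term = lit)
  })
}

eval_fragment_expr <- function(parsed, symbols) {
  out <- chem_formula()
  for (p in parsed) {
    f <- if (is.character(p$term)) {
      s <- symbols[[p$term]]
      if (is.null(s)) {
        stop("fragment expression refers to '", p$term,
             "' which is undefined for this species", call. = FALSE)
      }
      s
    } else {
      p$term
    }
    out <- if (p$op == "+") out + f else out - f
  }
  out
}

#' Load fragment templates
#'
#' Reads per-class diagnostic-ion templates from YAML (see the packaged
#' `fragment-templates.yaml` for the schema) and pre-parses the fragment
#' expressions.
#'
#' @param path YAML path; defaults to the templates shipped with the
#'   package.
#' @return A template list usable by [generate_spectrum()].
#' @export
fragment_templates <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sphingo_env$templates)) return(.sphingo_env$templates)
    path <- system.file("extdata", "fragment-templates.yaml",
                        package = "sphingolibr", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  defs <- yaml::read_yaml(path)
  tpl <- purrr::map(defs, function(d) {
    d$entries <- purrr::map(d$entries, function(e) {
      stopifnot(e$intensity >= 0, e$intensity <= 999)
      e$parsed <- parse_fragment_expr(e$fragment)
      rd <- rule_delta(unlist(e$rules))
      if (!identical(rd$polarity, d$polarity)) {
        stop("entry '", e$label, "' uses rules of the wrong polarity",
             call. = FALSE)
      }
      e$hydrogen_delta <- rd$delta
      e
    })
    if (!any(purrr::map_dbl(d$entries, "intensity") == 999)) {
      stop("template '", d$name, "' lacks a base-peak (999) entry",
           call. = FALSE)
    }
    d
  })
  if (cache) .sphingo_env$templates <- tpl
  tpl
}

find_template <- function(class_code, adduct, templates) {
  pol <- get_adduct(adduct)$polarity
  hit <- purrr::detect(templates, function(t) {
    class_code %in% t$classes && adduct %in% t$adducts && t$polarity == pol
  })
  if (is.null(hit)) {
    stop("no fragment template registered for class ", class_code,
         " with adduct ", adduct, call. = FALSE)
  }
  hit
}

species_symbols <- function(row) {
  syms <- list(
    M = species_formula_one(row),
    fa = fa_formula(row$fa_c, row$fa_db, row$fa_type),
    base = base_formula(row$base_c, row$base_db, row$base_oh))
  if (!is.na(row$est_c)) {
    syms$ester <- fa_formula(row$est_c, row$est_db, "N")
  }
  syms
}

#' Generate an annotated in silico MS/MS spectrum
#'
#' Applies the registered fragment template for (class, adduct) to one
#' species: each template entry yields one product ion; peaks closer than
#' 0.001 Th are merged keeping the larger intensity; peaks are sorted by
#' m/z. Intensities follow the template's 0-999 rank convention.
#'
#' @param species A one-row species tibble (or a shorthand name string).
#' @param adduct Adduct name, e.g. `"[M+CH3COO]-"`.
#' @param templates Templates from [fragment_templates()].
#' @param include_electron Include the electron mass in all m/z?
#' @return A one-row record tibble with columns `name`, `class`, `adduct`,
#'   `polarity`, `precursor_mz`, `formula`, `exact_mass`, `n_peaks` and a
#'   `peaks` list column (tibble: `mz`, `intensity`, `label`, `rule`,
#'   `formula`, `hydrogen_delta`, `origin`).
#' @examples
#' generate_spectrum("Cer[AS] d18:1/16:0", "[M+CH3COO]-")
#' @export
generate_spectrum <- function(species, adduct,
                              templates = fragment_templates(),
                              include_electron = TRUE) {
  if (is.character(species)) species <- parse_lipid_names(species)
  stopifnot(nrow(species) == 1)
  row <- species[1, ]
  name <- if ("name" %in% names(row)) row$name else format_lipid_names(row)
  tpl <- find_template(row$class, adduct, templates)
  syms <- species_symbols(row)
  charge <- if (tpl$polarity == "positive") 1L else -1L
  peaks <- purrr::map_dfr(tpl$entries, function(e) {
    f <- tryCatch(eval_fragment_expr(e$parsed, syms),
                  error = function(err) {
                    stop("template entry '", e$label, "' failed for ",
                         name, ": ", conditionMessage(err),
                         call. = FALSE)
                  })
    tibble::tibble(
      mz = ion_mz(f, e$hydrogen_delta, charge, include_electron),
      intensity = as.numeric(e$intensity),
      label = e$label,
      rule = paste(unlist(e$rules), collapse = "+"),
      formula = format(f),
      hydrogen_delta = as.integer(e$hydrogen_delta),
      origin = e$origin)
  })
  peaks <- merge_peaks(peaks, tol = 0.001)
  precursor <- adduct_mz(syms$M, adduct, include_electron)
  if (any(peaks$mz > precursor + 0.5)) {
    stop("product ion above precursor m/z for ", name, call. = FALSE)
  }
  rec <- tibble::tibble(
    name = name, class = row$class, adduct = adduct,
    polarity = tpl$polarity, precursor_mz = precursor,
    formula = format(syms$M), exact_mass = formula_mass(syms$M),
    n_peaks = nrow(peaks), peaks = list(peaks))
  class(rec) <- c("spectrum_record", class(rec))
  rec
}

merge_peaks <- function(peaks, tol = 0.001) {
  peaks <- dplyr::arrange(peaks, .data$mz, dplyr::desc(.data$intensity))
  if (nrow(peaks) < 2) return(peaks)
  grp <- cumsum(c(TRUE, diff(peaks$mz) >= tol))
  peaks |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::slice_max(.data$intensity, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$mz)
}

#' Build a spectral library for a configuration
#'
#' One record per enumerated species per configured adduct.
#'
#' @param config Enumeration configuration ([enumeration_config()]).
#' @param templates Templates from [fragment_templates()].
#' @param species Optional pre-enumerated species tibble (bypasses
#'   enumeration; the per-class adduct lists of `config` still apply).
#' @return A record tibble (rows as in [generate_spectrum()]).
#' @export
build_library <- function(config = enumeration_config(),
                          templates = fragment_templates(),
                          species = NULL) {
  if (is.null(species)) species <- enumerate_species(config)
  if (nrow(species) == 0) return(generate_spectrum_empty())
  purrr::map_dfr(seq_len(nrow(species)), function(i) {
    row <- species[i, ]
    adducts <- config[[row$class]]$adducts %||% class_info(row$class)$adducts[[1]]
    purrr::map_dfr(adducts, function(a) {
      tryCatch(generate_spectrum(row, a, templates),
               error = function(err) {
                 stop("while building ", row$name, " ", a, ": ",
                      conditionMessage(err), call. = FALSE)
               })
    })
  })
}

generate_spectrum_empty <- function() {
  tibble::tibble(name = character(0), class = character(0),
                 adduct = character(0), polarity = character(0),
                 precursor_mz = numeric(0), formula = character(0),
                 exact_mass = numeric(0), n_peaks = integer(0),
                 peaks = list())
}

#' Annotate observed peaks against a species template
#'
#' Each observed peak is matched to the nearest template ion within the
#' tolerance (ties go to the lower template m/z) or left unassigned.
#' Template ions involve at most two cleavages, mirroring a fragmentation
#' tree depth of two.
#'
#' @param peaks A tibble/data frame with at least an `mz` column.
#' @param species One-row species tibble or shorthand name.
#' @param adduct Adduct name.
#' @param tolerance_mda Match tolerance in mDa (default 10).
#' @param templates Templates from [fragment_templates()].
#' @return `peaks` with columns `matched`, `theo_mz`, `delta_mda`, `label`,
#'   `rule` added.
#' @export
annotate_peaks <- function(peaks, species, adduct, tolerance_mda = 10,
                           templates = fragment_templates()) {
  stopifnot(tolerance_mda > 0)
  rec <- generate_spectrum(species, adduct, templates)
  theo <- rec$peaks[[1]]
  peaks <- tibble::as_tibble(peaks)
  ann <- purrr::map_dfr(peaks$mz, function(mz) {
    d <- abs(theo$mz - mz)
    ok <- which(d * 1000 <= tolerance_mda)
    if (length(ok) == 0) {
      return(tibble::tibble(matched = FALSE, theo_mz = NA_real_,
                            delta_mda = NA_real_, label = NA_character_,
                            rule = NA_character_))
    }
    best <- ok[order(d[ok], theo$mz[ok])][1]  # tie -> lower theoretical m/z
    tibble::tibble(matched = TRUE, theo_mz = theo$mz[best],
                   delta_mda = (mz - theo$mz[best]) * 1000,
                   label = theo$label[best], rule = theo$rule[best])
  })
  dplyr::bind_cols(peaks, ann)
}
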