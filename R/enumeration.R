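# Sphingolipid building-block grammar: class registry, shorthand parsing,
# combinatorial enumeration.
#
# A species is one row of a tibble with the composition columns
# (class, head, fa_type, base_kind, base_c, base_db, base_oh, fa_c, fa_db,
# est_c, est_db); all user-facing functions take and return such tibbles.

HEXOSE <- "C6H12O6"          # one hexose unit (glucose/galactose)
PHOSPHOCHOLINE <- "C5H14NO4P"
WATER <- "H2O"

#' Registry of supported sphingolipid classes
#'
#' The 21 classes supported by the library generator: ceramides and
#' monohexosylceramides for fatty-acid hydroxylation types N (non-hydroxy),
#' A (alpha-hydroxy), B (beta-hydroxy) and EO (esterified omega-hydroxy)
#' crossed with sphingoid bases S (sphingosine), DS (dihydrosphingosine) and
#' P (phytosphingosine) where biologically described, plus sphingomyelin.
#'
#' @return A tibble with columns `class`, `head`, `fa_type`, `base_kind`,
#'   `adducts` (list column of default adduct names).
#' @export
lipid_classes <- function() {
  cer3 <- list(c("[M+H]+", "[M+HCOO]-", "[M+CH3COO]-"))
  combos <- tibble::tribble(
    ~fa_type, ~base_kind,
    "N", "S", "N", "DS", "N", "P",
    "A", "S", "A", "DS", "A", "P",
    "B", "S", "B", "DS",
    "EO", "S", "EO", "DS"
  )
  cer <- dplyr::mutate(combos, head = "Cer")
  hex <- dplyr::mutate(combos, head = "HexCer")
  out <- dplyr::bind_rows(cer, hex)
  out$class <- paste0(out$head, "[", out$fa_type, out$base_kind, "]")
  out$adducts <- rep(cer3, nrow(out))
  sm <- tibble::tibble(fa_type = "N", base_kind = "S", head = "SM",
                       class = "SM",
                       adducts = list(c("[M+HCOO]-", "[M+CH3COO]-")))
  dplyr::bind_rows(out, sm)[, c("class", "head", "fa_type", "base_kind", "adducts")]
}

class_info <- function(class_code) {
  cls <- lipid_classes()
  hit <- cls[cls$class == class_code, ]
  if (nrow(hit) != 1) {
    stop("unknown lipid class '", class_code, "'", call. = FALSE)
  }
  hit
}

base_hydroxyls <- function(base_kind) ifelse(base_kind == "P", 3L, 2L)

# Sphingoid base C_c H_(2c+3-2db) N O_oh (amino-diol/-triol backbone).
base_formula <- function(c, db, oh) {
  chem_formula(c(C = c, H = 2 * c + 3 - 2 * db, N = 1, O = oh))
}

# Fatty acid C_c H_(2c-2db) O_2, +O for alpha/beta/omega hydroxylation.
fa_formula <- function(c, db, fa_type) {
  o <- if (fa_type == "N") 2 else 3
  chem_formula(c(C = c, H = 2 * c - 2 * db, O = o))
}

#' Parse sphingolipid shorthand names
#'
#' Accepts names such as `"Cer[AS] d18:1/16:0"`, `"Cer[AP](t18:0/24:0)"`,
#' `"SM d18:1/16:0"` and the three-chain EO convention
#' `"Cer[EOS] d18:1/30:0/18:2"` (base / omega-hydroxy FA / esterified FA).
#' The `d`/`t` prefix (di-/tri-hydroxy base) must agree with the class code.
#'
#' @param text Character vector of shorthand names.
#' @return A species tibble (one row per name) with composition columns,
#'   `formula` and `exact_mass`.
#' @examples
#' parse_lipid_names("Cer[NS] d18:1/26:0")
#' @export
parse_lipid_names <- function(text) {
  rx <- paste0(
    "^\\s*(Cer|HexCer|SM)\\s*",
    "(?:\\[\\s*(N|A|B|EO)\\s*(S|DS|P)\\s*\\])?\\s*",
    "\\(?\\s*([dt])(\\d+):(\\d+)",
    "\\s*/\\s*(\\d+):(\\d+)",
    "(?:\\s*/\\s*(\\d+):(\\d+))?\\s*\\)?\\s*$")
  m <- regmatches(text, regexec(rx, text))
  rows <- purrr::map2(text, m, function(txt, g) {
    if (length(g) == 0) {
      stop("cannot parse lipid name '", txt,
           "': expected CLASS[TYPE] dNN:M/KK:J", call. = FALSE)
    }
    head <- g[2]
    fa_type <- g[3]; base_kind <- g[4]
    if (head == "SM") {
      if (nzchar(fa_type) || nzchar(base_kind)) {
        stop("parse error in '", txt, "' near '[", fa_type, base_kind,
             "]': SM takes no class-type bracket", call. = FALSE)
      }
      fa_type <- "N"; base_kind <- "S"
      class_code <- "SM"
    } else {
      if (!nzchar(fa_type)) {
        stop("parse error in '", txt, "' after '", head,
             "': missing [TYPE] bracket", call. = FALSE)
      }
      class_code <- paste0(head, "[", fa_type, base_kind, "]")
    }
    info <- class_info(class_code)  # rejects e.g. Cer[BP]
    prefix <- g[5]
    oh <- if (prefix == "t") 3L else 2L
    if (oh != base_hydroxyls(base_kind)) {
      stop("parse error in '", txt, "': prefix '", prefix,
           "' inconsistent with base kind ", base_kind, call. = FALSE)
    }
    has_ester <- nzchar(g[10])
    if (has_ester != (fa_type == "EO")) {
      stop("parse error in '", txt, "': a third (esterified) chain is ",
           if (fa_type == "EO") "required" else "not allowed",
           " for class ", class_code, call. = FALSE)
    }
    tibble::tibble(
      class = class_code, head = head, fa_type = fa_type,
      base_kind = base_kind,
      base_c = as.integer(g[6]), base_db = as.integer(g[7]), base_oh = oh,
      fa_c = as.integer(g[8]), fa_db = as.integer(g[9]),
      est_c = if (has_ester) as.integer(g[10]) else NA_integer_,
      est_db = if (has_ester) as.integer(g[11]) else NA_integer_)
  })
  species_formula(dplyr::bind_rows(rows))
}

#' Format species rows as shorthand names
#'
#' Inverse of [parse_lipid_names()]: `parse_lipid_names(format_lipid_names(x))`
#' reproduces `x`'s composition columns.
#'
#' @param species A species tibble.
#' @return Character vector of shorthand names.
#' @export
format_lipid_names <- function(species) {
  prefix <- ifelse(species$base_oh == 3, "t", "d")
  chains <- paste0(prefix, species$base_c, ":", species$base_db, "/",
                   species$fa_c, ":", species$fa_db)
  est <- !is.na(species$est_c)
  chains[est] <- paste0(chains[est], "/", species$est_c[est], ":",
                        species$est_db[est])
  paste0(species$class, " ", chains)
}

species_formula_one <- function(row) {
  stopifnot(row$fa_c >= 2)
  f <- base_formula(row$base_c, row$base_db, row$base_oh) +
    fa_formula(row$fa_c, row$fa_db, row$fa_type) - chem_formula(WATER)
  if (row$fa_type == "EO") {
    f <- f + fa_formula(row$est_c, row$est_db, "N") - chem_formula(WATER)
  }
  if (row$head == "HexCer") f <- f + chem_formula(HEXOSE) - chem_formula(WATER)
  if (row$head == "SM") f <- f + chem_formula(PHOSPHOCHOLINE) - chem_formula(WATER)
  f
}

#' Molecular formula and exact mass of species
#'
#' Condenses the building blocks: sphingoid base + fatty acid (+ esterified
#' chain for EO classes, + hexose for HexCer, + phosphocholine for SM), with
#' one water removed per bond formed.
#'
#' @param species A species tibble (see [parse_lipid_names()]).
#' @return The input with `name`, `formula` (Hill string) and `exact_mass`
#'   (Da) columns set.
#' @export
species_formula <- function(species) {
  if (nrow(species) == 0) {
    return(dplyr::mutate(species, name = character(0), formula = character(0),
                         exact_mass = numeric(0)))
  }
  fs <- purrr::map(seq_len(nrow(species)),
                   function(i) species_formula_one(species[i, ]))
  species$name <- format_lipid_names(species)
  species$formula <- purrr::map_chr(fs, format)
  species$exact_mass <- purrr::map_dbl(fs, formula_mass)
  dplyr::relocate(species, "name")
}

# ---- enumeration configuration --------------------------------------------

check_range <- function(x, what) {
  # an empty allowed-value vector is legal (it enumerates nothing);
  # a min/max range with min > max is a configuration error
  if (length(x) == 0) return(integer(0))
  if (is.list(x)) {
    if (is.null(x$min) || is.null(x$max)) {
      stop("range for ", what, " must have min and max", call. = FALSE)
    }
    if (x$min > x$max) {
      stop("invalid range for ", what, ": min ", x$min, " > max ", x$max,
           call. = FALSE)
    }
    x <- seq(x$min, x$max)
  }
  if (any(x < 0)) stop("negative values in range for ", what, call. = FALSE)
  as.integer(x)
}

#' Enumeration configuration with the published default ranges
#'
#' Default ranges: fatty-acid carbons 12-36, fatty-acid double bonds 0-3,
#' sphingoid carbons 14-30, sphingoid double bonds 0-7, every adduct of the
#' class registry. The esterified chain of EO classes mirrors the fatty-acid
#' range. A parity filter (`"even"`) restricts chain carbons to even counts.
#'
#' @param classes Character vector of class codes (default: all 21).
#' @param fa_c,fa_db,base_c,base_db,est_c,est_db Integer vectors of allowed
#'   values per block.
#' @param parity `"all"` or `"even"` (even-carbon chains only).
#' @param adducts Optional character vector overriding per-class adducts.
#' @return A named list (one entry per class) usable by
#'   [enumerate_class()] and [enumerate_species()].
#' @export
enumeration_config <- function(classes = lipid_classes()$class,
                               fa_c = 12:36, fa_db = 0:3,
                               base_c = 14:30, base_db = 0:7,
                               est_c = fa_c, est_db = fa_db,
                               parity = c("all", "even"),
                               adducts = NULL) {
  parity <- match.arg(parity)
  purrr::map(stats::setNames(classes, classes), function(cl) {
    info <- class_info(cl)
    list(class = cl,
         fa_c = check_range(fa_c, "fa_c"), fa_db = check_range(fa_db, "fa_db"),
         base_c = check_range(base_c, "base_c"),
         base_db = check_range(base_db, "base_db"),
         est_c = check_range(est_c, "est_c"),
         est_db = check_range(est_db, "est_db"),
         parity = parity,
         adducts = adducts %||% info$adducts[[1]])
  })
}

#' Load an enumeration configuration from YAML
#'
#' Per-class entries with `fa_c`/`fa_db`/`base_c`/`base_db` (and optionally
#' `est_c`/`est_db`, `parity`, `adducts`); ranges are `{min, max}` maps or
#' explicit value lists. Validation happens at load time.
#'
#' @param path Path to the YAML file.
#' @return A configuration list as from [enumeration_config()].
#' @export
load_enumeration_config <- function(path) {
  defs <- yaml::read_yaml(path)
  purrr::map(defs, function(d) {
    info <- class_info(d$class)
    list(class = d$class,
         fa_c = check_range(d$fa_c, "fa_c"),
         fa_db = check_range(d$fa_db %||% 0:3, "fa_db"),
         base_c = check_range(d$base_c, "base_c"),
         base_db = check_range(d$base_db %||% 0:7, "base_db"),
         est_c = check_range(d$est_c %||% d$fa_c, "est_c"),
         est_db = check_range(d$est_db %||% (d$fa_db %||% 0:3), "est_db"),
         parity = d$parity %||% "all",
         adducts = unlist(d$adducts) %||% info$adducts[[1]])
  }) |>
    (\(x) stats::setNames(x, purrr::map_chr(x, "class")))()
}

#' Enumerate all species of one class
#'
#' Cartesian product of the configured block ranges, one representative
#' structure per composition, in deterministic lexicographic order
#' (fatty-acid carbons, fatty-acid double bonds, sphingoid carbons, sphingoid
#' double bonds, then esterified-chain carbons/double bonds for EO classes).
#'
#' @param class_code A class code from [lipid_classes()].
#' @param config Configuration from [enumeration_config()].
#' @return A species tibble; empty ranges give an empty tibble.
#' @export
enumerate_class <- function(class_code, config = enumeration_config()) {
  cfg <- config[[class_code]]
  if (is.null(cfg)) {
    stop("class '", class_code, "' is not in the configuration", call. = FALSE)
  }
  info <- class_info(class_code)
  keep_parity <- function(x) if (cfg$parity == "even") x[x %% 2 == 0] else x
  grids <- list(fa_c = keep_parity(cfg$fa_c), fa_db = cfg$fa_db,
                base_c = keep_parity(cfg$base_c), base_db = cfg$base_db)
  if (info$fa_type == "EO") {
    grids$est_c <- keep_parity(cfg$est_c)
    grids$est_db <- cfg$est_db
  }
  grid <- rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)) |>
    tibble::as_tibble()
  if (nrow(grid) == 0) return(species_formula(empty_species()))
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::all_of(names(grids))))
  grid$class <- class_code
  grid$head <- info$head
  grid$fa_type <- info$fa_type
  grid$base_kind <- info$base_kind
  grid$base_oh <- base_hydroxyls(info$base_kind)
  if (info$fa_type != "EO") {
    grid$est_c <- NA_integer_
    grid$est_db <- NA_integer_
  }
  cols <- c("class", "head", "fa_type", "base_kind", "base_c", "base_db",
            "base_oh", "fa_c", "fa_db", "est_c", "est_db")
  species_formula(dplyr::mutate(grid[, cols],
                                dplyr::across(dplyr::where(is.numeric),
                                              as.integer)))
}

empty_species <- function() {
  tibble::tibble(class = character(0), head = character(0),
                 fa_type = character(0), base_kind = character(0),
                 base_c = integer(0), base_db = integer(0),
                 base_oh = integer(0), fa_c = integer(0), fa_db = integer(0),
                 est_c = integer(0), est_db = integer(0))
}

#' Enumerate species for every configured class
#'
#' @param config Configuration from [enumeration_config()].
#' @return A species tibble over all configured classes.
#' @export
enumerate_species <- function(config = enumeration_config()) {
  purrr::map_dfr(names(config), enumerate_class, config = config)
}

#' Per-class structure and spectra counts of a generated library
#'
#' @param library A spectra tibble from [build_library()] (one row per
#'   species x adduct).
#' @return A tibble with `class`, `structures`, `adducts` and
#'   `spectra` (= structures x adducts for every class).
#' @export
build_manifest <- function(library) {
  library |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(structures = dplyr::n_distinct(.data$name),
                     adducts = dplyr::n_distinct(.data$adduct),
                     spectra = dplyr::n(), .groups = "drop")
}

#' Published per-class manifest
#'
#' Per-class structure and spectra counts of the original distributed
#' library, kept as reference data: the exact class-specific enumeration
#' filters behind these counts were not published, so they are not a
#' generation target (see the methods vignette).
#'
#' @return A tibble with `class`, `structures`, `adducts` (count),
#'   `spectra`.
#' @export
reference_manifest <- function() {
  tibble::tribble(
    ~class,          ~structures, ~adducts,
    "SM",                   3384L,       2L,
    "Cer[NS]",              3360L,       3L,
    "HexCer[NS]",           3360L,       3L,
    "Cer[NDS]",             1120L,       3L,
    "HexCer[NDS]",          1120L,       3L,
    "Cer[AS]",              3360L,       3L,
    "HexCer[AS]",           3360L,       3L,
    "Cer[ADS]",             1120L,       3L,
    "HexCer[ADS]",          1120L,       3L,
    "Cer[BS]",              3360L,       3L,
    "HexCer[BS]",           3360L,       3L,
    "Cer[BDS]",             1120L,       3L,
    "HexCer[BDS]",          1120L,       3L,
    "Cer[EOS]",            25536L,       3L,
    "HexCer[EOS]",         25536L,       3L,
    "Cer[EODS]",            8512L,       3L,
    "HexCer[EODS]",         8512L,       3L,
    "Cer[AP]",              2772L,       3L,
    "HexCer[AP]",           2772L,       3L,
    "Cer[NP]",              2772L,       3L,
    "HexCer[NP]",           2772L,       3L
  ) |>
    dplyr::mutate(spectra = .data$structures * .data$adducts)
}
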