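# Elemental formula arithmetic and ion m/z.
#
# All m/z printed by the package trace back to the monoisotopic constants
# below and to ion_mz(); nothing downstream re-derives masses.

# IUPAC 2013 monoisotopic masses of the most abundant isotope, >= 6 decimals.
.MONOISOTOPIC <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370668,
  Cl = 34.96885271
)

# CODATA electron rest mass in Da.
.ELECTRON_MASS <- 0.00054857990924

#' Construct an elemental formula
#'
#' A `chem_formula` is a named numeric vector of non-negative element counts
#' (e.g. `c(C = 16, H = 32, O = 3)`). It supports `+` and `-` (element-wise;
#' `-` errors rather than produce a negative count), [formula_mass()], and
#' formatting in Hill order.
#'
#' @param x A formula string such as `"C16H32O3"`, a named numeric vector of
#'   element counts, or an existing `chem_formula`.
#' @return A `chem_formula` object.
#' @examples
#' chem_formula("H2O") + chem_formula("C2H4")
#' formula_mass(chem_formula("C16H32O3"))
#' @export
chem_formula <- function(x = character()) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) {
    counts <- if (length(x) == 0 || !nzchar(x)) {
      stats::setNames(numeric(0), character(0))
    } else {
      parse_formula_string(x)
    }
  } else if (is.numeric(x)) {
    if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop("numeric input to chem_formula() must be fully named", call. = FALSE)
    }
    counts <- x
  } else {
    stop("cannot build a chem_formula from class ", class(x)[1], call. = FALSE)
  }
  new_chem_formula(counts)
}

new_chem_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("negative element count for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- counts[hill_order(names(counts))]
  structure(as.double(counts) |> stats::setNames(names(counts)),
            class = "chem_formula")
}

parse_formula_string <- function(s) {
  s <- gsub("\\s", "", s)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s) || nchar(s) == 0) {
    stop("malformed formula string: '", s, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  tapply(n, el, sum) |> c()
}

hill_order <- function(els) {
  # Carbon first, hydrogen second, then alphabetical.
  rank <- match(els, c("C", "H"), nomatch = NA)
  order(ifelse(is.na(rank), 3L, rank), els)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  n <- unclass(x)
  paste0(names(n), ifelse(n == 1, "", format(n, trim = TRUE, scientific = FALSE)),
         collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", round(formula_mass(x), 6), " Da)\n",
      sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  e1 <- chem_formula(e1); e2 <- chem_formula(e2)
  els <- union(names(e1), names(e2))
  new_chem_formula(stats::setNames(
    ifelse(is.na(e1[els]), 0, e1[els]) + ifelse(is.na(e2[els]), 0, e2[els]),
    els))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas", call. = FALSE)
  e1 <- chem_formula(e1); e2 <- chem_formula(e2)
  els <- union(names(e1), names(e2))
  counts <- ifelse(is.na(e1[els]), 0, e1[els]) - ifelse(is.na(e2[els]), 0, e2[els])
  if (any(counts < 0)) {
    bad <- els[counts < 0]
    stop("formula subtraction would leave negative count for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_chem_formula(stats::setNames(counts, els))
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  identical(format(chem_formula(e1)), format(chem_formula(e2)))
}

#' Does one formula contain another?
#'
#' @param f,g Formulas (strings or `chem_formula`).
#' @return `TRUE` if every element count of `g` is `<=` the count in `f`.
#' @export
formula_contains <- function(f, g) {
  f <- chem_formula(f); g <- chem_formula(g)
  all(names(g) %in% names(f)) && all(g <= f[names(g)])
}

#' Monoisotopic mass of a formula
#'
#' @param f A formula string or `chem_formula`.
#' @return Monoisotopic mass in Da (0 for the empty formula).
#' @examples
#' formula_mass("H2O") # 18.010565
#' @export
formula_mass <- function(f) {
  f <- chem_formula(f)
  if (length(f) == 0) return(0)
  sum(.MONOISOTOPIC[names(f)] * as.double(f))
}

#' m/z of a hydrogen-rearranged ion
#'
#' Computes `(mass(f) + hydrogen_delta * m_H - charge * m_e) / |charge|`.
#' `f` is the neutral (valence-satisfied) fragment; `hydrogen_delta` is the
#' signed number of hydrogens gained/lost on ionization, so for example a
#' deprotonation is `hydrogen_delta = -1, charge = -1`. The electron mass is
#' included by default; set `include_electron = FALSE` for the bare-proton
#' convention (difference 0.55 mDa per charge, below QTOF accuracy).
#'
#' @param f Neutral formula (string or `chem_formula`).
#' @param hydrogen_delta Signed integer count of rearranged hydrogens.
#' @param charge Signed integer charge, non-zero.
#' @param include_electron Include the electron mass in the ion mass?
#' @return m/z in Th (numeric scalar).
#' @examples
#' ion_mz("C16H32O3", hydrogen_delta = -1, charge = -1) # 271.2279
#' @export
ion_mz <- function(f, hydrogen_delta = 0, charge = -1, include_electron = TRUE) {
  if (length(charge) != 1 || charge == 0) {
    stop("charge must be a non-zero signed integer", call. = FALSE)
  }
  f <- chem_formula(f)
  n_h <- if ("H" %in% names(f)) f[["H"]] else 0
  if (n_h + hydrogen_delta < 0) {
    stop("formula ", format(f), " cannot lose ", -hydrogen_delta, " hydrogens",
         call. = FALSE)
  }
  me <- if (include_electron) .ELECTRON_MASS else 0
  mz <- (formula_mass(f) + hydrogen_delta * .MONOISOTOPIC[["H"]] - charge * me) /
    abs(charge)
  if (mz <= 0) stop("non-positive m/z", call. = FALSE)
  unname(mz)
}

# ---- adduct registry -------------------------------------------------------

.sphingo_env <- new.env(parent = emptyenv())

default_adduct_table <- function() {
  tibble::tribble(
    ~name,           ~polarity,  ~charge, ~add,       ~remove,
    "[M+H]+",        "positive",  1L,     "H",        "",
    "[M+NH4]+",      "positive",  1L,     "NH4",      "",
    "[M+Na]+",       "positive",  1L,     "Na",       "",
    "[M-H]-",        "negative", -1L,     "",         "H",
    "[M+HCOO]-",     "negative", -1L,     "CHO2",     "",
    "[M+CH3COO]-",   "negative", -1L,     "C2H3O2",   ""
  )
}

adduct_shift <- function(add, remove, charge, include_electron = TRUE) {
  me <- if (include_electron) .ELECTRON_MASS else 0
  (formula_mass(chem_formula(add)) - formula_mass(chem_formula(remove)) -
     charge * me) / abs(charge)
}

#' Adduct registry
#'
#' Read-only view of the registered ESI adducts. Ships `[M+H]+`, `[M+NH4]+`,
#' `[M+Na]+`, `[M-H]-`, `[M+HCOO]-` and `[M+CH3COO]-`; more can be loaded
#' from YAML with [load_adducts()].
#'
#' @return A tibble with columns `name`, `polarity`, `charge`, `add`,
#'   `remove`, `mz_shift`.
#' @export
sphingo_adducts <- function() {
  if (is.null(.sphingo_env$adducts)) {
    tbl <- default_adduct_table()
    tbl$mz_shift <- purrr::pmap_dbl(
      tbl[c("add", "remove", "charge")],
      function(add, remove, charge) adduct_shift(add, remove, charge))
    .sphingo_env$adducts <- tbl
  }
  .sphingo_env$adducts
}

#' Register adducts from a YAML file
#'
#' The YAML is a list of entries with fields `name`, `polarity`, `charge`,
#' and `add`/`remove` formula strings, mirroring [sphingo_adducts()].
#'
#' @param path Path to a YAML adduct definition file.
#' @return The updated registry tibble, invisibly.
#' @export
load_adducts <- function(path) {
  defs <- yaml::read_yaml(path)
  tbl <- purrr::map_dfr(defs, function(d) {
    tibble::tibble(name = d$name, polarity = d$polarity,
                   charge = as.integer(d$charge),
                   add = d$add %||% "", remove = d$remove %||% "")
  })
  if (any(abs(tbl$charge) != 1)) {
    stop("only singly charged adducts are supported", call. = FALSE)
  }
  if (any((tbl$charge > 0) != (tbl$polarity == "positive"))) {
    stop("adduct polarity inconsistent with charge sign", call. = FALSE)
  }
  tbl$mz_shift <- purrr::pmap_dbl(
    tbl[c("add", "remove", "charge")],
    function(add, remove, charge) adduct_shift(add, remove, charge))
  reg <- sphingo_adducts()
  .sphingo_env$adducts <- dplyr::bind_rows(
    reg[!reg$name %in% tbl$name, ], tbl)
  invisible(.sphingo_env$adducts)
}

get_adduct <- function(name) {
  reg <- sphingo_adducts()
  hit <- reg[reg$name == name, ]
  if (nrow(hit) != 1) {
    stop("unsupported adduct '", name, "'; supported: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  }
  hit
}

#' Precursor m/z of a neutral molecule under an adduct
#'
#' @param neutral Neutral formula (string or `chem_formula`), non-empty.
#' @param adduct Adduct name registered in [sphingo_adducts()], e.g.
#'   `"[M+CH3COO]-"`.
#' @param include_electron Include the electron mass?
#' @return Precursor m/z in Th.
#' @examples
#' adduct_mz("C48H93NO8", "[M+CH3COO]-") # 870.704
#' @export
adduct_mz <- function(neutral, adduct, include_electron = TRUE) {
  neutral <- chem_formula(neutral)
  if (length(neutral) == 0) stop("neutral formula is empty", call. = FALSE)
  a <- get_adduct(adduct)
  formula_mass(neutral) / abs(a$charge) +
    adduct_shift(a$add, a$remove, a$charge, include_electron)
}

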