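# Template-based assembly of one representative SMILES per species, and a
# small SMILES element counter used to verify atom bookkeeping against the
# block-condensation formula.
#
# Conventions for the representative structure: sphingoid double bonds are
# trans, starting at delta-4 (delta-5 for trihydroxy bases) and spaced by
# two bonds; fatty-acid double bonds are cis, methylene-interrupted and
# placed relative to the methyl end. Strings are template-concatenated, not
# canonicalized.

place_db <- function(n_carbons, n_db, start, step, label) {
  if (n_db == 0) return(list(pos = integer(0), standard = TRUE))
  std <- seq(start, by = step, length.out = n_db)
  if (max(std) <= n_carbons - 2) return(list(pos = std, standard = TRUE))
  # Fallback for extreme double-bond counts: maximal non-adjacent packing,
  # geometry left unspecified.
  alt <- seq(1, n_carbons - 1, by = 2)
  if (n_db > length(alt)) {
    stop("cannot place ", n_db, " double bonds on a ", n_carbons,
         "-carbon ", label, " chain", call. = FALSE)
  }
  list(pos = alt[seq_len(n_db)], standard = FALSE)
}

# db placement for fatty acids, counted from the methyl end.
place_db_fa <- function(n_carbons, n_db, min_pos) {
  if (n_db == 0) return(list(pos = integer(0), standard = TRUE))
  pos <- n_carbons - 3 * (n_db:1)
  if (min(pos) < min_pos) {
    stop("cannot place ", n_db, " double bonds on a ", n_carbons,
         "-carbon fatty acid", call. = FALSE)
  }
  list(pos = pos, standard = TRUE)
}

# Build a linear carbon backbone. subs: named list carbon-index -> branch
# SMILES (emitted in parentheses). db: list(pos, standard); geometry "trans"
# or "cis" markers are emitted only for standard placements.
chain_smiles <- function(n_carbons, subs = list(), db = list(pos = integer(0), standard = TRUE),
                         geometry = "trans") {
  n_bonds <- n_carbons - 1
  ann <- rep("", max(n_bonds, 0))
  for (p in db$pos) {
    ann[p] <- "="
    if (db$standard) {
      if (p > 1 && ann[p - 1] == "") ann[p - 1] <- "/"
      if (p < n_bonds && ann[p + 1] == "") {
        ann[p + 1] <- if (geometry == "cis") "\\" else "/"
      }
    }
  }
  pieces <- character(n_carbons)
  for (i in seq_len(n_carbons)) {
    branch <- subs[[as.character(i)]]
    atom <- paste0("C", if (!is.null(branch)) paste0("(", branch, ")") else "")
    pieces[i] <- paste0(if (i > 1) ann[i - 1] else "", atom)
  }
  paste(pieces, collapse = "")
}

# Acyl moiety attached to the amide nitrogen (or ester oxygen): carbonyl
# carbon C1 plus chain C2..Cc.
acyl_smiles <- function(c, db, fa_type, ester = NULL) {
  if (c < 2) stop("acyl chain needs at least 2 carbons", call. = FALSE)
  min_pos <- switch(fa_type, N = 3, A = 3, B = 4, EO = 3)
  placed <- place_db_fa(c, db, min_pos)
  subs <- list()
  if (fa_type == "A") subs[["2"]] <- "O"
  if (fa_type == "B") subs[["3"]] <- "O"
  if (fa_type == "EO") {
    if (is.null(ester)) stop("EO acyl requires an esterified chain", call. = FALSE)
    subs[[as.character(c)]] <- paste0("O", acyl_smiles(ester$c, ester$db, "N"))
  }
  # chain_smiles indexes the chain C2..Cc as 1..c-1
  subs_shift <- stats::setNames(subs, as.character(as.numeric(names(subs)) - 1))
  db_shift <- list(pos = placed$pos - 1, standard = placed$standard)
  paste0("C(=O)", chain_smiles(c - 1, subs_shift, db_shift, geometry = "cis"))
}

GLUCOSYL_BRANCH <- "OC1OC(CO)C(O)C(O)C1O"          # O-linked hexopyranose
PHOSPHOCHOLINE_BRANCH <- "OP(=O)([O-])OCC[N+](C)(C)C"

#' Assemble a representative SMILES per species
#'
#' One SMILES string per species row, built by concatenating head, sphingoid
#' and acyl block templates. Fatty-acid double bonds are encoded cis,
#' sphingoid double bonds trans; positions follow a fixed representative
#' scheme (see the methods vignette). Strings are not canonicalized.
#'
#' @param species A species tibble (from [parse_lipid_names()] or
#'   [enumerate_class()]).
#' @return Character vector of SMILES, one per row.
#' @examples
#' assemble_smiles(parse_lipid_names("Cer[NS] d18:1/16:0"))
#' @export
assemble_smiles <- function(species) {
  purrr::map_chr(seq_len(nrow(species)), function(i) {
    row <- species[i, ]
    if (row$fa_c < 2 || row$base_c < 3) {
      stop("degenerate chain lengths for ", row$class, " (fa_c = ", row$fa_c,
           ", base_c = ", row$base_c, ")", call. = FALSE)
    }
    head_branch <- switch(row$head,
      Cer = "O", HexCer = GLUCOSYL_BRANCH, SM = PHOSPHOCHOLINE_BRANCH,
      stop("no SMILES template for head '", row$head, "'", call. = FALSE))
    ester <- if (!is.na(row$est_c)) list(c = row$est_c, db = row$est_db)
    acyl <- acyl_smiles(row$fa_c, row$fa_db, row$fa_type, ester)
    subs <- list(`1` = head_branch, `2` = paste0("N", acyl), `3` = "O")
    start <- 4
    if (row$base_oh == 3) {
      subs[["4"]] <- "O"
      start <- 5
    }
    placed <- place_db(row$base_c, row$base_db, start = start, step = 2,
                       label = "sphingoid")
    chain_smiles(row$base_c, subs, placed, geometry = "trans")
  })
}

# ---- SMILES element bookkeeping -------------------------------------------

.ORGANIC_VALENCE <- list(C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6))

#' Element counts of a SMILES string
#'
#' Counts atoms (including implicit hydrogens under standard valences) for
#' the acyclic/ring SMILES subset emitted by [assemble_smiles()]: organic
#' subset atoms C/N/O/P/S, bracket atoms with explicit H and charge, single,
#' double and directional bonds, branches, and ring-closure digits. Used to
#' assert that assembled structures agree with [species_formula()].
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of named count vectors (one per input string), each with a
#'   `charge` attribute.
#' @export
smiles_element_counts <- function(smiles) {
  purrr::map(smiles, smiles_element_counts_one)
}

smiles_element_counts_one <- function(s) {
  rx <- "\\[[^]]+\\]|Cl|Br|[BCNOPSFI]|[=#/\\\\.-]|\\(|\\)|[0-9]"
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("unparseable SMILES: '", s, "'", call. = FALSE)
  }
  atoms <- list()  # each: element, h (NA = implicit), charge, bonds
  prev <- NA_integer_
  stack <- integer(0)
  rings <- list()
  pending <- 1
  add_bond <- function(i, j, order) {
    atoms[[i]]$bonds <<- atoms[[i]]$bonds + order
    atoms[[j]]$bonds <<- atoms[[j]]$bonds + order
  }
  for (tok in toks) {
    if (tok %in% c("=", "#")) {
      pending <- if (tok == "=") 2 else 3
    } else if (tok %in% c("/", "\\", "-")) {
      pending <- 1
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^[0-9]$", tok)) {
      if (is.null(rings[[tok]])) {
        rings[[tok]] <- list(atom = prev, order = pending)
      } else {
        add_bond(rings[[tok]]$atom, prev, max(rings[[tok]]$order, pending))
        rings[[tok]] <- NULL
      }
      pending <- 1
    } else {
      atom <- parse_smiles_atom(tok)
      atoms[[length(atoms) + 1]] <- atom
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      prev <- idx
      pending <- 1
    }
  }
  counts <- numeric(0)
  charge <- 0
  h <- 0
  bump <- function(v, el, by) {
    v[el] <- (if (el %in% names(v)) v[[el]] else 0) + by
    v
  }
  for (a in atoms) {
    counts <- bump(counts, a$element, 1)
    charge <- charge + a$charge
    if (!is.na(a$h)) {
      h <- h + a$h
    } else {
      vals <- .ORGANIC_VALENCE[[a$element]]
      if (is.null(vals)) {
        stop("no default valence for element ", a$element, call. = FALSE)
      }
      v <- vals[vals >= a$bonds][1]
      if (is.na(v)) {
        stop("valence overflow on ", a$element, " in '", s, "'", call. = FALSE)
      }
      h <- h + v - a$bonds
    }
  }
  counts <- bump(counts, "H", h)
  counts <- counts[counts > 0]
  structure(counts, charge = charge)
}

parse_smiles_atom <- function(tok) {
  if (startsWith(tok, "[")) {
    inner <- substr(tok, 2, nchar(tok) - 1)
    mm <- regexec("^([0-9]*)([A-Z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+*|-*)$",
                  inner)[[1]]
    g <- regmatches(inner, list(mm))[[1]]
    if (length(g) == 0) stop("unparseable bracket atom ", tok, call. = FALSE)
    h <- if (nzchar(g[5])) {
      hn <- substr(g[5], 2, nchar(g[5]))
      if (nzchar(hn)) as.integer(hn) else 1L
    } else 0L
    ch <- g[6]
    charge <- if (!nzchar(ch)) 0L
      else if (ch %in% c("+", "-")) ifelse(ch == "+", 1L, -1L)
      else if (grepl("^[+-][0-9]+$", ch)) as.integer(ch)
      else nchar(ch) * ifelse(startsWith(ch, "+"), 1L, -1L)
    list(element = g[3], h = h, charge = charge, bonds = 0)
  } else {
    list(element = tok, h = NA, charge = 0L, bonds = 0)
  }
}
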