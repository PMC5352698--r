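# Shared fixtures, built in code: a small two-class library that exercises
# both template families and all three negative-mode adducts.

small_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- enumeration_config(
        classes = c("Cer[NS]", "Cer[AS]"),
        fa_c = 16:24, fa_db = 0:1, base_c = 18, base_db = 1,
        adducts = c("[M-H]-", "[M+HCOO]-", "[M+CH3COO]-"))
      cache <<- build_library(cfg)
    }
    cache
  }
})

# Descriptor row with every model descriptor zeroed; override as needed.
zero_descriptors <- function(...) {
  base <- tibble::tibble(XLogP = 0, SssCH2 = 0, C2SP3 = 0, BIC0 = 0,
                         ATSC2m = 0, ATSC2v = 0, LipoaffinityIndex = 0,
                         SpMAD_Dzi = 0)
  dplyr::mutate(base, ...)
}

random_formula <- function() {
  els <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:5, 1)
  pick <- sample(els, n)
  chem_formula(stats::setNames(sample(1:40, n, replace = TRUE), pick))
}
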