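# Library-based identification: dot-product spectral similarity plus
# precursor, retention-time and score gating.

#' Identification tolerances and cutoff
#'
#' Defaults mirror standard untargeted-lipidomics settings: MS1 accurate
#' mass tolerance 0.01 Da, MS2 tolerance 0.05 Da, retention-time tolerance
#' 2 min, identification score cutoff 80 (percent).
#'
#' @param ms1_tol,ms2_tol Mass tolerances in Da.
#' @param rt_tol Retention-time tolerance in minutes.
#' @param cutoff Total-score acceptance cutoff on the 0-100 scale.
#' @return A `match_config` list.
#' @export
match_config <- function(ms1_tol = 0.01, ms2_tol = 0.05, rt_tol = 2,
                         cutoff = 80) {
  stopifnot(ms1_tol > 0, ms2_tol > 0, rt_tol > 0, cutoff > 0)
  structure(list(ms1_tol = ms1_tol, ms2_tol = ms2_tol, rt_tol = rt_tol,
                 cutoff = cutoff), class = "match_config")
}

# Greedy nearest-m/z peak pairing, each peak used once; ties -> lower m/z.
pair_peaks <- function(mz_a, mz_b, tol) {
  pairs <- tidyr::expand_grid(i = seq_along(mz_a), j = seq_along(mz_b))
  pairs$d <- abs(mz_a[pairs$i] - mz_b[pairs$j])
  pairs <- pairs[pairs$d <= tol, ]
  pairs <- pairs[order(pairs$d, mz_a[pairs$i], mz_b[pairs$j]), ]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  pairs[keep, c("i", "j")]
}

#' Dot-product similarity between two spectra
#'
#' Peaks are paired greedily by nearest m/z within the tolerance (each peak
#' used at most once); the score is 100 times the cosine of the intensity
#' vectors over the union of paired and unpaired positions. Symmetric in
#' its arguments; 100 iff the paired intensities are proportional with no
#' unpaired peaks.
#'
#' @param query,library_peaks Data frames with `mz` and `intensity`
#'   columns, non-empty.
#' @param ms2_tol m/z pairing tolerance in Da (default 0.05).
#' @return Score in `[0, 100]`.
#' @examples
#' a <- data.frame(mz = 100, intensity = 999)
#' b <- data.frame(mz = c(100, 200), intensity = c(999, 999))
#' dot_product_score(a, b) # 70.7
#' @export
dot_product_score <- function(query, library_peaks, ms2_tol = 0.05) {
  if (nrow(query) == 0 || nrow(library_peaks) == 0) {
    stop("both peak lists must be non-empty", call. = FALSE)
  }
  m <- pair_peaks(query$mz, library_peaks$mz, ms2_tol)
  qa <- c(query$intensity[m$i],
          query$intensity[setdiff(seq_len(nrow(query)), m$i)],
          rep(0, nrow(library_peaks) - nrow(m)))
  lb <- c(library_peaks$intensity[m$j],
          rep(0, nrow(query) - nrow(m)),
          library_peaks$intensity[setdiff(seq_len(nrow(library_peaks)), m$j)])
  denom <- sqrt(sum(qa^2)) * sqrt(sum(lb^2))
  if (denom == 0) return(0)
  100 * sum(qa * lb) / denom
}

# Cosine restricted to library positions (unpaired query peaks ignored).
reverse_dot_product_score <- function(query, library_peaks, ms2_tol = 0.05) {
  m <- pair_peaks(query$mz, library_peaks$mz, ms2_tol)
  q <- rep(0, nrow(library_peaks))
  q[m$j] <- query$intensity[m$i]
  l <- library_peaks$intensity
  denom <- sqrt(sum(q^2)) * sqrt(sum(l^2))
  if (denom == 0) return(0)
  100 * sum(q * l) / denom
}

matched_fraction <- function(query, library_peaks, ms2_tol = 0.05) {
  m <- pair_peaks(query$mz, library_peaks$mz, ms2_tol)
  nrow(m) / nrow(library_peaks)
}

#' Identify a query MS/MS feature against a spectral library
#'
#' Candidates are prefiltered on polarity and precursor m/z (MS1 tolerance),
#' then on retention time when both the query and the record carry one
#' (records without RT bypass the gate), scored and ranked. The total score
#' is the equal-weight mean of the dot product, the reverse dot product and
#' 100 times the matched-diagnostic-ion fraction; each component is
#' reported so a cutoff can also be applied to the raw dot product.
#'
#' @param query A list or one-row tibble with `precursor_mz`, `polarity`,
#'   `peaks` (data frame `mz`/`intensity`), optional `rt`.
#' @param library A record tibble from [build_library()], optionally with
#'   an `rt_pred` column from [attach_predicted_rt()].
#' @param config A [match_config()].
#' @return A tibble of candidates sorted by `total` descending: `name`,
#'   `class`, `adduct`, `precursor_error`, `rt_error`, `dot`, `reverse_dot`,
#'   `matched_frac`, `total`, `accepted`.
#' @export
identify_feature <- function(query, library, config = match_config()) {
  stopifnot(nrow(library) > 0)
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1)
    query <- as.list(query)
    if (is.list(query$peaks) && is.data.frame(query$peaks[[1]])) {
      query$peaks <- query$peaks[[1]]
    }
  }
  qrt <- query$rt %||% NA_real_
  cand <- library[library$polarity == query$polarity &
                    abs(library$precursor_mz - query$precursor_mz) <=
                      config$ms1_tol, ]
  if (nrow(cand) == 0) return(empty_match_result())
  has_rt <- "rt_pred" %in% names(cand)
  rt_err <- if (has_rt) qrt - cand$rt_pred else rep(NA_real_, nrow(cand))
  gate <- is.na(rt_err) | abs(rt_err) <= config$rt_tol
  cand <- cand[gate, ]
  rt_err <- rt_err[gate]
  if (nrow(cand) == 0) return(empty_match_result())
  scores <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    lp <- cand$peaks[[i]]
    tibble::tibble(
      dot = dot_product_score(query$peaks, lp, config$ms2_tol),
      reverse_dot = reverse_dot_product_score(query$peaks, lp, config$ms2_tol),
      matched_frac = matched_fraction(query$peaks, lp, config$ms2_tol))
  })
  out <- tibble::tibble(
    name = cand$name, class = cand$class, adduct = cand$adduct,
    precursor_error = query$precursor_mz - cand$precursor_mz,
    rt_error = rt_err) |>
    dplyr::bind_cols(scores) |>
    dplyr::mutate(total = (.data$dot + .data$reverse_dot +
                             100 * .data$matched_frac) / 3,
                  accepted = .data$total >= config$cutoff) |>
    dplyr::arrange(dplyr::desc(.data$total))
  out
}

empty_match_result <- function() {
  tibble::tibble(name = character(0), class = character(0),
                 adduct = character(0), precursor_error = numeric(0),
                 rt_error = numeric(0), dot = numeric(0),
                 reverse_dot = numeric(0), matched_frac = numeric(0),
                 total = numeric(0), accepted = logical(0))
}

#' Identify many query features
#'
#' @param queries A tibble of query features (columns as in
#'   [identify_feature()], plus an optional `query_id`).
#' @param library,config As in [identify_feature()].
#' @param top_n Keep the best `top_n` candidates per query (default 5).
#' @return A tibble of ranked candidates with `query_id` and `rank`.
#' @export
identify_features <- function(queries, library, config = match_config(),
                              top_n = 5) {
  ids <- if ("query_id" %in% names(queries)) queries$query_id
         else as.character(seq_len(nrow(queries)))
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    res <- identify_feature(queries[i, ], library, config)
    if (nrow(res) == 0) return(res)
    res$rank <- seq_len(nrow(res))
    res$query_id <- ids[i]
    dplyr::relocate(utils::head(res, top_n), "query_id", "rank")
  })
}

#' Attach predicted retention times to a library
#'
#' Joins a descriptor table by species name and predicts RT with the given
#' model. Records without a (complete) descriptor row keep `rt_pred = NA`
#' and bypass the RT gate in [identify_feature()]; a warning reports how
#' many.
#'
#' @param library A record tibble.
#' @param descriptors Data frame with a `name` column plus descriptor
#'   columns.
#' @param model An `rt_model`.
#' @return `library` with an `rt_pred` column.
#' @export
attach_predicted_rt <- function(library, descriptors,
                                model = rt_model_published()) {
  descriptors <- tibble::as_tibble(descriptors)
  stopifnot("name" %in% names(descriptors))
  need <- unique(c("XLogP", unlist(purrr::map(model$segments,
                                              ~names(.x$coefficients)))))
  norm <- normalize_descriptor_names(names(descriptors))
  idx <- match(normalize_descriptor_names(need), norm)
  if (anyNA(idx)) {
    stop("descriptor table lacks column(s): ",
         paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(descriptors[, idx]) &
    apply(as.matrix(descriptors[, idx]), 1, function(r) all(is.finite(r)))
  usable <- descriptors[ok, ]
  preds <- if (nrow(usable) > 0) predict_rt(usable, model) else
    dplyr::mutate(usable, rt_pred = numeric(0))
  out <- dplyr::left_join(library,
                          preds[, c("name", "rt_pred")], by = "name")
  n_missing <- sum(is.na(out$rt_pred))
  if (n_missing > 0) {
    warning(n_missing, " record(s) without usable descriptors; ",
            "RT left unattached", call. = FALSE)
  }
  out
}
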