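# Deterministic generators of synthetic test inputs: noisy query spectra
# drawn from library records, decoy spectra, and descriptor/RT datasets
# with known linear structure. All generators are pure functions of their
# inputs and the seed.

#' Perturb a library record into a noisy query feature
#'
#' Gaussian m/z jitter (`mz_sigma`, Da), multiplicative log-normal intensity
#' noise with coefficient of variation `intensity_cv`, and Bernoulli peak
#' dropout with probability `dropout`. The precursor m/z is jittered with
#' `mz_sigma / 2`. If dropout removes every peak, peaks are resampled so at
#' least one survives.
#'
#' @param record A one-row record tibble.
#' @param mz_sigma m/z noise SD in Da (>= 0).
#' @param intensity_cv Intensity coefficient of variation (>= 0).
#' @param dropout Peak dropout probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A one-row query tibble (`query_id`, `true_name`, `precursor_mz`,
#'   `rt`, `polarity`, `peaks`).
#' @export
perturb_spectrum <- function(record, mz_sigma = 0.002, intensity_cv = 0.2,
                             dropout = 0, seed = 1L) {
  stopifnot(mz_sigma >= 0, intensity_cv >= 0, dropout >= 0, dropout < 1)
  stopifnot(nrow(record) == 1)
  withr::local_seed(seed)
  pk <- record$peaks[[1]]
  keep <- stats::runif(nrow(pk)) >= dropout
  while (!any(keep)) keep <- stats::runif(nrow(pk)) >= dropout
  pk <- pk[keep, ]
  sdlog <- sqrt(log(1 + intensity_cv^2))
  out <- tibble::tibble(
    mz = pk$mz + stats::rnorm(nrow(pk), 0, mz_sigma),
    intensity = pk$intensity * stats::rlnorm(nrow(pk), 0, sdlog))
  tibble::tibble(
    query_id = paste0(record$name, "|", record$adduct, "|seed", seed),
    true_name = record$name,
    precursor_mz = record$precursor_mz + stats::rnorm(1, 0, mz_sigma / 2),
    rt = if ("rt_pred" %in% names(record)) record$rt_pred else NA_real_,
    polarity = record$polarity,
    peaks = list(dplyr::arrange(out, .data$mz)))
}

#' Synthetic descriptor/RT dataset with known linear structure
#'
#' Standard-normal descriptors `x1..xp`; RT is `intercept + X beta` plus
#' Gaussian noise. The ground truth is returned alongside so parameter
#' recovery can be asserted.
#'
#' @param n Number of samples (`n > p + 2`).
#' @param p Number of descriptor columns.
#' @param coefficients Named numeric vector of true coefficients; names
#'   must be a subset of the generated (or supplied) descriptor names.
#' @param intercept True intercept.
#' @param noise_sd Gaussian noise SD in minutes.
#' @param seed Integer seed.
#' @param descriptor_names Optional descriptor column names (default
#'   `x01..`).
#' @return A list: `descriptors` (tibble), `rt`, `coefficients`,
#'   `intercept`, `noise_sd`.
#' @export
synth_rt_dataset <- function(n, p, coefficients, intercept = 0,
                             noise_sd = 0.14, seed = 1L,
                             descriptor_names = NULL) {
  if (n <= p + 2) stop("need n > p + 2", call. = FALSE)
  withr::local_seed(seed)
  nms <- descriptor_names %||% sprintf("x%02d", seq_len(p))
  stopifnot(length(nms) == p, all(names(coefficients) %in% nms))
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nms))
  beta <- stats::setNames(rep(0, p), nms)
  beta[names(coefficients)] <- coefficients
  rt <- intercept + drop(X %*% beta) + stats::rnorm(n, 0, noise_sd)
  list(descriptors = tibble::as_tibble(X), rt = rt,
       coefficients = coefficients, intercept = intercept,
       noise_sd = noise_sd)
}

#' Precursor-preserving decoy records
#'
#' Samples `k` records and replaces every fragment m/z by a uniform draw
#' over `[50, precursor_mz - 1]` (intensities and peak counts kept), so a
#' decoy retains its precursor gate behaviour but no true fragmentation
#' structure.
#'
#' @param library A record tibble.
#' @param k Number of decoys (`k <= nrow(library)`).
#' @param seed Integer seed.
#' @return A record tibble of `k` decoys with `decoy = TRUE` and names
#'   suffixed `" (decoy)"`.
#' @export
make_decoys <- function(library, k, seed = 1L) {
  stopifnot(k <= nrow(library), k >= 0)
  if (k == 0) return(dplyr::mutate(library[0, ], decoy = logical(0)))
  withr::local_seed(seed)
  idx <- sample(nrow(library), k)
  out <- library[idx, ]
  out$peaks <- purrr::map(seq_len(k), function(i) {
    pk <- out$peaks[[i]]
    pk$mz <- sort(stats::runif(nrow(pk), 50, out$precursor_mz[i] - 1))
    pk
  })
  out$name <- paste0(out$name, " (decoy)")
  out$decoy <- TRUE
  out
}
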