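# Segmented QSRR retention-time model: published coefficients, XLogP
# routing with boundary blending, and the refitting pipeline (correlation
# prefilter + forward stepwise AIC regression).

normalize_descriptor_names <- function(x) {
  gsub("[[:space:]_]", "", tolower(x))
}

#' The published segmented retention-time model
#'
#' Two ordinary-least-squares segments routed on XLogP: the early/isocratic
#' segment (`ab`, applied at XLogP <= 15.9) uses XLogP, SssCH2, C2SP3, BIC0,
#' ATSC2m and ATSC2v; the late-gradient segment (`c`, applied at
#' XLogP >= 16.6) uses XLogP, LipoaffinityIndex, SpMAD_Dzi and C2SP3. Inside
#' the open interval (15.9, 16.6) the prediction is the unweighted mean of
#' the two segment predictions. Units are minutes.
#'
#' @return An object of class `rt_model`.
#' @export
rt_model_published <- function() {
  new_rt_model(
    segments = list(
      ab = list(coefficients = c(XLogP = 0.55, SssCH2 = 0.17, C2SP3 = 0.048,
                                 BIC0 = 71, ATSC2m = -0.0022,
                                 ATSC2v = 0.00081),
                intercept = -14),
      c = list(coefficients = c(XLogP = 0.16, LipoaffinityIndex = 0.076,
                                SpMAD_Dzi = -0.14, C2SP3 = 0.085),
               intercept = 9.5)),
    low_bound = 15.9, high_bound = 16.6, name = "paper-2017")
}

new_rt_model <- function(segments, low_bound, high_bound, name = "custom") {
  stopifnot(low_bound <= high_bound,
            all(c("ab", "c") %in% names(segments)))
  structure(list(segments = segments, low_bound = low_bound,
                 high_bound = high_bound, name = name),
            class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("<rt_model '", x$name, "'> XLogP routing: segment ab <= ",
      x$low_bound, ", segment c >= ", x$high_bound,
      ", blended in between\n", sep = "")
  for (s in names(x$segments)) {
    seg <- x$segments[[s]]
    cat("  ", s, ": intercept ", seg$intercept, "; ",
        paste(names(seg$coefficients), round(seg$coefficients, 6),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

segment_predict <- function(seg, descriptors) {
  need <- names(seg$coefficients)
  norm <- normalize_descriptor_names(names(descriptors))
  idx <- match(normalize_descriptor_names(need), norm)
  if (anyNA(idx)) {
    stop("missing descriptor column(s): ", paste(need[is.na(idx)],
                                                 collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(descriptors[, idx, drop = FALSE])
  if (!is.numeric(mat)) stop("descriptor columns must be numeric", call. = FALSE)
  drop(mat %*% seg$coefficients) + seg$intercept
}

#' Predict retention times from molecular descriptors
#'
#' Routes each row on XLogP (segment `ab` at `XLogP <= low_bound`, segment
#' `c` at `XLogP >= high_bound`, the arithmetic mean of both in between; no
#' clamping). Descriptor names are matched case-insensitively with
#' whitespace and underscores stripped, so `"ATSC2 m"` and `"ATSC2m"` are
#' the same column.
#'
#' @param descriptors A data frame of descriptor columns (one row per
#'   molecule); must contain every descriptor of the model and `XLogP`.
#' @param model An `rt_model` (default: the published coefficients).
#' @return The input tibble with columns `rt_segment` and `rt_pred`
#'   (minutes) added.
#' @examples
#' predict_rt(data.frame(XLogP = 20, LipoaffinityIndex = 0, SpMAD_Dzi = 0,
#'                       C2SP3 = 0, SssCH2 = 0, BIC0 = 0, ATSC2m = 0,
#'                       ATSC2v = 0))
#' @export
predict_rt <- function(descriptors, model = rt_model_published()) {
  descriptors <- tibble::as_tibble(descriptors)
  if (nrow(descriptors) == 0) {
    return(dplyr::mutate(descriptors, rt_segment = character(0),
                         rt_pred = numeric(0)))
  }
  need <- unique(c("XLogP",
                   unlist(purrr::map(model$segments,
                                     ~names(.x$coefficients)))))
  norm <- normalize_descriptor_names(names(descriptors))
  idx <- match(normalize_descriptor_names(need), norm)
  if (anyNA(idx)) {
    stop("missing descriptor column(s): ",
         paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- descriptors[, idx, drop = FALSE]
  bad <- !stats::complete.cases(vals) |
    !apply(as.matrix(vals), 1, function(r) all(is.finite(r)))
  if (any(bad)) {
    stop("non-finite descriptor values in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  xlogp <- vals[[match(normalize_descriptor_names("XLogP"),
                       normalize_descriptor_names(names(vals)))]]
  pred_ab <- segment_predict(model$segments$ab, descriptors)
  pred_c <- segment_predict(model$segments$c, descriptors)
  seg <- dplyr::case_when(
    xlogp <= model$low_bound ~ "ab",
    xlogp >= model$high_bound ~ "c",
    TRUE ~ "blend")
  pred <- dplyr::case_when(
    seg == "ab" ~ pred_ab,
    seg == "c" ~ pred_c,
    TRUE ~ (pred_ab + pred_c) / 2)
  dplyr::mutate(descriptors, rt_segment = seg, rt_pred = pred)
}

#' Serialize / deserialize an RT model as JSON
#'
#' @param model An `rt_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or an `rt_model` (read).
#' @export
write_rt_model_json <- function(model, path) {
  obj <- list(name = model$name, low_bound = model$low_bound,
              high_bound = model$high_bound,
              segments = purrr::map(model$segments, function(s) {
                list(descriptors = names(s$coefficients),
                     coefficients = unname(s$coefficients),
                     intercept = s$intercept)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rt_model_json
#' @export
read_rt_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- purrr::map(obj$segments, function(s) {
    list(coefficients = stats::setNames(as.numeric(s$coefficients),
                                        s$descriptors),
         intercept = as.numeric(s$intercept))
  })
  new_rt_model(segs, obj$low_bound, obj$high_bound, obj$name %||% "json")
}

# ---- refitting pipeline ----------------------------------------------------

#' Correlation prefilter for descriptor selection
#'
#' Removes constant ("uniform") and duplicate ("redundant") descriptor
#' columns, then keeps descriptors whose absolute Pearson correlation with
#' the retention time meets the threshold. The absolute value is used
#' because hydrophilicity-type descriptors anticorrelate with reverse-phase
#' retention.
#'
#' @param descriptors Data frame of numeric descriptor columns.
#' @param rt Numeric retention-time vector, `length(rt) == nrow(descriptors)`,
#'   at least 3 values.
#' @param threshold Absolute-correlation threshold (default 0.85).
#' @return A tibble with one row per input descriptor: `descriptor`, `r`,
#'   `abs_r`, `status` (`"selected"`, `"rejected"`, `"constant"`,
#'   `"duplicate"`).
#' @export
correlation_prefilter <- function(descriptors, rt, threshold = 0.85) {
  descriptors <- tibble::as_tibble(descriptors)
  if (length(rt) != nrow(descriptors) || length(rt) < 3) {
    stop("need rt for every row and at least 3 samples", call. = FALSE)
  }
  status <- stats::setNames(rep("rejected", ncol(descriptors)),
                            names(descriptors))
  const <- purrr::map_lgl(descriptors, ~dplyr::n_distinct(.x) == 1)
  status[const] <- "constant"
  keep <- names(descriptors)[!const]
  seen <- list()
  for (nm in keep) {
    key <- paste(signif(descriptors[[nm]], 12), collapse = ",")
    if (!is.null(seen[[key]])) {
      status[nm] <- "duplicate"
    } else {
      seen[[key]] <- nm
    }
  }
  r <- purrr::map_dbl(names(descriptors), function(nm) {
    if (status[nm] %in% c("constant", "duplicate")) return(NA_real_)
    stats::cor(descriptors[[nm]], rt)
  })
  sel <- !is.na(r) & abs(r) >= threshold
  status[sel] <- "selected"
  tibble::tibble(descriptor = names(descriptors), r = r, abs_r = abs(r),
                 status = unname(status))
}

aic_ols <- function(fit) {
  # n * log(RSS / n) + 2k, the stepwise-tool convention; constant offsets
  # relative to the likelihood AIC cancel in comparisons.
  res <- stats::residuals(fit)
  n <- length(res)
  rss <- max(sum(res^2), 1e-300)
  n * log(rss / n) + 2 * (length(stats::coef(fit)))
}

#' Forward stepwise AIC regression
#'
#' Starts from the intercept-only model and at each step adds the candidate
#' descriptor that minimizes the AIC (`n log(RSS/n) + 2k`), stopping when no
#' addition lowers it. Ordinary least squares within steps; ties are broken
#' by descriptor name.
#'
#' @param descriptors Data frame of numeric candidate columns.
#' @param rt Numeric response vector (retention times, minutes).
#' @return An object of class `rt_stepwise` with elements `fit` (the final
#'   `lm`), `selected`, `aic_trace`, `sigma` (residual SD), `n`. Use
#'   [tidy.rt_stepwise()] / [glance.rt_stepwise()] for tabular summaries.
#' @export
fit_stepwise <- function(descriptors, rt) {
  descriptors <- tibble::as_tibble(descriptors)
  n <- nrow(descriptors)
  if (length(rt) != n || n <= 2) {
    stop("need rt for every row and n > 2", call. = FALSE)
  }
  candidates <- sort(names(descriptors))
  data <- dplyr::mutate(descriptors, .rt = rt)
  selected <- character(0)
  current <- stats::lm(.rt ~ 1, data = data)
  trace <- tibble::tibble(step = 0L, added = NA_character_,
                          aic = aic_ols(current))
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0 || n <= length(selected) + 2) break
    fits <- purrr::map(pool, function(nm) {
      fml <- stats::reformulate(c(selected, nm), response = ".rt")
      stats::lm(fml, data = data)
    })
    aics <- purrr::map_dbl(fits, aic_ols)
    best <- which.min(aics)  # pool is name-sorted, so ties go alphabetically
    if (aics[best] >= dplyr::last(trace$aic)) break
    selected <- c(selected, pool[best])
    current <- fits[[best]]
    trace <- dplyr::bind_rows(trace,
      tibble::tibble(step = length(selected), added = pool[best],
                     aic = aics[best]))
    # an (effectively) exact fit cannot be improved further
    if (sum(stats::residuals(current)^2) < 1e-16 * n) break
  }
  res <- stats::residuals(current)
  structure(list(fit = current, selected = selected, aic_trace = trace,
                 sigma = stats::sd(res), n = n),
            class = "rt_stepwise")
}

#' @export
print.rt_stepwise <- function(x, ...) {
  cat("<rt_stepwise> n = ", x$n, ", selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)",
      ", residual SD = ", signif(x$sigma, 4), " min\n", sep = "")
  invisible(x)
}

#' Tidy a stepwise RT fit
#'
#' @param x An `rt_stepwise` object.
#' @param ... Unused.
#' @return A tibble of terms, estimates, standard errors, t and p values.
#' @export
tidy.rt_stepwise <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
                 p.value = unname(sm[, 4]))
}

#' One-row summary of a stepwise RT fit
#'
#' @param x An `rt_stepwise` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_selected`, `aic`, `sigma`,
#'   `r.squared`.
#' @export
glance.rt_stepwise <- function(x, ...) {
  tibble::tibble(n = x$n, n_selected = length(x$selected),
                 aic = dplyr::last(x$aic_trace$aic), sigma = x$sigma,
                 r.squared = summary(x$fit)$r.squared)
}

#' Generic for broom-style tidying
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries
#' @param x Object to summarize.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Split a training table into the two XLogP segments
#'
#' The published windows overlap: segment `ab` spans XLogP 5.0-16.6 and
#' segment `c` spans 15.9-32.1, so rows inside [15.9, 16.6] may belong to
#' both. `policy = "both"` duplicates such rows into both segments (the
#' default); `"assign_low"`/`"assign_high"` give them to one side only.
#'
#' @param descriptors Data frame containing an XLogP column.
#' @param ab_range,c_range Numeric length-2 windows on XLogP.
#' @param policy Overlap policy.
#' @return A long tibble: the input rows plus a `segment` column.
#' @export
split_by_segment <- function(descriptors, ab_range = c(5.0, 16.6),
                             c_range = c(15.9, 32.1),
                             policy = c("both", "assign_low", "assign_high")) {
  policy <- match.arg(policy)
  descriptors <- tibble::as_tibble(descriptors)
  norm <- normalize_descriptor_names(names(descriptors))
  ix <- match("xlogp", norm)
  if (is.na(ix)) stop("no XLogP column present", call. = FALSE)
  x <- descriptors[[ix]]
  # the outer bounds describe the training-data extent, not gates:
  # routing only depends on the inner (overlapping) boundaries
  in_ab <- x <= ab_range[2]
  in_c <- x >= c_range[1]
  overlap <- in_ab & in_c
  if (policy == "assign_low") in_c[overlap] <- FALSE
  if (policy == "assign_high") in_ab[overlap] <- FALSE
  dplyr::bind_rows(
    dplyr::mutate(descriptors[in_ab, ], segment = "ab"),
    dplyr::mutate(descriptors[in_c, ], segment = "c"))
}

#' Refit the full segmented RT model
#'
#' Convenience pipeline: correlation prefilter, segment split, forward
#' stepwise AIC per segment, packaged as an `rt_model` with the same
#' routing/blending behaviour as the published model.
#'
#' @param descriptors Data frame of numeric descriptor columns incl. XLogP.
#' @param rt Retention times (minutes).
#' @param threshold Prefilter threshold on `|r|`.
#' @param ab_range,c_range XLogP windows for the two segments.
#' @return A list with `model` (an `rt_model`), `fits` (per-segment
#'   `rt_stepwise`), and `prefilter` (the prefilter report).
#' @export
fit_rt_model <- function(descriptors, rt, threshold = 0.85,
                         ab_range = c(5.0, 16.6), c_range = c(15.9, 32.1)) {
  pre <- correlation_prefilter(descriptors, rt, threshold)
  keep <- pre$descriptor[pre$status == "selected"]
  norm <- normalize_descriptor_names(keep)
  keep <- unique(c(keep, names(descriptors)[
    normalize_descriptor_names(names(descriptors)) == "xlogp"]))
  tbl <- tibble::as_tibble(descriptors)[, keep, drop = FALSE]
  tbl$.rt <- rt
  long <- split_by_segment(tbl, ab_range, c_range)
  fits <- purrr::map(c(ab = "ab", c = "c"), function(s) {
    part <- long[long$segment == s, ]
    fit_stepwise(part[, setdiff(names(part), c(".rt", "segment"))], part$.rt)
  })
  segs <- purrr::map(fits, function(f) {
    cf <- stats::coef(f$fit)
    list(coefficients = cf[names(cf) != "(Intercept)"],
         intercept = unname(cf["(Intercept)"]))
  })
  model <- new_rt_model(segs, low_bound = c_range[1], high_bound = ab_range[2],
                        name = "refit")
  list(model = model, fits = fits, prefilter = pre)
}
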