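test_that("published coefficients reproduce hand-computed predictions", {
  d <- zero_descriptors()
  expect_equal(predict_rt(d)$rt_pred, -14.0)                       # intercept
  expect_equal(predict_rt(dplyr::mutate(d, XLogP = 20))$rt_pred,
               9.5 + 0.16 * 20)                                    # 12.7
  # inside the open blending window: unweighted mean of both segments
  p16 <- predict_rt(dplyr::mutate(d, XLogP = 16))
  expect_equal(p16$rt_segment, "blend")
  expect_equal(p16$rt_pred, mean(c(-14 + 0.55 * 16, 9.5 + 0.16 * 16))) # 3.43
  # a full-coefficient check on the early segment
  d2 <- zero_descriptors(XLogP = 10, SssCH2 = 2, C2SP3 = 3, BIC0 = 0.1,
                         ATSC2m = 100, ATSC2v = 200)
  expect_equal(predict_rt(d2)$rt_pred,
               -14 + 0.55 * 10 + 0.17 * 2 + 0.048 * 3 + 71 * 0.1 -
                 0.0022 * 100 + 0.00081 * 200)
  d3 <- zero_descriptors(XLogP = 25, LipoaffinityIndex = 30, SpMAD_Dzi = 4,
                         C2SP3 = 10)
  expect_equal(predict_rt(d3)$rt_pred,
               9.5 + 0.16 * 25 + 0.076 * 30 - 0.14 * 4 + 0.085 * 10)
})

test_that("blended predictions lie between the two segment predictions", {
  withr::local_seed(3)
  for (i in 1:20) {
    d <- zero_descriptors(XLogP = stats::runif(1, 15.9001, 16.5999),
                          SssCH2 = stats::rnorm(1, 0, 10),
                          LipoaffinityIndex = stats::rnorm(1, 0, 10))
    ab <- -14 + 0.55 * d$XLogP + 0.17 * d$SssCH2
    cc <- 9.5 + 0.16 * d$XLogP + 0.076 * d$LipoaffinityIndex
    p <- predict_rt(d)$rt_pred
    expect_gte(p, min(ab, cc) - 1e-9)
    expect_lte(p, max(ab, cc) + 1e-9)
  }
})

test_that("descriptor names are matched loosely and gaps are fatal", {
  d <- zero_descriptors()
  names(d)[names(d) == "ATSC2m"] <- "ATSC2 m"   # the printed spelling
  names(d)[names(d) == "XLogP"] <- "xlogp"
  expect_equal(predict_rt(dplyr::mutate(d, xlogp = 20))$rt_pred, 12.7)
  expect_error(predict_rt(d[, setdiff(names(d), "BIC0")]), "BIC0")
  expect_error(predict_rt(dplyr::mutate(d, BIC0 = NA_real_)), "non-finite")
})

test_that("the correlation prefilter keeps |r| >= threshold after cleanup", {
  withr::local_seed(5)
  rt <- stats::rnorm(30)
  tbl <- tibble::tibble(
    doubled = 2 * rt,              # r = 1
    negated = -rt,                 # r = -1, kept under |r|
    weak = rt + stats::rnorm(30, 0, 3),
    flat = rep(7, 30),             # uniform
    doubled_copy = 2 * rt)         # redundant duplicate
  rep_ <- correlation_prefilter(tbl, rt, threshold = 0.85)
  status <- stats::setNames(rep_$status, rep_$descriptor)
  expect_equal(unname(status[c("doubled", "negated")]),
               c("selected", "selected"))
  expect_equal(unname(status["flat"]), "constant")
  expect_equal(unname(status["doubled_copy"]), "duplicate")
  expect_equal(unname(status["weak"]), "rejected")
  expect_error(correlation_prefilter(tbl[1:2, ], rt[1:2]), "at least 3")
})

test_that("forward stepwise recovers a noiseless linear model exactly", {
  withr::local_seed(9)
  n <- 60
  x1 <- stats::rnorm(n)
  noise <- matrix(stats::rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("z", 1:4)))
  tbl <- dplyr::bind_cols(tibble::tibble(x1 = x1), tibble::as_tibble(noise))
  fit <- fit_stepwise(tbl, 2 * x1)
  expect_equal(fit$selected[1], "x1")
  est <- suppressWarnings(tidy(fit))
  expect_equal(est$estimate[est$term == "x1"], 2, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-8)
  expect_lt(suppressWarnings(glance(fit))$sigma, 1e-8)
})

test_that("stepwise returns intercept-only when nothing explains the response", {
  y <- rep(c(1, -1), 10)
  x <- rep(c(1, 1, -1, -1), 5)      # exactly orthogonal to y
  fit <- fit_stepwise(tibble::tibble(x = x), y)
  expect_equal(length(fit$selected), 0)
  expect_equal(nrow(fit$aic_trace), 1)
  expect_error(fit_stepwise(tibble::tibble(x = 1:2), c(1, 2)), "n > 2")
})

test_that("stepwise AIC trace is strictly decreasing over accepted steps", {
  ds <- synth_rt_dataset(n = 120, p = 8,
                         coefficients = c(x01 = 3, x02 = -1),
                         noise_sd = 0.1, seed = 21)
  fit <- fit_stepwise(ds$descriptors, ds$rt)
  expect_true(all(diff(fit$aic_trace$aic) < 0))
})

test_that("refitting recovers the published early-segment equation", {
  # synthetic training data generated from the published A+B equation with
  # the reported training residual SD of 0.14 min
  coefs <- c(XLogP = 0.55, SssCH2 = 0.17, C2SP3 = 0.048, BIC0 = 71,
             ATSC2m = -0.0022, ATSC2v = 0.00081)
  ds <- synth_rt_dataset(n = 200, p = 20, coefficients = coefs,
                         intercept = -14, noise_sd = 0.14, seed = 33,
                         descriptor_names = c(names(coefs),
                                              sprintf("noise%02d", 1:14)))
  fit <- fit_stepwise(ds$descriptors, ds$rt)
  # effects clearly above the noise floor must be selected
  expect_true(all(c("XLogP", "SssCH2", "C2SP3", "BIC0") %in% fit$selected))
  est <- suppressWarnings(tidy(fit))
  for (nm in intersect(fit$selected, names(coefs))) {
    row <- est[est$term == nm, ]
    expect_lt(abs(row$estimate - coefs[[nm]]), 3 * row$std.error)
  }
  expect_equal(fit$sigma, 0.14, tolerance = 0.25)
  # refitting with the true descriptor set recovers every coefficient
  # within 3 standard errors (independent OLS oracle)
  ols <- stats::lm(ds$rt ~ ., data = ds$descriptors[, names(coefs)])
  sm <- summary(ols)$coefficients
  for (nm in names(coefs)) {
    expect_lt(abs(sm[nm, 1] - coefs[[nm]]), 3 * sm[nm, 2])
  }
  expect_lt(abs(sm["(Intercept)", 1] - (-14)), 3 * sm["(Intercept)", 2])
})

test_that("segment split honours the overlapping published windows", {
  tbl <- tibble::tibble(XLogP = c(10, 16.0, 40), id = 1:3)
  long <- split_by_segment(tbl)
  expect_equal(long$segment[long$id == 1], "ab")
  expect_equal(sort(long$segment[long$id == 2]), c("ab", "c"))
  expect_equal(long$segment[long$id == 3], "c")
  low <- split_by_segment(tbl, policy = "assign_low")
  expect_equal(low$segment[low$id == 2], "ab")
  expect_error(split_by_segment(tibble::tibble(a = 1)), "XLogP")
})

test_that("models serialize to JSON and back without loss", {
  path <- withr::local_tempfile(fileext = ".json")
  write_rt_model_json(rt_model_published(), path)
  back <- read_rt_model_json(path)
  d <- zero_descriptors(XLogP = 16.2, SssCH2 = 5, LipoaffinityIndex = 2)
  expect_equal(predict_rt(d, back)$rt_pred, predict_rt(d)$rt_pred)
})

test_that("a model refitted on its own predictions has zero residual SD", {
  withr::local_seed(14)
  d <- tibble::as_tibble(matrix(stats::rnorm(80 * 6), 80, 6,
                                dimnames = list(NULL, c("XLogP", "SssCH2",
                                                        "C2SP3", "BIC0",
                                                        "ATSC2m", "ATSC2v"))))
  d$XLogP <- stats::runif(80, 5, 15)   # keep every row in the early segment
  rt <- predict_rt(dplyr::mutate(d, LipoaffinityIndex = 0, SpMAD_Dzi = 0))$rt_pred
  fit <- fit_stepwise(d, rt)
  expect_lt(fit$sigma, 1e-8)
})
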