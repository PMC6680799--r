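#' All pairwise phase differences of a daily parameter
#'
#' The change in a daily parameter is measured as every festival daily
#' value minus every pre-festival daily value (full cross product;
#' 19 x 19 = 361 differences per individual for complete phases). A
#' reduction during the festival therefore yields negative differences.
#'
#' @param pre,festival numeric daily values (missing days already removed).
#' @return numeric vector of length `length(festival) * length(pre)`.
#' @examples
#' pairwise_diffs(c(1, 2), 4)  # 3, 2
#' @export
pairwise_diffs <- function(pre, festival) {
  stopifnot(length(pre) > 0, length(festival) > 0)
  as.numeric(outer(festival, pre, "-"))
}

#' Transform daily values before differencing
#'
#' The standard transforms used ahead of the mixed model: the diurnality
#' index (bounded at -1) is shifted by one and log-transformed,
#' `ln(DI + 1 + eps)`; TSdusk is shifted by the absolute value of its
#' dataset minimum so all values are positive; daily ODBA sums are
#' z-scored over the dataset; everything else is left unchanged.
#'
#' @param values numeric daily values (the whole dataset for the
#'   parameter, since shift and z-score are dataset-wide).
#' @param transform one of `"identity"`, `"log_di"`, `"shift_min"`,
#'   `"zscore"`.
#' @param eps guard added inside the DI log; with `eps = 0` a DI of -1
#'   errors and directs the user to `eps`.
#' @return transformed numeric vector.
#' @examples
#' apply_transform(c(-30, 10), "shift_min")  # 0, 40
#' @export
apply_transform <- function(values,
                            transform = c("identity", "log_di", "shift_min",
                                          "zscore"),
                            eps = 1e-6) {
  transform <- match.arg(transform)
  switch(transform,
    identity = values,
    log_di = {
      if (any(values + 1 + eps <= 0, na.rm = TRUE)) {
        stop("DI of -1 with eps = 0 is not log-transformable; ",
             "set a positive `eps`", call. = FALSE)
      }
      log(values + 1 + eps)
    },
    shift_min = values + abs(min(values, na.rm = TRUE)),
    zscore = as.numeric(scale(values))
  )
}

# canonical transform for each pipeline parameter
.param_transform <- function(parameter) {
  if (parameter == "di") return("log_di")
  if (parameter == "tsdusk_min") return("shift_min")
  if (parameter == "odba_sum") return("zscore")
  "identity"
}

#' Build the pairwise-difference set of one parameter
#'
#' Applies the parameter's transform to the daily values, then forms all
#' festival-minus-pre pairwise differences per individual. Individuals
#' with no usable day in either phase are excluded with a warning.
#'
#' @param daily tibble with `individual_id`, `phase` (`"pre"` /
#'   `"festival"`), and the value column.
#' @param value_col name of the value column.
#' @param transform transform tag (see [apply_transform()]); the
#'   parameter's canonical transform when `NULL`.
#' @param transform_diffs apply the transform to the differences instead
#'   of the daily values (non-default variant).
#' @return tibble: `individual_id`, `diff`; the transform tag is attached
#'   as `attr(, "transform")`.
#' @export
build_diffs <- function(daily, value_col, transform = NULL,
                        transform_diffs = FALSE) {
  stopifnot(all(c("individual_id", "phase", value_col) %in% names(daily)))
  if (is.null(transform)) transform <- .param_transform(value_col)
  df <- daily[!is.na(daily[[value_col]]), ]
  if (!transform_diffs) {
    df[[value_col]] <- apply_transform(df[[value_col]], transform)
  }
  out <- list()
  for (id in unique(daily$individual_id)) {
    pre <- df[[value_col]][df$individual_id == id & df$phase == "pre"]
    fest <- df[[value_col]][df$individual_id == id & df$phase == "festival"]
    if (length(pre) == 0 || length(fest) == 0) {
      warning(sprintf("individual %s has no usable day in one phase; excluded", id))
      next
    }
    out[[length(out) + 1]] <- tibble::tibble(
      individual_id = id, diff = pairwise_diffs(pre, fest)
    )
  }
  res <- dplyr::bind_rows(out)
  if (transform_diffs && nrow(res) > 0) {
    res$diff <- apply_transform(res$diff, transform)
  }
  attr(res, "transform") <- transform
  res
}

#' Random-intercept model over pairwise differences
#'
#' Fits `diff ~ 1 + (1 | individual_id)` by REML and predicts each
#' individual's mean expected change as the shrunken (BLUP) conditional
#' mean `mu + b_i`, with a 95% interval from the conditional variance of
#' `b_i` plus the sampling variance of `mu`. A change is flagged
#' significant when its interval excludes zero. When the between-individual
#' variance is estimated at the boundary (zero), the fit falls back to a
#' pooled intercept and flags it.
#'
#' Note that the pairwise differences are statistically dependent
#' pseudo-replicates of the underlying daily values (each day enters many
#' differences); the per-individual intervals inherit that optimism. See
#' the methods vignette for the effective-sample-size caveat.
#'
#' @param diffs tibble from [build_diffs()] (`individual_id`, `diff`;
#'   at least 2 individuals with 2 differences each).
#' @param conf_level interval coverage (default 0.95). The interval
#'   half-width is `z * sqrt(condVar(b_i) + (1 - s_i)^2 * var(mu))` with
#'   shrinkage weight `s_i`; it collapses to zero in the noise-free limit.
#' @return object of class `change_fit`: tibble `estimates`
#'   (`individual_id`, `pred_change`, `ci_lo`, `ci_hi`, `significant`),
#'   plus `mu`, `sigma_b`, `sigma_e`, `pooled`, `model`.
#' @export
fit_random_intercept <- function(diffs, conf_level = 0.95) {
  stopifnot(all(c("individual_id", "diff") %in% names(diffs)))
  ids <- unique(diffs$individual_id)
  if (length(ids) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (any(table(diffs$individual_id) < 2)) {
    stop("need at least 2 differences per individual", call. = FALSE)
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit <- suppressMessages(lme4::lmer(
    diff ~ 1 + (1 | individual_id), data = diffs, REML = TRUE
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- vc$sdcor[vc$grp == "individual_id"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  mu <- unname(lme4::fixef(fit)[1])
  var_mu <- as.numeric(stats::vcov(fit))
  pooled <- lme4::isSingular(fit, tol = 1e-5) || sigma_b < 1e-8
  if (pooled) {
    est <- tibble::tibble(
      individual_id = ids,
      pred_change = mu,
      ci_lo = mu - zq * sqrt(var_mu),
      ci_hi = mu + zq * sqrt(var_mu)
    )
  } else {
    re <- lme4::ranef(fit, condVar = TRUE)$individual_id
    pv <- as.numeric(attr(re, "postVar"))
    b <- re[ids, 1]
    pv <- pv[match(ids, rownames(re))]
    # prediction-error variance of mu + b_i: the conditional variance of
    # b_i plus the fixed-intercept variance damped by the shrinkage
    # weight (the errors of mu-hat and b-hat cancel as shrinkage -> 1,
    # so the width collapses to the conditional part when sigma_e -> 0)
    n_i <- as.numeric(table(diffs$individual_id)[ids])
    s_i <- sigma_b^2 / (sigma_b^2 + sigma_e^2 / n_i)
    se <- sqrt(pv + (1 - s_i)^2 * var_mu)
    est <- tibble::tibble(
      individual_id = ids,
      pred_change = mu + b,
      ci_lo = mu + b - zq * se,
      ci_hi = mu + b + zq * se
    )
  }
  est$significant <- est$ci_lo > 0 | est$ci_hi < 0
  structure(
    list(estimates = est, mu = mu, sigma_b = sigma_b, sigma_e = sigma_e,
         pooled = pooled, conf_level = conf_level, model = fit),
    class = "change_fit"
  )
}

#' @export
print.change_fit <- function(x, ...) {
  cat(sprintf(
    "random-intercept change fit: mu = %.4g, sigma_b = %.4g, sigma_e = %.4g%s\n",
    x$mu, x$sigma_b, x$sigma_e,
    if (x$pooled) " (boundary fit: pooled intercept)" else ""))
  print(x$estimates)
  invisible(x)
}

#' Summarize per-individual changes across parameters
#'
#' For each fitted parameter, counts the individuals with a significant
#' decrease, no significant change, and a significant increase.
#'
#' @param fits named list of [fit_random_intercept()] objects, one per
#'   parameter.
#' @return tibble: `parameter`, `n_individuals`, `n_decrease`,
#'   `n_no_change`, `n_increase`.
#' @export
summarize_changes <- function(fits) {
  out <- lapply(names(fits), function(p) {
    est <- fits[[p]]$estimates
    tibble::tibble(
      parameter = p,
      n_individuals = nrow(est),
      n_decrease = sum(est$significant & est$pred_change < 0),
      n_no_change = sum(!est$significant),
      n_increase = sum(est$significant & est$pred_change > 0)
    )
  })
  dplyr::bind_rows(out)
}

#' Forest-style plot of per-individual predicted changes
#'
#' @param fit a [fit_random_intercept()] object.
#' @param title optional plot title (typically the parameter name).
#' @return a ggplot object.
#' @export
plot_change_estimates <- function(fit, title = NULL) {
  est <- fit$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$individual_id,
                                    y = .data$pred_change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi,
                                          colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "predicted change (festival - pre)",
                  title = title) +
    ggplot2::theme_minimal()
}
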