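#' Compare an ROI-level characteristic across biological conditions
#'
#' Fits a random-intercept mixed-effects model treating the image
#' position (technical replicate) as a random effect and the biological
#' condition as a fixed effect: a linear mixed model (`lme4::lmer`) for
#' continuous outcomes, or a Poisson log-link generalized linear mixed
#' model (`lme4::glmer`, Laplace approximation) for count outcomes.
#' Pairwise condition contrasts are reported with Wald 95% confidence
#' intervals and p-values; the first included condition is the reference.
#' The study design assumes a single biological replicate per condition,
#' with images/positions as technical replicates.
#'
#' @param data data frame of ROI-level rows (e.g. a [measure_rois()] table
#'   with a condition column, or any tidy table).
#' @param y_var name of the outcome column.
#' @param cond_var name of the condition column.
#' @param subsamp_var name of the image/position (technical replicate)
#'   column.
#' @param cond_inc conditions to include, in order (first = reference);
#'   defaults to all observed conditions in order of appearance.
#' @param trans_name transformation applied to the outcome before
#'   modeling: `"identity"` or `"log"` (log requires positive values).
#' @param y_count `TRUE` to force the Poisson count model, `FALSE` to force
#'   the linear model; by default counts are auto-detected (non-negative
#'   integer outcome on the identity scale).
#' @param conf_level confidence level for the Wald intervals.
#' @return An object of class `condition_comparison` with elements
#'   `model_kind`, `model` (the lme4 fit), `contrasts` (tibble of pairwise
#'   estimates, intervals and p-values), `narrative` (plain-text summary),
#'   `data` and `spec` (echo of the inputs). Use [tidy()] / [glance()] for
#'   tabular access.
#' @export
#' @examples
#' d <- data.frame(
#'   y = rnorm(40, rep(c(0, 1), each = 20)),
#'   cond = rep(c("wt", "mut"), each = 20),
#'   img = rep(sprintf("pos%d", 1:8), each = 5)
#' )
#' cmp <- compare_conditions(d, "y", "cond", "img")
#' tidy(cmp)
compare_conditions <- function(data, y_var, cond_var, subsamp_var,
                               cond_inc = NULL,
                               trans_name = c("identity", "log"),
                               y_count = NULL, conf_level = 0.95) {
  trans_name <- match.arg(trans_name)
  for (v in c(y_var, cond_var, subsamp_var)) {
    if (!v %in% names(data)) {
      stop("column '", v, "' not found in data", call. = FALSE)
    }
  }
  cond_obs <- unique(as.character(data[[cond_var]]))
  cond_inc <- cond_inc %||% cond_obs
  if (!all(cond_inc %in% cond_obs)) {
    stop("cond_inc contains conditions absent from the data: ",
         paste(setdiff(cond_inc, cond_obs), collapse = ", "), call. = FALSE)
  }
  d <- data[as.character(data[[cond_var]]) %in% cond_inc, , drop = FALSE]
  y <- d[[y_var]]
  if (!all(is.finite(y))) stop("outcome contains non-finite values", call. = FALSE)
  if (length(cond_inc) < 2L) {
    stop("at least 2 conditions are required for a comparison", call. = FALSE)
  }
  is_count <- is_count_vector(y)
  if (is.null(y_count)) {
    y_count <- is_count && trans_name == "identity"
  } else if (isTRUE(y_count) && !is_count) {
    stop("y_count = TRUE but the outcome is not a non-negative integer variable",
         call. = FALSE)
  }
  if (trans_name == "log") {
    if (any(y <= 0)) {
      stop("log transformation requires strictly positive outcome values",
           call. = FALSE)
    }
    y <- log(y)
  }
  df <- data.frame(
    .y = y,
    .cond = factor(as.character(d[[cond_var]]), levels = cond_inc),
    .sub = factor(as.character(d[[subsamp_var]])))
  # with one observation per subsample the random intercept is confounded
  # with the residual; the model then reduces to the fixed-effects fit on
  # the (trivial) position means
  degenerate <- nlevels(df$.sub) >= nrow(df)
  if (y_count) {
    model_kind <- "poisson-log-link-mixed"
    fit <- if (degenerate) {
      stats::glm(.y ~ .cond, data = df, family = stats::poisson)
    } else {
      lme4::glmer(.y ~ .cond + (1 | .sub), data = df, family = stats::poisson)
    }
  } else {
    model_kind <- "linear-mixed"
    fit <- if (degenerate) {
      stats::lm(.y ~ .cond, data = df)
    } else {
      lme4::lmer(.y ~ .cond + (1 | .sub), data = df)
    }
  }
  # reference distribution for the Wald statistics: a t with
  # between-cluster degrees of freedom for the linear mixed model (guards
  # against anti-conservative normal quantiles with few positions), the
  # asymptotic normal for the Poisson GLMM
  wald_df <- if (degenerate) {
    stats::df.residual(fit)
  } else if (y_count) Inf else nlevels(df$.sub) - length(cond_inc)
  contrasts <- wald_pairwise_contrasts(fit, cond_inc, conf_level, wald_df)
  spec <- list(y_var = y_var, cond_var = cond_var, subsamp_var = subsamp_var,
               cond_inc = cond_inc, trans_name = trans_name,
               y_count = y_count, conf_level = conf_level,
               approximation = if (degenerate) {
                 "single observation per subsample: fixed-effects fit"
               } else if (y_count) "Laplace (glmer, nAGQ = 1)" else "REML (lmer)")
  narrative <- comparison_narrative(y_var, model_kind, trans_name, contrasts,
                                    conf_level, df)
  structure(list(model_kind = model_kind, model = fit, contrasts = contrasts,
                 narrative = narrative, data = d, spec = spec),
            class = "condition_comparison")
}

# all pairwise condition differences on the model's link/response scale,
# Wald z intervals from the fixed-effects covariance
wald_pairwise_contrasts <- function(fit, cond_levels, conf_level, df = Inf) {
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  k <- length(cond_levels)
  df <- max(df, 1)
  zq <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  # coefficient vector per condition: reference has no dummy
  coef_of <- function(i) {
    v <- numeric(length(beta))
    if (i > 1L) {
      nm <- paste0(".cond", cond_levels[i])
      v[match(nm, names(beta))] <- 1
    }
    v
  }
  rows <- list()
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      L <- coef_of(j) - coef_of(i)
      est <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% V %*% L))
      z <- est / se
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contrast = paste(cond_levels[j], "-", cond_levels[i]),
        estimate = est, std_error = se,
        conf_low = est - zq * se, conf_high = est + zq * se,
        statistic = z, df = df, p_value = 2 * stats::pt(-abs(z), df = df))
    }
  }
  dplyr::bind_rows(rows)
}

comparison_narrative <- function(y_var, model_kind, trans_name, contrasts,
                                 conf_level, df) {
  scale_txt <- if (model_kind == "poisson-log-link-mixed") {
    "log rate ratio"
  } else if (trans_name == "log") "log-scale difference" else "difference"
  lines <- sprintf(
    paste("'%s' was compared across %d conditions (%d ROIs in %d",
          "image positions) with a %s model treating the image position as",
          "a random intercept."),
    y_var, nlevels(df$.cond), nrow(df), nlevels(df$.sub),
    if (model_kind == "poisson-log-link-mixed") {
      "Poisson log-link mixed-effects"
    } else "linear mixed-effects")
  per <- vapply(seq_len(nrow(contrasts)), function(i) {
    with(contrasts[i, ], sprintf(
      "%s: %s %.4g (%.0f%% CI %.4g to %.4g, p = %.3g)%s",
      contrast, scale_txt, estimate, conf_level * 100, conf_low, conf_high,
      p_value,
      if (p_value < 0.05) " - statistically significant at the 0.05 level" else ""))
  }, character(1))
  paste(c(lines, per), collapse = "\n")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>", x$model_kind, "\n\n")
  cat(x$narrative, "\n")
  invisible(x)
}

#' Tidy the pairwise contrasts of a condition comparison
#'
#' @param x a `condition_comparison` from [compare_conditions()].
#' @param ... unused.
#' @return Tibble of pairwise contrasts with estimates, Wald confidence
#'   intervals and p-values.
#' @export
tidy.condition_comparison <- function(x, ...) x$contrasts

#' One-row model summary of a condition comparison
#'
#' @param x a `condition_comparison` from [compare_conditions()].
#' @param ... unused.
#' @return One-row tibble with the model kind, group counts, and fit
#'   statistics.
#' @export
glance.condition_comparison <- function(x, ...) {
  ll <- stats::logLik(x$model)
  tibble::tibble(
    model_kind = x$model_kind,
    n_obs = nrow(x$data),
    n_conditions = length(x$spec$cond_inc),
    n_subsamples = length(unique(x$data[[x$spec$subsamp_var]])),
    logLik = as.numeric(ll),
    AIC = stats::AIC(x$model))
}
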