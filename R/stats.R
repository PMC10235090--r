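#' @title Treatment comparison and correlation layer
#'
#' @description
#' Mixed-effects treatment comparisons on the tidy per-trial metrics
#' table: a full model with treatment as fixed effect and male, plant,
#' repetition and operator random intercepts is reduced by stepwise
#' backward elimination on AIC, then estimated marginal means are compared
#' pairwise with the Tukey method and summarized as a compact letter
#' display. Pearson and repeated-measures (within-subject, ANCOVA-based)
#' correlations complete the layer.
#'
#' @name stats_layer
NULL

.DEFAULT_RANDOM <- c("male_id", "plant_id", "repetition", "operator")

.rand_formula <- function(response, random) {
  rhs <- paste(c("treatment",
                 if (length(random)) paste0("(1 | ", random, ")")),
               collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

.fit_one <- function(response, random, data, family) {
  f <- .rand_formula(response, random)
  if (length(random)) {
    if (family == "gaussian")
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = data, REML = TRUE)))
    else
      suppressMessages(suppressWarnings(
        lme4::glmer(f, data = data, family = stats::binomial())))
  } else {
    if (family == "gaussian") stats::lm(f, data = data)
    else stats::glm(f, data = data, family = stats::binomial())
  }
}

# AIC for the elimination path. The candidate models share their fixed
# effects and differ only in random intercepts, so Gaussian models are
# compared on the REML criterion (including the lm endpoint, via its
# REML-type log-likelihood); binomial models use the ML deviance.
.model_aic <- function(m) {
  if (inherits(m, "lm") && !inherits(m, "glm")) {
    ll <- stats::logLik(m, REML = TRUE)
    -2 * as.numeric(ll) + 2 * attr(ll, "df")
  } else {
    stats::AIC(m)
  }
}

#' Fit the treatment model and compute Tukey contrasts
#'
#' @param table tidy metrics data.frame (one row per trial) with a
#'   `treatment` column, the response column, and the candidate grouping
#'   columns.
#' @param response name of the response column. For `family = "binomial"`
#'   it must be logical or 0/1.
#' @param family `"gaussian"` or `"binomial"`.
#' @param random candidate random-intercept terms (default male, plant,
#'   repetition, operator; only those present in `table` are used).
#' @param alpha significance level for the letter display.
#' @return object of class `vib_contrast`: chosen model, AIC elimination
#'   path, estimated marginal means, Tukey-adjusted pairwise contrasts and
#'   the compact letter display.
#' @export
fit_and_contrast <- function(table, response, family = c("gaussian", "binomial"),
                             random = .DEFAULT_RANDOM, alpha = 0.05) {
  family <- match.arg(family)
  if (!response %in% names(table)) stop("no such response column: ", response)
  keep_cols <- c(response, "treatment", intersect(random, names(table)))
  data <- table[stats::complete.cases(table[keep_cols]), keep_cols,
                drop = FALSE]
  data$treatment <- factor(data$treatment)
  if (nlevels(data$treatment) < 2)
    stop("need at least 2 treatment levels")
  if (any(stats::xtabs(~treatment, data) < 2))
    stop("need at least 2 observations per treatment")
  random <- intersect(random, names(table))
  for (r in random) data[[r]] <- factor(data[[r]])
  if (family == "binomial") data[[response]] <- as.integer(data[[response]])

  # backward elimination: drop the random term whose removal most improves
  # AIC; stop when no removal improves
  current <- random
  model <- .fit_one(response, current, data, family)
  path <- data.frame(terms = paste(current, collapse = "+"),
                     AIC = .model_aic(model), stringsAsFactors = FALSE)
  repeat {
    if (!length(current)) break
    cand <- lapply(seq_along(current), function(k)
      .fit_one(response, current[-k], data, family))
    aics <- vapply(cand, .model_aic, numeric(1))
    best <- which.min(aics)
    if (aics[best] < .model_aic(model)) {
      current <- current[-best]
      model <- cand[[best]]
      path <- rbind(path, data.frame(terms = paste(current, collapse = "+"),
                                     AIC = aics[best]))
    } else break
  }

  emm <- emmeans::emmeans(model, "treatment")
  emm_df <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  lev <- levels(data$treatment)
  pmat <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
  for (k in seq_len(nrow(prs))) {
    ij <- strsplit(prs$contrast[k], " - ", fixed = TRUE)[[1]]
    ij <- gsub("^\\(|\\)$", "", ij)
    pmat[ij[1], ij[2]] <- pmat[ij[2], ij[1]] <- prs$p.value[k]
  }
  letters <- .cld_letters(pmat, alpha = alpha,
                          means = stats::setNames(emm_df$emmean,
                                                  emm_df$treatment))
  structure(list(model = model, response = response, family = family,
                 random_terms = current, aic_path = path,
                 emmeans = emm_df, contrasts = prs, p_matrix = pmat,
                 letters = letters, alpha = alpha),
            class = "vib_contrast")
}

# compact letter display by insert-and-absorb on the non-significance graph
.cld_letters <- function(pmat, alpha = 0.05, means = NULL) {
  lev <- rownames(pmat)
  k <- length(lev)
  sets <- list(seq_len(k))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      new <- list()
      for (s in sets) {
        if (all(c(i, j) %in% s)) new <- c(new, list(setdiff(s, i)),
                                          list(setdiff(s, j)))
        else new <- c(new, list(s))
      }
      new <- new[lengths(new) > 0]
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new))
      for (a in seq_along(new)) {
        for (b in seq_along(new)) {
          if (a == b || !keep[a]) next
          if (all(new[[a]] %in% new[[b]]) &&
              (length(new[[a]]) < length(new[[b]]) || a > b)) keep[a] <- FALSE
        }
      }
      sets <- unique(new[keep])
    }
  }
  ord <- if (is.null(means)) seq_len(k) else order(means[lev])
  rank_of <- function(s) min(match(s, ord))
  sets <- sets[order(vapply(sets, rank_of, numeric(1)))]
  out <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = ""), character(1))
  stats::setNames(out, lev)
}

#' @export
print.vib_contrast <- function(x, ...) {
  cat("Treatment comparison for '", x$response, "' (", x$family, ")\n",
      sep = "")
  cat("Random intercepts kept by AIC: ",
      if (length(x$random_terms)) paste(x$random_terms, collapse = ", ")
      else "(none)", "\n", sep = "")
  em <- x$emmeans
  em$.group <- x$letters[as.character(em$treatment)]
  print(em, digits = 4)
  cat("\nTukey-adjusted pairwise contrasts:\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (n >= 3 complete pairs).
#' @return list with `r`, `df` (n - 2), `p` (two-sided) and `ci` (95%).
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, df = length(x) - 2L, p = NA_real_,
                ci = c(NA_real_, NA_real_)))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, ci = as.numeric(ct$conf.int))
}

#' Repeated-measures (within-subject) correlation
#'
#' The common within-subject correlation from the ANCOVA decomposition:
#' `y` is regressed on subject indicators plus `x`; the correlation is
#' `sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = N_obs - n_subjects - 1`, a two-sided t test on that df, and a 95%
#' CI from the Fisher z transform with standard error `1/sqrt(df - 1)`.
#' Between-subject offsets in `y` do not affect the estimate.
#'
#' @param subject subject identifiers.
#' @param x,y numeric vectors parallel to `subject`.
#' @return list with `r`, `df`, `p`, `ci` and `n_subjects`.
#' @export
rm_corr <- function(subject, x, y) {
  ok <- stats::complete.cases(subject, x, y)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  xvar <- tapply(x, subject, function(v) length(v) >= 2 && stats::sd(v) > 0)
  informative <- names(xvar)[xvar]
  if (!length(informative))
    stop("no subject has within-subject variation in x")
  keep <- subject %in% informative
  subject <- droplevels(subject[keep]); x <- x[keep]; y <- y[keep]
  if (nlevels(subject) < 2) stop("need at least 2 informative subjects")

  fit <- stats::lm(y ~ subject + x)
  an <- suppressWarnings(stats::anova(fit))
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_err))
  df <- length(y) - nlevels(subject) - 1L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(r)
  se <- 1 / sqrt(df - 1)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, df = df, p = p, ci = ci, n_subjects = nlevels(subject))
}
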