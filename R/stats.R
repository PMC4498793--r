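FIXED_VOCAB <- c("hemisphere", "lobe", "class_total", "class_cogm",
                 "pma_at_scan", "interval", "fissure_width",
                 "hemisphere:lobe")

#' Specify a mixed model for a descriptor
#'
#' @param response descriptor name (must be present in the table).
#' @param fixed character vector of fixed terms from the vocabulary
#'   `hemisphere`, `lobe`, `class_total`, `class_cogm`, `pma_at_scan`,
#'   `interval`, `fissure_width`, and the `hemisphere:lobe` interaction.
#' @param random_intercept include a per-subject random intercept.
#' @return a `model_spec`.
#' @export
model_spec <- function(response, fixed = character(),
                       random_intercept = TRUE) {
  bad <- setdiff(fixed, FIXED_VOCAB)
  if (length(bad)) stop("unknown model term(s): ", paste(bad, collapse = ", "),
                        " (vocabulary: ", paste(FIXED_VOCAB, collapse = ", "), ")")
  structure(list(response = response, fixed = fixed,
                 random_intercept = isTRUE(random_intercept)),
            class = "model_spec")
}

#' Join descriptor records to covariates for modelling
#'
#' Adds `hemisphere` (reference level L) and `lobe` factors derived from
#' the region code, the PMA at the row's scan, and all covariate columns.
#'
#' @param descriptors long descriptor table.
#' @param covariates covariate table (see [read_covariate_csv()]).
#' @return modelling data.frame.
#' @export
join_covariates <- function(descriptors, covariates) {
  covariates <- validate_covariates(covariates)
  x <- merge(descriptors, covariates, by = "subject_id")
  hemi <- ifelse(x$region %in% c("R", "FR", "TR", "PR", "OR"), "R",
                 ifelse(x$region %in% c("L", "FL", "TL", "PL", "OL"), "L", NA))
  x$hemisphere <- factor(hemi, levels = c("L", "R"))
  lobe <- ifelse(nchar(x$region) == 2, substr(x$region, 1, 1), NA)
  x$lobe <- factor(lobe, levels = c("F", "T", "P", "O"))
  x$pma_at_scan <- ifelse(x$timepoint < 35, x$pma_30, x$pma_40)
  x
}

#' Fit a linear mixed model for one descriptor
#'
#' Restricted-maximum-likelihood fit with a per-subject random intercept
#' (lme4); effects are reported relative to the reference levels (class
#' `normal`, hemisphere `L`). Fixed-effect p-values are Wald z. When any
#' included subject contributes fewer than 2 observations the random
#' intercept is not identifiable and the fit silently downgrades to a
#' fixed-effects linear model (flagged in the result). Rank-deficient
#' designs are refused, naming the aliased columns.
#'
#' @param data modelling data.frame from [join_covariates()] (long rows;
#'   the `descriptor` column is filtered to the response).
#' @param spec a [model_spec()].
#' @param reml use REML (TRUE, default) or ML (for AIC comparison).
#' @return a `model_fit`: coefficient table (term, estimate, se, z, p),
#'   AIC (of an ML refit, comparable across fixed structures), engine used,
#'   convergence flag, and the fitted object.
#' @export
fit_lmm <- function(data, spec, reml = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  df <- data[data$descriptor == spec$response & !is.na(data$value), ]
  if (!nrow(df)) stop("no rows for response ", spec$response)
  df <- droplevels(df)
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fixed_formula <- as.formula(paste("value ~", rhs))
  mm <- model.matrix(fixed_formula, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  use_lmm <- spec$random_intercept
  if (use_lmm) {
    nobs <- table(df$subject_id[df$subject_id %in% unique(df$subject_id)])
    if (min(nobs) < 2) {
      message("random intercept not identifiable (a subject has < 2 observations); downgrading to a fixed-effects fit")
      use_lmm <- FALSE
    }
  }
  converged <- TRUE
  if (use_lmm) {
    fml <- as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = df, REML = reml),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w))) converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    aic_ml <- AIC(update(fit, REML = FALSE))
    engine <- "lmer"
  } else {
    fit <- lm(fixed_formula, data = df)
    sm <- summary(fit)$coefficients[, 1:2, drop = FALSE]
    aic_ml <- AIC(fit)
    engine <- "lm"
  }
  est <- sm[, 1]; se <- sm[, 2]
  z <- est / se
  coefs <- data.frame(term = rownames(sm), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * pnorm(-abs(unname(z))),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, aic = aic_ml, engine = engine,
                 converged = converged, n = nrow(df),
                 n_subjects = length(unique(df$subject_id)),
                 spec = spec, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s%s): %s ~ %s, n=%d (%d subjects), AIC(ML)=%.1f\n",
              x$engine, if (!x$converged) ", NOT converged" else "",
              x$spec$response,
              if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ") else "1",
              x$n, x$n_subjects, x$aic))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' AIC model selection among candidate specifications
#'
#' Fits every candidate by maximum likelihood (REML is not comparable
#' across fixed structures) and returns the candidate with the lowest AIC;
#' ties are broken toward fewer parameters. Candidates that fail to
#' converge are excluded (with a message).
#'
#' @param data modelling data.frame.
#' @param candidates list of [model_spec()]s with a common response.
#' @return list: `best` (the winning spec), `aic` (data.frame of all
#'   candidates), `fits`.
#' @export
select_model_aic <- function(data, candidates) {
  stopifnot(length(candidates) >= 1)
  resp <- unique(vapply(candidates, function(s) s$response, ""))
  if (length(resp) != 1) stop("all candidates must share one response")
  if (length(candidates) == 1L)
    return(list(best = candidates[[1]], aic = NULL, fits = NULL))
  fits <- lapply(candidates, function(s) {
    tryCatch(fit_lmm(data, s, reml = FALSE), error = function(e) e)
  })
  rows <- lapply(seq_along(candidates), function(i) {
    f <- fits[[i]]
    ok <- inherits(f, "model_fit") && f$converged
    if (!ok) message("candidate ", i, " excluded (",
                     if (inherits(f, "model_fit")) "did not converge"
                     else conditionMessage(f), ")")
    data.frame(candidate = i,
               fixed = paste(candidates[[i]]$fixed, collapse = " + "),
               npar = if (ok) attr(stats::logLik(f$fit), "df") else NA,
               aic = if (ok) f$aic else NA_real_)
  })
  tab <- do.call(rbind, rows)
  usable <- which(!is.na(tab$aic))
  if (!length(usable)) stop("no candidate converged")
  ord <- usable[order(tab$aic[usable] + 1e-9 * tab$npar[usable])]
  list(best = candidates[[ord[1]]], aic = tab, fits = fits)
}

#' Spearman rank correlation
#'
#' Mid-rank (tie-averaged) Spearman rho with a two-sided p-value from the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom.
#'
#' @param x,y paired numeric vectors, `n >= 3` complete pairs.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (is.na(rho)) stop("rank correlation undefined (constant input)")
  p <- if (abs(rho) >= 1 - 1e-12) 0
       else 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  list(rho = rho, p = p, n = n)
}

#' Abnormality-class effect table
#'
#' For each requested descriptor, fits the random-intercept mixed model
#' `value ~ class + (1 | subject)` on the regional rows of one timepoint
#' and reports the estimated effect of each non-reference class (mild,
#' moderate and severe combined) relative to the normal class, with Wald-z
#' p-values; alpha = 0.05 with no multiplicity correction by default
#' (`p_adjust = "holm"` is available). Descriptors in which no class shows
#' a significant effect are flagged (`any_significant = FALSE`) rather
#' than dropped.
#'
#' @param descriptors long descriptor table.
#' @param covariates covariate table.
#' @param responses descriptors to test.
#' @param timepoint which scan's rows to use (matched within +-2 weeks).
#' @param class_var `"class_cogm"` or `"class_total"`.
#' @param alpha significance level.
#' @param p_adjust `"none"` (default) or a method of [stats::p.adjust()].
#' @return data.frame: descriptor, class, estimate, se, p, significant,
#'   any_significant.
#' @export
class_effect_table <- function(descriptors, covariates,
                               responses = c("T_median", "A_inner", "GI",
                                             "C_global"),
                               timepoint = 41, class_var = "class_cogm",
                               alpha = 0.05, p_adjust = "none") {
  stopifnot(class_var %in% c("class_cogm", "class_total"))
  data <- join_covariates(descriptors, covariates)
  data <- data[abs(data$timepoint - timepoint) <= 2, ]
  out <- list()
  for (resp in responses) {
    fit <- fit_lmm(data, model_spec(resp, fixed = class_var))
    cf <- fit$coefficients
    sel <- grepl(paste0("^", class_var), cf$term)
    cls <- sub(paste0("^", class_var), "", cf$term[sel])
    out[[resp]] <- data.frame(descriptor = resp, class = cls,
                              estimate = cf$estimate[sel], se = cf$se[sel],
                              p = cf$p[sel], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (p_adjust != "none") tab$p <- stats::p.adjust(tab$p, method = p_adjust)
  tab$significant <- tab$p < alpha
  any_sig <- tapply(tab$significant, tab$descriptor, any)
  tab$any_significant <- unname(any_sig[tab$descriptor])
  tab
}
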