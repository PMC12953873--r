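#' Paired t-test on block-by-voice mean accuracies
#'
#' Collapses piece-level accuracy records to one mean per block x voice x
#' condition, pairs the two requested conditions within each block x
#' voice cell (32 pairs for the default design), and runs a two-sided
#' paired t-test with Cohen's d for paired data
#' (`mean(diff) / sd(diff)`) and its 95% CI.
#'
#' @param piece_table piece-level accuracy table (see
#'   [compute_accuracy()]).
#' @param measure response column, `"LMOE"` or `"LMAPE"`.
#' @param conditions length-2 character vector; differences are
#'   `conditions[1] - conditions[2]`.
#' @return list: `t`, `df`, `p`, `d`, `ci_d`, `n_pairs`, `mean_diff`.
#' @export
paired_accuracy_ttest <- function(piece_table, measure = "LMOE",
                                  conditions = c("touch", "no_touch")) {
  stopifnot(length(conditions) == 2, measure %in% names(piece_table))
  tab <- piece_table[piece_table$condition %in% conditions &
                       !is.na(piece_table[[measure]]), ]
  agg <- stats::aggregate(tab[[measure]],
                          by = list(block = tab$block, voice = tab$voice,
                                    condition = tab$condition),
                          FUN = mean)
  names(agg)[4] <- "value"
  a <- agg[agg$condition == conditions[1], ]
  b <- agg[agg$condition == conditions[2], ]
  key_a <- paste(a$block, a$voice)
  key_b <- paste(b$block, b$voice)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    miss <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("unpaired block x voice cell(s): ", paste(miss, collapse = ", "))
  }
  d_vec <- a$value - b$value[match(key_a, key_b)]
  n <- length(d_vec)
  if (stats::sd(d_vec) == 0) {
    if (all(d_vec == 0))  # identical conditions: no effect, by definition
      return(list(t = 0, df = n - 1, p = 1, d = 0, ci_d = c(0, 0),
                  n_pairs = n, mean_diff = 0))
    stop("constant non-zero paired differences; t statistic degenerate")
  }
  tt <- stats::t.test(d_vec)
  d <- mean(d_vec) / stats::sd(d_vec)
  se_d <- sqrt(1 / n + d^2 / (2 * n))
  crit <- stats::qt(0.975, n - 1)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, ci_d = c(d - crit * se_d, d + crit * se_d),
       n_pairs = n, mean_diff = mean(d_vec))
}

# Diagnostics for a merMod fit.
fit_flags <- function(fit) {
  if (!inherits(fit, "merMod"))
    return(list(converged = TRUE, singular = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  list(converged = is.null(msgs) ||
         !any(grepl("failed to converge", msgs, ignore.case = TRUE)),
       singular = lme4::isSingular(fit, tol = 1e-4))
}

# Fixed-term summary row (beta, SE, CI, t, p) from a lmerTest or lm fit.
extract_term <- function(fit, term) {
  co <- stats::coef(summary(fit))
  if (!term %in% rownames(co)) stop("term '", term, "' not in the fit")
  row <- co[term, ]
  if (inherits(fit, "merMod")) {
    beta <- row[["Estimate"]]; se <- row[["Std. Error"]]
    df <- if ("df" %in% names(row)) row[["df"]] else Inf
    tval <- row[["t value"]]
    p <- if ("Pr(>|t|)" %in% names(row)) row[["Pr(>|t|)"]] else
      2 * stats::pnorm(-abs(tval))
  } else {
    beta <- row[["Estimate"]]; se <- row[["Std. Error"]]
    df <- fit$df.residual
    tval <- row[["t value"]]; p <- row[["Pr(>|t|)"]]
  }
  crit <- stats::qt(0.975, df)
  list(beta = unname(beta), se = unname(se),
       ci = c(unname(beta - crit * se), unname(beta + crit * se)),
       t = unname(tval), p = unname(p), df = unname(df))
}

#' Mixed-effects condition-contrast model
#'
#' Fits `measure ~ condition_c + (1 | voice) + (1 | piece)` on the
#' piece-level table restricted to two conditions, with the contrast coded
#' +0.5 for `conditions[1]` and -0.5 for `conditions[2]`, so the contrast
#' beta is the `conditions[1] - conditions[2]` difference. Significance is
#' reported both by the `|t| > 2` convention and by a
#' Satterthwaite-approximation p-value. Non-convergence is flagged, not
#' raised.
#'
#' @inheritParams paired_accuracy_ttest
#' @return A `fit_result` list: `fit`, `formula`, `term` (beta, se, ci, t,
#'   p, df), `significant_t2`, `converged`, `singular`, `n_obs`,
#'   `log_lik`.
#' @export
fit_contrast_model <- function(piece_table, measure = "LMOE",
                               conditions = c("touch", "no_touch")) {
  stopifnot(length(conditions) == 2)
  dat <- piece_table[piece_table$condition %in% conditions &
                       !is.na(piece_table[[measure]]), ]
  dat$y <- dat[[measure]]
  if (stats::sd(dat$y) == 0) stop("response has zero variance")
  dat$condition_c <- ifelse(dat$condition == conditions[1], 0.5, -0.5)
  form <- y ~ condition_c + (1 | voice) + (1 | piece)
  # optimizer grievances are surfaced through the convergence flag instead
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = dat,
                   control = lme4::lmerControl(calc.derivs = TRUE))))
  flags <- fit_flags(fit)
  term <- extract_term(fit, "condition_c")
  structure(list(fit = fit, formula = deparse(form), term = term,
                 significant_t2 = abs(term$t) > 2,
                 converged = flags$converged, singular = flags$singular,
                 n_obs = nrow(dat), log_lik = as.numeric(stats::logLik(fit))),
            class = "fit_result")
}

# Random-effects structure as a list of list(group, slope) terms.
# Builds the lme4 formula "y ~ x + (1 + x | g1) + (1 | g2) ...".
re_formula <- function(response, predictor, re_terms) {
  re <- vapply(re_terms, function(tm)
    sprintf("(1%s | %s)", if (tm$slope) paste0(" + ", predictor) else "",
            tm$group), character(1))
  rhs <- paste(c(predictor, re), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

fit_one <- function(response, predictor, re_terms, data) {
  if (length(re_terms) == 0) {
    fit <- stats::lm(stats::as.formula(paste(response, "~", predictor)),
                     data = data)
    return(list(fit = fit, formula = paste(response, "~", predictor),
                npar = length(stats::coef(fit)) + 1L))
  }
  form <- re_formula(response, predictor, re_terms)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = data, REML = FALSE)))
  list(fit = fit, formula = paste(deparse(form), collapse = ""),
       npar = length(unlist(lme4::getME(fit, c("theta", "beta")))) + 1L)
}

# Candidate one-step reductions: a random slope collapses to an intercept,
# an intercept-only term is dropped.
reduce_candidates <- function(re_terms) {
  out <- list()
  for (i in seq_along(re_terms)) {
    cand <- re_terms
    if (cand[[i]]$slope) cand[[i]]$slope <- FALSE else cand[[i]] <- NULL
    out[[length(out) + 1]] <- cand
  }
  out
}

#' Mixed-effects prediction of accuracy from respiration coupling
#'
#' Starts from the stated maximal-feasible model -- for timing
#' (`response = "LMOE"`):
#' `LMOE ~ x + (1 | voice) + (1 + x | block) + (1 + x | condition)`,
#' for intonation (`"LMAPE"`):
#' `LMAPE ~ x + (1 + x | voice) + (1 + x | block) + (1 | condition)` --
#' and reduces the random-effects structure by likelihood-ratio tests
#' (ML fits), accepting at each step the reduction with the largest LRT
#' p-value while it exceeds `alpha`; singular or non-convergent fits are
#' reduced regardless. Returns the best fitting model with the fewest
#' parameters and the full reduction trace.
#'
#' @param unit_table recording-unit-level analysis table containing the
#'   response, the coupling predictor, and `voice`, `block`, `condition`.
#' @param response `"LMOE"` or `"LMAPE"`.
#' @param index name of the coupling predictor column (e.g. `"aci"`).
#' @param alpha LRT retention threshold for model reduction.
#' @return A `fit_result` list: `fit`, `formula`, `term`, `trace`
#'   (data.frame of reduction steps), `converged`, `singular`, `n_obs`.
#' @export
fit_prediction_model <- function(unit_table, response = c("LMOE", "LMAPE"),
                                 index = "aci", alpha = 0.05) {
  response <- match.arg(response)
  stopifnot(index %in% names(unit_table),
            all(c("voice", "block", "condition") %in% names(unit_table)))
  dat <- unit_table[!is.na(unit_table[[response]]) &
                      !is.na(unit_table[[index]]), ]
  dat$block <- factor(dat$block)
  dat$voice <- factor(dat$voice)
  dat$condition <- factor(dat$condition)
  re_terms <- if (response == "LMOE") {
    list(list(group = "voice", slope = FALSE),
         list(group = "block", slope = TRUE),
         list(group = "condition", slope = TRUE))
  } else {
    list(list(group = "voice", slope = TRUE),
         list(group = "block", slope = TRUE),
         list(group = "condition", slope = FALSE))
  }
  # a grouping factor needs at least two levels to carry a random effect
  re_terms <- Filter(function(tm) nlevels(dat[[tm$group]]) >= 2, re_terms)
  current <- fit_one(response, index, re_terms, dat)
  flags <- fit_flags(current$fit)
  trace <- data.frame(step = 0L, formula = current$formula,
                      npar = current$npar,
                      log_lik = as.numeric(stats::logLik(current$fit)),
                      lrt_p = NA_real_, singular = flags$singular,
                      accepted = TRUE, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cands <- reduce_candidates(re_terms)
    if (length(cands) == 0) break
    fits <- lapply(cands, function(ct) fit_one(response, index, ct, dat))
    lrt_p <- vapply(fits, function(f) {
      ll0 <- as.numeric(stats::logLik(f$fit))
      ll1 <- as.numeric(stats::logLik(current$fit))
      dfd <- current$npar - f$npar
      if (dfd <= 0) return(1)
      stats::pchisq(2 * pmax(ll1 - ll0, 0), df = dfd, lower.tail = FALSE)
    }, numeric(1))
    best <- which.max(lrt_p)
    must_reduce <- flags$singular || !flags$converged
    accept <- lrt_p[best] > alpha || must_reduce
    step <- step + 1L
    bf <- fit_flags(fits[[best]]$fit)
    trace <- rbind(trace, data.frame(
      step = step, formula = fits[[best]]$formula, npar = fits[[best]]$npar,
      log_lik = as.numeric(stats::logLik(fits[[best]]$fit)),
      lrt_p = lrt_p[best], singular = bf$singular, accepted = accept,
      stringsAsFactors = FALSE))
    if (!accept) break
    re_terms <- cands[[best]]
    current <- fits[[best]]
    flags <- bf
  }
  # refit the selected structure by REML for reporting, if it is mixed
  final <- if (length(re_terms) > 0) {
    f <- suppressMessages(suppressWarnings(
      lmerTest::lmer(re_formula(response, index, re_terms), data = dat,
                     REML = TRUE)))
    f
  } else current$fit
  flags <- fit_flags(final)
  term <- extract_term(final, index)
  structure(list(fit = final,
                 formula = if (length(re_terms) > 0)
                   paste(deparse(re_formula(response, index, re_terms)),
                         collapse = "")
                 else paste(response, "~", index),
                 term = term, trace = trace,
                 significant_t2 = abs(term$t) > 2,
                 converged = flags$converged, singular = flags$singular,
                 n_obs = nrow(dat)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model:", x$formula, "\n")
  cat(sprintf("  beta = %.4f, SE = %.4f, 95%% CI [%.4f, %.4f], t = %.3f, p = %.4g\n",
              x$term$beta, x$term$se, x$term$ci[1], x$term$ci[2],
              x$term$t, x$term$p))
  if (isTRUE(x$singular)) cat("  (singular fit)\n")
  if (!isTRUE(x$converged)) cat("  (did not converge)\n")
  invisible(x)
}

#' Tabulate a set of model fits
#'
#' @param fits named list of `fit_result` objects (names label the rows).
#' @return data.frame: `model`, `formula`, `beta`, `se`, `ci_lower`,
#'   `ci_upper`, `t`, `p`, `converged`, `singular`. Empty input gives an
#'   empty table.
#' @export
report_tables <- function(fits) {
  if (length(fits) == 0)
    return(data.frame(model = character(0), formula = character(0),
                      beta = numeric(0), se = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      t = numeric(0), p = numeric(0),
                      converged = logical(0), singular = logical(0)))
  out <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(model = names(fits)[i] %||% paste0("fit_", i),
               formula = f$formula, beta = f$term$beta, se = f$term$se,
               ci_lower = f$term$ci[1], ci_upper = f$term$ci[2],
               t = f$term$t, p = f$term$p,
               converged = f$converged, singular = f$singular,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
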