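#' Build the regression frame for a response model
#'
#' Expands button-press records into (action-step x trial) binary
#' observations: for every trial, one row per eSEC column up to (and
#' including) the column of the response; the outcome is 1 in the response
#' column and 0 before. Steps after a response are not observed (the scene
#' blanks once the observer commits), so trials contribute no rows beyond
#' their response column.
#'
#' @param responses `data.frame` with columns `action`, `trial`,
#'   `response_column` (integer or `NA` for no response).
#' @param info An `info_table`.
#' @param action Action to model, or `NULL` to pool all actions.
#' @param model One of [INFO_MODELS].
#' @return `data.frame` with `action`, `trial`, `column`, `absolute`,
#'   `cumulative`, `response`.
#' @export
response_frame <- function(responses, info, action = NULL, model) {
  acts <- if (is.null(action)) unique(responses$action) else action
  parts <- lapply(acts, function(act) {
    steps <- action_steps(info, act, model)
    if (nrow(steps) == 0L)
      stop("domain error: no information rows for action '", act, "'")
    rr <- responses[responses$action == act, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
      rc <- rr$response_column[i]
      last <- if (is.na(rc)) nrow(steps) else rc
      if (!is.na(rc) && (rc < 1L || rc > nrow(steps)))
        stop("validation error: response_column ", rc,
             " outside column range of action '", act, "'")
      data.frame(action = act, trial = rr$trial[i],
                 column = steps$column[seq_len(last)],
                 absolute = steps$info[seq_len(last)],
                 cumulative = steps$cum_info[seq_len(last)],
                 response = as.integer(!is.na(rc) &
                                         steps$column[seq_len(last)] == rc),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Fit a logistic observer-response model
#'
#' Regresses the presence of a response in each action step on the step's
#' absolute information, the information accumulated up to the step, and
#' their interaction, under the chosen observer model. Predictors enter by
#' stepwise forward selection (likelihood-ratio test, entry when
#' `p < alpha`); the fit is by maximum likelihood. Fit quality is reported
#' as BIC and McFadden's pseudo R-squared against the intercept-only null.
#'
#' @param responses `data.frame` of button presses (see [response_frame()]).
#' @param info An `info_table`.
#' @param action Action to model, or `NULL` to pool actions.
#' @param model One of [INFO_MODELS].
#' @param alpha Forward-entry significance level.
#' @return An `esec_model_fit`: list with `model`, `action`, `predictors`
#'   (selected, in entry order), `coefficients`, `logLik`, `null_logLik`,
#'   `BIC`, `AIC`, `mcfadden`, `n`, `separation` flag.
#' @export
fit_response_model <- function(responses, info, action = NULL, model,
                               alpha = 0.05) {
  df <- response_frame(responses, info, action, model)
  if (sum(df$response) == 0L)
    stop("no events: all outcomes are zero for this action/model")
  if (all(df$response == 1L))
    stop("no events: all outcomes are one for this action/model")
  df$interaction <- df$absolute * df$cumulative
  candidates <- c("absolute", "cumulative", "interaction")
  selected <- character(0)
  separation <- FALSE
  fit_with <- function(terms) {
    f <- if (length(terms))
      stats::reformulate(terms, response = "response")
    else response ~ 1
    withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  current <- fit_with(selected)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(tm) fit_with(c(selected, tm)))
    lr <- vapply(trials, function(f)
      2 * (as.numeric(stats::logLik(f)) - as.numeric(stats::logLik(current))),
      numeric(1))
    pval <- stats::pchisq(pmax(lr, 0), df = 1, lower.tail = FALSE)
    best <- which.min(pval)
    if (pval[best] >= alpha) break
    selected <- c(selected, remaining[best])
    current <- trials[[best]]
  }
  ll <- as.numeric(stats::logLik(current))
  ll0 <- as.numeric(stats::logLik(fit_with(character(0))))
  if (separation)
    warning("possible separation: fitted probabilities of 0/1 encountered")
  structure(list(model = model, action = action, predictors = selected,
                 coefficients = stats::coef(current), logLik = ll,
                 null_logLik = ll0,
                 BIC = stats::BIC(current), AIC = stats::AIC(current),
                 mcfadden = 1 - ll / ll0, n = nrow(df),
                 separation = separation),
            class = "esec_model_fit")
}

#' @export
print.esec_model_fit <- function(x, ...) {
  cat(sprintf("Observer model %s%s: BIC %.2f, McFadden R2 %.3f, n = %d\n",
              x$model,
              if (!is.null(x$action)) paste0(" (", x$action, ")") else "",
              x$BIC, x$mcfadden, x$n))
  cat("  predictors:",
      if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(none entered)", "\n")
  invisible(x)
}

#' Rank observer-model fits by BIC
#'
#' @param fits List of `esec_model_fit` objects fitted to the same response
#'   data.
#' @return `data.frame` ordered by ascending BIC with columns `model`,
#'   `BIC`, `mcfadden`, `predictors`, `winner` and a `tie` flag marking
#'   models whose BIC equals the best (to within 1e-8).
#' @export
compare_models <- function(fits) {
  df <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    mcfadden = vapply(fits, `[[`, numeric(1), "mcfadden"),
    predictors = vapply(fits, function(f)
      paste(f$predictors, collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$BIC), ]
  df$winner <- df$BIC <= df$BIC[1L] + 1e-8
  df$tie <- sum(df$winner) > 1L
  rownames(df) <- NULL
  df
}
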