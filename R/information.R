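#' Observer models
#'
#' The eight information models: the three relation sub-tables alone
#' (T = touching, S = static, D = dynamic), their pairwise and triple sums
#' (bits add across sub-tables), and "Overall", which treats each whole
#' 30-symbol column as a single code.
#' @export
INFO_MODELS <- c("T", "S", "D", "T+S", "T+D", "S+D", "T+S+D", "Overall")

ENDED_CODE <- "ENDED"

model_rows <- function(model) {
  switch(model,
         "T" = 1:10, "S" = 11:20, "D" = 21:30,
         "T+S" = 1:20, "T+D" = c(1:10, 21:30), "S+D" = 11:30,
         "T+S+D" = 1:30, "Overall" = 1:30,
         stop("domain error: unknown model '", model, "'"))
}

#' Column code of an action's eSEC under a model
#'
#' Strings the symbols of the model's sub-table rows at one column together
#' into a single code describing the action stage. Columns beyond the
#' action's eSEC length return the `ENDED` pseudo-code: the lack of an eSEC
#' description is itself an observable event.
#'
#' @param esecs Named list of canonical `esec_matrix` objects (one per
#'   action).
#' @param action Action name (must be in `names(esecs)`).
#' @param column 1-based column index.
#' @param model One of [INFO_MODELS].
#' @return A code string.
#' @export
column_code <- function(esecs, action, column, model = "Overall") {
  rows <- model_rows(model)
  m <- esec_mat(esecs[[action]])
  if (is.null(m)) stop("domain error: unknown action '", action, "'")
  if (column > ncol(m)) return(ENDED_CODE)
  paste(m[rows, column], collapse = "|")
}

#' Per-column code likelihoods and self-information
#'
#' For every column index up to the longest action, each action's column
#' code (under the given model) is assigned the likelihood
#' `p = (number of actions sharing that code at that column) / n_actions`,
#' with the `ENDED` pseudo-code of already-finished actions participating as
#' an ordinary code. If all actions share one code the likelihood is 1; a
#' code unique to one action among ten gets 0.1. Self-information is
#' `-log2(p)` bits.
#'
#' @param esecs Named list of canonical `esec_matrix` objects, one per
#'   action class (at least two).
#' @param model One of `"T"`, `"S"`, `"D"`, `"Overall"` (frequency-based
#'   models; the sum models are derived by [combine_and_accumulate()]).
#' @return `data.frame` with columns `action`, `column`, `code`,
#'   `likelihood`, `info` (bits).
#' @export
likelihood_table <- function(esecs, model = "Overall") {
  if (length(esecs) < 2L)
    stop("domain error: need at least 2 actions for likelihoods")
  acts <- names(esecs)
  if (is.null(acts) || any(!nzchar(acts)))
    stop("domain error: esecs must be a named list")
  kmax <- max(vapply(esecs, n_columns, integer(1)))
  out <- do.call(rbind, lapply(seq_len(kmax), function(j) {
    codes <- vapply(acts, function(a) column_code(esecs, a, j, model),
                    character(1))
    counts <- table(codes)
    p <- as.numeric(counts[codes]) / length(acts)
    data.frame(action = acts, column = j, code = unname(codes),
               likelihood = p, info = self_information(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Shannon self-information of a likelihood
#'
#' @param p Likelihood in `(0, 1]`.
#' @return `-log2(p)` bits.
#' @export
self_information <- function(p) {
  if (any(p <= 0) || any(p > 1))
    stop("domain error: likelihood must be in (0, 1]")
  -log2(p)
}

#' Combine sub-table information and accumulate over columns
#'
#' Builds the full information table for all eight observer models from the
#' frequency-based tables of the T, S and D sub-tables (plus the
#' independently computed Overall table). The sum models add the per-column
#' bits of their components (equivalently, multiply likelihoods); cumulative
#' information is the running sum of bits over columns within each action
#' and model.
#'
#' @param tables Named list with elements `T`, `S`, `D` and optionally
#'   `Overall`, each a [likelihood_table()] result on the same action/column
#'   grid.
#' @return An `info_table`: data.frame with columns `action`, `column`,
#'   `model`, `code`, `likelihood`, `info`, `cum_info`.
#' @export
combine_and_accumulate <- function(tables) {
  need <- c("T", "S", "D")
  if (!all(need %in% names(tables)))
    stop("domain error: tables must contain elements T, S and D")
  grid <- function(t) paste(t$action, t$column)
  g <- grid(tables$T)
  for (nm in setdiff(names(tables), "T"))
    if (!identical(g, grid(tables[[nm]])))
      stop("domain error: action/column grid mismatch between sub-tables")
  base <- tables$T[c("action", "column")]
  bits <- cbind("T" = tables$T$info, "S" = tables$S$info,
                "D" = tables$D$info)
  sums <- list("T+S" = bits[, "T"] + bits[, "S"],
               "T+D" = bits[, "T"] + bits[, "D"],
               "S+D" = bits[, "S"] + bits[, "D"],
               "T+S+D" = rowSums(bits))
  one <- function(model, info, code, likelihood) {
    df <- base
    df$model <- model
    df$code <- code
    df$likelihood <- likelihood
    df$info <- info
    df
  }
  parts <- c(
    lapply(c("T", "S", "D"), function(m)
      one(m, tables[[m]]$info, tables[[m]]$code, tables[[m]]$likelihood)),
    lapply(names(sums), function(m)
      one(m, sums[[m]], NA_character_, 2^(-sums[[m]])))
  )
  if (!is.null(tables$Overall))
    parts <- c(parts, list(one("Overall", tables$Overall$info,
                               tables$Overall$code,
                               tables$Overall$likelihood)))
  out <- do.call(rbind, parts)
  out <- out[order(match(out$model, INFO_MODELS), out$action, out$column), ]
  out$cum_info <- stats::ave(out$info, out$action, out$model, FUN = cumsum)
  rownames(out) <- NULL
  class(out) <- c("info_table", "data.frame")
  out
}

#' Full information table of a canonical action set
#'
#' Convenience wrapper: frequency tables for T, S, D and Overall via
#' [likelihood_table()], combined and accumulated into all eight models.
#'
#' @param esecs Named list of canonical `esec_matrix` objects.
#' @return An `info_table` (see [combine_and_accumulate()]).
#' @export
info_table <- function(esecs) {
  combine_and_accumulate(list(
    "T" = likelihood_table(esecs, "T"),
    "S" = likelihood_table(esecs, "S"),
    "D" = likelihood_table(esecs, "D"),
    "Overall" = likelihood_table(esecs, "Overall")))
}

# steps belonging to an action's own eSEC (not the ENDED tail of the grid)
action_steps <- function(info, act, model) {
  rows <- info[info$action == act & info$model == model, ]
  rows <- rows[order(rows$column), ]
  # ENDED steps are grid padding beyond the action's length
  if (!all(is.na(rows$code))) {
    real <- rows$code != ENDED_CODE | is.na(rows$code)
    rows <- rows[real, ]
  } else {
    # sum models carry no code; use the T model of the same action
    tl <- info[info$action == act & info$model == "T", ]
    tl <- tl[order(tl$column), ]
    rows <- rows[tl$code != ENDED_CODE, ]
  }
  rows
}
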