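#' Published PTML linear models
#'
#' Built-in evaluators for the two published fitted equations over the
#' two-block catalyst/reaction partition: the full-dataset model (`"eq5"`)
#' and the model refit with the double-carbonylation subset excluded
#' (`"eq6"`). Coefficients are stored exactly at printed precision and are
#' never re-derived. The predicted yield is
#' \deqn{Yld(\%)_n = a_0 + a_1 \cdot Yld(\%)_{c0} + \sum_k b_k \Delta_k}
#' where \eqn{Yld(\%)_{c0}} is the reference (reuse-cycle cohort mean) yield
#' and the \eqn{\Delta_k} are the eight perturbation terms of
#' [published_recipe()].
#'
#' @param model_id `"eq5"` or `"eq6"`.
#' @return an object of class `ptml_linear_model` with fields `a0`, `a1`, `b`
#'   (named by term id), `recipe`, `scheme_id`, `model_id`.
#' @examples
#' m <- published_model("eq6")
#' zero <- zero_feature_row()
#' predict(m, zero)           # intercept: 1.7555
#' @export
published_model <- function(model_id = c("eq6", "eq5")) {
  model_id <- match.arg(model_id)
  terms <- published_recipe(model_id)$term_id
  coefs <- switch(model_id,
    eq5 = list(a0 = 2.0103, a1 = 0.9749,
               b = c(0.0001, 0.0144, 0.9899, 0.1526,
                     -2.9991, 14.2967, -14.1591, 1.0950)),
    eq6 = list(a0 = 1.7555, a1 = 0.9731,
               b = c(0.00003, 0.0381, 1.0443, -0.2962,
                     -2.7938, 16.8403, -16.5780, 1.0987))
  )
  new_ptml_linear_model(
    a0 = coefs$a0, a1 = coefs$a1, b = setNames(coefs$b, terms),
    recipe = published_recipe(model_id), scheme_id = "PTML3",
    model_id = model_id
  )
}

new_ptml_linear_model <- function(a0, a1, b, recipe = NULL, scheme_id = NA,
                                  model_id = NA, fit = NULL,
                                  diagnostics = NULL) {
  structure(
    list(a0 = a0, a1 = a1, b = b, recipe = recipe, scheme_id = scheme_id,
         model_id = model_id, fit = fit, diagnostics = diagnostics),
    class = c(if (!is.null(fit)) "ptml_mlr", "ptml_linear_model")
  )
}

#' A feature row of zeros
#'
#' Convenience constructor for probing a linear model: all perturbation terms
#' zero (every quantity exactly at its group moving average) and a chosen
#' reference yield.
#'
#' @param model a `ptml_linear_model` (defines the term set).
#' @param yield_ref reference yield (default 0).
#' @return a one-row feature tibble.
#' @export
zero_feature_row <- function(model = published_model("eq6"), yield_ref = 0) {
  row <- tibble(reaction_id = "probe", yield_ref = yield_ref)
  for (t in names(model$b)) row[[t]] <- 0
  row
}

#' @export
print.ptml_linear_model <- function(x, ...) {
  cat("<ptml_linear_model",
      if (!is.na(x$model_id)) paste0(" ", x$model_id), ">\n", sep = "")
  cat("  a0 =", format(x$a0), " a1 =", format(x$a1), "\n")
  for (t in names(x$b)) cat("  ", t, " = ", format(x$b[[t]]), "\n", sep = "")
  invisible(x)
}

#' Predict yields from a PTML linear model
#'
#' @param object a `ptml_linear_model`.
#' @param features a feature table with `yield_ref` and every model term.
#' @param clip clip predictions to `[0, 100]`? Off by default: the linear
#'   model is reported honestly, clipping is a reporting option.
#' @param ... unused.
#' @return a named numeric vector of predicted yields (named by
#'   `reaction_id` when present).
#' @export
predict.ptml_linear_model <- function(object, features, clip = FALSE, ...) {
  need <- c("yield_ref", names(object$b))
  missing_col <- setdiff(need, names(features))
  if (length(missing_col)) {
    abort(paste0("feature table lacks model column(s): ",
                 paste(missing_col, collapse = ", ")),
          class = "ptml_contract_error")
  }
  x <- as.matrix(features[names(object$b)])
  pred <- object$a0 + object$a1 * features$yield_ref +
    drop(x %*% unname(object$b))
  if (clip) pred <- pmin(pmax(pred, 0), 100)
  if ("reaction_id" %in% names(features)) {
    names(pred) <- features$reaction_id
  }
  pred
}

# joins yields onto features by reaction_id (or accepts a bare vector)
.align_yields <- function(features, yields) {
  if (!is.null(names(yields)) && "reaction_id" %in% names(features)) {
    y <- unname(yields[features$reaction_id])
  } else {
    y <- as.numeric(yields)
  }
  if (length(y) != nrow(features) || anyNA(y)) {
    abort("yields do not align with the feature table")
  }
  y
}

.feature_terms <- function(features) {
  setdiff(names(features), c("reaction_id", "yield_ref"))
}

#' Fit a PTML multiple linear regression
#'
#' Ordinary least squares for the perturbation model: intercept, reference
#' slope, and one coefficient per selected term. The reference column is
#' always part of the design (it is never subject to selection).
#'
#' @param features a [assemble_features()] table (or any tibble with
#'   `yield_ref` and term columns).
#' @param yields observed yields: a numeric vector aligned with `features`,
#'   or named by `reaction_id`.
#' @param terms term columns to include (default: all).
#' @return a `ptml_mlr` object (inherits `ptml_linear_model`): printed
#'   coefficients plus `fit` (the underlying `lm`) and `diagnostics`
#'   (`r`, `mae`, `rmse`, `n`, and per-coefficient p-values).
#' @export
fit_mlr <- function(features, yields, terms = .feature_terms(features)) {
  y <- .align_yields(features, yields)
  if (nrow(features) < length(terms) + 2) {
    abort("too few rows for the requested terms")
  }
  dat <- as.data.frame(features[c("yield_ref", terms)])
  dat$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~ yield_ref",
    if (length(terms)) paste("+", paste0("`", terms, "`", collapse = " + ")) else ""
  ))
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    collinear <- names(cf)[is.na(cf)]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(gsub("`", "", collinear), collapse = ", ")),
          class = "ptml_singularity_error")
  }
  pred <- unname(stats::fitted(fit))
  b <- cf[-(1:2)]
  names(b) <- gsub("`", "", names(b))
  sm <- summary(fit)
  diag <- list(
    r = if (sd(y) > 0 && sd(pred) > 0) cor(y, pred) else NA_real_,
    mae = mean(abs(y - pred)),
    rmse = sqrt(mean((y - pred)^2)),
    n = length(y),
    p_values = setNames(sm$coefficients[, 4],
                        gsub("`", "", rownames(sm$coefficients)))
  )
  new_ptml_linear_model(
    a0 = unname(cf[1]), a1 = unname(cf[2]), b = b,
    recipe = attr(features, "recipe"),
    scheme_id = attr(features, "scheme_id") %||% NA,
    fit = fit, diagnostics = diag
  )
}

#' @method tidy ptml_linear_model
#' @export
tidy.ptml_linear_model <- function(x, ...) {
  est <- c(a0 = x$a0, a1 = x$a1, x$b)
  out <- tibble(
    term = c("(Intercept)", "yield_ref", names(x$b)),
    estimate = unname(est)
  )
  if (!is.null(x$diagnostics$p_values)) {
    pv <- x$diagnostics$p_values
    out$p.value <- unname(pv[c("(Intercept)", "yield_ref", names(x$b))])
  }
  out
}

#' @method glance ptml_linear_model
#' @export
glance.ptml_linear_model <- function(x, ...) {
  d <- x$diagnostics
  if (is.null(d)) {
    return(tibble(r = NA_real_, mae = NA_real_, rmse = NA_real_, n = NA_integer_))
  }
  tibble(r = d$r, mae = d$mae, rmse = d$rmse, n = d$n)
}

#' Forward-stepwise term selection
#'
#' Greedy selection by the partial F-test: starting from the reference-only
#' model, at each step the candidate term with the largest F-to-enter
#' (smallest p-value; ties broken by recipe order) joins the model if its
#' p-value is below `enter_p`, stopping at `max_steps` steps or when no
#' candidate qualifies. The reference column is always in the design.
#'
#' @param features feature table.
#' @param yields observed yields.
#' @param max_steps maximum number of terms to enter (default 10).
#' @param enter_p p-to-enter threshold (default 0.05); `Inf` admits
#'   unconditionally.
#' @param candidates candidate term columns (default: all).
#' @return character vector of selected terms, in entry order.
#' @export
forward_stepwise <- function(features, yields, max_steps = 10,
                             enter_p = 0.05,
                             candidates = .feature_terms(features)) {
  if (max_steps < 1) abort("max_steps must be >= 1")
  y <- .align_yields(features, yields)
  dat <- as.data.frame(features[c("yield_ref", candidates)])
  dat$.y <- y
  selected <- character()
  remaining <- candidates
  base_fml <- ".y ~ yield_ref"
  while (length(selected) < max_steps && length(remaining)) {
    cur_fml <- paste(
      base_fml,
      if (length(selected)) paste("+", paste0("`", selected, "`", collapse = " + "))
    )
    fit0 <- lm(stats::as.formula(cur_fml), data = dat)
    pvals <- vapply(remaining, function(trm) {
      fit1 <- lm(stats::as.formula(paste0(cur_fml, " + `", trm, "`")), data = dat)
      a <- anova(fit0, fit1)
      p <- a[["Pr(>F)"]][2]
      if (is.na(p)) 1 else p
    }, double(1))
    best <- which.min(pvals)   # which.min takes the first on ties: recipe order
    if (pvals[best] < enter_p) {
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
    } else {
      break
    }
  }
  selected
}

#' Expert-guided selection
#'
#' Union of an automatic (forward-stepwise) selection with manually forced
#' terms, preserving stepwise order first and forced order second, without
#' duplicates.
#'
#' @param base_selection character vector (e.g. from [forward_stepwise()]).
#' @param forced_terms character vector of terms to force in.
#' @param recipe optional recipe used to validate the forced terms.
#' @return character vector of terms.
#' @export
expert_guided_selection <- function(base_selection, forced_terms,
                                    recipe = NULL) {
  if (!is.null(recipe)) {
    unknown <- setdiff(forced_terms, recipe$term_id)
    if (length(unknown)) {
      abort(paste0("unknown forced term(s): ", paste(unknown, collapse = ", ")))
    }
  }
  unique(c(base_selection, forced_terms))
}

#' Leave-one-out cross-validation
#'
#' Each record in turn is held out, the model is refit on the remainder, and
#' the held-out yield is predicted. Relative errors use
#' `|obs - pred| / max(obs, 1)` (the floor of 1 keeps near-zero yields from
#' exploding the ratio). When `groups` is supplied (e.g. reaction type), the
#' report flags groups whose mean relative error exceeds `flag_threshold`.
#'
#' @param features feature table.
#' @param yields observed yields.
#' @param terms model terms (default: all).
#' @param groups optional per-record group labels for the high-error screen.
#' @param flag_threshold mean relative error above which a group is flagged
#'   (default 0.25).
#' @return a list: `predictions` (tibble: `reaction_id`, `observed`,
#'   `predicted`, `rel_error`, `group`), `flagged_groups`, and summary
#'   metrics `r`, `mae`, `rmse` over the held-out predictions.
#' @export
loo_cv <- function(features, yields, terms = .feature_terms(features),
                   groups = NULL, flag_threshold = 0.25) {
  y <- .align_yields(features, yields)
  n <- nrow(features)
  if (n < 3) abort("leave-one-out needs at least 3 rows")
  preds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      fit_mlr(features[-i, ], y[-i], terms = terms),
      error = function(e) NULL
    )
    if (is.null(fit_i)) {
      warn(paste0("singular fold fit at row ", i, "; row skipped"))
      next
    }
    preds[i] <- predict(fit_i, features[i, ])
  }
  rel <- abs(y - preds) / pmax(y, 1)
  out <- tibble(
    reaction_id = features$reaction_id %||% as.character(seq_len(n)),
    observed = y, predicted = preds, rel_error = rel,
    group = if (is.null(groups)) NA_character_ else as.character(groups)
  )
  flagged <- character()
  if (!is.null(groups)) {
    gm <- tapply(rel, groups, mean, na.rm = TRUE)
    flagged <- names(gm)[!is.na(gm) & gm > flag_threshold]
  }
  ok <- !is.na(preds)
  list(
    predictions = out,
    flagged_groups = flagged,
    r = if (sum(ok) > 2 && sd(y[ok]) > 0) cor(y[ok], preds[ok]) else NA_real_,
    mae = mean(abs(y[ok] - preds[ok])),
    rmse = sqrt(mean((y[ok] - preds[ok])^2))
  )
}

#' Leave-group-out cross-validation
#'
#' Removes every record of one group (typically a reaction type, e.g. the
#' double-carbonylation subset) from both training and validation, refits,
#' and reports metrics on the reduced population. Useful for quantifying how
#' much a systematically mispredicted subset degrades the model.
#'
#' @param features feature table.
#' @param yields observed yields.
#' @param groups per-record group labels.
#' @param held_group the group to exclude.
#' @param terms model terms (default: all).
#' @return a list: `model` (refit `ptml_mlr`), `metrics` (`r`, `mae`, `rmse`,
#'   `n`), `excluded_n`.
#' @export
leave_group_out_cv <- function(features, yields, groups, held_group,
                               terms = .feature_terms(features)) {
  y <- .align_yields(features, yields)
  drop_rows <- which(groups == held_group)
  keep <- setdiff(seq_len(nrow(features)), drop_rows)
  if (!length(keep)) {
    abort("held group absorbs all data; nothing left to fit",
          class = "ptml_empty_fit_error")
  }
  model <- fit_mlr(features[keep, ], y[keep], terms = terms)
  list(
    model = model,
    metrics = glance(model),
    excluded_n = length(drop_rows)
  )
}

#' Serialize / restore a PTML linear model
#'
#' @param model a `ptml_linear_model`.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `ptml_linear_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(a0 = model$a0, a1 = model$a1, b = as.list(model$b),
         scheme_id = model$scheme_id, model_id = model$model_id),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ptml_linear_model(
    a0 = obj$a0, a1 = obj$a1, b = unlist(obj$b),
    scheme_id = obj$scheme_id %||% NA, model_id = obj$model_id %||% NA
  )
}
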