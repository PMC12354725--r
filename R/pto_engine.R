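#' Condition-partition schemes
#'
#' A partition scheme groups the qualitative reaction-condition variables into
#' named blocks (c_I, c_II, ...). Moving averages — and hence the perturbation
#' operators \eqn{\Delta D_k} and \eqn{\Delta V_k} — are taken within the
#' groups a block induces on the dataset. Four standard schemes are shipped:
#'
#' * `PTML1` — `c_I` = catalyst nature, support type, form, metal
#'   (`c_1`..`c_4`); `c_II` = preparation process, support treatment, assembly
#'   generation (`c_5`..`c_7`); `c_III` = reaction characteristics: reaction
#'   type, reuse cycle, detection method (`c_8`, `reuse_cycle`, `c_9`).
#' * `PTML2` — as `PTML1` with the support-treatment label `c_6` replaced by
#'   the nucleophile addition step.
#' * `PTML3` — two blocks: everything catalyst-related (`c_1`..`c_7`) and
#'   everything reaction-related (`c_8`, `reuse_cycle`, `c_9`).
#' * `PTML4` — one all-inclusive block.
#'
#' The exact membership in the source supplementary tables is not public, so
#' these defaults are the package's frozen reading; pass custom `blocks` to
#' override.
#'
#' @param scheme_id `"PTML1"`, `"PTML2"`, `"PTML3"` or `"PTML4"`, or any id
#'   when `blocks` is supplied.
#' @param blocks optional named list of character vectors of record columns.
#' @return an object of class `ptml_scheme`: list with `scheme_id`, `blocks`.
#' @export
partition_scheme <- function(scheme_id, blocks = NULL) {
  if (is.null(blocks)) {
    defaults <- list(
      PTML1 = list(
        c_I   = c("c_1", "c_2", "c_3", "c_4"),
        c_II  = c("c_5", "c_6", "c_7"),
        c_III = c("c_8", "reuse_cycle", "c_9")
      ),
      PTML2 = list(
        c_I   = c("c_1", "c_2", "c_3", "c_4"),
        c_II  = c("c_5", "nucleophile_step_code", "c_7"),
        c_III = c("c_8", "reuse_cycle", "c_9")
      ),
      PTML3 = list(
        c_I  = paste0("c_", 1:7),
        c_II = c("c_8", "reuse_cycle", "c_9")
      ),
      PTML4 = list(
        c_all = c(paste0("c_", 1:9), "reuse_cycle")
      )
    )
    if (!scheme_id %in% names(defaults)) {
      abort(paste0("unknown scheme_id: ", scheme_id,
                   " (supply blocks for a custom scheme)"))
    }
    blocks <- defaults[[scheme_id]]
  }
  if (!length(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("blocks must be a non-empty named list")
  }
  if (any(lengths(blocks) == 0)) abort("blocks must be non-empty")
  allowed <- c(paste0("c_", 1:9), "reuse_cycle", "nucleophile_step_code",
               "reaction_type")
  bad <- setdiff(unlist(blocks), allowed)
  if (length(bad)) {
    abort(paste0("blocks reference undeclared condition variables: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(scheme_id = scheme_id, blocks = blocks),
            class = "ptml_scheme")
}

#' @rdname partition_scheme
#' @export
default_partition_schemes <- function() {
  setNames(lapply(paste0("PTML", 1:4), partition_scheme), paste0("PTML", 1:4))
}

#' @export
print.ptml_scheme <- function(x, ...) {
  cat("<ptml_scheme ", x$scheme_id, ">\n", sep = "")
  for (b in names(x$blocks)) {
    cat("  ", b, ": ", paste(x$blocks[[b]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Group key for a partition block
#'
#' Deterministic label: the record's values on the block's condition
#' variables, trimmed and pasted (case preserved). Identical block values give
#' identical keys.
#'
#' @param records canonical records.
#' @param block character vector of record columns.
#' @return a character vector of group labels, one per record.
#' @export
group_key <- function(records, block) {
  missing_col <- setdiff(block, names(records))
  if (length(missing_col)) {
    abort(paste0("missing condition variable(s): ",
                 paste(missing_col, collapse = ", ")),
          class = "ptml_keying_error")
  }
  vals <- lapply(records[block], function(v) trimws(as.character(v)))
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    bad <- block[vapply(vals, function(v) any(is.na(v)), logical(1))]
    abort(paste0("missing condition value(s) in: ", paste(bad, collapse = ", ")),
          class = "ptml_keying_error")
  }
  do.call(paste, c(vals, sep = "\r"))
}

#' Moving averages within partition groups
#'
#' The moving average of a quantity under a condition partition is the
#' arithmetic mean of its values over all records sharing a group label.
#'
#' @param values numeric vector.
#' @param labels group label per value (same length).
#' @return a tibble with one row per group: `label`, `mean`, `count`.
#' @export
moving_averages <- function(values, labels) {
  if (length(values) != length(labels)) abort("values and labels differ in length")
  if (!length(values)) {
    return(tibble(label = character(), mean = double(), count = integer()))
  }
  tibble(label = as.character(labels), value = as.numeric(values)) |>
    group_by(.data$label) |>
    summarise(mean = mean(.data$value), count = n(), .groups = "drop")
}

#' Perturbation-theory operator
#'
#' The PTO of a value is its deviation from the moving average of its own
#' group: `value - group_mean`. A value sitting exactly at its group mean —
#' including every member of a singleton group — has a PTO of zero.
#'
#' @param value numeric.
#' @param group_mean the moving average of the value's group.
#' @return `value - group_mean`.
#' @export
compute_pto <- function(value, group_mean) {
  value - group_mean
}

#' Reference yield function
#'
#' The reference function anchors the perturbation model: each trial's
#' reference is the mean observed yield of its conditioning cohort, by
#' default the set of trials at the same catalyst reuse cycle.
#'
#' @param records canonical records with `yield_pct`.
#' @param conditioner record column defining the cohorts (default
#'   `"reuse_cycle"`).
#' @param fit_rows optional logical/integer index of the rows over which
#'   cohort means are computed (e.g. training rows); defaults to all rows. A
#'   cohort unseen in `fit_rows` falls back to the global mean with a warning.
#' @return a named numeric vector of references, one per record, named by
#'   `reaction_id`.
#' @export
reference_yield <- function(records, conditioner = "reuse_cycle",
                            fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(records))
  g <- group_key(records, conditioner)
  y <- records$yield_pct
  yf <- y[fit_rows]
  gf <- g[fit_rows]
  ok <- !is.na(yf)
  if (!any(ok)) abort("no yields in the conditioning population",
                      class = "ptml_reference_error")
  means <- tapply(yf[ok], gf[ok], mean)
  ref <- unname(means[g])
  if (anyNA(ref)) {
    warn(paste0(sum(is.na(ref)), " record(s) in a cohort unseen by the fit ",
                "population; using the global mean reference"))
    ref[is.na(ref)] <- mean(yf[ok])
  }
  setNames(as.numeric(ref), records$reaction_id)
}

# ---------------------------------------------------------------------------
# Feature recipes
# ---------------------------------------------------------------------------

#' Feature recipes
#'
#' A recipe is an ordered list of perturbation terms. Each term names an
#' algebraic combination of raw descriptor/variable columns (e.g. `D2 * V2`,
#' `V29 * (V22 + V26)`), the partition block whose groups define its moving
#' average, and a unit label. Combination terms combine the raw values first
#' and then subtract the group moving average of the combined quantity.
#'
#' @param term_id character vector of unique term names.
#' @param expr character vector of R arithmetic expressions over value-table
#'   columns.
#' @param block block id (must exist in the scheme used at assembly time).
#' @param unit unit label (metadata only).
#' @return a tibble of class `ptml_recipe`.
#' @export
feature_recipe <- function(term_id, expr, block, unit = "") {
  out <- tibble(term_id = term_id, expr = expr, block = block, unit = unit)
  if (anyDuplicated(out$term_id)) abort("duplicate term_id in recipe")
  class(out) <- c("ptml_recipe", class(out))
  out
}

#' Published model feature recipes
#'
#' The two published linear models share one nine-input recipe (the reference
#' yield plus eight perturbation terms) over the two-block catalyst/reaction
#' partition (`PTML3`): \eqn{\Delta(D_2 V_2)} (pm·ug), \eqn{\Delta V_{31}}
#' (h), \eqn{\Delta V_{33}}, \eqn{\Delta(V_{11} V_{13})} (mmol),
#' \eqn{\Delta[V_{29}(V_{22}+V_{26})]} (D·mL), \eqn{\Delta(D_6 V_8)}
#' (D·mmol), \eqn{\Delta[D_{15}(V_{10}+V_{35})]} and \eqn{\Delta V_{30}}
#' (deg C). Descriptor-bearing terms take their moving averages over the
#' catalyst block `c_I`; pure reaction variables over `c_II`.
#'
#' @param model_id `"eq5"` (full dataset) or `"eq6"` (double carbonylation
#'   excluded); both use the same term list.
#' @return a [feature_recipe()] of 8 perturbation terms (plus the implicit
#'   reference input, making 9 model inputs).
#' @export
published_recipe <- function(model_id = c("eq6", "eq5")) {
  model_id <- match.arg(model_id)
  feature_recipe(
    term_id = c("d_D2V2", "d_V31", "d_V33", "d_V11V13",
                "d_V29_V22pV26", "d_D6V8", "d_D15_V10pV35", "d_V30"),
    expr = c("D2 * V2", "V31", "V33", "V11 * V13",
             "V29 * (V22 + V26)", "D6 * V8", "D15 * (V10 + V35)", "V30"),
    block = c("c_I", "c_II", "c_II", "c_II", "c_II", "c_I", "c_I", "c_II"),
    unit = c("pm·µg", "h", "", "mmol", "D·mL", "D·mmol", "", "°C")
  )
}

#' Assemble the perturbation feature table
#'
#' Evaluates a feature recipe over a dataset: for each term, the raw combined
#' value is computed per reaction from the value table, its moving average is
#' taken within the groups of the term's block over the fit population, and
#' the term value is the deviation `raw - group_mean`. The reference yield
#' column is prepended. Records whose group was absent from the fit
#' population are centered on the term's global fit-population mean, with a
#' warning.
#'
#' @param records canonical records.
#' @param values per-reaction value table from [build_value_table()] (or
#'   `descriptors`/`variables` to build it here).
#' @param scheme a [partition_scheme()].
#' @param recipe a [feature_recipe()].
#' @param fit_population `"all"` (moving averages over the full dataset, the
#'   default) or `"train"` (over `split_label == "t"` rows only, avoiding
#'   leakage into validation features).
#' @param descriptors,variables optional long tables used when `values` is
#'   `NULL`.
#' @param reference optional precomputed reference vector; by default
#'   [reference_yield()] with the reuse-cycle conditioner over the same fit
#'   population.
#' @return a tibble of class `ptml_features`: `reaction_id`, `yield_ref`, one
#'   numeric column per recipe term; attributes `scheme_id`, `recipe`,
#'   `fit_population`.
#' @export
assemble_features <- function(records, values = NULL, scheme, recipe,
                              fit_population = c("all", "train"),
                              descriptors = NULL, variables = NULL,
                              reference = NULL) {
  fit_population <- match.arg(fit_population)
  if (is.null(values)) {
    values <- build_value_table(records, descriptors, variables)
  }
  if (!identical(values$reaction_id, records$reaction_id)) {
    values <- values[match(records$reaction_id, values$reaction_id), ]
  }
  fit_rows <- if (fit_population == "train") {
    which(records$split_label == "t")
  } else {
    seq_len(nrow(records))
  }
  if (!length(fit_rows)) abort("empty fit population")
  if (is.null(reference)) {
    reference <- reference_yield(records, fit_rows = fit_rows)
  }
  out <- tibble(reaction_id = records$reaction_id,
                yield_ref = unname(reference))
  for (i in seq_len(nrow(recipe))) {
    trm <- recipe[i, ]
    raw <- tryCatch(
      rlang::eval_tidy(rlang::parse_expr(trm$expr), data = values),
      error = function(e) {
        abort(paste0("unresolvable recipe term ", trm$term_id, " (",
                     trm$expr, "): ", conditionMessage(e)),
              class = "ptml_recipe_error")
      }
    )
    if (length(raw) == 1) raw <- rep(raw, nrow(records))
    if (anyNA(raw)) {
      abort(paste0("missing raw values for term ", trm$term_id,
                   "; impute or complete the value table first"),
            class = "ptml_recipe_error")
    }
    block_vars <- scheme$blocks[[trm$block]]
    if (is.null(block_vars)) {
      abort(paste0("recipe term ", trm$term_id, " references block ",
                   trm$block, " absent from scheme ", scheme$scheme_id),
            class = "ptml_recipe_error")
    }
    g <- group_key(records, block_vars)
    ma <- moving_averages(raw[fit_rows], g[fit_rows])
    gm <- ma$mean[match(g, ma$label)]
    if (anyNA(gm)) {
      warn(paste0(sum(is.na(gm)), " record(s) of term ", trm$term_id,
                  " in groups unseen by the fit population; ",
                  "centering on the global mean"))
      gm[is.na(gm)] <- mean(raw[fit_rows])
    }
    out[[trm$term_id]] <- compute_pto(raw, gm)
  }
  structure(out,
            scheme_id = scheme$scheme_id,
            recipe = recipe,
            fit_population = fit_population,
            class = c("ptml_features", class(out)))
}
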